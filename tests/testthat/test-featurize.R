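# Featurization: point-cloud preparation, Gaussian voxelization, Hilbert
# curves and images, surface meshes.

test_that("point-cloud preparation shifts, pads/subsamples and shuffles", {
  fr <- fixture_conformer("PRO", 2)
  pc <- prepare_pointcloud(fr, 24L, seed = 3)
  expect_equal(dim(pc), c(24L, 3L))
  expect_equal(apply(pc, 2, min), c(0, 0, 0))
  shifted <- sweep(fr$coords, 2, apply(fr$coords, 2, min))
  # all 17 shifted originals present plus 7 origin pads
  key <- function(m) sort(apply(round(m, 9), 1, paste, collapse = ","))
  expect_true(all(key(shifted) %in% key(pc)))
  expect_equal(sum(rowSums(abs(pc)) == 0), 24L - 17L)
  # exact-size input: output is a permutation of the shifted originals
  pts <- matrix(rnorm(72), 24, 3)
  pc2 <- prepare_pointcloud(pts, 24L, seed = 5)
  expect_equal(key(sweep(pts, 2, apply(pts, 2, min))), key(pc2))
  # oversized input: output is a sub-multiset
  pts50 <- matrix(rnorm(150), 50, 3)
  pc3 <- prepare_pointcloud(pts50, 24L, seed = 7)
  expect_true(all(key(pc3) %in% key(sweep(pts50, 2, apply(pts50, 2, min)))))
  # deterministic given seed
  expect_identical(unclass(prepare_pointcloud(pts50, 24L, seed = 7)),
                   unclass(pc3))
  expect_error(prepare_pointcloud(matrix(0, 0, 3), 5), "point")
})

test_that("voxel kernel matches direct evaluation and honors the cutoff", {
  # single atom: after centering it sits at the box center (8,8,8); nearest
  # voxel centers are 0.25*sqrt(3) away
  g <- voxelize(matrix(0, 1, 3))
  expect_equal(dim(g), c(32L, 32L, 32L))
  expect_equal(attr(g, "spacing"), 0.5)
  d2 <- function(i, j, k) sum(((c(i, j, k) - 0.5) * 0.5 - 8)^2)
  for (v in list(c(16, 16, 16), c(17, 17, 17), c(20, 16, 16), c(16, 24, 30))) {
    expect_equal(g[v[1], v[2], v[3]],
                 exp(-d2(v[1], v[2], v[3]) / 2), tolerance = 1e-12)
  }
  # exact hit: on an odd grid the box center IS a voxel center, so a single
  # centered atom contributes exactly exp(0) = 1 there and exp(-0.5) one
  # Angstrom away
  p31 <- voxel_params(dim = 31L, box_edge = 15.5)
  g2 <- voxelize(matrix(5, 1, 3), p31)
  expect_identical(g2[16, 16, 16], 1.0)
  expect_equal(g2[18, 16, 16], exp(-0.5), tolerance = 1e-12)
  # beyond the cutoff the contribution is exactly zero
  two <- rbind(c(0, 0, 0), c(30, 0, 0))  # centered: atoms at x = -7, +23
  suppressWarnings(g3 <- voxelize(two))
  centers_x <- (seq_len(32) - 0.5) * 0.5
  d1 <- sqrt((centers_x - (-7))^2 + 2 * 0.25^2)  # to atom 1 along row y=z=8.25
  d2 <- sqrt((centers_x - 23)^2 + 2 * 0.25^2)
  far <- which(d1 > 12 & d2 > 12)
  expect_gt(length(far), 0)
  expect_true(all(g3[far, 17, 17] == 0))
  near <- which(d1 <= 12 | d2 <= 12)
  expect_true(all(g3[near, 17, 17] > 0))
})

test_that("voxelization is translation invariant and mirror/rotation equivariant", {
  fr <- fixture_conformer("LEU", 6)
  g <- voxelize(fr)
  g_t <- voxelize(fr$coords + 17.3)
  expect_equal(unclass(g), unclass(g_t), tolerance = 1e-12)
  # 90-degree lattice rotation about the box center: (x,y,z) -> (y,-x,z)
  rot <- fr$coords[, c(2, 1, 3)]
  rot[, 2] <- -rot[, 2]
  g_r <- voxelize(rot)
  expect_equal(unclass(g_r), unclass(aperm(g, c(2, 1, 3))[, 32:1, ]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # mirror through the center
  g_m <- voxelize(-fr$coords)
  expect_equal(unclass(g_m), unclass(g[32:1, 32:1, 32:1]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("hilbert curve: frozen base orientation, bijection, round trip", {
  expect_equal(hilbert_cell(1, 2, 0:3),
               rbind(c(0L, 0L), c(0L, 1L), c(1L, 1L), c(1L, 0L)))
  cells <- hilbert_cell(2, 3, 0:63)
  expect_equal(nrow(unique(cells)), 64L)
  expect_equal(hilbert_index(2, 3, cells), 0:63)
  expect_error(hilbert_cell(1, 2, 4), "range")
})

test_that("consecutive curve cells are lattice neighbors", {
  for (cfg in list(c(3, 2), c(2, 3), c(4, 3))) {
    cells <- hilbert_cell(cfg[1], cfg[2], 0:(2^(cfg[1] * cfg[2]) - 1))
    expect_true(all(rowSums(abs(diff(cells))) == 1),
                info = paste(cfg, collapse = "/"))
  }
})

test_that("flatten/downsample/image obey the stated arithmetic", {
  expect_equal(downsample_curve(c(0, 2, 4, 6)), c(1, 5))
  expect_error(downsample_curve(c(1, 2, 3)), "even")
  const <- array(2.5, c(32, 32, 32))
  expect_equal(flatten_voxels(const), rep(2.5, 32768))
  img <- make_hilbert_image(const)
  expect_equal(dim(img), c(128L, 128L))
  expect_true(all(img == 2.5))
  # one-hot grid: single nonzero voxel lands at its curve index
  oh <- array(0, c(32, 32, 32))
  cell <- hilbert_cell(5, 3, 12345)
  oh[cell[1] + 1, cell[2] + 1, cell[3] + 1] <- 7
  v <- flatten_voxels(oh)
  expect_equal(which(v != 0), 12346L)
  expect_equal(sum(v), sum(oh))
  # total intensity halves under mean-pair downsampling
  g <- voxelize(fixture_conformer("TRP", 8))
  expect_equal(sum(make_hilbert_image(g)), sum(g) / 2, tolerance = 1e-12)
})

test_that("image construction is linear in the grid", {
  g1 <- voxelize(fixture_conformer("ALA", 3))
  g2 <- voxelize(fixture_conformer("PHE", 3))
  lhs <- make_hilbert_image(array(2 * g1 - 3 * g2, dim(g1)))
  rhs <- 2 * make_hilbert_image(g1) - 3 * make_hilbert_image(g2)
  expect_equal(unclass(lhs), unclass(rhs), tolerance = 1e-12)
})

test_that("hilbert ordering beats row-major on neighbor locality", {
  loc <- hilbert_locality(n_pairs = 400L, seed = 5)
  expect_lt(loc$hilbert, loc$row_major)
})

test_that("surface meshes are watertight and near-analytic for one atom", {
  fr <- fragment("ALA", "C1", "C", matrix(0, 1, 3), complete = FALSE)
  m0 <- compute_surface(fr, smooth_steps = 0)
  m1 <- laplacian_smooth(m0, 1)
  tp <- mesh_topology(m1)
  expect_equal(tp$n_components, 1)
  expect_equal(tp$euler, 2)  # closed genus-0 surface
  r <- 1.7 + 1.4
  expect_lt(abs(mesh_area(m1) - 4 * pi * r^2) / (4 * pi * r^2), 0.15)
  # one smoothing pass shrinks the area
  expect_lt(mesh_area(m1), mesh_area(m0))
})

test_that("far-separated atoms give two mesh components", {
  co <- rbind(c(0, 0, 0), c(40, 0, 0))
  m <- compute_surface(co, spacing = 1.0, radii = c(1.7, 1.7))
  expect_equal(mesh_topology(m)$n_components, 2)
})

test_that("fragment surfaces support the surface point-cloud path", {
  fr <- fixture_conformer("SER", 13)
  mesh <- compute_surface(fr, spacing = 0.5)  # coarser lattice for speed
  expect_gt(nrow(mesh$vertices), 300)
  pc <- prepare_pointcloud(mesh, 1500L, seed = 2)
  expect_equal(dim(pc), c(1500L, 3L))
})
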