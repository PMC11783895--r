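# Conformation-blocked splitting: superposition RMSD, Butina clustering,
# subclustering, and the full baseline recipe.

test_that("superpose_rmsd: identity, rigid invariance, oracle agreement", {
  set.seed(4)
  A <- matrix(rnorm(24), 8, 3)
  expect_lt(superpose_rmsd(A, A), 1e-7)
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_lt(superpose_rmsd(A, A %*% R + 3), 1e-9)
  # mirror images are NOT superposable by proper rotations
  expect_gt(superpose_rmsd(A, -A), 0.1)
  # brute-force oracle: optimization over Euler angles from many starts
  sq <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0), 4, 3, byrow = TRUE)
  sq2 <- sq; sq2[4, 3] <- 1
  brute <- function(A, B) {
    Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
    obj <- function(ang) {
      Rz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                              c(0, 0, 1))
      Ry <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0),
                              c(-sin(a), 0, cos(a)))
      Rm <- Rz(ang[1]) %*% Ry(ang[2]) %*% Rz(ang[3])
      sqrt(mean(rowSums((Bc %*% Rm - Ac)^2)))
    }
    best <- Inf
    for (s in 1:25) {
      st <- runif(3, 0, 2 * pi)
      r <- stats::optim(st, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
      best <- min(best, r$value)
    }
    best
  }
  expect_lt(abs(superpose_rmsd(sq, sq2) - brute(sq, sq2)), 1e-3)
  expect_error(superpose_rmsd(A, A[1:4, ]), "equal")
  expect_error(superpose_rmsd(A[1:2, ], A[1:2, ]), "3 atoms")
})

test_that("pairwise_rmsd caps, symmetrizes and zeroes the diagonal", {
  ens <- fixture_ensemble("VAL", 12, seed = 2)
  D <- pairwise_rmsd(ens)
  expect_equal(dim(D), c(12L, 12L))
  expect_equal(diag(D), rep(0, 12))
  expect_equal(D, t(D))
  Dcap <- pairwise_rmsd(ens, cap = 5L, seed = 3)
  expect_equal(dim(Dcap), c(5L, 5L))
  expect_length(attr(Dcap, "subset"), 5L)
  mixed <- c(ens[1:2], fixture_ensemble("ALA", 2, seed = 2)[1])
  expect_error(pairwise_rmsd(mixed), "one class")
  # identical conformers: all-zero matrix
  same <- ens[c(1, 1, 1)]
  expect_true(all(pairwise_rmsd(same) < 1e-12))
})

test_that("butina clustering follows the leader algorithm", {
  d5 <- as.matrix(dist(c(0, 1, 2, 10, 11)))
  cl <- butina_cluster(d5, 1.5)
  expect_equal(lapply(cl, sort), list(1:3, 4:5))
  # threshold larger than every distance: one cluster
  expect_length(butina_cluster(d5, 100), 1)
  # zero threshold with positive off-diagonals: all singletons
  expect_length(butina_cluster(d5, 0), 5)
  # partition: each index exactly once; sizes non-increasing
  set.seed(8)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    D <- as.matrix(dist(matrix(rnorm(2 * n), n)))
    cl <- butina_cluster(D, runif(1, 0.2, 2))
    expect_equal(sort(unlist(cl)), 1:n)
    expect_true(all(diff(lengths(cl)) <= 0))
  }
  expect_error(butina_cluster(matrix(c(0, 1, 2, 0), 2), 1), "symmetric")
})

test_that("subcluster embeds the distance metric and is deterministic", {
  # two well-separated distance blobs: subclusters never mix blobs
  set.seed(10)
  pts <- rbind(matrix(rnorm(40, 0, 0.3), 20), matrix(rnorm(40, 10, 0.3), 20))
  D <- as.matrix(dist(pts))
  lab <- subcluster(D, k = 10L, seed = 4)
  expect_equal(length(unique(lab)), 10L)
  blob <- rep(1:2, each = 20)
  expect_true(all(vapply(split(blob, lab),
                         function(b) length(unique(b)) == 1, TRUE)))
  expect_identical(subcluster(D, k = 10L, seed = 4), lab)
  expect_error(subcluster(D[1:8, 1:8], k = 10L), "small")
})

test_that("baseline split: partition, bottom-quartile blocking, caps", {
  ens <- fixture_ensemble("MET", 80, seed = 6, mode = "k_modes",
                          n_modes = 4L, spread = 6)
  sp <- build_baseline_split(ens, seed = 3)
  expect_s3_class(sp, "split_assignment")
  expect_equal(nrow(sp), 80L)
  tr <- sp$sample[sp$assignment == "train"]
  te <- sp$sample[sp$assignment == "test"]
  expect_length(intersect(tr, te), 0)
  # bottom 25% of the size-sorted cluster list contributes no train samples
  ncl <- max(sp$cluster, na.rm = TRUE)
  bottom <- seq(ncl - floor(0.25 * ncl) + 1, ncl)
  if (length(bottom) && bottom[1] <= ncl) {
    in_bottom <- sp$cluster %in% bottom
    expect_true(all(sp$assignment[in_bottom] != "train"))
  }
  # per-cluster caps
  for (ci in seq_len(ncl)) {
    cs <- sp[which(sp$cluster == ci), ]
    expect_lte(sum(cs$assignment == "train"), 10L)
    if (!ci %in% bottom) expect_lte(sum(cs$assignment == "test"), 5L)
  }
  expect_equal(attr(sp, "threshold"),
               0.75 * attr(sp, "mean_rmsd"))
})

test_that("degenerate all-identical ensembles fall back to the 2:1 path", {
  ens <- fixture_ensemble("ALA", 1, seed = 1)[rep(1, 100)]
  expect_warning(sp <- build_baseline_split(ens, seed = 2), "degenerate")
  expect_equal(sum(sp$assignment == "train"), 10L)
  expect_equal(sum(sp$assignment == "test"), 5L)
  expect_equal(sum(sp$assignment == "excluded"), 85L)
})

test_that("two tight modes are recovered as two clusters at the 0.75x threshold", {
  ens <- fixture_ensemble("MET", 40, seed = 9, mode = "k_modes",
                          n_modes = 2L, spread = 4)
  D <- pairwise_rmsd(ens)
  thr <- 0.75 * mean(D[upper.tri(D)])
  cl <- butina_cluster(D, thr)
  expect_length(cl, 2L)
  # modes alternate by construction: clusters match the parity classes
  par <- (seq_len(40) - 1) %% 2
  expect_true(all(vapply(cl, function(m) length(unique(par[m])) == 1, TRUE)))
})

test_that("blocking increases the minimum train/test RMSD gap vs random", {
  diffs <- vapply(1:8, function(s) {
    ens <- generate_class_ensemble(conformer_spec(
      "LEU", 100, seed = 3000 + s, mode = "k_modes", n_modes = 2L,
      spread = 12))
    D <- pairwise_rmsd(ens)
    spb <- suppressWarnings(build_baseline_split(ens, seed = s))
    ntr <- sum(spb$assignment == "train"); nte <- sum(spb$assignment == "test")
    if (ntr == 0 || nte == 0) return(NA_real_)
    spr <- build_random_split(100, ntr, nte, seed = s)
    cross_set_rmsd(D, spb) - cross_set_rmsd(D, spr)
  }, 0)
  expect_gte(mean(diffs, na.rm = TRUE), 0)
})

test_that("split manifests serialize the parameters used", {
  skip_if_not_installed("jsonlite")
  ens <- fixture_ensemble("VAL", 12, seed = 2)
  sp <- suppressWarnings(build_baseline_split(ens, seed = 1))
  path <- tempfile(fileext = ".json")
  write_split_manifest(sp, path)
  man <- jsonlite::read_json(path)
  expect_equal(man$parameters$threshold_factor, 0.75)
  expect_equal(man$parameters$bottom_fraction, 0.25)
  expect_equal(man$parameters$k_sub, 10L)
  expect_length(man$assignments, 12L)
})
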