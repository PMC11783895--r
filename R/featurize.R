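# The four fragment representations: prepared point clouds, Gaussian density
# voxel grids, 2D Hilbert-curve images, and molecular surface meshes.

#' Prepare a fixed-size point cloud
#'
#' Shifts points so the per-axis minimum is zero, pads (with copies of the
#' origin) or subsamples (uniformly, without replacement) to `target_count`,
#' then randomly permutes the points so classifiers cannot latch onto point
#' order. Deterministic given `seed`.
#'
#' @param x A `fragment`, `surface_mesh`, or numeric n x 3 matrix of points.
#' @param target_count Output point count (24 for single-residue coordinates,
#'   42 for dipeptides, 1500 for surface vertices).
#' @param seed Integer seed for subsampling/shuffling.
#' @return Numeric `target_count` x 3 matrix of class `point_cloud`.
#' @export
prepare_pointcloud <- function(x, target_count, seed = 1L) {
  pts <- if (inherits(x, "fragment")) x$coords
  else if (inherits(x, "surface_mesh")) x$vertices
  else as.matrix(x)
  if (!is.matrix(pts) || ncol(pts) != 3 || nrow(pts) < 1)
    stop("prepare_pointcloud: need at least one 3D point")
  if (target_count < 1) stop("target_count must be >= 1")
  pts <- sweep(pts, 2, apply(pts, 2, min))
  n <- nrow(pts)
  .with_seed(seed, {
    if (n > target_count) {
      pts <- pts[sample.int(n, target_count), , drop = FALSE]
    } else if (n < target_count) {
      pad <- matrix(0, target_count - n, 3)
      pts <- rbind(pts, pad)
    }
    pts <- pts[sample.int(target_count), , drop = FALSE]
    structure(unname(pts), class = c("point_cloud", "matrix", "array"))
  })
}

#' Default voxelization parameters
#'
#' 32 voxels per axis over a 16 Angstrom cube (0.5 A spacing), Gaussian
#' smoothness sigma = 1 A, cutoff 12 A, uniform atom weight 1.
#'
#' @param dim Voxels per axis.
#' @param box_edge Cube edge length (Angstrom).
#' @param sigma Gaussian smoothness (Angstrom).
#' @param cutoff Contribution cutoff distance (Angstrom).
#' @param weight Per-atom property value.
#' @return List of parameters.
#' @export
voxel_params <- function(dim = 32L, box_edge = 16, sigma = 1, cutoff = 12,
                         weight = 1) {
  list(dim = as.integer(dim), box_edge = box_edge,
       spacing = box_edge / dim, sigma = sigma, cutoff = cutoff,
       weight = weight)
}

#' Gaussian density voxelization of a fragment
#'
#' Translates the fragment so its geometric center (mean over all atoms)
#' coincides with the box center, then accumulates, at every voxel center v,
#' `sum_a w * exp(-d(v, a)^2 / (2 sigma^2))` over atoms `a` within the cutoff.
#' All atoms carry the same weight regardless of type, so no type information
#' leaks into the density. Atoms falling outside the box still contribute to
#' in-box voxels within the cutoff (a warning is logged).
#'
#' @param fragment A `fragment`, or a numeric n x 3 coordinate matrix.
#' @param params See [voxel_params()].
#' @return A `voxel_grid`: 3D array `dim^3` with attributes `origin`,
#'   `spacing`, `box_edge`, `sigma`, `cutoff`.
#' @export
voxelize <- function(fragment, params = voxel_params()) {
  coords <- if (inherits(fragment, "fragment")) fragment$coords
  else as.matrix(fragment)
  if (nrow(coords) < 1) stop("voxelize: empty fragment")
  center <- colMeans(coords)
  half <- params$box_edge / 2
  coords <- sweep(coords, 2, center - half)       # geometric center -> box center
  if (any(coords < 0 | coords > params$box_edge))
    warning("atoms outside the bounding box still contribute within the cutoff")
  origin <- c(0, 0, 0)
  v <- .voxelize_cpp(coords, params$dim, origin, params$spacing,
                     params$sigma, params$cutoff, params$weight)
  structure(array(v, dim = rep(params$dim, 3)),
            origin = origin, spacing = params$spacing,
            box_edge = params$box_edge, sigma = params$sigma,
            cutoff = params$cutoff, class = c("voxel_grid", "array"))
}

.check_grid32 <- function(grid) {
  if (!is.array(grid) || length(dim(grid)) != 3 ||
      !all(dim(grid) == dim(grid)[1]))
    stop("expected a cubic 3D voxel grid")
  d <- dim(grid)[1]
  if (bitwAnd(d, d - 1L) != 0L) stop("grid side must be a power of two")
  d
}

#' Flatten a voxel grid along a 3D Hilbert curve
#'
#' Element `i` of the result is the voxel at `hilbert_cell(order, 3, i - 1)`;
#' for the standard 32-per-axis lattice the order is 5 (2^(3*5) = 32^3).
#'
#' @param grid Cubic 3D array with power-of-two side.
#' @return Numeric vector of length `prod(dim(grid))`.
#' @export
flatten_voxels <- function(grid) {
  d <- .check_grid32(grid)
  order <- as.integer(round(log2(d)))
  cells <- .hilbert_curve(order, 3)
  grid[cells[, 1] + 1L + d * cells[, 2] + d * d * cells[, 3]]
}

#' Downsample a curve-ordered vector by pairwise means
#'
#' Aggregates adjacent non-overlapping pairs along the curve (mean), halving
#' the length; used to bring the 32768-element 3D curve down to the 16384
#' pixels of an order-7 2D curve.
#'
#' @param vec Numeric vector of even length.
#' @param factor Downsampling factor (currently 2).
#' @return Numeric vector of length `length(vec) / 2`.
#' @export
downsample_curve <- function(vec, factor = 2L) {
  if (factor != 2L) stop("only factor 2 is supported")
  n <- length(vec)
  if (n %% 2L != 0L) stop("downsample_curve: vector length must be even")
  (vec[seq(1, n, 2)] + vec[seq(2, n, 2)]) / 2
}

#' Map a voxel grid to a 2D Hilbert-curve image
#'
#' Flattens the grid along the order-5 3D Hilbert curve, mean-downsamples the
#' 32768-vector to 16384 elements, and writes them along the order-7 2D
#' Hilbert curve into a 128 x 128 image. Both mappings preserve spatial
#' locality, so voxels that are close in 3D tend to land on nearby pixels.
#'
#' @param grid A 32^3 voxel grid (see [voxelize()]).
#' @return 128 x 128 numeric matrix of class `hilbert_image`.
#' @export
make_hilbert_image <- function(grid) {
  d <- .check_grid32(grid)
  if (d != 32L) stop("make_hilbert_image expects a 32^3 grid")
  vec <- downsample_curve(flatten_voxels(grid))
  cells <- .hilbert_curve(7, 2)
  img <- matrix(0, 128, 128)
  img[cells[, 1] + 1L + 128L * cells[, 2]] <- vec
  structure(img, class = c("hilbert_image", "matrix", "array"))
}

#' Molecular surface mesh of a fragment
#'
#' Builds the envelope of the atom spheres (per-element van der Waals radii
#' plus a solvent probe) as the zero level set of the signed distance field
#' sampled on a fine lattice, triangulated by marching tetrahedra, followed by
#' Laplacian smoothing.
#'
#' @param fragment A `fragment`, or an n x 3 coordinate matrix (then `radii`
#'   must be given).
#' @param spacing Lattice spacing in Angstrom (default 0.35).
#' @param probe Probe radius added to the atom radii (default 1.4 A).
#' @param smooth_steps Number of Laplacian smoothing passes (default 1).
#' @param radii Optional explicit per-atom radii (Angstrom).
#' @return A `surface_mesh`: list with `vertices` (V x 3) and `faces`
#'   (F x 3, 1-based).
#' @export
compute_surface <- function(fragment, spacing = 0.35, probe = 1.4,
                            smooth_steps = 1L, radii = NULL) {
  if (inherits(fragment, "fragment")) {
    coords <- fragment$coords
    if (is.null(radii))
      radii <- unname(.VDW[fragment$elements]) + probe
  } else {
    coords <- as.matrix(fragment)
    if (is.null(radii)) stop("radii required for bare coordinate input")
    radii <- radii + probe
  }
  if (nrow(coords) < 1) stop("compute_surface: empty fragment")
  if (anyNA(radii)) stop("unknown element radius")
  mesh <- .surface_mesh_cpp(coords, radii, spacing, pad = 2 * spacing)
  mesh$vertices <- unname(mesh$vertices)
  mesh$faces <- unname(mesh$faces)
  class(mesh) <- "surface_mesh"
  if (smooth_steps > 0) mesh <- laplacian_smooth(mesh, steps = smooth_steps)
  mesh
}

#' Laplacian mesh smoothing
#'
#' Each pass replaces every vertex by the mean of its edge-connected
#' neighbors, which smooths lattice artifacts and mildly shrinks the mesh.
#'
#' @param mesh A `surface_mesh`.
#' @param steps Number of passes.
#' @return Smoothed `surface_mesh`.
#' @export
laplacian_smooth <- function(mesh, steps = 1L) {
  V <- mesh$vertices
  Fc <- mesh$faces
  n <- nrow(V)
  edges <- rbind(Fc[, 1:2], Fc[, 2:3], Fc[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  for (s in seq_len(steps)) {
    sums <- rowsum(V[edges[, 2], , drop = FALSE], edges[, 1],
                   reorder = FALSE)
    cnt <- as.numeric(table(factor(edges[, 1], levels = seq_len(n))))
    ord <- as.integer(rownames(sums))
    Vnew <- V
    Vnew[ord, ] <- sums / cnt[ord]
    V <- Vnew
  }
  mesh$vertices <- V
  mesh
}

#' Total surface area of a triangle mesh
#' @param mesh A `surface_mesh`.
#' @return Area in Angstrom^2.
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices
  Fc <- mesh$faces
  a <- V[Fc[, 2], ] - V[Fc[, 1], ]
  b <- V[Fc[, 3], ] - V[Fc[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Connected components and Euler characteristic of a mesh
#' @param mesh A `surface_mesh`.
#' @return List with `n_components`, `euler` (V - E + F, unique edges).
#' @export
mesh_topology <- function(mesh) {
  V <- nrow(mesh$vertices)
  Fc <- mesh$faces
  edges <- rbind(Fc[, 1:2], Fc[, 2:3], Fc[, c(3, 1)])
  ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  E <- length(unique(ek))
  # components via union-find on edges
  parent <- seq_len(V)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(V), find, 0L)
  list(n_components = length(unique(roots)), euler = V - E + nrow(Fc))
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Stack fragment features into a training matrix
#'
#' Featurizes a list of fragments and returns the flattened features as one
#' matrix with one sample per column, the layout the classifiers consume.
#'
#' @param frags List of completed `fragment` objects.
#' @param rep `"voxel"`, `"hilbert"`, or `"coord_pc"`.
#' @param target_points Point count for `"coord_pc"`.
#' @param seed Seed for point-cloud preparation.
#' @param params Voxelization parameters.
#' @return Numeric matrix features x n.
#' @export
stack_features <- function(frags, rep = c("voxel", "hilbert", "coord_pc"),
                           target_points = 24L, seed = 1L,
                           params = voxel_params()) {
  rep <- match.arg(rep)
  cols <- lapply(seq_along(frags), function(i) {
    fr <- frags[[i]]
    switch(rep,
      voxel = as.numeric(voxelize(fr, params)),
      hilbert = as.numeric(make_hilbert_image(voxelize(fr, params))),
      coord_pc = as.numeric(t(prepare_pointcloud(fr, target_points,
                                                 seed = seed + i))))
  })
  do.call(cbind, cols)
}
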