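# Hilbert space-filling curves in arbitrary dimension, used to flatten 3D
# voxel lattices into locality-preserving 1D vectors and re-fold them into 2D
# images. Gray-code (transpose) construction; the base orientation is the one
# produced by this algorithm and is fixed for the package (any fixed variant
# preserves the bijection and unit-step adjacency that the featurization
# relies on).

.hilbert_cache <- new.env(parent = emptyenv())

# index (0-based, vector) -> transpose form: matrix n x dim of integers with
# `order` bits each; bit j of the index (MSB first) belongs to axis j %% dim.
.index_to_transpose <- function(index, order, dim) {
  n <- length(index)
  X <- matrix(0L, n, dim)
  nbits <- order * dim
  for (j in seq_len(nbits) - 1L) {           # j = 0 is the MSB
    bitpos <- nbits - 1L - j                 # position in the index
    axis <- (j %% dim) + 1L
    outbit <- order - 1L - (j %/% dim)       # position within the axis word
    b <- bitwAnd(index %/% (2L^bitpos), 1L)
    X[, axis] <- X[, axis] + b * 2L^outbit
  }
  X
}

.transpose_to_index <- function(X, order, dim) {
  n <- nrow(X)
  nbits <- order * dim
  idx <- numeric(n)
  for (j in seq_len(nbits) - 1L) {
    bitpos <- nbits - 1L - j
    axis <- (j %% dim) + 1L
    outbit <- order - 1L - (j %/% dim)
    b <- bitwAnd(X[, axis] %/% 2L^outbit, 1L)
    idx <- idx + b * 2^bitpos
  }
  idx
}

# Skilling-style transpose -> axes (vectorized over rows of X).
.transpose_to_axes <- function(X, order, dim) {
  N <- 2L^(order - 1L)
  # Gray decode
  t0 <- X[, dim] %/% 2L
  if (dim > 1) for (i in dim:2) X[, i] <- bitwXor(X[, i], X[, i - 1L])
  X[, 1L] <- bitwXor(X[, 1L], t0)
  Q <- 2L
  while (Q != 2L * N) {
    P <- Q - 1L
    for (i in dim:1) {
      hasQ <- bitwAnd(X[, i], Q) > 0L
      # branch 1: X[,1] ^= P where bit set
      X[hasQ, 1L] <- bitwXor(X[hasQ, 1L], P)
      # branch 2: swap low bits between X[,1] and X[,i]
      tt <- bitwAnd(bitwXor(X[!hasQ, 1L], X[!hasQ, i]), P)
      X[!hasQ, 1L] <- bitwXor(X[!hasQ, 1L], tt)
      X[!hasQ, i] <- bitwXor(X[!hasQ, i], tt)
    }
    Q <- Q * 2L
  }
  X
}

.axes_to_transpose <- function(X, order, dim) {
  M <- 2L^(order - 1L)
  Q <- M
  while (Q > 1L) {
    P <- Q - 1L
    for (i in 1:dim) {
      hasQ <- bitwAnd(X[, i], Q) > 0L
      X[hasQ, 1L] <- bitwXor(X[hasQ, 1L], P)
      tt <- bitwAnd(bitwXor(X[!hasQ, 1L], X[!hasQ, i]), P)
      X[!hasQ, 1L] <- bitwXor(X[!hasQ, 1L], tt)
      X[!hasQ, i] <- bitwXor(X[!hasQ, i], tt)
    }
    Q <- Q %/% 2L
  }
  if (dim > 1) for (i in 2:dim) X[, i] <- bitwXor(X[, i], X[, i - 1L])
  t0 <- rep(0L, nrow(X))
  Q <- M
  while (Q > 1L) {
    hasQ <- bitwAnd(X[, dim], Q) > 0L
    t0[hasQ] <- bitwXor(t0[hasQ], Q - 1L)
    Q <- Q %/% 2L
  }
  for (i in 1:dim) X[, i] <- bitwXor(X[, i], t0)
  X
}

#' Hilbert curve cell lookup
#'
#' Maps positions along the `dim`-dimensional Hilbert curve of the given order
#' to lattice coordinates. The curve visits all `2^(dim*order)` cells of the
#' `2^order`-per-axis lattice exactly once, with consecutive indices mapping
#' to cells one lattice step apart.
#'
#' @param order Curve order (>= 1).
#' @param dim Dimension (>= 1).
#' @param index 0-based position(s) along the curve, in `[0, 2^(dim*order))`.
#' @return Integer matrix `length(index)` x `dim` of 0-based lattice
#'   coordinates.
#' @seealso [hilbert_index()] for the inverse map.
#' @export
hilbert_cell <- function(order, dim, index) {
  nmax <- 2^(dim * order)
  if (any(index < 0 | index >= nmax))
    stop(sprintf("index out of range [0, %d)", nmax))
  X <- .index_to_transpose(as.numeric(index), order, dim)
  .transpose_to_axes(X, order, dim)
}

#' Inverse Hilbert lookup: lattice coordinates to curve index
#' @param order,dim As in [hilbert_cell()].
#' @param cells Integer matrix n x dim of 0-based lattice coordinates.
#' @return Numeric vector of 0-based curve indices.
#' @export
hilbert_index <- function(order, dim, cells) {
  cells <- matrix(as.integer(cells), ncol = dim)
  if (any(cells < 0 | cells >= 2^order)) stop("cell coordinate out of range")
  X <- .axes_to_transpose(cells, order, dim)
  .transpose_to_index(X, order, dim)
}

# Full curve table (cells in index order), cached per (order, dim).
.hilbert_curve <- function(order, dim) {
  key <- paste0("o", order, "d", dim)
  if (is.null(.hilbert_cache[[key]])) {
    .hilbert_cache[[key]] <-
      hilbert_cell(order, dim, seq_len(2^(dim * order)) - 1)
  }
  .hilbert_cache[[key]]
}

#' Compare pixel locality of Hilbert vs row-major flattening
#'
#' Draws random pairs of 3D-adjacent voxels of the 32^3 lattice, maps each
#' voxel through the image construction (3D curve position, pairwise
#' downsampling, 2D curve position) and through a plain row-major
#' counterpart, and reports the mean Manhattan pixel distance between the
#' members of each pair under both orderings. Hilbert ordering keeps 3D
#' neighbors closer in the image.
#'
#' @param n_pairs Number of random adjacent voxel pairs.
#' @param seed RNG seed.
#' @return List with `hilbert`, `row_major` (mean pixel distances) and
#'   `ratio` (hilbert / row_major).
#' @export
hilbert_locality <- function(n_pairs = 1000L, seed = 1L) {
  d <- 32L
  img_side <- 128L
  cells2 <- .hilbert_curve(7, 2)
  to_pixel_hilbert <- function(cells3) {
    idx3 <- hilbert_index(5, 3, cells3)
    cells2[idx3 %/% 2 + 1L, , drop = FALSE]
  }
  to_pixel_rowmajor <- function(cells3) {
    lin <- cells3[, 1] + d * cells3[, 2] + d * d * cells3[, 3]
    lin2 <- lin %/% 2
    cbind(lin2 %% img_side, lin2 %/% img_side)
  }
  .with_seed(seed, {
    a <- cbind(sample.int(d, n_pairs, TRUE) - 1L,
               sample.int(d, n_pairs, TRUE) - 1L,
               sample.int(d, n_pairs, TRUE) - 1L)
    ax <- sample.int(3, n_pairs, TRUE)
    dir <- sample(c(-1L, 1L), n_pairs, TRUE)
    b <- a
    b[cbind(seq_len(n_pairs), ax)] <- pmin(pmax(
      b[cbind(seq_len(n_pairs), ax)] + dir, 0L), d - 1L)
    same <- rowSums(abs(a - b)) == 0
    if (any(same)) {  # clipped at the boundary: flip direction
      b[same, ] <- a[same, ]
      b[cbind(which(same), ax[same])] <- a[cbind(which(same), ax[same])] -
        dir[same]
    }
    ph_a <- to_pixel_hilbert(a); ph_b <- to_pixel_hilbert(b)
    pr_a <- to_pixel_rowmajor(a); pr_b <- to_pixel_rowmajor(b)
    h <- mean(rowSums(abs(ph_a - ph_b)))
    r <- mean(rowSums(abs(pr_a - pr_b)))
    list(hilbert = h, row_major = r, ratio = h / r)
  })
}
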