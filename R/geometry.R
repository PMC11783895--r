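# Internal-coordinate geometry: atom placement (natural extension reference
# frame), bond/angle/torsion measurement, and rigid-body superposition.

`%||%` <- function(a, b) if (is.null(a)) b else a

.deg2rad <- pi / 180

#' Place an atom from internal coordinates
#'
#' Given the Cartesian positions of three reference atoms, returns the position
#' of a fourth atom at bond length `r` from `p1`, bond angle `theta` (degrees,
#' x-p1-p2) and torsion `phi` (degrees, x-p1-p2-p3).
#'
#' @param p1,p2,p3 Numeric length-3 vectors: bonded parent, angle reference and
#'   torsion reference positions.
#' @param r Bond length in Angstrom.
#' @param theta Bond angle in degrees.
#' @param phi Torsion angle in degrees.
#' @return Numeric length-3 vector.
#' @keywords internal
place_atom <- function(p1, p2, p3, r, theta, phi) {
  th <- theta * .deg2rad
  ph <- phi * .deg2rad
  bc <- p1 - p2
  bc <- bc / sqrt(sum(bc^2))
  ab <- p2 - p3
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) {
    # colinear references: pick an arbitrary perpendicular
    n <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- n - sum(n * bc) * bc
    nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-r * cos(th), r * sin(th) * cos(ph), -r * sin(th) * sin(ph))
  p1 + d[1] * bc + d[2] * m + d[3] * n
}

#' Measure a torsion angle
#'
#' @param a,b,c,d Numeric length-3 vectors.
#' @return Torsion a-b-c-d in degrees in (-180, 180].
#' @export
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) / .deg2rad
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Measure a bond angle
#' @param a,b,c Numeric length-3 vectors; angle at `b`.
#' @return Angle in degrees.
#' @export
bond_angle <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  cs <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cs))) / .deg2rad
}

#' Optimal rigid-body superposition RMSD (Kabsch)
#'
#' Minimal root-mean-square deviation between two equal-length coordinate sets
#' over all rotations and translations, computed by the Kabsch SVD method with
#' proper-rotation (determinant) correction.
#'
#' @param A,B Numeric n x 3 matrices with corresponding rows.
#' @return Nonnegative RMSD in Angstrom.
#' @export
superpose_rmsd <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3)
    stop("superpose_rmsd: coordinate sets must be equal-size n x 3 matrices")
  n <- nrow(A)
  if (n < 3) stop("superpose_rmsd: need at least 3 atoms")
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  H <- crossprod(Bc, Ac)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  e2 <- sum(Ac^2) + sum(Bc^2) - 2 * (sv$d[1] + sv$d[2] + d * sv$d[3])
  sqrt(max(0, e2) / n)
}
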