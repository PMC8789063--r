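## Small rotation / superposition toolkit. Conventions: rotation matrices are
## 3x3 with columns = frame axes expressed in world coordinates; angles are
## right-handed about the given axis.

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula. The axis need not be normalized.
#'
#' @param axis length-3 numeric, rotation axis.
#' @param theta angle in radians, right-handed about `axis`.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_about <- function(axis, theta) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-300) stop("rotation axis has zero length")
  u <- axis / n
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Angle of a rotation matrix (radians, in [0, pi])
#' @keywords internal
rot_angle <- function(R) {
  tr <- sum(diag(R))
  acos(max(-1, min(1, (tr - 1) / 2)))
}

## Geodesic fraction of a rotation: R^t for t in [0,1] via axis-angle.
rot_pow <- function(R, t) {
  theta <- rot_angle(R)
  if (theta < 1e-12) return(diag(3))
  ## axis from the skew part; handle theta ~ pi separately
  if (theta < pi - 1e-6) {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  } else {
    ## near pi: axis from the symmetric part
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    ## fix signs using off-diagonals
    i <- which.max(ax)
    if (ax[i] > 0) {
      ax <- B[, i] / ax[i]
    }
  }
  rot_about(ax, t * theta)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation and translation mapping `from` onto `onto`:
#' onto ~ from %*% t(R) + translation (rows are points). The proper-rotation
#' branch (det = +1) is always selected.
#'
#' @param from,onto n x 3 coordinate matrices, matched rows.
#' @param weights optional per-point non-negative weights.
#' @return list with `R` (3x3), `t` (length 3), `rmsd` of the fit.
#' @keywords internal
kabsch <- function(from, onto, weights = NULL) {
  from <- as.matrix(from); onto <- as.matrix(onto)
  stopifnot(ncol(from) == 3L, ncol(onto) == 3L, nrow(from) == nrow(onto))
  n <- nrow(from)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cf <- colSums(from * w); co <- colSums(onto * w)
  A <- sweep(from, 2, cf); B <- sweep(onto, 2, co)
  H <- t(A * w) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fit <- A %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fit - B)^2)))
  list(R = R, t = as.numeric(co - R %*% cf), rmsd = rmsd)
}

#' Apply a rigid motion to an n x 3 coordinate matrix
#' @keywords internal
apply_rigid <- function(xyz, R, t = c(0, 0, 0)) {
  sweep(as.matrix(xyz) %*% t(R), 2, -as.numeric(t))
}

## orthonormality check used by frame constructors
is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(t(R) %*% R - diag(3))) < tol && abs(det(R) - 1) < tol
}
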