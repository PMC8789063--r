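## Essential dynamics: iterative superposition, coordinate covariance PCA,
## projections, back-projection, and 2-D projection free-energy surfaces.

#' Iterative superposition of a coordinate ensemble
#'
#' All frames are superposed onto the first frame, the mean structure is
#' computed and set as the new reference, and the process repeats until the
#' RMSD between successive mean structures falls below `tol` (default 1e-4
#' Angstrom). Removes the six rigid-body degrees of freedom.
#'
#' @param coords n_frames x n_atoms x 3 array (or n_frames x 3N matrix).
#' @param tol convergence tolerance on the mean-shift RMSD (Angstrom).
#' @param max_iter maximum iterations (default 100).
#' @return object of class `aligned_ensemble`: `coords` (n x 3N matrix of
#'   aligned frames), `mean` (3N), `n_atoms`, `history` of mean-shift RMSDs.
#' @export
iterative_superposition <- function(coords, tol = 1e-4, max_iter = 100L) {
  X <- .as_frame_matrix(coords)
  n <- nrow(X); N <- ncol(X) / 3L
  if (n < 2L) stop("need at least 2 frames")
  ref <- X[1, ]
  history <- numeric(0)
  for (iter in seq_len(max_iter)) {
    refm <- matrix(ref, N, 3L, byrow = FALSE)
    dim(refm) <- c(N, 3L)
    refm <- .vec_to_xyz(ref)
    A <- t(vapply(seq_len(n), function(f) {
      xyz <- .vec_to_xyz(X[f, ])
      k <- kabsch(xyz, refm)
      as.numeric(t(apply_rigid(xyz, k$R, k$t)))
    }, numeric(3L * N)))
    new_mean <- colMeans(A)
    shift <- sqrt(sum((new_mean - ref)^2) / N)
    history <- c(history, shift)
    ref <- new_mean
    if (shift < tol) {
      ## final pass: align everything onto the converged mean
      refm <- .vec_to_xyz(ref)
      A <- t(vapply(seq_len(n), function(f) {
        xyz <- .vec_to_xyz(X[f, ])
        k <- kabsch(xyz, refm)
        as.numeric(t(apply_rigid(xyz, k$R, k$t)))
      }, numeric(3L * N)))
      return(structure(list(coords = A, mean = colMeans(A), n_atoms = N,
                            history = history),
                       class = "aligned_ensemble"))
    }
  }
  stop("iterative superposition did not converge in ", max_iter,
       " iterations; history: ",
       paste(sprintf("%.2e", utils::tail(history, 5)), collapse = ", "))
}

#' Orthonormal basis of the rigid-body subspace at a structure
#'
#' Three uniform translations and three infinitesimal rotations about the
#' center of geometry, orthonormalized; the six directions that superposition
#' removes from an ensemble.
#'
#' @param xyz n_atoms x 3 reference coordinates.
#' @return 3N x 6 matrix with orthonormal columns (atom-major ordering).
#' @export
rigid_body_basis <- function(xyz) {
  xyz <- as.matrix(xyz)
  N <- nrow(xyz)
  cen <- sweep(xyz, 2, colMeans(xyz))
  B <- matrix(0, 3L * N, 6L)
  for (a in 1:3) B[seq(a, 3L * N, by = 3L), a] <- 1  # translations
  for (a in 1:3) {                                   # rotations
    e <- c(0, 0, 0); e[a] <- 1
    disp <- t(apply(cen, 1, function(r) .cross(e, r)))  # N x 3
    B[, 3L + a] <- as.numeric(t(disp))
  }
  qr.Q(qr(B))
}

## frames as rows of length 3N, atom-major (x1,y1,z1,x2,...)
.as_frame_matrix <- function(coords) {
  if (is.matrix(coords)) return(coords)
  d <- dim(coords)
  stopifnot(length(d) == 3L, d[3] == 3L)
  out <- matrix(0, d[1], d[2] * 3L)
  for (f in seq_len(d[1])) {
    out[f, ] <- as.numeric(t(coords[f, , ]))
  }
  out
}

.vec_to_xyz <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

#' @export
print.aligned_ensemble <- function(x, ...) {
  cat("<aligned_ensemble>", nrow(x$coords), "frames,", x$n_atoms,
      "atoms; converged after", length(x$history),
      "iterations (final shift",
      format(utils::tail(x$history, 1), digits = 3), "A)\n")
  invisible(x)
}

#' Essential modes of an aligned ensemble
#'
#' Eigendecomposition of the (unweighted) coordinate covariance
#' C = <(x - <x>)(x - <x>)^T>. The six smallest-magnitude eigenvalues -- the
#' rigid-body remnants left numerically near zero by the superposition -- are
#' discarded; the remaining modes are sorted by decreasing eigenvalue.
#' Eigenvector signs are fixed by making each vector's largest-magnitude
#' component positive.
#'
#' @param aligned an `aligned_ensemble`.
#' @param n_discard number of rigid-body modes to discard (default 6).
#' @return object of class `mode_set`: `values` (eigenvalues, A^2,
#'   descending), `vectors` (3N x k, orthonormal columns), `mean`,
#'   `discarded` (the removed eigenvalues), `rank_warning`.
#' @export
essential_modes <- function(aligned, n_discard = 6L) {
  stopifnot(inherits(aligned, "aligned_ensemble"))
  X <- aligned$coords
  n <- nrow(X)
  rank_warning <- n <= ncol(X)
  C <- stats::cov(X)
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  ord <- order(abs(e$values))
  discard_idx <- ord[seq_len(min(n_discard, length(ord)))]
  keep <- setdiff(seq_along(e$values), discard_idx)
  keep <- keep[order(e$values[keep], decreasing = TRUE)]
  vals <- e$values[keep]
  vecs <- e$vectors[, keep, drop = FALSE]
  if (length(vals) && length(discard_idx)) {
    if (max(abs(e$values[discard_idx])) > 1e-6 * max(abs(vals))) {
      warning("discarded 'zero' modes are not negligible (",
              format(max(abs(e$values[discard_idx])), digits = 3),
              " vs largest ", format(max(abs(vals)), digits = 3), ")")
    }
  }
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(values = vals, vectors = vecs, mean = aligned$mean,
                 discarded = e$values[discard_idx],
                 n_frames = n, rank_warning = rank_warning),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat("<mode_set>", length(x$values), "modes from", x$n_frames, "frames\n")
  k <- min(5L, length(x$values))
  cat("  top eigenvalues (A^2):",
      paste(sprintf("%.3g", x$values[seq_len(k)]), collapse = ", "), "\n")
  tot <- sum(x$values)
  if (tot > 0) {
    cat("  variance fraction of top 2:",
        sprintf("%.1f%%", 100 * sum(x$values[seq_len(min(2L, k))]) / tot), "\n")
  }
  invisible(x)
}

#' Project frames onto an essential mode
#'
#' p_i(t) = nu_i . (x(t) - <x>). On the generating ensemble the variance of
#' p_i equals the mode eigenvalue.
#'
#' @param frames n x 3N matrix (aligned), or an `aligned_ensemble`.
#' @param modes a `mode_set`.
#' @param which mode indices (default 1).
#' @param check verify frames appear aligned (center-of-geometry offset from
#'   the mean below `tol`); set FALSE to skip.
#' @param tol alignment-check tolerance (Angstrom, default 0.5).
#' @return matrix of projections, n x length(which) (column per mode).
#' @export
project_modes <- function(frames, modes, which = 1L, check = TRUE,
                          tol = 0.5) {
  X <- if (inherits(frames, "aligned_ensemble")) frames$coords else
    .as_frame_matrix(frames)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  stopifnot(inherits(modes, "mode_set"))
  if (ncol(X) != length(modes$mean)) {
    stop("frame length ", ncol(X), " does not match mode dimension ",
         length(modes$mean))
  }
  if (check) {
    cog_off <- colMeans(.vec_to_xyz(colMeans(X))) -
      colMeans(.vec_to_xyz(modes$mean))
    if (sqrt(sum(cog_off^2)) > tol) {
      stop("frames do not appear aligned to the mode reference ",
           "(center-of-geometry offset ",
           sprintf("%.3f", sqrt(sum(cog_off^2))), " A)")
    }
  }
  D <- sweep(X, 2, modes$mean)
  P <- D %*% modes$vectors[, which, drop = FALSE]
  colnames(P) <- paste0("p", which)
  P
}

#' Back-project a mode amplitude to Cartesian coordinates
#'
#' x*(t) = p nu_i + <x>; the exact right-inverse of [project_modes()] on the
#' mode subspace.
#'
#' @param p scalar (or vector of) projection amplitude(s), Angstrom.
#' @param modes a `mode_set`.
#' @param which single mode index.
#' @return matrix length(p) x 3N of coordinates.
#' @export
backproject_mode <- function(p, modes, which = 1L) {
  stopifnot(inherits(modes, "mode_set"), length(which) == 1L)
  outer(as.numeric(p), modes$vectors[, which]) +
    matrix(modes$mean, length(p), length(modes$mean), byrow = TRUE)
}

#' 2-D projection free-energy surface
#'
#' Histograms two projection series on square bins (default edge 0.2 Angstrom,
#' bin area 0.04 A^2) and converts populations to free energies
#' -kB T ln(n_ij / n_max), zero at the most populated bin. Empty bins are NA,
#' not zero.
#'
#' @param p1,p2 equal-length projection series (Angstrom).
#' @param bin_edge bin edge length (Angstrom, default 0.2).
#' @param temperature temperature in K (default 298).
#' @return object of class `projection_surface`: `x`, `y` bin centers, `F`
#'   free-energy matrix (kcal/mol, NA = unvisited), `counts`.
#' @export
projection_surface <- function(p1, p2, bin_edge = 0.2, temperature = 298) {
  stopifnot(length(p1) == length(p2))
  bx <- .surface_breaks(p1, bin_edge)
  by <- .surface_breaks(p2, bin_edge)
  ix <- findInterval(p1, bx, rightmost.closed = TRUE)
  iy <- findInterval(p2, by, rightmost.closed = TRUE)
  counts <- matrix(0L, length(bx) - 1L, length(by) - 1L)
  for (k in seq_along(ix)) {
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  }
  if (sum(counts > 0) == 1L) {
    warning("all samples fall in a single bin; degenerate surface")
  }
  kT <- .kB_kcal * temperature
  Fm <- matrix(NA_real_, nrow(counts), ncol(counts))
  nz <- counts > 0
  Fm[nz] <- -kT * log(counts[nz] / max(counts))
  structure(list(x = (bx[-1] + bx[-length(bx)]) / 2,
                 y = (by[-1] + by[-length(by)]) / 2,
                 F = Fm, counts = counts, bin_edge = bin_edge,
                 temperature = temperature),
            class = "projection_surface")
}

.surface_breaks <- function(p, edge) {
  lo <- floor(min(p) / edge) * edge
  hi <- ceiling(max(p) / edge) * edge
  if (hi <= lo) hi <- lo + edge
  seq(lo, hi + edge / 2, by = edge)
}

#' @export
print.projection_surface <- function(x, ...) {
  cat("<projection_surface>", nrow(x$F), "x", ncol(x$F), "bins of",
      x$bin_edge, "A (area", x$bin_edge^2, "A^2);",
      sum(x$counts), "samples\n")
  invisible(x)
}

#' @export
plot.projection_surface <- function(x, xlab = "p1 (A)", ylab = "p2 (A)", ...) {
  graphics::image(x$x, x$y, x$F, xlab = xlab, ylab = ylab,
                  col = grDevices::hcl.colors(32, "viridis", rev = TRUE), ...)
  graphics::contour(x$x, x$y, x$F, add = TRUE, col = "grey30")
  invisible(x)
}

#' Serialize / read a mode set
#'
#' JSON header (counts, eigenvalues, mean) plus columnar eigenvector text.
#'
#' @param modes a `mode_set`.
#' @param path output path (two files: `<path>.json` and `<path>.vec`).
#' @return invisibly, the paths written.
#' @export
write_mode_set <- function(modes, path) {
  hdr <- list(n_modes = length(modes$values), n_frames = modes$n_frames,
              eigenvalues = modes$values, mean = modes$mean,
              discarded = modes$discarded)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(format(modes$vectors, digits = 12),
                     paste0(path, ".vec"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(c(paste0(path, ".json"), paste0(path, ".vec")))
}

#' @rdname write_mode_set
#' @export
read_mode_set <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vecs <- as.matrix(utils::read.table(paste0(path, ".vec")))
  dimnames(vecs) <- NULL
  structure(list(values = hdr$eigenvalues, vectors = vecs, mean = hdr$mean,
                 discarded = hdr$discarded, n_frames = hdr$n_frames,
                 rank_warning = FALSE),
            class = "mode_set")
}
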