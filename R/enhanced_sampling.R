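## Eigenvector-projection collective variable, ABF-style PMF assembly from
## windowed force statistics, the ABF standard-error bound, and
## Flyvbjerg-Petersen blocking analysis.

#' Eigenvector-projection collective variable
#'
#' xi = sum_i nu_i . (U (x_i - x_cog) - (x_i^ref - x_cog^ref)), where U is the
#' optimal (least-squares) rotation of the centered frame onto the centered
#' reference. Invariant to rigid motion of the frame; additive along nu.
#'
#' @param frame n_atoms x 3 coordinates.
#' @param colvar list with `ref` (n_atoms x 3 reference coordinates) and `nu`
#'   (unit 3N vector, atom-major), as built by [colvar_definition()].
#' @return scalar xi (Angstrom).
#' @export
eval_colvar <- function(frame, colvar) {
  frame <- as.matrix(frame)
  ref <- colvar$ref
  if (!all(dim(frame) == dim(ref))) {
    stop("frame has ", nrow(frame), " atoms; colvar reference has ",
         nrow(ref))
  }
  A <- sweep(frame, 2, colMeans(frame))
  B <- sweep(ref, 2, colMeans(ref))
  k <- kabsch(A, B)
  dev <- A %*% t(k$R) - B
  sum(colvar$nu * as.numeric(t(dev)))
}

#' @rdname eval_colvar
#' @param ref reference coordinates (n_atoms x 3).
#' @param nu direction vector, length 3N (normalized internally).
#' @export
colvar_definition <- function(ref, nu) {
  ref <- as.matrix(ref)
  nu <- as.numeric(nu)
  if (length(nu) != 3L * nrow(ref)) {
    stop("nu must have length 3 * n_atoms")
  }
  n <- sqrt(sum(nu^2))
  if (n < 1e-12) stop("nu has zero norm")
  structure(list(ref = ref, nu = nu / n), class = "colvar_definition")
}

#' Windowed ABF force data container
#'
#' @param bin_center colvar values at bin centers (Angstrom).
#' @param mean_force per-bin mean thermodynamic force (kcal/mol/A).
#' @param force_variance per-bin force variance sigma^2.
#' @param n_samples per-bin force-sample counts.
#' @param tau force correlation length (samples).
#' @param window_id identifier.
#' @param interval the window interval `c(xi_a, xi_b)`; defaults to the
#'   bin-edge span (bins partition the window, so the edges sit half a bin
#'   spacing outside the outermost centers).
#' @return object of class `window_force_data`.
#' @export
window_force_data <- function(bin_center, mean_force, force_variance = 0,
                              n_samples = 1, tau = 0, window_id = "w",
                              interval = NULL) {
  k <- length(bin_center)
  stopifnot(length(mean_force) == k)
  bin_center <- as.numeric(bin_center)
  if (is.null(interval)) {
    half <- if (k > 1) stats::median(diff(sort(bin_center))) / 2 else 0.5
    interval <- c(min(bin_center) - half, max(bin_center) + half)
  }
  structure(list(bin_center = bin_center,
                 mean_force = as.numeric(mean_force),
                 force_variance = rep_len(force_variance, k),
                 n_samples = rep_len(n_samples, k),
                 tau = rep_len(tau, k),
                 window_id = window_id,
                 interval = as.numeric(interval)),
            class = "window_force_data")
}

#' Read window force data from CSV
#'
#' Columns: bin_center, mean_force, force_variance, n_samples, tau.
#' @param path CSV path.
#' @param window_id identifier (default: file name).
#' @return `window_force_data`.
#' @export
read_window_csv <- function(path, window_id = basename(path)) {
  tab <- utils::read.csv(path)
  window_force_data(tab$bin_center, tab$mean_force, tab$force_variance,
                    tab$n_samples, tab$tau, window_id = window_id)
}

## default window layout: five overlapping windows spanning [-5, 10] Angstrom
## along the twist colvar, 15 bins each. The second interval is [-2, 3].
.default_windows <- list(c(-5, -1), c(-2, 3), c(1, 6), c(4, 8), c(6, 10))

#' Default ABF window layout
#'
#' Five overlapping windows covering [-5, 10] Angstrom along the junction
#' twist colvar, each split into 15 force bins.
#'
#' @param n_bins bins per window (default 15).
#' @return list of data frames (window id, bin centers).
#' @export
abf_window_layout <- function(n_bins = 15L) {
  lapply(seq_along(.default_windows), function(i) {
    w <- .default_windows[[i]]
    width <- diff(w) / n_bins
    data.frame(window = i,
               bin_center = seq(w[1] + width / 2, w[2] - width / 2,
                                length.out = n_bins))
  })
}

#' Integrate windowed mean forces into a PMF
#'
#' Per window, A(xi) = -integral of the mean force (trapezoidal, from the
#' window's first bin); overlapping windows are then stitched by constant
#' offsets chosen by least squares on the overlap regions (interpolated onto
#' the finer grid); finally the global minimum is gauged to zero.
#'
#' @param windows list of `window_force_data`.
#' @return object of class `pmf_profile`: data frame `profile` (xi, A,
#'   sd_bound, window), per-window offsets.
#' @export
integrate_pmf <- function(windows) {
  if (inherits(windows, "window_force_data")) windows <- list(windows)
  stopifnot(length(windows) >= 1L)
  ## per-window integration
  parts <- lapply(windows, function(w) {
    ord <- order(w$bin_center)
    xi <- w$bin_center[ord]; f <- w$mean_force[ord]
    if (anyNA(f)) {
      ok <- !is.na(f)
      if (sum(ok) < 2) stop("window ", w$window_id, " has too few sampled bins")
      f[!ok] <- stats::approx(xi[ok], f[ok], xout = xi[!ok], rule = 2)$y
      warning("window ", w$window_id, ": empty bin(s) interpolated")
    }
    A <- c(0, cumsum(-(f[-1] + f[-length(f)]) / 2 * diff(xi)))
    sd_bound <- abf_error(w)
    data.frame(xi = xi, A = A, sd_bound = sd_bound,
               window = w$window_id, stringsAsFactors = FALSE)
  })
  ## coverage check
  ivs <- t(vapply(parts, function(p) range(p$xi), numeric(2)))
  ord <- order(ivs[, 1])
  if (length(parts) > 1L) {
    for (k in seq_len(length(parts) - 1L)) {
      a <- ivs[ord[k], ]; b <- ivs[ord[k + 1L], ]
      if (b[1] > a[2]) {
        stop("window coverage gap between xi = ", a[2], " and xi = ", b[1])
      }
    }
  }
  ## least-squares constant offsets: minimize sum over overlapping pairs of
  ## integral (A_i + c_i - A_j - c_j)^2 evaluated on shared support
  m <- length(parts)
  offsets <- numeric(m)
  if (m > 1L) {
    AtA <- matrix(0, m, m); Atb <- numeric(m)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      lo <- max(min(parts[[i]]$xi), min(parts[[j]]$xi))
      hi <- min(max(parts[[i]]$xi), max(parts[[j]]$xi))
      if (hi <= lo) next
      grid <- sort(unique(c(parts[[i]]$xi[parts[[i]]$xi >= lo & parts[[i]]$xi <= hi],
                            parts[[j]]$xi[parts[[j]]$xi >= lo & parts[[j]]$xi <= hi])))
      if (length(grid) < 2L) next
      Ai <- stats::approx(parts[[i]]$xi, parts[[i]]$A, grid)$y
      Aj <- stats::approx(parts[[j]]$xi, parts[[j]]$A, grid)$y
      d <- Ai - Aj
      w <- length(grid)
      ## d(c): sum (d + ci - cj)^2 -> normal equations
      AtA[i, i] <- AtA[i, i] + w; AtA[j, j] <- AtA[j, j] + w
      AtA[i, j] <- AtA[i, j] - w; AtA[j, i] <- AtA[j, i] - w
      Atb[i] <- Atb[i] - sum(d); Atb[j] <- Atb[j] + sum(d)
    }
    ## gauge: fix offset of first window to 0
    AtA[1, ] <- 0; AtA[, 1] <- 0; AtA[1, 1] <- 1; Atb[1] <- 0
    offsets <- solve(AtA + diag(1e-12, m), Atb)
  }
  prof <- do.call(rbind, lapply(seq_len(m), function(i) {
    p <- parts[[i]]; p$A <- p$A + offsets[i]; p
  }))
  ## merge duplicate grid points (average A over covering windows)
  prof <- prof[order(prof$xi), ]
  agg <- stats::aggregate(prof[c("A", "sd_bound")],
                          by = list(xi = prof$xi), FUN = mean)
  win <- vapply(split(as.character(prof$window), prof$xi),
                function(z) paste(unique(z), collapse = "+"), character(1))
  agg$window <- win[as.character(agg$xi)]
  agg$A <- agg$A - min(agg$A)
  structure(list(profile = agg, offsets = offsets,
                 n_windows = m),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat("<pmf_profile>", nrow(x$profile), "grid points from", x$n_windows,
      "window(s); barrier", sprintf("%.3f", max(x$profile$A)), "kcal/mol\n")
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, xlab = "xi (A)", ylab = "A (kcal/mol)", ...) {
  p <- x$profile
  graphics::plot(p$xi, p$A, type = "l", xlab = xlab, ylab = ylab, ...)
  graphics::polygon(c(p$xi, rev(p$xi)),
                    c(p$A + p$sd_bound, rev(p$A - p$sd_bound)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(p$xi, p$A)
  invisible(x)
}

#' ABF standard-error bound for a free-energy difference
#'
#' SD[dA] = (xi_b - xi_a) * sigma / sqrt(K) * sqrt(1 + 2 tau): sigma^2 the
#' force variance, K the number of force evaluations, tau the force
#' correlation length in samples.
#'
#' @param window a `window_force_data` (pooled sigma, total K, max tau are
#'   used), or NULL if the scalar arguments are given.
#' @param interval c(xi_a, xi_b); default the window interval.
#' @param sigma,K,tau scalar overrides.
#' @return non-negative SD bound (kcal/mol).
#' @export
abf_error <- function(window = NULL, interval = NULL, sigma = NULL,
                      K = NULL, tau = NULL) {
  if (!is.null(window)) {
    if (is.null(interval)) interval <- window$interval
    if (is.null(sigma)) sigma <- sqrt(mean(window$force_variance))
    if (is.null(K)) K <- sum(window$n_samples)
    if (is.null(tau)) tau <- max(window$tau)
  }
  if (is.null(K) || K <= 0) stop("K must be positive")
  if (sigma < 0 || tau < 0) stop("sigma and tau must be non-negative")
  abs(diff(interval)) * sigma / sqrt(K) * sqrt(1 + 2 * tau)
}

#' Flyvbjerg-Petersen blocking analysis
#'
#' Successive pairwise block averaging of a correlated scalar series. The
#' standard error of the mean is estimated at each blocking level; the
#' plateau value gives the true SE, and the correlation time follows from the
#' ratio to the naive (level-0) SE: tau_c = dt ((SE_plateau/SE_naive)^2 - 1)/2.
#'
#' @param series numeric time series (length >= 64).
#' @param dt time per sample (default 1; any unit).
#' @param min_blocks stop blocking below this many blocks (default 16).
#' @return object of class `blocking_result`: `levels` data frame (level,
#'   n_blocks, se, se_err), `se_naive`, `se_plateau`, `tau_c` (in units of
#'   `dt`), `plateau_found`.
#' @export
blocking_analysis <- function(series, dt = 1, min_blocks = 16L) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 64L) stop("need at least 64 samples, got ", n)
  levels <- list()
  lvl <- 0L
  repeat {
    m <- length(x)
    se <- stats::sd(x) / sqrt(m)
    se_err <- se / sqrt(2 * (m - 1))
    levels[[lvl + 1L]] <- data.frame(level = lvl, n_blocks = m,
                                     se = se, se_err = se_err)
    if (m %/% 2L < min_blocks) break
    m2 <- (m %/% 2L) * 2L
    x <- (x[seq(1L, m2, by = 2L)] + x[seq(2L, m2, by = 2L)]) / 2
    lvl <- lvl + 1L
  }
  tab <- do.call(rbind, levels)
  se_naive <- tab$se[1]
  ## plateau: first level whose SE is within its own error of the next level's
  plateau_found <- FALSE
  se_plateau <- tab$se[nrow(tab)]
  for (i in seq_len(nrow(tab) - 1L)) {
    if (abs(tab$se[i + 1L] - tab$se[i]) <= tab$se_err[i + 1L]) {
      ## consolidate: average remaining levels from i
      se_plateau <- mean(tab$se[i:min(i + 2L, nrow(tab))])
      plateau_found <- TRUE
      break
    }
  }
  if (!plateau_found) {
    warning("no SE plateau before blocks fell below ", min_blocks,
            "; tau_c is a lower bound")
  }
  tau_c <- dt * ((se_plateau / se_naive)^2 - 1) / 2
  structure(list(levels = tab, se_naive = se_naive, se_plateau = se_plateau,
                 tau_c = max(tau_c, 0), dt = dt,
                 plateau_found = plateau_found),
            class = "blocking_result")
}

#' @export
print.blocking_result <- function(x, ...) {
  cat("<blocking_result>", nrow(x$levels), "blocking levels\n")
  cat(sprintf("  naive SE %.4g, plateau SE %.4g%s\n", x$se_naive,
              x$se_plateau, if (x$plateau_found) "" else " (no plateau)"))
  cat(sprintf("  correlation time tau_c = %.4g (dt = %g)\n", x$tau_c, x$dt))
  invisible(x)
}

#' Flag under-sampled force bins
#'
#' The minimum-sampling rule: each force bin should be sampled for at least
#' `min_time` (default 5 ns, chosen above the ~4 ns decorrelation time of the
#' second essential mode). Bins whose sampled time n_samples * dt falls short
#' are flagged.
#'
#' @param window a `window_force_data`.
#' @param dt time per force sample (ns).
#' @param min_time minimum per-bin sampling (ns, default 5).
#' @return logical vector, TRUE = under-sampled.
#' @export
undersampled_bins <- function(window, dt, min_time = 5) {
  window$n_samples * dt < min_time
}
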