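## Time-resolved FRET donor-decay model: a mixture of two Gaussian
## donor-acceptor distance distributions, one per stacked junction isomer,
## weighted by the equilibrium isomer fractions, convolved with the intrinsic
## (multi-exponential) donor decay.

#' Construct a two-isomer FRET decay model
#'
#' I(t) = sum_i fr_i integral P_i(R) sum_j alpha_j exp[-t/tau_j (1+(R0/R)^6)] dR,
#' with P_i a Gaussian in the donor-acceptor distance R (truncated at R > 0 and
#' renormalized), fr_2 = 1 - fr_1. The intrinsic donor decay (amplitudes
#' alpha_j, lifetimes tau_j) is measured on a donor-only sample.
#'
#' @param fr_iso1 fraction of isomer I in [0, 1].
#' @param R_iso1,R_iso2 mean D-A distances (Angstrom) of isomers I and II.
#' @param sigma_iso1,sigma_iso2 distance-distribution widths (Angstrom).
#' @param R0 Foerster radius (Angstrom); default 50, a standard literature
#'   value for the fluorescein / tetramethylrhodamine pair.
#' @param lifetimes intrinsic donor lifetimes (ns); default two components,
#'   typical for fluorescein.
#' @param amplitudes intrinsic amplitudes (normalized to sum 1).
#' @return object of class `fret_model`.
#' @export
fret_model <- function(fr_iso1, R_iso1 = 45, R_iso2 = 70,
                       sigma_iso1 = 5, sigma_iso2 = 5, R0 = 50,
                       lifetimes = c(4.1, 1.5),
                       amplitudes = c(0.7, 0.3)) {
  if (fr_iso1 < 0 || fr_iso1 > 1) stop("fr_iso1 must be in [0, 1]")
  if (any(c(R_iso1, R_iso2, sigma_iso1, sigma_iso2, R0) <= 0)) {
    stop("distances, widths and R0 must be positive")
  }
  if (any(lifetimes <= 0)) stop("lifetimes must be positive")
  stopifnot(length(lifetimes) == length(amplitudes))
  amplitudes <- amplitudes / sum(amplitudes)
  structure(list(fr_iso1 = fr_iso1,
                 R = c(R_iso1, R_iso2), sigma = c(sigma_iso1, sigma_iso2),
                 R0 = R0, lifetimes = lifetimes, amplitudes = amplitudes),
            class = "fret_model")
}

#' @export
print.fret_model <- function(x, ...) {
  cat("<fret_model> fr(Iso I) =", sprintf("%.3f", x$fr_iso1), "\n")
  cat(sprintf("  Iso I:  R = %.1f A (sigma %.1f); Iso II: R = %.1f A (sigma %.1f); R0 = %.1f A\n",
              x$R[1], x$sigma[1], x$R[2], x$sigma[2], x$R0))
  cat("  intrinsic decay:",
      paste(sprintf("%.2f x %.2f ns", x$amplitudes, x$lifetimes),
            collapse = " + "), "\n")
  invisible(x)
}

## fixed Gauss-Legendre-free quadrature over the truncated Gaussian:
## midpoint rule on a fine grid over [max(eps, Rbar - 6 sigma), Rbar + 6 sigma],
## weights prop. to the Gaussian density, renormalized after truncation.
.distance_quadrature <- function(Rbar, sigma, n = 201L) {
  lo <- max(1e-3, Rbar - 6 * sigma)
  hi <- Rbar + 6 * sigma
  r <- seq(lo, hi, length.out = n)
  w <- stats::dnorm(r, Rbar, sigma)
  w <- w / sum(w)
  list(r = r, w = w)
}

#' Donor fluorescence decay of a two-isomer FRET model
#'
#' @param model a `fret_model`.
#' @param times time grid (ns).
#' @param n_quad quadrature points per distance distribution (default 201).
#' @return intensity values (arbitrary units, I(0) = 1).
#' @export
donor_decay <- function(model, times, n_quad = 201L) {
  stopifnot(inherits(model, "fret_model"))
  fr <- c(model$fr_iso1, 1 - model$fr_iso1)
  out <- numeric(length(times))
  for (i in 1:2) {
    if (fr[i] == 0) next
    q <- .distance_quadrature(model$R[i], model$sigma[i], n_quad)
    rate_factor <- 1 + (model$R0 / q$r)^6   # per-distance rate multiplier
    comp <- numeric(length(times))
    for (j in seq_along(model$lifetimes)) {
      ## outer(times, rate_factor): decay of lifetime j at each distance
      E <- exp(-outer(times, rate_factor) / model$lifetimes[j])
      comp <- comp + model$amplitudes[j] * as.numeric(E %*% q$w)
    }
    out <- out + fr[i] * comp
  }
  out
}

#' Read a decay curve from two-column text
#'
#' @param path text file with columns t (ns) and counts.
#' @return data frame (t, counts).
#' @export
read_decay_curve <- function(path) {
  tab <- utils::read.table(path, header = TRUE)
  names(tab)[1:2] <- c("t", "counts")
  if (any(tab$counts < 0)) stop("negative counts in ", path)
  if (length(unique(round(diff(tab$t), 9))) > 1L) {
    stop("time bins must be uniform")
  }
  tab
}

#' Fit the isomer-I fraction to a donor-decay curve
#'
#' Weighted least squares with Poisson weights (w = 1/max(counts, 1)) over
#' the isomer fraction and, optionally, the distance-distribution parameters;
#' the intrinsic donor decay and the Foerster radius are fixed inputs
#' (measured on a donor-only sample / taken from calibration). Uses
#' Levenberg-Marquardt (minpack.lm) with a Nelder-Mead fallback.
#'
#' @param curve data frame (t, counts) (see [read_decay_curve()]).
#' @param model a `fret_model` giving the fixed quantities and initial
#'   guesses.
#' @param fit_distances also optimize the two distribution means (default
#'   FALSE: fraction only, the widths and means held at calibration values).
#' @param n_boot bootstrap replicates for the confidence interval (default 0:
#'   no CI).
#' @param conf confidence level (default 0.95).
#' @return object of class `fret_fit`: `fr` (fitted fraction), `model`
#'   (updated), `ci`, `at_bound` flag, `fitted` curve, `rss`.
#' @export
fit_isomer_fraction <- function(curve, model, fit_distances = FALSE,
                                n_boot = 0L, conf = 0.95) {
  stopifnot(all(c("t", "counts") %in% names(curve)))
  t <- curve$t; y <- curve$counts
  wt <- 1 / pmax(y, 1)           # Poisson weights
  scale0 <- sum(y) / sum(donor_decay(model, t))

  predict_counts <- function(fr, R1, R2, scale) {
    m <- model; m$fr_iso1 <- fr; m$R <- c(R1, R2)
    scale * donor_decay(m, t)
  }

  fit_once <- function(y_obs, w_obs) {
    ## logit-bounded fraction keeps fr in [0,1] without constrained optim
    start <- list(qfr = stats::qlogis(min(max(model$fr_iso1, 0.02), 0.98)),
                  lsc = log(scale0))
    if (fit_distances) {
      start$R1 <- model$R[1]; start$R2 <- model$R[2]
    }
    resid_fn <- function(par) {
      fr <- stats::plogis(par[["qfr"]])
      R1 <- if (fit_distances) par[["R1"]] else model$R[1]
      R2 <- if (fit_distances) par[["R2"]] else model$R[2]
      (y_obs - predict_counts(fr, R1, R2, exp(par[["lsc"]]))) * sqrt(w_obs)
    }
    p0 <- unlist(start)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info %in% c(0, 9)) {
      obj <- function(par) sum(resid_fn(par)^2)
      op <- stats::optim(p0, obj, method = "Nelder-Mead",
                         control = list(maxit = 2000))
      if (op$convergence != 0) {
        stop("FRET fit did not converge; last parameters: ",
             paste(sprintf("%s=%.4g", names(op$par), op$par), collapse = ", "))
      }
      par <- op$par; rss <- op$value
    } else {
      par <- fit$par; rss <- sum(fit$fvec^2)
    }
    list(par = par, rss = rss)
  }

  f <- fit_once(y, wt)
  fr_hat <- stats::plogis(f$par[["qfr"]])
  at_bound <- fr_hat < 0.005 || fr_hat > 0.995
  out_model <- model
  out_model$fr_iso1 <- fr_hat
  if (fit_distances) out_model$R <- c(f$par[["R1"]], f$par[["R2"]])
  fitted <- predict_counts(out_model$fr_iso1, out_model$R[1], out_model$R[2],
                           exp(f$par[["lsc"]]))

  ci <- NULL
  if (n_boot > 0L) {
    boots <- vapply(seq_len(n_boot), function(b) {
      yb <- stats::rpois(length(fitted), fitted)
      stats::plogis(fit_once(yb, 1 / pmax(yb, 1))$par[["qfr"]])
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- stats::quantile(boots, c(a, 1 - a), names = FALSE)
  }

  structure(list(fr = fr_hat, model = out_model, ci = ci, conf = conf,
                 at_bound = at_bound, fitted = fitted, rss = f$rss,
                 scale = exp(f$par[["lsc"]])),
            class = "fret_fit")
}

#' @export
print.fret_fit <- function(x, ...) {
  cat("<fret_fit> fr(Iso I) =", sprintf("%.4f", x$fr),
      if (x$at_bound) "(at bound)" else "", "\n")
  if (!is.null(x$ci)) {
    cat(sprintf("  %.0f%% bootstrap CI: [%.4f, %.4f]\n", 100 * x$conf,
                x$ci[1], x$ci[2]))
  }
  cat("  weighted RSS:", format(x$rss, digits = 4), "\n")
  invisible(x)
}
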