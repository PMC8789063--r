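## Per-step covariance, stiffness and configurational volume.
##
## The helicoidal stiffness matrix F_h follows from the sampled covariance of
## the six step parameters via C_h = kB T F_h^-1; the determinant of C_h (the
## product of its eigenvalues) is the configurational volume, a scalar
## deformability summary that keeps the off-diagonal couplings.

#' Sample covariance of a step-parameter series
#'
#' @param series a `step_series` (or plain n x 6 matrix).
#' @return object of class `step_covariance` with fields `C` (6x6, n-1
#'   denominator), `mean`, `n_frames`, `label`.
#' @export
step_covariance <- function(series) {
  v <- if (inherits(series, "step_series")) series$values else as.matrix(series)
  label <- if (inherits(series, "step_series")) series$label else NULL
  if (nrow(v) < 7L) {
    stop("need at least 7 frames for a non-singular 6x6 covariance, got ",
         nrow(v))
  }
  C <- stats::cov(v)
  C <- (C + t(C)) / 2
  structure(list(label = label, C = C, mean = colMeans(v),
                 n_frames = nrow(v)),
            class = "step_covariance")
}

#' @export
print.step_covariance <- function(x, ...) {
  lab <- if (!is.null(x$label)) render_step_label(x$label) else "(unlabelled)"
  cat("<step_covariance>", lab, "-", x$n_frames, "frames\n")
  cat("  mean:", sprintf("%.3f", x$mean), "\n")
  cat("  diag:", sprintf("%.4f", diag(x$C)), "\n")
  invisible(x)
}

#' Helicoidal stiffness matrix from a step covariance
#'
#' F_h = kB T C_h^-1, with kB = 1.987204e-3 kcal mol^-1 K^-1. Units by block:
#' kcal mol^-1 A^-2 (translations), kcal mol^-1 deg^-2 (rotations) and the
#' mixed kcal mol^-1 A^-1 deg^-1 couplings.
#'
#' @param cov a `step_covariance`.
#' @param temperature simulation temperature in K (default 298).
#' @param pseudo_inverse use the Moore-Penrose pseudo-inverse for a singular
#'   covariance (default FALSE: singularity is an error).
#' @return object of class `stiffness_matrix` with fields `F` (6x6),
#'   `temperature`, `condition_number`, `label`.
#' @export
stiffness_from_covariance <- function(cov, temperature = 298,
                                      pseudo_inverse = FALSE) {
  stopifnot(inherits(cov, "step_covariance"))
  C <- cov$C
  e <- eigen(C, symmetric = TRUE)
  tol <- 1e-8 * sum(abs(e$values))
  if (min(e$values) < -tol) {
    stop("covariance has a negative eigenvalue beyond tolerance (",
         format(min(e$values)), "); data-quality problem")
  }
  kT <- .kB_kcal * temperature
  if (min(abs(e$values)) <= tol) {
    if (!pseudo_inverse) {
      stop("singular covariance; re-run with pseudo_inverse = TRUE ",
           "to use the Moore-Penrose inverse")
    }
    keep <- e$values > tol
    Finv <- e$vectors[, keep, drop = FALSE] %*%
      diag(1 / e$values[keep], sum(keep)) %*%
      t(e$vectors[, keep, drop = FALSE])
    Fh <- kT * Finv
  } else {
    Fh <- kT * solve(C)
  }
  Fh <- (Fh + t(Fh)) / 2
  dimnames(Fh) <- dimnames(C)
  structure(list(label = cov$label, F = Fh, temperature = temperature,
                 condition_number = max(e$values) / max(min(e$values), 1e-300)),
            class = "stiffness_matrix")
}

#' @export
print.stiffness_matrix <- function(x, ...) {
  lab <- if (!is.null(x$label)) render_step_label(x$label) else "(unlabelled)"
  cat("<stiffness_matrix>", lab, "at", x$temperature, "K; cond",
      format(x$condition_number, digits = 3), "\n")
  cat("  diag:", sprintf("%.4g", diag(x$F)), "\n")
  invisible(x)
}

#' Configurational volume of a base-pair step
#'
#' Determinant of the 6x6 step-parameter covariance (the product of its
#' eigenvalues), in A^3 deg^3; larger volume means a more deformable step.
#'
#' @param cov a `step_covariance`.
#' @return scalar volume (A^3 deg^3).
#' @export
configurational_volume <- function(cov) {
  stopifnot(inherits(cov, "step_covariance"))
  d <- det(cov$C)
  if (d <= 0) {
    stop("non-positive covariance determinant (", format(d),
         "); covariance is not positive definite")
  }
  d
}

## display defaults for the hexagonal deviation reports
.deviation_defaults <- list(
  mean_threshold = c(translation = 0.2, rotation = 2),
  mean_rings = list(translation = c(0.5, 1.0), rotation = c(5, 10)),
  stiffness_rings = list(translation = c(1, 2), rotation = c(0.005, 0.01)),
  volume_rings = c(10, 100)
)

#' Per-step deviation report versus a B-form reference
#'
#' Signed deviations of per-step means (and optionally stiffness diagonals and
#' configurational volumes) from reference values matched by dinucleotide
#' context. Mean deviations smaller than 0.2 Angstrom (translations) or 2
#' degrees (rotations) are flagged suppressed, mirroring the hexagonal-plot
#' convention (rings at 0.5/1.0 A and 5/10 degrees for means; 1/2
#' kcal mol^-1 A^-2 and 0.005/0.01 kcal mol^-1 deg^-2 for stiffness; 10/100
#' A^3 deg^3 for volumes).
#'
#' @param target data frame with columns `label`, `dinucleotide`, the six
#'   mean columns `shift..twist`, optionally six stiffness-diagonal columns
#'   `f_shift..f_twist` and `volume`.
#' @param reference data frame with column `dinucleotide` plus the same
#'   quantity columns (a B-form reference table; see
#'   [read_reference_table()]).
#' @param thresholds,rings display defaults; override to change suppression
#'   thresholds or ring scales.
#' @return data frame of class `deviation_report`: one row per (label,
#'   quantity) with `value`, `reference`, `deviation`, `suppressed`, `source`.
#' @export
deviation_report <- function(target, reference,
                             thresholds = .deviation_defaults$mean_threshold,
                             rings = .deviation_defaults) {
  pars <- c("shift", "slide", "rise", "tilt", "roll", "twist")
  stopifnot(all(c("label", "dinucleotide", pars) %in% names(target)))
  rows <- list()
  for (i in seq_len(nrow(target))) {
    di <- target$dinucleotide[i]
    j <- match(di, reference$dinucleotide)
    if (is.na(j)) {
      stop("no reference entry for dinucleotide context '", di,
           "' (step ", target$label[i], ")")
    }
    src <- if ("source" %in% names(reference)) reference$source[j] else "reference"
    for (p in pars) {
      dev <- target[[p]][i] - reference[[p]][j]
      thr <- if (p %in% c("shift", "slide", "rise")) {
        thresholds[["translation"]]
      } else thresholds[["rotation"]]
      rows[[length(rows) + 1L]] <- data.frame(
        label = target$label[i], dinucleotide = di, quantity = p,
        value = target[[p]][i], reference = reference[[p]][j],
        deviation = dev, suppressed = abs(dev) < thr, source = src,
        stringsAsFactors = FALSE)
    }
    for (p in pars) {
      fp <- paste0("f_", p)
      if (fp %in% names(target) && fp %in% names(reference)) {
        dev <- target[[fp]][i] - reference[[fp]][j]
        rows[[length(rows) + 1L]] <- data.frame(
          label = target$label[i], dinucleotide = di, quantity = fp,
          value = target[[fp]][i], reference = reference[[fp]][j],
          deviation = dev, suppressed = FALSE, source = src,
          stringsAsFactors = FALSE)
      }
    }
    if ("volume" %in% names(target) && "volume" %in% names(reference)) {
      dev <- target$volume[i] - reference$volume[j]
      rows[[length(rows) + 1L]] <- data.frame(
        label = target$label[i], dinucleotide = di, quantity = "volume",
        value = target$volume[i], reference = reference$volume[j],
        deviation = dev, suppressed = FALSE, source = src,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "rings") <- rings
  class(out) <- c("deviation_report", class(out))
  out
}

#' Summarize a set of step series into a deviation-report target table
#'
#' @param series_list named list of `step_series` (as from
#'   [extract_step_series()]).
#' @param topology the `junction_topology` the series came from (for
#'   dinucleotide contexts).
#' @param isomer isomer the series belong to.
#' @param temperature temperature (K) for stiffness diagonals.
#' @param excluded_terminal_steps as used during extraction.
#' @return data frame suitable as `target` for [deviation_report()].
#' @export
step_summary_table <- function(series_list, topology, isomer,
                               temperature = 298,
                               excluded_terminal_steps = 3L) {
  rows <- lapply(series_list, function(s) {
    cv <- step_covariance(s)
    st <- stiffness_from_covariance(cv, temperature)
    lab <- s$label
    hs <- helix_strands(topology, isomer, lab$helix)
    phys <- lab$step_index + excluded_terminal_steps
    di <- substr(hs$sequence, phys, phys + 1L)
    m <- as.list(cv$mean)
    f <- as.list(stats::setNames(diag(st$F),
                                 paste0("f_", colnames(cv$C))))
    c(list(label = render_step_label(lab), dinucleotide = di), m, f,
      list(volume = configurational_volume(cv)))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Read a B-form reference table
#'
#' CSV with columns `dinucleotide`, the six mean columns `shift..twist`,
#' optionally `f_shift..f_twist` stiffness diagonals, `volume` and `source`.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_reference_table <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("dinucleotide", "shift", "slide", "rise", "tilt", "roll",
             "twist") %in% names(ref))) {
    stop("reference table must have dinucleotide and the six mean columns")
  }
  ref
}
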