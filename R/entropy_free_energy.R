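## Schlitter quasiharmonic entropy, MM-PBSA end-state bookkeeping, and the
## conformer-ratio Boltzmann relation.

#' Schlitter entropy estimate
#'
#' Upper-bound configurational entropy from the coordinate covariance:
#' S' = (1/2) kB sum_i ln[1 + (kB T e^2 / hbar^2) <q_i^2>], where <q_i^2> are
#' the eigenvalues of the mass-weighted covariance C' = M^(1/2) C M^(1/2).
#' Always >= the true entropy of the underlying (harmonic) density.
#'
#' @param covariance 3N x 3N coordinate covariance (A^2), atom-major
#'   (x1,y1,z1,x2,...).
#' @param masses per-atom masses (amu), length N (recycled to 3N), or length
#'   3N.
#' @param temperature temperature in K.
#' @return object of class `entropy_estimate`: `S` in kcal mol^-1 K^-1,
#'   `TS` (kcal/mol at `temperature`), per-mode arguments.
#' @export
schlitter_entropy <- function(covariance, masses, temperature = 298) {
  C <- as.matrix(covariance)
  n <- nrow(C)
  stopifnot(ncol(C) == n)
  if (any(masses <= 0)) stop("masses must be positive")
  if (length(masses) == n / 3) masses <- rep(masses, each = 3L)
  if (length(masses) != n) {
    stop("masses must have length N (atoms) or 3N, got ", length(masses))
  }
  sm <- sqrt(masses)
  Cp <- C * outer(sm, sm)
  ev <- eigen((Cp + t(Cp)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-8 * max(sum(abs(ev)), .Machine$double.eps)
  if (min(ev) < -tol) {
    stop("mass-weighted covariance has negative eigenvalue ",
         format(min(ev)), " beyond tolerance")
  }
  ev <- pmax(ev, 0)
  arg <- .schlitter_prefactor * temperature * ev
  S <- 0.5 * .kB_kcal * sum(log1p(arg))
  structure(list(S = S, TS = temperature * S, temperature = temperature,
                 mode_args = arg),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat("<entropy_estimate> S' =", format(x$S, digits = 6),
      "kcal/mol/K; TS' =", format(x$TS, digits = 6), "kcal/mol at",
      x$temperature, "K\n")
  if (!is.null(x$converged)) {
    cat("  convergence:", if (x$converged) "converged" else "NOT converged",
        sprintf("(relative change %.3g over last %d%% of frames)\n",
                x$rel_change, round(100 * x$tail_fraction)))
  }
  invisible(x)
}

#' Schlitter entropy convergence over growing frame prefixes
#'
#' Recomputes S' on growing prefixes of an aligned coordinate ensemble and
#' applies a relative-change convergence criterion (< `rel_tol` over the last
#' `tail_fraction` of frames). When the criterion fails, downstream MM-PBSA
#' totals should omit the -TS term (see [mmpbsa_combine()]).
#'
#' @param coords n x 3N aligned coordinate matrix (or `aligned_ensemble`).
#' @param masses per-atom masses (amu).
#' @param temperature temperature in K.
#' @param n_points number of prefix lengths to evaluate.
#' @param rel_tol relative-change threshold (default 0.01).
#' @param tail_fraction fraction of the frame range to test (default 0.2).
#' @return `entropy_estimate` for the full ensemble with extra fields
#'   `series` (data frame n_frames, S) and `converged`.
#' @export
schlitter_convergence <- function(coords, masses, temperature = 298,
                                  n_points = 10L, rel_tol = 0.01,
                                  tail_fraction = 0.2) {
  X <- if (inherits(coords, "aligned_ensemble")) coords$coords else
    .as_frame_matrix(coords)
  n <- nrow(X)
  sizes <- unique(round(seq(max(10, n / n_points), n, length.out = n_points)))
  series <- vapply(sizes, function(k) {
    schlitter_entropy(stats::cov(X[seq_len(k), , drop = FALSE]), masses,
                      temperature)$S
  }, numeric(1))
  full <- schlitter_entropy(stats::cov(X), masses, temperature)
  tail_idx <- sizes >= (1 - tail_fraction) * n
  rel <- if (sum(tail_idx) >= 2) {
    s <- series[tail_idx]
    (max(s) - min(s)) / max(abs(s))
  } else NA_real_
  full$series <- data.frame(n_frames = sizes, S = series)
  full$converged <- isTRUE(rel < rel_tol)
  full$rel_change <- rel
  full$tail_fraction <- tail_fraction
  full
}

#' Read an MM-PBSA energy term table
#'
#' Tab-separated with header FRAME, optional BASE, INT, ELE, VDW, PB, SA
#' (kcal/mol): the per-frame (and optionally per-base) gas-phase and solvation
#' terms produced by an external end-state solver.
#'
#' @param path file path.
#' @return data frame with standardized lower-case column names.
#' @export
read_energy_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("frame", "int", "ele", "vdw", "pb", "sa")
  if (!all(need %in% names(tab))) {
    stop("energy table must have columns FRAME, INT, ELE, VDW, PB, SA; ",
         "missing: ", paste(setdiff(need, names(tab)), collapse = ", "))
  }
  if (any(!stats::complete.cases(tab[need]))) {
    stop("incomplete term rows in ", path)
  }
  tab
}

#' Combine MM-PBSA terms into end-state totals
#'
#' Frame-averaged E_gas = E_int + E_ele + E_vdw, dG_solvation = dG_PB + dG_SA,
#' and dG_solvated = E_gas + dG_solvation - T S_solute. The entropy term is
#' included only when the supplied estimate is flagged converged; otherwise
#' totals omit -TS and carry `entropy_omitted = TRUE`. With per-base rows the
#' result also contains per-base totals.
#'
#' @param terms data frame as from [read_energy_table()].
#' @param entropy optional `entropy_estimate` (from
#'   [schlitter_convergence()]).
#' @param temperature temperature in K.
#' @return object of class `mmpbsa_result` with `totals` (named numeric) and
#'   optionally `per_base` (data frame base, e_total, ...).
#' @export
mmpbsa_combine <- function(terms, entropy = NULL, temperature = 298) {
  per_frame <- if ("base" %in% names(terms)) {
    agg <- stats::aggregate(terms[c("int", "ele", "vdw", "pb", "sa")],
                            by = list(frame = terms$frame), FUN = sum)
    agg
  } else terms
  means <- colMeans(per_frame[c("int", "ele", "vdw", "pb", "sa")])
  e_gas <- sum(means[c("int", "ele", "vdw")])
  dg_solv <- sum(means[c("pb", "sa")])
  include_S <- !is.null(entropy) && isTRUE(entropy$converged)
  ts <- if (include_S) entropy$temperature * entropy$S else 0
  totals <- c(e_internal = unname(means["int"]),
              e_electrostatic = unname(means["ele"]),
              e_vdw = unname(means["vdw"]),
              dg_pb = unname(means["pb"]), dg_sa = unname(means["sa"]),
              e_gas = e_gas, dg_solvation = dg_solv,
              ts_solute = ts,
              dg_solvated = e_gas + dg_solv - ts)
  out <- list(totals = totals, temperature = temperature,
              entropy_omitted = !include_S && !is.null(entropy),
              n_frames = length(unique(terms$frame)))
  if ("base" %in% names(terms)) {
    pb <- stats::aggregate(terms[c("int", "ele", "vdw", "pb", "sa")],
                           by = list(base = terms$base), FUN = mean)
    pb$e_total <- rowSums(pb[c("int", "ele", "vdw", "pb", "sa")])
    out$per_base <- pb
  }
  structure(out, class = "mmpbsa_result")
}

#' @export
print.mmpbsa_result <- function(x, ...) {
  cat("<mmpbsa_result>", x$n_frames, "frames\n")
  print(round(x$totals, 3))
  if (isTRUE(x$entropy_omitted)) {
    cat("  note: -TS term omitted (entropy estimate not converged)\n")
  }
  invisible(x)
}

#' Per-base isomerization energy differences
#'
#' ddE = dE(isomer 1) - dE(isomer 2), per base and in total. Requires both
#' results to carry per-base tables over the same base set.
#'
#' @param iso1,iso2 `mmpbsa_result` objects with `per_base` tables.
#' @return data frame (base, plus per-term and total differences) with
#'   attribute `total` = sum of per-base e_total differences.
#' @export
mmpbsa_isomer_diff <- function(iso1, iso2) {
  if (is.null(iso1$per_base) || is.null(iso2$per_base)) {
    stop("both results need per-base decompositions")
  }
  b1 <- iso1$per_base; b2 <- iso2$per_base
  if (!setequal(b1$base, b2$base)) {
    stop("mismatched base sets: ",
         paste(c(setdiff(b1$base, b2$base), setdiff(b2$base, b1$base)),
               collapse = ", "))
  }
  b2 <- b2[match(b1$base, b2$base), ]
  cols <- c("int", "ele", "vdw", "pb", "sa", "e_total")
  out <- data.frame(base = b1$base)
  for (cl in cols) out[[paste0("dd_", cl)]] <- b1[[cl]] - b2[[cl]]
  attr(out, "total") <- sum(out$dd_e_total)
  out
}

#' Isomerization free energy from conformer fractions
#'
#' ddG = -R T ln(fr_IsoI / fr_IsoII) with fr_IsoII = 1 - fr_IsoI. Negative
#' when isomer I dominates. Fractions at 0 or 1 return signed infinity with a
#' bound flag (populations reported as bounds, e.g. ">= 0.95").
#'
#' @param fr_iso1 equilibrium fraction of isomer I, in (0, 1) (0 or 1 allowed,
#'   giving infinite bounds).
#' @param temperature temperature in K (default 298).
#' @return object of class `isomer_thermo`: fractions, ratio, `ddG_kcal`,
#'   `ddG_kJ`, `at_bound`.
#' @export
#' @examples
#' isomer_dg(0.95)  # approx -1.74 kcal/mol
#' isomer_dg(0.49)  # approx +0.02 kcal/mol
isomer_dg <- function(fr_iso1, temperature = 298) {
  if (fr_iso1 < 0 || fr_iso1 > 1) stop("fraction must be in [0, 1]")
  fr2 <- 1 - fr_iso1
  at_bound <- fr_iso1 %in% c(0, 1)
  ratio <- fr_iso1 / fr2
  ddG_kcal <- -.kB_kcal * temperature * log(ratio)
  ddG_kJ <- -.R_kJ * temperature * log(ratio)
  structure(list(fr_iso1 = fr_iso1, fr_iso2 = fr2, ratio = ratio,
                 temperature = temperature,
                 ddG_kcal = ddG_kcal, ddG_kJ = ddG_kJ, at_bound = at_bound),
            class = "isomer_thermo")
}

#' @export
print.isomer_thermo <- function(x, ...) {
  cat("<isomer_thermo> fr(Iso I) =", x$fr_iso1, " fr(Iso II) =", x$fr_iso2,
      if (x$at_bound) "(bound)" else "", "\n")
  cat(sprintf("  ratio I:II = %.3g; ddG = %.3f kcal/mol = %.3f kJ/mol at %g K\n",
              x$ratio, x$ddG_kcal, x$ddG_kJ, x$temperature))
  invisible(x)
}
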