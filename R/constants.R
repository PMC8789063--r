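## Physical constants used across the package (CODATA 2018).

#' Boltzmann constant in kcal mol^-1 K^-1
#'
#' Gas constant per mole, the k_B that enters the stiffness relation
#' C_h = k_B T F_h^-1 and the Boltzmann inversion of population histograms.
#' @keywords internal
.kB_kcal <- 1.987204e-3

#' Gas constant in kJ mol^-1 K^-1
#' @keywords internal
.R_kJ <- 8.31446e-3

## Dimensionless prefactor of the Schlitter formula:
## (k_B T e^2 / hbar^2) * <q_i^2> with <q_i^2> in amu.A^2 equals
## .schlitter_prefactor * T[K] * <q_i^2>[amu.A^2].
## Built from k_B = 1.380649e-23 J/K, hbar = 1.054571817e-34 J.s,
## 1 amu = 1.66053907e-27 kg, 1 A^2 = 1e-20 m^2, e = exp(1).
.schlitter_prefactor <- local({
  kB_J <- 1.380649e-23
  hbar <- 1.054571817e-34
  amu  <- 1.66053907e-27
  kB_J * exp(1)^2 / hbar^2 * amu * 1e-20
})

## Atomic masses (amu) for the elements that occur in nucleic-acid heavy atoms
## plus hydrogen; used for mass-weighting in the Schlitter entropy.
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974)

#' Element masses for atom names
#'
#' Maps PDB-style atom names (e.g. "C1'", "OP1", "N9", "P") to atomic masses
#' in amu by their leading element letter.
#'
#' @param atom_names character vector of atom names.
#' @return numeric vector of masses (amu).
#' @export
atom_masses <- function(atom_names) {
  el <- sub("^([A-Za-z]).*$", "\\1", trimws(atom_names))
  el <- toupper(el)
  m <- .atomic_masses[el]
  if (anyNA(m)) {
    stop("unknown element for atom name(s): ",
         paste(unique(atom_names[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
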