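---
title: "Models and methods behind hjdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hjdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`hjdyn` analyses immobile DNA four-way (Holliday) junctions: the base-pair
level structure and flexibility of their pseudo-duplex arms, their global
collective dynamics, and the thermodynamics of the stacked-isomer
equilibrium. This vignette records the models implemented, the conventions
and defaults chosen where more than one reasonable option exists, and what
the synthetic-data generators do and do not establish about real
trajectories.

## The junction model and its bookkeeping

A stacked-X antiparallel junction is treated as two coaxially stacked
pseudo-duplexes (helices 1 and 2). Each helix has one continuous *reading
strand* that defines the 5'→3' step order: strand I (isomer 1) or II
(isomer 2) for helix 1, strand III (isomer 1) or IV (isomer 2) for helix 2.
A base-pair step is addressed as `x n^i_(h,b)` — topology letter (J full
junction, B/D the two single-crossover variants, N nicked duplex, d duplex),
core-sequence id, isomer, helix, and analyzed-step index. With 16-bp
pseudo-duplexes the three terminal steps at each end are excluded (terminal
fraying), so index `b` runs 1–9 over physical steps 4–12.

The shipped topology files (`inst/extdata/j1_topology.json`,
`j24_topology.json`) are **synthetic fixtures**: full strand sequences are
constructed to be Watson–Crick closed under the four-arm pairing convention
and to reproduce the documented core steps (J1: CT at `(1,5)`, TG at `(1,6)`
and at isomer-2 `(2,5)`; J24: CA, TA, GG at the corresponding cores). They
are placeholders for the experimental sequences, which are adequate for all
bookkeeping, generation and recovery analyses in this package because no
result here depends on the non-core filler sequence. The single-crossover
side convention (B keeps strand II crossing in isomer 1, D keeps strand I in
isomer 2) is encoded as an explicit flag, not inferred from geometry.

## Base-pair step geometry

Base frames are obtained by least-squares (Kabsch) superposition of an
embedded standard-geometry ring — ring heavy atoms only, never sugar or
phosphate atoms — onto the observed ring, always selecting the proper
(det = +1) rotation branch. The frame x-axis points away from the
minor-groove edge, y toward the complementary base, z along the rise.
The complementary base's frame is flipped 180° about its own x-axis before
pairing (the standard convention, stated here explicitly), and the base-pair
frame is the rotation-geodesic midpoint of the two frames with the midpoint
origin.

Step parameters follow the CEHS mid-step construction: both pair frames are
rotated by half the bending angle Γ about the hinge axis z₁×z₂ so their
z-axes coincide; twist is the angle between the rotated x-axes about the
common z; Γ decomposes into roll = Γ cos φ and tilt = Γ sin φ, where φ is
the angle from the hinge to the mid-frame y-axis; the origin displacement in
mid-frame coordinates gives shift, slide, rise. Twist is reported in
(−180°, 180°], so strong untwisting appears as values well below 36°.
`rebuild_step()` is the exact closed-form inverse
(R₂ = R₁·Rz(ω/2)·R_hinge(Γ)·Rz(ω/2)); the roundtrip is exact to ~1e−12 and
is asserted at 1e−8 over 10⁴ random draws. Useful symmetries, both tested:
global rigid motions leave all six parameters unchanged, and reading a step
from the complementary strand negates shift and tilt only.

The embedded standard ring coordinates follow the published consensus
reference frame for the four bases; because every geometric test in the
package is self-consistent against these constants, transcription-level
differences in the last decimal cannot affect any asserted result. Frame
fitting uses the ring-only atom set by default (the ring+C1′ alternative
changes frames negligibly for intact rings and is not implemented).

## Deformability

For each analyzed step the 6-parameter sample covariance `C_h` (n−1
denominator; the bias difference is negligible at the ~10⁴-frame scale this
is meant for, but n−1 is the unbiased choice) gives the helicoidal stiffness
`F_h = k_B T C_h⁻¹` with k_B = 1.987204×10⁻³ kcal mol⁻¹ K⁻¹ and T defaulting
to 298 K. Stiffness units are kcal mol⁻¹ Å⁻² / kcal mol⁻¹ deg⁻² (force
constants per mole) — the only reading consistent with k_B taken per mole.
The configurational volume det(C_h) (Å³ deg³) summarizes deformability
including the off-diagonal couplings. No decorrelation thinning is applied
before the covariance (all samples enter); a stride option exists on the
sub-sampling consistency test instead. Deviation reports match steps to a
B-form reference by local dinucleotide context and suppress mean deviations
below 0.2 Å / 2°, with ring scales 0.5/1.0 Å and 5/10° (means), 1/2
kcal mol⁻¹ Å⁻² and 0.005/0.01 kcal mol⁻¹ deg⁻² (stiffness diagonals — the
report exposes diagonal entries, the natural per-parameter scalarization),
and 10/100 Å³ deg³ (volumes). Singular covariances are an error unless the
Moore–Penrose pseudo-inverse is explicitly requested.

## Essential dynamics

Ensembles are aligned by iterative superposition: align all frames to the
first frame, recompute the mean, re-align to the mean, and repeat until the
mean moves by less than 1e−4 Å RMSD (error with full history if 100
iterations are exceeded). The coordinate covariance of the aligned frames is
*unweighted* — mass-weighting enters only the Schlitter entropy. After
eigendecomposition the six smallest-magnitude eigenvalues are discarded as
rigid-body remnants; they are numerical rather than exact zeros, so a sanity
check warns if any exceeds 1e−6 of the largest retained eigenvalue.
Eigenvector signs are fixed by making the largest-magnitude component
positive so mode signs are reproducible. Projections, back-projections and
the variance bookkeeping (Σλ plus discarded mass equals the total aligned
variance) follow directly.

Projection free-energy surfaces histogram two projection series on 0.2 Å ×
0.2 Å bins (0.04 Å² area) and apply −k_B T ln(n/n_max) at 298 K; unvisited
bins are NA, never zero. The conversion between the twist projection in Å
and a junction-twist angle in degrees is an affine map anchored at
(−5 Å, −90°) and (+10 Å, +90°); it is configuration, not inference, because
it cannot be derived from the projection alone.

## Entropy and end-state free energies

The Schlitter estimate mass-weights the coordinate covariance as
C′ = M^{1/2} C M^{1/2} (the self-referential printed variant of this formula
is treated as a typographical slip) and sums
S′ = ½ k_B Σ ln[1 + (k_B T e²/ħ²)⟨q_i²⟩] over the eigenvalues ⟨q_i²⟩ of C′
(amu Å²). S′ upper-bounds the classical Gaussian entropy ½ k_B Σ ln[(k_B T
e²/ħ²)⟨q_i²⟩] for every dataset, since ln(1+x) > ln(x); this bound property
is asserted, together with an exact closed-form single-mode case
(argument e²−1 gives S′ = k_B). Convergence is declared when S′ changes by
less than 1% over the last 20% of frames; otherwise MM-PBSA totals omit the
−TS term and carry a flag.

MM-PBSA combination consumes per-frame (optionally per-base) term tables
from external end-state solvers — the package deliberately contains no
Poisson–Boltzmann solver, force-field evaluator or surface-area
decomposition. Totals are frame averages of E_gas = E_int + E_ele + E_vdW
and ΔG_solv = ΔG_PB + ΔG_SA; per-base tables yield isomerization
differences ΔΔE = ΔE_iso1 − ΔE_iso2 whose per-base sum reproduces the
molecular total exactly (conservation is asserted). The per-base SA term is
accepted from either an LCPO or a molecular-surface split, tagged by source.
The conformer relation ΔΔG = −RT ln(fr_I/fr_II) is evaluated in both
kcal/mol and kJ/mol; fractions at 0 or 1 return signed infinities with a
bound flag, mirroring how boundary populations (e.g. "≥0.95") are reported.
The temperature defaults to 298 K and is configurable.

## ABF statistics

The collective variable is the projection of superposed backbone deviations
onto a mode vector: centers of geometry are removed, the frame is optimally
rotated onto the reference, and the rotated deviation is projected onto the
unit vector. It is invariant to rigid motions of the frame and additive
along the vector, both tested.

PMFs are assembled from per-bin mean-force statistics. The default layout is
five overlapping windows [−5,−1], [−2,3], [1,6], [4,8], [6,10] Å with 15
bins each (a window list whose second entry is occasionally printed with
inverted bounds is normalized to [−2,3]; windows must overlap and jointly
cover [−5,10]). How 75 bins reduce to 46 published grid points is
under-determined — uniform 1/3-Å spacing over [−5,10] gives 46 points but is
inconsistent with 15 bins per 4–5 Å window — so the package integrates on
bin centers and documents the discrepancy instead of resolving it. Windows
are integrated by the trapezoidal rule and stitched with constant offsets
chosen by least squares over all pairwise overlaps (robust to noisy edge
bins near the harmonic walls, unlike endpoint matching); the global minimum
is gauged to zero.

The error bound SD[ΔA] = (ξ_b−ξ_a)·σ·K^{−1/2}·(1+2τ)^{1/2} is an upper limit
for the *standard deviation* of an integrated free-energy difference, with
σ² the force-sample variance, K the number of force evaluations in the
interval and τ the force correlation length in samples. The window interval
is the bin-edge span (bins partition the window), which makes the bound
conservative for trapezoidal integration; the coverage tests verify
precisely this property — the SD of repeated estimates stays below the bound
across nested intervals in ≥90% of cases. A per-realization |error| can
exceed a 1-SD bound about a third of the time for any Gaussian estimator,
so that is not the property asserted.

Blocking analysis (pairwise block averaging) estimates the standard error of
a correlated series at successive blocking levels; the plateau is detected
where consecutive levels agree within the level's own uncertainty, and the
correlation time follows from τ_c = dt·((SE_plateau/SE_naive)² − 1)/2. On
AR(1) series this recovers the integrated autocorrelation time φ/(1−φ)
within 25% at 10⁵ samples. The minimum-sampling rule flags force bins
sampled for less than 5 ns — chosen above the ~4 ns decorrelation of the
second essential mode — given the per-sample time step.

## tr-FRET isomer fractions

The donor decay is modelled as a fraction-weighted mixture over the two
isomers, each contributing a Gaussian donor–acceptor distance distribution
(truncated at R > 0 and renormalized) under Förster kinetics:
I(t) = Σᵢ frᵢ ∫ Pᵢ(R) Σⱼ αⱼ exp[−t/τⱼ·(1+(R₀/R)⁶)] dR, fr₂ = 1 − fr₁. The
intrinsic decay (αⱼ, τⱼ) is a fixed input measured on a donor-only sample;
two lifetimes are the default (typical for fluorescein) and the count is
configurable. R₀ defaults to 50 Å, a standard literature value for the
fluorescein/tetramethylrhodamine pair, and is configuration. Quadrature
uses a dense renormalized grid over [max(ε, R̄−6σ), R̄+6σ]. Instrument
response convolution is off by default.

Fitting minimizes Poisson-weighted squared residuals over the isomer
fraction (logit-bounded) and a global scale, optionally also the two
distribution means; widths and means default to calibration values because
fraction-only optimization is the better-identified problem on single-curve
data. Levenberg–Marquardt with a Nelder–Mead fallback; parametric bootstrap
for confidence intervals. At 10⁶ total counts the fraction is recovered
within ±0.05 across the 0.05–0.95 range, and chaining the fitted fraction
through the Boltzmann relation reproduces the generating ΔΔG.

## Synthetic generators and what the tests show

The generators emulate the *statistical* structure the analyses assume, not
force-field physics: AR(1)-correlated Gaussian step parameters with a
prescribed stiffness (AR(1) because scalar decorrelation times are the only
time-correlation structure being modelled; richer kinetics would be
unverifiable at this level); coordinate ensembles that are a mean structure
plus planted orthonormal internal modes (projected off the rigid-body
subspace — internal motions are orthogonal to rigid motions by definition)
with AR(1) amplitudes, isotropic noise and optional per-frame rigid motions;
windowed force samples whose bin means scatter around −dA/dξ with the
sampling-distribution SD σ√(1+2τ)/√K; and Poisson photon counts around the
model decay. Every generator is seed-deterministic and records its
provenance.

Passing recovery tests on these ensembles demonstrates that the estimators
are correct and unbiased under their own assumptions — Gaussian
fluctuations, stationarity, harmonic wells, two-state mixtures. Real
junction trajectories violate these in known ways (anharmonic core
dynamics, slow isomer interconversion, sequence-dependent non-Gaussian
tails), so the tests validate the *machinery*, not the biological
conclusions one would draw from applying it.

Problem sizes used by the default test and acceptance runs — 10⁴ roundtrip
draws, 10⁵-frame step ensembles, 6×10³-frame PCA ensembles with 30 atoms,
200 PMF replicates, 10⁶-count decays — were chosen as the smallest sizes at
which the quoted tolerances (5% Frobenius error, 5% eigenvalue error, 2%
curvature, ±0.05 fraction) are comfortably inside the estimators' sampling
noise.

## Known limitations

- Intra-base-pair parameters (buckle, propeller, opening), groove geometry
  and backbone torsions are out of scope, as are trajectory formats beyond
  multi-model PDB / PDB directories.
- The PCA has no time-lagged or cross-validated variants; mode selection is
  by eigenvalue order only.
- The nicked/single-crossover variant constructors edit connectivity
  bookkeeping; they do not build coordinates for the variants.
- The FRET model assumes κ² orientational averaging is absorbed into R₀ and
  performs no global analysis across acceptor positions.
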