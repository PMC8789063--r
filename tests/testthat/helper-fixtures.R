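## Shared fixtures and small utilities for the test suite.

j1_topology <- function() {
  read_topology(system.file("extdata", "j1_topology.json", package = "hjdyn"))
}

j24_topology <- function() {
  read_topology(system.file("extdata", "j24_topology.json", package = "hjdyn"))
}

## a random proper-rotation frame with random origin
random_frame <- function() {
  orth_frame(hjdyn:::rot_about(stats::rnorm(3), stats::runif(1, 0, 2 * pi)),
             stats::rnorm(3, sd = 5))
}

## random step parameters within the physically sensible range
random_params <- function(trans = 2, rot = 30) {
  c(shift = stats::runif(1, -trans, trans),
    slide = stats::runif(1, -trans, trans),
    rise = stats::runif(1, 2, 5),
    tilt = stats::runif(1, -rot, rot),
    roll = stats::runif(1, -rot, rot),
    twist = stats::runif(1, -rot, rot) + 30)
}

## rotate an atom-major 3N mode vector by a 3x3 rotation
rotate_mode <- function(v, R) {
  M <- matrix(v, ncol = 3, byrow = TRUE)
  as.numeric(t(M %*% t(R)))
}

## random symmetric positive-definite matrix with unit-scale eigenvalues
random_spd <- function(d, scale = 1) {
  A <- matrix(stats::rnorm(d * d), d, d)
  Q <- qr.Q(qr(A))
  Q %*% diag(stats::runif(d, 0.2, 2) * scale, d) %*% t(Q)
}

## small B-form backbone-like mean structure for PCA tests: two stacked arms
test_mean_structure <- function(n_atoms = 30, seed = 42) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n_atoms, sd = 8), n_atoms, 3)
}
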