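test_that("superposition removes random rigid motions of a single structure", {
  set.seed(131)
  xyz <- test_mean_structure(20)
  n <- 15
  coords <- array(0, c(n, 20, 3))
  for (f in 1:n) {
    R <- hjdyn:::rot_about(rnorm(3), runif(1, 0, 2 * pi))
    coords[f, , ] <- hjdyn:::apply_rigid(xyz, R, rnorm(3, sd = 10))
  }
  al <- iterative_superposition(coords)
  ## all frames collapse onto one structure
  spread <- max(apply(al$coords, 2, function(col) diff(range(col))))
  expect_lt(spread, 1e-6)
  expect_lt(tail(al$history, 1), 1e-4)
})

test_that("an already-aligned ensemble converges immediately", {
  set.seed(141)
  xyz <- test_mean_structure(15)
  n <- 10
  coords <- array(0, c(n, 15, 3))
  for (f in 1:n) coords[f, , ] <- xyz + matrix(rnorm(45, 0, 0.01), 15, 3)
  al <- iterative_superposition(coords)
  expect_lte(length(al$history), 3)
})

test_that("a single planted mode is recovered in value and direction", {
  set.seed(151)
  mean_xyz <- test_mean_structure(25)
  nu <- matrix(rnorm(75), 75, 1)
  ge <- gen_mode_ensemble(mean_xyz, nu, variances = 4, n_frames = 5000,
                          noise_sd = 0.02, rigid_motions = FALSE, seed = 151)
  ms <- essential_modes(iterative_superposition(ge$coords))
  expect_equal(ms$values[1], 4, tolerance = 0.1)
  expect_gt(abs(sum(ms$vectors[, 1] * ge$modes[, 1])), 0.99)
  ## projection variance matches the eigenvalue
  p <- project_modes(ge$coords, ms, 1)
  expect_equal(stats::var(p[, 1]), ms$values[1], tolerance = 1e-6)
})

test_that("two planted modes are recovered in order with low cross-talk", {
  set.seed(161)
  mean_xyz <- test_mean_structure(30)
  V <- matrix(rnorm(180), 90, 2)
  ge <- gen_mode_ensemble(mean_xyz, V, variances = c(9, 1), n_frames = 4000,
                          noise_sd = 0.05, rigid_motions = TRUE, seed = 161)
  al <- iterative_superposition(ge$coords)
  ms <- essential_modes(al)
  expect_gt(ms$values[1], ms$values[2])
  expect_equal(ms$values[1], 9, tolerance = 0.15)
  expect_equal(ms$values[2], 1, tolerance = 0.15)
  ## rotate planted modes into the aligned frame before comparing
  k <- hjdyn:::kabsch(matrix(ge$mean, ncol = 3, byrow = TRUE),
                      matrix(ms$mean, ncol = 3, byrow = TRUE))
  M <- abs(t(ms$vectors[, 1:2]) %*%
             cbind(rotate_mode(ge$modes[, 1], k$R),
                   rotate_mode(ge$modes[, 2], k$R)))
  expect_gt(M[1, 1], 0.99)
  expect_gt(M[2, 2], 0.99)
  expect_lt(M[1, 2], 0.1)
  expect_lt(M[2, 1], 0.1)
})

test_that("white-noise ensembles have no spurious dominant mode", {
  set.seed(171)
  N <- 20; n <- 2000
  coords <- array(rnorm(n * N * 3, 0, 0.5), c(n, N, 3))
  base <- test_mean_structure(N, seed = 171)
  for (f in 1:n) coords[f, , ] <- coords[f, , ] + base
  ms <- essential_modes(iterative_superposition(coords))
  ## eigenvalue spread stays within the Marchenko-Pastur-like band: the top
  ## eigenvalue is not an outlier relative to the bulk
  expect_lt(ms$values[1] / stats::median(ms$values), 2.5)
})

test_that("mode-set bookkeeping: orthonormal vectors and variance sums", {
  set.seed(181)
  mean_xyz <- test_mean_structure(15)
  V <- matrix(rnorm(90), 45, 2)
  ge <- gen_mode_ensemble(mean_xyz, V, c(4, 2), 600, noise_sd = 0.1,
                          rigid_motions = FALSE, seed = 181)
  al <- iterative_superposition(ge$coords)
  ms <- essential_modes(al)
  G <- t(ms$vectors) %*% ms$vectors
  expect_lt(max(abs(G - diag(ncol(ms$vectors)))), 1e-8)
  expect_length(ms$discarded, 6)
  total_var <- sum(apply(al$coords, 2, stats::var))
  expect_equal(sum(ms$values) + sum(ms$discarded), total_var,
               tolerance = 1e-6)
})

test_that("projection and back-projection are mutually consistent", {
  set.seed(191)
  mean_xyz <- test_mean_structure(12)
  V <- matrix(rnorm(72), 36, 2)
  ge <- gen_mode_ensemble(mean_xyz, V, c(3, 1), 500, noise_sd = 0.05,
                          rigid_motions = FALSE, seed = 191)
  ms <- essential_modes(iterative_superposition(ge$coords))
  ## mean projects to zero; mean + 2.5 nu projects to 2.5
  expect_equal(as.numeric(project_modes(matrix(ms$mean, 1), ms, 1)), 0,
               tolerance = 1e-10)
  x <- matrix(ms$mean + 2.5 * ms$vectors[, 1], 1)
  expect_equal(as.numeric(project_modes(x, ms, 1)), 2.5, tolerance = 1e-10)
  ## backproject(0) is the mean; project(backproject(p)) = p exactly
  expect_equal(as.numeric(backproject_mode(0, ms, 1)), ms$mean)
  p <- seq(-3, 3, by = 0.5)
  bp <- backproject_mode(p, ms, 1)
  expect_equal(as.numeric(project_modes(bp, ms, 1, check = FALSE)), p,
               tolerance = 1e-10)
  ## rank-k residual is orthogonal to the modes
  D <- sweep(iterative_superposition(ge$coords)$coords, 2, ms$mean)
  P <- D %*% ms$vectors[, 1:2]
  resid <- D - P %*% t(ms$vectors[, 1:2])
  expect_lt(max(abs(resid %*% ms$vectors[, 1:2])), 1e-8)
  ## linear path RMSD: endpoints of a sweep differ by (2 * 3 sigma) / sqrt(N)
  sigma <- sqrt(ms$values[1])
  ends <- backproject_mode(c(-3 * sigma, 3 * sigma), ms, 1)
  rmsd <- sqrt(mean(rowSums(
    (matrix(ends[1, ], ncol = 3, byrow = TRUE) -
       matrix(ends[2, ], ncol = 3, byrow = TRUE))^2)))
  expect_equal(rmsd, 6 * sigma / sqrt(12), tolerance = 1e-8)
})

test_that("unaligned frames are rejected by the projection guard", {
  set.seed(201)
  mean_xyz <- test_mean_structure(12)
  V <- matrix(rnorm(36), 36, 1)
  ge <- gen_mode_ensemble(mean_xyz, V, 2, 200, rigid_motions = FALSE,
                          seed = 201)
  ms <- essential_modes(iterative_superposition(ge$coords))
  shifted <- sweep(iterative_superposition(ge$coords)$coords, 2, -5)
  expect_error(project_modes(shifted, ms, 1), "aligned")
})

test_that("projection surfaces Boltzmann-invert known densities", {
  set.seed(211)
  kT <- 1.987204e-3 * 298
  ## isotropic Gaussian: F(r) = kT r^2 / (2 sigma^2) relative to the center
  n <- 1e5
  p1 <- rnorm(n); p2 <- rnorm(n)
  s <- projection_surface(p1, p2, bin_edge = 0.2)
  expect_equal(min(s$F, na.rm = TRUE), 0)
  grid <- expand.grid(x = s$x, y = s$y)
  r2 <- grid$x^2 + grid$y^2
  keep <- !is.na(as.numeric(s$F)) & s$counts >= 50 & r2 > 0.1
  fit <- stats::lm(as.numeric(s$F)[keep] ~ r2[keep])
  expect_equal(unname(coef(fit)[2]), kT / 2, tolerance = 0.1)
  ## two clusters 95:5 -> basin free-energy gap kT ln 19
  m <- 2e4
  which2 <- runif(m) < 0.05
  q1 <- rnorm(m, ifelse(which2, 6, 0), 0.3)
  q2 <- rnorm(m, 0, 0.3)
  s2 <- projection_surface(q1, q2, bin_edge = 0.2)
  left <- s2$x < 3
  f_left <- min(s2$F[left, ], na.rm = TRUE)
  f_right <- min(s2$F[!left, ], na.rm = TRUE)
  expect_equal(f_right - f_left, kT * log(19), tolerance = 0.25)
  ## degenerate surface warns
  expect_warning(projection_surface(rep(1, 10), rep(1, 10)), "single bin")
})

test_that("mode sets serialize and read back", {
  set.seed(221)
  mean_xyz <- test_mean_structure(10)
  V <- matrix(rnorm(60), 30, 2)
  ge <- gen_mode_ensemble(mean_xyz, V, c(2, 1), 300, rigid_motions = FALSE,
                          seed = 221)
  ms <- essential_modes(iterative_superposition(ge$coords))
  path <- file.path(tempdir(), "modes")
  write_mode_set(ms, path)
  ms2 <- read_mode_set(path)
  expect_equal(ms2$values, ms$values, tolerance = 1e-12)
  expect_equal(ms2$vectors, ms$vectors, tolerance = 1e-10)
  expect_equal(ms2$mean, ms$mean, tolerance = 1e-12)
})
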