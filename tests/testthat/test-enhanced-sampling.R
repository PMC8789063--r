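test_that("the projection colvar satisfies its defining identities", {
  set.seed(291)
  N <- 20
  ref <- test_mean_structure(N)
  nu <- rnorm(3 * N); nu <- nu / sqrt(sum(nu^2))
  cv <- colvar_definition(ref, nu)
  ## frame == reference -> 0
  expect_equal(eval_colvar(ref, cv), 0, tolerance = 1e-10)
  ## frame == reference + a nu -> a (nu has no net translation component
  ## removed here, so project after centering: use a centered nu)
  nu_c <- nu - rep(colMeans(matrix(nu, ncol = 3, byrow = TRUE)), N)
  ## keep nu_c orthogonal to rigid rotations of ref as well, so the optimal
  ## rotation stays the identity
  Rb <- rigid_body_basis(ref)
  nu_c <- nu_c - Rb %*% (t(Rb) %*% nu_c)
  nu_c <- as.numeric(nu_c / sqrt(sum(nu_c^2)))
  cv_c <- colvar_definition(ref, nu_c)
  disp <- matrix(nu_c, ncol = 3, byrow = TRUE)
  expect_equal(eval_colvar(ref + 1.7 * disp, cv_c), 1.7, tolerance = 1e-6)
  ## rigid motion of the frame evaluates to 0
  R <- hjdyn:::rot_about(rnorm(3), runif(1, 0, 2 * pi))
  moved <- hjdyn:::apply_rigid(ref, R, rnorm(3, sd = 4))
  expect_equal(eval_colvar(moved, cv), 0, tolerance = 1e-8)
  ## invariance: common rigid motion of a displaced frame
  frame <- ref + 0.8 * disp
  moved2 <- hjdyn:::apply_rigid(frame, R, c(3, -2, 1))
  expect_equal(eval_colvar(moved2, cv_c), eval_colvar(frame, cv_c),
               tolerance = 1e-8)
  ## mismatched atom count errors
  expect_error(eval_colvar(ref[-1, ], cv), "atoms")
})

test_that("a constant mean force integrates to a linear PMF", {
  w <- window_force_data(seq(0.1, 1.9, by = 0.2), rep(-2, 10))
  pmf <- integrate_pmf(w)
  p <- pmf$profile
  fit <- stats::lm(A ~ xi, data = p)
  expect_equal(unname(coef(fit)[2]), 2, tolerance = 1e-10)
  expect_equal(min(p$A), 0)
})

test_that("harmonic forces recover the curvature within 2 percent", {
  kappa <- 0.8
  wins <- gen_abf_forces(function(x) kappa * x, sigma = 0, seed = 301)
  pmf <- integrate_pmf(wins)
  p <- pmf$profile
  fit <- stats::lm(A ~ I(xi^2) + xi, data = p)
  expect_equal(2 * unname(coef(fit)[["I(xi^2)"]]), kappa, tolerance = 0.02)
})

test_that("stitching with artificial offsets matches the single window", {
  kappa <- 0.5
  dA <- function(x) kappa * x
  single <- gen_abf_forces(dA, windows = list(c(-5, 10)), n_bins = 90,
                           sigma = 0, seed = 311)
  multi <- gen_abf_forces(dA, n_bins = 15, sigma = 0, seed = 311)
  pmf_s <- integrate_pmf(single)
  pmf_m <- integrate_pmf(multi)
  ## compare on the multi-window grid against the analytic PMF (gauged)
  ref <- function(x) kappa / 2 * x^2
  for (pmf in list(pmf_s, pmf_m)) {
    p <- pmf$profile
    expect_lt(max(abs(p$A - (ref(p$xi) - min(ref(p$xi))))), 0.02)
  }
  ## internal consistency of the stitch on shared grid points
  shared <- intersect(round(pmf_s$profile$xi, 9), round(pmf_m$profile$xi, 9))
  if (length(shared) > 2) {
    as <- pmf_s$profile$A[match(shared, round(pmf_s$profile$xi, 9))]
    am <- pmf_m$profile$A[match(shared, round(pmf_m$profile$xi, 9))]
    expect_lt(max(abs(as - am)), 1e-6)
  }
})

test_that("disconnected window coverage is a named error", {
  w1 <- window_force_data(seq(-4.9, -1.1, length.out = 10), rep(0, 10))
  w2 <- window_force_data(seq(2.1, 5.9, length.out = 10), rep(0, 10))
  expect_error(integrate_pmf(list(w1, w2)), "gap")
})

test_that("empty bins are interpolated with a flag", {
  mf <- rep(-1, 10); mf[5] <- NA
  w <- window_force_data(seq(0.05, 0.95, by = 0.1), mf)
  expect_warning(pmf <- integrate_pmf(w), "interpolated")
  expect_false(anyNA(pmf$profile$A))
})

test_that("the ABF error bound follows the printed formula", {
  ## uncorrelated limit
  expect_equal(abf_error(interval = c(0, 2), sigma = 3, K = 100, tau = 0),
               2 * 3 / 10)
  ## quadrupling K halves the bound
  b1 <- abf_error(interval = c(-1, 3), sigma = 2, K = 400, tau = 1.5)
  b4 <- abf_error(interval = c(-1, 3), sigma = 2, K = 1600, tau = 1.5)
  expect_equal(b1 / b4, 2)
  expect_error(abf_error(interval = c(0, 1), sigma = 1, K = 0, tau = 0),
               "positive")
})

test_that("the error bound is monotone in its arguments", {
  set.seed(321)
  for (i in 1:50) {
    iv <- sort(runif(2, -5, 10)); s <- runif(1, 0.1, 3)
    K <- sample(100:10000, 1); tau <- runif(1, 0, 10)
    b <- abf_error(interval = iv, sigma = s, K = K, tau = tau)
    expect_gt(abf_error(interval = iv, sigma = s * 1.5, K = K, tau = tau), b)
    expect_gt(abf_error(interval = iv, sigma = s, K = K, tau = tau + 1), b)
    expect_lt(abf_error(interval = iv, sigma = s, K = K * 2, tau = tau), b)
    expect_gt(abf_error(interval = iv + c(-1, 1), sigma = s, K = K,
                        tau = tau), b)
  }
})

test_that("the bound upper-bounds the SD of repeated PMF estimates", {
  ## 200 replicates of noisy harmonic force bins in one window; the SD over
  ## replicates of the endpoint free-energy difference must not exceed the
  ## bound for the corresponding interval (checked over nested intervals)
  set.seed(331)
  kappa <- 1; sigma <- 0.6; K_bin <- 400; tau <- 1
  reps <- 200
  est <- replicate(reps, {
    w <- gen_abf_forces(function(x) kappa * x, windows = list(c(-2, 2)),
                        n_bins = 15, sigma = sigma, tau = tau, K_bin = K_bin,
                        seed = sample.int(1e6, 1))[[1]]
    pmf <- integrate_pmf(w)$profile
    pmf$A - pmf$A[1]    # gauge at the first grid point
  })
  w0 <- gen_abf_forces(function(x) kappa * x, windows = list(c(-2, 2)),
                       n_bins = 15, sigma = sigma, tau = tau, K_bin = K_bin,
                       seed = 1)[[1]]
  centers <- sort(w0$bin_center)
  half <- diff(centers[1:2]) / 2
  ok <- logical(0)
  for (j in 2:15) {
    sd_emp <- stats::sd(est[j, ])
    ## interval = bin-edge span of the j bins entering the estimate
    bound <- abf_error(interval = c(centers[1] - half, centers[j] + half),
                       sigma = sigma, K = j * K_bin, tau = tau)
    ok <- c(ok, sd_emp <= bound)
  }
  expect_gte(mean(ok), 0.9)
})

test_that("blocking analysis distinguishes white noise from AR(1)", {
  set.seed(341)
  wn <- rnorm(2^14)
  bw <- blocking_analysis(wn, dt = 1)
  expect_lt(bw$tau_c, 0.5)
  ## AR(1) phi = 0.9: integrated autocorrelation time phi/(1-phi) = 9
  phi <- 0.9
  x <- as.numeric(stats::arima.sim(list(ar = phi), 1e5))
  b <- blocking_analysis(x, dt = 1)
  expect_equal(b$tau_c, phi / (1 - phi), tolerance = 0.25)
  expect_error(blocking_analysis(rnorm(32)), "64")
})

test_that("the minimum-sampling rule flags short bins", {
  ## dt = 10 ps per force sample; bins below 5 ns (500 samples) are flagged
  w <- window_force_data(1:5, rep(0, 5),
                         n_samples = c(100, 499, 500, 600, 2000))
  flags <- undersampled_bins(w, dt = 0.01, min_time = 5)
  expect_identical(flags, c(TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("the default window layout covers [-5, 10] with overlaps", {
  lay <- abf_window_layout()
  expect_length(lay, 5)
  expect_identical(nrow(lay[[1]]), 15L)
  all_centers <- unlist(lapply(lay, function(d) d$bin_center))
  expect_lt(min(all_centers), -4.5)
  expect_gt(max(all_centers), 9.5)
  ## consecutive windows overlap
  ivs <- t(vapply(lay, function(d) range(d$bin_center), numeric(2)))
  ivs <- ivs[order(ivs[, 1]), ]
  for (i in 1:4) expect_lt(ivs[i + 1, 1], ivs[i, 2])
})
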