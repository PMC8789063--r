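test_that("base-frame fitting recovers identity and rigid motions exactly", {
  for (b in c("A", "C", "G", "T")) {
    std <- hjdyn:::.std_base_rings[[b]]
    f0 <- fit_base_frame(std, b)
    expect_lt(max(abs(f0$R - diag(3))), 1e-10)
    expect_lt(max(abs(f0$origin)), 1e-10)
    expect_lt(attr(f0, "rmsd"), 1e-10)

    Q <- hjdyn:::rot_about(c(1, 2, -0.5), 0.9)
    tr <- c(4, -7, 2.5)
    moved <- sweep(std %*% t(Q), 2, -tr)
    f1 <- fit_base_frame(moved, b)
    expect_lt(max(abs(f1$R - Q)), 1e-9)
    expect_lt(max(abs(f1$origin - tr)), 1e-9)
  }
})

test_that("base-frame fitting under coordinate noise stays within 1 degree", {
  ## Monte-Carlo: isotropic sigma = 0.05 A on the ring recovers the rotation
  ## to about a degree on average (the ring spans only ~2.5 A, so individual
  ## draws fluctuate; the tolerance is on the MC mean)
  set.seed(21)
  angs <- numeric(300)
  for (i in 1:300) {
    Q <- hjdyn:::rot_about(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
    std <- hjdyn:::.std_base_rings[["G"]]
    noisy <- std %*% t(Q) + matrix(rnorm(length(std), 0, 0.05),
                                   nrow(std), 3)
    rownames(noisy) <- rownames(std)
    fh <- fit_base_frame(noisy, "G")
    angs[i] <- hjdyn:::rot_angle(t(Q) %*% fh$R) * 180 / pi
  }
  ## MC-derived tolerance: the expected angular error is sigma over the ring
  ## gyration lever (~0.05 / 1.2 rad per axis, three axes), about 1.2 degrees
  expect_lt(mean(angs), 1.3)
  expect_lt(stats::quantile(angs, 0.99), 4)
})

test_that("missing ring atoms and degenerate rings are structured errors", {
  std <- hjdyn:::.std_base_rings[["A"]]
  expect_error(fit_base_frame(std[-1, ], "A"), "N9")
  collinear <- matrix(rep(1:6, each = 3) * c(1, 0, 0), ncol = 3, byrow = TRUE)
  rownames(collinear) <- rownames(hjdyn:::.std_base_rings[["C"]])
  expect_error(fit_base_frame(collinear, "C"), "degenerate|collinear")
})

test_that("pair frame is the geodesic mid-frame", {
  ## idempotence
  f <- random_frame()
  pf <- pair_frame(f, f)
  expect_lt(max(abs(pf$R - f$R)), 1e-12)
  ## 10-degree rotation about a shared axis -> 5-degree mid-frame
  ax <- c(0.3, -1, 0.2)
  f2 <- orth_frame(hjdyn:::rot_about(ax, 10 * pi / 180) %*% f$R, f$origin)
  pf2 <- pair_frame(f, f2)
  half <- hjdyn:::rot_about(ax, 5 * pi / 180) %*% f$R
  expect_lt(max(abs(pf2$R - half)), 1e-10)
  ## equidistance for random pairs
  set.seed(31)
  for (i in 1:50) {
    a <- random_frame()
    b <- orth_frame(hjdyn:::rot_about(rnorm(3), runif(1, 0, 1.4)) %*% a$R,
                    a$origin + rnorm(3))
    m <- suppressWarnings(pair_frame(a, b))
    da <- hjdyn:::rot_angle(t(m$R) %*% a$R)
    db <- hjdyn:::rot_angle(t(m$R) %*% b$R)
    expect_lt(abs(da - db), 1e-9)
    expect_equal(m$origin, (a$origin + b$origin) / 2)
  }
})

test_that("broken pairs (z-axes beyond 90 degrees) warn but compute", {
  f <- orth_frame()
  g <- orth_frame(hjdyn:::rot_about(c(1, 0, 0), 2.5))  # z rotated ~143 deg
  expect_warning(pair_frame(f, g), "90")
})

test_that("canonical steps give their textbook parameters", {
  ## pure rise
  f1 <- orth_frame()
  f2 <- orth_frame(diag(3), c(0, 0, 3.4))
  expect_equal(unname(step_parameters(f1, f2)), c(0, 0, 3.4, 0, 0, 0),
               tolerance = 1e-12)
  ## ideal B-step: 36 degree twist + 3.4 A rise
  f3 <- orth_frame(hjdyn:::rot_about(c(0, 0, 1), 36 * pi / 180), c(0, 0, 3.4))
  p <- step_parameters(f1, f3)
  expect_equal(unname(p), c(0, 0, 3.4, 0, 0, 36), tolerance = 1e-10)
})

test_that("step parameters and rebuild are exact inverses", {
  set.seed(41)
  worst <- 0
  for (i in 1:500) {
    F1 <- random_frame()
    p <- random_params()
    F2 <- rebuild_step(F1, p)
    p2 <- step_parameters(F1, F2)
    worst <- max(worst, max(abs(p2 - p)))
  }
  expect_lt(worst, 1e-8)
})

test_that("step parameters are invariant under global rigid motions", {
  set.seed(51)
  for (i in 1:50) {
    F1 <- random_frame()
    F2 <- rebuild_step(F1, random_params())
    p <- step_parameters(F1, F2)
    R <- hjdyn:::rot_about(rnorm(3), runif(1, 0, 2 * pi))
    t0 <- rnorm(3, sd = 10)
    G1 <- orth_frame(R %*% F1$R, as.numeric(R %*% F1$origin) + t0)
    G2 <- orth_frame(R %*% F2$R, as.numeric(R %*% F2$origin) + t0)
    expect_lt(max(abs(step_parameters(G1, G2) - p)), 1e-10)
  }
})

test_that("reading from the complementary strand negates shift and tilt only", {
  set.seed(61)
  for (i in 1:50) {
    F1 <- random_frame()
    p <- random_params()
    F2 <- rebuild_step(F1, p)
    fwd <- step_parameters(F1, F2)
    rev <- step_parameters(flip_frame(F2), flip_frame(F1))
    expect_equal(unname(rev[c("shift", "tilt")]),
                 unname(-fwd[c("shift", "tilt")]), tolerance = 1e-9)
    expect_equal(unname(rev[c("slide", "rise", "roll", "twist")]),
                 unname(fwd[c("slide", "rise", "roll", "twist")]),
                 tolerance = 1e-9)
  }
})

test_that("composing ideal B-steps builds a straight helix", {
  frames <- ideal_helix_frames(11)
  expect_equal(frames[[11]]$origin, c(0, 0, 34), tolerance = 1e-10)
  ## z axes all along the helical axis
  for (f in frames) expect_lt(max(abs(f$R[, 3] - c(0, 0, 1))), 1e-10)
})

test_that("extracted step series reproduce the generating parameters", {
  top <- j1_topology()
  gs <- gen_step_ensemble(top, isomer = 1, n_frames = 6, seed = 7)
  ss <- extract_step_series(gs$ensemble, top, isomer = 1)
  expect_length(ss, 18)  # 9 analyzed steps x 2 helices
  expect_setequal(names(ss), names(gs$series))
  for (nm in names(ss)) {
    expect_lt(max(abs(ss[[nm]]$values - gs$series[[nm]]$values)), 1e-5)
  }
  ## labels carry helix and step index
  lab <- ss[["J1^1_(1,5)"]]$label
  expect_identical(lab$helix, 1L)
  expect_identical(lab$step_index, 5L)
})

test_that("frame order reversal relabels but preserves values", {
  top <- j1_topology()
  gs <- gen_step_ensemble(top, isomer = 2, n_frames = 5, seed = 8)
  ens_rev <- gs$ensemble
  ens_rev$coords <- ens_rev$coords[5:1, , , drop = FALSE]
  fwd <- extract_step_series(gs$ensemble, top, isomer = 2)
  rev <- extract_step_series(ens_rev, top, isomer = 2)
  for (nm in names(fwd)) {
    expect_equal(rev[[nm]]$values, fwd[[nm]]$values[5:1, ],
                 ignore_attr = TRUE)
  }
})
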