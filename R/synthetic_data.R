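## Seeded generators that emulate the statistical structure the analysis
## modules assume: AR(1)-correlated Gaussian step parameters with a
## prescribed stiffness, coordinate ensembles dominated by planted collective
## modes, windowed ABF force samples from a known 1-D potential, and Poisson
## photon-count donor decays. Each generator is fully determined by its seed.

## multivariate normal draw via Cholesky (avoids an extra dependency for a
## three-line primitive)
.rmvn <- function(n, mean, Sigma) {
  L <- chol(Sigma)
  d <- length(mean)
  Z <- matrix(stats::rnorm(n * d), n, d)
  sweep(Z %*% L, 2, -mean)
}

#' Generate AR(1)-correlated step-parameter series
#'
#' Draws a stationary AR(1) sequence of 6-vectors whose stationary
#' distribution is Gaussian with the given mean and covariance
#' C = kB T F^-1 (or a covariance supplied directly):
#' x_t = mu + phi (x_{t-1} - mu) + sqrt(1 - phi^2) L eps_t, chol(C) = L^T L.
#'
#' @param n_frames number of frames.
#' @param mean length-6 mean step parameters.
#' @param stiffness 6x6 stiffness matrix F (kcal/mol units); used as
#'   C = kB T F^-1 unless `covariance` is given.
#' @param covariance 6x6 covariance; overrides `stiffness`.
#' @param phi AR(1) coefficient, |phi| < 1 (default 0).
#' @param temperature temperature (K) for the stiffness conversion.
#' @param label optional `step_label` for the series.
#' @param sampling_interval ps between frames (default 10).
#' @param seed optional integer seed (set for reproducibility).
#' @return a `step_series`.
#' @export
gen_step_series <- function(n_frames, mean = c(0, 0, 3.4, 0, 0, 36),
                            stiffness = NULL, covariance = NULL, phi = 0,
                            temperature = 298, label = NULL,
                            sampling_interval = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(phi) >= 1) stop("AR(1) coefficient must satisfy |phi| < 1")
  if (is.null(covariance)) {
    if (is.null(stiffness)) stop("give stiffness or covariance")
    covariance <- .kB_kcal * temperature * solve(stiffness)
  }
  covariance <- (covariance + t(covariance)) / 2
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("covariance must be positive definite")
  L <- chol(covariance)
  X <- matrix(0, n_frames, 6L)
  x <- as.numeric(stats::rnorm(6) %*% L)        # stationary start
  X[1, ] <- x
  s <- sqrt(1 - phi^2)
  if (n_frames > 1) for (t in 2:n_frames) {
    x <- phi * x + s * as.numeric(stats::rnorm(6) %*% L)
    X[t, ] <- x
  }
  X <- sweep(X, 2, -mean)
  if (is.null(label)) label <- step_label("d", "syn", 1L, 1L, 1L)
  step_series(label, X, sampling_interval)
}

#' Generate a junction step ensemble and rebuilt coordinates
#'
#' For each analyzed step of both helices of one isomer, draws AR(1) Gaussian
#' step parameters (shared per-step covariance unless a list is given) and
#' rebuilds full base-pair frames and idealized ring-atom coordinates per
#' frame via [rebuild_step()], producing a `structure_ensemble` that
#' [extract_step_series()] can consume.
#'
#' @param topology a `junction_topology`.
#' @param isomer 1 or 2.
#' @param n_frames frames to generate.
#' @param mean,covariance per-step mean (6) and covariance (6x6), or lists
#'   keyed by step index.
#' @param phi AR(1) coefficient.
#' @param sampling_interval ps between frames.
#' @param seed integer seed.
#' @return list with `ensemble` (a `structure_ensemble`) and `series` (the
#'   generating `step_series` per analyzed step of each helix).
#' @export
gen_step_ensemble <- function(topology, isomer, n_frames,
                              mean = c(0, 0, 3.4, 0, 0, 36),
                              covariance = diag(c(0.3, 0.3, 0.1, 9, 16, 25)),
                              phi = 0, sampling_interval = 10, seed = 1L) {
  set.seed(seed)
  L <- 2L * topology$arm_length
  n_steps <- L - 1L
  get6 <- function(obj, k, d) {
    if (is.list(obj)) { if (!is.null(obj[[k]])) obj[[k]] else d } else obj
  }
  series <- list()
  ## draw step parameters for every physical step of both helices
  helix_params <- list()
  for (hx in 1:2) {
    P <- array(0, c(n_frames, n_steps, 6L))
    for (k in seq_len(n_steps)) {
      ss <- gen_step_series(n_frames, mean = get6(mean, k, c(0, 0, 3.4, 0, 0, 36)),
                            covariance = get6(covariance, k,
                                              diag(c(0.3, 0.3, 0.1, 9, 16, 25))),
                            phi = phi, sampling_interval = sampling_interval)
      P[, k, ] <- ss$values
    }
    helix_params[[hx]] <- P
  }
  ## rebuild coordinates: for each frame, walk pair frames down each helix and
  ## place idealized ring atoms of reading and complementary bases
  ana <- analyzed_steps(L, 0L)   # all steps; extraction handles exclusion
  atoms <- NULL
  coords_list <- NULL
  ## atom bookkeeping: reading + complementary base ring atoms per bp per helix
  bp_info <- list()
  for (hx in 1:2) {
    hs <- helix_strands(topology, isomer, hx)
    for (pos in 1:L) {
      q <- pair_of(topology, hs$reading, pos)
      base_r <- substr(topology$strands[[hs$reading]], pos, pos)
      base_c <- substr(topology$strands[[q$strand]], q$pos, q$pos)
      bp_info[[length(bp_info) + 1L]] <- list(
        helix = hx, pos = pos,
        read_strand = hs$reading, read_pos = pos, base_r = base_r,
        comp_strand = q$strand, comp_pos = q$pos, base_c = base_c)
    }
  }
  ## assemble atom table once
  atom_rows <- list()
  for (b in bp_info) {
    for (nm in ring_atoms(b$base_r)) {
      atom_rows[[length(atom_rows) + 1L]] <- data.frame(
        strand = b$read_strand, pos = b$read_pos, base = b$base_r, atom = nm,
        stringsAsFactors = FALSE)
    }
    for (nm in ring_atoms(b$base_c)) {
      atom_rows[[length(atom_rows) + 1L]] <- data.frame(
        strand = b$comp_strand, pos = b$comp_pos, base = b$base_c, atom = nm,
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, atom_rows)
  ## drop duplicated residues (each base appears in exactly one helix per
  ## isomer, so no duplicates are expected; keep a guard)
  key <- paste(atoms$strand, atoms$pos, atoms$atom)
  atoms <- atoms[!duplicated(key), ]
  n_atoms <- nrow(atoms)
  coords <- array(NA_real_, c(n_frames, n_atoms, 3L))
  row_of <- function(strand, pos, atom_names) {
    idx <- which(atoms$strand == strand & atoms$pos == pos)
    idx[match(atom_names, atoms$atom[idx])]
  }
  for (f in seq_len(n_frames)) {
    for (hx in 1:2) {
      start <- orth_frame(diag(3), c(30 * (hx - 1), 0, 0))
      frames_bp <- vector("list", L)
      frames_bp[[1]] <- start
      for (k in seq_len(n_steps)) {
        p <- helix_params[[hx]][f, k, ]
        names(p) <- c("shift", "slide", "rise", "tilt", "roll", "twist")
        frames_bp[[k + 1L]] <- rebuild_step(frames_bp[[k]], p)
      }
      for (pos in 1:L) {
        b <- bp_info[[(hx - 1L) * L + pos]]
        fr <- frames_bp[[pos]]
        ## reading base in pair frame; complementary base flipped about x
        std_r <- .std_base_rings[[b$base_r]]
        xyz_r <- sweep(std_r %*% t(fr$R), 2, -fr$origin)
        rows <- row_of(b$read_strand, b$read_pos, rownames(std_r))
        coords[f, rows, ] <- xyz_r
        std_c <- .std_base_rings[[b$base_c]]
        flipx <- diag(c(1, -1, -1))
        Rc <- fr$R %*% flipx
        xyz_c <- sweep(std_c %*% t(Rc), 2, -fr$origin)
        rows <- row_of(b$comp_strand, b$comp_pos, rownames(std_c))
        coords[f, rows, ] <- xyz_c
      }
    }
  }
  ## generating series restricted to analyzed steps for convenience
  steps <- analyzed_steps(L, 3L)
  for (hx in 1:2) {
    for (k in seq_len(nrow(steps))) {
      lab <- step_label(topology$topology_letter, topology$core, isomer, hx,
                        steps$step_index[k])
      v <- helix_params[[hx]][, steps$physical_step[k], , drop = FALSE]
      dim(v) <- c(n_frames, 6L)
      series[[render_step_label(lab)]] <-
        step_series(lab, v, sampling_interval)
    }
  }
  ensemble <- structure(list(atoms = atoms, coords = coords,
                             times = (seq_len(n_frames) - 1) * sampling_interval,
                             provenance = list(seed = seed, phi = phi,
                                               generator = "gen_step_ensemble")),
                        class = "structure_ensemble")
  list(ensemble = ensemble, series = series)
}

#' Generate a coordinate ensemble with planted collective modes
#'
#' mean structure + sum_k a_k(t) nu_k + isotropic noise; the amplitudes a_k
#' are AR(1) Gaussians with specified stationary variances. Optionally applies
#' a random rigid motion per frame so superposition is exercised.
#'
#' @param mean_xyz n_atoms x 3 mean structure.
#' @param mode_vectors 3N x k matrix of planted directions (orthonormalized
#'   internally via QR).
#' @param variances stationary variance per mode (A^2).
#' @param n_frames frames to generate.
#' @param noise_sd isotropic per-coordinate noise SD (A, default 0.1).
#' @param phi AR(1) coefficient for the amplitudes (default 0).
#' @param rigid_motions apply a random rotation + translation per frame
#'   (default TRUE).
#' @param seed integer seed.
#' @return list: `coords` (n_frames x n_atoms x 3), `amplitudes` (n x k),
#'   `modes` (orthonormalized 3N x k), `mean` (3N vector, atom-major).
#' @export
gen_mode_ensemble <- function(mean_xyz, mode_vectors, variances,
                              n_frames, noise_sd = 0.1, phi = 0,
                              rigid_motions = TRUE, seed = 1L) {
  set.seed(seed)
  mean_xyz <- as.matrix(mean_xyz)
  N <- nrow(mean_xyz)
  V <- as.matrix(mode_vectors)
  stopifnot(nrow(V) == 3L * N, length(variances) == ncol(V))
  if (ncol(V) > 3L * N - 6L) stop("more modes than internal degrees of freedom")
  ## planted modes must be internal motions: project out the rigid-body
  ## subspace at the mean structure (3 translations + 3 rotations), else the
  ## superposition step would remove part of the planted variance
  Rb <- rigid_body_basis(mean_xyz)
  V <- V - Rb %*% (t(Rb) %*% V)
  V <- qr.Q(qr(V))           # orthonormalize
  k <- ncol(V)
  mu <- as.numeric(t(mean_xyz))
  A <- matrix(0, n_frames, k)
  a <- stats::rnorm(k, 0, sqrt(variances))
  A[1, ] <- a
  s <- sqrt(1 - phi^2)
  if (n_frames > 1) for (t in 2:n_frames) {
    a <- phi * a + s * stats::rnorm(k, 0, sqrt(variances))
    A[t, ] <- a
  }
  coords <- array(0, c(n_frames, N, 3L))
  for (f in seq_len(n_frames)) {
    x <- mu + as.numeric(V %*% A[f, ]) +
      stats::rnorm(3L * N, 0, noise_sd)
    xyz <- .vec_to_xyz(x)
    if (rigid_motions) {
      R <- rot_about(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
      t0 <- stats::rnorm(3, 0, 5)
      xyz <- apply_rigid(xyz, R, t0)
    }
    coords[f, , ] <- xyz
  }
  list(coords = coords, amplitudes = A, modes = V, mean = mu,
       provenance = list(seed = seed, phi = phi, variances = variances,
                         generator = "gen_mode_ensemble"))
}

#' Generate windowed ABF force statistics from a known potential
#'
#' Per bin, the mean force is -dA/dxi at the bin center plus Gaussian noise
#' with the sampling-distribution SD sigma sqrt(1 + 2 tau) / sqrt(K_bin)
#' (the SE of a mean of K_bin AR(1)-correlated force samples of marginal SD
#' sigma and correlation length tau).
#'
#' @param dA function: derivative of the target potential (kcal/mol/A).
#' @param windows list of c(lo, hi) intervals (default the standard layout).
#' @param n_bins bins per window (default 15).
#' @param sigma marginal force-sample SD (kcal/mol/A; 0 = exact forces).
#' @param tau force correlation length (samples).
#' @param K_bin force evaluations per bin.
#' @param seed integer seed.
#' @return list of `window_force_data`.
#' @export
gen_abf_forces <- function(dA, windows = .default_windows, n_bins = 15L,
                           sigma = 0, tau = 0, K_bin = 1000L, seed = 1L) {
  set.seed(seed)
  lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    width <- diff(w) / n_bins
    centers <- seq(w[1] + width / 2, w[2] - width / 2, length.out = n_bins)
    truth <- -vapply(centers, dA, numeric(1))
    se <- sigma * sqrt(1 + 2 * tau) / sqrt(K_bin)
    mf <- truth + stats::rnorm(n_bins, 0, se)
    window_force_data(centers, mf, force_variance = sigma^2,
                      n_samples = K_bin, tau = tau,
                      window_id = paste0("w", i))
  })
}

#' Generate a Poisson photon-count donor decay
#'
#' Evaluates [donor_decay()] on a uniform time grid, scales to the requested
#' total counts, and Poisson-samples each bin under the seed.
#'
#' @param model a `fret_model`.
#' @param total_counts expected total photon count (default 1e6).
#' @param t_max time range (ns, default 25).
#' @param n_bins number of time bins (default 250).
#' @param seed integer seed.
#' @return data frame (t, counts) with attribute `expected` (noise-free
#'   curve) and `provenance`.
#' @export
gen_decay <- function(model, total_counts = 1e6, t_max = 25, n_bins = 250L,
                      seed = 1L) {
  set.seed(seed)
  t <- seq(0, t_max, length.out = n_bins)
  I <- donor_decay(model, t)
  expected <- I * total_counts / sum(I)
  counts <- stats::rpois(n_bins, expected)
  out <- data.frame(t = t, counts = counts)
  attr(out, "expected") <- expected
  attr(out, "provenance") <- list(seed = seed, fr_iso1 = model$fr_iso1,
                                  total_counts = total_counts,
                                  generator = "gen_decay")
  out
}
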