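## Base reference frames and base-pair step helical parameters.
##
## The scheme is the CEHS / 3DNA convention: a standard-geometry base ring is
## least-squares superposed onto the observed ring atoms to give each base a
## right-handed orthonormal frame (x away from the minor-groove edge, y toward
## the complementary base, z along the helical rise); complementary-base
## frames are flipped 180 degrees about x and averaged along the rotation
## geodesic to give the base-pair frame; consecutive pair frames yield the six
## step parameters (shift, slide, rise in Angstrom; tilt, roll, twist in
## degrees) via the mid-step frame construction.

## Standard reference-frame ring coordinates (Angstrom, base plane z = 0),
## consensus standard nucleic-acid reference frame (Tsukuba convention), as
## embedded in common helical-analysis software. Rows are ring heavy atoms.
.std_base_rings <- list(
  A = rbind(
    N9 = c(-1.291, 4.498, 0), C8 = c(0.024, 4.897, 0),
    N7 = c(0.877, 3.902, 0), C5 = c(0.071, 2.771, 0),
    C6 = c(0.369, 1.398, 0), N1 = c(-0.668, 0.532, 0),
    C2 = c(-1.912, 1.023, 0), N3 = c(-2.320, 2.290, 0),
    C4 = c(-1.267, 3.124, 0)),
  G = rbind(
    N9 = c(-1.289, 4.551, 0), C8 = c(0.023, 4.962, 0),
    N7 = c(0.870, 3.969, 0), C5 = c(0.071, 2.833, 0),
    C6 = c(0.424, 1.460, 0), N1 = c(-0.700, 0.641, 0),
    C2 = c(-1.999, 1.087, 0), N3 = c(-2.342, 2.364, 0),
    C4 = c(-1.265, 3.177, 0)),
  C = rbind(
    N1 = c(-1.285, 4.542, 0), C2 = c(-1.472, 3.158, 0),
    N3 = c(-0.391, 2.344, 0), C4 = c(0.837, 2.868, 0),
    C5 = c(1.056, 4.275, 0), C6 = c(-0.023, 5.068, 0)),
  T = rbind(
    N1 = c(-1.284, 4.500, 0), C2 = c(-1.462, 3.135, 0),
    N3 = c(-0.298, 2.407, 0), C4 = c(0.994, 2.897, 0),
    C5 = c(1.106, 4.338, 0), C6 = c(-0.024, 5.057, 0))
)

#' Ring atom names of a base type
#' @param base_type one of "A", "C", "G", "T".
#' @return character vector of ring heavy-atom names.
#' @export
ring_atoms <- function(base_type) {
  if (!base_type %in% names(.std_base_rings)) {
    stop("unknown base type '", base_type, "'")
  }
  rownames(.std_base_rings[[base_type]])
}

#' Construct an orthonormal reference frame
#'
#' @param rotation 3x3 rotation matrix, columns = x, y, z axes.
#' @param origin length-3 origin (Angstrom).
#' @return object of class `orth_frame`.
#' @export
orth_frame <- function(rotation = diag(3), origin = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!is_rotation(rotation)) {
    stop("rotation must be a proper orthonormal 3x3 matrix (det +1)")
  }
  structure(list(R = rotation, origin = as.numeric(origin)),
            class = "orth_frame")
}

#' @export
print.orth_frame <- function(x, ...) {
  cat("<orth_frame> origin", sprintf("%.3f", x$origin), "\n")
  print(round(x$R, 4))
  invisible(x)
}

#' Fit the standard base frame to observed ring coordinates
#'
#' Rigid least-squares (Kabsch) superposition of the embedded standard-geometry
#' ring onto the observed ring atoms; the transformed standard frame is the
#' base frame.
#'
#' @param atom_coords matrix of observed coordinates with rownames = atom
#'   names (must contain every ring atom of the base type), columns x, y, z.
#' @param base_type "A", "C", "G" or "T".
#' @return `orth_frame` with attribute `"rmsd"`, the fit RMSD in Angstrom.
#' @export
fit_base_frame <- function(atom_coords, base_type) {
  std <- .std_base_rings[[base_type]]
  if (is.null(std)) stop("unknown base type '", base_type, "'")
  need <- rownames(std)
  have <- rownames(atom_coords)
  missing <- setdiff(need, have)
  if (length(missing)) {
    stop("missing ring atom(s) for base ", base_type, ": ",
         paste(missing, collapse = ", "))
  }
  obs <- as.matrix(atom_coords[need, , drop = FALSE])
  if (any(!is.finite(obs))) stop("non-finite ring coordinates")
  ## degenerate geometry check: observed ring must span a plane
  s <- svd(scale(obs, scale = FALSE))$d
  if (s[2] < 1e-8) stop("degenerate (collinear) ring coordinates; cannot fit")
  fit <- kabsch(std, obs)
  out <- orth_frame(fit$R, fit$t)  # standard origin is (0,0,0)
  attr(out, "rmsd") <- fit$rmsd
  out
}

#' Flip a base frame to the pairing convention
#'
#' The complementary base's frame is rotated 180 degrees about its own x-axis
#' (y and z axes negated) before averaging into a base-pair frame.
#'
#' @param frame an `orth_frame`.
#' @return flipped `orth_frame`.
#' @export
flip_frame <- function(frame) {
  R <- frame$R
  R[, 2] <- -R[, 2]
  R[, 3] <- -R[, 3]
  orth_frame(R, frame$origin)
}

#' Base-pair reference frame
#'
#' Geodesic mid-frame of the two base frames: the rotation is carried halfway
#' from `frame_a` toward `frame_b` along the rotation geodesic, and the origin
#' is the midpoint of the two origins. `frame_b` must already be flipped to
#' the pairing convention (see [flip_frame()]).
#'
#' @param frame_a,frame_b `orth_frame` objects.
#' @return `orth_frame` of the base pair.
#' @export
pair_frame <- function(frame_a, frame_b) {
  Ra <- frame_a$R; Rb <- frame_b$R
  if (sum(Ra[, 3] * Rb[, 3]) < 0) {
    warning("paired frames' z-axes differ by more than 90 degrees; ",
            "broken pair?")
  }
  D <- t(Ra) %*% Rb
  Rm <- Ra %*% rot_pow(D, 0.5)
  orth_frame(Rm, (frame_a$origin + frame_b$origin) / 2)
}

#' Six base-pair step parameters between consecutive pair frames
#'
#' Mid-step construction: both pair frames are rotated by half the bending
#' angle about the RollTilt hinge axis (z1 x z2) so their z-axes coincide;
#' twist is the angle between the rotated x-axes about the common z; the
#' bending angle is decomposed into roll (about the mid-frame y) and tilt
#' (about the mid-frame x); the origin displacement expressed in the mid-step
#' frame gives shift, slide and rise.
#'
#' @param pair_frame_1,pair_frame_2 consecutive base-pair frames, in 5'->3'
#'   order of the reading strand.
#' @return named numeric vector `shift, slide, rise` (Angstrom) and
#'   `tilt, roll, twist` (degrees, twist in (-180, 180]).
#' @export
step_parameters <- function(pair_frame_1, pair_frame_2) {
  R1 <- pair_frame_1$R; R2 <- pair_frame_2$R
  o1 <- pair_frame_1$origin; o2 <- pair_frame_2$origin
  z1 <- R1[, 3]; z2 <- R2[, 3]
  cg <- max(-1, min(1, sum(z1 * z2)))
  gamma <- acos(cg)
  if (gamma > 1e-10) {
    hinge <- c(z1[2] * z2[3] - z1[3] * z2[2],
               z1[3] * z2[1] - z1[1] * z2[3],
               z1[1] * z2[2] - z1[2] * z2[1])
    H1 <- rot_about(hinge, gamma / 2)
    H2 <- rot_about(hinge, -gamma / 2)
    R1p <- H1 %*% R1
    R2p <- H2 %*% R2
    hinge <- hinge / sqrt(sum(hinge^2))
  } else {
    hinge <- NULL
    R1p <- R1; R2p <- R2
  }
  zm <- R1p[, 3]
  x1 <- R1p[, 1]; x2 <- R2p[, 1]
  twist <- atan2(sum((.cross(x1, x2)) * zm), sum(x1 * x2))
  xm <- x1 + x2
  xm <- xm - sum(xm * zm) * zm
  xm <- xm / sqrt(sum(xm^2))
  ym <- .cross(zm, xm)
  Rm <- cbind(xm, ym, zm)
  disp <- as.numeric(t(Rm) %*% (o2 - o1))
  if (!is.null(hinge)) {
    phi <- atan2(sum(.cross(hinge, ym) * zm), sum(hinge * ym))
    roll <- gamma * cos(phi)
    tilt <- gamma * sin(phi)
  } else {
    roll <- 0; tilt <- 0
  }
  r2d <- 180 / pi
  c(shift = disp[1], slide = disp[2], rise = disp[3],
    tilt = tilt * r2d, roll = roll * r2d, twist = twist * r2d)
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rebuild the successor pair frame from step parameters
#'
#' Exact inverse of [step_parameters()]: returns the unique frame such that
#' `step_parameters(start, rebuild_step(start, params))` reproduces `params`.
#'
#' @param start an `orth_frame` (the 5' base-pair frame).
#' @param params named vector with `shift, slide, rise, tilt, roll, twist`
#'   (Angstrom / degrees).
#' @return `orth_frame` of the successor base pair.
#' @export
rebuild_step <- function(start, params) {
  p <- params[c("shift", "slide", "rise", "tilt", "roll", "twist")]
  if (anyNA(p)) stop("params must name shift, slide, rise, tilt, roll, twist")
  d2r <- pi / 180
  tilt <- p[["tilt"]] * d2r; roll <- p[["roll"]] * d2r
  omega <- p[["twist"]] * d2r
  gamma <- sqrt(tilt^2 + roll^2)
  phi <- if (gamma > 0) atan2(tilt, roll) else 0
  R1 <- start$R
  Rz_half <- rot_about(c(0, 0, 1), omega / 2)
  if (gamma > 0) {
    hinge_mid <- c(sin(phi), cos(phi), 0)  # hinge in mid-frame coords
    Rg  <- rot_about(hinge_mid, gamma)
    Rg2 <- rot_about(hinge_mid, gamma / 2)
  } else {
    Rg <- diag(3); Rg2 <- diag(3)
  }
  R2 <- R1 %*% Rz_half %*% Rg %*% Rz_half
  Rm <- R1 %*% Rz_half %*% Rg2
  o2 <- start$origin +
    as.numeric(Rm %*% c(p[["shift"]], p[["slide"]], p[["rise"]]))
  orth_frame(R2, o2)
}

#' Build an ideal helix of base-pair frames
#'
#' Repeatedly applies [rebuild_step()] from a start frame; useful for
#' constructing reference B-form geometries (rise 3.4 Angstrom, twist 36
#' degrees).
#'
#' @param n_bp number of base pairs.
#' @param params step parameters applied between consecutive pairs.
#' @param start starting frame (default identity at the origin).
#' @return list of `orth_frame`s, length `n_bp`.
#' @export
ideal_helix_frames <- function(n_bp,
                               params = c(shift = 0, slide = 0, rise = 3.4,
                                          tilt = 0, roll = 0, twist = 36),
                               start = orth_frame()) {
  frames <- vector("list", n_bp)
  frames[[1]] <- start
  if (n_bp > 1) for (i in 2:n_bp) {
    frames[[i]] <- rebuild_step(frames[[i - 1]], params)
  }
  frames
}

#' Extract step-parameter time series from a coordinate ensemble
#'
#' For each pseudo-duplex (helix) of the requested isomer, fits base frames to
#' the reading-strand and complementary bases, forms base-pair frames, and
#' computes the six step parameters for every analyzed step (terminal steps
#' excluded per [analyzed_steps()]) in every ensemble frame.
#'
#' @param ensemble a `structure_ensemble` (see [read_structure_ensemble()] or
#'   [gen_step_ensemble()]): list with `atoms` (data frame strand, pos, base,
#'   atom) and `coords` (n_frames x n_atoms x 3 array), optional `times` (ps).
#' @param topology a `junction_topology`.
#' @param isomer 1 or 2.
#' @param excluded_terminal_steps terminal steps dropped per arm end
#'   (default 3).
#' @param sampling_interval sampling interval in ps (default from ensemble,
#'   else 10).
#' @return named list of `step_series` objects, one per (helix, step_index),
#'   names are rendered step labels.
#' @export
extract_step_series <- function(ensemble, topology, isomer,
                                excluded_terminal_steps = 3L,
                                sampling_interval = NULL) {
  stopifnot(inherits(topology, "junction_topology"))
  atoms <- ensemble$atoms
  coords <- ensemble$coords
  n_frames <- dim(coords)[1]
  if (is.null(sampling_interval)) {
    sampling_interval <- if (!is.null(ensemble$times) &&
                             length(ensemble$times) > 1) {
      diff(ensemble$times[1:2])
    } else 10
  }
  L <- 2L * topology$arm_length
  steps <- analyzed_steps(L, excluded_terminal_steps)
  out <- list()
  for (hx in 1:2) {
    hs <- helix_strands(topology, isomer, hx)
    ## per-bp atom row indices for reading and complementary bases
    bp_rows <- lapply(1:L, function(pos) {
      q <- pair_of(topology, hs$reading, pos)
      r1 <- which(atoms$strand == hs$reading & atoms$pos == pos)
      r2 <- which(atoms$strand == q$strand & atoms$pos == q$pos)
      if (!length(r1) || !length(r2)) {
        stop("unresolvable residue: ", hs$reading, pos, " / ",
             q$strand, q$pos)
      }
      list(read = r1, comp = r2,
           base_r = atoms$base[r1[1]], base_c = atoms$base[r2[1]],
           names_r = atoms$atom[r1], names_c = atoms$atom[r2])
    })
    needed_bp <- sort(unique(c(steps$physical_step, steps$physical_step + 1L)))
    vals <- array(NA_real_, c(n_frames, nrow(steps), 6L))
    for (f in seq_len(n_frames)) {
      pframes <- vector("list", L)
      for (pos in needed_bp) {
        b <- bp_rows[[pos]]
        xyz_r <- coords[f, b$read, , drop = FALSE]
        dim(xyz_r) <- c(length(b$read), 3L)
        rownames(xyz_r) <- b$names_r
        xyz_c <- coords[f, b$comp, , drop = FALSE]
        dim(xyz_c) <- c(length(b$comp), 3L)
        rownames(xyz_c) <- b$names_c
        fr <- fit_base_frame(xyz_r, b$base_r)
        fc <- fit_base_frame(xyz_c, b$base_c)
        pframes[[pos]] <- pair_frame(fr, flip_frame(fc))
      }
      for (k in seq_len(nrow(steps))) {
        ps <- steps$physical_step[k]
        vals[f, k, ] <- step_parameters(pframes[[ps]], pframes[[ps + 1L]])
      }
    }
    for (k in seq_len(nrow(steps))) {
      lab <- step_label(topology$topology_letter, topology$core, isomer, hx,
                        steps$step_index[k],
                        max_step = max(steps$step_index))
      v <- vals[, k, , drop = FALSE]
      dim(v) <- c(n_frames, 6L)
      colnames(v) <- c("shift", "slide", "rise", "tilt", "roll", "twist")
      out[[render_step_label(lab)]] <- step_series(
        label = lab, values = v, sampling_interval = sampling_interval)
    }
  }
  out
}

#' Step-parameter time series container
#'
#' @param label a `step_label`.
#' @param values n x 6 matrix with columns shift, slide, rise, tilt, roll,
#'   twist.
#' @param sampling_interval sampling interval in ps.
#' @return object of class `step_series`.
#' @export
step_series <- function(label, values, sampling_interval = 10) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == 6L)
  colnames(values) <- c("shift", "slide", "rise", "tilt", "roll", "twist")
  structure(list(label = label, values = values,
                 sampling_interval = sampling_interval,
                 times = (seq_len(nrow(values)) - 1) * sampling_interval),
            class = "step_series")
}

#' @export
print.step_series <- function(x, ...) {
  cat("<step_series>", render_step_label(x$label), "-",
      nrow(x$values), "frames at", x$sampling_interval, "ps\n")
  print(round(colMeans(x$values), 3))
  invisible(x)
}
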