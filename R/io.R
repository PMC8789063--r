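## Ensemble and table I/O. PDB parsing is delegated to bio3d; everything else
## is plain columnar text so outputs are diffable.

#' Read a coordinate ensemble from multi-model PDB or a frame directory
#'
#' MODEL/ENDMDL records are honored (bio3d multi-model read); alternatively a
#' directory of per-frame PDB files (sorted by name, non-PDB files skipped
#' with a message) is accepted. Atom indexing is taken from the first frame
#' and must be consistent across frames. Chains are mapped to junction
#' strands I-IV via `chain_map` (default A-D in order).
#'
#' @param path multi-model PDB file or directory of `.pdb` files.
#' @param chain_map named character vector chain -> strand, default
#'   c(A = "I", B = "II", C = "III", D = "IV").
#' @return `structure_ensemble`: list with `atoms` (data frame strand, pos,
#'   base, atom), `coords` (n_frames x n_atoms x 3), `times` (ps, frame index
#'   based).
#' @export
read_structure_ensemble <- function(path,
                                    chain_map = c(A = "I", B = "II",
                                                  C = "III", D = "IV")) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE))
    is_pdb <- grepl("\\.pdb$", files, ignore.case = TRUE)
    if (any(!is_pdb)) {
      message("skipping non-PDB file(s): ",
              paste(basename(files[!is_pdb]), collapse = ", "))
    }
    files <- files[is_pdb]
    if (!length(files)) stop("no PDB files in ", path)
    pdbs <- lapply(files, bio3d::read.pdb, verbose = FALSE)
    first <- pdbs[[1]]
    nat <- vapply(pdbs, function(p) nrow(p$atom), integer(1))
    if (length(unique(nat)) != 1L) {
      stop("inconsistent atom counts across frames: ",
           paste(basename(files[nat != nat[1]]), collapse = ", "))
    }
    xyz <- do.call(rbind, lapply(pdbs, function(p) p$xyz))
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    first <- pdb
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  }
  at <- first$atom
  ## prefer altloc 'A' (or blank)
  keep <- at$alt %in% c("", " ", "A") | is.na(at$alt)
  at <- at[keep, ]
  strand <- chain_map[at$chain]
  if (anyNA(strand)) {
    stop("unmapped chain(s): ",
         paste(unique(at$chain[is.na(strand)]), collapse = ", "))
  }
  base <- toupper(sub("^D?", "", at$resid))
  base <- substr(base, nchar(base), nchar(base))
  atoms <- data.frame(strand = unname(strand), pos = at$resno, base = base,
                      atom = trimws(at$elety), stringsAsFactors = FALSE)
  n_frames <- nrow(xyz)
  idx <- which(keep)
  coords <- array(NA_real_, c(n_frames, length(idx), 3L))
  for (f in seq_len(n_frames)) {
    m <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    coords[f, , ] <- m[idx, , drop = FALSE]
  }
  structure(list(atoms = atoms, coords = coords,
                 times = (seq_len(n_frames) - 1) * 10),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat("<structure_ensemble>", dim(x$coords)[1], "frames,",
      nrow(x$atoms), "atoms,",
      length(unique(x$atoms$strand)), "strands\n")
  invisible(x)
}

#' Write a coordinate ensemble as a multi-model PDB
#'
#' @param ensemble a `structure_ensemble`.
#' @param path output path.
#' @param chain_map named character vector strand -> chain, default
#'   c(I = "A", II = "B", III = "C", IV = "D").
#' @return invisibly, `path`.
#' @export
write_structure_ensemble <- function(ensemble, path,
                                     chain_map = c(I = "A", II = "B",
                                                   III = "C", IV = "D")) {
  atoms <- ensemble$atoms
  chain <- chain_map[atoms$strand]
  con <- file(path, "w")
  on.exit(close(con))
  n_frames <- dim(ensemble$coords)[1]
  for (f in seq_len(n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    for (i in seq_len(nrow(atoms))) {
      xyz <- ensemble$coords[f, i, ]
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        i, atoms$atom[i], paste0("D", atoms$base[i]), chain[i],
        atoms$pos[i], xyz[1], xyz[2], xyz[3]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write step-parameter series as a 3DNA-dialect table
#'
#' One header line, then per step and frame: label, shift, slide, rise, tilt,
#' roll, twist (tab-separated, 4 decimals) plus a time column (long format).
#'
#' @param series_list named list of `step_series`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_step_table <- function(series_list, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("label", "time_ps", "shift", "slide", "rise",
                   "tilt", "roll", "twist", sep = "\t"), con)
  for (s in series_list) {
    lab <- render_step_label(s$label)
    for (i in seq_len(nrow(s$values))) {
      writeLines(paste(lab, format(s$times[i]),
                       paste(sprintf("%.4f", s$values[i, ]), collapse = "\t"),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_step_table
#' @export
read_step_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  split_tabs <- split(tab, tab$label)
  out <- lapply(split_tabs, function(d) {
    d <- d[order(d$time_ps), ]
    dt <- if (nrow(d) > 1) diff(d$time_ps[1:2]) else 10
    step_series(parse_step_label(d$label[1]),
                as.matrix(d[c("shift", "slide", "rise",
                              "tilt", "roll", "twist")]),
                sampling_interval = dt)
  })
  out
}

#' Write a PMF profile as CSV
#'
#' Columns xi, A, sd_bound, window.
#' @param pmf a `pmf_profile`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pmf_csv <- function(pmf, path) {
  utils::write.csv(pmf$profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a projection surface as CSV of bin centers and free energies
#'
#' @param surface a `projection_surface`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_surface_csv <- function(surface, path) {
  grid <- expand.grid(p1 = surface$x, p2 = surface$y)
  grid$free_energy <- as.numeric(surface$F)
  grid$count <- as.integer(surface$counts)
  utils::write.csv(grid[!is.na(grid$free_energy) | grid$count > 0, ],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
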