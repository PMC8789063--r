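## Junction nomenclature and bookkeeping.
##
## A base-pair step inside a four-way-junction pseudo-duplex is addressed as
## x n^i_(h,b): topology letter (J junction, B SXB single crossover, D SXD
## single crossover, N nicked duplex, d duplex), core-sequence identifier,
## isomer (1 or 2), helix (1 or 2) and step index b. With 16-bp arms the three
## terminal steps at each end are excluded from analysis, so b runs 1..9 over
## physical steps 4..12.

.topology_letters <- c("J", "B", "D", "N", "d")

#' Parse a junction step label
#'
#' Labels follow the grammar `topology core [^isomer] [_(helix,step)]`, e.g.
#' `"J1^1_(1,5)"`: junction topology, core sequence 1, isomer 1, helix 1,
#' analyzed step 5. Topology letters are J (full junction), B (SXB), D (SXD),
#' N (nicked duplex) and d (duplex).
#'
#' @param text label string.
#' @param max_step largest admissible step index (default 9, the 16-bp-arm
#'   convention with three terminal steps excluded at each end).
#' @return object of class `step_label` with fields `topology`, `core`,
#'   `isomer`, `helix`, `step_index` (the latter three may be `NA` when the
#'   label omits them).
#' @seealso [render_step_label()], [analyzed_steps()]
#' @export
#' @examples
#' parse_step_label("J1^1_(1,5)")
#' parse_step_label("d24^2_(2,1)")
parse_step_label <- function(text, max_step = 9L) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec(
    "^([JBDNd])([0-9A-Za-z]+?)(?:\\^([0-9]+))?(?:_\\(([0-9]+),([0-9]+)\\))?$",
    text))[[1]]
  if (length(m) == 0L) {
    stop("malformed step label '", text,
         "': expected topology letter (J/B/D/N/d), core id, optional ^isomer",
         " and optional _(helix,step)")
  }
  topology <- m[2]; core <- m[3]
  isomer <- if (nzchar(m[4])) as.integer(m[4]) else NA_integer_
  helix  <- if (nzchar(m[5])) as.integer(m[5]) else NA_integer_
  step   <- if (nzchar(m[6])) as.integer(m[6]) else NA_integer_
  if (!is.na(isomer) && !isomer %in% 1:2) {
    stop("step label '", text, "': isomer must be 1 or 2, got ", isomer)
  }
  if (!is.na(helix) && !helix %in% 1:2) {
    stop("step label '", text, "': helix must be 1 or 2, got ", helix)
  }
  if (!is.na(step) && (step < 1L || step > max_step)) {
    stop("step label '", text, "': step index ", step,
         " outside 1..", max_step)
  }
  structure(list(topology = topology, core = core, isomer = isomer,
                 helix = helix, step_index = step),
            class = "step_label")
}

#' Render a step label back to its string form
#'
#' Inverse of [parse_step_label()]: `parse_step_label(render_step_label(x))`
#' reproduces `x` for every valid label.
#'
#' @param label a `step_label` object.
#' @return label string.
#' @export
render_step_label <- function(label) {
  stopifnot(inherits(label, "step_label"))
  out <- paste0(label$topology, label$core)
  if (!is.na(label$isomer)) out <- paste0(out, "^", label$isomer)
  if (!is.na(label$helix) && !is.na(label$step_index)) {
    out <- paste0(out, "_(", label$helix, ",", label$step_index, ")")
  }
  out
}

#' @export
print.step_label <- function(x, ...) {
  cat("<step_label>", render_step_label(x), "\n")
  invisible(x)
}

#' @export
format.step_label <- function(x, ...) render_step_label(x)

#' Build a step label from components
#' @param topology one of J, B, D, N, d.
#' @param core core-sequence identifier (e.g. "1", "24").
#' @param isomer,helix integers in {1,2} or NA.
#' @param step_index integer step index or NA.
#' @param max_step largest admissible step index.
#' @return `step_label` object.
#' @export
step_label <- function(topology, core, isomer = NA_integer_,
                       helix = NA_integer_, step_index = NA_integer_,
                       max_step = 9L) {
  if (!topology %in% .topology_letters) {
    stop("unknown topology letter '", topology, "'")
  }
  lab <- structure(list(topology = topology, core = as.character(core),
                        isomer = as.integer(isomer), helix = as.integer(helix),
                        step_index = as.integer(step_index)),
                   class = "step_label")
  parse_step_label(render_step_label(lab), max_step = max_step)
}

.revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

#' Load or construct a four-way-junction topology
#'
#' A junction topology holds the four strand sequences (5'->3', Roman-numbered
#' I-IV), the Watson-Crick pairing map of the four arms, and the helix/strand
#' assignment per stacked isomer: helix 1 contains strand I (isomer 1) or
#' strand II (isomer 2); helix 2 contains strand III (isomer 1) or strand IV
#' (isomer 2). The arm pairing convention is: strand I positions 1..L/2 pair
#' strand IV positions L/2+1..L, strand I L/2+1..L pair strand II 1..L/2,
#' strand II L/2+1..L pair strand III 1..L/2, strand III L/2+1..L pair strand
#' IV 1..L/2, each arm antiparallel.
#'
#' @param path path to a topology JSON file with fields `core` (identifier),
#'   `strands` (named list I..IV of 5'->3' sequences), and optionally `nicks`
#'   and `crossovers`.
#' @return object of class `junction_topology`.
#' @export
read_topology <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  junction_topology(strands = unlist(cfg$strands), core = cfg$core,
                    nicks = cfg$nicks, crossovers = cfg$crossovers)
}

#' @rdname read_topology
#' @param strands named character vector of strand sequences `I`..`IV`.
#' @param core core-sequence identifier.
#' @param nicks optional data frame (strand, after_position) of backbone nicks.
#' @param crossovers optional character vector naming the crossing strands.
#' @param allow_mismatch logical; if FALSE (default) any non-Watson-Crick
#'   pair in the arm map is an error.
#' @export
junction_topology <- function(strands, core = "1", nicks = NULL,
                              crossovers = NULL, allow_mismatch = FALSE) {
  need <- c("I", "II", "III", "IV")
  if (!all(need %in% names(strands))) {
    stop("strands must be named I, II, III, IV")
  }
  strands <- toupper(unlist(strands)[need])
  L <- unique(nchar(strands))
  if (length(L) != 1L) stop("all four strands must have equal length")
  if (L %% 2L != 0L) stop("strand length must be even (two arms per strand)")
  h <- L %/% 2L

  ## pairing map: rows (strand_a, pos_a, strand_b, pos_b), antiparallel arms
  arm <- function(sa, ra, sb, rb) {
    data.frame(strand_a = sa, pos_a = ra, strand_b = sb, pos_b = rev(rb),
               stringsAsFactors = FALSE)
  }
  pairing <- rbind(
    arm("I", 1:h, "IV", (h + 1):L),
    arm("I", (h + 1):L, "II", 1:h),
    arm("II", (h + 1):L, "III", 1:h),
    arm("III", (h + 1):L, "IV", 1:h))

  ## Watson-Crick validation
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ok <- mapply(function(sa, pa, sb, pb) {
    ba <- substr(strands[[sa]], pa, pa)
    bb <- substr(strands[[sb]], pb, pb)
    identical(unname(comp[ba]), bb)
  }, pairing$strand_a, pairing$pos_a, pairing$strand_b, pairing$pos_b)
  if (!all(ok) && !allow_mismatch) {
    bad <- pairing[!ok, , drop = FALSE]
    stop("non-Watson-Crick pair(s) in arm map, e.g. ",
         bad$strand_a[1], bad$pos_a[1], " with ", bad$strand_b[1], bad$pos_b[1])
  }

  structure(list(core = as.character(core), strands = strands,
                 arm_length = h, pairing = pairing,
                 nicks = nicks, crossovers = crossovers,
                 topology_letter = "J"),
            class = "junction_topology")
}

#' @export
print.junction_topology <- function(x, ...) {
  cat("<junction_topology> core", x$core, "-",
      x$topology_letter, "topology,", 2L * x$arm_length, "nt strands\n")
  for (s in names(x$strands)) cat(sprintf("  %-3s 5'-%s-3'\n", s, x$strands[[s]]))
  if (!is.null(x$nicks) && NROW(x$nicks)) {
    cat("  nicks:", paste0(x$nicks$strand, ":", x$nicks$after_position,
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reading and complementary strands of a pseudo-duplex
#'
#' For a stacked isomer, each pseudo-duplex (helix) has one continuous reading
#' strand that defines the 5'->3' step order, and two complementary half
#' strands. Helix 1 reads strand I in isomer 1 and strand II in isomer 2;
#' helix 2 reads strand III in isomer 1 and strand IV in isomer 2.
#'
#' @param topology a `junction_topology`.
#' @param isomer,helix integers in {1,2}.
#' @return list with `reading` (strand id), `complement` (character vector of
#'   strand ids contributing the complementary halves, in the order they face
#'   the reading strand 5'->3'), and `sequence` of the reading strand.
#' @export
helix_strands <- function(topology, isomer, helix) {
  stopifnot(inherits(topology, "junction_topology"))
  if (!isomer %in% 1:2) stop("isomer must be 1 or 2, got ", isomer)
  if (!helix %in% 1:2) stop("helix must be 1 or 2, got ", helix)
  reading <- rbind(c("I", "III"), c("II", "IV"))[isomer, helix]
  p <- topology$pairing
  ## complements of the reading strand's positions, in reading order
  idx_a <- p$strand_a == reading
  idx_b <- p$strand_b == reading
  partners <- character(2L * topology$arm_length)
  partners[p$pos_a[idx_a]] <- p$strand_b[idx_a]
  partners[p$pos_b[idx_b]] <- p$strand_a[idx_b]
  list(reading = reading, complement = unique(partners),
       sequence = topology$strands[[reading]])
}

#' Pairing partner of one base position
#'
#' @param topology a `junction_topology`.
#' @param strand strand id ("I".."IV").
#' @param pos 1-based position along the strand, 5'->3'.
#' @return list(strand, pos) of the Watson-Crick partner.
#' @export
pair_of <- function(topology, strand, pos) {
  p <- topology$pairing
  i <- which(p$strand_a == strand & p$pos_a == pos)
  if (length(i)) return(list(strand = p$strand_b[i], pos = p$pos_b[i]))
  i <- which(p$strand_b == strand & p$pos_b == pos)
  if (length(i)) return(list(strand = p$strand_a[i], pos = p$pos_a[i]))
  stop("position ", strand, pos, " is unpaired")
}

#' Analyzed base-pair steps of a pseudo-duplex arm
#'
#' The terminal steps at both ends of each helical arm are excluded from
#' helical-parameter analysis (fraying); the remaining physical steps are
#' re-indexed from 1. For a 16-bp pseudo-duplex with the default exclusion of
#' three steps per end, the analyzed steps are physical steps 4..12, indexed
#' 1..9.
#'
#' @param arm_length_bp number of base pairs in the pseudo-duplex.
#' @param excluded_terminal_steps steps dropped at each end (default 3).
#' @return data frame with columns `physical_step` and `step_index`.
#' @export
#' @examples
#' analyzed_steps(16)      # physical steps 4..12 -> indices 1..9
analyzed_steps <- function(arm_length_bp, excluded_terminal_steps = 3L) {
  arm_length_bp <- as.integer(arm_length_bp)
  k <- as.integer(excluded_terminal_steps)
  if (k < 0L) stop("excluded_terminal_steps must be >= 0")
  if (arm_length_bp < 2L * k + 2L) {
    stop("arm of ", arm_length_bp, " bp too short to exclude ", k,
         " terminal steps at each end")
  }
  n_steps <- arm_length_bp - 1L
  phys <- seq.int(k + 1L, n_steps - k)
  data.frame(physical_step = phys, step_index = seq_along(phys))
}

#' Topological variants of a junction
#'
#' Derives the nicked-duplex, single-crossover (SXB/SXD) and duplex variants
#' from a full junction topology by editing backbone connectivity, mirroring
#' how such constructs are built from the junction structure. For a given
#' isomer, `nicked_duplex` keeps one pseudo-duplex and breaks the backbone of
#' the complementary strands at the crossover point; `duplex` is the same
#' without the break; `single_crossover` keeps the full junction but marks
#' only one crossing strand intact (side "B" = left crossing strand, side "D"
#' = right, an explicit flag rather than a geometric inference).
#'
#' @param topology a `junction_topology`.
#' @param isomer isomer (1 or 2) the variant is derived from.
#' @param helix for duplex variants, which pseudo-duplex to keep.
#' @return a `junction_topology` with an updated topology letter and nick /
#'   crossover bookkeeping.
#' @export
nicked_duplex <- function(topology, isomer, helix = 1L) {
  hs <- helix_strands(topology, isomer, helix)
  h <- topology$arm_length
  nicks <- do.call(rbind, lapply(hs$complement, function(s) {
    data.frame(strand = s, after_position = h, stringsAsFactors = FALSE)
  }))
  out <- topology
  out$topology_letter <- "N"
  out$nicks <- nicks
  out$kept_helix <- helix
  out$isomer <- isomer
  out
}

#' @rdname nicked_duplex
#' @export
duplex_variant <- function(topology, isomer, helix = 1L) {
  out <- nicked_duplex(topology, isomer, helix)
  out$topology_letter <- "d"
  out$nicks <- NULL
  out
}

#' @rdname nicked_duplex
#' @param side "B" (left crossing strand kept) or "D" (right kept).
#' @export
single_crossover <- function(topology, isomer, side = c("B", "D")) {
  side <- match.arg(side)
  ## crossing strands: II and IV in isomer 1; I and III in isomer 2.
  ## Side convention: the B variant of isomer 1 keeps strand II crossing and
  ## the D variant of isomer 2 keeps strand I crossing.
  crossing <- if (isomer == 1L) c(B = "II", D = "IV") else c(B = "III", D = "I")
  kept <- unname(crossing[side])
  broken <- setdiff(crossing, kept)
  out <- topology
  out$topology_letter <- side
  out$crossovers <- kept
  out$nicks <- data.frame(strand = broken,
                          after_position = topology$arm_length,
                          stringsAsFactors = FALSE)
  out$isomer <- isomer
  out
}

#' Helix membership of every base position for one isomer
#'
#' Each paired position belongs to exactly one pseudo-duplex per isomer; the
#' union of the two helices covers all positions.
#'
#' @param topology a `junction_topology`.
#' @param isomer 1 or 2.
#' @return data frame (strand, pos, helix, bp_index) where `bp_index` is the
#'   base-pair index along the helix in reading-strand order.
#' @export
helix_membership <- function(topology, isomer) {
  out <- NULL
  for (hx in 1:2) {
    hs <- helix_strands(topology, isomer, hx)
    L <- 2L * topology$arm_length
    rows <- data.frame(strand = hs$reading, pos = 1:L, helix = hx,
                       bp_index = 1:L, stringsAsFactors = FALSE)
    partners <- do.call(rbind, lapply(1:L, function(p) {
      q <- pair_of(topology, hs$reading, p)
      data.frame(strand = q$strand, pos = q$pos, helix = hx, bp_index = p,
                 stringsAsFactors = FALSE)
    }))
    out <- rbind(out, rows, partners)
  }
  out
}
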