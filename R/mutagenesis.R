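# Length-matched REF/ALT sequence construction for each SV and its four
# augmentations (none, -1 bp shift, +1 bp shift, reverse complement).
#
# All coordinates are 0-based half-open.  The prediction window spans
# L_IN = 1,048,576 bp; only the central 448 x 2048 = 917,504 bp are visible
# in the predicted map (32 bins of margin are cropped per side).

#' Build the prediction window around a structural variant
#'
#' The window is centered on the SV midpoint, floor((start + end) / 2), and
#' clamped to the contig: if either flank would extend past a contig edge the
#' center is shifted (never truncated) so the window keeps its full
#' 1,048,576 bp span.
#'
#' @param sv one-row SV data.frame (or list with chrom, start, end).
#' @param genome named character vector of contig sequences.
#' @param center optional explicit center (0-based), overriding the midpoint
#'   rule; used for breakend windows.
#' @return list of class `prediction_window`: chrom, input_start, input_end,
#'   visible_start, visible_end, bin_size, n_bins, clamped.
#' @export
build_window <- function(sv, genome, center = NULL) {
  chrom <- sv$chrom
  if (!chrom %in% names(genome))
    stop("contig not in genome: ", chrom)
  clen <- slen(genome[[chrom]])
  if (clen < L_IN)
    stop("contig_too_short: ", chrom, " has ", clen, " bp < ", L_IN)
  if (is.null(center))
    center <- (sv$start + sv$end) %/% 2L
  input_start <- center - L_IN %/% 2L
  clamped <- FALSE
  if (input_start < 0L) {
    input_start <- 0L
    clamped <- TRUE
  }
  if (input_start + L_IN > clen) {
    input_start <- clen - L_IN
    clamped <- TRUE
  }
  w <- list(chrom = chrom,
            input_start = as.integer(input_start),
            input_end = as.integer(input_start + L_IN),
            visible_start = as.integer(input_start + MARGIN),
            visible_end = as.integer(input_start + MARGIN + VISIBLE_SPAN),
            bin_size = BIN_SIZE, n_bins = N_BINS, clamped = clamped)
  class(w) <- "prediction_window"
  w
}

#' @export
#' @method print prediction_window
print.prediction_window <- function(x, ...) {
  cat(sprintf("prediction window %s:%d-%d (visible %d-%d, %d x %d bp bins%s)\n",
              x$chrom, x$input_start, x$input_end, x$visible_start,
              x$visible_end, x$n_bins, x$bin_size,
              if (x$clamped) ", clamped" else ""))
  invisible(x)
}

# bins of the visible window overlapped by genomic interval [start, end)
bins_for_interval <- function(window, start, end) {
  if (end <= start || end <= window$visible_start ||
      start >= window$visible_end)
    return(integer(0))
  lo <- max(start, window$visible_start)
  hi <- min(end, window$visible_end)
  b0 <- (lo - window$visible_start) %/% window$bin_size
  b1 <- (hi - 1L - window$visible_start) %/% window$bin_size
  seq.int(b0, b1)
}

aug_shift <- function(augmentation) {
  switch(augmentation, none = 0L, shift_minus1 = -1L, shift_plus1 = 1L,
         revcomp = 0L, stop("unknown augmentation: ", augmentation))
}

check_n_fraction <- function(seq, cap = 0.05) {
  (count_char_cpp(seq, "N") / seq_len_cpp(seq)) > cap
}

new_sequence_pair <- function(ref_seq, alt_seq, window, mask_bins,
                              augmentation, side = NULL, flags = character()) {
  stopifnot(seq_len_cpp(ref_seq) == L_IN, seq_len_cpp(alt_seq) == L_IN)
  p <- list(ref_seq = ref_seq, alt_seq = alt_seq, window = window,
            mask_bins = as.integer(mask_bins), augmentation = augmentation,
            side = side, flags = flags)
  class(p) <- "sequence_pair"
  p
}

#' Build the length-matched REF/ALT sequence pair for a non-BND variant
#'
#' REF is the genome over the prediction window.  ALT applies the variant and
#' restores the input length by symmetric flank adjustment: DEL extends the
#' flanks by ceil(l/2) on the left and floor(l/2) on the right; DUP inserts a
#' tandem copy after the segment and trims the same amounts from the two
#' ends; INS inserts the novel sequence at `start` and trims symmetrically;
#' INV reverse-complements the segment in place (no length change).
#' `mask_bins` are the visible bins intersecting the variant in REF
#' coordinates, plus the ALT junction bin for DEL/INS.  The -1/+1 bp
#' augmentations move the input window by that amount before mutation; the
#' revcomp augmentation reverse-complements both final sequences (and
#' reflects the mask to the rotated map orientation).
#'
#' @param sv one-row SV data.frame (svtype DEL/DUP/INS/INV).
#' @param genome named character vector.
#' @param augmentation one of `"none"`, `"shift_minus1"`, `"shift_plus1"`,
#'   `"revcomp"`.
#' @param n_cap warn-flag threshold on the fraction of N bases in the window.
#' @return object of class `sequence_pair`.
#' @export
build_sequence_pair <- function(sv, genome, augmentation = "none",
                                n_cap = 0.05) {
  stopifnot(sv$svtype %in% c("DEL", "DUP", "INS", "INV"))
  l <- if (sv$svtype == "INS") nchar(sv$inserted_seq) else sv$end - sv$start
  if (l > 500000L)
    stop("variant longer than 500 kb cannot be scored")
  delta <- aug_shift(augmentation)
  w <- build_window(sv, genome)
  contig <- genome[[sv$chrom]]
  clen <- slen(contig)
  is <- w$input_start + delta
  ie <- w$input_end + delta
  if (is < 0L || ie > clen)
    stop("shifted window outside contig")
  ref_seq <- subseq0(contig, is, ie)

  lceil <- (l + 1L) %/% 2L
  lfloor <- l %/% 2L
  st <- sv$start
  en <- sv$end

  # single-allocation assembly of the ALT sequence; the flank-trimmed forms
  # below are algebraically identical to "apply the edit, then trim
  # ceil(l/2)/floor(l/2) from the two ends"
  gsplice <- function(from, to, rc = rep(FALSE, length(from)),
                      idx = rep(1L, length(from)),
                      literal = rep(NA_character_, length(from))) {
    as.character(splice_cpp(list(contig), as.integer(idx), from, to, rc,
                            literal))
  }
  if (sv$svtype == "DEL") {
    if (is - lceil < 0L || ie + lfloor > clen)
      stop("flank extension beyond contig")
    alt_seq <- gsplice(c(is - lceil, en), c(st, ie + lfloor))
  } else if (sv$svtype == "DUP") {
    alt_seq <- gsplice(c(is + lceil, st, en), c(en, en, ie - lfloor))
  } else if (sv$svtype == "INS") {
    alt_seq <- gsplice(c(is + lceil, 0, st), c(st, 0, ie - lfloor),
                       idx = c(1L, 0L, 1L),
                       literal = c(NA, sv$inserted_seq, NA))
  } else { # INV
    alt_seq <- gsplice(c(is, st, en), c(st, en, ie), rc = c(FALSE, TRUE,
                                                            FALSE))
  }

  # mask: REF-coordinate bins of the variant (shifted window geometry)
  wsh <- w
  wsh$visible_start <- w$visible_start + delta
  wsh$visible_end <- w$visible_end + delta
  mask <- bins_for_interval(wsh, st, en)
  if (sv$svtype %in% c("DEL", "INS")) {
    # junction bin in ALT coordinates mapped onto the visible grid
    jpos_alt <- st - is + lceil                 # 0-based within ALT window
    jbin <- (jpos_alt - MARGIN) %/% BIN_SIZE
    if (jbin >= 0L && jbin < N_BINS) mask <- c(mask, jbin)
  }
  mask <- sort(unique(as.integer(mask)))

  flags <- character()
  # the N-content of the window is augmentation-invariant up to 1 bp;
  # checking the unshifted pair once is enough for the flag
  if (augmentation %in% c("none", "revcomp") &&
      check_n_fraction(ref_seq, n_cap)) flags <- c(flags, "high_N")
  if (w$clamped) flags <- c(flags, "clamped_window")

  if (augmentation == "revcomp") {
    ref_seq <- revcomp(ref_seq)
    alt_seq <- revcomp(alt_seq)
    mask <- sort((N_BINS - 1L) - mask)
  }
  new_sequence_pair(ref_seq, alt_seq, w, mask, augmentation, flags = flags)
}

# per-orientation geometry of the fusion allele, from the perspective of the
# recorded breakend ("A" side).  Junction j is sv$end.
#   a_side: which half of the window the A sequence occupies
#   b_side/b_rc: which piece of the mate contig is joined, and its strand
bnd_geometry <- function(orientation) {
  switch(orientation,
    "t[p[" = list(a_side = "left",  b_side = "right", b_rc = FALSE),
    "t]p]" = list(a_side = "left",  b_side = "left",  b_rc = TRUE),
    "]p]t" = list(a_side = "right", b_side = "left",  b_rc = FALSE),
    "[p[t" = list(a_side = "right", b_side = "right", b_rc = TRUE),
    stop("unknown orientation: ", orientation))
}

#' Build the two REF/ALT pairs for a breakend (BND) variant
#'
#' A junction joins two loci A (the recorded breakend) and B (its mate).  For
#' each locus the reference window is centered on the junction and the
#' alternate sequence is the fusion allele: the half-window of that locus
#' ending (or starting) at the junction, concatenated with a half-window
#' from the partner locus, reverse-complemented when the bracket orientation
#' joins like strands.  Scoring of each pair is restricted to the cells
#' involving that locus' half of the map; the `side` element records which
#' bins those are, and `mask_bins` holds the two junction-flanking bins.
#'
#' @param sv one-row BND SV data.frame (mate fields populated).
#' @param genome named character vector.
#' @param augmentation augmentation tag as in [build_sequence_pair()].
#' @return list of two `sequence_pair` objects (A locus, B locus).
#' @export
build_bnd_pairs <- function(sv, genome, augmentation = "none") {
  stopifnot(sv$svtype == "BND")
  if (is.na(sv$mate_chrom) || is.na(sv$mate_pos) || is.na(sv$orientation))
    stop("unresolved mate for BND ", sv$id)
  delta <- aug_shift(augmentation)
  half_bins <- N_BINS %/% 2L

  one_pair <- function(chrom_a, j_a, orient_a, chrom_b, q0_b) {
    g <- bnd_geometry(orient_a)
    contig_a <- genome[[chrom_a]]
    contig_b <- genome[[chrom_b]]
    half <- L_IN %/% 2L
    # REF window centered on the junction so the A half matches REF exactly
    w <- build_window(list(chrom = chrom_a, start = j_a, end = j_a),
                      genome, center = j_a)
    if (w$input_start != j_a - half)
      stop("breakend window clamped; junction too close to contig edge")
    ref_seq <- subseq0(contig_a, w$input_start + delta, w$input_end + delta)
    # B-side junction coordinate: first base of the joined piece is mate_pos
    # (1-based); for left-extending pieces the piece ends at mate_pos.
    j_b <- (if (g$b_side == "right") q0_b else q0_b + 1L) + delta
    ja <- j_a + delta
    a_rng <- if (g$a_side == "left") c(ja - half, ja) else c(ja, ja + half)
    b_rng <- if (g$b_side == "right") c(j_b, j_b + half)
             else c(j_b - half, j_b)
    ord <- if (g$a_side == "left") 1:2 else 2:1
    alt_seq <- as.character(splice_cpp(
      list(contig_a, contig_b),
      c(1L, 2L)[ord],
      c(a_rng[1], b_rng[1])[ord], c(a_rng[2], b_rng[2])[ord],
      c(FALSE, g$b_rc)[ord],
      rep(NA_character_, 2L)))
    side_bins <- if (g$a_side == "left") seq.int(0L, half_bins - 1L)
                 else seq.int(half_bins, N_BINS - 1L)
    mask <- c(half_bins - 1L, half_bins)   # the two junction-flanking bins
    if (augmentation == "revcomp") {
      ref_seq <- revcomp(ref_seq)
      alt_seq <- revcomp(alt_seq)
      mask <- sort((N_BINS - 1L) - mask)
      side_bins <- sort((N_BINS - 1L) - side_bins)
    }
    new_sequence_pair(ref_seq, alt_seq, w, mask, augmentation,
                      side = as.integer(side_bins))
  }

  # A perspective
  pair_a <- one_pair(sv$chrom, sv$end, sv$orientation,
                     sv$mate_chrom, sv$mate_pos - 1L)
  # B perspective: reciprocal record
  o2 <- mate_orientation(sv$orientation)
  j_b <- if (o2 %in% c("t[p[", "t]p]")) sv$mate_pos - 1L + 1L
         else sv$mate_pos - 1L
  # the reciprocal bracket points at this record's printed position
  pos_a_printed <- if (sv$orientation %in% c("t[p[", "t]p]")) sv$end
                   else sv$end + 1L
  pair_b <- one_pair(sv$mate_chrom, j_b, o2, sv$chrom, pos_a_printed - 1L)
  list(pair_a, pair_b)
}
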