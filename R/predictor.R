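# Contact-map predictor contract and the deterministic mechanistic toy
# predictor.  A predictor is a function of one 1,048,576 bp sequence that
# returns a symmetric 448 x 448 matrix of log-scale contact scores with the
# near-diagonal (|i - j| < 2) set to 0.  The toy predictor encodes domain
# boundaries and loop anchors as fixed 12-mers so that planted variants have
# known, mechanistically interpretable effects.

#' Parameters of the toy contact-map predictor
#'
#' The toy model scans the visible 917,504 bp of the input window for two
#' motifs on both strands.  Bins containing a boundary-motif hit delimit
#' blocks (domains); contacts within a block are elevated by `c_in` over the
#' baseline `c_out`.  All cells carry a distance-decay term
#' `-gamma * log10(|i - j| + 1)`.  A convergent anchor pair (forward-strand
#' anchor hit in bin i, reverse-strand hit in bin j > i, j - i <=
#' `loop_max_dist`) adds `loop_bonus` to that cell (symmetrized).
#'
#' @param boundary_motif,anchor_motif non-palindromic, mutually distinct
#'   12-mers.
#' @param gamma distance-decay coefficient (> 0).
#' @param c_in within-block elevation.
#' @param c_out between-block baseline.
#' @param loop_bonus loop-anchor contact bonus.
#' @param loop_max_dist maximum anchor separation, in bins.
#' @return list of class `toy_params`.
#' @export
toy_params <- function(boundary_motif = "ACGCGTTATGCC",
                       anchor_motif = "TTCGACGGTAAC",
                       gamma = 1.0, c_in = 0.6, c_out = 0.0,
                       loop_bonus = 0.8, loop_max_dist = 200L) {
  stopifnot(gamma > 0,
            nchar(boundary_motif) == 12L, nchar(anchor_motif) == 12L,
            boundary_motif != revcomp(boundary_motif),
            anchor_motif != revcomp(anchor_motif),
            boundary_motif != anchor_motif,
            boundary_motif != revcomp(anchor_motif))
  p <- list(boundary_motif = boundary_motif, anchor_motif = anchor_motif,
            gamma = gamma, c_in = c_in, c_out = c_out,
            loop_bonus = loop_bonus, loop_max_dist = as.integer(loop_max_dist))
  class(p) <- "toy_params"
  p
}

# bins of the visible span overlapped by motif hits (0-based starts within
# the visible sequence); a hit can straddle two bins
hit_bins <- function(starts, motif_len) {
  if (length(starts) == 0) return(integer(0))
  b0 <- starts %/% BIN_SIZE
  b1 <- (starts + motif_len - 1L) %/% BIN_SIZE
  bins <- unique(c(b0, b1))
  sort(bins[bins >= 0L & bins < N_BINS])
}



#' Predict a contact map with the toy mechanistic model
#'
#' Deterministic: the same sequence always yields the identical map.  The map
#' is exactly strand-symmetric: `toy_predict(revcomp(s))` equals the 180
#' degree rotation of `toy_predict(s)`.
#'
#' @param seq character sequence of length 1,048,576 (alphabet A/C/G/T/N; N
#'   never matches a motif).
#' @param params [toy_params()] object.
#' @return 448 x 448 symmetric numeric matrix (class `matrix`), near-diagonal
#'   cells 0.
#' @export
toy_predict <- function(seq, params = toy_params()) {
  if (seq_len_cpp(seq) != L_IN)
    stop("predictor input must be exactly ", L_IN, " bp, got ",
         seq_len_cpp(seq))
  # one pass over the visible span for both motifs on both strands
  hits <- scan_motifs4_cpp(seq, c(params$boundary_motif,
                                  revcomp(params$boundary_motif),
                                  params$anchor_motif,
                                  revcomp(params$anchor_motif)),
                           MARGIN, MARGIN + VISIBLE_SPAN)
  ml <- nchar(params$boundary_motif)
  boundary_bins <- hit_bins(c(hits[[1]], hits[[2]]), ml)
  anchor_f <- hit_bins(hits[[3]], nchar(params$anchor_motif))
  anchor_r <- hit_bins(hits[[4]], nchar(params$anchor_motif))
  toy_map_cpp(N_BINS, boundary_bins, anchor_f, anchor_r,
              params$gamma, params$c_in, params$c_out,
              params$loop_bonus, params$loop_max_dist, DIAG_MIN)
}

#' Construct a predictor object
#'
#' A predictor bundles a `predict(seq)` function with a name and its
#' parameters; the pipeline is agnostic to which predictor it runs.
#' `"toy"` is the deterministic mechanistic model; `"akita_adapter"` is a
#' documented stub for plugging in a trained contact-map model and errors
#' with `"predictor_unavailable"` when invoked without one.
#'
#' @param name `"toy"` or `"akita_adapter"`.
#' @param params predictor parameters ([toy_params()] for the toy model).
#' @return list of class `svfold_predictor` with elements `name`, `params`,
#'   and `predict`.
#' @export
make_predictor <- function(name = c("toy", "akita_adapter"),
                           params = toy_params()) {
  name <- match.arg(name)
  pred_fun <- if (name == "toy") {
    function(seq) toy_predict(seq, params)
  } else {
    function(seq) stop("predictor_unavailable: no trained contact-map ",
                       "model is bundled; supply one via an adapter")
  }
  p <- list(name = name, params = params, predict = pred_fun)
  class(p) <- "svfold_predictor"
  p
}

#' @export
#' @method print svfold_predictor
print.svfold_predictor <- function(x, ...) {
  cat("svfold contact-map predictor:", x$name, "\n")
  invisible(x)
}
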