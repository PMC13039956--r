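# REF-vs-ALT contact map scoring: overall MSE and CORR (1 - Pearson r)
# disruption scores, the per-bin 1D disruption track, and per-variant
# aggregation over the four augmentations.

as_bin_mask <- function(n, bins) {
  m <- rep(FALSE, n)
  bins <- bins[bins >= 0L & bins < n]
  m[bins + 1L] <- TRUE
  m
}

#' Compare two contact maps outside the masked region
#'
#' Evaluation cells are the upper-triangle entries with `|i - j| >=
#' min_sep`, neither bin masked and (for breakend half-window comparisons) at
#' least one bin in `req_bins`.  `mse` is the mean squared difference over
#' those cells and `corr` is 1 - Pearson correlation over the same cells, so
#' both increase with disruption.
#'
#' @param ref,alt symmetric numeric matrices of equal dimension (any size;
#'   448 x 448 in the pipeline).
#' @param mask_bins 0-based bins excluded from scoring (the variant region).
#' @param req_bins optional 0-based bins; when given, a cell is evaluated
#'   only if at least one of its bins is in this set.
#' @param min_sep near-diagonal exclusion, default 2.
#' @return list with `mse`, `corr`, `n_cells`, `zero_variance`.  `corr` is 0
#'   with `zero_variance = TRUE` when either map is constant over the
#'   evaluation cells.
#' @export
compare_maps <- function(ref, alt, mask_bins = integer(0), req_bins = NULL,
                         min_sep = DIAG_MIN) {
  stopifnot(is.matrix(ref), is.matrix(alt), all(dim(ref) == dim(alt)),
            nrow(ref) == ncol(ref))
  n <- nrow(ref)
  mask <- as_bin_mask(n, as.integer(mask_bins))
  req <- if (is.null(req_bins)) rep(TRUE, n)
         else as_bin_mask(n, as.integer(req_bins))
  res <- compare_maps_cpp(ref, alt, mask, req, as.integer(min_sep))
  if (res$n_cells == 0)
    stop("empty evaluation set: all cells masked")
  res
}

#' Per-bin disruption track
#'
#' `track[i]` is the mean of `(ref[i,j] - alt[i,j])^2` over unmasked bins j
#' with `|i - j| >= min_sep`; masked bins get 0.  With no mask the mean of
#' the track is (up to edge-bin cell counts) the overall MSE.
#'
#' @inheritParams compare_maps
#' @return numeric vector of length `nrow(ref)`.
#' @export
disruption_track <- function(ref, alt, mask_bins = integer(0),
                             min_sep = DIAG_MIN) {
  stopifnot(is.matrix(ref), is.matrix(alt), all(dim(ref) == dim(alt)))
  mask <- as_bin_mask(nrow(ref), as.integer(mask_bins))
  as.numeric(disruption_track_cpp(ref, alt, mask, as.integer(min_sep)))
}

#' Score one structural variant against a predictor
#'
#' Builds the four augmented REF/ALT sequence pairs, predicts contact maps,
#' and compares them.  For the reverse-complement augmentation the per-bin
#' track is un-flipped before accumulation so all tracks align to genomic
#' orientation.  A BND is scored as the mean of its two half-window
#' comparisons (one per breakpoint), and carries one track per breakpoint
#' window.  Aggregate scores are the median and the mean of the four
#' per-augmentation values.
#'
#' @param sv one-row SV data.frame.
#' @param genome named character vector of contigs.
#' @param predictor [make_predictor()] object.
#' @param augmentations subset of the four augmentation tags (all by
#'   default).
#' @param keep_tracks compute and return the per-bin tracks (default TRUE);
#'   disable for score-only cohort sweeps.
#' @return object of class `disruption_result`: per-augmentation scores,
#'   aggregates `mse_median`/`mse_mean`/`corr_median`/`corr_mean`, `tracks`
#'   (list of one 448-vector, or two for BND), `windows`, `masked_bins`,
#'   `flags`.
#' @export
score_variant <- function(sv, genome, predictor = make_predictor("toy"),
                          augmentations = AUGMENTATIONS,
                          keep_tracks = TRUE) {
  stopifnot(inherits(predictor, "svfold_predictor"))
  is_bnd <- sv$svtype == "BND"
  per_aug <- data.frame(augmentation = augmentations,
                        mse = NA_real_, corr = NA_real_,
                        stringsAsFactors = FALSE)
  flags <- character()
  n_pieces <- if (is_bnd) 2L else 1L
  track_sum <- vector("list", n_pieces)
  windows <- vector("list", n_pieces)
  masked <- vector("list", n_pieces)

  for (ai in seq_along(augmentations)) {
    aug <- augmentations[ai]
    pairs <- if (is_bnd) build_bnd_pairs(sv, genome, aug)
             else list(build_sequence_pair(sv, genome, aug))
    mses <- numeric(length(pairs))
    corrs <- numeric(length(pairs))
    for (pi in seq_along(pairs)) {
      p <- pairs[[pi]]
      flags <- union(flags, p$flags)
      ref_map <- predictor$predict(p$ref_seq)
      alt_map <- predictor$predict(p$alt_seq)
      mask <- p$mask_bins
      side <- p$side
      if (aug == "revcomp") {
        # un-rotate to genomic orientation before scoring: tracks then align
        # across augmentations and the evaluation order is canonical
        nb <- nrow(ref_map)
        ref_map <- ref_map[nb:1, nb:1]
        alt_map <- alt_map[nb:1, nb:1]
        mask <- (nb - 1L) - mask
        if (!is.null(side)) side <- (nb - 1L) - side
      }
      cmp <- compare_maps(ref_map, alt_map, mask, req_bins = side)
      if (isTRUE(cmp$zero_variance)) flags <- union(flags, "zero_variance")
      mses[pi] <- cmp$mse
      corrs[pi] <- cmp$corr
      if (keep_tracks) {
        tr <- disruption_track(ref_map, alt_map, mask)
        track_sum[[pi]] <- if (is.null(track_sum[[pi]])) tr
                           else track_sum[[pi]] + tr
      }
      if (aug == "none") {
        windows[[pi]] <- p$window
        masked[[pi]] <- p$mask_bins
      }
    }
    per_aug$mse[ai] <- mean(mses)
    per_aug$corr[ai] <- mean(corrs)
  }

  tracks <- if (any(!vapply(track_sum, is.null, TRUE)))
    lapply(track_sum, function(t) t / length(augmentations)) else NULL
  res <- list(sv_id = sv$id, svtype = sv$svtype,
              per_augmentation = per_aug,
              mse_median = median(per_aug$mse),
              mse_mean = mean(per_aug$mse),
              corr_median = median(per_aug$corr),
              corr_mean = mean(per_aug$corr),
              tracks = tracks, windows = windows, masked_bins = masked,
              flags = flags)
  class(res) <- "disruption_result"
  res
}

#' @export
#' @method print disruption_result
print.disruption_result <- function(x, ...) {
  cat(sprintf("disruption of %s (%s): MSE %.4g (median), CORR %.4g (median)\n",
              x$sv_id, x$svtype, x$mse_median, x$corr_median))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Score a whole callset
#'
#' Applies [score_variant()] to every row; per-variant failures are caught,
#' recorded, and excluded rather than aborting the run.
#'
#' @param svs SV data.frame (filtered callset).
#' @param genome named character vector.
#' @param predictor [make_predictor()] object.
#' @param keep_tracks keep the per-variant 1D tracks (needed for ABC
#'   weighting); default TRUE.
#' @param verbose print a progress line every 200 variants.
#' @return list of class `svfold_scores`: `scores` (data.frame with the
#'   aggregate metrics per variant), `tracks` (named list: per variant, the
#'   track(s) and window(s)), `errors` (named character vector of failed
#'   variant ids).
#' @export
score_cohort <- function(svs, genome, predictor = make_predictor("toy"),
                         keep_tracks = TRUE, verbose = FALSE) {
  n <- nrow(svs)
  rows <- vector("list", n)
  tracks <- if (keep_tracks) vector("list", n) else NULL
  errors <- character()
  for (i in seq_len(n)) {
    sv <- svs[i, ]
    res <- tryCatch(score_variant(sv, genome, predictor,
                                  keep_tracks = keep_tracks),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[sv$id] <- conditionMessage(res)
      next
    }
    rows[[i]] <- data.frame(
      id = sv$id, sample_id = sv$sample_id, chrom = sv$chrom,
      start = sv$start, end = sv$end, svtype = sv$svtype,
      length = sv_length(sv),
      mate_chrom = sv$mate_chrom, mate_pos = sv$mate_pos,
      mse_median = res$mse_median, mse_mean = res$mse_mean,
      corr_median = res$corr_median, corr_mean = res$corr_mean,
      flags = paste(res$flags, collapse = ";"),
      stringsAsFactors = FALSE)
    if (keep_tracks)
      tracks[[i]] <- list(tracks = res$tracks, windows = res$windows)
    if (verbose && i %% 200L == 0L)
      message("scored ", i, "/", n, " variants")
  }
  ok <- !vapply(rows, is.null, TRUE)
  scores <- do.call(rbind, rows[ok])
  if (keep_tracks) {
    tracks <- tracks[ok]
    names(tracks) <- scores$id
  }
  out <- list(scores = scores, tracks = tracks, errors = errors)
  class(out) <- "svfold_scores"
  out
}

#' @export
#' @method print svfold_scores
print.svfold_scores <- function(x, ...) {
  cat(sprintf("svfold scores: %d variants, %d samples, %d failed\n",
              nrow(x$scores), length(unique(x$scores$sample_id)),
              length(x$errors)))
  invisible(x)
}

#' Write the scored-variants table to TSV
#'
#' @param scored [score_cohort()] result (or its `scores` data.frame).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scored, path) {
  df <- if (inherits(scored, "svfold_scores")) scored$scores else scored
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a disruption track as bedGraph over the visible-window bins
#'
#' @param track numeric vector of per-bin MSE values.
#' @param window `prediction_window` the track belongs to.
#' @param path output bedGraph path.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, window, path) {
  starts <- window$visible_start + (seq_along(track) - 1L) * window$bin_size
  df <- data.frame(chrom = window$chrom, start = starts,
                   end = starts + window$bin_size, value = track)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
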