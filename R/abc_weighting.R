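# Activity-by-Contact (ABC) weighting of disruption scores.  Enhancer
# activity is the geometric mean of ATAC and H3K27ac read counts at ~500 bp
# candidate regulatory elements; the ABC disruption score is the
# activity-weighted mean of the per-bin disruption track, and variants are
# re-ranked to find those up- or down-weighted by enhancer context.

#' Enhancer activity from paired read counts
#'
#' Geometric mean `sqrt(atac * h3k27ac)`; zero if either assay saw no reads.
#'
#' @param atac_count,h3k27ac_count non-negative read counts (vectorized).
#' @return numeric activity values.
#' @export
element_activity <- function(atac_count, h3k27ac_count) {
  if (any(atac_count < 0) || any(h3k27ac_count < 0))
    stop("read counts must be non-negative")
  sqrt(atac_count * h3k27ac_count)
}

#' Read regulatory elements from a BED6+2 file
#'
#' Columns: chrom, start, end, name, score, strand, atac_count,
#' h3k27ac_count.  An `activity` column (geometric mean of the two counts)
#' is added.
#'
#' @param path BED6+2 file.
#' @return data.frame of elements with 0-based half-open coordinates.
#' @export
read_elements_bed <- function(path) {
  el <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand", "atac_count", "h3k27ac_count"))
  el$activity <- element_activity(el$atac_count, el$h3k27ac_count)
  el
}

#' Project enhancer activity onto the 448 bins of a prediction window
#'
#' Every visible bin overlapping an element (half-open interval overlap)
#' receives that element's activity; bins overlapped by several elements take
#' the maximum (or the sum, via `combine`); all other bins are 0.
#'
#' @param elements data.frame with chrom, start, end and either an
#'   `activity` column or `atac_count`/`h3k27ac_count`.
#' @param window `prediction_window`.
#' @param combine `"max"` (default) or `"sum"` for bins with several
#'   elements.
#' @return numeric vector of length 448.
#' @export
bin_activity <- function(elements, window, combine = c("max", "sum")) {
  combine <- match.arg(combine)
  a <- rep(0, window$n_bins)
  if (is.null(elements) || nrow(elements) == 0) return(a)
  if (is.null(elements$activity))
    elements$activity <- element_activity(elements$atac_count,
                                          elements$h3k27ac_count)
  el <- elements[elements$chrom == window$chrom &
                 elements$end > window$visible_start &
                 elements$start < window$visible_end, , drop = FALSE]
  for (i in seq_len(nrow(el))) {
    bins <- bins_for_interval(window, el$start[i], el$end[i]) + 1L
    if (combine == "max") {
      a[bins] <- pmax(a[bins], el$activity[i])
    } else {
      a[bins] <- a[bins] + el$activity[i]
    }
  }
  a
}

#' ABC disruption score of one prediction window
#'
#' Activity-weighted mean of the per-bin disruption track:
#' `sum(A * D) / sum(A)`.  A window with no enhancer activity scores 0 and is
#' flagged.
#'
#' @param track numeric disruption track (448 values).
#' @param activity numeric activity track of the same length.
#' @return list with `score` and `flag` (`"no_enhancer_in_window"` or NA).
#' @export
abc_disruption_score <- function(track, activity) {
  if (length(track) != length(activity))
    stop("track and activity lengths differ")
  s <- sum(activity)
  if (s == 0)
    return(list(score = 0, flag = "no_enhancer_in_window"))
  list(score = sum(activity * track) / s, flag = NA_character_)
}

#' ABC disruption score of a breakend
#'
#' Arithmetic mean of the per-breakpoint activity-weighted scores;
#' enhancer-free windows enter as 0.
#'
#' @param tracks list of disruption tracks, one per breakpoint window.
#' @param activities list of matching activity tracks.
#' @return list with `score` and `flags` (per-breakpoint).
#' @export
abc_score_bnd <- function(tracks, activities) {
  stopifnot(length(tracks) >= 1, length(tracks) == length(activities))
  per <- mapply(function(t, a) abc_disruption_score(t, a),
                tracks, activities, SIMPLIFY = FALSE)
  list(score = mean(vapply(per, `[[`, 0, "score")),
       flags = vapply(per, `[[`, NA_character_, "flag"))
}

#' ABC-weight a scored callset
#'
#' Computes, for every variant in `scored`, the activity track of its
#' prediction window(s) and the ABC disruption score (mean over breakpoints
#' for BNDs).
#'
#' @param scored [score_cohort()] result with tracks retained.
#' @param elements regulatory-element data.frame (see [read_elements_bed()]).
#' @param combine bin combination rule, as in [bin_activity()].
#' @return data.frame: id, abc_score, abc_flag.
#' @export
abc_score_cohort <- function(scored, elements, combine = "max") {
  stopifnot(inherits(scored, "svfold_scores"), !is.null(scored$tracks))
  ids <- scored$scores$id
  out <- data.frame(id = ids, abc_score = NA_real_,
                    abc_flag = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    tr <- scored$tracks[[ids[k]]]
    acts <- lapply(tr$windows, function(w)
      bin_activity(elements, w, combine = combine))
    res <- abc_score_bnd(tr$tracks, acts)
    out$abc_score[k] <- res$score
    flg <- res$flags[!is.na(res$flags)]
    if (length(flg)) out$abc_flag[k] <- paste(unique(flg), collapse = ";")
  }
  out
}

#' Rank shifts between plain and ABC-weighted disruption scores
#'
#' Variants are ranked by each score in descending order (rank 1 = most
#' disruptive; ties broken by the stable order of `sv_id`).  The rank
#' difference `rank_plain - rank_abc` is normalized by `1000 / N` so the
#' threshold is comparable across callsets of different size; variants with
#' `normalized >= threshold` are upweighted, `<= -threshold` downweighted.
#'
#' @param plain_scores data.frame with columns `id` and `score` (the
#'   unweighted metric, e.g. aggregate MSE).
#' @param abc_scores data.frame with columns `id` and `score` (ABC-weighted).
#' @param threshold normalized-rank-shift cutoff, default 40.
#' @return data.frame: id, rank_plain, rank_abc, delta, normalized, label.
#' @export
rank_shifts <- function(plain_scores, abc_scores, threshold = 40) {
  if (!setequal(plain_scores$id, abc_scores$id))
    stop("the two score tables cover different variant sets")
  n <- nrow(plain_scores)
  if (n < 2) stop("need at least 2 variants to rank")
  abc <- abc_scores[match(plain_scores$id, abc_scores$id), ]
  rank_desc <- function(x) {
    # descending scores; ties resolved by stable input (sv_id) order
    ord <- order(-x, seq_along(x))
    r <- integer(n); r[ord] <- seq_len(n)
    r
  }
  rp <- rank_desc(plain_scores$score)
  ra <- rank_desc(abc$score)
  delta <- rp - ra
  normalized <- delta * 1000 / n
  label <- ifelse(normalized >= threshold, "upweighted",
                  ifelse(normalized <= -threshold, "downweighted",
                         "unchanged"))
  data.frame(id = plain_scores$id, rank_plain = rp, rank_abc = ra,
             delta = delta, normalized = normalized, label = label,
             stringsAsFactors = FALSE)
}
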