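# Recurrently disrupted region (RDR) discovery: per-sample maximum
# disruption scores over 1 Mb genome bins, low-dimensional embedding plus
# density clustering of samples, shared-bin identification per cluster, and
# a binomial recurrence test against the genome-wide background rate.

#' Sample-by-bin matrix of maximum disruption scores
#'
#' The genome is divided into fixed-width bins (1 Mb by default; the last
#' bin of each contig is truncated).  Each entry holds the highest aggregate
#' disruption score among that sample's SVs overlapping the bin, 0 if none.
#' A BND contributes its full score at both breakpoint loci.
#'
#' @param scored [score_cohort()] result or its `scores` data.frame.
#' @param contig_lengths named integer vector of contig lengths.
#' @param metric `"mse"` or `"corr"`.
#' @param aggregate `"median"` or `"mean"` (which aggregate column to use).
#' @param bin_size bin width in bp, default 1e6.
#' @return numeric matrix (samples x bins) with attributes `bin_info`
#'   (data.frame chrom/start per column) and `mutated` (logical matrix: does
#'   the sample have any scored SV in the bin).
#' @export
build_bin_matrix <- function(scored, contig_lengths, metric = c("mse", "corr"),
                             aggregate = c("median", "mean"),
                             bin_size = 1000000L) {
  metric <- match.arg(metric)
  aggregate <- match.arg(aggregate)
  df <- if (inherits(scored, "svfold_scores")) scored$scores else scored
  if (is.null(df) || nrow(df) == 0) stop("no scored SVs")
  score_col <- paste0(metric, "_", aggregate)
  bins <- do.call(rbind, lapply(names(contig_lengths), function(ch) {
    starts <- seq.int(0L, contig_lengths[[ch]] - 1L, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, contig_lengths[[ch]]),
               stringsAsFactors = FALSE)
  }))
  bin_id <- paste0(bins$chrom, ":", bins$start)
  samples <- sort(unique(df$sample_id))
  m <- matrix(0, nrow = length(samples), ncol = nrow(bins),
              dimnames = list(samples, bin_id))
  mut <- matrix(FALSE, nrow = length(samples), ncol = nrow(bins),
                dimnames = list(samples, bin_id))

  # intervals at which each SV registers: its span, plus the mate locus for
  # BNDs (each breakpoint is a 1 bp locus)
  iv <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                   sample = df$sample_id, score = df[[score_col]],
                   stringsAsFactors = FALSE)
  is_bnd <- df$svtype == "BND" & !is.na(df$mate_chrom)
  if (any(is_bnd)) {
    iv <- rbind(iv, data.frame(chrom = df$mate_chrom[is_bnd],
                               start = df$mate_pos[is_bnd] - 1L,
                               end = df$mate_pos[is_bnd],
                               sample = df$sample_id[is_bnd],
                               score = df[[score_col]][is_bnd],
                               stringsAsFactors = FALSE))
  }
  for (k in seq_len(nrow(iv))) {
    ch <- iv$chrom[k]
    cols <- which(bins$chrom == ch & bins$start < iv$end[k] &
                  bins$end > iv$start[k])
    if (!length(cols)) next
    r <- match(iv$sample[k], samples)
    m[r, cols] <- pmax(m[r, cols], iv$score[k])
    mut[r, cols] <- TRUE
  }
  attr(m, "bin_info") <- bins
  attr(m, "mutated") <- mut
  m
}

# Compact DBSCAN on a coordinate matrix.  Clusters are connected components
# of core points (>= min_pts neighbours within eps, self included); border
# points join their nearest core point; everything else is noise.  This
# formulation is invariant to the input row order.
dbscan_components <- function(x, eps, min_pts) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts
  labels <- rep(-1L, n)
  if (any(core)) {
    comp <- rep(0L, n)
    cur <- 0L
    for (i in which(core)) {
      if (comp[i] != 0L) next
      cur <- cur + 1L
      queue <- i
      comp[i] <- cur
      while (length(queue)) {
        v <- queue[1L]
        queue <- queue[-1L]
        nbrs <- which(nb[v, ] & core & comp == 0L)
        comp[nbrs] <- cur
        queue <- c(queue, nbrs)
      }
    }
    labels[core] <- comp[core]
    for (i in which(!core)) {
      cand <- which(core & nb[i, ])
      if (length(cand)) {
        labels[i] <- comp[cand[which.min(d[i, cand])]]
      }
    }
  }
  labels
}

# largest-gap k-distance heuristic for the DBSCAN radius
eps_heuristic <- function(x, k) {
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  kdist <- apply(d, 1L, function(r) sort(r)[min(k, length(r) - 1L)])
  s <- sort(kdist)
  if (max(s) < 1e-12) return(1e-12)  # degenerate: all points coincide
  gaps <- diff(s)
  g <- which.max(gaps)
  (s[g] + s[g + 1L]) / 2
}

#' Embed samples and find candidate clusters
#'
#' Principal-component embedding of the sample-by-bin score matrix to two
#' dimensions, followed by density clustering (DBSCAN) on the embedding.
#' With a `threshold`, the embedding uses the binary past-cutoff profile
#' (entry >= threshold) instead of the raw scores: candidate groups are
#' defined by *which* bins a sample disrupts, not by how strongly, so
#' carriers of weak and strong events at one locus land on the same point.
#' The background is the largest cluster (plus all noise points), labelled
#' -1; remaining clusters are the candidate groups of samples sharing a
#' disrupted bin.  Deterministic given the matrix; `seed` is recorded for
#' the run manifest.
#'
#' @param m sample-by-bin matrix from [build_bin_matrix()].
#' @param seed integer, recorded (the embedding itself is deterministic).
#' @param n_dim embedding dimensions, default 2.
#' @param eps DBSCAN radius; NULL (default) uses the largest-gap k-distance
#'   heuristic.
#' @param min_pts DBSCAN core-point threshold, default 3.
#' @param threshold optional disruption cutoff; when given, the embedding
#'   is computed on the thresholded indicator matrix.
#' @return list of class `rdr_clustering`: `embedding` (samples x 2),
#'   `cluster` (integer labels, -1 = background), `eps`, `min_pts`, `seed`.
#' @export
embed_and_cluster <- function(m, seed = 1L, n_dim = 2L, eps = NULL,
                              min_pts = 3L, threshold = NULL) {
  if (nrow(m) < 10L) stop("need at least 10 samples to cluster")
  x <- if (is.null(threshold)) m else (m >= threshold) * 1
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_dim, ncol(pc$x))
  emb <- pc$x[, seq_len(k), drop = FALSE]
  if (is.null(eps)) eps <- eps_heuristic(emb, min_pts)
  labels <- dbscan_components(emb, eps, min_pts)
  # relabel the largest cluster (the undistinguished bulk) as background
  if (any(labels > 0L)) {
    sizes <- table(labels[labels > 0L])
    big <- as.integer(names(sizes)[sizes == max(sizes)])
    if (length(big) > 1L) {
      # tie: the cluster with the lowest mean per-sample maximum score is
      # the least disrupted, hence background
      rowmax <- apply(m, 1L, max)
      means <- vapply(big, function(b) mean(rowmax[labels == b]), 0)
      big <- big[which.min(means)]
    } else big <- big[1L]
    labels[labels == big] <- -1L
    old <- sort(unique(labels[labels > 0L]))
    labels[labels > 0L] <- match(labels[labels > 0L], old)
  }
  out <- list(embedding = emb, cluster = labels, eps = eps,
              min_pts = min_pts, seed = seed)
  class(out) <- "rdr_clustering"
  out
}

#' Shared disrupted bin of a sample cluster
#'
#' The bin in which every cluster member's matrix entry reaches `cutoff`;
#' on ties the bin with the smallest genomic coordinate wins.
#'
#' @param cluster_samples character vector of sample ids.
#' @param m sample-by-bin matrix.
#' @param cutoff disruption score cutoff.
#' @return bin id (column name) or NA if no bin is shared above cutoff.
#' @export
driver_bin <- function(cluster_samples, m, cutoff) {
  stopifnot(length(cluster_samples) >= 1)
  sub <- m[cluster_samples, , drop = FALSE]
  shared <- which(apply(sub, 2L, function(col) all(col >= cutoff)))
  if (!length(shared)) return(NA_character_)
  # columns are ordered by contig then start; first hit = smallest coordinate
  colnames(m)[shared[1L]]
}

#' Recurrence test of every genome bin
#'
#' For each bin, counts the samples with any SV in the bin (`n_mutated`) and
#' with an SV at or above the disruption cutoff (`n_disrupted`), and tests
#' both counts with a one-sided binomial test against the genome-wide mean
#' per-bin rate, Benjamini-Hochberg corrected across bins.
#'
#' @param m sample-by-bin matrix from [build_bin_matrix()].
#' @param cutoff disruption score cutoff defining "disrupted".
#' @return data.frame: bin, chrom, start, n_mutated, n_disrupted, p_mutated,
#'   p_disrupted, q_mutated, q_disrupted.
#' @export
recurrence_test <- function(m, cutoff) {
  mut <- attr(m, "mutated")
  bins <- attr(m, "bin_info")
  stopifnot(!is.null(mut), !is.null(bins))
  n_samples <- nrow(m)
  n_mutated <- colSums(mut)
  n_disrupted <- colSums(m >= cutoff & mut)
  p0_mut <- mean(mut)
  p0_dis <- mean(m >= cutoff & mut)
  test1 <- function(x, p0) {
    if (p0 <= 0) return(if (x > 0) 0 else 1)
    if (p0 >= 1) return(1)
    binom.test(x, n_samples, p0, alternative = "greater")$p.value
  }
  p_mutated <- vapply(n_mutated, test1, 0, p0 = p0_mut)
  p_disrupted <- vapply(n_disrupted, test1, 0, p0 = p0_dis)
  data.frame(bin = colnames(m), chrom = bins$chrom, start = bins$start,
             n_mutated = as.integer(n_mutated),
             n_disrupted = as.integer(n_disrupted),
             p_mutated = p_mutated, p_disrupted = p_disrupted,
             q_mutated = p.adjust(p_mutated, "BH"),
             q_disrupted = p.adjust(p_disrupted, "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Reference-map quality check for a candidate bin
#'
#' Compares the predicted reference contact map with a supplied experimental
#' (or ground-truth) map by Pearson correlation over the evaluation cells;
#' bins whose predicted map does not match are dropped from the RDR list and
#' exported for manual review.
#'
#' @param predicted_map predicted REF contact map (matrix).
#' @param reference_map experimental map, or NULL if unavailable.
#' @param threshold minimum Pearson r to keep the bin, default 0.5.
#' @param min_sep near-diagonal exclusion, default 2.
#' @return list with `keep` (logical), `r` (correlation or NA), `flag`
#'   (`"unchecked"` when no reference map was supplied, else NA).
#' @export
reference_quality_filter <- function(predicted_map, reference_map = NULL,
                                     threshold = 0.5, min_sep = DIAG_MIN) {
  if (is.null(reference_map))
    return(list(keep = TRUE, r = NA_real_, flag = "unchecked"))
  n <- nrow(predicted_map)
  idx <- which(upper.tri(predicted_map) &
               abs(row(predicted_map) - col(predicted_map)) >= min_sep)
  r <- suppressWarnings(cor(predicted_map[idx], reference_map[idx]))
  if (is.na(r)) r <- 0
  list(keep = r >= threshold, r = r, flag = NA_character_)
}

#' Full recurrently-disrupted-region discovery
#'
#' Runs the whole RDR procedure: bin matrix, embedding and clustering,
#' shared-bin identification per candidate cluster, recurrence testing, and
#' (when reference maps are supplied) the reference-map quality filter.
#'
#' @param scored [score_cohort()] result.
#' @param contig_lengths named integer vector.
#' @param metric,aggregate score column selection, as in
#'   [build_bin_matrix()].
#' @param cutoff disruption cutoff inside the discovery; NULL (default) uses
#'   the 98.8th percentile of the cohort score vector.
#' @param q_threshold BH-adjusted significance threshold on the disruption
#'   recurrence test, default 0.05.
#' @param eps,min_pts DBSCAN parameters (see [embed_and_cluster()]).
#' @param seed recorded seed.
#' @param reference_maps optional named list (by bin id) of experimental
#'   maps for the quality filter; bins without an entry are kept flagged
#'   `"unchecked"`.
#' @param genome,predictor needed only when `reference_maps` is given, to
#'   predict the reference map of each candidate bin (window centered on the
#'   bin midpoint).
#' @return list of class `rdr_result`: `calls` (data.frame of RDR bins),
#'   `candidates` (all cluster-derived bins with test results), `clustering`,
#'   `matrix`, `cutoff`, `review` (bins dropped or unchecked).
#' @export
find_rdrs <- function(scored, contig_lengths, metric = "mse",
                      aggregate = "median", cutoff = NULL,
                      q_threshold = 0.05, eps = NULL, min_pts = 3L,
                      seed = 1L, reference_maps = NULL, genome = NULL,
                      predictor = NULL) {
  df <- scored$scores
  score_col <- paste0(metric, "_", aggregate)
  if (is.null(cutoff)) cutoff <- quantile(df[[score_col]], 0.988, names = FALSE)
  m <- build_bin_matrix(scored, contig_lengths, metric = metric,
                        aggregate = aggregate)
  cl <- embed_and_cluster(m, seed = seed, eps = eps, min_pts = min_pts,
                          threshold = cutoff)
  tests <- recurrence_test(m, cutoff)

  cand_bins <- character(0)
  cand_cluster <- integer(0)
  for (g in setdiff(sort(unique(cl$cluster)), -1L)) {
    members <- rownames(m)[cl$cluster == g]
    b <- driver_bin(members, m, cutoff)
    if (!is.na(b)) {
      cand_bins <- c(cand_bins, b)
      cand_cluster <- c(cand_cluster, g)
    }
  }
  keep_unique <- !duplicated(cand_bins)
  cand_bins <- cand_bins[keep_unique]
  cand_cluster <- cand_cluster[keep_unique]

  candidates <- tests[match(cand_bins, tests$bin), , drop = FALSE]
  candidates$cluster <- cand_cluster
  candidates$quality_flag <- rep(NA_character_, nrow(candidates))
  candidates$ref_map_r <- rep(NA_real_, nrow(candidates))

  if (nrow(candidates)) {
    for (k in seq_len(nrow(candidates))) {
      rm_k <- if (!is.null(reference_maps))
        reference_maps[[candidates$bin[k]]] else NULL
      if (!is.null(rm_k) && !is.null(genome) && !is.null(predictor)) {
        ch <- candidates$chrom[k]
        center <- candidates$start[k] + 500000L
        w <- build_window(list(chrom = ch, start = center, end = center),
                          genome, center = center)
        pm <- predictor$predict(subseq0(genome[[ch]], w$input_start,
                                        w$input_end))
        qf <- reference_quality_filter(pm, rm_k)
      } else {
        qf <- reference_quality_filter(NULL, NULL)
        qf$keep <- TRUE
      }
      candidates$quality_flag[k] <- if (!is.null(qf$flag) && !is.na(qf$flag))
        qf$flag else if (!qf$keep) "low_quality_reference" else "checked"
      candidates$ref_map_r[k] <- qf$r
    }
  }

  calls <- candidates[candidates$q_disrupted < q_threshold &
                      candidates$quality_flag != "low_quality_reference", ,
                      drop = FALSE]
  calls$samples <- rep(NA_character_, nrow(calls))
  # member samples per call
  if (nrow(calls)) {
    calls$samples <- vapply(calls$bin, function(b) {
      paste(rownames(m)[m[, b] >= cutoff], collapse = ",")
    }, "")
  }
  out <- list(calls = calls, candidates = candidates, clustering = cl,
              matrix = m, cutoff = cutoff, tests = tests)
  class(out) <- "rdr_result"
  out
}

#' @export
#' @method print rdr_result
print.rdr_result <- function(x, ...) {
  cat(sprintf("RDR discovery: %d candidate bin(s), %d call(s) at cutoff %.4g\n",
              nrow(x$candidates), nrow(x$calls), x$cutoff))
  if (nrow(x$calls)) print(x$calls[, c("bin", "n_mutated", "n_disrupted",
                                       "q_mutated", "q_disrupted")])
  invisible(x)
}
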