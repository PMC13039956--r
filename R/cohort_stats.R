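# Cohort-level analyses: per-category summaries, initial-vs-progressive
# burden tests, disruption-cutoff calibration, disrupted-gene annotation,
# regulatory-peak enrichment, expression extremity, breakpoint confidence
# intervals and repeat concordance, and score-covariate associations.

svs_to_granges <- function(svs) {
  GenomicRanges::GRanges(svs$chrom,
                         IRanges::IRanges(start = svs$start + 1L,
                                          end = pmax(svs$end, svs$start + 1L)))
}

#' Per-category cohort summary
#'
#' For each tumor category: sample count, median SVs per sample, SV-type
#' fractions, stage fractions, the median across samples of the per-sample
#' median CORR score, and the fraction of the category's variants above the
#' cohort-wide 90th percentile of the chosen metric.
#'
#' @param scored [score_cohort()] result or its `scores` data.frame.
#' @param meta sample metadata (see [read_sample_meta()]).
#' @param metric score column for the percentile comparison, default
#'   `"corr_median"`.
#' @return data.frame, one row per category, plus attribute
#'   `type_fractions`/`stage_fractions` wide tables.
#' @export
summarize_categories <- function(scored, meta, metric = "corr_median") {
  df <- if (inherits(scored, "svfold_scores")) scored$scores else scored
  unknown <- !df$sample_id %in% meta$sample_id
  if (any(unknown)) {
    warning(sum(unknown), " variants from samples missing in metadata; ",
            "excluded")
    df <- df[!unknown, , drop = FALSE]
  }
  df <- merge(df, meta[, c("sample_id", "tumor_category", "stage")],
              by = "sample_id")
  p90 <- quantile(df[[metric]], 0.90, names = FALSE)
  cats <- sort(unique(df$tumor_category))
  rows <- lapply(cats, function(cc) {
    sub <- df[df$tumor_category == cc, ]
    per_sample <- table(sub$sample_id)
    type_frac <- prop.table(table(factor(sub$svtype, levels = SV_TYPES)))
    sample_stage <- meta[meta$tumor_category == cc &
                         meta$sample_id %in% df$sample_id, ]
    stage_frac <- prop.table(table(factor(sample_stage$stage,
                                          levels = c("initial",
                                                     "progressive"))))
    med_corr <- median(vapply(split(sub$corr_median, sub$sample_id),
                              median, 0))
    data.frame(tumor_category = cc,
               n_samples = length(per_sample),
               median_svs_per_sample = median(as.numeric(per_sample)),
               frac_DEL = type_frac[["DEL"]], frac_DUP = type_frac[["DUP"]],
               frac_INV = type_frac[["INV"]], frac_INS = type_frac[["INS"]],
               frac_BND = type_frac[["BND"]],
               frac_initial = stage_frac[["initial"]],
               frac_progressive = stage_frac[["progressive"]],
               median_sample_corr = med_corr,
               frac_above_p90 = mean(sub[[metric]] > p90),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "p90") <- p90
  out
}

#' Initial-versus-progressive comparison per participant
#'
#' For every participant with at least one initial and one progressive
#' sample, one sample of each stage is chosen uniformly at random (seeded;
#' the selection is returned so downstream analyses reuse it).  SVs of the
#' progressive sample that exactly match an initial SV on (chrom, start,
#' end, svtype) are removed; a Welch two-sample t-test then compares the
#' remaining progressive score vector with the initial one (positive
#' statistic = progressive more disruptive).  `logfc_total` is the log2
#' ratio of total SV counts in the two samples; `logfc_private` uses the
#' subtracted progressive set and is NA (flagged) when that set is empty.
#'
#' @param scored [score_cohort()] result or scores data.frame (must carry
#'   `sample_id` and the score column).
#' @param meta sample metadata.
#' @param metric score column used in the t-test, default `"corr_median"`.
#' @param seed RNG seed for the sample selection.
#' @return list of class `stage_comparison`: `per_participant` data.frame
#'   (participant_id, initial/progressive sample ids and counts,
#'   logfc_total, logfc_private, t_statistic, p_value, flag), `selection`
#'   (the chosen samples), and `overall` (Welch test over all initial vs all
#'   progressive scores in the cohort).
#' @export
progressive_vs_initial <- function(scored, meta, metric = "corr_median",
                                   seed = 1L) {
  df <- if (inherits(scored, "svfold_scores")) scored$scores else scored
  df <- merge(df, meta[, c("sample_id", "participant_id", "stage")],
              by = "sample_id")
  set.seed(seed)
  parts <- split(meta, meta$participant_id)
  rows <- list()
  selection <- list()
  for (pid in names(parts)) {
    pm <- parts[[pid]]
    ini <- pm$sample_id[pm$stage == "initial"]
    pro <- pm$sample_id[pm$stage == "progressive"]
    if (length(ini) < 1 || length(pro) < 1) next
    s_ini <- if (length(ini) == 1) ini else sample(ini, 1L)
    s_pro <- if (length(pro) == 1) pro else sample(pro, 1L)
    selection[[pid]] <- c(initial = s_ini, progressive = s_pro)
    svi <- df[df$sample_id == s_ini, ]
    svp <- df[df$sample_id == s_pro, ]
    key <- function(x) paste(x$chrom, x$start, x$end, x$svtype, sep = "\r")
    private <- svp[!key(svp) %in% key(svi), , drop = FALSE]
    flag <- NA_character_
    logfc_total <- log2(nrow(svp) / nrow(svi))
    logfc_private <- if (nrow(private) == 0) {
      flag <- "empty_private_progressive_set"
      NA_real_
    } else log2(nrow(private) / nrow(svi))
    tstat <- p <- NA_real_
    if (nrow(private) >= 2 && nrow(svi) >= 2) {
      tt <- t.test(private[[metric]], svi[[metric]], var.equal = FALSE)
      tstat <- unname(tt$statistic)
      p <- tt$p.value
    } else if (is.na(flag)) {
      flag <- "too_few_scores_for_test"
    }
    rows[[pid]] <- data.frame(
      participant_id = pid, initial_sample = s_ini,
      progressive_sample = s_pro, n_initial = nrow(svi),
      n_progressive = nrow(svp), n_private = nrow(private),
      logfc_total = logfc_total, logfc_private = logfc_private,
      t_statistic = tstat, p_value = p, flag = flag,
      stringsAsFactors = FALSE)
  }
  per_participant <- if (length(rows)) do.call(rbind, rows) else NULL
  all_ini <- df[[metric]][df$stage == "initial"]
  all_pro <- df[[metric]][df$stage == "progressive"]
  overall <- if (length(all_ini) >= 2 && length(all_pro) >= 2) {
    tt <- t.test(all_pro, all_ini, var.equal = FALSE)
    list(mean_initial = mean(all_ini), mean_progressive = mean(all_pro),
         t_statistic = unname(tt$statistic), p_value = tt$p.value)
  } else NULL
  out <- list(per_participant = per_participant, selection = selection,
              overall = overall, metric = metric, seed = seed)
  class(out) <- "stage_comparison"
  out
}

#' Calibrate the "highly disruptive" score cutoff
#'
#' Evaluates a coarse percentile grid (90-99 in 1-point steps) and a fine
#' grid (98.5-99.9 in 0.1 steps), recording the score threshold at every
#' grid point and, for each, the review list of the 10 lowest-scoring
#' variants above the cutoff (5 by MSE, 5 by CORR) that the qualitative
#' inspection step looks at.  Variants at or above the chosen percentile's
#' threshold on either metric (configurable) are labelled highly disruptive.
#'
#' @param scored [score_cohort()] result or scores data.frame with
#'   `mse_median` and `corr_median` columns.
#' @param coarse,fine percentile grids (percent).
#' @param chosen chosen percentile, default 98.8.
#' @param rule `"either"` (default): a variant is highly disruptive if either
#'   metric reaches its own threshold; `"mse"`/`"corr"`: that metric only.
#' @return list of class `cutoff_calibration`: `grid` (percentile,
#'   mse_threshold, corr_threshold, n_selected), `chosen`, `threshold_mse`,
#'   `threshold_corr`, `review` (per grid point, the 5+5 lowest-scoring
#'   variant ids above cutoff), `highly_disruptive` (ids).
#' @export
calibrate_cutoff <- function(scored, coarse = seq(90, 99, by = 1),
                             fine = seq(98.5, 99.9, by = 0.1),
                             chosen = 98.8, rule = c("either", "mse", "corr")) {
  rule <- match.arg(rule)
  df <- if (inherits(scored, "svfold_scores")) scored$scores else scored
  if (is.null(df) || nrow(df) == 0) stop("no scores to calibrate on")
  if (nrow(df) < 1000)
    warning("fewer than 1000 scores; percentile thresholds will be unstable")
  pts <- sort(unique(round(c(coarse, fine, chosen), 10)))
  review <- list()
  grid <- data.frame(percentile = pts, mse_threshold = NA_real_,
                     corr_threshold = NA_real_, n_selected = NA_integer_)
  for (k in seq_along(pts)) {
    p <- pts[k] / 100
    thr_m <- quantile(df$mse_median, p, names = FALSE)
    thr_c <- quantile(df$corr_median, p, names = FALSE)
    sel <- selected_ids(df, thr_m, thr_c, rule)
    grid$mse_threshold[k] <- thr_m
    grid$corr_threshold[k] <- thr_c
    grid$n_selected[k] <- length(sel)
    above_m <- df[df$mse_median >= thr_m, ]
    above_c <- df[df$corr_median >= thr_c, ]
    review[[as.character(pts[k])]] <- list(
      mse = head(above_m$id[order(above_m$mse_median)], 5L),
      corr = head(above_c$id[order(above_c$corr_median)], 5L))
  }
  thr_m <- quantile(df$mse_median, chosen / 100, names = FALSE)
  thr_c <- quantile(df$corr_median, chosen / 100, names = FALSE)
  out <- list(grid = grid, chosen = chosen, threshold_mse = thr_m,
              threshold_corr = thr_c, rule = rule, review = review,
              highly_disruptive = selected_ids(df, thr_m, thr_c, rule))
  class(out) <- "cutoff_calibration"
  out
}

selected_ids <- function(df, thr_m, thr_c, rule) {
  sel <- switch(rule,
    either = df$mse_median >= thr_m | df$corr_median >= thr_c,
    mse = df$mse_median >= thr_m,
    corr = df$corr_median >= thr_c)
  df$id[sel]
}

#' @export
#' @method print cutoff_calibration
print.cutoff_calibration <- function(x, ...) {
  cat(sprintf("cutoff calibration: chosen %.1fth percentile -> MSE >= %.4g, CORR >= %.4g; %d variants highly disruptive\n",
              x$chosen, x$threshold_mse, x$threshold_corr,
              length(x$highly_disruptive)))
  invisible(x)
}

#' Read gene annotation from GFF3
#'
#' Expects `gene` and `exon` features; the gene id is taken from the ID (or
#' Parent, for exons) attribute.
#'
#' @param path GFF3 file.
#' @return list with `genes` (data.frame gene_id, chrom, start, end, strand,
#'   protein_coding) and `exons` (data.frame gene_id, chrom, start, end),
#'   0-based half-open.
#' @export
read_gene_annotation <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  genes <- g[g$type == "gene"]
  exons <- g[g$type == "exon"]
  biotype <- if (!is.null(genes$biotype)) genes$biotype
             else rep("protein_coding", length(genes))
  list(genes = data.frame(
         gene_id = genes$ID,
         chrom = as.character(GenomicRanges::seqnames(genes)),
         start = GenomicRanges::start(genes) - 1L,
         end = GenomicRanges::end(genes),
         strand = as.character(GenomicRanges::strand(genes)),
         protein_coding = biotype == "protein_coding",
         stringsAsFactors = FALSE),
       exons = data.frame(
         gene_id = as.character(unlist(exons$Parent)),
         chrom = as.character(GenomicRanges::seqnames(exons)),
         start = GenomicRanges::start(exons) - 1L,
         end = GenomicRanges::end(exons),
         stringsAsFactors = FALSE))
}

#' Genes disrupted by highly disruptive SVs
#'
#' A protein-coding gene is "disrupted" by an SV when its span intersects
#' the flanking region (`flank` bp on either side of the SV) but not the SV
#' interval itself; with `criterion = "exon"` the overlap exclusion applies
#' to the gene's exons instead of its whole span (an intron-only overlap is
#' then allowed).  Genes hit in two or more tumor types are labelled
#' recurrently disrupted.
#'
#' @param svs SV data.frame of the highly disruptive variants; if a
#'   `tumor_type` column is present it feeds the recurrence labelling.
#' @param annotation [read_gene_annotation()] result (or a compatible list).
#' @param flank flank width in bp, default 300000.
#' @param criterion `"span"` (default) or `"exon"`.
#' @return list with `pairs` (gene_id, sv id, tumor_type) and
#'   `recurrent_genes` (gene ids hit in >= 2 tumor types).
#' @export
disrupted_genes <- function(svs, annotation, flank = 300000L,
                            criterion = c("span", "exon")) {
  criterion <- match.arg(criterion)
  genes <- annotation$genes[annotation$genes$protein_coding, , drop = FALSE]
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L,
                                                     genes$end))
  exon_gr <- GenomicRanges::GRanges(annotation$exons$chrom,
                                    IRanges::IRanges(annotation$exons$start + 1L,
                                                     annotation$exons$end))
  pairs <- list()
  for (i in seq_len(nrow(svs))) {
    sv <- svs[i, ]
    flank_gr <- GenomicRanges::GRanges(
      rep(sv$chrom, 2L),
      IRanges::IRanges(start = c(max(sv$start - flank, 0L) + 1L, sv$end + 1L),
                       end = c(sv$start, sv$end + flank)))
    sv_gr <- GenomicRanges::GRanges(sv$chrom,
                                    IRanges::IRanges(sv$start + 1L, sv$end))
    near <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gene_gr, flank_gr)))
    if (!length(near)) next
    if (criterion == "span") {
      bad <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(gene_gr[near], sv_gr)))
    } else {
      ex_hit <- unique(annotation$exons$gene_id[S4Vectors::queryHits(
        GenomicRanges::findOverlaps(exon_gr, sv_gr))])
      bad <- which(genes$gene_id[near] %in% ex_hit)
    }
    keep <- if (length(bad)) near[-bad] else near
    if (!length(keep)) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      gene_id = genes$gene_id[keep], sv_id = sv$id,
      tumor_type = if (!is.null(sv$tumor_type)) sv$tumor_type
                   else NA_character_,
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_id = character(), sv_id = character(),
               tumor_type = character(), stringsAsFactors = FALSE)
  by_gene <- split(pairs$tumor_type, pairs$gene_id)
  recurrent <- names(by_gene)[vapply(by_gene, function(tt)
    length(unique(tt[!is.na(tt)])) >= 2, TRUE)]
  list(pairs = pairs, recurrent_genes = recurrent)
}

#' Peak-overlap enrichment of disruptive variants
#'
#' Per variant, the fraction of its span covered by the peak set; per SV
#' length bin (log10 decades by default), a two-sided Mann-Whitney U test
#' compares the overlap fractions of disruptive versus other variants.
#' BNDs (undefined length) are excluded.
#'
#' @param svs SV data.frame with a logical `disruptive` column.
#' @param peaks data.frame with chrom, start, end (0-based half-open).
#' @param length_breaks breakpoints (bp) of the length bins; default log10
#'   decades from 10 bp to 1 Mb.
#' @return data.frame per length bin: n_disruptive, n_other, median overlap
#'   fractions, p_value (NA when either group has < 2 variants).
#' @export
peak_overlap_enrichment <- function(svs, peaks,
                                    length_breaks = 10^(1:6)) {
  svs <- svs[svs$svtype != "BND", , drop = FALSE]
  len <- svs$end - svs$start
  frac <- rep(0, nrow(svs))
  if (!is.null(peaks) && nrow(peaks) > 0) {
    peak_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end)))
    sv_gr <- svs_to_granges(svs)
    ov <- GenomicRanges::findOverlaps(sv_gr, peak_gr)
    if (length(ov)) {
      inter <- IRanges::pintersect(sv_gr[S4Vectors::queryHits(ov)],
                                   peak_gr[S4Vectors::subjectHits(ov)])
      bp <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
      frac[as.integer(names(bp))] <- as.numeric(bp) / len[as.integer(names(bp))]
    }
  }
  bin <- cut(len, breaks = c(0, length_breaks, Inf), right = FALSE)
  out <- lapply(levels(bin), function(b) {
    sel <- which(bin == b)
    d <- frac[sel][svs$disruptive[sel]]
    o <- frac[sel][!svs$disruptive[sel]]
    p <- if (length(d) >= 2 && length(o) >= 2)
      suppressWarnings(wilcox.test(d, o)$p.value) else NA_real_
    data.frame(length_bin = b, n_disruptive = length(d), n_other = length(o),
               median_overlap_disruptive = if (length(d)) median(d) else NA,
               median_overlap_other = if (length(o)) median(o) else NA,
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Expression extremity of a focal sample at a gene
#'
#' Compares the focal sample's TPM to comparison samples of the same tumor
#' type that carry no SV within `flank` of the gene.  Counts are strict
#' (ties are neither below nor above).
#'
#' @param gene_id gene identifier (row of the TPM table).
#' @param focal_sample sample carrying the variant of interest.
#' @param tpm TPM matrix or data.frame, genes x samples.
#' @param svs cohort SV data.frame (used to exclude variant-bearing
#'   comparison samples).
#' @param meta sample metadata.
#' @param annotation gene annotation list (for the gene's locus).
#' @param flank exclusion flank, default 300000.
#' @return list: direction ("higher"/"lower"/"intermediate"), n_below,
#'   n_above, n_ties, n_total, label (e.g. "higher than 27/28 samples"),
#'   flag.
#' @export
expression_extremity <- function(gene_id, focal_sample, tpm, svs, meta,
                                 annotation, flank = 300000L) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
  if (nrow(g) != 1) stop("gene not found in annotation: ", gene_id)
  focal_type <- meta$tumor_type[meta$sample_id == focal_sample]
  if (length(focal_type) != 1) stop("focal sample not in metadata")
  near <- svs$chrom == g$chrom & svs$start < g$end + flank &
          svs$end > g$start - flank
  carriers <- unique(svs$sample_id[near])
  comparison <- setdiff(meta$sample_id[meta$tumor_type == focal_type],
                        c(carriers, focal_sample))
  comparison <- intersect(comparison, colnames(tpm))
  if (!length(comparison))
    return(list(direction = NA_character_, n_below = NA_integer_,
                n_above = NA_integer_, n_ties = NA_integer_,
                n_total = 0L, label = NA_character_,
                flag = "empty_comparison_set"))
  x <- as.numeric(tpm[gene_id, focal_sample])
  y <- as.numeric(tpm[gene_id, comparison])
  n_below <- sum(y < x)
  n_above <- sum(y > x)
  n_ties <- sum(y == x)
  n <- length(y)
  direction <- if (n_below >= n_above) "higher" else "lower"
  label <- if (direction == "higher")
    sprintf("higher than %d/%d samples", n_below, n)
  else sprintf("lower than %d/%d samples", n_above, n)
  list(direction = direction, n_below = n_below, n_above = n_above,
       n_ties = n_ties, n_total = n, label = label, flag = NA_character_)
}

#' Breakpoint confidence intervals and repeat concordance
#'
#' Per SV: the total confidence-interval width (CIPOS span plus CIEND span)
#' and whether both breakpoints fall, within `match_window` bp, in repeat
#' annotations of the same family.
#'
#' @param svs SV data.frame.
#' @param repeats data.frame with chrom, start, end, family (0-based
#'   half-open).
#' @param match_window breakpoint search window in bp, default 50.
#' @return data.frame: id, ci_width_total, repeat_matched, repeat_family.
#' @export
breakpoint_ci_and_repeats <- function(svs, repeats, match_window = 50L) {
  rep_gr <- GenomicRanges::GRanges(repeats$chrom,
                                   IRanges::IRanges(repeats$start + 1L,
                                                    repeats$end))
  families_at <- function(chrom, pos0) {
    q <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(max(pos0 - match_window, 0L) + 1L,
                       pos0 + match_window + 1L))
    unique(repeats$family[S4Vectors::subjectHits(
      GenomicRanges::findOverlaps(q, rep_gr))])
  }
  out <- data.frame(id = svs$id,
                    ci_width_total = (svs$cipos_hi - svs$cipos_lo) +
                                     (svs$ciend_hi - svs$ciend_lo),
                    repeat_matched = FALSE,
                    repeat_family = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(svs))) {
    sv <- svs[i, ]
    if (sv$svtype == "BND") {
      f1 <- families_at(sv$chrom, sv$end)
      f2 <- if (!is.na(sv$mate_chrom))
        families_at(sv$mate_chrom, sv$mate_pos - 1L) else character(0)
    } else {
      f1 <- families_at(sv$chrom, sv$start)
      f2 <- families_at(sv$chrom, sv$end)
    }
    shared <- intersect(f1, f2)
    if (length(shared)) {
      out$repeat_matched[i] <- TRUE
      out$repeat_family[i] <- shared[1L]
    }
  }
  out
}

#' Score-covariate associations and genic context
#'
#' Spearman correlations of disruption score with variant length and with
#' tumor purity, and a genic-context class per SV: `coding` when the SV
#' interval overlaps an exon, `intronic` when it overlaps a gene span but no
#' exon, `intergenic` otherwise.
#'
#' @param scored [score_cohort()] result or scores data.frame.
#' @param meta sample metadata (for purity).
#' @param annotation gene annotation list, or NULL to skip genic classes.
#' @param metric score column, default `"corr_median"`.
#' @return list: `length_assoc` and `purity_assoc` (rho, p, n), `genic`
#'   (data.frame id, class), `by_class` (score summaries per class).
#' @export
score_associations <- function(scored, meta, annotation = NULL,
                               metric = "corr_median") {
  df <- if (inherits(scored, "svfold_scores")) scored$scores else scored
  assoc <- function(x, y) {
    ok <- complete.cases(x, y)
    if (sum(ok) < 3) return(list(rho = NA_real_, p = NA_real_, n = sum(ok)))
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
    list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  }
  length_assoc <- assoc(df$length, df[[metric]])
  pur <- meta$purity[match(df$sample_id, meta$sample_id)]
  purity_assoc <- assoc(pur, df[[metric]])
  genic <- NULL
  by_class <- NULL
  if (!is.null(annotation)) {
    sv_gr <- svs_to_granges(df)
    exon_gr <- GenomicRanges::GRanges(annotation$exons$chrom,
      IRanges::IRanges(annotation$exons$start + 1L, annotation$exons$end))
    gene_gr <- GenomicRanges::GRanges(annotation$genes$chrom,
      IRanges::IRanges(annotation$genes$start + 1L, annotation$genes$end))
    in_exon <- GenomicRanges::countOverlaps(sv_gr, exon_gr) > 0
    in_gene <- GenomicRanges::countOverlaps(sv_gr, gene_gr) > 0
    cls <- ifelse(in_exon, "coding", ifelse(in_gene, "intronic",
                                            "intergenic"))
    genic <- data.frame(id = df$id, class = cls, stringsAsFactors = FALSE)
    by_class <- do.call(rbind, lapply(split(df[[metric]], cls), function(v)
      data.frame(n = length(v), median = median(v), mean = mean(v))))
    by_class$class <- rownames(by_class)
  }
  list(length_assoc = length_assoc, purity_assoc = purity_assoc,
       genic = genic, by_class = by_class)
}
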