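mk_meta <- function(n, types = "tA", cats = "cA", stage = "initial",
                    prefix = "S") {
  data.frame(sample_id = sprintf("%s%03d", prefix, seq_len(n)),
             participant_id = sprintf("P%03d", seq_len(n)),
             tumor_type = rep_len(types, n),
             tumor_category = rep_len(cats, n),
             stage = rep_len(stage, n),
             purity = runif(n, 0.3, 0.9), stringsAsFactors = FALSE)
}

mk_scored <- function(ids, samples, mse, corr = mse, svtype = "DEL",
                      chrom = "ctg1", start = NULL, len = 1000L) {
  n <- length(ids)
  if (is.null(start)) start <- seq_len(n) * 10000L
  data.frame(id = ids, sample_id = rep_len(samples, n), chrom = chrom,
             start = start, end = start + len, svtype = rep_len(svtype, n),
             length = len, mate_chrom = NA_character_,
             mate_pos = NA_integer_, mse_median = mse, mse_mean = mse,
             corr_median = corr, corr_mean = corr, flags = "",
             stringsAsFactors = FALSE)
}

test_that("category summaries report normalized fractions", {
  set.seed(51)
  meta <- rbind(mk_meta(6, "tA", "cA"),
                mk_meta(4, "tB", "cB", prefix = "T"))
  sc <- mk_scored(sprintf("v%03d", 1:100),
                  rep(meta$sample_id, each = 10),
                  mse = c(runif(60, 0, 0.01), runif(40, 0.05, 0.1)),
                  svtype = rep(c("DEL", "DUP", "INV", "INS", "BND"), 20))
  out <- summarize_categories(sc, meta, metric = "corr_median")
  expect_equal(nrow(out), 2L)
  type_frac <- out[, paste0("frac_", c("DEL", "DUP", "INV", "INS", "BND"))]
  expect_equal(unname(rowSums(type_frac)), c(1, 1))
  expect_equal(unname(out$frac_initial + out$frac_progressive), c(1, 1))
  # the category with planted high scores wins the above-90th fraction
  expect_gt(out$frac_above_p90[out$tumor_category == "cB"],
            out$frac_above_p90[out$tumor_category == "cA"])
  # unknown samples are dropped with a warning
  sc_bad <- rbind(sc, mk_scored("vx", "GHOST", 0.5))
  expect_warning(summarize_categories(sc_bad, meta), "missing in metadata")
})

test_that("Welch statistics match the textbook closed form", {
  x <- c(0.08, 0.11, 0.07, 0.10, 0.12, 0.09)   # progressive
  y <- c(0.05, 0.06, 0.04, 0.07, 0.05)          # initial
  meta <- data.frame(sample_id = c("I1", "R1"), participant_id = "P1",
                     tumor_type = "tA", tumor_category = "cA",
                     stage = c("initial", "progressive"), purity = 0.5,
                     stringsAsFactors = FALSE)
  sc <- rbind(mk_scored(paste0("i", seq_along(y)), "I1", y,
                        start = 1000L * seq_along(y)),
              mk_scored(paste0("p", seq_along(x)), "R1", x,
                        start = 100000L + 1000L * seq_along(x)))
  res <- progressive_vs_initial(sc, meta, metric = "mse_median", seed = 1)
  pp <- res$per_participant
  # closed form
  nx <- length(x); ny <- length(y)
  se2 <- var(x) / nx + var(y) / ny
  t_exp <- (mean(x) - mean(y)) / sqrt(se2)
  df_exp <- se2^2 / ((var(x) / nx)^2 / (nx - 1) + (var(y) / ny)^2 / (ny - 1))
  p_exp <- 2 * pt(-abs(t_exp), df_exp)
  expect_lt(abs(pp$t_statistic - t_exp), 1e-10)
  expect_lt(abs(pp$p_value - p_exp), 1e-10)
  expect_gt(pp$t_statistic, 0)  # progressive more disruptive
})

test_that("shared SVs are subtracted by exact coordinates and type only", {
  meta <- data.frame(sample_id = c("I1", "R1"), participant_id = "P1",
                     tumor_type = "tA", tumor_category = "cA",
                     stage = c("initial", "progressive"), purity = 0.5,
                     stringsAsFactors = FALSE)
  ini <- mk_scored(paste0("i", 1:4), "I1", runif(4), start = c(10L, 20L,
                                                               30L, 40L))
  pro <- mk_scored(paste0("p", 1:4), "R1", runif(4), start = c(10L, 20L,
                                                               35L, 45L))
  pro$svtype[1] <- "DUP"  # same coordinates, different type: kept
  res <- progressive_vs_initial(rbind(ini, pro), meta,
                                metric = "mse_median", seed = 1)
  expect_equal(res$per_participant$n_private, 3L)  # only exact p2 removed
  # identical callsets empty the private set and flag the participant
  pro2 <- ini
  pro2$sample_id <- "R1"
  pro2$id <- paste0("p", 1:4)
  res2 <- progressive_vs_initial(rbind(ini, pro2), meta,
                                 metric = "mse_median", seed = 1)
  expect_equal(res2$per_participant$n_private, 0L)
  expect_equal(res2$per_participant$flag, "empty_private_progressive_set")
  expect_true(is.na(res2$per_participant$logfc_private))
})

test_that("cutoff calibration reproduces order statistics on uniform scores", {
  set.seed(52)
  u <- runif(100000)
  sc <- mk_scored(sprintf("u%06d", seq_along(u)), "S1", u)
  cal <- calibrate_cutoff(sc)
  expect_equal(cal$threshold_mse, 0.988, tolerance = 0.002)
  frac <- length(cal$highly_disruptive) / length(u)
  expect_equal(frac, 0.012, tolerance = 0.002)
  # thresholds and selections are monotone along the percentile grid
  expect_true(all(diff(cal$grid$mse_threshold) > 0))
  expect_true(all(diff(cal$grid$n_selected) <= 0))
})

test_that("the review list is the known lowest scorers above each cutoff", {
  sc <- mk_scored(sprintf("r%04d", 1:1000), "S1", mse = (1:1000) / 1000)
  expect_warning(cal <- calibrate_cutoff(sc, chosen = 99), NA)
  # at the 99th percentile of 1..1000/1000 the threshold keeps the top 11
  # scores; the five lowest of them are known exactly
  thr <- cal$threshold_mse
  above <- sc$id[sc$mse_median >= thr]
  expect_equal(cal$review[["99"]]$mse,
               head(above[order(sc$mse_median[sc$mse_median >= thr])], 5))
  # constant scores: threshold equals the constant
  scc <- mk_scored(sprintf("c%04d", 1:1000), "S1", mse = rep(0.5, 1000))
  calc <- calibrate_cutoff(scc)
  expect_equal(calc$threshold_mse, 0.5)
  expect_equal(length(calc$highly_disruptive), 1000L)  # >= keeps ties
})

test_that("disrupted genes lie in the flanks but not on the variant", {
  genes <- data.frame(
    gene_id = c("gDown", "gInside", "gFar", "gIntron"),
    chrom = "ctg1",
    start = c(1100000L, 1005000L, 2000000L, 995000L),
    end = c(1120000L, 1006000L, 2020000L, 1020000L),
    strand = "+", protein_coding = TRUE, stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gIntron", "gIntron"), chrom = "ctg1",
    start = c(995000L, 1015000L), end = c(996000L, 1016000L),
    stringsAsFactors = FALSE)
  ann <- make_annotation(genes, exons)
  sv <- make_sv("d1", chrom = "ctg1", start = 1000000L, end = 1010000L)
  sv$tumor_type <- "tA"
  # span criterion: gDown is 90 kb downstream (in), gInside overlaps (out),
  # gFar is ~1 Mb away (out), gIntron overlaps the span (out)
  res <- disrupted_genes(sv, ann, criterion = "span")
  expect_setequal(res$pairs$gene_id, "gDown")
  # exon criterion: gIntron's exons avoid the variant, so it comes back in
  res2 <- disrupted_genes(sv, ann, criterion = "exon")
  expect_setequal(res2$pairs$gene_id, c("gDown", "gIntron"))
  # flank symmetry: mirrored gene upstream is equally eligible
  genes_up <- genes
  genes_up$start[1] <- 1000000L - 120000L
  genes_up$end[1] <- 1000000L - 100000L
  res3 <- disrupted_genes(sv, make_annotation(genes_up, exons))
  expect_true("gDown" %in% res3$pairs$gene_id)
  # recurrence needs two tumor types
  sv2 <- rbind(sv, sv)
  sv2$id <- c("d1", "d2")
  sv2$tumor_type <- c("tA", "tB")
  res4 <- disrupted_genes(sv2, ann)
  expect_equal(res4$recurrent_genes, "gDown")
})

test_that("peak overlap enrichment separates planted groups", {
  set.seed(53)
  n <- 50L
  peaks <- data.frame(chrom = "ctg1", start = (1:n) * 50000L,
                      end = (1:n) * 50000L + 2000L)
  on_peak <- make_sv(sprintf("on%02d", 1:n), chrom = "ctg1",
                     start = (1:n) * 50000L + 200L,
                     end = (1:n) * 50000L + 1200L)
  off_peak <- make_sv(sprintf("off%02d", 1:n), chrom = "ctg1",
                      start = (1:n) * 50000L + 10000L,
                      end = (1:n) * 50000L + 11000L)
  svs <- rbind(on_peak, off_peak)
  svs$disruptive <- rep(c(TRUE, FALSE), each = n)
  res <- peak_overlap_enrichment(svs, peaks)
  row <- res[res$n_disruptive > 0, ][1, ]
  expect_lt(row$p_value, 1e-4)
  expect_equal(row$median_overlap_disruptive, 1)
  expect_equal(row$median_overlap_other, 0)
  # empty peak set: all fractions zero, tests skipped
  res0 <- peak_overlap_enrichment(svs, peaks[0, ])
  expect_true(all(is.na(res0$p_value) |
                  res0$median_overlap_disruptive == 0))
})

test_that("expression extremity counts strict ranks and ties", {
  genes <- data.frame(gene_id = "g1", chrom = "ctg1", start = 5000000L,
                      end = 5050000L, strand = "+", protein_coding = TRUE,
                      stringsAsFactors = FALSE)
  ann <- make_annotation(genes)
  meta <- mk_meta(31, types = "tA")
  focal <- meta$sample_id[1]
  carrier2 <- meta$sample_id[2]   # also carries an SV near g1: excluded
  svs <- rbind(make_sv("f1", chrom = "ctg1", start = 5100000L,
                       end = 5101000L, sample_id = focal),
               make_sv("c2", chrom = "ctg1", start = 4800000L,
                       end = 4801000L, sample_id = carrier2))
  # 28 comparison samples; 27 below the focal value, 1 above
  tpm <- matrix(0, 1, 31, dimnames = list("g1", meta$sample_id))
  tpm[1, ] <- c(100, 50, runif(27, 1, 20), 150, 60)
  # comparison set = samples 3..31 minus... construct explicitly below
  res <- expression_extremity("g1", focal, tpm, svs, meta, ann)
  expect_equal(res$n_total, 29L)  # 31 - focal - carrier2
  # recreate the published pattern exactly with a trimmed metadata table
  meta28 <- meta[c(1, 3:30), ]
  tpm28 <- tpm[, meta28$sample_id, drop = FALSE]
  res28 <- expression_extremity("g1", focal, tpm28, svs[1, ], meta28, ann)
  expect_equal(res28$n_total, 28L)
  expect_equal(res28$direction, "higher")
  expect_equal(res28$n_below, 27L)
  expect_equal(res28$label, "higher than 27/28 samples")
  # focal below every comparison sample
  tpm28[1, focal] <- 0.001
  res_low <- expression_extremity("g1", focal, tpm28, svs[1, ], meta28, ann)
  expect_equal(res_low$label, sprintf("lower than %d/%d samples", 28, 28))
  # empty comparison set is flagged
  meta1 <- meta[1, , drop = FALSE]
  res_e <- expression_extremity("g1", focal, tpm, svs, meta1, ann)
  expect_equal(res_e$flag, "empty_comparison_set")
})

test_that("breakpoint CI widths and repeat concordance are computed per SV", {
  repeats <- data.frame(
    chrom = "ctg1",
    start = c(100000L, 150000L, 200000L),
    end = c(100500L, 150500L, 200500L),
    family = c("SINE", "SINE", "LINE"), stringsAsFactors = FALSE)
  svs <- rbind(
    make_sv("ciw", chrom = "ctg1", start = 500000L, end = 501000L,
            cipos_lo = -10L, cipos_hi = 10L, ciend_lo = -5L, ciend_hi = 5L),
    make_sv("sine", chrom = "ctg1", start = 100200L, end = 150200L),
    make_sv("mixed", chrom = "ctg1", start = 100200L, end = 200200L))
  res <- breakpoint_ci_and_repeats(svs, repeats)
  expect_equal(res$ci_width_total, c(30L, 0L, 0L))
  expect_true(res$repeat_matched[res$id == "sine"])
  expect_equal(res$repeat_family[res$id == "sine"], "SINE")
  expect_false(res$repeat_matched[res$id == "mixed"])  # SINE vs LINE
})

test_that("score associations recover planted correlations and genic classes", {
  set.seed(54)
  meta <- mk_meta(10)
  n <- 60L
  lens <- sample(100:10000, n)
  sc <- mk_scored(sprintf("a%03d", 1:n), meta$sample_id, mse = lens / 1e4)
  sc$length <- lens
  genes <- data.frame(gene_id = "g1", chrom = "ctg1", start = 0L,
                      end = 50000L, strand = "+", protein_coding = TRUE,
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1", chrom = "ctg1", start = 10000L,
                      end = 12000L, stringsAsFactors = FALSE)
  ann <- make_annotation(genes, exons)
  sc$start <- c(10500L, 20000L, 60000L, sample(70000:900000, n - 3L))
  sc$end <- sc$start + 500L
  res <- score_associations(sc, meta, ann, metric = "mse_median")
  expect_equal(res$length_assoc$rho, 1)
  expect_equal(res$genic$class[1:3], c("coding", "intronic", "intergenic"))
  # independent purity: small correlation, typically not significant
  expect_lt(abs(res$purity_assoc$rho), 0.5)
})
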