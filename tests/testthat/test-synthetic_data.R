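# The generator runs here use a reduced genome (one or two contigs) so each
# stage stays fast; the full default study is exercised by the acceptance
# suite.

small_cfg <- function(seed = 9, ...) {
  args <- list(seed = seed, n_contigs = 2L, contig_length = 3000000L,
               tumor_types = paste0("t", 1:2), tumor_categories = "c1",
               samples_per_type = 4L, sv_rate = 6,
               driver_bins = data.frame(chrom = "ctg1", start = 1000000L),
               carriers_per_bin = 3L, n_enhancer_drivers = 2L,
               n_genes = 30L, n_enhancers = 150L, n_repeats = 60L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("the genome generator is deterministic and plants its motifs", {
  cfg <- small_cfg()
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  p <- toy_params()
  # every contig carries several boundary motifs at the annotated positions
  for (ch in names(g1$genome)) {
    b <- g1$boundaries[g1$boundaries$chrom == ch, ]
    expect_gte(nrow(b), 4L)
    for (k in seq_len(nrow(b))) {
      found <- substr(g1$genome[[ch]], b$start[k] + 1L, b$end[k])
      expect_true(found %in% c(p$boundary_motif, revcomp(p$boundary_motif)))
    }
  }
  # anchors are convergent pairs: forward motif left of the reverse one
  expect_true(all(g1$anchors$fwd_start < g1$anchors$rev_start))
  expect_error(generate_genome(sim_config(contig_length = 2000000L)),
               "too short")
})

test_that("enhancer counts follow the configured correlated distribution", {
  cfg <- small_cfg(n_enhancers = 5000L)
  g <- generate_genome(cfg)
  enh <- generate_epigenome(cfg, g)
  expect_true(all(enh$atac_count >= 0 & enh$h3k27ac_count >= 0))
  expect_true(all(enh$atac_count == round(enh$atac_count)))
  expect_equal(mean(enh$atac_count), cfg$count_mean, tolerance = 0.1)
  expect_equal(mean(enh$h3k27ac_count), cfg$count_mean, tolerance = 0.1)
  # the shared gamma factor induces positive correlation
  expect_gt(cor(enh$atac_count, enh$h3k27ac_count), 0.5)
  expect_equal(unique(enh$end - enh$start), cfg$enhancer_width)
  # zero-enhancer configuration gives an empty table
  expect_equal(nrow(generate_epigenome(small_cfg(n_enhancers = 0L), g)), 0L)
})

test_that("the cohort plants drivers that delete exactly one boundary motif", {
  cfg <- small_cfg()
  g <- generate_genome(cfg)
  enh <- generate_epigenome(cfg, g)
  co <- generate_cohort(cfg, g, enh)
  truth_b <- co$truth[co$truth$class == "boundary", ]
  expect_equal(nrow(truth_b), cfg$carriers_per_bin * nrow(cfg$driver_bins))
  p <- toy_params()
  for (k in seq_len(nrow(truth_b))) {
    seg <- substr(g$genome[[truth_b$chrom[k]]], truth_b$start[k] + 1L,
                  truth_b$end[k])
    hits <- length(scan_motif_cpp(seg, p$boundary_motif)) +
            length(scan_motif_cpp(seg, revcomp(p$boundary_motif)))
    expect_equal(hits, 1L)
  }
  # carriers span at least two tumor types
  types <- co$meta$tumor_type[match(truth_b$sample_id, co$meta$sample_id)]
  expect_gte(length(unique(types)), 2L)
  # drivers carry wider breakpoint confidence intervals than passengers
  drv <- co$svs[co$svs$id %in% co$truth$sv_id, ]
  pas <- co$svs[!co$svs$id %in% co$truth$sv_id, ]
  expect_gt(min(drv$cipos_hi), max(0L, min(pas$cipos_hi)))
})

test_that("stage structure and determinism hold at cohort scale", {
  cfg <- sim_config(seed = 10, n_contigs = 1L, contig_length = 3000000L,
                    tumor_types = paste0("t", 1:4),
                    tumor_categories = c("c1", "c2"),
                    samples_per_type = 50L, sv_rate = 2,
                    driver_bins = data.frame(chrom = "ctg1",
                                             start = 1000000L),
                    carriers_per_bin = 3L, n_enhancer_drivers = 0L,
                    n_genes = 10L, n_enhancers = 20L)
  g <- generate_genome(cfg)
  co <- generate_cohort(cfg, g)
  expect_equal(nrow(co$meta), 200L)
  expect_equal(mean(co$meta$stage == "progressive"), 0.25, tolerance = 0.05)
  # progressive samples share a subset of their initial sample's SVs
  pairs <- split(co$meta$sample_id, co$meta$participant_id)
  pairs <- pairs[lengths(pairs) == 2L]
  expect_gt(length(pairs), 0L)
  key <- function(df) paste(df$chrom, df$start, df$end, df$svtype)
  shared_any <- vapply(pairs, function(ss) {
    a <- co$svs[co$svs$sample_id == ss[1], ]
    b <- co$svs[co$svs$sample_id == ss[2], ]
    sum(key(b) %in% key(a))
  }, 0)
  expect_gt(sum(shared_any), 0)
  co2 <- generate_cohort(cfg, g)
  expect_identical(co$svs, co2$svs)
  expect_identical(co$meta, co2$meta)
})

test_that("expression shifts driver targets and is otherwise exchangeable", {
  cfg <- small_cfg()
  g <- generate_genome(cfg)
  enh <- generate_epigenome(cfg, g)
  co <- generate_cohort(cfg, g, enh)
  tpm <- generate_expression(cfg, g, co)
  expect_true(all(tpm > 0))
  expect_equal(dim(tpm), c(nrow(g$genes), nrow(co$meta)))
  expect_identical(tpm, generate_expression(cfg, g, co))
  tr <- co$truth[!is.na(co$truth$target_gene), ]
  if (nrow(tr)) {
    k <- tr[1, ]
    others <- setdiff(colnames(tpm), co$truth$sample_id)
    carrier_val <- tpm[k$target_gene, k$sample_id]
    other_vals <- tpm[k$target_gene, others]
    if (k$expr_shift_sign > 0) {
      expect_gt(carrier_val, quantile(other_vals, 0.75))
    } else {
      expect_lt(carrier_val, quantile(other_vals, 0.25))
    }
  }
})

test_that("generated VCFs round-trip through the parser without errors", {
  cfg <- small_cfg()
  outdir <- withr::local_tempdir()
  study <- simulate_study(cfg, outdir = outdir)
  expect_true(file.exists(file.path(outdir, "genome.fa")))
  sid <- study$meta$sample_id[1]
  back <- read_sv_vcf(file.path(outdir, "vcf", paste0(sid, ".vcf")), sid)
  expect_length(attr(back, "parse_errors"), 0L)
  orig <- study$svs[study$svs$sample_id == sid, ]
  expect_equal(nrow(back), nrow(orig))
  back <- back[match(orig$id, back$id), ]
  rownames(back) <- rownames(orig) <- NULL
  expect_equal(back, orig, ignore_attr = TRUE)
  # FASTA round trip preserves the genome byte for byte
  expect_identical(load_genome(file.path(outdir, "genome.fa")),
                   study$genome)
  # gene annotation round trip through rtracklayer
  ann <- read_gene_annotation(file.path(outdir, "genes.gff3"))
  expect_equal(nrow(ann$genes), nrow(study$annotations$genes))
  expect_equal(sort(ann$genes$gene_id),
               sort(study$annotations$genes$gene_id))
})
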