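test_that("VCF records are converted to 0-based half-open coordinates", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
               '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
               '##INFO=<ID=CIPOS,Number=2,Type=Integer,Description="c">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               paste("chr4", 6948840, "d1", "N", "<DEL>", ".", "PASS",
                     "SVTYPE=DEL;END=6949029;CIPOS=-10,10", sep = "\t")),
             tf)
  sv <- read_sv_vcf(tf, "s1")
  expect_equal(nrow(sv), 1L)
  expect_equal(sv$start, 6948839L)
  expect_equal(sv$end, 6949029L)
  expect_equal(sv_length(sv), 190L)
  expect_equal(c(sv$cipos_lo, sv$cipos_hi), c(-10L, 10L))
  expect_equal(sv$ciend_lo, 0L)  # absent CIEND defaults to zero width
})

test_that("BND mate pairs are joined into a single record", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
               '##INFO=<ID=MATEID,Number=1,Type=String,Description="m">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t45703450\tb1\tN\tN[chrX:112696292[\t.\tPASS\tSVTYPE=BND;MATEID=b2",
               "chrX\t112696292\tb2\tN\t]chr1:45703450]N\t.\tPASS\tSVTYPE=BND;MATEID=b1"),
             tf)
  sv <- read_sv_vcf(tf, "s1")
  expect_equal(nrow(sv), 1L)
  expect_equal(sv$svtype, "BND")
  expect_equal(sv$chrom, "chr1")
  expect_equal(sv$end, 45703450L)          # junction after the printed base
  expect_equal(sv$mate_chrom, "chrX")
  expect_equal(sv$mate_pos, 112696292L)
  expect_equal(sv$orientation, "t[p[")
  expect_true(sv$mate_resolved)
  expect_true(is.na(sv_length(sv)))
})

test_that("empty and malformed records are handled non-fatally", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), tf)
  expect_equal(nrow(read_sv_vcf(tf, "s1")), 0L)

  writeLines(c("##fileformat=VCFv4.2",
               '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
               '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\tbad1\tN\tN[chrX-112[\t.\tPASS\tSVTYPE=BND",
               "chr1\t200\tbad2\tN\t<DEL>\t.\tPASS\tEND=300",
               "chr1\t400\tok\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=500"), tf)
  expect_warning(sv <- read_sv_vcf(tf, "s1"), "could not be parsed")
  expect_equal(sv$id, "ok")
  expect_length(attr(sv, "parse_errors"), 2L)
})

test_that("the callset filter removes each exclusion class and conserves counts", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_filter_fixture(tf)
  svs <- read_sv_vcf(tf, "s1")
  expect_equal(nrow(svs), 12L)
  flt <- filter_variants(svs)
  expect_equal(flt$retained$id, paste0("ok", 1:6))
  rep_counts <- setNames(flt$report$n, flt$report$reason)
  expect_equal(rep_counts[["non_pass"]], 2L)
  expect_equal(rep_counts[["over_length"]], 1L)
  expect_equal(rep_counts[["duplicate_breakpoints"]], 2L)
  expect_equal(rep_counts[["unresolved_mate"]], 1L)
  expect_equal(sum(flt$report$n), nrow(svs))

  # idempotence: filtering the retained set removes nothing
  flt2 <- filter_variants(flt$retained)
  expect_equal(nrow(flt2$retained), nrow(flt$retained))
  expect_equal(sum(flt2$report$n[flt2$report$reason != "retained"]), 0L)
})

test_that("duplicate-breakpoint removal drops every group member, within sample", {
  a <- make_sv("a", start = 100L, end = 200L, sample_id = "S1")
  b <- make_sv("b", start = 100L, end = 200L, sample_id = "S1")
  c <- make_sv("c", start = 100L, end = 200L, sample_id = "S2")
  flt <- filter_variants(rbind(a, b, c))
  expect_equal(flt$retained$id, "c")  # S2's copy survives: matching is per sample
  flt_cohort <- filter_variants(rbind(a, b, c), duplicate_scope = "cohort")
  expect_equal(nrow(flt_cohort$retained), 0L)
  flt_keep <- filter_variants(rbind(a, b, c), duplicate_keep_one = TRUE)
  expect_equal(sort(flt_keep$retained$id), c("a", "c"))
})

test_that("sv_length covers all variant classes", {
  svs <- rbind(
    make_sv("d", start = 6948839L, end = 6949029L, svtype = "DEL"),
    make_sv("i", start = 10L, end = 11L, svtype = "INS",
            inserted_seq = strrep("A", 50L)),
    make_sv("b", start = 99L, end = 100L, svtype = "BND",
            orientation = "t[p[", mate_chrom = "ctgA", mate_pos = 500L,
            mate_resolved = TRUE))
  expect_equal(sv_length(svs), c(190L, 50L, NA_integer_))
})

test_that("writing retained variants and re-reading reproduces them exactly", {
  svs <- rbind(
    make_sv("v1", start = 700000L, end = 705000L, svtype = "DEL",
            cipos_lo = -5L, cipos_hi = 5L),
    make_sv("v2", start = 800000L, end = 812000L, svtype = "DUP"),
    make_sv("v3", start = 900000L, end = 903000L, svtype = "INV",
            ciend_lo = -7L, ciend_hi = 7L),
    make_sv("v4", start = 1000000L, end = 1000001L, svtype = "INS",
            inserted_seq = "ACGTACGTGGCC"),
    make_sv("v5", start = 1099999L, end = 1100000L, svtype = "BND",
            orientation = "t]p]", mate_chrom = "ctgA", mate_pos = 1200000L,
            mate_id = "v5_m", mate_resolved = TRUE))
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(svs, tf, contigs = c(ctgA = 2400000L))
  back <- read_sv_vcf(tf, "S1")
  attr(back, "parse_errors") <- NULL
  back <- back[match(svs$id, back$id), ]
  rownames(back) <- rownames(svs) <- NULL
  expect_equal(back, svs, ignore_attr = TRUE)
})

test_that("sample metadata is validated on read", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  m <- data.frame(sample_id = c("S1", "S2"), participant_id = c("P1", "P2"),
                  tumor_type = "t", tumor_category = "c",
                  stage = c("initial", "progressive"), purity = c(0.5, NA))
  write.table(m, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_silent(meta <- read_sample_meta(tf))
  expect_equal(meta$stage, c("initial", "progressive"))

  m$stage[2] <- "relapse"
  write.table(m, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sample_meta(tf), "stage")
})
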