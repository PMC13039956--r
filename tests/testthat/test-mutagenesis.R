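# Independent oracle used throughout: apply the variant to the whole contig
# with plain string surgery, then read the expected ALT window out of the
# edited contig.  This checks the flank-extension arithmetic end to end.

test_that("prediction window geometry matches the published span", {
  g <- fixture_genome()
  sv <- make_sv(start = 1199000L, end = 1201000L)
  w <- build_window(sv, g$genome)
  expect_equal(w$input_end - w$input_start, 1048576L)
  expect_equal(w$visible_end - w$visible_start, 448L * 2048L)
  expect_equal(w$visible_end - w$visible_start, 186410215L - 185492711L)
  expect_equal(w$input_start, 1200000L - 1048576L %/% 2L)  # midpoint centering
  expect_false(w$clamped)
})

test_that("windows near contig edges are clamped by shifting the center", {
  g <- fixture_genome()
  sv <- make_sv(start = 100000L, end = 100100L)
  w <- build_window(sv, g$genome)
  expect_equal(w$input_start, 0L)
  expect_true(w$clamped)
  short <- c(tiny = strrep("A", 1000L))
  expect_error(build_window(make_sv(chrom = "tiny"), short),
               "contig_too_short")
})

test_that("ALT sequences equal windows of an independently edited contig", {
  g <- fixture_genome()
  contig <- g$genome[["ctgA"]]
  len <- nchar(contig)
  L <- 1048576L
  cases <- list(
    list(svtype = "DEL", start = 1199000L, end = 1203097L),   # 4097 bp, odd
    list(svtype = "DUP", start = 1195000L, end = 1203000L),
    list(svtype = "INV", start = 1190000L, end = 1200000L),
    list(svtype = "INS", start = 1201000L, end = 1201001L,
         inserted_seq = paste0(rep("ACGGT", 401L), collapse = "")))  # 2005 bp
  for (cs in cases) {
    sv <- do.call(make_sv, c(list(id = cs$svtype), cs))
    pair <- build_sequence_pair(sv, g$genome, "none")
    expect_equal(nchar(pair$ref_seq), L)
    expect_equal(nchar(pair$alt_seq), L)
    st <- cs$start; en <- cs$end
    l <- if (cs$svtype == "INS") nchar(cs$inserted_seq) else en - st
    lceil <- (l + 1L) %/% 2L; lfloor <- l %/% 2L
    w <- pair$window
    is <- w$input_start; ie <- w$input_end
    edited <- switch(cs$svtype,
      DEL = paste0(substr(contig, 1, st), substr(contig, en + 1L, len)),
      DUP = paste0(substr(contig, 1, en), substr(contig, st + 1L, en),
                   substr(contig, en + 1L, len)),
      INS = paste0(substr(contig, 1, st), cs$inserted_seq,
                   substr(contig, st + 1L, len)),
      INV = paste0(substr(contig, 1, st),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(substr(contig, st + 1L, en)))),
                   substr(contig, en + 1L, len)))
    expected <- switch(cs$svtype,
      DEL = substr(edited, is - lceil + 1L, ie + lfloor - l),
      DUP = substr(edited, is + lceil + 1L, ie - lfloor + l),
      INS = substr(edited, is + lceil + 1L, ie - lfloor + l),
      INV = substr(edited, is + 1L, ie))
    expect_identical(pair$alt_seq, expected)
    expect_identical(pair$ref_seq, substr(contig, is + 1L, ie))
  }
})

test_that("variant mask bins cover the variant and the ALT junction", {
  g <- fixture_genome()
  sv <- make_sv(svtype = "DEL", start = 1199000L, end = 1203097L)
  pair <- build_sequence_pair(sv, g$genome, "none")
  w <- pair$window
  b0 <- (sv$start - w$visible_start) %/% 2048L
  b1 <- (sv$end - 1L - w$visible_start) %/% 2048L
  expect_true(all(seq.int(b0, b1) %in% pair$mask_bins))
  expect_true(all(pair$mask_bins >= 0 & pair$mask_bins < 448))
})

test_that("augmentations shift the window or reverse-complement the pair", {
  g <- fixture_genome()
  sv <- make_sv(svtype = "DEL", start = 1199000L, end = 1203000L)
  pairs <- lapply(c("none", "shift_minus1", "shift_plus1", "revcomp"),
                  function(a) build_sequence_pair(sv, g$genome, a))
  expect_equal(vapply(pairs, function(p) p$augmentation, ""),
               c("none", "shift_minus1", "shift_plus1", "revcomp"))
  # shifted REF windows move by one base
  expect_identical(substr(pairs[[2]]$ref_seq, 2L, 10L),
                   substr(pairs[[1]]$ref_seq, 1L, 9L))
  expect_identical(substr(pairs[[3]]$ref_seq, 1L, 9L),
                   substr(pairs[[1]]$ref_seq, 2L, 10L))
  # revcomp pair is the exact reverse complement of the unaugmented pair
  expect_identical(pairs[[4]]$ref_seq,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(pairs[[1]]$ref_seq))))
  expect_equal(sort(pairs[[4]]$mask_bins), sort(447L - pairs[[1]]$mask_bins))
})

test_that("INV changes exactly the inverted segment", {
  g <- fixture_genome()
  sv <- make_sv(svtype = "INV", start = 1190000L, end = 1200000L)
  pair <- build_sequence_pair(sv, g$genome, "none")
  is <- pair$window$input_start
  ref <- pair$ref_seq; alt <- pair$alt_seq
  a <- sv$start - is; b <- sv$end - is   # 0-based within window
  expect_identical(substr(alt, 1L, a), substr(ref, 1L, a))
  expect_identical(substr(alt, b + 1L, nchar(alt)),
                   substr(ref, b + 1L, nchar(ref)))
  expect_false(substr(alt, a + 1L, b) == substr(ref, a + 1L, b))
})

test_that("breakend fusion sequences match hand-built strings, all orientations", {
  g <- fixture_genome()
  contig <- g$genome[["ctgA"]]
  half <- 1048576L %/% 2L
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  sub0 <- function(a, b) substr(contig, a + 1L, b)   # 0-based half-open
  jA <- 700000L   # junction on the A side
  pB <- 1500000L  # printed partner position (1-based)
  q0 <- pB - 1L
  mk_bnd <- function(orient) {
    # internal representation: end = junction; for t-first forms the printed
    # POS equals the junction, otherwise junction + 1
    make_sv("bx", svtype = "BND", start = jA - 1L, end = jA,
            orientation = orient, mate_chrom = "ctgA", mate_pos = pB,
            mate_id = "bx_m", mate_resolved = TRUE)
  }
  expected_alt_a <- list(
    "t[p[" = paste0(sub0(jA - half, jA), sub0(q0, q0 + half)),
    "t]p]" = paste0(sub0(jA - half, jA), rc(sub0(q0 + 1L - half, q0 + 1L))),
    "]p]t" = paste0(sub0(q0 + 1L - half, q0 + 1L), sub0(jA, jA + half)),
    "[p[t" = paste0(rc(sub0(q0, q0 + half)), sub0(jA, jA + half)))
  for (o in names(expected_alt_a)) {
    pairs <- build_bnd_pairs(mk_bnd(o), g$genome, "none")
    expect_identical(pairs[[1]]$alt_seq, expected_alt_a[[o]])
    # REF of pair 1 is the unbroken window around the A junction
    expect_identical(pairs[[1]]$ref_seq, sub0(jA - half, jA + half))
    # the A half of the fusion equals the matching REF half
    a_first <- o %in% c("t[p[", "t]p]")
    if (a_first) {
      expect_identical(substr(pairs[[1]]$alt_seq, 1L, half),
                       substr(pairs[[1]]$ref_seq, 1L, half))
      expect_equal(pairs[[1]]$side, 0:223)
    } else {
      expect_equal(pairs[[1]]$side, 224:447)
    }
    expect_equal(sort(pairs[[1]]$mask_bins), c(223L, 224L))
  }
})

test_that("a reference-orientation junction at adjacent coordinates is silent", {
  g <- fixture_genome()
  j <- 1200000L
  sv <- make_sv("ident", svtype = "BND", start = j - 1L, end = j,
                orientation = "t[p[", mate_chrom = "ctgA",
                mate_pos = j + 1L, mate_id = "ident_m", mate_resolved = TRUE)
  pairs <- build_bnd_pairs(sv, g$genome, "none")
  expect_identical(pairs[[1]]$alt_seq, pairs[[1]]$ref_seq)
  res <- score_variant(sv, g$genome, make_predictor("toy", g$params))
  expect_equal(res$mse_median, 0)
  expect_equal(res$corr_median, 0)  # zero-variance difference flagged as 0
})
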