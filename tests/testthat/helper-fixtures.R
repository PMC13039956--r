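# Shared fixtures and independent oracles.  The fixture genome is built once
# per test run and memoized; all expected values are computed by brute-force
# or hand arithmetic, never by the code paths under test.

.fixtures <- new.env(parent = emptyenv())

# single 2.4 Mb contig with boundary motifs every 300 kb and one convergent
# anchor pair; deterministic
fixture_genome <- function() {
  if (!is.null(.fixtures$genome)) return(.fixtures$genome)
  set.seed(4242)
  p <- toy_params()
  len <- 2400000L
  v <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  plant <- function(v, pos, m) {
    v[(pos + 1L):(pos + nchar(m))] <- strsplit(m, "")[[1]]
    v
  }
  bpos <- seq(200000L, 2200000L, by = 300000L)
  for (b in bpos) v <- plant(v, b, p$boundary_motif)
  v <- plant(v, 950000L, p$anchor_motif)
  v <- plant(v, 1050000L, revcomp(p$anchor_motif))
  g <- list(genome = c(ctgA = paste0(v, collapse = "")),
            boundaries = bpos,
            anchors = c(f = 950000L, r = 1050000L),
            params = p)
  .fixtures$genome <- g
  g
}

make_sv <- function(id = "sv1", chrom = "ctgA", start = 0L, end = 1L,
                    svtype = "DEL", inserted_seq = NA_character_,
                    orientation = NA_character_,
                    mate_chrom = NA_character_, mate_pos = NA_integer_,
                    mate_id = NA_character_, mate_resolved = NA,
                    cipos_lo = 0L, cipos_hi = 0L, ciend_lo = 0L,
                    ciend_hi = 0L, filter_status = "PASS",
                    sample_id = "S1") {
  data.frame(id = id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), svtype = svtype,
             inserted_seq = inserted_seq, orientation = orientation,
             mate_chrom = mate_chrom, mate_pos = mate_pos,
             mate_id = mate_id, mate_resolved = mate_resolved,
             cipos_lo = cipos_lo, cipos_hi = cipos_hi, ciend_lo = ciend_lo,
             ciend_hi = ciend_hi, filter_status = filter_status,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

# random symmetric map with zeroed near-diagonal, any size
rand_sym_map <- function(n, min_sep = 2L) {
  m <- matrix(rnorm(n * n), n, n)
  m <- (m + t(m)) / 2
  m[abs(row(m) - col(m)) < min_sep] <- 0
  m
}

# brute-force nested-loop comparison oracle (independent of the package's
# compiled path)
oracle_compare <- function(ref, alt, mask_bins = integer(0),
                           req_bins = NULL, min_sep = 2L) {
  n <- nrow(ref)
  mask <- rep(FALSE, n); mask[mask_bins + 1L] <- TRUE
  req <- rep(TRUE, n)
  if (!is.null(req_bins)) { req <- rep(FALSE, n); req[req_bins + 1L] <- TRUE }
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i < min_sep) next
      if (mask[i] || mask[j]) next
      if (!(req[i] || req[j])) next
      xs <- c(xs, ref[i, j]); ys <- c(ys, alt[i, j])
    }
  }
  list(mse = mean((xs - ys)^2),
       corr = 1 - suppressWarnings(cor(xs, ys)),
       n_cells = length(xs))
}

oracle_track <- function(ref, alt, mask_bins = integer(0), min_sep = 2L) {
  n <- nrow(ref)
  mask <- rep(FALSE, n); mask[mask_bins + 1L] <- TRUE
  tr <- numeric(n)
  for (i in seq_len(n)) {
    if (mask[i]) next
    vals <- numeric(0)
    for (j in seq_len(n)) {
      if (abs(i - j) < min_sep || mask[j]) next
      vals <- c(vals, (ref[i, j] - alt[i, j])^2)
    }
    tr[i] <- if (length(vals)) mean(vals) else 0
  }
  tr
}

# rank-based AUROC of positive vs negative score vectors
auroc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# 12-record filter fixture: 6 clean variants, 2 non-PASS, 1 over-length,
# 2 sharing identical breakpoints, 1 breakend without its mate record
write_filter_fixture <- function(path) {
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="l">',
           '##INFO=<ID=MATEID,Number=1,Type=String,Description="m">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rec <- c(
    "chr1\t1001\tok1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=2000",
    "chr1\t5001\tok2\tN\t<DUP>\t.\tPASS\tSVTYPE=DUP;END=9000",
    "chr1\t20001\tok3\tN\t<INV>\t.\tPASS\tSVTYPE=INV;END=25000",
    "chr2\t100\tok4\tN\tNACGTACGT\t.\tPASS\tSVTYPE=INS;SVLEN=8",
    "chr2\t30001\tok5\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=30500",
    "chr2\t40001\tok6\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=41000",
    "chr1\t50001\tnp1\tN\t<DEL>\t.\tLowQual\tSVTYPE=DEL;END=51000",
    "chr1\t60001\tnp2\tN\t<DUP>\t.\tMinSomaticScore\tSVTYPE=DUP;END=61000",
    "chr3\t1001\tlong1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=601001",
    "chr3\t700001\tdupA\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=701000",
    "chr3\t700001\tdupB\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=701000",
    "chr4\t100\tlone\tN\tN[chr5:900[\t.\tPASS\tSVTYPE=BND;MATEID=ghost")
  writeLines(c(hdr, rec), path)
  path
}

# minimal gene annotation list compatible with read_gene_annotation() output
make_annotation <- function(genes, exons = NULL) {
  if (is.null(exons))
    exons <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE)
  list(genes = genes, exons = exons)
}
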