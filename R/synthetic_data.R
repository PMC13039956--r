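# Synthetic study generator: a toy genome with motif-encoded domain
# boundaries and loop anchors, enhancer elements with paired ATAC/H3K27ac
# counts, multi-tumor-type SV cohorts with planted boundary-deleting
# drivers, initial/progressive sample pairs, and expression values shifted
# in driver-bearing samples.  The whole study is a pure function of the
# configuration (all randomness flows from config$seed via fixed per-stage
# sub-seeds).

#' Configuration of the synthetic study
#'
#' Defaults encode the study conditions the pipeline is exercised under:
#' three 6 Mb contigs with domain boundaries every ~400 kb, six tumor types
#' in three categories with ten samples each, Poisson(35) SVs per sample
#' (the cohort-wide median SV burden), two designated 1 Mb driver bins with
#' eight boundary-deleting DEL carriers each, a quarter of samples being
#' progressive recurrences sharing half their SVs with the matched initial
#' sample, and a +/-1.5 log2 expression shift at driver target genes.
#'
#' @param seed master seed (integer < 2^31).
#' @param n_contigs,contig_length genome shape (default 3 x 6 Mb).
#' @param boundary_spacing_mean,boundary_jitter_sd boundary motif spacing
#'   (bp).
#' @param anchor_pair_rate probability a domain gets a convergent loop
#'   anchor pair.
#' @param n_genes,n_repeats annotation counts.
#' @param n_enhancers enhancer count; `enhancer_width` their width (bp).
#' @param count_mean,count_size negative-binomial mean and size for the
#'   ATAC/H3K27ac read counts (shared-gamma correlated).
#' @param tumor_types,tumor_categories type and category labels (types are
#'   assigned to categories round-robin).
#' @param samples_per_type samples per tumor type.
#' @param sv_rate Poisson mean SVs per sample.
#' @param sv_type_mix named mixture over DEL/DUP/INV/INS/BND for passenger
#'   SVs.
#' @param passenger_log10_len range of log10 passenger lengths (bp).
#' @param driver_bins data.frame (chrom, start) of designated 1 Mb driver
#'   bins.
#' @param carriers_per_bin boundary-driver carriers per bin.
#' @param n_enhancer_drivers DEL/DUP drivers overlapping top-activity
#'   enhancers (a second, enhancer-proximal driver class).
#' @param progressive_fraction fraction of samples that are progressive
#'   recurrences (their participant also has an initial sample).
#' @param shared_sv_fraction fraction of the initial sample's SVs retained
#'   in its progressive sample.
#' @param ci_passenger,ci_driver breakpoint confidence-interval half-width
#'   ranges (bp).
#' @param expr_meanlog,expr_sdlog_gene,expr_sdlog_noise log-normal
#'   expression baseline parameters.
#' @param driver_expr_shift absolute log2 fold change at driver target
#'   genes.
#' @param edge_margin minimum distance of any SV from a contig edge (bp);
#'   keeps prediction windows unclamped.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 3L, contig_length = 6000000L,
                       boundary_spacing_mean = 400000L,
                       boundary_jitter_sd = 50000L,
                       anchor_pair_rate = 0.6,
                       n_genes = 120L, n_repeats = 400L,
                       n_enhancers = 900L, enhancer_width = 500L,
                       count_mean = 50, count_size = 5,
                       tumor_types = paste0("type", 1:6),
                       tumor_categories = paste0("category", 1:3),
                       samples_per_type = 10L,
                       sv_rate = 35,
                       sv_type_mix = c(DEL = 0.40, DUP = 0.25, INV = 0.15,
                                       INS = 0.10, BND = 0.10),
                       passenger_log10_len = c(2, 4),
                       driver_bins = data.frame(
                         chrom = c("ctg1", "ctg2"),
                         start = c(2000000L, 3000000L)),
                       carriers_per_bin = 8L,
                       n_enhancer_drivers = 4L,
                       progressive_fraction = 0.25,
                       shared_sv_fraction = 0.5,
                       ci_passenger = c(0L, 10L), ci_driver = c(10L, 60L),
                       expr_meanlog = log(10), expr_sdlog_gene = 0.8,
                       expr_sdlog_noise = 0.4,
                       driver_expr_shift = 1.5,
                       edge_margin = 600000L) {
  stopifnot(abs(sum(sv_type_mix) - 1) < 1e-8, all(sv_type_mix >= 0),
            seed < 2^31)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Generate the toy genome and its annotations
#'
#' Random background sequence with boundary motifs at jittered spacing
#' (random strand), convergent anchor pairs inside a fraction of the
#' domains, genes with exon chains, and labelled repeat intervals.  Only the
#' two motifs are written into the sequence; genes, repeats and enhancers
#' are annotations.
#'
#' @param config [sim_config()].
#' @param params [toy_params()] supplying the motif strings.
#' @return list: `genome` (named character vector), `boundaries`, `anchors`,
#'   `genes`, `exons`, `repeats` (data.frames, 0-based half-open),
#'   `contig_lengths`.
#' @export
generate_genome <- function(config, params = toy_params()) {
  set.seed(config$seed + 1L)
  if (config$contig_length < L_IN + 2L * config$edge_margin)
    stop("contig too short for the prediction window geometry")
  contigs <- paste0("ctg", seq_len(config$n_contigs))
  motif_b <- params$boundary_motif
  motif_a <- params$anchor_motif
  genome <- character(0)
  boundaries <- anchors <- list()
  for (ch in contigs) {
    len <- config$contig_length
    seq_vec <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    # boundary positions: jittered spacing across the contig
    pos <- config$boundary_spacing_mean %/% 2L
    bpos <- integer(0)
    while (pos < len - config$edge_margin %/% 2L) {
      bpos <- c(bpos, pos)
      step <- round(rnorm(1, config$boundary_spacing_mean,
                          config$boundary_jitter_sd))
      pos <- pos + max(step, 150000L)
    }
    bstrand <- sample(c("+", "-"), length(bpos), replace = TRUE)
    for (k in seq_along(bpos)) {
      m <- if (bstrand[k] == "+") motif_b else revcomp(motif_b)
      seq_vec[(bpos[k] + 1L):(bpos[k] + 12L)] <- strsplit(m, "")[[1]]
    }
    boundaries[[ch]] <- data.frame(chrom = ch, start = bpos,
                                   end = bpos + 12L, strand = bstrand,
                                   stringsAsFactors = FALSE)
    # convergent anchor pairs within domains
    blocks <- cbind(c(0L, bpos + 12L), c(bpos, len))
    apos <- list()
    for (b in seq_len(nrow(blocks))) {
      if (runif(1) > config$anchor_pair_rate) next
      b0 <- blocks[b, 1L] + 20000L
      b1 <- blocks[b, 2L] - 20000L
      if (b1 - b0 < 80000L) next
      f <- round(runif(1, b0, b0 + (b1 - b0) * 0.4))
      r <- round(runif(1, f + 30000L, b1))
      seq_vec[(f + 1L):(f + 12L)] <- strsplit(motif_a, "")[[1]]
      seq_vec[(r + 1L):(r + 12L)] <- strsplit(revcomp(motif_a), "")[[1]]
      apos[[length(apos) + 1L]] <- data.frame(
        chrom = ch, fwd_start = f, rev_start = r, stringsAsFactors = FALSE)
    }
    anchors[[ch]] <- if (length(apos)) do.call(rbind, apos) else
      data.frame(chrom = character(), fwd_start = integer(),
                 rev_start = integer(), stringsAsFactors = FALSE)
    genome[ch] <- paste0(seq_vec, collapse = "")
  }
  boundaries <- do.call(rbind, boundaries)
  anchors <- do.call(rbind, anchors)
  rownames(boundaries) <- rownames(anchors) <- NULL

  # genes with exon chains
  genes <- exons <- list()
  for (g in seq_len(config$n_genes)) {
    ch <- sample(contigs, 1L)
    glen <- round(runif(1, 5000, 60000))
    gstart <- round(runif(1, config$edge_margin,
                          config$contig_length - config$edge_margin - glen))
    n_ex <- sample(3:8, 1L)
    ex_starts <- sort(round(runif(n_ex, gstart, gstart + glen - 300L)))
    ex_len <- sample(100:300, n_ex, replace = TRUE)
    ex_end <- pmin(ex_starts + ex_len, gstart + glen)
    genes[[g]] <- data.frame(
      gene_id = sprintf("gene%03d", g), chrom = ch, start = gstart,
      end = gstart + glen, strand = sample(c("+", "-"), 1L),
      protein_coding = runif(1) > 0.1, stringsAsFactors = FALSE)
    exons[[g]] <- data.frame(gene_id = sprintf("gene%03d", g), chrom = ch,
                             start = ex_starts, end = ex_end,
                             stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)

  # labelled repeat intervals
  fams <- c("SINE", "LINE", "LTR", "Simple_repeat")
  rep_ch <- sample(contigs, config$n_repeats, replace = TRUE)
  rep_len <- sample(200:2000, config$n_repeats, replace = TRUE)
  rep_start <- round(runif(config$n_repeats, 1000,
                           config$contig_length - 3000))
  repeats <- data.frame(chrom = rep_ch, start = rep_start,
                        end = rep_start + rep_len,
                        family = sample(fams, config$n_repeats,
                                        replace = TRUE),
                        stringsAsFactors = FALSE)
  list(genome = genome, boundaries = boundaries, anchors = anchors,
       genes = genes, exons = exons, repeats = repeats,
       contig_lengths = setNames(rep(config$contig_length,
                                     config$n_contigs), contigs))
}

#' Generate enhancer elements with correlated ATAC and H3K27ac counts
#'
#' Enhancers are ~500 bp elements placed preferentially near gene starts
#' (70% within 50 kb of a transcription start, the rest uniform).  The two
#' read counts are negative-binomially distributed and correlated through a
#' shared per-element gamma factor.
#'
#' @param config [sim_config()].
#' @param genome_art [generate_genome()] result.
#' @return data.frame: chrom, start, end, name, score, strand, atac_count,
#'   h3k27ac_count, activity.
#' @export
generate_epigenome <- function(config, genome_art) {
  set.seed(config$seed + 2L)
  n <- config$n_enhancers
  if (n == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = integer(),
                      strand = character(), atac_count = integer(),
                      h3k27ac_count = integer(), activity = numeric(),
                      stringsAsFactors = FALSE))
  genes <- genome_art$genes
  near_gene <- runif(n) < 0.7 & nrow(genes) > 0
  chrom <- character(n)
  start <- integer(n)
  for (i in seq_len(n)) {
    if (near_gene[i]) {
      g <- genes[sample(nrow(genes), 1L), ]
      tss <- if (g$strand == "+") g$start else g$end
      pos <- round(rnorm(1, tss, 20000))
      chrom[i] <- g$chrom
    } else {
      chrom[i] <- sample(names(genome_art$contig_lengths), 1L)
      pos <- round(runif(1, 1000,
                         genome_art$contig_lengths[[chrom[i]]] - 1000))
    }
    start[i] <- min(max(pos, 1000L),
                    genome_art$contig_lengths[[chrom[i]]] - 1000L)
  }
  shared <- rgamma(n, shape = config$count_size, rate = config$count_size)
  atac <- rpois(n, config$count_mean * shared)
  h3k <- rpois(n, config$count_mean * shared)
  data.frame(chrom = chrom, start = start,
             end = start + config$enhancer_width,
             name = sprintf("enh%04d", seq_len(n)), score = 0L,
             strand = ".", atac_count = atac, h3k27ac_count = h3k,
             activity = element_activity(atac, h3k),
             stringsAsFactors = FALSE)
}

# all motif intervals to avoid when placing passengers (both motif classes)
motif_intervals <- function(genome_art) {
  b <- genome_art$boundaries[, c("chrom", "start", "end")]
  a1 <- data.frame(chrom = genome_art$anchors$chrom,
                   start = genome_art$anchors$fwd_start,
                   end = genome_art$anchors$fwd_start + 12L)
  a2 <- data.frame(chrom = genome_art$anchors$chrom,
                   start = genome_art$anchors$rev_start,
                   end = genome_art$anchors$rev_start + 12L)
  rbind(b, a1, a2)
}

overlaps_any <- function(mot, chrom, start, end) {
  any(mot$chrom == chrom & mot$start < end & mot$end > start)
}

#' Generate the SV cohort with planted drivers
#'
#' Passenger SVs are placed uniformly away from the planted motifs; boundary
#' drivers are DELs removing exactly one boundary motif inside the
#' designated driver bins, carried by `carriers_per_bin` samples spanning at
#' least two tumor types; enhancer drivers are DELs/DUPs overlapping
#' top-activity enhancers.  Progressive samples retain a configurable
#' fraction of their matched initial sample's SVs and add new private ones.
#' Breakpoint confidence intervals are wider for drivers.
#'
#' @param config [sim_config()].
#' @param genome_art [generate_genome()] result.
#' @param enhancers [generate_epigenome()] result (may be NULL when
#'   `n_enhancer_drivers` is 0).
#' @return list: `svs` (cohort SV data.frame), `meta` (sample metadata),
#'   `truth` (planted driver table: sv id, sample, class, bin, target gene,
#'   expression shift sign).
#' @export
generate_cohort <- function(config, genome_art, enhancers = NULL) {
  set.seed(config$seed + 3L)
  mot <- motif_intervals(genome_art)
  contigs <- names(genome_art$contig_lengths)
  clen <- genome_art$contig_lengths
  margin <- config$edge_margin

  n_types <- length(config$tumor_types)
  type_cat <- setNames(config$tumor_categories[
    ((seq_len(n_types) - 1L) %% length(config$tumor_categories)) + 1L],
    config$tumor_types)

  # sample sheet: per type, samples_per_type samples; a share of them are
  # progressive recurrences of another (initial) sample in the same type
  total <- n_types * config$samples_per_type
  n_pairs_total <- round(total * config$progressive_fraction)
  pairs_per_type <- diff(round(seq(0, n_pairs_total, length.out = n_types + 1)))
  meta <- list()
  s_idx <- 0L
  p_idx <- 0L
  pair_of <- character(0)   # progressive sample -> its initial sample
  for (ti in seq_len(n_types)) {
    tt <- config$tumor_types[ti]
    n_pair <- pairs_per_type[ti]
    n_singles <- config$samples_per_type - 2L * n_pair
    stopifnot(n_singles >= 0)
    for (k in seq_len(n_singles)) {
      s_idx <- s_idx + 1L; p_idx <- p_idx + 1L
      meta[[s_idx]] <- data.frame(
        sample_id = sprintf("S%03d", s_idx),
        participant_id = sprintf("P%03d", p_idx), tumor_type = tt,
        tumor_category = type_cat[[tt]], stage = "initial",
        purity = round(runif(1, 0.3, 0.95), 3), stringsAsFactors = FALSE)
    }
    for (k in seq_len(n_pair)) {
      p_idx <- p_idx + 1L
      s_idx <- s_idx + 1L
      ini_id <- sprintf("S%03d", s_idx)
      meta[[s_idx]] <- data.frame(
        sample_id = ini_id, participant_id = sprintf("P%03d", p_idx),
        tumor_type = tt, tumor_category = type_cat[[tt]], stage = "initial",
        purity = round(runif(1, 0.3, 0.95), 3), stringsAsFactors = FALSE)
      s_idx <- s_idx + 1L
      pro_id <- sprintf("S%03d", s_idx)
      meta[[s_idx]] <- data.frame(
        sample_id = pro_id, participant_id = sprintf("P%03d", p_idx),
        tumor_type = tt, tumor_category = type_cat[[tt]],
        stage = "progressive", purity = round(runif(1, 0.3, 0.95), 3),
        stringsAsFactors = FALSE)
      pair_of[pro_id] <- ini_id
    }
  }
  meta <- do.call(rbind, meta)

  rand_passenger <- function(sample_id, sv_no) {
    svtype <- sample(names(config$sv_type_mix), 1L,
                     prob = config$sv_type_mix)
    for (try in 1:50) {
      ch <- sample(contigs, 1L)
      if (svtype == "BND") {
        d <- round(10^runif(1, 3, 4.3))
        j1 <- round(runif(1, margin, clen[[ch]] - margin - d))
        j2 <- j1 + d
        if (overlaps_any(mot, ch, j1 - 12L, j1 + 12L) ||
            overlaps_any(mot, ch, j2 - 12L, j2 + 12L)) next
        ci <- sample(config$ci_passenger[1]:config$ci_passenger[2], 2L,
                     replace = TRUE)
        return(data.frame(
          id = sprintf("%s_sv%03d", sample_id, sv_no), chrom = ch,
          start = j1 - 1L, end = j1, svtype = "BND",
          inserted_seq = NA_character_, orientation = "t[p[",
          mate_chrom = ch, mate_pos = j2 + 1L,
          mate_id = sprintf("%s_sv%03d_m", sample_id, sv_no),
          mate_resolved = TRUE, cipos_lo = -ci[1], cipos_hi = ci[1],
          ciend_lo = -ci[2], ciend_hi = ci[2], filter_status = "PASS",
          sample_id = sample_id, stringsAsFactors = FALSE))
      }
      l <- round(10^runif(1, config$passenger_log10_len[1],
                          config$passenger_log10_len[2]))
      st <- round(runif(1, margin, clen[[ch]] - margin - l))
      if (svtype == "INS") {
        if (overlaps_any(mot, ch, st - 12L, st + 12L)) next
        ins <- paste0(sample(c("A", "C", "G", "T"), l, replace = TRUE),
                      collapse = "")
        ci <- sample(config$ci_passenger[1]:config$ci_passenger[2], 2L,
                     replace = TRUE)
        return(data.frame(
          id = sprintf("%s_sv%03d", sample_id, sv_no), chrom = ch,
          start = st, end = st + 1L, svtype = "INS", inserted_seq = ins,
          orientation = NA_character_, mate_chrom = NA_character_,
          mate_pos = NA_integer_, mate_id = NA_character_,
          mate_resolved = NA, cipos_lo = -ci[1], cipos_hi = ci[1],
          ciend_lo = -ci[2], ciend_hi = ci[2], filter_status = "PASS",
          sample_id = sample_id, stringsAsFactors = FALSE))
      }
      if (overlaps_any(mot, ch, st - 12L, st + l + 12L)) next
      ci <- sample(config$ci_passenger[1]:config$ci_passenger[2], 2L,
                   replace = TRUE)
      return(data.frame(
        id = sprintf("%s_sv%03d", sample_id, sv_no), chrom = ch,
        start = st, end = st + l, svtype = svtype,
        inserted_seq = NA_character_, orientation = NA_character_,
        mate_chrom = NA_character_, mate_pos = NA_integer_,
        mate_id = NA_character_, mate_resolved = NA,
        cipos_lo = -ci[1], cipos_hi = ci[1], ciend_lo = -ci[2],
        ciend_hi = ci[2], filter_status = "PASS", sample_id = sample_id,
        stringsAsFactors = FALSE))
    }
    stop("could not place passenger SV away from motifs")
  }

  # passengers for initial samples (progressives are derived below)
  svs <- list()
  initial_ids <- meta$sample_id[meta$stage == "initial"]
  for (sid in initial_ids) {
    n_sv <- rpois(1, config$sv_rate)
    for (k in seq_len(n_sv))
      svs[[length(svs) + 1L]] <- rand_passenger(sid, k)
  }

  # progressive samples: shared subset of the initial SVs plus new private
  # passengers (same expected burden)
  for (pro in names(pair_of)) {
    ini <- pair_of[[pro]]
    ini_svs <- do.call(rbind, svs[vapply(svs, function(x)
      x$sample_id == ini, TRUE)])
    n_ini <- if (is.null(ini_svs)) 0L else nrow(ini_svs)
    n_share <- if (n_ini > 0)
      rbinom(1, n_ini, config$shared_sv_fraction) else 0L
    if (n_share > 0) {
      shared <- ini_svs[sample(nrow(ini_svs), n_share), , drop = FALSE]
      shared$sample_id <- pro
      shared$id <- sub(paste0("^", ini), pro, shared$id)
      shared$mate_id <- sub(paste0("^", ini), pro, shared$mate_id)
      for (k in seq_len(nrow(shared)))
        svs[[length(svs) + 1L]] <- shared[k, ]
    }
    n_new <- rpois(1, config$sv_rate * (1 - config$shared_sv_fraction))
    for (k in seq_len(n_new))
      svs[[length(svs) + 1L]] <- rand_passenger(pro, 500L + k)
  }
  svs <- do.call(rbind, svs)

  # boundary-deleting drivers in the designated bins
  truth <- list()
  bnd_tab <- genome_art$boundaries
  for (b in seq_len(nrow(config$driver_bins))) {
    bin_ch <- config$driver_bins$chrom[b]
    bin_start <- config$driver_bins$start[b]
    in_bin <- bnd_tab[bnd_tab$chrom == bin_ch &
                      bnd_tab$start >= bin_start &
                      bnd_tab$end <= bin_start + 1000000L, , drop = FALSE]
    if (nrow(in_bin) == 0)
      stop("driver bin ", bin_ch, ":", bin_start,
           " contains no boundary motif")
    # carriers span at least two tumor types
    repeat {
      carriers <- sample(meta$sample_id, config$carriers_per_bin)
      if (length(unique(meta$tumor_type[match(carriers,
                                              meta$sample_id)])) >= 2) break
    }
    for (ci_ in seq_along(carriers)) {
      sid <- carriers[ci_]
      mrow <- in_bin[sample(nrow(in_bin), 1L), ]
      # interval containing exactly this one boundary motif
      others <- mot[mot$chrom == bin_ch &
                    !(mot$start == mrow$start & mot$end == mrow$end), ]
      for (try in 1:50) {
        u1 <- round(runif(1, 1000, 8000))
        u2 <- round(runif(1, 1000, 8000))
        st <- mrow$start - u1
        en <- mrow$end + u2
        if (!overlaps_any(others, bin_ch, st, en)) break
        if (try == 50) stop("could not isolate driver boundary motif")
      }
      ciw <- sample(config$ci_driver[1]:config$ci_driver[2], 2L,
                    replace = TRUE)
      drv_id <- sprintf("%s_drv%d", sid, b)
      svs <- rbind(svs, data.frame(
        id = drv_id, chrom = bin_ch, start = st, end = en, svtype = "DEL",
        inserted_seq = NA_character_, orientation = NA_character_,
        mate_chrom = NA_character_, mate_pos = NA_integer_,
        mate_id = NA_character_, mate_resolved = NA,
        cipos_lo = -ciw[1], cipos_hi = ciw[1], ciend_lo = -ciw[2],
        ciend_hi = ciw[2], filter_status = "PASS", sample_id = sid,
        stringsAsFactors = FALSE))
      truth[[length(truth) + 1L]] <- data.frame(
        sv_id = drv_id, sample_id = sid, class = "boundary",
        bin = paste0(bin_ch, ":", bin_start), chrom = bin_ch, start = st,
        end = en, stringsAsFactors = FALSE)
    }
  }

  # enhancer-proximal drivers: DEL/DUP over the highest-activity enhancers
  if (config$n_enhancer_drivers > 0 && !is.null(enhancers) &&
      nrow(enhancers) > 0) {
    top <- enhancers[order(-enhancers$activity), ]
    top <- top[top$start > margin &
               top$end < clen[top$chrom] - margin, , drop = FALSE]
    n_ed <- min(config$n_enhancer_drivers, nrow(top))
    carriers <- sample(meta$sample_id, n_ed)
    for (k in seq_len(n_ed)) {
      e <- top[k, ]
      sid <- carriers[k]
      st <- e$start - round(runif(1, 500, 3000))
      en <- e$end + round(runif(1, 500, 3000))
      svtype <- sample(c("DEL", "DUP"), 1L)
      ciw <- sample(config$ci_driver[1]:config$ci_driver[2], 2L,
                    replace = TRUE)
      drv_id <- sprintf("%s_edrv%d", sid, k)
      svs <- rbind(svs, data.frame(
        id = drv_id, chrom = e$chrom, start = st, end = en, svtype = svtype,
        inserted_seq = NA_character_, orientation = NA_character_,
        mate_chrom = NA_character_, mate_pos = NA_integer_,
        mate_id = NA_character_, mate_resolved = NA,
        cipos_lo = -ciw[1], cipos_hi = ciw[1], ciend_lo = -ciw[2],
        ciend_hi = ciw[2], filter_status = "PASS", sample_id = sid,
        stringsAsFactors = FALSE))
      truth[[length(truth) + 1L]] <- data.frame(
        sv_id = drv_id, sample_id = sid, class = "enhancer",
        bin = paste0(e$chrom, ":",
                     (e$start %/% 1000000L) * 1000000L),
        chrom = e$chrom, start = st, end = en, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sv_id = character(), sample_id = character(),
               class = character(), bin = character(), chrom = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)

  # driver target genes and expression shift signs (one sign per bin)
  truth$target_gene <- NA_character_
  truth$expr_shift_sign <- NA_integer_
  if (nrow(truth)) {
    bin_sign <- setNames(sample(c(-1L, 1L), length(unique(truth$bin)),
                                replace = TRUE), unique(truth$bin))
    genes <- genome_art$genes
    for (k in seq_len(nrow(truth))) {
      cand <- genes[genes$chrom == truth$chrom[k] &
                    genes$start < truth$end[k] + 300000L &
                    genes$end > truth$start[k] - 300000L &
                    # target lies beside, not inside, the variant
                    !(genes$start < truth$end[k] &
                      genes$end > truth$start[k]), , drop = FALSE]
      if (nrow(cand)) {
        mid <- (truth$start[k] + truth$end[k]) / 2
        d <- pmin(abs(cand$start - mid), abs(cand$end - mid))
        truth$target_gene[k] <- cand$gene_id[which.min(d)]
        truth$expr_shift_sign[k] <- bin_sign[[truth$bin[k]]]
      }
    }
  }
  rownames(svs) <- rownames(meta) <- rownames(truth) <- NULL
  list(svs = svs, meta = meta, truth = truth)
}

#' Generate the expression table
#'
#' Log-normal baseline per gene; samples carrying a planted driver within
#' 300 kb of a gene get the configured log2 shift, with the sign recorded in
#' the truth table.
#'
#' @param config [sim_config()].
#' @param genome_art [generate_genome()] result.
#' @param cohort [generate_cohort()] result.
#' @return numeric matrix, genes x samples (TPM-like, all > 0).
#' @export
generate_expression <- function(config, genome_art, cohort) {
  set.seed(config$seed + 4L)
  genes <- genome_art$genes$gene_id
  samples <- cohort$meta$sample_id
  base <- rlnorm(length(genes), config$expr_meanlog, config$expr_sdlog_gene)
  tpm <- matrix(rlnorm(length(genes) * length(samples),
                       meanlog = rep(log(base), length(samples)),
                       sdlog = config$expr_sdlog_noise),
                nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  tr <- cohort$truth
  if (!is.null(tr) && nrow(tr)) {
    for (k in seq_len(nrow(tr))) {
      g <- tr$target_gene[k]
      if (is.na(g)) next
      shift <- 2^(tr$expr_shift_sign[k] * config$driver_expr_shift)
      tpm[g, tr$sample_id[k]] <- tpm[g, tr$sample_id[k]] * shift
    }
  }
  tpm
}

#' Generate and (optionally) write the complete synthetic study
#'
#' Runs all four generator stages.  With `outdir`, writes the study to disk
#' in standard formats: genome FASTA, gene/exon GFF3, boundary/anchor/repeat
#' BEDs, enhancer BED6+2, one VCF per sample, metadata TSV, truth TSV and
#' expression TSV.
#'
#' @param config [sim_config()].
#' @param params [toy_params()] used for the motif strings.
#' @param outdir output directory or NULL (in-memory only).
#' @return list: config, genome artifacts, enhancers, cohort (svs, meta,
#'   truth), tpm, and `files` when written.
#' @export
simulate_study <- function(config = sim_config(), params = toy_params(),
                           outdir = NULL) {
  genome_art <- generate_genome(config, params)
  enhancers <- generate_epigenome(config, genome_art)
  cohort <- generate_cohort(config, genome_art, enhancers)
  tpm <- generate_expression(config, genome_art, cohort)
  study <- list(config = config, genome = genome_art$genome,
                annotations = genome_art[c("boundaries", "anchors", "genes",
                                           "exons", "repeats")],
                contig_lengths = genome_art$contig_lengths,
                enhancers = enhancers, svs = cohort$svs, meta = cohort$meta,
                truth = cohort$truth, tpm = tpm)
  class(study) <- "svfold_study"
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(outdir, x)
    write_genome(study$genome, fp("genome.fa"))
    write_gene_gff3(genome_art$genes, genome_art$exons, fp("genes.gff3"))
    wbed <- function(df, path, cols) {
      write.table(df[, cols], path, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
      path
    }
    wbed(genome_art$boundaries, fp("boundaries.bed"),
         c("chrom", "start", "end", "strand"))
    wbed(cbind(genome_art$repeats, name = genome_art$repeats$family),
         fp("repeats.bed"), c("chrom", "start", "end", "family"))
    wbed(enhancers, fp("enhancers.bed"),
         c("chrom", "start", "end", "name", "score", "strand",
           "atac_count", "h3k27ac_count"))
    vcf_dir <- fp("vcf")
    dir.create(vcf_dir, showWarnings = FALSE)
    for (sid in study$meta$sample_id) {
      write_sv_vcf(study$svs[study$svs$sample_id == sid, , drop = FALSE],
                   file.path(vcf_dir, paste0(sid, ".vcf")),
                   contigs = study$contig_lengths,
                   source_tag = "svfold-simulate")
    }
    write.table(study$meta, fp("samples.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(study$truth, fp("truth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(gene_id = rownames(tpm), tpm,
                           check.names = FALSE),
                fp("tpm.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    study$files <- list(outdir = outdir)
  }
  study
}

# GFF3 writer for the toy annotation via rtracklayer
write_gene_gff3 <- function(genes, exons, path) {
  g1 <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end),
                               strand = genes$strand)
  g1$type <- "gene"
  g1$ID <- genes$gene_id
  g1$biotype <- ifelse(genes$protein_coding, "protein_coding",
                       "non_coding")
  g2 <- GenomicRanges::GRanges(exons$chrom,
                               IRanges::IRanges(exons$start + 1L, exons$end))
  g2$type <- "exon"
  g2$ID <- paste0(exons$gene_id, "_ex", seq_along(g2))
  g2$Parent <- exons$gene_id
  gr <- suppressWarnings(c(g1, g2))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @export
#' @method print svfold_study
print.svfold_study <- function(x, ...) {
  cat(sprintf("synthetic study: %d contigs, %d samples, %d SVs (%d planted drivers), %d enhancers\n",
              length(x$genome), nrow(x$meta), nrow(x$svs), nrow(x$truth),
              nrow(x$enhancers)))
  invisible(x)
}
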