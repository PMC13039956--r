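# SV callset I/O and the callset filters applied before scoring.
#
# Internally an SV callset is a plain data.frame with one row per variant and
# 0-based half-open coordinates:
#   id, chrom, start, end, svtype, inserted_seq, orientation, mate_chrom,
#   mate_pos, mate_id, mate_resolved, cipos_lo, cipos_hi, ciend_lo, ciend_hi,
#   filter_status, sample_id
# For DEL/DUP/INV, [start, end) is the affected segment.  For INS, end =
# start + 1 and the novel sequence is in inserted_seq.  For BND, end is the
# 0-based inter-base junction coordinate (start = end - 1 is the base
# immediately left of the junction), orientation is one of the four VCF
# bracket forms "t[p[", "t]p]", "]p]t", "[p[t", and mate_pos is the partner
# locus as printed (1-based).

SV_COLS <- c("id", "chrom", "start", "end", "svtype", "inserted_seq",
             "orientation", "mate_chrom", "mate_pos", "mate_id",
             "mate_resolved", "cipos_lo", "cipos_hi", "ciend_lo", "ciend_hi",
             "filter_status", "sample_id")

empty_sv_frame <- function() {
  data.frame(id = character(), chrom = character(), start = integer(),
             end = integer(), svtype = character(),
             inserted_seq = character(), orientation = character(),
             mate_chrom = character(), mate_pos = integer(),
             mate_id = character(), mate_resolved = logical(),
             cipos_lo = integer(), cipos_hi = integer(),
             ciend_lo = integer(), ciend_hi = integer(),
             filter_status = character(), sample_id = character(),
             stringsAsFactors = FALSE)
}

info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
  out <- rep(NA_character_, length(info))
  hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0
  out[hit] <- sub(paste0("^;?", key, "="), "", m)
  out
}

parse_ci <- function(x) {
  lo <- rep(0L, length(x)); hi <- rep(0L, length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    parts <- strsplit(x[ok], ",", fixed = TRUE)
    lo[ok] <- as.integer(vapply(parts, `[`, "", 1L))
    hi[ok] <- as.integer(vapply(parts, `[`, "", 2L))
  }
  list(lo = lo, hi = hi)
}

parse_bracket_alt <- function(alt) {
  # returns list(ok, orientation, mate_chrom, mate_pos)
  m <- regexec("^([ACGTN]*)(\\[|\\])([^\\[\\]:]+):([0-9]+)(\\[|\\])([ACGTN]*)$",
               alt, perl = TRUE)
  g <- regmatches(alt, m)[[1]]
  if (length(g) == 0 || g[3] != g[6])
    return(list(ok = FALSE))
  t_first <- nzchar(g[2])
  t_last <- nzchar(g[7])
  if (t_first == t_last) return(list(ok = FALSE))
  br <- g[3]
  orientation <- if (t_first) {
    if (br == "[") "t[p[" else "t]p]"
  } else {
    if (br == "[") "[p[t" else "]p]t"
  }
  list(ok = TRUE, orientation = orientation, mate_chrom = g[4],
       mate_pos = as.integer(g[5]))
}

mate_orientation <- function(o) {
  switch(o, "t[p[" = "]p]t", "]p]t" = "t[p[", "t]p]" = "t]p]",
         "[p[t" = "[p[t", stop("unknown orientation: ", o))
}

#' Read structural variant calls from a Manta-style VCF
#'
#' Parses DEL/DUP/INV/INS/BND records into the package's 0-based half-open
#' representation.  BND mates are joined through MATEID and each mate pair is
#' emitted once (the breakend that sorts first by chromosome and position is
#' kept; its partner locus is recorded in the `mate_*` columns).  Records with
#' a malformed bracket ALT or a missing SVTYPE are dropped, collected in the
#' `parse_errors` attribute of the result, and reported with a warning.
#'
#' @param path VCF file (v4.2; INFO keys SVTYPE, END, SVLEN, CIPOS, CIEND,
#'   MATEID).
#' @param sample_id sample label attached to every returned variant.
#' @return data.frame of variants (see package internals for columns), with
#'   attribute `parse_errors`.
#' @export
read_sv_vcf <- function(path, sample_id = NA_character_) {
  stopifnot(file.exists(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(fx) || nrow(fx) == 0) {
    out <- empty_sv_frame()
    attr(out, "parse_errors") <- character()
    return(out)
  }
  fx <- as.data.frame(fx, stringsAsFactors = FALSE)
  info <- fx$INFO
  svtype <- info_field(info, "SVTYPE")
  errors <- character()
  keep <- rep(TRUE, nrow(fx))

  bad_type <- is.na(svtype) | !(svtype %in% SV_TYPES)
  if (any(bad_type)) {
    errors <- c(errors, paste0("record ", which(bad_type),
                               ": missing or unsupported SVTYPE"))
    keep[bad_type] <- FALSE
  }

  pos <- suppressWarnings(as.integer(fx$POS))
  endv <- suppressWarnings(as.integer(info_field(info, "END")))
  svlen <- suppressWarnings(as.integer(info_field(info, "SVLEN")))
  cipos <- parse_ci(info_field(info, "CIPOS"))
  ciend <- parse_ci(info_field(info, "CIEND"))
  mateid <- info_field(info, "MATEID")
  ids <- fx$ID
  no_id <- is.na(ids) | ids == "." | ids == ""
  ids[no_id] <- paste0("sv", which(no_id))

  n <- nrow(fx)
  out <- data.frame(
    id = ids, chrom = fx$CHROM, start = NA_integer_, end = NA_integer_,
    svtype = svtype, inserted_seq = NA_character_,
    orientation = NA_character_, mate_chrom = NA_character_,
    mate_pos = NA_integer_, mate_id = mateid,
    mate_resolved = NA, cipos_lo = cipos$lo, cipos_hi = cipos$hi,
    ciend_lo = ciend$lo, ciend_hi = ciend$hi,
    filter_status = fx$FILTER, sample_id = rep(sample_id, n),
    stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    if (!keep[i]) next
    st <- svtype[i]
    if (st %in% c("DEL", "DUP", "INV")) {
      if (is.na(endv[i]) || is.na(pos[i]) || endv[i] <= pos[i] - 1L) {
        errors <- c(errors, paste0("record ", i, ": missing/invalid END"))
        keep[i] <- FALSE
        next
      }
      out$start[i] <- pos[i] - 1L
      out$end[i] <- endv[i]
    } else if (st == "INS") {
      out$start[i] <- pos[i] - 1L
      out$end[i] <- pos[i]
      alt <- fx$ALT[i]
      if (grepl("^[ACGTNacgtn]+$", alt) && nchar(alt) > 1) {
        out$inserted_seq[i] <- toupper(substring(alt, 2L))
      } else if (!is.na(svlen[i]) && svlen[i] > 0) {
        # symbolic <INS> without sequence: length honored, content unknown
        out$inserted_seq[i] <- strrep("N", abs(svlen[i]))
      } else {
        warning("INS record ", i, " has no sequence and no SVLEN; rejected")
        errors <- c(errors, paste0("record ", i, ": INS without sequence"))
        keep[i] <- FALSE
      }
    } else if (st == "BND") {
      br <- parse_bracket_alt(fx$ALT[i])
      if (!br$ok) {
        errors <- c(errors, paste0("record ", i, ": malformed BND ALT '",
                                   fx$ALT[i], "'"))
        keep[i] <- FALSE
        next
      }
      # junction j (0-based inter-base): after POS base for t-first forms,
      # before POS base otherwise
      j <- if (br$orientation %in% c("t[p[", "t]p]")) pos[i] else pos[i] - 1L
      out$start[i] <- j - 1L
      out$end[i] <- j
      out$orientation[i] <- br$orientation
      out$mate_chrom[i] <- br$mate_chrom
      out$mate_pos[i] <- br$mate_pos
    }
  }
  out <- out[keep, , drop = FALSE]

  # join BND mates: emit each pair once, keeping the first-sorting breakend
  is_bnd <- out$svtype == "BND"
  if (any(is_bnd)) {
    bnd <- out[is_bnd, , drop = FALSE]
    present <- !is.na(bnd$mate_id) & bnd$mate_id %in% bnd$id
    bnd$mate_resolved <- present
    ord_key <- order(bnd$chrom, bnd$end, bnd$id)
    rank <- integer(nrow(bnd)); rank[ord_key] <- seq_len(nrow(bnd))
    drop <- rep(FALSE, nrow(bnd))
    idx_of <- setNames(seq_len(nrow(bnd)), bnd$id)
    for (k in seq_len(nrow(bnd))) {
      if (!present[k]) next
      mk <- idx_of[[bnd$mate_id[k]]]
      if (rank[mk] < rank[k]) drop[k] <- TRUE
    }
    out <- rbind(out[!is_bnd, , drop = FALSE], bnd[!drop, , drop = FALSE])
  } else if (nrow(out)) {
    out$mate_resolved[out$svtype == "BND"] <- FALSE
  }
  rownames(out) <- NULL
  if (length(errors))
    warning(length(errors), " VCF record(s) could not be parsed; see ",
            "attr(, 'parse_errors')")
  attr(out, "parse_errors") <- errors
  out
}

#' Write structural variants to a VCF file
#'
#' Inverse of [read_sv_vcf()]: emits one record per non-BND variant and a
#' mate pair of records per BND row.  Coordinates are converted back to
#' 1-based VCF positions; reading the file back reproduces the input rows.
#'
#' @param svs SV data.frame as produced by [read_sv_vcf()] or the cohort
#'   generator.
#' @param path output path.
#' @param contigs optional named integer vector of contig lengths for
#'   `##contig` header lines.
#' @param source_tag value for the `##source` header line.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(svs, path, contigs = NULL, source_tag = "svfold") {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=", source_tag),
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Difference in length between REF and ALT alleles">',
           '##INFO=<ID=CIPOS,Number=2,Type=Integer,Description="Confidence interval around POS">',
           '##INFO=<ID=CIEND,Number=2,Type=Integer,Description="Confidence interval around END">',
           '##INFO=<ID=MATEID,Number=1,Type=String,Description="ID of mate breakend">')
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- character(0)
  ci_str <- function(lo, hi) paste0(lo, ",", hi)
  for (i in seq_len(nrow(svs))) {
    r <- svs[i, ]
    flt <- if (is.na(r$filter_status)) "PASS" else r$filter_status
    if (r$svtype %in% c("DEL", "DUP", "INV")) {
      info <- paste0("SVTYPE=", r$svtype, ";END=", r$end,
                     ";SVLEN=", if (r$svtype == "DEL") -(r$end - r$start)
                                else r$end - r$start,
                     ";CIPOS=", ci_str(r$cipos_lo, r$cipos_hi),
                     ";CIEND=", ci_str(r$ciend_lo, r$ciend_hi))
      recs <- c(recs, paste(r$chrom, r$start + 1L, r$id, "N",
                            paste0("<", r$svtype, ">"), ".", flt, info,
                            sep = "\t"))
    } else if (r$svtype == "INS") {
      info <- paste0("SVTYPE=INS;END=", r$start + 1L,
                     ";SVLEN=", nchar(r$inserted_seq),
                     ";CIPOS=", ci_str(r$cipos_lo, r$cipos_hi),
                     ";CIEND=", ci_str(r$ciend_lo, r$ciend_hi))
      recs <- c(recs, paste(r$chrom, r$start + 1L, r$id, "N",
                            paste0("N", r$inserted_seq), ".", flt, info,
                            sep = "\t"))
    } else if (r$svtype == "BND") {
      o <- r$orientation
      j <- r$end
      pos1 <- if (o %in% c("t[p[", "t]p]")) j else j + 1L
      mid <- if (is.na(r$mate_id)) paste0(r$id, "_m") else r$mate_id
      alt1 <- switch(o,
        "t[p[" = sprintf("N[%s:%d[", r$mate_chrom, r$mate_pos),
        "t]p]" = sprintf("N]%s:%d]", r$mate_chrom, r$mate_pos),
        "]p]t" = sprintf("]%s:%d]N", r$mate_chrom, r$mate_pos),
        "[p[t" = sprintf("[%s:%d[N", r$mate_chrom, r$mate_pos))
      info1 <- paste0("SVTYPE=BND;MATEID=", mid,
                      ";CIPOS=", ci_str(r$cipos_lo, r$cipos_hi),
                      ";CIEND=", ci_str(r$ciend_lo, r$ciend_hi))
      recs <- c(recs, paste(r$chrom, pos1, r$id, "N", alt1, ".", flt, info1,
                            sep = "\t"))
      # reconstruct the reciprocal mate record
      o2 <- mate_orientation(o)
      alt2 <- switch(o2,
        "t[p[" = sprintf("N[%s:%d[", r$chrom, pos1),
        "t]p]" = sprintf("N]%s:%d]", r$chrom, pos1),
        "]p]t" = sprintf("]%s:%d]N", r$chrom, pos1),
        "[p[t" = sprintf("[%s:%d[N", r$chrom, pos1))
      info2 <- paste0("SVTYPE=BND;MATEID=", r$id,
                      ";CIPOS=", ci_str(r$ciend_lo, r$ciend_hi),
                      ";CIEND=", ci_str(r$cipos_lo, r$cipos_hi))
      recs <- c(recs, paste(r$mate_chrom, r$mate_pos, mid, "N", alt2, ".",
                            flt, info2, sep = "\t"))
    }
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Filter an SV callset the way the cohort screen expects
#'
#' Applies, in order: (1) removal of non-PASS records; (2) removal of non-BND
#' variants longer than `max_len` (the predictor window cannot accommodate
#' them); (3) removal of *every* member of any within-sample group of two or
#' more variants sharing identical (chrom, start, end, svtype) breakpoints;
#' (4) removal of BNDs whose reciprocal mate record was absent.
#'
#' @param svs SV data.frame.
#' @param max_len maximum non-BND span in bp (default 500000).
#' @param duplicate_scope `"sample"` (default) restricts identical-breakpoint
#'   matching to each sample's callset; `"cohort"` matches across samples.
#' @param duplicate_keep_one keep one representative of each duplicate group
#'   instead of removing the whole group (default FALSE).
#' @return list with `retained` (data.frame) and `report` (data.frame of
#'   exclusion counts; reasons: non_pass, over_length, duplicate_breakpoints,
#'   unresolved_mate, plus the retained count).
#' @export
filter_variants <- function(svs, max_len = 500000L,
                            duplicate_scope = c("sample", "cohort"),
                            duplicate_keep_one = FALSE) {
  duplicate_scope <- match.arg(duplicate_scope)
  n_in <- nrow(svs)
  counts <- c(non_pass = 0L, over_length = 0L, duplicate_breakpoints = 0L,
              unresolved_mate = 0L)

  cur <- svs
  bad <- !is.na(cur$filter_status) & cur$filter_status != "PASS"
  counts["non_pass"] <- sum(bad)
  cur <- cur[!bad, , drop = FALSE]

  bad <- cur$svtype != "BND" & (cur$end - cur$start) > max_len
  counts["over_length"] <- sum(bad)
  cur <- cur[!bad, , drop = FALSE]

  if (nrow(cur)) {
    key <- paste(cur$chrom, cur$start, cur$end, cur$svtype, sep = "\r")
    if (duplicate_scope == "sample")
      key <- paste(cur$sample_id, key, sep = "\r")
    tab <- table(key)
    in_group <- key %in% names(tab)[tab >= 2]
    if (duplicate_keep_one) {
      bad <- in_group & duplicated(key)
    } else {
      bad <- in_group
    }
    counts["duplicate_breakpoints"] <- sum(bad)
    cur <- cur[!bad, , drop = FALSE]
  }

  bad <- cur$svtype == "BND" & !is.na(cur$mate_resolved) & !cur$mate_resolved
  counts["unresolved_mate"] <- sum(bad)
  cur <- cur[!bad, , drop = FALSE]

  report <- data.frame(reason = c(names(counts), "retained"),
                       n = c(unname(counts), nrow(cur)),
                       stringsAsFactors = FALSE)
  stopifnot(sum(report$n) == n_in)
  rownames(cur) <- NULL
  list(retained = cur, report = report)
}

#' Length of each structural variant
#'
#' Span for DEL/DUP/INV, inserted-sequence length for INS, and NA for BND
#' (length is undefined for a junction).
#'
#' @param svs SV data.frame.
#' @return integer vector of lengths (NA for BND).
#' @export
sv_length <- function(svs) {
  len <- ifelse(svs$svtype %in% c("DEL", "DUP", "INV"),
                svs$end - svs$start,
                ifelse(svs$svtype == "INS", nchar(svs$inserted_seq),
                       NA_integer_))
  as.integer(len)
}

#' Read the sample metadata table
#'
#' @param path TSV with header columns sample_id, participant_id, tumor_type,
#'   tumor_category, stage, purity.
#' @return data.frame.
#' @export
read_sample_meta <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "participant_id", "tumor_type", "tumor_category",
            "stage", "purity")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop("metadata is missing columns: ", paste(missing, collapse = ", "))
  bad_stage <- !m$stage %in% c("initial", "progressive")
  if (any(bad_stage))
    stop("stage must be 'initial' or 'progressive'")
  if (anyDuplicated(m$sample_id))
    stop("sample_id values must be unique")
  m
}
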