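# End-to-end orchestration: simulate -> score -> abc-score -> rdr -> cohort
# statistics, driven by a single configuration list (or JSON file), with a
# run manifest for reproducibility.  The exported functions are the
# interface; inst/scripts/svfold-run.R is a thin command-line wrapper.

#' Default pipeline configuration
#'
#' @param seed master seed.
#' @param outdir output directory.
#' @param predictor `"toy"` or `"akita_adapter"`.
#' @param metric `"mse"`, `"corr"` or `"both"` (reporting; RDR discovery
#'   uses the first).
#' @param aggregate `"median"` or `"mean"`.
#' @param cutoff_percentile highly-disruptive percentile (percent).
#' @param rdr_q BH-adjusted significance threshold for RDR calls.
#' @return configuration list.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("svfold_run_"),
                            predictor = "toy", metric = "mse",
                            aggregate = "median", cutoff_percentile = 98.8,
                            rdr_q = 0.05) {
  list(seed = seed, outdir = outdir, predictor = predictor, metric = metric,
       aggregate = aggregate, cutoff_percentile = cutoff_percentile,
       rdr_q = rdr_q)
}

validate_pipeline_config <- function(config) {
  defaults <- pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  config <- utils::modifyList(defaults, config)
  if (!config$predictor %in% c("toy", "akita_adapter"))
    stop("unknown predictor key: ", config$predictor)
  if (!config$metric %in% c("mse", "corr", "both"))
    stop("unknown metric key: ", config$metric)
  if (!config$aggregate %in% c("median", "mean"))
    stop("unknown aggregate key: ", config$aggregate)
  config
}

#' Run the full pipeline on a synthetic study
#'
#' Simulates the study, reads the per-sample VCFs back through the VCF
#' parser, filters, scores every variant, ABC-weights the top decile,
#' discovers RDRs, runs the cohort statistics, and writes one TSV per stage
#' plus a JSON run manifest.
#'
#' @param config list from [pipeline_config()] (or a path to a JSON file
#'   with those fields).
#' @param sim [sim_config()] for the synthetic study; defaults to
#'   `sim_config(seed = config$seed)`.
#' @return list of class `svfold_run`: study, filtered callset and filter
#'   report, scores, abc table, rank shifts, rdr result, calibration, stage
#'   comparison, manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), sim = NULL) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  config <- validate_pipeline_config(config)
  if (is.null(sim)) sim <- sim_config(seed = config$seed)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(config$outdir, x)

  params <- toy_params()
  predictor <- make_predictor(config$predictor, params)
  study <- simulate_study(sim, params, outdir = fp("study"))

  # read the emitted VCFs back through the parser (the canonical entry path)
  svs <- do.call(rbind, lapply(study$meta$sample_id, function(sid)
    read_sv_vcf(file.path(fp("study"), "vcf", paste0(sid, ".vcf")), sid)))
  flt <- filter_variants(svs)
  write.table(flt$report, fp("filter_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  scored <- score_cohort(flt$retained, study$genome, predictor)
  write_scores_tsv(scored, fp("scored_variants.tsv"))

  score_col <- paste0(if (config$metric == "both") "mse" else config$metric,
                      "_", config$aggregate)
  cal <- calibrate_cutoff(scored, chosen = config$cutoff_percentile)

  # ABC weighting of the top decile of variants
  top <- scored$scores[scored$scores[[score_col]] >=
                       quantile(scored$scores[[score_col]], 0.9), ]
  abc <- abc_score_cohort(
    list_scores_subset(scored, top$id), study$enhancers)
  shifts <- rank_shifts(
    data.frame(id = top$id, score = top[[score_col]]),
    data.frame(id = abc$id, score = abc$abc_score))
  abc_out <- merge(merge(top[, c("id", "sample_id", "svtype", score_col)],
                         abc, by = "id"), shifts, by = "id")
  write.table(abc_out, fp("abc_scores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  rdr <- find_rdrs(scored, study$contig_lengths,
                   metric = if (config$metric == "both") "mse"
                            else config$metric,
                   aggregate = config$aggregate,
                   q_threshold = config$rdr_q, seed = config$seed)
  write.table(rdr$tests, fp("rdr_tests.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(rdr$calls))
    write.table(rdr$calls, fp("rdr_calls.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

  cats <- summarize_categories(scored, study$meta)
  write.table(cats, fp("category_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  stages <- progressive_vs_initial(scored, study$meta,
                                   metric = score_col, seed = config$seed)
  if (!is.null(stages$per_participant))
    write.table(stages$per_participant, fp("stage_comparison.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    config = config,
    sim_seed = sim$seed,
    n_input_svs = nrow(svs),
    n_retained = nrow(flt$retained),
    n_scored = nrow(scored$scores),
    n_score_errors = length(scored$errors),
    cutoff = list(percentile = cal$chosen, mse = cal$threshold_mse,
                  corr = cal$threshold_corr,
                  n_highly_disruptive = length(cal$highly_disruptive)),
    rdr = list(cutoff = rdr$cutoff, n_calls = nrow(rdr$calls),
               bins = rdr$calls$bin),
    outputs = list.files(config$outdir, recursive = TRUE))
  jsonlite::write_json(manifest, fp("run_manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  out <- list(study = study, svs = flt$retained, filter_report = flt$report,
              scored = scored, calibration = cal, abc = abc_out,
              rank_shifts = shifts, rdr = rdr, categories = cats,
              stages = stages, manifest = manifest, config = config)
  class(out) <- "svfold_run"
  out
}

# subset an svfold_scores object to a set of variant ids
list_scores_subset <- function(scored, ids) {
  keep <- scored$scores$id %in% ids
  out <- list(scores = scored$scores[keep, , drop = FALSE],
              tracks = scored$tracks[scored$scores$id[keep]],
              errors = scored$errors)
  class(out) <- "svfold_scores"
  out
}

#' @export
#' @method print svfold_run
print.svfold_run <- function(x, ...) {
  cat("svfold pipeline run\n")
  cat(sprintf("  scored %d/%d variants (%d samples)\n",
              nrow(x$scored$scores), nrow(x$svs) + x$manifest$n_score_errors,
              nrow(x$study$meta)))
  cat(sprintf("  highly disruptive: %d at the %.1fth percentile\n",
              length(x$calibration$highly_disruptive), x$calibration$chosen))
  cat(sprintf("  RDR calls: %d (%s)\n", nrow(x$rdr$calls),
              paste(x$rdr$calls$bin, collapse = ", ")))
  invisible(x)
}
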