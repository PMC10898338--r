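# Config-driven orchestration of the full workflow: generate or read dPCR
# counts, collapse to sample VAFs, run the cohort statistics, summarise a
# testis, and fit/test the stem-cell models.  Results are written as CSV
# (tables) and JSON (statistics) with all seeds and thresholds logged.

#' Run the analysis pipeline from a configuration
#'
#' The configuration is a named list (or path to a YAML file) with an
#' optional block per stage; stages present are run in order:
#' \describe{
#'   \item{`synth`}{`cohort` (arguments to [cohort_spec()]) and/or `testis`
#'     (arguments to [testis_spec()]) plus a `seed`; generated tables are
#'     written and fed to the later stages.}
#'   \item{`vaf`}{`reactions` (CSV path) unless synthetic; writes the
#'     per-sample VAF table.}
#'   \item{`cohort`}{`donors` (CSV path) unless synthetic; writes the
#'     per-variant summary and age-association JSON.}
#'   \item{`testis`}{`pieces` (CSV path) unless synthetic; `threshold`
#'     (default 5e-5); writes pool table, drill-down report and clustering
#'     summary.}
#'   \item{`fit`}{arguments to [germ_fit()] (`observed_avg`, `observed_max`,
#'     `donor_age`, `model`, `fit_reps`, `n_matched`, ...); writes the fit
#'     JSON, plus a replicate-level simulation trace CSV when `trace_reps`
#'     is given.}
#' }
#' A top-level `seed` seeds every stage that lacks its own; `out_dir` sets
#' the output directory.
#'
#' @param config named list or YAML file path.
#' @param out_dir output directory (default `config$out_dir` or tempdir()).
#' @return invisibly, a list with the per-stage results and output paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config) || length(config) == 0)
    stop("empty or invalid configuration")
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- file.path(tempdir(), "spermosaic-run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(config$seed)) config$seed else 1L
  results <- list()
  log <- list(seed = seed,
              version = as.character(utils::packageVersion("spermosaic")))

  synth_reactions <- NULL
  synth_donors <- NULL
  synth_map <- NULL
  if (!is.null(config$synth)) {
    sseed <- if (!is.null(config$synth$seed)) config$synth$seed else seed
    if (!is.null(config$synth$cohort)) {
      sp <- do.call(cohort_spec, config$synth$cohort)
      gc <- gen_cohort(sp, seed = sseed)
      synth_reactions <- gc$reactions
      synth_donors <- gc$donors
      write.csv(gc$reactions, file.path(out_dir, "synthetic_reactions.csv"),
                row.names = FALSE)
      write.csv(gc$donors, file.path(out_dir, "synthetic_donors.csv"),
                row.names = FALSE)
      write.csv(gc$truth, file.path(out_dir, "synthetic_cohort_truth.csv"),
                row.names = FALSE)
      results$synth_cohort <- gc
    }
    if (!is.null(config$synth$testis)) {
      targs <- config$synth$testis
      if (!is.null(targs$planted_clones))
        targs$planted_clones <- as.data.frame(targs$planted_clones)
      sp <- do.call(testis_spec, targs)
      gt <- gen_testis(sp, seed = sseed + 1)
      synth_map <- gt$map
      write.csv(gt$truth, file.path(out_dir, "synthetic_testis_truth.csv"),
                row.names = FALSE)
      results$synth_testis <- gt
    }
    log$synth_seed <- sseed
  }

  if (!is.null(config$vaf) || !is.null(synth_reactions)) {
    reactions <- if (!is.null(config$vaf$reactions))
      read_dpcr_reactions(config$vaf$reactions) else synth_reactions
    if (is.null(reactions)) stop("vaf stage: no reactions input")
    samples <- summarize_dpcr_samples(reactions)
    write_dpcr_samples(samples, file.path(out_dir, "sample_vafs.csv"))
    results$vaf <- samples
  }

  if (!is.null(config$cohort) || !is.null(synth_donors)) {
    donors <- if (!is.null(config$cohort$donors))
      read_donor_table(config$cohort$donors) else synth_donors
    if (is.null(donors)) stop("cohort stage: no donor input")
    summaries <- do.call(rbind, lapply(split(donors, donors$variant_id),
                                       summarize_variant))
    rownames(summaries) <- NULL
    assoc <- age_associations(donors)
    write.csv(summaries, file.path(out_dir, "variant_summaries.csv"),
              row.names = FALSE)
    jsonlite::write_json(assoc, file.path(out_dir, "age_associations.json"),
                         dataframe = "rows", digits = NA, auto_unbox = TRUE)
    results$cohort <- list(summaries = summaries, associations = assoc)
  }

  if (!is.null(config$testis) || !is.null(synth_map)) {
    threshold <- if (!is.null(config$testis$threshold)) config$testis$threshold else 5e-5
    map <- if (!is.null(config$testis$pieces)) {
      tab <- read_testis_table(config$testis$pieces)
      testis_map(tab[tab$unit_type == "piece", ])
    } else synth_map
    if (is.null(map)) stop("testis stage: no piece input")
    pools <- pool_pieces(map)
    drill <- hot_pool_drilldown(map, threshold, pools = pools)
    summ <- testis_summary(map, threshold)
    write.csv(pools, file.path(out_dir, "pool_vafs.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(threshold = threshold,
           flagged_pools = drill$flagged,
           summary = summ),
      file.path(out_dir, "testis_report.json"),
      dataframe = "rows", digits = NA, auto_unbox = TRUE)
    results$testis <- list(pools = pools, drilldown = drill, summary = summ)
    log$testis_threshold <- threshold
  }

  if (!is.null(config$fit)) {
    fargs <- config$fit
    if (is.null(fargs$seed)) fargs$seed <- seed
    trace_reps <- fargs$trace_reps
    fargs$trace_reps <- NULL
    fit <- do.call(germ_fit, fargs)
    if (!is.null(trace_reps)) {
      tr <- simulate(fit, nsim = trace_reps, seed = fargs$seed)
      tr$replicate <- seq_len(nrow(tr))
      write.csv(tr[, c("replicate", "avg_freq", "max_piece_freq")],
                file.path(out_dir, "simulation_trace.csv"), row.names = FALSE)
    }
    s <- summary(fit)
    jsonlite::write_json(
      list(model = s$model,
           parameter = as.list(s$coefficients),
           matched_fraction = s$matched_fraction,
           p_value = s$p_value,
           n_matched = s$n_matched,
           n_sims = s$n_sims,
           seed = fargs$seed,
           version = log$version),
      file.path(out_dir, "model_fit.json"), digits = NA, auto_unbox = TRUE)
    results$fit <- fit
  }

  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       digits = NA, auto_unbox = TRUE)
  results$out_dir <- out_dir
  invisible(results)
}
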