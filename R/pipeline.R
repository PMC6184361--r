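#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: the cohort and design
#' specifications, the estimation grids, analysis toggles and seeds. Fully
#' serializable; every stochastic stage derives its own seed from the base
#' seed so stages are individually re-runnable.
#'
#' @param cohort A [cohort_spec()].
#' @param design A [design_spec()].
#' @param mle_grid_n Points per dimension of the psychometric [mle_grid()]
#'   (201 for the canonical analysis; smaller grids trade resolution for
#'   speed in demonstrations).
#' @param rt_family RT family for [fit_rt_cohort()].
#' @param run_stats,run_classify Stage toggles.
#' @param cv_runs Cross-validation repetitions.
#' @param seed Base seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), design = design_spec(),
                            mle_grid_n = 201L, rt_family = "exgauss",
                            run_stats = TRUE, run_classify = TRUE,
                            cv_runs = 1000L, seed = 1L) {
  structure(list(cohort = cohort, design = design,
                 mle_grid_n = as.integer(mle_grid_n), rt_family = rt_family,
                 run_stats = run_stats, run_classify = run_classify,
                 cv_runs = as.integer(cv_runs), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [pipeline_config()],
#' [cohort_spec()] (`n_adhd`, `n_control`) and [design_spec()]
#' (`block_order`, `trials_per_block`).
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path) else yaml::read_yaml(path)
  cohort_args <- cfg[intersect(names(cfg), c("n_adhd", "n_control", "seed"))]
  design_args <- cfg[intersect(names(cfg), c("block_order", "trials_per_block"))]
  top_args <- cfg[intersect(names(cfg), c("mle_grid_n", "rt_family", "run_stats",
                                          "run_classify", "cv_runs", "seed"))]
  args <- c(list(cohort = do.call(cohort_spec, cohort_args),
                 design = do.call(design_spec, design_args)), top_args)
  do.call(pipeline_config, args)
}

pipeline_log <- function(stage, msg, con = NULL) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full analysis pipeline
#'
#' One command from configuration to artifact directory: simulate the
#' cohort (trials CSV + ground-truth sidecar CSV), fit the psychometric and
#' RT models, assemble the metric table, run the group statistics (ANOVAs,
#' post hocs, Spearman matrix with the effective-number-of-tests
#' correction), and run the classification report. All tabular outputs are
#' CSV; summary statistics land in a JSON report alongside a provenance
#' record (config, seeds, package version). Idempotent given an identical
#' configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param engine Optional shared [psi_engine()].
#' @return `out_dir`, invisibly; artifacts are written inside it.
#' @export
run_pipeline <- function(config, out_dir, engine = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out_dir, "pipeline.log"), open = "wt")
  on.exit(close(logf))
  wcsv <- function(x, name) utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)

  pipeline_log("simulate", sprintf("cohort of %d + %d observers, seed %d",
                                   config$cohort$n_adhd, config$cohort$n_control,
                                   config$seed), logf)
  sim <- simulate_cohort(config$cohort, config$design, engine = engine,
                         seed = config$seed)
  write_trials(sim$trials, file.path(out_dir, "trials.csv"))
  wcsv(sim$truth, "truth.csv")

  pipeline_log("fit", sprintf("psychometric grid ML (%d^3 grid) and %s RT fits",
                              config$mle_grid_n, config$rt_family), logf)
  grid <- mle_grid(config$mle_grid_n)
  psych_fits <- fit_cohort(sim$trials, grid, model = "main")
  wcsv(psych_fits, "psych_fits.csv")
  rt_fits <- fit_rt_cohort(sim$trials, config$rt_family)
  wcsv(rt_fits, "rt_fits.csv")

  pipeline_log("metrics", "building the per-participant metric table", logf)
  metrics <- build_metric_table(sim$trials, psych_fits, rt_fits)
  wcsv(as.data.frame(metrics), "metrics.csv")

  summary_json <- list(config = list(n_adhd = config$cohort$n_adhd,
                                     n_control = config$cohort$n_control,
                                     trials_per_block = config$design$trials_per_block,
                                     mle_grid_n = config$mle_grid_n,
                                     seed = config$seed),
                       package_version = as.character(utils::packageVersion("psyswitch")))

  if (config$run_stats && length(unique(metrics$group)) == 2L) {
    pipeline_log("stats", "mixed ANOVAs, post hocs, Spearman matrix", logf)
    anovas <- list()
    for (m in c("timo", "rt_median", "rt_tau", "sigma")) {
      long <- metric_long(metrics, m, log = TRUE,
                          n_trials_per_condition = config$design$trials_per_block * 2)
      anovas[[m]] <- cbind(metric = m, mixed_anova(long, "value"))
    }
    wcsv(do.call(rbind, anovas), "anova.csv")
    sigma_vals <- data.frame(participant_id = metrics$participant_id,
                             group = metrics$group,
                             metrics[, paste0("sigma_", condition_names())])
    names(sigma_vals)[3:6] <- condition_names()
    wcsv(posthoc_tests(sigma_vals, "threeway"), "posthoc_sigma.csv")
    sp <- spearman_matrix(metrics[, c("log_timo", "log_rt_median", "log_rt_tau",
                                      "log_sigma", "log_lambda")])
    wcsv(as.data.frame(sp$rho), "spearman_rho.csv")
    me <- meff_sidak(sp$rho)
    summary_json$meff <- list(M = me$M, M_eff = me$M_eff, alpha_sid = me$alpha_sid)
  }

  if (config$run_classify && length(unique(metrics$group)) == 2L) {
    pipeline_log("classify", sprintf("logistic classification, %d CV runs",
                                     config$cv_runs), logf)
    k <- min(10L, min(table(metrics$group[metrics$complete])))
    report <- classification_report(metrics, runs = config$cv_runs, k = k,
                                    seed = config$seed)
    wcsv(report, "classification.csv")
    summary_json$classification <- report
  }

  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log("done", paste("artifacts in", out_dir), logf)
  invisible(out_dir)
}
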