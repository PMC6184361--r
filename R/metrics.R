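#' Task-irrelevant motor output metrics
#'
#' Per participant and condition: the proportion of trials on which an
#' irrelevant key was pressed, with a breakdown of the irrelevant presses
#' into spatial, feature and both-error subtypes. A condition with zero
#' trials yields `NA` proportions (flagged, never silently zero).
#'
#' @param trials A validated trial table.
#' @return Data frame with columns `participant_id`, `condition`, `n`,
#'   `n_timo`, `timo` (proportion), `n_spatial`, `n_feature`, `n_both`.
#' @export
timo_metrics <- function(trials) {
  cond <- condition_name(trials$feature, trials$load)
  ids <- unique(trials$participant_id)
  grid <- expand.grid(participant_id = ids, condition = condition_names(),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- trials$participant_id == grid$participant_id[i] & cond == grid$condition[i]
    n <- sum(sel)
    tt <- trials[sel, , drop = FALSE]
    n_timo <- sum(tt$response_class == "timo")
    data.frame(participant_id = grid$participant_id[i],
               condition = grid$condition[i], n = n, n_timo = n_timo,
               timo = if (n > 0) n_timo / n else NA_real_,
               n_spatial = sum(tt$timo_subtype == "spatial"),
               n_feature = sum(tt$timo_subtype == "feature"),
               n_both = sum(tt$timo_subtype == "both"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Proportion correct over relevant-key trials
#'
#' Computed per participant and condition over the non-TIMO trials only.
#' Under adaptive stimulus placement this proportion is expected to be
#' stable (roughly 0.75-0.85) across observers and conditions, which is why
#' the psychometric parameters, not accuracy, carry the analysis.
#'
#' @param trials A validated trial table.
#' @return Data frame with `participant_id`, `condition`, `n_relevant`,
#'   `prop_correct` (`NA` when a cell has no relevant trials).
#' @export
proportion_correct <- function(trials) {
  cond <- condition_name(trials$feature, trials$load)
  rel <- trials$response_class %in% c("r0", "r1")
  ids <- unique(trials$participant_id)
  grid <- expand.grid(participant_id = ids, condition = condition_names(),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- rel & trials$participant_id == grid$participant_id[i] &
      cond == grid$condition[i]
    n <- sum(sel)
    data.frame(participant_id = grid$participant_id[i],
               condition = grid$condition[i], n_relevant = n,
               prop_correct = if (n > 0) mean(trials$correct[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

log_with_offset <- function(x, n, offset_rule = TRUE) {
  out <- ifelse(x > 0, log(x), NA_real_)
  if (offset_rule) {
    zero <- !is.na(x) & x == 0
    out[zero] <- log(0.5 / n[zero])
  }
  out
}

#' Assemble the per-participant metric table
#'
#' Joins the five behavioral metrics — TIMO proportion, RT median,
#' ex-Gaussian RT tau, perceptual variability sigma and lapse rate lambda —
#' per condition, their across-condition averages, natural-log versions of
#' the averages (all five metrics are lower-bounded by zero; a zero TIMO
#' average is logged after adding 0.5 divided by the participant's trial
#' count, a documented and configurable continuity rule), and the clinical
#' scores when supplied. The sigma average mixes the two feature-specific
#' normalized scales; per-condition columns are retained for
#' feature-specific analyses.
#'
#' @param trials Trial table for the cohort.
#' @param psych_fits Output of [fit_cohort()] (`main` model).
#' @param rt_fits Output of [fit_rt_cohort()] (ex-Gaussian).
#' @param clinical Optional data frame `participant_id`, `gec`, `acds`.
#' @param timo_log_offset Apply the zero-TIMO offset rule (default `TRUE`).
#' @return Data frame of class `metric_table`, one row per participant, with
#'   `complete` flagging rows missing any component.
#' @export
build_metric_table <- function(trials, psych_fits, rt_fits, clinical = NULL,
                               timo_log_offset = TRUE) {
  ids <- unique(trials$participant_id)
  tm <- timo_metrics(trials)
  cond <- condition_names()
  rows <- lapply(ids, function(id) {
    tt <- trials[trials$participant_id == id, , drop = FALSE]
    row <- list(participant_id = id, group = tt$group[1])
    # per-condition metrics
    for (cn in cond) {
      row[[paste0("timo_", cn)]] <- tm$timo[tm$participant_id == id & tm$condition == cn]
      rt_row <- rt_fits[rt_fits$participant_id == id & rt_fits$condition == cn, , drop = FALSE]
      row[[paste0("rt_median_", cn)]] <- if (nrow(rt_row)) rt_row$rt_median else NA_real_
      row[[paste0("rt_tau_", cn)]] <- if (nrow(rt_row)) rt_row$tau else NA_real_
      parts <- condition_parts(cn)
      pf <- psych_fits[psych_fits$participant_id == id &
                         psych_fits$feature == parts$feature, , drop = FALSE]
      if (nrow(pf)) {
        row[[paste0("sigma_", cn)]] <- if (parts$load == "switch") pf$sigma_switch else pf$sigma_noswitch
        row[[paste0("lambda_", cn)]] <- pf$lambda
      } else {
        row[[paste0("sigma_", cn)]] <- NA_real_
        row[[paste0("lambda_", cn)]] <- NA_real_
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  for (m in c("timo", "rt_median", "rt_tau", "sigma", "lambda")) {
    per_cond <- as.matrix(out[, paste0(m, "_", cond)])
    out[[m]] <- rowMeans(per_cond)
  }
  n_trials <- vapply(out$participant_id,
                     function(id) sum(trials$participant_id == id), numeric(1))
  out$log_timo <- log_with_offset(out$timo, n_trials, timo_log_offset)
  out$log_rt_median <- log(out$rt_median)
  out$log_rt_tau <- log(out$rt_tau)
  out$log_sigma <- log(out$sigma)
  out$log_lambda <- log(out$lambda)

  if (!is.null(clinical)) {
    idx <- match(out$participant_id, clinical$participant_id)
    out$gec <- clinical$gec[idx]
    out$acds <- clinical$acds[idx]
  } else {
    out$gec <- NA_real_
    out$acds <- NA_real_
  }
  core <- c("timo", "rt_median", "rt_tau", "sigma", "lambda")
  out$complete <- stats::complete.cases(out[, core])
  class(out) <- c("metric_table", "data.frame")
  out
}

#' Read and write clinical score tables
#'
#' CSV with columns `participant_id`, `gec`, `acds` (one row per
#' participant; missing values allowed and flagged with a warning).
#'
#' @param path File path.
#' @return Data frame of clinical scores.
#' @export
read_clinical <- function(path) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  need <- c("participant_id", "gec", "acds")
  if (!all(need %in% names(cl))) {
    stop("clinical CSV must have columns participant_id, gec, acds", call. = FALSE)
  }
  if (anyDuplicated(cl$participant_id)) {
    stop("clinical table must have one row per participant", call. = FALSE)
  }
  if (anyNA(cl[, c("gec", "acds")])) {
    warning("clinical table contains missing scores", call. = FALSE)
  }
  cl
}

#' Per-condition long format of a metric table
#'
#' Reshapes the wide per-condition columns of a [build_metric_table()] into
#' participant x condition rows with `feature` and `load` factors — the
#' layout the mixed-design ANOVA consumes. Metrics are log-transformed on
#' request (per-condition values, the zero-TIMO offset rule using the
#' condition's trial count is approximated with the participant total / 4).
#'
#' @param metrics A `metric_table`.
#' @param metric One of `"timo"`, `"rt_median"`, `"rt_tau"`, `"sigma"`,
#'   `"lambda"`.
#' @param log Log-transform the metric?
#' @param n_trials_per_condition Trial count used by the zero-TIMO log
#'   offset.
#' @return Long data frame: `participant_id`, `group`, `condition`,
#'   `feature`, `load`, `value`.
#' @export
metric_long <- function(metrics, metric, log = TRUE, n_trials_per_condition = 200) {
  cond <- condition_names()
  rows <- lapply(cond, function(cn) {
    parts <- condition_parts(cn)
    data.frame(participant_id = metrics$participant_id, group = metrics$group,
               condition = cn, feature = parts$feature, load = parts$load,
               value = metrics[[paste0(metric, "_", cn)]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (log) {
    out$value <- log_with_offset(out$value,
                                 rep(n_trials_per_condition, nrow(out)))
  }
  out
}
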