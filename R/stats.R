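#' Bootstrap percentile confidence interval for the median
#'
#' Resamples the data with replacement (resample size equal to the original
#' size), computes the median of each resample, and returns the 2.5th and
#' 97.5th percentiles of the resampled medians (for the default 95% level)
#' together with the sample median.
#'
#' @param x Nonempty numeric vector.
#' @param n_iter Number of bootstrap iterations (default 50,000).
#' @param conf Confidence level.
#' @param seed Optional seed applied locally.
#' @return Named vector `c(median, ci_low, ci_high)`.
#' @export
bootstrap_median_ci <- function(x, n_iter = 50000L, conf = 0.95, seed = NULL) {
  if (!length(x)) stop("empty input", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  meds <- vapply(seq_len(n_iter),
                 function(i) stats::median(x[sample.int(n, n, replace = TRUE)]),
                 numeric(1))
  a <- (1 - conf) / 2
  q <- stats::quantile(meds, c(a, 1 - a), names = FALSE)
  c(median = stats::median(x), ci_low = q[1], ci_high = q[2])
}

#' Sidak-corrected significance level
#'
#' `1 - (1 - alpha)^(1/m)` for `m` comparisons: the per-comparison level
#' that keeps the familywise error at `alpha` under independence. With the
#' study's comparison plans, `m = 12` gives 0.0043 and `m = 4` gives 0.0127.
#'
#' @param m Number of comparisons (>= 1); may be fractional (used with the
#'   effective number of tests).
#' @param alpha Familywise level.
#' @return Corrected per-comparison level.
#' @export
sidak_alpha <- function(m, alpha = 0.05) {
  if (any(m < 1)) stop("m must be >= 1", call. = FALSE)
  1 - (1 - alpha)^(1 / m)
}

#' Effective number of tests from a correlation matrix
#'
#' Nyholt's eigenvalue-variance correction for correlated measures: with
#' `M` measures and eigenvalues of their correlation matrix
#' `lambda_obs`, the effective number of comparisons is
#' `M_eff = 1 + (M - 1) * (1 - var(lambda_obs)/M)` and the corrected
#' Sidak level is `1 - (1 - alpha)^(1/M_eff)`. The eigenvalue variance is
#' the sample variance (denominator `M - 1`), which makes the fully
#' redundant all-ones matrix collapse exactly to `M_eff = 1`.
#'
#' @param R Symmetric correlation matrix with unit diagonal.
#' @param alpha Familywise level.
#' @return Object of class `meff` with `M`, `eigenvalues`,
#'   `var_eigenvalues`, `M_eff` and `alpha_sid`.
#' @export
meff_sidak <- function(R, alpha = 0.05) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > 1e-8) {
    stop("R must be a symmetric square matrix", call. = FALSE)
  }
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have unit diagonal", call. = FALSE)
  if (max(abs(R)) > 1 + 1e-8) stop("correlations must lie in [-1, 1]", call. = FALSE)
  M <- nrow(R)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  v <- stats::var(ev)
  m_eff <- 1 + (M - 1) * (1 - v / M)
  out <- list(M = M, eigenvalues = ev, var_eigenvalues = v, M_eff = m_eff,
              alpha_sid = sidak_alpha(m_eff, alpha), alpha = alpha)
  class(out) <- "meff"
  out
}

#' @export
print.meff <- function(x, ...) {
  cat(sprintf("Effective number of tests: M = %d, var(eigenvalues) = %.4f\n",
              x$M, x$var_eigenvalues))
  cat(sprintf("  M_eff = %.4f -> corrected alpha = %.4f (familywise %.2f)\n",
              x$M_eff, x$alpha_sid, x$alpha))
  invisible(x)
}

#' Pairwise Spearman correlation matrix
#'
#' Rank correlations (average ranks on ties) over pairwise-complete
#' observations, with two-sided p values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x Data frame or matrix of numeric columns.
#' @param min_n Minimum complete pairs per correlation.
#' @return List with matrices `rho`, `p` and `n`.
#' @export
spearman_matrix <- function(x, min_n = 3L) {
  x <- as.data.frame(x)
  m <- ncol(x)
  rho <- p <- nn <- matrix(NA_real_, m, m, dimnames = list(names(x), names(x)))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)[-i]) {
      ok <- stats::complete.cases(x[[i]], x[[j]])
      n <- sum(ok)
      nn[i, j] <- n
      if (n < min_n) next
      if (stats::sd(x[[i]][ok]) == 0 || stats::sd(x[[j]][ok]) == 0) {
        warning("constant column: correlation undefined for ",
                names(x)[i], " vs ", names(x)[j], call. = FALSE)
        next
      }
      r <- stats::cor(rank(x[[i]][ok]), rank(x[[j]][ok]))
      rho[i, j] <- r
      p[i, j] <- if (abs(r) >= 1) 0 else {
        tstat <- r * sqrt((n - 2) / (1 - r^2))
        2 * stats::pt(-abs(tstat), df = n - 2)
      }
    }
  }
  diag(nn) <- vapply(x, function(v) sum(!is.na(v)), numeric(1))
  list(rho = rho, p = p, n = nn)
}

#' Balanced mixed-design ANOVA with two-level within factors
#'
#' Univariate mixed-design ANOVA for one between-participants factor (two
#' groups of equal size) and one to three within-participants factors, each
#' with two levels — the 2 x 2 (x 2) repeated-measures designs of the task
#' (load x feature, optionally x time for the split-half learning check).
#' Each within effect (and its interactions) is tested through the
#' per-participant contrast score of the corresponding +/-1 cell contrast;
#' sphericity holds trivially for two-level factors. Reports F, degrees of
#' freedom, p, and partial eta squared
#' (`SS_effect / (SS_effect + SS_error)` with each effect's own error term).
#' Unbalanced or incomplete designs are rejected explicitly.
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column (log-transform
#'   lower-bounded metrics upstream, e.g. via [metric_long()]).
#' @param between Name of the group column (two levels).
#' @param within Character vector of within-factor columns (each two
#'   levels).
#' @param id Name of the participant-id column.
#' @return Data frame of class `anova_table`: `effect`, `F`, `df1`, `df2`,
#'   `p`, `pes` (partial eta squared).
#' @export
mixed_anova <- function(data, dv, between = "group", within = c("load", "feature"),
                        id = "participant_id") {
  y <- data[[dv]]
  if (anyNA(y)) stop("dependent variable contains missing values", call. = FALSE)
  g <- factor(data[[between]])
  if (nlevels(g) != 2L) stop("between factor must have exactly two levels", call. = FALSE)
  wf <- lapply(within, function(w) factor(data[[w]]))
  if (any(vapply(wf, nlevels, 1L) != 2L)) {
    stop("each within factor must have exactly two levels", call. = FALSE)
  }
  pid <- factor(data[[id]])

  cell <- interaction(wf, drop = FALSE)
  n_cells <- 2L^length(within)
  tab <- table(pid, cell)
  if (any(tab != 1L)) {
    stop("design must be balanced and complete: every participant needs exactly ",
         "one observation per within-cell", call. = FALSE)
  }
  pgroup <- tapply(as.character(g), pid, function(v) {
    u <- unique(v)
    if (length(u) != 1L) stop("participant assigned to both groups", call. = FALSE)
    u
  })
  pgroup <- factor(pgroup[levels(pid)])
  if (length(unique(table(pgroup))) != 1L) {
    stop("groups must be of equal size", call. = FALSE)
  }
  n_per_group <- unname(table(pgroup)[1])
  N <- nlevels(pid)

  # participant x cell matrix of responses
  Y <- matrix(NA_real_, N, n_cells, dimnames = list(levels(pid), levels(cell)))
  Y[cbind(as.integer(pid), as.integer(cell))] <- y

  # within-effect contrast codes per cell: product of +/-1 over the factors in the effect
  codes <- lapply(wf, function(f) {
    lv <- levels(f)
    stats::setNames(c(-1, 1), lv)
  })
  cell_levels <- do.call(expand.grid, lapply(wf, levels))
  names(cell_levels) <- within
  # align cell_levels rows with columns of Y
  cl_key <- interaction(cell_levels, drop = FALSE)
  ord <- match(colnames(Y), as.character(cl_key))
  cell_levels <- cell_levels[ord, , drop = FALSE]

  effects <- list()
  p_w <- length(within)
  for (k in seq_len(p_w)) {
    for (comb in utils::combn(p_w, k, simplify = FALSE)) {
      cvec <- rep(1, n_cells)
      for (fidx in comb) {
        cvec <- cvec * codes[[fidx]][as.character(cell_levels[[within[fidx]]])]
      }
      effects[[paste(within[comb], collapse = ":")]] <- cvec / n_cells
    }
  }

  one_way <- function(score, test_mean) {
    gb <- tapply(score, pgroup, mean)
    grand <- mean(score)
    ss_err <- sum((score - gb[pgroup])^2)
    df2 <- N - 2L
    mse <- ss_err / df2
    if (test_mean) ss_eff <- N * grand^2
    else ss_eff <- sum(n_per_group * (gb - grand)^2)
    Fv <- ss_eff / mse
    c(F = Fv, df1 = 1, df2 = df2, p = stats::pf(Fv, 1, df2, lower.tail = FALSE),
      pes = ss_eff / (ss_eff + ss_err))
  }

  rows <- list()
  # between effect: participant means over cells
  pm <- rowMeans(Y)
  rows[[between]] <- one_way(pm, test_mean = FALSE)
  for (nm in names(effects)) {
    score <- as.vector(Y %*% effects[[nm]])
    rows[[nm]] <- one_way(score, test_mean = TRUE)
    rows[[paste(between, nm, sep = ":")]] <- one_way(score, test_mean = FALSE)
  }
  out <- data.frame(effect = names(rows), do.call(rbind, rows),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Planned post hoc comparisons with Sidak control
#'
#' The comparison plans used after the mixed ANOVAs: `"threeway"` performs
#' 12 comparisons — Wilcoxon rank-sum tests between groups within each of
#' the four conditions, and Wilcoxon signed-rank tests within each group for
#' the load pairs (Ori vs OriS, Col vs ColS) and feature pairs (Ori vs Col,
#' OriS vs ColS) — at Sidak level `sidak_alpha(12)` = 0.0043. `"twoway"`
#' performs the 4 feature-only comparisons (between groups for each feature,
#' within each group Ori vs Col collapsed over load is not collapsed here:
#' the plan uses the no-switch conditions) at `sidak_alpha(4)` = 0.0127.
#' Tests use the normal approximation; a degenerate signed-rank comparison
#' (all paired differences zero) is reported as p = 1 by convention.
#'
#' @param values Data frame with `participant_id`, `group` and one column
#'   per condition (`Ori`, `Col`, `OriS`, `ColS`) of the metric under test.
#' @param plan `"threeway"` (12 comparisons) or `"twoway"` (4 comparisons).
#' @return Data frame: `comparison`, `type`, `group`, `p`, `alpha_sid`,
#'   `significant`.
#' @export
posthoc_tests <- function(values, plan = c("threeway", "twoway")) {
  plan <- match.arg(plan)
  grp <- values$group
  groups <- sort(unique(grp))
  if (length(groups) != 2L) stop("need exactly two groups", call. = FALSE)

  safe_wilcox <- function(x, y, paired) {
    if (paired && all(x - y == 0)) return(1)
    stats::wilcox.test(x, y, paired = paired, exact = FALSE, correct = TRUE)$p.value
  }
  rows <- list()
  add <- function(comparison, type, group, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = comparison, type = type, group = group, p = p,
      stringsAsFactors = FALSE)
  }
  if (plan == "threeway") {
    for (cn in condition_names()) {
      add(cn, "between", "both",
          safe_wilcox(values[[cn]][grp == groups[1]],
                      values[[cn]][grp == groups[2]], paired = FALSE))
    }
    pairs <- list(c("Ori", "OriS"), c("Col", "ColS"), c("Ori", "Col"), c("OriS", "ColS"))
    for (gv in groups) {
      for (pr in pairs) {
        add(paste(pr, collapse = " vs "), "within", gv,
            safe_wilcox(values[[pr[1]]][grp == gv], values[[pr[2]]][grp == gv],
                        paired = TRUE))
      }
    }
    m <- 12L
  } else {
    for (cn in c("Ori", "Col")) {
      add(cn, "between", "both",
          safe_wilcox(values[[cn]][grp == groups[1]],
                      values[[cn]][grp == groups[2]], paired = FALSE))
    }
    for (gv in groups) {
      add("Ori vs Col", "within", gv,
          safe_wilcox(values[["Ori"]][grp == gv], values[["Col"]][grp == gv],
                      paired = TRUE))
    }
    m <- 4L
  }
  out <- do.call(rbind, rows)
  out$alpha_sid <- sidak_alpha(m)
  out$significant <- out$p < out$alpha_sid
  out
}

#' Linear regression of a clinical score on the log behavioral metrics
#'
#' Ordinary least squares of `gec` or `acds` on the five log-transformed
#' task metrics (TIMO, RT median, RT tau, sigma, lambda), reporting the
#' coefficients with per-coefficient p values, R squared, and the
#' determinant of the regressors' correlation matrix as the
#' multicollinearity diagnostic (a determinant near 0 signals collinear
#' regressors). Rank deficiency is reported, never silently dropped.
#'
#' @param metrics A [build_metric_table()] with clinical columns.
#' @param response `"gec"` or `"acds"`.
#' @param regressors Log-metric columns to use.
#' @return List of class `clinical_regression`: `coefficients` table, `r_squared`,
#'   `cor_determinant`, `rank_deficient`, `n`.
#' @export
regress_clinical <- function(metrics, response = c("gec", "acds"),
                             regressors = c("log_timo", "log_rt_median",
                                            "log_rt_tau", "log_sigma", "log_lambda")) {
  response <- match.arg(response)
  dat <- metrics[, c(response, regressors)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) <= length(regressors) + 1L) {
    stop("too few complete rows for the regression", call. = FALSE)
  }
  X <- as.matrix(dat[, regressors, drop = FALSE])
  qrX <- qr(cbind(1, X))
  rank_deficient <- qrX$rank < ncol(X) + 1L
  cor_det <- det(stats::cor(X))
  fml <- stats::as.formula(paste(response, "~", paste(regressors, collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  out <- list(response = response,
              coefficients = stats::coef(sm),
              r_squared = sm$r.squared,
              cor_determinant = cor_det,
              rank_deficient = rank_deficient,
              n = nrow(dat), fit = fit)
  class(out) <- "clinical_regression"
  out
}

#' @export
print.clinical_regression <- function(x, ...) {
  cat(sprintf("OLS of %s on %d log metrics (n = %d): R^2 = %.3f\n",
              x$response, nrow(x$coefficients) - 1L, x$n, x$r_squared))
  cat(sprintf("det of regressor correlation matrix = %.3f%s\n", x$cor_determinant,
              if (x$rank_deficient) " [RANK DEFICIENT]" else ""))
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' Published correlation structure of the seven study metrics
#'
#' The 7 x 7 Spearman correlation matrix among the five averaged log task
#' metrics (TIMO, RT median, RT tau, perceptual variability sigma, lapse
#' rate lambda) and the two clinical scores (GEC, ACDS) reported for the
#' adult ADHD / control cohort of the visuomotor task-switching study this
#' package models. Used to demonstrate and test the effective-number-of-
#' tests correction: [meff_sidak()] applied to this matrix gives a
#' corrected level of 0.0089.
#'
#' @return A symmetric 7 x 7 correlation matrix.
#' @export
reference_correlations <- function() {
  nm <- c("timo", "rt_median", "rt_tau", "sigma", "lambda", "gec", "acds")
  R <- diag(7)
  dimnames(R) <- list(nm, nm)
  vals <- rbind(
    c("timo", "rt_median", 0.46), c("timo", "rt_tau", 0.42),
    c("timo", "sigma", 0.41), c("timo", "lambda", 0.46),
    c("timo", "gec", 0.53), c("timo", "acds", 0.40),
    c("rt_median", "rt_tau", 0.84), c("rt_median", "sigma", 0.55),
    c("rt_median", "lambda", 0.23), c("rt_median", "gec", 0.25),
    c("rt_median", "acds", 0.31),
    c("rt_tau", "sigma", 0.57), c("rt_tau", "lambda", 0.17),
    c("rt_tau", "gec", 0.34), c("rt_tau", "acds", 0.45),
    c("sigma", "lambda", 0.28), c("sigma", "gec", 0.50), c("sigma", "acds", 0.51),
    c("lambda", "gec", 0.30), c("lambda", "acds", 0.18),
    c("gec", "acds", 0.80))
  for (i in seq_len(nrow(vals))) {
    R[vals[i, 1], vals[i, 2]] <- as.numeric(vals[i, 3])
    R[vals[i, 2], vals[i, 1]] <- as.numeric(vals[i, 3])
  }
  R
}
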