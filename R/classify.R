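#' Logistic-regression diagnosis classifier
#'
#' Unregularized maximum-likelihood logistic regression (logit link, fitted
#' by iteratively reweighted least squares through [stats::glm()]) of the
#' 0/1 diagnosis on one or more behavioral metrics. Log-transformed metrics
#' are the intended regressors. Complete separation is detected (the
#' likelihood diverges and coefficients run away) and flagged; the fitted
#' direction remains usable for prediction.
#'
#' @param X Numeric matrix or data frame of regressors (no missing values).
#' @param y 0/1 diagnosis labels (1 = case); both classes must occur.
#' @return Object of class `diag_classifier`: `coefficients` (intercept
#'   first), `regressors`, `converged`, `separation`, `n`.
#' @export
fit_logistic <- function(X, y) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing values in classifier input", call. = FALSE)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) != 2L) {
    stop("y must contain both 0 and 1 labels", call. = FALSE)
  }
  dat <- data.frame(y = y, X)
  fit <- suppressWarnings(stats::glm(y ~ ., data = dat, family = stats::binomial("logit")))
  p <- stats::fitted(fit)
  separation <- all(p[y == 1] > 1 - 1e-6) && all(p[y == 0] < 1e-6)
  structure(list(coefficients = stats::coef(fit),
                 regressors = colnames(X),
                 converged = fit$converged,
                 separation = separation,
                 n = length(y)),
            class = "diag_classifier")
}

#' @export
print.diag_classifier <- function(x, ...) {
  cat(sprintf("Logistic diagnosis classifier (n = %d)%s\n", x$n,
              if (x$separation) " [complete separation]" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
predict.diag_classifier <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  beta <- object$coefficients
  # aliased regressors (rank-deficient training sets) carry NA coefficients
  # in glm; drop them from the linear predictor as predict.glm does
  beta[is.na(beta)] <- 0
  eta <- as.vector(cbind(1, X) %*% beta)
  if (type == "link") eta else stats::plogis(eta)
}

#' Classification accuracy, hit rate and false-alarm rate
#'
#' Thresholds the fitted probability of diagnosis at `threshold` (ties at
#' the threshold predict the positive class, i.e. a `>=` rule) and reports
#' overall accuracy, the hit rate (sensitivity, over true cases) and the
#' false-alarm rate (1 - specificity, over true controls).
#'
#' @param model A `diag_classifier`.
#' @param X Regressor matrix.
#' @param y True 0/1 labels (both classes present).
#' @param threshold Decision threshold on p(Diagnosis).
#' @return Named vector `c(accuracy, hit_rate, false_alarm_rate)`.
#' @export
evaluate <- function(model, X, y, threshold = 0.5) {
  y <- as.integer(y)
  if (length(unique(y)) != 2L) stop("y must contain both classes", call. = FALSE)
  p <- predict(model, X)
  pred <- as.integer(p >= threshold)
  c(accuracy = mean(pred == y),
    hit_rate = mean(pred[y == 1] == 1),
    false_alarm_rate = mean(pred[y == 0] == 1))
}

make_stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    # class sizes divisible by k give equal folds; a remainder is dealt
    # round-robin to the lowest-index folds (documented remainder rule)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation of the classifier
#'
#' For each run, participants are partitioned at random into `k` folds
#' stratified by diagnosis (with 20 cases and 20 controls and `k = 10`,
#' every fold holds exactly two of each). The classifier is trained on the
#' remaining folds and evaluated on the held-out fold; fold accuracies are
#' averaged within a run and then across runs. Deterministic given the
#' seed.
#'
#' @param X Regressor matrix.
#' @param y 0/1 labels.
#' @param k Number of folds.
#' @param runs Number of random fold assignments (default 1,000).
#' @param seed Integer seed.
#' @param threshold Decision threshold.
#' @return Object of class `cv_result`: `mean_accuracy`, `run_accuracy`
#'   (per run), `folds` (runs x n matrix of fold ids), `k`, `runs`.
#' @export
stratified_cv <- function(X, y, k = 10L, runs = 1000L, seed = 1L, threshold = 0.5) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (min(table(y)) < k) {
    stop("each class needs at least k members for stratified k-fold CV", call. = FALSE)
  }
  set.seed(seed)
  n <- length(y)
  folds <- matrix(0L, runs, n)
  run_acc <- numeric(runs)
  for (r in seq_len(runs)) {
    fold <- make_stratified_folds(y, k)
    folds[r, ] <- fold
    acc <- numeric(k)
    for (f in seq_len(k)) {
      test <- fold == f
      model <- fit_logistic(X[!test, , drop = FALSE], y[!test])
      p <- predict(model, X[test, , drop = FALSE])
      acc[f] <- mean(as.integer(p >= threshold) == y[test])
    }
    run_acc[r] <- mean(acc)
  }
  structure(list(mean_accuracy = mean(run_acc), run_accuracy = run_acc,
                 folds = folds, k = k, runs = runs),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Stratified %d-fold CV, %d runs: mean accuracy %.3f (run SD %.3f)\n",
              x$k, x$runs, x$mean_accuracy, stats::sd(x$run_accuracy)))
  invisible(x)
}

#' Receiver operating characteristic over a threshold sweep
#'
#' Thresholds the scores at linearly spaced values in \[0, 1\] with the
#' `>=` rule (at threshold 1 exactly, the rule is exclusive, so the curve
#' ends at (0, 0); at threshold 0 every case is predicted positive, so it
#' starts at (1, 1)), and reports the (false-alarm, hit) pair per threshold
#' plus the trapezoidal area under the curve after sorting by false-alarm
#' rate.
#'
#' @param scores Fitted probabilities in \[0, 1\].
#' @param y True 0/1 labels (both classes present).
#' @param thresholds Threshold sweep.
#' @return Object of class `roc_curve`: `points` data frame (`threshold`,
#'   `false_alarm_rate`, `hit_rate`) and `auc`.
#' @export
roc_curve <- function(scores, y, thresholds = seq(0, 1, length.out = 201L)) {
  y <- as.integer(y)
  if (length(unique(y)) != 2L) stop("y must contain both classes", call. = FALSE)
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]", call. = FALSE)
  pts <- t(vapply(thresholds, function(t) {
    pred <- if (t >= 1) as.integer(scores > t) else as.integer(scores >= t)
    c(false_alarm_rate = mean(pred[y == 0] == 1),
      hit_rate = mean(pred[y == 1] == 1))
  }, numeric(2)))
  df <- data.frame(threshold = thresholds, pts)
  ord <- order(df$false_alarm_rate, df$hit_rate)
  fa <- df$false_alarm_rate[ord]
  hit <- df$hit_rate[ord]
  auc <- sum(diff(fa) * (utils::head(hit, -1) + utils::tail(hit, -1)) / 2)
  structure(list(points = df, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve over %d thresholds: AUC = %.3f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  ord <- order(x$points$false_alarm_rate, x$points$hit_rate)
  graphics::plot(x$points$false_alarm_rate[ord], x$points$hit_rate[ord],
                 type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "false-alarm rate", ylab = "hit rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Classification report over the study's regressor sets
#'
#' Runs training evaluation and repeated stratified cross-validation for
#' the four regressor sets of interest: sigma only, TIMO only, both, and
#' all five log metrics.
#'
#' @param metrics A complete [build_metric_table()].
#' @param runs,k,seed Cross-validation settings.
#' @return Data frame with one row per regressor set: training accuracy,
#'   hit and false-alarm rates, and mean CV accuracy.
#' @export
classification_report <- function(metrics, runs = 1000L, k = 10L, seed = 1L) {
  metrics <- metrics[metrics$complete, , drop = FALSE]
  y <- as.integer(metrics$group == "adhd")
  sets <- list(sigma = "log_sigma", timo = "log_timo",
               sigma_timo = c("log_sigma", "log_timo"),
               all_metrics = c("log_sigma", "log_timo", "log_rt_median",
                               "log_rt_tau", "log_lambda"))
  rows <- lapply(names(sets), function(nm) {
    X <- as.matrix(metrics[, sets[[nm]], drop = FALSE])
    model <- fit_logistic(X, y)
    ev <- evaluate(model, X, y)
    cv <- stratified_cv(X, y, k = k, runs = runs, seed = seed)
    data.frame(regressors = nm, accuracy = ev["accuracy"],
               hit_rate = ev["hit_rate"], false_alarm_rate = ev["false_alarm_rate"],
               cv_accuracy = cv$mean_accuracy, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
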