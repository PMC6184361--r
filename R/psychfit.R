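#' The lapse-extended psychometric curve
#'
#' Probability of the positive response (clockwise, or more yellow) as a
#' function of normalized stimulus strength `s`:
#' `p(r = 1 | s) = lambda/2 + (1 - lambda) * Phi((s - mu) / sigma)`,
#' where `Phi` is the standard normal CDF, `mu` the point of subjective
#' equality, `sigma` the noise (inverse slope) parameter and `lambda` the
#' lapse rate. The curve is increasing in `s` and bounded in
#' `[lambda/2, 1 - lambda/2]`.
#'
#' @param s Normalized stimulus value(s).
#' @param mu Point of subjective equality.
#' @param sigma Noise parameter (> 0).
#' @param lambda Lapse rate in \[0, 1\].
#' @return Probability of the positive response.
#' @export
psychometric_prob <- function(s, mu, sigma, lambda) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  if (any(lambda < 0 | lambda > 1)) stop("lambda must lie in [0, 1]", call. = FALSE)
  lambda / 2 + (1 - lambda) * stats::pnorm((s - mu) / sigma)
}

#' Estimation grid for psychometric maximum likelihood
#'
#' The fixed grids the maximum-likelihood search runs on: 201 linear points
#' on \[-0.2, 0.2\] for mu, 201 logarithmic points on \[1e-4, 0.3\] for
#' lambda, and 201 logarithmic points on \[0.002, 0.6\] for sigma. Estimates
#' are grid-valued by design; no continuous refinement is applied.
#'
#' @param n Points per dimension.
#' @param mu_range,lambda_range,sigma_range Grid endpoints.
#' @return An object of class `mle_grid`.
#' @export
mle_grid <- function(n = 201L, mu_range = c(-0.2, 0.2),
                     lambda_range = c(1e-4, 0.3), sigma_range = c(0.002, 0.6)) {
  g <- list(
    mu = seq(mu_range[1], mu_range[2], length.out = n),
    lambda = exp(seq(log(lambda_range[1]), log(lambda_range[2]), length.out = n)),
    sigma = exp(seq(log(sigma_range[1]), log(sigma_range[2]), length.out = n))
  )
  class(g) <- "mle_grid"
  g
}

# clip probabilities away from 0/1 before taking logs
clip_prob <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

relevant_trials <- function(trials, feature = NULL) {
  keep <- trials$response_class %in% c("r0", "r1")
  if (!is.null(feature)) keep <- keep & trials$feature == feature
  trials[keep, , drop = FALSE]
}

# bin relevant trials of one group by unique stimulus value
bin_responses <- function(s, r) {
  su <- sort(unique(s))
  idx <- match(s, su)
  list(s = su,
       c1 = as.numeric(tabulate(idx[r == 1], nbins = length(su))),
       c0 = as.numeric(tabulate(idx[r == 0], nbins = length(su))))
}

#' Log-likelihood of the shared-parameter ("main") psychometric model
#'
#' For the relevant-key trials of one feature dimension, sums per-trial
#' Bernoulli log-likelihoods under a model in which `mu` and `lambda` are
#' shared across the two load conditions while `sigma` may differ:
#' no-switch trials are scored with `sigma_ns`, switch trials with
#' `sigma_sw`. Probabilities are clipped to `[1e-12, 1 - 1e-12]`.
#'
#' @param trials Trial table rows, all relevant-key presses of one feature.
#' @param mu,lambda,sigma_ns,sigma_sw Model parameters.
#' @return The log-likelihood (scalar).
#' @export
loglik_main <- function(trials, mu, lambda, sigma_ns, sigma_sw) {
  if (any(trials$response_class == "timo")) {
    stop("loglik_main() received TIMO trials; filter to relevant-key presses",
         call. = FALSE)
  }
  sigma <- ifelse(trials$load == "switch", sigma_sw, sigma_ns)
  p1 <- clip_prob(psychometric_prob(trials$w_target, mu, sigma, lambda))
  r <- as.integer(trials$response_class == "r1")
  sum(r * log(p1) + (1 - r) * log(1 - p1))
}

new_psychfit <- function(model, estimates, grid) {
  structure(list(model = model, estimates = estimates, grid = grid),
            class = "psychfit")
}

#' Fit the shared-parameter psychometric model by grid maximum likelihood
#'
#' For each feature dimension present, finds the exact grid argmax of the
#' shared-parameter log-likelihood (mu and lambda common to both load
#' conditions, separate sigma for no-switch and switch). The search
#' exploits the separability of the sigma terms at fixed (mu, lambda) —
#' the maximum over both sigmas is the sum of per-load maxima — and is
#' provably equal to the exhaustive 4-D search. Ties resolve to the lowest
#' grid index on (mu, lambda, sigma_ns, sigma_sw), in that order.
#'
#' @param trials A validated trial table (one participant); TIMO trials are
#'   excluded automatically.
#' @param grid An [mle_grid()].
#' @param features Feature dimensions to fit (default: those present).
#' @return An object of class `psychfit` (model `"main"`) whose `estimates`
#'   element is a data frame with one row per feature: `mu`, `lambda`,
#'   `sigma_noswitch`, `sigma_switch`, `loglik`, `n_trials`.
#' @export
fit_main <- function(trials, grid = mle_grid(), features = NULL) {
  rel <- relevant_trials(trials)
  if (is.null(features)) features <- intersect(c("ori", "col"), unique(rel$feature))
  rows <- lapply(features, function(f) {
    tf <- rel[rel$feature == f, , drop = FALSE]
    ns <- tf[tf$load == "noswitch", , drop = FALSE]
    sw <- tf[tf$load == "switch", , drop = FALSE]
    if (nrow(ns) == 0L || nrow(sw) == 0L) {
      stop("fit_main() requires at least one relevant trial per load condition (feature ",
           f, ")", call. = FALSE)
    }
    bn <- bin_responses(ns$w_target, as.integer(ns$response_class == "r1"))
    bs <- bin_responses(sw$w_target, as.integer(sw$response_class == "r1"))
    res <- psych_grid_argmax(grid$mu, grid$lambda, grid$sigma,
                             list(bn$s, bs$s), list(bn$c1, bs$c1),
                             list(bn$c0, bs$c0))
    data.frame(feature = f,
               mu = grid$mu[res$i_mu], lambda = grid$lambda[res$i_lambda],
               sigma_noswitch = grid$sigma[res$i_sigma[1]],
               sigma_switch = grid$sigma[res$i_sigma[2]],
               loglik = res$loglik, n_trials = nrow(tf),
               stringsAsFactors = FALSE)
  })
  new_psychfit("main", do.call(rbind, rows), grid)
}

#' Fit the unconstrained ("full") psychometric model
#'
#' Per-condition 3-D grid argmax: each of the four conditions gets its own
#' (mu, sigma, lambda). Same grids and tie rule as [fit_main()].
#'
#' @inheritParams fit_main
#' @param conditions Conditions to fit (default: those present).
#' @return An object of class `psychfit` (model `"full"`) with one estimate
#'   row per condition: `mu`, `sigma`, `lambda`, `loglik`, `n_trials`.
#' @export
fit_full <- function(trials, grid = mle_grid(), conditions = NULL) {
  rel <- relevant_trials(trials)
  cond <- condition_name(rel$feature, rel$load)
  if (is.null(conditions)) conditions <- intersect(condition_names(), unique(cond))
  rows <- lapply(conditions, function(cn) {
    tc <- rel[cond == cn, , drop = FALSE]
    if (nrow(tc) == 0L) stop("no relevant trials in condition ", cn, call. = FALSE)
    b <- bin_responses(tc$w_target, as.integer(tc$response_class == "r1"))
    res <- psych_grid_argmax(grid$mu, grid$lambda, grid$sigma,
                             list(b$s), list(b$c1), list(b$c0))
    data.frame(condition = cn, feature = condition_parts(cn)$feature,
               load = condition_parts(cn)$load,
               mu = grid$mu[res$i_mu], sigma = grid$sigma[res$i_sigma[1]],
               lambda = grid$lambda[res$i_lambda],
               loglik = res$loglik, n_trials = nrow(tc),
               stringsAsFactors = FALSE)
  })
  new_psychfit("full", do.call(rbind, rows), grid)
}

#' @export
print.psychfit <- function(x, ...) {
  cat(sprintf("Psychometric grid-ML fit (%s model)\n", x$model))
  print(x$estimates, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.psychfit <- function(object, ...) {
  est <- object$estimates
  if (object$model == "main") {
    out <- unlist(lapply(seq_len(nrow(est)), function(i) {
      stats::setNames(as.numeric(est[i, c("mu", "lambda", "sigma_noswitch", "sigma_switch")]),
                      paste0(c("mu_", "lambda_", "sigma_noswitch_", "sigma_switch_"),
                             est$feature[i]))
    }))
  } else {
    out <- unlist(lapply(seq_len(nrow(est)), function(i) {
      stats::setNames(as.numeric(est[i, c("mu", "sigma", "lambda")]),
                      paste0(c("mu_", "sigma_", "lambda_"), est$condition[i]))
    }))
  }
  out
}

#' @export
logLik.psychfit <- function(object, ...) {
  val <- sum(object$estimates$loglik)
  k <- if (object$model == "main") 4L * nrow(object$estimates) else 3L * nrow(object$estimates)
  structure(val, df = k, nobs = sum(object$estimates$n_trials), class = "logLik")
}

#' Predicted response probabilities from a psychometric fit
#'
#' @param object A `psychfit`.
#' @param newdata Data frame with columns `w_target`, `feature`, `load` (any
#'   trial table works).
#' @param ... Unused.
#' @return Vector of fitted probabilities of the positive response.
#' @export
predict.psychfit <- function(object, newdata, ...) {
  est <- object$estimates
  cond <- condition_name(newdata$feature, newdata$load)
  vapply(seq_len(nrow(newdata)), function(i) {
    if (object$model == "main") {
      row <- est[est$feature == newdata$feature[i], ]
      sigma <- if (newdata$load[i] == "switch") row$sigma_switch else row$sigma_noswitch
      psychometric_prob(newdata$w_target[i], row$mu, sigma, row$lambda)
    } else {
      row <- est[est$condition == cond[i], ]
      psychometric_prob(newdata$w_target[i], row$mu, row$sigma, row$lambda)
    }
  }, numeric(1))
}

#' @export
plot.psychfit <- function(x, trials = NULL, ...) {
  est <- x$estimates
  s <- seq(-0.5, 0.5, length.out = 201)
  n_panel <- nrow(est)
  old <- graphics::par(mfrow = c(1, n_panel), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (i in seq_len(n_panel)) {
    if (x$model == "main") {
      p_ns <- psychometric_prob(s, est$mu[i], est$sigma_noswitch[i], est$lambda[i])
      p_sw <- psychometric_prob(s, est$mu[i], est$sigma_switch[i], est$lambda[i])
      graphics::plot(s, p_ns, type = "l", ylim = c(0, 1), xlab = "stimulus (n.u.)",
                     ylab = "p(positive response)", main = est$feature[i], ...)
      graphics::lines(s, p_sw, lty = 2)
      graphics::legend("topleft", legend = c("no-switch", "switch"), lty = 1:2, bty = "n")
    } else {
      p <- psychometric_prob(s, est$mu[i], est$sigma[i], est$lambda[i])
      graphics::plot(s, p, type = "l", ylim = c(0, 1), xlab = "stimulus (n.u.)",
                     ylab = "p(positive response)", main = est$condition[i], ...)
    }
    if (!is.null(trials)) {
      sub <- relevant_trials(trials,
                             if (x$model == "main") est$feature[i] else condition_parts(est$condition[i])$feature)
      if (x$model == "full") sub <- sub[sub$load == est$load[i], , drop = FALSE]
      if (nrow(sub)) {
        br <- seq(-0.5, 0.5, length.out = 12)
        bin <- cut(sub$w_target, br, include.lowest = TRUE)
        pr <- tapply(sub$response_class == "r1", bin, mean)
        mid <- (br[-1] + br[-length(br)]) / 2
        graphics::points(mid, pr, pch = 16)
      }
    }
  }
  invisible(x)
}

#' Compare the shared-parameter and unconstrained psychometric models
#'
#' Reports AIC and BIC for both models fitted to the same trials (main: 4
#' free parameters per feature; full: 6 per feature, i.e. 3 per condition)
#' and the preferred model under each criterion. AIC is the headline
#' criterion; disagreement between the two is flagged.
#'
#' @param fit_main_obj A `psychfit` from [fit_main()].
#' @param fit_full_obj A `psychfit` from [fit_full()] on the same trials.
#' @return A list of class `psych_model_comparison` with per-model `loglik`,
#'   `k`, `aic`, `bic`, the per-criterion preference and `headline`.
#' @export
compare_models <- function(fit_main_obj, fit_full_obj) {
  stopifnot(fit_main_obj$model == "main", fit_full_obj$model == "full")
  n_main <- sum(fit_main_obj$estimates$n_trials)
  n_full <- sum(fit_full_obj$estimates$n_trials)
  if (n_main != n_full) {
    stop("model comparison requires identical trial sets (n = ", n_main,
         " vs ", n_full, ")", call. = FALSE)
  }
  ll <- c(main = sum(fit_main_obj$estimates$loglik),
          full = sum(fit_full_obj$estimates$loglik))
  k <- c(main = 4L * nrow(fit_main_obj$estimates),
         full = 3L * nrow(fit_full_obj$estimates))
  aic <- 2 * k - 2 * ll
  bic <- k * log(n_main) - 2 * ll
  pick <- function(crit) names(crit)[which.min(crit)]
  out <- list(loglik = ll, k = k, n = n_main, aic = aic, bic = bic,
              preferred = c(aic = pick(aic), bic = pick(bic)),
              headline = pick(aic),
              agree = pick(aic) == pick(bic))
  class(out) <- "psych_model_comparison"
  out
}

#' @export
print.psych_model_comparison <- function(x, ...) {
  cat("Psychometric model comparison (n =", x$n, "trials)\n")
  tab <- data.frame(k = x$k, loglik = x$loglik, AIC = x$aic, BIC = x$bic)
  print(round(tab, 2))
  cat("preferred: AIC ->", x$preferred["aic"], "; BIC ->", x$preferred["bic"], "\n")
  if (!x$agree) cat("note: AIC and BIC disagree; AIC is the headline criterion\n")
  invisible(x)
}

#' Split-half psychometric fits (learning check)
#'
#' Splits each condition's relevant trials chronologically (presentation
#' order = row order; an odd count puts the extra trial in the first half)
#' and fits the unconstrained model to each half. Comparing first- and
#' second-half sigma estimates across participants probes learning over the
#' session.
#'
#' @inheritParams fit_full
#' @return List with `psychfit` elements `first` and `second`.
#' @export
fit_split_half <- function(trials, grid = mle_grid()) {
  rel <- relevant_trials(trials)
  cond <- condition_name(rel$feature, rel$load)
  halves <- lapply(unique(cond), function(cn) {
    tc <- rel[cond == cn, , drop = FALSE]
    if (nrow(tc) < 2L) stop("need at least 2 relevant trials per condition to split",
                            call. = FALSE)
    n1 <- ceiling(nrow(tc) / 2)
    list(first = tc[seq_len(n1), , drop = FALSE],
         second = tc[(n1 + 1):nrow(tc), , drop = FALSE])
  })
  first <- do.call(rbind, lapply(halves, `[[`, "first"))
  second <- do.call(rbind, lapply(halves, `[[`, "second"))
  list(first = fit_full(first, grid), second = fit_full(second, grid))
}

#' Fit psychometric models to every participant in a cohort
#'
#' @param trials Trial table (multiple participants).
#' @param grid An [mle_grid()].
#' @param model `"main"` or `"full"`.
#' @return Data frame of estimates keyed by `participant_id` (columns as in
#'   the corresponding single-participant fit).
#' @export
fit_cohort <- function(trials, grid = mle_grid(), model = c("main", "full")) {
  model <- match.arg(model)
  ids <- unique(trials$participant_id)
  do.call(rbind, lapply(ids, function(id) {
    tt <- trials[trials$participant_id == id, , drop = FALSE]
    fit <- if (model == "main") fit_main(tt, grid) else fit_full(tt, grid)
    cbind(participant_id = id, fit$estimates, stringsAsFactors = FALSE)
  }))
}
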