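test_that("psychometric_prob matches the formula and its bounds", {
  expect_equal(psychometric_prob(0.06, 0, 0.06, 0), pnorm(1))
  expect_equal(psychometric_prob(0, 0, 0.1, 0.2), 0.1 + 0.8 * 0.5)
  s <- seq(-0.5, 0.5, by = 0.05)
  p <- psychometric_prob(s, 0.02, 0.08, 0.04)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0.02 & p <= 0.98))
  expect_equal(psychometric_prob(-Inf, 0, 0.1, 0.06), 0.03)
  expect_error(psychometric_prob(0, 0, -1, 0), "sigma")
  expect_error(psychometric_prob(0, 0, 1, 2), "lambda")
})

test_that("loglik_main equals a direct R computation and rejects TIMO rows", {
  set.seed(21)
  ns <- simulate_psych_trials(40, 0.01, 0.06, 0.02, load = "noswitch")
  sw <- simulate_psych_trials(40, 0.01, 0.12, 0.02, load = "switch")
  tr <- rbind(ns, sw)
  ll <- loglik_main(tr, mu = 0.01, lambda = 0.02, sigma_ns = 0.06, sigma_sw = 0.12)
  direct <- sum(vapply(seq_len(nrow(tr)), function(i) {
    sig <- if (tr$load[i] == "switch") 0.12 else 0.06
    p <- psychometric_prob(tr$w_target[i], 0.01, sig, 0.02)
    if (tr$response_class[i] == "r1") log(p) else log(1 - p)
  }, numeric(1)))
  expect_equal(ll, direct, tolerance = 1e-12)

  timo_row <- tr[1, ]
  timo_row$key <- as.integer(timo_keys("ori", timo_row$side, "both")[1])
  timo_row$response_class <- "timo"
  timo_row$timo_subtype <- "both"
  timo_row$correct <- NA_integer_
  expect_error(loglik_main(rbind(tr, timo_row), 0, 0.01, 0.1, 0.1), "TIMO")
})

test_that("the separable grid argmax equals an exhaustive pure-R 4-D search", {
  grid <- mle_grid(7L)
  set.seed(31)
  for (rep in 1:2) {
    ns <- simulate_psych_trials(30, 0.02, 0.05, 0.03, load = "noswitch",
                                s_values = seq(-0.4, 0.4, length.out = 9))
    sw <- simulate_psych_trials(30, 0.02, 0.15, 0.03, load = "switch",
                                s_values = seq(-0.4, 0.4, length.out = 9))
    tr <- rbind(ns, sw)
    fit <- fit_main(tr, grid)

    best <- -Inf; best_par <- NULL
    for (mu in grid$mu) for (lam in grid$lambda)
      for (s1 in grid$sigma) for (s2 in grid$sigma) {
        ll <- loglik_main(tr, mu, lam, s1, s2)
        if (ll > best) { best <- ll; best_par <- c(mu, lam, s1, s2) }
      }
    est <- fit$estimates
    expect_equal(est$loglik, best, tolerance = 1e-8)
    achieved <- loglik_main(tr, est$mu, est$lambda,
                            est$sigma_noswitch, est$sigma_switch)
    expect_equal(achieved, best, tolerance = 1e-8)
  }
})

test_that("degenerate all-positive data pins mu to the lowest grid value", {
  tr <- synthetic_trials(s = seq(-0.4, 0.4, length.out = 20), r = rep(1L, 20))
  sw <- synthetic_trials(s = seq(-0.4, 0.4, length.out = 20), r = rep(1L, 20),
                         load = "switch")
  fit <- fit_main(rbind(tr, sw), mle_grid(21L))
  # a curve saturated at 1 fits best: mu as low as the grid allows,
  # with the lowest-index tie rule making the choice deterministic
  expect_equal(fit$estimates$mu, -0.2)
})

test_that("psychfit methods are mutually consistent", {
  set.seed(41)
  ns <- simulate_psych_trials(120, 0, 0.06, 0.02, load = "noswitch")
  sw <- simulate_psych_trials(120, 0, 0.1, 0.02, load = "switch")
  tr <- rbind(ns, sw)
  grid <- mle_grid(41L)
  fm <- fit_main(tr, grid)
  ff <- fit_full(tr, grid)

  cf <- coef(fm)
  expect_named(cf, c("mu_ori", "lambda_ori", "sigma_noswitch_ori", "sigma_switch_ori"))
  ll <- logLik(fm)
  expect_equal(as.numeric(ll), sum(fm$estimates$loglik))
  expect_equal(attr(ll, "df"), 4L)
  expect_equal(attr(logLik(ff), "df"), 6L)

  pr <- predict(fm, tr[1:5, ])
  manual <- vapply(1:5, function(i) {
    sig <- if (tr$load[i] == "switch") cf[["sigma_switch_ori"]] else cf[["sigma_noswitch_ori"]]
    psychometric_prob(tr$w_target[i], cf[["mu_ori"]], sig, cf[["lambda_ori"]])
  }, numeric(1))
  expect_equal(pr, manual)

  expect_output(print(fm), "main model")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fm, trials = tr))
})

test_that("model comparison follows the nesting and flags mismatched data", {
  set.seed(51)
  ns <- simulate_psych_trials(100, 0, 0.06, 0.02, load = "noswitch")
  sw <- simulate_psych_trials(100, 0, 0.1, 0.02, load = "switch")
  tr <- rbind(ns, sw)
  grid <- mle_grid(41L)
  fm <- fit_main(tr, grid)
  ff <- fit_full(tr, grid)
  cmp <- compare_models(fm, ff)
  # the full model nests main on the same grid: its maximum cannot be lower
  expect_gte(cmp$loglik[["full"]], cmp$loglik[["main"]] - 1e-9)
  expect_equal(unname(cmp$aic), unname(2 * cmp$k - 2 * cmp$loglik))
  expect_equal(unname(cmp$bic), unname(cmp$k * log(cmp$n) - 2 * cmp$loglik))
  expect_true(cmp$headline %in% c("main", "full"))
  expect_output(print(cmp), "AIC")
  ff_sub <- fit_full(tr[1:150, ], grid)
  expect_error(compare_models(fm, ff_sub), "identical trial sets")
})

test_that("split-half fitting divides each condition chronologically", {
  set.seed(61)
  ns <- simulate_psych_trials(21, 0, 0.08, 0.02, load = "noswitch")
  sw <- simulate_psych_trials(20, 0, 0.12, 0.02, load = "switch")
  tr <- rbind(ns, sw)
  sh <- fit_split_half(tr, mle_grid(21L))
  n1 <- sh$first$estimates$n_trials
  n2 <- sh$second$estimates$n_trials
  expect_equal(sort(n1 + n2), c(20L, 21L))
  expect_equal(n1[sh$first$estimates$condition == "Ori"], 11L)  # odd count: extra in first half
  expect_error(fit_split_half(tr[1, ], mle_grid(21L)), "at least 2")
})

test_that("fit_cohort returns per-participant estimates", {
  sim <- quick_cohort()
  fits <- fit_cohort(sim$trials, mle_grid(21L), model = "main")
  expect_setequal(unique(fits$participant_id), sim$truth$participant_id)
  expect_equal(nrow(fits), 6L * 2L)  # two features per participant
  expect_true(all(c("mu", "lambda", "sigma_noswitch", "sigma_switch") %in% names(fits)))
})

test_that("fit_main requires trials in both load conditions", {
  tr <- simulate_psych_trials(30, 0, 0.08, 0.02, load = "noswitch")
  expect_error(fit_main(tr), "per load condition")
})
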