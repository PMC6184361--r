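test_that("simulate_response honors the TIMO machinery", {
  set.seed(10)
  obs_always <- observer_params(timo_rate = c(Ori = 1, Col = 1, OriS = 1, ColS = 1),
                                timo_weights = c(spatial = 0, feature = 1, both = 0))
  for (i in 1:25) {
    r <- simulate_response(obs_always, "Ori", "left", 0.1)
    expect_equal(r$response_class, "timo")
    expect_equal(r$timo_subtype, "feature")
    expect_true(r$key %in% timo_keys("ori", "left", "feature"))
    expect_true(is.na(r$r))
    expect_gt(r$rt, 0)
  }
  obs_never <- observer_params(timo_rate = c(Ori = 0, Col = 0, OriS = 0, ColS = 0))
  for (i in 1:25) {
    r <- simulate_response(obs_never, "ColS", "right", -0.2)
    expect_true(r$response_class %in% c("r0", "r1"))
    expect_true(r$key %in% relevant_keys("col", "right"))
    expect_equal(r$timo_subtype, "none")
  }
})

test_that("response probabilities follow the lapse-extended curve", {
  set.seed(11)
  obs <- observer_params(mu = c(ori = 0, col = 0), lambda = c(ori = 0, col = 0),
                         sigma = c(ori_noswitch = 0.06, ori_switch = 0.06,
                                   col_noswitch = 0.06, col_switch = 0.06),
                         timo_rate = c(Ori = 0, Col = 0, OriS = 0, ColS = 0))
  # at w = sigma, p(r = 1) = Phi(1) = 0.8413
  n <- 3000
  r <- vapply(seq_len(n), function(i)
    simulate_response(obs, "Ori", "left", 0.06)$r, integer(1))
  expect_equal(mean(r), pnorm(1), tolerance = 0.035)
})

test_that("orientation distractors have the documented spread, colour is uniform", {
  set.seed(12)
  d <- sample_distractor("ori", n = 4000, kappa = 30)
  # von Mises(0, 30) halved: SD about 180 / (pi * 2 * sqrt(30)) ~ 5.2 degrees
  expect_equal(mean(d$degrees), 0, tolerance = 0.3)
  expect_gt(sd(d$degrees), 4.5)
  expect_lt(sd(d$degrees), 6)
  expect_equal(d$w, d$degrees * pi / 180)
  dc <- sample_distractor("col", n = 4000)
  expect_true(all(abs(dc$w) <= 0.5))
  expect_equal(mean(dc$w), 0, tolerance = 0.05)
  expect_gt(suppressWarnings(ks.test(dc$w, "punif", -0.5, 0.5))$p.value, 1e-4)
})

test_that("a simulated session follows the block design exactly", {
  tr <- demo_participant()
  expect_equal(nrow(tr), 800L)
  expect_equal(sort(unique(tr$block_index)), 1:8)
  expect_true(all(table(tr$block_index) == 100L))
  expect_equal(as.vector(tapply(tr$block_type, tr$block_index, unique)),
               c("O", "C", "S", "S", "S", "S", "C", "O"))
  cond <- condition_name(tr$feature, tr$load)
  expect_equal(sum(cond == "Ori"), 200L)
  expect_equal(sum(cond == "Col"), 200L)
  expect_equal(sum(cond %in% c("OriS", "ColS")), 400L)
  expect_silent(validate_trials(tr))
})

test_that("the staircase is updated only on relevant-key trials", {
  tr <- demo_participant()
  states <- attr(tr, "staircase_states")
  cond <- condition_name(tr$feature, tr$load)
  for (cn in condition_names()) {
    n_rel <- sum(cond == cn & tr$response_class != "timo")
    expect_equal(states[[cn]]$trial_count, n_rel)
  }
})

test_that("simulation is deterministic under a fixed seed", {
  eng <- shared_engine()
  obs <- observer_params()
  design <- design_spec(block_order = c("O", "S"), trials_per_block = 15L)
  set.seed(77); a <- simulate_participant(obs, design, eng)
  set.seed(77); b <- simulate_participant(obs, design, eng)
  attr(a, "staircase_states") <- attr(b, "staircase_states") <- NULL
  expect_identical(a, b)
})

test_that("cohort simulation produces labeled groups and matching ground truth", {
  sim <- quick_cohort()
  expect_equal(nrow(sim$truth), 6L)
  expect_equal(sum(sim$truth$group == "adhd"), 3L)
  expect_equal(sum(sim$truth$group == "control"), 3L)
  expect_false(anyDuplicated(sim$truth$participant_id) > 0)
  expect_setequal(unique(sim$trials$participant_id), sim$truth$participant_id)
  per <- table(sim$trials$participant_id)
  expect_true(all(per == 100L))
  # truth carries the full generative parameter set
  expect_true(all(c("mu_ori", "lambda_col", "sigma_ori_switch", "timo_ColS",
                    "rt_tau_Ori") %in% names(sim$truth)))
  # determinism of the cohort under its seed
  sim2 <- simulate_cohort(cohort_spec(n_adhd = 3L, n_control = 3L, seed = 11L),
                          design_spec(block_order = c("O", "C", "S", "S"),
                                      trials_per_block = 25L),
                          engine = shared_engine(), seed = 11L)
  expect_identical(sim$trials, sim2$trials)
  expect_identical(sim$truth, sim2$truth)
})

test_that("cohort parameter overrides and bounds are respected", {
  spec <- cohort_spec(n_adhd = 2L, n_control = 2L,
                      adhd = list(mu_ori = psyswitch:::dist_spec("fixed", value = 0.05)))
  set.seed(4)
  o <- sample_observer(spec, "adhd")
  expect_equal(o$mu[["ori"]], 0.05)
  expect_true(all(o$sigma > 0))
  expect_true(all(o$timo_rate >= 0 & o$timo_rate <= 1))
  expect_error(psyswitch:::draw_param(
    psyswitch:::dist_spec("fixed", value = 2, lower = 0, upper = 1)),
    "rejection")
})
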