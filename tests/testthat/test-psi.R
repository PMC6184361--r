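test_that("posterior update reproduces a hand-computed two-cell Bayes rule", {
  grid <- stair_grid(n_mu = 2L, mu_range = c(-0.2, 0.2),
                     n_sigma = 1L, sigma_range = c(0.1, 0.1),
                     n_lambda = 1L, lambda_range = c(0, 0))
  st <- psi_init(psi_engine(grid, candidates = c(-0.1, 0, 0.1)))
  expect_equal(st$posterior, c(0.5, 0.5))
  st <- update_posterior(st, s = 0, r = 1)
  lik <- pnorm((0 - c(-0.2, 0.2)) / 0.1)   # p(r=1) per cell, lambda = 0
  expect_equal(st$posterior, lik / sum(lik), tolerance = 1e-12)
  expect_equal(st$trial_count, 1L)
  st <- update_posterior(st, s = 0.1, r = 0)
  lik2 <- lik * (1 - pnorm((0.1 - c(-0.2, 0.2)) / 0.1))
  expect_equal(st$posterior, lik2 / sum(lik2), tolerance = 1e-12)
})

test_that("expected entropy matches the brute-force oracle on small grids", {
  set.seed(42)
  for (dims in list(c(3L, 3L, 2L), c(5L, 5L, 3L))) {
    eng <- tiny_engine(dims[1], dims[2], dims[3])
    st <- psi_init(eng)
    for (rep in 1:4) {
      ee <- expected_entropy(st)
      expect_equal(ee, brute_expected_entropy(st), tolerance = 1e-10)
      # per-stimulus slow path agrees with the batched fast path
      expect_equal(expected_entropy(st, s = eng$candidates), ee, tolerance = 1e-10)
      s <- select_stimulus(st)
      # the selection attains the brute-force minimum (tie order aside)
      bee <- brute_expected_entropy(st)
      expect_lt(bee[match(s, eng$candidates)], min(bee) + 1e-9)
      st <- update_posterior(st, s, rbinom(1, 1, 0.5))
    }
  }
})

test_that("entropy base only rescales and never changes the selection", {
  set.seed(1)
  st <- psi_init(tiny_engine())
  st <- update_posterior(st, 0.15, 1)
  nats <- expected_entropy(st)
  bits <- expected_entropy(st, base = 2)
  expect_equal(bits, nats / log(2), tolerance = 1e-12)
  expect_equal(which.min(bits), which.min(nats))
})

test_that("ties resolve to the smallest |s|, then the negative member", {
  # a fresh symmetric posterior makes +/- s exact ties by symmetry
  grid <- stair_grid(n_mu = 5L, mu_range = c(-0.4, 0.4),
                     n_sigma = 3L, sigma_range = c(0.05, 0.5),
                     n_lambda = 2L, lambda_range = c(0, 0.2))
  st <- psi_init(psi_engine(grid, candidates = c(-0.3, 0.3)))
  ee <- expected_entropy(st)
  expect_equal(ee[1], ee[2], tolerance = 1e-12)
  expect_equal(select_stimulus(st), -0.3)
  st2 <- psi_init(psi_engine(grid, candidates = c(-0.3, -0.1, 0.1, 0.3)))
  expect_equal(select_stimulus(st2), -0.1)
})

test_that("the posterior concentrates near the generating parameters", {
  set.seed(99)
  eng <- shared_engine()
  st <- psi_init(eng)
  mu_true <- 0.02; sigma_true <- 0.08; lambda_true <- 0.02
  for (t in 1:300) {
    s <- select_stimulus(st)
    r <- rbinom(1, 1, psychometric_prob(s, mu_true, sigma_true, lambda_true))
    st <- update_posterior(st, s, r)
  }
  est <- posterior_estimates(st)
  expect_lt(abs(est[["mu"]] - mu_true), 0.03)
  expect_lt(abs(est[["sigma"]] - sigma_true) / sigma_true, 0.5)
  expect_lt(posterior_entropy(st$posterior), posterior_entropy(psi_init(eng)$posterior))
})

test_that("sigma_marginal scope targets the sigma marginal's entropy", {
  set.seed(5)
  eng <- tiny_engine()
  stj <- psi_init(eng, entropy_scope = "joint")
  stm <- psi_init(eng, entropy_scope = "sigma_marginal")
  for (t in 1:3) {
    s <- eng$candidates[t + 1]
    stj <- update_posterior(stj, s, 1)
    stm <- update_posterior(stm, s, 1)
  }
  eej <- expected_entropy(stj)
  eem <- expected_entropy(stm)
  expect_false(isTRUE(all.equal(eej, eem)))
  # oracle for the marginal scope on the tiny grid
  e <- eng
  oracle <- vapply(e$candidates, function(s) {
    p1 <- psychometric_prob(s, e$mu_v, e$sigma_v, e$lambda_v)
    marg_H <- function(w) {
      q <- rowsum(w, match(e$sigma_v, sort(unique(e$sigma_v))))
      q <- q[q > 0] / sum(q)
      -sum(q * log(q))
    }
    u <- stm$posterior * p1; v <- stm$posterior * (1 - p1)
    sum(u) * marg_H(u) + sum(v) * marg_H(v)
  }, numeric(1))
  expect_equal(eem, oracle, tolerance = 1e-10)
})

test_that("staircase state JSON round-trips with row-major posterior layout", {
  eng <- tiny_engine(2L, 2L, 2L, candidates = c(-0.2, 0, 0.2))
  st <- psi_init(eng)
  # distinct masses: internal layout is mu fastest, then sigma, then lambda
  st$posterior <- (1:8) / 36
  st$trial_count <- 5L
  js <- psi_state_json(st)
  obj <- jsonlite::fromJSON(js)
  # row-major (lambda fastest): (mu1,s1,l1),(mu1,s1,l2),(mu1,s2,l1),...
  expect_equal(obj$posterior_row_major, c(1, 5, 3, 7, 2, 6, 4, 8) / 36)
  back <- psi_state_restore(js)
  expect_equal(back$posterior, st$posterior)
  expect_equal(back$trial_count, 5L)
  expect_equal(back$engine$grid$mu, eng$grid$mu)
  expect_equal(back$engine$candidates, eng$candidates)
  # restoring into a shared engine gives the same selections
  back2 <- psi_state_restore(js, engine = eng)
  expect_equal(select_stimulus(back2), select_stimulus(back))
  # file round-trip
  p <- tempfile(fileext = ".json")
  psi_state_json(st, p)
  expect_equal(psi_state_restore(p)$posterior, st$posterior)
})

test_that("stimulus-unit conversions match their stated formulas", {
  expect_equal(w_to_orientation(0.5), 90 / pi)
  expect_equal(round(w_to_orientation(0.5), 4), 28.6479)
  expect_equal(w_to_orientation(-0.25), -45 / pi)
  expect_equal(w_to_orientation(0), 0)
  expect_equal(w_to_orientation(0.5, "linear60"), 30)
  expect_equal(w_to_orientation(-0.5, "linear60"), -30)
  expect_error(w_to_orientation(0.6), "0.5")

  lab <- w_to_lab(c(-0.5, 0, 0.5))
  expect_equal(lab[, "L"], rep(78, 3))
  expect_equal(lab[1, ], c(L = 78, a = -30, b = -40))
  expect_equal(lab[3, ], c(L = 78, a = 0, b = 80))
  expect_equal(lab[2, ], c(L = 78, a = -15, b = 20))  # linear midpoint
  expect_error(w_to_lab(1), "0.5")
})

test_that("degenerate updates are rejected and xlogx handles zero", {
  st <- psi_init(tiny_engine())
  expect_error(update_posterior(st, 0.9, 1), "0.5")
  expect_error(update_posterior(st, 0, 2))
  expect_equal(psyswitch:::xlogx(c(0, 1, 0.5)), c(0, 0, 0.5 * log(0.5)))
})
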