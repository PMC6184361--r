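# Shared test helpers: small engines, synthetic trial builders, and
# brute-force oracles. Expensive shared objects are memoized for the session.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# default engine shared across test files (likelihood tables are pure)
shared_engine <- function() memo("engine", psi_engine())

tiny_grid <- function(n_mu = 5L, n_sigma = 5L, n_lambda = 3L) {
  stair_grid(n_mu = n_mu, mu_range = c(-0.4, 0.4),
             n_sigma = n_sigma, sigma_range = c(0.01, 0.5),
             n_lambda = n_lambda, lambda_range = c(0, 0.2))
}

tiny_engine <- function(n_mu = 5L, n_sigma = 5L, n_lambda = 3L,
                        candidates = seq(-0.45, 0.45, length.out = 7L)) {
  psi_engine(tiny_grid(n_mu, n_sigma, n_lambda), candidates)
}

# Brute-force expected entropy: for each candidate and each response,
# perform the Bayes update explicitly and average the posterior entropies
# weighted by the predictive probabilities. Independent of the package's
# crossprod/C++ algebra.
brute_expected_entropy <- function(state, candidates = state$engine$candidates) {
  e <- state$engine
  post <- state$posterior
  vapply(candidates, function(s) {
    p1 <- psychometric_prob(s, e$mu_v, e$sigma_v, e$lambda_v)
    pr1 <- sum(post * p1)
    pr0 <- 1 - pr1
    h <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
    h1 <- if (pr1 > 0) h(post * p1 / pr1) else 0
    h0 <- if (pr0 > 0) h(post * (1 - p1) / pr0) else 0
    pr1 * h1 + pr0 * h0
  }, numeric(1))
}

# Build a valid trial table from response vectors for one feature.
# s: stimulus values; r: 0/1 responses (relevant presses only).
synthetic_trials <- function(s, r, feature = "ori", load = "noswitch",
                             participant_id = "p01", group = "unknown",
                             rt = NULL) {
  n <- length(s)
  stopifnot(length(r) == n)
  block_type <- if (load == "switch") "S" else if (feature == "ori") "O" else "C"
  side <- rep(c("left", "right"), length.out = n)
  key <- mapply(function(sd, ri) response_key(feature, sd, if (ri == 1) "r1" else "r0"),
                side, r)
  if (is.null(rt)) rt <- rep(0.5, n)
  trials <- data.frame(
    participant_id = participant_id, group = group,
    block_index = if (block_type == "O") 1L else if (block_type == "C") 2L else 3L,
    block_type = block_type, feature = feature, load = load, side = side,
    w_target = s, w_distractor = 0, key = as.integer(key),
    response_class = ifelse(r == 1, "r1", "r0"), timo_subtype = "none",
    correct = ifelse(r == 1, as.integer(s >= 0), as.integer(s < 0)),
    rt = rt, stringsAsFactors = FALSE)
  validate_trials(trials)
  trials
}

# Simulate relevant-press responses of a known psychometric observer at
# fixed stimulus values (no staircase) and return a valid trial table.
simulate_psych_trials <- function(n, mu, sigma, lambda, feature = "ori",
                                  load = "noswitch",
                                  s_values = seq(-0.5, 0.5, length.out = 101),
                                  participant_id = "p01", group = "unknown") {
  s <- sample(s_values, n, replace = TRUE)
  r <- as.integer(stats::runif(n) < psychometric_prob(s, mu, sigma, lambda))
  synthetic_trials(s, r, feature = feature, load = load,
                   participant_id = participant_id, group = group)
}

# one default-design participant, reused by several test files
demo_participant <- function() {
  memo("demo_participant", {
    set.seed(20240101)
    simulate_participant(observer_params(), design_spec(), shared_engine(),
                         participant_id = "demo", group = "control")
  })
}

# a small simulated cohort on a reduced design, for pipeline-level tests
quick_cohort <- function() {
  memo("quick_cohort", {
    spec <- cohort_spec(n_adhd = 3L, n_control = 3L, seed = 11L)
    design <- design_spec(block_order = c("O", "C", "S", "S"),
                          trials_per_block = 25L)
    simulate_cohort(spec, design, engine = shared_engine(), seed = 11L)
  })
}

# a complete metric table for classifier-level tests (cheap grids)
quick_metrics <- function() {
  memo("quick_metrics", {
    sim <- quick_cohort()
    psych_fits <- fit_cohort(sim$trials, mle_grid(41L), model = "main")
    rt_fits <- fit_rt_cohort(sim$trials)
    build_metric_table(sim$trials, psych_fits, rt_fits)
  })
}
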