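#' Parameter grid for the adaptive staircase
#'
#' The staircase maintains its posterior on a fixed 3-D grid over the
#' psychometric parameters: a linear grid for the point of subjective
#' equality mu, a logarithmic grid for the noise parameter sigma, and a
#' linear grid for the lapse rate lambda. Defaults are 51 points on
#' \[-0.5, 0.5\] for mu, 25 log-spaced points on \[0.002, 0.8\] for sigma and
#' 25 points on \[0, 0.3\] for lambda.
#'
#' @param n_mu,n_sigma,n_lambda Grid sizes.
#' @param mu_range,sigma_range,lambda_range Grid endpoints (inclusive).
#' @return An object of class `stair_grid`: list of the three grid vectors.
#' @export
stair_grid <- function(n_mu = 51L, mu_range = c(-0.5, 0.5),
                       n_sigma = 25L, sigma_range = c(0.002, 0.8),
                       n_lambda = 25L, lambda_range = c(0, 0.3)) {
  stopifnot(n_mu >= 1, n_sigma >= 1, n_lambda >= 1, sigma_range[1] > 0)
  g <- list(
    mu = seq(mu_range[1], mu_range[2], length.out = n_mu),
    sigma = exp(seq(log(sigma_range[1]), log(sigma_range[2]), length.out = n_sigma)),
    lambda = seq(lambda_range[1], lambda_range[2], length.out = n_lambda)
  )
  class(g) <- "stair_grid"
  g
}

# x * log(x) with the 0 log 0 = 0 convention
xlogx <- function(x) {
  out <- x * log(x)
  out[x <= 0] <- 0
  out
}

#' Precompute the staircase likelihood tables
#'
#' Builds the reusable part of the adaptive engine: for every grid cell
#' (mu, sigma, lambda) and every candidate stimulus, the probability of the
#' positive response under the psychometric curve, plus the p*log(p) tables
#' the entropy computation needs. One engine can be shared by any number of
#' staircases running on the same grid and candidate set (the tables depend
#' on neither the posterior nor the data).
#'
#' @param grid A [stair_grid()].
#' @param candidates Candidate stimulus values in \[-0.5, 0.5\]; default 101
#'   linearly spaced values.
#' @return An object of class `psi_engine`.
#' @export
psi_engine <- function(grid = stair_grid(),
                       candidates = seq(-0.5, 0.5, length.out = 101L)) {
  stopifnot(inherits(grid, "stair_grid"), length(candidates) >= 1,
            all(abs(candidates) <= 0.5 + 1e-12))
  # cell order: mu fastest, then sigma, then lambda (column-major over 51x25x25)
  mu_v <- rep(grid$mu, times = length(grid$sigma) * length(grid$lambda))
  sigma_v <- rep(rep(grid$sigma, each = length(grid$mu)), times = length(grid$lambda))
  lambda_v <- rep(grid$lambda, each = length(grid$mu) * length(grid$sigma))
  P <- vapply(candidates, function(s) psychometric_prob(s, mu_v, sigma_v, lambda_v),
              numeric(length(mu_v)))
  engine <- list(grid = grid, candidates = candidates,
                 mu_v = mu_v, sigma_v = sigma_v, lambda_v = lambda_v,
                 P = P, XLsum = xlogx(P) + xlogx(1 - P))
  class(engine) <- "psi_engine"
  engine
}

#' Initialize a staircase posterior
#'
#' Returns the staircase state at trial zero: a uniform prior over the grid
#' (each of the n_mu x n_sigma x n_lambda cells carries equal mass).
#'
#' @param engine A [psi_engine()] (or a [stair_grid()], from which a default
#'   engine is built).
#' @param entropy_scope `"joint"` minimizes the entropy of the full joint
#'   posterior; `"sigma_marginal"` minimizes the entropy of the marginal
#'   posterior over sigma only.
#' @return An object of class `psi_posterior` with elements `engine`,
#'   `posterior` (vector over grid cells, summing to 1) and `trial_count`.
#' @export
psi_init <- function(engine = psi_engine(), entropy_scope = c("joint", "sigma_marginal")) {
  if (inherits(engine, "stair_grid")) engine <- psi_engine(engine)
  stopifnot(inherits(engine, "psi_engine"))
  k <- length(engine$mu_v)
  state <- list(engine = engine,
                posterior = rep(1 / k, k),
                trial_count = 0L,
                entropy_scope = match.arg(entropy_scope))
  class(state) <- "psi_posterior"
  state
}

#' Bayesian update of the staircase posterior
#'
#' Multiplies the current posterior by the likelihood of the observed binary
#' response under the psychometric curve at every grid cell, and
#' renormalizes. Only relevant-key trials may be fed to the staircase; the
#' caller (see [simulate_participant()]) enforces that TIMO trials never
#' reach the update.
#'
#' @param state A `psi_posterior`.
#' @param s Normalized stimulus value in \[-0.5, 0.5\].
#' @param r Observed response, 0 or 1 (1 = clockwise / more yellow).
#' @return The updated `psi_posterior`.
#' @export
update_posterior <- function(state, s, r) {
  stopifnot(inherits(state, "psi_posterior"), length(s) == 1L,
            abs(s) <= 0.5 + 1e-12, r %in% c(0, 1))
  e <- state$engine
  p1 <- psychometric_prob(s, e$mu_v, e$sigma_v, e$lambda_v)
  lik <- if (r == 1) p1 else 1 - p1
  post <- state$posterior * lik
  z <- sum(post)
  if (!is.finite(z) || z <= 0) {
    stop("posterior mass vanished after update (degenerate likelihood)", call. = FALSE)
  }
  state$posterior <- post / z
  state$trial_count <- state$trial_count + 1L
  state
}

posterior_entropy <- function(post, base = exp(1)) {
  -sum(xlogx(post)) / log(base)
}

sigma_index <- function(engine) {
  rep(rep(seq_along(engine$grid$sigma), each = length(engine$grid$mu)),
      times = length(engine$grid$lambda))
}

#' Expected posterior entropy of a candidate stimulus
#'
#' For each candidate stimulus, computes the entropy of the updated posterior
#' averaged over the two possible responses, weighted by their predictive
#' probabilities under the current posterior:
#' `sum_r p(r|s) H[posterior after (s, r)]`. Shannon entropy uses the
#' 0 log 0 = 0 convention; `base` only rescales the result (it can never
#' change which stimulus minimizes it).
#'
#' @param state A `psi_posterior`.
#' @param s Stimulus value(s); defaults to the engine's candidate set, for
#'   which precomputed tables make the computation a handful of
#'   matrix-vector products.
#' @param base Logarithm base (`exp(1)` for nats, 2 for bits).
#' @return Numeric vector of expected entropies, one per element of `s`.
#' @export
expected_entropy <- function(state, s = NULL, base = exp(1)) {
  stopifnot(inherits(state, "psi_posterior"))
  e <- state$engine
  post <- state$posterior
  scope <- state$entropy_scope

  if (is.null(s) && scope == "joint") {
    # Fast path over the engine's candidate set. With U = post * p and
    # V = post * (1 - p), the expected entropy at candidate j is
    #   -sum_i (U log U + V log V) + pr1 log pr1 + pr0 log pr0,
    # and the first sum splits into a candidate-independent posterior term
    # plus one crossprod with the precomputed p log p + (1-p) log (1-p)
    # table. Cells carrying numerically negligible mass contribute less
    # than ~1e-10 nats in total and are skipped once the posterior has
    # concentrated (a pure speed device; selection is unaffected).
    ee <- psi_expected_entropy_cpp(e$P, e$XLsum, post, 1e-15)
    return(ee / log(base))
  }

  if (is.null(s)) s <- e$candidates
  vapply(s, function(si) {
    p1 <- psychometric_prob(si, e$mu_v, e$sigma_v, e$lambda_v)
    u <- post * p1
    v <- post * (1 - p1)
    pr1 <- sum(u)
    pr0 <- sum(v)
    if (scope == "sigma_marginal") {
      idx <- sigma_index(e)
      um <- rowsum(u, idx)
      vm <- rowsum(v, idx)
      h1 <- if (pr1 > 0) posterior_entropy(um / pr1) else 0
      h0 <- if (pr0 > 0) posterior_entropy(vm / pr0) else 0
    } else {
      h1 <- if (pr1 > 0) (-sum(xlogx(u)) + xlogx(pr1)) / pr1 else 0
      h0 <- if (pr0 > 0) (-sum(xlogx(v)) + xlogx(pr0)) / pr0 else 0
    }
    (pr1 * h1 + pr0 * h0) / log(base)
  }, numeric(1))
}

#' Entropy-minimizing stimulus selection
#'
#' Returns the candidate stimulus that minimizes the expected posterior
#' entropy. Ties (within a small numerical tolerance) are broken
#' deterministically: smallest absolute stimulus first, then the negative
#' member of a +/- pair.
#'
#' @param state A `psi_posterior`.
#' @param candidates Candidate stimulus values; defaults to the engine's set.
#' @return The selected stimulus value (scalar).
#' @export
select_stimulus <- function(state, candidates = NULL) {
  stopifnot(inherits(state, "psi_posterior"))
  use_default <- is.null(candidates)
  if (use_default) candidates <- state$engine$candidates
  if (!length(candidates)) stop("empty candidate list", call. = FALSE)
  ee <- if (use_default) expected_entropy(state) else expected_entropy(state, candidates)
  tol <- 1e-9 * max(1, abs(min(ee)))
  tied <- which(ee <= min(ee) + tol)
  s_t <- candidates[tied]
  # smallest |s| wins, negative breaks the remaining tie; |s| is compared
  # with a tolerance so representation noise (e.g. seq() endpoints) cannot
  # flip the sign preference
  a <- abs(s_t)
  tol_a <- 1e-9 * max(1, max(a))
  min(s_t[a <= min(a) + tol_a])
}

#' Marginal posterior means of the staircase parameters
#'
#' @param state A `psi_posterior`.
#' @return Named numeric vector `c(mu, sigma, lambda)` of posterior means.
#' @export
posterior_estimates <- function(state) {
  stopifnot(inherits(state, "psi_posterior"))
  e <- state$engine
  post <- state$posterior
  c(mu = sum(post * e$mu_v), sigma = sum(post * e$sigma_v),
    lambda = sum(post * e$lambda_v))
}

#' @export
print.psi_posterior <- function(x, ...) {
  est <- posterior_estimates(x)
  cat(sprintf(
    "Adaptive staircase posterior (%d x %d x %d grid, %d updates)\n",
    length(x$engine$grid$mu), length(x$engine$grid$sigma),
    length(x$engine$grid$lambda), x$trial_count))
  cat(sprintf("  posterior means: mu = %.4f, sigma = %.4f, lambda = %.4f\n",
              est["mu"], est["sigma"], est["lambda"]))
  cat(sprintf("  entropy: %.3f nats\n", posterior_entropy(x$posterior)))
  invisible(x)
}

#' Serialize / restore a staircase state
#'
#' The JSON dump stores the three grid vectors, the candidate set, the trial
#' count and the posterior flattened row-major over (mu, sigma, lambda)
#' (lambda index varying fastest), for resuming a staircase or building test
#' fixtures.
#'
#' @param state A `psi_posterior`.
#' @param path File path; if `NULL`, the JSON string is returned.
#' @return `psi_state_json()`: the path (or JSON string);
#'   `psi_state_restore()`: a `psi_posterior`.
#' @export
psi_state_json <- function(state, path = NULL) {
  stopifnot(inherits(state, "psi_posterior"))
  e <- state$engine
  dims <- c(length(e$grid$mu), length(e$grid$sigma), length(e$grid$lambda))
  arr <- array(state$posterior, dim = dims)  # column-major: mu fastest
  flat <- as.vector(aperm(arr, c(3, 2, 1)))  # now lambda fastest = row-major mu,sigma,lambda
  obj <- list(mu_grid = e$grid$mu, sigma_grid = e$grid$sigma,
              lambda_grid = e$grid$lambda, candidates = e$candidates,
              trial_count = state$trial_count, entropy_scope = state$entropy_scope,
              posterior_row_major = flat)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname psi_state_json
#' @param json Path to, or string of, a staircase JSON dump.
#' @param engine Optionally, an existing compatible [psi_engine()] to reuse.
#' @export
psi_state_restore <- function(json, engine = NULL) {
  obj <- jsonlite::fromJSON(json)
  grid <- list(mu = obj$mu_grid, sigma = obj$sigma_grid, lambda = obj$lambda_grid)
  class(grid) <- "stair_grid"
  if (is.null(engine)) engine <- psi_engine(grid, obj$candidates)
  state <- psi_init(engine, entropy_scope = obj$entropy_scope)
  dims <- c(length(grid$lambda), length(grid$sigma), length(grid$mu))
  arr <- array(obj$posterior_row_major, dim = dims)
  state$posterior <- as.vector(aperm(arr, c(3, 2, 1)))
  state$trial_count <- as.integer(obj$trial_count)
  state
}

#' Stimulus-unit conversions
#'
#' The staircase works in normalized units w in \[-0.5, 0.5\].
#' `w_to_orientation()` converts to degrees of tilt from vertical. The
#' default convention is `180 * w / pi` degrees (so w = 0.5 maps to 90/pi,
#' about 28.65 deg); the alternative `"linear60"` convention maps w linearly
#' onto \[-30, 30\] deg (60 * w). The two conventions disagree by under 5%
#' at the range ends and are both offered because an orientation range of
#' -30 to 30 deg is the stated physical span while 180w/pi is the stated
#' formula; no silent reconciliation is attempted.
#'
#' @param w Normalized stimulus value(s) in \[-0.5, 0.5\].
#' @param convention `"180_over_pi"` (default) or `"linear60"`.
#' @return Orientation in degrees (odd function of `w`).
#' @export
w_to_orientation <- function(w, convention = c("180_over_pi", "linear60")) {
  if (any(!is.finite(w)) || any(abs(w) > 0.5 + 1e-12)) {
    stop("w must lie in [-0.5, 0.5]", call. = FALSE)
  }
  convention <- match.arg(convention)
  if (convention == "180_over_pi") 180 * w / pi else 60 * w
}

#' @rdname w_to_orientation
#' @return `color_endpoints()`: the CIELAB endpoints of the colour continuum
#'   (lightness fixed at L = 78; blue at a = -30, b = -40; yellow at a = 0,
#'   b = 80).
#' @export
color_endpoints <- function() {
  list(L = 78, a_blue = -30, b_blue = -40, a_yellow = 0, b_yellow = 80)
}

#' @rdname w_to_orientation
#' @param endpoints Colour endpoints, see [color_endpoints()].
#' @return `w_to_lab()`: matrix with columns `L`, `a`, `b`; linear
#'   interpolation between the blue (w = -0.5) and yellow (w = +0.5)
#'   endpoints.
#' @export
w_to_lab <- function(w, endpoints = color_endpoints()) {
  if (any(!is.finite(w)) || any(abs(w) > 0.5 + 1e-12)) {
    stop("w must lie in [-0.5, 0.5]", call. = FALSE)
  }
  cbind(L = rep(endpoints$L, length(w)),
        a = (w + 0.5) * endpoints$a_yellow + (0.5 - w) * endpoints$a_blue,
        b = (w + 0.5) * endpoints$b_yellow + (0.5 - w) * endpoints$b_blue)
}
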