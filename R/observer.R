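#' Ground-truth generative parameters of a synthetic observer
#'
#' A synthetic participant is defined by: per feature, a psychometric curve
#' (mu, lambda shared over load; a noise sigma per load condition); per
#' condition, a probability of task-irrelevant motor output (TIMO) and an
#' ex-Gaussian reaction-time distribution; plus a probability split of TIMO
#' over its three subtypes.
#'
#' @param mu Named numeric `c(ori =, col =)`: points of subjective equality.
#' @param lambda Named numeric `c(ori =, col =)`: lapse rates in \[0, 1\].
#' @param sigma Named numeric with entries `ori_noswitch`, `ori_switch`,
#'   `col_noswitch`, `col_switch` (all > 0, normalized units).
#' @param timo_rate Named numeric over conditions `Ori`, `Col`, `OriS`,
#'   `ColS`, each in \[0, 1\].
#' @param timo_weights Probabilities over subtypes `spatial`, `feature`,
#'   `both`, summing to 1. The default (0.25, 0.5, 0.25) puts most
#'   irrelevant presses on feature errors.
#' @param exgauss Named list over conditions, each `c(mu =, sigma =, tau =)`
#'   in seconds (Gaussian mean and SD plus exponential tail of the
#'   reaction-time distribution).
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(
    mu = c(ori = 0, col = 0),
    lambda = c(ori = 0.02, col = 0.04),
    sigma = c(ori_noswitch = 0.06, ori_switch = 0.06,
              col_noswitch = 0.09, col_switch = 0.09),
    timo_rate = c(Ori = 0.02, Col = 0.02, OriS = 0.08, ColS = 0.08),
    timo_weights = c(spatial = 0.25, feature = 0.5, both = 0.25),
    exgauss = list(Ori = c(mu = 0.45, sigma = 0.08, tau = 0.15),
                   Col = c(mu = 0.55, sigma = 0.08, tau = 0.17),
                   OriS = c(mu = 0.55, sigma = 0.08, tau = 0.17),
                   ColS = c(mu = 0.65, sigma = 0.08, tau = 0.19))) {
  stopifnot(all(c("ori", "col") %in% names(mu)),
            all(c("ori", "col") %in% names(lambda)),
            all(lambda >= 0 & lambda <= 1),
            all(c("ori_noswitch", "ori_switch", "col_noswitch", "col_switch") %in% names(sigma)),
            all(sigma > 0),
            all(condition_names() %in% names(timo_rate)),
            all(timo_rate >= 0 & timo_rate <= 1),
            all(c("spatial", "feature", "both") %in% names(timo_weights)),
            abs(sum(timo_weights) - 1) < 1e-8, all(timo_weights >= 0),
            all(condition_names() %in% names(exgauss)))
  for (cn in condition_names()) {
    ex <- exgauss[[cn]]
    stopifnot(all(c("mu", "sigma", "tau") %in% names(ex)), ex["sigma"] > 0, ex["tau"] >= 0)
  }
  structure(list(mu = mu, lambda = lambda, sigma = sigma, timo_rate = timo_rate,
                 timo_weights = timo_weights, exgauss = exgauss),
            class = "observer_params")
}

#' Experiment design of a simulated session
#'
#' The default session comprises eight blocks of 100 trials in the order
#' O-C-S-S-S-S-C-O (the mirrored order C-O-S-S-S-S-O-C is equivalent for
#' analysis), totalling 800 trials: exactly 200 each in the pure Ori and Col
#' conditions and about 200 each in OriS and ColS (the relevant feature in
#' switch blocks is an independent fair coin per trial). The distractor
#' stimulus is drawn from a von Mises distribution (kappa = 30, angle halved)
#' for orientation and uniformly over the normalized range for colour.
#'
#' @param block_order Character vector over `"O"`, `"C"`, `"S"`.
#' @param trials_per_block Trials per block.
#' @param distractor_kappa Concentration of the orientation distractor's von
#'   Mises distribution (drawn angle is divided by 2).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(block_order = c("O", "C", "S", "S", "S", "S", "C", "O"),
                        trials_per_block = 100L, distractor_kappa = 30) {
  stopifnot(all(block_order %in% c("O", "C", "S")), trials_per_block >= 1,
            distractor_kappa > 0)
  structure(list(block_order = block_order,
                 trials_per_block = as.integer(trials_per_block),
                 distractor_kappa = distractor_kappa),
            class = "design_spec")
}

# von Mises sampler (Best & Fisher 1979 rejection algorithm), angles in (-pi, pi]
rvonmises <- function(n, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

#' Draw distractor stimulus values
#'
#' Orientation distractors: an angle from von Mises(0, kappa) in radians,
#' converted to degrees and divided by 2 (approximately Gaussian with SD
#' about 5 degrees at kappa = 30); returned both in degrees and in the
#' normalized w units the orientation conversion implies
#' (w = pi * degrees / 180, the inverse of [w_to_orientation()]). Colour
#' distractors: w uniform on \[-0.5, 0.5\].
#'
#' @param feature `"ori"` or `"col"`.
#' @param n Number of draws.
#' @param kappa von Mises concentration (orientation only).
#' @return A list with `w` (normalized units) and, for orientation,
#'   `degrees`.
#' @export
sample_distractor <- function(feature, n = 1L, kappa = 30) {
  feature <- match.arg(feature, c("ori", "col"))
  if (feature == "ori") {
    deg <- rvonmises(n, kappa) * 180 / pi / 2
    list(w = deg * pi / 180, degrees = deg)
  } else {
    list(w = stats::runif(n, -0.5, 0.5))
  }
}

#' Simulate one behavioral response
#'
#' With probability `timo_rate` for the trial's condition the observer emits
#' a task-irrelevant key (subtype drawn from `timo_weights`, key uniform
#' within the subtype's pair); otherwise the binary response follows the
#' lapse-extended psychometric curve with the condition's parameters and the
#' corresponding relevant key is pressed. The reaction time is drawn from
#' the condition's ex-Gaussian (truncated to positive values by rejection);
#' TIMO trials share the same RT distribution.
#'
#' @param observer An [observer_params()].
#' @param condition Condition name (`Ori`, `Col`, `OriS`, `ColS`).
#' @param side Cued side.
#' @param w Normalized target stimulus value.
#' @param keymap Key map.
#' @return List with `key`, `response_class`, `timo_subtype`, `r` (0/1, `NA`
#'   for TIMO) and `rt`.
#' @export
simulate_response <- function(observer, condition, side, w, keymap = key_map()) {
  parts <- condition_parts(condition)
  f <- parts$feature
  ex <- observer$exgauss[[condition]]
  rt <- rexgauss(1L, ex[["mu"]], ex[["sigma"]], ex[["tau"]], truncate = TRUE)
  if (stats::runif(1) < observer$timo_rate[[condition]]) {
    subtype <- sample(c("spatial", "feature", "both"), 1L,
                      prob = observer$timo_weights[c("spatial", "feature", "both")])
    key <- sample(timo_keys(f, side, subtype, keymap), 1L)
    return(list(key = key, response_class = "timo", timo_subtype = subtype,
                r = NA_integer_, rt = rt))
  }
  sig <- observer$sigma[[paste0(f, "_", parts$load)]]
  p1 <- psychometric_prob(w, observer$mu[[f]], sig, observer$lambda[[f]])
  r <- as.integer(stats::runif(1) < p1)
  resp <- if (r == 1L) "r1" else "r0"
  list(key = response_key(f, side, resp, keymap), response_class = resp,
       timo_subtype = "none", r = r, rt = rt)
}

#' Simulate a full participant session
#'
#' Runs the block design with four independent adaptive staircases, one per
#' condition. On each trial the staircase of the trial's condition proposes
#' the target stimulus by expected-entropy minimization; the spatial cue is
#' uniform random, as is the relevant feature within switch blocks. The
#' staircase is updated only when the response is a relevant-key press —
#' TIMO trials never reach the posterior update.
#'
#' @param observer An [observer_params()].
#' @param design A [design_spec()].
#' @param engine A shared [psi_engine()] (built on demand if `NULL`;
#'   supplying one avoids recomputing the likelihood tables per participant).
#' @param participant_id,group Identification columns for the trial table.
#' @return A validated trial table. The number of posterior updates per
#'   condition equals its number of non-TIMO trials.
#' @export
simulate_participant <- function(observer, design = design_spec(), engine = NULL,
                                 participant_id = "p01", group = "unknown") {
  if (is.null(engine)) engine <- psi_engine()
  keymap <- key_map()
  states <- lapply(condition_names(), function(x) psi_init(engine))
  names(states) <- condition_names()

  n_total <- length(design$block_order) * design$trials_per_block
  col <- function(proto) rep(proto, n_total)
  out <- list(block_index = col(NA_integer_), block_type = col(NA_character_),
              feature = col(NA_character_), load = col(NA_character_),
              side = col(NA_character_), w_target = col(NA_real_),
              w_distractor = col(NA_real_), key = col(NA_integer_),
              response_class = col(NA_character_), timo_subtype = col(NA_character_),
              correct = col(NA_integer_), rt = col(NA_real_))

  i <- 0L
  for (b in seq_along(design$block_order)) {
    btype <- design$block_order[b]
    load <- if (btype == "S") "switch" else "noswitch"
    for (t in seq_len(design$trials_per_block)) {
      i <- i + 1L
      feature <- switch(btype, O = "ori", C = "col",
                        S = sample(c("ori", "col"), 1L))
      cond <- condition_name(feature, load)
      side <- sample(c("left", "right"), 1L)
      w <- select_stimulus(states[[cond]])
      resp <- simulate_response(observer, cond, side, w, keymap)
      if (resp$response_class != "timo") {
        states[[cond]] <- update_posterior(states[[cond]], w, resp$r)
      }
      out$block_index[i] <- b
      out$block_type[i] <- btype
      out$feature[i] <- feature
      out$load[i] <- load
      out$side[i] <- side
      out$w_target[i] <- w
      out$w_distractor[i] <- sample_distractor(feature, 1L, design$distractor_kappa)$w
      out$key[i] <- resp$key
      out$response_class[i] <- resp$response_class
      out$timo_subtype[i] <- resp$timo_subtype
      out$correct[i] <- if (resp$response_class == "timo") NA_integer_ else {
        if (resp$r == 1L) as.integer(w >= 0) else as.integer(w < 0)
      }
      out$rt[i] <- resp$rt
    }
  }
  trials <- data.frame(participant_id = participant_id, group = group,
                       out, stringsAsFactors = FALSE)
  attr(trials, "staircase_states") <- states
  validate_trials(trials)
  trials
}

# ---- cohort specification -------------------------------------------------

dist_spec <- function(dist, ..., lower = -Inf, upper = Inf) {
  list(dist = dist, pars = list(...), lower = lower, upper = upper)
}

draw_param <- function(spec) {
  for (k in 1:1000) {
    x <- switch(spec$dist,
                normal = stats::rnorm(1, spec$pars$mean, spec$pars$sd),
                lognormal = stats::rlnorm(1, spec$pars$meanlog, spec$pars$sdlog),
                fixed = spec$pars$value,
                stop("unknown distribution: ", spec$dist, call. = FALSE))
    if (x >= spec$lower && x <= spec$upper) return(x)
    if (spec$dist == "fixed") break
  }
  stop("rejection sampling failed for a cohort parameter", call. = FALSE)
}

group_param_defaults <- function(group) {
  adhd <- group == "adhd"
  ln <- function(median, sdlog, lower = 0, upper = Inf) {
    dist_spec("lognormal", meanlog = log(median), sdlog = sdlog,
              lower = lower, upper = upper)
  }
  p <- list(
    mu_ori = dist_spec("normal", mean = 0, sd = 0.02, lower = -0.2, upper = 0.2),
    mu_col = dist_spec("normal", mean = 0, sd = 0.02, lower = -0.2, upper = 0.2),
    lambda_ori = ln(0.015, 0.7, lower = 1e-4, upper = 0.3),
    lambda_col = ln(0.035, 0.7, lower = 1e-4, upper = 0.3),
    sigma_ori_noswitch = ln(if (adhd) 0.12 else 0.05, 0.35, lower = 0.002, upper = 0.6),
    sigma_ori_switch = ln(if (adhd) 0.12 else 0.05, 0.35, lower = 0.002, upper = 0.6),
    sigma_col_noswitch = ln(if (adhd) 0.11 else 0.08, 0.35, lower = 0.002, upper = 0.6),
    sigma_col_switch = ln(if (adhd) 0.11 else 0.08, 0.35, lower = 0.002, upper = 0.6)
  )
  timo_ns <- if (adhd) 0.030 else 0.015
  timo_sw <- if (adhd) 0.128 else 0.067
  p$timo_Ori <- ln(timo_ns, 0.6, upper = 1)
  p$timo_Col <- ln(timo_ns, 0.6, upper = 1)
  p$timo_OriS <- ln(timo_sw, 0.6, upper = 1)
  p$timo_ColS <- ln(timo_sw, 0.6, upper = 1)
  rt_shift <- if (adhd) 0.08 else 0
  rt_mu <- c(Ori = 0.45, Col = 0.55, OriS = 0.55, ColS = 0.65) + rt_shift
  tau_base <- if (adhd) 0.25 else 0.15
  tau <- tau_base * c(Ori = 1, Col = 1.1, OriS = 1.15, ColS = 1.25)
  for (cn in condition_names()) {
    p[[paste0("rt_mu_", cn)]] <- dist_spec("normal", mean = rt_mu[[cn]], sd = 0.08,
                                           lower = 0.05)
    p[[paste0("rt_sigma_", cn)]] <- ln(0.08, 0.3, lower = 1e-3)
    p[[paste0("rt_tau_", cn)]] <- ln(tau[[cn]], 0.4, lower = 1e-3)
  }
  p
}

#' Cohort specification for the synthetic-data generator
#'
#' Describes how many observers to draw per group and the per-group sampling
#' distribution of every generative parameter. The defaults emulate the
#' group differences the task was built to expose: higher perceptual
#' variability in the ADHD group (strongly for orientation, mildly for
#' colour), higher TIMO in ADHD and under switch load, longer and more
#' variable (larger exponential tail) reaction times in ADHD, more lapses
#' for colour, and no group difference in bias or lapse rate. Distributions
#' are log-normal for positive, ratio-scaled parameters (sigma, lapse, TIMO
#' rate, RT tail) and normal for location parameters, with rejection
#' resampling outside each parameter's valid range.
#'
#' @param n_adhd,n_control Group sizes.
#' @param adhd,control Named lists of distribution specifications (see
#'   source of `group_param_defaults`); entries override the defaults.
#' @param timo_weights Shared TIMO subtype split.
#' @param seed Default seed used by [simulate_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_adhd = 20L, n_control = 20L, adhd = list(),
                        control = list(),
                        timo_weights = c(spatial = 0.25, feature = 0.5, both = 0.25),
                        seed = 1L) {
  stopifnot(n_adhd >= 0, n_control >= 0)
  pa <- utils::modifyList(group_param_defaults("adhd"), adhd)
  pc <- utils::modifyList(group_param_defaults("control"), control)
  structure(list(n_adhd = as.integer(n_adhd), n_control = as.integer(n_control),
                 params = list(adhd = pa, control = pc),
                 timo_weights = timo_weights, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param spec A `cohort_spec`.
#' @param group `"adhd"` or `"control"`.
#' @return `sample_observer()`: an [observer_params()] drawn from the
#'   group's distributions.
#' @export
sample_observer <- function(spec, group) {
  p <- spec$params[[group]]
  d <- lapply(p, draw_param)
  ex <- lapply(condition_names(), function(cn) {
    c(mu = d[[paste0("rt_mu_", cn)]], sigma = d[[paste0("rt_sigma_", cn)]],
      tau = d[[paste0("rt_tau_", cn)]])
  })
  names(ex) <- condition_names()
  observer_params(
    mu = c(ori = d$mu_ori, col = d$mu_col),
    lambda = c(ori = d$lambda_ori, col = d$lambda_col),
    sigma = c(ori_noswitch = d$sigma_ori_noswitch, ori_switch = d$sigma_ori_switch,
              col_noswitch = d$sigma_col_noswitch, col_switch = d$sigma_col_switch),
    timo_rate = c(Ori = d$timo_Ori, Col = d$timo_Col,
                  OriS = d$timo_OriS, ColS = d$timo_ColS),
    timo_weights = spec$timo_weights,
    exgauss = ex)
}

observer_truth_row <- function(observer, participant_id, group) {
  flat <- c(
    stats::setNames(as.numeric(observer$mu[c("ori", "col")]), c("mu_ori", "mu_col")),
    stats::setNames(as.numeric(observer$lambda[c("ori", "col")]),
                    c("lambda_ori", "lambda_col")),
    stats::setNames(as.numeric(observer$sigma[c("ori_noswitch", "ori_switch",
                                                "col_noswitch", "col_switch")]),
                    paste0("sigma_", c("ori_noswitch", "ori_switch",
                                       "col_noswitch", "col_switch"))),
    stats::setNames(as.numeric(observer$timo_rate[condition_names()]),
                    paste0("timo_", condition_names())),
    stats::setNames(as.numeric(observer$timo_weights[c("spatial", "feature", "both")]),
                    paste0("timo_w_", c("spatial", "feature", "both"))),
    unlist(lapply(condition_names(), function(cn) {
      stats::setNames(as.numeric(observer$exgauss[[cn]][c("mu", "sigma", "tau")]),
                      paste0("rt_", c("mu", "sigma", "tau"), "_", cn))
    }))
  )
  data.frame(participant_id = participant_id, group = group, t(flat),
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of synthetic observers
#'
#' Draws ground-truth parameters per observer from the cohort specification
#' and simulates every session. Deterministic given the seed. The ground
#' truth is returned as a separate table (and written by the pipeline to a
#' sidecar CSV, never into the trial table) so that analysis code cannot
#' peek at it.
#'
#' @param spec A [cohort_spec()].
#' @param design A [design_spec()].
#' @param engine Optional shared [psi_engine()].
#' @param seed Integer seed (defaults to the spec's).
#' @return List with `trials` (validated trial table for all observers) and
#'   `truth` (one row of generative parameters per observer).
#' @export
simulate_cohort <- function(spec = cohort_spec(), design = design_spec(),
                            engine = NULL, seed = spec$seed) {
  set.seed(seed)
  if (is.null(engine)) engine <- psi_engine()
  plan <- data.frame(
    group = rep(c("adhd", "control"), c(spec$n_adhd, spec$n_control)),
    stringsAsFactors = FALSE)
  plan$participant_id <- sprintf("%s%02d", substr(plan$group, 1, 1),
                                 c(seq_len(spec$n_adhd), seq_len(spec$n_control)))
  trials <- vector("list", nrow(plan))
  truth <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    obs <- sample_observer(spec, plan$group[i])
    trials[[i]] <- simulate_participant(obs, design, engine,
                                        participant_id = plan$participant_id[i],
                                        group = plan$group[i])
    attr(trials[[i]], "staircase_states") <- NULL
    truth[[i]] <- observer_truth_row(obs, plan$participant_id[i], plan$group[i])
  }
  list(trials = do.call(rbind, trials), truth = do.call(rbind, truth))
}
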