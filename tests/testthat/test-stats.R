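test_that("sidak_alpha matches its formula and limiting cases", {
  expect_equal(sidak_alpha(1), 0.05)
  expect_equal(sidak_alpha(12), 1 - 0.95^(1 / 12))
  expect_equal(sidak_alpha(2.5, 0.1), 1 - 0.9^(1 / 2.5))
  expect_true(all(diff(sidak_alpha(1:20)) < 0))
  expect_error(sidak_alpha(0.5), ">= 1")
})

test_that("meff_sidak spans the identity and fully redundant extremes", {
  id7 <- diag(7)
  me <- meff_sidak(id7)
  expect_equal(me$M_eff, 7)
  expect_equal(round(me$alpha_sid, 4), 0.0073)
  ones <- matrix(1, 5, 5)
  me1 <- meff_sidak(ones)
  expect_equal(me1$M_eff, 1)               # sample variance (M - 1) makes this exact
  expect_equal(me1$alpha_sid, 0.05)
  # oracle recomputation for an arbitrary matrix
  R <- reference_correlations()
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  v <- sum((ev - mean(ev))^2) / (length(ev) - 1)
  expect_equal(meff_sidak(R)$M_eff, 1 + 6 * (1 - v / 7), tolerance = 1e-12)
  expect_error(meff_sidak(matrix(c(1, 0.5, 0.2, 1), 2, 2)), "symmetric")
  bad <- diag(3); bad[1, 1] <- 2
  expect_error(meff_sidak(bad), "unit diagonal")
})

test_that("reference_correlations is a valid correlation matrix", {
  R <- reference_correlations()
  expect_equal(dim(R), c(7L, 7L))
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 7))
  expect_equal(R["rt_median", "rt_tau"], 0.84)
  expect_equal(R["gec", "acds"], 0.80)
  expect_equal(R["timo", "gec"], 0.53)
  expect_true(all(eigen(R, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("spearman_matrix matches cor()/cor.test on data with ties and NAs", {
  set.seed(81)
  x <- data.frame(a = rnorm(30), b = rnorm(30), c = sample(1:5, 30, TRUE))
  x$b[c(3, 11)] <- NA
  sp <- spearman_matrix(x)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    ok <- complete.cases(x[[i]], x[[j]])
    expect_equal(sp$rho[i, j],
                 cor(x[[i]][ok], x[[j]][ok], method = "spearman"),
                 tolerance = 1e-12)
    expect_equal(sp$n[i, j], sum(ok))
  }
  # t-approximation p value oracle
  r <- sp$rho[1, 2]; n <- sp$n[1, 2]
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(sp$p[1, 2], 2 * pt(-abs(tstat), n - 2))
  expect_warning(spearman_matrix(data.frame(a = rep(1, 10), b = rnorm(10))),
                 "constant")
})

aov_oracle <- function(long, within) {
  fml <- as.formula(paste(
    "value ~ group *", paste(within, collapse = " * "),
    "+ Error(participant_id/(", paste(within, collapse = " * "), "))"))
  sm <- summary(aov(fml, data = long))
  out <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    res <- which(rn == "Residuals")
    for (k in seq_len(nrow(tab))) {
      if (k == res) next
      out[[rn[k]]] <- c(F = tab$`F value`[k], p = tab$`Pr(>F)`[k],
                        pes = tab$`Sum Sq`[k] / (tab$`Sum Sq`[k] + tab$`Sum Sq`[res]))
    }
  }
  out
}

test_that("mixed_anova agrees with the aov error-stratum oracle", {
  set.seed(82)
  make_long <- function(n_per_group, within_levels) {
    cells <- do.call(expand.grid, within_levels)
    ids <- sprintf("p%02d", seq_len(2 * n_per_group))
    grp <- rep(c("g1", "g2"), each = n_per_group)
    out <- do.call(rbind, lapply(seq_along(ids), function(i) {
      data.frame(participant_id = ids[i], group = grp[i], cells,
                 value = rnorm(nrow(cells), mean = ifelse(grp[i] == "g1", 0, 0.5)),
                 stringsAsFactors = FALSE)
    }))
    out
  }
  long <- make_long(5, list(load = c("noswitch", "switch"), feature = c("ori", "col")))
  res <- mixed_anova(long, "value")
  oracle <- aov_oracle(long, c("load", "feature"))
  map <- c(group = "group", load = "load", feature = "feature",
           "load:feature" = "load:feature", "group:load" = "group:load",
           "group:feature" = "group:feature",
           "group:load:feature" = "group:load:feature")
  for (eff in res$effect) {
    okey <- names(oracle)[match(gsub(" ", "", eff),
                                gsub(" ", "", names(oracle)))]
    expect_false(is.na(okey), info = eff)
    o <- oracle[[okey]]
    row <- res[res$effect == eff, ]
    expect_equal(row$F, unname(o["F"]), tolerance = 1e-6, info = eff)
    expect_equal(row$p, unname(o["p"]), tolerance = 1e-6, info = eff)
    expect_equal(row$pes, unname(o["pes"]), tolerance = 1e-6, info = eff)
  }

  # three within factors (the split-half learning design)
  long3 <- make_long(4, list(load = c("noswitch", "switch"),
                             feature = c("ori", "col"),
                             time = c("first", "second")))
  res3 <- mixed_anova(long3, "value", within = c("load", "feature", "time"))
  oracle3 <- aov_oracle(long3, c("load", "feature", "time"))
  expect_equal(nrow(res3), 15L)  # 1 between + 7 within + 7 interactions
  for (eff in c("time", "load:feature:time", "group:load:feature:time")) {
    okey <- names(oracle3)[match(gsub(" ", "", eff), gsub(" ", "", names(oracle3)))]
    o <- oracle3[[okey]]
    row <- res3[res3$effect == eff, ]
    expect_equal(row$F, unname(o["F"]), tolerance = 1e-6, info = eff)
  }
})

test_that("mixed_anova rejects unbalanced or incomplete designs", {
  set.seed(83)
  long <- expand.grid(participant_id = sprintf("p%d", 1:6),
                      load = c("noswitch", "switch"),
                      feature = c("ori", "col"), stringsAsFactors = FALSE)
  long$group <- ifelse(long$participant_id %in% c("p1", "p2", "p3"), "g1", "g2")
  long$value <- rnorm(nrow(long))
  expect_silent(mixed_anova(long, "value"))
  expect_error(mixed_anova(long[-1, ], "value"), "balanced")
  long_uneq <- long
  long_uneq$group[long_uneq$participant_id == "p3"] <- "g2"
  expect_error(mixed_anova(long_uneq, "value"), "equal size")
  long_na <- long; long_na$value[1] <- NA
  expect_error(mixed_anova(long_na, "value"), "missing")
})

test_that("bootstrap_median_ci is deterministic, ordered and degenerate-safe", {
  set.seed(84)
  x <- rlnorm(25)
  a <- bootstrap_median_ci(x, n_iter = 500, seed = 9)
  b <- bootstrap_median_ci(x, n_iter = 500, seed = 9)
  expect_identical(a, b)
  expect_lte(a[["ci_low"]], a[["median"]])
  expect_gte(a[["ci_high"]], a[["median"]])
  const <- bootstrap_median_ci(rep(2, 10), n_iter = 100, seed = 1)
  expect_equal(unname(const), c(2, 2, 2))
  expect_error(bootstrap_median_ci(numeric(0)), "empty")
})

test_that("posthoc plans run the documented comparison counts at Sidak levels", {
  set.seed(85)
  vals <- data.frame(participant_id = sprintf("p%d", 1:12),
                     group = rep(c("adhd", "control"), each = 6),
                     Ori = rnorm(12), Col = rnorm(12),
                     OriS = rnorm(12, 0.5), ColS = rnorm(12, 0.5))
  ph3 <- posthoc_tests(vals, "threeway")
  expect_equal(nrow(ph3), 12L)
  expect_equal(unique(ph3$alpha_sid), sidak_alpha(12))
  expect_equal(sum(ph3$type == "between"), 4L)
  expect_equal(sum(ph3$type == "within"), 8L)
  ph2 <- posthoc_tests(vals, "twoway")
  expect_equal(nrow(ph2), 4L)
  expect_equal(unique(ph2$alpha_sid), sidak_alpha(4))
  # oracle: the between-group comparison is a rank-sum test
  w <- wilcox.test(vals$Ori[vals$group == "adhd"], vals$Ori[vals$group == "control"],
                   exact = FALSE, correct = TRUE)$p.value
  expect_equal(ph3$p[ph3$comparison == "Ori" & ph3$type == "between"], w)
  # degenerate paired comparison reports p = 1
  vals$ColS <- vals$Col
  phd <- posthoc_tests(vals, "threeway")
  expect_equal(phd$p[phd$comparison == "Col vs ColS"], c(1, 1))
})

test_that("clinical regression reports fit, collinearity and rank deficiency", {
  mt <- quick_metrics()
  mt$gec <- 2 * mt$log_sigma - mt$log_timo   # exact linear combination, no noise
  mt$acds <- rnorm(nrow(mt))
  # n = 6 rows cannot support 5 regressors
  expect_error(regress_clinical(mt, "gec"), "too few")
  fit <- regress_clinical(mt, "gec", regressors = c("log_sigma", "log_timo"))
  expect_equal(fit$r_squared, 1)
  expect_equal(unname(fit$coefficients[, "Estimate"]), c(0, 2, -1), tolerance = 1e-8)
  expect_false(fit$rank_deficient)
  # det of a 1-column regressor correlation matrix is 1
  f1 <- regress_clinical(mt, "gec", regressors = "log_sigma")
  expect_equal(f1$cor_determinant, 1)
  # duplicated regressor triggers the rank-deficiency flag
  mt$log_dup <- mt$log_sigma
  fd <- regress_clinical(mt, "gec", regressors = c("log_sigma", "log_dup"))
  expect_true(fd$rank_deficient)
})
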