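# Typed ANOVA, marginal-mean contrasts, Mann-Whitney, covariate screen.

test_that("one balanced factor: F equals the squared pooled t statistic", {
  set.seed(21)
  d <- data.frame(y = c(rnorm(12, 0), rnorm(12, 0.8)),
                  g = rep(c("A", "B"), each = 12))
  fit <- fit_anova(d, "y", "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(fit$table$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$table$p[1], tt$p.value, tolerance = 1e-10)
  expect_equal(fit$table$df2[1], 22)
})

test_that("a constant response yields all-zero F statistics", {
  d <- data.frame(y = rep(1.5, 20), g = rep(c("A", "B"), 10),
                  s = rep(c("M", "F"), each = 10))
  fit <- fit_anova(d, "y", c("s", "g"))
  expect_equal(fit$table$F, c(0, 0))
  expect_equal(fit$model_F, 0)
})

test_that("type-2 and type-3 tables agree on a balanced 2x2 design", {
  set.seed(22)
  d <- expand.grid(g = c("A", "B"), s = c("M", "F"),
                   rep = 1:8, KEEP.OUT.ATTRS = FALSE)
  d$y <- rnorm(nrow(d)) + 0.5 * (d$g == "B") + 0.3 * (d$s == "M")
  t2 <- fit_anova(d, "y", c("s", "g", "s:g"), ss_type = 2)
  t3 <- fit_anova(d, "y", c("s", "g", "s:g"), ss_type = 3)
  expect_equal(t2$table$F, t3$table$F, tolerance = 1e-10)
  expect_equal(t2$table$p, t3$table$p, tolerance = 1e-10)
})

test_that("ss_type defaults to 3 with an interaction and 2 without", {
  set.seed(23)
  d <- data.frame(y = rnorm(24), g = rep(c("A", "B"), 12),
                  s = rep(c("M", "F"), each = 12))
  expect_equal(fit_anova(d, "y", c("s", "g"))$ss_type, 2)
  expect_equal(fit_anova(d, "y", c("s", "g", "s:g"))$ss_type, 3)
})

test_that("rank deficiency and missing data are reported, not silent", {
  set.seed(24)
  d <- data.frame(y = rnorm(20), g = rep(c("A", "B"), each = 10))
  d$g2 <- d$g  # alias
  expect_error(fit_anova(d, "y", c("g", "g2")), "aliased")

  d$sex <- rep(c("M", "F"), 10)
  d$sex[1:3] <- NA
  fit <- fit_anova(d, "y", c("sex", "g"))
  expect_equal(fit$n_dropped, 3)
  expect_equal(fit$n_used, 17)
})

test_that("two-level Tukey contrasts reduce to the model t-test", {
  set.seed(25)
  d <- data.frame(y = c(rnorm(10), rnorm(14, 0.5)),
                  g = rep(c("A", "B"), c(10, 14)),
                  s = sample(c("M", "F"), 24, TRUE))
  fit <- fit_anova(d, "y", c("s", "g"))
  ctr <- emm_pairwise(fit, "g")
  tstat <- ctr$estimate / ctr$se
  expect_equal(ctr$p_adj, 2 * pt(-abs(tstat), ctr$df), tolerance = 1e-10)
  # and the contrast equals the difference of the marginal means
  em <- as.data.frame(emmeans::emmeans(fit$fit, "g"))
  expect_equal(ctr$estimate, em$emmean[1] - em$emmean[2],
               tolerance = 1e-10)
})

test_that("identical group means give zero contrast estimates", {
  d <- expand.grid(g = c("A", "B", "C"), rep = 1:4)
  d$y <- rep(c(1, 2, 3, 4), each = 3)  # same values in every group
  d$s <- rep(c("M", "F"), 6)
  fit <- fit_anova(d, "y", c("s", "g"))
  ctr <- emm_pairwise(fit, "g")
  expect_equal(ctr$estimate, rep(0, 3), tolerance = 1e-10)
})

test_that("three-group Tukey p matches a Monte-Carlo studentized-range tail", {
  set.seed(26)
  d <- data.frame(y = c(rnorm(8, 0), rnorm(8, 0.6), rnorm(8, 1.0)),
                  g = rep(c("A", "B", "C"), each = 8))
  fit <- fit_anova(d, "y", "g")
  ctr <- emm_pairwise(fit, "g")
  df <- ctr$df[1]
  # observed studentized statistic for each pair: q = |diff| / SE, and
  # the Tukey p is P(range of 3 standardized means / (s*sqrt(1/n)) >= q*sqrt(2))
  q_obs <- abs(ctr$estimate) / ctr$se * sqrt(2)
  set.seed(27)
  nmc <- 1e6
  z <- matrix(rnorm(3 * nmc), ncol = 3)
  s <- sqrt(rchisq(nmc, df) / df)
  qmc <- (apply(z, 1, max) - apply(z, 1, min)) / s
  for (i in seq_along(q_obs)) {
    p_mc <- mean(qmc >= q_obs[i])
    expect_equal(ctr$p_adj[i], p_mc, tolerance = 0.005)
  }
})

test_that("Mann-Whitney U: separation, conservation, exact enumeration", {
  mw <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(mw$u, 0)
  expect_equal(mw$u_other, 9)

  set.seed(28)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(5)
    mw <- mann_whitney_u(x, y)
    expect_equal(mw$u + mw$u_other, 30)
  }

  set.seed(29)
  x <- rnorm(4); y <- rnorm(4, 1)
  mw <- mann_whitney_u(x, y)
  expect_identical(mw$method, "exact")
  expect_equal(mw$p, mw_enum_p(x, y), tolerance = 1e-10)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("ties fall back to midranks and the normal approximation", {
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  mw <- mann_whitney_u(x, y)
  expect_identical(mw$method, "normal_approx")
  r <- rank(c(x, y))
  expect_equal(mw$u, sum(r[1:4]) - 10)
})

test_that("F statistics are invariant to response rescaling and log base", {
  set.seed(30)
  mass <- runif(40, 10, 60)
  d <- data.frame(fish_id = sprintf("F%02d", 1:40),
                  smr = 0.2 * mass^0.8 * 10^rnorm(40, 0, 0.05),
                  g = rep(c("A", "B"), 20),
                  s = sample(c("M", "F"), 40, TRUE))
  r10 <- mass_residuals(d, mass, metrics = "smr", log_base = 10)
  re <- mass_residuals(d, mass, metrics = "smr", log_base = exp(1))
  d$y10 <- r10$smr$residuals$residual
  d$ye <- re$smr$residuals$residual
  f10 <- fit_anova(d, "y10", c("s", "g"))
  fe <- fit_anova(d, "ye", c("s", "g"))
  expect_equal(f10$table$F, fe$table$F, tolerance = 1e-10)
  expect_equal(f10$table$p, fe$table$p, tolerance = 1e-10)
  d$yaff <- 100 * d$y10 - 3
  faff <- fit_anova(d, "yaff", c("s", "g"))
  expect_equal(f10$table$F, faff$table$F, tolerance = 1e-10)
})

test_that("the morphology screen drops null covariates and keeps real ones", {
  set.seed(31)
  n <- 60
  d <- data.frame(y = rnorm(n), g = rep(c("A", "B"), n / 2),
                  s = sample(c("M", "F"), n, TRUE),
                  pc2 = rnorm(n), pc3 = rnorm(n))
  d$y <- d$y + 0.4 * (d$g == "B")

  # null covariates: dropped in ~95% of replicates
  dropped <- 0
  for (seed in 1:200) {
    set.seed(seed)
    d$pc2 <- rnorm(n)
    d$y2 <- rnorm(n) + 0.4 * (d$g == "B")
    sc <- screen_morphology_covariates(d, "y2", c("s", "g"),
                                       group_factor = "g",
                                       covariates = "pc2")
    if (!length(sc$retained)) dropped <- dropped + 1
  }
  expect_gt(dropped / 200, 0.85)

  # a strong covariate-by-group interaction is retained
  set.seed(32)
  d$pc2 <- rnorm(n)
  d$y3 <- rnorm(n, sd = 0.5) + 1.5 * d$pc2 * (d$g == "B")
  sc <- screen_morphology_covariates(d, "y3", c("s", "g"),
                                     group_factor = "g")
  expect_true("pc2" %in% sc$retained)
  expect_true(any(grepl("pc2", sc$reduced_terms)))

  # absent covariates pass through untouched
  sc0 <- screen_morphology_covariates(d[c("y", "g", "s")], "y",
                                      c("s", "g"), group_factor = "g")
  expect_equal(nrow(sc0$report), 0)
  expect_identical(sc0$reduced_terms, c("s", "g"))
})
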