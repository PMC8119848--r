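# Mixed ANOVA, Holm-Sidak, bootstrap Tukey, regression on the motor score.

test_that("two within-levels satisfy sphericity trivially", {
  set.seed(1)
  Y <- matrix(rnorm(16 * 2), 16)
  res <- mixed_anova(Y, rep(c("a", "b"), each = 8))
  expect_equal(res$epsilon, 1)
  expect_equal(res$mauchly_w, 1)
  expect_equal(res$mauchly_p, 1)
})

test_that("a 2x2 toy matches the hand-computed ANOVA table", {
  # two groups x two bands, two subjects each; hand sums of squares
  Y <- rbind(c(1, 3), c(2, 4),      # group a subjects
             c(5, 5), c(6, 8))      # group b subjects
  g <- c("a", "a", "b", "b")
  res <- mixed_anova(Y, g)
  # hand computation (balanced 2x2 split-plot):
  gm <- mean(Y)                                   # 4.25
  subj <- rowMeans(Y)                             # 2, 3, 5, 7
  ss_between <- 2 * sum((subj - gm)^2)
  ss_group <- 2 * (2 * (2.5 - 4.25)^2 + 2 * (6 - 4.25)^2)
  ss_subj <- ss_between - ss_group
  band <- colMeans(Y)
  ss_band <- 4 * sum((band - gm)^2)
  cells <- rbind(colMeans(Y[1:2, ]), colMeans(Y[3:4, ]))
  ss_int <- 2 * sum((cells - outer(c(2.5, 6), c(1, 1)) -
                       outer(c(1, 1), band) + gm)^2)
  ss_err <- sum((Y - gm)^2) - ss_between - ss_band - ss_int
  F_group <- (ss_group / 1) / (ss_subj / 2)
  F_band <- (ss_band / 1) / (ss_err / 2)
  F_int <- (ss_int / 1) / (ss_err / 2)
  eff <- res$effects
  expect_equal(eff$F[eff$term == "group"], F_group, tolerance = 1e-8)
  expect_equal(eff$F[eff$term == "frequency"], F_band, tolerance = 1e-8)
  expect_equal(eff$F[eff$term == "interaction"], F_int, tolerance = 1e-8)
})

test_that("the sum-of-squares decomposition is exact on arbitrary input", {
  for (s in 1:5) {
    set.seed(s)
    Y <- matrix(rnorm(18 * 4, sd = 1 + s / 3), 18)
    res <- mixed_anova(Y, rep(c("a", "b", "c"), each = 6))
    ss <- res$ss
    lhs <- ss["total"]
    rhs <- ss["group"] + ss["subj_within"] + ss["frequency"] +
      ss["interaction"] + ss["error"]
    expect_lt(abs(lhs - rhs) / lhs, 1e-8)
  }
})

test_that("GG correction does not shrink a supra-unity within-term p-value", {
  set.seed(2)
  # non-sphericity (band 4 inflated) plus a real frequency effect so F > 1;
  # Greenhouse-Geisser is conservative in that regime
  Y <- matrix(rnorm(20 * 4), 20)
  Y[, 4] <- Y[, 4] * 4 + rowMeans(Y) * 2
  Y <- Y + rep(1, 20) %o% c(0, 2, 4, 0)
  res <- mixed_anova(Y, rep(c("a", "b"), each = 10))
  expect_lt(res$mauchly_p, 0.05)
  eff <- res$effects
  expect_lt(res$epsilon, 1)
  expect_gte(eff$p_corrected[eff$term == "frequency"],
             eff$p[eff$term == "frequency"] - 1e-12)
})

test_that("Holm-Sidak steps down with the stated thresholds", {
  # single p: reject iff p < alpha
  expect_true(holm_sidak(0.04)$reject)
  expect_false(holm_sidak(0.06)$reject)
  # m = 3 hand case: thresholds 0.016952, 0.025321, 0.05
  hs <- holm_sidak(c(0.001, 0.5, 0.9))
  expect_equal(hs$threshold, 1 - (1 - 0.05)^(1 / c(3, 2, 1)))
  expect_equal(hs$reject, c(TRUE, FALSE, FALSE))
  expect_false(any(holm_sidak(rep(1, 5))$reject))
})

test_that("Holm-Sidak rejections sit between Bonferroni and unadjusted", {
  set.seed(3)
  for (s in 1:5) {
    p <- runif(8)^2
    hs <- holm_sidak(p)$reject
    bonf <- p < 0.05 / 8
    raw <- p < 0.05
    expect_true(all(hs[bonf]))          # superset of Bonferroni
    expect_true(all(raw[hs]))           # subset of unadjusted
  }
})

test_that("bootstrap Tukey is seeded and calibrated", {
  set.seed(4)
  g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8))
  r1 <- bootstrap_tukey(g, n_boot = 200, seed = 9)
  r2 <- bootstrap_tukey(g, n_boot = 200, seed = 9)
  expect_identical(r1, r2)
  # identical populations: p roughly uniform over seeds
  pbar <- mean(vapply(1:30, function(s) {
    set.seed(400 + s)
    gg <- list(a = rnorm(6), b = rnorm(6))
    bootstrap_tukey(gg, n_boot = 120, seed = s)$p[1]
  }, 0))
  expect_gt(pbar, 0.35)
  expect_lt(pbar, 0.65)
  # widely separated groups: p at the resolution floor
  far <- list(a = rnorm(6), b = rnorm(6) + 10)
  res <- bootstrap_tukey(far, n_boot = 400, seed = 5)
  expect_lte(res$p[1], 1 / 401 + 1e-9)
  expect_error(bootstrap_tukey(list(a = c(1, 1), b = c(1, 2))), "degenerate")
})

test_that("regression on the motor score matches closed-form OLS", {
  fma <- c(20, 30, 40, 50)
  y <- 2 * fma + 1
  fit <- regress_on_fma(y, fma)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # hand 4-point normal equations
  y2 <- c(3, 5, 4, 8)
  sxx <- sum((fma - mean(fma))^2)
  sxy <- sum((fma - mean(fma)) * (y2 - mean(y2)))
  b1 <- sxy / sxx
  b0 <- mean(y2) - b1 * mean(fma)
  fit2 <- regress_on_fma(y2, fma)
  expect_equal(fit2$slope, b1, tolerance = 1e-10)
  expect_equal(fit2$intercept, b0, tolerance = 1e-10)
  expect_error(regress_on_fma(y2, rep(30, 4)), "constant predictor")
})

test_that("regression defaults to stroke subjects; controls enter at FMA 66", {
  set.seed(5)
  fma <- c(NA, NA, 30, 40, 50, 60)
  grp <- c("control", "control", rep("stroke", 4))
  y <- c(9, 9, fma[3:6] * 0.1)
  fit <- regress_on_fma(y, fma, grp)
  expect_equal(fit$slope, 0.1, tolerance = 1e-10)
  fit_all <- regress_on_fma(y, fma, grp, include_controls = TRUE)
  expect_equal(length(stats::residuals(fit_all$fit)), 6L)
})

test_that("an orthogonal noise predictor gives near-zero R^2", {
  set.seed(6)
  r2 <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(40); y <- rnorm(40)
    regress_on_fma(y, x)$r_squared
  }, 0)
  expect_lt(mean(r2), 0.08)
})
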