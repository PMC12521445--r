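test_that("pool_fixed matches hand-worked weighted means", {
  expect_equal(pool_fixed(make_effects(c(0.1, 0.3)))$rr_pp, 0.2)
  pf <- pool_fixed(make_effects(c(0.0, 0.2, 0.4)))
  expect_equal(pf$rr_pp, 0.2)
  expect_equal(pf$var, 1 / 300)
  expect_equal(pool_fixed(make_effects(rep(0.13, 5)))$rr_pp, 0.13)
  expect_error(pool_fixed(make_effects(0.1)), "at least 2")
  expect_true(pf$rr_pp >= 0 && pf$rr_pp <= 0.4)  # within input range
})

test_that("pool_fixed agrees with metafor's fixed-effects fit", {
  skip_if_not_installed("metafor")
  set.seed(21)
  for (i in 1:5) {
    k <- sample(5:30, 1)
    x <- rnorm(k, 0.1, 0.3); v <- runif(k, 0.001, 0.05)
    pf <- pool_fixed(data.frame(log_rr = x, v = v))
    rf <- metafor::rma(yi = x, vi = v, method = "FE")
    expect_equal(pf$rr_pp, unname(coef(rf)), tolerance = 1e-10)
    expect_equal(sqrt(pf$var), unname(rf$se), tolerance = 1e-10)
  }
})

test_that("q_test reproduces the hand-worked heterogeneity example", {
  eff <- make_effects(c(0.0, 0.2, 0.4))
  q <- q_test(eff, 0.2)
  expect_equal(q$q_total, 8)             # 100 * (0.04 + 0 + 0.04)
  expect_equal(q$df, 2L)
  expect_equal(q$p_value, exp(-4))       # chi-sq df 2 survival: e^{-Q/2}
  expect_true(q$significant)
  # identical effects: Q = 0, p = 1
  q0 <- q_test(make_effects(rep(0.3, 4)), 0.3)
  expect_equal(q0$q_total, 0)
  expect_equal(q0$p_value, 1)
  # Q invariant under shifting all effects by a constant
  set.seed(8)
  x <- rnorm(10); v <- runif(10, 0.005, 0.05)
  e1 <- data.frame(log_rr = x, v = v)
  e2 <- data.frame(log_rr = x + 0.7, v = v)
  mu1 <- pool_fixed(e1)$rr_pp
  expect_equal(q_test(e1, mu1)$q_total,
               q_test(e2, mu1 + 0.7)$q_total)
})

test_that("DerSimonian-Laird tau2 matches the moments formula", {
  expect_equal(tau2_dl(8, rep(100, 3)), 0.03)     # (8-2)/200
  expect_equal(tau2_dl(1, rep(100, 3)), 0)        # Q <= df truncates
  expect_warning(t0 <- tau2_dl(5, 1), "degenerate")
  expect_equal(t0, 0)
  # brute-force check of the formula on random weights
  set.seed(9)
  w <- runif(8, 1, 300); q <- runif(1, 0, 40)
  expect_equal(tau2_dl(q, w),
               max(0, (q - 7) / (sum(w) - sum(w^2) / sum(w))))
})

test_that("pool_mixed reduces to fixed at tau2 = 0 and to the mean as tau2 grows", {
  eff <- make_effects(c(0.0, 0.2, 0.4), v = c(0.01, 0.02, 0.04))
  expect_equal(pool_mixed(eff, 0), pool_fixed(eff))
  expect_equal(pool_mixed(make_effects(c(0.0, 0.2, 0.4)), 0.03)$rr_pp, 0.2)
  expect_equal(pool_mixed(eff, 1e9)$rr_pp, mean(eff$log_rr),
               tolerance = 1e-6)
})

test_that("mixed-effects pooling agrees with metafor DL", {
  skip_if_not_installed("metafor")
  set.seed(22)
  k <- 15; x <- rnorm(k, 0, 0.3); v <- runif(k, 0.002, 0.03)
  eff <- data.frame(log_rr = x, v = v)
  q <- q_test(eff, pool_fixed(eff)$rr_pp)
  t2 <- tau2_dl(q$q_total, 1 / v)
  rd <- metafor::rma(yi = x, vi = v, method = "DL")
  expect_equal(q$q_total, unname(rd$QE), tolerance = 1e-10)
  expect_equal(t2, unname(rd$tau2), tolerance = 1e-10)
  expect_equal(pool_mixed(eff, t2)$rr_pp, unname(coef(rd)), tolerance = 1e-10)
})

test_that("select_and_pool gates the model on the heterogeneity test", {
  hom <- make_effects(rep(0.15, 6))
  r <- select_and_pool(hom)
  expect_equal(r$model, "fixed")
  expect_equal(r$rr_pp, 0.15)
  het <- select_and_pool(make_effects(c(0.0, 0.2, 0.4)))
  expect_equal(het$model, "mixed")
  expect_equal(het$rr_pp, 0.2)
  expect_equal(het$tau2, 0.03)
  # mixed variance never smaller than the fixed variance on the same data
  set.seed(13)
  for (i in 1:20) {
    k <- sample(4:25, 1)
    eff <- data.frame(log_rr = rnorm(k, 0, 0.4), v = runif(k, 0.002, 0.05))
    s <- select_and_pool(eff)
    expect_gte(s$var + 1e-15, pool_fixed(eff)$var)
  }
})

test_that("bootstrap_ci is seed-reproducible and handles degeneracy", {
  eff <- make_effects(c(0.05, 0.1, 0.2, 0.3, 0.12, 0.4, 0.22))
  ci1 <- bootstrap_ci(eff, b = 1999, seed = 5)
  ci2 <- bootstrap_ci(eff, b = 1999, seed = 5)
  expect_identical(ci1, ci2)
  expect_lte(ci1$ci_low, ci1$ci_high)
  expect_warning(cid <- bootstrap_ci(make_effects(rep(0.2, 5)), b = 999),
                 "identical")
  expect_equal(cid$ci_low, 0.2)
  expect_equal(cid$ci_high, 0.2)
  expect_error(bootstrap_ci(eff, b = 500), "999")
})

test_that("on a symmetric case the BC interval is close to the percentile interval", {
  # symmetric effects around 0 with equal weights: median bias ~ 0, z0 ~ 0,
  # so BC endpoints must be near-symmetric and near the plain percentiles
  eff <- make_effects(c(-0.3, -0.2, -0.1, 0, 0.1, 0.2, 0.3))
  ci <- bootstrap_ci(eff, b = 9999, seed = 17)
  expect_lt(abs(ci$z0), 0.08)
  expect_lt(abs(ci$ci_low + ci$ci_high), 0.06)
})

test_that("study-level cluster bootstrap runs and respects the seed", {
  eff <- make_effects(rnorm(12, 0.2, 0.1),
                      study_id = rep(paste0("s", 1:4), each = 3))
  c1 <- bootstrap_ci(eff, b = 999, seed = 2, unit = "study")
  c2 <- bootstrap_ci(eff, b = 999, seed = 2, unit = "study")
  expect_identical(c1, c2)
  expect_lte(c1$ci_low, c1$ci_high)
})

test_that("fit_gaussian is the ML normal fit", {
  expect_equal(fit_gaussian(c(-1, 1))$mu, 0)
  set.seed(30)
  x <- rnorm(1e4, 0.1, 0.2)
  g <- fit_gaussian(x)
  expect_equal(g$mu, 0.1, tolerance = 3 * 0.2 / sqrt(1e4) / 0.1)
  expect_equal(g$sigma, 0.2, tolerance = 0.02)
  expect_warning(g0 <- fit_gaussian(rep(0.5, 4)), "sigma = 0")
  expect_equal(g0$sigma, 0)
  expect_error(fit_gaussian(0.3), "at least 2")
})

test_that("pool_effects returns a coherent classed fit with methods", {
  eff <- make_effects(c(0.0, 0.2, 0.4))
  fit <- pool_effects(eff, b = 1999, seed = 42, factor = "n_addition")
  expect_s3_class(fit, "pooled_effect")
  expect_equal(fit$model, "mixed")
  expect_equal(unname(coef(fit)), 0.2)
  expect_equal(fit$percent_change, percent_change(0.2))
  ci <- confint(fit)
  expect_equal(unname(ci[1, ]), c(fit$ci_low, fit$ci_high))
  expect_equal(fit$significant, fit$ci_low > 0 || fit$ci_high < 0)
  s <- summary(fit)
  expect_equal(s$k_obs, 3)
  expect_output(print(fit), "mixed-effects")
})
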