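test_that("build_matrix applies the 12-month split and complete-case rule", {
  obs <- suppressWarnings(
    generate_meta_dataset(n_studies_per_factor = 2, obs_per_study = 3,
                          n_control_only = 60, seed = 3))
  h <- harmonize(obs)
  m_all <- build_matrix(h, "both", "all")
  m_le <- build_matrix(h, "both", "le12")
  m_gt <- build_matrix(h, "both", "gt12")
  expect_equal(nrow(m_le) + nrow(m_gt), nrow(m_all))   # exact partition
  expect_true(all(m_le$duration_months <= 12))         # boundary in <= group
  expect_true(all(m_gt$duration_months > 12))
  expect_true(all(stats::complete.cases(m_all)))
  expect_true("duration_months" %in% names(m_all))
  # a row with missing AUR is dropped from the quality set
  h2 <- h; h2$aur[1] <- NA
  expect_equal(nrow(build_matrix(h2, "quality", "all")),
               nrow(build_matrix(h, "quality", "all")) - 1)
  # boundary duration 12.0 goes to le12
  h3 <- h; h3$duration_months[] <- 12
  expect_equal(nrow(build_matrix(h3, "both", "le12")), nrow(h3))
})

test_that("forest explained variance separates signal from noise and is seed-stable", {
  set.seed(31)
  n <- 400
  m_sig <- data.frame(mass_loss = NA, duration_months = runif(n, 1, 36),
                      x1 = runif(n), x2 = runif(n))
  m_sig$mass_loss <- 80 * sin(2 * m_sig$x1) + rnorm(n, 0, 1)
  m_noise <- m_sig
  m_noise$mass_loss <- rnorm(n)
  r_sig <- rf_variance_explained(m_sig, n_trees = 200, seed = 4)
  r_noise <- rf_variance_explained(m_noise, n_trees = 200, seed = 4)
  expect_gte(r_sig, 0.8)
  expect_lte(r_noise, 0.1)
  expect_identical(r_sig, rf_variance_explained(m_sig, n_trees = 200, seed = 4))
  expect_error(rf_variance_explained(m_sig[1:10, ]), "at least 30")
})

test_that("permutation importance ranks a dominant predictor first with add-one p", {
  set.seed(32)
  n <- 200
  m <- data.frame(mass_loss = NA, duration_months = runif(n, 1, 36),
                  x1 = runif(n), x2 = runif(n))
  m$mass_loss <- 10 * m$x1 + rnorm(n, 0, 0.5)
  imp <- suppressWarnings(
    rf_permutation_importance(m, n_trees = 100, n_perm = 25, seed = 5))
  expect_equal(imp$predictor[which.max(imp$importance)], "x1")
  expect_equal(imp$p_value[imp$predictor == "x1"], 1 / 26)
  expect_true(all(imp$p_value > 0))          # add-one rule
  expect_warning(rf_permutation_importance(m, n_trees = 50, n_perm = 5,
                                           seed = 5),
                 "unstable")
})

test_that("group mean contribution averages importances within groups", {
  imp <- data.frame(predictor = c("a", "b", "c", "d"),
                    importance = c(4, 8, 2, 2))
  gm <- group_mean_contribution(imp, list(g1 = c("a", "b"), g2 = c("c", "d")))
  expect_equal(unname(gm), c(6, 2))
  # one group per predictor returns importances unchanged
  gm1 <- group_mean_contribution(imp, as.list(setNames(imp$predictor,
                                                       imp$predictor)))
  expect_equal(unname(gm1), imp$importance)
  # scaled variant sums (over predictors) to 100 * R2
  gms <- group_mean_contribution(imp, list(g1 = c("a", "b"), g2 = c("c", "d")),
                                 scale_to_r2 = 0.8)
  expect_equal(sum(gms * c(2, 2)), 80)
  expect_error(group_mean_contribution(imp, list(g = "zz")), "unknown")
})

test_that("pc1_composite standardizes, centres, and obeys the anchor sign rule", {
  set.seed(33)
  n <- 50
  base <- rnorm(n)
  m <- data.frame(n_conc = base + rnorm(n, 0, 0.01),
                  aur = 3 * base + rnorm(n, 0, 0.03))
  s <- pc1_composite(m, c("n_conc", "aur"), anchor = "n_conc")
  expect_equal(mean(s), 0, tolerance = 1e-10)
  expect_gte(attr(s, "var_explained"), 0.99)  # two near-collinear columns
  expect_gt(attr(s, "loadings")[["n_conc"]], 0)
  # flipping the input data flips scores, anchor rule restores orientation
  m2 <- -m
  s2 <- pc1_composite(m2, c("n_conc", "aur"), anchor = "n_conc")
  expect_equal(unclass(s2), -unclass(s), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_gt(attr(s2, "loadings")[["n_conc"]], 0)
  m$aur <- 1
  expect_error(pc1_composite(m, c("n_conc", "aur")), "zero-variance")
})

test_that("hierarchical partitioning matches closed forms and the ordering oracle", {
  # constructed 2-group case: R2(A)=.5, R2(B)=.3, R2(AB)=.6
  # IC_A = .5*(0.5 + (0.6-0.3)) = 0.4; IC_B = 0.2 (checked vs oracle too)
  set.seed(34)
  n <- 500
  a <- rnorm(n); b <- rnorm(n)
  for (g in 2:4) {
    comps <- as.data.frame(matrix(rnorm(n * g), n))
    names(comps) <- paste0("g", 1:g)
    y <- rowSums(comps[, 1:min(2, g)]) + rnorm(n, 0, 1.5)
    hp <- hierarchical_partition(y, comps)
    expect_equal(hp$independent_contribution, hp_oracle(y, comps),
                 tolerance = 1e-10)
    expect_equal(sum(hp$independent_contribution), hp$total_model_r2[1],
                 tolerance = 1e-10)
  }
})

test_that("orthogonal composites get their marginal R2 as independent contribution", {
  n <- 64
  # columns exactly orthogonal to each other and to the intercept
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, -1]
  comps <- data.frame(a = q[, 1], b = q[, 2])
  y <- 2 * comps$a + 1 * comps$b + q[, 3] * 0.5
  hp <- hierarchical_partition(y, comps)
  r2a <- summary(lm(y ~ comps$a))$r.squared
  r2b <- summary(lm(y ~ comps$b))$r.squared
  expect_equal(hp$independent_contribution,
               c(r2a, r2b), tolerance = 1e-8)
  expect_error(hierarchical_partition(y, comps["a"]), "at least 2")
})

test_that("trait correlations recover built-in chemistry effects", {
  obs <- suppressWarnings(
    generate_meta_dataset(n_studies_per_factor = 4, obs_per_study = 2,
                          n_control_only = 200, seed = 9))
  h <- harmonize(obs)
  aur <- trait_correlation(h, "aur")
  expect_lt(aur$r, 0)
  expect_lt(aur$p_value, 0.05)
  nconc <- trait_correlation(h, "n_conc")
  expect_gt(nconc$r, 0)
  # exact anticorrelation
  toy <- data.frame(mean_c = 10:1, aur = 1:10)
  expect_equal(trait_correlation(toy, "aur")$r, -1)
  toy$aur <- 5
  expect_error(trait_correlation(toy, "aur"), "constant")
  expect_error(trait_correlation(toy, "nope"), "not found")
})
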