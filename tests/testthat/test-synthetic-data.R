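test_that("site generation matches the intended geography", {
  s <- generate_sites(69, seed = 2)
  expect_equal(nrow(s), 69)
  expect_true(all(abs(s$latitude) >= 25 & abs(s$latitude) <= 55))
  expect_true(all(s$map > 0))
  expect_identical(s, generate_sites(69, seed = 2))
  # mat decreases with absolute latitude by construction
  expect_lt(coef(lm(mat ~ abs(latitude), data = s))[2], 0)
})

test_that("chemistry generation respects truncation, ratios and target medians", {
  ch <- generate_chemistry(1e4, seed = 3)
  expect_true(all(ch$aur > 5))
  expect_equal(ch$aur_n, ch$aur / ch$n_conc)
  expect_equal(ch$c_n, ch$c / ch$n_conc)
  expect_equal(median(ch$n_conc), 0.8, tolerance = 0.1)
  expect_equal(median(ch$aur), 25, tolerance = 0.1)
  expect_equal(median(ch$c), 42, tolerance = 0.1)
})

test_that("the decay model has the configured signs and limits", {
  tr <- default_truth()
  site <- data.frame(mat = 8, map = 450)
  lo <- data.frame(n_conc = 0.8, aur = 20)
  hi <- data.frame(n_conc = 0.8, aur = 40)
  m_lo <- control_mass_loss(site, lo, 12, noise_cv = 0, seed = 1, u_site = 0)
  m_hi <- control_mass_loss(site, hi, 12, noise_cv = 0, seed = 1, u_site = 0)
  expect_lt(m_hi, m_lo)   # more AUR, less decomposition
  # long-duration limit approaches (but never reaches) complete loss
  m_inf <- control_mass_loss(site, lo, 1e5, noise_cv = 0, seed = 1, u_site = 0)
  expect_equal(m_inf, 99.9)
  expect_error(control_mass_loss(site, lo, -1, u_site = 0), "duration")
})

test_that("median one-year ambient mass loss is calibrated near 40%", {
  n <- 1e4
  sites <- generate_sites(n, seed = 5)
  chem <- generate_chemistry(n, seed = 5)
  m <- control_mass_loss(sites, chem, rep(12, n), noise_cv = 0.1, seed = 5)
  expect_equal(median(m), 40, tolerance = 3 / 40)
})

test_that("default truth mirrors the established direction pattern", {
  tr <- default_truth()
  pos <- c("n_addition", "p_addition", "warming", "increased_precip",
           "elevated_co2", "grazing")
  neg <- c("reduced_precip", "vegetated_soil", "plant_richness",
           "litter_richness", "home_field", "fauna_exclusion")
  expect_true(all(tr$percent_change[pos] > 0))
  expect_true(all(tr$percent_change[neg] < 0))
  expect_true(all(abs(tr$percent_change) >= 4 & abs(tr$percent_change) <= 28))
  expect_equal(percent_change(tr$log_rr), tr$percent_change)
})

test_that("dataset generation is byte-deterministic and schema-valid", {
  obs <- suppressWarnings(
    generate_meta_dataset(n_studies_per_factor = 3, obs_per_study = 2,
                          n_control_only = 10, seed = 11))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_observations(obs, f1)
  obs2 <- suppressWarnings(
    generate_meta_dataset(n_studies_per_factor = 3, obs_per_study = 2,
                          n_control_only = 10, seed = 11))
  write_observations(obs2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # round-trips through validation with zero issues
  back <- read_observations(f1)
  expect_equal(nrow(back), nrow(obs))
  expect_equal(nrow(attr(back, "issues")), 0)
  # paired rows share study and duration by construction
  expect_equal(sum(obs$factor != "control_only"), 12 * 3 * 2)
})

test_that("degenerate truth gives back the configured effects exactly", {
  tr <- default_truth(tau = 0, cv = 1e-6, p_missing_sd = 0, p_ambiguous = 0)
  obs <- suppressWarnings(
    generate_meta_dataset(tr, n_studies_per_factor = 4,
                          obs_per_study = 2, n_control_only = 0,
                          seed = 21))
  # near-zero CV makes the variance floor kick in, by design
  expect_warning(eff <- compute_effect_sizes(harmonize(obs)), "floored")
  err <- abs(eff$log_rr - tr$log_rr[eff$factor])
  expect_lt(max(err), 1e-4)
})

test_that("missing and ambiguous dispersion fractions match the configuration", {
  tr <- default_truth(p_missing_sd = 0.3, p_ambiguous = 0.2)
  obs <- suppressWarnings(
    generate_meta_dataset(tr, n_studies_per_factor = 42,
                          obs_per_study = 10, n_control_only = 0,
                          seed = 13))
  lab <- c(obs$disp_label_t, obs$disp_label_c)   # ~10^4 draws
  expect_lt(abs(mean(lab == "missing") - 0.3), 0.02)
  expect_lt(abs(mean(lab == "ambiguous") - 0.2), 0.02)
})

test_that("truth records round-trip through YAML", {
  tr <- default_truth(percent_change = c(warming = 12), tau = 0.05)
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(percent_change = list(warming = 12), tau = 0.05), f)
  tr2 <- read_truth(f)
  expect_equal(tr2$percent_change, tr$percent_change)
  expect_equal(tr2$tau, tr$tau)
})
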