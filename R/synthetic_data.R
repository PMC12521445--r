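# Seeded synthetic multi-study root-decomposition datasets with known
# ground truth, emulating the statistical structure the analysis assumes:
# ~70 globally distributed grassland sites, ~1,100 treatment/control
# mass-loss pairs over 12 factors, study-level heterogeneity,
# chemistry-dependent decay, and messy dispersion reporting.

# Independent sub-streams (sites / chemistry / studies / noise) so that
# changing one component's count does not perturb the others' draws.
.substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 97 * k) %% (.Machine$integer.max - 1)) + 1L
}

#' Ground-truth generator parameters
#'
#' Default truth record for the synthetic generator. Per-factor true
#' percent changes carry the direction pattern established for grassland
#' root decomposition (positive for nutrient addition, warming, increased
#' precipitation, elevated CO2 and grazing; negative for reduced
#' precipitation, vegetated soil, plant and litter richness, home-field
#' decomposition and soil-fauna exclusion), with magnitudes between 4 and
#' 28 percent. Decay-model coefficients are calibrated so that median
#' one-year ambient mass loss is about 40 percent.
#'
#' @param percent_change Optional named replacement for the per-factor
#'   true percent changes.
#' @param tau Between-study SD of the true log response ratio (per factor).
#' @param cv Measurement coefficient of variation of replicate mass loss.
#' @param p_missing_sd Probability that a dispersion value is unreported.
#' @param p_ambiguous Probability that a reported dispersion value is an
#'   SE mislabelled as ambiguous.
#' @param sigma_site SD of the site random effect on `ln k`.
#' @return A list of class `truth_record`.
#' @export
default_truth <- function(percent_change = NULL, tau = 0.08, cv = 0.10,
                          p_missing_sd = 0.20, p_ambiguous = 0.10,
                          sigma_site = 0.30) {
  pct <- c(n_addition = 4.49, p_addition = 16.26, warming = 9.80,
           increased_precip = 5.95, reduced_precip = -15.60,
           elevated_co2 = 14.03, grazing = 7.51, vegetated_soil = -27.84,
           plant_richness = -4.99, litter_richness = -5.93,
           home_field = -4.34, fauna_exclusion = -10.40)
  if (!is.null(percent_change)) pct[names(percent_change)] <- percent_change
  stopifnot(all(names(pct) %in% factor_levels()),
            tau >= 0, cv >= 0, sigma_site >= 0,
            p_missing_sd >= 0, p_missing_sd <= 1,
            p_ambiguous >= 0, p_ambiguous <= 1)
  structure(list(
    percent_change = pct,
    log_rr = log(1 + pct / 100),
    tau = stats::setNames(rep(tau, length(pct)), names(pct)),
    beta0 = 0.12, beta_n = 0.6, beta_aur = 0.8,
    beta_mat = 0.15, beta_map = 0.2,
    sigma_site = sigma_site, cv = cv,
    p_missing_sd = p_missing_sd, p_ambiguous = p_ambiguous),
    class = "truth_record")
}

#' Generate synthetic grassland site profiles
#'
#' Sites are placed in the two temperate latitude bands (25-55 degrees in
#' either hemisphere). Mean annual temperature decreases with absolute
#' latitude (`mat = 28 - 0.6 |lat| + noise`); mean annual precipitation is
#' log-normal with median about 400 mm/yr, the typical grassland range.
#'
#' @param n_sites Number of sites (>= 1).
#' @param seed Integer seed.
#' @return `data.frame`: `site_id`, `latitude`, `longitude`, `elevation`,
#'   `mat`, `map`.
#' @export
generate_sites <- function(n_sites = 69, seed = 1L) {
  stopifnot(n_sites >= 1)
  set.seed(.substream(seed, 1L))
  hemi <- sample(c(-1, 1), n_sites, replace = TRUE)
  lat <- hemi * stats::runif(n_sites, 25, 55)
  data.frame(
    site_id = sprintf("site_%03d", seq_len(n_sites)),
    latitude = lat,
    longitude = stats::runif(n_sites, -180, 180),
    elevation = stats::rlnorm(n_sites, log(800), 0.8),
    mat = 28 - 0.6 * abs(lat) + stats::rnorm(n_sites, 0, 2),
    map = stats::rlnorm(n_sites, log(400), 0.5),
    stringsAsFactors = FALSE)
}

#' Generate synthetic initial litter chemistry
#'
#' N concentration is log-normal (median about 0.8 percent of dry mass,
#' clipped to 0.3-2.5); AUR is normal (mean 25, SD 7) truncated above 5
#' percent; C is about 42 +/- 3 percent; P is log-normal (median about
#' 0.09 percent). The ratio columns are computed from the components, not
#' drawn.
#'
#' @param n_litters Number of litter types (>= 1).
#' @param seed Integer seed.
#' @return `data.frame`: `aur`, `c`, `n_conc`, `p_conc`, `aur_n`, `c_n`.
#' @export
generate_chemistry <- function(n_litters, seed = 1L) {
  stopifnot(n_litters >= 1)
  set.seed(.substream(seed, 2L))
  n_conc <- pmin(pmax(stats::rlnorm(n_litters, log(0.8), 0.45), 0.3), 2.5)
  # truncated normal above 5 via inverse-CDF so draws stay seed-stable
  p_lo <- stats::pnorm(5, 25, 7)
  aur <- stats::qnorm(p_lo + stats::runif(n_litters) * (1 - p_lo), 25, 7)
  cc <- stats::rnorm(n_litters, 42, 3)
  p_conc <- stats::rlnorm(n_litters, log(0.09), 0.4)
  data.frame(aur = aur, c = cc, n_conc = n_conc, p_conc = p_conc,
             aur_n = aur / n_conc, c_n = cc / n_conc,
             stringsAsFactors = FALSE)
}

# Deterministic part of the decay model: expected percent mass loss for a
# site/chemistry/duration combination, given the site random effect.
.expected_mass_loss <- function(truth, site, chem, duration_months, u_site) {
  ln_k <- truth$beta0 +
    truth$beta_n * log(chem$n_conc) -
    truth$beta_aur * (chem$aur / 25) +
    truth$beta_mat * (site$mat / 10) +
    truth$beta_map * (site$map / 1000) +
    u_site
  mass_loss_from_k(exp(ln_k), duration_months)
}

#' Ambient-condition mass loss under the synthetic decay model
#'
#' Draws percent mass loss from the generator's ground-truth decay model:
#' `ln k` is linear in log N concentration (positive), AUR (negative),
#' MAT and MAP (positive), plus a site random effect; mass loss follows
#' the single negative exponential and receives multiplicative
#' measurement noise, clamped to (0.1, 99.9) so the log response ratio
#' stays defined.
#'
#' @param site One-row site profile (needs `mat`, `map`).
#' @param chem One-row chemistry record (needs `n_conc`, `aur`).
#' @param duration_months Duration in months (> 0).
#' @param noise_cv Multiplicative noise CV (0 = deterministic).
#' @param seed Integer seed (used for the site effect and noise draws).
#' @param truth Truth record; see [default_truth()].
#' @param u_site Optional fixed site effect; when `NULL`, drawn from
#'   `Normal(0, sigma_site)`.
#' @return Percent mass loss.
#' @export
control_mass_loss <- function(site, chem, duration_months, noise_cv = 0,
                              seed = 1L, truth = default_truth(),
                              u_site = NULL) {
  stopifnot(all(duration_months > 0))
  set.seed(.substream(seed, 4L))
  n <- max(length(duration_months), nrow(as.data.frame(site)))
  if (is.null(u_site)) u_site <- stats::rnorm(n, 0, truth$sigma_site)
  m <- .expected_mass_loss(truth, site, chem, duration_months, u_site)
  if (noise_cv > 0) m <- m * exp(stats::rnorm(length(m), 0, noise_cv))
  pmin(pmax(m, 0.1), 99.9)
}

#' Generate a full synthetic meta-analysis dataset
#'
#' For each of the twelve factors, `n_studies_per_factor` studies each
#' contribute `obs_per_study` paired observations. A study draws one site,
#' one litter chemistry, and a study-level true effect
#' `delta_s ~ Normal(true lnRR, tau)`; the treatment group's true mean is
#' the control mean times `exp(delta_s)` (clipped at 99.9 percent with a
#' warning when exponentiation would exceed it). Observed group means get
#' sampling error `Normal(0, (cv * mean)^2 / n)` with replicate counts of
#' 3-5, and reported SDs are chi-scaled around `cv * mean`. Dispersion
#' values are then blanked with probability `p_missing_sd` and converted
#' to a mislabelled standard error with probability `p_ambiguous`,
#' emulating ambiguous literature reporting. Additional unpaired
#' control-only rows feed the variance-partitioning stage.
#'
#' Output is byte-stable: identical `(truth, counts, seed)` give an
#' identical table.
#'
#' @param truth Truth record from [default_truth()].
#' @param n_studies_per_factor Studies per factor (>= 1).
#' @param obs_per_study Paired observations per study (>= 1).
#' @param n_sites Size of the site pool.
#' @param n_control_only Extra unpaired ambient-condition rows.
#' @param seed Integer seed.
#' @return Observation `data.frame` in the [read_observations()] schema,
#'   with the truth record in attribute `truth`.
#' @export
generate_meta_dataset <- function(truth = default_truth(),
                                  n_studies_per_factor = 24,
                                  obs_per_study = 4,
                                  n_sites = 69,
                                  n_control_only = 340,
                                  seed = 1L) {
  stopifnot(n_studies_per_factor >= 1, obs_per_study >= 1)
  factors <- names(truth$log_rr)
  sites <- generate_sites(n_sites, seed)
  n_studies_total <- length(factors) * n_studies_per_factor +
    max(1L, ceiling(n_control_only / max(1L, obs_per_study)))
  chem <- generate_chemistry(n_studies_total, seed)

  set.seed(.substream(seed, 3L))
  u_site <- stats::rnorm(n_sites, 0, truth$sigma_site)
  study_site <- sample.int(n_sites, n_studies_total, replace = TRUE)
  delta <- stats::rnorm(length(factors) * n_studies_per_factor) # scaled below

  set.seed(.substream(seed, 4L))
  rows <- list()
  obs_counter <- 0L
  study_counter <- 0L
  clipped <- 0L

  draw_durations <- function(n) {
    round(pmin(pmax(stats::rlnorm(n, log(9), 0.7), 1), 48), 1)
  }
  make_group <- function(true_mean, n_rep) {
    obs_mean <- true_mean + stats::rnorm(1, 0, truth$cv * true_mean / sqrt(n_rep))
    obs_mean <- min(max(obs_mean, 0.1), 99.9)
    sd_rep <- truth$cv * true_mean *
      sqrt(stats::rchisq(1, n_rep - 1) / (n_rep - 1))
    list(mean = obs_mean, sd = sd_rep, n = n_rep)
  }
  disguise <- function(sd, n) {
    u <- stats::runif(1)
    if (u < truth$p_missing_sd) {
      list(value = NA_real_, label = "missing")
    } else if (u < truth$p_missing_sd + truth$p_ambiguous) {
      list(value = sd / sqrt(n), label = "ambiguous")
    } else {
      list(value = sd, label = "sd")
    }
  }

  for (fi in seq_along(factors)) {
    fac <- factors[fi]
    for (s in seq_len(n_studies_per_factor)) {
      study_counter <- study_counter + 1L
      d_idx <- (fi - 1L) * n_studies_per_factor + s
      delta_s <- truth$log_rr[fac] + truth$tau[fac] * delta[d_idx]
      si <- study_site[study_counter]
      site <- sites[si, ]
      ch <- chem[study_counter, ]
      durations <- draw_durations(obs_per_study)
      for (d in durations) {
        obs_counter <- obs_counter + 1L
        n_rep <- sample(3:5, 1)
        m_c <- .expected_mass_loss(truth, site, ch, d, u_site[si])
        m_c <- min(max(m_c, 0.1), 99.9)
        m_t <- m_c * exp(delta_s)
        if (m_t > 99.9) { m_t <- 99.9; clipped <- clipped + 1L }
        g_c <- make_group(m_c, n_rep)
        g_t <- make_group(m_t, n_rep)
        dis_c <- disguise(g_c$sd, g_c$n)
        dis_t <- disguise(g_t$sd, g_t$n)
        rows[[obs_counter]] <- data.frame(
          obs_id = sprintf("obs_%05d", obs_counter),
          study_id = sprintf("study_%04d", study_counter),
          site_id = site$site_id, factor = fac, duration_months = d,
          mean_t = g_t$mean, disp_t = dis_t$value,
          disp_label_t = dis_t$label, n_t = g_t$n,
          mean_c = g_c$mean, disp_c = dis_c$value,
          disp_label_c = dis_c$label, n_c = g_c$n,
          k_t = NA_real_, k_c = NA_real_,
          non_replacement = TRUE, root_substrate = TRUE,
          latitude = site$latitude, longitude = site$longitude,
          elevation = site$elevation, mat = site$mat, map = site$map,
          aur = ch$aur, c = ch$c, n_conc = ch$n_conc, p_conc = ch$p_conc,
          aur_n = ch$aur_n, c_n = ch$c_n,
          mesh_mm = sample(c(0.1, 1, 2), 1), depth_cm = 10,
          diameter_mm = round(stats::runif(1, 0.5, 2), 2),
          stringsAsFactors = FALSE)
      }
    }
  }

  # unpaired ambient rows for the variance-partitioning stage
  co <- 0L
  while (co < n_control_only) {
    study_counter <- study_counter + 1L
    si <- study_site[min(study_counter, length(study_site))]
    site <- sites[si, ]
    ch <- chem[min(study_counter, nrow(chem)), ]
    durations <- draw_durations(min(obs_per_study, n_control_only - co))
    for (d in durations) {
      co <- co + 1L; obs_counter <- obs_counter + 1L
      n_rep <- sample(3:5, 1)
      m_c <- .expected_mass_loss(truth, site, ch, d, u_site[si])
      m_c <- min(max(m_c * exp(stats::rnorm(1, 0, truth$cv)), 0.1), 99.9)
      sd_c <- truth$cv * m_c
      dis_c <- disguise(sd_c, n_rep)
      rows[[obs_counter]] <- data.frame(
        obs_id = sprintf("obs_%05d", obs_counter),
        study_id = sprintf("study_%04d", study_counter),
        site_id = site$site_id, factor = "control_only", duration_months = d,
        mean_t = NA_real_, disp_t = NA_real_,
        disp_label_t = "missing", n_t = NA_real_,
        mean_c = m_c, disp_c = dis_c$value,
        disp_label_c = dis_c$label, n_c = n_rep,
        k_t = NA_real_, k_c = NA_real_,
        non_replacement = TRUE, root_substrate = TRUE,
        latitude = site$latitude, longitude = site$longitude,
        elevation = site$elevation, mat = site$mat, map = site$map,
        aur = ch$aur, c = ch$c, n_conc = ch$n_conc, p_conc = ch$p_conc,
        aur_n = ch$aur_n, c_n = ch$c_n,
        mesh_mm = sample(c(0.1, 1, 2), 1), depth_cm = 10,
        diameter_mm = round(stats::runif(1, 0.5, 2), 2),
        stringsAsFactors = FALSE)
    }
  }

  if (clipped > 0)
    warning(clipped, " treatment mean(s) clipped at 99.9%")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}

#' Write an observation table to CSV
#'
#' UTF-8, comma-separated, `.` decimal, empty cell = missing; byte-stable
#' for a fixed table.
#'
#' @param obs Observation `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a truth record from YAML
#'
#' @param path YAML file with any subset of the [default_truth()] fields.
#' @return A `truth_record`.
#' @export
read_truth <- function(path) {
  y <- yaml::read_yaml(path)
  tr <- default_truth(
    percent_change = if (!is.null(y$percent_change)) unlist(y$percent_change),
    tau = y$tau %||% 0.08, cv = y$cv %||% 0.10,
    p_missing_sd = y$p_missing_sd %||% 0.20,
    p_ambiguous = y$p_ambiguous %||% 0.10,
    sigma_site = y$sigma_site %||% 0.30)
  for (f in c("beta0", "beta_n", "beta_aur", "beta_mat", "beta_map"))
    if (!is.null(y[[f]])) tr[[f]] <- y[[f]]
  tr
}
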