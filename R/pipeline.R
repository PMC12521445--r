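# End-to-end orchestration: ingest -> effect sizes -> per-factor pooling
# -> subgroups -> meta-regression -> publication bias -> variance
# partitioning, with a consolidated JSON report and a run manifest.

#' Build and validate a pipeline configuration
#'
#' @param input Path to an observation CSV (or `NULL` when a table is
#'   passed to [run_pipeline()] directly).
#' @param alpha Significance level, in (0, 0.5).
#' @param bootstrap_iterations Bootstrap iterations (>= 999; 64,999 for
#'   production runs).
#' @param seed Integer seed for every stochastic stage.
#' @param duration_edges Duration bin edges in months.
#' @param n_trees Trees per random forest.
#' @param n_perm Response permutations for importance significance.
#' @param moderators Moderator columns for the per-factor meta-regressions.
#' @param out_dir Output directory for the stage CSVs and reports.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, alpha = 0.05,
                            bootstrap_iterations = 64999, seed = 1L,
                            duration_edges = default_duration_edges(),
                            n_trees = 500, n_perm = 100,
                            moderators = c("duration_months", "aur", "aur_n",
                                           "n_conc", "mat", "map"),
                            out_dir = tempfile("rootmeta_run_")) {
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)")
  if (bootstrap_iterations < 999) stop("bootstrap_iterations must be >= 999")
  if (any(diff(duration_edges) <= 0)) stop("duration_edges must be increasing")
  structure(list(input = input, alpha = alpha,
                 bootstrap_iterations = as.integer(bootstrap_iterations),
                 seed = as.integer(seed),
                 duration_edges = duration_edges,
                 n_trees = as.integer(n_trees), n_perm = as.integer(n_perm),
                 moderators = moderators, out_dir = out_dir),
            class = "pipeline_config")
}

.stage_log <- function(stage, n_in, n_out, t0) {
  message(sprintf("[%s] in=%d out=%d elapsed=%.2fs", stage, n_in, n_out,
                  as.numeric(proc.time()["elapsed"]) - t0))
}

#' Run the full analysis pipeline
#'
#' Executes every stage on an observation table (read from
#' `config$input`, or passed directly): harmonization, effect sizes,
#' heterogeneity-gated pooling with bias-corrected bootstrap intervals per
#' factor, duration subgroup analysis, per-factor meta-regressions on the
#' configured moderators, fail-safe publication-bias checks, and the
#' variance-partitioning stage (random-forest explained variance and
#' importances for the geoclimate-only, quality-only and combined
#' predictor sets on all data and the two temporal halves, PC1-composite
#' hierarchical partitioning, trait correlations). All stage outputs are
#' written as CSV under `config$out_dir`, along with `ingest_report.json`,
#' a consolidated `report.json` and a `manifest.json` (seed, config hash,
#' row counts). Reruns with an identical configuration and seed produce a
#' byte-identical `report.json`.
#'
#' @param config A [pipeline_config()].
#' @param observations Optional observation table overriding `config$input`.
#' @return Invisibly, a list with all stage results (`harmonized`,
#'   `effects`, `pooled`, `subgroups`, `meta_regression`,
#'   `publication_bias`, `variance_partitioning`, `report`).
#' @export
run_pipeline <- function(config, observations = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(proc.time()["elapsed"])

  # -- ingest ---------------------------------------------------------
  obs <- observations %||% read_observations(config$input)
  harm <- harmonize(obs)
  report_ingest <- attr(harm, "report")
  utils::write.csv(harm, file.path(config$out_dir, "harmonized.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(report_ingest,
                       file.path(config$out_dir, "ingest_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  .stage_log("ingest", nrow(obs), nrow(harm), t0)

  # -- effect sizes ---------------------------------------------------
  eff <- compute_effect_sizes(harm)
  utils::write.csv(eff, file.path(config$out_dir, "effects.csv"),
                   row.names = FALSE, na = "")
  .stage_log("effects", nrow(harm), nrow(eff), t0)

  # -- per-factor pooling ---------------------------------------------
  factors <- intersect(factor_levels(), unique(eff$factor))
  pooled <- lapply(factors, function(fac) {
    sub <- eff[eff$factor == fac, , drop = FALSE]
    pool_effects(sub, alpha = config$alpha, b = config$bootstrap_iterations,
                 seed = config$seed, factor = fac)
  })
  names(pooled) <- factors
  pooled_df <- do.call(rbind, lapply(pooled, summary))
  utils::write.csv(pooled_df, file.path(config$out_dir, "pooled_effects.csv"),
                   row.names = FALSE, na = "")
  forest_df <- pooled_df[, c("factor", "rr_pp", "ci_low", "ci_high",
                             "k_obs", "significant")]
  utils::write.csv(forest_df,
                   file.path(config$out_dir, "forest_plot_data.csv"),
                   row.names = FALSE, na = "")
  .stage_log("pool", nrow(eff), nrow(pooled_df), t0)

  # -- subgroups ------------------------------------------------------
  sub_rows <- list()
  for (fac in factors) {
    sg <- subgroup_analysis(eff[eff$factor == fac, , drop = FALSE],
                            edges = config$duration_edges,
                            alpha = config$alpha,
                            b = config$bootstrap_iterations,
                            seed = config$seed)
    df <- sg$subgroups
    df <- cbind(factor = fac, df)
    df$p_between <- if (!is.null(sg$q_partition)) sg$q_partition$p_between
                    else NA_real_
    sub_rows[[fac]] <- df
  }
  subgroups_df <- do.call(rbind, sub_rows)
  rownames(subgroups_df) <- NULL
  utils::write.csv(subgroups_df, file.path(config$out_dir, "subgroups.csv"),
                   row.names = FALSE, na = "")
  .stage_log("subgroups", nrow(eff), nrow(subgroups_df), t0)

  # -- meta-regression ------------------------------------------------
  mr_rows <- list()
  for (fac in factors) {
    sub <- eff[eff$factor == fac, , drop = FALSE]
    for (mod in config$moderators) {
      res <- tryCatch(meta_regress(sub, mod, alpha = config$alpha),
                      error = function(e) NULL)
      if (is.null(res)) next
      mr_rows[[paste(fac, mod)]] <- data.frame(
        factor = fac, moderator_name = mod, k = res$k,
        slope = res$slope, intercept = res$intercept,
        slope_se = res$slope_se, tau2 = res$tau2,
        qm = res$qm, p_value = res$p_value,
        significant = res$significant, stringsAsFactors = FALSE)
    }
  }
  metareg_df <- do.call(rbind, mr_rows)
  rownames(metareg_df) <- NULL
  utils::write.csv(metareg_df,
                   file.path(config$out_dir, "meta_regression.csv"),
                   row.names = FALSE, na = "")
  .stage_log("metareg", nrow(eff), NROW(metareg_df), t0)

  # -- publication bias -----------------------------------------------
  bias_df <- do.call(rbind, lapply(factors, function(fac) {
    fail_safe(eff[eff$factor == fac, , drop = FALSE], factor = fac)
  }))
  utils::write.csv(bias_df,
                   file.path(config$out_dir, "publication_bias.csv"),
                   row.names = FALSE, na = "")
  .stage_log("bias", nrow(eff), nrow(bias_df), t0)

  # -- variance partitioning ------------------------------------------
  vp <- list()
  imp_rows <- list()
  for (tf in c("all", "le12", "gt12")) {
    for (cs in c("geoclimate", "quality", "both")) {
      m <- tryCatch(build_matrix(harm, column_set = cs, time_filter = tf),
                    error = function(e) NULL)
      if (is.null(m) || nrow(m) < 30) next
      key <- paste(cs, tf, sep = "_")
      r2 <- rf_variance_explained(m, n_trees = config$n_trees,
                                  seed = config$seed)
      vp[[key]] <- list(r2 = r2, n = nrow(m))
      if (cs == "both") {
        imp <- rf_permutation_importance(m, n_trees = config$n_trees,
                                         n_perm = config$n_perm,
                                         seed = config$seed,
                                         alpha = config$alpha)
        gm <- group_mean_contribution(imp, predictor_groups(),
                                      scale_to_r2 = r2)
        vp[[key]]$group_mean <- as.list(gm)
        imp_rows[[tf]] <- cbind(time_filter = tf, imp)
      }
    }
  }
  imp_df <- do.call(rbind, imp_rows)
  rownames(imp_df) <- NULL
  utils::write.csv(imp_df, file.path(config$out_dir, "rf_importance.csv"),
                   row.names = FALSE, na = "")

  m_both <- build_matrix(harm, column_set = "both", time_filter = "all")
  groups <- predictor_groups()
  comps <- data.frame(
    quality = pc1_composite(m_both, groups$quality, anchor = "n_conc"),
    geoclimate = pc1_composite(m_both, groups$geoclimate, anchor = "mat"))
  hp <- hierarchical_partition(m_both$mass_loss, comps)
  utils::write.csv(hp, file.path(config$out_dir, "hp_partition.csv"),
                   row.names = FALSE, na = "")

  traits <- c("aur", "aur_n", "n_conc")
  tc <- do.call(rbind, lapply(traits, function(tr) {
    r <- tryCatch(trait_correlation(harm, tr), error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(trait = tr, r = r$r, p_value = r$p_value, n = r$n,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(tc, file.path(config$out_dir, "trait_correlations.csv"),
                   row.names = FALSE, na = "")
  .stage_log("partition", nrow(harm), length(vp), t0)

  # -- consolidated report + manifest ---------------------------------
  report <- list(
    pooled = lapply(pooled, function(p) {
      list(factor = p$factor, k_obs = p$k_obs, model = p$model,
           rr_pp = p$rr_pp, tau2 = p$tau2,
           ci_low = p$ci_low, ci_high = p$ci_high,
           percent_change = p$percent_change, significant = p$significant)
    }),
    fail_safe = lapply(seq_len(nrow(bias_df)), function(i) as.list(bias_df[i, ])),
    variance_partitioning = vp,
    hierarchical_partition = lapply(seq_len(nrow(hp)),
                                    function(i) as.list(hp[i, ])),
    trait_correlations = if (!is.null(tc))
      lapply(seq_len(nrow(tc)), function(i) as.list(tc[i, ])))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  cfg_plain <- unclass(config); cfg_plain$out_dir <- NULL
  manifest <- list(
    seed = config$seed,
    config = cfg_plain,
    config_hash = sum(utf8ToInt(paste(
      names(cfg_plain), vapply(cfg_plain, function(x)
        paste(format(x), collapse = ","), character(1)),
      collapse = ";"))),
    rows = list(observations_in = nrow(obs),
                harmonized = nrow(harm),
                effects = nrow(eff),
                excluded = as.list(attr(eff, "excluded")),
                dropped = report_ingest[grep("^dropped", names(report_ingest))]))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(harmonized = harm, effects = eff, pooled = pooled,
                 subgroups = subgroups_df, meta_regression = metareg_df,
                 publication_bias = bias_df,
                 variance_partitioning = list(explained = vp,
                                              importance = imp_df,
                                              hierarchical = hp,
                                              traits = tc),
                 report = report, out_dir = config$out_dir))
}
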