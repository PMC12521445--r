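# Per-observation effect sizes: log response ratio, variance, weight.

#' Log response ratio
#'
#' Natural logarithm of the treatment-to-control mean ratio,
#' \eqn{\ln(X_t/X_c)}; the meta-analytic effect size. Antisymmetric under
#' swapping the two groups.
#'
#' @param x_t Treatment group mean mass loss (> 0).
#' @param x_c Control group mean mass loss (> 0).
#' @return The log response ratio.
#' @export
log_response_ratio <- function(x_t, x_c) {
  if (any(x_t <= 0, na.rm = TRUE))
    stop("treatment mean must be positive (zero mass loss cannot form a ratio)")
  if (any(x_c <= 0, na.rm = TRUE))
    stop("control mean must be positive (zero mass loss cannot form a ratio)")
  log(x_t / x_c)
}

#' Sampling variance of a log response ratio
#'
#' \eqn{v = S_t^2/(n_t X_t^2) + S_c^2/(n_c X_c^2)}, the delta-method
#' variance of the log ratio of two group means. Scale-free: rescaling
#' mass loss (percent vs fraction) leaves it unchanged.
#'
#' @param x_t,sd_t,n_t Treatment mean, standard deviation, replicate count.
#' @param x_c,sd_c,n_c Control mean, standard deviation, replicate count.
#' @return Nonnegative variance (0 only when both SDs are 0).
#' @export
effect_variance <- function(x_t, sd_t, n_t, x_c, sd_c, n_c) {
  if (any(x_t == 0 | x_c == 0, na.rm = TRUE))
    stop("zero group mean: variance undefined")
  sd_t^2 / (n_t * x_t^2) + sd_c^2 / (n_c * x_c^2)
}

#' Inverse-variance weight
#'
#' @param v Positive sampling variance.
#' @return `1 / v`.
#' @export
effect_weight <- function(v) {
  if (any(v <= 0, na.rm = TRUE)) stop("variance must be positive to weight")
  1 / v
}

#' Percent change implied by a pooled log response ratio
#'
#' Back-transforms a pooled effect to the original mass-loss scale:
#' \eqn{(e^{RR_{++}} - 1) \times 100}.
#'
#' @param rr_pp Pooled log response ratio.
#' @return Percent change in mass loss.
#' @examples
#' percent_change(log(2))  # 100
#' @export
percent_change <- function(rr_pp) {
  (exp(rr_pp) - 1) * 100
}

# Variance floor for observations where both resolved SDs are zero; the
# mean/10 imputation makes genuine zero dispersion an artifact, so such
# rows get a tiny positive variance instead of infinite weight.
.v_floor <- 1e-8

#' Compute per-observation effect sizes from a harmonized table
#'
#' Computes the log response ratio, its sampling variance and the
#' inverse-variance weight for every paired observation. Control-only
#' rows and rows with a nonpositive group mean (the log ratio is
#' undefined there) are excluded and counted in the `excluded` attribute.
#' Observations where both resolved SDs are zero receive a variance
#' floored at `1e-8`, with a warning.
#'
#' @param harmonized Output of [harmonize()].
#' @return A `data.frame` with columns `obs_id`, `study_id`, `site_id`,
#'   `factor`, `duration_months`, `log_rr`, `v`, `w` and all moderator
#'   columns, with attribute `excluded` (a named count vector).
#' @export
compute_effect_sizes <- function(harmonized) {
  obs <- harmonized
  excluded <- c(control_only = sum(obs$factor == "control_only"))
  obs <- obs[obs$factor != "control_only", , drop = FALSE]
  bad_mean <- is.na(obs$mean_t) | is.na(obs$mean_c) |
    obs$mean_t <= 0 | obs$mean_c <= 0
  excluded["nonpositive_mean"] <- sum(bad_mean)
  obs <- obs[!bad_mean, , drop = FALSE]

  log_rr <- log(obs$mean_t / obs$mean_c)
  v <- obs$sd_t^2 / (obs$n_t * obs$mean_t^2) +
       obs$sd_c^2 / (obs$n_c * obs$mean_c^2)
  floored <- !is.na(v) & v < .v_floor
  if (any(floored)) {
    warning(sum(floored), " observation(s) with zero sampling variance; ",
            "variance floored at ", .v_floor)
    v[floored] <- .v_floor
  }
  keep_cols <- intersect(c("latitude", "longitude", "elevation", "mat", "map",
                           "aur", "c", "n_conc", "p_conc", "aur_n", "c_n",
                           "mesh_mm", "depth_cm", "diameter_mm"), names(obs))
  out <- data.frame(obs_id = obs$obs_id, study_id = obs$study_id,
                    site_id = obs$site_id, factor = obs$factor,
                    duration_months = obs$duration_months,
                    log_rr = log_rr, v = v, w = 1 / v,
                    stringsAsFactors = FALSE)
  out <- cbind(out, obs[, keep_cols, drop = FALSE])
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
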