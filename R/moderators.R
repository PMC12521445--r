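# Duration-grouped subgroup meta-analysis and single-moderator
# meta-regression.

#' Default duration bin edges (months)
#'
#' Reconstructed from the decomposition stages at which effects are
#' typically reported to shift (4, 6, 12, 18 and 24 months); always
#' configurable.
#'
#' @return Numeric vector of bin edges.
#' @export
default_duration_edges <- function() c(4, 6, 12, 18, 24)

#' Bin effect sizes by decomposition duration
#'
#' Half-open bins `[e_i, e_{i+1})`; durations below the first edge fall
#' into `"<e_1"`, the last bin `">=e_last"` is open-ended. Every value is
#' assigned to exactly one bin.
#'
#' @param duration_months Numeric vector of durations.
#' @param edges Strictly increasing bin edges in months.
#' @return Factor of bin labels, ordered by time.
#' @export
bin_by_duration <- function(duration_months, edges = default_duration_edges()) {
  if (length(edges) == 0) stop("edges must be non-empty")
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  labels <- c(paste0("<", edges[1]),
              if (length(edges) > 1)
                paste0("[", edges[-length(edges)], ",", edges[-1], ")"),
              paste0(">=", edges[length(edges)]))
  idx <- findInterval(duration_months, edges) + 1L
  factor(labels[idx], levels = labels)
}

#' Duration-grouped subgroup meta-analysis
#'
#' Bins effects by duration, pools each bin that satisfies the subgroup
#' inclusion rule (data from at least 3 independent studies, or a minimum
#' of 10 observations), and partitions the fixed-effects heterogeneity
#' statistic over the included groups:
#' \eqn{Q_{total} = Q_{between} + \sum_g Q_{within,g}} under common
#' fixed-effects weights, with \eqn{Q_{between}} tested on a chi-square
#' with `G - 1` degrees of freedom.
#'
#' @param effects Effects `data.frame` (`log_rr`, `v`, `study_id`,
#'   `duration_months`).
#' @param edges Duration bin edges (months).
#' @param alpha Significance level.
#' @param b Bootstrap iterations per included subgroup.
#' @param seed Integer seed.
#' @return A list with `subgroups` (one `data.frame` row per bin:
#'   `group_label`, `n_studies`, `n_obs`, `included`, and for included
#'   bins the pooled columns) and `q_partition`.
#' @export
subgroup_analysis <- function(effects, edges = default_duration_edges(),
                              alpha = 0.05, b = 64999, seed = 1L) {
  bins <- bin_by_duration(effects$duration_months, edges)
  rows <- list(); pooled_effects <- list()
  for (lab in levels(bins)) {
    sub <- effects[bins == lab, , drop = FALSE]
    n_obs <- nrow(sub)
    n_studies <- length(unique(sub$study_id))
    included <- n_studies >= 3 || n_obs >= 10
    row <- data.frame(group_label = lab, n_studies = n_studies,
                      n_obs = n_obs, included = included,
                      model = NA_character_, rr_pp = NA_real_,
                      tau2 = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      percent_change = NA_real_, significant = NA,
                      stringsAsFactors = FALSE)
    if (included && n_obs >= 2) {
      fit <- pool_effects(sub, alpha = alpha, b = b, seed = seed)
      row$model <- fit$model; row$rr_pp <- fit$rr_pp; row$tau2 <- fit$tau2
      row$ci_low <- fit$ci_low; row$ci_high <- fit$ci_high
      row$percent_change <- fit$percent_change
      row$significant <- fit$significant
      pooled_effects[[lab]] <- fit
    }
    rows[[lab]] <- row
  }
  subgroups <- do.call(rbind, rows)
  rownames(subgroups) <- NULL

  inc <- bins %in% subgroups$group_label[subgroups$included]
  qp <- if (!any(inc)) {
    warning("no subgroup satisfies the inclusion rule")
    NULL
  } else {
    q_partition(effects$log_rr[inc], effects$v[inc], bins[inc, drop = TRUE])
  }
  list(subgroups = subgroups, q_partition = qp, fits = pooled_effects)
}

#' Partition the heterogeneity statistic between and within groups
#'
#' Fixed-effects decomposition: with weights `1/v`, group means and the
#' grand weighted mean, \eqn{Q_{total} = Q_{between} + \sum Q_{within}}
#' exactly (an algebraic identity).
#'
#' @param log_rr,v Effect sizes and variances.
#' @param groups Grouping factor.
#' @return A list with `q_total`, `q_between`, `q_within_sum`,
#'   `df_between`, `df_within`, `p_between`.
#' @export
q_partition <- function(log_rr, v, groups) {
  groups <- droplevels(as.factor(groups))
  w <- 1 / v
  grand <- sum(w * log_rr) / sum(w)
  q_total <- sum(w * (log_rr - grand)^2)
  mu_g <- tapply(w * log_rr, groups, sum) / tapply(w, groups, sum)
  q_within <- sum(w * (log_rr - mu_g[groups])^2)
  w_g <- tapply(w, groups, sum)
  q_between <- sum(w_g * (mu_g - grand)^2)
  df_between <- nlevels(groups) - 1L
  df_within <- length(log_rr) - nlevels(groups)
  list(q_total = q_total, q_between = q_between, q_within_sum = q_within,
       df_between = df_between, df_within = df_within,
       p_between = stats::pchisq(q_between, df_between, lower.tail = FALSE))
}

#' Single-moderator meta-regression
#'
#' Weighted least squares of the log response ratio on one continuous
#' moderator with random-effects weights \eqn{1/(v_i + \tau^2)}.
#' \eqn{\tau^2} comes from the method of moments applied to the residual
#' heterogeneity of the fixed-effects regression:
#' \eqn{\tau^2 = \max(0, (Q_E - (k - 2)) / \mathrm{tr}(P)} with
#' \eqn{P = W - WX(X'WX)^{-1}X'W} (the moderator-adjusted analogue of
#' DerSimonian-Laird). The moderator test is
#' \eqn{Q_M = (\beta/se_\beta)^2} on a chi-square with 1 df.
#'
#' @param effects Effects `data.frame` containing `log_rr`, `v` and the
#'   moderator column.
#' @param moderator_name Name of the moderator column.
#' @param alpha Significance level.
#' @return A `meta_regression` object (list with `moderator_name`,
#'   `slope`, `intercept`, `slope_se`, `tau2`, `qm`, `p_value`,
#'   `significant`, `k`).
#' @export
meta_regress <- function(effects, moderator_name, alpha = 0.05) {
  if (!moderator_name %in% names(effects))
    stop("moderator column not found: ", moderator_name)
  m <- effects[[moderator_name]]
  keep <- !is.na(m) & !is.na(effects$log_rr) & !is.na(effects$v)
  if (sum(keep) < 4) stop("at least 4 effects with a nonmissing moderator required")
  x <- m[keep]; y <- effects$log_rr[keep]; v <- effects$v[keep]
  if (length(unique(x)) < 2) stop("moderator is constant")

  X <- cbind(1, x)
  k <- length(y); p <- 2L
  W <- diag(1 / v)
  XtWX_inv <- solve(t(X) %*% W %*% X)
  beta_f <- XtWX_inv %*% t(X) %*% W %*% y
  resid <- y - X %*% beta_f
  qe <- sum((resid^2) / v)
  P <- W - W %*% X %*% XtWX_inv %*% t(X) %*% W
  trP <- sum(diag(P))
  tau2 <- max(0, (qe - (k - p)) / trP)

  ws <- 1 / (v + tau2)
  Ws <- diag(ws)
  cov_b <- solve(t(X) %*% Ws %*% X)
  beta <- cov_b %*% t(X) %*% Ws %*% y
  slope <- beta[2]; slope_se <- sqrt(cov_b[2, 2])
  qm <- (slope / slope_se)^2
  p_value <- stats::pchisq(qm, 1, lower.tail = FALSE)
  out <- list(moderator_name = moderator_name, k = k,
              slope = slope, intercept = beta[1], slope_se = slope_se,
              tau2 = tau2, qm = qm, p_value = p_value,
              significant = p_value < alpha, alpha = alpha)
  class(out) <- "meta_regression"
  out
}

#' @export
print.meta_regression <- function(x, ...) {
  cat(sprintf("Meta-regression of lnRR on %s (k = %d)\n", x$moderator_name, x$k))
  cat(sprintf("  slope = %.5f (SE %.5f), intercept = %.5f, tau2 = %.5f\n",
              x$slope, x$slope_se, x$intercept, x$tau2))
  cat(sprintf("  QM = %.3f on 1 df, p = %.4g%s\n", x$qm, x$p_value,
              if (x$significant) "  *" else ""))
  invisible(x)
}

#' @export
coef.meta_regression <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}
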