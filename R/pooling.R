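# Per-factor pooling: fixed-effects estimate, heterogeneity test,
# DerSimonian-Laird tau2, mixed-effects re-estimate, bias-corrected
# bootstrap CI, Gaussian fit of the effect distribution.

.effects_xy <- function(effects) {
  if (is.data.frame(effects)) {
    stopifnot(all(c("log_rr", "v") %in% names(effects)))
    list(x = effects$log_rr, v = effects$v)
  } else if (is.list(effects) && !is.null(effects$log_rr)) {
    list(x = effects$log_rr, v = effects$v)
  } else {
    stop("`effects` must be a data.frame with columns log_rr and v")
  }
}

#' Fixed-effects pooled estimate
#'
#' Inverse-variance weighted mean of the log response ratios:
#' \eqn{RR_{++} = \sum w_i \ln RR_i / \sum w_i}, with variance
#' \eqn{1/\sum w_i}.
#'
#' @param effects A `data.frame` with columns `log_rr` and `v` (from
#'   [compute_effect_sizes()]).
#' @return A list with `rr_pp` (pooled estimate) and `var` (variance of
#'   the pooled mean).
#' @export
pool_fixed <- function(effects) {
  e <- .effects_xy(effects)
  if (length(e$x) < 2) stop("at least 2 effect sizes required")
  if (any(e$v <= 0)) stop("all variances must be positive")
  w <- 1 / e$v
  sw <- sum(w)
  list(rr_pp = sum(w * e$x) / sw, var = 1 / sw)
}

#' Heterogeneity Q test
#'
#' \eqn{Q = \sum w_i (\ln RR_i - RR_{++})^2} against a chi-square with
#' `k - 1` degrees of freedom. Significance at `alpha` decides whether the
#' mixed-effects model replaces the fixed-effects fit.
#'
#' @param effects Effects `data.frame` (`log_rr`, `v`).
#' @param rr_pp Fixed-effects pooled estimate.
#' @param alpha Significance level (default 0.05).
#' @return A list with `q_total`, `df`, `p_value`, `significant`.
#' @export
q_test <- function(effects, rr_pp, alpha = 0.05) {
  e <- .effects_xy(effects)
  w <- 1 / e$v
  q <- sum(w * (e$x - rr_pp)^2)
  df <- length(e$x) - 1L
  p <- stats::pchisq(q, df, lower.tail = FALSE)
  list(q_total = q, df = df, p_value = p, significant = p < alpha)
}

#' DerSimonian-Laird between-study variance
#'
#' Method-of-moments estimator
#' \eqn{\tau^2 = \max(0, (Q - df) / (\sum w - \sum w^2 / \sum w))}
#' from the fixed-effects heterogeneity statistic.
#'
#' @param q Heterogeneity Q statistic.
#' @param weights Fixed-effects weights `1/v`.
#' @return Nonnegative tau-squared.
#' @export
tau2_dl <- function(q, weights) {
  stopifnot(all(weights > 0))
  df <- length(weights) - 1L
  cc <- sum(weights) - sum(weights^2) / sum(weights)
  if (cc <= 0) {
    warning("degenerate weight distribution; tau2 set to 0")
    return(0)
  }
  max(0, (q - df) / cc)
}

#' Mixed-effects pooled estimate
#'
#' Re-pools with random-effects weights \eqn{w^*_i = 1/(v_i + \tau^2)};
#' reduces to [pool_fixed()] at `tau2 = 0`.
#'
#' @param effects Effects `data.frame` (`log_rr`, `v`).
#' @param tau2 Between-study variance (>= 0).
#' @return A list with `rr_pp` and `var`.
#' @export
pool_mixed <- function(effects, tau2) {
  stopifnot(tau2 >= 0)
  e <- .effects_xy(effects)
  if (length(e$x) < 2) stop("at least 2 effect sizes required")
  w <- 1 / (e$v + tau2)
  sw <- sum(w)
  list(rr_pp = sum(w * e$x) / sw, var = 1 / sw)
}

# Core model-selection pooling on bare vectors; shared by the scalar path
# and the vectorised bootstrap (columns of a resample matrix).
.pool_select <- function(x, v, alpha) {
  w <- 1 / v
  sw <- sum(w)
  mu_f <- sum(w * x) / sw
  q <- sum(w * (x - mu_f)^2)
  df <- length(x) - 1L
  p <- stats::pchisq(q, df, lower.tail = FALSE)
  if (p < alpha) {
    cc <- sum(w) - sum(w^2) / sw
    tau2 <- if (cc > 0) max(0, (q - df) / cc) else 0
    ws <- 1 / (v + tau2)
    list(model = "mixed", rr_pp = sum(ws * x) / sum(ws), var = 1 / sum(ws),
         tau2 = tau2, q = q, df = df, p = p)
  } else {
    list(model = "fixed", rr_pp = mu_f, var = 1 / sw,
         tau2 = 0, q = q, df = df, p = p)
  }
}

# Vectorised variant: X, V are k x B matrices (one resample per column).
# Returns the per-column point estimate after full model re-selection.
.pool_select_mat <- function(X, V, alpha) {
  W <- 1 / V
  sw <- colSums(W)
  mu_f <- colSums(W * X) / sw
  Q <- colSums(W * (X - rep(mu_f, each = nrow(X)))^2)
  df <- nrow(X) - 1L
  p <- stats::pchisq(Q, df, lower.tail = FALSE)
  cc <- sw - colSums(W^2) / sw
  tau2 <- ifelse(p < alpha & cc > 0, pmax(0, (Q - df) / cc), 0)
  Ws <- 1 / (V + rep(tau2, each = nrow(V)))
  colSums(Ws * X) / colSums(Ws)
}

#' Heterogeneity-gated pooled effect
#'
#' A fixed-effects model is fitted first; if the total-heterogeneity Q
#' test is significant at `alpha`, a mixed-effects (random-effects) model
#' with DerSimonian-Laird \eqn{\tau^2} re-estimates the pooled effect.
#'
#' @param effects Effects `data.frame` (`log_rr`, `v`).
#' @param alpha Significance level for the heterogeneity gate.
#' @return A list with `model` (`"fixed"` or `"mixed"`), `rr_pp`, `var`,
#'   `tau2` and `heterogeneity` (the [q_test()] result).
#' @export
select_and_pool <- function(effects, alpha = 0.05) {
  e <- .effects_xy(effects)
  if (length(e$x) < 2) stop("at least 2 effect sizes required")
  if (any(e$v <= 0)) stop("all variances must be positive")
  r <- .pool_select(e$x, e$v, alpha)
  list(model = r$model, rr_pp = r$rr_pp, var = r$var, tau2 = r$tau2,
       heterogeneity = list(q_total = r$q, df = r$df, p_value = r$p,
                            significant = r$p < alpha))
}

#' Bias-corrected bootstrap confidence interval for the pooled effect
#'
#' Resamples effects with replacement (observation-level by default, or
#' clustered by study), re-runs the full heterogeneity-gated pooling on
#' every resample, and forms the bias-corrected (BC) percentile interval:
#' with \eqn{z_0 = \Phi^{-1}(\#\{\hat\theta^*_b < \hat\theta\}/B)}, the
#' endpoints are the bootstrap quantiles at
#' \eqn{\Phi(2 z_0 \pm z_{1-\alpha/2})}. A proportion of 0 or 1 is
#' clamped to \eqn{1/(2B)} before the probit.
#'
#' @param effects Effects `data.frame` (`log_rr`, `v`, and `study_id` if
#'   `unit = "study"`).
#' @param b Number of bootstrap iterations (>= 999; 64,999 in production).
#' @param alpha Two-sided confidence level complement.
#' @param seed Integer seed; results are reproducible given the seed.
#' @param unit Resampling unit: `"observation"` (default) or `"study"`
#'   (cluster bootstrap over `study_id`).
#' @return A list with `ci_low`, `ci_high`, `z0` and `estimate`.
#' @export
bootstrap_ci <- function(effects, b = 64999, alpha = 0.05, seed = 1L,
                         unit = c("observation", "study")) {
  unit <- match.arg(unit)
  e <- .effects_xy(effects)
  k <- length(e$x)
  if (k < 2) stop("at least 2 effect sizes required")
  if (b < 999) stop("at least 999 bootstrap iterations required")
  est <- .pool_select(e$x, e$v, alpha)$rr_pp

  set.seed(seed)
  if (unit == "observation") {
    idx <- matrix(sample.int(k, k * b, replace = TRUE), nrow = k)
    boots <- .pool_select_mat(matrix(e$x[idx], nrow = k),
                              matrix(e$v[idx], nrow = k), alpha)
  } else {
    # cluster bootstrap: resample whole studies; resamples vary in length,
    # so each is pooled individually
    sid <- effects$study_id
    if (is.null(sid)) stop("study-level bootstrap requires a study_id column")
    by_study <- split(seq_len(k), sid)
    s <- length(by_study)
    boots <- vapply(seq_len(b), function(j) {
      picked <- unlist(by_study[sample.int(s, s, replace = TRUE)],
                       use.names = FALSE)
      if (length(picked) < 2) return(e$x[picked][1])
      .pool_select(e$x[picked], e$v[picked], alpha)$rr_pp
    }, numeric(1))
  }

  if (length(unique(boots)) == 1L) {
    warning("all bootstrap estimates identical; degenerate interval")
    return(list(ci_low = boots[1], ci_high = boots[1], z0 = 0, estimate = est))
  }
  prop <- mean(boots < est)  # strictly-less-than, classical BC
  prop <- min(max(prop, 1 / (2 * b)), 1 - 1 / (2 * b))
  z0 <- stats::qnorm(prop)
  zc <- stats::qnorm(1 - alpha / 2)
  probs <- stats::pnorm(c(2 * z0 - zc, 2 * z0 + zc))
  ci <- unname(stats::quantile(boots, probs, type = 7))
  list(ci_low = ci[1], ci_high = ci[2], z0 = z0, estimate = est)
}

#' Maximum-likelihood Gaussian fit of the effect distribution
#'
#' Fits a normal distribution to the unweighted log response ratios (for
#' reporting the shape of each factor's effect-size distribution).
#'
#' @param values Numeric vector of log response ratios (k >= 2).
#' @return A list with `mu`, `sigma` (ML estimate, denominator `n`) and `n`.
#' @export
fit_gaussian <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("at least 2 values required")
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  if (sigma == 0) warning("all values identical; sigma = 0")
  list(mu = mu, sigma = sigma, n = n)
}

#' Pool one factor's effect sizes (full fit)
#'
#' The package's central fitting function: runs the heterogeneity-gated
#' pooling ([select_and_pool()]), the bias-corrected bootstrap interval
#' ([bootstrap_ci()]), the percent-change back-transform and the Gaussian
#' fit, returning a classed `pooled_effect` object with `print`,
#' `summary`, `coef` and `confint` methods.
#'
#' @param effects Effects `data.frame` for one factor (`log_rr`, `v`).
#' @param alpha Significance level (heterogeneity gate and CI).
#' @param b Bootstrap iterations.
#' @param seed Integer seed for the bootstrap.
#' @param unit Bootstrap resampling unit; see [bootstrap_ci()].
#' @param factor Optional factor label carried into the result.
#' @return A `pooled_effect` object.
#' @examples
#' eff <- data.frame(log_rr = c(0.0, 0.2, 0.4), v = rep(0.01, 3))
#' fit <- pool_effects(eff, b = 999, seed = 42)
#' coef(fit)
#' confint(fit)
#' @export
pool_effects <- function(effects, alpha = 0.05, b = 64999, seed = 1L,
                         unit = "observation", factor = NULL) {
  sel <- select_and_pool(effects, alpha)
  ci <- bootstrap_ci(effects, b = b, alpha = alpha, seed = seed, unit = unit)
  e <- .effects_xy(effects)
  out <- list(factor = factor %||% NA_character_,
              k_obs = length(e$x),
              model = sel$model,
              rr_pp = sel$rr_pp,
              se_param = sqrt(sel$var),
              tau2 = sel$tau2,
              ci_low = ci$ci_low, ci_high = ci$ci_high, z0 = ci$z0,
              percent_change = percent_change(sel$rr_pp),
              significant = ci$ci_low > 0 || ci$ci_high < 0,
              heterogeneity = sel$heterogeneity,
              gaussian = fit_gaussian(e$x),
              alpha = alpha, b = b, seed = seed, unit = unit)
  class(out) <- "pooled_effect"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pooled_effect <- function(x, ...) {
  cat("Pooled effect",
      if (!is.na(x$factor)) paste0("for factor '", x$factor, "'"), "\n")
  cat(sprintf("  k = %d observations, %s-effects model (Q = %.3f, df = %d, p = %.4g)\n",
              x$k_obs, x$model, x$heterogeneity$q_total,
              x$heterogeneity$df, x$heterogeneity$p_value))
  cat(sprintf("  RR++ = %.4f  [%.4f, %.4f] (BC bootstrap, B = %d)\n",
              x$rr_pp, x$ci_low, x$ci_high, x$b))
  cat(sprintf("  tau2 = %.5f;  percent change = %+.2f%%%s\n",
              x$tau2, x$percent_change,
              if (x$significant) "  *" else " (ns)"))
  invisible(x)
}

#' @export
summary.pooled_effect <- function(object, ...) {
  df <- data.frame(factor = object$factor, k_obs = object$k_obs,
                   model = object$model, rr_pp = object$rr_pp,
                   se_param = object$se_param, tau2 = object$tau2,
                   ci_low = object$ci_low, ci_high = object$ci_high,
                   percent_change = object$percent_change,
                   significant = object$significant,
                   q_total = object$heterogeneity$q_total,
                   q_p = object$heterogeneity$p_value,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' @export
coef.pooled_effect <- function(object, ...) {
  c(rr_pp = object$rr_pp)
}

#' @export
confint.pooled_effect <- function(object, parm, level, ...) {
  m <- matrix(c(object$ci_low, object$ci_high), nrow = 1,
              dimnames = list("rr_pp",
                              sprintf("%.1f %%", 100 * c(object$alpha / 2,
                                                         1 - object$alpha / 2))))
  m
}
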