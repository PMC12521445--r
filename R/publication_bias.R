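# Publication-bias robustness: Rosenthal fail-safe number against the
# 5n + 10 threshold.

#' Rosenthal fail-safe number
#'
#' Number of hypothetical null-result studies needed to dilute the pooled
#' evidence to non-significance under Stouffer's combined-z method with a
#' one-tailed critical value of \eqn{z_c = \Phi^{-1}(0.95)}:
#' \eqn{N_{fs} = \max(0, (\sum z_i)^2 / z_c^2 - k)} with
#' \eqn{z_i = \ln RR_i / \sqrt{v_i}}.
#'
#' @param effects Effects `data.frame` (`log_rr`, `v`), k >= 2.
#' @return Nonnegative fail-safe number (real-valued).
#' @export
fail_safe_n <- function(effects) {
  e <- .effects_xy(effects)
  if (length(e$x) < 2) stop("at least 2 effect sizes required")
  z <- e$x / sqrt(e$v)
  zc <- stats::qnorm(0.95)
  max(0, sum(z)^2 / zc^2 - length(z))
}

#' Fail-safe robustness verdict
#'
#' A meta-analysis is considered robust to publication bias when the
#' fail-safe number strictly exceeds `5 n + 10`, `n` being the number of
#' observations; a tie is reported as not robust.
#'
#' @param n_fs Fail-safe number.
#' @param n_obs Number of observations (>= 1).
#' @return Logical.
#' @export
robustness <- function(n_fs, n_obs) {
  stopifnot(n_obs >= 1)
  n_fs > 5 * n_obs + 10
}

#' Fail-safe analysis of one factor
#'
#' @param effects Effects `data.frame` for one factor.
#' @param factor Optional label.
#' @return A one-row `data.frame`: `factor`, `n_obs`, `n_fs`, `threshold`,
#'   `robust`.
#' @export
fail_safe <- function(effects, factor = NA_character_) {
  n_obs <- nrow(effects)
  n_fs <- fail_safe_n(effects)
  data.frame(factor = factor, n_obs = n_obs, n_fs = n_fs,
             threshold = 5 * n_obs + 10,
             robust = robustness(n_fs, n_obs),
             stringsAsFactors = FALSE)
}
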