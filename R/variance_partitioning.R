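# Driver-importance stage on ambient-condition (control) data: random
# forest explained variance and permutation importance, PCA PC1
# composites, hierarchical partitioning, trait correlations.

#' Predictor column groups
#'
#' Geoclimatic predictors (latitude, longitude, elevation, MAT, MAP) and
#' litter-quality predictors (AUR, C, N, P, AUR:N, C:N).
#'
#' @return Named list with elements `geoclimate` and `quality`.
#' @export
predictor_groups <- function() {
  list(geoclimate = c("latitude", "longitude", "elevation", "mat", "map"),
       quality = c("aur", "c", "n_conc", "p_conc", "aur_n", "c_n"))
}

#' Build a predictor matrix from ambient-condition observations
#'
#' Extracts the control-side mass loss (every row's control group, i.e.
#' conditions without experimental manipulation) as the response, together
#' with the chosen predictor columns plus decomposition duration.
#' Rows are filtered by the 12-month temporal split (`le12` keeps
#' durations <= 12 months, boundary included; `gt12` the rest) and reduced
#' to complete cases over the chosen columns.
#'
#' @param observations Harmonized observation table.
#' @param column_set `"geoclimate"`, `"quality"` or `"both"`.
#' @param time_filter `"all"`, `"le12"` or `"gt12"`.
#' @return A `data.frame` with column `mass_loss` (response), `duration_months`
#'   and the predictor columns; attribute `column_set` records the choice.
#' @export
build_matrix <- function(observations,
                         column_set = c("both", "geoclimate", "quality"),
                         time_filter = c("all", "le12", "gt12")) {
  column_set <- match.arg(column_set)
  time_filter <- match.arg(time_filter)
  groups <- predictor_groups()
  cols <- switch(column_set,
                 geoclimate = groups$geoclimate,
                 quality = groups$quality,
                 both = unlist(groups, use.names = FALSE))
  obs <- observations
  obs <- switch(time_filter,
                all = obs,
                le12 = obs[obs$duration_months <= 12, , drop = FALSE],
                gt12 = obs[obs$duration_months > 12, , drop = FALSE])
  m <- data.frame(mass_loss = obs$mean_c,
                  duration_months = obs$duration_months,
                  stringsAsFactors = FALSE)
  for (col in cols) m[[col]] <- obs[[col]]
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) == 0) stop("no complete-case rows for column set '",
                         column_set, "' and filter '", time_filter, "'")
  rownames(m) <- NULL
  attr(m, "column_set") <- column_set
  attr(m, "time_filter") <- time_filter
  m
}

.rf_fit <- function(m, n_trees, seed) {
  set.seed(seed)
  randomForest::randomForest(
    x = m[, setdiff(names(m), "mass_loss"), drop = FALSE],
    y = m$mass_loss, ntree = n_trees,
    mtry = max(1, floor((ncol(m) - 1) / 3)),
    importance = TRUE)
}

#' Out-of-bag variance explained by a regression forest
#'
#' Fits a regression random forest (default 500 trees, one third of the
#' predictors tried per split) and returns the out-of-bag pseudo-R²,
#' \eqn{1 - MSE_{oob} / \overline{(y - \bar y)^2}}.
#'
#' @param m Predictor matrix from [build_matrix()] (>= 30 rows).
#' @param n_trees Number of trees.
#' @param seed Integer seed (forests are seed-reproducible).
#' @return Fraction of response variance explained (can be negative for a
#'   pure-noise response).
#' @export
rf_variance_explained <- function(m, n_trees = 500, seed = 1L) {
  if (nrow(m) < 30) stop("at least 30 rows required for a stable forest")
  fit <- .rf_fit(m, n_trees, seed)
  y <- m$mass_loss
  1 - mean((y - fit$predicted)^2) / mean((y - mean(y))^2)
}

#' Permutation importance with response-permutation significance
#'
#' Observed importance per predictor is the forest's mean out-of-bag MSE
#' increase when that predictor is permuted (`%IncMSE`). Significance is
#' assessed against a null distribution obtained by refitting the forest
#' `n_perm` times with the *response* permuted and recording each
#' predictor's importance; the p-value uses the add-one rule
#' \eqn{p = (1 + \#\{null \ge observed\}) / (n_{perm} + 1)} and is never
#' exactly zero.
#'
#' @param m Predictor matrix from [build_matrix()].
#' @param n_trees Trees per forest.
#' @param n_perm Response permutations (>= 20 recommended).
#' @param seed Integer seed.
#' @param alpha Significance level for the flag.
#' @return A `data.frame`: `predictor`, `importance`, `p_value`,
#'   `significant`.
#' @export
rf_permutation_importance <- function(m, n_trees = 500, n_perm = 100,
                                      seed = 1L, alpha = 0.05) {
  if (n_perm < 20) warning("n_perm < 20: permutation p-values are unstable")
  fit <- .rf_fit(m, n_trees, seed)
  obs <- fit$importance[, "%IncMSE"]
  preds <- names(obs)
  set.seed(seed + 1L)
  null <- matrix(NA_real_, nrow = n_perm, ncol = length(preds),
                 dimnames = list(NULL, preds))
  x <- m[, preds, drop = FALSE]
  for (i in seq_len(n_perm)) {
    yp <- sample(m$mass_loss)
    nf <- randomForest::randomForest(x = x, y = yp, ntree = n_trees,
                                     mtry = max(1, floor(length(preds) / 3)),
                                     importance = TRUE)
    null[i, ] <- nf$importance[, "%IncMSE"]
  }
  p <- vapply(preds, function(j) {
    (1 + sum(null[, j] >= obs[[j]])) / (n_perm + 1)
  }, numeric(1))
  data.frame(predictor = preds, importance = unname(obs),
             p_value = unname(p), significant = unname(p < alpha),
             stringsAsFactors = FALSE)
}

#' Mean importance per predictor group
#'
#' Arithmetic mean of per-predictor permutation importances within each
#' named group. Optionally the importances are first rescaled so that
#' they sum to the model's explained variance (in percent), turning the
#' group means into "mean contribution" percentages.
#'
#' @param importances Output of [rf_permutation_importance()] (or any
#'   `data.frame` with `predictor` and `importance`).
#' @param grouping Named list mapping group name to predictor names.
#' @param scale_to_r2 Optional model pseudo-R² (fraction); when supplied,
#'   importances are rescaled to sum to `100 * scale_to_r2`.
#' @return Named numeric vector of group means.
#' @export
group_mean_contribution <- function(importances, grouping,
                                    scale_to_r2 = NULL) {
  unknown <- setdiff(unlist(grouping), importances$predictor)
  if (length(unknown))
    stop("unknown predictor(s) in grouping: ", paste(unknown, collapse = ", "))
  imp <- stats::setNames(importances$importance, importances$predictor)
  if (!is.null(scale_to_r2)) {
    pos <- pmax(imp, 0)
    if (sum(pos) > 0) imp <- pos / sum(pos) * 100 * scale_to_r2
  }
  vapply(grouping, function(p) mean(imp[p]), numeric(1))
}

#' First principal-component composite of one predictor group
#'
#' Standardizes the group's columns (mean 0, SD 1) and returns the first
#' principal-component scores, with the sign fixed so the loading of a
#' designated anchor column is positive (N concentration for the quality
#' group, MAT for the geoclimate group), making orientations reproducible.
#'
#' @param m Predictor matrix (complete cases).
#' @param columns Columns forming the group (>= 2).
#' @param anchor Column whose loading is forced positive; defaults to
#'   `"n_conc"` or `"mat"` when present, else the first column.
#' @return Numeric score vector (mean 0) with attribute `loadings` and
#'   `var_explained`.
#' @export
pc1_composite <- function(m, columns, anchor = NULL) {
  if (nrow(m) < 3) stop("at least 3 rows required")
  if (length(columns) < 2) stop("at least 2 columns required")
  x <- as.matrix(m[, columns, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance column(s): ",
                          paste(columns[sds == 0], collapse = ", "))
  if (is.null(anchor)) {
    anchor <- if ("n_conc" %in% columns) "n_conc"
              else if ("mat" %in% columns) "mat" else columns[1]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1]
  load1 <- pc$rotation[, 1]
  if (load1[anchor] < 0) { scores <- -scores; load1 <- -load1 }
  structure(unname(scores), loadings = load1,
            var_explained = pc$sdev[1]^2 / sum(pc$sdev^2))
}

.r2 <- function(y, X) {
  if (ncol(X) == 0) return(0)
  fit <- stats::lm.fit(cbind(1, X), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Hierarchical partitioning of explained variance
#'
#' Chevan-Sutherland hierarchical partitioning over group composites:
#' linear models are fitted for every subset of groups, and each group's
#' independent contribution is the average, over all orderings in which
#' predictors can enter the model, of the R² increment when that group
#' enters. For two groups A and B this reduces to
#' \eqn{IC_A = \frac{1}{2}[R^2(A) + (R^2(A,B) - R^2(B))]}. Contributions
#' telescope: they sum exactly to the full-model R².
#'
#' @param response Numeric response vector.
#' @param composites `data.frame` (or named list) of one score vector per
#'   group (>= 2 groups).
#' @return A `data.frame`: `group`, `independent_contribution`,
#'   `total_model_r2`.
#' @export
hierarchical_partition <- function(response, composites) {
  composites <- as.data.frame(composites)
  g <- ncol(composites)
  if (g < 2) stop("at least 2 groups required")
  stopifnot(length(response) == nrow(composites))
  groups <- names(composites)
  X <- as.matrix(composites)

  # R2 for every subset, indexed by bitmask
  r2 <- numeric(2^g)
  for (mask in 1:(2^g - 1)) {
    cols <- which(bitwAnd(mask, 2^(seq_len(g) - 1)) > 0)
    r2[mask + 1] <- .r2(response, X[, cols, drop = FALSE])
  }
  if (any(!is.finite(r2))) stop("singular fit in subset models")

  ic <- numeric(g)
  for (j in seq_len(g)) {
    bit <- 2^(j - 1)
    total <- 0
    for (mask in 0:(2^g - 1)) {
      if (bitwAnd(mask, bit) > 0) next
      s <- sum(bitwAnd(mask, 2^(seq_len(g) - 1)) > 0)
      wgt <- factorial(s) * factorial(g - s - 1) / factorial(g)
      total <- total + wgt * (r2[bitwOr(mask, bit) + 1] - r2[mask + 1])
    }
    ic[j] <- total
  }
  data.frame(group = groups, independent_contribution = ic,
             total_model_r2 = r2[2^g], stringsAsFactors = FALSE)
}

#' Correlation between a litter trait and mass loss
#'
#' Pearson correlation of ambient-condition mass loss against an initial
#' litter chemistry trait, with the two-tailed t-test p-value.
#'
#' @param observations Harmonized observation table.
#' @param trait Trait column name (e.g. `"aur"`, `"aur_n"`, `"n_conc"`).
#' @return A list with `r`, `p_value`, `n`.
#' @export
trait_correlation <- function(observations, trait) {
  if (!trait %in% names(observations)) stop("trait column not found: ", trait)
  y <- observations$mean_c
  x <- observations[[trait]]
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 3) stop("at least 3 complete pairs required")
  if (stats::sd(x[keep]) == 0) stop("trait is constant")
  ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(keep))
}
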