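# Shared fixtures, built in code.

# minimal effects table
make_effects <- function(log_rr, v = rep(0.01, length(log_rr)),
                         study_id = paste0("s", seq_along(log_rr)),
                         duration_months = rep(6, length(log_rr))) {
  data.frame(obs_id = paste0("o", seq_along(log_rr)),
             study_id = study_id, site_id = "x", factor = "n_addition",
             duration_months = duration_months,
             log_rr = log_rr, v = v, w = 1 / v,
             stringsAsFactors = FALSE)
}

# a small, fully valid observation CSV written to a temp file
write_tiny_csv <- function(path, drop_col = NULL, extra_row = NULL) {
  df <- data.frame(
    obs_id = c("o1", "o2", "o3"), study_id = c("s1", "s1", "s2"),
    site_id = c("a", "a", "b"),
    factor = c("n_addition", "n_addition", "warming"),
    duration_months = c(6, 12, 9),
    mean_t = c(42, 55, 30), disp_t = c(4, 2, NA),
    disp_label_t = c("sd", "se", "missing"), n_t = c(5, 4, 3),
    mean_c = c(40, 50, 35), disp_c = c(4, NA, 3.5),
    disp_label_c = c("sd", "missing", "ambiguous"), n_c = c(5, 4, 3),
    k_t = NA_real_, k_c = NA_real_,
    non_replacement = TRUE, root_substrate = TRUE,
    latitude = 45, longitude = 10, elevation = 500, mat = 8, map = 450,
    aur = 25, c = 42, n_conc = 0.8, p_conc = 0.1,
    aur_n = 31.25, c_n = 52.5, mesh_mm = 1, depth_cm = 10,
    diameter_mm = 1,
    stringsAsFactors = FALSE)
  if (!is.null(extra_row)) df <- rbind(df, extra_row)
  if (!is.null(drop_col)) df <- df[, setdiff(names(df), drop_col)]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# brute-force hierarchical partitioning oracle: enumerate all orderings
hp_oracle <- function(response, composites) {
  composites <- as.data.frame(composites)
  g <- ncol(composites)
  X <- as.matrix(composites)
  r2 <- function(cols) {
    if (length(cols) == 0) return(0)
    fit <- stats::lm(response ~ X[, cols, drop = FALSE])
    summary(fit)$r.squared
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  all_orders <- perms(seq_len(g))
  ic <- numeric(g)
  for (ord in all_orders) {
    seen <- integer(0)
    for (j in ord) {
      ic[j] <- ic[j] + (r2(c(seen, j)) - r2(seen)) / length(all_orders)
      seen <- c(seen, j)
    }
  }
  ic
}

# brute-force fail-safe oracle: add zero-effect studies until the combined
# one-tailed Stouffer p exceeds 0.05
failsafe_oracle <- function(log_rr, v, max_m = 50000) {
  z <- log_rr / sqrt(v)
  k <- length(z)
  zc <- stats::qnorm(0.95)
  for (m in 0:max_m) {
    if (abs(sum(z)) / sqrt(k + m) < zc) return(m)
  }
  Inf
}
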