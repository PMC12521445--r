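# Observation data model: schema, validation, harmonization.

#' Experimental factor levels
#'
#' The twelve manipulation factors recognised in the observation schema,
#' plus `"control_only"` for unpaired rows that feed the variance
#' partitioning stage only.
#'
#' @return Character vector of the twelve factor codes (without
#'   `"control_only"`).
#' @export
factor_levels <- function() {
  c("n_addition", "p_addition", "warming", "increased_precip",
    "reduced_precip", "elevated_co2", "grazing", "vegetated_soil",
    "plant_richness", "litter_richness", "home_field", "fauna_exclusion")
}

# Moderator columns carried through the pipeline; all numeric, all optional.
.moderator_cols <- c("latitude", "longitude", "elevation", "mat", "map",
                     "aur", "c", "n_conc", "p_conc", "aur_n", "c_n",
                     "mesh_mm", "depth_cm", "diameter_mm")

# Columns that must be present in the header. k-only records leave the mean
# columns empty and carry k_c / k_t instead.
.mandatory_cols <- c("obs_id", "study_id", "site_id", "factor",
                     "duration_months",
                     "mean_t", "disp_t", "disp_label_t", "n_t",
                     "mean_c", "disp_c", "disp_label_c", "n_c",
                     "non_replacement")

.optional_cols <- c("k_t", "k_c", "root_substrate", .moderator_cols)

.disp_labels <- c("sd", "se", "ambiguous", "missing")

#' Read a root-decomposition observation table
#'
#' Reads the documented CSV schema (UTF-8, comma separated, `.` decimal,
#' empty cell = missing; one row per treatment/control observation pair,
#' or a control-only row with the treatment columns empty). Units are
#' months for duration, percent of initial dry mass for mass loss, mm for
#' mesh size and root diameter.
#'
#' Rows violating a field invariant (mass loss outside \[0, 100\],
#' replicate count below 1, negative dispersion, unknown factor code,
#' non-numeric numeric cell) are quarantined: removed from the returned
#' table and listed, with the offending row index and reason, in the
#' `issues` attribute.
#'
#' @param path Path to the CSV file.
#' @param schema_version Schema version string; only `"1.0"` is defined.
#' @return A `data.frame` of validated observations with attribute
#'   `issues` (a `data.frame` with columns `row`, `field`, `message`).
#' @export
read_observations <- function(path, schema_version = "1.0") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!identical(schema_version, "1.0")) {
    stop("unknown schema version: ", schema_version)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = "")
  missing_cols <- setdiff(.mandatory_cols, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(.optional_cols, names(raw))) raw[[col]] <- NA_character_

  issues <- list()
  flag <- function(row, field, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      row = row, field = field, message = message,
      stringsAsFactors = FALSE)
  }

  num_cols <- c("duration_months", "mean_t", "disp_t", "n_t",
                "mean_c", "disp_c", "n_c", "k_t", "k_c", .moderator_cols)
  out <- raw
  for (col in num_cols) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(val))
    for (r in bad) flag(r, col, "non-numeric value")
    out[[col]] <- val
  }
  for (col in c("non_replacement", "root_substrate")) {
    v <- tolower(trimws(raw[[col]]))
    out[[col]] <- ifelse(is.na(v), NA,
                         v %in% c("true", "t", "1", "yes", "y"))
  }
  for (col in c("disp_label_t", "disp_label_c")) {
    v <- tolower(trimws(out[[col]]))
    v[is.na(v)] <- "missing"
    bad <- which(!v %in% .disp_labels)
    for (r in bad) flag(r, col, paste0("unknown dispersion label '", v[r], "'"))
    out[[col]] <- v
  }

  ok_factor <- out$factor %in% c(factor_levels(), "control_only")
  for (r in which(!ok_factor)) flag(r, "factor", "unknown factor code")

  check_range <- function(col, low, high, what) {
    v <- out[[col]]
    bad <- which(!is.na(v) & (v < low | v > high))
    for (r in bad) flag(r, col, what)
  }
  check_range("mean_t", 0, 100, "mass loss outside [0, 100]")
  check_range("mean_c", 0, 100, "mass loss outside [0, 100]")
  check_range("n_t", 1, Inf, "replicate count below 1")
  check_range("n_c", 1, Inf, "replicate count below 1")
  check_range("disp_t", 0, Inf, "negative dispersion")
  check_range("disp_c", 0, Inf, "negative dispersion")
  check_range("k_t", 0, Inf, "negative decay constant")
  check_range("k_c", 0, Inf, "negative decay constant")

  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(row = integer(), field = character(), message = character(),
               stringsAsFactors = FALSE)
  keep <- setdiff(seq_len(nrow(out)), unique(issues$row))
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "issues") <- issues
  res
}

#' Resolve a reported dispersion value to a standard deviation
#'
#' Applies the harmonization convention for literature-extracted
#' dispersion fields: a value labelled `sd` is returned unchanged; `se`
#' and `ambiguous` (variability of unclear type, conservatively taken as
#' a standard error) are multiplied by `sqrt(n)`; a missing value is
#' imputed as one tenth of the group mean.
#'
#' @param value Reported dispersion value (may be `NA`).
#' @param label One of `"sd"`, `"se"`, `"ambiguous"`, `"missing"`.
#' @param n Replicate count (>= 1).
#' @param mean_mass_loss Group mean mass loss in percent (>= 0).
#' @return Nonnegative standard deviation.
#' @examples
#' resolve_sd(NA, "missing", 5, 50)   # 5: mean/10 imputation
#' resolve_sd(2, "se", 9, 50)         # 6: SE * sqrt(n)
#' @export
resolve_sd <- function(value, label, n, mean_mass_loss) {
  stopifnot(length(label) == length(value), length(n) == length(value),
            length(mean_mass_loss) == length(value))
  if (any(n < 1, na.rm = TRUE)) stop("replicate count must be >= 1")
  if (any(mean_mass_loss < 0, na.rm = TRUE)) stop("mean mass loss must be >= 0")
  if (any(!is.na(value) & value < 0)) stop("negative dispersion value")
  label <- ifelse(is.na(value) | label == "missing", "missing", label)
  out <- ifelse(label == "sd", value,
         ifelse(label %in% c("se", "ambiguous"), value * sqrt(n),
                mean_mass_loss / 10))
  unname(out)
}

#' Convert a decay constant to percent mass loss
#'
#' Single negative exponential (Olson) decomposition model
#' \eqn{M_t = M_0 e^{-kt}}: mass loss after `duration_months` is
#' \eqn{(1 - e^{-k t})\times 100} with \eqn{t} in years.
#'
#' @param k Decay constant per year (>= 0).
#' @param duration_months Incubation duration in months (> 0).
#' @return Percent mass loss in \[0, 100).
#' @examples
#' mass_loss_from_k(log(2), 12)  # 50: one half-life
#' @export
mass_loss_from_k <- function(k, duration_months) {
  if (any(k < 0, na.rm = TRUE)) stop("negative decay constant")
  if (any(duration_months <= 0, na.rm = TRUE)) stop("duration must be positive")
  (1 - exp(-k * duration_months / 12)) * 100
}

#' Harmonize an observation table
#'
#' Applies the harmonization rules to a validated observation table:
#' k-only records are converted to percent mass loss via
#' [mass_loss_from_k()], dispersion fields of both groups are resolved to
#' standard deviations via [resolve_sd()] (stored in `sd_t`, `sd_c`, with
#' labels rewritten to `"sd"`), and rows failing the inclusion checks are
#' dropped with a per-reason count: missing duration, a row flagged as
#' non-root substrate, or a row flagged as violating the
#' non-replacement-sampling requirement.
#'
#' The operation is idempotent: harmonizing an already harmonized table
#' changes nothing.
#'
#' @param obs Observation `data.frame` from [read_observations()] (or the
#'   synthetic generator).
#' @return Harmonized `data.frame` with attribute `report`: a list with
#'   counts of imputations, SE conversions, k conversions and exclusions
#'   by reason.
#' @export
harmonize <- function(obs) {
  report <- list(rows_in = nrow(obs),
                 dropped_no_duration = 0L,
                 dropped_non_root = 0L,
                 dropped_replacement_sampling = 0L,
                 k_conversions = 0L,
                 se_conversions = 0L,
                 sd_imputations = 0L)

  drop <- is.na(obs$duration_months)
  report$dropped_no_duration <- sum(drop)
  non_root <- !is.na(obs$root_substrate) & !obs$root_substrate
  report$dropped_non_root <- sum(non_root & !drop)
  drop <- drop | non_root
  repl <- !is.na(obs$non_replacement) & !obs$non_replacement
  report$dropped_replacement_sampling <- sum(repl & !drop)
  drop <- drop | repl
  obs <- obs[!drop, , drop = FALSE]

  for (side in c("t", "c")) {
    mcol <- paste0("mean_", side); kcol <- paste0("k_", side)
    fill <- is.na(obs[[mcol]]) & !is.na(obs[[kcol]])
    if (any(fill)) {
      obs[[mcol]][fill] <- mass_loss_from_k(obs[[kcol]][fill],
                                            obs$duration_months[fill])
      report$k_conversions <- report$k_conversions + sum(fill)
    }
  }

  has_t <- !is.na(obs$mean_t)
  for (side in c("t", "c")) {
    mcol <- paste0("mean_", side); dcol <- paste0("disp_", side)
    lcol <- paste0("disp_label_", side); scol <- paste0("sd_", side)
    active <- if (side == "t") has_t else rep(TRUE, nrow(obs))
    lab <- obs[[lcol]]
    lab[is.na(obs[[dcol]])] <- "missing"
    report$se_conversions <- report$se_conversions +
      sum(active & lab %in% c("se", "ambiguous"))
    report$sd_imputations <- report$sd_imputations +
      sum(active & lab == "missing")
    sd <- rep(NA_real_, nrow(obs))
    if (any(active)) {
      sd[active] <- resolve_sd(obs[[dcol]][active], lab[active],
                               obs[[paste0("n_", side)]][active],
                               obs[[mcol]][active])
    }
    obs[[scol]] <- sd
    obs[[dcol]] <- sd
    obs[[lcol]] <- ifelse(active, "sd", obs[[lcol]])
  }

  report$rows_out <- nrow(obs)
  rownames(obs) <- NULL
  attr(obs, "report") <- report
  obs
}
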