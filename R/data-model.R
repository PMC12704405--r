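#' Construct a meta-analysis dataset for one outcome
#'
#' A dataset is a tibble with one row per study and columns `study_id`,
#' `n_treat`, `n_ctrl` (per-arm sample sizes), `y` (treatment effect on the
#' normal scale, e.g. a log risk ratio), `se` (its standard error) and
#' `reported`. An unreported outcome is a row where `y` and `se` are both
#' `NA` while the arm sizes are present -- the hallmark of outcome reporting
#' bias, where a published study discloses who was randomised but not the
#' result for this outcome.
#'
#' @param study_id Character vector of unique study labels.
#' @param n_treat,n_ctrl Integer per-arm sample sizes (>= 1).
#' @param y Numeric effects; `NA` for unreported outcomes.
#' @param se Positive standard errors; `NA` exactly where `y` is `NA`.
#' @param outcome Optional outcome name, stored as the `"outcome"` attribute.
#'
#' @return A validated tibble of class `meta_dataset`.
#' @export
#' @examples
#' meta_dataset(
#'   study_id = c("A", "B", "C"),
#'   n_treat = c(50, 60, 40), n_ctrl = c(50, 55, 45),
#'   y = c(0.4, 0.1, NA), se = c(0.25, 0.3, NA)
#' )
meta_dataset <- function(study_id, n_treat, n_ctrl, y = NULL, se = NULL,
                         outcome = NULL) {
  k <- length(study_id)
  if (is.null(y)) y <- rep(NA_real_, k)
  if (is.null(se)) se <- rep(NA_real_, k)
  out <- tibble::tibble(
    study_id = as.character(study_id),
    n_treat = as.integer(n_treat),
    n_ctrl = as.integer(n_ctrl),
    y = as.numeric(y),
    se = as.numeric(se),
    reported = !is.na(y) & !is.na(se)
  )
  validate_meta_dataset(out)
  attr(out, "outcome") <- outcome
  class(out) <- c("meta_dataset", class(out))
  out
}

#' Validate a meta-analysis dataset
#'
#' Checks the invariants of the study-level representation: reported rows
#' carry both `y` and a positive `se`, unreported rows carry neither, arm
#' sizes are always present and positive, and study ids are unique.
#'
#' @param data A data frame with columns `study_id`, `n_treat`, `n_ctrl`,
#'   `y`, `se` (a `reported` column is recomputed if absent).
#' @return The data, invisibly, if valid; otherwise an error of class
#'   `orbsel_error_validation`.
#' @export
validate_meta_dataset <- function(data) {
  need <- c("study_id", "n_treat", "n_ctrl", "y", "se")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort_validation(paste0(
      "dataset is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  partial <- xor(is.na(data$y), is.na(data$se))
  if (any(partial)) {
    abort_validation(paste0(
      "study '", data$study_id[which(partial)[1]],
      "' has exactly one of y/se missing; unreported outcomes must miss both"
    ))
  }
  if (any(is.na(data$n_treat)) || any(is.na(data$n_ctrl)) ||
      any(data$n_treat < 1) || any(data$n_ctrl < 1)) {
    abort_validation("per-arm sample sizes must be present and >= 1 for every study")
  }
  bad_se <- !is.na(data$se) & data$se <= 0
  if (any(bad_se)) {
    abort_validation(paste0(
      "study '", data$study_id[which(bad_se)[1]], "' has a nonpositive standard error"
    ))
  }
  if (anyDuplicated(data$study_id)) {
    abort_validation("study_id values must be unique")
  }
  if ("reported" %in% names(data)) {
    if (!identical(as.logical(data$reported), !is.na(data$y) & !is.na(data$se))) {
      abort_validation("reported flag disagrees with presence of y/se")
    }
  }
  invisible(data)
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "orbsel_error_validation")
}

abort_config <- function(msg) {
  rlang::abort(msg, class = "orbsel_error_config")
}

#' Read a meta-analysis dataset from CSV
#'
#' Two schemas are supported. `effect_se` files carry columns
#' `study_id, n_treat, n_ctrl, y, se`; `counts_2x2` files carry
#' `study_id, n_treat, n_ctrl, events_treat, events_ctrl` and are converted
#' to log risk ratios via [log_rr_from_counts()] (with continuity correction
#' for zero cells) on reading. In both schemas an unreported outcome is a row
#' whose effect columns are empty while the arm sizes are present.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schema `"effect_se"` or `"counts_2x2"`.
#' @param outcome Optional outcome name attached to the result.
#' @param cc Continuity correction used for the counts schema (default 0.5).
#' @return A `meta_dataset` tibble.
#' @export
read_meta_dataset <- function(path, schema = c("effect_se", "counts_2x2"),
                              outcome = NULL, cc = 0.5) {
  schema <- match.arg(schema)
  # parse numerics through base R's strtod (correctly rounded), so that a
  # write/read round trip reproduces doubles bit-exactly
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  raw <- dplyr::mutate(raw, dplyr::across(-dplyr::any_of("study_id"), as.numeric))
  if (schema == "effect_se") {
    need <- c("study_id", "n_treat", "n_ctrl", "y", "se")
    if (!all(need %in% names(raw))) {
      abort_validation(paste0(
        "effect_se schema requires columns: ", paste(need, collapse = ", ")
      ))
    }
    meta_dataset(raw$study_id, raw$n_treat, raw$n_ctrl, raw$y, raw$se,
                 outcome = outcome)
  } else {
    need <- c("study_id", "n_treat", "n_ctrl", "events_treat", "events_ctrl")
    if (!all(need %in% names(raw))) {
      abort_validation(paste0(
        "counts_2x2 schema requires columns: ", paste(need, collapse = ", ")
      ))
    }
    partial <- xor(is.na(raw$events_treat), is.na(raw$events_ctrl))
    if (any(partial)) {
      abort_validation(paste0(
        "study '", raw$study_id[which(partial)[1]],
        "' reports events for only one arm"
      ))
    }
    eff <- log_rr_from_counts(raw$events_treat, raw$events_ctrl,
                              raw$n_treat, raw$n_ctrl, cc = cc)
    meta_dataset(raw$study_id, raw$n_treat, raw$n_ctrl, eff$y, eff$se,
                 outcome = outcome)
  }
}

#' Write a meta-analysis dataset to CSV (effect_se schema)
#'
#' Unreported outcomes are written as empty cells, so a write/read round trip
#' reproduces the dataset exactly.
#'
#' @param data A `meta_dataset` (or conforming data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_meta_dataset <- function(data, path) {
  validate_meta_dataset(data)
  num17 <- function(x) {
    # 17 significant digits round-trips doubles exactly through strtod
    ifelse(is.na(x), NA_character_, formatC(x, digits = 17, format = "g"))
  }
  out <- tibble::tibble(
    study_id = data$study_id,
    n_treat = data$n_treat, n_ctrl = data$n_ctrl,
    y = num17(data$y), se = num17(data$se)
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Split a dataset into reported and unreported studies
#'
#' @param data A `meta_dataset`.
#' @return A named list with tibbles `reported` and `unreported`; the
#'   partition is disjoint and order-preserving.
#' @export
#' @examples
#' d <- epilepsy_dataset("seizure_freedom")
#' lengths(lapply(partition_reported(d), nrow))
partition_reported <- function(data) {
  validate_meta_dataset(data)
  data <- tibble::as_tibble(data)
  list(
    reported = dplyr::filter(data, .data$reported),
    unreported = dplyr::filter(data, !.data$reported)
  )
}

# internal: require >= k reported studies for estimation
check_min_reported <- function(data, k = 2L) {
  n_rep <- sum(data$reported)
  if (n_rep < k) {
    abort_validation(paste0(
      "at least ", k, " reported studies are required (found ", n_rep, ")"
    ))
  }
  invisible(n_rep)
}
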