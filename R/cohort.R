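#' Longitudinal lesion-area cohorts
#'
#' A `ga_cohort` holds time-aligned per-eye lesion-area series: a visit
#' table with columns `patient_id`, `eye_id`, `t` (years since the eye's
#' first visit), `area` (mm²) and `gradable`, plus provenance and a running
#' filter report. Eyes are identified by `patient_id` + `eye_id` (`eye_id`
#' is only unique within a patient, e.g. `"OD"`/`"OS"`).
#'
#' @param visits tibble of visit records.
#' @param provenance character scalar describing the source (file path or
#'   simulation seed).
#' @param filter_report named list of filtering counts.
#' @return an object of class `ga_cohort`.
#' @export
new_cohort <- function(visits, provenance = "in-memory", filter_report = list()) {
  visits <- tibble::as_tibble(visits)
  req <- c("patient_id", "eye_id", "t", "area", "gradable")
  missing <- setdiff(req, names(visits))
  if (length(missing)) {
    stop_schema(sprintf("visit table is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  visits$patient_id <- as.character(visits$patient_id)
  visits$eye_id <- as.character(visits$eye_id)
  visits <- dplyr::arrange(visits, .data$patient_id, .data$eye_id, .data$t)
  structure(list(visits = visits, provenance = provenance,
                 filter_report = filter_report),
            class = "ga_cohort")
}

eye_key <- function(patient_id, eye_id) paste(patient_id, eye_id, sep = "//")

#' @export
print.ga_cohort <- function(x, ...) {
  s <- cohort_summary(x)
  cat(sprintf("<ga_cohort> %d patients, %d eyes, %d visits (provenance: %s)\n",
              s$n_patients, s$n_eyes, s$n_visits, x$provenance))
  invisible(x)
}

#' Summarise a cohort
#'
#' @param cohort a `ga_cohort`.
#' @return a one-row tibble: patient/eye/visit counts, median (IQR) visits
#'   per eye, follow-up and baseline area, bilateral fraction, `max_area`
#'   and `t_span` (used to scale default priors).
#' @export
cohort_summary <- function(cohort) {
  v <- cohort$visits
  if (nrow(v) == 0) {
    return(tibble::tibble(n_patients = 0L, n_eyes = 0L, n_visits = 0L,
                          visits_median = NA_real_, visits_iqr = NA_real_,
                          followup_median = NA_real_, followup_iqr = NA_real_,
                          baseline_median = NA_real_, baseline_iqr = NA_real_,
                          bilateral_frac = NA_real_, max_area = NA_real_,
                          t_span = NA_real_))
  }
  per_eye <- v |>
    dplyr::group_by(.data$patient_id, .data$eye_id) |>
    dplyr::summarise(n = dplyr::n(), followup = max(.data$t) - min(.data$t),
                     baseline = .data$area[which.min(.data$t)],
                     .groups = "drop")
  per_pat <- per_eye |>
    dplyr::count(.data$patient_id, name = "n_eyes")
  tibble::tibble(
    n_patients = nrow(per_pat),
    n_eyes = nrow(per_eye),
    n_visits = nrow(v),
    visits_median = median(per_eye$n),
    visits_iqr = stats::IQR(per_eye$n),
    followup_median = median(per_eye$followup),
    followup_iqr = stats::IQR(per_eye$followup),
    baseline_median = median(per_eye$baseline),
    baseline_iqr = stats::IQR(per_eye$baseline),
    bilateral_frac = mean(per_pat$n_eyes >= 2),
    max_area = max(v$area),
    t_span = max(v$t)
  )
}

#' Read a lesion-area cohort from CSV
#'
#' The canonical dialect is comma-separated UTF-8 with a header row and `.`
#' decimals. Required columns: `patient_id`, `eye_id`, `area_mm2`, and one
#' of `visit_date` (ISO dates, converted to years since each eye's first
#' visit using day counts / 365.25) or `t_years`. An optional `gradable`
#' logical column defaults to `TRUE`. Within each eye, times are re-aligned
#' so the earliest visit sits at `t = 0`; duplicate timestamps keep the last
#' record with a warning.
#'
#' @param path CSV file path.
#' @return a validated [new_cohort()] object.
#' @export
read_cohort <- function(path) {
  # numeric columns are parsed via base R's strtod (correctly rounded to the
  # nearest double) so write_cohort() -> read_cohort() round-trips bit-exactly
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  for (col in intersect(c("t_years", "area_mm2"), names(raw))) {
    raw[[col]] <- as.numeric(raw[[col]])
  }
  if ("gradable" %in% names(raw)) {
    raw$gradable <- as.logical(raw$gradable)
  }
  validate_cohort_table(raw, provenance = as.character(path))
}

#' @rdname read_cohort
#' @param x a data frame already in memory with the same columns.
#' @param provenance provenance string recorded on the cohort.
#' @export
validate_cohort_table <- function(x, provenance = "in-memory") {
  x <- tibble::as_tibble(x)
  for (col in c("patient_id", "eye_id", "area_mm2")) {
    if (!col %in% names(x)) {
      stop_schema(sprintf("required column '%s' is missing", col))
    }
  }
  has_date <- "visit_date" %in% names(x)
  has_t <- "t_years" %in% names(x)
  if (!has_date && !has_t) {
    stop_schema("required column 'visit_date' or 't_years' is missing")
  }
  if (!"gradable" %in% names(x)) x$gradable <- TRUE
  x$gradable <- as.logical(x$gradable)
  if (nrow(x) == 0) {
    return(new_cohort(tibble::tibble(patient_id = character(), eye_id = character(),
                                     t = numeric(), area = numeric(),
                                     gradable = logical()),
                      provenance = provenance))
  }

  area <- as.numeric(x$area_mm2)
  bad <- which(!is.finite(area) | area < 0)
  if (length(bad)) {
    stop_validation(sprintf(
      "lesion area must be finite and >= 0; offending row(s): %s",
      paste(bad, collapse = ", ")), rows = bad)
  }

  v <- tibble::tibble(
    patient_id = as.character(x$patient_id),
    eye_id = as.character(x$eye_id),
    area = area,
    gradable = x$gradable
  )
  if (has_t) {
    tt <- as.numeric(x$t_years)
    if (any(!is.finite(tt))) {
      stop_validation(sprintf("non-finite t_years in row(s): %s",
                              paste(which(!is.finite(tt)), collapse = ", ")))
    }
    v$t <- tt
  } else {
    d <- as.Date(x$visit_date)
    if (any(is.na(d))) {
      stop_validation(sprintf("unparseable visit_date in row(s): %s",
                              paste(which(is.na(d)), collapse = ", ")))
    }
    v$t <- as.numeric(d) # days; re-aligned per eye below
  }

  v <- v |>
    dplyr::group_by(.data$patient_id, .data$eye_id) |>
    dplyr::mutate(t = .data$t - min(.data$t)) |>
    dplyr::ungroup()
  if (has_date) v$t <- v$t / 365.25

  # duplicate timestamps within an eye: keep the last record, warn
  v <- dplyr::arrange(v, .data$patient_id, .data$eye_id, .data$t)
  dup <- v |>
    dplyr::group_by(.data$patient_id, .data$eye_id) |>
    dplyr::mutate(.dup = duplicated(.data$t, fromLast = TRUE)) |>
    dplyr::ungroup()
  if (any(dup$.dup)) {
    warn(sprintf("%d duplicate timestamp(s) within an eye; keeping the last record",
                 sum(dup$.dup)))
    v <- v[!dup$.dup, ]
  }
  new_cohort(v, provenance = provenance)
}

#' Write a cohort in the canonical CSV dialect
#'
#' Columns `patient_id, eye_id, t_years, area_mm2, gradable`; doubles are
#' written with shortest round-trip precision so
#' `read_cohort(write_cohort(x))` reproduces the visit table exactly.
#'
#' @param cohort a `ga_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort$visits |>
    dplyr::transmute(patient_id = .data$patient_id, eye_id = .data$eye_id,
                     t_years = sprintf("%.17g", .data$t),
                     area_mm2 = sprintf("%.17g", .data$area),
                     gradable = .data$gradable)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Natural-history inclusion filters
#'
#' Retains eyes with at least `min_visits` gradable visits of which at least
#' `min_large_visits` show a lesion area strictly greater than
#' `large_area_threshold` mm² (the threshold itself does not count).
#' Non-gradable visits are dropped before counting and are not carried into
#' the output. The returned cohort's `filter_report` records how many eyes
#' and visits each rule removed; the operation is idempotent.
#'
#' @param cohort a `ga_cohort`.
#' @param min_visits minimum number of gradable visits per eye.
#' @param min_large_visits minimum number of gradable visits above threshold.
#' @param large_area_threshold mm²; comparison is strict (`>`).
#' @return the filtered `ga_cohort`.
#' @export
apply_inclusion_filters <- function(cohort, min_visits = 5L,
                                    min_large_visits = 3L,
                                    large_area_threshold = 2.0) {
  v <- cohort$visits
  n_visits_in <- nrow(v)
  keys_in <- unique(eye_key(v$patient_id, v$eye_id))

  g <- v[v$gradable, , drop = FALSE]
  n_nongradable <- n_visits_in - nrow(g)

  per_eye <- g |>
    dplyr::group_by(.data$patient_id, .data$eye_id) |>
    dplyr::summarise(n_gradable = dplyr::n(),
                     n_large = sum(.data$area > large_area_threshold),
                     .groups = "drop")
  per_eye$too_few <- per_eye$n_gradable < min_visits
  per_eye$too_small <- !per_eye$too_few & per_eye$n_large < min_large_visits
  keep <- per_eye[!per_eye$too_few & !per_eye$too_small, c("patient_id", "eye_id")]

  out <- dplyr::semi_join(g, keep, by = c("patient_id", "eye_id"))
  # eyes whose every visit is non-gradable never reach per_eye: count them
  # under the visit-count rule
  n_vanished <- length(keys_in) - nrow(per_eye)
  report <- list(
    n_eyes_in = length(keys_in),
    n_eyes_out = nrow(keep),
    n_eyes_dropped_few_visits = sum(per_eye$too_few) + n_vanished,
    n_eyes_dropped_small_lesion = sum(per_eye$too_small),
    n_visits_in = n_visits_in,
    n_visits_dropped_nongradable = n_nongradable,
    n_visits_out = nrow(out),
    min_visits = min_visits,
    min_large_visits = min_large_visits,
    large_area_threshold = large_area_threshold
  )
  new_cohort(out, provenance = cohort$provenance, filter_report = report)
}

#' Trial-eligibility annotation
#'
#' Flags every visit whose lesion area lies inside the standard trial
#' eligibility window (closed interval, both ends inclusive).
#'
#' @param cohort a `ga_cohort`.
#' @param window numeric length-2, mm²; default `c(2.5, 17.5)`.
#' @return the cohort with a logical `eligible` column added to its visits.
#' @export
eligibility_flags <- function(cohort, window = c(2.5, 17.5)) {
  if (length(window) != 2L || !all(is.finite(window)) || window[1] >= window[2]) {
    stop_config("eligibility window must be (lower, upper) with lower < upper")
  }
  cohort$visits$eligible <- cohort$visits$area >= window[1] &
    cohort$visits$area <= window[2]
  cohort
}

# restrict a cohort to a subset of eyes / truncate one eye's history;
# internal plumbing shared by the forecasting harness
subset_cohort <- function(cohort, keys, truncate_key = NULL, max_index = Inf) {
  v <- cohort$visits
  k <- eye_key(v$patient_id, v$eye_id)
  v <- v[k %in% keys, , drop = FALSE]
  if (!is.null(truncate_key)) {
    v <- v |>
      dplyr::group_by(.data$patient_id, .data$eye_id) |>
      dplyr::mutate(.idx = rank(.data$t, ties.method = "first")) |>
      dplyr::ungroup()
    focal <- eye_key(v$patient_id, v$eye_id) == truncate_key
    v <- v[!focal | v$.idx <= max_index, , drop = FALSE]
    v$.idx <- NULL
  }
  new_cohort(v, provenance = cohort$provenance,
             filter_report = cohort$filter_report)
}
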