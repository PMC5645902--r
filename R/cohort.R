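# Window arithmetic constants (days). Month-based criteria are fixed as day
# counts for internal consistency: 6 months = 183 d, 9 months = 275 d,
# 5 months = 152 d, 3 months = 92 d, 1 month = 31 d.
WASHOUT_DAYS <- 183L
POST_COVERAGE_DAYS <- 275L
BASELINE_BACK_DAYS <- 152L
BASELINE_FWD_DAYS <- 31L
FOLLOWUP_START_DAYS <- 92L
FOLLOWUP_END_DAYS <- 275L
DIAGNOSIS_WINDOW_DAYS <- 61L

#' Select depressive episodes from an event table
#'
#' Scans each patient's event stream for index dates that satisfy all of the
#' inclusion criteria and none of the exclusion criteria, and attaches the
#' baseline and follow-up windows to each qualifying episode:
#'
#' * an antidepressant (AD) prescription on the index date with exactly one
#'   distinct AD molecule prescribed that day (monotherapy);
#' * no AD prescription in the 183 days before the index date (washout);
#' * at least one depression diagnosis within 61 days of the index date, and
#'   no depression diagnosis in the 183 days before the index date outside
#'   that window (incident diagnosis);
#' * age 18 or over at the index date (mid-year convention on birth year);
#' * at least 183 days of data coverage before and 275 days after the index
#'   date, the latter waived if the patient dies within that span;
#' * no bipolar or schizophrenia diagnosis at any recorded time.
#'
#' Data coverage is taken from each patient's first and last recorded event.
#' A patient can contribute several episodes; a later index date qualifies
#' only when the 183-day AD washout holds again, so episodes never share an
#' index date. The baseline window is `[index - 152 d, index + 31 d]` and the
#' follow-up window `[index + 92 d, index + 275 d]`.
#'
#' @param events Event tibble as produced by [generate_event_stream()] (or
#'   read from the same CSV layout); dates are coerced with [as.Date()].
#' @param study_start,study_end Study window bounds; index dates outside the
#'   window are not considered.
#' @return A tibble of episodes: `episode_id, patient_id, index_date,
#'   baseline_start, baseline_end, followup_start, followup_end, death_date`.
#' @export
#' @examples
#' ev <- generate_event_stream(dhsi_sim_config(n_patients = 30, seed = 2))
#' select_episodes(ev)
select_episodes <- function(events, study_start = "2006-01-01",
                            study_end = "2012-12-31") {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  stopifnot(study_start < study_end)
  empty <- tibble::tibble(
    episode_id = character(), patient_id = character(),
    index_date = as.Date(character()),
    baseline_start = as.Date(character()), baseline_end = as.Date(character()),
    followup_start = as.Date(character()), followup_end = as.Date(character()),
    death_date = as.Date(character())
  )
  if (nrow(events) == 0) return(empty)
  events <- dplyr::arrange(dplyr::mutate(events, date = as.Date(.data$date)),
                           .data$patient_id, .data$date)

  eps <- events |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_map(~ patient_episodes(.x, .y$patient_id, study_start, study_end)) |>
    dplyr::bind_rows()
  if (nrow(eps) == 0) return(empty)
  eps |>
    dplyr::arrange(.data$patient_id, .data$index_date) |>
    dplyr::mutate(episode_id = sprintf("E%06d", dplyr::row_number()),
                  .before = 1)
}

patient_episodes <- function(pev, pid, study_start, study_end) {
  out <- NULL
  birth <- pev$code[pev$event_type == "birth_year_record"]
  if (length(birth) == 0 || is.na(suppressWarnings(as.integer(birth[1])))) {
    warning("patient ", pid, " has no birth_year_record; skipped", call. = FALSE)
    return(NULL)
  }
  birth_year <- as.integer(birth[1])
  if (any(pev$event_type %in% c("bipolar_diagnosis", "schizophrenia_diagnosis"))) {
    return(NULL)
  }
  first_ev <- min(pev$date)
  last_ev <- max(pev$date)
  death_date <- if (any(pev$event_type == "death")) {
    min(pev$date[pev$event_type == "death"])
  } else {
    as.Date(NA)
  }
  ad <- pev[pev$event_type == "ad_prescription", ]
  dep <- pev$date[pev$event_type == "depression_diagnosis"]
  candidates <- sort(unique(ad$date))
  candidates <- candidates[candidates >= study_start & candidates <= study_end]
  for (idx in as.list(candidates)) {
    # (a) monotherapy on index date
    if (length(unique(ad$molecule[ad$date == idx])) != 1) next
    # (b) AD washout
    if (any(ad$date >= idx - WASHOUT_DAYS & ad$date < idx)) next
    # (c) incident depression diagnosis within +/- 61 d
    if (!any(abs(as.integer(dep - idx)) <= DIAGNOSIS_WINDOW_DAYS)) next
    if (any(dep >= idx - WASHOUT_DAYS & dep < idx - DIAGNOSIS_WINDOW_DAYS)) next
    # (d) age >= 18, mid-year convention
    if (idx < as.Date(sprintf("%d-07-01", birth_year + 18L))) next
    # (e) data coverage
    if (first_ev > idx - WASHOUT_DAYS) next
    covered_after <- last_ev >= idx + POST_COVERAGE_DAYS
    died_within <- !is.na(death_date) &&
      death_date > idx && death_date <= idx + POST_COVERAGE_DAYS
    if (!covered_after && !died_within) next
    out <- dplyr::bind_rows(out, tibble::tibble(
      patient_id = pid, index_date = idx,
      baseline_start = idx - BASELINE_BACK_DAYS,
      baseline_end = idx + BASELINE_FWD_DAYS,
      followup_start = idx + FOLLOWUP_START_DAYS,
      followup_end = idx + FOLLOWUP_END_DAYS,
      death_date = death_date
    ))
  }
  out
}
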