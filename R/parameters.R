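# Event types counted as "psychiatric treatment" for the relapse-type
# detector and the ulterior-prescription check of X1/X2.
PSY_TREATMENT_TYPES <- c("ad_prescription", "psychiatric_prescription",
                         "hypnotic_prescription",
                         "antipsychotic_or_lithium_prescription")

# merge closed coverage intervals [start, end]; abutting intervals merge
merge_intervals <- function(starts, ends) {
  if (length(starts) == 0) {
    return(list(start = numeric(0), end = numeric(0)))
  }
  o <- order(starts)
  starts <- as.numeric(starts[o])
  ends <- as.numeric(ends[o])
  ms <- starts[1]
  me <- ends[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= me) {
      me <- max(me, ends[k])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[k]; me <- ends[k]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

# coverage-weighted mean daily dose over a set of prescriptions
weighted_dose <- function(rx) {
  if (nrow(rx) == 0 || all(is.na(rx$daily_dose))) return(NA_real_)
  w <- ifelse(is.na(rx$coverage_days), 1, rx$coverage_days)
  sum(rx$daily_dose * w) / sum(w)
}

#' Summarize one episode period
#'
#' Computes the per-period quantities behind the relative parameters:
#' visit counts, inter-visit gap statistics, distinct psychiatric molecules,
#' hypnotic and somatic prescription counts, distinct somatic comorbidities,
#' and the coverage-weighted mean daily dose of the index antidepressant.
#' Counts are taken over events in the closed window; the follow-up window is
#' truncated at the death date when the patient dies during follow-up.
#' Inter-visit statistics need at least three visits (two gaps) and are `NA`
#' otherwise.
#'
#' @param episode One row of the tibble returned by [select_episodes()].
#' @param events The event tibble the episode was derived from.
#' @param period `"baseline"` or `"followup"`.
#' @return A one-row tibble with columns `period, n_visits, inter_visit_mean,
#'   inter_visit_sd, n_distinct_psychiatric_molecules,
#'   n_hypnotic_prescriptions, n_somatic_prescriptions,
#'   n_distinct_somatic_comorbidities, ad_mean_daily_dose`.
#' @export
summarize_period <- function(episode, events, period = c("baseline", "followup")) {
  period <- match.arg(period)
  episode <- as.list(episode[1, ])
  events <- dplyr::mutate(events, date = as.Date(.data$date))
  pev <- dplyr::filter(events, .data$patient_id == episode$patient_id)
  win <- period_window(episode, period)
  wev <- dplyr::filter(pev, .data$date >= win[1], .data$date <= win[2])
  idx_mol <- index_molecule(episode, pev)
  visits <- sort(unique(wev$date[wev$event_type == "gp_visit"]))
  gaps <- if (length(visits) >= 3) as.numeric(diff(visits)) else numeric(0)
  ad_rx <- dplyr::filter(wev, .data$event_type == "ad_prescription",
                         !is.na(.data$molecule), .data$molecule == idx_mol)
  tibble::tibble(
    period = period,
    n_visits = length(visits),
    inter_visit_mean = if (length(gaps)) mean(gaps) else NA_real_,
    inter_visit_sd = if (length(gaps)) sd(gaps) else NA_real_,
    n_distinct_psychiatric_molecules = dplyr::n_distinct(
      wev$molecule[wev$event_type == "psychiatric_prescription"], na.rm = TRUE),
    n_hypnotic_prescriptions = sum(wev$event_type == "hypnotic_prescription"),
    n_somatic_prescriptions = sum(wev$event_type == "somatic_prescription"),
    n_distinct_somatic_comorbidities = dplyr::n_distinct(
      wev$code[wev$event_type == "somatic_comorbidity_diagnosis"], na.rm = TRUE),
    ad_mean_daily_dose = weighted_dose(ad_rx)
  )
}

period_window <- function(episode, period) {
  if (period == "baseline") {
    c(episode$baseline_start, episode$baseline_end)
  } else {
    fe <- episode$followup_end
    if (!is.null(episode$death_date) && !is.na(episode$death_date) &&
        episode$death_date >= episode$followup_start &&
        episode$death_date < fe) {
      fe <- episode$death_date
    }
    c(episode$followup_start, fe)
  }
}

index_molecule <- function(episode, pev) {
  mols <- pev$molecule[pev$event_type == "ad_prescription" &
                         pev$date == episode$index_date]
  mols <- unique(mols[!is.na(mols)])
  if (length(mols) >= 1) mols[1] else NA_character_
}

#' Detect the 29 binary clinical parameters for each episode
#'
#' Evaluates the ten improvement flags `X1..X10` and nineteen worsening flags
#' `Y1..Y19` for every episode, from the raw event table. Incident flags
#' record the presence of the corresponding event in the follow-up window;
#' relative flags compare follow-up against baseline (strict inequalities:
#' equal counts set neither the decrease nor the increase flag); the
#' treatment-pattern flags (switch `Y7`, combination `Y11`, augmentation
#' `Y12`, relapse-type `Y13`) use prescription-interval arithmetic with the
#' stop of an antidepressant defined as its last prescription date plus
#' coverage days. Comparisons that are undefined (for example fewer than
#' three visits in a period for the inter-visit gap statistics, or no dose
#' reference) yield 0.
#'
#' @param episodes Tibble from [select_episodes()].
#' @param events The event tibble the episodes were derived from.
#' @return A tibble with `episode_id` and 29 integer 0/1 columns
#'   `X1..X10, Y1..Y19`.
#' @export
#' @examples
#' ev <- generate_event_stream(dhsi_sim_config(n_patients = 30, seed = 2))
#' eps <- select_episodes(ev)
#' detect_parameters(eps, ev)
detect_parameters <- function(episodes, events) {
  events <- dplyr::mutate(events, date = as.Date(.data$date))
  rows <- purrr::map(seq_len(nrow(episodes)), function(i) {
    e <- episodes[i, ]
    pev <- dplyr::filter(events, .data$patient_id == e$patient_id)
    v <- detect_one(as.list(e), pev)
    tibble::tibble(episode_id = e$episode_id, !!!as.list(v))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(episode_id = character(),
                          !!!setNames(rep(list(integer()), 29),
                                      dhsi_parameter_ids()))
  }
  out
}

# all 29 flags for one episode; pev = that patient's events, dates as Date
detect_one <- function(e, pev) {
  ids <- dhsi_parameter_ids()
  v <- setNames(rep(0L, 29), ids)
  bs <- e$baseline_start; be <- e$baseline_end
  fs <- e$followup_start; fe <- e$followup_end
  idx_mol <- index_molecule(e, pev)

  in_fu <- function(d) d >= fs & d <= fe
  fu <- dplyr::filter(pev, in_fu(.data$date))
  base <- dplyr::filter(pev, .data$date >= bs, .data$date <= be)
  obs <- dplyr::filter(pev, .data$date >= bs, .data$date <= fe)

  sb <- summarize_period(tibble::as_tibble(e[c("patient_id", "index_date",
                                               "baseline_start", "baseline_end",
                                               "followup_start", "followup_end",
                                               "death_date")]),
                         pev, "baseline")
  sf <- summarize_period(tibble::as_tibble(e[c("patient_id", "index_date",
                                               "baseline_start", "baseline_end",
                                               "followup_start", "followup_end",
                                               "death_date")]),
                         pev, "followup")

  # --- incident flags (presence in follow-up) ---
  has_fu <- function(type) as.integer(any(fu$event_type == type))
  v["Y1"] <- has_fu("death")
  v["Y2"] <- has_fu("psychiatric_hospitalization")
  v["Y3"] <- has_fu("suicide_attempt")
  v["Y4"] <- has_fu("ect")
  v["Y5"] <- has_fu("psychiatrist_referral")
  v["Y6"] <- has_fu("sick_leave")
  v["Y8"] <- has_fu("pregnancy_termination")
  v["Y19"] <- has_fu("other_hospitalization")
  # new psychiatric comorbidity: follow-up code absent from baseline
  fu_pcom <- unique(fu$code[fu$event_type == "psychiatric_comorbidity_diagnosis"])
  base_pcom <- unique(base$code[base$event_type == "psychiatric_comorbidity_diagnosis"])
  v["Y10"] <- as.integer(length(setdiff(fu_pcom, base_pcom)) > 0)
  # pregnancy over the whole observation span, excluding terminated/delivered
  v["X9"] <- as.integer(
    any(obs$event_type == "pregnancy_record") &&
      !any(obs$event_type %in% c("pregnancy_termination", "delivery")))

  # --- visit-pattern flags ---
  fu_visits <- sort(unique(fu$date[fu$event_type == "gp_visit"]))
  psy_like <- c("ad_prescription", "psychiatric_prescription")
  if (length(fu_visits) >= 2) {
    for (k in seq_len(length(fu_visits) - 1)) {
      pair <- fu_visits[c(k, k + 1)]
      later_psy <- any(fu$event_type %in% psy_like & fu$date > pair[2])
      if (later_psy) next
      on_pair <- fu[fu$date %in% pair, ]
      if (!any(on_pair$event_type == "ad_prescription")) v["X1"] <- 1L
      if (!any(on_pair$event_type == "psychiatric_prescription")) v["X2"] <- 1L
      if (v["X1"] == 1L && v["X2"] == 1L) break
    }
  }
  if (!is.na(sb$inter_visit_mean) && !is.na(sf$inter_visit_mean) &&
      !is.na(sb$inter_visit_sd)) {
    v["X3"] <- as.integer(sf$inter_visit_mean >= sb$inter_visit_mean + sb$inter_visit_sd)
    v["Y14"] <- as.integer(sf$inter_visit_mean <= sb$inter_visit_mean - sb$inter_visit_sd)
  }
  # depression codes present in follow-up but not at the last visit(s)
  fu_dep <- fu$date[fu$event_type == "depression_diagnosis"]
  if (length(fu_dep) > 0) {
    last_visit <- if (length(fu_visits)) max(fu_visits) else as.Date(NA)
    v["X5"] <- as.integer(is.na(last_visit) || !any(fu_dep == last_visit))
  }

  # --- strict count comparisons, follow-up vs baseline ---
  cmp <- function(fu_n, base_n, lower, higher) {
    v[lower] <<- as.integer(fu_n < base_n)
    v[higher] <<- as.integer(fu_n > base_n)
  }
  cmp(sf$n_distinct_psychiatric_molecules, sb$n_distinct_psychiatric_molecules,
      "X4", "Y9")
  cmp(sf$n_distinct_somatic_comorbidities, sb$n_distinct_somatic_comorbidities,
      "X6", "Y16")
  cmp(sf$n_hypnotic_prescriptions, sb$n_hypnotic_prescriptions, "X7", "Y17")
  cmp(sf$n_somatic_prescriptions, sb$n_somatic_prescriptions, "X8", "Y18")

  # --- dose change for an unmodified molecule ---
  ad_obs <- dplyr::filter(obs, .data$event_type == "ad_prescription",
                          !is.na(.data$molecule))
  if (!is.na(idx_mol) && nrow(ad_obs) > 0 && all(ad_obs$molecule == idx_mol)) {
    ref_rx <- dplyr::filter(ad_obs, .data$date >= be - 30, .data$date <= be)
    ref_dose <- weighted_dose(ref_rx)
    fu_dose <- sf$ad_mean_daily_dose
    if (!is.na(ref_dose) && !is.na(fu_dose)) {
      v["X10"] <- as.integer(fu_dose < ref_dose)
      v["Y15"] <- as.integer(fu_dose > ref_dose)
    }
  }

  # --- treatment-pattern flags ---
  ad_all <- dplyr::filter(pev, .data$event_type == "ad_prescription",
                          !is.na(.data$molecule), .data$date >= bs,
                          .data$date <= fe)
  cov <- ifelse(is.na(ad_all$coverage_days), 0L, ad_all$coverage_days)
  if (!is.na(idx_mol)) {
    init <- ad_all[ad_all$molecule == idx_mol & ad_all$date >= e$index_date, ]
    if (nrow(init) > 0) {
      init_cov <- ifelse(is.na(init$coverage_days), 0L, init$coverage_days)
      initial_stop <- max(as.numeric(init$date) + init_cov)
      others <- ad_all[ad_all$molecule != idx_mol & ad_all$date > e$index_date, ]
      if (nrow(others) > 0) {
        # switch: first prescription of another AD near the initial stop,
        # inside follow-up
        for (m in unique(others$molecule)) {
          t_m <- min(as.numeric(others$date[others$molecule == m]))
          if (t_m >= initial_stop - 31 && t_m <= initial_stop + 183 &&
              t_m >= as.numeric(fs) && t_m <= as.numeric(fe)) {
            v["Y7"] <- 1L
            break
          }
        }
        # combination: another AD starting well before the initial stop,
        # with overlap observed in follow-up
        early <- others[as.numeric(others$date) <= initial_stop - 31, ]
        if (nrow(early) > 0 &&
            intervals_overlap_in(early, init, fs, fe)) {
          v["Y11"] <- 1L
        }
      }
    }
    # augmentation: antipsychotic/lithium starting > 31 d before the stop of
    # some AD it overlaps during follow-up
    ap <- dplyr::filter(pev, .data$event_type == "antipsychotic_or_lithium_prescription",
                        .data$date > e$index_date, .data$date <= fe)
    if (nrow(ap) > 0 && nrow(ad_all) > 0) {
      for (m in unique(ad_all$molecule)) {
        rx_m <- ad_all[ad_all$molecule == m, ]
        cov_m <- ifelse(is.na(rx_m$coverage_days), 0L, rx_m$coverage_days)
        stop_m <- max(as.numeric(rx_m$date) + cov_m)
        ap_early <- ap[as.numeric(ap$date) <= stop_m - 31, ]
        if (nrow(ap_early) > 0 && intervals_overlap_in(ap_early, rx_m, fs, fe)) {
          v["Y12"] <- 1L
          break
        }
      }
    }
  }
  # relapse-type: a psychiatric treatment 45-183 d after a previous AD stop
  if (nrow(ad_all) > 0) {
    un <- merge_intervals(as.numeric(ad_all$date), as.numeric(ad_all$date) + cov)
    psy_rx <- dplyr::filter(pev, .data$event_type %in% PSY_TREATMENT_TYPES,
                            .data$date >= bs, .data$date <= fe)
    for (t in as.numeric(psy_rx$date)) {
      if (any(t - un$end >= 45 & t - un$end <= 183)) {
        v["Y13"] <- 1L
        break
      }
    }
  }
  v
}

# do any two prescriptions from a and b overlap in time inside [fs, fe]?
intervals_overlap_in <- function(a, b, fs, fe) {
  ca <- ifelse(is.na(a$coverage_days), 0L, a$coverage_days)
  cb <- ifelse(is.na(b$coverage_days), 0L, b$coverage_days)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      lo <- max(as.numeric(a$date[i]), as.numeric(b$date[j]), as.numeric(fs))
      hi <- min(as.numeric(a$date[i]) + ca[i],
                as.numeric(b$date[j]) + cb[j], as.numeric(fe))
      if (lo <= hi) return(TRUE)
    }
  }
  FALSE
}
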