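#' Simulation configuration for synthetic primary-care event streams
#'
#' Bundles every knob of the synthetic data generator: cohort size, study
#' window, visit intensity, antidepressant initiation, the latent-severity
#' model that couples the 29 binary parameters to each other and to the
#' remission proxy, and the seed.
#'
#' The generator assumes a single latent severity scalar per episode
#' (standard normal scale, standard deviation `severity_sd`). Each
#' parameter's marginal probability is `clamp(prevalence + loading * severity)`
#' where improvement-type parameters (`X*`) carry negative loadings and
#' worsening-type parameters (`Y*`) carry positive ones, so that more severe
#' episodes show more worsening features, fewer improvement features, and a
#' lower chance of the prescription-gap remission proxy.
#'
#' @param n_patients Number of simulated patients (non-negative integer).
#' @param study_start,study_end Study window (coerced with [as.Date()]).
#' @param visit_rate Mean GP visits per 30 days (positive).
#' @param ad_initiation_prob Probability a patient starts an antidepressant
#'   episode during the study window.
#' @param severity_sd Standard deviation of the latent severity (>= 0).
#' @param parameter_prevalence Named numeric vector over exactly the 29
#'   parameter ids: baseline Bernoulli probability of each flag.
#' @param severity_loading Named numeric vector over the 29 parameter ids:
#'   signed shift of the flag probability per unit severity.
#' @param remission_base_prob Remission-proxy probability at severity 0.
#' @param remission_severity_slope Decrease in remission probability per unit
#'   severity (probabilities are clamped to \[0, 1\]).
#' @param exclusion_fraction Fraction of patients given a lifetime
#'   bipolar/schizophrenia diagnosis (excluded by cohort selection).
#' @param diagnosis_prob Probability that a depression diagnosis is recorded
#'   within the qualifying window around the index prescription.
#' @param seed Integer seed; every generator call is deterministic given the
#'   config.
#'
#' @return An object of class `dhsi_sim_config` (a named list).
#' @export
#' @examples
#' cfg <- dhsi_sim_config(n_patients = 20, seed = 1)
#' cfg$visit_rate
dhsi_sim_config <- function(n_patients = 500,
                            study_start = "2006-01-01",
                            study_end = "2012-12-31",
                            visit_rate = 1.0,
                            ad_initiation_prob = 0.6,
                            severity_sd = 1,
                            parameter_prevalence = default_parameter_prevalence(),
                            severity_loading = default_severity_loading(),
                            remission_base_prob = 0.65,
                            remission_severity_slope = 0.18,
                            exclusion_fraction = 0.03,
                            diagnosis_prob = 0.9,
                            seed = 1L) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  stopifnot(
    length(n_patients) == 1, n_patients >= 0, n_patients == floor(n_patients),
    study_end > study_start,
    visit_rate > 0,
    severity_sd >= 0
  )
  ids <- dhsi_parameter_ids()
  if (!setequal(names(parameter_prevalence), ids)) {
    stop("`parameter_prevalence` must be named by exactly the 29 parameter ids",
         call. = FALSE)
  }
  if (!setequal(names(severity_loading), ids)) {
    stop("`severity_loading` must be named by exactly the 29 parameter ids",
         call. = FALSE)
  }
  probs <- c(ad_initiation_prob, parameter_prevalence, remission_base_prob,
             exclusion_fraction, diagnosis_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      study_start = study_start,
      study_end = study_end,
      visit_rate = visit_rate,
      ad_initiation_prob = ad_initiation_prob,
      severity_sd = severity_sd,
      parameter_prevalence = parameter_prevalence[ids],
      severity_loading = severity_loading[ids],
      remission_base_prob = remission_base_prob,
      remission_severity_slope = remission_severity_slope,
      exclusion_fraction = exclusion_fraction,
      diagnosis_prob = diagnosis_prob,
      seed = as.integer(seed)
    ),
    class = "dhsi_sim_config"
  )
}

#' Default marginal prevalences of the 29 parameters
#'
#' Baseline flag probabilities at severity zero. Improvement features sit in
#' the 0.10-0.35 range typical of mixed primary-care depression cohorts;
#' severe incident events (death, ECT, suicide attempt) are rare.
#'
#' @return Named numeric vector over the 29 parameter ids.
#' @export
default_parameter_prevalence <- function() {
  c(
    X1 = 0.35, X2 = 0.30, X3 = 0.20, X4 = 0.15, X5 = 0.25,
    X6 = 0.15, X7 = 0.12, X8 = 0.20, X9 = 0.02, X10 = 0.10,
    Y1 = 0.005, Y2 = 0.012, Y3 = 0.010, Y4 = 0.003, Y5 = 0.05,
    Y6 = 0.04, Y7 = 0.10, Y8 = 0.005, Y9 = 0.12, Y10 = 0.06,
    Y11 = 0.05, Y12 = 0.04, Y13 = 0.10, Y14 = 0.15, Y15 = 0.10,
    Y16 = 0.15, Y17 = 0.10, Y18 = 0.20, Y19 = 0.05
  )
}

#' Default severity loadings of the 29 parameters
#'
#' Signed probability shift per unit latent severity: negative for
#' improvement features (they become rarer as severity rises), positive for
#' worsening features. Rare events get proportionally smaller loadings so
#' their probabilities stay in range for typical severities.
#'
#' @return Named numeric vector over the 29 parameter ids.
#' @export
default_severity_loading <- function() {
  c(
    X1 = -0.08, X2 = -0.08, X3 = -0.07, X4 = -0.06, X5 = -0.08,
    X6 = -0.05, X7 = -0.04, X8 = -0.05, X9 = -0.005, X10 = -0.04,
    Y1 = 0.003, Y2 = 0.008, Y3 = 0.006, Y4 = 0.002, Y5 = 0.03,
    Y6 = 0.025, Y7 = 0.06, Y8 = 0.003, Y9 = 0.07, Y10 = 0.035,
    Y11 = 0.03, Y12 = 0.025, Y13 = 0.06, Y14 = 0.08, Y15 = 0.06,
    Y16 = 0.08, Y17 = 0.06, Y18 = 0.08, Y19 = 0.03
  )
}

ad_molecules <- c("citalopram", "fluoxetine", "sertraline", "venlafaxine",
                  "mirtazapine", "paroxetine")
psy_molecules <- c("diazepam", "pregabalin", "buspirone", "propranolol")
hypnotic_molecules <- c("zopiclone", "zolpidem", "temazepam")
somatic_molecules <- c("simvastatin", "metformin", "ramipril", "omeprazole",
                       "salbutamol", "levothyroxine")
ap_molecules <- c("quetiapine", "olanzapine", "lithium", "aripiprazole")
somatic_codes <- c("DM2", "HTN", "COPD", "IHD", "OA", "HYPOTHY")
psy_comorb_codes <- c("ANX", "OCD", "PTSD", "EATD")

empty_event_table <- function() {
  tibble::tibble(
    patient_id = character(), date = as.Date(character()),
    event_type = character(), code = character(), drug_class = character(),
    molecule = character(), daily_dose = numeric(), coverage_days = integer(),
    flags = character()
  )
}

event_row <- function(patient_id, date, event_type, code = NA_character_,
                      drug_class = NA_character_, molecule = NA_character_,
                      daily_dose = NA_real_, coverage_days = NA_integer_,
                      flags = NA_character_) {
  tibble::tibble(
    patient_id = patient_id, date = as.Date(date, origin = "1970-01-01"),
    event_type = event_type, code = code, drug_class = drug_class,
    molecule = molecule, daily_dose = daily_dose,
    coverage_days = as.integer(coverage_days), flags = flags
  )
}

#' Generate a synthetic patient event stream
#'
#' Emits one dated clinical event per row for `config$n_patients` simulated
#' patients: GP visits, antidepressant prescriptions (initiation, repeats,
#' stop, switch, combination, augmentation), psychiatric / hypnotic / somatic
#' co-prescriptions, diagnoses, hospitalizations, referrals, sick leave,
#' pregnancy events, ECT, and death. A latent per-patient severity drives the
#' probabilities of worsening-type events and the persistence of
#' antidepressant treatment, so downstream parameter detection and the
#' remission proxy inherit realistic correlation structure.
#'
#' Internal consistency is enforced: prescriptions fall on GP-visit dates
#' (a visit row is added where needed), no event postdates a death, and
#' every patient carries a `birth_year_record`.
#'
#' @param config A [dhsi_sim_config()].
#' @return A tibble of events with columns `patient_id, date, event_type,
#'   code, drug_class, molecule, daily_dose, coverage_days, flags`, sorted by
#'   patient and date. Deterministic given `config` (including its seed).
#' @export
#' @examples
#' ev <- generate_event_stream(dhsi_sim_config(n_patients = 5, seed = 42))
#' dplyr::count(ev, event_type)
generate_event_stream <- function(config) {
  stopifnot(inherits(config, "dhsi_sim_config"))
  if (config$n_patients == 0) {
    return(empty_event_table())
  }
  set.seed(config$seed)
  rows <- purrr::map(seq_len(config$n_patients), function(i) {
    simulate_patient(sprintf("P%05d", i), config)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$patient_id, .data$date,
                 .data$event_type)
}

# one patient's events; consumes RNG sequentially so the stream is
# deterministic given the config seed
simulate_patient <- function(pid, config) {
  span_days <- as.integer(config$study_end - config$study_start)
  reg_start <- config$study_start - sample(0:730, 1)
  reg_end <- reg_start + 1200 + sample(0:1200, 1)
  if (reg_end > config$study_end + 365) reg_end <- config$study_end + 365

  severity <- rnorm(1, 0, config$severity_sd)
  birth_year <- sample(1940:1985, 1)

  # GP visit renewal process, mean gap 30 / visit_rate days
  gaps <- pmax(1, round(rexp(400, rate = config$visit_rate / 30)))
  visits <- reg_start + cumsum(gaps)
  visits <- visits[visits <= reg_end]

  out <- list(
    event_row(pid, reg_start, "birth_year_record", code = as.character(birth_year))
  )

  if (runif(1) < config$exclusion_fraction) {
    excl_type <- if (runif(1) < 0.5) "bipolar_diagnosis" else "schizophrenia_diagnosis"
    out <- c(out, list(event_row(pid, reg_start + sample(0:500, 1), excl_type,
                                 code = "EXCL")))
  }

  # candidate index visit: enough registration before and after
  feasible <- visits[visits >= reg_start + 200 & visits <= reg_end - 290 &
                       visits >= config$study_start & visits <= config$study_end]
  index_date <- NULL
  if (length(feasible) > 0 && runif(1) < config$ad_initiation_prob) {
    index_date <- feasible[1]
  }

  rx_dates <- as.Date(character())
  if (!is.null(index_date)) {
    molecule <- sample(ad_molecules, 1)
    dose <- sample(c(10, 20, 40), 1)
    cover <- 28L
    remit <- runif(1) < clamp01(config$remission_base_prob -
                                  config$remission_severity_slope * severity)
    # treatment length in days: remitters stop early enough to open a
    # >= 45-day prescription gap inside the 92-275 day follow-up window
    tx_len <- if (remit) sample(60:140, 1) else sample(280:320, 1)
    starts <- seq(0, tx_len, by = cover)
    switch_p <- clamp01(0.05 + 0.05 * severity)
    combo_p <- clamp01(0.03 + 0.04 * severity)
    augment_p <- clamp01(0.02 + 0.04 * severity)
    do_switch <- !remit && runif(1) < switch_p && length(starts) > 4
    switch_at <- if (do_switch) sample(3:(length(starts) - 1), 1) else Inf
    molecule2 <- sample(setdiff(ad_molecules, molecule), 1)
    # dose titration: remitters taper, non-remitters often get an increase
    dose_change_at <- if (length(starts) > 3) sample(3:length(starts), 1) else Inf
    dose_factor <- if (remit && runif(1) < 0.3) 0.5
                   else if (!remit && runif(1) < 0.3) 2
                   else 1
    for (k in seq_along(starts)) {
      mol_k <- if (k >= switch_at) molecule2 else molecule
      dose_k <- if (k >= dose_change_at) dose * dose_factor else dose
      d <- index_date + starts[k]
      out <- c(out, list(event_row(pid, d, "ad_prescription", code = "AD",
                                   drug_class = "antidepressant", molecule = mol_k,
                                   daily_dose = dose_k, coverage_days = cover)))
      rx_dates <- c(rx_dates, d)
    }
    if (!do_switch && runif(1) < combo_p && length(starts) > 3) {
      mol_c <- sample(setdiff(ad_molecules, molecule), 1)
      for (k in 2:min(length(starts), 6)) {
        d <- index_date + starts[k]
        out <- c(out, list(event_row(pid, d, "ad_prescription", code = "AD",
                                     drug_class = "antidepressant", molecule = mol_c,
                                     daily_dose = 20, coverage_days = cover)))
        rx_dates <- c(rx_dates, d)
      }
    }
    if (runif(1) < augment_p && length(starts) > 3) {
      mol_a <- sample(ap_molecules, 1)
      for (k in 2:min(length(starts), 8)) {
        d <- index_date + starts[k]
        out <- c(out, list(event_row(pid, d, "antipsychotic_or_lithium_prescription",
                                     code = "AP", drug_class = "antipsychotic",
                                     molecule = mol_a, daily_dose = 5,
                                     coverage_days = cover)))
        rx_dates <- c(rx_dates, d)
      }
    }
    if (runif(1) < config$diagnosis_prob) {
      out <- c(out, list(event_row(pid, index_date, "depression_diagnosis",
                                   code = "DEP")))
    }
    # follow-up depression codes persist more often for severe episodes
    fu_visits <- visits[visits > index_date + 92 & visits <= index_date + 275]
    for (v in as.list(fu_visits)) {
      if (runif(1) < clamp01(0.15 + 0.08 * severity)) {
        out <- c(out, list(event_row(pid, v, "depression_diagnosis", code = "DEP")))
      }
    }
  }

  # per-visit co-prescriptions and diagnoses
  p_psy <- clamp01(0.10 + 0.05 * severity)
  p_hyp <- clamp01(0.08 + 0.04 * severity)
  p_pcom <- clamp01(0.03 + 0.02 * severity)
  for (v in as.list(visits)) {
    if (runif(1) < p_psy) {
      out <- c(out, list(event_row(pid, v, "psychiatric_prescription", code = "PSY",
                                   drug_class = "psychiatric",
                                   molecule = sample(psy_molecules, 1),
                                   daily_dose = 5, coverage_days = 28L)))
    }
    if (runif(1) < p_hyp) {
      out <- c(out, list(event_row(pid, v, "hypnotic_prescription", code = "HYP",
                                   drug_class = "hypnotic",
                                   molecule = sample(hypnotic_molecules, 1),
                                   daily_dose = 7.5, coverage_days = 28L)))
    }
    if (runif(1) < 0.25) {
      out <- c(out, list(event_row(pid, v, "somatic_prescription", code = "SOM",
                                   drug_class = "somatic",
                                   molecule = sample(somatic_molecules, 1),
                                   daily_dose = 10, coverage_days = 28L)))
    }
    if (runif(1) < 0.10) {
      out <- c(out, list(event_row(pid, v, "somatic_comorbidity_diagnosis",
                                   code = sample(somatic_codes, 1))))
    }
    if (runif(1) < p_pcom) {
      out <- c(out, list(event_row(pid, v, "psychiatric_comorbidity_diagnosis",
                                   code = sample(psy_comorb_codes, 1))))
    }
  }

  # rare incident events anywhere in registration
  rare <- function(type, prob, code = type) {
    if (runif(1) < clamp01(prob)) {
      d <- reg_start + sample.int(max(1, as.integer(reg_end - reg_start)), 1)
      list(event_row(pid, d, type, code = code))
    } else {
      list()
    }
  }
  out <- c(out,
           rare("psychiatric_hospitalization", 0.01 + 0.01 * severity, "PHOSP"),
           rare("other_hospitalization", 0.03, "OHOSP"),
           rare("suicide_attempt", 0.005 + 0.005 * severity, "SUIC"),
           rare("ect", 0.002 + 0.002 * severity, "ECT"),
           rare("psychiatrist_referral", 0.04 + 0.03 * severity, "REF"),
           rare("sick_leave", 0.03 + 0.02 * severity, "SICK"))
  if (runif(1) < 0.015) {
    d <- reg_start + sample.int(max(1, as.integer(reg_end - reg_start)), 1)
    out <- c(out, list(event_row(pid, d, "pregnancy_record", code = "PREG")))
    u <- runif(1)
    if (u < 0.15) {
      out <- c(out, list(event_row(pid, d + 60, "pregnancy_termination", code = "TOP")))
    } else if (u < 0.8) {
      out <- c(out, list(event_row(pid, d + 250, "delivery", code = "DLV")))
    }
  }

  death_date <- NULL
  if (runif(1) < 0.006) {
    death_date <- reg_start + sample.int(max(1, as.integer(reg_end - reg_start)), 1)
  }

  ev <- dplyr::bind_rows(out)
  # visits + a visit row for every prescription date not already a visit
  visit_rows <- event_row(pid, unique(c(visits, rx_dates)), "gp_visit", code = "VISIT")
  ev <- dplyr::bind_rows(ev, visit_rows)
  if (!is.null(death_date)) {
    ev <- dplyr::filter(ev, .data$date <= .env$death_date)
    ev <- dplyr::bind_rows(ev, event_row(pid, death_date, "death", code = "DEATH"))
  }
  ev
}

#' Generate an episode-by-parameter binary matrix with latent truth
#'
#' Bypasses event extraction: draws the 29 binary flags directly from the
#' latent-severity model, together with the latent severity and a ground-truth
#' remission flag. Episode `i` has severity `s_i ~ Normal(0, severity_sd)`;
#' parameter `j` is Bernoulli with probability
#' `clamp(prevalence_j + loading_j * s_i)` and the remission flag is Bernoulli
#' with probability `clamp(remission_base_prob - remission_severity_slope * s_i)`,
#' so remission is monotone decreasing in severity by construction.
#'
#' @param n_episodes Number of episodes to draw (>= 1).
#' @param config A [dhsi_sim_config()]; only the severity / prevalence /
#'   loading / remission / seed fields are used.
#' @return A tibble with columns `episode_id`, the 29 parameter flags
#'   `X1..X10, Y1..Y19` (integer 0/1), `remission_truth` (logical) and
#'   `severity` (numeric). Deterministic given `config`.
#' @export
#' @examples
#' m <- generate_parameter_matrix(100, dhsi_sim_config(seed = 7))
#' colMeans(m[dhsi_parameter_ids()])
generate_parameter_matrix <- function(n_episodes, config) {
  stopifnot(inherits(config, "dhsi_sim_config"),
            length(n_episodes) == 1, n_episodes >= 1)
  n_episodes <- as.integer(n_episodes)
  ids <- dhsi_parameter_ids()
  set.seed(config$seed)
  severity <- rnorm(n_episodes, 0, config$severity_sd)
  flags <- purrr::map(ids, function(j) {
    p <- clamp01(config$parameter_prevalence[[j]] +
                   config$severity_loading[[j]] * severity)
    rbinom(n_episodes, 1L, p)
  })
  names(flags) <- ids
  rem_p <- clamp01(config$remission_base_prob -
                     config$remission_severity_slope * severity)
  tibble::tibble(
    episode_id = sprintf("E%06d", seq_len(n_episodes)),
    !!!flags,
    remission_truth = rbinom(n_episodes, 1L, rem_p) == 1L,
    severity = severity
  )
}
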