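# Event-table builders for hand-checked fixtures, independent of the
# package's internal constructors.

fx_events <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(rows)
}

fx_ev <- function(patient_id, date, event_type, code = NA_character_,
                  drug_class = NA_character_, molecule = NA_character_,
                  daily_dose = NA_real_, coverage_days = NA_integer_) {
  tibble::tibble(
    patient_id = patient_id, date = as.Date(date), event_type = event_type,
    code = code, drug_class = drug_class, molecule = molecule,
    daily_dose = daily_dose, coverage_days = as.integer(coverage_days),
    flags = NA_character_
  )
}

fx_visit <- function(pid, date) fx_ev(pid, date, "gp_visit", code = "VISIT")

fx_ad <- function(pid, date, molecule = "citalopram", dose = 20, cover = 28) {
  fx_ev(pid, date, "ad_prescription", code = "AD",
        drug_class = "antidepressant", molecule = molecule,
        daily_dose = dose, coverage_days = cover)
}

# a patient whose single episode passes every inclusion criterion:
# index 2008-03-01, depression diagnosis 9 days later, age 40,
# data span 2007-01-01 .. 2010-01-01
fx_qualifying_patient <- function(pid = "P1", index = "2008-03-01",
                                  birth_year = 1968) {
  idx <- as.Date(index)
  fx_events(
    fx_ev(pid, "2007-01-01", "birth_year_record", code = as.character(birth_year)),
    fx_visit(pid, "2007-01-01"),
    fx_visit(pid, idx),
    fx_ad(pid, idx),
    fx_ev(pid, idx + 9, "depression_diagnosis", code = "DEP"),
    fx_visit(pid, "2010-01-01")
  )
}

# the single episode tibble for a hand-built window, bypassing selection
fx_episode <- function(pid = "P1", index = "2008-03-01", death = NA) {
  idx <- as.Date(index)
  tibble::tibble(
    episode_id = "E000001", patient_id = pid, index_date = idx,
    baseline_start = idx - 152, baseline_end = idx + 31,
    followup_start = idx + 92, followup_end = idx + 275,
    death_date = as.Date(death)
  )
}

# counting-based average ranks, independent of base::rank
oracle_rank_asc <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }, numeric(1))
}

oracle_mean_ranks <- function(pos, neg) {
  (oracle_rank_asc(pos) + oracle_rank_asc(-neg)) / 2
}
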