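test_that("period summaries: empty window, constant gaps, coverage-weighted dose", {
  e <- fx_episode()
  # no events at all in either window
  ev <- fx_events(fx_visit("P1", "2006-01-01"))
  s <- summarize_period(e, ev, "followup")
  expect_equal(s$n_visits, 0)
  expect_true(is.na(s$inter_visit_mean))
  expect_equal(s$n_hypnotic_prescriptions, 0)
  expect_true(is.na(s$ad_mean_daily_dose))

  # three visits at days 0, 30, 60 of the follow-up window
  fs <- e$followup_start
  ev <- fx_events(fx_visit("P1", fs), fx_visit("P1", fs + 30),
                  fx_visit("P1", fs + 60))
  s <- summarize_period(e, ev, "followup")
  expect_equal(s$inter_visit_mean, 30)
  expect_equal(s$inter_visit_sd, 0)

  # coverage-weighted mean dose: (20*30 + 40*30) / 60 = 30
  ev <- fx_events(fx_ad("P1", e$index_date, dose = 20, cover = 30),
                  fx_ad("P1", e$index_date + 30, dose = 40, cover = 30))
  s <- summarize_period(e, ev, "baseline")
  expect_equal(s$ad_mean_daily_dose, 30)
})

test_that("the catalog is complete: 29 binary flags, 10 positive and 19 negative", {
  ids <- dhsi_parameter_ids()
  expect_length(ids, 29)
  expect_equal(sum(startsWith(ids, "X")), 10)
  expect_equal(sum(startsWith(ids, "Y")), 19)

  e <- fx_episode()
  ev <- fx_qualifying_patient()
  flags <- detect_parameters(e, ev)
  expect_setequal(setdiff(names(flags), "episode_id"), ids)
  expect_true(all(as.matrix(flags[ids]) %in% c(0L, 1L)))
})

test_that("incident flags record follow-up events", {
  e <- fx_episode()
  fs <- e$followup_start
  cases <- list(
    list(type = "psychiatric_hospitalization", flag = "Y2"),
    list(type = "suicide_attempt", flag = "Y3"),
    list(type = "ect", flag = "Y4"),
    list(type = "psychiatrist_referral", flag = "Y5"),
    list(type = "sick_leave", flag = "Y6"),
    list(type = "pregnancy_termination", flag = "Y8"),
    list(type = "other_hospitalization", flag = "Y19")
  )
  for (cs in cases) {
    ev <- fx_events(fx_ad("P1", e$index_date),
                    fx_ev("P1", fs + 10, cs$type, code = "EVT"))
    v <- detect_parameters(e, ev)
    expect_equal(v[[cs$flag]], 1L, info = cs$flag)
    # same event before follow-up does not fire the flag
    ev2 <- fx_events(fx_ad("P1", e$index_date),
                     fx_ev("P1", e$index_date + 10, cs$type, code = "EVT"))
    expect_equal(detect_parameters(e, ev2)[[cs$flag]], 0L, info = cs$flag)
  }
  # death in follow-up
  ev <- fx_events(fx_ad("P1", e$index_date),
                  fx_ev("P1", fs + 5, "death", code = "DEATH"))
  expect_equal(detect_parameters(e, ev)$Y1, 1L)
})

test_that("a new psychiatric comorbidity must be absent from baseline", {
  e <- fx_episode()
  ev_new <- fx_events(fx_ev("P1", e$followup_start + 3,
                            "psychiatric_comorbidity_diagnosis", code = "ANX"))
  expect_equal(detect_parameters(e, ev_new)$Y10, 1L)
  ev_old <- dplyr::bind_rows(
    ev_new,
    fx_ev("P1", e$index_date, "psychiatric_comorbidity_diagnosis", code = "ANX"))
  expect_equal(detect_parameters(e, ev_old)$Y10, 0L)
})

test_that("identical baseline and follow-up counts set no relative flag", {
  e <- fx_episode()
  bs <- e$baseline_start; fs <- e$followup_start
  ev <- fx_events(
    fx_ev("P1", bs + 5, "hypnotic_prescription", molecule = "zopiclone"),
    fx_ev("P1", fs + 5, "hypnotic_prescription", molecule = "zopiclone"),
    fx_ev("P1", bs + 6, "somatic_prescription", molecule = "metformin"),
    fx_ev("P1", fs + 6, "somatic_prescription", molecule = "metformin"),
    fx_ev("P1", bs + 7, "psychiatric_prescription", molecule = "diazepam"),
    fx_ev("P1", fs + 7, "psychiatric_prescription", molecule = "diazepam"),
    fx_ev("P1", bs + 8, "somatic_comorbidity_diagnosis", code = "HTN"),
    fx_ev("P1", fs + 8, "somatic_comorbidity_diagnosis", code = "HTN")
  )
  v <- detect_parameters(e, ev)
  for (f in c("X4", "X6", "X7", "X8", "Y9", "Y16", "Y17", "Y18")) {
    expect_equal(v[[f]], 0L, info = f)
  }
})

test_that("count comparisons fire strictly and agree with a direct recount", {
  e <- fx_episode()
  bs <- e$baseline_start; fs <- e$followup_start
  ev <- fx_events(
    # two baseline hypnotics vs one in follow-up: X7
    fx_ev("P1", bs + 1, "hypnotic_prescription", molecule = "zopiclone"),
    fx_ev("P1", bs + 20, "hypnotic_prescription", molecule = "zopiclone"),
    fx_ev("P1", fs + 1, "hypnotic_prescription", molecule = "zopiclone"),
    # one baseline somatic vs three in follow-up: Y18
    fx_ev("P1", bs + 2, "somatic_prescription", molecule = "metformin"),
    fx_ev("P1", fs + 2, "somatic_prescription", molecule = "metformin"),
    fx_ev("P1", fs + 12, "somatic_prescription", molecule = "ramipril"),
    fx_ev("P1", fs + 22, "somatic_prescription", molecule = "ramipril"),
    # two distinct psychiatric molecules at baseline vs one in follow-up: X4
    fx_ev("P1", bs + 3, "psychiatric_prescription", molecule = "diazepam"),
    fx_ev("P1", bs + 4, "psychiatric_prescription", molecule = "buspirone"),
    fx_ev("P1", fs + 3, "psychiatric_prescription", molecule = "diazepam"),
    # 0 baseline somatic comorbidities vs 2 distinct in follow-up: Y16
    fx_ev("P1", fs + 4, "somatic_comorbidity_diagnosis", code = "HTN"),
    fx_ev("P1", fs + 5, "somatic_comorbidity_diagnosis", code = "DM2")
  )
  v <- detect_parameters(e, ev)
  expect_equal(v$X7, 1L); expect_equal(v$Y17, 0L)
  expect_equal(v$Y18, 1L); expect_equal(v$X8, 0L)
  expect_equal(v$X4, 1L); expect_equal(v$Y9, 0L)
  expect_equal(v$Y16, 1L); expect_equal(v$X6, 0L)
})

test_that("visit-gap flags need three visits per period and use baseline mean plus one SD", {
  e <- fx_episode()
  bs <- e$baseline_start; fs <- e$followup_start
  # baseline gaps 10, 20 (mean 15, sd ~7.07); follow-up gaps 40, 40 (mean 40)
  ev <- fx_events(
    fx_visit("P1", bs), fx_visit("P1", bs + 10), fx_visit("P1", bs + 30),
    fx_visit("P1", fs), fx_visit("P1", fs + 40), fx_visit("P1", fs + 80)
  )
  v <- detect_parameters(e, ev)
  expect_equal(v$X3, 1L)  # 40 >= 15 + 7.07
  expect_equal(v$Y14, 0L)
  # swap periods: follow-up gaps shrink
  ev2 <- fx_events(
    fx_visit("P1", bs), fx_visit("P1", bs + 40), fx_visit("P1", bs + 80),
    fx_visit("P1", fs), fx_visit("P1", fs + 10), fx_visit("P1", fs + 20)
  )
  v2 <- detect_parameters(e, ev2)
  expect_equal(v2$X3, 0L)
  expect_equal(v2$Y14, 1L)  # 10 <= 60 - 23.1
  # only two follow-up visits: statistics undefined, both flags 0
  ev3 <- ev[-nrow(ev), ]
  v3 <- detect_parameters(e, ev3)
  expect_equal(v3$X3, 0L)
  expect_equal(v3$Y14, 0L)
})

test_that("depression codes vanish from the last follow-up visit for X5", {
  e <- fx_episode()
  fs <- e$followup_start
  ev <- fx_events(
    fx_visit("P1", fs + 10), fx_visit("P1", fs + 100),
    fx_ev("P1", fs + 10, "depression_diagnosis", code = "DEP")
  )
  expect_equal(detect_parameters(e, ev)$X5, 1L)
  # a code on the last visit defeats X5
  ev2 <- dplyr::bind_rows(ev, fx_ev("P1", fs + 100, "depression_diagnosis",
                                    code = "DEP"))
  expect_equal(detect_parameters(e, ev2)$X5, 0L)
})

test_that("no-AD visit pairs set X1/X2 unless prescriptions follow", {
  e <- fx_episode()
  fs <- e$followup_start
  base <- fx_events(fx_visit("P1", fs + 10), fx_visit("P1", fs + 40))
  v <- detect_parameters(e, base)
  expect_equal(v$X1, 1L)
  expect_equal(v$X2, 1L)
  # an AD on the second visit of the only pair blocks X1 but not X2
  ev2 <- dplyr::bind_rows(base, fx_ad("P1", fs + 40))
  v2 <- detect_parameters(e, ev2)
  expect_equal(v2$X1, 0L)
  expect_equal(v2$X2, 1L)
  # a later psychiatric prescription after the pair blocks both
  ev3 <- dplyr::bind_rows(base, fx_ev("P1", fs + 90, "psychiatric_prescription",
                                      molecule = "diazepam"))
  v3 <- detect_parameters(e, ev3)
  expect_equal(v3$X1, 0L)
  expect_equal(v3$X2, 0L)
})

test_that("switch and combination follow the interval arithmetic of the stop date", {
  e <- fx_episode()
  idx <- e$index_date
  # initial AD: prescriptions covering up to day 100 after index
  initial <- fx_events(
    fx_ad("P1", idx, cover = 50),
    fx_ad("P1", idx + 50, cover = 50)  # stop = idx + 100
  )
  # different molecule first prescribed day 150: inside [stop-31, stop+183]
  # and inside follow-up [92, 275] -> switch, not combination
  ev <- dplyr::bind_rows(initial, fx_ad("P1", idx + 150, molecule = "sertraline",
                                        cover = 28))
  v <- detect_parameters(e, ev)
  expect_equal(v$Y7, 1L)
  expect_equal(v$Y11, 0L)

  # different molecule at day 30 (>31 d before stop), overlapping during
  # follow-up -> combination, not switch
  ev2 <- dplyr::bind_rows(
    fx_ad("P1", idx, cover = 100),
    fx_ad("P1", idx + 100, cover = 100),           # stop = idx + 200
    fx_ad("P1", idx + 30, molecule = "sertraline", cover = 100),
    fx_ad("P1", idx + 130, molecule = "sertraline", cover = 28)
  )
  v2 <- detect_parameters(e, ev2)
  expect_equal(v2$Y11, 1L)
  expect_equal(v2$Y7, 0L)

  # augmentation: antipsychotic starting 31+ d before the AD stop with
  # follow-up overlap
  ev3 <- dplyr::bind_rows(
    fx_ad("P1", idx, cover = 100),
    fx_ad("P1", idx + 100, cover = 100),
    fx_ev("P1", idx + 40, "antipsychotic_or_lithium_prescription",
          molecule = "lithium", coverage_days = 150)
  )
  expect_equal(detect_parameters(e, ev3)$Y12, 1L)
})

test_that("relapse-type prescriptions 45-183 days after an AD stop set Y13", {
  e <- fx_episode()
  idx <- e$index_date
  # AD covered to day 60; psychiatric prescription at day 120 = 60 d later
  ev <- fx_events(
    fx_ad("P1", idx, cover = 60),
    fx_ev("P1", idx + 120, "psychiatric_prescription", molecule = "diazepam")
  )
  expect_equal(detect_parameters(e, ev)$Y13, 1L)
  # only 30 days after the stop: too soon to be a relapse-type event
  ev2 <- fx_events(
    fx_ad("P1", idx, cover = 60),
    fx_ev("P1", idx + 90, "psychiatric_prescription", molecule = "diazepam")
  )
  expect_equal(detect_parameters(e, ev2)$Y13, 0L)
  # an AD restart 50 days after the stop is itself a relapse-type event
  ev3 <- fx_events(
    fx_ad("P1", idx, cover = 60),
    fx_ad("P1", idx + 110)
  )
  expect_equal(detect_parameters(e, ev3)$Y13, 1L)
})

test_that("dose change flags compare follow-up to the last baseline month", {
  e <- fx_episode()
  idx <- e$index_date
  # last 31 d of baseline: [idx + 1, idx + 31]; dose 40 there, 20 in follow-up
  ev <- fx_events(
    fx_ad("P1", idx, dose = 40, cover = 28),
    fx_ad("P1", idx + 28, dose = 40, cover = 28),
    fx_ad("P1", idx + 100, dose = 20, cover = 28),
    fx_ad("P1", idx + 128, dose = 20, cover = 28)
  )
  v <- detect_parameters(e, ev)
  expect_equal(v$X10, 1L)
  expect_equal(v$Y15, 0L)
  # dose increase flips the pair
  ev2 <- dplyr::mutate(ev, daily_dose = rev(daily_dose))
  v2 <- detect_parameters(e, ev2)
  expect_equal(v2$X10, 0L)
  expect_equal(v2$Y15, 1L)
  # a different molecule during the observation span disables both flags
  ev3 <- dplyr::bind_rows(ev, fx_ad("P1", idx + 128, molecule = "sertraline"))
  v3 <- detect_parameters(e, ev3)
  expect_equal(v3$X10, 0L)
  expect_equal(v3$Y15, 0L)
})

test_that("pregnancy counts only without termination or delivery", {
  e <- fx_episode()
  ev <- fx_events(fx_ev("P1", e$index_date + 10, "pregnancy_record", code = "PREG"))
  expect_equal(detect_parameters(e, ev)$X9, 1L)
  ev2 <- dplyr::bind_rows(ev, fx_ev("P1", e$index_date + 70,
                                    "pregnancy_termination", code = "TOP"))
  v2 <- detect_parameters(e, ev2)
  expect_equal(v2$X9, 0L)
})

test_that("opposed relative flags are mutually exclusive and events outside the horizon are inert", {
  cfg <- dhsi_sim_config(n_patients = 80, seed = 13)
  ev <- generate_event_stream(cfg)
  eps <- select_episodes(ev)
  flags <- detect_parameters(eps, ev)
  pairs <- list(c("X4", "Y9"), c("X3", "Y14"), c("X6", "Y16"),
                c("X7", "Y17"), c("X8", "Y18"), c("X10", "Y15"))
  for (p in pairs) {
    expect_true(all(flags[[p[1]]] + flags[[p[2]]] <= 1), info = paste(p, collapse = "/"))
  }

  # locality on the hand fixture: an event far outside every window
  e <- fx_episode()
  base <- fx_events(fx_visit("P1", e$followup_start + 10),
                    fx_visit("P1", e$followup_start + 40),
                    fx_ad("P1", e$index_date))
  far <- fx_ev("P1", e$followup_end + 400, "psychiatric_hospitalization",
               code = "PHOSP")
  v0 <- detect_parameters(e, base)
  v1 <- detect_parameters(e, dplyr::bind_rows(base, far))
  expect_equal(v0, v1)
})

test_that("flags on tiny fixtures match a direct window-filter re-implementation", {
  # independent oracle for the count-based and incident flags, written as
  # plain dplyr filters over the raw rows
  oracle <- function(e, ev) {
    fu <- dplyr::filter(ev, date >= e$followup_start, date <= e$followup_end)
    ba <- dplyr::filter(ev, date >= e$baseline_start, date <= e$baseline_end)
    cnt <- function(d, t) sum(d$event_type == t)
    dis <- function(d, t, col) length(unique(na.omit(d[[col]][d$event_type == t])))
    c(
      Y2 = as.integer(cnt(fu, "psychiatric_hospitalization") > 0),
      Y19 = as.integer(cnt(fu, "other_hospitalization") > 0),
      X7 = as.integer(cnt(fu, "hypnotic_prescription") < cnt(ba, "hypnotic_prescription")),
      Y17 = as.integer(cnt(fu, "hypnotic_prescription") > cnt(ba, "hypnotic_prescription")),
      X8 = as.integer(cnt(fu, "somatic_prescription") < cnt(ba, "somatic_prescription")),
      Y18 = as.integer(cnt(fu, "somatic_prescription") > cnt(ba, "somatic_prescription")),
      X4 = as.integer(dis(fu, "psychiatric_prescription", "molecule") <
                        dis(ba, "psychiatric_prescription", "molecule")),
      Y9 = as.integer(dis(fu, "psychiatric_prescription", "molecule") >
                        dis(ba, "psychiatric_prescription", "molecule"))
    )
  }
  set.seed(42)
  e <- fx_episode()
  types <- c("psychiatric_hospitalization", "other_hospitalization",
             "hypnotic_prescription", "somatic_prescription",
             "psychiatric_prescription")
  mols <- c("diazepam", "buspirone", NA)
  for (rep in 1:25) {
    n <- sample(3:15, 1)
    ev <- purrr::map(seq_len(n), function(i) {
      fx_ev("P1", e$baseline_start + sample(0:430, 1), sample(types, 1),
            code = "C", molecule = sample(mols, 1))
    }) |> dplyr::bind_rows()
    got <- detect_parameters(e, ev)
    want <- oracle(e, ev)
    for (f in names(want)) {
      expect_equal(got[[f]], unname(want[f]), info = paste("rep", rep, f))
    }
  }
})
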