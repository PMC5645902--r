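#' Random learning/test split of episodes
#'
#' Uniform random partition without replacement: `round((1 - fraction) * n)`
#' episodes go to the test sample, the rest to the learning sample.
#' Deterministic given `seed`.
#'
#' @param episode_ids Vector of episode identifiers (n >= 10).
#' @param fraction Learning fraction in (0, 1); default 0.9.
#' @param seed Integer seed.
#' @return Tibble `episode_id, sample` with `sample` in
#'   `{"learning", "test"}`.
#' @export
#' @examples
#' split_learning_test(sprintf("E%02d", 1:20), seed = 1)
split_learning_test <- function(episode_ids, fraction = 0.9, seed) {
  n <- length(episode_ids)
  stopifnot(n >= 10)
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  n_test <- round((1 - fraction) * n)
  set.seed(seed)
  test_idx <- sample.int(n, n_test)
  tibble::tibble(
    episode_id = episode_ids,
    sample = ifelse(seq_len(n) %in% test_idx, "test", "learning")
  )
}

#' Residual summary of a model on an independently ranked test sample
#'
#' Compares the test episodes' rank-derived index (computed within the test
#' sample alone, with no reference to the learning sample) to the model's
#' predictions. Residuals are `ranking score - predicted score`. The residual
#' standard error is `sqrt(sum(r^2) / (n - 1))`, i.e. dispersion about zero.
#'
#' @param model A `dhsi_model`.
#' @param test_flags Tibble of test-episode parameter flags.
#' @param test_dhsi Numeric vector: the test episodes' own rank-derived index.
#' @return One-row tibble `residual_se, mean, median, iqr_low, iqr_high,
#'   min, max`.
#' @export
evaluate_on_test <- function(model, test_flags, test_dhsi) {
  if (nrow(test_flags) == 0) stop("empty test set", call. = FALSE)
  stopifnot(length(test_dhsi) == nrow(test_flags))
  pred <- predict_dhsi(model, test_flags)
  r <- test_dhsi - as.numeric(pred)
  qs <- unname(quantile(r, c(0.25, 0.75)))
  tibble::tibble(
    residual_se = sqrt(sum(r^2) / max(1, length(r) - 1)),
    mean = mean(r), median = median(r),
    iqr_low = qs[1], iqr_high = qs[2],
    min = min(r), max = max(r)
  )
}

#' Prescription-gap remission proxy
#'
#' An episode counts as remitted when the follow-up window contains a span of
#' 45 days or more not covered by any antidepressant prescription (coverage
#' runs from the prescription date for `coverage_days` days). Gaps abutting
#' the window edges count; the 45-day boundary is inclusive.
#'
#' @param episodes Tibble from [select_episodes()].
#' @param events The event tibble.
#' @return Tibble `episode_id, remission` (logical).
#' @export
remission_proxy <- function(episodes, events) {
  events <- dplyr::mutate(events, date = as.Date(.data$date))
  rows <- purrr::map(seq_len(nrow(episodes)), function(i) {
    e <- as.list(episodes[i, ])
    ad <- dplyr::filter(events, .data$patient_id == e$patient_id,
                        .data$event_type == "ad_prescription")
    tibble::tibble(episode_id = e$episode_id,
                   remission = has_ad_free_gap(ad, e$followup_start,
                                               e$followup_end, 45))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) out <- tibble::tibble(episode_id = character(),
                                            remission = logical())
  out
}

# TRUE when [fs, fe] contains an uncovered stretch of >= gap days
has_ad_free_gap <- function(ad, fs, fe, gap) {
  fs <- as.numeric(fs); fe <- as.numeric(fe)
  if (nrow(ad) == 0) return((fe - fs) >= gap)
  cov <- ifelse(is.na(ad$coverage_days), 0, ad$coverage_days)
  s <- as.numeric(ad$date)
  e <- s + cov
  keep <- e > fs & s < fe
  if (!any(keep)) return((fe - fs) >= gap)
  mi <- merge_intervals(pmax(s[keep], fs), pmin(e[keep], fe))
  free <- c(mi$start[1] - fs,
            if (length(mi$start) > 1) mi$start[-1] - mi$end[-length(mi$end)],
            fe - mi$end[length(mi$end)])
  any(free >= gap)
}

#' Quartile report of the index with remission rates
#'
#' Partitions episodes into four groups at the empirical 25/50/75 percentiles
#' of the index (ties assigned to the lower quartile) and reports per-group
#' episode counts, share of the total, observed score range, and the
#' remission-proxy rate.
#'
#' @param scores Numeric index values (n >= 4).
#' @param remission Logical remission flags, same length.
#' @return A tibble of class `dhsi_quartiles` with one row per quartile:
#'   `quartile, n, percent, score_low, score_high, remission_rate`.
#' @export
#' @examples
#' quartile_report(1:100, rep(c(FALSE, TRUE), 50))
quartile_report <- function(scores, remission) {
  stopifnot(length(scores) >= 4, length(remission) == length(scores))
  if (length(unique(scores)) < 4) {
    warning("fewer than 4 distinct scores; quartiles are degenerate",
            call. = FALSE)
  }
  qs <- quantile(scores, c(0.25, 0.5, 0.75))
  grp <- 1L + (scores > qs[1]) + (scores > qs[2]) + (scores > qs[3])
  out <- tibble::tibble(score = scores, remission = remission,
                        quartile = factor(grp, levels = 1:4,
                                          labels = paste0("Q", 1:4))) |>
    dplyr::group_by(.data$quartile, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      score_low = if (dplyr::n() > 0) min(.data$score) else NA_real_,
      score_high = if (dplyr::n() > 0) max(.data$score) else NA_real_,
      remission_rate = mean(.data$remission),
      .groups = "drop"
    ) |>
    dplyr::mutate(percent = 100 * .data$n / length(scores),
                  .after = "n")
  class(out) <- c("dhsi_quartiles", class(out))
  out
}
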