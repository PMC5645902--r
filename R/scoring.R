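#' Positive and negative pre-scores from parameter flags
#'
#' Sums the weights (`value_code * 6^exponent`) of the parameters present in
#' each episode, separately over the improvement (`X*`) and worsening (`Y*`)
#' parameters. Weights are exact integers; the largest attainable positive
#' pre-score under the default scheme is 51,078 and pre-scores of the
#' all-zero vector are (0, 0).
#'
#' @param flags Tibble with an `episode_id` column (optional) and the 29
#'   binary columns `X1..X10, Y1..Y19`.
#' @param weights Weight scheme tibble; defaults to [default_weight_scheme()].
#' @return The input tibble's `episode_id` (generated when absent) with
#'   `pos_prescore` and `neg_prescore` columns.
#' @export
#' @examples
#' m <- generate_parameter_matrix(5, dhsi_sim_config(seed = 3))
#' pre_scores(m)
pre_scores <- function(flags, weights = default_weight_scheme()) {
  ids <- dhsi_parameter_ids()
  missing <- setdiff(ids, names(flags))
  if (length(missing) > 0) {
    stop("missing parameter columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(flags[ids])
  if (!all(x %in% c(0, 1))) stop("parameter flags must be 0/1", call. = FALSE)
  weights <- validate_weight_scheme(weights)
  w <- weights$weight * (weights$sign == "positive")
  wneg <- weights$weight * (weights$sign == "negative")
  tibble::tibble(
    episode_id = if ("episode_id" %in% names(flags)) flags$episode_id
                 else sprintf("E%06d", seq_len(nrow(flags))),
    pos_prescore = as.numeric(x %*% w),
    neg_prescore = as.numeric(x %*% wneg)
  )
}

#' Dual ranking of episodes by pre-score
#'
#' Ranks episodes in ascending order of positive pre-score (smallest gets
#' rank 1) and in descending order of negative pre-score (largest gets rank
#' 1), averaging ties in both, and takes the arithmetic mean of the two ranks
#' as the merged rank. A higher mean rank indicates a better health state:
#' many improvement features or few worsening ones both push the mean rank
#' up.
#'
#' @param scores Tibble with `pos_prescore` and `neg_prescore` columns (as
#'   from [pre_scores()]).
#' @return The input with `pos_rank`, `neg_rank` and `mean_rank` appended.
#' @export
#' @examples
#' s <- tibble::tibble(pos_prescore = c(50000, 45000, 60000, 55000),
#'                     neg_prescore = c(1000, 15000, 2500, 10000))
#' rank_episodes(s)
rank_episodes <- function(scores) {
  if (nrow(scores) == 0) stop("cannot rank an empty episode set", call. = FALSE)
  dplyr::mutate(
    tibble::as_tibble(scores),
    pos_rank = rank(.data$pos_prescore, ties.method = "average"),
    neg_rank = rank(-.data$neg_prescore, ties.method = "average"),
    mean_rank = (.data$pos_rank + .data$neg_rank) / 2
  )
}

#' Linear normalization of mean ranks to the 0-100 index
#'
#' Maps the smallest mean rank to 0 (worst health state) and the largest to
#' 100 (best), linearly in between: `100 * (r - min) / (max - min)`.
#'
#' @param mean_ranks Numeric vector of mean ranks with at least two distinct
#'   values.
#' @return Numeric vector of index values in \[0, 100\].
#' @export
#' @examples
#' normalize_dhsi(c(3, 1, 3.5, 2.5))
normalize_dhsi <- function(mean_ranks) {
  rng <- range(mean_ranks)
  if (length(mean_ranks) < 2 || rng[1] == rng[2]) {
    stop("normalization needs at least two distinct mean ranks", call. = FALSE)
  }
  100 * (mean_ranks - rng[1]) / (rng[2] - rng[1])
}

#' Score episodes end to end: pre-scores, dual ranking, 0-100 index
#'
#' Convenience pipeline chaining [pre_scores()], [rank_episodes()] and
#' [normalize_dhsi()].
#'
#' @inheritParams pre_scores
#' @return Tibble with `episode_id, pos_prescore, neg_prescore, pos_rank,
#'   neg_rank, mean_rank, dhsi`.
#' @export
#' @examples
#' m <- generate_parameter_matrix(50, dhsi_sim_config(seed = 3))
#' score_episodes(m)
score_episodes <- function(flags, weights = default_weight_scheme()) {
  flags |>
    pre_scores(weights) |>
    rank_episodes() |>
    dplyr::mutate(dhsi = normalize_dhsi(.data$mean_rank))
}
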