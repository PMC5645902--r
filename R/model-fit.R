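#' Fit the initial main-effects linear model of the index
#'
#' Ordinary least squares of the rank-derived 0-100 index on the 29 binary
#' parameters (plus intercept). Exactly collinear columns are detected by a
#' rank-revealing QR decomposition (tolerance 1e-8), dropped before the fit,
#' and recorded in `dropped_terms`.
#'
#' @param flags Tibble with the 29 binary parameter columns (extra columns
#'   are ignored).
#' @param y Numeric response, one value per row of `flags` (the rank-derived
#'   index).
#' @param interactions Optional list of character pairs; each adds the
#'   product of the two named parameters as a regressor (used by
#'   [fit_improved_model()]).
#' @return An object of class `dhsi_model`: intercept, per-term coefficient
#'   tibble, interaction list, dropped terms, and fit statistics (R-squared,
#'   adjusted R-squared, F statistic, residual standard error, residual
#'   five-number summary).
#' @export
#' @examples
#' cfg <- dhsi_sim_config(seed = 5)
#' m <- generate_parameter_matrix(500, cfg)
#' sc <- score_episodes(m)
#' fit <- fit_initial_model(m, sc$dhsi)
#' glance(fit)
fit_initial_model <- function(flags, y, interactions = list()) {
  ids <- dhsi_parameter_ids()
  stopifnot(all(ids %in% names(flags)), length(y) == nrow(flags))
  X <- as.matrix(flags[ids])
  storage.mode(X) <- "double"
  terms <- ids
  for (pair in interactions) {
    stopifnot(length(pair) == 2, all(pair %in% ids))
    X <- cbind(X, X[, pair[1]] * X[, pair[2]])
    terms <- c(terms, paste(sort(pair), collapse = ":"))
  }
  colnames(X) <- terms

  # rank-revealing drop of exactly dependent columns (intercept protected)
  D <- cbind(`(Intercept)` = 1, X)
  qd <- qr(D, tol = 1e-8)
  keep <- sort(qd$pivot[seq_len(qd$rank)])
  dropped <- setdiff(colnames(D), colnames(D)[keep])
  kept_terms <- setdiff(colnames(D)[keep], "(Intercept)")
  Xk <- X[, kept_terms, drop = FALSE]

  df <- as.data.frame(Xk, check.names = FALSE)
  df$.y <- y
  fit <- lm(.y ~ ., data = df)
  co <- coef(fit)
  # belt and braces: lm-aliased terms also count as dropped
  aliased <- names(co)[is.na(co)]
  aliased <- gsub("^`|`$", "", aliased)
  dropped <- union(dropped, aliased)
  kept_terms <- setdiff(kept_terms, aliased)
  co <- co[!is.na(co)]
  names(co) <- gsub("^`|`$", "", names(co))

  sm <- summary(fit)
  res <- stats::residuals(fit)
  n <- length(y)
  p <- length(kept_terms)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else sm$r.squared
  adj <- if (sst == 0) 0 else sm$adj.r.squared
  fstat <- if (!is.null(sm$fstatistic)) unname(sm$fstatistic[1]) else NA_real_
  qs <- unname(quantile(res, c(0, 0.25, 0.5, 0.75, 1)))

  structure(
    list(
      intercept = unname(co["(Intercept)"]),
      coefficients = tibble::tibble(
        term = kept_terms,
        estimate = unname(co[kept_terms]),
        std_error = unname(sm$coefficients[match(kept_terms,
          gsub("^`|`$", "", rownames(sm$coefficients))), "Std. Error"])
      ),
      interactions = purrr::keep(purrr::map(interactions,
                                            ~ paste(sort(.x), collapse = ":")),
                                 ~ .x %in% kept_terms),
      dropped_terms = dropped,
      fit_stats = list(
        r_squared = r2, adjusted_r_squared = adj, f_statistic = fstat,
        residual_standard_error = sm$sigma,
        residual_min = qs[1], residual_q1 = qs[2], residual_median = qs[3],
        residual_q3 = qs[4], residual_max = qs[5]
      ),
      n = n, n_terms = p,
      fitted = unname(stats::fitted(fit)),
      residuals = unname(res)
    ),
    class = "dhsi_model"
  )
}

#' Fit the improved model with tree-discovered interaction terms
#'
#' Adds one product regressor per interaction pair to the main-effects
#' design, drops exactly collinear columns (rank-revealing QR, tolerance
#' 1e-8; dropped main effects and interactions are logged in
#' `dropped_terms`), and refits by ordinary least squares. With an empty
#' interaction list this reduces to [fit_initial_model()].
#'
#' @inheritParams fit_initial_model
#' @param interactions List of character pairs of parameter ids, e.g. from
#'   [derive_interactions()].
#' @return A `dhsi_model`.
#' @export
fit_improved_model <- function(flags, y, interactions) {
  fit_initial_model(flags, y, interactions = interactions)
}

#' Predict the index from a fitted model
#'
#' Applies the linear model (intercept + main effects + interaction
#' products) to new parameter vectors and clamps predictions to \[0, 100\].
#' The number of clamped predictions is attached as attribute `n_clamped`.
#'
#' @param model A `dhsi_model`.
#' @param flags Tibble with the 29 binary parameter columns.
#' @return Numeric vector of predicted index values in \[0, 100\], with
#'   attribute `n_clamped`.
#' @export
predict_dhsi <- function(model, flags) {
  stopifnot(inherits(model, "dhsi_model"))
  ids <- dhsi_parameter_ids()
  missing <- setdiff(ids, names(flags))
  if (length(missing) > 0) {
    stop("parameter vector must contain all 29 flags; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(flags[ids])
  storage.mode(X) <- "double"
  pred <- rep(model$intercept, nrow(X))
  for (k in seq_len(nrow(model$coefficients))) {
    term <- model$coefficients$term[k]
    beta <- model$coefficients$estimate[k]
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    col <- if (length(parts) == 2) X[, parts[1]] * X[, parts[2]] else X[, term]
    pred <- pred + beta * col
  }
  clamped <- sum(pred < 0 | pred > 100)
  out <- pmin(100, pmax(0, pred))
  attr(out, "n_clamped") <- clamped
  out
}

#' @export
predict.dhsi_model <- function(object, newdata, ...) {
  predict_dhsi(object, newdata)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Coefficient table of a fitted index model
#'
#' @param x A `dhsi_model`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`.
#' @method tidy dhsi_model
#' @export
tidy.dhsi_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "(Intercept)", estimate = x$intercept,
                   std_error = NA_real_),
    x$coefficients
  )
}

#' One-row fit summary of a fitted index model
#'
#' @param x A `dhsi_model`.
#' @param ... Unused.
#' @return One-row tibble of fit statistics.
#' @method glance dhsi_model
#' @export
glance.dhsi_model <- function(x, ...) {
  tibble::as_tibble(x$fit_stats) |>
    dplyr::mutate(n = x$n, n_terms = x$n_terms,
                  n_interactions = length(x$interactions),
                  n_dropped = length(x$dropped_terms))
}

#' @export
print.dhsi_model <- function(x, ...) {
  cat("Depression health state index model\n")
  cat(sprintf("  %d observations, %d terms (%d interaction terms, %d dropped)\n",
              x$n, x$n_terms, length(x$interactions), length(x$dropped_terms)))
  cat(sprintf("  R-squared %.4f (adjusted %.4f), residual SE %.3f\n",
              x$fit_stats$r_squared, x$fit_stats$adjusted_r_squared,
              x$fit_stats$residual_standard_error))
  invisible(x)
}
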