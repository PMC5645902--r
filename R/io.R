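#' Serialize a fitted index model to JSON
#'
#' Writes intercept, coefficients, interaction terms, dropped terms and fit
#' statistics so the model can be reloaded and applied to new episode
#' matrices without refitting.
#'
#' @param model A `dhsi_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dhsi_model <- function(model, path) {
  stopifnot(inherits(model, "dhsi_model"))
  payload <- list(
    intercept = model$intercept,
    coefficients = model$coefficients,
    interactions = model$interactions,
    dropped_terms = model$dropped_terms,
    fit_stats = model$fit_stats,
    n = model$n, n_terms = model$n_terms
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted index model from JSON
#'
#' @param path File written by [write_dhsi_model()].
#' @return A `dhsi_model` (without fitted values or residuals).
#' @export
read_dhsi_model <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(
    list(
      intercept = p$intercept,
      coefficients = tibble::as_tibble(p$coefficients),
      interactions = as.list(p$interactions),
      dropped_terms = unlist(p$dropped_terms) %||% character(0),
      fit_stats = p$fit_stats,
      n = p$n, n_terms = p$n_terms,
      fitted = NULL, residuals = NULL
    ),
    class = "dhsi_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
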