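#' Default lexicographic weight scheme
#'
#' The expert-assigned weights of the 29 parameters: each parameter belongs
#' to an ordered class encoded as a power of 6 (the coefficient `6^exponent`,
#' 6 being the maximum number of parameters sharing a class) and carries an
#' intra-class value code of 1, 2 or 3. The weight of a parameter is
#' `value_code * 6^exponent`; positive-weight parameters (`X*`) feed the
#' positive pre-score and negative-weight parameters (`Y*`) the negative
#' pre-score. The base-6 powers preserve the ordering between classes and the
#' value codes the ordering within a class.
#'
#' @return A tibble with columns `parameter, sign, value_code, exponent,
#'   weight`.
#' @export
#' @examples
#' default_weight_scheme()
default_weight_scheme <- function() {
  w <- tibble::tribble(
    ~parameter, ~value_code, ~exponent,
    "X1", 3L, 5L,
    "X2", 3L, 5L,
    "X3", 3L, 4L,
    "X4", 2L, 3L,
    "X5", 2L, 2L,
    "X6", 1L, 1L,
    "X7", 1L, 1L,
    "X8", 1L, 1L,
    "X9", 1L, 1L,
    "X10", 1L, 1L,
    "Y1", 3L, 10L,
    "Y2", 3L, 9L,
    "Y3", 3L, 9L,
    "Y4", 2L, 8L,
    "Y5", 2L, 8L,
    "Y6", 1L, 7L,
    "Y7", 3L, 6L,
    "Y8", 2L, 5L,
    "Y9", 1L, 4L,
    "Y10", 2L, 3L,
    "Y11", 2L, 3L,
    "Y12", 2L, 3L,
    "Y13", 2L, 3L,
    "Y14", 1L, 2L,
    "Y15", 1L, 1L,
    "Y16", 1L, 0L,
    "Y17", 1L, 0L,
    "Y18", 1L, 0L,
    "Y19", 1L, 0L
  )
  w |>
    dplyr::mutate(
      sign = ifelse(startsWith(.data$parameter, "X"), "positive", "negative"),
      weight = .data$value_code * 6^.data$exponent,
      .after = "parameter"
    ) |>
    validate_weight_scheme()
}

validate_weight_scheme <- function(w) {
  stopifnot(
    setequal(w$parameter, dhsi_parameter_ids()),
    all(w$value_code %in% 1:3),
    all(w$exponent >= 0 & w$exponent <= 10),
    all(w$sign %in% c("positive", "negative"))
  )
  w <- w[match(dhsi_parameter_ids(), w$parameter), ]
  w[c("parameter", "sign", "value_code", "exponent", "weight")]
}

#' Read a weight scheme from YAML or JSON
#'
#' The file holds a list of records with fields `parameter`, `sign`,
#' `value_code` and `exponent`; weights are recomputed as
#' `value_code * 6^exponent`. This makes sensitivity analyses over
#' alternative weightings a configuration change rather than a code change.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A weight-scheme tibble as from [default_weight_scheme()].
#' @export
read_weight_scheme <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    dplyr::bind_rows(lapply(yaml::read_yaml(path), tibble::as_tibble))
  }
  tibble::as_tibble(raw) |>
    dplyr::mutate(value_code = as.integer(.data$value_code),
                  exponent = as.integer(.data$exponent),
                  weight = .data$value_code * 6^.data$exponent) |>
    validate_weight_scheme()
}
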