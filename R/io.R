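# long tibble -> dense response / RT matrices with stable person/item order
assessment_matrices <- function(data) {
  stopifnot(all(c("person_id", "item_id", "response") %in% names(data)))
  persons <- unique(data$person_id)
  items <- unique(data$item_id)
  if (anyDuplicated(data[c("person_id", "item_id")])) {
    stop("Duplicate (person_id, item_id) rows.")
  }
  if (nrow(data) != length(persons) * length(items)) {
    stop("Data are not rectangular: every person must answer every item.")
  }
  n <- match(data$person_id, persons)
  i <- match(data$item_id, items)
  y <- matrix(NA_integer_, length(persons), length(items),
              dimnames = list(persons, items))
  y[cbind(n, i)] <- as.integer(data$response)
  t <- matrix(NA_real_, length(persons), length(items),
              dimnames = list(persons, items))
  if ("rt_seconds" %in% names(data)) t[cbind(n, i)] <- data$rt_seconds
  z <- NULL
  if ("true_class" %in% names(data)) {
    z <- matrix(NA_integer_, length(persons), length(items),
                dimnames = list(persons, items))
    z[cbind(n, i)] <- as.integer(data$true_class)
  }
  list(y = y, t = t, z = z, persons = persons, items = items)
}

#' Read an assessment table from CSV
#'
#' Accepts the canonical tidy long format (`person_id`, `item_id`,
#' `response`, `rt_seconds` or `rt_ms`) or a wide format with one row per
#' person and one `<item>` response column plus an optional `rt_<item>`
#' time column. Responses must be integer-coded `0..K`; times must be
#' strictly positive. Milliseconds are converted to seconds.
#'
#' @param path CSV path.
#' @param format `"long"` or `"wide"`.
#' @param rt_unit `"seconds"` or `"milliseconds"`.
#' @return An `"assessment_data"` tibble in long format.
#' @export
read_assessment <- function(path, format = c("long", "wide"),
                            rt_unit = c("seconds", "milliseconds")) {
  format <- match.arg(format)
  rt_unit <- match.arg(rt_unit)
  # base parser: correctly rounded doubles, so written shortest-round-trip
  # representations read back bit-identically
  raw <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (format == "wide") {
    rt_cols <- grep("^rt_", names(raw), value = TRUE)
    resp_cols <- setdiff(names(raw), c("person_id", rt_cols))
    long <- tidyr::pivot_longer(raw[c("person_id", resp_cols)],
                                -"person_id", names_to = "item_id",
                                values_to = "response")
    if (length(rt_cols)) {
      rt_long <- tidyr::pivot_longer(raw[c("person_id", rt_cols)],
                                     -"person_id", names_to = "item_id",
                                     values_to = "rt_seconds")
      rt_long$item_id <- sub("^rt_", "", rt_long$item_id)
      long <- dplyr::left_join(long, rt_long,
                               by = c("person_id", "item_id"))
    }
    raw <- long
  }
  if ("rt_ms" %in% names(raw) && !"rt_seconds" %in% names(raw)) {
    raw$rt_seconds <- raw$rt_ms / 1000
    raw$rt_ms <- NULL
    rt_unit <- "seconds"
  }
  validate_assessment(raw, rt_unit)
}

validate_assessment <- function(data, rt_unit = "seconds") {
  problems <- character()
  need <- c("person_id", "item_id", "response")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("Missing required columns: ", paste(miss, collapse = ", "))
  }
  if ("rt_seconds" %in% names(data) && rt_unit == "milliseconds") {
    data$rt_seconds <- data$rt_seconds / 1000
  }
  if (anyDuplicated(data[c("person_id", "item_id")])) {
    problems <- c(problems, "duplicate (person_id, item_id) rows")
  }
  if (anyNA(data$response)) {
    problems <- c(problems, "missing responses")
  } else if (any(data$response != round(data$response) | data$response < 0)) {
    problems <- c(problems, "responses must be integers in 0..K")
  }
  if ("rt_seconds" %in% names(data) &&
      any(!is.na(data$rt_seconds) & data$rt_seconds <= 0)) {
    problems <- c(problems, "nonpositive response times")
  }
  counts <- table(data$person_id)
  if (length(unique(counts)) > 1) {
    problems <- c(problems, "non-rectangular data (unequal items per person)")
  }
  if (length(problems)) {
    stop("Invalid assessment data: ", paste(problems, collapse = "; "))
  }
  data <- tibble::as_tibble(data)
  class(data) <- c("assessment_data", class(data))
  data
}

#' Write an assessment table (and its generating parameters) to disk
#'
#' The tidy long CSV holds one row per person-item cell; if the data carry
#' simulation ground truth, the generating person parameters and scalar
#' population parameters are written to a JSON sidecar.
#'
#' @param data An `"assessment_data"` tibble.
#' @param path Output CSV path.
#' @param sidecar Write the JSON parameter sidecar next to the CSV?
#' @return `path`, invisibly.
#' @export
write_assessment <- function(data, path, sidecar = TRUE) {
  readr::write_csv(as.data.frame(data), path)
  persons <- attr(data, "persons")
  design <- attr(data, "design")
  if (sidecar && !is.null(design)) {
    side <- list(
      n_categories = design$n_categories,
      pop = design$pop[c("nu_phi", "nu_psi", "lambda",
                         "sigma_s", "sigma_sf", "sigma_f")],
      Sigma = design$pop$Sigma,
      persons = persons)
    jsonlite::write_json(side, paste0(tools::file_path_sans_ext(path),
                                      "_params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read/write a scoring-weight table
#'
#' One row per item x category x dimension, `dimension` being `trait_<d>`
#' or `faking`.
#'
#' @param path CSV path.
#' @return For `read_weight_table()`, a named list of [scoring_weights()].
#' @export
read_weight_table <- function(path) {
  table_to_weights(readr::read_csv(path, show_col_types = FALSE,
                                   progress = FALSE))
}

#' @rdname read_weight_table
#' @param weights List of [scoring_weights()].
#' @param item_ids Item identifiers.
#' @export
write_weight_table <- function(weights, path, item_ids = NULL) {
  readr::write_csv(weights_to_table(weights, item_ids), path)
  invisible(path)
}
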