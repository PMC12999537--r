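#' Construct scoring weights for one item
#'
#' Scoring weights link response categories to latent dimensions in the
#' nominal response model. For a substantive trait measured by the item the
#' weights are the evenly spaced integers `0..K` (higher categories indicate
#' more of the trait); traits the item does not measure get all-zero weights.
#' Faking (desirability) weights are item- and category-specific values on a
#' common 0-6 metric and may be nonmonotonic across categories.
#'
#' @param n_traits Number of substantive trait dimensions `D`.
#' @param measured_trait Index (1-based) of the trait the item measures.
#' @param n_categories Number of response categories `K + 1`.
#' @param faking_weights Numeric vector of length `K + 1` in `[0, 6]`.
#'
#' @return A list with components `trait` (a `D x (K+1)` matrix) and
#'   `faking` (length `K + 1` vector), of class `"scoring_weights"`.
#' @export
scoring_weights <- function(n_traits, measured_trait, n_categories,
                            faking_weights) {
  stopifnot(n_traits >= 1, n_categories >= 2,
            measured_trait >= 1, measured_trait <= n_traits)
  faking_weights <- as.numeric(faking_weights)
  if (length(faking_weights) != n_categories) {
    stop("`faking_weights` must have one entry per response category.")
  }
  if (any(faking_weights < 0 | faking_weights > 6)) {
    stop("Faking weights must lie in [0, 6].")
  }
  trait <- matrix(0, n_traits, n_categories)
  trait[measured_trait, ] <- seq_len(n_categories) - 1
  structure(list(trait = trait, faking = faking_weights),
            class = "scoring_weights")
}

#' Desirability trajectories for faking scoring weights
#'
#' Generates a faking-weight vector on the 0-6 metric with one of three
#' trajectory shapes observed for real items: desirability increasing
#' monotonically with the category, peaking at an interior (non-extreme)
#' category, or peaking at the scale midpoint with symmetric decay.
#'
#' @param shape One of `"monotone-increasing"`, `"peak-interior"`,
#'   `"peak-at-midpoint"`.
#' @param K Highest category index (categories are `0..K`).
#' @param peak_category Category at which desirability is maximal. Defaults
#'   to `K` for the monotone shape, `K - 1` for `"peak-interior"`, and the
#'   midpoint for `"peak-at-midpoint"`.
#'
#' @return Numeric vector of length `K + 1` in `[0, 6]`, maximal at the peak.
#' @export
#' @examples
#' make_desirability_weights("monotone-increasing", K = 6)
#' make_desirability_weights("peak-at-midpoint", K = 6)
make_desirability_weights <- function(shape = c("monotone-increasing",
                                                "peak-interior",
                                                "peak-at-midpoint"),
                                      K, peak_category = NULL) {
  shape <- match.arg(shape)
  stopifnot(K >= 1)
  if (is.null(peak_category)) {
    peak_category <- switch(shape,
      "monotone-increasing" = K,
      "peak-interior"       = max(1L, K - 1L),
      "peak-at-midpoint"    = round(K / 2))
  }
  if (peak_category < 0 || peak_category > K) {
    stop("`peak_category` must lie in 0..K.")
  }
  k <- 0:K
  w <- switch(shape,
    "monotone-increasing" = k / K,
    # linear ramp up to the peak, linear decay after it
    "peak-interior" = {
      up <- if (peak_category > 0) k / peak_category else rep(1, K + 1)
      down <- if (peak_category < K) (K - k) / (K - peak_category)
              else rep(1, K + 1)
      pmin(up, down)
    },
    "peak-at-midpoint" = {
      d <- abs(k - peak_category)
      1 - d / max(d)
    })
  w <- w - min(w)
  6 * w / max(w)
}

#' Rescale raw desirability ratings to the 0-6 scoring-weight metric
#'
#' Mean desirability ratings collected on an arbitrary bounded rating scale
#' are mapped affinely so that the rating scale's possible minimum maps to 0
#' and its possible maximum to 6, preserving order and relative spacing.
#' This puts faking weights on the same metric as the integer trait weights.
#'
#' @param ratings Numeric vector/matrix of mean ratings.
#' @param scale_min,scale_max Possible range of the rating scale.
#'
#' @return Rescaled weights on `[0, 6]`, same shape as `ratings`.
#' @export
rescale_desirability <- function(ratings, scale_min, scale_max) {
  if (!is.numeric(scale_min) || !is.numeric(scale_max) ||
      scale_max <= scale_min) {
    stop("Degenerate rating scale: `scale_max` must exceed `scale_min`.")
  }
  if (any(ratings < scale_min | ratings > scale_max, na.rm = TRUE)) {
    stop("Ratings outside the declared rating scale range.")
  }
  (ratings - scale_min) * 6 / (scale_max - scale_min)
}

#' Tidy a list of per-item scoring weights into a weight table
#'
#' @param weights List of `scoring_weights`, one per item.
#' @param item_ids Optional character item identifiers.
#' @return Tibble with columns `item_id`, `category`, `dimension`, `weight`;
#'   `dimension` is `"trait_<d>"` or `"faking"`.
#' @export
weights_to_table <- function(weights, item_ids = NULL) {
  if (is.null(item_ids)) item_ids <- sprintf("item_%02d", seq_along(weights))
  purrr::map2_dfr(weights, item_ids, function(w, id) {
    D <- nrow(w$trait); K1 <- ncol(w$trait)
    trait_rows <- tidyr::expand_grid(d = seq_len(D), category = 0:(K1 - 1))
    dplyr::bind_rows(
      tibble::tibble(item_id = id,
                     category = trait_rows$category,
                     dimension = sprintf("trait_%d", trait_rows$d),
                     weight = w$trait[cbind(trait_rows$d, trait_rows$category + 1)]),
      tibble::tibble(item_id = id, category = 0:(K1 - 1),
                     dimension = "faking", weight = w$faking))
  })
}

#' Rebuild per-item scoring weights from a weight table
#'
#' Inverse of [weights_to_table()]. Validates that every item has exactly one
#' faking weight and one weight per trait for each contiguous category
#' `0..K`.
#'
#' @param table Tibble/data frame with columns `item_id`, `category`,
#'   `dimension`, `weight`.
#' @return Named list of `scoring_weights` keyed by `item_id`.
#' @export
table_to_weights <- function(table) {
  stopifnot(all(c("item_id", "category", "dimension", "weight") %in%
                  names(table)))
  dims <- sort(unique(table$dimension))
  trait_dims <- grep("^trait_", dims, value = TRUE)
  if (!"faking" %in% dims || length(trait_dims) == 0) {
    stop("Weight table must contain a 'faking' dimension and trait_<d> dimensions.")
  }
  D <- length(trait_dims)
  items <- unique(table$item_id)
  out <- lapply(items, function(id) {
    sub <- table[table$item_id == id, ]
    cats <- sort(unique(sub$category))
    K1 <- length(cats)
    if (!identical(as.integer(cats), 0:(K1 - 1L))) {
      stop("Categories must be contiguous 0..K for item ", id)
    }
    trait <- matrix(0, D, K1)
    for (d in seq_len(D)) {
      rows <- sub[sub$dimension == sprintf("trait_%d", d), ]
      if (nrow(rows) != K1) stop("Missing trait weights for item ", id)
      trait[d, rows$category + 1] <- rows$weight
    }
    fr <- sub[sub$dimension == "faking", ]
    if (nrow(fr) != K1) stop("Missing faking weights for item ", id)
    faking <- numeric(K1); faking[fr$category + 1] <- fr$weight
    structure(list(trait = trait, faking = faking),
              class = "scoring_weights")
  })
  names(out) <- items
  out
}
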