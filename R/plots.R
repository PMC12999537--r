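#' Plot desirability trajectories of items
#'
#' @param weights List of [scoring_weights()].
#' @param item_ids Optional item identifiers.
#' @param items Subset of items to display (indices or ids).
#' @return A ggplot.
#' @export
plot_desirability <- function(weights, item_ids = NULL, items = NULL) {
  tab <- weights_to_table(weights, item_ids) |>
    dplyr::filter(.data$dimension == "faking")
  if (!is.null(items)) {
    if (is.numeric(items)) items <- unique(tab$item_id)[items]
    tab <- dplyr::filter(tab, .data$item_id %in% items)
  }
  ggplot2::ggplot(tab, ggplot2::aes(.data$category, .data$weight)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~item_id) +
    ggplot2::labs(x = "Response category", y = "Desirability weight (0-6)") +
    ggplot2::theme_minimal()
}

#' Latent response functions: class probability against strategy inclination
#'
#' Plots, for selected items, the posterior-mean class-membership
#' probabilities as a function of the strategy inclination score.
#'
#' @param fit A person-by-item `"faking_fit"`.
#' @param items Item ids or indices to display.
#' @param psi_range Range of strategy inclination scores.
#' @return A ggplot.
#' @export
plot_latent_response <- function(fit, items = 1:3, psi_range = c(-3, 3)) {
  if (fit$config$mixture != 2) {
    stop("Latent response functions require a person-by-item mixture fit.")
  }
  est <- param_means(fit)
  npsi <- est["nu_psi"]
  if (is.numeric(items)) items_idx <- items
  else items_idx <- match(items, fit$items)
  psi <- seq(psi_range[1], psi_range[2], length.out = 101)
  df <- purrr::map_dfr(items_idx, function(i) {
    b1 <- est[sprintf("beta[%d,1]", i)]
    b2 <- est[sprintf("beta[%d,2]", i)]
    z <- cbind(0, npsi * psi + b1, 2 * npsi * psi + b2)
    p <- exp(z - apply(z, 1, matrixStats_logsumexp))
    tibble::tibble(item_id = fit$items[i],
                   psi = rep(psi, 3),
                   class = rep(c("S-only", "S&F", "F-only"), each = 101),
                   probability = c(p))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$psi, .data$probability,
                                   color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~item_id) +
    ggplot2::labs(x = "Strategy inclination", y = "Class probability") +
    ggplot2::theme_minimal()
}

#' Coefficient-style plot of posterior summaries
#'
#' @param object A `"faking_fit"`.
#' @param families Parameter families to display (prefixes such as
#'   `"alpha_s"`, `"delta_s"`, `"Sigma"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.faking_fit <- function(object,
                                families = c("nu_phi", "nu_psi", "lambda",
                                             "sigma_s", "sigma_sf",
                                             "sigma_f", "Sigma"),
                                ...) {
  td <- tidy.faking_fit(object) |>
    dplyr::mutate(family = param_family(.data$term)) |>
    dplyr::filter(.data$family %in% families)
  ggplot2::ggplot(td, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0) +
    ggplot2::labs(x = "Posterior mean (95% CrI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bias/RMSE panels of a recovery study
#'
#' @param object A `"recovery_study"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recovery_study <- function(object, ...) {
  long <- object$metrics |>
    tidyr::pivot_longer(c("bias", "rmse"), names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$family, .data$value,
                                     fill = .data$variant)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
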