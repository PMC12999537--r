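#' Default latent correlation matrix of the simulation scenario
#'
#' Correlations among the `D + 3` person parameters (traits, faking, speed,
#' strategy inclination) used by the default generating scenario. For
#' `D = 3` this is the empirically anchored matrix (moderate positive trait
#' intercorrelations, negative trait-faking correlations, a .32
#' faking-by-strategy-inclination correlation); for other `D` the trait
#' block is compound-symmetric at .25 and the cross-correlations recycle
#' the `D = 3` pattern.
#'
#' @param D Number of substantive traits.
#' @return A `(D + 3) x (D + 3)` correlation matrix.
#' @export
default_latent_correlations <- function(D = 3) {
  if (D == 3) {
    S <- diag(6)
    S[1, 2] <- .20; S[1, 3] <- .24; S[2, 3] <- .36
    S[1, 4] <- -.23; S[2, 4] <- -.01; S[3, 4] <- -.24
    S[1, 5] <- .11; S[2, 5] <- .09; S[3, 5] <- .08; S[4, 5] <- .01
    S[1, 6] <- -.06; S[2, 6] <- .14; S[3, 6] <- -.31; S[4, 6] <- .32
    S[5, 6] <- 0
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
    return(S)
  }
  S <- diag(D + 3)
  S[seq_len(D), seq_len(D)] <- .25
  diag(S) <- 1
  cross <- cbind(rep(-.16, D), rep(.09, D), rep(-.08, D))
  S[seq_len(D), D + 1:3] <- cross
  S[D + 1:3, seq_len(D)] <- t(cross)
  S[D + 1, D + 3] <- S[D + 3, D + 1] <- .32
  S[D + 1, D + 2] <- S[D + 2, D + 1] <- .01
  S
}

#' Simulation design for the recovery-study scenario
#'
#' Builds the complete generative specification: item parameters, scoring
#' weights (including nonmonotonic desirability trajectories), and
#' population parameters. Defaults mirror the recovery-study conditions —
#' 3 substantive traits measured by 10 items each on a 7-point scale,
#' N = 500 persons — with item-response, response-time and latent-response
#' generating values anchored at the empirical estimates (mean trait-only
#' time intensity 1.72, mean faking-only time intensity 1.53, lambda 0.23,
#' strategy-inclination slope 1.05) and item-level scatter around them.
#'
#' @param n_persons Number of persons `N`.
#' @param n_traits Number of substantive traits `D`.
#' @param items_per_trait Items measuring each trait.
#' @param n_categories Number of response categories `K + 1`.
#' @param pop Optional [population_parameters()]; defaults to the anchored
#'   scenario values.
#' @param item_seed Seed fixing the generating item parameters. Item-side
#'   generating values are a fixed property of the design so that
#'   replications differ only in persons, classes, responses and times.
#' @param n_replications Default number of study replications.
#' @param interleave Randomly interleave the items of the trait scales (the
#'   recorded item order has no model role).
#' @return An object of class `"sim_design"`: a list with elements `items`
#'   (list of [item_parameters()]), `weights` (list of [scoring_weights()]),
#'   `pop`, `item_ids`, `measured_trait`, `n_persons`, `n_categories`,
#'   `n_replications`.
#' @export
sim_design <- function(n_persons = 500, n_traits = 3, items_per_trait = 10,
                       n_categories = 7, pop = NULL, item_seed = 20260101,
                       n_replications = 50, interleave = TRUE) {
  stopifnot(n_persons >= 1, n_traits >= 1, items_per_trait >= 1,
            n_categories >= 2)
  D <- n_traits; K <- n_categories - 1L; I <- D * items_per_trait
  if (is.null(pop)) {
    pop <- population_parameters(
      Sigma = default_latent_correlations(D),
      nu_phi = 1.0, nu_psi = 1.05, lambda = 0.23,
      sigma_s = 0.40, sigma_sf = 0.45, sigma_f = 0.40)
  }
  if (nrow(pop$Sigma) != D + 3) {
    stop("`pop$Sigma` must have order D + 3.")
  }

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(item_seed)

  # desirability trajectory mix per scale: mostly monotone, some interior
  # peaks, some midpoint peaks (the three empirically observed shapes)
  shape_base <- c(rep("monotone-increasing", max(items_per_trait - 4, 1)),
                  rep("peak-interior", 2), rep("peak-at-midpoint", 2))
  shapes <- rep(shape_base[seq_len(items_per_trait)], D)
  measured <- rep(seq_len(D), each = items_per_trait)

  items <- vector("list", I)
  weights <- vector("list", I)
  for (i in seq_len(I)) {
    weights[[i]] <- scoring_weights(
      n_traits = D, measured_trait = measured[i], n_categories = K + 1L,
      faking_weights = make_desirability_weights(shapes[i], K = K))
    a_s <- numeric(D)
    a_s[measured[i]] <- runif(1, 0.5, 1.2)
    gam <- function() c(0, rnorm(K, 0, 1))
    items[[i]] <- item_parameters(
      trait_slopes = a_s,
      faking_slope = runif(1, 0.3, 0.9),
      gamma_s = gam(), gamma_sf = gam(), gamma_f = gam(),
      beta = c(0, rnorm(1, -0.44, 0.5), rnorm(1, -0.99, 0.5)),
      delta_s = rnorm(1, 1.72, 0.20),
      delta_f = rnorm(1, 1.53, 0.20))
  }
  ord <- if (interleave) sample.int(I) else seq_len(I)
  items <- items[ord]; weights <- weights[ord]; measured <- measured[ord]
  structure(list(items = items, weights = weights, pop = pop,
                 item_ids = sprintf("item_%02d", seq_len(I)),
                 measured_trait = measured,
                 n_persons = n_persons, n_traits = D,
                 n_categories = K + 1L,
                 n_replications = n_replications),
            class = "sim_design")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' Draw person parameters from the latent multivariate normal
#'
#' @param N Number of persons.
#' @param Sigma Correlation matrix of order `D + 3`.
#' @param seed Optional RNG seed.
#' @return Tibble with one row per person: `person_id`, `theta_1..theta_D`,
#'   `eta`, `phi`, `psi`.
#' @export
draw_persons <- function(N, Sigma, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- nrow(Sigma)
  D <- P - 3L
  if (D < 1) stop("`Sigma` must have order D + 3 with D >= 1.")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("`Sigma` must be positive definite.")
  X <- MASS::mvrnorm(N, mu = rep(0, P), Sigma = Sigma)
  X <- matrix(X, ncol = P)
  colnames(X) <- c(sprintf("theta_%d", seq_len(D)), "eta", "phi", "psi")
  dplyr::bind_cols(tibble::tibble(person_id = sprintf("p%04d", seq_len(N))),
                   tibble::as_tibble(X))
}

persons_to_list <- function(persons_tbl) {
  D <- sum(grepl("^theta_", names(persons_tbl)))
  purrr::pmap(persons_tbl[-1], function(...) {
    v <- c(...)
    person_parameters(theta = v[seq_len(D)], eta = v[["eta"]],
                      phi = v[["phi"]], psi = v[["psi"]])
  })
}

#' Simulate an assessment from the generative model
#'
#' For every person-item cell: draw the latent strategy class from the
#' latent response model, then the response from that class's item response
#' model, then the response time from that class's log-normal model.
#' Ground-truth person parameters and class memberships are retained.
#'
#' @param design A [sim_design()] object.
#' @param seed RNG seed (one replication = one seed).
#' @param persons Optional tibble of person parameters (as from
#'   [draw_persons()]) to reuse instead of drawing fresh ones.
#' @return Long-format tibble of class `"assessment_data"` with columns
#'   `person_id`, `item_id`, `response` (0..K), `rt_seconds`, `true_class`.
#'   The generating person tibble is attached as attribute `"persons"` and
#'   the design as `"design"`.
#' @export
simulate_assessment <- function(design, seed = NULL, persons = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(seed)) set.seed(seed)
  N <- design$n_persons
  I <- length(design$items)
  K1 <- design$n_categories
  if (is.null(persons)) {
    persons <- draw_persons(N, design$pop$Sigma)
  } else {
    N <- nrow(persons)
  }
  plist <- persons_to_list(persons)
  pop <- design$pop

  y <- matrix(NA_integer_, N, I)
  tt <- matrix(NA_real_, N, I)
  zeta <- matrix(NA_integer_, N, I)
  for (i in seq_len(I)) {
    item <- design$items[[i]]; w <- design$weights[[i]]
    for (n in seq_len(N)) {
      pr_c <- class_probabilities(plist[[n]], item, pop)
      z <- sample.int(3, 1, prob = pr_c) - 1L
      pr_y <- category_probabilities(z, plist[[n]], item, w)
      y[n, i] <- sample.int(K1, 1, prob = pr_y) - 1L
      mu <- rt_log_mean(z, plist[[n]]$phi, item, pop)
      tt[n, i] <- exp(rnorm(1, mu, rt_sd(z, pop)))
      zeta[n, i] <- z
    }
  }
  out <- tidyr::expand_grid(person_id = persons$person_id,
                            item_id = design$item_ids)
  idx <- cbind(rep(seq_len(N), each = I), rep(seq_len(I), times = N))
  out$response <- y[idx]
  out$rt_seconds <- tt[idx]
  out$true_class <- zeta[idx]
  attr(out, "persons") <- persons
  attr(out, "design") <- design
  class(out) <- c("assessment_data", class(out))
  out
}

#' Ground-truth person parameters of a simulated assessment
#' @param data An `"assessment_data"` tibble from [simulate_assessment()].
#' @return The generating person tibble.
#' @export
sim_truth <- function(data) attr(data, "persons")
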