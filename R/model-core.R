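#' Item, person, and population parameter containers
#'
#' Lightweight validated lists holding every parameter the mixture model
#' uses. Classes are coded `0` (trait-only responding, "S-only"), `1`
#' (trait-plus-faking, "S&F"), `2` (faking-only, "F-only").
#'
#' @param trait_slopes Nonnegative slopes of the substantive traits
#'   (length `D`); slopes of traits the item does not measure are 0.
#' @param faking_slope Nonnegative slope of the faking dimension.
#' @param gamma_s,gamma_sf,gamma_f Class-specific category intercepts,
#'   length `K + 1`, first entry fixed at 0 for identification.
#' @param beta Item-class intercepts of the latent response model, length 3,
#'   first entry fixed at 0.
#' @param delta_s,delta_f Item time intensities (expected log-RT in seconds
#'   at the latent speed mean) for the trait-only and faking-only classes.
#' @return An object of class `"item_parameters"`.
#' @export
item_parameters <- function(trait_slopes, faking_slope,
                            gamma_s, gamma_sf, gamma_f,
                            beta = c(0, 0, 0),
                            delta_s = NA_real_, delta_f = NA_real_) {
  K1 <- length(gamma_s)
  if (length(gamma_sf) != K1 || length(gamma_f) != K1) {
    stop("Class-specific intercept vectors must share length K + 1.")
  }
  if (any(c(trait_slopes, faking_slope) < 0)) {
    stop("Slopes must be nonnegative.")
  }
  if (length(beta) != 3) stop("`beta` must have one entry per class.")
  first <- c(gamma_s[1], gamma_sf[1], gamma_f[1], beta[1])
  if (any(abs(first) > 1e-12)) {
    stop("First category/class intercepts are fixed at 0 for identification.")
  }
  structure(list(trait_slopes = as.numeric(trait_slopes),
                 faking_slope = as.numeric(faking_slope),
                 gamma_s = as.numeric(gamma_s),
                 gamma_sf = as.numeric(gamma_sf),
                 gamma_f = as.numeric(gamma_f),
                 beta = as.numeric(beta),
                 delta_s = delta_s, delta_f = delta_f),
            class = "item_parameters")
}

#' @rdname item_parameters
#' @param theta Substantive trait scores (length `D`).
#' @param eta Faking score.
#' @param phi Speed score.
#' @param psi Strategy-inclination score.
#' @export
person_parameters <- function(theta, eta = 0, phi = 0, psi = 0) {
  x <- c(theta, eta, phi, psi)
  if (any(!is.finite(x))) stop("Person parameters must be finite.")
  structure(list(theta = as.numeric(theta), eta = eta, phi = phi, psi = psi),
            class = "person_parameters")
}

#' @rdname item_parameters
#' @param Sigma Latent correlation matrix of the `D + 3` person parameters
#'   (order: traits, faking, speed, strategy inclination).
#' @param nu_phi Positive item-invariant speed slope.
#' @param nu_psi Positive item-invariant strategy-inclination slope.
#' @param lambda Positive proportionality constant placing the faking time
#'   intensity on top of the trait time intensity in the dual-process class.
#' @param sigma_s,sigma_sf,sigma_f Positive residual SDs of log-RTs per class.
#' @export
population_parameters <- function(Sigma, nu_phi = 1, nu_psi = 1,
                                  lambda = 0.2, sigma_s = 0.4,
                                  sigma_sf = 0.45, sigma_f = 0.4) {
  Sigma <- as.matrix(Sigma)
  if (!isSymmetric(unname(Sigma), tol = 1e-8) ||
      any(abs(diag(Sigma) - 1) > 1e-8)) {
    stop("`Sigma` must be a symmetric correlation matrix with unit diagonal.")
  }
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("`Sigma` must be positive definite.")
  if (any(c(nu_phi, nu_psi, lambda, sigma_s, sigma_sf, sigma_f) <= 0)) {
    stop("Slopes, lambda and residual SDs must be positive.")
  }
  structure(list(Sigma = Sigma, nu_phi = nu_phi, nu_psi = nu_psi,
                 lambda = lambda, sigma_s = sigma_s, sigma_sf = sigma_sf,
                 sigma_f = sigma_f),
            class = "population_parameters")
}

log_softmax <- function(x) x - matrixStats_logsumexp(x)

# log-sum-exp without extra dependencies
matrixStats_logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

category_propensities <- function(cls, person, item, weights) {
  K1 <- length(item$gamma_s)
  if (ncol(weights$trait) != K1 || length(weights$faking) != K1) {
    stop("Scoring weights and intercepts disagree on the number of categories.")
  }
  if (nrow(weights$trait) != length(item$trait_slopes) ||
      nrow(weights$trait) != length(person$theta)) {
    stop("Trait dimensions of weights, slopes and person scores disagree.")
  }
  trait_term <- drop((item$trait_slopes * person$theta) %*% weights$trait)
  fake_term <- item$faking_slope * weights$faking * person$eta
  switch(as.character(cls),
    "0" = trait_term + item$gamma_s,
    "1" = trait_term + fake_term + item$gamma_sf,
    "2" = fake_term + item$gamma_f,
    stop("Latent class must be 0, 1 or 2."))
}

#' Class-specific category probabilities
#'
#' Probability of each response category `0..K` under one of the three
#' response strategies: a softmax over category propensities built from
#' trait and faking terms with class-specific intercepts. The trait-only
#' class zeroes the faking term; the faking-only class zeroes the trait
#' terms; the dual-process class uses both.
#'
#' @param cls Latent class: 0 (trait-only), 1 (trait + faking), 2
#'   (faking-only).
#' @param person A [person_parameters()] object.
#' @param item An [item_parameters()] object.
#' @param weights A [scoring_weights()] object for the item.
#' @return Numeric probability vector over the `K + 1` categories.
#' @export
category_probabilities <- function(cls, person, item, weights) {
  p <- exp(log_softmax(category_propensities(cls, person, item, weights)))
  p / sum(p)
}

#' Log-density of a response time under a class-specific log-normal model
#'
#' Log response times are normal with mean `delta_s - nu_phi * phi` in the
#' trait-only class, `delta_s + lambda * delta_f - nu_phi * phi` in the
#' dual-process class, and `delta_f - nu_phi * phi` in the faking-only
#' class, with class-specific residual SDs. Returns the log of the
#' log-normal density of the raw time `t` (in seconds).
#'
#' @inheritParams category_probabilities
#' @param t Response time in seconds, strictly positive.
#' @param pop A [population_parameters()] object.
#' @return Log-density value.
#' @export
rt_log_density <- function(cls, t, person, item, pop) {
  if (any(t <= 0)) stop("Response times must be strictly positive.")
  mu <- rt_log_mean(cls, person$phi, item, pop)
  sig <- rt_sd(cls, pop)
  dnorm(log(t), mu, sig, log = TRUE) - log(t)
}

rt_log_mean <- function(cls, phi, item, pop) {
  base <- switch(as.character(cls),
    "0" = item$delta_s,
    "1" = item$delta_s + pop$lambda * item$delta_f,
    "2" = item$delta_f,
    stop("Latent class must be 0, 1 or 2."))
  base - pop$nu_phi * phi
}

rt_sd <- function(cls, pop) {
  sig <- switch(as.character(cls), "0" = pop$sigma_s, "1" = pop$sigma_sf,
                "2" = pop$sigma_f)
  if (sig <= 0) stop("Residual SDs must be positive.")
  sig
}

#' Latent response model: class membership probabilities
#'
#' A partial credit model over the three ordered strategies. The propensity
#' of class `c` is `nu_psi * c * psi + beta_c` with `beta_0 = 0`; a softmax
#' turns propensities into mixing proportions. Higher strategy inclination
#' `psi` shifts mass toward the more pronounced self-presentation classes.
#'
#' @inheritParams category_probabilities
#' @param pop A [population_parameters()] object.
#' @return Probability 3-vector over classes `(0, 1, 2)`.
#' @export
class_probabilities <- function(person, item, pop) {
  if (pop$nu_psi <= 0) stop("`nu_psi` must be positive.")
  z <- pop$nu_psi * (0:2) * person$psi + item$beta
  exp(log_softmax(z))
}

cell_log_terms <- function(y, t, person, item, weights, pop,
                           include_rt = TRUE) {
  lp_class <- log(class_probabilities(person, item, pop))
  vapply(0:2, function(cls) {
    lp <- log(category_probabilities(cls, person, item, weights))[y + 1]
    if (include_rt) lp <- lp + rt_log_density(cls, t, person, item, pop)
    lp_class[cls + 1] + lp
  }, numeric(1))
}

#' Marginal joint log-likelihood of responses and response times
#'
#' Sums, over all person-item cells, the log of the three-component mixture:
#' class probability times class-specific response probability times (if
#' `include_rt`) the class-specific log-normal response-time density. With
#' `include_rt = FALSE` the response-only likelihood is returned.
#'
#' @param data An assessment tibble as produced by [simulate_assessment()]
#'   or [read_assessment()] (long format with `person_id`, `item_id`,
#'   `response`, `rt_seconds`).
#' @param items List of [item_parameters()] in item order.
#' @param weights List of [scoring_weights()] in item order.
#' @param persons List of [person_parameters()] in person order.
#' @param pop A [population_parameters()] object.
#' @param include_rt Include the response-time factors?
#' @return Scalar log-likelihood.
#' @export
joint_marginal_loglik <- function(data, items, weights, persons, pop,
                                  include_rt = TRUE) {
  mats <- assessment_matrices(data)
  y <- mats$y; t <- mats$t
  if (anyNA(y) || (include_rt && anyNA(t))) {
    stop("Complete responses (and response times) are required.")
  }
  total <- 0
  for (n in seq_len(nrow(y))) {
    for (i in seq_len(ncol(y))) {
      terms <- cell_log_terms(y[n, i], t[n, i], persons[[n]], items[[i]],
                              weights[[i]], pop, include_rt)
      total <- total + matrixStats_logsumexp(terms)
    }
  }
  total
}

#' Posterior class responsibilities for a single cell
#'
#' Normalizes the three mixture summands (class probability x response
#' probability x response-time density) for one observed person-item cell,
#' yielding the probability of each strategy given the observed data.
#' Computed in log space to avoid underflow.
#'
#' @inheritParams category_probabilities
#' @param y Observed response category.
#' @param t Observed response time in seconds (ignored when
#'   `include_rt = FALSE`).
#' @param pop A [population_parameters()] object.
#' @param include_rt Use the response-time factors?
#' @return Probability 3-vector over classes.
#' @export
responsibilities <- function(y, t, person, item, weights, pop,
                             include_rt = TRUE) {
  terms <- cell_log_terms(y, t, person, item, weights, pop, include_rt)
  exp(terms - matrixStats_logsumexp(terms))
}
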