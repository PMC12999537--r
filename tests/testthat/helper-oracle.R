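# Independent brute-force oracle for the three-class mixture, written with
# plain exp/sum softmaxes and dlnorm() -- deliberately not reusing the
# package kernel.
oracle_cell_terms <- function(y, t, person, item, weights, pop,
                              include_rt = TRUE) {
  K1 <- length(item$gamma_s)
  zprop <- c(0,
             pop$nu_psi * 1 * person$psi + item$beta[2],
             pop$nu_psi * 2 * person$psi + item$beta[3])
  pz <- exp(zprop) / sum(exp(zprop))
  out <- numeric(3)
  for (cl in 0:2) {
    pro <- numeric(K1)
    for (k in seq_len(K1)) {
      v <- switch(cl + 1, item$gamma_s[k], item$gamma_sf[k],
                  item$gamma_f[k])
      if (cl != 2) {
        v <- v + sum(item$trait_slopes * weights$trait[, k] * person$theta)
      }
      if (cl != 0) v <- v + item$faking_slope * weights$faking[k] * person$eta
      pro[k] <- v
    }
    py <- exp(pro[y + 1]) / sum(exp(pro))
    ft <- 1
    if (include_rt) {
      mu <- switch(cl + 1, item$delta_s,
                   item$delta_s + pop$lambda * item$delta_f,
                   item$delta_f) - pop$nu_phi * person$phi
      sig <- switch(cl + 1, pop$sigma_s, pop$sigma_sf, pop$sigma_f)
      ft <- dlnorm(t, mu, sig)
    }
    out[cl + 1] <- pz[cl + 1] * py * ft
  }
  out
}

oracle_loglik <- function(data, items, weights, persons, pop,
                          include_rt = TRUE) {
  total <- 0
  ids_p <- unique(data$person_id); ids_i <- unique(data$item_id)
  for (r in seq_len(nrow(data))) {
    n <- match(data$person_id[r], ids_p)
    i <- match(data$item_id[r], ids_i)
    terms <- oracle_cell_terms(data$response[r], data$rt_seconds[r],
                               persons[[n]], items[[i]], weights[[i]], pop,
                               include_rt)
    total <- total + log(sum(terms))
  }
  total
}

# random tiny model instance for oracle-equivalence checks
random_instance <- function(N = 3, I = 2, D = 1, K = 2) {
  K1 <- K + 1
  weights <- lapply(seq_len(I), function(i) {
    scoring_weights(D, sample.int(D, 1), K1,
                    faking_weights = sort(runif(K1, 0, 6)))
  })
  items <- lapply(seq_len(I), function(i) item_parameters(
    trait_slopes = runif(D, 0.2, 1.5),
    faking_slope = runif(1, 0.2, 1.5),
    gamma_s = c(0, rnorm(K)), gamma_sf = c(0, rnorm(K)),
    gamma_f = c(0, rnorm(K)),
    beta = c(0, rnorm(2)),
    delta_s = runif(1, 1, 2), delta_f = runif(1, 1, 2)))
  P <- D + 3
  A <- matrix(rnorm(P * P), P)
  S <- cov2cor(crossprod(A) + diag(P))
  pop <- population_parameters(S, nu_phi = runif(1, 0.5, 1.5),
                               nu_psi = runif(1, 0.5, 1.5),
                               lambda = runif(1, 0.1, 0.5),
                               sigma_s = runif(1, 0.3, 0.6),
                               sigma_sf = runif(1, 0.3, 0.6),
                               sigma_f = runif(1, 0.3, 0.6))
  persons <- lapply(seq_len(N), function(n) {
    person_parameters(theta = rnorm(D), eta = rnorm(1), phi = rnorm(1),
                      psi = rnorm(1))
  })
  data <- tidyr::expand_grid(person_id = sprintf("p%02d", seq_len(N)),
                             item_id = sprintf("i%02d", seq_len(I)))
  data$response <- sample(0:K, N * I, replace = TRUE)
  data$rt_seconds <- exp(rnorm(N * I, 1.6, 0.5))
  list(data = data, items = items, weights = weights, persons = persons,
       pop = pop, N = N, I = I, D = D, K = K)
}

# small shared fixture: simulated dataset plus a short full-model fit
tiny_design <- function(n_persons = 40, items_per_trait = 2,
                        n_traits = 2, n_categories = 4) {
  sim_design(n_persons = n_persons, n_traits = n_traits,
             items_per_trait = items_per_trait,
             n_categories = n_categories,
             pop = population_parameters(
               default_latent_correlations(n_traits),
               nu_phi = 1, nu_psi = 1.05, lambda = 0.23,
               sigma_s = 0.4, sigma_sf = 0.45, sigma_f = 0.4))
}

cached_tiny_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- tiny_design()
      dat <- simulate_assessment(d, seed = 101)
      fit <- fit_faking_model(dat, d$weights, "person_by_item_rt",
                              mcmc = mcmc_config(chains = 2, warmup = 150,
                                                 iter = 150, thin = 1,
                                                 seed = 101))
      cache <<- list(design = d, data = dat, fit = fit)
    }
    cache
  }
})

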