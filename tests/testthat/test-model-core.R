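flat_item <- function(K = 1, D = 1) {
  item_parameters(trait_slopes = rep(0, D), faking_slope = 0,
                  gamma_s = rep(0, K + 1), gamma_sf = rep(0, K + 1),
                  gamma_f = rep(0, K + 1), beta = c(0, 0, 0),
                  delta_s = 1.7, delta_f = 1.5)
}

test_that("category probabilities reduce to softmax of propensities", {
  w <- scoring_weights(1, 1, 2, faking_weights = c(0, 6))
  p0 <- category_probabilities(0, person_parameters(0), flat_item(1), w)
  expect_equal(p0, c(0.5, 0.5))

  # trait-only class with unit slope and weights (0,1,2) at theta = 1
  w3 <- scoring_weights(1, 1, 3, faking_weights = c(0, 3, 6))
  it <- item_parameters(1, 0.5, gamma_s = c(0, 0, 0), gamma_sf = c(0, 0, 0),
                        gamma_f = c(0, 0, 0), delta_s = 1, delta_f = 1)
  p <- category_probabilities(0, person_parameters(1), it, w3)
  expect_equal(p, exp(0:2) / sum(exp(0:2)), tolerance = 1e-12)
  expect_equal(round(p, 4), c(0.0900, 0.2447, 0.6652))

  # the trait-only class is invariant to the faking score
  p_a <- category_probabilities(0, person_parameters(1, eta = -2), it, w3)
  p_b <- category_probabilities(0, person_parameters(1, eta = 5), it, w3)
  expect_equal(p_a, p_b)
  # the faking-only class is invariant to the trait score
  p_c <- category_probabilities(2, person_parameters(-3, eta = 1), it, w3)
  p_d <- category_probabilities(2, person_parameters(2, eta = 1), it, w3)
  expect_equal(p_c, p_d)

  expect_error(category_probabilities(0, person_parameters(c(0, 0)), it, w3),
               "disagree")
})

test_that("probability vectors are proper and softmax is shift-invariant", {
  set.seed(42)
  for (rep in 1:20) {
    inst <- random_instance(N = 1, I = 1, D = 2, K = 4)
    it <- inst$items[[1]]; w <- inst$weights[[1]]; pr <- inst$persons[[1]]
    for (cls in 0:2) {
      p <- category_probabilities(cls, pr, it, w)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0))
    }
    pz <- class_probabilities(pr, it, inst$pop)
    expect_equal(sum(pz), 1, tolerance = 1e-12)
    # adding a constant to all category propensities changes nothing
    shift <- rnorm(1, 0, 3)
    it2 <- item_parameters(it$trait_slopes, it$faking_slope,
                           gamma_s = it$gamma_s,
                           gamma_sf = it$gamma_sf, gamma_f = it$gamma_f,
                           beta = it$beta, delta_s = it$delta_s,
                           delta_f = it$delta_f)
    prop1 <- fakemix:::category_propensities(1, pr, it2, w)
    p_direct <- exp(prop1 + shift) / sum(exp(prop1 + shift))
    expect_equal(category_probabilities(1, pr, it2, w), p_direct,
                 tolerance = 1e-12)
  }
})

test_that("dual-process response model collapses to trait-only model", {
  set.seed(7)
  for (rep in 1:10) {
    inst <- random_instance(N = 1, I = 1, D = 2, K = 5)
    it <- inst$items[[1]]
    shared <- item_parameters(it$trait_slopes, faking_slope = 0,
                              gamma_s = it$gamma_s, gamma_sf = it$gamma_s,
                              gamma_f = it$gamma_f, beta = it$beta,
                              delta_s = it$delta_s, delta_f = it$delta_f)
    p_sf <- category_probabilities(1, inst$persons[[1]], shared,
                                   inst$weights[[1]])
    p_s <- category_probabilities(0, inst$persons[[1]], shared,
                                  inst$weights[[1]])
    expect_equal(p_sf, p_s, tolerance = 1e-12)
  }
})

test_that("response-time log-density matches the class-specific log-normal", {
  pop <- population_parameters(diag(4), nu_phi = 1, lambda = 0.23,
                               sigma_f = 1)
  it <- flat_item()
  it$delta_f <- 0
  # standard log-normal at t = 1: log density is -log(sqrt(2 pi))
  expect_equal(rt_log_density(2, 1, person_parameters(0), it, pop),
               -0.5 * log(2 * pi))
  # mode of the log-time density sits at the time intensity
  ts <- seq(1, 12, by = 0.01)
  dens <- vapply(ts, function(t) {
    rt_log_density(0, t, person_parameters(0), it, pop) + log(t)
  }, numeric(1))
  expect_equal(log(ts[which.max(dens)]), it$delta_s, tolerance = 0.01)
  # implied dual-process log-mean: delta_s + lambda * delta_f
  it2 <- flat_item(); it2$delta_s <- 1.72; it2$delta_f <- 1.53
  m_sf <- fakemix:::rt_log_mean(1, 0, it2, pop)
  expect_equal(m_sf, 1.72 + 0.23 * 1.53, tolerance = 1e-12)
  # reported implied dual-process intensity (2.08, from unrounded inputs)
  expect_lt(abs(m_sf - 2.08), 0.015)
  # dual-process mean log-RT strictly exceeds the trait-only mean for
  # positive intensities and lambda
  expect_gt(m_sf, fakemix:::rt_log_mean(0, 0, it2, pop))
  expect_error(rt_log_density(0, -1, person_parameters(0), it, pop),
               "positive")
})

test_that("latent response model is a PCM over ordered strategies", {
  pop <- population_parameters(diag(4), nu_psi = 1)
  it <- flat_item()
  expect_equal(class_probabilities(person_parameters(0, psi = 0), it, pop),
               rep(1 / 3, 3))
  p1 <- class_probabilities(person_parameters(0, psi = 1), it, pop)
  expect_equal(p1, exp(0:2) / sum(exp(0:2)), tolerance = 1e-12)
  # expected class score strictly increasing in strategy inclination
  psis <- seq(-2, 2, by = 0.25)
  escore <- vapply(psis, function(ps) {
    sum(0:2 * class_probabilities(person_parameters(0, psi = ps), it, pop))
  }, numeric(1))
  expect_true(all(diff(escore) > 0))
})

test_that("marginal joint log-likelihood matches brute-force enumeration", {
  set.seed(11)
  for (rep in 1:30) {
    inst <- random_instance(N = sample(2:5, 1), I = sample(1:4, 1),
                            D = sample(1:2, 1), K = sample(1:3, 1))
    ll <- joint_marginal_loglik(inst$data, inst$items, inst$weights,
                                inst$persons, inst$pop, include_rt = TRUE)
    ll_oracle <- oracle_loglik(inst$data, inst$items, inst$weights,
                               inst$persons, inst$pop, include_rt = TRUE)
    expect_equal(ll, ll_oracle, tolerance = 1e-10)
    llr <- joint_marginal_loglik(inst$data, inst$items, inst$weights,
                                 inst$persons, inst$pop, include_rt = FALSE)
    llr_oracle <- oracle_loglik(inst$data, inst$items, inst$weights,
                                inst$persons, inst$pop, include_rt = FALSE)
    expect_equal(llr, llr_oracle, tolerance = 1e-10)
  }
})

test_that("log-likelihood is invariant to person order and degenerates to a
          single class when the mixture is forced", {
  set.seed(13)
  inst <- random_instance(N = 4, I = 3, D = 1, K = 2)
  ll <- joint_marginal_loglik(inst$data, inst$items, inst$weights,
                              inst$persons, inst$pop)
  perm <- c(3, 1, 4, 2)
  data_perm <- inst$data |>
    dplyr::mutate(ord = match(person_id, sprintf("p%02d", perm))) |>
    dplyr::arrange(ord, item_id) |>
    dplyr::select(-ord)
  ll_perm <- joint_marginal_loglik(data_perm, inst$items, inst$weights,
                                   inst$persons[perm], inst$pop)
  expect_equal(ll, ll_perm, tolerance = 1e-10)

  # beta -> -30 surrogate forces the trait-only class
  items_deg <- lapply(inst$items, function(it) {
    it$beta <- c(0, -30, -60); it
  })
  ll_deg <- joint_marginal_loglik(inst$data, items_deg, inst$weights,
                                  inst$persons, inst$pop)
  direct <- 0
  for (r in seq_len(nrow(inst$data))) {
    n <- match(inst$data$person_id[r], unique(inst$data$person_id))
    i <- match(inst$data$item_id[r], unique(inst$data$item_id))
    direct <- direct +
      log(category_probabilities(0, inst$persons[[n]], items_deg[[i]],
                                 inst$weights[[i]])[inst$data$response[r] + 1]) +
      rt_log_density(0, inst$data$rt_seconds[r], inst$persons[[n]],
                     items_deg[[i]], inst$pop)
  }
  expect_equal(ll_deg, direct, tolerance = 1e-8)

  # missing cells are rejected
  bad <- inst$data[-1, ]
  expect_error(joint_marginal_loglik(bad, inst$items, inst$weights,
                                     inst$persons, inst$pop), "rectangular")
})

test_that("responsibilities normalize the brute-force mixture summands", {
  set.seed(17)
  for (rep in 1:20) {
    inst <- random_instance(N = 1, I = 1, D = 1, K = 3)
    y <- inst$data$response[1]; t <- inst$data$rt_seconds[1]
    r <- responsibilities(y, t, inst$persons[[1]], inst$items[[1]],
                          inst$weights[[1]], inst$pop)
    terms <- oracle_cell_terms(y, t, inst$persons[[1]], inst$items[[1]],
                               inst$weights[[1]], inst$pop)
    expect_equal(r, terms / sum(terms), tolerance = 1e-10)
    expect_equal(sum(r), 1, tolerance = 1e-12)
  }
  # uninformative data: identical models across classes, flat prior
  w <- scoring_weights(1, 1, 2, faking_weights = c(0, 0))
  it <- flat_item(K = 1); it$delta_f <- it$delta_s
  pop <- population_parameters(diag(4), nu_psi = 1, lambda = 1e-9,
                               sigma_s = 0.5, sigma_sf = 0.5, sigma_f = 0.5)
  r <- responsibilities(1, 5, person_parameters(0), it, w, pop)
  expect_equal(r, rep(1 / 3, 3), tolerance = 1e-6)
  # degenerate prior pins the responsibility regardless of the data
  it$beta <- c(0, -30, -60)
  r2 <- responsibilities(1, 5, person_parameters(1, eta = 2, psi = 0),
                         it, w, pop)
  expect_equal(r2[1], 1, tolerance = 1e-10)
})
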