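test_that("fit enforces identification constraints in every retained draw", {
  tf <- cached_tiny_fit()
  fit <- tf$fit
  d <- fit$draws
  # positivity of slopes, lambda, residual SDs
  for (fam in c("^alpha_s", "^alpha_f", "^nu_phi$", "^nu_psi$", "^lambda$",
                "^sigma_")) {
    cols <- grep(fam, colnames(d))
    expect_true(all(d[, cols] > 0), label = fam)
  }
  # correlations within (-1, 1)
  sc <- grep("^Sigma\\[", colnames(d))
  expect_true(all(abs(d[, sc]) < 1))
  # first-category and first-class intercepts are not free parameters
  expect_false(any(grepl("gamma_..?\\[\\d+,0\\]", colnames(d))))
  expect_false(any(grepl("beta\\[\\d+,0\\]", colnames(d))))
  # stored draw count and chain bookkeeping
  expect_equal(nrow(d), fit$mcmc$chains * fit$mcmc$iter)
  expect_equal(sort(unique(fit$chain_id)), 1:2)
})

test_that("saved log-likelihoods equal the independent R kernel", {
  tf <- cached_tiny_fit()
  fit <- tf$fit
  s <- nrow(fit$draws)          # last draw
  u <- fakemix:::unpack_draw(fit, s)
  D <- fit$wa$D
  items <- lapply(seq_along(fit$items), function(i) item_parameters(
    trait_slopes = u$aS[i, ], faking_slope = u$aF[i],
    gamma_s = u$gS[i, ], gamma_sf = u$gSF[i, ], gamma_f = u$gF[i, ],
    beta = u$beta[i, ], delta_s = u$dS[i], delta_f = u$dF[i]))
  P <- fit$config$P
  Sig <- diag(P)
  dr <- fit$draws[s, ]
  for (a in 1:(P - 1)) for (b in (a + 1):P) {
    Sig[a, b] <- Sig[b, a] <- dr[sprintf("Sigma[%d,%d]", a, b)]
  }
  pop <- population_parameters(Sig, nu_phi = u$globals[1],
                               nu_psi = u$globals[2], lambda = u$globals[3],
                               sigma_s = u$globals[4],
                               sigma_sf = u$globals[5],
                               sigma_f = u$globals[6])
  persons <- lapply(seq_len(nrow(u$persons)), function(n) person_parameters(
    theta = u$persons[n, seq_len(D)], eta = u$persons[n, D + 1],
    phi = u$persons[n, D + 2], psi = u$persons[n, D + 3]))
  ll <- joint_marginal_loglik(tf$data, items, tf$design$weights, persons,
                              pop, include_rt = TRUE)
  expect_equal(ll, fit$ll_joint[s], tolerance = 1e-8)
  llr <- joint_marginal_loglik(tf$data, items, tf$design$weights, persons,
                               pop, include_rt = FALSE)
  expect_equal(llr, fit$ll_resp[s], tolerance = 1e-8)
})

test_that("split R-hat flags separated chains and passes stationary ones", {
  set.seed(31)
  x_good <- rnorm(400)
  chain <- rep(1:2, each = 200)
  rh_good <- fakemix:::split_rhat_one(x_good, chain)
  expect_lt(rh_good, 1.02)
  expect_gt(rh_good, 0.98)   # the split statistic can dip slightly below 1
  x_bad <- c(rnorm(200), rnorm(200) + 10)
  expect_gt(fakemix:::split_rhat_one(x_bad, chain), 1.1)
  expect_error(fakemix:::split_rhat_one(rnorm(100), rep(1, 100)), "chains")

  tf <- cached_tiny_fit()
  chk <- check_convergence(tf$fit, threshold = Inf)
  expect_true(chk$converged)
  chk2 <- check_convergence(tf$fit, threshold = 1.0)
  expect_false(chk2$converged)
  expect_gt(nrow(chk2$offending), 0)
  # person scores can be added to the monitored set
  rh_p <- split_rhat(tf$fit, include_persons = TRUE)
  expect_gt(nrow(rh_p), nrow(tf$fit$rhat))
})

test_that("tidy and glance summarize fits", {
  tf <- cached_tiny_fit()
  td <- tidy(tf$fit)
  expect_true(all(c("term", "estimate", "std.error", "conf.low",
                    "conf.high", "rhat") %in% names(td)))
  expect_equal(nrow(td), ncol(tf$fit$draws))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(tf$fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$variant, "person_by_item_rt")
  expect_lt(gl$loglik_joint, gl$loglik_resp)  # RT factors add density mass
})

test_that("marginalized sampler agrees with an explicit class-augmented
          Gibbs sampler on the same tiny posterior", {
  set.seed(5)
  d <- sim_design(n_persons = 16, n_traits = 1, items_per_trait = 3,
                  n_categories = 3)
  dat <- simulate_assessment(d, seed = 5)
  ref <- zeta_augmented_gibbs(dat, d, n_iter = 600, n_warmup = 350)
  fit <- fit_faking_model(dat, d$weights, "person_by_item_rt",
                          mcmc = mcmc_config(chains = 2, warmup = 300,
                                             iter = 500, thin = 2,
                                             seed = 5))
  # both samplers target the same posterior; posterior means must agree
  # within Monte-Carlo error (both posteriors are wide at this tiny size)
  expect_lt(abs(mean(ref$lambda) - mean(fit$draws[, "lambda"])),
            3 * (sd(ref$lambda) + sd(fit$draws[, "lambda"])) / sqrt(50))
  expect_lt(abs(mean(ref$nu_psi) - mean(fit$draws[, "nu_psi"])),
            3 * (sd(ref$nu_psi) + sd(fit$draws[, "nu_psi"])) / sqrt(50))
})

test_that("the person mixture recovers its own mixing structure", {
  # constant class per person; desirability trajectories chosen distinct
  # from the trait weights so the classes are well separated
  set.seed(77)
  K1 <- 4; I <- 8; N <- 150
  pi_true <- c(0.5, 0.2, 0.3)
  fws <- list(c(6, 4, 2, 0), c(0, 6, 6, 0), c(6, 0, 0, 6), c(5, 6, 1, 0),
              c(6, 4, 2, 0), c(0, 6, 6, 0), c(6, 0, 0, 6), c(5, 6, 1, 0))
  weights <- lapply(fws, function(f) scoring_weights(1, 1, K1, f))
  items <- lapply(seq_len(I), function(i) item_parameters(
    trait_slopes = runif(1, 0.8, 1.4), faking_slope = runif(1, 0.8, 1.4),
    gamma_s = c(0, rnorm(3)), gamma_sf = c(0, rnorm(3)),
    gamma_f = c(0, rnorm(3)), beta = c(0, 0, 0),
    delta_s = rnorm(1, 1.72, .2), delta_f = rnorm(1, 1.53, .2)))
  pop <- population_parameters(default_latent_correlations(1), nu_phi = 1,
                               nu_psi = 1.05, lambda = 0.23)
  persons <- draw_persons(N, pop$Sigma, seed = 79)
  plist <- fakemix:::persons_to_list(persons)
  zeta_n <- sample(0:2, N, replace = TRUE, prob = pi_true)
  rows <- list()
  for (n in seq_len(N)) for (i in seq_len(I)) {
    z <- zeta_n[n]
    y <- sample(0:3, 1, prob = category_probabilities(z, plist[[n]],
                                                      items[[i]],
                                                      weights[[i]]))
    mu <- fakemix:::rt_log_mean(z, plist[[n]]$phi, items[[i]], pop)
    rows[[length(rows) + 1]] <- tibble::tibble(
      person_id = persons$person_id[n], item_id = sprintf("i%02d", i),
      response = y, rt_seconds = exp(rnorm(1, mu, fakemix:::rt_sd(z, pop))),
      true_class = z)
  }
  dat <- fakemix:::validate_assessment(dplyr::bind_rows(rows))
  fit <- fit_faking_model(dat, weights, "person_mix_no_rt",
                          mcmc = mcmc_config(chains = 2, warmup = 300,
                                             iter = 300, thin = 3,
                                             seed = 80))
  pi_est <- colMeans(fit$draws[, c("pi[1]", "pi[2]", "pi[3]")])
  expect_equal(sum(pi_est), 1, tolerance = 1e-9)
  # the honest proportion and the combined faked proportion are well
  # identified; the split of the two faking classes is much less so (the
  # person mixture tends to shift mass from faking-only toward the
  # dual-process class, the documented behavior of this model family)
  expect_lt(abs(pi_est[1] - pi_true[1]), 0.15)
  expect_lt(abs(sum(pi_est[2:3]) - sum(pi_true[2:3])), 0.15)
})

test_that("prior misconfiguration and bad inputs are rejected", {
  tf <- cached_tiny_fit()
  expect_error(prior_config(slope_sd = -1), "positive")
  expect_error(fit_faking_model(tf$data, tf$design$weights,
                                variant = "nonexistent_model"))
  no_rt <- dplyr::select(tf$data, -rt_seconds)
  expect_error(fit_faking_model(no_rt, tf$design$weights,
                                "person_by_item_rt"), "response times")
})
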