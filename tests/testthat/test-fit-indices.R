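test_that("WAIC matches the analytic conjugate-normal oracle", {
  # Known-sigma normal mean model with conjugate normal prior: lppd and
  # p_waic have closed forms, evaluated here directly from the posterior.
  set.seed(3)
  sigma <- 1.3; tau <- 2; n <- 40
  yy <- rnorm(n, 0.8, sigma)
  v_post <- 1 / (n / sigma^2 + 1 / tau^2)
  m_post <- v_post * sum(yy) / sigma^2
  S <- 40000
  mu_draws <- rnorm(S, m_post, sqrt(v_post))
  L <- vapply(yy, function(yi) dnorm(yi, mu_draws, sigma, log = TRUE),
              numeric(S))
  got <- fakemix:::waic_from_loglik(L)
  lppd_true <- sum(dnorm(yy, m_post, sqrt(sigma^2 + v_post), log = TRUE))
  p_waic_true <- sum((2 * v_post^2 + 4 * v_post * (yy - m_post)^2) /
                       (4 * sigma^4))
  expect_equal(got$lppd, lppd_true, tolerance = 0.02)
  expect_equal(got$p_waic, p_waic_true, tolerance = 0.02)
  expect_equal(got$waic, -2 * (lppd_true - p_waic_true), tolerance = 0.1)
})

test_that("generalized Pareto fit recovers known shape parameters", {
  set.seed(4)
  for (k in c(0.2, 0.5)) {
    sigma <- 1
    u <- runif(4000)
    x <- sigma * (u^(-k) - 1) / k      # GPD quantile transform
    f <- fakemix:::gpd_fit(x)
    expect_equal(f$k, k, tolerance = 0.12)
    expect_equal(f$sigma, sigma, tolerance = 0.15)
  }
  # quantile function round-trip
  expect_equal(fakemix:::qgpd(0.5, 0.3, 2),
               2 * ((1 - 0.5)^(-0.3) - 1) / 0.3)
})

test_that("information criteria are deterministic given draws and scopes
          behave correctly", {
  tf <- cached_tiny_fit()
  ic1 <- information_criteria(tf$fit, "response_only", n_draws = 80)
  ic2 <- information_criteria(tf$fit, "response_only", n_draws = 80)
  expect_identical(ic1, ic2)

  # response-only criteria ignore the response times entirely
  fit_perturbed <- tf$fit
  fit_perturbed$logt <- tf$fit$logt + rnorm(length(tf$fit$logt), 0, 0.5)
  ic3 <- information_criteria(fit_perturbed, "response_only", n_draws = 80)
  expect_equal(ic1$waic, ic3$waic)
  expect_equal(ic1$looic, ic3$looic)

  # joint criteria do use them
  icj <- information_criteria(tf$fit, "joint", n_draws = 80)
  icj2 <- information_criteria(fit_perturbed, "joint", n_draws = 80)
  expect_false(isTRUE(all.equal(icj$waic, icj2$waic)))

  # non-RT model has no joint scope
  expect_error(pointwise_loglik(
    structure(list(config = list(include_rt = FALSE)),
              class = "faking_fit"), "joint"), "RT models")

  # WAIC and LOOIC estimate the same out-of-sample deviance; at modest
  # draw counts they agree to within a few percent
  expect_lt(abs(ic1$looic - ic1$waic) / abs(ic1$waic), 0.2)
})

test_that("SRMR has its hand-computable values on injected replications", {
  tf <- cached_tiny_fit()
  # replications identical to the observed data: zero misfit
  r0 <- ppmc_srmr(tf$fit, replications = list(tf$fit$y, tf$fit$y))
  expect_equal(r0$srmr, 0)
  # per-replicate flag averages replicate-wise SRMRs
  r1 <- ppmc_srmr(tf$fit, replications = list(tf$fit$y), per_replicate = TRUE)
  expect_equal(r1$srmr, 0)
  # model-simulated replications give small but nonzero misfit
  r2 <- ppmc_srmr(tf$fit, n_rep = 30, seed = 2)
  expect_gt(r2$srmr, 0)
  expect_lt(r2$srmr, 0.2)
})

test_that("RT posterior predictive p-values count exceedances per item", {
  tf <- cached_tiny_fit()
  obs_t <- exp(tf$fit$logt)
  reps <- list(obs_t * 2, obs_t * 2, obs_t * 2, obs_t * 0.5)
  p <- ppp_rt_means(tf$fit, replications = reps)
  expect_equal(p$ppp, rep(0.75, ncol(obs_t)))   # 3 of 4 replications above
  # a correctly specified model is not systematically off
  p2 <- ppp_rt_means(tf$fit, n_rep = 60, seed = 9)
  expect_true(all(p2$ppp > 0 & p2$ppp < 1))
  expect_gt(mean(p2$ppp), 0.1)
  expect_lt(mean(p2$ppp), 0.9)
  # inflating the time intensities pushes all p-values toward 1
  fit_inflated <- tf$fit
  dcols <- grep("^delta_", colnames(fit_inflated$draws))
  fit_inflated$draws[, dcols] <- fit_inflated$draws[, dcols] + 1
  p3 <- ppp_rt_means(fit_inflated, n_rep = 40, seed = 10)
  expect_true(all(p3$ppp > 0.9))
})
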