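#' Prior configuration
#'
#' Defaults follow the model's reference specification: positively
#' truncated normal N+(0, 2^2) priors for all slopes, N(0, 4^2) for
#' category and class intercepts, N(mean log-RT, 1) for time intensities,
#' N+(0, 0.5^2) for the proportionality constant, half-Cauchy t+(1) for
#' residual SDs of log-RTs, and a flat prior over positive definite
#' correlation matrices.
#'
#' @param slope_sd,intercept_sd,delta_sd,lambda_sd,cauchy_scale Prior
#'   scales; see description.
#' @return A list of class `"prior_config"`.
#' @export
prior_config <- function(slope_sd = 2, intercept_sd = 4, delta_sd = 1,
                         lambda_sd = 0.5, cauchy_scale = 1) {
  vals <- c(slope_sd, intercept_sd, delta_sd, lambda_sd, cauchy_scale)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("Prior scales must be positive and finite.")
  }
  structure(list(slope_sd = slope_sd, intercept_sd = intercept_sd,
                 delta_sd = delta_sd, lambda_sd = lambda_sd,
                 cauchy_scale = cauchy_scale),
            class = "prior_config")
}

#' MCMC configuration
#'
#' @param chains Number of chains.
#' @param warmup Warmup (adaptation) iterations per chain.
#' @param iter Retained sampling iterations per chain.
#' @param thin Internal Metropolis-within-Gibbs sweeps per iteration; every
#'   iteration of the sampler comprises `thin` full parameter sweeps, which
#'   compensates for the shorter moves of random-walk updates.
#' @param seed RNG seed.
#' @param init_jitter SD of the log/location jitter dispersing chain
#'   starting points.
#' @return A list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(chains = 2, warmup = 500, iter = 500, thin = 3,
                        seed = NULL, init_jitter = 0.25) {
  stopifnot(chains >= 1, warmup >= 1, iter >= 1, thin >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), thin = as.integer(thin),
                 seed = seed, init_jitter = init_jitter),
            class = "mcmc_config")
}

model_variants <- function() {
  c("person_by_item_rt", "person_by_item_no_rt", "person_mix_rt",
    "person_mix_no_rt", "nonmixture_mnrm", "nonmixture_mgpcm",
    "nonmixture_nrm")
}

variant_config <- function(variant) {
  switch(variant,
    person_by_item_rt    = list(mixture = 2L, include_rt = TRUE,
                                resp_class = 0L),
    person_by_item_no_rt = list(mixture = 2L, include_rt = FALSE,
                                resp_class = 0L),
    person_mix_rt        = list(mixture = 1L, include_rt = TRUE,
                                resp_class = 0L),
    person_mix_no_rt     = list(mixture = 1L, include_rt = FALSE,
                                resp_class = 0L),
    nonmixture_mnrm      = list(mixture = 0L, include_rt = FALSE,
                                resp_class = 1L),
    nonmixture_mgpcm     = list(mixture = 0L, include_rt = FALSE,
                                resp_class = 0L),
    nonmixture_nrm       = list(mixture = 0L, include_rt = FALSE,
                                resp_class = 2L),
    stop("Unknown model variant: ", variant))
}

weights_arrays <- function(weights) {
  I <- length(weights)
  D <- nrow(weights[[1]]$trait)
  K1 <- ncol(weights[[1]]$trait)
  ws <- array(0, c(I, D, K1))
  wf <- matrix(0, I, K1)
  for (i in seq_len(I)) {
    if (!identical(dim(weights[[i]]$trait), c(D, K1))) {
      stop("All items must share trait dimensions and category count.")
    }
    ws[i, , ] <- weights[[i]]$trait
    wf[i, ] <- weights[[i]]$faking
  }
  list(ws = ws, wf = wf, D = D, K1 = K1)
}

#' Fit the faking mixture model (or a reduced comparison model)
#'
#' Bayesian estimation via an adaptive Metropolis-within-Gibbs sampler.
#' For the person-by-item variants the discrete strategy classes are
#' marginalized out of the likelihood (exact three-term log-sum-exp per
#' cell) rather than sampled; for the person mixture variants the
#' person-level class is marginalized given mixing proportions with a flat
#' Dirichlet prior. Identification is imposed exactly: first category and
#' first-class intercepts fixed at 0, latent means 0 and variances 1,
#' positivity of slopes, the proportionality constant and residual SDs.
#'
#' @param data Assessment tibble (long format; see [read_assessment()]).
#' @param weights List of [scoring_weights()], one per item, in the item
#'   order of `data`.
#' @param variant One of `"person_by_item_rt"`, `"person_by_item_no_rt"`,
#'   `"person_mix_rt"`, `"person_mix_no_rt"`, `"nonmixture_mnrm"`,
#'   `"nonmixture_mgpcm"`, `"nonmixture_nrm"`.
#' @param priors A [prior_config()].
#' @param mcmc An [mcmc_config()].
#' @param rhat_threshold Convergence threshold for split R-hat.
#' @param monitor_persons Include per-person latent scores in the
#'   convergence-monitored set (model parameters only, by default).
#' @return An object of class `"faking_fit"`.
#' @export
fit_faking_model <- function(data, weights,
                             variant = "person_by_item_rt",
                             priors = prior_config(),
                             mcmc = mcmc_config(),
                             rhat_threshold = 1.1,
                             monitor_persons = FALSE) {
  variant <- match.arg(variant, model_variants())
  cfg <- variant_config(variant)
  stopifnot(inherits(priors, "prior_config"), inherits(mcmc, "mcmc_config"))
  mats <- assessment_matrices(data)
  wa <- weights_arrays(weights)
  if (length(weights) != ncol(mats$y)) {
    stop("One scoring-weight entry per item is required.")
  }
  if (anyNA(mats$y) || any(mats$y < 0 | mats$y > wa$K1 - 1)) {
    stop("Responses must be complete and within 0..K.")
  }
  logt <- matrix(0, nrow(mats$y), ncol(mats$y))
  if (cfg$include_rt) {
    if (anyNA(mats$t) || any(mats$t <= 0)) {
      stop("Complete positive response times are required for RT variants.")
    }
    logt <- log(mats$t)
  }
  priors_full <- c(unclass(priors),
                   list(delta_mean = if (cfg$include_rt) mean(logt) else 0))
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)

  # data-informed starting values (jittered per chain inside the sampler):
  # marginal category logits for intercepts, item mean log-RTs for time
  # intensities, standardized person summaries for trait/speed scores
  K1 <- wa$K1
  ginit <- t(vapply(seq_len(ncol(mats$y)), function(i) {
    f <- tabulate(mats$y[, i] + 1L, K1) + 0.5
    log(f / f[1])
  }, numeric(K1)))
  dinit <- if (cfg$include_rt) colMeans(logt) else rep(0, ncol(mats$y))
  std0 <- function(v) {
    s <- sd(v)
    if (s < 1e-12) rep(0, length(v)) else (v - mean(v)) / s
  }
  D <- wa$D
  theta_init <- vapply(seq_len(D), function(d) {
    on_d <- vapply(weights, function(w) any(w$trait[d, ] != 0), logical(1))
    if (!any(on_d)) return(rep(0, nrow(mats$y)))
    std0(rowMeans(mats$y[, on_d, drop = FALSE]))
  }, numeric(nrow(mats$y)))
  phi_init <- if (cfg$include_rt) -std0(rowMeans(logt))
              else rep(0, nrow(mats$y))
  inits <- list(gamma = ginit, delta = dinit,
                theta = theta_init, phi = phi_init,
                sigma = if (cfg$include_rt) sd(logt) else 1)

  res <- fit_sampler_cpp(mats$y, logt, wa$ws, wa$wf, cfg, priors_full,
                         list(chains = mcmc$chains, warmup = mcmc$warmup,
                              iter = mcmc$iter, thin = mcmc$thin,
                              init_jitter = mcmc$init_jitter),
                         inits)
  layout <- res$person_layout
  fit <- structure(list(
    variant = variant, config = c(cfg, layout),
    draws = res$draws, person_draws = res$person_draws,
    chain_id = res$chain_id,
    ll_joint = res$ll_joint, ll_resp = res$ll_resp,
    persons = mats$persons, items = mats$items,
    weights = weights, wa = wa,
    y = mats$y, logt = if (cfg$include_rt) logt else NULL,
    priors = priors, mcmc = mcmc), class = "faking_fit")
  fit$rhat <- split_rhat(fit, include_persons = monitor_persons)
  fit$converged <- all(fit$rhat$rhat < rhat_threshold, na.rm = TRUE)
  fit$rhat_threshold <- rhat_threshold
  fit
}

#' Split R-hat for all monitored parameters of a fit
#'
#' Each chain is split in half; the potential scale reduction factor is the
#' usual between/within variance ratio over the split chains.
#'
#' @param fit A `"faking_fit"`.
#' @param include_persons Also monitor the per-person latent scores.
#' @return Tibble with columns `term` and `rhat`.
#' @export
split_rhat <- function(fit, include_persons = FALSE) {
  draws <- fit$draws
  chain <- fit$chain_id
  rh <- vapply(seq_len(ncol(draws)), function(j) {
    split_rhat_one(draws[, j], chain)
  }, numeric(1))
  out <- tibble::tibble(term = colnames(draws), rhat = rh)
  if (include_persons) {
    pd <- fit$person_draws
    dm <- dim(pd)
    prh <- vapply(seq_len(dm[2] * dm[3]), function(j) {
      n <- (j - 1) %% dm[2] + 1
      p <- (j - 1) %/% dm[2] + 1
      split_rhat_one(pd[, n, p], chain)
    }, numeric(1))
    terms <- as.vector(outer(seq_len(dm[2]), seq_len(dm[3]),
                             function(n, p) sprintf("person[%d,%d]", n, p)))
    out <- dplyr::bind_rows(out, tibble::tibble(term = terms, rhat = prh))
  }
  out
}

split_rhat_one <- function(x, chain) {
  if (length(unique(chain)) < 2) {
    stop("Split R-hat requires at least 2 chains.")
  }
  pieces <- list()
  for (ch in unique(chain)) {
    xs <- x[chain == ch]
    h <- floor(length(xs) / 2)
    pieces <- c(pieces, list(xs[seq_len(h)], xs[h + seq_len(h)]))
  }
  m <- length(pieces)
  n <- length(pieces[[1]])
  if (m < 2 || n < 2) stop("Split R-hat requires at least 2 chains of 4+ draws.")
  means <- vapply(pieces, mean, numeric(1))
  vars <- vapply(pieces, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence check against an R-hat threshold
#'
#' @param fit A `"faking_fit"`.
#' @param threshold Split R-hat threshold (default 1.1).
#' @param include_persons Also check person latent scores.
#' @return List with `converged` flag and tibble `offending` of parameters
#'   at or above the threshold.
#' @export
check_convergence <- function(fit, threshold = 1.1,
                              include_persons = FALSE) {
  rh <- split_rhat(fit, include_persons = include_persons)
  bad <- dplyr::filter(rh, .data$rhat >= threshold)
  list(converged = nrow(bad) == 0, offending = bad)
}

# posterior means of every stored model parameter, as a named vector
param_means <- function(fit) colMeans(fit$draws)

# posterior-mean person scores: matrix N x P with latent column names
person_means <- function(fit) {
  pm <- apply(fit$person_draws, c(2, 3), mean)
  colnames(pm) <- person_colnames(fit)
  rownames(pm) <- fit$persons
  pm
}

person_colnames <- function(fit) {
  cfg <- fit$config
  D <- fit$wa$D
  nm <- character(cfg$P)
  if (cfg$col_theta0 >= 0) nm[cfg$col_theta0 + seq_len(D)] <-
      sprintf("theta_%d", seq_len(D))
  if (cfg$col_eta >= 0) nm[cfg$col_eta + 1] <- "eta"
  if (cfg$col_phi >= 0) nm[cfg$col_phi + 1] <- "phi"
  if (cfg$col_psi >= 0) nm[cfg$col_psi + 1] <- "psi"
  nm
}

#' @export
print.faking_fit <- function(x, ...) {
  cat("Faking mixture model fit (", x$variant, ")\n", sep = "")
  cat(sprintf("  %d persons x %d items, %d categories\n",
              length(x$persons), length(x$items), x$wa$K1))
  cat(sprintf("  %d chains x %d retained iterations (thin %d)\n",
              x$mcmc$chains, x$mcmc$iter, x$mcmc$thin))
  cat(sprintf("  converged (all split R-hat < %.2f): %s; max R-hat %.3f\n",
              x$rhat_threshold, x$converged, max(x$rhat$rhat)))
  cat(sprintf("  posterior mean joint log-likelihood: %.1f\n",
              mean(x$ll_joint)))
  invisible(x)
}

#' Tidy posterior summaries of a fitted model
#'
#' @param x A `"faking_fit"`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (posterior mean), `std.error`
#'   (posterior SD), `conf.low`/`conf.high` (central 95% credible
#'   interval), `rhat`.
#' @export
tidy.faking_fit <- function(x, ...) {
  d <- x$draws
  tibble::tibble(
    term = colnames(d),
    estimate = colMeans(d),
    std.error = apply(d, 2, sd),
    conf.low = apply(d, 2, quantile, 0.025),
    conf.high = apply(d, 2, quantile, 0.975)) |>
    dplyr::left_join(x$rhat, by = "term")
}

#' One-row model summary
#'
#' @inheritParams tidy.faking_fit
#' @return Tibble with fit metadata, convergence flag and posterior mean
#'   log-likelihoods (response-only and, for RT variants, joint).
#' @export
glance.faking_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    n_persons = length(x$persons),
    n_items = length(x$items),
    n_draws = nrow(x$draws),
    converged = x$converged,
    max_rhat = max(x$rhat$rhat),
    loglik_resp = mean(x$ll_resp),
    loglik_joint = if (x$config$include_rt) mean(x$ll_joint) else NA_real_)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
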