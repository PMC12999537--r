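# ---- pointwise log-likelihood --------------------------------------------

#' Pointwise log-likelihood matrix
#'
#' One row per posterior draw, one column per person-item cell; each entry
#' is the log marginal likelihood of the cell (classes marginalized out).
#' The `response_only` scope drops the response-time factors from the
#' mixture, matching fit indices computed "with respect to item responses
#' only"; the `joint` scope keeps them.
#'
#' @param fit A `"faking_fit"`.
#' @param scope `"response_only"` or `"joint"`.
#' @param n_draws Number of evenly thinned posterior draws.
#' @return Matrix `n_draws x (N * I)`.
#' @export
pointwise_loglik <- function(fit, scope = c("response_only", "joint"),
                             n_draws = 400) {
  scope <- match.arg(scope)
  if (scope == "joint" && !fit$config$include_rt) {
    stop("Joint-scope likelihood is defined only for RT models.")
  }
  map <- draw_index_map(fit)
  ss <- draw_subsample(fit, n_draws)
  N <- nrow(fit$y); I <- ncol(fit$y)
  out <- matrix(NA_real_, length(ss), N * I)
  for (j in seq_along(ss)) {
    terms <- draw_cell_terms(fit, ss[j], map)
    lp <- terms$cls + terms$resp
    if (scope == "joint") lp <- lp + terms$rt
    m <- pmax(lp[, , 1], pmax(lp[, , 2], lp[, , 3]))
    ok <- is.finite(m)
    v <- m + log(exp(lp[, , 1] - m) + exp(lp[, , 2] - m) +
                   exp(lp[, , 3] - m))
    v[!ok] <- -Inf
    out[j, ] <- as.vector(v)
  }
  out
}

#' WAIC and PSIS-LOO information criteria
#'
#' WAIC is `-2 * (lppd - p_waic)` with the effective number of parameters
#' `p_waic` equal to the sum of posterior variances of the pointwise
#' log-likelihood. LOOIC is computed from the same pointwise array via
#' Pareto-smoothed importance sampling; cells whose estimated Pareto shape
#' exceeds 0.7 are counted and reported, not hidden.
#'
#' @inheritParams pointwise_loglik
#' @return Tibble with `scope`, `waic`, `p_waic`, `looic`, `p_loo`,
#'   `n_high_pareto_k`.
#' @export
information_criteria <- function(fit, scope = c("response_only", "joint"),
                                 n_draws = 400) {
  scope <- match.arg(scope)
  L <- pointwise_loglik(fit, scope, n_draws)
  w <- waic_from_loglik(L)
  loo <- psis_loo(L)
  tibble::tibble(scope = scope,
                 waic = w$waic, p_waic = w$p_waic,
                 looic = loo$looic, p_loo = loo$p_loo,
                 n_high_pareto_k = loo$n_high_k)
}

# WAIC pieces from a draws x cells pointwise log-likelihood matrix
waic_from_loglik <- function(L) {
  S <- nrow(L)
  lppd_i <- apply(L, 2, matrixStats_logsumexp) - log(S)
  p_waic_i <- apply(L, 2, stats::var)
  list(waic = -2 * sum(lppd_i - p_waic_i), lppd = sum(lppd_i),
       p_waic = sum(p_waic_i))
}

# ---- Pareto-smoothed importance sampling ---------------------------------

# Generalized Pareto fit (profile-posterior method of Zhang & Stephens)
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30 + floor(sqrt(n))
  prior <- 3
  q <- x[max(1, floor(n / 4 + 0.5))]
  b <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (prior * q)
  profile_ll <- vapply(b, function(bb) {
    k <- -mean(log1p(-bb * x))
    n * (log(bb / k) + k - 1)
  }, numeric(1))
  w <- exp(profile_ll - matrixStats_logsumexp(profile_ll))
  b_hat <- sum(b * w)
  k_hat <- mean(log1p(-b_hat * x))      # shape in the usual xi convention
  sigma_hat <- -k_hat / b_hat
  list(k = k_hat, sigma = sigma_hat)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# smooth one cell's log importance weights; returns smoothed lw and k-hat
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  tail_len <- min(0.2 * S, 3 * sqrt(S))
  tail_len <- max(5, floor(tail_len))
  if (tail_len >= S - 1) return(list(lw = lw, k = Inf))
  ord <- order(lw)
  cut <- lw[ord[S - tail_len]]
  tail_ids <- ord[(S - tail_len + 1):S]
  exceed <- exp(lw[tail_ids]) - exp(cut)
  if (all(exceed <= 0) || length(unique(lw[tail_ids])) < 3) {
    return(list(lw = lw, k = 0))
  }
  fitg <- gpd_fit(exceed)
  p <- (rank(lw[tail_ids], ties.method = "first") - 0.5) / tail_len
  sm <- log(exp(cut) + vapply(p, qgpd, numeric(1), k = fitg$k,
                              sigma = fitg$sigma))
  lw[tail_ids] <- pmin(sm, 0)  # never above the raw maximum (= 0)
  list(lw = lw, k = fitg$k)
}

psis_loo <- function(L) {
  S <- nrow(L)
  elpd <- numeric(ncol(L))
  khat <- numeric(ncol(L))
  for (j in seq_len(ncol(L))) {
    sm <- psis_smooth(-L[, j])
    lw <- sm$lw - matrixStats_logsumexp(sm$lw)
    elpd[j] <- matrixStats_logsumexp(lw + L[, j])
    khat[j] <- sm$k
  }
  lppd <- apply(L, 2, matrixStats_logsumexp) - log(S)
  list(looic = -2 * sum(elpd), p_loo = sum(lppd - elpd),
       n_high_k = sum(khat > 0.7), pareto_k = khat)
}

# ---- Table-1-style fit report --------------------------------------------

#' Model-fit battery for a set of fitted models
#'
#' Computes, for each fit, the posterior mean log-likelihood, WAIC and
#' LOOIC (response-only, plus joint for RT models), the posterior
#' predictive SRMR for item intercorrelations, and (for RT models) the
#' mean and range of per-item response-time posterior predictive p-values.
#'
#' @param fits Named list of `"faking_fit"` objects.
#' @param n_draws Posterior draws for the information criteria.
#' @param n_rep Posterior predictive replications for SRMR / RT-PPP.
#' @return Tibble, one row per model.
#' @export
fit_report <- function(fits, n_draws = 300, n_rep = 100) {
  purrr::imap_dfr(fits, function(fit, name) {
    ic_resp <- information_criteria(fit, "response_only", n_draws)
    joint <- fit$config$include_rt
    ic_joint <- if (joint) information_criteria(fit, "joint", n_draws)
    srmr <- ppmc_srmr(fit, n_rep = n_rep)
    ppp <- if (joint) ppp_rt_means(fit, n_rep = n_rep)
    tibble::tibble(
      model = name,
      converged = fit$converged,
      loglik = mean(fit$ll_resp),
      waic = ic_resp$waic, looic = ic_resp$looic,
      loglik_joint = if (joint) mean(fit$ll_joint) else NA_real_,
      waic_joint = if (joint) ic_joint$waic else NA_real_,
      looic_joint = if (joint) ic_joint$looic else NA_real_,
      srmr = srmr$srmr,
      rt_ppp_mean = if (joint) mean(ppp$ppp) else NA_real_,
      rt_ppp_min = if (joint) min(ppp$ppp) else NA_real_,
      rt_ppp_max = if (joint) max(ppp$ppp) else NA_real_)
  })
}
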