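# vectorized categorical sampler over rows of a probability matrix
rcat_rows <- function(P) {
  K1 <- ncol(P)
  U <- upper.tri(matrix(0, K1, K1), diag = TRUE)
  CP <- P %*% U                       # row-wise cumulative probabilities
  u <- runif(nrow(P))
  as.integer(rowSums(u > CP))         # 0-based category
}

# simulate one replicated dataset from the parameters of posterior draw s
pp_simulate <- function(fit, s, map = draw_index_map(fit)) {
  u <- unpack_draw(fit, s, map)
  cfg <- fit$config
  N <- nrow(fit$y); I <- ncol(fit$y); K1 <- fit$wa$K1; D <- fit$wa$D
  theta <- if (cfg$col_theta0 >= 0)
    u$persons[, cfg$col_theta0 + seq_len(D), drop = FALSE]
  else matrix(0, N, D)
  eta <- if (cfg$col_eta >= 0) u$persons[, cfg$col_eta + 1] else numeric(N)
  phi <- if (cfg$col_phi >= 0) u$persons[, cfg$col_phi + 1] else numeric(N)
  psi <- if (cfg$col_psi >= 0) u$persons[, cfg$col_psi + 1] else numeric(N)
  nphi <- u$globals[1]; npsi <- u$globals[2]; lam <- u$globals[3]
  sig <- u$globals[4:6]

  # person-level class for the person mixture; cell-level otherwise
  zeta_person <- NULL
  if (cfg$mixture == 1) {
    zeta_person <- rcat_rows(matrix(exp(u$lpi), N, 3, byrow = TRUE))
  }
  y <- matrix(NA_integer_, N, I)
  tt <- if (cfg$include_rt) matrix(NA_real_, N, I)
  for (i in seq_len(I)) {
    # category propensities per class (N x K1 each)
    W <- matrix(fit$wa$ws[i, , ], nrow = D)   # D x K1, robust to D = 1
    trait_term <- theta %*% (u$aS[i, ] * W)
    fake_term <- outer(eta, u$aF[i] * fit$wa$wf[i, ])
    soft <- function(pro) {
      e <- exp(pro - apply(pro, 1, max))
      e / rowSums(e)
    }
    if (cfg$mixture == 2) {
      z1 <- npsi * psi + u$beta[i, 2]; z2 <- 2 * npsi * psi + u$beta[i, 3]
      pcl <- soft(cbind(0, z1, z2))
      zeta <- rcat_rows(pcl)
    } else if (cfg$mixture == 1) {
      zeta <- zeta_person
    } else {
      zeta <- rep(cfg$resp_class, N)
    }
    probs <- matrix(NA_real_, N, K1)
    for (cl in unique(zeta)) {
      rows <- which(zeta == cl)
      pro <- switch(as.character(cl),
        "0" = trait_term[rows, , drop = FALSE] +
              matrix(u$gS[i, ], length(rows), K1, byrow = TRUE),
        "1" = trait_term[rows, , drop = FALSE] +
              fake_term[rows, , drop = FALSE] +
              matrix(u$gSF[i, ], length(rows), K1, byrow = TRUE),
        "2" = fake_term[rows, , drop = FALSE] +
              matrix(u$gF[i, ], length(rows), K1, byrow = TRUE))
      probs[rows, ] <- soft(pro)
    }
    y[, i] <- rcat_rows(probs)
    if (cfg$include_rt) {
      mu <- ifelse(zeta == 0, u$dS[i],
                   ifelse(zeta == 1, u$dS[i] + lam * u$dF[i], u$dF[i])) -
            nphi * phi
      tt[, i] <- exp(rnorm(N, mu, sig[zeta + 1]))
    }
  }
  list(y = y, t = tt)
}

#' Posterior predictive replicated datasets
#'
#' @param fit A `"faking_fit"`.
#' @param n_rep Number of replicated datasets (each from a different
#'   posterior draw, evenly thinned).
#' @param seed Optional seed.
#' @return List of replications, each with elements `y` (responses) and,
#'   for RT models, `t` (seconds).
#' @export
posterior_predict <- function(fit, n_rep = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- draw_index_map(fit)
  ss <- draw_subsample(fit, n_rep)
  lapply(ss, function(s) pp_simulate(fit, s, map))
}

#' Posterior predictive SRMR for item intercorrelations
#'
#' Misfit between observed and model-implied item intercorrelations: the
#' root mean square difference, over unique item pairs, between the
#' observed Pearson correlations of the raw category scores and the mean
#' correlations across posterior predictive replications. Constant items
#' are excluded with a warning.
#'
#' @param fit A `"faking_fit"`.
#' @param n_rep Number of posterior predictive replications.
#' @param per_replicate Average per-replicate SRMRs instead of averaging
#'   the replicated correlations first (the default).
#' @param seed Optional seed.
#' @param replications Optional list of replicated response matrices to use
#'   instead of simulating from the posterior (mainly for checking the
#'   statistic itself).
#' @return List with `srmr`, the observed and mean replicated correlation
#'   matrices, and the replication count.
#' @export
ppmc_srmr <- function(fit, n_rep = 200, per_replicate = FALSE,
                      seed = NULL, replications = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- fit$y
  keep <- apply(y, 2, sd) > 0
  if (!all(keep)) {
    warning("Excluding ", sum(!keep), " constant item(s) from SRMR.")
  }
  obs <- cor(y[, keep, drop = FALSE])
  if (is.null(replications)) {
    map <- draw_index_map(fit)
    ss <- draw_subsample(fit, n_rep)
  } else {
    ss <- seq_along(replications)
  }
  up <- upper.tri(obs)
  acc <- matrix(0, nrow(obs), ncol(obs))
  srmrs <- numeric(length(ss))
  n_used <- 0
  for (j in seq_along(ss)) {
    rep_y <- if (is.null(replications)) {
      pp_simulate(fit, ss[j], map)$y[, keep, drop = FALSE]
    } else {
      replications[[j]][, keep, drop = FALSE]
    }
    if (any(apply(rep_y, 2, sd) == 0)) next
    rc <- cor(rep_y)
    acc <- acc + rc
    n_used <- n_used + 1
    srmrs[n_used] <- sqrt(mean((obs[up] - rc[up])^2))
  }
  if (n_used == 0) stop("All replications degenerate; cannot compute SRMR.")
  mean_rep <- acc / n_used
  srmr <- if (per_replicate) mean(srmrs[seq_len(n_used)])
          else sqrt(mean((obs[up] - mean_rep[up])^2))
  list(srmr = srmr, observed = obs, replicated = mean_rep, n_rep = n_used)
}

#' Posterior predictive p-values for item mean log response times
#'
#' For every item, the fraction of replicated datasets whose mean log-RT
#' exceeds the observed mean log-RT. Values near 0 or 1 indicate
#' systematic under-/over-prediction of item-level response times.
#'
#' @inheritParams ppmc_srmr
#' @param replications Optional list of replicated RT matrices (seconds).
#' @return Tibble with `item_id`, `ppp`, plus summary columns
#'   `observed_mean_logt` and `replicated_mean_logt`.
#' @export
ppp_rt_means <- function(fit, n_rep = 200, seed = NULL,
                         replications = NULL) {
  if (!fit$config$include_rt) {
    stop("RT posterior predictive checks require an RT model.")
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- colMeans(fit$logt)
  if (is.null(replications)) {
    map <- draw_index_map(fit)
    ss <- draw_subsample(fit, n_rep)
  } else {
    ss <- seq_along(replications)
  }
  exceed <- matrix(0, length(ss), length(obs))
  repmean <- matrix(0, length(ss), length(obs))
  for (j in seq_along(ss)) {
    rep_t <- if (is.null(replications)) pp_simulate(fit, ss[j], map)$t
             else replications[[j]]
    rm <- colMeans(log(rep_t))
    repmean[j, ] <- rm
    exceed[j, ] <- as.numeric(rm > obs)
  }
  tibble::tibble(item_id = fit$items,
                 ppp = colMeans(exceed),
                 observed_mean_logt = obs,
                 replicated_mean_logt = colMeans(repmean))
}
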