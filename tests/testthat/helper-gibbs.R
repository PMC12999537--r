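# Reference sampler: explicit class-augmented Gibbs for the full
# person-by-item RT model at D = 1. The discrete classes are sampled from
# their full conditionals and every continuous parameter is updated by
# random-walk Metropolis on the complete-data posterior -- an independent
# route to the same posterior that the marginalized C++ sampler targets.
# Vectorized complete-data likelihood; tractable only at tiny scale.
zeta_augmented_gibbs <- function(data, design, n_iter = 1500,
                                 n_warmup = 800) {
  mats <- fakemix:::assessment_matrices(data)
  y <- mats$y
  lt <- log(mats$t)
  N <- nrow(y); I <- ncol(y)
  stopifnot(design$n_traits == 1)
  K1 <- design$n_categories
  ws <- t(vapply(design$weights, function(w) w$trait[1, ], numeric(K1)))
  wf <- t(vapply(design$weights, function(w) w$faking, numeric(K1)))
  mlt <- mean(lt)

  st <- list(th = rnorm(N, 0, .3), eta = rnorm(N, 0, .3),
             phi = rnorm(N, 0, .3), psi = rnorm(N, 0, .3),
             aS = rep(0.8, I), aF = rep(0.5, I),
             gS = matrix(0, I, K1), gSF = matrix(0, I, K1),
             gF = matrix(0, I, K1),
             b1 = rep(-0.5, I), b2 = rep(-1, I),
             dS = rep(mlt, I), dF = rep(mlt, I),
             nphi = 1, npsi = 1, lam = 0.2,
             sig = rep(sd(lt), 3), Sig = diag(4))

  # per-class complete-data cell log-likelihood arrays (N x I x 3)
  cell_arrays <- function(s) {
    out <- array(NA_real_, c(N, I, 3))
    cls <- array(NA_real_, c(N, I, 3))
    z1 <- outer(s$npsi * s$psi, rep(1, I)) +
      matrix(s$b1, N, I, byrow = TRUE)
    z2 <- outer(2 * s$npsi * s$psi, rep(1, I)) +
      matrix(s$b2, N, I, byrow = TRUE)
    m <- pmax(0, pmax(z1, z2))
    lsum <- m + log(exp(-m) + exp(z1 - m) + exp(z2 - m))
    cls[, , 1] <- -lsum; cls[, , 2] <- z1 - lsum; cls[, , 3] <- z2 - lsum
    for (c in 1:3) {
      pro <- array(0, c(N, I, K1))
      for (k in seq_len(K1)) {
        v <- matrix(0, N, I)
        g <- switch(c, s$gS, s$gSF, s$gF)[, k]
        v <- v + matrix(g, N, I, byrow = TRUE)
        if (c != 3) v <- v + outer(s$th, s$aS * ws[, k])
        if (c != 1) v <- v + outer(s$eta, s$aF * wf[, k])
        pro[, , k] <- v
      }
      mx <- pro[, , 1]
      for (k in seq_len(K1)[-1]) mx <- pmax(mx, pro[, , k])
      se <- exp(pro[, , 1] - mx)
      for (k in seq_len(K1)[-1]) se <- se + exp(pro[, , k] - mx)
      lse <- mx + log(se)
      obs <- matrix(NA_real_, N, I)
      for (k in seq_len(K1)) {
        sel <- y == (k - 1)
        obs[sel] <- pro[, , k][sel]
      }
      mu <- switch(c,
                   matrix(s$dS, N, I, byrow = TRUE),
                   matrix(s$dS + s$lam * s$dF, N, I, byrow = TRUE),
                   matrix(s$dF, N, I, byrow = TRUE)) - s$nphi * s$phi
      rtl <- dnorm(lt, mu, s$sig[c], log = TRUE) - lt
      out[, , c] <- cls[, , c] + obs - lse + rtl
    }
    out
  }

  complete_ll <- function(s, zeta) {
    arr <- cell_arrays(s)
    sel <- cbind(rep(seq_len(N), I), rep(seq_len(I), each = N),
                 as.vector(zeta) + 1)
    sum(arr[sel])
  }
  person_prior <- function(s) {
    X <- cbind(s$th, s$eta, s$phi, s$psi)
    Sinv <- solve(s$Sig)
    -0.5 * sum((X %*% Sinv) * X) - N / 2 *
      determinant(s$Sig)$modulus[1]
  }
  lp_prior <- function(s) {
    -0.5 * sum(s$aS^2) / 4 - 0.5 * sum(s$aF^2) / 4 -
      0.5 * (s$nphi^2 + s$npsi^2) / 4 -
      0.5 * sum(s$gS^2 + s$gSF^2 + s$gF^2) / 16 -
      0.5 * sum(s$b1^2 + s$b2^2) / 16 -
      0.5 * sum((s$dS - mlt)^2 + (s$dF - mlt)^2) -
      0.5 * s$lam^2 / 0.25 - sum(log(1 + s$sig^2))
  }
  post <- function(s, zeta) complete_ll(s, zeta) + person_prior(s) +
    lp_prior(s)

  zeta <- matrix(0L, N, I)
  lam_draws <- npsi_draws <- numeric(n_iter)
  cur <- post(st, zeta)
  # generic scalar MH on one state element
  mh <- function(field, idx, step, positive = FALSE) {
    prop <- st
    if (is.null(idx)) prop[[field]] <- st[[field]] + rnorm(1, 0, step)
    else prop[[field]][idx] <- st[[field]][idx] + rnorm(1, 0, step)
    val <- if (is.null(idx)) prop[[field]] else prop[[field]][idx]
    if (positive && any(val <= 0)) return()
    cand <- post(prop, zeta)
    if (log(runif(1)) < cand - cur) { st <<- prop; cur <<- cand }
  }
  for (it in seq_len(n_warmup + n_iter)) {
    # classes from their full conditional (responsibilities)
    arr <- cell_arrays(st)
    mx <- pmax(arr[, , 1], pmax(arr[, , 2], arr[, , 3]))
    p1 <- exp(arr[, , 1] - mx); p2 <- exp(arr[, , 2] - mx)
    p3 <- exp(arr[, , 3] - mx)
    tot <- p1 + p2 + p3
    u <- matrix(runif(N * I), N, I)
    zeta <- (u > p1 / tot) + (u > (p1 + p2) / tot)
    cur <- post(st, zeta)
    # person scores
    for (f in c("th", "eta", "phi", "psi"))
      for (n in seq_len(N)) mh(f, n, 0.5)
    # item parameters
    for (i in seq_len(I)) {
      mh("aS", i, 0.3, positive = TRUE)
      mh("aF", i, 0.3, positive = TRUE)
      for (k in 2:K1) {
        mh("gS", cbind(i, k), 0.4)
        mh("gSF", cbind(i, k), 0.4)
        mh("gF", cbind(i, k), 0.4)
      }
      mh("b1", i, 0.4); mh("b2", i, 0.4)
      mh("dS", i, 0.15); mh("dF", i, 0.15)
    }
    # globals
    mh("nphi", NULL, 0.15, positive = TRUE)
    mh("npsi", NULL, 0.15, positive = TRUE)
    mh("lam", NULL, 0.1, positive = TRUE)
    for (c in 1:3) mh("sig", c, 0.08, positive = TRUE)
    # likelihood-invariant scale moves along identification ridges
    for (mv in 1:4) {
      lc <- rnorm(1, 0, 0.15); cc <- exp(lc)
      prop <- st
      d_down <- switch(mv, {
        prop$psi <- st$psi * cc; prop$npsi <- st$npsi / cc; 1
      }, {
        prop$phi <- st$phi * cc; prop$nphi <- st$nphi / cc; 1
      }, {
        prop$eta <- st$eta * cc; prop$aF <- st$aF / cc; I
      }, {
        prop$th <- st$th * cc; prop$aS <- st$aS / cc; I
      })
      cand <- post(prop, zeta)
      if (log(runif(1)) < cand - cur + (N - d_down) * lc) {
        st <- prop; cur <- cand
      }
    }
    # correlations, flat over the PD region
    for (a in 1:3) for (b in (a + 1):4) {
      prop <- st
      v <- st$Sig[a, b] + rnorm(1, 0, 0.1)
      if (v <= -1 || v >= 1) next
      prop$Sig[a, b] <- prop$Sig[b, a] <- v
      if (min(eigen(prop$Sig, symmetric = TRUE,
                    only.values = TRUE)$values) <= 1e-10) next
      cand <- post(prop, zeta)
      if (log(runif(1)) < cand - cur) { st <- prop; cur <- cand }
    }
    if (it > n_warmup) {
      lam_draws[it - n_warmup] <- st$lam
      npsi_draws[it - n_warmup] <- st$npsi
    }
  }
  list(lambda = lam_draws, nu_psi = npsi_draws)
}
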