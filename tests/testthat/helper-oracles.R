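# Independent oracles used to check package computations. These deliberately
# avoid the implementation's code paths (dense matrices instead of the
# Woodbury block identity, beta-quantile inversion instead of qt, explicit
# REML optimization instead of the Bayes engine).

# two-sided t quantile via the Beta relationship: if T ~ t_df then
# df/(df + T^2) ~ Beta(df/2, 1/2), so P(|T| > t) = alpha inverts to
# t = sqrt(df (1/qbeta(alpha, df/2, 1/2) - 1)).
t_quantile_oracle <- function(p, df) {
  alpha <- 2 * (1 - p)
  sqrt(df * (1 / stats::qbeta(alpha, df / 2, 0.5) - 1))
}

# dense brute-force hierarchical Bayes posterior for beta at fixed phi (or
# profiled over a phi grid), integrating tau on the same trapezoidal grid but
# with full-matrix linear algebra.
brute_force_hblm <- function(y, v, X = NULL, publication_id = NULL,
                             phi = 0, taus = NULL, phi_grid = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  p <- ncol(X)
  if (is.null(publication_id)) publication_id <- seq_len(n)
  block <- match(publication_id, unique(publication_id))
  M_of <- function(ph) {
    M <- outer(block, block, "==") * ph
    diag(M) <- 1
    M
  }
  w <- 1 / v
  s_tilde2 <- (n - 1) * sum(w) / (sum(w)^2 - sum(w^2))
  if (!is.finite(s_tilde2) || s_tilde2 <= 0) s_tilde2 <- mean(v)
  s0 <- sqrt(n / sum(w))
  if (is.null(taus)) taus <- seq(0, 10 * sqrt(s_tilde2), length.out = 201)
  dt <- taus[2] - taus[1]
  trap <- c(dt / 2, rep(dt, length(taus) - 2), dt / 2)
  log_prior <- log(s0) - 2 * log(s0 + taus)

  eval_phi <- function(ph) {
    M <- M_of(ph)
    K <- length(taus)
    ll <- numeric(K)
    betas <- matrix(0, K, p)
    vars <- matrix(0, K, p)
    for (k in seq_len(K)) {
      V <- diag(v, n) + taus[k]^2 * M
      Vi <- solve(V)
      A <- t(X) %*% Vi %*% X
      bvec <- t(X) %*% Vi %*% y
      beta_k <- solve(A, bvec)
      r <- y - X %*% beta_k
      quad <- drop(t(r) %*% Vi %*% r)
      ll[k] <- -0.5 * (determinant(V)$modulus + determinant(A)$modulus + quad)
      betas[k, ] <- beta_k
      vars[k, ] <- diag(solve(A))
    }
    lw <- ll + log_prior + log(trap)
    m <- max(lw)
    wts <- exp(lw - m)
    ev <- m + log(sum(wts))
    wts <- wts / sum(wts)
    list(wts = wts, betas = betas, vars = vars, evidence = ev)
  }
  if (!is.null(phi_grid)) {
    cand <- lapply(phi_grid, eval_phi)
    best <- which.max(vapply(cand, `[[`, 0, "evidence"))
    sel <- cand[[best]]
    phi <- phi_grid[best]
  } else {
    sel <- eval_phi(phi)
  }
  beta <- colSums(sel$wts * sel$betas)
  second <- colSums(sel$wts * (sel$vars + sel$betas^2))
  list(beta = beta, post_se = sqrt(second - beta^2), phi = phi,
       tau2 = sum(sel$wts * taus^2))
}

# explicit REML for the independent normal-normal random-effects model
# (intercept only): profile restricted likelihood over tau2.
reml_intercept_oracle <- function(y, v) {
  nll <- function(tau2) {
    w <- 1 / (v + tau2)
    mu <- sum(w * y) / sum(w)
    0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
  }
  opt <- stats::optimize(nll, c(0, 10 * (stats::var(y) + mean(v))))
  tau2 <- opt$minimum
  w <- 1 / (v + tau2)
  list(beta = sum(w * y) / sum(w), se = sqrt(1 / sum(w)), tau2 = tau2)
}

# small random meta-dataset with publication blocks, for property tests
random_small_effects <- function(n_pub, tau = 0.3, phi = 0.5, beta0 = 0.3) {
  n_obs <- sample(1:3, n_pub, replace = TRUE)
  n <- sum(n_obs)
  pub <- rep(sprintf("p%02d", seq_len(n_pub)), n_obs)
  b <- rep(stats::rnorm(n_pub, 0, sqrt(phi) * tau), n_obs)
  v <- stats::runif(n, 0.005, 0.08)
  y <- beta0 + b + stats::rnorm(n, 0, sqrt(1 - phi) * tau) +
    stats::rnorm(n, 0, sqrt(v))
  data.frame(y = y, v = v, publication_id = pub)
}

# fast fit settings used where a test exercises logic other than quadrature
# resolution (coarser tau grid, fixed phi)
fast_grid <- list(n_tau = 61L)
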