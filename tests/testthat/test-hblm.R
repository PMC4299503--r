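test_that("fixed-effect limit (tau = 0) equals weighted least squares", {
  set.seed(31)
  n <- 40
  x <- runif(n)
  X <- cbind(1, x)
  y <- 0.3 + 0.5 * x + rnorm(n, 0, 0.1)
  v <- runif(n, 0.005, 0.05)
  fit <- fit_hblm(y, v, X = X, tau = 0)
  w <- 1 / v
  wls <- solve(crossprod(X, X * w), crossprod(X, w * y))
  expect_equal(unname(fit$beta), unname(drop(wls)), tolerance = 1e-12)
  expect_equal(unname(fit$post_se),
               unname(sqrt(diag(solve(crossprod(X, X * w))))),
               tolerance = 1e-12)

  # degenerate and hand-checkable cases
  f1 <- fit_hblm(0.5, 0.01, tau = 0)
  expect_equal(unname(f1$beta), 0.5)
  expect_equal(unname(f1$post_se), 0.1)
  f2 <- fit_hblm(c(0.5, 0.1), c(0.01, 0.04), tau = 0)
  expect_equal(unname(f2$beta), 0.42)
})

test_that("posterior matches the dense brute-force oracle to 1e-4", {
  set.seed(32)
  for (i in 1:6) {
    d <- random_small_effects(sample(4:9, 1))
    ph <- sample(c(0, 0.3, 0.7), 1)
    fit <- fit_hblm(d$y, d$v, publication_id = d$publication_id, phi = ph)
    orc <- brute_force_hblm(d$y, d$v, publication_id = d$publication_id,
                            phi = ph)
    expect_lt(max(abs(fit$beta - orc$beta)), 1e-4)
    expect_lt(max(abs(fit$post_se - orc$post_se)), 1e-4)
    expect_lt(abs(fit$tau2 - orc$tau2), 1e-4)
  }
  # profiled phi agrees with an independently profiled dense evaluation
  d <- random_small_effects(8)
  fit <- fit_hblm(d$y, d$v, publication_id = d$publication_id)
  orc <- brute_force_hblm(d$y, d$v, publication_id = d$publication_id,
                          phi_grid = seq(0, 0.95, by = 0.05))
  expect_equal(fit$phi, orc$phi)
  expect_lt(max(abs(fit$beta - orc$beta)), 1e-4)
})

test_that("with singleton publications the fit is invariant to phi", {
  set.seed(33)
  n <- 15
  y <- rnorm(n, 0.3, 0.3)
  v <- runif(n, 0.01, 0.05)
  f0 <- fit_hblm(y, v, phi = 0)
  f9 <- fit_hblm(y, v, phi = 0.9)
  expect_equal(f0$beta, f9$beta)
  expect_equal(f0$post_se, f9$post_se)
  expect_equal(f0$tau2, f9$tau2)
})

test_that("independent intercept-only fit tracks an explicit REML oracle", {
  set.seed(34)
  n <- 100
  tau <- 0.25
  v <- runif(n, 0.01, 0.08)
  y <- 0.3 + rnorm(n, 0, tau) + rnorm(n, 0, sqrt(v))
  fit <- fit_hblm(y, v, phi = 0)
  orc <- reml_intercept_oracle(y, v)
  expect_lt(abs(unname(fit$beta) - orc$beta), 0.01)
  expect_lt(abs(unname(fit$post_se) - orc$se) / orc$se, 0.10)
})

test_that("credible intervals use the t quantile at N - p df", {
  # posterior SE back-derived so the printed-style interval is reproduced
  se <- 0.065 / t_quantile_oracle(0.975, 183)
  fit <- structure(list(beta = c(mu = 0.296), post_se = c(mu = se), df = 183),
                   class = "hblm")
  ci <- credible_interval(fit)
  expect_equal(round(ci$lower, 3), 0.231)
  expect_equal(round(ci$upper, 3), 0.361)

  # zero-width limit and level monotonicity
  fit0 <- structure(list(beta = c(mu = 0.3), post_se = c(mu = 0), df = 50),
                    class = "hblm")
  ci0 <- credible_interval(fit0)
  expect_equal(ci0$lower, ci0$upper)
  ci95 <- credible_interval(fit, 0.95)
  ci99 <- credible_interval(fit, 0.99)
  expect_lt(ci99$lower, ci95$lower)
  expect_gt(ci99$upper, ci95$upper)
  expect_error(credible_interval(fit, 1.2), "level")
})

test_that("heterogeneity reproduces the Higgins-Thompson identity", {
  # equal weights make the typical within-study variance equal s^2
  fake <- structure(list(tau2 = 0.03, tau = sqrt(0.03), v = rep(0.01, 10)),
                    class = "hblm")
  h <- heterogeneity(fake)
  expect_equal(h$s_tilde2, 0.01)
  expect_equal(h$I2, 75)

  fake0 <- structure(list(tau2 = 0, tau = 0, v = rep(0.01, 10)),
                     class = "hblm")
  expect_equal(heterogeneity(fake0)$I2, 0)

  # back-solved consistency with the printed-scale pair tau = 0.304,
  # I2 = 97.4: holds when s_tilde2 = 0.002467
  expect_equal(100 * 0.304^2 / (0.304^2 + 0.002467), 97.4, tolerance = 5e-4)
  expect_error(heterogeneity(fake, v = 0.01), "at least 2")
})

test_that("residuals and precision come back in input order", {
  set.seed(35)
  d <- random_small_effects(6)
  fit <- fit_hblm(d$y, d$v, publication_id = d$publication_id, phi = 0.5,
                  grid = fast_grid)
  rp <- residuals_and_precision(fit)
  expect_equal(rp$residual, d$y - unname(fit$beta))
  expect_equal(rp$precision, 1 / sqrt(d$v))
  expect_equal(residuals_and_precision(
    structure(list(residuals = 1, v = 0.04), class = "hblm"))$precision, 5)
})

test_that("fits are deterministic and guard their preconditions", {
  set.seed(36)
  d <- random_small_effects(5)
  f1 <- fit_hblm(d$y, d$v, publication_id = d$publication_id)
  f2 <- fit_hblm(d$y, d$v, publication_id = d$publication_id)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$grid$weights, f2$grid$weights)

  expect_error(fit_hblm(c(0.1, 0.2), c(0.01, 0)), "positive")
  expect_error(fit_hblm(0.1, 0.01, X = cbind(1, 2)), "N < p")
})
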