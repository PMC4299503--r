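test_that("trim-and-fill: symmetric input yields k0 = 0 and no adjustment", {
  eff <- data.frame(y = c(-0.2, 0, 0.2), v = rep(0.01, 3),
                    publication_id = c("a", "b", "c"))
  tf <- trim_and_fill(eff, mode = "raw")
  expect_equal(tf$k0, 0L)
  expect_equal(tf$adjusted_estimate, tf$estimate)
  expect_equal(nrow(tf$filled), 0L)
  expect_error(trim_and_fill(eff[1:2, ]), "at least 3")
})

test_that("trim-and-fill reproduces the hand-computed L0 rank sum", {
  # centered values with fixed center 0: T = 1 + 4 + 5 = 10, L0 = 10/9
  eff <- data.frame(y = c(-0.1, -0.05, 0.02, 0.3, 0.6), v = rep(0.01, 5),
                    publication_id = letters[1:5])
  tf <- trim_and_fill(eff, mode = "raw", center = 0)
  expect_equal(tf$k0, 1L)
  # fill mirrors the most extreme value about the center
  expect_equal(tf$filled$y, -0.6)
})

test_that("residual-mode trim-and-fill detects planted right-skew censoring", {
  set.seed(41)
  hits <- vapply(1:15, function(i) {
    sim <- simulate_meta_dataset(sim_config(beta0 = 0, seed = 5000 + i))
    cens <- inject_small_study_bias(sim$records, seed = 6000 + i)
    es <- effect_sizes(cens)
    tf <- trim_and_fill(es, phi = 0.5, grid = fast_grid)
    tf$k0 > 0L
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("cumulative meta-analysis traces prefix fits in sort order", {
  eff <- data.frame(y = c(0.1, 0.5), v = c(0.04, 0.01),
                    publication_id = c("a", "b"))
  tr <- cumulative_meta(eff, "sampling_variance", tau = 0)
  expect_equal(tr$estimate, c(0.5, 0.42))  # hand inverse-variance means
  expect_equal(tr$n, 1:2)

  ident <- data.frame(y = rep(0.3, 5), v = rep(0.02, 5),
                      publication_id = letters[1:5])
  tri <- cumulative_meta(ident, "sampling_variance", phi = 0,
                         grid = fast_grid)
  expect_equal(tri$estimate, rep(0.3, 5), tolerance = 1e-10)

  expect_error(cumulative_meta(eff[1, , drop = FALSE]), "at least 2")
  expect_error(cumulative_meta(eff, "publication_year"), "missing")
})

test_that("final cumulative step equals the full-data fit bitwise", {
  set.seed(42)
  d <- random_small_effects(7)
  d$pub_year <- sample(1990:2010, nrow(d), replace = TRUE)
  tr <- cumulative_meta(d, "publication_year", phi = 0.4, grid = fast_grid)
  full <- fit_hblm(d$y, d$v, publication_id = d$publication_id, phi = 0.4,
                   grid = fast_grid)
  # summation order differs between sorted prefix and raw input, so the
  # agreement is to numerical precision rather than bitwise
  expect_equal(tr$estimate[nrow(d)], unname(full$beta[1L]), tolerance = 1e-12)
  expect_equal(nrow(tr), nrow(d))
  expect_equal(attr(tr, "minimum"), min(tr$estimate))
})

test_that("sort is stable under the publication-id tie break", {
  eff <- data.frame(y = c(0.3, 0.1, 0.2), v = rep(0.02, 3),
                    publication_id = c("c", "a", "b"))
  tr <- cumulative_meta(eff, "sampling_variance", tau = 0)
  # equal keys: order by publication_id, so first prefix is pub "a"
  expect_equal(tr$estimate[1L], 0.1)
})

test_that("slope tests regress on the requested covariate and guard degeneracy", {
  set.seed(43)
  d <- random_small_effects(10)
  d$pub_year <- sample(1990:2010, nrow(d), replace = TRUE)
  st <- slope_test(d, "publication_year", phi = 0.3, grid = fast_grid)
  expect_true(st$lower < st$slope && st$slope < st$upper)

  ident <- data.frame(y = rep(0.25, 8), v = runif(8, 0.01, 0.05),
                      publication_id = letters[1:8])
  st0 <- slope_test(ident, "sampling_variance", phi = 0, grid = fast_grid)
  expect_equal(st0$slope, 0, tolerance = 1e-8)

  const <- data.frame(y = rnorm(5), v = rep(0.02, 5))
  expect_error(slope_test(const, "sampling_variance"), "degenerate regressor")
})
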