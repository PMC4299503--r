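uniform_map <- function(label = "field", n = 120, cell = 10) {
  land_cover_map(matrix(label, n, n), cell_size = cell)
}

# field for x < 600, forest for x >= 600, on a 1200 m square
half_map <- function(n = 120, cell = 10) {
  hab <- matrix("forest", n, n)
  hab[, 1:(n / 2)] <- "field"
  land_cover_map(hab, cell_size = cell)
}

test_that("uniform arable map gives exact metrics", {
  map <- uniform_map()
  tr <- place_transects(study_region(c(600, 600), 80), k = 5, seed = 1)
  for (t0 in tr) {
    m <- transect_metrics(t0, map)
    expect_equal(m$pct_arable, 100)
    expect_equal(m$n_habitats, 1L)
    expect_equal(sum(m$segment_lengths), 1000)
  }
  avg <- study_landscape_metrics(study_region(c(600, 600), 80), map, seed = 1)
  expect_equal(avg$pct_arable, 100)
  expect_equal(avg$n_habitats, 1)
})

test_that("half-plane boundary transect splits 50/50 exactly", {
  map <- half_map()
  # transect along x, centred on the x = 600 boundary
  t0 <- list(start = c(600, 555), orientation = 0,
             a = c(100, 555), b = c(1100, 555))
  m <- transect_metrics(t0, map)
  expect_equal(m$pct_arable, 50)
  expect_equal(m$n_habitats, 2L)
  expect_equal(unname(m$segment_lengths[c("field", "forest")]), c(500, 500))
})

test_that("average field size averages areas of intersected parcels", {
  # 1200 x 400 m all-field map, cell 10 m: parcel 1 = 4 ha strip, parcel 2 = rest
  hab <- matrix("field", 40, 120)
  parcel <- matrix(2L, 40, 120)
  parcel[, 1:10] <- 1L                     # 400 cells = 4 ha
  map <- land_cover_map(hab, parcel, cell_size = 10)
  tt <- list(start = c(550, 200), orientation = 0,
             a = c(50, 200), b = c(1050, 200))
  m <- transect_metrics(tt, map)
  a1 <- sum(parcel == 1L) * 100 / 1e4      # 4 ha
  a2 <- sum(parcel == 2L) * 100 / 1e4      # 44 ha
  expect_equal(m$avg_field_size, mean(c(a1, a2)))

  # a transect leaving the extent is an error
  out <- list(start = c(200, 200), orientation = 0,
              a = c(-100, 200), b = c(900, 200))
  expect_error(transect_metrics(out, map), "exits map")
})

test_that("transect placement is deterministic, non-crossing, uniform in d", {
  reg <- study_region(c(0, 0), 2000)
  tr1 <- place_transects(reg, k = 5, seed = 99)
  tr2 <- place_transects(reg, k = 5, seed = 99)
  expect_identical(tr1, tr2)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_false(agrimeta:::.segments_cross(tr1[[i]]$a, tr1[[i]]$b,
                                            tr1[[j]]$a, tr1[[j]]$b))
  }
  expect_length(place_transects(reg, k = 1, seed = 3), 1L)

  set.seed(17)
  ds <- replicate(1000, place_transects(reg, k = 1)[[1L]]$d)
  ks <- suppressWarnings(stats::ks.test(ds, "punif", 0, 2000))
  expect_gt(ks$p.value, 0.01)

  expect_equal(vapply(tr1, function(t0) sqrt(sum((t0$b - t0$a)^2)), 0),
               rep(1000, 5))
  expect_true(all(vapply(tr1, `[[`, 0, "orientation") %in% c(0, 45, 90, 180)))
})

test_that("metrics are invariant under a rigid 90-degree rotation", {
  map <- half_map()
  t0 <- list(start = c(600, 555), orientation = 0,
             a = c(100, 555), b = c(1100, 555))
  m0 <- transect_metrics(t0, map)
  # rotate map 90 deg counterclockwise about the centre (600, 600):
  # (x, y) -> (1200 - y, x); matrix: new[row, col] = old[col, nr + 1 - row]
  hab <- map$habitat
  hab90 <- t(hab)[, rev(seq_len(nrow(hab)))]
  rot <- function(p) c(1200 - p[2L], p[1L])
  map90 <- land_cover_map(hab90, cell_size = 10)
  t90 <- list(start = rot(t0$start), orientation = 90,
              a = rot(t0$a), b = rot(t0$b))
  m90 <- transect_metrics(t90, map90)
  expect_equal(m90$pct_arable, m0$pct_arable)
  expect_equal(m90$n_habitats, m0$n_habitats)
  expect_equal(sort(unname(m90$segment_lengths)),
               sort(unname(m0$segment_lengths)))
})

test_that("simulated land cover hits mixture quotas and is reproducible", {
  map <- simulate_landcover(c(80, 80), 10, c(field = 0.5, forest = 0.5),
                            mean_parcel_area_ha = 3, seed = 5)
  frac <- mean(map$habitat == "field")
  expect_lt(abs(frac - 0.5), 0.02)
  expect_true(all(map$parcel[map$habitat == "field"] > 0))
  map2 <- simulate_landcover(c(80, 80), 10, c(field = 0.5, forest = 0.5),
                             mean_parcel_area_ha = 3, seed = 5)
  expect_identical(map$habitat, map2$habitat)

  uni <- simulate_landcover(c(30, 30), 10, c(field = 1), seed = 2)
  expect_true(all(uni$habitat == "field"))
  expect_error(simulate_landcover(mixture = c(field = 0.7, forest = 0.7)),
               "sum to 1")
  expect_error(simulate_landcover(mixture = c(field = 0.5, moon = 0.5)),
               "unknown habitat")
})

test_that("country-mean imputation fills fully missing landscape triples", {
  rec <- rbind(
    data.frame(country = "SE", pct_arable = 40, n_habitats = 3,
               avg_field_size = 4),
    data.frame(country = "SE", pct_arable = 60, n_habitats = 5,
               avg_field_size = 6),
    data.frame(country = "SE", pct_arable = NA, n_habitats = NA,
               avg_field_size = NA),
    data.frame(country = "UK", pct_arable = 20, n_habitats = 2,
               avg_field_size = 2))
  out <- impute_country_means(rec)
  expect_equal(out$pct_arable[3L], 50)
  expect_equal(out$n_habitats[3L], 4)
  expect_equal(out$avg_field_size[3L], 5)
  expect_true(out$imputed_landscape[3L])
  expect_false(any(out$imputed_landscape[c(1, 2, 4)]))
  expect_equal(out$pct_arable[1L], 40)  # complete records untouched

  rec2 <- rbind(rec[3, ], data.frame(country = "FR", pct_arable = NA,
                                     n_habitats = NA, avg_field_size = NA))
  expect_error(impute_country_means(rec2), "SE|FR")
})
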