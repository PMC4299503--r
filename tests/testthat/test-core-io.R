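make_row <- function(publication_id = "pub001", observation_id = "obs001",
                     pub_year = 2005, country = "SE", region = "",
                     taxon_group = "plants", functional_group = "producers",
                     crop_type = "cereals", scale = "field",
                     mean_org = 12, sd_org = 3, n_org = 8,
                     mean_conv = 10, sd_conv = 3, n_conv = 8,
                     pct_arable = 55, n_habitats = 4, avg_field_size = 6.5) {
  data.frame(publication_id, observation_id, pub_year, country, region,
             taxon_group, functional_group, crop_type, scale,
             mean_org, sd_org, n_org, mean_conv, sd_conv, n_conv,
             pct_arable, n_habitats, avg_field_size,
             stringsAsFactors = FALSE)
}

write_rows <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}

test_that("well-formed files parse completely and round-trip", {
  df <- rbind(make_row(), make_row(observation_id = "obs002", scale = "farm"),
              make_row(publication_id = "pub002", observation_id = "obs003"))
  tab <- read_study_table(write_rows(df))
  expect_equal(nrow(tab$records), 3L)
  expect_equal(nrow(tab$rejections), 0L)

  f2 <- tempfile(fileext = ".csv")
  write_study_table(tab, f2)
  tab2 <- read_study_table(f2)
  expect_equal(tab2$records[names(df)], tab$records[names(df)])
})

test_that("inclusion rules reject rows with reasons, never silently", {
  df <- rbind(make_row(),
              make_row(observation_id = "obs002", n_org = 1),
              make_row(observation_id = "obs003", mean_conv = 0),
              make_row(observation_id = "obs004", taxon_group = "earthworms"),
              make_row(observation_id = "obs005", sd_org = 0, sd_conv = 0))
  tab <- read_study_table(write_rows(df))
  expect_equal(nrow(tab$records) + nrow(tab$rejections), 5L)
  expect_equal(tab$rejections$reason[tab$rejections$observation_id == "obs002"],
               "n must exceed 1")
  expect_match(tab$rejections$reason[tab$rejections$observation_id == "obs003"],
               "nonpositive mean")
  expect_match(tab$rejections$reason[tab$rejections$observation_id == "obs004"],
               "excluded")
  expect_match(tab$rejections$reason[tab$rejections$observation_id == "obs005"],
               "degenerate variance")
})

test_that("missing mandatory column is a hard error naming the column", {
  df <- make_row()
  df$sd_conv <- NULL
  expect_error(read_study_table(write_rows(df)), "sd_conv")
})

test_that("enum synonyms and middle-dot decimals are normalized on read", {
  df <- make_row(crop_type = "Grasses", taxon_group = "Plants")
  df$mean_org <- "12·5"
  tab <- read_study_table(write_rows(df))
  expect_equal(tab$records$crop_type, "grassland")
  expect_equal(tab$records$taxon_group, "plants")
  expect_equal(tab$records$mean_org, 12.5)
})

test_that("partially missing landscape covariates are rejected, fully missing kept", {
  df <- rbind(make_row(), make_row(observation_id = "obs002"),
              make_row(observation_id = "obs003"))
  df$pct_arable[2L] <- NA
  df[3L, c("pct_arable", "n_habitats", "avg_field_size")] <- NA
  tab <- validate_study_records(df)
  expect_equal(nrow(tab$records), 2L)
  expect_match(tab$rejections$reason, "partially missing")
})

test_that("to_sd matches direct conversions and is scale-equivariant", {
  expect_equal(to_sd(2.0, "sd", n = 10), 2.0)
  expect_equal(to_sd(0.5, "se", n = 16), 2.0)
  expect_equal(to_sd(9.0, "variance"), 3.0)
  # ci95 half-width round-trip: sd -> halfwidth -> sd
  sd0 <- 2.7; n <- 12
  hw <- stats::qt(0.975, n - 1) * sd0 / sqrt(n)
  expect_equal(to_sd(hw, "ci95_halfwidth", n = n), sd0)

  set.seed(11)
  for (kind in c("sd", "se", "variance", "ci95_halfwidth")) {
    val <- runif(1, 0.1, 5); cc <- runif(1, 0.1, 10); n <- sample(2:30, 1)
    scale_pow <- if (kind == "variance") 2 else 1
    expect_equal(to_sd(cc^scale_pow * val, kind, n = n),
                 cc * to_sd(val, kind, n = n),
                 info = kind)
  }
  expect_error(to_sd(-1, "sd"), "nonnegative")
  expect_error(to_sd(1, "ci95_halfwidth", n = 1), "n >= 2")
})
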