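#' Configuration for the synthetic meta-analytic data generator
#'
#' Defaults emulate the structure of the organic-farming species-richness
#' literature: about 94 publications contributing 184 observations (1 to 6
#' dependent observations per publication, mean close to 2), true effects
#' scattered with between-effect standard deviation \eqn{\tau = 0.3} around a
#' grand mean of 0.3 on the log response-ratio scale, half of the
#' between-effect variance shared within publications (\eqn{\phi = 0.5}),
#' arm replicate counts between 2 and 30, conventional-arm mean richness
#' log-normal with median about 15 species, within-arm coefficient of
#' variation 0.4, and categorical covariate frequencies proportional to the
#' published breakdown (e.g. producers 62, predators 49, pollinators 21 of
#' 184; cereals 100, mixed 40).
#'
#' @param n_publications number of publications (default 94).
#' @param obs_per_pub_probs probabilities for 1..6 observations per
#'   publication (mean approximately 184/94).
#' @param beta0 grand mean true effect (default 0.3).
#' @param beta_pct_arable slope of the true effect on the arable proportion
#'   in \eqn{[0,1]} (default 0).
#' @param tau between-effect SD of true effects (default 0.3).
#' @param phi share of between-effect variance at the publication level
#'   (default 0.5), in \eqn{[0, 1)}.
#' @param arm_n_range integer range of per-arm replicate counts (default
#'   \code{c(2, 30)}, discrete uniform).
#' @param conv_mean_meanlog,conv_mean_sdlog log-normal parameters of the
#'   conventional-arm mean richness (median \code{exp(meanlog)}, default 15).
#' @param cv within-arm coefficient of variation of richness (default 0.4).
#' @param taxon_probs,functional_probs,crop_probs,scale_probs named level
#'   frequencies (normalized internally).
#' @param p_missing_landscape probability a publication reports no landscape
#'   data (imputable by country means; default 0).
#' @param seed RNG seed.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_publications = 94L,
                       obs_per_pub_probs = c(`1` = 0.55, `2` = 0.20,
                                             `3` = 0.10, `4` = 0.08,
                                             `5` = 0.04, `6` = 0.03),
                       beta0 = 0.3, beta_pct_arable = 0,
                       tau = 0.3, phi = 0.5,
                       arm_n_range = c(2L, 30L),
                       conv_mean_meanlog = log(15), conv_mean_sdlog = 0.5,
                       cv = 0.4,
                       taxon_probs = c(arthropods = 89, birds = 17,
                                       microbes = 6, plants = 62),
                       functional_probs = c(producers = 62, predators = 49,
                                            other = 27, pollinators = 21,
                                            decomposers = 19, herbivores = 6),
                       crop_probs = c(cereals = 100, mixed = 40,
                                      vegetables = 16, grassland = 13,
                                      orchard = 9, miscellaneous = 6),
                       scale_probs = c(farm = 0.45, field = 0.40, plot = 0.15),
                       p_missing_landscape = 0,
                       seed = NULL) {
  stopifnot(tau >= 0, phi >= 0, phi < 1, cv > 0,
            n_publications >= 1L, all(obs_per_pub_probs >= 0))
  cfg <- list(
    n_publications = as.integer(n_publications),
    obs_per_pub_probs = obs_per_pub_probs / sum(obs_per_pub_probs),
    beta0 = beta0, beta_pct_arable = beta_pct_arable, tau = tau, phi = phi,
    arm_n_range = as.integer(arm_n_range),
    conv_mean_meanlog = conv_mean_meanlog, conv_mean_sdlog = conv_mean_sdlog,
    cv = cv,
    taxon_probs = taxon_probs / sum(taxon_probs),
    functional_probs = functional_probs / sum(functional_probs),
    crop_probs = crop_probs / sum(crop_probs),
    scale_probs = scale_probs / sum(scale_probs),
    p_missing_landscape = p_missing_landscape,
    seed = seed
  )
  class(cfg) <- "sim_config"
  cfg
}

.SIM_COUNTRIES <- c(SE = 0.18, UK = 0.16, DE = 0.14, DK = 0.10, NL = 0.08,
                    FI = 0.06, NO = 0.05, CH = 0.05, US = 0.12, CA = 0.06)

#' Simulate a meta-analytic study table with known ground truth
#'
#' True per-observation effects follow
#' \deqn{\theta_{ij} = x_{ij}'\beta + b_j + w_{ij}, \quad
#'   b_j \sim N(0, \phi\tau^2), \quad w_{ij} \sim N(0, (1-\phi)\tau^2),}
#' with \eqn{b_j} shared by all observations of publication \eqn{j}. The
#' conventional-arm mean is drawn log-normal, the organic-arm mean is
#' \eqn{\mu_c e^{\theta}}, and each arm's reported mean/SD are the sample
#' statistics of \eqn{n} log-normal replicate draws at the target mean and
#' CV, so sampling variance arises organically rather than being injected.
#'
#' @param config a [sim_config()].
#' @return list with \code{records} (a study-table data frame in the
#'   [read_study_table()] schema) and \code{truth} (true \code{beta0},
#'   \code{tau}, \code{phi}, per-observation \code{theta}, per-publication
#'   random effects \code{b}).
#' @export
simulate_meta_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  J <- config$n_publications
  n_obs_j <- sample(seq_along(config$obs_per_pub_probs), J, replace = TRUE,
                    prob = config$obs_per_pub_probs)
  N <- sum(n_obs_j)
  pub <- rep(sprintf("pub%03d", seq_len(J)), n_obs_j)
  obs <- sprintf("obs%03d", seq_len(N))
  b_j <- stats::rnorm(J, 0, sqrt(config$phi) * config$tau)
  w <- stats::rnorm(N, 0, sqrt(1 - config$phi) * config$tau)

  draw <- function(probs, n) sample(names(probs), n, TRUE, prob = probs)
  taxon <- draw(config$taxon_probs, N)
  func <- draw(config$functional_probs, N)
  crop <- draw(config$crop_probs, N)
  scale <- draw(config$scale_probs, N)
  country_j <- draw(.SIM_COUNTRIES, J)
  year_j <- sample(1981:2011, J, replace = TRUE)
  pct_arable_j <- 100 * stats::rbeta(J, 2, 2)
  n_hab_j <- 1L + stats::rpois(J, 3)
  afs_j <- stats::rlnorm(J, log(5), 0.6)
  miss_j <- stats::runif(J) < config$p_missing_landscape

  jj <- rep(seq_len(J), n_obs_j)
  theta <- config$beta0 +
    config$beta_pct_arable * (pct_arable_j[jj] / 100) +
    b_j[jj] + w

  sdlog <- sqrt(log(1 + config$cv^2))
  draw_arm <- function(mu, n) {
    x <- stats::rlnorm(n, log(mu) - sdlog^2 / 2, sdlog)
    c(mean(x), stats::sd(x))
  }
  n_org <- sample(config$arm_n_range[1L]:config$arm_n_range[2L], N, TRUE)
  n_conv <- sample(config$arm_n_range[1L]:config$arm_n_range[2L], N, TRUE)
  mu_conv <- stats::rlnorm(N, config$conv_mean_meanlog, config$conv_mean_sdlog)
  mu_org <- mu_conv * exp(theta)
  stat_org <- t(vapply(seq_len(N),
                       function(i) draw_arm(mu_org[i], n_org[i]), c(0, 0)))
  stat_conv <- t(vapply(seq_len(N),
                        function(i) draw_arm(mu_conv[i], n_conv[i]), c(0, 0)))

  records <- data.frame(
    publication_id = pub, observation_id = obs,
    pub_year = year_j[jj], country = country_j[jj], region = "",
    taxon_group = taxon, functional_group = func, crop_type = crop,
    scale = scale,
    mean_org = stat_org[, 1L], sd_org = stat_org[, 2L], n_org = n_org,
    mean_conv = stat_conv[, 1L], sd_conv = stat_conv[, 2L], n_conv = n_conv,
    pct_arable = ifelse(miss_j[jj], NA_real_, pct_arable_j[jj]),
    n_habitats = ifelse(miss_j[jj], NA_real_, n_hab_j[jj]),
    avg_field_size = ifelse(miss_j[jj], NA_real_, afs_j[jj]),
    richness_surrogate = FALSE,
    stringsAsFactors = FALSE
  )
  truth <- list(beta0 = config$beta0,
                beta_pct_arable = config$beta_pct_arable,
                tau = config$tau, phi = config$phi,
                theta = theta, b = b_j, publication_id = pub)
  list(records = records, truth = truth)
}

#' Write a simulated dataset and its ground-truth sidecar
#' @param sim output of [simulate_meta_dataset()].
#' @param csv_path study-table CSV path.
#' @param truth_path ground-truth JSON sidecar path (default: csv path with
#'   \code{.truth.json}).
#' @return \code{csv_path}, invisibly.
#' @export
write_sim_dataset <- function(sim, csv_path,
                              truth_path = paste0(csv_path, ".truth.json")) {
  write_study_table(sim$records, csv_path)
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Simulate a parcel-tessellated land-cover map
#'
#' The grid is tessellated into parcels by nearest-seed (Voronoi) assignment
#' of a number of uniformly placed seeds chosen so the mean parcel area
#' matches \code{mean_parcel_area_ha}. Parcels are then labelled by quota:
#' a random parcel order is filled greedily so realized habitat fractions
#' track the requested mixture as closely as whole parcels allow.
#'
#' @param n_cells integer \code{c(rows, cols)} grid size.
#' @param cell_size cell edge in metres.
#' @param mixture named habitat proportions summing to 1 (names from the
#'   habitat level set).
#' @param mean_parcel_area_ha target mean parcel area in hectares.
#' @param seed RNG seed.
#' @return a [land_cover_map()]; attribute \code{"mixture"} records the
#'   requested mixture.
#' @export
simulate_landcover <- function(n_cells = c(100L, 100L), cell_size = 10,
                               mixture = c(field = 0.5, forest = 0.5),
                               mean_parcel_area_ha = 5, seed = NULL) {
  if (abs(sum(mixture) - 1) > 1e-8 || any(mixture < 0)) {
    stop("habitat mixture proportions must be nonnegative and sum to 1")
  }
  bad <- setdiff(names(mixture), .HABITAT_LEVELS)
  if (length(bad) > 0L) stop("unknown habitat(s) in mixture: ",
                             paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  nr <- n_cells[1L]; nc <- n_cells[2L]
  area_ha <- nr * nc * cell_size^2 / 1e4
  k <- max(1L, as.integer(round(area_ha / mean_parcel_area_ha)))
  sx <- stats::runif(k, 0, nc); sy <- stats::runif(k, 0, nr)
  cx <- rep(seq_len(nc) - 0.5, each = nr)
  cy <- rep(seq_len(nr) - 0.5, times = nc)
  d2 <- outer(cx, sx, function(a, b) (a - b)^2) +
        outer(cy, sy, function(a, b) (a - b)^2)
  parcel <- matrix(max.col(-d2), nr, nc)
  # quota labelling over a random parcel order
  sizes <- tabulate(parcel, nbins = k)
  ord <- sample.int(k)
  target <- mixture * nr * nc
  labels <- character(k)
  filled <- stats::setNames(numeric(length(mixture)), names(mixture))
  for (id in ord) {
    deficit <- target - filled
    lab <- names(mixture)[which.max(deficit)]
    labels[id] <- lab
    filled[lab] <- filled[lab] + sizes[id]
  }
  habitat <- matrix(labels[parcel], nr, nc)
  parcel[habitat != "field"] <- 0L
  m <- land_cover_map(habitat, parcel, cell_size = cell_size)
  attr(m, "mixture") <- mixture
  m
}

#' Censor a study table to mimic small-study publication bias
#'
#' Drops observations according to a censoring rule on the effect size and
#' its sampling variance, emulating a literature in which negative or weak
#' results from small (high-variance) studies remain unpublished. The default
#' rule drops, with probability \code{p_drop}, observations whose effect size
#' is negative and whose sampling variance exceeds the table median.
#'
#' @param records study-record data frame (or \code{study_table}).
#' @param rule function \code{(y, v) -> drop probability vector}; default
#'   \code{make_censor_rule()}.
#' @param seed RNG seed for probabilistic rules.
#' @return censored records; attribute \code{"n_dropped"} gives the count.
#' @export
inject_small_study_bias <- function(records, rule = make_censor_rule(),
                                    seed = NULL) {
  if (inherits(records, "study_table")) records <- records$records
  if (nrow(records) == 0L) stop("empty table")
  if (!is.null(seed)) set.seed(seed)
  es <- log_response_ratio(records$mean_org, records$sd_org, records$n_org,
                           records$mean_conv, records$sd_conv, records$n_conv)
  p <- rule(es$y, es$v)
  stopifnot(length(p) == nrow(records), all(p >= 0 & p <= 1))
  drop <- stats::runif(nrow(records)) < p
  if (all(drop)) stop("censor rule drops every observation")
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Build a small-study censoring rule
#' @param y_cut effect sizes below this are candidates for censoring
#'   (default 0).
#' @param v_quantile variance quantile above which candidates are censored
#'   (default 0.5, the median).
#' @param p_drop drop probability for candidates (default 1: deterministic).
#' @return function \code{(y, v) -> drop probabilities}.
#' @export
make_censor_rule <- function(y_cut = 0, v_quantile = 0.5, p_drop = 1) {
  force(y_cut); force(v_quantile); force(p_drop)
  function(y, v) {
    thr <- stats::quantile(v, v_quantile, names = FALSE)
    ifelse(y < y_cut & v > thr, p_drop, 0)
  }
}
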