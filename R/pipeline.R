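#' Default analysis configuration
#'
#' Reference levels, model set, quadrature settings and diagnostic options
#' reproducing the package's standard analysis: grand mean, per-covariate
#' subgroup models (cell means and treatment contrasts), landscape-metric
#' slopes with the outlier-sensitivity refit, heterogeneity, and the
#' publication-bias block. A committed YAML copy ships as
#' \code{inst/extdata/default_config.yaml}.
#'
#' @return nested configuration list.
#' @export
default_analysis_config <- function() {
  list(
    model = list(
      subgroup_terms = c("functional_group", "taxon_group", "crop_type",
                         "scale"),
      refs = list(scale = "farm", taxon_group = "arthropods",
                  functional_group = "producers", crop_type = "cereals"),
      pct_arable_as_proportion = TRUE,
      outlier_threshold = 2.0
    ),
    hblm = list(phi = "profile", n_tau = 201L, tau_max = NULL,
                phi_grid = seq(0, 0.95, by = 0.05)),
    bias = list(trim_fill_side = "right"),
    level = 0.95
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load an analysis configuration from YAML
#' @param path YAML file; keys override [default_analysis_config()].
#' @return configuration list.
#' @export
read_analysis_config <- function(path) {
  .merge_config(default_analysis_config(), yaml::read_yaml(path))
}

.stage_log <- function(quiet, stage, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
}

.hblm_args <- function(config) {
  list(phi = config$hblm$phi,
       grid = list(n_tau = config$hblm$n_tau, tau_max = config$hblm$tau_max,
                   phi_grid = config$hblm$phi_grid))
}

.fit_cfg <- function(y, v, X, pub, config, tau = NULL) {
  a <- .hblm_args(config)
  fit_hblm(y, v, X = X, publication_id = pub, tau = tau,
           phi = a$phi, grid = a$grid)
}

#' Run the full meta-analysis pipeline
#'
#' Executes, in order: read/validate the study table, effect sizes and the
#' adequacy summary, country-mean imputation of landscape covariates, the
#' intercept-only grand-mean hierarchical fit, per-covariate subgroup
#' meta-regressions (cell-means and treatment-contrast codings), landscape
#' slope models with the extreme-value sensitivity refit (effect sizes above
#' the outlier threshold removed), heterogeneity, and the publication-bias
#' diagnostics (funnel data, trim-and-fill on the hierarchical residual
#' funnel, cumulative meta-analyses by sampling variance and by publication
#' year, and both slope tests). Each stage is logged with record counts.
#'
#' @param study path to a study-table CSV, or a \code{study_table}, or a
#'   records data frame.
#' @param config configuration list (see [default_analysis_config()]) or a
#'   YAML path.
#' @param out_dir optional output directory for the report JSON, coefficient
#'   and trace CSVs, and funnel-data CSV.
#' @param seed integer seed recorded in the provenance block (the analysis
#'   itself is deterministic; the seed matters when the caller also
#'   simulates).
#' @param quiet suppress stage logging.
#' @return an \code{analysis_report} list.
#' @export
run_full_analysis <- function(study, config = default_analysis_config(),
                              out_dir = NULL, seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_analysis_config(config)
  stage <- "read"
  res <- tryCatch({
    tab <- if (is.character(study)) read_study_table(study)
           else if (inherits(study, "study_table")) study
           else validate_study_records(study)
    .stage_log(quiet, stage, "%d accepted, %d rejected",
               nrow(tab$records), nrow(tab$rejections))

    stage <- "effect_sizes"
    records <- impute_country_means(tab$records)
    effects <- effect_sizes(records)
    if (isTRUE(config$model$pct_arable_as_proportion)) {
      effects$pct_arable_prop <- effects$pct_arable / 100
    }
    adequacy <- adequacy_summary(effects)
    .stage_log(quiet, stage, "%d effect sizes; %.0f%% of minima below 3",
               nrow(effects), 100 * adequacy$frac_below_min[1L])

    stage <- "grand_mean"
    grand <- .fit_cfg(effects$y, effects$v, NULL, effects$publication_id,
                      config)
    gci <- credible_interval(grand, config$level)
    .stage_log(quiet, stage, "estimate %.3f (%.3f-%.3f), phi = %.2f",
               gci$estimate, gci$lower, gci$upper, grand$phi)

    stage <- "subgroups"
    subgroups <- lapply(config$model$subgroup_terms, function(term) {
      cm <- build_design(effects, terms = term, cell_means = TRUE)
      tc <- build_design(effects, terms = term,
                         refs = config$model$refs[term])
      fit_cm <- .fit_cfg(effects$y, effects$v, cm, effects$publication_id,
                         config)
      fit_tc <- .fit_cfg(effects$y, effects$v, tc, effects$publication_id,
                         config)
      list(term = term,
           cell_means = credible_interval(fit_cm, config$level),
           contrasts = credible_interval(fit_tc, config$level))
    })
    names(subgroups) <- config$model$subgroup_terms
    .stage_log(quiet, stage, "%d covariates fitted", length(subgroups))

    stage <- "landscape_slopes"
    ls_cols <- c(
      pct_arable = if (isTRUE(config$model$pct_arable_as_proportion))
        "pct_arable_prop" else "pct_arable",
      n_habitats = "n_habitats", avg_field_size = "avg_field_size")
    landscape <- lapply(ls_cols, function(col) {
      X <- cbind(`(Intercept)` = 1, slope = effects[[col]])
      fit <- .fit_cfg(effects$y, effects$v, X, effects$publication_id, config)
      credible_interval(fit, config$level)[2L, ]
    })
    outlier <- outlier_refit(effects, threshold = config$model$outlier_threshold,
                             covariate = ls_cols[["pct_arable"]],
                             config = config)
    .stage_log(quiet, stage, "pct_arable slope %.3f (%.3f after removing %d)",
               landscape$pct_arable$estimate, outlier$slope_after,
               outlier$n_removed)

    stage <- "heterogeneity"
    het <- heterogeneity(grand)
    .stage_log(quiet, stage, "tau = %.3f, I2 = %.1f%%", het$tau, het$I2)

    stage <- "bias"
    funnel <- residuals_and_precision(grand)
    a <- .hblm_args(config)
    # repeated refits (trim iterations, cumulative prefixes) hold phi at the
    # full-data profiled estimate: profiling on short prefixes is unstable
    # and multiplies cost by the phi-grid size
    phi_fix <- grand$phi
    tf <- trim_and_fill(effects, side = config$bias$trim_fill_side,
                        mode = "residual", phi = phi_fix, grid = a$grid)
    cum_v <- cumulative_meta(effects, "sampling_variance",
                             phi = phi_fix, grid = a$grid)
    cum_y <- cumulative_meta(effects, "publication_year",
                             phi = phi_fix, grid = a$grid)
    try_slope <- function(cov) {
      tryCatch(
        slope_test(effects, cov, level = config$level, phi = a$phi,
                   grid = a$grid),
        error = function(e) list(slope = NA_real_, lower = NA_real_,
                                 upper = NA_real_,
                                 note = conditionMessage(e)))
    }
    slope_v <- try_slope("sampling_variance")
    slope_y <- try_slope("publication_year")
    .stage_log(quiet, stage,
               "k0 = %d; cumulative minimum %.3f; slopes v %.3f, year %.4f",
               tf$k0, attr(cum_v, "minimum"), slope_v$slope, slope_y$slope)

    list(tab = tab, records = records, effects = effects,
         adequacy = adequacy, grand = grand, gci = gci,
         subgroups = subgroups, landscape = landscape, outlier = outlier,
         het = het, funnel = funnel, tf = tf, cum_v = cum_v, cum_y = cum_y,
         slope_v = slope_v, slope_y = slope_y)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  report <- list(
    grand_mean = list(
      estimate = res$gci$estimate, lower = res$gci$lower,
      upper = res$gci$upper,
      percent_change = percent_change(res$gci$estimate),
      percent_change_ci = percent_change(c(res$gci$lower, res$gci$upper)),
      phi = res$grand$phi, post_se = res$gci$post_se,
      N = res$grand$N, p = res$grand$p),
    adequacy = res$adequacy,
    subgroups = res$subgroups,
    landscape_slopes = res$landscape,
    outlier_sensitivity = res$outlier[c("slope_before", "slope_after",
                                        "n_removed", "threshold")],
    heterogeneity = list(tau = res$het$tau, tau_var = res$grand$tau_var,
                         tau2 = res$het$tau2, tau2_var = res$grand$tau2_var,
                         I2 = res$het$I2, s_tilde2 = res$het$s_tilde2),
    bias = list(
      trim_fill = res$tf[c("k0", "side", "estimate", "adjusted_estimate",
                           "iterations")],
      cumulative_variance_minimum = attr(res$cum_v, "minimum"),
      cumulative_variance_minimum_step = attr(res$cum_v, "minimum_step"),
      cumulative_year_minimum = attr(res$cum_y, "minimum"),
      slope_sampling_variance = res$slope_v[c("slope", "lower", "upper")],
      slope_publication_year = res$slope_y[c("slope", "lower", "upper")]),
    counts = list(accepted = nrow(res$records),
                  rejected = nrow(res$tab$rejections),
                  effects = nrow(res$effects),
                  publications = length(unique(res$effects$publication_id))),
    provenance = list(seed = seed, config = config,
                      timestamp = NA_character_)
  )
  class(report) <- "analysis_report"

  if (!is.null(out_dir)) {
    ok <- FALSE
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    on.exit(if (!ok) unlink(out_dir, recursive = TRUE), add = TRUE)
    report_for_json <- report
    report_for_json$provenance$config <- NULL
    jsonlite::write_json(report_for_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         na = "null")
    utils::write.csv(res$funnel, file.path(out_dir, "funnel.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(res$cum_v),
                     file.path(out_dir, "cumulative_variance.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(res$cum_y),
                     file.path(out_dir, "cumulative_year.csv"),
                     row.names = FALSE)
    coef_tab <- do.call(rbind, lapply(res$subgroups, function(s) s$cell_means))
    utils::write.csv(coef_tab, file.path(out_dir, "subgroup_coefficients.csv"),
                     row.names = FALSE)
    write_effect_table(res$effects, file.path(out_dir, "effect_sizes.csv"))
    write_rejection_report(res$tab, file.path(out_dir, "rejections.csv"))
    ok <- TRUE
  }
  attr(report, "fits") <- res
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  g <- x$grand_mean
  cat(sprintf("grand mean log RR %.3f (95%% CI %.3f-%.3f); richness +%.0f%%\n",
              g$estimate, g$lower, g$upper, g$percent_change))
  cat(sprintf("tau = %.3f, I2 = %.1f%%; trim-and-fill k0 = %d (adj %.4f)\n",
              x$heterogeneity$tau, x$heterogeneity$I2, x$bias$trim_fill$k0,
              x$bias$trim_fill$adjusted_estimate))
  cat(sprintf("cumulative minimum (by variance): %.3f at step %d of %d\n",
              x$bias$cumulative_variance_minimum,
              x$bias$cumulative_variance_minimum_step, x$counts$effects))
  invisible(x)
}

#' Sensitivity refit of the arable-cover slope without extreme effect sizes
#'
#' Refits the slope model for percent arable cover after removing effect
#' sizes with \code{y > threshold} and reports slopes before and after.
#'
#' @param effects effect-size data frame (needs \code{y}, \code{v},
#'   \code{publication_id}, and the covariate column).
#' @param threshold log response-ratio cutoff (default 2.0).
#' @param covariate slope covariate column (default
#'   \code{"pct_arable_prop"}).
#' @param config analysis configuration (grid/phi settings).
#' @return list with \code{slope_before}, \code{slope_after},
#'   \code{n_removed}, \code{threshold}, and both fits.
#' @export
outlier_refit <- function(effects, threshold = 2.0,
                          covariate = "pct_arable_prop",
                          config = default_analysis_config()) {
  stopifnot(threshold > 0)
  if (is.null(effects[[covariate]])) {
    stop("covariate not present: ", covariate)
  }
  fit1 <- .fit_cfg(effects$y, effects$v,
                   cbind(`(Intercept)` = 1, slope = effects[[covariate]]),
                   effects$publication_id, config)
  keep <- effects$y <= threshold
  if (!any(keep)) stop("outlier threshold removes every effect size")
  sub <- effects[keep, , drop = FALSE]
  fit2 <- .fit_cfg(sub$y, sub$v,
                   cbind(`(Intercept)` = 1, slope = sub[[covariate]]),
                   sub$publication_id, config)
  list(slope_before = unname(fit1$beta[2L]),
       slope_after = unname(fit2$beta[2L]),
       n_removed = sum(!keep), threshold = threshold,
       fit_before = fit1, fit_after = fit2)
}
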