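#' Trim-and-fill assessment of funnel asymmetry
#'
#' Rank-based (L0 estimator) assessment of funnel-plot skew, assuming missing
#' studies on one side of the pooled estimate. Values are centered at the
#' current pooled estimate; with \eqn{T} the sum of the absolute-value ranks
#' of the positively centered values (for \code{side = "right"}),
#' \deqn{L_0 = \frac{4T - n(n+1)}{2n - 1}, \qquad k_0 = \max(0,
#' \mathrm{round}(L_0)).}
#' The algorithm iterates trim (remove the \eqn{k_0} most extreme values on
#' the bias side), re-estimate the center on the trimmed set, and re-rank the
#' full set, until \eqn{k_0} stabilizes or \code{max_iter} is reached. The
#' fill step mirrors the \eqn{k_0} most extreme values about the final center
#' (same sampling variances, fresh pseudo-publication ids) and refits.
#'
#' In \code{mode = "residual"} (the pipeline default) the center is the
#' intercept of the hierarchical model with publication-level dependence, so
#' the centered values are exactly the hierarchical-model residuals whose
#' funnel is being assessed; \code{mode = "raw"} uses the classical
#' fixed-effect (inverse-variance) mean for cross-checks against textbook
#' examples.
#'
#' @param effects data frame with columns \code{y}, \code{v} and (for
#'   residual mode) \code{publication_id}.
#' @param side funnel side assumed to hold the excess: \code{"right"}
#'   (default; excess of positive values) or \code{"left"}.
#' @param mode \code{"residual"} or \code{"raw"} center estimator.
#' @param center optional fixed center; disables re-estimation (used for
#'   textbook cross-checks).
#' @param max_iter iteration cap (default 20).
#' @param ... further arguments passed to [fit_hblm()] (e.g. \code{tau},
#'   \code{grid}).
#' @return object of class \code{trimfill}: \code{k0}, \code{side},
#'   \code{iterations}, unadjusted \code{estimate}/\code{ci}, adjusted
#'   \code{adjusted_estimate}/\code{adjusted_ci}, and the imputed
#'   \code{filled} rows.
#' @export
trim_and_fill <- function(effects, side = c("right", "left"),
                          mode = c("residual", "raw"), center = NULL,
                          max_iter = 20L, ...) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  y <- effects$y
  v <- effects$v
  n <- length(y)
  if (n < 3L) stop("trim-and-fill requires at least 3 effect sizes")
  pub <- if (!is.null(effects$publication_id)) as.character(effects$publication_id)
         else as.character(seq_len(n))
  sgn <- if (side == "right") 1 else -1

  est_center <- function(idx) {
    if (!is.null(center)) return(list(mu = center, fit = NULL))
    if (mode == "residual") {
      fit <- fit_hblm(y[idx], v[idx], publication_id = pub[idx], ...)
      list(mu = unname(fit$beta[1L]), fit = fit)
    } else {
      w <- 1 / v[idx]
      list(mu = sum(w * y[idx]) / sum(w), fit = NULL)
    }
  }
  k0_of <- function(mu) {
    z <- sgn * (y - mu)
    r <- rank(abs(z))
    T_pos <- sum(r[z > 0])
    L0 <- (4 * T_pos - n * (n + 1)) / (2 * n - 1)
    max(0L, as.integer(round(L0)))
  }

  idx <- seq_len(n)
  cen <- est_center(idx)
  k0 <- k0_of(cen$mu)
  iter <- 1L
  while (iter < max_iter) {
    trim_idx <- if (k0 > 0L) {
      z <- sgn * (y - cen$mu)
      order(z, decreasing = TRUE)[seq_len(k0)]
    } else integer()
    idx <- setdiff(seq_len(n), trim_idx)
    cen <- est_center(idx)
    k0_new <- k0_of(cen$mu)
    iter <- iter + 1L
    if (k0_new == k0) { k0 <- k0_new; break }
    k0 <- k0_new
  }

  base_fit <- if (mode == "residual" && is.null(center)) {
    fit_hblm(y, v, publication_id = pub, ...)
  } else NULL
  estimate <- if (!is.null(base_fit)) unname(base_fit$beta[1L]) else {
    w <- 1 / v; sum(w * y) / sum(w)
  }
  ci <- if (!is.null(base_fit)) {
    unlist(credible_interval(base_fit)[1L, c("lower", "upper")])
  } else c(lower = NA_real_, upper = NA_real_)

  if (k0 > 0L) {
    z <- sgn * (y - cen$mu)
    ext <- order(z, decreasing = TRUE)[seq_len(k0)]
    fill <- data.frame(
      y = 2 * cen$mu - y[ext], v = v[ext],
      publication_id = paste0("fill_", seq_len(k0)),
      stringsAsFactors = FALSE
    )
    y2 <- c(y, fill$y); v2 <- c(v, fill$v); pub2 <- c(pub, fill$publication_id)
    if (mode == "residual" && is.null(center)) {
      adj_fit <- fit_hblm(y2, v2, publication_id = pub2, ...)
      adjusted <- unname(adj_fit$beta[1L])
      adj_ci <- unlist(credible_interval(adj_fit)[1L, c("lower", "upper")])
    } else {
      w2 <- 1 / v2
      adjusted <- sum(w2 * y2) / sum(w2)
      adj_ci <- c(lower = NA_real_, upper = NA_real_)
    }
  } else {
    fill <- data.frame(y = numeric(), v = numeric(),
                       publication_id = character())
    adjusted <- estimate
    adj_ci <- ci
  }

  structure(list(k0 = k0, side = side, mode = mode, iterations = iter,
                 estimate = estimate, ci = ci,
                 adjusted_estimate = adjusted, adjusted_ci = adj_ci,
                 filled = fill),
            class = "trimfill")
}

#' @export
print.trimfill <- function(x, ...) {
  cat(sprintf("trim-and-fill (%s, %s side): k0 = %d imputed, estimate %.4f -> %.4f\n",
              x$mode, x$side, x$k0, x$estimate, x$adjusted_estimate))
  invisible(x)
}

#' Cumulative meta-analysis
#'
#' Progressively adds effect sizes in order of the sort key (increasing
#' sampling variance, or publication year) and refits the full hierarchical
#' intercept-only model on each prefix. The minimum of the trace is the most
#' conservative pooled estimate under the assumption that late-added (less
#' reliable or more recent) studies carry the bias.
#'
#' @param effects data frame with \code{y}, \code{v}, \code{publication_id},
#'   and \code{pub_year} when sorting by year.
#' @param sort_key \code{"sampling_variance"} (default) or
#'   \code{"publication_year"}.
#' @param ... arguments passed to [fit_hblm()] (e.g. \code{tau},
#'   \code{phi}, \code{grid}).
#' @return data frame of class \code{cumulative_trace} with columns
#'   \code{step}, \code{key}, \code{estimate}, \code{lower}, \code{upper},
#'   \code{n}; attributes \code{minimum} (smallest cumulative estimate) and
#'   \code{minimum_step}. Ties in the key are broken by
#'   \code{publication_id}, then \code{observation_id}.
#' @export
cumulative_meta <- function(effects,
                            sort_key = c("sampling_variance",
                                         "publication_year"), ...) {
  sort_key <- match.arg(sort_key)
  n <- nrow(effects)
  if (n < 2L) stop("cumulative meta-analysis requires at least 2 effect sizes")
  key <- switch(sort_key,
    sampling_variance = effects$v,
    publication_year = effects$pub_year
  )
  if (is.null(key) || any(is.na(key))) {
    stop("sort key missing for some effect sizes: ", sort_key)
  }
  pub <- if (!is.null(effects$publication_id))
    as.character(effects$publication_id) else as.character(seq_len(n))
  obs <- if (!is.null(effects$observation_id))
    as.character(effects$observation_id) else as.character(seq_len(n))
  ord <- order(key, pub, obs)
  y <- effects$y[ord]; v <- effects$v[ord]; pub <- pub[ord]
  out <- data.frame(step = seq_len(n), key = key[ord],
                    estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                    n = seq_len(n))
  for (k in seq_len(n)) {
    fit <- fit_hblm(y[seq_len(k)], v[seq_len(k)],
                    publication_id = pub[seq_len(k)], ...)
    ci <- credible_interval(fit)
    out$estimate[k] <- ci$estimate[1L]
    out$lower[k] <- ci$lower[1L]
    out$upper[k] <- ci$upper[1L]
  }
  attr(out, "minimum") <- min(out$estimate)
  attr(out, "minimum_step") <- which.min(out$estimate)
  attr(out, "sort_key") <- sort_key
  class(out) <- c("cumulative_trace", "data.frame")
  out
}

#' Slope test for small-study or temporal trends
#'
#' Hierarchical meta-regression of the effect size on an intercept plus one
#' covariate: the sampling variance (small-study / publication-bias trend) or
#' the publication year (temporal stability).
#'
#' @param effects data frame with \code{y}, \code{v}, \code{publication_id},
#'   and \code{pub_year} when needed.
#' @param covariate \code{"sampling_variance"} or \code{"publication_year"}.
#' @param level credible level (default 0.95).
#' @param ... passed to [fit_hblm()].
#' @return list with \code{slope}, \code{lower}, \code{upper}, \code{fit}.
#' @export
slope_test <- function(effects,
                       covariate = c("sampling_variance", "publication_year"),
                       level = 0.95, ...) {
  covariate <- match.arg(covariate)
  x <- switch(covariate,
    sampling_variance = effects$v,
    publication_year = effects$pub_year
  )
  if (is.null(x) || any(is.na(x))) stop("covariate missing: ", covariate)
  if (length(unique(x)) < 2L) stop("degenerate regressor: constant covariate")
  X <- cbind(`(Intercept)` = 1, x)
  colnames(X)[2L] <- covariate
  pub <- if (!is.null(effects$publication_id))
    as.character(effects$publication_id) else NULL
  fit <- fit_hblm(effects$y, effects$v, X = X, publication_id = pub, ...)
  ci <- credible_interval(fit, level = level)
  list(slope = ci$estimate[2L], lower = ci$lower[2L], upper = ci$upper[2L],
       fit = fit)
}
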