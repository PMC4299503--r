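#' Convert a reported variation measure to a standard deviation
#'
#' Publications report dispersion in several guises; the meta-analysis needs
#' arm-level standard deviations. Supported kinds: \code{"sd"} (identity),
#' \code{"se"} (standard error, multiplied by \eqn{\sqrt{n}}),
#' \code{"variance"} (square root), and \code{"ci95_halfwidth"} (half-width of
#' a two-sided 95\% confidence interval, converted via the t quantile with
#' \eqn{n - 1} degrees of freedom: \eqn{value \cdot \sqrt{n} / t_{n-1,0.975}}).
#'
#' @param value nonnegative measure value(s).
#' @param kind one of \code{"sd"}, \code{"se"}, \code{"variance"},
#'   \code{"ci95_halfwidth"}; recycled against \code{value}.
#' @param n sample size; required (\code{n >= 2}) for \code{"se"} and
#'   \code{"ci95_halfwidth"}.
#' @return standard deviation(s), same length as \code{value}.
#' @examples
#' to_sd(0.5, "se", n = 16)    # 2
#' to_sd(9, "variance")        # 3
#' @export
to_sd <- function(value, kind = c("sd", "se", "variance", "ci95_halfwidth"),
                  n = NA_real_) {
  kind <- match.arg(kind)
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("variation measure must be finite and nonnegative")
  }
  switch(kind,
    sd = value,
    variance = sqrt(value),
    se = {
      if (any(is.na(n)) || any(n < 2)) stop("se conversion requires n >= 2")
      value * sqrt(n)
    },
    ci95_halfwidth = {
      if (any(is.na(n)) || any(n < 2)) {
        stop("ci95_halfwidth conversion requires n >= 2")
      }
      value * sqrt(n) / stats::qt(0.975, df = n - 1)
    }
  )
}
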