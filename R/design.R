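#' Build a meta-regression design matrix
#'
#' Constructs the fixed-effects design with treatment-contrast coding:
#' categorical terms contribute one dummy column per non-reference level
#' (reference absorbed into the intercept), continuous terms enter raw, and
#' an interaction of a continuous term with a categorical one yields one slope
#' column per level of the categorical ("separate slopes"). With
#' \code{cell_means = TRUE} a single categorical term is coded without an
#' intercept so each level gets its own estimate (forest-plot style).
#'
#' Column order is deterministic: spec order, then declared level order.
#'
#' @param data data frame of effect sizes / records holding the covariates.
#' @param terms character vector of main-effect column names (categorical or
#'   numeric); may be empty for an intercept-only design.
#' @param refs named list of reference levels for categorical terms; defaults
#'   to the first level in sorted order.
#' @param levels optional named list declaring the admissible level set per
#'   categorical term; data levels outside a declared set raise an error
#'   naming the offending level.
#' @param interactions list of length-2 character vectors
#'   \code{c(continuous, categorical)}; each produces per-level slope columns
#'   (no common slope).
#' @param intercept include an intercept column (default \code{TRUE}).
#' @param cell_means no-intercept one-column-per-level coding; requires
#'   exactly one categorical term and no interactions.
#' @return numeric matrix with descriptive column labels; attribute
#'   \code{"terms"} records the model specification.
#' @examples
#' d <- data.frame(scale = c("farm", "field", "plot"), pct_arable = c(10, 50, 90))
#' build_design(d, terms = "scale", refs = list(scale = "farm"))
#' @export
build_design <- function(data, terms = character(), refs = list(),
                         levels = list(), interactions = list(),
                         intercept = TRUE, cell_means = FALSE) {
  n <- nrow(data)
  cols <- list()
  labels <- character()
  add_col <- function(x, lab) {
    cols[[length(cols) + 1L]] <<- x
    labels[length(labels) + 1L] <<- lab
  }
  get_levels <- function(term) {
    x <- as.character(data[[term]])
    ref <- refs[[term]]
    if (!is.null(levels[[term]])) {
      lev <- levels[[term]]
      unseen <- setdiff(unique(x), c(lev, ref))
      if (length(unseen) > 0L) {
        stop("unseen level in ", term, ": ", paste(unseen, collapse = ", "))
      }
    } else {
      lev <- sort(unique(x))
    }
    if (!is.null(ref)) {
      lev <- c(ref, setdiff(lev, ref))
    }
    lev
  }
  if (cell_means) {
    if (length(terms) != 1L || length(interactions) > 0L) {
      stop("cell_means coding requires exactly one categorical term")
    }
    term <- terms[[1L]]
    x <- as.character(data[[term]])
    for (lev in get_levels(term)) {
      add_col(as.numeric(x == lev), paste0(term, ":", lev))
    }
  } else {
    if (intercept) add_col(rep(1, n), "(Intercept)")
    for (term in terms) {
      if (is.null(data[[term]])) stop("unknown term: ", term)
      x <- data[[term]]
      if (is.numeric(x)) {
        add_col(as.numeric(x), term)
      } else {
        x <- as.character(x)
        lev <- get_levels(term)
        if (any(!(x %in% lev))) {
          stop("unseen level in ", term, ": ",
               paste(setdiff(unique(x), lev), collapse = ", "))
        }
        for (l in lev[-1L]) add_col(as.numeric(x == l), paste0(term, ":", l))
      }
    }
    for (ia in interactions) {
      stopifnot(length(ia) == 2L)
      cont <- data[[ia[[1L]]]]
      cat_ <- as.character(data[[ia[[2L]]]])
      if (!is.numeric(cont)) stop("first interaction term must be continuous: ",
                                  ia[[1L]])
      for (lev in sort(unique(cat_))) {
        add_col(as.numeric(cat_ == lev) * cont,
                paste0(ia[[1L]], ":", ia[[2L]], ":", lev))
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- labels
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- labels[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  attr(X, "terms") <- list(terms = terms, refs = refs,
                           interactions = interactions,
                           intercept = intercept, cell_means = cell_means)
  X
}
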