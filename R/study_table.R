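#' @title Study-table schema
#' @description Column layout of the tabular study file: one row per
#'   observation (a within-publication subgroup comparison), holding arm-level
#'   species-richness summaries and landscape covariates.
#' @details Categorical columns are normalized case-insensitively against the
#'   documented level sets; a small synonym map (e.g. \code{"grasses"} ->
#'   \code{"grassland"}, \code{"unspecified"} -> \code{"miscellaneous"})
#'   absorbs spelling variants seen in the literature. The machine-readable
#'   schema ships as \code{inst/extdata/study_schema.json}.
#' @format A data frame with columns \code{name}, \code{type}, \code{required}.
#' @keywords internal
#' @name study_schema
NULL

.TAXON_LEVELS <- c("arthropods", "birds", "microbes", "plants")
.FUNCTIONAL_LEVELS <- c("producers", "herbivores", "pollinators", "predators",
                        "decomposers", "other")
.CROP_LEVELS <- c("cereals", "grassland", "mixed", "orchard", "vegetables",
                  "miscellaneous")
.SCALE_LEVELS <- c("plot", "field", "farm")

# synonym map applied after lower-casing; left = as found, right = canonical
.ENUM_SYNONYMS <- c(
  grasses = "grassland", grass = "grassland", pasture = "grassland",
  unspecified = "miscellaneous", misc = "miscellaneous",
  orchards = "orchard", vegetable = "vegetables", cereal = "cereals",
  arthropod = "arthropods", bird = "birds", microbe = "microbes",
  plant = "plants", producer = "producers", herbivore = "herbivores",
  pollinator = "pollinators", predator = "predators",
  decomposer = "decomposers", others = "other"
)

.NUMERIC_COLS <- c("pub_year", "mean_org", "sd_org", "n_org", "mean_conv",
                   "sd_conv", "n_conv", "pct_arable", "n_habitats",
                   "avg_field_size")
.LANDSCAPE_COLS <- c("pct_arable", "n_habitats", "avg_field_size")

.MANDATORY_COLS <- c("publication_id", "observation_id", "pub_year", "country",
                     "taxon_group", "functional_group", "crop_type", "scale",
                     "mean_org", "sd_org", "n_org",
                     "mean_conv", "sd_conv", "n_conv")
.OPTIONAL_COLS <- c("region", .LANDSCAPE_COLS, "richness_surrogate")
.ALL_COLS <- c(.MANDATORY_COLS, .OPTIONAL_COLS)

.normalize_enum <- function(x, levels, column) {
  x <- tolower(trimws(as.character(x)))
  hit <- x %in% names(.ENUM_SYNONYMS)
  x[hit] <- unname(.ENUM_SYNONYMS[x[hit]])
  x
}

#' Read the tabular study file
#'
#' Parses a CSV of per-observation study records. Rows violating the inclusion
#' rules (replication \code{n > 1} in both arms, positive means, recognized
#' taxonomic group) are collected into a structured rejection report rather
#' than silently dropped. A decimal middle dot is normalized to \code{"."} on
#' read.
#'
#' @param path path to a UTF-8 comma-separated file whose header matches the
#'   documented schema (case-insensitive).
#' @return An object of class \code{study_table}: a list with elements
#'   \code{records} (data frame of accepted rows) and \code{rejections}
#'   (data frame with \code{row}, \code{observation_id}, \code{reason}).
#' @examples
#' tab <- simulate_meta_dataset(sim_config(n_publications = 5, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_study_table(tab$records, f)
#' st <- read_study_table(f)
#' nrow(st$records)
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) stop("study table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, encoding = "UTF-8")
  names(raw) <- tolower(trimws(names(raw)))
  missing_cols <- setdiff(.MANDATORY_COLS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(.OPTIONAL_COLS, names(raw))) raw[[col]] <- NA
  raw <- raw[.ALL_COLS]
  # decimal middle-dot normalization, then numeric coercion
  for (col in .NUMERIC_COLS) {
    x <- raw[[col]]
    if (is.character(x)) x <- gsub("·", ".", x, fixed = TRUE)
    raw[[col]] <- suppressWarnings(as.numeric(x))
  }
  validate_study_records(raw)
}

#' Validate study records against the inclusion rules
#'
#' @param df data frame with the schema columns (already numeric-coerced).
#' @return a \code{study_table} (see [read_study_table()]).
#' @keywords internal
validate_study_records <- function(df) {
  n <- nrow(df)
  reasons <- character(n)
  add_reason <- function(reasons, bad, msg) {
    bad <- which(bad & !nzchar(reasons))
    reasons[bad] <- msg
    reasons
  }
  df$taxon_group <- .normalize_enum(df$taxon_group)
  df$functional_group <- .normalize_enum(df$functional_group)
  df$crop_type <- .normalize_enum(df$crop_type)
  df$scale <- .normalize_enum(df$scale)

  num_bad <- rep(FALSE, n)
  for (col in setdiff(.NUMERIC_COLS, .LANDSCAPE_COLS)) {
    num_bad <- num_bad | is.na(df[[col]])
  }
  reasons <- add_reason(reasons, num_bad, "unparseable or missing numeric field")
  reasons <- add_reason(reasons, !num_bad & (df$n_org <= 1 | df$n_conv <= 1),
                        "n must exceed 1")
  reasons <- add_reason(reasons, !num_bad & (df$mean_org <= 0 | df$mean_conv <= 0),
                        "nonpositive mean richness")
  reasons <- add_reason(reasons, !num_bad & (df$sd_org < 0 | df$sd_conv < 0),
                        "negative standard deviation")
  reasons <- add_reason(reasons, !num_bad & df$sd_org == 0 & df$sd_conv == 0,
                        "zero dispersion in both arms (degenerate variance)")
  reasons <- add_reason(reasons, !(df$taxon_group %in% .TAXON_LEVELS),
                        "taxon group excluded (small sample size, n < 5)")
  reasons <- add_reason(reasons, !(df$functional_group %in% .FUNCTIONAL_LEVELS),
                        "unrecognized functional group")
  reasons <- add_reason(reasons, !(df$crop_type %in% .CROP_LEVELS),
                        "unrecognized crop type")
  reasons <- add_reason(reasons, !(df$scale %in% .SCALE_LEVELS),
                        "unrecognized sampling scale")
  # landscape covariates: all present or all missing per record
  ls_na <- rowSums(is.na(df[.LANDSCAPE_COLS]))
  reasons <- add_reason(reasons, ls_na %in% c(1L, 2L),
                        "landscape covariates partially missing")
  ok_ls <- ls_na == 0L & !num_bad
  reasons <- add_reason(
    reasons,
    ok_ls & (df$pct_arable < 0 | df$pct_arable > 100),
    "pct_arable outside [0, 100]")
  reasons <- add_reason(reasons, ok_ls & df$n_habitats < 1,
                        "n_habitats below 1")
  reasons <- add_reason(reasons, ok_ls & df$avg_field_size <= 0,
                        "nonpositive avg_field_size")

  keep <- !nzchar(reasons)
  rejections <- data.frame(
    row = which(!keep),
    observation_id = as.character(df$observation_id[!keep]),
    reason = reasons[!keep],
    stringsAsFactors = FALSE
  )
  records <- df[keep, , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, rejections = rejections),
            class = "study_table")
}

#' @export
print.study_table <- function(x, ...) {
  cat("study_table:", nrow(x$records), "accepted record(s),",
      nrow(x$rejections), "rejected\n")
  invisible(x)
}

#' Write study records to CSV
#'
#' Inverse of [read_study_table()] on valid records (round-trip identity).
#'
#' @param records data frame of study records (the \code{records} element of a
#'   \code{study_table}, or a compatible data frame).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_study_table <- function(records, path) {
  if (inherits(records, "study_table")) records <- records$records
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the rejection report
#' @param tab a \code{study_table}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_rejection_report <- function(tab, path) {
  stopifnot(inherits(tab, "study_table"))
  utils::write.csv(tab$rejections, path, row.names = FALSE)
  invisible(path)
}

#' Export the machine-readable schema
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_schema_json <- function(path) {
  schema <- list(
    columns = lapply(.ALL_COLS, function(nm) {
      list(name = nm,
           type = if (nm %in% .NUMERIC_COLS) "numeric" else "string",
           required = nm %in% .MANDATORY_COLS)
    }),
    enums = list(taxon_group = .TAXON_LEVELS,
                 functional_group = .FUNCTIONAL_LEVELS,
                 crop_type = .CROP_LEVELS,
                 scale = .SCALE_LEVELS),
    synonyms = as.list(.ENUM_SYNONYMS)
  )
  jsonlite::write_json(schema, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
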