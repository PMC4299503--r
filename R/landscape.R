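.HABITAT_LEVELS <- c("field", "pasture", "forest", "wetland", "water",
                     "rural", "urban", "line_element")

#' Construct a categorical land-cover map
#'
#' A planar raster of habitat labels with an arable field-parcel id layer.
#' Coordinates are metric, origin at the lower-left corner; cell
#' \code{[row, col]} covers
#' \code{x in [ox + (col-1)s, ox + col*s)}, \code{y in [oy + (row-1)s, oy + row*s)}
#' with \code{s} the cell size. No geodesy: maps are synthetic stand-ins for
#' digitized landscape imagery.
#'
#' @param habitat character matrix of habitat labels (one of field, pasture,
#'   forest, wetland, water, rural, urban, line_element).
#' @param parcel integer matrix of the same dimension giving an arable parcel
#'   id (> 0) for every \code{"field"} cell; defaults to a single parcel
#'   covering all field cells.
#' @param cell_size cell edge length in metres (> 0).
#' @param origin numeric \code{c(x, y)} of the lower-left corner in metres.
#' @return object of class \code{land_cover_map}.
#' @export
land_cover_map <- function(habitat, parcel = NULL, cell_size = 10,
                           origin = c(0, 0)) {
  stopifnot(is.matrix(habitat), cell_size > 0, length(origin) == 2L)
  bad <- setdiff(unique(as.vector(habitat)), .HABITAT_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown habitat label(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(parcel)) {
    parcel <- matrix(0L, nrow(habitat), ncol(habitat))
    parcel[habitat == "field"] <- 1L
  }
  stopifnot(all(dim(parcel) == dim(habitat)))
  if (any(habitat == "field" & parcel <= 0)) {
    stop("every arable (field) cell needs a positive parcel id")
  }
  structure(list(habitat = habitat, parcel = parcel,
                 cell_size = cell_size, origin = as.numeric(origin),
                 extent = c(origin[1L] + ncol(habitat) * cell_size,
                            origin[2L] + nrow(habitat) * cell_size)),
            class = "land_cover_map")
}

#' @export
print.land_cover_map <- function(x, ...) {
  cat(sprintf("land_cover_map: %d x %d cells of %gm (%g x %g m)\n",
              nrow(x$habitat), ncol(x$habitat), x$cell_size,
              x$extent[1L] - x$origin[1L], x$extent[2L] - x$origin[2L]))
  print(table(x$habitat))
  invisible(x)
}

#' Define a circular study region
#' @param centre numeric \code{c(x, y)} central measuring point, metres.
#' @param radius sampling radius in metres (> 0).
#' @return object of class \code{study_region}.
#' @export
study_region <- function(centre, radius) {
  stopifnot(length(centre) == 2L, is.numeric(radius), radius > 0)
  structure(list(centre = as.numeric(centre), radius = radius),
            class = "study_region")
}

.deg2rad <- function(d) d * pi / 180

# segment intersection, endpoints inclusive (shared endpoint = crossing)
.segments_cross <- function(p1, p2, p3, p4) {
  o <- function(a, b, c) {
    val <- (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
    if (abs(val) < 1e-9) 0L else if (val > 0) 1L else -1L
  }
  on_seg <- function(a, b, c) {
    min(a[1L], b[1L]) - 1e-9 <= c[1L] && c[1L] <= max(a[1L], b[1L]) + 1e-9 &&
    min(a[2L], b[2L]) - 1e-9 <= c[2L] && c[2L] <= max(a[2L], b[2L]) + 1e-9
  }
  o1 <- o(p1, p2, p3); o2 <- o(p1, p2, p4)
  o3 <- o(p3, p4, p1); o4 <- o(p3, p4, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0L && on_seg(p1, p2, p3)) || (o2 == 0L && on_seg(p1, p2, p4)) ||
  (o3 == 0L && on_seg(p3, p4, p1)) || (o4 == 0L && on_seg(p3, p4, p2))
}

#' Randomly place non-crossing 1-km transects in a study region
#'
#' Each transect is defined by three random numbers: a distance
#' \eqn{d \sim U[0, radius]} from the central point, a bearing
#' \eqn{\sim U[0, 360)} degrees fixing the transect start point, and an
#' orientation drawn uniformly from \{0, 45, 90, 180\} degrees along which
#' the transect extends 500 m to each side of the start point. A drawn
#' transect that crosses an already-accepted one (shared endpoints count as
#' crossing) is rejected and redrawn, up to \code{max_attempts} per transect.
#' Start points always lie inside the region; ends may overhang it.
#'
#' @param region a [study_region()].
#' @param k number of transects (default 5).
#' @param seed RNG seed; required for reproducibility, applied with
#'   \code{set.seed}.
#' @param max_attempts redraw cap per transect (default 1000).
#' @return list of \code{k} transects, each a list with \code{start},
#'   \code{orientation} (degrees), \code{a}, \code{b} (endpoints),
#'   \code{d}, \code{bearing}.
#' @export
place_transects <- function(region, k = 5L, seed = NULL, max_attempts = 1000L) {
  stopifnot(inherits(region, "study_region"), k >= 1L)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      d <- stats::runif(1, 0, region$radius)
      bearing <- stats::runif(1, 0, 360)
      orientation <- sample(c(0, 45, 90, 180), 1L)
      start <- region$centre + d * c(cos(.deg2rad(bearing)),
                                     sin(.deg2rad(bearing)))
      dir <- c(cos(.deg2rad(orientation)), sin(.deg2rad(orientation)))
      a <- start - 500 * dir
      b <- start + 500 * dir
      crosses <- FALSE
      for (t0 in out[seq_len(i - 1L)]) {
        if (.segments_cross(a, b, t0$a, t0$b)) { crosses <- TRUE; break }
      }
      if (!crosses) {
        out[[i]] <- list(start = start, orientation = orientation,
                         a = a, b = b, d = d, bearing = bearing)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place ", k, " non-crossing transects after ",
           max_attempts, " attempts; consider a larger study radius")
    }
  }
  out
}

.lookup_cells <- function(map, xs, ys) {
  col <- floor((xs - map$origin[1L]) / map$cell_size) + 1L
  row <- floor((ys - map$origin[2L]) / map$cell_size) + 1L
  if (any(col < 1L | col > ncol(map$habitat) |
          row < 1L | row > nrow(map$habitat))) {
    stop("transect exits map extent")
  }
  cbind(row, col)
}

#' Land-use intensity metrics along one transect
#'
#' The 1-km line is discretized at 1-m steps (midpoint sampling: 1000 points,
#' each standing for 1 m of transect, so per-habitat segment lengths sum to
#' exactly 1000 m). Metrics: \code{pct_arable} = 100 x (length over
#' field-labelled cells)/1000; \code{n_habitats} = number of distinct habitat
#' labels intersected; \code{avg_field_size} = mean area (hectares, from the
#' parcel layer) of the distinct arable parcels intersected (\code{NA} if the
#' transect meets no field). Transects are bufferless lines.
#'
#' @param transect a transect from [place_transects()].
#' @param map a [land_cover_map()].
#' @param step sampling step in metres (default 1).
#' @return list with \code{pct_arable}, \code{n_habitats},
#'   \code{avg_field_size}, and the named \code{segment_lengths} vector.
#' @export
transect_metrics <- function(transect, map, step = 1) {
  n_pts <- as.integer(round(1000 / step))
  tfrac <- (seq_len(n_pts) - 0.5) / n_pts
  xs <- transect$a[1L] + tfrac * (transect$b[1L] - transect$a[1L])
  ys <- transect$a[2L] + tfrac * (transect$b[2L] - transect$a[2L])
  rc <- .lookup_cells(map, xs, ys)
  hab <- map$habitat[rc]
  seg <- tapply(rep(step, n_pts), hab, sum)
  seg <- stats::setNames(as.numeric(seg), names(seg))
  field_pts <- hab == "field"
  pct_arable <- 100 * sum(field_pts) * step / 1000
  parcels <- unique(map$parcel[rc[field_pts, , drop = FALSE]])
  avg_field_size <- if (length(parcels) > 0L) {
    areas <- vapply(parcels, function(id) {
      sum(map$parcel == id & map$habitat == "field") * map$cell_size^2 / 1e4
    }, 0)
    mean(areas)
  } else NA_real_
  list(pct_arable = pct_arable,
       n_habitats = length(unique(hab)),
       avg_field_size = avg_field_size,
       segment_lengths = seg)
}

#' Averaged landscape metrics for a study region
#'
#' Places \code{k} random non-crossing transects and returns the arithmetic
#' mean of each metric across them (\code{avg_field_size} averaged over
#' transects that intersect at least one field). Deterministic per seed.
#'
#' @inheritParams place_transects
#' @param map a [land_cover_map()].
#' @param step sampling step in metres for [transect_metrics()].
#' @return list with the three averaged metrics, plus \code{per_transect}
#'   (data frame) and \code{transects}.
#' @export
study_landscape_metrics <- function(region, map, k = 5L, seed = NULL,
                                    step = 1, max_attempts = 1000L) {
  tr <- place_transects(region, k = k, seed = seed,
                        max_attempts = max_attempts)
  per <- lapply(tr, transect_metrics, map = map, step = step)
  df <- data.frame(
    pct_arable = vapply(per, `[[`, 0, "pct_arable"),
    n_habitats = vapply(per, `[[`, 0, "n_habitats"),
    avg_field_size = vapply(per, `[[`, 0, "avg_field_size")
  )
  list(pct_arable = mean(df$pct_arable),
       n_habitats = mean(df$n_habitats),
       avg_field_size = if (all(is.na(df$avg_field_size))) NA_real_
                        else mean(df$avg_field_size, na.rm = TRUE),
       per_transect = df, transects = tr)
}

#' Impute missing landscape covariates by country means
#'
#' Records whose three landscape covariates are all missing (region known
#' only at country level) receive the per-country means of the complete
#' records; an \code{imputed_landscape} flag is added.
#'
#' @param records study-record data frame (or \code{study_table}).
#' @return the records with landscape covariates filled.
#' @export
impute_country_means <- function(records) {
  if (inherits(records, "study_table")) records <- records$records
  miss <- rowSums(is.na(records[.LANDSCAPE_COLS])) == 3L
  records$imputed_landscape <- miss
  if (!any(miss)) return(records)
  complete <- records[!miss, , drop = FALSE]
  for (ctry in unique(records$country[miss])) {
    donors <- complete[complete$country == ctry, , drop = FALSE]
    if (nrow(donors) == 0L) {
      stop("no donor records with landscape data in country: ", ctry)
    }
    sel <- miss & records$country == ctry
    for (col in .LANDSCAPE_COLS) {
      records[[col]][sel] <- mean(donors[[col]])
    }
  }
  records
}
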