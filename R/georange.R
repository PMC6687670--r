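# Lambert azimuthal equal-area projection on a 6371-km sphere, centered on
# the point set's centroid; returns x/y in km. Equal-area by construction,
# so planar areas in the projection are areas on the sphere.
.laea_project <- function(lon, lat, center = c(mean(lon), mean(lat))) {
  R <- 6371
  lam <- lon * pi / 180; phi <- lat * pi / 180
  lam0 <- center[1L] * pi / 180; phi1 <- center[2L] * pi / 180
  denom <- 1 + sin(phi1) * sin(phi) + cos(phi1) * cos(phi) * cos(lam - lam0)
  kp <- sqrt(2 / denom)
  cbind(x = R * kp * cos(phi) * sin(lam - lam0),
        y = R * kp * (cos(phi1) * sin(phi) - sin(phi1) * cos(phi) * cos(lam - lam0)))
}

# shoelace polygon area; vertices in order
.polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Extent of Occurrence (convex-hull area)
#'
#' Projects the points onto an azimuthal equal-area plane centered on their
#' centroid and returns the area of the 2-D convex hull in square km. Fewer
#' than 3 non-collinear points yield 0.
#'
#' @param points Locality data frame with \code{lon}, \code{lat} (decimal
#'   degrees).
#' @return EOO in square km.
#' @export
eoo <- function(points) {
  points <- if (is.data.frame(points)) points else as.data.frame(points)
  if (nrow(points) < 1L) stop("at least one point is required")
  if (nrow(points) < 3L) return(0)
  xy <- .laea_project(points$lon, points$lat)
  xy <- unique(xy)
  if (nrow(xy) < 3L) return(0)
  h <- grDevices::chull(xy[, 1L], xy[, 2L])
  if (length(h) < 3L) return(0)
  .polygon_area(xy[h, 1L], xy[h, 2L])
}

#' Area of Occupancy (occupied grid cells)
#'
#' Counts occupied cells of a fixed-origin square grid (default 2 x 2 km,
#' the IUCN reference scale) in the equal-area projection, with the grid
#' origin at the projection center, and returns cells times cell area.
#'
#' @param points Locality data frame with \code{lon}, \code{lat}.
#' @param cell_km Grid cell edge in km (default 2).
#' @return AOO in square km (a positive multiple of \code{cell_km^2}).
#' @export
aoo <- function(points, cell_km = 2) {
  points <- if (is.data.frame(points)) points else as.data.frame(points)
  if (nrow(points) < 1L) stop("at least one point is required")
  xy <- .laea_project(points$lon, points$lat)
  cells <- unique(paste(floor(xy[, 1L] / cell_km), floor(xy[, 2L] / cell_km)))
  length(cells) * cell_km^2
}

#' Range metrics for one species
#'
#' @param points Locality data frame for a single species.
#' @param n_locations Number of threat-defined locations (sensu IUCN);
#'   analyst-supplied, cannot be computed from coordinates.
#' @param cell_km AOO grid cell edge in km.
#' @return List with \code{eoo_km2}, \code{aoo_km2}, \code{n_points},
#'   \code{n_locations}.
#' @export
range_metrics <- function(points, n_locations = NA_integer_, cell_km = 2) {
  list(eoo_km2 = eoo(points), aoo_km2 = aoo(points, cell_km),
       n_points = nrow(points), n_locations = n_locations)
}

.sd_b_thresholds <- list(
  CR = c(eoo = 100,   aoo = 10),
  EN = c(eoo = 5000,  aoo = 500),
  VU = c(eoo = 20000, aoo = 2000))
.sd_loc_thresholds <- c(CR = 1L, EN = 5L, VU = 10L)

#' IUCN criterion-B Red List categorization
#'
#' Applies the criterion-B geographic-range thresholds (B1 on EOO: CR < 100,
#' EN < 5000, VU < 20000 square km; B2 on AOO: CR < 10, EN < 500, VU < 2000
#' square km). A threatened category requires, in addition to a range
#' threshold, at least two of the conditions \emph{a} (few locations, taken
#' as 10 or fewer), \emph{b(iii)} (continuing decline in habitat) and
#' \emph{c} (extreme fluctuations). A degenerate EOO of 0 (fewer than three
#' non-collinear points) never triggers B1; the assessment then rests on
#' AOO. \code{data_deficient} short-circuits to DD; when no threshold or too
#' few conditions are met the category is LC (NT is never emitted
#' automatically).
#'
#' @param metrics List from \code{\link{range_metrics}} (or any list with
#'   \code{eoo_km2}, \code{aoo_km2}, \code{n_locations}).
#' @param decline Continuing decline in extent/quality of habitat
#'   (condition b(iii)); analyst-supplied flag.
#' @param fluctuation Extreme fluctuations (condition c); analyst-supplied.
#' @param data_deficient Knowledge too poor for assessment.
#' @param species Optional species label carried into the result.
#' @return An object of class \code{redlist_assessment}: \code{species},
#'   \code{category} in \{DD, LC, VU, EN, CR\}, \code{criteria} string such
#'   as \code{"B1ab(iii)+2ab(iii)"}, and \code{rationale} (thresholds met
#'   and conditions).
#' @export
assess_category <- function(metrics, decline = FALSE, fluctuation = FALSE,
                            data_deficient = FALSE, species = NA_character_) {
  eoo_km2 <- metrics$eoo_km2
  aoo_km2 <- if (is.null(metrics$aoo_km2)) NA_real_ else metrics$aoo_km2
  n_loc <- if (is.null(metrics$n_locations)) NA_integer_ else metrics$n_locations
  if ((!is.na(eoo_km2) && eoo_km2 < 0) || (!is.na(aoo_km2) && aoo_km2 < 0))
    stop("range metrics must be non-negative")
  cond_a <- !is.na(n_loc) && n_loc <= .sd_loc_thresholds[["VU"]]
  cond_b <- isTRUE(decline)
  cond_c <- isTRUE(fluctuation)
  n_cond <- sum(cond_a, cond_b, cond_c)
  rationale <- list(eoo_km2 = eoo_km2, aoo_km2 = aoo_km2,
                    n_locations = n_loc,
                    location_category = {
                      lc <- names(which(n_loc <= .sd_loc_thresholds))
                      if (is.na(n_loc) || length(lc) == 0L) NA_character_ else lc[1L]
                    },
                    conditions = c(a = cond_a, b_iii = cond_b, c = cond_c))
  if (isTRUE(data_deficient)) {
    return(structure(list(species = species, category = "DD", criteria = "",
                          rationale = rationale),
                     class = "redlist_assessment"))
  }
  category <- "LC"; criteria <- ""
  if (n_cond >= 2L) {
    for (level in c("CR", "EN", "VU")) {
      thr <- .sd_b_thresholds[[level]]
      b1 <- !is.na(eoo_km2) && eoo_km2 > 0 && eoo_km2 < thr[["eoo"]]
      b2 <- !is.na(aoo_km2) && aoo_km2 < thr[["aoo"]]
      if (b1 || b2) {
        conds <- paste0(if (cond_a) "a" else "",
                        if (cond_b) "b(iii)" else "",
                        if (cond_c) "c" else "")
        parts <- c(if (b1) paste0("B1", conds),
                   if (b2) paste0(if (b1) "2" else "B2", conds))
        category <- level
        criteria <- paste(parts, collapse = "+")
        break
      }
    }
  }
  structure(list(species = species, category = category, criteria = criteria,
                 rationale = rationale),
            class = "redlist_assessment")
}

#' @export
print.redlist_assessment <- function(x, ...) {
  cat(sprintf("Red List assessment%s: %s%s\n",
              if (is.na(x$species)) "" else paste0(" (", x$species, ")"),
              x$category,
              if (nzchar(x$criteria)) paste0(" ", x$criteria) else ""))
  r <- x$rationale
  cat(sprintf("  EOO %.1f km^2; AOO %s km^2; locations %s; decline %s; fluctuation %s\n",
              r$eoo_km2,
              if (is.na(r$aoo_km2)) "NA" else format(r$aoo_km2),
              if (is.na(r$n_locations)) "NA" else r$n_locations,
              r$conditions[["b_iii"]], r$conditions[["c"]]))
  invisible(x)
}

#' Write per-species range/Red List JSON
#' @param assessments List of \code{redlist_assessment} objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_assessments_json <- function(assessments, path) {
  out <- lapply(assessments, function(a)
    list(species = a$species,
         eoo_km2 = a$rationale$eoo_km2,
         aoo_km2 = a$rationale$aoo_km2,
         n_locations = a$rationale$n_locations,
         category = a$category, criteria = a$criteria))
  names(out) <- vapply(assessments, function(a) as.character(a$species),
                       character(1L))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
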