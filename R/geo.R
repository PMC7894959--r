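# Mean Earth radius (km), IUGG mean radius R1
EARTH_RADIUS_KM <- 6371.0088

#' Project WGS84 occurrences to planar kilometres
#'
#' Lambert azimuthal equal-area projection on the sphere, centred on the
#' centroid of the input points. Equal-area projection is what range-area
#' measurement requires; centring on the data avoids any UTM-zone
#' configuration. Output coordinates are in km east (x) and north (y) of the
#' centroid.
#'
#' @param points data.frame with `lon`, `lat` in decimal degrees (and
#'   optionally `subpopulation`, which is carried through)
#' @return data.frame with columns `x`, `y` (km) plus any `subpopulation`
#'   column; the projection centre is attached as attribute `center`
#' @export
project_points <- function(points) {
  if (nrow(points) < 1) {
    stop_endemica("project_points needs at least one point",
                  "endemica_validation_error")
  }
  lam0 <- mean(points$lon) * pi / 180
  phi0 <- mean(points$lat) * pi / 180
  lam <- points$lon * pi / 180
  phi <- points$lat * pi / 180
  dl <- lam - lam0
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dl)
  if (any(denom < 1e-9)) {
    stop_endemica("points span an antipodal extent; projection undefined",
                  "endemica_validation_error")
  }
  k <- sqrt(2 / denom)
  out <- data.frame(
    x = EARTH_RADIUS_KM * k * cos(phi) * sin(dl),
    y = EARTH_RADIUS_KM * k *
      (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dl)))
  if (!is.null(points$subpopulation)) out$subpopulation <- points$subpopulation
  attr(out, "center") <- c(lon = mean(points$lon), lat = mean(points$lat))
  out
}

# shoelace area of a polygon given vertex coordinates in order
shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

#' Extent of occurrence by minimum convex polygon
#'
#' Area of the convex hull of projected occurrence points (km^2). With fewer
#' than three distinct points, or collinear points, the raw area is 0 and the
#' result is flagged degenerate. Following IUCN guidance the reported EOO is
#' never allowed below the AOO: when `aoo_km2` is supplied and exceeds the
#' raw hull area, the adjusted value is raised to the AOO.
#'
#' @param xy data.frame of projected points with columns `x`, `y` (km)
#' @param aoo_km2 optional area of occupancy used for the IUCN adjustment
#' @return list with `eoo_km2` (raw), `eoo_km2_adjusted`, `degenerate` flag
#'   and `hull` (data.frame of hull vertices in counter-clockwise order)
#' @export
eoo <- function(xy, aoo_km2 = NULL) {
  if (nrow(xy) < 1) {
    stop_endemica("eoo needs at least one point", "endemica_validation_error")
  }
  pts <- unique(xy[, c("x", "y")])
  hull_idx <- grDevices::chull(pts$x, pts$y)
  hull <- pts[hull_idx, , drop = FALSE]
  area <- shoelace_area(hull$x, hull$y)
  degenerate <- nrow(pts) < 3 || area <= 0
  if (degenerate) area <- 0
  adjusted <- area
  if (!is.null(aoo_km2) && adjusted < aoo_km2) adjusted <- aoo_km2
  list(eoo_km2 = area, eoo_km2_adjusted = adjusted,
       degenerate = degenerate, hull = hull)
}

#' Area of occupancy by occupied grid cells
#'
#' Counts the distinct grid cells (half-open squares
#' `[origin + k*cell, origin + (k+1)*cell)`) containing at least one point
#' and multiplies by the cell area. The default 1 km cell follows the IUCN
#' standard grid; shifting `origin` emulates alternative reference grids
#' (cell counts change by at most a boundary effect, so the origin used is
#' logged by the pipeline).
#'
#' @param xy data.frame of projected points with columns `x`, `y` (km)
#' @param cell_km grid cell edge length in km (default 1)
#' @param origin numeric length-2 grid anchor in km (default `c(0, 0)`)
#' @return list with `aoo_km2`, `n_cells`, and `cells` (data.frame of cell
#'   indices, plus per-point cell assignment if `subpopulation` is present)
#' @export
aoo <- function(xy, cell_km = 1, origin = c(0, 0)) {
  if (cell_km <= 0) {
    stop_endemica("cell_km must be positive", "endemica_validation_error")
  }
  if (nrow(xy) < 1) {
    stop_endemica("aoo needs at least one point", "endemica_validation_error")
  }
  cx <- floor((xy$x - origin[1]) / cell_km)
  cy <- floor((xy$y - origin[2]) / cell_km)
  cells <- unique(data.frame(cx = cx, cy = cy))
  out <- list(aoo_km2 = nrow(cells) * cell_km^2, n_cells = nrow(cells),
              cells = cells)
  if (!is.null(xy$subpopulation)) {
    key <- paste(cx, cy)
    out$cells_by_subpop <- tapply(key, xy$subpopulation,
                                  function(k) length(unique(k)))
  }
  out
}

#' Plant density
#'
#' Mature individuals divided by the local extent of occurrence, in plants
#' per m^2. The value is returned at full precision; [format_density()]
#' reproduces the display rounding used in monitoring tables (one
#' significant figure below 0.1, otherwise one or two decimals).
#'
#' @param n_mature count of mature individuals
#' @param local_eoo_m2 local extent of occurrence in m^2
#' @return plants per m^2
#' @export
plant_density <- function(n_mature, local_eoo_m2) {
  if (any(local_eoo_m2 <= 0)) {
    stop_endemica("local_eoo_m2 must be positive", "endemica_validation_error")
  }
  if (any(n_mature < 0)) {
    stop_endemica("n_mature must be non-negative", "endemica_validation_error")
  }
  n_mature / local_eoo_m2
}

#' Display rounding for plant density
#'
#' @param d density value (plants per m^2)
#' @return numeric rounded the way monitoring tables print density: one
#'   significant figure
#' @export
format_density <- function(d) {
  signif(d, 1)
}
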