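# Equal-area hexagonal grids (planar and spherical) plus discrete-global-grid
# cell arithmetic. The spherical grid tiles the Lambert cylindrical equal-area
# projection of a latitude band with regular hexagons: the projection is
# area-preserving, so projected hexagon area equals true area on the sphere.

#' Authalic Earth radius in km
#'
#' Radius of the sphere with the same surface area as the Earth ellipsoid.
#' All great-circle and equal-area computations in the package use it.
#' @export
EARTH_RADIUS_KM <- 6371.007

hex_side_for_area <- function(area) sqrt(2 * area / (3 * sqrt(3)))

new_grid <- function(cell_id, centroids, polygons, area_km2, crs_kind,
                     target_area, side, metadata = list()) {
  stopifnot(!anyDuplicated(cell_id))
  structure(
    list(cell_id = as.character(cell_id), centroids = centroids,
         polygons = polygons, area_km2 = area_km2, crs_kind = crs_kind,
         target_area = target_area, side = side, metadata = metadata),
    class = "paranet_grid")
}

#' @export
print.paranet_grid <- function(x, ...) {
  cat(sprintf("<paranet_grid> %d cells, crs = %s\n", length(x$cell_id), x$crs_kind))
  cat(sprintf("  target cell area: %.6g km2 (hex side %.6g)\n", x$target_area, x$side))
  cat(sprintf("  provenance: %s\n", x$metadata$provenance %||% "unknown"))
  invisible(x)
}

#' @export
length.paranet_grid <- function(x) length(x$cell_id)

`%||%` <- function(a, b) if (is.null(a)) b else a

subset_grid <- function(grid, keep) {
  new_grid(grid$cell_id[keep], grid$centroids[keep, , drop = FALSE],
           grid$polygons[keep], grid$area_km2[keep], grid$crs_kind,
           grid$target_area, grid$side, grid$metadata)
}

#' Build a planar grid of equal-area regular hexagons
#'
#' Tiles a rectangle (km coordinates) with pointy-top regular hexagons of
#' exactly \code{target_area} each, in offset rows. The lattice extends one
#' row/column beyond every edge so that the full rectangle is covered;
#' boundary cells may overhang the extent. Cell ids are deterministic,
#' row-major \code{"r<row>c<col>"} lattice indices.
#'
#' @param extent numeric length 4, \code{c(xmin, xmax, ymin, ymax)} in km.
#' @param target_area hexagon area in km^2.
#' @return a \code{paranet_grid} with \code{crs_kind = "planar_km"}.
#' @examples
#' g <- build_planar_hex_grid(c(0, 30, 0, 30), 10)
#' range(g$area_km2)
#' @export
build_planar_hex_grid <- function(extent, target_area) {
  if (length(extent) != 4L || !is.numeric(extent)) {
    stop("`extent` must be numeric c(xmin, xmax, ymin, ymax)")
  }
  if (extent[2] <= extent[1] || extent[4] <= extent[3]) {
    stop("`extent` must have positive width and height")
  }
  if (!is.numeric(target_area) || length(target_area) != 1L || target_area <= 0) {
    stop("`target_area` must be a single positive number")
  }
  s <- hex_side_for_area(target_area)
  colsp <- sqrt(3) * s
  rowsp <- 1.5 * s
  nr <- ceiling((extent[4] - extent[3]) / rowsp) + 1L
  nc <- ceiling((extent[2] - extent[1]) / colsp) + 1L
  rows <- -1L:nr
  cols <- -1L:nc
  ids <- character(0); cx <- numeric(0); cy <- numeric(0)
  for (r in rows) {
    y <- extent[3] + r * rowsp
    xoff <- if (r %% 2L == 0L) 0 else colsp / 2
    x <- extent[1] + cols * colsp + xoff
    ids <- c(ids, sprintf("r%dc%d", r, cols))
    cx <- c(cx, x)
    cy <- c(cy, rep(y, length(cols)))
  }
  polys <- lapply(seq_along(cx), function(i) hex_vertices(cx[i], cy[i], s))
  # drop lattice cells that do not actually share area with the extent
  rect <- cbind(extent[c(1, 2, 2, 1)], extent[c(3, 3, 4, 4)])
  keep <- vapply(polys, function(p) {
    intersection_area_convex(p, rect) > 1e-12 * target_area
  }, logical(1))
  new_grid(ids[keep], cbind(cx, cy)[keep, , drop = FALSE], polys[keep],
           rep(target_area, sum(keep)),
           "planar_km", target_area, s,
           metadata = list(provenance = "generated_planar", extent = extent))
}

#' Build an equal-area hexagonal grid over a latitude band of the sphere
#'
#' The band is projected with the Lambert cylindrical equal-area projection
#' (x = R*lon, y = R*sin(lat)), tiled with regular hexagons, and vertices are
#' mapped back to lon/lat. Because the projection preserves area, every cell
#' encloses its projected-plane area on the sphere; hexagon shapes distort at
#' high latitude but areas do not. The hex side is rescaled slightly so an
#' integer number of columns closes the full longitude circle without gap or
#' overlap, and rows are centred on the band midpoint.
#'
#' @param target_area requested cell area in km^2.
#' @param lat_band either a positive scalar L (band from -L to +L degrees)
#'   or \code{c(lat1, lat2)}; must lie within +/-85 degrees.
#' @param earth_radius sphere radius in km.
#' @return a \code{paranet_grid} with \code{crs_kind = "lonlat_sphere"};
#'   polygon coordinates are lon/lat degrees (per-ring longitudes are kept
#'   continuous across the antimeridian rather than wrapped).
#' @export
build_sphere_hex_grid <- function(target_area, lat_band,
                                  earth_radius = EARTH_RADIUS_KM) {
  R <- earth_radius
  if (!is.numeric(target_area) || target_area <= 0 ||
      target_area >= 4 * pi * R^2) {
    stop("`target_area` must be in (0, Earth surface area)")
  }
  if (length(lat_band) == 1L) {
    if (lat_band <= 0) stop("degenerate latitude band")
    lat_band <- c(-lat_band, lat_band)
  }
  lat_band <- sort(lat_band)
  if (any(abs(lat_band) > 85)) {
    stop("unsupported domain: latitude band must be within +/-85 degrees")
  }
  if (diff(lat_band) <= 0) stop("degenerate latitude band")
  circ <- 2 * pi * R
  s0 <- hex_side_for_area(target_area)
  ncols <- max(1L, as.integer(round(circ / (sqrt(3) * s0))))
  s <- circ / (ncols * sqrt(3))
  colsp <- sqrt(3) * s
  rowsp <- 1.5 * s
  area <- 3 * sqrt(3) / 2 * s^2
  y1 <- R * sin(lat_band[1] * pi / 180)
  y2 <- R * sin(lat_band[2] * pi / 180)
  nrows <- max(1L, as.integer(round((y2 - y1) / rowsp)))
  ymid <- (y1 + y2) / 2
  ys <- ymid + (seq_len(nrows) - (nrows + 1) / 2) * rowsp
  ys <- ys[abs(ys) + s < R]  # guard: hexagon tips must stay off the poles
  if (length(ys) == 0L) stop("latitude band too narrow for this cell size")
  ids <- character(0); polys <- list(); cents <- NULL
  to_lonlat <- function(xy) {
    cbind(xy[, 1] / R * 180 / pi, asin(pmax(-1, pmin(1, xy[, 2] / R))) * 180 / pi)
  }
  for (r in seq_along(ys)) {
    xoff <- if (r %% 2L == 0L) colsp / 2 else 0
    xs <- -circ / 2 + (seq_len(ncols) - 1L) * colsp + xoff
    for (ci in seq_len(ncols)) {
      hx <- hex_vertices(xs[ci], ys[r], s)
      polys[[length(polys) + 1L]] <- to_lonlat(hx)
      lon_c <- xs[ci] / R * 180 / pi
      if (lon_c >= 180) lon_c <- lon_c - 360
      cents <- rbind(cents, c(lon_c, asin(ys[r] / R) * 180 / pi))
    }
    ids <- c(ids, sprintf("b%di%d", r, seq_len(ncols)))
  }
  new_grid(ids, cents, polys, rep(area, length(ids)), "lonlat_sphere",
           target_area, s,
           metadata = list(provenance = "generated_sphere",
                           lat_band = lat_band, earth_radius = R,
                           ncols = ncols))
}

#' Number of cells of an aperture-a hexagonal DGGS at a given resolution
#'
#' An icosahedral hexagonal discrete global grid of aperture \eqn{a} has
#' \eqn{10 a^r + 2} cells at resolution \eqn{r} (including the 12 pentagons).
#'
#' @param aperture 3, 4 or 7.
#' @param resolution non-negative integer.
#' @return cell count.
#' @examples
#' dggs_cell_count(3, 7)  # 21872
#' @export
dggs_cell_count <- function(aperture, resolution) {
  if (!aperture %in% c(3, 4, 7)) stop("unsupported aperture: must be 3, 4 or 7")
  if (resolution < 0 || resolution != round(resolution)) {
    stop("`resolution` must be a non-negative integer")
  }
  10 * aperture^resolution + 2
}

#' Mean DGGS cell area on the authalic sphere
#'
#' Earth surface area divided by the cell count; at aperture 3, resolution 7
#' this is about 23,320 km^2, the cell size used for global gridding here.
#'
#' @inheritParams dggs_cell_count
#' @param earth_radius sphere radius in km.
#' @return mean cell area in km^2.
#' @export
dggs_mean_cell_area <- function(aperture, resolution,
                                earth_radius = EARTH_RADIUS_KM) {
  if (!is.numeric(earth_radius) || earth_radius <= 0) {
    stop("`earth_radius` must be positive")
  }
  4 * pi * earth_radius^2 / dggs_cell_count(aperture, resolution)
}

# Projected (km-plane) polygons of a grid: identity for planar grids,
# Lambert cylindrical equal-area for sphere grids.
grid_proj_polygons <- function(grid) {
  if (grid$crs_kind == "planar_km") return(grid$polygons)
  R <- grid$metadata$earth_radius %||% EARTH_RADIUS_KM
  lapply(grid$polygons, function(p) lonlat_to_cea(p, R))
}

lonlat_to_cea <- function(lonlat, R = EARTH_RADIUS_KM) {
  cbind(lonlat[, 1] * pi / 180 * R, R * sin(lonlat[, 2] * pi / 180))
}

grid_proj_centroids <- function(grid) {
  if (grid$crs_kind == "planar_km") return(grid$centroids)
  R <- grid$metadata$earth_radius %||% EARTH_RADIUS_KM
  lonlat_to_cea(grid$centroids, R)
}

#' Keep only grid cells intersecting land
#'
#' Retains cells whose polygon shares positive area with at least one land
#' polygon; ids and order are preserved. For sphere grids the test is done in
#' the equal-area projection plane, so land must be lon/lat polygons.
#'
#' @param grid a \code{paranet_grid}.
#' @param land a single polygon matrix or a list of polygon matrices in the
#'   grid's coordinate system.
#' @return the clipped \code{paranet_grid}.
#' @export
clip_grid_to_land <- function(grid, land) {
  if (is.matrix(land)) land <- list(land)
  if (length(land) == 0L) {
    warning("empty land set: returning empty grid")
    return(subset_grid(grid, logical(length(grid$cell_id))))
  }
  land_proj <- if (grid$crs_kind == "lonlat_sphere") {
    R <- grid$metadata$earth_radius %||% EARTH_RADIUS_KM
    lapply(land, function(p) lonlat_to_cea(p, R))
  } else land
  polys <- grid_proj_polygons(grid)
  land_bb <- lapply(land_proj, polygon_bbox)
  keep <- vapply(polys, function(cell) {
    cb <- polygon_bbox(cell)
    tol <- 1e-12 * polygon_area(cell)
    for (j in seq_along(land_proj)) {
      if (!bbox_overlap(cb, land_bb[[j]])) next
      if (intersection_area_convex(land_proj[[j]], cell) > tol) return(TRUE)
    }
    FALSE
  }, logical(1))
  g <- subset_grid(grid, keep)
  g$metadata$provenance <- paste0(grid$metadata$provenance %||% "unknown",
                                  "+land_clipped")
  g
}

#' Assign points to grid cells
#'
#' Uses nearest-centroid assignment, which for a regular hexagonal lattice is
#' exactly the hexagonal tiling (the tiling is the Voronoi diagram of its
#' centres); boundary ties are broken towards the lowest cell index, giving a
#' unique half-open assignment. Points are x/y km for planar grids, lon/lat
#' for sphere grids (assigned in the equal-area plane).
#'
#' @param grid a \code{paranet_grid}.
#' @param points n x 2 matrix.
#' @return integer vector of cell indices (NA when a point is farther than
#'   one hexagon diameter from every centroid).
#' @export
assign_cells <- function(grid, points) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 2)
  pts <- if (grid$crs_kind == "lonlat_sphere") {
    lonlat_to_cea(points, grid$metadata$earth_radius %||% EARTH_RADIUS_KM)
  } else points
  cents <- grid_proj_centroids(grid)
  circ <- if (grid$crs_kind == "lonlat_sphere") {
    2 * pi * (grid$metadata$earth_radius %||% EARTH_RADIUS_KM)
  } else Inf
  out <- integer(nrow(pts))
  lim <- (2 * grid$side)^2
  for (i in seq_len(nrow(pts))) {
    dx <- abs(cents[, 1] - pts[i, 1])
    if (is.finite(circ)) dx <- pmin(dx, circ - dx)  # antimeridian seam
    d2 <- dx^2 + (cents[, 2] - pts[i, 2])^2
    j <- which.min(d2)
    out[i] <- if (d2[j] <= lim) j else NA_integer_
  }
  out
}

#' Write a grid as a GeoJSON FeatureCollection
#'
#' Each cell becomes a Polygon feature with properties \code{cell_id} and
#' \code{area_km2}; grid-level fields (\code{crs_kind}, target area, hex
#' side) are stored as foreign members of the collection. Planar grids store
#' km coordinates in the GeoJSON coordinate slots.
#'
#' @param grid a \code{paranet_grid}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
save_grid <- function(grid, path) {
  feats <- lapply(seq_along(grid$cell_id), function(i) {
    ring <- grid$polygons[[i]]
    ring <- rbind(ring, ring[1, , drop = FALSE])  # close the ring
    list(type = "Feature",
         properties = list(cell_id = grid$cell_id[i],
                           area_km2 = grid$area_km2[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(lapply(
                           seq_len(nrow(ring)),
                           function(k) unname(ring[k, ]))))))
  })
  fc <- list(type = "FeatureCollection",
             crs_kind = grid$crs_kind,
             target_area_km2 = grid$target_area,
             hex_side = grid$side,
             provenance = grid$metadata$provenance %||% "unknown",
             features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a grid from a GeoJSON FeatureCollection
#'
#' Accepts files written by \code{\link{save_grid}} or third-party hexagon
#' layers, provided every polygon feature carries a \code{cell_id} property.
#' Cell areas are recomputed from the geometry unless an \code{area_km2}
#' property is present.
#'
#' @param path GeoJSON file.
#' @param crs_kind coordinate interpretation, used when the file does not
#'   record one: \code{"planar_km"} or \code{"lonlat_sphere"}.
#' @return a \code{paranet_grid}.
#' @export
load_grid <- function(path, crs_kind = NULL) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(fc$features)) stop("not a GeoJSON FeatureCollection: ", path)
  crs <- fc$crs_kind %||% crs_kind %||% "planar_km"
  n <- length(fc$features)
  ids <- character(n); polys <- vector("list", n); areas <- numeric(n)
  for (i in seq_len(n)) {
    f <- fc$features[[i]]
    id <- f$properties$cell_id
    if (is.null(id)) stop("format error: feature ", i, " has no cell_id property")
    ids[i] <- as.character(id)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    if (nrow(ring) > 1L && all(ring[1, ] == ring[nrow(ring), ])) {
      ring <- ring[-nrow(ring), , drop = FALSE]  # store rings open
    }
    polys[[i]] <- ring
    areas[i] <- if (!is.null(f$properties$area_km2)) {
      as.numeric(f$properties$area_km2)
    } else if (crs == "planar_km") {
      polygon_area(ring)
    } else {
      polygon_area(lonlat_to_cea(ring))
    }
  }
  if (anyDuplicated(ids)) {
    stop("format error: duplicate cell_id in ", path)
  }
  cents <- t(vapply(polys, polygon_centroid, numeric(2)))
  side <- fc$hex_side %||% sqrt(2 * stats::median(areas) / (3 * sqrt(3)))
  new_grid(ids, cents, polys, areas, crs,
           fc$target_area_km2 %||% stats::median(areas), side,
           metadata = list(provenance = "loaded", path = path))
}
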