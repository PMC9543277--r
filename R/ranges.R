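# Species range polygons and their intersection with the grid.
# Ranges use the conventional range-map integer attribute codes where present:
# presence 1 = extant, origin 1 = native, seasonal 1 = resident, 2 = breeding.

#' Normalise species names for joining ranges and interactions
#'
#' Lowercases, trims and collapses internal whitespace, then applies an
#' optional synonym map. This is the single join key used across range files
#' and interaction tables; the synonym table lets users harmonise the two
#' sources against one checklist.
#'
#' @param x character vector of species names.
#' @param synonyms optional named character vector mapping (normalised)
#'   variant names to canonical names.
#' @return character vector of canonical names.
#' @export
normalize_species <- function(x, synonyms = NULL) {
  out <- tolower(trimws(x))
  out <- gsub("\\s+", " ", out)
  if (!is.null(synonyms)) {
    names(synonyms) <- normalize_species(names(synonyms))
    hit <- match(out, names(synonyms))
    out[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  }
  out
}

new_ranges <- function(entries, crs_kind) {
  structure(entries, crs_kind = crs_kind, class = "paranet_ranges")
}

#' @export
print.paranet_ranges <- function(x, ...) {
  cat(sprintf("<paranet_ranges> %d species, crs = %s\n",
              length(x), attr(x, "crs_kind")))
  invisible(x)
}

#' Read species range polygons from a GeoJSON layer
#'
#' One feature per range part; multi-feature species are merged into a single
#' multi-part \code{SpeciesRange}. Under the \code{"native_breeding"} policy
#' only parts coded extant (presence = 1), native (origin = 1) and resident
#' or breeding (seasonal in 1:2) are kept, mirroring how native breeding
#' range maps are defined; when a file carries no such attribute fields all
#' parts are kept and a warning is issued. Species losing every part to the
#' filter are dropped with a named warning.
#'
#' @param path GeoJSON file of Polygon/MultiPolygon features.
#' @param attribute_filter \code{"native_breeding"} or \code{"all"}.
#' @param species_field name of the property holding the species name.
#' @param synonyms optional synonym map passed to
#'   \code{\link{normalize_species}}.
#' @param crs_kind coordinate interpretation when the file records none.
#' @return a \code{paranet_ranges} collection (named list; each element has
#'   \code{species_id}, \code{polygons}, \code{attributes}).
#' @export
read_ranges <- function(path, attribute_filter = c("native_breeding", "all"),
                        species_field = "species", synonyms = NULL,
                        crs_kind = NULL) {
  attribute_filter <- match.arg(attribute_filter)
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(fc$features)) stop("not a GeoJSON FeatureCollection: ", path)
  crs <- fc$crs_kind %||% crs_kind %||% "planar_km"
  if (length(fc$features) == 0L) {
    warning("empty range file: ", path)
    return(new_ranges(list(), crs))
  }
  entries <- list()
  dropped <- character(0)
  saw_attrs <- FALSE
  for (i in seq_along(fc$features)) {
    f <- fc$features[[i]]
    sp <- f$properties[[species_field]]
    if (is.null(sp)) {
      stop("format error: feature ", i, " has no '", species_field, "' field")
    }
    sp <- normalize_species(sp, synonyms)
    attrs <- list(presence = f$properties$presence,
                  origin = f$properties$origin,
                  seasonal = f$properties$seasonal)
    has_attrs <- !all(vapply(attrs, is.null, logical(1)))
    saw_attrs <- saw_attrs || has_attrs
    if (attribute_filter == "native_breeding" && has_attrs) {
      ok <- (is.null(attrs$presence) || attrs$presence == 1) &&
        (is.null(attrs$origin) || attrs$origin == 1) &&
        (is.null(attrs$seasonal) || attrs$seasonal %in% c(1, 2))
      if (!ok) { dropped <- c(dropped, sp); next }
    }
    polys <- geojson_polygons(f$geometry)
    if (is.null(entries[[sp]])) {
      entries[[sp]] <- list(species_id = sp, polygons = polys,
                            attributes = attrs)
    } else {
      entries[[sp]]$polygons <- c(entries[[sp]]$polygons, polys)
    }
  }
  if (attribute_filter == "native_breeding" && !saw_attrs) {
    warning("no presence/origin/seasonal fields in ", path,
            ": keeping all range parts")
  }
  lost <- setdiff(unique(dropped), names(entries))
  if (length(lost)) {
    warning("species with zero range parts after filtering, dropped: ",
            paste(lost, collapse = ", "))
  }
  new_ranges(entries, crs)
}

# Extract a list of open polygon rings (outer rings only) from a GeoJSON
# geometry node.
geojson_polygons <- function(geom) {
  ring_mat <- function(ring) {
    m <- do.call(rbind, lapply(ring, unlist))
    if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  }
  if (geom$type == "Polygon") {
    list(ring_mat(geom$coordinates[[1]]))
  } else if (geom$type == "MultiPolygon") {
    lapply(geom$coordinates, function(p) ring_mat(p[[1]]))
  } else {
    stop("unsupported geometry type: ", geom$type)
  }
}

#' Write a range collection as GeoJSON
#'
#' @param ranges a \code{paranet_ranges}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
save_ranges <- function(ranges, path) {
  feats <- list()
  for (sp in names(ranges)) {
    e <- ranges[[sp]]
    for (poly in e$polygons) {
      ring <- rbind(poly, poly[1, , drop = FALSE])
      props <- list(species = e$species_id)
      for (k in c("presence", "origin", "seasonal")) {
        if (!is.null(e$attributes[[k]])) props[[k]] <- e$attributes[[k]]
      }
      feats[[length(feats) + 1L]] <- list(
        type = "Feature", properties = props,
        geometry = list(type = "Polygon",
                        coordinates = list(unname(lapply(
                          seq_len(nrow(ring)), function(k) unname(ring[k, ]))))))
    }
  }
  fc <- list(type = "FeatureCollection",
             crs_kind = attr(ranges, "crs_kind"), features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Presence-absence of species across grid cells
#'
#' A species is scored present in a cell when its range polygons intersect
#' the cell polygon with positive area (the inclusive reading that yields
#' "potential" co-occurrence); tangential zero-area contact counts as absent.
#' With \code{min_fraction > 0} the summed intersection area must instead
#' reach that fraction of the cell area. Sphere-grid intersections are
#' evaluated in the Lambert cylindrical equal-area plane, where areas equal
#' their spherical values.
#'
#' @param grid a \code{paranet_grid}.
#' @param ranges a \code{paranet_ranges} with matching \code{crs_kind}.
#' @param min_fraction minimum intersected fraction of the cell area
#'   (0 = any positive overlap).
#' @return a logical cell x species matrix of class \code{presence_matrix}
#'   with cell ids as row names and species ids as column names.
#' @export
presence_absence <- function(grid, ranges, min_fraction = 0) {
  if (!identical(attr(ranges, "crs_kind"), grid$crs_kind)) {
    stop("crs mismatch: grid is ", grid$crs_kind, ", ranges are ",
         attr(ranges, "crs_kind"))
  }
  if (min_fraction < 0 || min_fraction >= 1) {
    stop("`min_fraction` must be in [0, 1)")
  }
  cells <- grid_proj_polygons(grid)
  cell_bb <- lapply(cells, polygon_bbox)
  R <- grid$metadata$earth_radius %||% EARTH_RADIUS_KM
  n <- length(cells)
  m <- matrix(FALSE, n, length(ranges),
              dimnames = list(grid$cell_id, names(ranges)))
  for (j in seq_along(ranges)) {
    for (poly in ranges[[j]]$polygons) {
      if (grid$crs_kind == "lonlat_sphere") poly <- lonlat_to_cea(poly, R)
      pb <- polygon_bbox(poly)
      acc <- numeric(n)
      for (i in seq_len(n)) {
        if (m[i, j] && min_fraction == 0) next
        if (!bbox_overlap(pb, cell_bb[[i]])) next
        a <- intersection_area_convex(poly, cells[[i]])
        if (min_fraction == 0) {
          if (a > 1e-12 * grid$area_km2[i]) m[i, j] <- TRUE
        } else {
          acc[i] <- acc[i] + a
        }
      }
      if (min_fraction > 0) {
        m[, j] <- m[, j] | (acc >= min_fraction * grid$area_km2)
      }
    }
  }
  structure(m, class = c("presence_matrix", class(m)))
}

#' Per-cell species richness
#'
#' Counts, in every grid cell, how many species of a subset are present.
#'
#' @param presence a \code{presence_matrix}.
#' @param species_subset character vector of species ids (default: all).
#' @return named integer vector, one count per cell.
#' @export
richness <- function(presence, species_subset = NULL) {
  if (is.null(species_subset)) species_subset <- colnames(presence)
  unknown <- setdiff(species_subset, colnames(presence))
  if (length(unknown)) {
    stop("unknown species in subset: ", paste(unknown, collapse = ", "))
  }
  if (length(species_subset) == 0L) {
    return(stats::setNames(integer(nrow(presence)), rownames(presence)))
  }
  rowSums(presence[, species_subset, drop = FALSE])
}

#' Write a presence-absence matrix as CSV
#'
#' @param presence a \code{presence_matrix}.
#' @param path output file.
#' @param format \code{"long"} (rows cell_id, species_id for each presence)
#'   or \code{"wide"} (cells x species 0/1 matrix).
#' @return \code{path}, invisibly.
#' @export
write_presence_csv <- function(presence, path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (format == "long") {
    idx <- which(presence, arr.ind = TRUE)
    df <- data.frame(cell_id = rownames(presence)[idx[, 1]],
                     species_id = colnames(presence)[idx[, 2]])
    df <- df[order(df$cell_id, df$species_id), ]
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    df <- data.frame(cell_id = rownames(presence),
                     as.data.frame(presence * 1L, check.names = FALSE))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
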