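# Independent oracles used across tests: these deliberately reimplement
# primitives by different algorithms than the package uses.

# Winding-number point-in-polygon (package uses even-odd ray casting).
oracle_point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  wn <- 0
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    cross <- (b[1] - a[1]) * (pt[2] - a[2]) - (pt[1] - a[1]) * (b[2] - a[2])
    if (a[2] <= pt[2]) {
      if (b[2] > pt[2] && cross > 0) wn <- wn + 1
    } else {
      if (b[2] <= pt[2] && cross < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# Normal-equations least squares (package uses QR).
oracle_normal_eq_beta <- function(y, X) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# Hand-rolled Moran statistic (row-standardised weights matrix).
oracle_moran <- function(x, Wm) {
  z <- x - mean(x)
  sum(z * (Wm %*% z)) / sum(z^2) * length(x) / sum(Wm)
}

# Random bipartite parasite-host network with at least one edge.
random_network <- function(max_p = 6, max_h = 10) {
  p <- sample.int(max_p, 1)
  h <- sample.int(max_h, 1)
  all_edges <- expand.grid(parasite = paste0("p", seq_len(p)),
                           host = paste0("h", seq_len(h)),
                           stringsAsFactors = FALSE)
  m <- sample.int(nrow(all_edges), 1)
  edges <- all_edges[sample.int(nrow(all_edges), m), , drop = FALSE]
  interaction_table(edges$parasite, edges$host)
}

# Presence matrix where every listed species is present in every cell.
presence_everywhere <- function(cell_ids, species) {
  m <- matrix(TRUE, length(cell_ids), length(species),
              dimnames = list(cell_ids, species))
  structure(m, class = c("presence_matrix", class(m)))
}

# Presence matrix from a named list cell_id -> character vector of species.
presence_from_list <- function(cells, all_species = NULL) {
  sp <- all_species
  if (is.null(sp)) sp <- sort(unique(unlist(cells)))
  m <- matrix(FALSE, length(cells), length(sp),
              dimnames = list(names(cells), sp))
  for (cid in names(cells)) m[cid, cells[[cid]]] <- TRUE
  structure(m, class = c("presence_matrix", class(m)))
}

# A ~20x20 planar hex lattice (>= 400 cells) and its 6-neighbour
# distance-band weights.
lattice_20x20 <- function(target_area = 900) {
  s <- sqrt(2 * target_area / (3 * sqrt(3)))
  g <- build_planar_hex_grid(c(0, 19.5 * sqrt(3) * s, 0, 19.5 * 1.5 * s),
                             target_area)
  W <- distance_band_weights(g$centroids,
                             threshold_km = 1.4 * sqrt(3) * s,
                             ids = g$cell_id)
  list(grid = g, W = W, side = s)
}

# Build a cell_network through the package's own path: all species of the
# edge list present in a single cell.
new_network_from_edges <- function(parasite, host, cell_id = "cell") {
  tb <- interaction_table(parasite, host)
  pm <- presence_everywhere(cell_id, union(tb$parasites, tb$hosts))
  cell_network(cell_id, pm, tb)
}

global_network_of <- function(tb, cell_id = "cell") {
  pm <- presence_everywhere(cell_id, union(tb$parasites, tb$hosts))
  cell_network(cell_id, pm, tb)
}

# Deterministic 6-parasite, 80-host network with 241 distinct interactions:
# hosts are dealt to parasites round-robin in three passes (80 + 80 + 81st
# truncated), covering every node.
max_complexity_edges <- function(prefix = "") {
  pa <- character(0); ho <- character(0)
  k <- 0L
  for (pass in 0:3) {
    for (j in seq_len(80)) {
      if (k == 241L) break
      pa <- c(pa, sprintf("%sp%d", prefix, (j + pass) %% 6 + 1))
      ho <- c(ho, sprintf("%sh%02d", prefix, j))
      k <- k + 1L
    }
  }
  data.frame(parasite = pa, host = ho, stringsAsFactors = FALSE)
}

max_complexity_network <- function() {
  e <- max_complexity_edges()
  new_network_from_edges(e$parasite, e$host)
}

# Three-cell fixture whose networks are (1 parasite, 1 host, 1 edge),
# (2, 2, 4) and (6, 80, 241); returns the complexity table with the three
# cell ids in attr(, "worked_cells").
worked_fixture_complexity <- function() {
  g <- build_planar_hex_grid(c(0, 20, 0, 20), 30)
  e_big <- max_complexity_edges(prefix = "big_")
  pa <- c("a_p1", rep(c("b_p1", "b_p2"), each = 2), e_big$parasite)
  ho <- c("a_h1", rep(c("b_h1", "b_h2"), 2), e_big$host)
  tb <- interaction_table(pa, ho)
  ids <- g$cell_id[1:3]
  cells <- setNames(rep(list(character(0)), length(g$cell_id)), g$cell_id)
  cells[[ids[1]]] <- c("a_p1", "a_h1")
  cells[[ids[2]]] <- c("b_p1", "b_p2", "b_h1", "b_h2")
  cells[[ids[3]]] <- union(e_big$parasite, e_big$host)
  pm <- presence_from_list(cells, all_species = union(tb$parasites, tb$hosts))
  ct <- complexity_table(g, pm, tb)
  attr(ct, "worked_cells") <- ids
  ct
}

# Minimal GeoJSON writers for range fixtures (independent of save_ranges).
ring_coords <- function(poly) {
  ring <- rbind(poly, poly[1, , drop = FALSE])
  lapply(seq_len(nrow(ring)), function(k) unname(ring[k, ]))
}

write_range_geojson <- function(path, features, crs_kind = "planar_km") {
  feats <- lapply(features, function(f) {
    list(type = "Feature",
         properties = f$properties,
         geometry = list(type = "Polygon",
                         coordinates = list(ring_coords(f$poly))))
  })
  writeLines(jsonlite::toJSON(
    list(type = "FeatureCollection", crs_kind = crs_kind, features = feats),
    auto_unbox = TRUE, digits = NA), path)
  path
}

square_poly <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}
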