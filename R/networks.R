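# Per-cell "potential networks": the bipartite network implied, in each grid
# cell, by globally documented parasite-host interactions between species
# co-present in that cell.

#' Assemble the potential network of one grid cell
#'
#' The cell's network keeps exactly those global interactions whose parasite
#' and host are both present in the cell. Nodes are derived from the retained
#' edges only: a host present without any co-present documented parasite is
#' not part of the network.
#'
#' @param cell_id a cell id present in \code{presence}.
#' @param presence a \code{presence_matrix}.
#' @param table an \code{interaction_table}.
#' @return a \code{cell_network}: list with \code{cell_id}, \code{edges},
#'   \code{parasite_nodes}, \code{host_nodes}, \code{n_interactions},
#'   \code{n_species} (dual-role species counted once).
#' @export
cell_network <- function(cell_id, presence, table) {
  if (!cell_id %in% rownames(presence)) stop("unknown cell: ", cell_id)
  here <- colnames(presence)[presence[cell_id, ]]
  e <- table$edges
  keep <- e$parasite %in% here & e$host %in% here
  new_cell_network(cell_id, e[keep, , drop = FALSE])
}

new_cell_network <- function(cell_id, edges) {
  rownames(edges) <- NULL
  pn <- sort(unique(edges$parasite))
  hn <- sort(unique(edges$host))
  structure(list(cell_id = cell_id, edges = edges,
                 parasite_nodes = pn, host_nodes = hn,
                 n_interactions = nrow(edges),
                 n_species = length(union(pn, hn))),
            class = "cell_network")
}

#' @export
print.cell_network <- function(x, ...) {
  cat(sprintf("<cell_network %s> %d interactions, %d parasites, %d hosts (%s)\n",
              x$cell_id, x$n_interactions, length(x$parasite_nodes),
              length(x$host_nodes), classify_topology(x)))
  invisible(x)
}

#' Linkage density of a potential network
#'
#' The network-complexity statistic: number of interactions divided by the
#' total number of species in the network. Its minimum over non-empty
#' networks is 0.5, attained by a single parasite-host pair with one
#' interaction; the complete two-parasite, two-host network with four
#' interactions scores 1.0. Reporting layers round to one decimal place.
#'
#' @param net a \code{cell_network} with at least one edge.
#' @return interactions per species (unrounded).
#' @export
linkage_density <- function(net) {
  if (net$n_interactions < 1L) {
    stop("linkage density undefined for an empty network")
  }
  net$n_interactions / net$n_species
}

#' Classify the bipartite topology of a potential network
#'
#' Whole-network classification by the counts of parasite and host nodes:
#' one parasite and one host is \code{one_to_one}; one parasite with several
#' hosts \code{one_to_many}; several parasites sharing one host
#' \code{many_to_one}; several of both \code{many_to_many}; no edges
#' \code{empty}.
#'
#' @param net a \code{cell_network}.
#' @return one of \code{"empty"}, \code{"one_to_one"}, \code{"one_to_many"},
#'   \code{"many_to_one"}, \code{"many_to_many"}.
#' @export
classify_topology <- function(net) {
  p <- length(net$parasite_nodes); h <- length(net$host_nodes)
  if (p == 0L || h == 0L) return("empty")
  if (p == 1L && h == 1L) return("one_to_one")
  if (p == 1L) return("one_to_many")
  if (h == 1L) return("many_to_one")
  "many_to_many"
}

#' Topology classes of the connected components of a network
#'
#' Secondary diagnostic: the whole-network class of
#' \code{\link{classify_topology}} can mask internal structure (e.g. two
#' disjoint pairs classify as many-to-many); this breaks the network into
#' connected components and classifies each.
#'
#' @param net a \code{cell_network}.
#' @return character vector, one class per connected component (empty for an
#'   empty network).
#' @export
component_topologies <- function(net) {
  e <- net$edges
  if (nrow(e) == 0L) return(character(0))
  nodes <- c(paste0("p:", e$parasite), paste0("h:", e$host))
  ids <- unique(nodes)
  comp <- stats::setNames(seq_along(ids), ids)
  repeat {  # label propagation until stable (small networks)
    changed <- FALSE
    for (k in seq_len(nrow(e))) {
      a <- paste0("p:", e$parasite[k]); b <- paste0("h:", e$host[k])
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[a] <- m; comp[b] <- m; changed <- TRUE
      }
    }
    if (!changed) break
  }
  vapply(split(names(comp), comp), function(members) {
    ps <- sub("^p:", "", members[startsWith(members, "p:")])
    hs <- sub("^h:", "", members[startsWith(members, "h:")])
    keep <- e$parasite %in% ps & e$host %in% hs
    classify_topology(new_cell_network(net$cell_id, e[keep, , drop = FALSE]))
  }, character(1), USE.NAMES = FALSE)
}

#' Per-cell network complexity table
#'
#' One row per grid cell with the cell's linkage density (raw and rounded to
#' one decimal place), parasite/host richness from the presence matrix,
#' optional total bird richness, topology class and network size. Cells with
#' no interactions get \code{NA} linkage density (never zero) and topology
#' \code{"empty"}; this table is both the regression input and the heatmap
#' source.
#'
#' @param grid a \code{paranet_grid}.
#' @param presence a \code{presence_matrix} over (at least) the interacting
#'   species.
#' @param table an \code{interaction_table}.
#' @param all_bird_presence optional \code{presence_matrix} over the full
#'   avifauna, used for the \code{total_bird_richness} column.
#' @return a \code{complexity_table} data frame.
#' @export
complexity_table <- function(grid, presence, table, all_bird_presence = NULL) {
  if (!all(grid$cell_id %in% rownames(presence))) {
    stop("presence matrix does not cover every grid cell")
  }
  presence <- presence[grid$cell_id, , drop = FALSE]
  e <- table$edges
  sp <- colnames(presence)
  pres_of <- function(ids) {
    out <- matrix(FALSE, nrow(presence), length(ids))
    hit <- ids %in% sp
    out[, hit] <- presence[, ids[hit], drop = FALSE]
    out
  }
  n_cells <- length(grid$cell_id)
  if (nrow(e) > 0L) {
    E <- pres_of(e$parasite) & pres_of(e$host)       # cells x edges
    n_int <- rowSums(E)
    species <- union(e$parasite, e$host)
    Mp <- outer(e$parasite, species, "==") * 1       # edges x species
    Mh <- outer(e$host, species, "==") * 1
    node_p <- (E %*% Mp) > 0                          # cells x species
    node_h <- (E %*% Mh) > 0
    n_par <- rowSums(node_p)
    n_host <- rowSums(node_h)
    n_sp <- rowSums(node_p | node_h)
  } else {
    n_int <- n_par <- n_host <- n_sp <- numeric(n_cells)
  }
  ld <- ifelse(n_int > 0, n_int / pmax(n_sp, 1), NA_real_)
  topo <- ifelse(n_int == 0, "empty",
          ifelse(n_par == 1 & n_host == 1, "one_to_one",
          ifelse(n_par == 1, "one_to_many",
          ifelse(n_host == 1, "many_to_one", "many_to_many"))))
  out <- data.frame(
    cell_id = grid$cell_id,
    linkage_density = ld,
    linkage_density_1dp = round(ld, 1),
    parasite_richness = unname(richness(presence, intersect(table$parasites, sp))),
    host_richness = unname(richness(presence, intersect(table$hosts, sp))),
    topology_class = topo,
    n_interactions = as.integer(n_int),
    n_species = as.integer(n_sp),
    stringsAsFactors = FALSE)
  if (!is.null(all_bird_presence)) {
    if (!all(grid$cell_id %in% rownames(all_bird_presence))) {
      stop("all_bird_presence does not cover every grid cell")
    }
    out$total_bird_richness <-
      unname(richness(all_bird_presence[grid$cell_id, , drop = FALSE]))
  }
  class(out) <- c("complexity_table", "data.frame")
  out
}

#' Write a complexity table as CSV
#' @param ct a \code{complexity_table}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_complexity_csv <- function(ct, path) {
  utils::write.csv(as.data.frame(ct), path, row.names = FALSE)
  invisible(path)
}

#' Write a complexity table as heatmap-ready GeoJSON
#'
#' Joins the per-cell metrics onto the grid polygons so the result can be
#' rendered directly as a choropleth.
#'
#' @param ct a \code{complexity_table}.
#' @param grid the \code{paranet_grid} the table was computed on.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_complexity_geojson <- function(ct, grid, path) {
  idx <- match(grid$cell_id, ct$cell_id)
  feats <- lapply(seq_along(grid$cell_id), function(i) {
    ring <- grid$polygons[[i]]
    ring <- rbind(ring, ring[1, , drop = FALSE])
    row <- ct[idx[i], ]
    props <- lapply(as.list(row), function(v) if (is.na(v)) NULL else v)
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(unname(lapply(
                           seq_len(nrow(ring)), function(k) unname(ring[k, ]))))))
  })
  fc <- list(type = "FeatureCollection", crs_kind = grid$crs_kind,
             features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}
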