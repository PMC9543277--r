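# End-to-end orchestration: grid -> presence -> potential networks ->
# complexity table -> OLS / error-SAR regressions, with every artifact
# written to disk and every exclusion logged.

#' Build a pipeline run configuration
#'
#' Exactly one grid source must be given: a grid file or generation
#' parameters. Regressions of linkage density are fitted separately on each
#' requested richness covariate (parasite, host, and - when an all-bird
#' range layer is supplied - total bird richness), each as a univariate
#' model with intercept.
#'
#' @param ranges path to the species range GeoJSON.
#' @param interactions path to the parasite-host edge list CSV.
#' @param out_dir output directory.
#' @param grid optional path to a grid GeoJSON.
#' @param grid_params optional list(extent, target_area_km2) to generate a
#'   planar grid instead.
#' @param land optional land polygon GeoJSON used to clip the grid.
#' @param all_bird_ranges optional range GeoJSON for the full avifauna.
#' @param min_fraction presence predicate: minimum intersected fraction of
#'   the cell (0 = any positive overlap).
#' @param threshold_km spatial weights neighbourhood distance (default 200).
#' @param covariates richness covariates to regress linkage density on.
#' @param attribute_filter range attribute policy (see
#'   \code{\link{read_ranges}}).
#' @return a \code{run_config} list.
#' @export
run_config <- function(ranges, interactions, out_dir,
                       grid = NULL, grid_params = NULL, land = NULL,
                       all_bird_ranges = NULL, min_fraction = 0,
                       threshold_km = 200,
                       covariates = c("parasite_richness", "host_richness",
                                      "total_bird_richness"),
                       attribute_filter = "native_breeding") {
  if (is.null(grid) == is.null(grid_params)) {
    stop("exactly one grid source required: `grid` or `grid_params`")
  }
  for (p in c(ranges, interactions, grid, land, all_bird_ranges)) {
    if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(list(ranges = ranges, interactions = interactions,
                 out_dir = out_dir, grid = grid, grid_params = grid_params,
                 land = land, all_bird_ranges = all_bird_ranges,
                 min_fraction = min_fraction, threshold_km = threshold_km,
                 covariates = covariates,
                 attribute_filter = attribute_filter),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Accepts the same keys as \code{\link{run_config}}; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) NULL
    else if (file.exists(p)) p
    else file.path(base, p)
  }
  for (k in c("ranges", "interactions", "grid", "land", "all_bird_ranges")) {
    cfg[[k]] <- fix(cfg[[k]])
  }
  cfg$out_dir <- cfg$out_dir %||% file.path(base, "out")
  do.call(run_config, cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[paranet:%s] pipeline aborted at stage '%s': %s",
                 name, name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full network-complexity pipeline
#'
#' Stages: load/generate the grid (optionally clipped to land), read ranges
#' and interactions, compute presence-absence and the per-cell complexity
#' table, then fit OLS and error-SAR models of linkage density on each
#' richness covariate over the cells with a defined (non-empty) network.
#' Writes \code{complexity.csv}, \code{complexity.geojson}, weights files
#' (\code{weights.gal}, \code{weights.csv}) and one \code{model_<covariate>.json}
#' report per covariate. Every stage logs its counts (cells, species, edges,
#' exclusions) via \code{message()}; any stage error aborts with the stage
#' name and a machine-readable code.
#'
#' @param config a \code{run_config} or path to a YAML config.
#' @return invisibly, a \code{paranet_run}: loaded inputs, the complexity
#'   table, weights, fitted models and artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  grid <- stage("grid", {
    g <- if (!is.null(config$grid)) load_grid(config$grid)
         else build_planar_hex_grid(config$grid_params$extent,
                                    config$grid_params$target_area_km2)
    message("grid: ", length(g$cell_id), " cells (", g$crs_kind, ")")
    if (!is.null(config$land)) {
      land_fc <- read_ranges(config$land, attribute_filter = "all",
                             species_field = "species",
                             crs_kind = g$crs_kind)
      land_polys <- unlist(lapply(land_fc, `[[`, "polygons"),
                           recursive = FALSE)
      before <- length(g$cell_id)
      g <- clip_grid_to_land(g, land_polys)
      message("grid: land clip dropped ", before - length(g$cell_id),
              " cell(s), ", length(g$cell_id), " remain")
    }
    g
  })

  ranges <- stage("ranges", {
    r <- read_ranges(config$ranges, attribute_filter = config$attribute_filter,
                     crs_kind = grid$crs_kind)
    message("ranges: ", length(r), " species range(s) read")
    r
  })

  table <- stage("interactions", {
    tb <- read_interactions(config$interactions)
    if (nrow(tb$edges) == 0L) stop("no interaction rows")
    message("interactions: ", nrow(tb$edges), " edges, ",
            length(tb$parasites), " parasites, ", length(tb$hosts), " hosts")
    tb
  })

  presence <- stage("presence", {
    inter_sp <- names(ranges)[names(ranges) %in% c(table$parasites, table$hosts)]
    no_range <- setdiff(c(table$parasites, table$hosts), names(ranges))
    if (length(no_range)) {
      message("presence: ", length(no_range),
              " interacting species have no range and are absent everywhere: ",
              paste(utils::head(no_range, 5), collapse = ", "),
              if (length(no_range) > 5) ", ..." else "")
    }
    pm <- presence_absence(grid, new_ranges(ranges[inter_sp],
                                            attr(ranges, "crs_kind")),
                           min_fraction = config$min_fraction)
    message("presence: ", sum(pm), " cell-species presences")
    pm
  })

  all_bird <- stage("presence", {
    if (is.null(config$all_bird_ranges)) NULL else {
      ab <- read_ranges(config$all_bird_ranges,
                        attribute_filter = config$attribute_filter,
                        crs_kind = grid$crs_kind)
      presence_absence(grid, ab, min_fraction = config$min_fraction)
    }
  })

  ct <- stage("networks", {
    x <- complexity_table(grid, presence, table, all_bird)
    message("networks: ", sum(!is.na(x$linkage_density)), " of ",
            nrow(x), " cells have a non-empty potential network")
    x
  })

  paths <- c(complexity_csv = file.path(config$out_dir, "complexity.csv"),
             complexity_geojson = file.path(config$out_dir, "complexity.geojson"))
  write_complexity_csv(ct, paths["complexity_csv"])
  write_complexity_geojson(ct, grid, paths["complexity_geojson"])

  keep <- !is.na(ct$linkage_density)
  fits <- list(); weights <- NULL
  if (sum(keep) >= 3L) {
    weights <- stage("weights", {
      metric <- if (grid$crs_kind == "lonlat_sphere") "great_circle" else "euclidean_km"
      w <- distance_band_weights(grid$centroids[keep, , drop = FALSE],
                                 config$threshold_km, metric = metric,
                                 ids = grid$cell_id[keep])
      if (length(w$islands)) {
        message("weights: ", length(w$islands),
                " island cell(s) kept with untransformed errors: ",
                paste(w$ids[w$islands], collapse = ", "))
      }
      w
    })
    paths["weights_gal"] <- file.path(config$out_dir, "weights.gal")
    paths["weights_csv"] <- file.path(config$out_dir, "weights.csv")
    write_weights_gal(weights, paths["weights_gal"])
    write_weights_csv(weights, paths["weights_csv"])

    covs <- config$covariates
    if (is.null(all_bird)) covs <- setdiff(covs, "total_bird_richness")
    fits <- stage("stats", {
      lapply(stats::setNames(covs, covs), function(cv) {
        X <- cbind("(Intercept)" = 1, ct[[cv]][keep])
        colnames(X)[2] <- cv
        ols <- ols_fit(ct$linkage_density[keep], X)
        sar <- sar_error_fit(ct$linkage_density[keep], X, weights)
        rep_path <- file.path(config$out_dir, paste0("model_", cv, ".json"))
        report <- list(
          response = "linkage_density", covariate = cv,
          n = ols$n,
          ols = list(beta = as.list(ols$beta), r2 = ols$r2, F = ols$F,
                     df = ols$df, sigma2 = ols$sigma2, logLik = ols$logLik),
          sar = list(lambda = sar$lambda, beta = as.list(sar$beta),
                     sigma2 = sar$sigma2, logLik = sar$logLik,
                     nagelkerke_r2 = sar$nagelkerke_r2,
                     LR = sar$lr_vs_ols, df = sar$lr_df, n = sar$n))
        writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA),
                   rep_path)
        message("stats: ", cv, " OLS R2 = ", round(ols$r2, 3),
                ", SAR lambda = ", round(sar$lambda, 3))
        list(ols = ols, sar = sar, report_path = rep_path)
      })
    })
    for (cv in names(fits)) {
      paths[paste0("model_", cv)] <- fits[[cv]]$report_path
    }
  } else {
    message("stats: fewer than 3 cells with defined linkage density; ",
            "regressions skipped")
  }

  invisible(structure(list(config = config, grid = grid, ranges = ranges,
                           interactions = table, presence = presence,
                           all_bird_presence = all_bird, complexity = ct,
                           weights = weights, fits = fits, paths = paths),
                      class = "paranet_run"))
}

#' @export
print.paranet_run <- function(x, ...) {
  cat(sprintf("<paranet_run> %d cells, %d networks, %d model pair(s)\n",
              nrow(x$complexity),
              sum(!is.na(x$complexity$linkage_density)), length(x$fits)))
  cat("  artifacts in ", x$config$out_dir, "\n", sep = "")
  invisible(x)
}

#' Plain-text summary of a pipeline run
#'
#' Reports the linkage-density range with the composition of the extreme
#' cells, topology-class tallies over all cells, and the species-level
#' interaction summary; percentages are rounded to whole numbers.
#'
#' @param run a \code{paranet_run} from \code{\link{run_pipeline}}.
#' @param file connection or "" (stdout).
#' @return the report lines, invisibly.
#' @export
report_summary <- function(run, file = "") {
  if (!inherits(run, "paranet_run")) stop("missing artifacts: not a paranet_run")
  ct <- run$complexity
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  add("Potential-network complexity summary")
  add("  cells: %d (%d with a non-empty network)",
      nrow(ct), sum(!is.na(ct$linkage_density)))
  if (any(!is.na(ct$linkage_density))) {
    lo <- ct[which.min(ct$linkage_density), ]
    hi <- ct[which.max(ct$linkage_density), ]
    comp <- function(row) {
      net <- cell_network(row$cell_id, run$presence, run$interactions)
      sprintf("%d parasites, %d hosts, %d interactions",
              length(net$parasite_nodes), length(net$host_nodes),
              net$n_interactions)
    }
    add("  linkage density: min %.1f in cell %s (%s)",
        lo$linkage_density_1dp, lo$cell_id, comp(lo))
    add("  linkage density: max %.1f in cell %s (%s)",
        hi$linkage_density_1dp, hi$cell_id, comp(hi))
  } else {
    add("  no cell contains any potential network")
  }
  tal <- table(factor(ct$topology_class,
                      levels = c("empty", "one_to_one", "one_to_many",
                                 "many_to_one", "many_to_many")))
  add("  topology classes: %s",
      paste(sprintf("%s = %d", names(tal), as.integer(tal)), collapse = ", "))
  ss <- species_summaries(run$interactions)
  add("  %d parasites: median %.1f hosts (IQR %.1f, max %d), %d%% with >1 host",
      ss$parasites$n, ss$parasites$median, ss$parasites$iqr,
      ss$parasites$max, ss$parasites$pct_multi)
  add("  %d hosts: median %.1f parasites (IQR %.1f, max %d), %d%% with >1 parasite",
      ss$hosts$n, ss$hosts$median, ss$hosts$iqr,
      ss$hosts$max, ss$hosts$pct_multi)
  if (identical(file, "")) file <- stdout()
  writeLines(lines, con = file)
  invisible(lines)
}
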