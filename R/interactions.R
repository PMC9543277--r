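# The global parasite -> host edge list and its species-level summaries.

#' Construct a parasite-host interaction table
#'
#' Validates and deduplicates an edge list of documented brood
#' parasite-host interactions. Duplicate pairs are collapsed (with a
#' message recording how many), and self-pairs are rejected: a species
#' cannot be its own brood-parasite host.
#'
#' @param parasite,host character vectors of equal length (one edge per
#'   position); already-normalised names are used as-is.
#' @param synonyms optional synonym map applied through
#'   \code{\link{normalize_species}}.
#' @return an \code{interaction_table}: list with \code{edges} (data frame
#'   \code{parasite}, \code{host}), \code{parasites}, \code{hosts}.
#' @export
interaction_table <- function(parasite, host, synonyms = NULL) {
  stopifnot(length(parasite) == length(host))
  parasite <- normalize_species(parasite, synonyms)
  host <- normalize_species(host, synonyms)
  bad <- which(parasite == host)
  if (length(bad)) {
    stop("self-interaction (parasite == host) in row(s): ",
         paste(bad, collapse = ", "))
  }
  edges <- data.frame(parasite = parasite, host = host,
                      stringsAsFactors = FALSE)
  ndup <- nrow(edges) - nrow(unique(edges))
  if (ndup > 0) {
    message(ndup, " duplicate interaction(s) collapsed")
    edges <- unique(edges)
  }
  edges <- edges[order(edges$parasite, edges$host), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 parasites = sort(unique(edges$parasite)),
                 hosts = sort(unique(edges$host))),
            class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("<interaction_table> %d interactions: %d parasites, %d hosts\n",
              nrow(x$edges), length(x$parasites), length(x$hosts)))
  invisible(x)
}

#' Read a parasite-host edge list from CSV
#'
#' Expects header columns \code{parasite_species} and \code{host_species}.
#'
#' @param path CSV file.
#' @param synonyms optional synonym map.
#' @return an \code{interaction_table} (empty, with a warning, for a
#'   headed but row-less file).
#' @export
read_interactions <- function(path, synonyms = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("parasite_species", "host_species")
  if (!all(need %in% names(df))) {
    stop("format error: ", path, " must have columns ",
         paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warning("empty interaction file: ", path)
    return(structure(list(edges = data.frame(parasite = character(0),
                                             host = character(0)),
                          parasites = character(0), hosts = character(0)),
                     class = "interaction_table"))
  }
  interaction_table(df$parasite_species, df$host_species, synonyms)
}

#' Report declared parasites that have no documented host
#'
#' Brood-parasite checklists typically include species with no host record;
#' those cannot enter any network and must be excluded from parasite
#' richness maps. The table itself never contains them - this operation
#' reports which declared species they are.
#'
#' @param table an \code{interaction_table}.
#' @param declared_parasites character vector of all recognised brood
#'   parasite species; must cover every parasite in the table.
#' @return list with \code{table} (unchanged) and \code{excluded}
#'   (declared parasites with zero edges).
#' @export
drop_hostless_parasites <- function(table, declared_parasites) {
  declared_parasites <- unique(normalize_species(declared_parasites))
  missing <- setdiff(table$parasites, declared_parasites)
  if (length(missing)) {
    stop("declared_parasites must include every parasite with edges; missing: ",
         paste(missing, collapse = ", "))
  }
  list(table = table,
       excluded = sort(setdiff(declared_parasites, table$parasites)))
}

#' Species-level summary statistics of an interaction table
#'
#' For parasites: the distribution of documented hosts per parasite
#' (median, interquartile range as Q3 - Q1 with linear interpolation
#' between order statistics, maximum) and the fraction with more than one
#' host. For hosts: the mirror statistics over parasites per host.
#' Fractions are reported raw and rounded to the nearest whole percent.
#'
#' @param table a non-empty \code{interaction_table}.
#' @return a \code{species_summary} list with components \code{parasites}
#'   and \code{hosts}, each holding \code{counts}, \code{median},
#'   \code{iqr}, \code{max}, \code{frac_multi}, \code{pct_multi}, \code{n}.
#' @export
species_summaries <- function(table) {
  if (nrow(table$edges) == 0L) stop("empty interaction table")
  one_side <- function(key) {
    counts <- table(table$edges[[key]])
    counts <- stats::setNames(as.integer(counts), names(counts))
    q <- stats::quantile(counts, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    frac <- mean(counts > 1)
    list(counts = counts, median = q[2], iqr = q[3] - q[1],
         max = max(counts), frac_multi = frac,
         pct_multi = round(100 * frac), n = length(counts))
  }
  structure(list(parasites = one_side("parasite"), hosts = one_side("host")),
            class = "species_summary")
}

#' @export
print.species_summary <- function(x, ...) {
  cat("Species-level interaction summary\n")
  cat(sprintf("  %d brood parasites: median %.1f hosts (IQR %.1f, max %d); %d%% with >1 host\n",
              x$parasites$n, x$parasites$median, x$parasites$iqr,
              x$parasites$max, x$parasites$pct_multi))
  cat(sprintf("  %d hosts: median %.1f parasites (IQR %.1f, max %d); %d%% with >1 parasite\n",
              x$hosts$n, x$hosts$median, x$hosts$iqr,
              x$hosts$max, x$hosts$pct_multi))
  invisible(x)
}
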