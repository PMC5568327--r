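#' Whole-network structural summary
#'
#' Computes structural descriptives of the aggregated directed tie
#' network: node and tie counts, the number of posters (members with at
#' least one reader, i.e. at least one outgoing tie), the largest
#' strongly connected component (LSCC) and its share of all nodes, the
#' average directed shortest-path length over ordered node pairs within
#' the LSCC, clustering coefficients, and complementary cumulative degree
#' tables for in-degree and out-degree-aware (the tabular content of the
#' usual degree-distribution figures).
#'
#' Two clustering variants are reported, since "probability of triads"
#' admits both readings: the average local clustering coefficient on the
#' undirected projection (`clustering_coefficient`, nodes with fewer than
#' two neighbours contributing zero) and the global transitivity ratio
#' (`transitivity_global`).
#'
#' @param ties tie `data.table` from [build_ties()].
#' @return object of class `network_summary`: a list with `n_nodes`,
#'   `n_ties`, `n_posters`, `lscc_size`, `lscc_fraction` (percent, one
#'   decimal), `avg_path_length`, `clustering_coefficient`,
#'   `transitivity_global`, and `degree_table` (complementary cumulative
#'   counts).
#' @export
network_summary <- function(ties) {
  tt <- as.data.table(ties)
  if (nrow(tt) == 0) {
    out <- list(n_nodes = 0L, n_ties = 0L, n_posters = 0L, lscc_size = 0L,
                lscc_fraction = NA_real_, avg_path_length = NA_real_,
                clustering_coefficient = NA_real_,
                transitivity_global = NA_real_,
                degree_table = data.table(metric = character(),
                                          degree = integer(),
                                          n_nodes_ge = integer()))
    return(structure(out, class = "network_summary"))
  }
  g <- igraph::graph_from_data_frame(tt[, .(source, target)],
                                     directed = TRUE)
  comp <- igraph::components(g, mode = "strong")
  lscc_id <- which.max(comp$csize)
  lscc_size <- as.integer(max(comp$csize))
  apl <- if (lscc_size >= 2) {
    sub <- igraph::induced_subgraph(g, which(comp$membership == lscc_id))
    igraph::mean_distance(sub, directed = TRUE)
  } else NA_real_
  und <- igraph::as_undirected(g, mode = "collapse")
  loc <- igraph::transitivity(und, type = "local", isolates = "zero")
  loc[is.nan(loc)] <- 0

  ccdf <- function(deg, metric) {
    ks <- sort(unique(deg))
    data.table(metric = metric, degree = as.integer(ks),
               n_nodes_ge = vapply(ks, function(k) sum(deg >= k),
                                   integer(1)))
  }
  in_deg <- igraph::degree(g, mode = "in")
  oa_ties <- tt[aware == TRUE]
  oa_deg <- integer(igraph::vcount(g))
  names(oa_deg) <- igraph::V(g)$name
  if (nrow(oa_ties)) {
    cnt <- oa_ties[, .N, by = source]
    oa_deg[cnt$source] <- cnt$N
  }

  out <- list(
    n_nodes = igraph::vcount(g),
    n_ties = nrow(tt),
    n_posters = uniqueN(tt$source),
    lscc_size = lscc_size,
    lscc_fraction = pct(lscc_size, igraph::vcount(g)),
    avg_path_length = apl,
    clustering_coefficient = mean(loc),
    transitivity_global = igraph::transitivity(und, type = "global"),
    degree_table = rbindlist(list(ccdf(in_deg, "in_degree"),
                                  ccdf(oa_deg, "out_degree_aware")))
  )
  structure(out, class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("<network_summary>\n")
  cat(sprintf("  nodes (>=1 tie): %d   ties: %d   posters: %d\n",
              x$n_nodes, x$n_ties, x$n_posters))
  if (x$n_nodes > 0) {
    cat(sprintf("  LSCC: %d nodes (%.1f%% of all nodes)\n",
                x$lscc_size, x$lscc_fraction))
    cat(sprintf("  average path length in LSCC: %s\n",
                ifelse(is.na(x$avg_path_length), "NA",
                       sprintf("%.2f", x$avg_path_length))))
    cat(sprintf("  clustering: %.3f (avg local), %.3f (global transitivity)\n",
                x$clustering_coefficient, x$transitivity_global))
  }
  invisible(x)
}

#' Export a tie list as delimited text
#'
#' Columns: `source`, `target`, `formed_at` (ISO-8601 UTC), `channel`,
#' `aware` (0/1), `aware_at` (empty when not aware). The column names
#' match common graph-exchange attribute conventions so the file can be
#' ingested as an edge list with attributes.
#'
#' @param ties tie `data.table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(ties, path) {
  tt <- as.data.table(ties)
  out <- tt[, .(source, target,
                formed_at = format(formed_at, "%Y-%m-%dT%H:%M:%SZ",
                                   tz = "UTC"),
                channel, aware = as.integer(aware),
                aware_at = fifelse(is.na(aware_at), "",
                                   format(aware_at, "%Y-%m-%dT%H:%M:%SZ",
                                          tz = "UTC")))]
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
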