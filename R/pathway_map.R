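#' Pathway over-representation analysis
#'
#' Hypergeometric over-representation of a query gene list against each set
#' of a GMT collection, within a gene universe. Sets are intersected with
#' the universe before testing; the BH adjustment runs across the whole
#' collection.
#'
#' @param query Character vector of query genes (upper-cased internally);
#'   must be contained in the universe.
#' @param collection Named list of gene sets (see \code{\link{read_gmt}}).
#' @param universe Character vector of background genes; defaults to the
#'   union of all collection genes.
#' @return Data frame: \code{set}, \code{set_size} (within universe),
#'   \code{overlap}, \code{p_raw}, \code{q}; overlapping genes in the
#'   list column \code{overlap_genes}.
#' @export
ora <- function(query, collection, universe = NULL) {
  query <- unique(toupper(trimws(query)))
  collection <- lapply(collection, function(s) unique(toupper(trimws(s))))
  if (is.null(universe)) universe <- sort(unique(unlist(collection)))
  universe <- unique(toupper(trimws(universe)))
  if (!length(universe)) stop("empty gene universe")
  if (!length(query)) stop("empty query gene list")
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "),
         if (length(outside) > 5) ", ...")
  sets_u <- lapply(collection, intersect, universe)
  ov <- lapply(sets_u, intersect, query)
  res <- data.frame(
    set = names(collection),
    set_size = lengths(sets_u),
    overlap = lengths(ov),
    stringsAsFactors = FALSE
  )
  res$p_raw <- hypergeom_upper_tail(res$overlap, res$set_size,
                                    length(query), length(universe))
  res$q <- bh_adjust(res$p_raw)
  res$overlap_genes <- lapply(ov, sort)
  rownames(res) <- NULL
  res[order(res$p_raw, res$set), , drop = FALSE]
}

#' Combined set-similarity coefficient
#'
#' Equal-weight combination of the Jaccard index and the overlap
#' coefficient, the metric enrichment-map tools use to weight edges between
#' enriched pathways:
#' \deqn{0.5\,|i \cap j|/|i \cup j| + 0.5\,|i \cap j|/\min(|i|,|j|).}
#'
#' @param set_i,set_j Non-empty character vectors.
#' @param method \code{"combined"} (default), \code{"jaccard"}, or
#'   \code{"overlap"}.
#' @return Similarity in \code{[0, 1]}.
#' @export
combined_similarity <- function(set_i, set_j,
                                method = c("combined", "jaccard", "overlap")) {
  method <- match.arg(method)
  set_i <- unique(set_i); set_j <- unique(set_j)
  if (!length(set_i) || !length(set_j)) stop("similarity of an empty set is undefined")
  inter <- length(intersect(set_i, set_j))
  jac <- inter / length(union(set_i, set_j))
  ovl <- inter / min(length(set_i), length(set_j))
  switch(method,
         combined = 0.5 * jac + 0.5 * ovl,
         jaccard = jac,
         overlap = ovl)
}

#' Build an enrichment-map similarity network
#'
#' Nodes are the gene sets passing the q-value cutoff; an edge joins two
#' nodes whose similarity reaches the edge cutoff; clusters are the
#' connected components, each labeled by its largest member set. The
#' default cutoffs (q at 0.05, similarity at 0.375) follow the usual
#' enrichment-map convention.
#'
#' @param enrichments ORA results (see \code{\link{ora}}).
#' @param collection The gene-set list the enrichments refer to.
#' @param q_cutoff Node cutoff on the adjusted p-value.
#' @param edge_cutoff Minimum similarity for an edge.
#' @param method Similarity variant passed to
#'   \code{\link{combined_similarity}}.
#' @return List of class \code{similarity_network}: \code{nodes} (set, q,
#'   size, cluster, cluster_label), \code{edges} (set_i, set_j,
#'   similarity), and \code{graph}, an igraph object.
#' @export
build_map <- function(enrichments, collection, q_cutoff = 0.05,
                      edge_cutoff = 0.375,
                      method = c("combined", "jaccard", "overlap")) {
  method <- match.arg(method)
  keep <- enrichments[enrichments$q <= q_cutoff, , drop = FALSE]
  nodes <- data.frame(set = keep$set, q = keep$q, size = keep$set_size,
                      stringsAsFactors = FALSE)
  edges <- data.frame(set_i = character(0), set_j = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE)
  if (nrow(nodes) > 1L) {
    pr <- utils::combn(nodes$set, 2L)
    sim <- apply(pr, 2L, function(p)
      combined_similarity(collection[[p[1L]]], collection[[p[2L]]], method))
    keep_e <- sim >= edge_cutoff
    edges <- data.frame(set_i = pr[1L, keep_e], set_j = pr[2L, keep_e],
                        similarity = sim[keep_e], stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  if (nrow(nodes)) {
    comp <- igraph::components(g)
    nodes$cluster <- comp$membership[nodes$set]
    labels <- vapply(split(nodes, nodes$cluster), function(d)
      d$set[which.max(d$size)], character(1))
    nodes$cluster_label <- labels[as.character(nodes$cluster)]
  } else {
    nodes$cluster <- integer(0)
    nodes$cluster_label <- character(0)
  }
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "similarity_network")
}

#' Export a similarity network
#'
#' Writes the node table and edge table as TSV and the graph as GraphML for
#' external visualization.
#'
#' @param map A \code{similarity_network} from \code{\link{build_map}}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_map <- function(map, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(map$nodes, file.path(dir, "map_nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(map$edges, file.path(dir, "map_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  igraph::write_graph(map$graph, file.path(dir, "map.graphml"),
                      format = "graphml")
  invisible(dir)
}
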