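#' Construct a protein-protein interaction graph
#'
#' A lightweight undirected graph: a fixed node set (the proteins of interest,
#' typically novel proteins -- isolated proteins count) plus scored edges.
#' Edges touching proteins outside `nodes` are dropped; self-loops are
#' rejected by the edge normalizer.
#'
#' @param edges Tibble with columns `protein_a`, `protein_b`, `score`
#'   (see [read_edge_list()]).
#' @param nodes Character vector of node ids. Defaults to the union of edge
#'   endpoints.
#' @return An object of class `ppi_graph`: list with `nodes` (character) and
#'   `edges` (tibble).
#' @export
ppi_graph <- function(edges, nodes = NULL) {
  edges <- normalize_edges(tibble::as_tibble(edges))
  if (is.null(nodes)) nodes <- union(edges$protein_a, edges$protein_b)
  nodes <- sort(unique(as.character(nodes)))
  edges <- edges[edges$protein_a %in% nodes & edges$protein_b %in% nodes, ,
                 drop = FALSE]
  structure(list(nodes = nodes, edges = edges), class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("<ppi_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Filter graph edges by interaction score
#'
#' Keeps edges with `score >= min_score` (inclusive boundary, the STRING
#' convention); the node set is unchanged, so nodes losing all their edges
#' become isolated rather than disappearing.
#'
#' @param graph A [ppi_graph()].
#' @param min_score Minimum combined interaction score (default 0.4).
#' @return A `ppi_graph` with the same nodes and the retained edges.
#' @export
filter_edges <- function(graph, min_score = 0.4) {
  stopifnot(inherits(graph, "ppi_graph"))
  graph$edges <- graph$edges[graph$edges$score >= min_score, , drop = FALSE]
  graph
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[c("protein_a", "protein_b")],
    directed = FALSE,
    vertices = data.frame(name = graph$nodes)
  )
}

#' Fraction of proteins with at least one interaction
#'
#' @param graph A [ppi_graph()] (filter first with [filter_edges()] if a score
#'   threshold applies).
#' @return A one-row tibble with `n_connected`, `n_total`, `fraction`.
#' @export
connected_fraction <- function(graph) {
  stopifnot(inherits(graph, "ppi_graph"))
  if (length(graph$nodes) == 0) stop("graph has no nodes", call. = FALSE)
  touched <- unique(c(graph$edges$protein_a, graph$edges$protein_b))
  n_conn <- sum(graph$nodes %in% touched)
  tibble::tibble(
    n_connected = n_conn,
    n_total = length(graph$nodes),
    fraction = n_conn / length(graph$nodes)
  )
}

#' Connected components of minimum size
#'
#' Components of the graph with at least `min_size` members, in a
#' deterministic order (decreasing size, then lexicographically smallest
#' member) so output files are diff-stable.
#'
#' @param graph A [ppi_graph()].
#' @param min_size Minimum component size (default 3, the usual display
#'   threshold for interaction networks).
#' @return A list of character vectors (sorted members), possibly empty.
#' @export
components_min_size <- function(graph, min_size = 3) {
  stopifnot(inherits(graph, "ppi_graph"), min_size >= 1)
  if (length(graph$nodes) == 0) return(list())
  comp <- igraph::components(as_igraph(graph))
  groups <- split(names(comp$membership), comp$membership)
  groups <- purrr::map(groups, sort)
  groups <- groups[lengths(groups) >= min_size]
  if (length(groups) == 0) return(list())
  ord <- order(-lengths(groups), purrr::map_chr(groups, 1))
  unname(groups[ord])
}

#' Permutation test for edge-count enrichment
#'
#' Asks whether the focal protein set carries more interactions among
#' themselves than a random protein set of the same size drawn from the
#' background universe. This is a transparent permutation stand-in for
#' database-internal enrichment models (which correct for node degree); the
#' output records that explicitly.
#'
#' @param graph A [ppi_graph()] on the focal proteins (already
#'   score-filtered).
#' @param background_nodes Character vector: the universe to sample from;
#'   must contain every focal node.
#' @param background_edges Edge tibble over the background universe (same
#'   score filtering applied by the caller).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @return A one-row tibble: `observed_edges`, `expected_mean`, `empirical_p`
#'   (computed as `(1 + #{perm >= obs}) / (n_perm + 1)`), `n_perm`, `method`.
#' @export
edge_enrichment_permutation <- function(graph, background_nodes,
                                        background_edges, n_perm = 1000,
                                        seed = 1) {
  stopifnot(inherits(graph, "ppi_graph"))
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  background_nodes <- unique(as.character(background_nodes))
  if (!all(graph$nodes %in% background_nodes)) {
    stop("graph nodes must all be contained in background_nodes", call. = FALSE)
  }
  bed <- normalize_edges(tibble::as_tibble(background_edges))
  k <- length(graph$nodes)
  observed <- nrow(graph$edges)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm_counts <- vapply(seq_len(n_perm), function(i) {
    s <- sample(background_nodes, k)
    sum(bed$protein_a %in% s & bed$protein_b %in% s)
  }, numeric(1))

  tibble::tibble(
    observed_edges = observed,
    expected_mean = mean(perm_counts),
    empirical_p = (1 + sum(perm_counts >= observed)) / (n_perm + 1),
    n_perm = n_perm,
    method = "subset permutation (no degree correction)"
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
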