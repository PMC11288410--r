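# Per-bin similarity networks and their structural / node-level metrics.
#
# Topological metrics (density, global clustering, average path length,
# betweenness, eigenvector centrality) are computed on the unweighted
# topology by default, matching the conventions of the common
# network-analysis GUIs; community detection uses the edge weights.

#' Build an undirected similarity network
#'
#' One node per context; an edge for every strictly positive similarity,
#' with the similarity as edge weight. No self-loops, no thresholding.
#'
#' @param J Symmetric similarity matrix (typically the normalised Jaccard
#'   matrix of one bin).
#' @param bin Optional bin label stored as a graph attribute.
#' @return An [igraph][igraph::aaa-igraph-package] graph.
#' @export
build_network <- function(J, bin = NULL) {
  J <- as.matrix(J)
  if (nrow(J) < 2L) {
    stop("a similarity network needs at least 2 contexts", call. = FALSE)
  }
  g <- igraph::graph_from_adjacency_matrix(J, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g <- igraph::delete_edges(g, which(igraph::E(g)$weight <= 0))
  if (!is.null(bin)) g <- igraph::set_graph_attr(g, "bin", bin)
  g
}

metric_weights <- function(g, weighted) {
  if (weighted && "weight" %in% igraph::edge_attr_names(g)) NULL else NA
}

#' Network density
#'
#' Realised fraction of possible edges, `2m / (n (n - 1))`.
#'
#' @param g An undirected graph with at least 2 nodes.
#' @return Density in `[0, 1]`.
#' @export
net_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) stop("density is undefined for graphs with < 2 nodes",
                   call. = FALSE)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' Global clustering coefficient (triangle method)
#'
#' Transitivity: three times the number of triangles over the number of
#' connected triples, on the unweighted topology; 0 when the graph has
#' no connected triple.
#'
#' @param g An undirected graph.
#' @return Value in `[0, 1]`.
#' @export
clustering_global <- function(g) {
  t <- igraph::transitivity(g, type = "global")
  if (is.nan(t)) 0 else t
}

#' Average path length within components
#'
#' Mean unweighted shortest-path length over all reachable node pairs;
#' pairs in different components are excluded, so fragmented graphs get
#' the within-component average.
#'
#' @param g An undirected graph with at least 1 edge.
#' @param weighted Use edge weights as distances (off by default).
#' @return Average path length (>= 1).
#' @export
net_apl <- function(g, weighted = FALSE) {
  if (igraph::ecount(g) == 0L) {
    stop("average path length is undefined for an edgeless graph",
         call. = FALSE)
  }
  igraph::mean_distance(g, weights = metric_weights(g, weighted),
                        directed = FALSE, unconnected = TRUE)
}

#' Shortest-path betweenness centrality
#'
#' Standard unweighted betweenness; each unordered node pair counts
#' once, so the centre of a 5-node star scores 6.
#'
#' @param g An undirected graph.
#' @param weighted Use edge weights as distances (off by default).
#' @return Named numeric vector of raw pair counts.
#' @export
node_betweenness <- function(g, weighted = FALSE) {
  igraph::betweenness(g, weights = metric_weights(g, weighted),
                      directed = FALSE)
}

#' Eigenvector centrality
#'
#' Principal-eigenvector centrality on the unweighted topology, scaled
#' so the maximum is 1.
#'
#' @param g An undirected graph.
#' @param weighted Use edge weights (off by default).
#' @return Named numeric vector with maximum 1.
#' @export
node_eigenvector <- function(g, weighted = FALSE) {
  igraph::eigen_centrality(g, weights = metric_weights(g, weighted))$vector
}

#' Constant Potts Model quality of a partition
#'
#' `Q = sum_c [ w_in(c) - resolution * n_c (n_c - 1) / 2 ]`, where
#' `w_in(c)` is the total weight of edges inside community c. The
#' singleton partition scores exactly 0.
#'
#' @param g An undirected weighted graph.
#' @param membership Integer community labels, one per vertex.
#' @param resolution CPM resolution parameter.
#' @param weights Edge weights (defaults to the graph's `weight`
#'   attribute, else 1).
#' @return The raw CPM objective.
#' @export
cpm_quality <- function(g, membership, resolution,
                        weights = NULL) {
  if (is.null(weights)) {
    weights <- if ("weight" %in% igraph::edge_attr_names(g)) {
      igraph::E(g)$weight
    } else {
      rep(1, igraph::ecount(g))
    }
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  within <- membership[el[, 1L]] == membership[el[, 2L]]
  sizes <- tabulate(membership)
  sum(weights[within]) - resolution * sum(sizes * (sizes - 1) / 2)
}

#' Leiden community detection under the Constant Potts Model
#'
#' Runs the Leiden algorithm on the weighted graph with the CPM quality
#' function, restarting `restarts` times from the seeded random state
#' and keeping the best partition by CPM quality. The reported
#' `quality_norm` rescales the objective by the total edge weight, which
#' maps the returned (best) partition into `[0, 1]`: the singleton
#' partition scores 0 and a partition capturing all weight with no
#' penalty scores 1.
#'
#' @param g An undirected graph; edge weights are used when present.
#' @param resolution CPM resolution (default 0.02).
#' @param iterations Leiden iterations per restart (default 1000).
#' @param restarts Independent restarts (default 100).
#' @param seed Integer seed for the restart randomisation.
#' @return Object of class `leiden_partition`: list with `membership`
#'   (named integer vector), `n_communities`, `quality` (raw CPM),
#'   `quality_norm`, `resolution`.
#' @export
leiden_cpm <- function(g, resolution = 0.02, iterations = 1000,
                       restarts = 100, seed = 1) {
  n <- igraph::vcount(g)
  if (n < 1L) stop("empty graph", call. = FALSE)
  w <- if ("weight" %in% igraph::edge_attr_names(g)) {
    igraph::E(g)$weight
  } else {
    rep(1, igraph::ecount(g))
  }
  if (n == 1L) {
    memb <- stats::setNames(1L, igraph::V(g)$name)
    return(structure(list(membership = memb, n_communities = 1L,
                          quality = 0, quality_norm = NA_real_,
                          resolution = resolution),
                     class = "leiden_partition"))
  }
  set.seed(seed)
  best <- NULL
  best_q <- -Inf
  for (r in seq_len(restarts)) {
    cl <- igraph::cluster_leiden(g, objective_function = "CPM",
                                 weights = w, resolution = resolution,
                                 n_iterations = iterations)
    memb <- igraph::membership(cl)
    q <- cpm_quality(g, memb, resolution, weights = w)
    if (q > best_q) {
      best_q <- q
      best <- memb
    }
  }
  W <- sum(w)
  structure(list(membership = best,
                 n_communities = length(unique(best)),
                 quality = best_q,
                 quality_norm = if (W > 0) best_q / W else NA_real_,
                 resolution = resolution),
            class = "leiden_partition")
}

#' @export
print.leiden_partition <- function(x, ...) {
  cat(sprintf("Leiden/CPM partition: %d communities, quality %.4f (norm %.3f)\n",
              x$n_communities, x$quality,
              ifelse(is.na(x$quality_norm), NaN, x$quality_norm)))
  invisible(x)
}

#' Node turnover ratio between consecutive bins
#'
#' For each transition from bin t-1 to bin t with node sets `N_{t-1}` and
#' `N_t`: `created = |N_t \ N_{t-1}|`, `destroyed = |N_{t-1} \ N_t|`,
#' `ntr = (created - destroyed) / |N_t|`. Positive values signal node
#' creation, negative values destruction, 0 a balanced (or identical)
#' transition.
#'
#' @param node_sets Ordered (oldest first) named list of character
#'   vectors of node ids, one per bin.
#' @return Data frame `from,to,created,destroyed,n_nodes,ntr`, one row
#'   per transition.
#' @export
ntr <- function(node_sets) {
  if (length(node_sets) < 2L) {
    stop("node turnover needs at least 2 bins", call. = FALSE)
  }
  labs <- names(node_sets)
  if (is.null(labs)) labs <- as.character(seq_along(node_sets))
  rows <- lapply(seq_along(node_sets)[-1L], function(t) {
    prev <- unique(node_sets[[t - 1L]])
    curr <- unique(node_sets[[t]])
    if (length(curr) == 0L) {
      stop(sprintf("bin %s has an empty node set; turnover undefined",
                   labs[t]), call. = FALSE)
    }
    created <- length(setdiff(curr, prev))
    destroyed <- length(setdiff(prev, curr))
    data.frame(from = labs[t - 1L], to = labs[t],
               created = created, destroyed = destroyed,
               n_nodes = length(curr),
               ntr = (created - destroyed) / length(curr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Structural and node-level metric bundle for one network
#'
#' @param g An undirected (weighted) similarity network.
#' @param leiden List of Leiden settings
#'   (`resolution`, `iterations`, `restarts`, `seed`).
#' @param weighted Compute topological metrics on weights (off by
#'   default).
#' @return List with `n_nodes`, `n_edges`, `density`, `clustering`,
#'   `apl` (`NA` for edgeless graphs), `n_communities`, `leiden_quality`
#'   (normalised), `leiden_quality_raw`, `membership`, `betweenness`,
#'   `eigenvector`.
#' @export
network_metrics <- function(g,
                            leiden = list(resolution = 0.02,
                                          iterations = 1000,
                                          restarts = 100, seed = 1),
                            weighted = FALSE) {
  part <- leiden_cpm(g, resolution = leiden$resolution,
                     iterations = leiden$iterations,
                     restarts = leiden$restarts, seed = leiden$seed)
  has_edges <- igraph::ecount(g) > 0L
  list(n_nodes = igraph::vcount(g),
       n_edges = igraph::ecount(g),
       density = net_density(g),
       clustering = clustering_global(g),
       apl = if (has_edges) net_apl(g, weighted = weighted) else NA_real_,
       n_communities = part$n_communities,
       leiden_quality = part$quality_norm,
       leiden_quality_raw = part$quality,
       membership = part$membership,
       betweenness = node_betweenness(g, weighted = weighted),
       eigenvector = if (has_edges) node_eigenvector(g, weighted = weighted)
                     else stats::setNames(rep(0, igraph::vcount(g)),
                                          igraph::V(g)$name))
}
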