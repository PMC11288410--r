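# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles share no code with the package implementation:
# metrics are recomputed from adjacency matrices by enumeration and
# Floyd-Warshall.

oracle_density <- function(A) {
  n <- nrow(A)
  sum(A[upper.tri(A)] > 0) / (n * (n - 1) / 2)
}

oracle_clustering <- function(A) {
  A <- (A > 0) * 1
  n <- nrow(A)
  tri <- 0
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      if (A[i, j] && A[j, k] && A[i, k]) tri <- tri + 1
    }
  }
  deg <- rowSums(A)
  triples <- sum(choose(deg, 2))
  if (triples == 0) 0 else 3 * tri / triples
}

oracle_apl <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  d <- D[upper.tri(D)]
  d <- d[is.finite(d)]
  if (length(d) == 0) NA_real_ else mean(d)
}

oracle_jaccard <- function(a, b) {
  # a, b: integer index sets of present types
  u <- length(union(a, b))
  if (u == 0) 0 else length(intersect(a, b)) / u
}

# Adjacency matrix for edge mask over the upper-triangle pairs of n nodes.
mask_to_adj <- function(n, mask) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  A <- matrix(0, n, n)
  for (p in seq_len(nrow(pairs))) {
    if (bitwAnd(mask, bitwShiftL(1L, p - 1L)) != 0L) {
      A[pairs[p, 1L], pairs[p, 2L]] <- 1
      A[pairs[p, 2L], pairs[p, 1L]] <- 1
    }
  }
  A
}

adj_to_graph <- function(A) {
  rownames(A) <- colnames(A) <- paste0("v", seq_len(nrow(A)))
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# All set partitions of 1..n as membership vectors (restricted growth).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(memb, mx) {
    i <- length(memb) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- memb
      return(invisible(NULL))
    }
    for (g in seq_len(mx + 1L)) recurse(c(memb, g), max(mx, g))
  }
  recurse(integer(0), 0L)
  out
}

# Exhaustive best-CPM-quality search over all partitions of a small graph.
oracle_best_cpm <- function(g, resolution) {
  n <- igraph::vcount(g)
  w <- if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight
       else rep(1, igraph::ecount(g))
  el <- igraph::as_edgelist(g, names = FALSE)
  best_q <- -Inf
  best <- NULL
  for (memb in all_partitions(n)) {
    within <- memb[el[, 1L]] == memb[el[, 2L]]
    sizes <- tabulate(memb)
    q <- sum(w[within]) - resolution * sum(sizes * (sizes - 1) / 2)
    if (q > best_q) {
      best_q <- q
      best <- memb
    }
  }
  list(quality = best_q, membership = best,
       n_communities = length(unique(best)))
}

# A small assemblage fixture: `sets` is a named list context -> character
# vector of type codes; returns a binary matrix.
binary_from_sets <- function(sets) {
  types <- sort(unique(unlist(sets)))
  B <- t(vapply(sets, function(s) as.integer(types %in% s),
                integer(length(types))))
  colnames(B) <- types
  B
}

# Records data frame from per-context type-code count lists.
records_from_counts <- function(counts) {
  rows <- list()
  for (ctx in names(counts)) {
    for (tc in names(counts[[ctx]])) {
      k <- counts[[ctx]][[tc]]
      site_level <- strsplit(ctx, ":", fixed = TRUE)[[1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = site_level[1L], level_id = site_level[2L],
        type_code = rep(tc, k), context = ctx, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

membership_table <- function(...) {
  m <- list(...)
  data.frame(context = names(m),
             bins = vapply(m, paste, "", collapse = ";"),
             stringsAsFactors = FALSE)
}

complete_weight_matrix <- function(n, w = 0.5, names = NULL) {
  J <- matrix(w, n, n)
  diag(J) <- 1
  if (is.null(names)) names <- paste0("C", seq_len(n))
  dimnames(J) <- list(names, names)
  J
}
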