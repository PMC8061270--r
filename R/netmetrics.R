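#' Node metrics on a population graph
#'
#' Degree; closeness = 1 / (mean shortest-path distance to the reachable
#' nodes of the same component); betweenness on weighted shortest paths;
#' and eigenvector centrality computed per connected component on the
#' similarity-weighted adjacency (similarity = 1/weight, so strong genetic
#' connections score high), scaled to unit Euclidean norm within each
#' component. Isolated nodes carry NA closeness and NA eigenvector scores.
#' Higher closeness therefore means greater genetic distance to the rest of
#' the network; higher degree/betweenness/centrality mark gene-flow hubs.
#'
#' @param graph igraph population graph with edge weights (genetic
#'   distances).
#' @param weighted use edge weights (default TRUE); FALSE treats all edges
#'   as unit length.
#' @return data.frame: locale_id, degree, closeness, betweenness,
#'   eigenvector.
#' @export
node_metrics <- function(graph, weighted = TRUE) {
  if (igraph::vcount(graph) == 0) stop_popland("empty graph")
  data.frame(locale_id = igraph::V(graph)$name %||%
               as.character(seq_len(igraph::vcount(graph))),
             degree = compute_metric(graph, "degree", weighted),
             closeness = compute_metric(graph, "closeness", weighted),
             betweenness = compute_metric(graph, "betweenness", weighted),
             eigenvector = compute_metric(graph, "eigenvector", weighted),
             row.names = NULL)
}

# One node-metric vector; factored out so permutation replicates pay only
# for the metric under test.
compute_metric <- function(graph, metric, weighted = TRUE) {
  has_w <- weighted && igraph::ecount(graph) > 0 &&
    "weight" %in% igraph::edge_attr_names(graph)
  w <- if (has_w) igraph::E(graph)$weight else NA
  nv <- igraph::vcount(graph)
  switch(metric,
    degree = igraph::degree(graph),
    betweenness = igraph::betweenness(graph, weights = w, directed = FALSE),
    closeness = {
      dmat <- igraph::distances(graph, weights = w)
      vapply(seq_len(nv), function(i) {
        di <- dmat[i, -i]
        di <- di[is.finite(di)]
        if (!length(di)) NA_real_ else 1 / mean(di)
      }, numeric(1))
    },
    eigenvector = {
      adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE,
                                         attr = if (has_w) "weight" else NULL)
      sim <- if (has_w) ifelse(adj > 0, 1 / adj, 0) else (adj > 0) * 1
      ev <- rep(NA_real_, nv)
      comp <- igraph::components(graph)
      for (cid in seq_len(comp$no)) {
        members <- which(comp$membership == cid)
        if (length(members) == 1) next
        e <- eigen(sim[members, members, drop = FALSE], symmetric = TRUE)
        v <- e$vectors[, 1]
        ev[members] <- abs(v) / sqrt(sum(v^2))
      }
      ev
    },
    stop_popland("unknown metric '%s'", metric))
}

# Counted double-edge-swap rewiring: performs `nswaps` successful swaps
# (pick two edges a-b, c-d with four distinct endpoints, replace by a-d,
# c-b or a-c, b-d; reject self-loops and multi-edges). Operates on an
# integer edge matrix; O(1) per attempt via a logical adjacency matrix,
# with randomness drawn in blocks to keep the attempt loop cheap.
double_edge_swap <- function(el, k, nswaps, max_attempts = NULL) {
  m <- nrow(el)
  if (m < 2) stop_popland("degree-preserving null needs >= 2 edges")
  max_attempts <- max_attempts %||% max(200L * nswaps, 1000L)
  adj <- matrix(FALSE, k, k)
  adj[el] <- TRUE; adj[el[, 2:1, drop = FALSE]] <- TRUE
  done <- 0L; tries <- 0L
  block <- 512L
  repeat {
    i1 <- sample.int(m, block, replace = TRUE)
    i2 <- sample.int(m, block, replace = TRUE)
    flip <- stats::runif(block) < 0.5
    for (bb in seq_len(block)) {
      tries <- tries + 1L
      if (tries > max_attempts)
        stop_popland("graph admits no further double-edge swaps (%d of %d done)",
                     done, nswaps)
      ia <- i1[bb]; ib <- i2[bb]
      if (ia == ib) next
      a <- el[ia, 1L]; b <- el[ia, 2L]
      if (flip[bb]) { c <- el[ib, 2L]; d <- el[ib, 1L] }
      else { c <- el[ib, 1L]; d <- el[ib, 2L] }
      if (a == c || a == d || b == c || b == d) next
      if (adj[a, d] || adj[c, b]) next
      adj[a, b] <- FALSE; adj[b, a] <- FALSE
      adj[c, d] <- FALSE; adj[d, c] <- FALSE
      adj[a, d] <- TRUE; adj[d, a] <- TRUE
      adj[c, b] <- TRUE; adj[b, c] <- TRUE
      el[ia, 1L] <- a; el[ia, 2L] <- d
      el[ib, 1L] <- c; el[ib, 2L] <- b
      done <- done + 1L
      if (done >= nswaps) return(el)
    }
  }
}

# One null-model replicate: a rewired edge matrix on the same node set.
null_graph_edges <- function(el, k, null_model, n_swaps_factor = 10L) {
  m <- nrow(el)
  if (null_model == "edge_permutation") {
    # uniform simple graph with the same node set and edge count
    all_pairs <- pair_index(k)
    pick <- sample.int(nrow(all_pairs), m)
    all_pairs[pick, , drop = FALSE]
  } else {
    double_edge_swap(el, k, n_swaps_factor * m)
  }
}

#' Permutation test of a network node metric
#'
#' The observed statistic is the mean of a node metric over a focus subset
#' of locales. Null replicates randomize the graph topology while the node
#' set stays fixed: `edge_permutation` draws a uniformly random simple
#' graph with the same node set and edge count; `degree_preserving`
#' performs at least 10 x |E| successful double-edge swaps, preserving the
#' exact degree sequence. In both nulls the observed edge-weight multiset
#' is retained and reassigned to the new edges by random permutation, so
#' the metric scale stays comparable between observed and null.
#'
#' @param graph igraph population graph.
#' @param metric one of "degree", "closeness", "betweenness",
#'   "eigenvector".
#' @param focus character vector of locale ids (default: all nodes).
#' @param n_perm replicates (default 1000).
#' @param seed integer seed.
#' @param null_model "edge_permutation" or "degree_preserving".
#' @param tail "two-sided" (default), "lower" or "upper".
#' @param weighted pass-through to [node_metrics()].
#' @return a `perm_result`.
#' @export
metric_permutation_test <- function(graph, metric = c("degree", "closeness",
                                                      "betweenness", "eigenvector"),
                                    focus = NULL, n_perm = 1000L, seed = 1L,
                                    null_model = c("edge_permutation",
                                                   "degree_preserving"),
                                    tail = "two-sided", weighted = TRUE) {
  metric <- match.arg(metric)
  null_model <- match.arg(null_model)
  if (n_perm < 1) stop_popland("n_perm must be >= 1")
  ids <- igraph::V(graph)$name
  focus <- focus %||% ids
  if (!length(focus) || !all(focus %in% ids))
    stop_popland("focus must be a nonempty subset of graph locales")
  fidx <- match(focus, ids)
  k <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  storage.mode(el) <- "integer"
  wts <- igraph::E(graph)$weight
  focus_mean <- function(v) {
    v <- v[fidx]
    if (anyNA(v)) {
      warning("focus includes nodes with undefined ", metric, "; excluded from mean")
      v <- v[!is.na(v)]
    }
    if (!length(v)) NA_real_ else mean(v)
  }
  observed <- focus_mean(compute_metric(graph, metric, weighted))
  set.seed(derive_seed(seed, 6L))
  nulls <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    nel <- null_graph_edges(el, k, null_model)
    ng <- igraph::make_empty_graph(n = k, directed = FALSE)
    ng <- igraph::add_edges(ng, t(nel))
    igraph::V(ng)$name <- ids
    igraph::E(ng)$weight <- wts[sample.int(length(wts))]
    nulls[b] <- suppressWarnings(focus_mean(compute_metric(ng, metric, weighted)))
  }
  perm_result(observed, nulls, tail = tail, seed = seed,
              null_model = null_model)
}

#' Write a node-metric table as CSV
#' @param metrics data.frame from [node_metrics()].
#' @param path output path.
#' @export
write_node_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
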