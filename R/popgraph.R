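#' Encode genotypes as centered allele-dosage columns
#'
#' Per polymorphic locus, the dosage of each non-reference allele becomes a
#' numeric column (for biallelic SNPs: one column per locus; the reference
#' allele column is dropped to avoid exact collinearity); rows are
#' individuals. Columns are centered on the grand mean. Monomorphic loci
#' contribute no columns. Missing dosages are mean-imputed per locus before
#' centering so the downstream covariance stays well defined.
#'
#' @param dataset an `snp_dataset`.
#' @return numeric matrix (samples x encoded columns) of class
#'   `encoded_genotypes`, with attribute `locale_id`.
#' @export
encode_alleles <- function(dataset) {
  poly <- !monomorphic_loci(dataset)
  if (!any(poly)) stop_popland("no polymorphic loci to encode")
  g <- dataset$geno[, poly, drop = FALSE]
  storage.mode(g) <- "double"
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- mu[idx[, 2]]
  }
  g <- scale(g, center = TRUE, scale = FALSE)
  structure(g, locale_id = dataset$locale_id, class = c("encoded_genotypes", "matrix"))
}

#' Among-locale genetic covariance by Gower double-centering
#'
#' Locale centroids are the mean encoded vectors per locale; D2 holds the
#' squared Euclidean distances among centroids; the covariance is
#' C = -1/2 J D2 J with J = I - 11'/K the centering projector (so rows of C
#' sum to zero and d2_ij = c_ii + c_jj - 2 c_ij recovers D2 exactly).
#'
#' @param encoded an `encoded_genotypes` matrix (or any numeric matrix with
#'   a `locale_id` attribute / paired `locales` argument).
#' @param locales optional `locale_frame`; defaults to the locales carried
#'   on `encoded`. Must have >= 3 locales for a meaningful graph.
#' @return object of class `locale_covariance`: list(ids, C, D2, shrinkage).
#' @export
locale_covariance <- function(encoded, locales = NULL) {
  loc <- attr(encoded, "locale_id")
  if (is.null(loc)) stop_popland("encoded matrix lacks locale assignment")
  ids <- if (!is.null(locales)) locales$locale_id else sort(unique(loc))
  if (length(ids) < 3) stop_popland("population graph needs >= 3 locales")
  f <- factor(loc, levels = ids)
  if (anyNA(f)) stop_popland("locale ids in data not covered by locale frame")
  centroids <- rowsum(unclass(encoded), f) / as.vector(table(f))
  d2 <- as.matrix(stats::dist(centroids))^2
  k <- length(ids)
  j <- diag(k) - matrix(1 / k, k, k)
  c_mat <- -0.5 * j %*% d2 %*% j
  c_mat <- (c_mat + t(c_mat)) / 2
  dimnames(c_mat) <- dimnames(d2) <- list(ids, ids)
  structure(list(ids = ids, C = c_mat, D2 = d2, shrinkage = 0),
            class = "locale_covariance")
}

# Precision (concentration) matrix via eigendecomposition. The Gower
# centering leaves an exact null direction (the all-ones vector), which is
# excluded before inversion; if the retained spectrum is still
# ill-conditioned, a diagonal shrinkage delta doubling from 1e-8 to 1e-2 is
# applied until the condition number drops below 1e10.
precision_matrix <- function(c_mat, cond_max = 1e10) {
  e <- eigen(c_mat, symmetric = TRUE)
  lmax <- max(e$values)
  if (lmax <= 0) stop_popland("covariance has no positive eigenvalues")
  keep <- e$values > lmax * 1e-10
  lam <- e$values[keep]
  delta <- 0
  if (max(lam) / min(lam) > cond_max) {
    delta <- 1e-8
    while (delta <= 1e-2 && (max(lam) + delta) / (min(lam) + delta) > cond_max)
      delta <- delta * 2
    if ((max(lam) + delta) / (min(lam) + delta) > cond_max)
      stop_popland("covariance not invertible: condition number %.3g after maximum shrinkage",
                   max(lam) / min(lam))
    lam <- lam + delta
  }
  q <- e$vectors[, keep, drop = FALSE]
  omega <- q %*% (t(q) / lam)
  list(omega = (omega + t(omega)) / 2, shrinkage = delta)
}

#' Build a population graph by conditional-independence edge exclusion
#'
#' From the among-locale covariance, partial correlations rho_ij =
#' -Omega_ij / sqrt(Omega_ii Omega_jj) are computed from the precision
#' matrix Omega, and each potential edge is tested with the edge-exclusion
#' deviance EED = -n ln(1 - rho^2) against chi-square with 1 df. An edge is
#' retained iff its exclusion is rejected at `alpha`; its weight is the
#' genetic distance w_ij = sqrt(c_ii + c_jj - 2 c_ij). No multiple-testing
#' correction is applied across edges by default (mirroring the original
#' population-graph procedure); `bonferroni = TRUE` enables one.
#'
#' @param cov a `locale_covariance`, or a plain symmetric covariance matrix
#'   with dimnames.
#' @param alpha edge-exclusion significance level (default 0.05).
#' @param n sample size used in the deviance; defaults to the number of
#'   sampled individuals when the covariance carries one (attribute
#'   `n_samples`), and must be supplied otherwise. Must exceed the number
#'   of locales.
#' @param bonferroni divide alpha by the number of potential edges.
#' @return an igraph graph with vertex attribute `name` (locale ids), edge
#'   attributes `weight`, `partial_correlation`, `deviance`, `p`, and graph
#'   attributes `alpha`, `n`, `shrinkage`.
#' @export
prune_edges <- function(cov, alpha = 0.05, n, bonferroni = FALSE) {
  if (inherits(cov, "locale_covariance")) {
    c_mat <- cov$C; ids <- cov$ids
  } else {
    c_mat <- as.matrix(cov)
    ids <- rownames(c_mat) %||% sprintf("V%02d", seq_len(nrow(c_mat)))
  }
  k <- nrow(c_mat)
  if (missing(n)) stop_popland("supply n, the sample size behind the covariance")
  if (n < k + 1) stop_popland("n (%d) must be >= number of locales + 1 (%d)", n, k + 1)
  if (alpha < 0 || alpha > 1) stop_popland("alpha must lie in [0, 1]")
  pm <- precision_matrix(c_mat)
  om <- pm$omega
  d <- sqrt(diag(om))
  rho <- -om / tcrossprod(d)
  diag(rho) <- 1
  rho[abs(rho) > 1] <- sign(rho[abs(rho) > 1])  # numerical guard at +-1
  eed <- -n * log(pmax(1 - rho^2, .Machine$double.xmin))
  pval <- stats::pchisq(eed, df = 1, lower.tail = FALSE)
  thr <- if (bonferroni) alpha / (k * (k - 1) / 2) else alpha
  idx <- pair_index(k)
  keep <- pval[idx] <= thr
  w <- sqrt(pmax(outer(diag(c_mat), diag(c_mat), `+`) - 2 * c_mat, 0))
  el <- idx[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[el[, 1]], to = ids[el[, 2]],
               weight = w[el], partial_correlation = rho[el],
               deviance = eed[el], p = pval[el]),
    directed = FALSE,
    vertices = data.frame(name = ids)
  )
  g <- igraph::set_graph_attr(g, "alpha", alpha)
  g <- igraph::set_graph_attr(g, "n", n)
  igraph::set_graph_attr(g, "shrinkage", pm$shrinkage)
}

#' Convenience wrapper: dataset to population graph
#'
#' Encodes alleles, forms the among-locale covariance and prunes edges,
#' with n defaulting to the number of sampled individuals.
#'
#' @param dataset an `snp_dataset`.
#' @param locales optional `locale_frame`.
#' @param alpha,bonferroni see [prune_edges()].
#' @param n deviance sample size (default: number of individuals).
#' @return list with `graph` (igraph) and `cov` (`locale_covariance`).
#' @export
build_popgraph <- function(dataset, locales = NULL, alpha = 0.05,
                           n = NULL, bonferroni = FALSE) {
  enc <- encode_alleles(dataset)
  cv <- locale_covariance(enc, locales)
  g <- prune_edges(cv, alpha = alpha, n = n %||% nrow(dataset$geno),
                   bonferroni = bonferroni)
  cv$shrinkage <- igraph::graph_attr(g, "shrinkage")
  list(graph = g, cov = cv)
}

#' Conditional genetic distance (cGD) matrix
#'
#' All-pairs shortest-path distances over the retained population-graph
#' edges using the genetic-distance edge weights. cGD summarizes
#' connectivity through the whole network: two locales are close when a
#' chain of significant conditional-covariance links connects them, not
#' merely when their pairwise dissimilarity is low. Unreachable pairs are
#' `Inf` in the returned matrix and written as NA by
#' [write_pairwise_csv()].
#'
#' @param graph an igraph population graph from [prune_edges()].
#' @return symmetric matrix with zero diagonal and attribute
#'   `statistic = "cGD"`.
#' @export
cgd_matrix <- function(graph) {
  if (igraph::vcount(graph) == 0) stop_popland("empty graph")
  d <- igraph::distances(graph, weights = igraph::E(graph)$weight)
  attr(d, "statistic") <- "cGD"
  d
}

#' Locales disconnected from the population graph
#'
#' Degree-zero nodes: locales whose allelic variation adds no conditional
#' information about the rest of the network (not "isolated" populations in
#' the demographic sense).
#'
#' @param graph an igraph population graph.
#' @return character vector of locale ids.
#' @export
isolated_nodes <- function(graph) {
  deg <- igraph::degree(graph)
  ids <- igraph::V(graph)$name %||% as.character(seq_along(deg))
  ids[deg == 0]
}

#' Export a population graph
#'
#' @param graph igraph population graph.
#' @param path output path.
#' @export
write_popgraph_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_popgraph_graphml
#' @export
write_edgelist_csv <- function(graph, path) {
  df <- igraph::as_data_frame(graph, what = "edges")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
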