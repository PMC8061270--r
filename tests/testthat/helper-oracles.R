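# Independent brute-force oracles used across the suite. These deliberately
# re-derive each statistic from first principles (pair enumeration, path
# enumeration, closed forms) and never call the package's own fast paths.

# Expand a dosage matrix into a per-locus list of allele vectors.
alleles_by_locus <- function(geno, ploidy) {
  lapply(seq_len(ncol(geno)), function(l) {
    d <- geno[, l]
    d <- d[!is.na(d)]
    if (ploidy == 1) d else unlist(lapply(d, function(x) c(rep(1, x), rep(0, ploidy - x))))
  })
}

# Mean pairwise difference count summed over loci, by full pair enumeration.
enum_pi_total <- function(geno, ploidy) {
  sum(vapply(alleles_by_locus(geno, ploidy), function(al) {
    n <- length(al)
    if (n < 2) return(0)
    tot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) tot <- tot + (al[i] != al[j])
    tot / (n * (n - 1) / 2)
  }, numeric(1)))
}

# Hudson FST by exhaustive within/between allele-pair enumeration,
# multi-locus ratio of averages.
enum_hudson_fst <- function(geno_a, geno_b, ploidy) {
  la <- alleles_by_locus(geno_a, ploidy)
  lb <- alleles_by_locus(geno_b, ploidy)
  num <- den <- 0
  for (l in seq_along(la)) {
    a <- la[[l]]; b <- lb[[l]]
    if (length(a) < 2 || length(b) < 2) next
    hw <- function(v) {
      n <- length(v); tot <- 0
      for (i in seq_len(n - 1)) for (j in (i + 1):n) tot <- tot + (v[i] != v[j])
      tot / (n * (n - 1) / 2)
    }
    hb <- mean(outer(a, b, `!=`))
    num <- num + hb - (hw(a) + hw(b)) / 2
    den <- den + hb
  }
  if (den == 0) NA_real_ else num / den
}

# Tajima's 1989 constants, transcribed independently of R/diversity.R.
oracle_tajima_d <- function(pi_total, s, n) {
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (pi_total - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}

# All simple paths between two nodes of a small weighted graph (adjacency
# matrix of weights, 0 = no edge), returning total lengths and node sets.
all_paths <- function(w, s, t) {
  n <- nrow(w)
  out <- list()
  walk <- function(path, len) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1]] <<- list(len = len, nodes = path)
      return()
    }
    for (u in seq_len(n)) {
      if (w[v, u] > 0 && !(u %in% path)) walk(c(path, u), len + w[v, u])
    }
  }
  walk(s, 0)
  out
}

# Exhaustive weighted betweenness / closeness for graphs with <= ~7 nodes.
enum_metrics <- function(w) {
  n <- nrow(w)
  btw <- numeric(n)
  dmat <- matrix(Inf, n, n); diag(dmat) <- 0
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(w, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, `[[`, numeric(1), "len")
    dmin <- min(lens)
    dmat[s, t] <- dmat[t, s] <- dmin
    geo <- paths[abs(lens - dmin) < 1e-9]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(geo, function(p) v %in% p$nodes, logical(1)))
      btw[v] <- btw[v] + through / length(geo)
    }
  }
  clo <- vapply(seq_len(n), function(i) {
    di <- dmat[i, -i]; di <- di[is.finite(di)]
    if (!length(di)) NA_real_ else 1 / mean(di)
  }, numeric(1))
  list(betweenness = btw, closeness = clo, dist = dmat)
}

# Small random toy dataset for oracle comparisons.
toy_dataset <- function(seed, n_locales = 3, n_per = 5, n_loci = 6, ploidy = 1) {
  set.seed(seed)
  geno <- matrix(rbinom(n_locales * n_per * n_loci, ploidy, runif(n_loci, 0.2, 0.8)),
                 nrow = n_locales * n_per, byrow = TRUE)
  snp_dataset(geno, rep(sprintf("P%d", seq_len(n_locales)), each = n_per),
              ploidy = ploidy)
}

# Weighted graph from an edge data frame, keeping isolated vertices.
graph_from_edges <- function(edges, ids, weights = NULL) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  if (!is.null(weights)) igraph::E(g)$weight <- weights
  g
}

# Build a symmetric locale matrix from a vector over upper-triangle pairs
# (column-major order; use named-pair assignment when row order matters).
pairs_to_matrix <- function(v, ids) {
  k <- length(ids)
  m <- matrix(0, k, k, dimnames = list(ids, ids))
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Simulate an MLPE-structured response over all pairs of k locales:
# y = slope * x + noise with cov sigma^2 (I + rho A), rows aligned with the
# pair table's membership.
simulate_mlpe <- function(k, slope, rho, sigma = 1, seed = 1) {
  set.seed(seed)
  ids <- sprintf("L%02d", seq_len(k))
  lf <- locale_frame(ids, stats::runif(k, 0, 100), stats::runif(k, 0, 100),
                     rep(4, k))
  geo <- geographic_distance_matrix(lf)
  tab0 <- build_pair_table(pairs_to_matrix(stats::rnorm(choose(k, 2)), ids), geo)
  a <- popland:::pair_sharing_matrix(tab0)
  ea <- eigen(a, symmetric = TRUE)
  noise <- ea$vectors %*% (sqrt(pmax(1 + rho * ea$values, 0)) *
                             stats::rnorm(nrow(tab0))) * sigma
  y <- slope * tab0$geo + drop(noise)
  m <- matrix(0, k, k, dimnames = list(ids, ids))
  m[cbind(tab0$locale_a, tab0$locale_b)] <- y
  m[cbind(tab0$locale_b, tab0$locale_a)] <- y
  list(table = build_pair_table(m, geo), geo = geo)
}
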