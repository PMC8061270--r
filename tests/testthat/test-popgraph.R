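test_that("allele encoding drops monomorphic loci and centers dosages", {
  # diploid AA, AT, TT at one biallelic locus -> centered column (-1, 0, 1)
  g <- cbind(c(0L, 1L, 2L), c(0L, 0L, 0L))  # second locus monomorphic
  ds <- snp_dataset(g, c("A", "B", "C"), ploidy = 2)
  enc <- encode_alleles(ds)
  expect_equal(ncol(enc), 1L)
  expect_equal(unname(enc[, 1]), c(-1, 0, 1))

  hap <- toy_dataset(2, ploidy = 1)
  e <- encode_alleles(hap)
  expect_true(all(abs(colSums(e)) < 1e-10))
  expect_true(all(hap$geno[, !monomorphic_loci(hap)] %in% 0:1))

  allmono <- snp_dataset(matrix(1L, 4, 3), rep(c("A", "B"), 2), ploidy = 1)
  expect_error(encode_alleles(allmono), "polymorphic")
})

test_that("Gower double-centering reproduces its matrix identity", {
  # 3 centroids at positions 0, 1, 2 on a line
  enc <- structure(matrix(c(0, 1, 2), ncol = 1),
                   locale_id = c("A", "B", "C"), class = c("encoded_genotypes", "matrix"))
  cv <- locale_covariance(enc)
  expect_equal(unname(cv$D2), rbind(c(0, 1, 4), c(1, 0, 1), c(4, 1, 0)))
  # independent double-centering: C = -1/2 (I - 11'/k) D2 (I - 11'/k)
  j <- diag(3) - 1 / 3
  expect_equal(cv$C, -(j %*% cv$D2 %*% j) / 2, ignore_attr = TRUE)
  expect_true(all(abs(rowSums(cv$C)) < 1e-10))

  # identical centroids -> zero covariance
  enc0 <- structure(matrix(1, 4, 2), locale_id = c("A", "B", "C", "D"),
                    class = c("encoded_genotypes", "matrix"))
  expect_true(all(abs(locale_covariance(enc0)$C) < 1e-12))
})

test_that("Gower identity holds on random datasets: D2 rebuilt from C", {
  for (seed in 1:5) {
    ds <- toy_dataset(seed, n_locales = 6, n_per = 5, n_loci = 30)
    cv <- locale_covariance(encode_alleles(ds))
    d2_back <- outer(diag(cv$C), diag(cv$C), `+`) - 2 * cv$C
    expect_equal(unname(d2_back), unname(cv$D2), tolerance = 1e-8)
  }
})

test_that("edge pruning spans its alpha limits and is monotone in alpha", {
  ds <- toy_dataset(9, n_locales = 6, n_per = 6, n_loci = 40)
  cv <- locale_covariance(encode_alleles(ds))
  n <- nrow(ds$geno)
  full <- prune_edges(cv, alpha = 1, n = n)
  expect_equal(igraph::ecount(full), choose(6, 2))  # complete graph
  empty <- prune_edges(cv, alpha = 1e-300, n = n)
  expect_equal(igraph::ecount(empty), 0)

  alphas <- c(0.001, 0.01, 0.05, 0.2, 1)
  sets <- lapply(alphas, function(a) {
    g <- prune_edges(cv, alpha = a, n = n)
    apply(igraph::as_edgelist(g), 1, function(r) paste(sort(r), collapse = "-"))
  })
  for (i in seq_len(length(alphas) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("pruning recovers a planted chain precision structure", {
  omega <- diag(4)
  omega[cbind(1:3, 2:4)] <- -0.5
  omega[cbind(2:4, 1:3)] <- -0.5
  ch <- chol(solve(omega))
  hits <- 0
  for (i in 1:100) {
    set.seed(i)
    x <- matrix(stats::rnorm(200 * 4), 200, 4) %*% ch
    cc <- stats::cov(x)
    dimnames(cc) <- list(paste0("V", 1:4), paste0("V", 1:4))
    g <- prune_edges(cc, alpha = 0.01, n = 200)
    el <- apply(igraph::as_edgelist(g), 1, paste, collapse = "-")
    hits <- hits + setequal(el, c("V1-V2", "V2-V3", "V3-V4"))
  }
  expect_gte(hits, 95)
})

test_that("deviance arithmetic: retained edges carry consistent statistics", {
  ds <- toy_dataset(12, n_locales = 5, n_per = 6, n_loci = 50)
  pg <- build_popgraph(ds, alpha = 0.5)
  g <- pg$graph
  n <- igraph::graph_attr(g, "n")
  rho <- igraph::E(g)$partial_correlation
  expect_equal(igraph::E(g)$deviance, -n * log(1 - rho^2))
  expect_equal(igraph::E(g)$p,
               stats::pchisq(-n * log(1 - rho^2), 1, lower.tail = FALSE))
  expect_true(all(igraph::E(g)$p <= 0.5))
  expect_true(all(abs(rho) <= 1))
  # weight is the centroid genetic distance
  el <- igraph::as_edgelist(g)
  cm <- pg$cov$C
  w_expect <- sqrt(cm[cbind(el[, 1], el[, 1])] + cm[cbind(el[, 2], el[, 2])] -
                     2 * cm[cbind(el[, 1], el[, 2])])
  expect_equal(igraph::E(g)$weight, unname(w_expect))
})

test_that("preconditions: small n, too few locales, invalid alpha", {
  ds <- toy_dataset(1, n_locales = 4, n_per = 3, n_loci = 10)
  cv <- locale_covariance(encode_alleles(ds))
  expect_error(prune_edges(cv, n = 4), "locales")
  expect_error(prune_edges(cv, alpha = 2, n = 50), "alpha")
  two <- snp_dataset(matrix(rbinom(20, 1, 0.5), 10), rep(c("A", "B"), 5), ploidy = 1)
  expect_error(locale_covariance(encode_alleles(two)), ">= 3 locales")
})

test_that("cGD: shortest paths, pruning detours, unreachable flags", {
  ids <- c("A", "B", "C")
  # triangle with weights 1, 1, 3; the weight-3 edge pruned -> cGD across = 2
  g <- graph_from_edges(data.frame(from = c("A", "B"), to = c("B", "C")),
                        ids, weights = c(1, 1))
  d <- cgd_matrix(g)
  expect_equal(d["A", "C"], 2)
  expect_equal(d["A", "B"], 1)

  # two nodes joined by one edge of weight w -> cGD = w
  g2 <- graph_from_edges(data.frame(from = "A", to = "B"), c("A", "B"),
                         weights = 2.5)
  expect_equal(cgd_matrix(g2)["A", "B"], 2.5)

  # isolated node -> unreachable (Inf internally, NA in exports)
  g3 <- graph_from_edges(data.frame(from = "A", to = "B"), ids, weights = 1)
  d3 <- cgd_matrix(g3)
  expect_true(is.infinite(d3["A", "C"]))
  td <- withr::local_tempdir()
  write_pairwise_csv(d3, file.path(td, "cgd.csv"))
  back <- utils::read.csv(file.path(td, "cgd.csv"))
  expect_true(is.na(back$C[1]))
  expect_identical(isolated_nodes(g3), "C")
  expect_identical(isolated_nodes(igraph::make_full_graph(4)), character(0))
})

test_that("cGD metric invariants hold on random popgraphs", {
  for (seed in 21:24) {
    ds <- toy_dataset(seed, n_locales = 7, n_per = 6, n_loci = 60)
    g <- build_popgraph(ds, alpha = 0.4)$graph
    d <- cgd_matrix(g)
    expect_equal(d, t(d), ignore_attr = TRUE)
    expect_true(all(diag(d) == 0))
    k <- nrow(d)
    # triangle inequality on reachable triples
    for (i in 1:k) for (j in 1:k) for (l in 1:k) {
      if (is.finite(d[i, l]) && is.finite(d[l, j]))
        expect_lte(d[i, j], d[i, l] + d[l, j] + 1e-10)
    }
    # cGD >= direct edge weight; equality when the edge is on a shortest path
    el <- igraph::as_edgelist(g)
    if (nrow(el)) {
      w <- igraph::E(g)$weight
      expect_true(all(d[el] <= w + 1e-10))
    }
  }
})

test_that("popgraph exports GraphML and edge-list CSV with attributes", {
  ds <- toy_dataset(5, n_locales = 5, n_per = 6, n_loci = 40)
  g <- build_popgraph(ds, alpha = 0.6)$graph
  td <- withr::local_tempdir()
  gm <- file.path(td, "g.graphml")
  write_popgraph_graphml(g, gm)
  gb <- igraph::read_graph(gm, format = "graphml")
  expect_equal(igraph::ecount(gb), igraph::ecount(g))
  expect_true(all(c("weight", "partial_correlation", "deviance", "p") %in%
                    igraph::edge_attr_names(gb)))
  ec <- file.path(td, "edges.csv")
  write_edgelist_csv(g, ec)
  df <- utils::read.csv(ec)
  expect_equal(nrow(df), igraph::ecount(g))
})
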