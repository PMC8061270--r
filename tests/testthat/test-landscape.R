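test_that("geographic distances: euclidean and haversine closed forms", {
  lf <- locale_frame(c("A", "B", "C"), x = c(0, 3, 0), y = c(0, 4, 0) ,
                     n_samples = c(2, 2, 2))
  expect_warning(d <- geographic_distance_matrix(lf), "duplicate")
  expect_equal(d["A", "B"], 5)       # 3-4-5 triangle
  expect_equal(d["A", "C"], 0)
  expect_equal(d, t(d), ignore_attr = TRUE)
  expect_true(all(diag(d) == 0))

  lf2 <- locale_frame(c("P", "Q"), x = c(0, 1), y = c(0, 0), n_samples = c(2, 2))
  h <- geographic_distance_matrix(lf2, mode = "haversine")
  # one degree of longitude on the equator: 2 pi R / 360, R = 6371 km
  expect_equal(h["P", "Q"], 2 * pi * 6371 / 360, tolerance = 1e-4)
})

test_that("supercover transect: degenerate, constant and gradient cases", {
  r <- make_landscape(c(10, 10), "constant", params = list(value = 5))
  tr <- extract_transect(r, c(3.2, 4.7), c(3.2, 4.7))
  expect_equal(tr$values, 5)
  expect_equal(nrow(tr$cells), 1L)

  tr2 <- extract_transect(r, c(0.5, 0.5), c(9.5, 9.5))
  expect_true(all(tr2$values == 5))

  g <- make_landscape(c(20, 100), "gradient",
                      params = list(direction = "east", range = c(0, 100)))
  tr3 <- extract_transect(g, c(10.5, 10), c(90.5, 10))
  # horizontal transect across a column gradient: arithmetic progression
  expect_equal(diff(tr3$values), rep(100 / 99, length(tr3$values) - 1))
  expect_lt(abs(mean(tr3$values) - 100 * 50 / 99), 100 / 99 / 2 + 1e-9)

  expect_error(extract_transect(g, c(-5, 10), c(50, 10)), "extent")
})

test_that("supercover traversal is symmetric and covers touched pixels", {
  r <- make_landscape(c(30, 30), "gradient", params = list(range = c(0, 1)))
  set.seed(33)
  for (i in 1:25) {
    a <- stats::runif(2, 0.2, 29.8); b <- stats::runif(2, 0.2, 29.8)
    f <- extract_transect(r, a, b)
    rv <- extract_transect(r, b, a)
    kf <- paste(f$cells[, 1], f$cells[, 2])
    kr <- paste(rv$cells[, 1], rv$cells[, 2])
    expect_setequal(kf, kr)
    expect_identical(kf, rev(kr))
    # path is contiguous: consecutive cells share a side or corner
    if (nrow(f$cells) > 1) {
      step <- abs(diff(f$cells[, 1])) + abs(diff(f$cells[, 2]))
      expect_true(all(step >= 1 & step <= 2))
    }
  }
})

test_that("edge resistance summaries: constant, gradient and nodata handling", {
  lf <- locale_frame(c("A", "B", "C", "D"), x = c(5.5, 45.5, 5.5, 45.5),
                     y = c(10, 10, 30, 30), n_samples = rep(2, 4))
  cr <- make_landscape(c(50, 50), "constant", params = list(value = 3))
  es <- edge_resistance_summary(cr, rbind(c("A", "B"), c("C", "D")), lf)
  expect_equal(es$mean, c(3, 3))
  expect_equal(es$variance, c(0, 0))
  expect_false(any(es$missing))

  # two parallel equal-length transects on a gradient: different means,
  # equal variances
  g <- make_landscape(c(50, 50), "gradient",
                      params = list(direction = "north", range = c(0, 100)))
  eg <- edge_resistance_summary(g, rbind(c("A", "B"), c("C", "D")), lf)
  expect_true(abs(eg$mean[1] - eg$mean[2]) > 1)
  expect_equal(eg$variance[1], eg$variance[2])

  # nodata excluded; n_pixels reflects the retained count
  vals <- matrix(2, 20, 20); vals[, 8:10] <- -9999
  nr <- raster_layer(vals)
  lf2 <- locale_frame(c("P", "Q"), x = c(0.5, 19.5), y = c(10.5, 10.5),
                      n_samples = c(2, 2))
  en <- edge_resistance_summary(nr, rbind(c("P", "Q")), lf2)
  expect_equal(en$n_pixels, 17)
  expect_equal(en$mean, 2)

  # fully-nodata edge flagged missing, not an error at summary level
  allna <- raster_layer(matrix(-9999, 5, 5))
  lf3 <- locale_frame(c("P", "Q"), x = c(0.5, 4.5), y = c(2.5, 2.5),
                      n_samples = c(2, 2))
  em <- edge_resistance_summary(allna, rbind(c("P", "Q")), lf3)
  expect_true(em$missing)
  expect_true(is.na(em$mean))

  expect_error(
    edge_resistance_summary(
      make_landscape(c(5, 5), "categorical_patches", params = list(seed = 1)),
      rbind(c("P", "Q")), lf3),
    "continuous")
})

test_that("categorical profiles: proportions over classes, boundary geometry", {
  # half-plane two-class raster; transect crossing the boundary at midpoint
  vals <- cbind(matrix(1, 20, 10), matrix(2, 20, 10))
  r <- raster_layer(vals, kind = "categorical",
                    class_table = c("1" = "fynbos", "2" = "cultivation"))
  lf <- locale_frame(c("W", "E"), x = c(0.5, 19.5), y = c(10, 10),
                     n_samples = c(2, 2))
  pr <- categorical_edge_profile(r, rbind(c("W", "E")), lf)
  expect_equal(pr$prop_1 + pr$prop_2, 1)
  expect_lt(abs(pr$prop_1 - 0.5), 1 / pr$n_pixels + 1e-9)

  # single-class raster -> proportion 1
  r1 <- raster_layer(matrix(3, 10, 10), kind = "categorical")
  lf1 <- locale_frame(c("A", "B"), x = c(1, 9), y = c(5, 5), n_samples = c(2, 2))
  p1 <- categorical_edge_profile(r1, rbind(c("A", "B")), lf1)
  expect_equal(p1$prop_3, 1)

  # class present in raster but not on the transect -> proportion 0
  vals2 <- matrix(1, 10, 10); vals2[1, 1] <- 9
  r2 <- raster_layer(vals2, kind = "categorical")
  lf2 <- locale_frame(c("A", "B"), x = c(2, 9), y = c(3, 3), n_samples = c(2, 2))
  p2 <- categorical_edge_profile(r2, rbind(c("A", "B")), lf2)
  expect_equal(p2$prop_9, 0)
  expect_equal(p2$prop_1, 1)
})

test_that("landscape permutation: degenerate raster, determinism, aggregate invariance", {
  set.seed(12)
  k <- 10
  lf <- locale_frame(sprintf("L%02d", 1:k), stats::runif(k, 1, 39),
                     stats::runif(k, 1, 39), rep(2, k))
  g0 <- igraph::sample_gnm(k, 16)
  g <- graph_from_edges(igraph::as_data_frame(g0, "edges") |>
                          transform(from = sprintf("L%02d", as.integer(from)),
                                    to = sprintf("L%02d", as.integer(to))),
                        lf$locale_id, weights = stats::runif(16, 0.5, 2))
  cr <- make_landscape(c(40, 40), "constant", params = list(value = 7))
  suppressMessages(
    t1 <- landscape_permutation_test(g, cr, lf, "mean", n_perm = 30, seed = 2))
  expect_equal(t1$p_value, 1)           # observed equals every replicate
  expect_true(all(t1$null_values == t1$observed))

  gr <- make_landscape(c(40, 40), "gradient", params = list(range = c(0, 10)))
  t2 <- landscape_permutation_test(g, gr, lf, "mean", n_perm = 60, seed = 5)
  t3 <- landscape_permutation_test(g, gr, lf, "mean", n_perm = 60, seed = 5)
  expect_identical(t2$null_values, t3$null_values)
  expect_identical(t2$p_value, t3$p_value)
  expect_identical(t2$null_model, "degree_preserving_rewire")

  # aggregate statistic invariant to edge ordering
  perm <- sample(igraph::ecount(g))
  el <- igraph::as_data_frame(g, "edges")[perm, ]
  g_perm <- graph_from_edges(el[, 1:2], lf$locale_id, weights = el$weight)
  t4 <- landscape_permutation_test(g_perm, gr, lf, "mean", n_perm = 60, seed = 5)
  expect_equal(t4$observed, t2$observed)

  # variance and category statistics run end to end
  t5 <- landscape_permutation_test(g, gr, lf, "variance", n_perm = 20, seed = 1)
  expect_s3_class(t5, "perm_result")
  catr <- make_landscape(c(40, 40), "categorical_patches",
                         params = list(n_classes = 3, seed = 9))
  t6 <- landscape_permutation_test(g, catr, lf, "category:1", n_perm = 20, seed = 1)
  expect_gte(t6$p_value, 0)
  expect_error(landscape_permutation_test(g, catr, lf, "category:99",
                                          n_perm = 5, seed = 1), "absent")
})

test_that("barrier fixture: cross-barrier depression is detected, lower tail", {
  sc <- syn_scenario(n_locales = 20, samples_per_locale = 6, n_loci = 200,
                     fst_target = 0.05, seed = 77)
  bs <- simulate_barrier_scenario(sc, 0.4)
  pg <- build_popgraph(bs$dataset, bs$locales, alpha = 0.05)
  tst <- landscape_permutation_test(pg$graph, bs$raster, bs$locales, "mean",
                                    n_perm = 199, seed = 3, tail = "lower")
  expect_lte(tst$p_value, 0.05)
  expect_lt(tst$observed, mean(tst$null_values))
})
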