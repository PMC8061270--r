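#' Geographic distance matrix among locales
#'
#' Euclidean mode treats coordinates as planar map units (the replication
#' default; the study computed Euclidean distances on coordinates as
#' given). Haversine mode interprets (x, y) as (longitude, latitude) in
#' degrees and returns great-circle distances in kilometres (R = 6371 km).
#'
#' @param locales a `locale_frame`.
#' @param mode "euclidean" or "haversine".
#' @return symmetric zero-diagonal matrix with locale dimnames and
#'   attribute `statistic = "geographic_distance"`.
#' @export
geographic_distance_matrix <- function(locales, mode = c("euclidean", "haversine")) {
  mode <- match.arg(mode)
  xy <- cbind(locales$x, locales$y)
  if (anyDuplicated(xy))
    warning("duplicate locale coordinates: zero distances present")
  d <- if (mode == "euclidean") {
    as.matrix(stats::dist(xy))
  } else {
    m <- geosphere::distm(xy, xy, fun = function(p1, p2)
      geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
    dimnames(m) <- NULL
    m
  }
  dimnames(d) <- list(locales$locale_id, locales$locale_id)
  attr(d, "statistic") <- "geographic_distance"
  d
}

resolve_pairs <- function(graph_or_pairs, locales) {
  if (inherits(graph_or_pairs, "igraph")) {
    el <- igraph::as_edgelist(graph_or_pairs)
    if (nrow(el) < 1) stop_popland("graph has no edges")
  } else {
    el <- as.matrix(graph_or_pairs)
    if (ncol(el) != 2) stop_popland("pairs must be a 2-column matrix of locale ids")
  }
  if (!all(el %in% locales$locale_id))
    stop_popland("edge locales missing from locale frame")
  el
}

transect_stats <- function(raster, locales, a_id, b_id) {
  ia <- match(a_id, locales$locale_id); ib <- match(b_id, locales$locale_id)
  tr <- extract_transect(raster, c(locales$x[ia], locales$y[ia]),
                         c(locales$x[ib], locales$y[ib]))
  v <- tr$values
  if (!length(v)) {
    return(list(n_pixels = 0L, mean = NA_real_, variance = NA_real_,
                values = v, missing = TRUE))
  }
  list(n_pixels = length(v), mean = mean(v),
       variance = sum((v - mean(v))^2) / length(v),  # population variance
       values = v, missing = FALSE)
}

#' Per-edge resistance summaries on a continuous raster
#'
#' For each locale pair, the mean and population variance of the raster
#' pixel values along the straight-line supercover transect between the
#' two locales. The mean captures the typical resistance along the
#' connection; the variance captures topographic change between the
#' endpoints that a simple endpoint difference would miss. Nodata pixels
#' are excluded; an edge is flagged missing only when its transect is
#' entirely nodata.
#'
#' @param raster a continuous `raster_layer`.
#' @param graph_or_pairs an igraph graph (edges are used) or a 2-column
#'   matrix/data.frame of locale-id pairs.
#' @param locales a `locale_frame` sharing the raster CRS.
#' @return data.frame: locale_a, locale_b, n_pixels, mean, variance,
#'   missing.
#' @export
edge_resistance_summary <- function(raster, graph_or_pairs, locales) {
  stopifnot(inherits(raster, "raster_layer"))
  if (raster$kind != "continuous")
    stop_popland("mean/variance resistance requires a continuous raster; use categorical_edge_profile()")
  validate_locales_on_raster(raster, locales)
  el <- resolve_pairs(graph_or_pairs, locales)
  rows <- lapply(seq_len(nrow(el)), function(i) {
    st <- suppressWarnings(transect_stats(raster, locales, el[i, 1], el[i, 2]))
    data.frame(locale_a = el[i, 1], locale_b = el[i, 2],
               n_pixels = st$n_pixels, mean = st$mean,
               variance = st$variance, missing = st$missing)
  })
  do.call(rbind, rows)
}

#' Per-edge class proportions on a categorical raster
#'
#' Fraction of traversed (non-nodata) pixels falling in each class along
#' each edge's transect. Class codes are never averaged (a mean of class
#' codes is meaningless); categorical layers are summarized by
#' proportions.
#'
#' @inheritParams edge_resistance_summary
#' @param raster a categorical `raster_layer`.
#' @return data.frame with locale_a, locale_b, n_pixels, missing, and one
#'   `prop_<code>` column per class present in the raster.
#' @export
categorical_edge_profile <- function(raster, graph_or_pairs, locales) {
  stopifnot(inherits(raster, "raster_layer"))
  if (raster$kind != "categorical")
    stop_popland("categorical profile requires a categorical raster")
  validate_locales_on_raster(raster, locales)
  el <- resolve_pairs(graph_or_pairs, locales)
  vals <- raster$values[raster$values != raster$nodata & !is.na(raster$values)]
  classes <- sort(unique(as.integer(vals)))
  rows <- lapply(seq_len(nrow(el)), function(i) {
    st <- suppressWarnings(transect_stats(raster, locales, el[i, 1], el[i, 2]))
    props <- if (st$n_pixels > 0)
      vapply(classes, function(cl) mean(st$values == cl), numeric(1))
    else rep(NA_real_, length(classes))
    out <- data.frame(locale_a = el[i, 1], locale_b = el[i, 2],
                      n_pixels = st$n_pixels, missing = st$missing)
    out[paste0("prop_", classes)] <- as.list(props)
    out
  })
  do.call(rbind, rows)
}

validate_locales_on_raster <- function(raster, locales) {
  inside <- point_in_raster(raster, locales$x, locales$y)
  if (!all(inside))
    stop_popland("locales outside raster extent (no reprojection performed): %s",
                 paste(locales$locale_id[!inside], collapse = ", "))
  invisible(TRUE)
}

#' Precompute a per-pair transect statistic for every locale pair
#'
#' K x K lookup of a transect statistic ("mean", "variance" or
#' "category:<code>") over all unordered locale pairs. Used as the
#' per-pair predictor source for MLPE tables and to make permutation
#' replicates re-aggregation-only.
#'
#' @param raster a `raster_layer`.
#' @param locales a `locale_frame`.
#' @param statistic "mean", "variance", or "category:<code>".
#' @return symmetric matrix with locale dimnames (NA diagonal).
#' @export
pair_stat_matrix <- function(raster, locales, statistic) {
  k <- nrow(locales)
  idx <- pair_index(k)
  pairs <- cbind(locales$locale_id[idx[, 1]], locales$locale_id[idx[, 2]])
  if (startsWith(statistic, "category:")) {
    code <- sub("^category:", "", statistic)
    prof <- categorical_edge_profile(raster, pairs, locales)
    col <- paste0("prop_", code)
    if (!col %in% names(prof))
      stop_popland("class code %s absent from raster", code)
    v <- prof[[col]]
  } else {
    summ <- edge_resistance_summary(raster, pairs, locales)
    v <- summ[[statistic]]
  }
  m <- matrix(NA_real_, k, k, dimnames = list(locales$locale_id, locales$locale_id))
  m[idx] <- v; m[idx[, 2:1, drop = FALSE]] <- v
  m
}

#' Degree-constrained landscape permutation test
#'
#' Tests whether the landscape values traversed by the observed
#' population-graph edges differ from what random connectivity among the
#' same locales would traverse. The observed statistic is the mean over
#' the graph's edges of a per-edge transect statistic (transect mean,
#' transect variance, or a class proportion `"category:<code>"`). Null
#' replicates are degree-preserving rewirings (at least 10 x |E|
#' successful double-edge swaps; node positions fixed on the landscape)
#' whose edges are re-overlaid on the raster. Per-pair transect statistics
#' are precomputed once for all locale pairs, so replicates only
#' re-aggregate. p uses the add-one rule; default two-sided.
#'
#' @param graph igraph population graph (>= 2 edges).
#' @param raster a `raster_layer` (continuous for mean/variance,
#'   categorical for class statistics).
#' @param locales a `locale_frame`.
#' @param statistic "mean", "variance", or "category:<code>".
#' @param n_perm replicates (default 1000).
#' @param seed integer seed.
#' @param tail "two-sided" (default), "lower" or "upper".
#' @param pair_stats optional precomputed locale x locale lookup of the
#'   per-pair statistic (from [pair_stat_matrix()]); supplying it avoids
#'   re-traversing all transects when several tests share one raster.
#' @return a `perm_result` (null model "degree_preserving_rewire").
#' @export
landscape_permutation_test <- function(graph, raster, locales,
                                       statistic = "mean", n_perm = 1000L,
                                       seed = 1L, tail = "two-sided",
                                       pair_stats = NULL) {
  if (igraph::ecount(graph) < 2)
    stop_popland("graph needs >= 2 edges for the landscape permutation test")
  if (n_perm < 1) stop_popland("n_perm must be >= 1")
  ids <- igraph::V(graph)$name
  locales <- locales[match(ids, locales$locale_id), , drop = FALSE]
  if (anyNA(locales$locale_id))
    stop_popland("graph locales missing from locale frame")
  lut <- pair_stats %||% pair_stat_matrix(raster, locales, statistic)
  if (!identical(dimnames(lut), list(ids, ids)))
    lut <- lut[ids, ids]
  if (all(!is.finite(lut[upper.tri(lut)])))
    stop_popland("all locale pairs have missing transect statistics")
  el <- igraph::as_edgelist(graph, names = FALSE)
  storage.mode(el) <- "integer"
  agg <- function(e) mean(lut[e], na.rm = TRUE)
  observed <- agg(el)
  set.seed(derive_seed(seed, 7L))
  nulls <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    nel <- double_edge_swap(el, length(ids), 10L * nrow(el))
    nulls[b] <- agg(nel)
  }
  if (stats::var(nulls) == 0 && all(nulls == observed))
    message("degenerate raster statistic: observed equals every null replicate")
  perm_result(observed, nulls, tail = tail, seed = seed,
              null_model = "degree_preserving_rewire")
}
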