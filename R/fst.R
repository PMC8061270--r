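# Hudson-type FST components from per-locus allele counts of two locales.
# Hw (per locale) = 2 p (1-p) n/(n-1) -- the exact mean pairwise difference
# over within-locale allele pairs; Hb = p1(1-p2) + p2(1-p1) -- the exact
# mean over between-locale pairs. FST = 1 - mean(Hw)/Hb, multi-locus by
# ratio of averages: 1 - sum(Hw_bar)/sum(Hb).
hudson_components <- function(x1, n1, x2, n2) {
  ok <- n1 >= 2 & n2 >= 2
  p1 <- x1 / n1; p2 <- x2 / n2
  hw <- 0.5 * (2 * p1 * (1 - p1) * n1 / (n1 - 1) +
               2 * p2 * (1 - p2) * n2 / (n2 - 1))
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  hw[!ok] <- NA_real_; hb[!ok] <- NA_real_
  list(num = hb - hw, den = hb, usable = ok)
}

#' Hudson's FST between two locales
#'
#' Multi-locus Hudson-type estimator 1 - Hw/Hb, where Hw is the mean
#' within-locale pairwise difference (average of the two locales, each with
#' the unbiased n/(n-1) sample-size correction) and Hb the mean
#' between-locale pairwise difference, combined across loci as a ratio of
#' averages (sum of per-locus numerators over sum of denominators).
#' Negative values are reported as computed, never clamped. Loci missing in
#' more than `max_missing` of a locale's samples are dropped for that pair;
#' remaining missing genotypes use pairwise deletion.
#'
#' @param dataset an `snp_dataset`.
#' @param locale_a,locale_b locale ids.
#' @param max_missing per-locale missingness threshold above which a locus
#'   is dropped (default 0.5).
#' @return FST (scalar; NA with a warning when no locus is usable).
#' @export
hudson_fst <- function(dataset, locale_a, locale_b, max_missing = 0.5) {
  ac <- allele_counts(dataset)
  ia <- match(locale_a, ac$locales); ib <- match(locale_b, ac$locales)
  if (is.na(ia) || is.na(ib)) stop_popland("unknown locale id")
  n_max_a <- sum(dataset$locale_id == locale_a) * dataset$ploidy
  n_max_b <- sum(dataset$locale_id == locale_b) * dataset$ploidy
  keep <- ac$n[ia, ] >= (1 - max_missing) * n_max_a &
          ac$n[ib, ] >= (1 - max_missing) * n_max_b
  h <- hudson_components(ac$x[ia, keep], ac$n[ia, keep],
                         ac$x[ib, keep], ac$n[ib, keep])
  num <- sum(h$num[h$usable]); den <- sum(h$den[h$usable])
  if (!any(h$usable) || den == 0) {
    warning(sprintf("FST undefined for pair (%s, %s): no usable polymorphic loci",
                    locale_a, locale_b))
    return(NA_real_)
  }
  num / den
}

# Fast complete-data pairwise Hudson FST from count matrices (locales x loci).
# Returns list(fst = K x K matrix, num = per-pair summed numerators,
# den = per-pair summed denominators).
fst_matrix_from_counts <- function(x, n) {
  p <- x / n
  hw <- 2 * p * (1 - p) * n / (n - 1)       # locales x loci
  rw <- rowSums(hw)
  rp <- rowSums(p)
  ppt <- tcrossprod(p)
  hb <- outer(rp, rp, `+`) - 2 * ppt        # summed Hb over loci per pair
  hwbar <- outer(rw, rw, `+`) / 2
  num <- hb - hwbar
  fst <- num / hb
  diag(fst) <- NaN; diag(num) <- NA; diag(hb) <- NA
  list(fst = fst, num = num, den = hb)
}

#' All pairwise Hudson FST values and the global multi-locus FST
#'
#' Fills the symmetric locale x locale FST matrix (NaN diagonal) and the
#' global multi-locus value pooling all between-locale comparisons with the
#' same ratio-of-averages rule. With complete data a vectorized count-based
#' path is used; it is algebraically identical to per-pair
#' [hudson_fst()] calls.
#'
#' @param dataset an `snp_dataset`.
#' @param max_missing see [hudson_fst()].
#' @return matrix with attributes `statistic` ("hudson_fst") and `global`
#'   (pooled multi-locus FST).
#' @export
pairwise_fst_matrix <- function(dataset, max_missing = 0.5) {
  ac <- allele_counts(dataset)
  k <- length(ac$locales)
  if (k < 2) stop_popland("need >= 2 locales")
  if (!anyNA(dataset$geno)) {
    r <- fst_matrix_from_counts(ac$x, ac$n)
    m <- r$fst
    ut <- upper.tri(m)
    global <- sum(r$num[ut]) / sum(r$den[ut])
  } else {
    m <- matrix(NaN, k, k)
    num_tot <- den_tot <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      v <- tryCatch(hudson_fst(dataset, ac$locales[i], ac$locales[j], max_missing),
                    warning = function(w) {
                      warning(conditionMessage(w)); NA_real_
                    })
      m[i, j] <- m[j, i] <- v
      n_max_i <- sum(dataset$locale_id == ac$locales[i]) * dataset$ploidy
      n_max_j <- sum(dataset$locale_id == ac$locales[j]) * dataset$ploidy
      keep <- ac$n[i, ] >= (1 - max_missing) * n_max_i &
              ac$n[j, ] >= (1 - max_missing) * n_max_j
      h <- hudson_components(ac$x[i, keep], ac$n[i, keep],
                             ac$x[j, keep], ac$n[j, keep])
      num_tot <- num_tot + sum(h$num[h$usable])
      den_tot <- den_tot + sum(h$den[h$usable])
    }
    global <- if (den_tot > 0) num_tot / den_tot else NA_real_
  }
  dimnames(m) <- list(ac$locales, ac$locales)
  attr(m, "statistic") <- "hudson_fst"
  attr(m, "global") <- global
  m
}

#' Global multi-locus Hudson FST
#' @param dataset an `snp_dataset`.
#' @return scalar global FST (ratio of averages over all pairs and loci).
#' @export
global_fst <- function(dataset) {
  attr(pairwise_fst_matrix(dataset), "global")
}

#' Pooled-resampling permutation test of panmixia
#'
#' Pools all sampled individuals, then in each replicate reassigns them to
#' locales at random (without replacement, preserving every locale's sample
#' size; the exact permutation null) and recomputes all pairwise FST
#' values. Each pair's upper-tail p-value is (1 + #\{null FST >= observed\})
#' / (1 + n_perm). A with-replacement bootstrap resampling mode is
#' available behind `mode = "bootstrap"`.
#'
#' @param dataset an `snp_dataset` (complete data; the permutation engine
#'   requires no missing genotypes).
#' @param n_perm number of replicates (default 1000).
#' @param seed integer seed.
#' @param mode "permute" (default, without replacement) or "bootstrap".
#' @param keep_null retain the per-pair null matrix (pairs x n_perm).
#' @return object of class `panmixia_test`: `observed` and `p_value`
#'   locale x locale matrices, `global_observed`, `global_p`, plus the call
#'   parameters. Use [pair_perm_result()] to extract a single pair's
#'   `perm_result`.
#' @export
panmixia_permutation <- function(dataset, n_perm = 1000L, seed = 1L,
                                 mode = c("permute", "bootstrap"),
                                 keep_null = FALSE) {
  mode <- match.arg(mode)
  if (n_perm < 1) stop_popland("n_perm must be >= 1")
  if (anyNA(dataset$geno))
    stop_popland("panmixia permutation requires complete genotype data")
  loc <- factor(dataset$locale_id, levels = sort(unique(dataset$locale_id)))
  k <- nlevels(loc)
  g <- dataset$geno
  nvec <- as.vector(table(loc)) * dataset$ploidy
  count_mats <- function(labels) {
    x <- rowsum(g, labels)
    n <- matrix(nvec, k, ncol(g))
    list(x = x, n = n)
  }
  obs_c <- count_mats(loc)
  obs <- fst_matrix_from_counts(obs_c$x, obs_c$n)
  ut <- upper.tri(obs$fst)
  obs_pairs <- obs$fst[ut]
  obs_global <- sum(obs$num[ut]) / sum(obs$den[ut])
  set.seed(derive_seed(seed, 5L))
  n_samp <- nrow(g)
  ge_counts <- numeric(length(obs_pairs))
  ge_global <- 0
  null_mat <- if (keep_null) matrix(NA_real_, length(obs_pairs), n_perm) else NULL
  for (b in seq_len(n_perm)) {
    idx <- if (mode == "permute") sample.int(n_samp)
           else sample.int(n_samp, replace = TRUE)
    gg <- g[idx, , drop = FALSE]
    x <- rowsum(gg, loc)
    r <- fst_matrix_from_counts(x, matrix(nvec, k, ncol(g)))
    nullp <- r$fst[ut]
    ge_counts <- ge_counts + (nullp >= obs_pairs)
    ge_global <- ge_global + (sum(r$num[ut]) / sum(r$den[ut]) >= obs_global)
    if (keep_null) null_mat[, b] <- nullp
  }
  pmat <- matrix(NaN, k, k, dimnames = list(levels(loc), levels(loc)))
  pmat[ut] <- (1 + ge_counts) / (1 + n_perm)
  pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
  omat <- obs$fst
  dimnames(omat) <- dimnames(pmat)
  structure(
    list(observed = omat, p_value = pmat, global_observed = obs_global,
         global_p = (1 + ge_global) / (1 + n_perm),
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         mode = mode, null_values = null_mat,
         locales = levels(loc)),
    class = "panmixia_test"
  )
}

#' @export
print.panmixia_test <- function(x, ...) {
  cat(sprintf("Panmixia permutation test (%s, %d replicates, seed %d)\n",
              x$mode, x$n_perm, x$seed))
  cat(sprintf("  global FST = %.4f (p = %.4g)\n", x$global_observed, x$global_p))
  cat(sprintf("  %d locale pairs; %d with p <= 0.05\n",
              sum(upper.tri(x$p_value)),
              sum(x$p_value[upper.tri(x$p_value)] <= 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Extract one locale pair's permutation result
#'
#' Requires the test to have been run with `keep_null = TRUE`.
#'
#' @param test a `panmixia_test`.
#' @param locale_a,locale_b locale ids.
#' @return a `perm_result`.
#' @export
pair_perm_result <- function(test, locale_a, locale_b) {
  stopifnot(inherits(test, "panmixia_test"))
  if (is.null(test$null_values))
    stop_popland("run panmixia_permutation with keep_null = TRUE")
  k <- length(test$locales)
  i <- match(locale_a, test$locales); j <- match(locale_b, test$locales)
  if (is.na(i) || is.na(j)) stop_popland("unknown locale id")
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  ut <- which(upper.tri(matrix(0, k, k)))
  row <- match((j - 1) * k + i, ut)
  perm_result(test$observed[i, j], test$null_values[row, ],
              tail = "upper", seed = test$seed,
              null_model = paste0("panmixia_", test$mode))
}

#' Write a pairwise matrix as CSV
#' @param m matrix with dimnames (e.g. from [pairwise_fst_matrix()]).
#' @param path output CSV; non-finite entries are written as NA.
#' @export
write_pairwise_csv <- function(m, path) {
  mm <- as.data.frame(m)
  mm[!vapply(mm, is.finite, logical(nrow(mm)))] <- NA
  utils::write.csv(cbind(locale_id = rownames(m), mm), path, row.names = FALSE)
  invisible(path)
}
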