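# Mean pairwise difference count per locus from allele counts.
# x alt alleles among n: E(diff over all n(n-1)/2 allele pairs) = 2x(n-x)/(n(n-1)).
locus_pi <- function(x, n) {
  out <- rep(0, length(x))
  ok <- n >= 2
  out[ok] <- 2 * x[ok] * (n[ok] - x[ok]) / (n[ok] * (n[ok] - 1))
  out[!ok] <- NA_real_
  out
}

group_counts <- function(dataset, group) {
  if (is.null(group) || identical(group, "all")) {
    keep <- rep(TRUE, length(dataset$locale_id))
  } else {
    keep <- dataset$locale_id == group
    if (!any(keep)) stop_popland("unknown locale '%s'", group)
  }
  g <- dataset$geno[keep, , drop = FALSE]
  miss <- is.na(g)
  g0 <- g; g0[miss] <- 0L
  list(x = colSums(g0), n = colSums(!miss) * dataset$ploidy,
       n_alleles = nrow(g) * dataset$ploidy)
}

#' Per-site nucleotide diversity (theta-pi)
#'
#' Mean pairwise nucleotide difference count over all allele pairs in the
#' group, summed across loci and divided by the surveyed sequence length L.
#' Missing genotypes are handled by pairwise deletion per locus.
#'
#' @param dataset an `snp_dataset`.
#' @param group a locale id, or NULL/"all" for the pooled dataset.
#' @return per-site theta-pi (numeric scalar).
#' @export
nucleotide_diversity <- function(dataset, group = NULL) {
  cc <- group_counts(dataset, group)
  if (cc$n_alleles < 2) stop_popland("group needs >= 2 alleles")
  pil <- locus_pi(cc$x, cc$n)
  sum(pil, na.rm = TRUE) / dataset$n_sites
}

harmonic <- function(n, pow = 1) if (n < 2) 0 else sum(1 / seq_len(n - 1)^pow)

#' Per-site Watterson estimator (theta-S)
#'
#' S / (a1 * L) with a1 the harmonic number over n - 1 for n alleles.
#' With missing data the estimator is accumulated per locus with each
#' locus's own non-missing allele count.
#'
#' @inheritParams nucleotide_diversity
#' @return per-site theta-S.
#' @export
watterson_theta <- function(dataset, group = NULL) {
  cc <- group_counts(dataset, group)
  if (cc$n_alleles < 2) stop_popland("group needs >= 2 alleles")
  seg <- cc$x > 0 & cc$x < cc$n & cc$n >= 2
  if (!any(seg)) return(0)
  sum(1 / vapply(cc$n[seg], harmonic, numeric(1))) / dataset$n_sites
}

#' Count of segregating sites in a group
#' @inheritParams nucleotide_diversity
#' @export
segregating_sites <- function(dataset, group = NULL) {
  cc <- group_counts(dataset, group)
  sum(cc$x > 0 & cc$x < cc$n & cc$n >= 2)
}

tajima_constants <- function(n) {
  a1 <- harmonic(n, 1)
  a2 <- harmonic(n, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' D = (pi_total - S/a1) / sqrt(e1 S + e2 S (S - 1)), computed on the
#' concatenated SNP set of the group (one D per marker dataset), with
#' pi_total the summed mean pairwise difference count and the 1989
#' normalizing constants derived from the allele count n. When S = 0 the
#' statistic is undefined and NA is returned with a warning (never a silent
#' zero).
#'
#' @inheritParams nucleotide_diversity
#' @return Tajima's D, or NA when there are no segregating sites.
#' @export
tajimas_d <- function(dataset, group = NULL) {
  cc <- group_counts(dataset, group)
  if (cc$n_alleles < 2) stop_popland("group needs >= 2 alleles")
  seg <- cc$x > 0 & cc$x < cc$n & cc$n >= 2
  s <- sum(seg)
  if (s == 0) {
    warning("Tajima's D undefined: no segregating sites")
    return(NA_real_)
  }
  n <- round(mean(cc$n[seg]))
  k <- tajima_constants(n)
  pi_total <- sum(locus_pi(cc$x, cc$n)[seg])
  (pi_total - s / k$a1) / sqrt(k$e1 * s + k$e2 * s * (s - 1))
}

#' Diversity summary table
#'
#' Per-site theta-pi, theta-S, segregating sites, Tajima's D and allele
#' count for the pooled dataset and (optionally) each locale.
#'
#' @param dataset an `snp_dataset`.
#' @param by_locale also compute per-locale rows (D is reported only for
#'   the pooled group, as one statistic per marker dataset).
#' @return data.frame with columns group, n_alleles, S, theta_pi, theta_s,
#'   tajimas_d.
#' @export
diversity_stats <- function(dataset, by_locale = TRUE) {
  groups <- "all"
  if (by_locale) groups <- c(groups, sort(unique(dataset$locale_id)))
  rows <- lapply(groups, function(g) {
    gg <- if (g == "all") NULL else g
    cc <- group_counts(dataset, gg)
    s <- segregating_sites(dataset, gg)
    d <- if (g == "all" && s > 0) tajimas_d(dataset, gg) else NA_real_
    data.frame(group = g, n_alleles = cc$n_alleles, S = s,
               theta_pi = nucleotide_diversity(dataset, gg),
               theta_s = watterson_theta(dataset, gg),
               tajimas_d = d)
  })
  do.call(rbind, rows)
}
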