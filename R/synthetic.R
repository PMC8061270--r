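#' Synthetic study scenario
#'
#' Parameters of the synthetic sampling design. The defaults emulate the
#' haploid (chloroplast-like) arm of the study system: 51 locales, 6 haploid
#' sequences per locale (306 alleles) and strong differentiation; the
#' diploid (nuclear-like) arm is obtained with `ploidy = 2`,
#' `samples_per_locale = 4` (408 allele sequences), more loci and weak
#' differentiation. Locale allele frequencies follow the Balding-Nichols
#' model, whose dispersion parameter F equals the expected multi-locus
#' Hudson FST, giving the generator a closed-form ground truth.
#'
#' @param n_locales number of sampling locales (>= 2).
#' @param samples_per_locale individuals sampled per locale (>= 2).
#' @param ploidy 1 or 2.
#' @param n_loci number of biallelic SNP loci.
#' @param fst_target Balding-Nichols F in [0, 1): expected differentiation.
#' @param ancestral_freq_range `c(lo, hi)` for the uniform ancestral allele
#'   frequency, 0 < lo <= hi < 1. The (0.1, 0.9) default keeps near-fixed
#'   loci from dominating the covariance.
#' @param raster_extent integer `c(rows, cols)` of companion rasters; locale
#'   coordinates are drawn inside this extent (cellsize 1, origin 0).
#' @param n_sites surveyed sequence length L (default: `n_loci`).
#' @param seed master integer seed; all sub-streams derive from it.
#' @return object of class `syn_scenario`.
#' @export
syn_scenario <- function(n_locales = 51L, samples_per_locale = 6L, ploidy = 1L,
                         n_loci = 500L, fst_target = 0.3,
                         ancestral_freq_range = c(0.1, 0.9),
                         raster_extent = c(100L, 100L), n_sites = NULL,
                         seed = 1L) {
  s <- list(n_locales = as.integer(n_locales),
            samples_per_locale = as.integer(samples_per_locale),
            ploidy = as.integer(ploidy), n_loci = as.integer(n_loci),
            fst_target = as.numeric(fst_target),
            ancestral_freq_range = as.numeric(ancestral_freq_range),
            raster_extent = as.integer(raster_extent),
            n_sites = as.integer(n_sites %||% n_loci),
            seed = as.integer(seed))
  if (s$n_locales < 2L) stop_popland("n_locales must be >= 2")
  if (s$samples_per_locale < 2L) stop_popland("samples_per_locale must be >= 2")
  if (!s$ploidy %in% c(1L, 2L)) stop_popland("ploidy must be 1 or 2")
  if (s$n_loci < 1L) stop_popland("n_loci must be >= 1")
  if (s$fst_target < 0 || s$fst_target >= 1)
    stop_popland("fst_target must lie in [0, 1)")
  fr <- s$ancestral_freq_range
  if (length(fr) != 2L || fr[1] <= 0 || fr[2] >= 1 || fr[1] > fr[2])
    stop_popland("ancestral_freq_range must satisfy 0 < lo <= hi < 1")
  if (length(s$raster_extent) != 2L || any(s$raster_extent <= 0))
    stop_popland("raster_extent must be positive c(rows, cols)")
  structure(s, class = "syn_scenario")
}

#' @export
print.syn_scenario <- function(x, ...) {
  cat(sprintf(
    "syn_scenario: %d locales x %d samples (ploidy %d), %d loci, F = %.2f, seed %d\n",
    x$n_locales, x$samples_per_locale, x$ploidy, x$n_loci, x$fst_target, x$seed))
  invisible(x)
}

#' @rdname syn_scenario
#' @param path YAML path.
#' @export
write_scenario_yaml <- function(x, path) {
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname syn_scenario
#' @export
read_scenario_yaml <- function(path) {
  do.call(syn_scenario, yaml::read_yaml(path))
}

# Draw locale coordinates uniformly inside the raster extent.
make_locales <- function(scenario, seed_offset = 1L) {
  set.seed(derive_seed(scenario$seed, seed_offset))
  nr <- scenario$raster_extent[1]; nc <- scenario$raster_extent[2]
  k <- scenario$n_locales
  locale_frame(sprintf("L%02d", seq_len(k)),
               x = stats::runif(k, 0.02 * nc, 0.98 * nc),
               y = stats::runif(k, 0.02 * nr, 0.98 * nr),
               n_samples = rep(scenario$samples_per_locale, k))
}

# Balding-Nichols locale frequencies around ancestral p with dispersion F.
bn_locale_freqs <- function(p, n_locales, f) {
  if (f <= 0) return(matrix(p, nrow = n_locales, ncol = length(p), byrow = TRUE))
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  matrix(stats::rbeta(n_locales * length(p),
                      rep(a, each = n_locales), rep(b, each = n_locales)),
         nrow = n_locales)
}

# Sample dosages given a locale x locus frequency matrix.
sample_genotypes <- function(freqs, samples_per_locale, ploidy) {
  k <- nrow(freqs); l <- ncol(freqs)
  probs <- freqs[rep(seq_len(k), each = samples_per_locale), , drop = FALSE]
  matrix(stats::rbinom(length(probs), size = ploidy, prob = probs),
         nrow = k * samples_per_locale)
}

#' Simulate a SNP dataset under the Balding-Nichols model
#'
#' Per locus, an ancestral frequency p is drawn uniformly from
#' `ancestral_freq_range`; each locale's frequency is drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with F = `fst_target` (F = 0 means every
#' locale uses p); alleles/genotypes are then binomial draws. Because
#' E(within-locale heterozygosity) = (1-F) * E(between-locale
#' heterozygosity), the expected multi-locus Hudson FST equals F. Loci that
#' come out monomorphic are retained but flagged (see [monomorphic_loci()]).
#'
#' @param scenario a `syn_scenario`.
#' @param locales optional pre-built `locale_frame` (default: drawn from the
#'   scenario seed).
#' @return list with `dataset` (an `snp_dataset`) and `locales`.
#' @export
simulate_snp_dataset <- function(scenario, locales = NULL) {
  stopifnot(inherits(scenario, "syn_scenario"))
  locales <- locales %||% make_locales(scenario)
  set.seed(derive_seed(scenario$seed, 2L))
  fr <- scenario$ancestral_freq_range
  p <- stats::runif(scenario$n_loci, fr[1], fr[2])
  freqs <- bn_locale_freqs(p, scenario$n_locales, scenario$fst_target)
  geno <- sample_genotypes(freqs, scenario$samples_per_locale, scenario$ploidy)
  loc_id <- rep(locales$locale_id, each = scenario$samples_per_locale)
  ds <- snp_dataset(geno, locale_id = loc_id, ploidy = scenario$ploidy,
                    n_sites = scenario$n_sites)
  list(dataset = ds, locales = locales)
}

#' Simulate a two-cluster barrier scenario
#'
#' Locales are placed on both sides of a high-valued ridge raster (the
#' "barrier") and allele frequencies follow a hierarchical Balding-Nichols
#' model: one cluster-level draw per side with dispersion `barrier_strength`
#' on top of the scenario's within-cluster `fst_target`, so expected
#' cross-barrier differentiation is 1 - (1 - barrier_strength) *
#' (1 - fst_target) while within-side differentiation stays at
#' `fst_target`. This depresses cross-barrier genetic covariance and gives
#' the landscape permutation test a planted signal with a known tail.
#'
#' @param scenario a `syn_scenario`; `n_locales` is split evenly (first half
#'   west of the barrier, second half east).
#' @param barrier_strength between-cluster Balding-Nichols F in [0, 1).
#' @param barrier_raster optional `raster_layer`; default is a vertical
#'   Gaussian ridge through the middle of the scenario extent (base 0,
#'   height 100, width extent/12).
#' @return list with `dataset`, `locales`, `raster`, and `side` (a
#'   character vector "W"/"E" per locale).
#' @export
simulate_barrier_scenario <- function(scenario, barrier_strength,
                                      barrier_raster = NULL) {
  stopifnot(inherits(scenario, "syn_scenario"))
  if (barrier_strength < 0 || barrier_strength >= 1)
    stop_popland("barrier_strength must lie in [0, 1)")
  nr <- scenario$raster_extent[1]; nc <- scenario$raster_extent[2]
  barrier_raster <- barrier_raster %||% make_landscape(
    c(nr, nc), "ridge",
    params = list(center = nc / 2, width = nc / 12, base = 0, height = 100))
  k <- scenario$n_locales
  k_w <- k %/% 2L; k_e <- k - k_w
  set.seed(derive_seed(scenario$seed, 3L))
  x <- c(stats::runif(k_w, 0.04 * nc, 0.36 * nc),
         stats::runif(k_e, 0.64 * nc, 0.96 * nc))
  y <- stats::runif(k, 0.04 * nr, 0.96 * nr)
  side <- rep(c("W", "E"), c(k_w, k_e))
  locales <- locale_frame(sprintf("L%02d", seq_len(k)), x, y,
                          rep(scenario$samples_per_locale, k))
  # validate both sides of the high band
  center <- (which.max(barrier_raster$values[1, ]) - 0.5) * barrier_raster$cellsize +
    barrier_raster$xll
  if (all(x < center) || all(x > center))
    stop_popland("all locales fall on one side of the barrier")
  set.seed(derive_seed(scenario$seed, 4L))
  fr <- scenario$ancestral_freq_range
  p <- stats::runif(scenario$n_loci, fr[1], fr[2])
  cluster_freqs <- bn_locale_freqs(p, 2L, barrier_strength)
  freqs <- matrix(0, k, scenario$n_loci)
  freqs[side == "W", ] <- bn_locale_freqs(cluster_freqs[1, ], k_w, scenario$fst_target)
  freqs[side == "E", ] <- bn_locale_freqs(cluster_freqs[2, ], k_e, scenario$fst_target)
  geno <- sample_genotypes(freqs, scenario$samples_per_locale, scenario$ploidy)
  ds <- snp_dataset(geno, rep(locales$locale_id, each = scenario$samples_per_locale),
                    ploidy = scenario$ploidy, n_sites = scenario$n_sites)
  list(dataset = ds, locales = locales, raster = barrier_raster, side = side)
}
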