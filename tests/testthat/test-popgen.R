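test_that("theta-pi matches hand enumeration and handles degenerate groups", {
  # 4 haploid alleles, 2 SNP sites: rows (0,0),(0,0),(0,1),(1,1); L = 2
  g <- rbind(c(0, 0), c(0, 0), c(0, 1), c(1, 1))
  ds <- snp_dataset(g, rep("A", 4), ploidy = 1, n_sites = 2)
  expect_equal(nucleotide_diversity(ds), 7 / 12)          # 7 diffs over 6 pairs, /L
  expect_equal(nucleotide_diversity(ds), enum_pi_total(g, 1) / 2)

  same <- snp_dataset(matrix(1L, 5, 3), rep("A", 5), ploidy = 1)
  expect_equal(nucleotide_diversity(same), 0)

  one <- snp_dataset(matrix(0L, 1, 3), "A", ploidy = 1)
  expect_error(nucleotide_diversity(one), "2 alleles")
})

test_that("theta-pi and theta-S agree with enumeration on random toys and are order-invariant", {
  for (seed in 1:5) {
    ds <- toy_dataset(seed, ploidy = 1 + seed %% 2)
    expect_equal(nucleotide_diversity(ds),
                 enum_pi_total(ds$geno, ds$ploidy) / ds$n_sites)
    # reorder samples and loci: statistics unchanged
    perm_s <- sample(nrow(ds$geno)); perm_l <- sample(ncol(ds$geno))
    ds2 <- snp_dataset(ds$geno[perm_s, perm_l], ds$locale_id[perm_s],
                       ploidy = ds$ploidy, n_sites = ds$n_sites)
    expect_equal(nucleotide_diversity(ds2), nucleotide_diversity(ds))
    expect_equal(watterson_theta(ds2), watterson_theta(ds))
  }
})

test_that("Watterson's estimator follows its closed form", {
  # S = 3 segregating among n = 4 alleles, L = 100
  g <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(1, 1, 1))
  ds <- snp_dataset(g, rep("A", 4), ploidy = 1, n_sites = 100)
  a1 <- 1 + 1/2 + 1/3
  expect_equal(watterson_theta(ds), 3 / (a1 * 100))
  expect_equal(segregating_sites(ds), 3L)

  mono <- snp_dataset(matrix(0L, 4, 5), rep("A", 4), ploidy = 1)
  expect_equal(watterson_theta(mono), 0)

  # n = 2: a1 = 1, theta-S = S / L exactly
  g2 <- rbind(c(0, 0, 1), c(1, 0, 1))
  ds2 <- snp_dataset(g2, c("A", "A"), ploidy = 1, n_sites = 3)
  expect_equal(watterson_theta(ds2), 1 / 3)
})

test_that("Tajima's D matches an independent transcription and signals S = 0", {
  g <- rbind(c(0, 0), c(0, 0), c(0, 1), c(1, 1))
  ds <- snp_dataset(g, rep("A", 4), ploidy = 1, n_sites = 2)
  expect_equal(tajimas_d(ds), oracle_tajima_d(7 / 6, 2, 4))

  for (seed in 6:8) {
    ds <- toy_dataset(seed, n_locales = 2, n_per = 6, n_loci = 10)
    s <- segregating_sites(ds)
    expect_equal(tajimas_d(ds),
                 oracle_tajima_d(enum_pi_total(ds$geno, 1), s, 12))
  }

  mono <- snp_dataset(matrix(1L, 6, 4), rep("A", 6), ploidy = 1)
  expect_warning(d <- tajimas_d(mono), "undefined")
  expect_true(is.na(d))
})

test_that("Hudson FST matches enumeration, limits and its worked value", {
  # frequencies 0.8 vs 0.2, n = 10 haploids each, one locus
  g <- matrix(c(rep(1L, 8), rep(0L, 2), rep(1L, 2), rep(0L, 8)), ncol = 1)
  ds <- snp_dataset(g, rep(c("A", "B"), each = 10), ploidy = 1)
  expect_equal(hudson_fst(ds, "A", "B"), 1 - (2 * .8 * .2 * 10 / 9) / 0.68)
  expect_equal(hudson_fst(ds, "A", "B"),
               enum_hudson_fst(g[1:10, , drop = FALSE], g[11:20, , drop = FALSE], 1))

  # fixed difference -> 1
  gf <- matrix(rep(c(1L, 0L), each = 6), ncol = 1)
  dsf <- snp_dataset(gf, rep(c("A", "B"), each = 6), ploidy = 1)
  expect_equal(hudson_fst(dsf, "A", "B"), 1)

  # identical balanced frequencies -> ~0, may be slightly negative, not clamped
  gi <- matrix(rep(c(0L, 1L), 50), ncol = 1)          # p = 0.5 in both locales
  dsi <- snp_dataset(gi, rep(c("A", "B"), each = 50), ploidy = 1)
  fi <- hudson_fst(dsi, "A", "B")
  expect_lt(abs(fi), 0.05)
  expect_lt(fi, 0)  # unbiased estimator dips slightly negative, not clamped

  # no usable polymorphic loci -> NA with warning
  dsm <- snp_dataset(matrix(0L, 8, 3), rep(c("A", "B"), each = 4), ploidy = 1)
  expect_warning(v <- hudson_fst(dsm, "A", "B"), "undefined")
  expect_true(is.na(v))
})

test_that("pairwise matrix is compositional, symmetric and bounded by 1", {
  for (seed in 11:14) {
    ds <- toy_dataset(seed, n_locales = 4, n_per = 5, n_loci = 8,
                      ploidy = 1 + seed %% 2)
    m <- pairwise_fst_matrix(ds)
    expect_identical(m, t(m))
    expect_true(all(is.nan(diag(m))))
    expect_true(all(m[upper.tri(m)] <= 1))
    loc <- sort(unique(ds$locale_id))
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(m[i, j], hudson_fst(ds, loc[i], loc[j]))
    }
  }
})

test_that("fast count-based matrix equals the general per-pair path", {
  ds <- toy_dataset(42, n_locales = 5, n_per = 6, n_loci = 12)
  fast <- pairwise_fst_matrix(ds)
  # force the general path by inserting (then masking) a missing value
  ds_na <- ds
  ds_na$geno[1, 1] <- NA
  slow <- suppressWarnings(pairwise_fst_matrix(ds_na))
  # pairs untouched by the missing cell agree exactly
  expect_equal(fast[2:5, 2:5], slow[2:5, 2:5], tolerance = 1e-12)
})

test_that("panmixia permutation: exact null probability, determinism, bootstrap mode", {
  # two locales of 6 haploids, fixed difference at 10 loci: null FST = 1 only
  # when the permutation reproduces the split, P = 2 / choose(12, 6)
  g <- matrix(rep(c(1L, 0L), each = 6), nrow = 12, ncol = 10)
  ds <- snp_dataset(g, rep(c("A", "B"), each = 6), ploidy = 1)
  pt <- panmixia_permutation(ds, n_perm = 1000, seed = 8)
  expect_equal(pt$observed["A", "B"], 1)
  expect_lte(pt$p_value["A", "B"], 0.01)

  pt2 <- panmixia_permutation(ds, n_perm = 1000, seed = 8)
  expect_identical(pt$p_value, pt2$p_value)

  # all alleles identical everywhere: observed FST 0/0 -> NaN pairs get p = 1
  same <- snp_dataset(matrix(0L, 12, 4), rep(c("A", "B"), each = 6), ploidy = 1)
  pts <- panmixia_permutation(same, n_perm = 20, seed = 1)
  expect_true(all(!pts$p_value[upper.tri(pts$p_value)] < 1, na.rm = TRUE))

  bt <- panmixia_permutation(ds, n_perm = 50, seed = 3, mode = "bootstrap")
  expect_s3_class(bt, "panmixia_test")
  expect_identical(bt$mode, "bootstrap")
})

test_that("per-pair perm_result honours the add-one rule", {
  ds <- toy_dataset(3, n_locales = 2, n_per = 6, n_loci = 15)
  pt <- panmixia_permutation(ds, n_perm = 99, seed = 4, keep_null = TRUE)
  pr <- pair_perm_result(pt, "P1", "P2")
  expect_s3_class(pr, "perm_result")
  expect_equal(pr$p_value,
               (1 + sum(pr$null_values >= pr$observed)) / (1 + 99))
  expect_equal(pr$p_value, pt$p_value["P1", "P2"])
  expect_gt(pr$p_value, 0)
})

test_that("type-I error of the panmixia test is near nominal under the null", {
  # 400 simulated pairs under exchangeability (labels carry no signal)
  rej <- 0
  for (i in 1:400) {
    sc <- syn_scenario(n_locales = 2, samples_per_locale = 6, n_loci = 30,
                       fst_target = 0, seed = 2000 + i)
    ds <- simulate_snp_dataset(sc)$dataset
    pt <- panmixia_permutation(ds, n_perm = 99, seed = i)
    rej <- rej + (pt$p_value[1, 2] <= 0.05)
  }
  expect_gte(rej / 400, 0.03)
  expect_lte(rej / 400, 0.07)
})
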