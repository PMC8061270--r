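#!/usr/bin/env Rscript
# Stage 2 — diversity statistics, Hudson FST matrices, panmixia tests.
#
# Per-site theta-pi / theta-S and Tajima's D per arm; pairwise and global
# Hudson FST; 1000-replicate pooled-resampling permutation test of
# panmixia for each arm. Expectation under the generator: the haploid arm
# shows strong, ubiquitous differentiation, the diploid arm weak
# differentiation with fewer significant pairs.

library(popland)
out <- "results"
cp <- read_snp_csv(file.path(out, "cp_genotypes.csv"), ploidy = 1)
nu <- read_snp_csv(file.path(out, "nu_genotypes.csv"), ploidy = 2)

for (arm in list(list(ds = cp, tag = "cp"), list(ds = nu, tag = "nu"))) {
  st <- diversity_stats(arm$ds)
  write.csv(st, file.path(out, paste0(arm$tag, "_diversity.csv")),
            row.names = FALSE)
  m <- pairwise_fst_matrix(arm$ds)
  write_pairwise_csv(m, file.path(out, paste0(arm$tag, "_fst_matrix.csv")))
  pan <- panmixia_permutation(arm$ds, n_perm = 1000,
                              seed = 100 + nchar(arm$tag))
  write_pairwise_csv(pan$p_value, file.path(out, paste0(arm$tag, "_panmixia_p.csv")))
  cat(sprintf(
    "%s arm: global FST = %.3f (panmixia p = %.4g), D = %.2f, %d/%d pairs p <= 0.05\n",
    arm$tag, attr(m, "global"), pan$global_p, st$tajimas_d[st$group == "all"],
    sum(pan$p_value[upper.tri(pan$p_value)] <= 0.05),
    sum(upper.tri(pan$p_value))))
}
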