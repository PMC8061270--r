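#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study system.
#
# Two marker arms over the same 51-locale sampling design: a haploid
# "chloroplast-like" arm (6 sequences/locale, >100 SNPs, high structure,
# F = 0.8) and a diploid "nuclear-like" arm (4 individuals/locale = 408
# allele sequences, >800 SNPs, weak structure, F = 0.1), plus five
# landscape layers: two gradients (elevation, precipitation analogues), a
# ridge (rainfall-concentration analogue), and two categorical mosaics
# (vegetation, land-use analogues).

library(popland)
seed <- 20260926L
out <- "results"
dir.create(out, showWarnings = FALSE)

sc_cp <- syn_scenario(n_locales = 51, samples_per_locale = 6, ploidy = 1,
                      n_loci = 120, fst_target = 0.8, seed = seed)
sc_nu <- syn_scenario(n_locales = 51, samples_per_locale = 4, ploidy = 2,
                      n_loci = 850, fst_target = 0.1,
                      seed = derive_seed(seed, 1))

cp <- simulate_snp_dataset(sc_cp)
nu <- simulate_snp_dataset(sc_nu, locales = cp$locales)  # shared locales

write_snp_csv(cp$dataset, file.path(out, "cp_genotypes.csv"))
write_snp_csv(nu$dataset, file.path(out, "nu_genotypes.csv"))
write_vcf(cp$dataset, file.path(out, "cp_genotypes.vcf"))
write_vcf(nu$dataset, file.path(out, "nu_genotypes.vcf"))
write_locales_csv(cp$locales, file.path(out, "locales.csv"))
write_scenario_yaml(sc_cp, file.path(out, "scenario_cp.yaml"))
write_scenario_yaml(sc_nu, file.path(out, "scenario_nu.yaml"))

ext <- sc_cp$raster_extent
rasters <- list(
  ELE = make_landscape(ext, "gradient",
                       params = list(direction = "east", range = c(50, 1800))),
  PPT = make_landscape(ext, "gradient",
                       params = list(direction = "north", range = c(200, 1100))),
  CON = make_landscape(ext, "ridge",
                       params = list(center = ext[2] / 3, width = ext[2] / 8,
                                     base = 0.5, height = 3)),
  VEG = make_landscape(ext, "categorical_patches",
                       params = list(n_classes = 5, seed = derive_seed(seed, 2))),
  LAN = make_landscape(ext, "categorical_patches",
                       params = list(n_classes = 3, seed = derive_seed(seed, 3)))
)
for (nm in names(rasters))
  write_ascii_grid(rasters[[nm]], file.path(out, paste0(tolower(nm), ".asc")))

cat(sprintf("haploid arm: %d samples x %d loci (%d segregating)\n",
            nrow(cp$dataset$geno), ncol(cp$dataset$geno),
            segregating_sites(cp$dataset)))
cat(sprintf("diploid arm: %d samples x %d loci (%d segregating)\n",
            nrow(nu$dataset$geno), ncol(nu$dataset$geno),
            segregating_sites(nu$dataset)))
cat("rasters written:", paste(names(rasters), collapse = ", "), "\n")
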