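#!/usr/bin/env Rscript
# Stage 3 — population graphs and conditional genetic distance.
#
# Saturated-graph edge exclusion on the among-locale genetic covariance
# (partial correlations tested by -n ln(1 - rho^2) against chi-square 1 df
# at alpha = 0.05), then all-pairs shortest-path cGD over the retained
# edges. The weakly structured diploid arm is expected to yield a sparse,
# largely disconnected graph — locales share allelic variation roughly
# equally — while the haploid arm retains rich conditional structure.

library(popland)
library(igraph)
out <- "results"
locales <- read_locales_csv(file.path(out, "locales.csv"))

for (tag in c("cp", "nu")) {
  ds <- read_snp_csv(file.path(out, paste0(tag, "_genotypes.csv")),
                     ploidy = if (tag == "cp") 1 else 2)
  pg <- build_popgraph(ds, locales, alpha = 0.05)
  write_popgraph_graphml(pg$graph, file.path(out, paste0(tag, "_popgraph.graphml")))
  write_edgelist_csv(pg$graph, file.path(out, paste0(tag, "_popgraph_edges.csv")))
  cgd <- cgd_matrix(pg$graph)
  write_pairwise_csv(cgd, file.path(out, paste0(tag, "_cgd.csv")))
  iso <- isolated_nodes(pg$graph)
  fin <- cgd[upper.tri(cgd)]
  cat(sprintf(
    "%s popgraph: %d edges, %d disconnected locales, %.0f%% pairs reachable, shrinkage %.2g\n",
    tag, ecount(pg$graph), length(iso),
    100 * mean(is.finite(fin)), graph_attr(pg$graph, "shrinkage")))
}
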