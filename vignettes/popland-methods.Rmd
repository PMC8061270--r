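---
title: "Methods: population-graph connectivity and landscape permutation inference"
author: "popland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-graph connectivity and landscape permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

popland implements a population- and landscape-genetic workflow for SNP data
sampled from many small locales: classical diversity and differentiation
statistics, a conditional-independence population graph with conditional
genetic distance (cGD), permutation tests for network structure and for
landscape associations, and a mixed regression of pairwise genetic distance
on landscape predictors. This vignette documents the models, the parameter
choices and their rationale, the numerical decisions, and what the synthetic
validation does and does not demonstrate.

## Diversity and differentiation

Per-site diversity uses the two standard estimators of the population
mutation parameter: `nucleotide_diversity()` returns the mean pairwise
difference count over all allele pairs divided by the surveyed sequence
length $L$ ($\theta_\pi$), and `watterson_theta()` returns
$S / (a_1 L)$ with $a_1 = \sum_{i=1}^{n-1} 1/i$ for $n$ alleles
($\theta_S$). `tajimas_d()` combines them with the 1989 normalizing
constants,
$$D = \frac{\pi_{\mathrm{total}} - S/a_1}{\sqrt{e_1 S + e_2 S(S-1)}},$$
computed once on the concatenated SNP set of a marker dataset. $D$ is
undefined at $S = 0$ and is returned as `NA` with a warning, never silently
as zero. With missing genotypes, $\pi$ and $S$ accumulate per locus with
each locus's own non-missing allele count (pairwise deletion); the
constants use the mean allele count over segregating loci. Note that on a
SNP-only panel with $L$ set to the locus count, $D$ is computed on an
ascertained frequency spectrum; for comparison with sequence-based values,
$L$ should be the full surveyed length.

Differentiation uses the Hudson-type estimator
$$F_{ST} = 1 - \frac{H_w}{H_b},$$
where $H_w$ is the mean within-locale pairwise difference (average of the
two locales, each with the unbiased $n/(n-1)$ correction) and $H_b$ the
mean between-locale pairwise difference. Because both quantities are exact
means over allele pairs, the count-based formulas used internally agree
with brute-force pair enumeration to machine precision, which the test
suite asserts at $10^{-12}$. Multi-locus values combine loci as a **ratio
of averages** (summed numerators over summed denominators) — the stable
convention for Hudson-type estimators, chosen because the source analyses
do not state a rule and the average-of-ratios alternative is badly behaved
at low-diversity loci. Negative estimates are reported as computed;
clamping at zero would bias the permutation null.

The panmixia test pools all individuals and, per replicate, reassigns them
to locales at random without replacement, preserving observed sample sizes
— the exact permutation null for the hypothesis that locale labels carry
no information. A with-replacement bootstrap variant sits behind
`mode = "bootstrap"`. All p-values use the add-one rule
$p = (1 + \#\{T_{\mathrm{null}} \ge T_{\mathrm{obs}}\})/(1 + B)$, so $p$
is never zero and the test is exactly valid under exchangeability.

## The population graph and cGD

Individual genotypes are encoded as centered allele-dosage columns (one
column per non-reference allele per polymorphic locus; the reference
column is dropped to avoid exact collinearity; missing dosages are
mean-imputed per locus). Locale centroids give squared Euclidean distances
$D^2$, and Gower double-centering
$$C = -\tfrac{1}{2} J D^2 J, \qquad J = I - \tfrac{1}{k}\mathbf{1}\mathbf{1}^\top$$
yields the among-locale covariance. The identity
$d^2_{ij} = c_{ii} + c_{jj} - 2 c_{ij}$ is asserted in tests to $10^{-8}$.

Edges are then pruned by conditional independence, as in the published
population-graph procedure: from the precision matrix $\Omega$, partial
correlations $\rho_{ij} = -\Omega_{ij} / \sqrt{\Omega_{ii}\Omega_{jj}}$
are tested with the edge-exclusion deviance $-n \ln(1 - \rho_{ij}^2)$
against $\chi^2_1$; an edge is retained iff its exclusion is rejected at
`alpha` (default 0.05). Numerical decisions:

* **Null-space handling.** Gower centering makes $C$ exactly singular
  (rows sum to zero), so the precision matrix is computed on the non-null
  eigenspace (eigenvalues below $10^{-10} \lambda_{\max}$ are excluded) —
  a pseudo-inverse. Inverting $C + \delta I$ directly would let the null
  direction dominate and drive every partial correlation to $-1$. For a
  full-rank covariance (e.g. one estimated from raw multivariate samples)
  the pseudo-inverse is the ordinary inverse, so planted-structure
  recovery tests exercise the same code path.
* **Shrinkage.** If the retained spectrum is still ill-conditioned
  (condition number above $10^{10}$), a diagonal shrinkage $\delta$
  doubling from $10^{-8}$ to at most $10^{-2}$ is applied and recorded in
  the graph attributes; failure beyond that bound is an explicit error
  naming the condition number.
* **Deviance sample size.** $n$ defaults to the number of sampled
  individuals. The original method description is ambiguous between
  individuals and strata, so $n$ is a visible argument; larger $n$ retains
  more edges at fixed `alpha`.
* **No multiplicity correction across edges** by default, mirroring the
  original procedure; `bonferroni = TRUE` is available. Exact recovery of
  planted sparse structures benefits from a smaller `alpha` (the suite
  uses 0.001 for 8-node chains) because the expected number of false
  edges grows with the number of absent pairs.

Edge weights are the centroid genetic distances
$w_{ij} = \sqrt{c_{ii} + c_{jj} - 2c_{ij}}$, and `cgd_matrix()` returns
all-pairs shortest-path distances over retained edges — the conditional
genetic distance. cGD summarizes connectivity through the entire network;
unreachable pairs are flagged (`Inf` internally, `NA` in CSV exports).
Degree-zero locales are reported by `isolated_nodes()`: they add no
conditional information about the rest of the network, which is not the
same claim as demographic isolation.

## Network metrics and their nulls

`node_metrics()` reports degree; closeness (reciprocal mean shortest-path
distance to reachable nodes — higher closeness means the locale is
genetically *farther* from the rest, because edge weights are distances);
weighted betweenness; and eigenvector centrality. Eigenvector centrality
is computed per connected component on similarity weights $1/w$ (distance
weights would invert its meaning) and scaled to unit Euclidean norm within
each component; isolated nodes carry `NA` closeness/eigenvector values and
are excluded from focus means with a warning, never treated as zero.

`metric_permutation_test()` takes the mean of a metric over a focus set of
locales and compares it with metrics on topology-randomized graphs in
which every node stays fixed: either uniformly random graphs with the same
node set and edge count (`edge_permutation`) or degree-preserving
double-edge-swap rewirings with at least $10|E|$ *successful* swaps per
replicate (`degree_preserving`; the swap counter is part of the contract
and is tested). Null replicates keep the observed edge-weight multiset,
reassigned by random permutation, so the metric scale is comparable
between observed and null — this is how we read the source description of
nulls "drawn from a distribution that included the observed parameter
estimates". The default tail is two-sided because both directions of
deviation are interpretable; one-sided tails are available. Note the
interaction between metric and null: degree is exactly conserved by the
degree-preserving null (such a test returns $p = 1$ by construction), so
degree questions should use `edge_permutation` and path-based metrics
carry the signal under `degree_preserving`.

## Landscape overlays and the degree-constrained permutation test

Edges are overlaid on rasters as straight-line transects between locale
coordinates (the analyses this package supports overlay graph connections
directly; least-cost routing is out of scope). `extract_transect()` uses a
supercover traversal — every pixel the segment crosses with positive
length, endpoints included, each pixel once — rather than Bresenham
sampling, so short diagonal edges are not under-sampled; the traversal is
symmetric in its endpoints and its contiguity and symmetry are
property-tested. Pixels touched only at a corner (a measure-zero
intersection) are not included. Continuous layers are summarized per edge
by the transect mean and population variance; the variance captures
terrain change along the connection that endpoint differencing would miss.
Categorical layers are summarized by per-class pixel proportions — class
codes are never averaged, since a mean vegetation code is meaningless;
this is our defensible reading of mean/variance summaries applied to
categorical sources. Nodata pixels are dropped from statistics and counted;
an edge is flagged missing only when fully nodata. Locales must share the
raster's CRS — validation fails fast; no reprojection is attempted.

`landscape_permutation_test()` compares the mean per-edge statistic over
the observed graph against degree-preserving rewirings re-overlaid on the
raster (node positions fixed on the landscape). Per-pair transect
statistics are precomputed once for all $k(k-1)/2$ pairs, so replicates
only re-aggregate — this makes 1000 replicates on a dense 51-locale graph
a matter of seconds. The add-one rule and two-sided default apply; the
barrier analyses use the lower tail (connections routed through
low-resistance terrain).

## MLPE regression

For pairwise responses (FST or cGD), rows sharing a locale are not
independent. `fit_mlpe()` maximizes the Gaussian likelihood under
$$V_{rs} = \sigma^2\left(\mathbf{1}\{r = s\} + \rho\,\mathbf{1}\{r, s \text{ share exactly one locale}\}\right),$$
the maximum-likelihood-population-effects covariance — our realization of
a mixed model that "accounts for nonindependence of distance matrices".
The likelihood is profiled over $\rho$ with a single eigendecomposition of
the sharing matrix; $\beta$ and $\sigma^2$ are closed-form GLS given
$\rho$. Positive definiteness bounds $\rho$ strictly below
$-1/\lambda_{\min}$ (equal to $1/2$ for a complete pair table), which is
tighter than the conceptual "correlation below 1" bound. ML rather than
REML is used so AIC is comparable across fixed-effect structures;
$k$ counts coefficients, $\sigma^2$, and $\rho$ when estimated.
Predictors are z-scored (scaling recorded for back-transformation); the
response stays on its natural scale. Pseudo-$R^2$ is defined as the
squared Pearson correlation of fitted and observed values — the
variance-explained measure of the motivating analyses is not fully
specified there, so we document our own and make no claim of equivalence.
Exact replication of any particular published mixed-model coefficient set
is likewise not claimed.

## The synthetic generator: what it emulates, and what it does not

`simulate_snp_dataset()` draws, per locus, an ancestral frequency $p$ from
Uniform(0.1, 0.9) (bounded away from fixation so near-fixed loci do not
dominate the covariance) and locale frequencies from the Balding–Nichols
distribution $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, then binomial
alleles or genotypes. Balding–Nichols was chosen over coalescent
simulation because it gives a closed-form link between the dispersion
parameter and the estimand: expected within-locale heterozygosity is
$(1-F)$ times expected between-locale heterozygosity, so the expected
multi-locus Hudson $F_{ST}$ equals $F$ and parameter recovery is directly
assertable (the suite requires $|\hat F - F| < 0.05$ at 51 locales × 6
haploids × 500 loci for $F \in \{0.1, 0.3, 0.5, 0.8\}$).
`simulate_barrier_scenario()` stacks two Balding–Nichols layers — a
cluster draw per side of a high ridge with dispersion `barrier_strength`,
then locale draws within sides — planting depressed cross-barrier
covariance with a known tail for the landscape test.

The default study design mirrors a two-marker sampling campaign over 51
locales: a haploid arm (6 sequences/locale = 306 alleles, >100 SNPs,
$F = 0.8$, matching a maternally inherited, seed-dispersal-limited marker
with strong structure) and a diploid arm (4 individuals/locale = 408
allele sequences, >800 SNPs, $F = 0.1$, matching a pollen-dispersed
nuclear marker near panmixia). Coordinates are planar map units so
Euclidean distances are exact; all randomness derives from one integer
seed per scenario through fixed sub-stream offsets, and every generator is
bit-reproducible under a fixed seed.

What the generator does **not** emulate: linkage and recombination,
mutation processes, isolation by distance (locale frequencies are
exchangeable given the ancestral frequency — geography carries no signal
except where the barrier scenario plants one), missing-data patterns,
ascertainment against a reference, and demographic history. Passing tests
therefore demonstrate estimator correctness, calibration of the
permutation machinery, and power against planted covariance structure —
not that any particular real landscape association would be detected.

Validation problem sizes were chosen to exercise the study-scale design
while keeping the full suite quick: calibration checks use 200 seeded runs
of 99-replicate tests (the add-one p-value's discreteness, at most
$1/(B+1)$, is negligible against the KS criterion), power checks use 20
seeded runs at 199–999 replicates, and parameter-recovery checks use 50
seeds. The planted-cluster power check places a 10-of-40-node cluster with
triple the within-cluster edge retention over a base retention of 0.2,
a density typical of the population graphs this pipeline produces.

## Known limitations

* Raster I/O supports the ESRI ASCII grid text format; pair the package
  with a GIS tool to convert GeoTIFFs.
* Multiallelic sites are handled as dosage columns per non-reference
  allele in the graph encoding, but the diversity and FST estimators
  assume biallelic SNPs.
* The deviance sample size and covariance conditioning of other
  population-graph implementations are not fully published; graphs built
  here are methodologically faithful but not guaranteed edge-for-edge
  identical to other software.
* cGD inherits the pruning threshold's discreteness: near-threshold edges
  can flip with small data changes, so downstream conclusions should be
  checked across a small range of `alpha`.
* The MLPE implementation fits a single global $\rho$; marker-specific or
  distance-dependent dependence structures are out of scope.
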