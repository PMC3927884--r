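---
title: "Methods: genetic stock delineation and conservation prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic stock delineation and conservation prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stockpriority)
```

## The problem

Anadromous river herring — alewife (*Alosa pseudoharengus*) and blueback
herring (*Alosa aestivalis*) — spawn in hundreds of coastal rivers, but
long-term demographic monitoring (spawning-run counts, mean length of
spawning adults) exists for only a handful of them. Because population
genetic structure is the footprint of demographic connectivity, genetics can
group rivers into stocks within which demographic status can reasonably be
generalized. The package implements that workflow end to end: multilocus
microsatellite genotypes are screened and summarized, among-river
differentiation is estimated and clustered into stocks, demographic time
series are reduced to robust trend slopes, and threshold rules convert
slopes into low/medium/high conservation priorities that are extended from
monitored to unmonitored rivers within each stock.

## Genetic components

**Data model.** Genotypes are diploid allele-length pairs per locus, grouped
into collections keyed by (river, year). An individual missing one allele
at a locus is treated as wholly missing there — the conservative convention
shared by the common population-genetics tools. Temporal replicates are
pooled per river (`pool_temporal_replicates()`) once a hierarchical AMOVA
has shown the among-year component to be negligible; clustering defaults to
pooled collections as well, with the unpooled route available by simply not
pooling.

**Diversity.** Per river and locus: observed heterozygosity, Nei's unbiased
expected heterozygosity $H_E = \frac{2n}{2n-1}(1-\sum_a p_a^2)$, the
Weir–Cockerham single-population inbreeding coefficient $f$ from summed
variance components (sums of components across loci, not means of ratios),
and rarefied allelic richness. Rarefaction is computed on genes:
standardizing to $g$ diploid individuals means drawing $2g$ genes, and
$R=\sum_a [1-\binom{N-N_a}{2g}/\binom{N}{2g}]$ is evaluated with
log-binomials to avoid overflow. The "standard individuals" parameter is
exposed directly because sample-size standardization conventions differ
between tools; $2g$ genes is the default interpretation.

**Conformance screens.** Hardy–Weinberg and linkage-disequilibrium tests
are Monte-Carlo exact tests (default 9 999 permutations, seeded): alleles
are shuffled among individuals within a locus, and the statistic is either
the Levene conditional probability of the genotype array or a one-sided
heterozygote-deficit count (deficit is the alternative of interest here,
since departures in these data trace to sporadic null alleles). LD permutes
one locus's genotypes across individuals with a log-likelihood-ratio
statistic on the two-locus table. p-values use add-one smoothing,
$p=(b+1)/(n_{\mathrm{perm}}+1)$, so they can never be 0 and are bounded
below by the permutation floor. A Monte-Carlo test with the same null
replaces Markov-chain exact tests because it is directly checkable against
enumeration on small tables. Family-wise significance uses the sequential
Bonferroni (Holm) step-down; the family of simultaneous tests is an
explicit argument rather than a hard-coded grouping, because family sizes
depend on reporting choices. The lnRV/lnRH neutrality screen converts
fragment lengths to repeat numbers as (length − min observed)/repeat-unit
and flags loci with |z| > 1.96 after standardizing the pair-averaged
log-ratios across loci; pairs with zero variance or $H=1$ are excluded for
that locus rather than propagating infinities.

**Differentiation.** $\theta$ is the Weir–Cockerham estimator from summed
per-allele, per-locus variance components; small negative estimates are
retained, not clamped. Standardized differentiation is
$\theta' = \theta/\theta_{\max}$, where $\theta_{\max}$ re-estimates
$\theta$ after recoding allele labels so no allele is shared between
populations while preserving within-population frequencies — the global
$\theta'$ uses whole-dataset recoding (the pairwise version recodes just
the pair). Genic heterogeneity tests permute population labels among gene
copies on the alleles × populations table, and per-locus p-values combine
by Fisher's method with add-one smoothing guarding $\ln(0)$. The AMOVA uses
the number of non-shared alleles between diploid genotypes (0/1/2 per
locus) as the squared inter-individual distance — the standard choice for
unordered microsatellite alleles — with three permutation schemes matched
to the three levels (populations among groups, individuals among
populations within groups, individuals overall). The POWSIM-style power
assessment drifts replicate populations for $t$ generations with
$F_{ST}=1-(1-1/(2N_e))^t$ ($t$ rounded to the nearest integer, the
realized expectation reported), samples genotypes, and scores the
chi-square contingency test combined across loci; at target
$F_{ST}=0$ the rejection rate is the realized $\alpha$.

**Clustering.** The admixture Gibbs sampler updates gene-copy origins,
cluster allele frequencies (conjugate Dirichlet), individual admixture
vectors, and the symmetric Dirichlet parameter $\alpha$ by Metropolis. Two
allele-frequency priors are available: independent Dirichlet(1) (the
default in tests — it mixes faster) and the correlated F-model, where
cluster frequencies are Dirichlet-tied to ancestral frequencies through
per-cluster drift parameters updated by Metropolis.
$\widehat{\ln\Pr(X|K)} = \overline{\ln L} - \tfrac{1}{2}\mathrm{var}(\ln L)$
over post-burn-in sweeps. K selection reports both the lnP plateau (mean
and SD per K) and the Evanno $\Delta K$ (second difference scaled by the
replicate SD); when the two criteria disagree the result carries an
explicit disagreement flag instead of a silent auto-selection, since
$\Delta K$ is known to point at the top split of hierarchical structure
(K = 2) even when deeper K fits better. The hierarchical re-scan inside
clusters selects sub-K by the lnP plateau, because $\Delta K$ is undefined
at K = 1, which is exactly the answer a homogeneous cluster should give.
Label switching is handled after the fact by exhaustive assignment matching
(K ≤ 8), not by identifiability constraints in the sampler. The sampler's
inner loops are in C++; all randomness flows through R's RNG so a seed
makes runs identical. A second clustering engine (BAPS-style mixture) is
out of scope; concordance between engines is not reproduced here.

**Ordination and IBD.** PCoA double-centres $-D^2/2$ and reports percent
variation over positive eigenvalues, plus an OLS regression of Axis 1 on
latitude. Marine distances are shortest paths over an 8-neighbour graph of
ocean raster cells with per-step great-circle lengths (so east–west steps
shrink with the cosine of latitude); the degree-to-kilometre conversion is
therefore exact per step rather than a single global factor. Dijkstra (via
igraph) was chosen over fast-marching because it is exactly testable
against an independent oracle; a fast-marching engine would only refine the
discretization error. River mouths snap to the nearest passable cell within
3 cells. Differentiation is linearized as $\theta'/(1-\theta')$ before the
Mantel test, whose p-value comes from simultaneous row/column permutation,
one-tailed for positive association by default.

## Demographic components

Trend estimation is deliberately nonparametric: the Theil–Sen slope
(median of all pairwise slopes) and the Mann–Kendall test with
tie-corrected variance, continuity correction, and the exact S distribution
for n ≤ 10 without ties. Run-size series are normalized to (x − mean)/SD
before slope estimation — the sample (n − 1) SD, a convention recorded in
the output because the source assessments do not state it — so run-size
slopes are in SD units per year, which is what the −0.05 threshold
presumes; mean-length series stay in mm/yr. Each series is classified into
five categories (significant/nonsignificant decline/increase, no change)
from the slope sign and two-sided p < 0.05; "no change" means a slope of
exactly zero (|slope| < 1e−12). Group comparisons of slopes use ordinary
fixed-effects linear models (`aov`) with Tukey HSD (Tukey–Kramer under
unequal n) for pairwise contrasts.

## Prioritization rules

Positive slopes are low priority; slopes between the variable's cut and
zero are medium; slopes at or below the cut (−0.75 for mean length, −0.05
for normalized run size) are high. When a river has designations from both
variables they merge by the precautionary principle — a join on the ordered
lattice low < medium < high (commutative, associative, idempotent). When a
river has separate male/female series the same conservative join applies
(the source is silent; precaution is the consistent extension). Stock-level
designations average all member series slopes per variable, classify the
means, and merge. Rivers without their own demographic data inherit their
stock's designation; rivers never genotyped are first attached to the stock
of the nearest sampled river (along-coast distance when a grid is supplied,
otherwise great-circle), with exact ties broken toward the northern
neighbour and warned. Case-specific upgrades are explicit, logged overrides
in the call — never hidden logic.

## Synthetic data: what it emulates, and what it does not

The genotype generator is a hierarchical F-model: ancestral allele
frequencies are symmetric Dirichlet; stock frequencies are
Dirichlet$(p_{\mathrm{anc}}(1-F_{\mathrm{stock}})/F_{\mathrm{stock}})$;
river frequencies repeat the step with $F_{\mathrm{river}}$; genotypes are
Hardy–Weinberg draws. Defaults (3 stocks × 5 rivers × 30 individuals, 12
loci, 8 alleles, $F_{\mathrm{stock}}=0.10$, $F_{\mathrm{river}}=0.01$)
emulate the empirical situation this pipeline targets: distinct stocks
containing weakly differentiated rivers with global $F_{ST}$ in the few-percent
range. A Dirichlet F-model was preferred to coalescent simulation because
the pipeline tests estimators, not genealogies; consequently the synthetic
data contain no mutation-model realism (no stepwise-mutation allele-size
structure), no migration-drift dynamics, and no null alleles — passing
tests demonstrate estimator and rule correctness under the assumed model,
not robustness to genotyping artifacts in field data. The series generator
adds AR(1) noise and missing years to a linear trend, matching the gapped,
autocorrelated shape of run-count records. The coastline generator builds
an irregular land/ocean edge with mouths in shore order so along-coast
distance ordering is known by construction.

## Numerical choices and problem sizes

Monte-Carlo tests default to 9 999 permutations; calibration experiments in
the test suite use 199 permutations × 500 replicates, which bounds the
attainable p at 1/200 and keeps the whole suite comfortably inside a desk
budget. MCMC defaults are burn-in 5 000 / 25 000 sweeps — one tenth of
field-standard settings, appropriate for the panel sizes here — while the
recovery experiments use 400–2 500 sweeps on 150-individual, 12-locus
datasets, where chains mix in a few hundred sweeps; a trending-lnL warning
flags non-mixing. Rarefaction and binomial tails use log-space throughout.
Negative $\theta$ values propagate unclamped. The end-to-end experiments
(clustering recovery, pipeline determinism) fix every seed and run in a few
minutes on one CPU.

## Known limitations

The clustering model assumes unlinked loci and within-cluster
Hardy–Weinberg; it will absorb null-allele heterozygote deficits into
spurious admixture rather than flagging them (the conformance screens exist
to catch that upstream). $\Delta K$ cannot select K = 1 and inherits the
known bias toward the top hierarchical split. The AMOVA distance treats
alleles as unordered, discarding size information. Marine distances are
grid-resolution-limited and ignore bathymetry. The power simulation's
chi-square route is anti-conservative for very sparse allele tables; the
permutation route is available where that matters. Threshold-based
prioritization is sensitive to the normalization convention for run size —
a documented, parameterized choice.
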