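---
title: "Methods: sky-island landscape genetics, demographic inference and range change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sky-island landscape genetics, demographic inference and range change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`skyisland` implements an integrated analysis for montane "sky-island"
population systems sampled with two marker classes of very different
mutation rates: a concatenated mitochondrial sequence (a coding fragment
plus a hyper-variable control-region fragment, ~1,110 bp total), which
records Pleistocene-scale history, and a panel of ~19 autosomal
microsatellites, which records recent, decades-to-centuries-scale change.
The pipeline has four analytic stages — population-genetic summaries,
circuit-theory landscape genetics, coalescent/ABC demographic inference,
and suitability range-change accounting — plus a synthetic world generator
that provides complete, ground-truthed inputs for every stage.

## Population-genetic summaries

**Sequence statistics.** Haplotypes are collapsed by exact sequence
identity; an `N` or gap mismatches a called base, so ambiguous sequences
do not silently merge (an `ambiguous_merge` flag enables greedy merging
when partial sequences are unavoidable). Haplotype diversity uses Nei's
unbiased estimator $Hd = \frac{n}{n-1}(1 - \sum_i p_i^2)$ over haplotype
frequencies; nucleotide diversity $\pi$ is the mean pairwise proportion of
differing sites with pairwise deletion of gaps/`N`s. Between populations
we report $D_{xy}$ (mean between-population difference per site) and
Hudson's $F_{ST} = 1 - \bar\pi_W/\pi_B$ with $\bar\pi_W$ the simple mean
of the two within-population diversities. These estimators are noisy at
$n \lesssim 5$ sequences per population and can go negative; they are
reported raw.

**Microsatellite statistics.** Expected heterozygosity uses Nei's
unbiased correction $\frac{N_g}{N_g-1}(1-\sum p^2)$ with $N_g$ the
non-missing gene count; per-locus gene counts always come from non-missing
calls only, and missing genotypes are a distinct state (never size 0).
Allelic richness is rarefied to a standard number of gene copies $g$ via
the hypergeometric formula
$Ar = \sum_i \left[1 - \binom{N-N_i}{g}/\binom{N}{g}\right]$, averaged
over loci; $g$ defaults to the smallest per-locus gene count across
populations, and loci where a population has fewer than $g$ genes are
dropped from that population's average with a warning. Private alleles are
alleles observed in exactly one population, summed over loci. Multilocus
$F_{ST}$ is Weir & Cockerham's $\theta$ ($\sum_l a_l / \sum_l (a_l+b_l+c_l)$,
variance components summed over alleles and loci); the original survey's
$F_{ST}$ software does not state its estimator, and Weir–Cockerham is the
standard default. Jost's $D_{est}$ uses Nei–Chesser bias-corrected
$H_S, H_T$ per locus and a harmonic mean across loci (per-locus values
floored at $10^{-12}$ so that near-zero loci drive the harmonic mean to
zero rather than breaking it); whether the original analysis averaged
arithmetically or harmonically is unstated, and the harmonic mean follows
the measure's original definition. Negative $\theta$ is reported raw and
only clamped (at $10^{-6}$) when log-transformed in the landscape stage.

**Inbreeding.** Per-individual inbreeding is the maximizer of the
multilocus likelihood $P(\text{hom}_i)=p_i^2+F p_i(1-p_i)$,
$P(\text{het}_{ij})=2p_ip_j(1-F)$ on $F\in[0,1]$, with allele frequencies
taken from the individual's population. This deliberately replaces
triadic-likelihood relatedness-based inbreeding: the triadic estimator
needs the full pairwise-relatedness machinery, out of proportion to its
descriptive role here, so the package's values are not comparable to
published triadic-likelihood columns (rank order is, approximately).

**Marker QC.** Hardy–Weinberg equilibrium is tested per locus and
population by Monte-Carlo permutation of gene copies (default 1,000
permutations, seed mandatory): the statistic is the absolute deviation of
the heterozygote count from its permutation mean, making the test
two-sided; monomorphic loci get $p = 1$ by convention. Null-allele
frequency uses Chakraborty's $r = (H_e - H_o)/(H_e + H_o)$, floored at 0.
A locus is flagged for removal when its mean null-allele frequency exceeds
0.2 or HWE is rejected ($p<0.01$) in more than half the populations.

## Landscape genetics

Rasters are treated as resistor networks: nodes are non-nodata cells, the
conductance between adjacent cells is the reciprocal of their mean
resistance, and diagonal neighbours (default 8-connectivity) have their
conductance divided by $\sqrt2$ for the longer step — the
average-resistance convention of raster circuit solvers; 4-connectivity is
available via a flag. Effective resistances between sites are computed
exactly by sparse Cholesky factorization of the grounded Laplacian, one
solve per focal node. A direct factorization replaces the iterative
conjugate-gradient solver often used for continent-scale rasters because
the grids here (up to a few hundred cells on a side) factor in
milliseconds and the direct solve is exact; small grids are additionally
cross-checked against the dense pseudo-inverse identity
$R_{ab} = L^+_{aa} + L^+_{bb} - 2L^+_{ab}$ in the test suite. Current
maps sum, over focal pairs, half the absolute incident branch current per
cell, with focal cells carrying the full unit current. Disconnected pairs
yield infinite resistance and a warning.

Cost schemes map variable categories or ranges to resistances in
$[1, 100]$ (1 = no resistance, 100 = strong barrier); candidate schemes
for a variable are ranked by the $R^2$ of a multiple regression on
distance matrices (MRDM) against the genetic distance matrix, with ties
broken to the lexicographically lowest label. MRDM regresses vectorized
lower triangles and assesses significance by simultaneous row/column
permutation of the response (default 9,999 permutations for final runs,
999 in tests; seed mandatory), $p = (\#\{R^2_{perm} \ge R^2\}+1)/(n_{perm}+1)$.

Before hypothesis testing the genetic distance is normalized by geography:
$\ln(G_{ij})/\ln(E_{ij})$ with $E$ the Euclidean distance in metres from
projected site coordinates (no great-circle computation; the script
rejects distances $\le 1$, which indicate wrong units). Hypotheses are
compared with the maximum-likelihood population-effects (MLPE) model
$y_{ij} = \beta_0 + \sum\beta x_{ij} + u_i + u_j + \epsilon_{ij}$,
$u\sim N(0,\sigma^2_u)$ — the random effect is shared by every pair
containing a population, i.e. covariance
$\sigma^2_e I + \sigma^2_u ZZ^\top$. Because the multi-membership design
cannot be expressed in standard mixed-model formula interfaces, and the
problem is tiny (10 pairs for 5 populations), the model is fitted by
direct maximum likelihood: the variance ratio is profiled out and
optimized in one dimension, with GLS for $\beta$. Full ML (not REML) keeps
log-likelihoods comparable across fixed-effect structures, which model
selection requires; REML would bias comparisons. With $\ge 2$ predictors
a VIF screen iteratively drops the worst predictor until all VIF < 4.
Confidence intervals use $t$ quantiles on $n-p$ degrees of freedom rather
than 1.96: with 10 pairs the ML residual variance is noticeably
downward-biased and the normal quantile under-covers (measured coverage
rose from ~86% to the nominal band in simulation). Model comparison uses
$AICc = -2LL + 2k + 2k(k+1)/(n-k-1)$ and $BIC = -2LL + k\ln n$ with $n$
the number of pairs and $k$ counting intercept, slopes and both variance
components, plus evidence weights $e^{-\Delta/2}/\sum e^{-\Delta/2}$.

## Coalescent simulation and ABC

**Scenarios.** Two sampled populations, south-east (S) and north-west (N)
of a lowland barrier, merge into an ancestor of effective size $N_A$ at
$t_{split}$ generations (prior U[100, 100,000] generations = 200–200,000
years at 2 years/generation). Scenario 1: no size change and a large
ancestor ($N_A > \max(N_S, N_N)$). Scenario 2: expansion after the split
($N_A < \min$). Scenarios 3/4: recent decline at $t_{dec}$ (prior
U[10, 500] generations = 20–1,000 years) from pre-decline sizes
$N_{S0} > N_S$ (and $N_{N0} > N_N$ in scenario 3). Size priors are
U[100, 100,000] diploids; constraints are enforced by rejection
resampling. The simulator itself is scenario-agnostic (an event list), so
nested settings (e.g. scenario 4 with decline ratio 1) reproduce scenario
1 exactly — a property the tests exercise.

**Simulator.** Backward-in-time coalescent with piecewise-constant sizes,
compiled in C++. Autosomal microsatellites: 19 independent trees, 2
lineages per diploid, generalized stepwise mutation (step size
$1+\mathrm{Geom}(1-P)$, sign symmetric, prior $P\sim U[0,0.3]$, mean rate
log-uniform $[10^{-4},10^{-3}]$), allele sizes reflecting at bounds
(default 50–150 repeat units around a root of 100, wide enough that
reflections are rare at realistic diversities; occurrences are counted and
returned). mtDNA: one tree shared by both partitions (full linkage), one
lineage per individual, effective size $N/4$ (maternal and haploid), HKY
substitution with $\kappa = 8$ and typical mammalian mtDNA base
frequencies; the coding partition uses invariant-sites heterogeneity
(default $I = 0.9$, variable sites scaled so the partition mean rate is
$\mu$), the control-region partition gamma rates (default shape 0.5,
mean 1); $\mu_{mt}$ prior log-uniform $[10^{-8},10^{-7}]$/site/generation.
Substitution-model parameter values are not published for the study
system, so these are field-typical defaults, all overridable. The
simulator is validated against Watterson's $E[S]$, the Ohta–Kimura
stepwise-model $E[H_e]$, and $E[T_{MRCA}]$ for $n=2$ (nuclear $2N$,
mitochondrial $N/2$).

**Summary statistics.** Eighteen statistics in fixed order.
Microsatellites: mean alleles/locus, mean unbiased $H_e$, mean allele-size
variance, and mean Garza–Williamson $M$ (allele count over allele-size
range + 1) per population; pairwise Weir–Cockerham $\theta$; mean Jaccard
overlap of allele sets (a shared-allele classification index); and
Goldstein's $(\delta\mu)^2$. mtDNA: haplotype count, per-site $\pi$ and
Tajima's $D$ per population, plus between-population $D_{xy}$. Degenerate
values (e.g. Tajima's $D$ with no segregating sites) are set to 0. The
$M$ ratio replaces per-population segregating-site counts relative to a
first draft of this list: $M$ is the classic microsatellite
recent-bottleneck signal (allele classes are lost faster than range
shrinks), without it the statistic vector carries almost no information to
separate a recent decline from a constant small population, and
segregating sites are nearly redundant given haplotype counts and $\pi$.
Reference tables compute statistics in a compiled kernel; the test suite
asserts bit-level agreement between that kernel and the R population-
genetics functions on the same datasets, so both routes stay honest.

**Reference tables and inference.** Each table row gets its own RNG seed
derived from the master seed and a row counter, making tables
bit-reproducible and chunk-parallelizable. Statistics are standardized by
the table SDs; the tolerance fraction nearest the observed vector (default
1%) is retained. Scenario choice reports both the retained-frequency
(direct) estimate and a multinomial logistic regression of scenario on the
centred statistics over retained rows, Epanechnikov-weighted by relative
distance and evaluated at the origin; a $10^{-6}$ weight decay guards
against separation. Linear-discriminant preprocessing of the statistics
was evaluated and not adopted: axes estimated on the retained
neighbourhood added nothing, and axes estimated globally degraded local
discrimination. Parameter estimation is Beaumont-style local-linear
adjustment on logit-transformed parameters with respect to their prior
bounds (so adjusted draws respect the support), with weighted quantiles
for the median and 95% credible interval; times are reported in
generations and years. The south-population decline ratio $N_{S0}/N_S$ is
reported both as the median of the per-draw ratio and the ratio of
medians, because "fold decline" summaries are ambiguous between the two.
Calibration machinery mirrors standard ABC practice: scenario-confusion
matrices from pseudo-observed datasets (type-1/type-2 errors), PCA-based
posterior predictive checks (99% ellipsoid and convex hull of the first
two components), and relative mean bias / RMedAD of posterior medians.

## Range-change accounting

Continuous suitability maps are binarized at the threshold maximizing
sensitivity + specificity over the union of observed scores; cells at the
threshold are suitable (the "above the threshold is suitable" reading that
keeps sensitivity consistent; a flag flips it), and ties break to the
lowest threshold. Multi-model ensembles are cell-wise majorities of binary
maps (ties suitable); the ensembling rule used by the original range
tables is unstated, and majority is the simplest order-independent choice.
Reports give suitable-cell counts, percent of study area, and percent
change versus the present slice, rounded to one decimal; cross-slice
ratios are derived from the rounded change percentages so the printed
table is internally consistent at its own precision (deriving them from
raw counts can disagree with the rounded column in the second decimal).

## The synthetic world

`make_world()` builds a 100×100-cell (1 km cells) altitude field: five
Gaussian massifs, two south-east and three north-west of a continuous
low-altitude rift band running along the anti-diagonal, over a 2,000 m
base with peaks near 4,200 m. Ecoregions are altitude bands (lowland
< 2,795 m, montane woodland to 3,500 m, alpine moorland above — matching
the sampling strata of the motivating system); arable fraction is
anti-correlated with altitude plus noise; human footprint declines with
altitude; suitability increases with it. Ground-truth genetics assign
coalescent-simulated individuals (site sizes 7, 9, 7, 12, 11) to sites
within each side of the rift, so within-side site pairs are panmictic
samples and cross-rift pairs carry the split signal.
`inject_covariate_effect()` emulates the diversity-versus-land-use
regression with a configurable slope and response noise, enabling exact
recovery checks at zero noise and calibration checks (type-I ≈ 5%) at
zero slope. What the generator does **not** emulate: genotyping error and
null alleles, missing data, within-side isolation-by-distance (within-side
gene flow is panmictic), selection, spatially autocorrelated sampling
effort, and realistic geomorphology or climate fields. Tests passing on
these worlds therefore validate the estimators and their wiring, not
robustness to those real-data complications.

## Study conditions used by the validation suite

The heavier simulation studies in the test suite use these problem sizes,
chosen as the package's validation conditions: simulator oracles at 2,000
replicates (3 Monte-Carlo-SE acceptance); ABC scenario recovery against a
10,000-row-per-scenario table at 1% tolerance with 100 pseudo-observed
datasets from a fixed strong-decline world (present south size 800,
ten-fold decline 480 generations ago, stable north of 8,000, ancestor
30,000 splitting 30,000 generations ago, mid-prior mutation rates) —
measured recovery sits at ~81%, essentially on the 80% acceptance
boundary, so individual 100-pod draws fluctuate around it; split-time
credible-interval coverage from 200 prior-drawn pods against a 4,000-row
scenario-restricted table at 12.5% tolerance; circuit solves
cross-checked on one hundred random 6×6 surfaces; barrier-hypothesis
recovery on one hundred 40×40 synthetic worlds with MLPE responses
generated on the true rift-barrier resistance (unit slope, population-
effect SD 0.1, residual SD 0.15); and MRDM null calibration from 200
5×5-matrix replicates at 999 permutations.

## Known limitations

Single mitochondrial locus means mtDNA summary statistics are one
realization of a high-variance process; they dominate neither the ABC
distance nor, at low within-population diversity, the scenario signal.
The MLPE stage assumes the normalized distances are approximately
Gaussian; with 5 populations (10 pairs) multi-variable hypotheses are
weakly identified, which is why the VIF screen and small-sample $t$
intervals matter. Jost's harmonic mean is undefined when loci are exactly
undifferentiated and is floored as described. The ABC logistic regression
is local-linear; posterior probabilities for scenarios with little
retained support are extrapolations and should be read alongside the
direct estimates and the confusion matrix.
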