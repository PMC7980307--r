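# skyisland

Integrated population-genetic, landscape-genetic, demographic and
range-change analysis for montane "sky-island" systems — isolated
high-altitude populations separated by inhospitable lowlands, sampled
with mixed mitochondrial-sequence and microsatellite markers.

The package is aimed at conservation and landscape geneticists who need
to connect four questions about a fragmented montane species in one
reproducible pipeline:

1. **How much diversity is left, and where?** Haplotype diversity
   $Hd = \frac{n}{n-1}(1-\sum p_i^2)$ and nucleotide diversity $\pi$ for
   mtDNA; rarefied allelic richness (hypergeometric expectation at a
   standard gene count), private alleles, unbiased heterozygosity,
   maximum-likelihood individual inbreeding, Hardy–Weinberg Monte-Carlo
   tests and null-allele screening for microsatellites; Weir–Cockerham
   $\theta$ and Jost's $D_{est}$ between populations; OLS models of
   diversity against land-use covariates.
2. **What limits gene flow?** Rasters become resistor networks (edge
   conductance = 1/mean cell resistance, $\sqrt2$-corrected diagonals);
   pairwise effective resistances and current-density maps are solved
   exactly via the graph Laplacian. Candidate resistance-cost schemes are
   ranked by multiple regression on distance matrices (MRDM) with
   permutation tests, and landscape hypotheses are compared with
   maximum-likelihood population-effects (MLPE) mixed models
   ($y_{ij} = \beta_0+\beta x_{ij}+u_i+u_j+\epsilon_{ij}$) under AICc/BIC
   evidence weights.
3. **What happened demographically?** A compiled coalescent simulator for
   two populations splitting from a common ancestor, with optional recent
   declines, generalized stepwise microsatellite mutation and
   HKY+I/+Gamma mtDNA substitution, drives approximate Bayesian
   computation: reference tables, scenario choice by weighted multinomial
   logistic regression, local-linear parameter adjustment, confusion
   matrices, posterior predictive checks, and bias/RMedAD calibration.
4. **Where could the species live, and when?** MaxSSS thresholding of
   continuous suitability maps (maximizing sensitivity + specificity),
   majority ensembling, and range-change accounting across time slices.

A synthetic world generator (`make_world()`) builds complete ground-truthed
study systems — five mountain massifs split 2 : 3 by a lowland rift,
altitude-derived ecoregion/arable/footprint/suitability rasters, and
coalescent genotypes assigned to sites — so every stage can be validated
end to end without any external data.

## Worked example

```r
library(skyisland)
world <- make_world(n_side = 60, seed = 11)       # synthetic sky-island system
gen   <- simulate_truth_genetics(world, seed = 12) # coalescent ground truth

div <- microsat_summaries(gen$gt, gen$popmap)
mt  <- lapply(split(names(gen$popmap), unclass(gen$popmap)), function(ids)
  mtdna_diversity(aln_subset(gen$aln, ids)))
div$Hd <- round(sapply(div$population, function(p) mt[[p]]$Hd), 3)
print(div, digits = 3)
```

```
  population  N    Na    Ar Pa    Ho    He    Hd
1      BaleD  7 10.37 10.37 53 0.925 0.947 0.476
2      BaleS  9 11.89 10.03 81 0.953 0.943 0.222
3     Guassa  7  8.89  8.89 16 0.895 0.913 0.667
4     Simien 12 12.00  8.91 29 0.908 0.915 0.636
5      Abune 11 12.37  9.48 36 0.947 0.929 0.709
```

Per-site sample sizes, allelic richness rarefied to the smallest shared
gene count (`Ar`), private alleles (`Pa`), observed/expected
heterozygosity, and mtDNA haplotype diversity per site. Differentiation
shows the rift, not the within-side site structure:

```r
diff <- pairwise_differentiation(gen$gt, gen$popmap)
round(unclass(diff$theta)[, ], 3)
```

```
        BaleD  BaleS Guassa Simien Abune
BaleD   0.000 -0.002  0.052  0.052 0.046
BaleS  -0.002  0.000  0.056  0.055 0.049
Guassa  0.052  0.056  0.000  0.009 0.003
Simien  0.052  0.055  0.009  0.000 0.001
Abune   0.046  0.049  0.003  0.001 0.000
```

Cross-rift pairs (BaleD/BaleS vs the three northern sites) sit at
$\theta \approx 0.05$ while within-side pairs are ~0 — the two-sided
split the generator encodes. The landscape stage then asks whether a
rift-barrier resistance surface explains the (distance-normalized)
genetic structure better than geography alone:

```r
nodes  <- node_set(world$sites$label, world$sites$row, world$sites$col)
resist <- reclassify(world$rasters$ecoregion, world$truth$cost_scheme)
rd     <- resistance_distances(resist, nodes)
y      <- normalize_genetic_distance(diff$theta, euclidean_distances(world$sites))
flat   <- cost_scheme("alt", "uniform", data.frame(from = -Inf, to = Inf, cost = 1))
fits <- list(
  ecoregion = mlpe_fit(y, list(eco = rd)),
  geography = mlpe_fit(y, list(geo = resistance_distances(
    reclassify(world$rasters$altitude, flat), nodes))))
model_compare(fits)
```

```
          hypothesis   logLik k  AICc    BIC aicc_weight bic_weight rank
geography  geography -0.02261 4 16.05  9.256      0.6471     0.6471    1
ecoregion  ecoregion -0.62898 4 17.26 10.468      0.3529     0.3529    2
```

On this single world realization the two hypotheses are nearly tied
(evidence weights 0.65 vs 0.35): with five sites and a barrier that is
itself collinear with distance, one dataset rarely settles the question —
which is exactly why the package ships a replicated power study (the
barrier hypothesis wins in ≥80% of simulated worlds when gene flow is
generated on the barrier surface; see the test suite). `run_pipeline()`
chains all stages from a plain-text config and writes versioned report
tables; `build_reference_table()` / `model_choice()` /
`estimate_parameters()` run the ABC stage.

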