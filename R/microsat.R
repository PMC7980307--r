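## Microsatellite summary statistics, QC and differentiation.
## Internal kernels operate on plain integer matrices so the coalescent
## summariser can share them without container overhead.

# allele count table for one locus: integer vector of counts named by size
allele_counts <- function(a1, a2) {
  x <- c(a1, a2)
  x <- x[!is.na(x)]
  if (!length(x)) return(integer(0))
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}

# Nei's unbiased expected heterozygosity from gene counts
he_unbiased <- function(counts) {
  N <- sum(counts)
  if (N < 2L) return(NA_real_)
  p <- counts / N
  N / (N - 1) * (1 - sum(p^2))
}

# rarefied allelic richness for one locus: expected number of distinct
# alleles in a subsample of g gene copies
rarefied_richness <- function(counts, g) {
  N <- sum(counts)
  if (g > N) return(NA_real_)
  # 1 - C(N - Ni, g)/C(N, g) per allele, on log scale for stability
  sum(vapply(counts, function(ni) {
    if (N - ni < g) return(1)
    1 - exp(lchoose(N - ni, g) - lchoose(N, g))
  }, 0))
}

#' Per-population microsatellite diversity summaries
#'
#' Computes, per population: sample size `N`, mean number of alleles per
#' locus (`Na`), rarefied allelic richness (`Ar`, expected distinct alleles
#' in `rarefaction_g` gene copies, averaged over loci), number of private
#' alleles (`Pa`, alleles observed in exactly one population, summed over
#' loci), observed (`Ho`) and Nei's unbiased expected (`He`)
#' heterozygosity.
#'
#' @param gt a [genotype_matrix()].
#' @param popmap a [pop_map()].
#' @param rarefaction_g number of gene copies to rarefy to; default is the
#'   smallest per-locus non-missing gene count over populations.
#' @return data frame, one row per population. Loci where a population has
#'   fewer than `rarefaction_g` scored genes are dropped from that
#'   population's `Ar` with a warning.
#' @export
microsat_summaries <- function(gt, popmap, rarefaction_g = NULL) {
  pops <- popmap_lookup(popmap, gt$ids)
  upops <- unique(pops)
  L <- length(gt$loci)
  counts <- lapply(upops, function(p) {
    idx <- which(pops == p)
    lapply(seq_len(L), function(l)
      allele_counts(gt$calls[idx, l, 1], gt$calls[idx, l, 2]))
  })
  names(counts) <- upops
  if (is.null(rarefaction_g)) {
    gmin <- min(vapply(counts, function(cl)
      min(vapply(cl, sum, 0L)), 0L))
    rarefaction_g <- max(2L, gmin)
  }
  # private alleles: per locus, alleles seen in exactly one population
  pa <- stats::setNames(numeric(length(upops)), upops)
  for (l in seq_len(L)) {
    seen <- lapply(counts, function(cl) names(cl[[l]]))
    all_alleles <- unlist(seen)
    priv <- names(which(table(all_alleles) == 1L))
    for (p in upops) pa[p] <- pa[p] + sum(seen[[p]] %in% priv)
  }
  rows <- lapply(upops, function(p) {
    cl <- counts[[p]]
    idx <- which(pops == p)
    na <- mean(vapply(cl, length, 0L))
    ar_vals <- vapply(cl, rarefied_richness, 0, g = rarefaction_g)
    if (anyNA(ar_vals)) {
      warning(sprintf("population %s: %d loci dropped from Ar (fewer than g=%d genes)",
                      p, sum(is.na(ar_vals)), rarefaction_g))
    }
    he <- mean(vapply(cl, he_unbiased, 0), na.rm = TRUE)
    a1 <- gt$calls[idx, , 1, drop = FALSE]
    a2 <- gt$calls[idx, , 2, drop = FALSE]
    ho <- mean(colMeans(a1 != a2, na.rm = TRUE), na.rm = TRUE)
    data.frame(population = p, N = length(idx), Na = na,
               Ar = mean(ar_vals, na.rm = TRUE), Pa = as.integer(pa[p]),
               Ho = ho, He = he, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "rarefaction_g") <- rarefaction_g
  out
}

# negative log-likelihood of an individual's genotypes given F and
# per-locus allele frequency vectors
indiv_f_nll <- function(f, geno, freqs) {
  ll <- 0
  for (l in seq_along(freqs)) {
    g <- geno[[l]]
    if (is.null(g)) next
    p <- freqs[[l]]
    if (g[1] == g[2]) {
      pi <- p[as.character(g[1])]
      pr <- pi^2 + f * pi * (1 - pi)
    } else {
      pi <- p[as.character(g[1])]; pj <- p[as.character(g[2])]
      pr <- 2 * pi * pj * (1 - f)
    }
    pr <- max(pr, 1e-300)
    ll <- ll + log(pr)
  }
  -ll
}

#' Maximum-likelihood individual inbreeding coefficients
#'
#' For each individual, maximizes the multilocus likelihood
#' \eqn{P(\mathrm{hom}_i) = p_i^2 + F p_i(1-p_i)},
#' \eqn{P(\mathrm{het}_{ij}) = 2 p_i p_j (1-F)} over \eqn{F \in [0,1]},
#' with allele frequencies estimated from the individual's population
#' (including the individual itself).
#'
#' @param gt a [genotype_matrix()].
#' @param popmap a [pop_map()].
#' @return list with `individual` (data frame `id, population, F`) and
#'   `population` (named vector of population mean F). Individuals with all
#'   loci missing get `NA`.
#' @export
inbreeding_ml <- function(gt, popmap) {
  pops <- popmap_lookup(popmap, gt$ids)
  upops <- unique(pops)
  L <- length(gt$loci)
  freqs_by_pop <- lapply(upops, function(p) {
    idx <- which(pops == p)
    lapply(seq_len(L), function(l) {
      cnt <- allele_counts(gt$calls[idx, l, 1], gt$calls[idx, l, 2])
      cnt / sum(cnt)
    })
  })
  names(freqs_by_pop) <- upops
  fhat <- vapply(seq_along(gt$ids), function(i) {
    freqs <- freqs_by_pop[[pops[i]]]
    geno <- lapply(seq_len(L), function(l) {
      g <- gt$calls[i, l, ]
      if (anyNA(g)) NULL else g
    })
    if (all(vapply(geno, is.null, TRUE))) return(NA_real_)
    stats::optimize(indiv_f_nll, c(0, 1), geno = geno, freqs = freqs,
                    tol = 1e-8)$minimum
  }, 0)
  # optimize() never returns exact interval endpoints; snap near-boundary
  fhat <- pmin(pmax((fhat - 1e-6) / (1 - 2e-6), 0), 1)
  ind <- data.frame(id = gt$ids, population = pops, F = fhat,
                    stringsAsFactors = FALSE)
  popmean <- tapply(fhat, pops, mean, na.rm = TRUE)
  list(individual = ind, population = popmean[upops])
}

# Monte-Carlo exact HWE test for one locus in one population.
# Statistic: |observed heterozygote count - permutation mean|.
hwe_mc_test <- function(a1, a2, n_perm, obs_only = FALSE) {
  ok <- !is.na(a1) & !is.na(a2)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n < 2L) return(NA_real_)
  genes <- c(a1, a2)
  if (length(unique(genes)) < 2L) return(1)  # monomorphic convention
  obs_het <- sum(a1 != a2)
  perm_het <- vapply(seq_len(n_perm), function(k) {
    g <- sample(genes)
    sum(g[seq_len(n)] != g[seq.int(n + 1L, 2L * n)])
  }, 0L)
  mu <- mean(perm_het)
  (sum(abs(perm_het - mu) >= abs(obs_het - mu)) + 1) / (n_perm + 1)
}

#' Marker quality control: HWE tests and null-allele frequencies
#'
#' Hardy-Weinberg equilibrium is tested per locus and population by a
#' Monte-Carlo exact test that permutes gene copies within the population
#' and compares the observed heterozygote count to its permutation
#' distribution (two-sided). The null-allele frequency estimate is
#' Chakraborty's \eqn{r = (He - Ho)/(He + Ho)}, floored at zero.
#'
#' @param gt a [genotype_matrix()].
#' @param popmap a [pop_map()].
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed (required for reproducibility).
#' @param p_threshold HWE rejection level per test (default 0.01).
#' @param null_threshold mean null-allele frequency above which a locus is
#'   flagged for dropping (default 0.2).
#' @return list with `hwe_p` (loci x populations matrix), `null_freq`
#'   (loci x populations), and `flags` data frame with `locus`, `retain`.
#'   A locus is flagged `retain = FALSE` if its mean null-allele frequency
#'   exceeds `null_threshold` or HWE is rejected in more than half the
#'   populations.
#' @export
marker_qc <- function(gt, popmap, n_perm = 1000, seed,
                      p_threshold = 0.01, null_threshold = 0.2) {
  if (missing(seed)) stop("marker_qc requires an explicit seed")
  if (n_perm < 100) stop("n_perm must be >= 100")
  set.seed(seed)
  pops <- popmap_lookup(popmap, gt$ids)
  upops <- unique(pops)
  L <- length(gt$loci)
  hwe <- nullf <- matrix(NA_real_, L, length(upops),
                         dimnames = list(gt$loci, upops))
  for (p in upops) {
    idx <- which(pops == p)
    for (l in seq_len(L)) {
      a1 <- gt$calls[idx, l, 1]; a2 <- gt$calls[idx, l, 2]
      hwe[l, p] <- hwe_mc_test(a1, a2, n_perm)
      cnt <- allele_counts(a1, a2)
      if (length(cnt) >= 2L) {
        he <- he_unbiased(cnt)
        ho <- mean(a1 != a2, na.rm = TRUE)
        nullf[l, p] <- max(0, (he - ho) / (he + ho))
      } else nullf[l, p] <- 0
    }
  }
  rej <- rowSums(hwe < p_threshold, na.rm = TRUE)
  ntest <- rowSums(!is.na(hwe))
  retain <- !(rowMeans(nullf, na.rm = TRUE) > null_threshold |
                rej > ntest / 2)
  list(hwe_p = hwe, null_freq = nullf,
       flags = data.frame(locus = gt$loci, retain = retain,
                          stringsAsFactors = FALSE))
}

# Weir & Cockerham (1984) variance components for one locus between two
# (or more) populations. counts: list of named allele-count vectors per
# population; hets: per population, per allele, count of heterozygous
# individuals carrying that allele; nind: individuals scored per population.
wc_components <- function(counts, het_counts, nind) {
  r <- length(counts)
  alleles <- unique(unlist(lapply(counts, names)))
  n_i <- nind                      # individuals scored per population
  nbar <- mean(n_i)
  if (nbar <= 1 || r < 2) return(c(a = 0, b = 0, c = 0))
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  a <- b <- cc <- 0
  for (al in alleles) {
    p_i <- vapply(seq_len(r), function(k) {
      cnt <- counts[[k]]
      if (al %in% names(cnt)) cnt[[al]] / (2 * n_i[k]) else 0
    }, 0)
    h_i <- vapply(seq_len(r), function(k) {
      hc <- het_counts[[k]]
      if (al %in% names(hc)) hc[[al]] / n_i[k] else 0
    }, 0)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- a + nbar / nc * (s2 - 1 / (nbar - 1) *
           (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- b + nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- cc + hbar / 2
  }
  c(a = a, b = b, c = cc)
}

# per-population per-locus allele counts, het-carrier counts, n scored
locus_pop_tables <- function(calls, idx_by_pop, l) {
  lapply(idx_by_pop, function(idx) {
    a1 <- calls[idx, l, 1]; a2 <- calls[idx, l, 2]
    ok <- !is.na(a1) & !is.na(a2)
    a1 <- a1[ok]; a2 <- a2[ok]
    cnt <- allele_counts(a1, a2)
    hets <- a1 != a2
    hc <- integer(0)
    if (any(hets)) {
      hcv <- table(c(a1[hets], a2[hets]))
      hc <- stats::setNames(as.integer(hcv), names(hcv))
    }
    list(counts = cnt, hets = hc, n = length(a1))
  })
}

# multilocus Weir-Cockerham theta between two index sets
wc_theta_pair <- function(calls, idx1, idx2, loci = seq_len(dim(calls)[2])) {
  A <- B <- C <- 0
  for (l in loci) {
    tabs <- locus_pop_tables(calls, list(idx1, idx2), l)
    if (tabs[[1]]$n < 1 || tabs[[2]]$n < 1) next
    comp <- wc_components(lapply(tabs, `[[`, "counts"),
                          lapply(tabs, `[[`, "hets"),
                          vapply(tabs, `[[`, 0L, "n"))
    A <- A + comp["a"]; B <- B + comp["b"]; C <- C + comp["c"]
  }
  denom <- A + B + C
  if (denom == 0) return(0)
  unname(A / denom)
}

# Jost's D_est between populations for one locus (Nei & Chesser corrected
# Hs/Ht), all populations at once
jost_d_locus <- function(tabs) {
  r <- length(tabs)
  n_i <- vapply(tabs, `[[`, 0L, "n")
  if (any(n_i < 2) || r < 2) return(NA_real_)
  ntilde <- r / sum(1 / n_i)  # harmonic mean sample size (individuals)
  alleles <- unique(unlist(lapply(tabs, function(t) names(t$counts))))
  if (length(alleles) < 2L) return(0)
  pmat <- vapply(tabs, function(t) {
    p <- stats::setNames(numeric(length(alleles)), alleles)
    p[names(t$counts)] <- t$counts / (2 * t$n)
    p
  }, numeric(length(alleles)))
  # observed heterozygosity: het-carrier table counts each heterozygote twice
  ho <- mean(vapply(tabs, function(t) sum(t$hets) / (2 * t$n), 0))
  hs_obs <- 1 - mean(colSums(pmat^2))
  pbar <- rowMeans(pmat)
  ht_obs <- 1 - sum(pbar^2)
  # Nei & Chesser (1983) bias corrections
  hs <- ntilde / (ntilde - 1) * (hs_obs - ho / (2 * ntilde))
  ht <- ht_obs + hs / (ntilde * r) - ho / (2 * ntilde * r)
  if (hs >= 1) return(NA_real_)
  (ht - hs) / (1 - hs) * r / (r - 1)
}

jost_d_pair <- function(calls, idx1, idx2, loci = seq_len(dim(calls)[2])) {
  dvals <- vapply(loci, function(l) {
    tabs <- locus_pop_tables(calls, list(idx1, idx2), l)
    jost_d_locus(tabs)
  }, 0)
  dvals <- dvals[!is.na(dvals)]
  if (!length(dvals)) return(NA_real_)
  # harmonic mean across loci; non-positive locus values are floored at a
  # tiny positive constant, which drives the harmonic mean towards zero
  dpos <- pmax(dvals, 1e-12)
  hm <- length(dpos) / sum(1 / dpos)
  if (hm < 1e-9) 0 else hm
}

#' Pairwise population differentiation: Weir-Cockerham theta and Jost's D
#'
#' Multilocus \eqn{\theta} follows Weir & Cockerham (1984):
#' \eqn{\sum_l a_l / \sum_l (a_l + b_l + c_l)} over variance components
#' summed across alleles and loci. Jost's \eqn{D_{est}} uses Nei-Chesser
#' bias-corrected \eqn{H_S, H_T} per locus and a harmonic mean across loci.
#' Negative theta values are reported raw.
#'
#' @param gt a [genotype_matrix()].
#' @param popmap a [pop_map()] with at least two populations.
#' @return list of two [pairwise_matrix()] objects `theta` and `jost_d`.
#' @export
pairwise_differentiation <- function(gt, popmap) {
  pops <- popmap_lookup(popmap, gt$ids)
  upops <- unique(pops)
  if (length(upops) < 2L) stop("need >=2 populations")
  k <- length(upops)
  theta <- dmat <- matrix(0, k, k, dimnames = list(upops, upops))
  idx_by_pop <- lapply(upops, function(p) which(pops == p))
  for (a in seq_len(k - 1)) {
    for (b in seq.int(a + 1, k)) {
      th <- wc_theta_pair(gt$calls, idx_by_pop[[a]], idx_by_pop[[b]])
      dd <- jost_d_pair(gt$calls, idx_by_pop[[a]], idx_by_pop[[b]])
      theta[a, b] <- theta[b, a] <- th
      dmat[a, b] <- dmat[b, a] <- dd
    }
  }
  list(theta = pairwise_matrix(theta, "WC_theta"),
       jost_d = pairwise_matrix(dmat, "Jost_D"))
}

#' Linear model of genetic diversity against a land-use covariate
#'
#' Ordinary least squares of a per-population diversity measure (e.g.
#' rarefied allelic richness or mean inbreeding) on a per-population
#' land-use covariate (e.g. arable-land fraction within a buffer), with the
#' F-test of the slope on (1, n-2) degrees of freedom.
#'
#' @param response numeric vector, one value per population.
#' @param covariate numeric vector, same length (>= 3).
#' @return list with `slope`, `intercept`, `F`, `df` (c(1, n-2)), `p`,
#'   `r_squared`, and the underlying `lm` fit.
#' @export
diversity_landuse_regression <- function(response, covariate) {
  if (length(response) != length(covariate)) stop("length mismatch")
  if (length(response) < 3L) stop("need >=3 populations")
  if (stats::sd(covariate) == 0) stop("zero-variance covariate")
  fit <- stats::lm(response ~ covariate)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       F = unname(fstat[1]), df = unname(fstat[2:3]),
       p = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
       r_squared = sm$r.squared, fit = fit)
}
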