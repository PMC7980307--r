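#' Simulate a mixed microsatellite + mtDNA dataset under a scenario
#'
#' Backward-in-time coalescent simulation of `n_loci` unlinked autosomal
#' microsatellite loci (2 lineages per diploid; generalized stepwise
#' mutation with geometrically distributed step sizes and reflecting
#' allele-size bounds) and one fully linked mitochondrial tree carrying
#' two partitions (coding: HKY + invariant sites; control region: HKY +
#' gamma rates) with one lineage per individual and effective size `N/4`
#' (maternally inherited haploid marker).
#'
#' @param scenario a [demographic_scenario()] or id 1-4.
#' @param params named parameter vector as produced by [sample_priors()]
#'   (demographic entries; `mu_ms`/`gsm_p`/`mu_mt` entries override the
#'   mutation model's rates when present).
#' @param n_s,n_n diploid sample sizes south / north (defaults 22 and 28).
#' @param mutation a [mutation_model()].
#' @param n_loci number of microsatellite loci (default 19).
#' @param seed integer seed (required; drives a dedicated simulator RNG).
#' @param raw if `TRUE` return raw integer matrices (fast path for
#'   reference tables); otherwise wrap into package containers.
#' @return if `raw`, a list with `ms` (n x 2*n_loci allele sizes), `mt`
#'   (n x L base indices 0-3), `tmrca`, `overflow`, `n_s`; otherwise a
#'   list with `gt` ([genotype_matrix()]), `aln` ([seq_alignment()] with
#'   `cytb`/`hv1` partitions), `popmap` (populations `"S"`, `"N"`), and
#'   `truth` (scenario id and parameters).
#' @export
simulate_dataset <- function(scenario, params, n_s = 22, n_n = 28,
                             mutation = mutation_model(), n_loci = 19,
                             seed, raw = FALSE) {
  if (missing(seed)) stop("simulate_dataset requires an explicit seed")
  if (!inherits(scenario, "demographic_scenario")) {
    scenario <- demographic_scenario(scenario)
  }
  p <- as.list(params)
  need <- c("N_S", "N_N", "N_A", "t_split")
  if (!all(need %in% names(p))) {
    stop("params must include ", paste(need, collapse = ", "))
  }
  if (is.null(p$N_S0)) p$N_S0 <- p$N_S
  if (is.null(p$N_N0)) p$N_N0 <- p$N_N
  if (is.null(p$t_dec)) p$t_dec <- p$t_split / 2
  mu_ms <- if (!is.null(p$mu_ms)) p$mu_ms else mutation$mu_ms
  gsm_p <- if (!is.null(p$gsm_p)) p$gsm_p else mutation$gsm_p
  mu_mt <- if (!is.null(p$mu_mt)) p$mu_mt else mutation$mu_mt
  out <- .sim_dataset_cpp(as.integer(n_s), as.integer(n_n),
                          p$N_S, p$N_N, p$N_S0, p$N_N0, p$N_A,
                          p$t_dec, p$t_split,
                          as.integer(n_loci), mu_ms, gsm_p,
                          mutation$size_root, mutation$size_min,
                          mutation$size_max,
                          mu_mt, mutation$kappa, mutation$base_freq,
                          mutation$prop_inv, mutation$gamma_shape,
                          mutation$len_cytb, mutation$len_hv1,
                          0.25, as.integer(seed %% .Machine$integer.max))
  out$n_s <- as.integer(n_s)
  if (raw) return(out)
  n <- n_s + n_n
  ids <- sprintf("ind%03d", seq_len(n))
  pops <- c(rep("S", n_s), rep("N", n_n))
  calls <- array(NA_integer_, c(n, n_loci, 2L))
  calls[, , 1] <- out$ms[, 2 * seq_len(n_loci) - 1, drop = FALSE]
  calls[, , 2] <- out$ms[, 2 * seq_len(n_loci), drop = FALSE]
  gt <- genotype_matrix(calls, ids, sprintf("locus%02d", seq_len(n_loci)))
  bases <- c("A", "C", "G", "T")
  L <- mutation$len_cytb + mutation$len_hv1
  seqs <- apply(out$mt, 1, function(r) paste(bases[r + 1L], collapse = ""))
  aln <- seq_alignment(ids, seqs,
                       partitions = list(cytb = c(1L, mutation$len_cytb),
                                         hv1 = c(mutation$len_cytb + 1L, L)))
  list(gt = gt, aln = aln, popmap = pop_map(ids, pops),
       truth = list(scenario = scenario$id, params = unlist(p)),
       tmrca = out$tmrca, overflow = out$overflow)
}

#' Names and order of the 18 ABC summary statistics
#'
#' Microsatellites: mean alleles per locus (S, N), mean unbiased expected
#' heterozygosity (S, N), mean allele-size variance (S, N), pairwise
#' Weir-Cockerham theta, shared-allele classification index (mean Jaccard
#' overlap of allele sets between S and N), Goldstein's (delta mu)^2, and
#' the Garza-Williamson M ratio (mean allele count over allele-size range,
#' S and N) which is sensitive to recent bottlenecks. mtDNA: haplotype
#' count (S, N), per-site nucleotide diversity (S, N), Tajima's D (S, N),
#' and between-population per-site divergence (Dxy). Degenerate statistics
#' (e.g. Tajima's D with no segregating sites) are set to 0.
#'
#' @return character vector of length 18.
#' @export
summary_stat_names <- function() {
  c("nal_S", "nal_N", "he_S", "he_N", "sizevar_S", "sizevar_N",
    "fst_ms", "allele_share", "dmu2",
    "mratio_S", "mratio_N", "hap_S", "hap_N", "pi_S", "pi_N",
    "tajd_S", "tajd_N", "dxy_mt")
}

#' Compute the 18 ABC summary statistics for a dataset
#'
#' For container input (`gt`/`aln`/`popmap`) the statistics are computed
#' through the package's population-genetic functions; for the raw
#' simulator output a compiled kernel produces identical values (asserted
#' by the test suite), which is the path used when building large
#' reference tables.
#'
#' @param ds output of [simulate_dataset()] (raw or container form), or a
#'   list with `gt`, `aln`, `popmap` for observed data (populations must
#'   be labelled `"S"` and `"N"`).
#' @return named numeric vector of length 18 (see [summary_stat_names()]).
#' @export
summarize_dataset <- function(ds) {
  if (!is.null(ds$ms)) {
    s <- .summary_stats_cpp(ds$ms, ds$mt, ds$n_s)
    names(s) <- summary_stat_names()
    return(s)
  }
  gt <- ds$gt; aln <- ds$aln; popmap <- ds$popmap
  pops <- popmap_lookup(popmap, gt$ids)
  if (!setequal(unique(pops), c("S", "N"))) {
    stop("summarize_dataset expects populations labelled S and N")
  }
  idxS <- which(pops == "S"); idxN <- which(pops == "N")
  L <- length(gt$loci)
  per_pop <- function(idx) {
    cl <- lapply(seq_len(L), function(l)
      allele_counts(gt$calls[idx, l, 1], gt$calls[idx, l, 2]))
    nal <- mean(vapply(cl, length, 0L))
    he <- mean(vapply(cl, he_unbiased, 0), na.rm = TRUE)
    sizevar <- mean(vapply(seq_len(L), function(l) {
      x <- c(gt$calls[idx, l, 1], gt$calls[idx, l, 2])
      stats::var(x[!is.na(x)])
    }, 0))
    mratio <- mean(vapply(cl, function(cnt) {
      sz <- as.integer(names(cnt))
      length(cnt) / (max(sz) - min(sz) + 1)
    }, 0))
    c(nal = nal, he = he, sizevar = sizevar, mratio = mratio)
  }
  ms_s <- per_pop(idxS); ms_n <- per_pop(idxN)
  theta <- wc_theta_pair(gt$calls, idxS, idxN)
  share <- mean(vapply(seq_len(L), function(l) {
    aS <- names(allele_counts(gt$calls[idxS, l, 1], gt$calls[idxS, l, 2]))
    aN <- names(allele_counts(gt$calls[idxN, l, 1], gt$calls[idxN, l, 2]))
    length(intersect(aS, aN)) / length(union(aS, aN))
  }, 0))
  dmu2 <- mean(vapply(seq_len(L), function(l) {
    mS <- mean(c(gt$calls[idxS, l, ]), na.rm = TRUE)
    mN <- mean(c(gt$calls[idxN, l, ]), na.rm = TRUE)
    (mS - mN)^2
  }, 0))
  alnS <- aln_subset(aln, gt$ids[idxS])
  alnN <- aln_subset(aln, gt$ids[idxN])
  mt_pop <- function(a) {
    dv <- mtdna_diversity(a)
    m <- a$mat
    seg <- sum(apply(m, 2, function(col) {
      b <- col[col %in% c("A", "C", "G", "T")]
      length(unique(b)) > 1
    }))
    pw <- pairwise_site_diffs(m)
    k <- mean(pw$diff[upper.tri(pw$diff)])
    c(hap = dv$Hap, seg = seg, pi = dv$Pi,
      tajd = tajima_d_r(seg, k, nrow(m)))
  }
  mt_s <- mt_pop(alnS); mt_n <- mt_pop(alnN)
  div <- mtdna_divergence(aln, popmap)
  s <- c(ms_s[["nal"]], ms_n[["nal"]], ms_s[["he"]], ms_n[["he"]],
         ms_s[["sizevar"]], ms_n[["sizevar"]], theta, share, dmu2,
         ms_s[["mratio"]], ms_n[["mratio"]],
         mt_s[["hap"]], mt_n[["hap"]],
         mt_s[["pi"]], mt_n[["pi"]], mt_s[["tajd"]], mt_n[["tajd"]],
         div$dxy["S", "N"])
  s[!is.finite(s)] <- 0
  stats::setNames(s, summary_stat_names())
}

# Tajima's D from segregating sites and mean pairwise difference count
tajima_d_r <- function(S, pi_count, n) {
  if (S <= 0 || n < 4) return(0)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  V <- c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1)
  if (V <= 0) return(0)
  (pi_count - S / a1) / sqrt(V)
}
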