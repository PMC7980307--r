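test_that("monomorphic and rarefaction-identity cases behave", {
  # two pops, one monomorphic locus + one with g = N giving Ar = Na
  gt <- gt_fixture(list(
    list(c(100, 100), c(101, 102)),
    list(c(100, 100), c(101, 101)),
    list(c(100, 100), c(103, 104)),
    list(c(100, 100), c(103, 103))))
  pm <- pop_map(gt$ids, c("A", "A", "B", "B"))
  ms <- microsat_summaries(gt, pm, rarefaction_g = 4)
  # locus 1 monomorphic: Na = 1, Ar = 1, He = 0 contribution
  expect_equal(ms$Na, c(1.5, 1.5))
  # g = N = 4 genes: rarefied richness equals observed count
  # pop A locus 2 alleles {101 x3, 102 x1} -> 2 alleles
  expect_equal(ms$Ar[ms$population == "A"], mean(c(1, 2)))
  he_obs <- ms$He[ms$population == "A"]
  # unbiased He at locus2: 4/3 * (1 - (9+1)/16)
  expect_equal(he_obs, mean(c(0, 4 / 3 * (1 - 10 / 16))), tolerance = 1e-12)
})

test_that("rarefied richness matches exhaustive subsample enumeration", {
  # one locus, 2 diploids, copies {A:3, B:1}, g = 2:
  # over all C(4,2)=6 gene pairs, mean distinct alleles = (3*1 + 3*2)/6 = 1.5
  counts <- c(`100` = 3L, `101` = 1L)
  expect_equal(skyisland:::rarefied_richness(counts, 2), 1.5)

  # exhaustive oracle on random locus configurations
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    cnt <- stats::setNames(sample(1:4, k, replace = TRUE),
                           as.character(100 + seq_len(k)))
    N <- sum(cnt)
    g <- sample(2:N, 1)
    genes <- rep(names(cnt), cnt)
    combs <- utils::combn(N, g)
    oracle <- mean(apply(combs, 2, function(ix) length(unique(genes[ix]))))
    expect_equal(skyisland:::rarefied_richness(cnt, g), oracle,
                 tolerance = 1e-10)
  }
})

test_that("Ar is monotone in g and private alleles are counted per pop", {
  set.seed(11)
  gt <- random_gt(12, list(c(`100` = .4, `102` = .3, `104` = .3),
                           c(`200` = .6, `201` = .4)), seed = 12)
  pm <- pop_map(gt$ids, rep(c("A", "B"), each = 6))
  ar <- vapply(2:8, function(g)
    mean(microsat_summaries(gt, pm, rarefaction_g = g)$Ar), 0)
  expect_true(all(diff(ar) >= -1e-12))

  # forced private allele: allele 999 only in pop A
  gt2 <- gt_fixture(list(list(c(999, 100)), list(c(100, 100)),
                         list(c(100, 100)), list(c(100, 100))))
  pm2 <- pop_map(gt2$ids, c("A", "A", "B", "B"))
  ms2 <- microsat_summaries(gt2, pm2, rarefaction_g = 2)
  expect_equal(ms2$Pa[ms2$population == "A"], 1L)
  expect_equal(ms2$Pa[ms2$population == "B"], 0L)
})

test_that("ML inbreeding hits the boundaries and matches a grid search", {
  # all heterozygous -> F = 0; all homozygous (freqs < 1) -> F = 1
  gt <- gt_fixture(list(
    list(c(100, 101), c(200, 201)),
    list(c(100, 100), c(200, 200)),
    list(c(100, 101), c(200, 200))))
  pm <- pop_map(gt$ids, rep("P", 3))
  fit <- inbreeding_ml(gt, pm)
  expect_equal(fit$individual$F[1], 0, tolerance = 1e-5)
  expect_equal(fit$individual$F[2], 1, tolerance = 1e-5)

  # grid-search oracle for the mixed individual
  counts1 <- skyisland:::allele_counts(gt$calls[, 1, 1], gt$calls[, 1, 2])
  counts2 <- skyisland:::allele_counts(gt$calls[, 2, 1], gt$calls[, 2, 2])
  f1 <- counts1 / sum(counts1); f2 <- counts2 / sum(counts2)
  grid <- seq(0, 1, by = 1e-4)
  ll <- vapply(grid, function(f) {
    p_het <- 2 * f1["100"] * f1["101"] * (1 - f)
    p_hom <- f2["200"]^2 + f * f2["200"] * (1 - f2["200"])
    log(p_het) + log(p_hom)
  }, 0)
  expect_equal(fit$individual$F[3], grid[which.max(ll)], tolerance = 2e-4)
})

test_that("HWE Monte-Carlo test separates balanced and pathological loci", {
  # perfectly HWE-proportioned: 5 AA, 10 AB, 5 BB
  calls <- c(rep(list(list(c(1, 1))), 5), rep(list(list(c(1, 2))), 10),
             rep(list(list(c(2, 2))), 5))
  gt <- gt_fixture(calls)
  pm <- pop_map(gt$ids, rep("P", 20))
  qc <- marker_qc(gt, pm, n_perm = 500, seed = 71)
  expect_gt(qc$hwe_p[1, "P"], 0.5)
  expect_true(qc$flags$retain[1])

  # all homozygotes at a 50/50 two-allele locus, n = 20
  calls2 <- c(rep(list(list(c(1, 1))), 10), rep(list(list(c(2, 2))), 10))
  gt2 <- gt_fixture(calls2)
  qc2 <- marker_qc(gt2, pm, n_perm = 2000, seed = 72)
  expect_lt(qc2$hwe_p[1, "P"], 0.01)
  expect_false(qc2$flags$retain[1])

  # monomorphic convention
  gt3 <- gt_fixture(rep(list(list(c(5, 5))), 20))
  qc3 <- marker_qc(gt3, pm, n_perm = 200, seed = 73)
  expect_equal(qc3$hwe_p[1, "P"], 1)
})

test_that("null allele frequency follows the He/Ho formula", {
  # He = 0.5, Ho = 0.4 -> r = 0.1/0.9
  expect_equal(max(0, (0.5 - 0.4) / (0.5 + 0.4)), 1 / 9, tolerance = 1e-12)
  # floored at zero when Ho > He
  expect_equal(max(0, (0.3 - 0.5) / (0.3 + 0.5)), 0)
})

test_that("Weir-Cockerham theta matches a hand-computed variance-component oracle", {
  # 2 pops, 1 locus, explicit genotypes
  gt <- gt_fixture(list(
    list(c(1, 1)), list(c(1, 2)), list(c(2, 2)),       # pop A
    list(c(2, 2)), list(c(2, 3)), list(c(3, 3)), list(c(2, 3)))) # pop B
  pm <- pop_map(gt$ids, c(rep("A", 3), rep("B", 4)))
  diff <- pairwise_differentiation(gt, pm)
  # independent implementation of WC84 written directly in the test
  oracle_theta <- local({
    n1 <- 3; n2 <- 4; r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    A <- B <- C <- 0
    for (al in 1:3) {
      cnt1 <- sum(gt$calls[1:3, 1, ] == al)
      cnt2 <- sum(gt$calls[4:7, 1, ] == al)
      h1 <- sum(gt$calls[1:3, 1, 1] != gt$calls[1:3, 1, 2] &
                  (gt$calls[1:3, 1, 1] == al | gt$calls[1:3, 1, 2] == al))
      h2 <- sum(gt$calls[4:7, 1, 1] != gt$calls[4:7, 1, 2] &
                  (gt$calls[4:7, 1, 1] == al | gt$calls[4:7, 1, 2] == al))
      p1 <- cnt1 / (2 * n1); p2 <- cnt2 / (2 * n2)
      pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      hbar <- (h1 + h2) / (r * nbar)
      A <- A + nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      B <- B + nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                      (2 * nbar - 1) / (4 * nbar) * hbar)
      C <- C + hbar / 2
    }
    A / (A + B + C)
  })
  expect_equal(unname(diff$theta["A", "B"]), oracle_theta, tolerance = 1e-10)
})

test_that("differentiation hits its extremes", {
  # fixed for different alleles at every locus -> theta = 1, D = 1
  gt <- gt_fixture(list(
    list(c(1, 1), c(5, 5)), list(c(1, 1), c(5, 5)),
    list(c(2, 2), c(9, 9)), list(c(2, 2), c(9, 9))))
  pm <- pop_map(gt$ids, c("A", "A", "B", "B"))
  diff <- pairwise_differentiation(gt, pm)
  expect_equal(unname(diff$theta["A", "B"]), 1)
  expect_equal(unname(diff$jost_d["A", "B"]), 1, tolerance = 1e-9)

  # identical tables -> theta <= 0 (raw), D ~ 0
  gt2 <- gt_fixture(list(
    list(c(1, 2), c(5, 6)), list(c(1, 1), c(6, 6)),
    list(c(1, 2), c(5, 6)), list(c(1, 1), c(6, 6))))
  diff2 <- pairwise_differentiation(gt2, pm)
  expect_lte(unname(diff2$theta["A", "B"]), 0)
  expect_lt(abs(diff2$jost_d["A", "B"]), 0.05)
})

test_that("theta and D are invariant to individual order and allele relabeling", {
  set.seed(44)
  gt <- random_gt(16, list(c(`100` = .5, `104` = .3, `108` = .2),
                           c(`200` = .7, `202` = .3),
                           c(`300` = .25, `301` = .25, `302` = .5)), seed = 45)
  pm <- pop_map(gt$ids, rep(c("A", "B"), each = 8))
  d1 <- pairwise_differentiation(gt, pm)
  ord <- sample(length(gt$ids))
  gt_perm <- gt_subset(gt, ord)
  d2 <- pairwise_differentiation(gt_perm, pm)
  expect_equal(unname(d1$theta["A", "B"]), unname(d2$theta["A", "B"]),
               tolerance = 1e-12)
  # relabel allele sizes with an arbitrary injective map
  calls <- gt$calls
  calls[] <- calls + 1000L * (calls %% 7L)
  gt_rel <- genotype_matrix(calls, gt$ids, gt$loci)
  d3 <- pairwise_differentiation(gt_rel, pm)
  expect_equal(unname(d1$theta["A", "B"]), unname(d3$theta["A", "B"]),
               tolerance = 1e-12)
  expect_equal(unname(d1$jost_d["A", "B"]), unname(d3$jost_d["A", "B"]),
               tolerance = 1e-12)
})

test_that("panmictic populations concentrate theta and D near zero", {
  set.seed(77)
  freqs <- lapply(1:19, function(l) {
    k <- sample(3:8, 1)
    p <- stats::runif(k); p <- p / sum(p)
    stats::setNames(p, as.character(100 + 2 * seq_len(k)))
  })
  th <- dd <- numeric(200)
  for (r in 1:200) {
    gt <- random_gt(50, freqs, seed = 1000 + r)
    pm <- pop_map(gt$ids, rep(c("A", "B"), each = 25))
    diff <- pairwise_differentiation(gt, pm)
    th[r] <- diff$theta["A", "B"]
    dd[r] <- diff$jost_d["A", "B"]
  }
  expect_lt(abs(mean(th)), 0.02)
  expect_lt(abs(mean(dd)), 0.02)
})

test_that("diversity-landuse regression matches the closed-form oracle", {
  x <- c(0.1, 0.3, 0.45, 0.6, 0.8)
  y <- c(6.1, 5.8, 5.9, 5.2, 5.0)
  fit <- diversity_landuse_regression(y, x)
  # normal-equation oracle
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  Fstat <- r2 / (1 - r2) * (5 - 2)
  expect_equal(fit$slope, b, tolerance = 1e-12)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)
  expect_equal(fit$F, Fstat, tolerance = 1e-10)
  expect_equal(fit$df, c(1, 3))

  # exact collinearity -> R2 = 1; zero slope -> F ~ 0
  fitc <- diversity_landuse_regression(2 + 3 * x, x)
  expect_equal(fitc$r_squared, 1, tolerance = 1e-12)
  set.seed(8)
  # data constructed with exactly zero empirical slope
  y0 <- 5 + stats::residuals(stats::lm(stats::rnorm(5) ~ x))
  expect_lt(diversity_landuse_regression(y0, x)$F, 1e-12)
  expect_error(diversity_landuse_regression(y, rep(1, 5)), "zero-variance")
})
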