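test_that("prior draws respect bounds, constraints, and degenerate bounds", {
  spec <- prior_spec(t_split = list(dist = "uniform", min = 5000, max = 5000))
  d <- sample_priors(spec, 1, seed = 1)
  expect_equal(d[["t_split"]], 5000)

  spec2 <- prior_spec()
  draws <- t(vapply(1:500, function(i) sample_priors(spec2, 4, seed = i),
                    numeric(10)))
  expect_true(all(draws[, "t_dec"] < draws[, "t_split"]))
  expect_true(all(draws[, "N_S0"] > draws[, "N_S"]))
  expect_true(all(draws[, "mu_ms"] >= 1e-4 & draws[, "mu_ms"] <= 1e-3))

  # uniform moments: mean of t_split ~ U(100, 100000)
  big <- vapply(1:10000, function(i)
    sample_priors(spec2, 1, seed = 20000 + i)[["t_split"]], 0)
  se <- stats::sd(big) / sqrt(length(big))
  expect_lt(abs(mean(big) - 50050), 3 * se)

  expect_error(prior_spec(t_split = list(dist = "uniform", min = 10, max = 1)),
               "invalid bounds")
  expect_error(prior_spec(bogus = list(dist = "uniform", min = 0, max = 1)),
               "unknown prior")
})

test_that("scenario constraints implement the four histories", {
  spec <- prior_spec()
  for (i in 1:50) {
    d1 <- sample_priors(spec, 1, seed = 100 + i)
    expect_gt(d1[["N_A"]], max(d1[["N_S"]], d1[["N_N"]]))
    d2 <- sample_priors(spec, 2, seed = 200 + i)
    expect_lt(d2[["N_A"]], min(d2[["N_S"]], d2[["N_N"]]))
    d3 <- sample_priors(spec, 3, seed = 300 + i)
    expect_gt(d3[["N_S0"]], d3[["N_S"]])
    expect_gt(d3[["N_N0"]], d3[["N_N"]])
  }
})

test_that("pairwise coalescence times match 2N (nuclear) and N/2 (mtDNA)", {
  N <- 5000
  reps <- 800
  tm <- matrix(0, reps, 2)
  for (i in seq_len(reps)) {
    x <- skyisland:::.sim_dataset_cpp(1L, 0L, N, N, N, N, N, 0, 0,
                                      1L, 1e-9, 0, 100L, 50L, 150L,
                                      1e-9, 2, rep(.25, 4), 0, 0, 4L, 0L,
                                      0.25, 5000L + i)
    # one diploid individual: the single microsat tree has 2 tips
    tm[i, 1] <- x$tmrca[1]
    x2 <- skyisland:::.sim_dataset_cpp(2L, 0L, N, N, N, N, N, 0, 0,
                                       0L, 1e-9, 0, 100L, 50L, 150L,
                                       1e-9, 2, rep(.25, 4), 0, 0, 4L, 0L,
                                       0.25, 90000L + i)
    tm[i, 2] <- x2$tmrca[1]
  }
  se1 <- stats::sd(tm[, 1]) / sqrt(reps)
  se2 <- stats::sd(tm[, 2]) / sqrt(reps)
  expect_lt(abs(mean(tm[, 1]) - 2 * N), 3 * se1)
  expect_lt(abs(mean(tm[, 2]) - 2 * (N / 4)), 3 * se2)
})

test_that("allele-size bounds reflect and overflow is counted", {
  # absurdly high rate forces the walk into the bounds
  x <- skyisland:::.sim_dataset_cpp(5L, 0L, 2000, 2000, 2000, 2000, 2000,
                                    0, 0, 2L, 0.05, 0.4, 100L, 95L, 105L,
                                    1e-9, 2, rep(.25, 4), 0, 0, 4L, 0L,
                                    0.25, 7L)
  expect_true(all(x$ms >= 95 & x$ms <= 105))
  expect_gt(x$overflow, 0)
})

test_that("GSM allele-size divergence grows with split time", {
  spec_grid <- seq(1000, 40000, length.out = 25)
  dmu2 <- vapply(seq_along(spec_grid), function(k) {
    vals <- vapply(1:8, function(r) {
      ds <- simulate_dataset(1, c(N_S = 3000, N_N = 3000, N_A = 3000,
                                  t_split = spec_grid[k]),
                             n_s = 10, n_n = 10,
                             seed = 1e5 + k * 100 + r, raw = TRUE)
      skyisland:::.summary_stats_cpp(ds$ms, ds$mt, ds$n_s)[9]
    }, 0)
    mean(vals)
  }, 0)
  fit <- summary(stats::lm(dmu2 ~ spec_grid))
  expect_gt(fit$coefficients[2, 1], 0)
  expect_lt(fit$coefficients[2, 4], 0.01)
})

test_that("scenario nesting: equal pre/post sizes reproduce the no-change history", {
  # scenario 4 with N_S0 = N_S (and scenario 2 with N_A = N_S = N_N) must be
  # distributionally identical to scenario 1 at the same sizes
  base <- c(N_S = 4000, N_N = 6000, N_A = 20000, t_split = 20000)
  p4 <- c(base, N_S0 = 4000, t_dec = 300)
  reps <- 400
  s1 <- s4 <- matrix(0, reps, 18)
  for (i in seq_len(reps)) {
    d1 <- simulate_dataset(1, base, n_s = 12, n_n = 12, seed = 3e5 + i,
                           raw = TRUE)
    d4 <- simulate_dataset(4, p4, n_s = 12, n_n = 12, seed = 6e5 + i,
                           raw = TRUE)
    s1[i, ] <- skyisland:::.summary_stats_cpp(d1$ms, d1$mt, d1$n_s)
    s4[i, ] <- skyisland:::.summary_stats_cpp(d4$ms, d4$mt, d4$n_s)
  }
  for (j in seq_len(18)) {
    se <- sqrt(stats::var(s1[, j]) / reps + stats::var(s4[, j]) / reps)
    if (se == 0) {
      expect_equal(mean(s1[, j]), mean(s4[, j]))
    } else {
      expect_lt(abs(mean(s1[, j]) - mean(s4[, j])), 4 * se)
    }
  }
})

test_that("summary statistics have fixed length/order and flag degenerate data", {
  ds <- simulate_dataset(1, c(N_S = 2000, N_N = 2000, N_A = 9000,
                              t_split = 10000), n_s = 8, n_n = 8, seed = 2)
  s <- summarize_dataset(list(gt = ds$gt, aln = ds$aln, popmap = ds$popmap))
  expect_length(s, 18L)
  expect_identical(names(s), summary_stat_names())
  # fully monomorphic dataset: all diversity statistics zero
  gt0 <- gt_fixture(rep(list(list(c(100, 100))), 6))
  aln0 <- aln_fixture(rep("ACGTACGT", 6), ids = gt0$ids)
  pm0 <- pop_map(gt0$ids, rep(c("S", "N"), each = 3))
  s0 <- summarize_dataset(list(gt = gt0, aln = aln0, popmap = pm0))
  expect_equal(unname(s0[c("he_S", "he_N", "sizevar_S", "sizevar_N",
                           "pi_S", "pi_N", "tajd_S", "tajd_N", "dxy_mt")]),
               rep(0, 9))
  expect_equal(unname(s0[c("nal_S", "nal_N", "hap_S", "hap_N")]),
               c(1, 1, 1, 1))
})

test_that("raw (compiled) and container (popgen) summary paths agree", {
  p <- c(N_S = 5000, N_N = 8000, N_A = 20000, N_S0 = 30000,
         t_split = 30000, t_dec = 100)
  for (s in 1:4) {
    raw <- simulate_dataset(4, p, n_s = 9, n_n = 11, seed = s, raw = TRUE)
    full <- simulate_dataset(4, p, n_s = 9, n_n = 11, seed = s)
    expect_equal(unname(summarize_dataset(raw)),
                 unname(summarize_dataset(list(gt = full$gt, aln = full$aln,
                                               popmap = full$popmap))),
                 tolerance = 1e-12)
  }
})

test_that("the F_ST summary entry equals the popgen estimator on the same data", {
  ds <- simulate_dataset(1, c(N_S = 3000, N_N = 3000, N_A = 15000,
                              t_split = 30000), n_s = 10, n_n = 10, seed = 8)
  s <- summarize_dataset(list(gt = ds$gt, aln = ds$aln, popmap = ds$popmap))
  diff <- pairwise_differentiation(ds$gt, ds$popmap)
  expect_equal(unname(s["fst_ms"]), unname(diff$theta["S", "N"]),
               tolerance = 1e-12)
})
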