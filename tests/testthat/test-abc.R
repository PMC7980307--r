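# Small shared reference table for the cheap ABC behaviour tests
abc_test_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      tab <<- build_reference_table(prior_spec(), 1:4, 150, seed = 99,
                                    n_s = 10, n_n = 12, n_loci = 10)
    }
    tab
  }
})

test_that("reference tables have the right shape and are seed-reproducible", {
  spec <- prior_spec()
  t1 <- build_reference_table(spec, 1:4, 25, seed = 5, n_s = 6, n_n = 6,
                              n_loci = 5)
  expect_equal(nrow(t1$stats), 100L)
  expect_equal(tabulate(t1$scenario), rep(25L, 4))
  t2 <- build_reference_table(spec, 1:4, 25, seed = 5, n_s = 6, n_n = 6,
                              n_loci = 5)
  expect_identical(t1$stats, t2$stats)
  expect_identical(t1$params, t2$params)
  t3 <- build_reference_table(spec, 1:4, 25, seed = 6, n_s = 6, n_n = 6,
                              n_loci = 5)
  expect_false(identical(t1$stats, t3$stats))
})

test_that("reference tables round-trip through manifest CSV", {
  tab <- build_reference_table(prior_spec(), c(1, 4), 10, seed = 9,
                               n_s = 5, n_n = 5, n_loci = 4)
  path <- tempfile(fileext = ".csv")
  write_reference_table(tab, path)
  back <- read_reference_table(path)
  expect_equal(back$stats, tab$stats, tolerance = 1e-9)
  expect_equal(back$scenario, tab$scenario)
  expect_equal(back$seed, tab$seed)
})

test_that("model choice returns proper probabilities and honours duplication", {
  tab <- abc_test_table()
  obs <- tab$stats[7, ]
  mc <- suppressWarnings(model_choice(obs, tab, tolerance = 0.1))
  expect_equal(sum(mc$direct), 1, tolerance = 1e-9)
  expect_equal(sum(mc$regression), 1, tolerance = 1e-6)
  expect_true(mc$selected %in% 1:4)
  # duplicating every row must not change the result
  tab2 <- tab
  tab2$stats <- rbind(tab$stats, tab$stats)
  tab2$params <- rbind(tab$params, tab$params)
  tab2$scenario <- c(tab$scenario, tab$scenario)
  mc2 <- suppressWarnings(model_choice(obs, tab2, tolerance = 0.1))
  expect_equal(mc$direct, mc2$direct, tolerance = 1e-9)
  expect_error(model_choice(obs, tab, tolerance = 0), "tolerance")
})

test_that("identically defined scenarios split the posterior evenly", {
  # two copies of the same history competing: probabilities ~ (0.5, 0.5)
  spec <- prior_spec()
  n <- 400
  stats_m <- matrix(0, 2 * n, 18)
  for (i in seq_len(2 * n)) {
    d <- sample_priors(spec, 1, seed = 4000 + i)
    ds <- simulate_dataset(1, d, n_s = 8, n_n = 8, n_loci = 8,
                           seed = 40000 + i, raw = TRUE)
    stats_m[i, ] <- skyisland:::.summary_stats_cpp(ds$ms, ds$mt, ds$n_s)
  }
  colnames(stats_m) <- summary_stat_names()
  tab <- structure(list(stats = stats_m,
                        params = matrix(0, 2 * n, 1,
                                        dimnames = list(NULL, "N_S")),
                        scenario = rep(c(1L, 2L), each = n),
                        seed = 1L, n_s = 8L, n_n = 8L, n_loci = 8L),
                   class = "reference_table")
  probs <- t(vapply(1:20, function(k) {
    dd <- sample_priors(spec, 1, seed = 90000 + k)
    dso <- simulate_dataset(1, dd, n_s = 8, n_n = 8, n_loci = 8,
                            seed = 95000 + k, raw = TRUE)
    obs <- skyisland:::.summary_stats_cpp(dso$ms, dso$mt, dso$n_s)
    suppressWarnings(model_choice(obs, tab, tolerance = 0.25))$direct
  }, numeric(2)))
  expect_lt(abs(mean(probs[, 1]) - 0.5), 0.1)
})

test_that("rejection-only estimation at full tolerance returns the prior", {
  tab <- abc_test_table()
  spec <- prior_spec()
  obs <- tab$stats[3, ]
  post <- estimate_parameters(obs, tab, 1, spec, tolerance = 1,
                              adjust = FALSE, kernel = "uniform")
  # retained draws are exactly the scenario-1 prior sample
  rows <- tab$scenario == 1
  s <- post$summary[post$summary$parameter == "t_split", ]
  qs <- stats::quantile(tab$params[rows, "t_split"], c(0.025, 0.5, 0.975))
  expect_equal(s$median, qs[[2]], tolerance = 0.05 * diff(range(qs)))
  expect_true(s$ci_lower >= spec$t_split$min - 1e-9)
  expect_true(s$ci_upper <= spec$t_split$max + 1e-9)
  # times reported in years at 2 y/gen
  expect_equal(s$median_years, s$median * 2)
})

test_that("adjusted draws stay inside the prior support and CIs bracket medians", {
  tab <- abc_test_table()
  spec <- prior_spec()
  obs <- tab$stats[nrow(tab$stats), ]
  post <- estimate_parameters(obs, tab, 4, spec, tolerance = 0.3)
  for (pm in names(post$draws)) {
    expect_true(all(post$draws[[pm]] >= spec[[pm]]$min - 1e-6))
    expect_true(all(post$draws[[pm]] <= spec[[pm]]$max + 1e-6))
  }
  s <- post$summary
  expect_true(all(s$ci_lower <= s$median & s$median <= s$ci_upper))
  expect_false(is.null(post$decline_ratio))
  expect_gt(post$decline_ratio$median_of_ratio, 0)
})

test_that("confidence analysis produces a stochastic-matrix confusion table", {
  tab <- abc_test_table()
  spec <- prior_spec()
  rep <- confidence_analysis(tab, spec, n_pods = 8, seed = 17,
                             selected = 4L, tolerance = 0.1, n_loci = 10)
  expect_equal(unname(rowSums(rep$confusion)), rep(1, 4), tolerance = 1e-9)
  expect_true(rep$type1 >= 0 && rep$type1 <= 1)
  expect_length(rep$type2, 3L)
})

test_that("bias and precision formulas match direct evaluation on a toy set", {
  # estimator == truth -> 0/0; estimator == 2x truth -> 1/1
  truths <- c(10, 20, 40, 80, 160)
  est1 <- truths
  est2 <- 2 * truths
  expect_equal(mean((est1 - truths) / truths), 0)
  expect_equal(stats::median(abs(est1 - truths) / truths), 0)
  expect_equal(mean((est2 - truths) / truths), 1)
  expect_equal(stats::median(abs(est2 - truths) / truths), 1)
  # end-to-end run returns finite values per scenario parameter
  tab <- abc_test_table()
  br <- bias_precision(tab, prior_spec(), scenario = 4L, n_pods = 4,
                       seed = 23, tolerance = 0.3, n_loci = 10)
  expect_true(all(is.finite(br$rel_mean_bias)))
  expect_true(all(br$rmedad >= 0))
})

test_that("posterior predictive checks are deterministic and well-calibrated shapes", {
  tab <- abc_test_table()
  spec <- prior_spec()
  obs <- tab$stats[12, ]
  post <- estimate_parameters(obs, tab, 1, spec, tolerance = 0.4)
  ppc <- posterior_predictive_check(post, obs, spec, seed = 31, n_sim = 60,
                                    n_s = 10, n_n = 12, n_loci = 10)
  ppc2 <- posterior_predictive_check(post, obs, spec, seed = 31, n_sim = 60,
                                     n_s = 10, n_n = 12, n_loci = 10)
  expect_identical(ppc$scores, ppc2$scores)
  # PCA rotation is orthonormal
  rot <- ppc$pca$rotation
  expect_equal(unname(as.matrix(crossprod(rot))), diag(ncol(rot)),
               tolerance = 1e-8)
  expect_true(is.logical(ppc$inside_ellipsoid))
  expect_error(posterior_predictive_check(post, obs, spec, seed = 1,
                                          n_sim = 5), "n_sim")
})

test_that("an observation drawn from the posterior predictive lies inside the cloud", {
  tab <- abc_test_table()
  spec <- prior_spec()
  inside <- 0
  for (k in 1:10) {
    d <- sample_priors(spec, 1, seed = 700 + k)
    dso <- simulate_dataset(1, d, n_s = 10, n_n = 12, n_loci = 10,
                            seed = 7000 + k, raw = TRUE)
    obs <- skyisland:::.summary_stats_cpp(dso$ms, dso$mt, dso$n_s)
    post <- estimate_parameters(obs, tab, 1, spec, tolerance = 0.4)
    ppc <- posterior_predictive_check(post, obs, spec, seed = 800 + k,
                                      n_sim = 40, n_s = 10, n_n = 12,
                                      n_loci = 10)
    inside <- inside + ppc$inside_ellipsoid
  }
  expect_gte(inside, 8)
})
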