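test_that("worlds are seed-reproducible and rift cells sit below the montane band", {
  w1 <- make_world(n_side = 60, seed = 3)
  w2 <- make_world(n_side = 60, seed = 3)
  expect_identical(w1$rasters$altitude$values, w2$rasters$altitude$values)
  expect_identical(w1$sites, w2$sites)
  w3 <- make_world(n_side = 60, seed = 4)
  expect_false(identical(w1$rasters$altitude$values,
                         w3$rasters$altitude$values))
  # rift band entirely below the montane threshold
  n <- w1$n_side
  rowm <- matrix(seq_len(n), n, n)
  colm <- matrix(seq_len(n), n, n, byrow = TRUE)
  in_rift <- abs(rowm + colm - (n + 1)) <= w1$rift_half
  expect_true(all(w1$rasters$altitude$values[in_rift] < 2795))
  # sites on distinct cells, 2 south-east / 3 north-west
  expect_equal(nrow(unique(w1$sites[, c("row", "col")])), 5L)
  expect_equal(sum(w1$sites$side == "SE"), 2L)
  expect_equal(sum(w1$sites$side == "NW"), 3L)
})

test_that("site distances match hand-computed values from coordinates", {
  w <- make_world(n_side = 50, seed = 8)
  ed <- euclidean_distances(w$sites)
  i <- 1; j <- 3
  hand <- sqrt((w$sites$x[i] - w$sites$x[j])^2 +
                 (w$sites$y[i] - w$sites$y[j])^2)
  expect_equal(unname(ed[w$sites$label[i], w$sites$label[j]]), hand,
               tolerance = 1e-9)
  # cells are 1 km: distances in metres
  expect_gt(min(lower_vec(ed)), 1000)
})

test_that("arable fraction is anti-correlated with altitude", {
  w <- make_world(n_side = 60, seed = 12)
  expect_lt(stats::cor(as.vector(w$rasters$altitude$values),
                       as.vector(w$rasters$arable$values)), -0.7)
  eco <- w$rasters$ecoregion$values
  expect_true(all(eco %in% 1:3))
})

test_that("ground-truth genetics match configured sizes and manifest round-trips", {
  w <- make_world(n_side = 50, seed = 21)
  gen <- simulate_truth_genetics(w, seed = 22)
  tab <- table(unclass(gen$popmap))
  expect_equal(tab[["BaleD"]], 7L)
  expect_equal(tab[["Simien"]], 12L)
  expect_equal(sum(tab), 46L)
  expect_equal(sum(gen$side_popmap == "S"), 16L)  # BaleD + BaleS
  path <- tempfile()
  write_manifest(gen$manifest, path)
  expect_identical(read_manifest(path), gen$manifest)
})

test_that("a deep split separates cross-rift from within-side differentiation", {
  w <- make_world(n_side = 40, seed = 31)
  cross <- within <- numeric(20)
  for (r in 1:20) {
    gen <- simulate_truth_genetics(
      w, scenario = 1,
      params = c(N_S = 2000, N_N = 2000, N_A = 20000, t_split = 40000),
      seed = 400 + r)
    diff <- pairwise_differentiation(gen$gt, gen$popmap)
    th <- diff$theta
    sides <- stats::setNames(w$sites$side, w$sites$label)
    pairs <- t(utils::combn(rownames(th), 2))
    is_cross <- sides[pairs[, 1]] != sides[pairs[, 2]]
    vals <- th[pairs]
    cross[r] <- mean(vals[is_cross])
    within[r] <- mean(vals[!is_cross])
  }
  expect_gt(mean(cross), mean(within))
})

test_that("injected covariate effects are recovered by the regression", {
  w <- make_world(n_side = 50, seed = 41)
  # zero noise -> exact recovery
  d0 <- inject_covariate_effect(w, slope = -3, noise_sd = 0, seed = 42)
  fit0 <- diversity_landuse_regression(d0$response, d0$covariate)
  expect_equal(fit0$slope, -3, tolerance = 1e-9)
  expect_equal(fit0$r_squared, 1, tolerance = 1e-9)
  # configured slope recovered within 2 SE over replicates
  slopes <- vapply(1:200, function(r) {
    d <- inject_covariate_effect(w, slope = -3, noise_sd = 0.3,
                                 seed = 500 + r)
    diversity_landuse_regression(d$response, d$covariate)$slope
  }, 0)
  se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - (-3)), 2 * se + 1e-9)
})

test_that("with zero true slope the regression rejects at the nominal rate", {
  w <- make_world(n_side = 50, seed = 51)
  pvals <- vapply(1:500, function(r) {
    d <- inject_covariate_effect(w, slope = 0, noise_sd = 0.3,
                                 seed = 900 + r)
    diversity_landuse_regression(d$response, d$covariate)$p
  }, 0)
  rate <- mean(pvals < 0.05)
  # binomial 3 SE band around 0.05 with n = 500
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 500) + 1e-9)
})

test_that("the fixture bundle is written in readable formats", {
  w <- make_world(n_side = 30, seed = 61)
  gen <- simulate_truth_genetics(w, seed = 62)
  dir <- tempfile()
  write_world_bundle(w, gen, dir)
  expect_true(file.exists(file.path(dir, "altitude.asc")))
  alt <- read_ascii_grid(file.path(dir, "altitude.asc"))
  expect_equal(alt$values, w$rasters$altitude$values, tolerance = 1e-6)
  gp <- read_genepop(file.path(dir, "genotypes.gen"))
  expect_equal(length(gp$gt$ids), length(gen$gt$ids))
  expect_identical(gp$gt$calls[, , ], gen$gt$calls[, , ])
  aln <- read_fasta(file.path(dir, "mtdna.fasta"))
  expect_identical(aln$mat, gen$aln$mat)
  pm <- read_popmap(file.path(dir, "popmap.csv"))
  expect_identical(pm, gen$popmap)
})
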