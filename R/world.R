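## Synthetic sky-island study systems with known ground truth.
## The generator emulates a highland study design: five isolated mountain
## massifs on a grid, split 2 vs 3 by one continuous low-altitude rift
## band, with ecoregion classes derived from altitude bands, arable-land
## fraction anti-correlated with altitude, a human-footprint surface, and
## a suitability score increasing with altitude.

#' Generate a synthetic sky-island world
#'
#' Builds a smooth altitude field (metres) with `n_mountains` Gaussian
#' peaks separated into a south-eastern group of 2 and a north-western
#' group of 3 by a diagonal low-altitude rift band, then derives:
#' `ecoregion` classes (1 = lowland < 2795 m, 2 = montane woodland
#' 2795-3500 m, 3 = alpine moorland > 3500 m), `arable` fraction
#' (anti-correlated with altitude, plus noise), `footprint` (human
#' footprint index, higher at low altitude), and a `suitability` score in
#' \[0, 1\] increasing with altitude. Site coordinates are the peak cells,
#' in projected metres (cell size 1000 m).
#'
#' @param n_side grid side length (default 100 cells).
#' @param n_mountains number of peaks (default 5; 2 south-east of the
#'   rift, the rest north-west).
#' @param barrier_depth altitude (m) of the rift floor (default 1500).
#' @param seed master seed; all layers derive from it via counter-based
#'   child seeds.
#' @return `synthetic_world`: list with `rasters` (named list of
#'   [raster_grid()]: altitude, ecoregion, arable, footprint,
#'   suitability), `sites` (data frame `label,row,col,x,y,side`), `truth`
#'   (list with the true cost scheme and covariate effects slots, filled
#'   by downstream generators), and `seed`.
#' @export
make_world <- function(n_side = 100, n_mountains = 5, barrier_depth = 1500,
                       seed) {
  if (missing(seed)) stop("make_world requires a seed")
  if (n_mountains < 2) stop("need at least 2 mountains (one per side)")
  set.seed(child_seed(seed, 1L))
  n_se <- 2L
  n_nw <- n_mountains - n_se
  # rift along the anti-diagonal: cells with |row + col - (n_side+1)| small
  rift_half <- max(3L, round(n_side * 0.06))
  rowm <- matrix(seq_len(n_side), n_side, n_side)
  colm <- matrix(seq_len(n_side), n_side, n_side, byrow = TRUE)
  diagd <- rowm + colm - (n_side + 1)
  in_rift <- abs(diagd) <= rift_half
  # peak centres: jittered positions well away from the rift
  place_peaks <- function(k, side) {
    out <- matrix(0, k, 2)
    tries <- 0
    i <- 1
    while (i <= k) {
      tries <- tries + 1
      if (tries > 5000) stop("could not fit ", k, " peaks on one side")
      r <- sample.int(n_side, 1); c <- sample.int(n_side, 1)
      dd <- r + c - (n_side + 1)
      if (side == "SE" && dd < rift_half + n_side * 0.12) next
      if (side == "NW" && dd > -(rift_half + n_side * 0.12)) next
      if (i > 1 && any(sqrt((out[seq_len(i - 1), 1] - r)^2 +
                            (out[seq_len(i - 1), 2] - c)^2) < n_side * 0.18)) next
      out[i, ] <- c(r, c)
      i <- i + 1
    }
    out
  }
  pk_se <- place_peaks(n_se, "SE")
  pk_nw <- place_peaks(n_nw, "NW")
  peaks <- rbind(pk_se, pk_nw)
  side <- c(rep("SE", n_se), rep("NW", n_nw))
  # altitude: base 2000 m + Gaussian bumps to ~4200 m, rift floor cut down
  alt <- matrix(2000, n_side, n_side)
  sigma <- n_side * 0.10
  for (k in seq_len(nrow(peaks))) {
    d2 <- (rowm - peaks[k, 1])^2 + (colm - peaks[k, 2])^2
    alt <- alt + 2200 * exp(-d2 / (2 * sigma^2))
  }
  alt <- alt + matrix(stats::rnorm(n_side^2, 0, 30), n_side, n_side)
  rift_depth_profile <- barrier_depth +
    (2000 - barrier_depth) * (abs(diagd[in_rift]) / rift_half)^2
  alt[in_rift] <- pmin(alt[in_rift], rift_depth_profile)
  ecoregion <- ifelse(alt < 2795, 1, ifelse(alt <= 3500, 2, 3))
  set.seed(child_seed(seed, 2L))
  altn <- (alt - min(alt)) / (max(alt) - min(alt))
  arable <- pmin(pmax(0.85 - 0.9 * altn +
                        matrix(stats::rnorm(n_side^2, 0, 0.05), n_side), 0), 1)
  set.seed(child_seed(seed, 3L))
  footprint <- pmin(pmax(40 - 35 * altn +
                           matrix(stats::rnorm(n_side^2, 0, 3), n_side), 0), 50)
  suit <- pmin(pmax((alt - 2500) / 1800 +
                      matrix(stats::rnorm(n_side^2, 0, 0.04), n_side), 0), 1)
  cellsize <- 1000
  mk <- function(v) raster_grid(v, cellsize = cellsize)
  sites <- data.frame(
    label = c("BaleD", "BaleS", "Guassa", "Simien", "Abune")[seq_len(n_mountains)],
    row = peaks[, 1], col = peaks[, 2], side = side,
    stringsAsFactors = FALSE)
  xy <- cell_xy(mk(alt), sites$row, sites$col)
  sites$x <- xy[, "x"]; sites$y <- xy[, "y"]
  # true resistance scheme: movement is cheap through high ground,
  # expensive through the lowland rift
  true_scheme <- cost_scheme("ecoregion", "true-ecoregion",
                             data.frame(from = c(1, 2, 3), to = c(1, 2, 3),
                                        cost = c(100, 10, 1)))
  structure(list(
    rasters = list(altitude = mk(alt), ecoregion = mk(ecoregion),
                   arable = mk(arable), footprint = mk(footprint),
                   suitability = mk(suit)),
    sites = sites,
    truth = list(cost_scheme = true_scheme, covariate_effects = NULL),
    seed = seed, n_side = n_side, rift_half = rift_half,
    barrier_depth = barrier_depth),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic_world: %dx%d grid, %d sites (%s), seed %d\n",
              x$n_side, x$n_side, nrow(x$sites),
              paste(x$sites$label, collapse = ", "), x$seed))
  invisible(x)
}

#' Simulate ground-truth genetics for a synthetic world
#'
#' Runs the two-population coalescent simulator (south-east vs north-west
#' of the rift) and distributes the simulated individuals over the
#' world's sites within each side. Default per-site sample sizes are
#' (7, 9, 7, 12, 11) diploids for (BaleD, BaleS, Guassa, Simien, Abune).
#'
#' @param world a [make_world()] object with 5 sites.
#' @param scenario scenario id or [demographic_scenario()].
#' @param params parameter vector (see [sample_priors()]); default is a
#'   strong-decline history used for end-to-end demonstrations.
#' @param sizes named per-site diploid sample sizes.
#' @param mutation a [mutation_model()].
#' @param seed integer seed.
#' @return list with `gt`, `aln`, `popmap` (per-site populations),
#'   `side_popmap` (S/N populations for ABC), and `manifest` (ground
#'   truth as a key=value character vector).
#' @export
simulate_truth_genetics <- function(world, scenario = 4,
                                    params = c(N_S = 8000, N_N = 20000,
                                               N_A = 50000, N_S0 = 48000,
                                               t_split = 45000, t_dec = 75),
                                    sizes = c(BaleD = 7, BaleS = 9,
                                              Guassa = 7, Simien = 12,
                                              Abune = 11),
                                    mutation = mutation_model(), seed) {
  if (missing(seed)) stop("simulate_truth_genetics requires a seed")
  st <- world$sites
  if (!setequal(names(sizes), st$label)) {
    stop("sizes must be named by the world's site labels")
  }
  se_sites <- st$label[st$side == "SE"]
  nw_sites <- st$label[st$side == "NW"]
  n_s <- sum(sizes[se_sites]); n_n <- sum(sizes[nw_sites])
  ds <- simulate_dataset(scenario, params, n_s = n_s, n_n = n_n,
                         mutation = mutation, seed = child_seed(seed, 1L))
  # assign simulated individuals to sites within their side
  site_of <- c(rep(se_sites, times = sizes[se_sites]),
               rep(nw_sites, times = sizes[nw_sites]))
  popmap <- pop_map(ds$gt$ids, site_of)
  manifest <- c(sprintf("scenario=%d", ds$truth$scenario),
                sprintf("%s=%s", names(ds$truth$params),
                        format(ds$truth$params, trim = TRUE, scientific = FALSE)),
                sprintf("seed=%d", seed),
                sprintf("n_s=%d", n_s), sprintf("n_n=%d", n_n))
  list(gt = ds$gt, aln = ds$aln, popmap = popmap,
       side_popmap = ds$popmap, manifest = manifest)
}

#' Write / read a ground-truth manifest (key=value text)
#' @param manifest character vector of `key=value` lines.
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  writeLines(manifest, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) readLines(path)

#' Generate per-population covariates with a known regression structure
#'
#' Emulates a diversity-against-land-use regression with controllable
#' effect size: the covariate is the mean arable-land fraction within a
#' buffer around each site, and the response (e.g. rarefied allelic
#' richness) is `intercept + slope * covariate + N(0, noise_sd)`.
#'
#' @param world a [make_world()] object.
#' @param slope configured regression slope.
#' @param intercept response at zero covariate (default 6).
#' @param noise_sd response noise standard deviation (default 0.2).
#' @param buffer_cells buffer radius in cells for the covariate (default 5).
#' @param seed integer seed.
#' @return data frame `population, covariate, response` with attributes
#'   `slope`, `intercept`, `noise_sd`.
#' @export
inject_covariate_effect <- function(world, slope, intercept = 6,
                                    noise_sd = 0.2, buffer_cells = 5, seed) {
  if (missing(seed)) stop("inject_covariate_effect requires a seed")
  if (!is.finite(slope)) stop("slope must be finite")
  set.seed(child_seed(seed, 7L))
  ar <- world$rasters$arable$values
  n <- nrow(ar)
  cov <- vapply(seq_len(nrow(world$sites)), function(k) {
    r <- world$sites$row[k]; c <- world$sites$col[k]
    rr <- max(1, r - buffer_cells):min(n, r + buffer_cells)
    cc <- max(1, c - buffer_cells):min(n, c + buffer_cells)
    mean(ar[rr, cc])
  }, 0)
  resp <- intercept + slope * cov + stats::rnorm(length(cov), 0, noise_sd)
  out <- data.frame(population = world$sites$label, covariate = cov,
                    response = resp, stringsAsFactors = FALSE)
  attr(out, "slope") <- slope
  attr(out, "intercept") <- intercept
  attr(out, "noise_sd") <- noise_sd
  out
}

#' Write the complete synthetic fixture bundle to a directory
#'
#' Emits the exact formats the pipeline reads: `.asc` rasters, a Genepop
#' genotype file, a FASTA alignment, popmap and sites CSVs, and a
#' manifest.
#'
#' @param world a [make_world()] object.
#' @param genetics output of [simulate_truth_genetics()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_world_bundle <- function(world, genetics, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(world$rasters)) {
    write_ascii_grid(world$rasters[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  utils::write.csv(world$sites[, c("label", "x", "y")],
                   file.path(dir, "sites.csv"), row.names = FALSE,
                   quote = FALSE)
  write_genepop(genetics$gt, genetics$popmap,
                file.path(dir, "genotypes.gen"))
  write_fasta(genetics$aln, file.path(dir, "mtdna.fasta"))
  write_popmap(genetics$popmap, file.path(dir, "popmap.csv"))
  write_popmap(genetics$side_popmap, file.path(dir, "popmap_sides.csv"))
  write_manifest(genetics$manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
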