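#' Read a pipeline run configuration (key = value text)
#'
#' Known keys (all optional unless a stage needing them is enabled):
#' `out_dir`, `seed`, `world_seed`, `n_side`, `stages` (comma-separated
#' subset of `popgen,landscape,abc,range`), `hwe_perm`, `mrdm_perm`,
#' `abc_rows_per_scenario`, `abc_tolerance`, `rarefaction_g`.
#' Unknown keys are rejected. Every stochastic stage takes its seed from
#' `seed` via counter-based child seeds.
#'
#' @param path config file path.
#' @return named list (`run_config`).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  known <- c("out_dir", "seed", "world_seed", "n_side", "stages",
             "hwe_perm", "mrdm_perm", "abc_rows_per_scenario",
             "abc_tolerance", "rarefaction_g")
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- as.list(stats::setNames(vals, keys))
  for (nm in intersect(names(cfg), c("seed", "world_seed", "n_side",
                                     "hwe_perm", "mrdm_perm",
                                     "abc_rows_per_scenario",
                                     "rarefaction_g"))) {
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  if (!is.null(cfg$abc_tolerance)) cfg$abc_tolerance <- as.numeric(cfg$abc_tolerance)
  if (!is.null(cfg$stages)) cfg$stages <- strsplit(cfg$stages, ",")[[1]]
  defaults <- list(stages = c("popgen", "landscape", "abc", "range"),
                   n_side = 60L, hwe_perm = 200L, mrdm_perm = 199L,
                   abc_rows_per_scenario = 200L, abc_tolerance = 0.05,
                   seed = 1L, world_seed = NULL)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$world_seed)) cfg$world_seed <- cfg$seed
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  structure(cfg, class = "run_config")
}

#' Run the integrated pipeline on a synthetic world
#'
#' Generates a synthetic sky-island world, simulates ground-truth
#' genetics, and executes the enabled stages in order: `popgen`
#' (diversity table, differentiation matrices, marker QC,
#' diversity-land-use regression), `landscape` (resistance distances
#' under candidate cost schemes, MLPE hypothesis comparison), `abc`
#' (reference table, scenario choice, parameter estimation), `range`
#' (MaxSSS threshold and range-change report across synthetic slices).
#' Every stage writes its tables under `out_dir` and a `run_log.txt`
#' records per-stage seeds, so re-running with the same config reproduces
#' the outputs byte for byte.
#'
#' @param config a `run_config` from [read_run_config()], or a path.
#' @return named list of stage outputs (also written to `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("seed=%d", config$seed),
                 sprintf("world_seed=%d", config$world_seed),
                 sprintf("stages=%s", paste(config$stages, collapse = ",")))
  world <- make_world(n_side = config$n_side, seed = config$world_seed)
  gen <- simulate_truth_genetics(world, seed = child_seed(config$seed, 100L))
  write_world_bundle(world, gen, file.path(config$out_dir, "bundle"))
  out <- list(world = world)

  if ("popgen" %in% config$stages) {
    div <- microsat_summaries(gen$gt, gen$popmap)
    mtd <- lapply(split(gen$gt$ids, popmap_lookup(gen$popmap, gen$gt$ids)),
                  function(ids) {
                    if (length(ids) < 2) return(NULL)
                    mtdna_diversity(aln_subset(gen$aln, ids))
                  })
    div$Hap <- vapply(div$population, function(p) mtd[[p]]$Hap, 0)
    div$Hd <- vapply(div$population, function(p) mtd[[p]]$Hd, 0)
    div$Pi <- vapply(div$population, function(p) mtd[[p]]$Pi, 0)
    fmean <- inbreeding_ml(gen$gt, gen$popmap)$population
    div$F_ind <- unname(fmean[div$population])
    diff <- pairwise_differentiation(gen$gt, gen$popmap)
    qc <- marker_qc(gen$gt, gen$popmap, n_perm = config$hwe_perm,
                    seed = child_seed(config$seed, 101L))
    covd <- inject_covariate_effect(world, slope = -3,
                                    seed = child_seed(config$seed, 102L))
    reg <- diversity_landuse_regression(covd$response, covd$covariate)
    utils::write.csv(div, file.path(config$out_dir, "diversity_table.csv"),
                     row.names = FALSE)
    write_matrix_csv(diff$theta, file.path(config$out_dir, "fst.csv"))
    write_matrix_csv(diff$jost_d, file.path(config$out_dir, "jost_d.csv"))
    out$popgen <- list(diversity = div, differentiation = diff, qc = qc,
                       regression = reg)
    log_lines <- c(log_lines, "stage popgen: ok")
  }

  if ("landscape" %in% config$stages) {
    nodes <- node_set(world$sites$label, world$sites$row, world$sites$col)
    if (is.null(out$popgen)) {
      diff <- pairwise_differentiation(gen$gt, gen$popmap)
    } else diff <- out$popgen$differentiation
    euc <- euclidean_distances(world$sites)
    y <- normalize_genetic_distance(diff$theta, euc)
    schemes <- list(
      ecoregion = world$truth$cost_scheme,
      altitude = cost_scheme("altitude", "altitude-linear",
        data.frame(from = c(-Inf, 2795, 3500), to = c(2795, 3500, Inf),
                   cost = c(80, 30, 1))),
      footprint = cost_scheme("footprint", "footprint-linear",
        data.frame(from = c(-Inf, 10, 25), to = c(10, 25, Inf),
                   cost = c(1, 40, 90))))
    rasters <- list(ecoregion = world$rasters$ecoregion,
                    altitude = world$rasters$altitude,
                    footprint = world$rasters$footprint)
    fits <- lapply(names(schemes), function(nm) {
      rd <- resistance_distances(reclassify(rasters[[nm]], schemes[[nm]]),
                                 nodes)
      mlpe_fit(y, stats::setNames(list(rd), nm))
    })
    names(fits) <- names(schemes)
    cmp <- model_compare(fits)
    utils::write.csv(cmp, file.path(config$out_dir, "mlpe_table.csv"),
                     row.names = FALSE)
    out$landscape <- list(fits = fits, comparison = cmp)
    log_lines <- c(log_lines, "stage landscape: ok")
  }

  if ("abc" %in% config$stages) {
    spec <- prior_spec()
    tab <- build_reference_table(spec, 1:4, config$abc_rows_per_scenario,
                                 seed = child_seed(config$seed, 103L),
                                 n_s = sum(gen$side_popmap == "S"),
                                 n_n = sum(gen$side_popmap == "N"))
    obs <- summarize_dataset(list(gt = gen$gt, aln = gen$aln,
                                  popmap = gen$side_popmap))
    mc <- suppressWarnings(model_choice(obs, tab, config$abc_tolerance))
    post <- estimate_parameters(obs, tab, mc$selected, spec,
                                tolerance = min(1, config$abc_tolerance * 5))
    utils::write.csv(data.frame(scenario = names(mc$regression),
                                direct = mc$direct,
                                regression = mc$regression),
                     file.path(config$out_dir, "abc_model_choice.csv"),
                     row.names = FALSE)
    utils::write.csv(post$summary,
                     file.path(config$out_dir, "abc_posterior.csv"),
                     row.names = FALSE)
    out$abc <- list(table = tab, choice = mc, posterior = post)
    log_lines <- c(log_lines, "stage abc: ok")
  }

  if ("range" %in% config$stages) {
    suit <- world$rasters$suitability
    set.seed(child_seed(config$seed, 104L))
    pres_cells <- cbind(world$sites$row, world$sites$col)
    pres <- suit$values[pres_cells]
    bg <- sample(suit$values[!is.na(suit$values)], 200)
    thr <- max_sss_threshold(pmin(pmax(pres, 0), 1), pmin(pmax(bg, 0), 1))
    present <- binarize_suitability(suit, thr$threshold)
    # synthetic past/future slices: shift the score to emulate broader
    # (cooler) and narrower (warmer) suitable ranges
    shift <- function(d) raster_grid(pmin(pmax(suit$values + d, 0), 1),
                                     suit$cellsize, suit$xllcorner,
                                     suit$yllcorner, suit$nodata)
    maps <- list(present = present,
                 past = binarize_suitability(shift(0.25), thr$threshold),
                 future = binarize_suitability(shift(-0.2), thr$threshold))
    rep <- range_report(maps, present = "present")
    write_range_report(rep, file.path(config$out_dir, "range_report.csv"))
    out$range <- list(threshold = thr, report = rep)
    log_lines <- c(log_lines, "stage range: ok")
  }
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  out$log <- log_lines
  invisible(out)
}
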