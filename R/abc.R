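## Approximate Bayesian computation on coalescent reference tables.
## Rows are seeded individually from the master seed (counter-based
## splitting) so tables are bit-reproducible and chunkable.

# derive a child seed from (master, counter); stays below 2^31
child_seed <- function(master, counter) {
  x <- (as.double(master) * 48271 + as.double(counter) * 16807 + 12345) %%
    2147483647
  as.integer(x) + 1L
}

#' Build an ABC reference table
#'
#' For each scenario, draws `n_per_scenario` parameter vectors from the
#' priors and simulates a dataset for each, storing the 18 summary
#' statistics. Every row receives its own RNG seed derived from the master
#' seed and row counter, so the table is reproducible and can be built in
#' chunks.
#'
#' @param spec a [prior_spec()].
#' @param scenarios integer vector of scenario ids (default 1:4).
#' @param n_per_scenario simulated datasets per scenario.
#' @param seed master seed.
#' @param n_s,n_n,mutation,n_loci forwarded to [simulate_dataset()].
#' @return `reference_table`: list with `stats` (matrix rows x 18),
#'   `params` (matrix of parameter draws), `scenario` (integer vector),
#'   `seed`.
#' @export
build_reference_table <- function(spec, scenarios = 1:4, n_per_scenario,
                                  seed, n_s = 22, n_n = 28,
                                  mutation = mutation_model(), n_loci = 19) {
  if (missing(seed)) stop("build_reference_table requires a seed")
  nrow_total <- length(scenarios) * n_per_scenario
  stats_m <- matrix(NA_real_, nrow_total, 18,
                    dimnames = list(NULL, summary_stat_names()))
  parnames <- c("N_S", "N_N", "N_A", "N_S0", "N_N0", "t_split", "t_dec",
                "mu_ms", "gsm_p", "mu_mt")
  params_m <- matrix(NA_real_, nrow_total, length(parnames),
                     dimnames = list(NULL, parnames))
  scen_v <- integer(nrow_total)
  row <- 0L
  for (sc in scenarios) {
    scen <- demographic_scenario(sc)
    for (i in seq_len(n_per_scenario)) {
      row <- row + 1L
      rs <- child_seed(seed, row)
      d <- sample_priors(spec, scen, seed = rs)
      ds <- simulate_dataset(scen, d, n_s = n_s, n_n = n_n,
                             mutation = mutation, n_loci = n_loci,
                             seed = child_seed(rs, 1L), raw = TRUE)
      stats_m[row, ] <- .summary_stats_cpp(ds$ms, ds$mt, ds$n_s)
      params_m[row, ] <- d[parnames]
      scen_v[row] <- sc
    }
  }
  structure(list(stats = stats_m, params = params_m,
                 scenario = scen_v, seed = seed,
                 n_s = n_s, n_n = n_n, n_loci = n_loci),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("reference_table: %d rows (%s), seed %d\n", nrow(x$stats),
              paste(sprintf("scenario %d: %d", unique(x$scenario),
                            tabulate(x$scenario)[unique(x$scenario)]),
                    collapse = ", "), x$seed))
  invisible(x)
}

#' Write / read a reference table as columnar CSV with a manifest header
#' @param table a `reference_table`.
#' @param path output CSV path (manifest lines start with `#`).
#' @export
write_reference_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seed: %d", table$seed),
               sprintf("# n_s: %d", table$n_s),
               sprintf("# n_n: %d", table$n_n),
               sprintf("# n_loci: %d", table$n_loci)), con)
  df <- data.frame(scenario = table$scenario, table$params, table$stats,
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- lapply(strsplit(sub("^#\\s*", "", hdr), ":\\s*"), identity)
  meta <- stats::setNames(lapply(meta, function(x) as.numeric(x[2])),
                          vapply(meta, `[`, "", 1L))
  df <- utils::read.csv(path, skip = length(hdr), check.names = FALSE)
  sn <- summary_stat_names()
  parnames <- setdiff(names(df), c("scenario", sn))
  structure(list(stats = as.matrix(df[, sn]),
                 params = as.matrix(df[, parnames]),
                 scenario = df$scenario,
                 seed = as.integer(meta$seed),
                 n_s = as.integer(meta$n_s), n_n = as.integer(meta$n_n),
                 n_loci = as.integer(meta$n_loci)),
            class = "reference_table")
}

# standardize table stats by their SD; returns list(scaled, center=FALSE
# semantics: we only divide by sd so distances match DIYABC practice)
stat_scale <- function(stats_m) {
  sds <- apply(stats_m, 2, stats::sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  sds
}

# Euclidean distances of table rows to obs, in SD units
abc_distances <- function(stats_m, obs, sds) {
  sw <- sweep(stats_m, 2, obs, "-")
  sw <- sweep(sw, 2, sds, "/")
  sqrt(rowSums(sw^2))
}

#' ABC scenario choice by rejection and weighted multinomial logistic regression
#'
#' Statistics are standardized by the reference-table standard deviations;
#' the `tolerance` fraction of rows nearest to the observed vector (in
#' Euclidean distance) is retained. The direct estimate is the scenario
#' frequency among retained rows; the regression estimate fits a
#' multinomial logistic regression of scenario on the centred statistics
#' over the retained rows, weighted by an Epanechnikov kernel on relative
#' distance, and evaluates it at the observed vector (the origin of the
#' centred statistics). A small weight decay regularizes the logit
#' against separation.
#'
#' @param obs named numeric vector of the 18 observed statistics.
#' @param table a `reference_table`.
#' @param tolerance retained fraction in (0, 1].
#' @return `model_choice_result`: list with `direct`, `regression`
#'   (probability vectors over scenarios), `selected` (by regression),
#'   `tolerance`, `n_retained`.
#' @export
model_choice <- function(obs, table, tolerance = 0.01) {
  if (tolerance <= 0 || tolerance > 1) stop("tolerance must be in (0, 1]")
  scens <- sort(unique(table$scenario))
  sds <- stat_scale(table$stats)
  d <- abc_distances(table$stats, obs, sds)
  n_keep <- max(2L, ceiling(tolerance * length(d)))
  keep <- order(d)[seq_len(n_keep)]
  dk <- d[keep]
  direct <- vapply(scens, function(s) mean(table$scenario[keep] == s), 0)
  names(direct) <- paste0("scenario", scens)
  missing_sc <- scens[!scens %in% table$scenario[keep]]
  if (length(missing_sc)) {
    warning("scenario(s) absent from retained set: ",
            paste(missing_sc, collapse = ", "))
  }
  present <- scens[scens %in% table$scenario[keep]]
  if (length(present) < 2L) {
    regression <- direct
  } else {
    dmax <- max(dk) * (1 + 1e-9)
    w <- 1 - (dk / dmax)^2
    X <- sweep(table$stats[keep, , drop = FALSE], 2, obs, "-")
    X <- sweep(X, 2, sds, "/")
    X <- X[, apply(X, 2, stats::sd) > 0, drop = FALSE]
    grp <- factor(table$scenario[keep], levels = present)
    x0 <- rep(0, ncol(X))
    df <- data.frame(scen = grp, X)
    fit <- tryCatch(
      nnet::multinom(scen ~ ., data = df, weights = w, trace = FALSE,
                     decay = 1e-6, maxit = 1000),
      error = function(e) NULL)
    if (is.null(fit)) {
      regression <- direct
    } else {
      nd <- as.data.frame(matrix(x0, 1))
      names(nd) <- colnames(X)
      pr <- stats::predict(fit, newdata = nd, type = "probs")
      if (length(present) == 2L) pr <- c(1 - pr, pr)
      regression <- stats::setNames(numeric(length(scens)),
                                    paste0("scenario", scens))
      regression[paste0("scenario", present)] <- pr
    }
  }
  structure(list(direct = direct, regression = regression,
                 selected = scens[which.max(regression)],
                 tolerance = tolerance, n_retained = n_keep),
            class = "model_choice_result")
}

#' @export
print.model_choice_result <- function(x, ...) {
  cat("ABC model choice (tolerance ", x$tolerance, ", ", x$n_retained,
      " retained)\n", sep = "")
  print(round(rbind(direct = x$direct, regression = x$regression), 4))
  cat("selected: scenario", x$selected, "\n")
  invisible(x)
}

logit_bounded <- function(x, lo, hi) {
  z <- (x - lo) / (hi - lo)
  z <- pmin(pmax(z, 1e-12), 1 - 1e-12)
  log(z / (1 - z))
}

inv_logit_bounded <- function(z, lo, hi) {
  lo + (hi - lo) / (1 + exp(-z))
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], 0)
}

#' ABC parameter estimation with local-linear regression adjustment
#'
#' Rejection sampling on the scenario-restricted reference table followed
#' by Beaumont-style local-linear adjustment: each parameter is
#' logit-transformed with respect to its prior bounds, regressed on the
#' standardized statistics over the retained rows with Epanechnikov
#' weights, and the fitted linear trend is subtracted so the adjusted
#' draws are conditioned on the observed vector. Back-transformation
#' keeps the draws inside the prior support.
#'
#' @param obs observed 18-statistic vector.
#' @param table a `reference_table` (will be restricted to `scenario`).
#' @param scenario scenario id whose rows to use.
#' @param spec the [prior_spec()] used to build the table (for bounds).
#' @param tolerance retained fraction.
#' @param parameters which parameters to estimate (default: those the
#'   scenario uses).
#' @param adjust apply the local-linear regression adjustment (default
#'   `TRUE`; `FALSE` gives plain rejection).
#' @param kernel `"epanechnikov"` (default) or `"uniform"` weights on the
#'   retained rows.
#' @return `parameter_posterior`: list with per-parameter adjusted draws,
#'   weights, `summary` data frame (median and 95% credible interval, for
#'   time parameters also in years), and `decline_ratio` (posterior draws
#'   of `N_S0/N_S` with both the median of the ratio and the ratio of
#'   medians).
#' @export
estimate_parameters <- function(obs, table, scenario, spec,
                                tolerance = 0.05, parameters = NULL,
                                adjust = TRUE,
                                kernel = c("epanechnikov", "uniform")) {
  kernel <- match.arg(kernel)
  rows <- which(table$scenario == scenario)
  if (!length(rows)) stop("no rows for scenario ", scenario)
  if (is.null(parameters)) {
    parameters <- intersect(demographic_scenario(scenario)$parameters,
                            colnames(table$params))
  }
  stats_m <- table$stats[rows, , drop = FALSE]
  params_m <- table$params[rows, , drop = FALSE]
  sds <- stat_scale(stats_m)
  d <- abc_distances(stats_m, obs, sds)
  n_keep <- max(10L, ceiling(tolerance * length(d)))
  keep <- order(d)[seq_len(n_keep)]
  dk <- d[keep]
  if (kernel == "epanechnikov") {
    dmax <- max(dk) * (1 + 1e-9)
    w <- 1 - (dk / dmax)^2
    w[w <= 0] <- min(w[w > 0]) / 2
  } else {
    w <- rep(1, n_keep)
  }
  X <- sweep(stats_m[keep, , drop = FALSE], 2, obs, "-")
  X <- sweep(X, 2, sds, "/")
  # drop statistics with no variation among retained rows
  X <- X[, apply(X, 2, stats::sd) > 0, drop = FALSE]
  draws <- list()
  for (pm in parameters) {
    lo <- spec[[pm]]$min; hi <- spec[[pm]]$max
    if (lo == hi) { draws[[pm]] <- rep(lo, n_keep); next }
    z <- logit_bounded(params_m[keep, pm], lo, hi)
    fit <- if (adjust) {
      tryCatch(stats::lm.wfit(cbind(1, X), z, w), error = function(e) NULL)
    } else NULL
    if (is.null(fit) || anyNA(fit$coefficients)) {
      zadj <- z  # rejection-only fallback
      attr(draws, "regression_failed") <- TRUE
    } else {
      zadj <- z - X %*% fit$coefficients[-1]
    }
    draws[[pm]] <- inv_logit_bounded(as.numeric(zadj), lo, hi)
  }
  summ <- do.call(rbind, lapply(parameters, function(pm) {
    q <- weighted_quantile(draws[[pm]], w, c(0.5, 0.025, 0.975))
    data.frame(parameter = pm, median = q[1], ci_lower = q[2],
               ci_upper = q[3], stringsAsFactors = FALSE)
  }))
  gentime <- spec$.generation_time
  istime <- summ$parameter %in% c("t_split", "t_dec")
  summ$median_years <- ifelse(istime, summ$median * gentime, NA)
  summ$ci_lower_years <- ifelse(istime, summ$ci_lower * gentime, NA)
  summ$ci_upper_years <- ifelse(istime, summ$ci_upper * gentime, NA)
  decline <- NULL
  if (all(c("N_S0", "N_S") %in% names(draws))) {
    ratio <- draws[["N_S0"]] / draws[["N_S"]]
    decline <- list(
      draws = ratio,
      median_of_ratio = weighted_quantile(ratio, w, 0.5),
      ratio_of_medians = weighted_quantile(draws[["N_S0"]], w, 0.5) /
        weighted_quantile(draws[["N_S"]], w, 0.5))
  }
  structure(list(draws = draws, weights = w, summary = summ,
                 decline_ratio = decline, scenario = scenario,
                 tolerance = tolerance, n_retained = n_keep),
            class = "parameter_posterior")
}

#' @export
print.parameter_posterior <- function(x, ...) {
  cat("ABC posterior, scenario ", x$scenario, " (", x$n_retained,
      " retained)\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  if (!is.null(x$decline_ratio)) {
    cat(sprintf("decline ratio N_S0/N_S: median of ratio %.2f, ratio of medians %.2f\n",
                x$decline_ratio$median_of_ratio,
                x$decline_ratio$ratio_of_medians))
  }
  invisible(x)
}

#' Confidence in scenario choice from pseudo-observed datasets
#'
#' Simulates `n_pods` pseudo-observed datasets under each scenario (prior
#' draws), classifies each against the reference table, and reports the
#' scenario-by-scenario confusion matrix, the type-1 error of the
#' `selected` scenario (fraction of its own pods assigned elsewhere) and
#' the type-2 error (per other scenario, fraction of pods assigned to the
#' selected scenario; mean and sd reported).
#'
#' @param table a `reference_table`.
#' @param spec the [prior_spec()].
#' @param n_pods pods per scenario (>= 50 recommended; smaller allowed).
#' @param seed master seed.
#' @param selected scenario whose error rates to report (default: 4).
#' @param tolerance forwarded to [model_choice()].
#' @param mutation,n_loci forwarded to the simulator.
#' @return `confidence_report`: list with `confusion` (rows sum to 1),
#'   `type1`, `type2_mean`, `type2_sd`, `type2` (per-scenario).
#' @export
confidence_analysis <- function(table, spec, n_pods = 100, seed,
                                selected = 4L, tolerance = 0.01,
                                mutation = mutation_model(), n_loci = 19) {
  if (missing(seed)) stop("confidence_analysis requires a seed")
  scens <- sort(unique(table$scenario))
  conf <- matrix(0, length(scens), length(scens),
                 dimnames = list(true = paste0("scenario", scens),
                                 assigned = paste0("scenario", scens)))
  ctr <- 0L
  for (s in scens) {
    for (i in seq_len(n_pods)) {
      ctr <- ctr + 1L
      rs <- child_seed(seed, ctr)
      d <- sample_priors(spec, s, seed = rs)
      ds <- simulate_dataset(s, d, n_s = table$n_s, n_n = table$n_n,
                             mutation = mutation, n_loci = n_loci,
                             seed = child_seed(rs, 1L), raw = TRUE)
      obs <- .summary_stats_cpp(ds$ms, ds$mt, ds$n_s)
      mc <- suppressWarnings(model_choice(obs, table, tolerance))
      conf[match(s, scens), match(mc$selected, scens)] <-
        conf[match(s, scens), match(mc$selected, scens)] + 1
    }
  }
  conf <- conf / n_pods
  isel <- match(selected, scens)
  type1 <- 1 - conf[isel, isel]
  type2 <- conf[-isel, isel]
  structure(list(confusion = conf, selected = selected, type1 = type1,
                 type2 = type2, type2_mean = mean(type2),
                 type2_sd = stats::sd(type2), n_pods = n_pods),
            class = "confidence_report")
}

#' Posterior predictive model check by PCA
#'
#' Simulates `n_sim` datasets from the posterior draws, fits a PCA on
#' their standardized summary statistics, projects the observed vector,
#' and reports whether it falls inside the 99% ellipsoid (and the convex
#' hull) of the first two components.
#'
#' @param posterior a `parameter_posterior`.
#' @param obs observed 18-statistic vector.
#' @param spec the [prior_spec()].
#' @param seed master seed.
#' @param n_sim number of posterior predictive simulations (>= 10).
#' @param n_s,n_n,mutation,n_loci forwarded to the simulator.
#' @return list with `scores` (n_sim x 2), `obs_scores`, `inside_ellipsoid`,
#'   `inside_hull`, `pca` (the `prcomp` object).
#' @export
posterior_predictive_check <- function(posterior, obs, spec, seed,
                                       n_sim = 1000, n_s = 22, n_n = 28,
                                       mutation = mutation_model(),
                                       n_loci = 19) {
  if (missing(seed)) stop("posterior_predictive_check requires a seed")
  if (n_sim < 10) stop("n_sim must be >= 10")
  dr <- posterior$draws
  w <- posterior$weights / sum(posterior$weights)
  set.seed(child_seed(seed, 0L))
  pick <- sample.int(length(w), n_sim, replace = TRUE, prob = w)
  stats_m <- matrix(NA_real_, n_sim, 18)
  for (i in seq_len(n_sim)) {
    d <- vapply(names(dr), function(pm) dr[[pm]][pick[i]], 0)
    full <- sample_priors(spec, posterior$scenario,
                          seed = child_seed(seed, i))
    full[names(d)] <- d
    if (!"N_S0" %in% names(dr)) full[["N_S0"]] <- full[["N_S"]]
    if (!"N_N0" %in% names(dr)) full[["N_N0"]] <- full[["N_N"]]
    ds <- simulate_dataset(posterior$scenario, full, n_s = n_s, n_n = n_n,
                           mutation = mutation, n_loci = n_loci,
                           seed = child_seed(seed, i + n_sim), raw = TRUE)
    stats_m[i, ] <- .summary_stats_cpp(ds$ms, ds$mt, ds$n_s)
  }
  sds <- stat_scale(stats_m)
  keepcol <- apply(stats_m, 2, stats::sd) > 0
  pca <- stats::prcomp(stats_m[, keepcol, drop = FALSE], center = TRUE,
                       scale. = TRUE)
  sc <- pca$x[, 1:2, drop = FALSE]
  obs_sc <- stats::predict(pca, matrix(obs[keepcol], 1))[, 1:2]
  S <- stats::cov(sc)
  mu <- colMeans(sc)
  md <- mahalanobis_dist(obs_sc, mu, S)
  inside <- md <= stats::qchisq(0.99, df = 2)
  hull <- grDevices::chull(sc)
  inside_hull <- point_in_polygon(obs_sc, sc[hull, , drop = FALSE])
  list(scores = sc, obs_scores = obs_sc, inside_ellipsoid = inside,
       inside_hull = inside_hull, pca = pca)
}

mahalanobis_dist <- function(x, mu, S) {
  d <- as.numeric(x - mu)
  as.numeric(t(d) %*% solve(S, d))
}

# ray-casting point-in-polygon (vertices in order)
point_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > p[2]) != (yj > p[2]) &&
        p[1] < (xj - xi) * (p[2] - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

#' Bias and precision of ABC parameter estimation
#'
#' Simulates pods with known parameters under one scenario, estimates each
#' with [estimate_parameters()] against the reference table, and reports
#' the relative mean bias `mean((est - true)/true)` and the relative
#' median absolute deviation `median(|est - true|/true)` per parameter
#' (`est` is the posterior median).
#'
#' @param table a `reference_table`.
#' @param spec the [prior_spec()].
#' @param scenario scenario id.
#' @param n_pods number of pseudo-observed datasets.
#' @param seed master seed.
#' @param tolerance forwarded to [estimate_parameters()].
#' @param mutation,n_loci forwarded to the simulator.
#' @return data frame per parameter: `rel_mean_bias`, `rmedad`.
#' @export
bias_precision <- function(table, spec, scenario = 4L, n_pods = 50, seed,
                           tolerance = 0.05, mutation = mutation_model(),
                           n_loci = 19) {
  if (missing(seed)) stop("bias_precision requires a seed")
  parameters <- intersect(demographic_scenario(scenario)$parameters,
                          colnames(table$params))
  errs <- matrix(NA_real_, n_pods, length(parameters),
                 dimnames = list(NULL, parameters))
  for (i in seq_len(n_pods)) {
    rs <- child_seed(seed, i)
    d <- sample_priors(spec, scenario, seed = rs)
    ds <- simulate_dataset(scenario, d, n_s = table$n_s, n_n = table$n_n,
                           mutation = mutation, n_loci = n_loci,
                           seed = child_seed(rs, 1L), raw = TRUE)
    obs <- .summary_stats_cpp(ds$ms, ds$mt, ds$n_s)
    post <- estimate_parameters(obs, table, scenario, spec,
                                tolerance = tolerance,
                                parameters = parameters)
    est <- stats::setNames(post$summary$median, post$summary$parameter)
    errs[i, ] <- (est[parameters] - d[parameters]) / d[parameters]
  }
  data.frame(parameter = parameters,
             rel_mean_bias = colMeans(errs),
             rmedad = apply(abs(errs), 2, stats::median),
             row.names = NULL, stringsAsFactors = FALSE)
}
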