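#' Demographic split/decline scenarios
#'
#' Four competing two-population histories for a south-eastern (S) and a
#' north-western (N) population separated by a deep lowland barrier, all
#' sharing a merge into a single ancestor of size `N_A` at `t_split`
#' generations ago:
#'
#' 1. ancient split of a large ancestral population, no later size change
#'    (`N_A > max(N_S, N_N)`);
#' 2. expansion after the split (`N_A < min(N_S, N_N)`);
#' 3. recent decline of both populations at `t_dec` (`N_S0 > N_S`,
#'    `N_N0 > N_N`, with `0 < t_dec < t_split`);
#' 4. recent decline of the southern population only (`N_S0 > N_S`).
#'
#' Sizes are diploid effective sizes; times are generations ago. `N_S0`,
#' `N_N0` are the pre-decline sizes that apply on `[t_dec, t_split)`.
#'
#' @param id scenario id, 1-4.
#' @return a `demographic_scenario` object.
#' @export
demographic_scenario <- function(id) {
  id <- as.integer(id)
  if (!id %in% 1:4) stop("scenario id must be 1-4")
  pars <- switch(id,
    c("N_S", "N_N", "N_A", "t_split"),
    c("N_S", "N_N", "N_A", "t_split"),
    c("N_S", "N_N", "N_A", "N_S0", "N_N0", "t_split", "t_dec"),
    c("N_S", "N_N", "N_A", "N_S0", "t_split", "t_dec"))
  structure(list(id = id, parameters = pars), class = "demographic_scenario")
}

# does a full parameter draw satisfy the scenario's ordering constraints?
scenario_ok <- function(id, d) {
  base <- d[["t_dec"]] < d[["t_split"]]
  switch(id,
    base && d[["N_A"]] > max(d[["N_S"]], d[["N_N"]]),
    base && d[["N_A"]] < min(d[["N_S"]], d[["N_N"]]),
    base && d[["N_S0"]] > d[["N_S"]] && d[["N_N0"]] > d[["N_N"]],
    base && d[["N_S0"]] > d[["N_S"]])
}

#' Prior specification for demographic and mutation parameters
#'
#' Defaults: population sizes (`N_S`, `N_N`, `N_A`, `N_S0`, `N_N0`)
#' uniform on \[100, 100000\] diploid individuals; split time uniform on
#' \[100, 100000\] generations (200-200,000 years at 2 years/generation);
#' decline time uniform on \[10, 500\] generations (20-1,000 years); mean
#' microsatellite rate log-uniform on \[1e-4, 1e-3\]; GSM geometric
#' parameter uniform on \[0, 0.3\]; mtDNA rate log-uniform on
#' \[1e-8, 1e-7\] per site per generation.
#'
#' @param ... named overrides, each `list(dist = "uniform"|"loguniform",
#'   min =, max =)`.
#' @param generation_time years per generation for reporting (default 2).
#' @return `prior_spec` object.
#' @export
prior_spec <- function(..., generation_time = 2) {
  defaults <- list(
    N_S   = list(dist = "uniform", min = 100, max = 1e5),
    N_N   = list(dist = "uniform", min = 100, max = 1e5),
    N_A   = list(dist = "uniform", min = 100, max = 1e5),
    N_S0  = list(dist = "uniform", min = 100, max = 1e5),
    N_N0  = list(dist = "uniform", min = 100, max = 1e5),
    t_split = list(dist = "uniform", min = 100, max = 1e5),
    t_dec   = list(dist = "uniform", min = 10, max = 500),
    mu_ms  = list(dist = "loguniform", min = 1e-4, max = 1e-3),
    gsm_p  = list(dist = "uniform", min = 0, max = 0.3),
    mu_mt  = list(dist = "loguniform", min = 1e-8, max = 1e-7))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown prior parameter(s): ",
                            paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  for (nm in names(defaults)) {
    p <- defaults[[nm]]
    if (!is.finite(p$min) || !is.finite(p$max) || p$min > p$max) {
      stop("invalid bounds for ", nm)
    }
    if (p$dist == "loguniform" && p$min <= 0) stop("log-uniform needs positive bounds")
  }
  structure(c(defaults, list(.generation_time = generation_time)),
            class = "prior_spec")
}

draw_one <- function(p) {
  if (p$min == p$max) return(p$min)
  u <- stats::runif(1)
  if (p$dist == "loguniform") {
    exp(log(p$min) + u * (log(p$max) - log(p$min)))
  } else {
    p$min + u * (p$max - p$min)
  }
}

#' Draw parameters from the priors under a scenario's constraints
#'
#' Rejection-resamples the full parameter vector until the scenario's
#' ordering constraints hold (e.g. `t_dec < t_split`, decline sizes larger
#' than present sizes). Parameters the scenario does not use are tied to
#' their "no change" values (`N_S0 = N_S`, `N_N0 = N_N`, `t_dec` halfway
#' to the split) so every draw fully specifies the simulator.
#'
#' @param spec a [prior_spec()].
#' @param scenario a [demographic_scenario()] or scenario id.
#' @param seed optional RNG seed.
#' @return named numeric vector of all parameters.
#' @export
sample_priors <- function(spec, scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!inherits(scenario, "demographic_scenario")) {
    scenario <- demographic_scenario(scenario)
  }
  parnames <- c("N_S", "N_N", "N_A", "N_S0", "N_N0", "t_split", "t_dec",
                "mu_ms", "gsm_p", "mu_mt")
  for (it in seq_len(10000)) {
    d <- vapply(parnames, function(nm) draw_one(spec[[nm]]), 0)
    if (!"N_S0" %in% scenario$parameters) d[["N_S0"]] <- d[["N_S"]]
    if (!"N_N0" %in% scenario$parameters) d[["N_N0"]] <- d[["N_N"]]
    if (!"t_dec" %in% scenario$parameters) d[["t_dec"]] <- d[["t_split"]] / 2
    if (scenario_ok(scenario$id, d)) return(d)
  }
  stop("could not satisfy scenario constraints; check prior bounds")
}

#' Mutation model for microsatellite and mitochondrial markers
#'
#' @param mu_ms per-locus microsatellite mutation rate per generation.
#' @param gsm_p geometric parameter of the generalized stepwise model
#'   (step size is 1 + Geometric(`1 - gsm_p`); `0` gives strict SMM).
#' @param size_root,size_min,size_max root allele size (repeat units) and
#'   reflecting bounds.
#' @param mu_mt mtDNA substitution rate per site per generation.
#' @param kappa HKY transition/transversion rate ratio.
#' @param base_freq stationary base frequencies (A, C, G, T).
#' @param prop_inv proportion of invariant sites (coding partition).
#' @param gamma_shape gamma shape for rate heterogeneity (control-region
#'   partition); `0` disables.
#' @param len_cytb,len_hv1 partition lengths in bp.
#' @return `mutation_model` object.
#' @export
mutation_model <- function(mu_ms = 5e-4, gsm_p = 0.22,
                           size_root = 100L, size_min = 50L, size_max = 150L,
                           mu_mt = 3e-8, kappa = 8,
                           base_freq = c(0.31, 0.26, 0.13, 0.30),
                           prop_inv = 0.9, gamma_shape = 0.5,
                           len_cytb = 650L, len_hv1 = 460L) {
  stopifnot(mu_ms > 0, gsm_p >= 0, gsm_p < 1, mu_mt > 0, kappa > 0,
            prop_inv >= 0, prop_inv < 1, gamma_shape >= 0,
            size_min < size_root, size_root < size_max)
  base_freq <- base_freq / sum(base_freq)
  structure(list(mu_ms = mu_ms, gsm_p = gsm_p, size_root = size_root,
                 size_min = size_min, size_max = size_max, mu_mt = mu_mt,
                 kappa = kappa, base_freq = base_freq, prop_inv = prop_inv,
                 gamma_shape = gamma_shape, len_cytb = as.integer(len_cytb),
                 len_hv1 = as.integer(len_hv1)), class = "mutation_model")
}
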