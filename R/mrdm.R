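#' Multiple regression on distance matrices (MRDM)
#'
#' Ordinary least squares on the vectorized lower triangles of the response
#' and predictor matrices, with significance assessed by simultaneous
#' row/column permutation of the response matrix (Legendre): the rows and
#' columns of `Y` are shuffled together, predictors stay fixed, and
#' \eqn{p = (\#\{R^2_{perm} \ge R^2_{obs}\} + 1)/(n_{perm} + 1)}.
#' Coefficient p-values use the same permutations and two-sided |t|
#' statistics.
#'
#' @param Y response [pairwise_matrix()].
#' @param X a single [pairwise_matrix()] or a named list of them.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed (required).
#' @return list with `r_squared`, `coefficients`, `p_model`, `p_coef`,
#'   `n_perm`.
#' @export
mrdm <- function(Y, X, n_perm = 999, seed) {
  if (missing(seed)) stop("mrdm requires an explicit seed")
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (!is.list(X)) X <- list(X1 = X)
  if (is.null(names(X))) names(X) <- paste0("X", seq_along(X))
  k <- nrow(Y)
  if (any(vapply(X, nrow, 0L) != k)) stop("matrices not conformable")
  y <- lower_vec(Y)
  if (stats::sd(y) == 0) stop("constant response matrix")
  xs <- vapply(X, lower_vec, numeric(length(y)))
  n <- length(y)
  Xd <- cbind(1, xs)
  p <- ncol(Xd)
  XtXi <- solve(crossprod(Xd))
  hat <- XtXi %*% t(Xd)                # (X'X)^-1 X'
  dxx <- diag(XtXi)[-1]
  ols_stats <- function(yv) {
    # returns c(R2, |t| of slopes) for fixed design Xd
    beta <- hat %*% yv
    res <- yv - Xd %*% beta
    rss <- sum(res^2)
    tss <- sum((yv - mean(yv))^2)
    s2 <- rss / (n - p)
    unname(c(1 - rss / tss, abs(beta[-1]) / sqrt(s2 * dxx)))
  }
  obs <- ols_stats(y)
  obs_r2 <- obs[1]
  obs_t <- obs[-1]
  set.seed(seed)
  ge_r2 <- 0L
  ge_t <- rep(0L, length(obs_t))
  Ym <- as.matrix(Y)
  lt <- lower.tri(Ym)
  for (b in seq_len(n_perm)) {
    ord <- sample.int(k)
    st <- ols_stats(Ym[ord, ord][lt])
    if (st[1] >= obs_r2 - 1e-12) ge_r2 <- ge_r2 + 1L
    ge_t <- ge_t + as.integer(st[-1] >= obs_t - 1e-12)
  }
  coefs <- as.numeric(hat %*% y)
  names(coefs) <- c("(Intercept)", names(X))
  list(r_squared = obs_r2,
       coefficients = coefs,
       p_model = (ge_r2 + 1) / (n_perm + 1),
       p_coef = stats::setNames((ge_t + 1) / (n_perm + 1), names(X)),
       n_perm = n_perm)
}

#' Select the best resistance-cost scheme for a landscape variable
#'
#' Computes circuit resistance distances for each candidate scheme applied
#' to the variable's raster and ranks schemes by MRDM \eqn{R^2} against a
#' genetic distance matrix. Ties break to the lexicographically lowest
#' scheme label.
#'
#' @param raster the landscape variable [raster_grid()].
#' @param schemes list of candidate [cost_scheme()]s.
#' @param nodes a [node_set()].
#' @param genetic genetic distance [pairwise_matrix()] (same label order).
#' @param connectivity 4 or 8.
#' @param n_perm,seed forwarded to [mrdm()].
#' @return list with `best` (the winning scheme), `table` (label, R2, p).
#' @export
select_cost_scheme <- function(raster, schemes, nodes, genetic,
                               connectivity = 8, n_perm = 999, seed) {
  if (missing(seed)) stop("select_cost_scheme requires an explicit seed")
  if (!length(schemes)) stop("no candidate schemes")
  res <- lapply(schemes, function(sch) {
    rd <- resistance_distances(reclassify(raster, sch), nodes, connectivity)
    m <- mrdm(genetic, rd, n_perm = n_perm, seed = seed)
    data.frame(label = sch$label, r_squared = m$r_squared,
               p = m$p_model, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  ord <- order(-tab$r_squared, tab$label)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  list(best = schemes[[ord[1]]], table = tab)
}

#' Normalize genetic distance by log Euclidean distance
#'
#' Returns \eqn{\ln(G_{ij}) / \ln(E_{ij})} per pair, removing the
#' isolation-by-distance component before landscape hypotheses are
#' compared. Non-positive genetic distances are clamped to `clamp`
#' (default 1e-6) before the log.
#'
#' @param G genetic distance [pairwise_matrix()].
#' @param E Euclidean distance [pairwise_matrix()]; all off-diagonal
#'   entries must exceed 1 map unit (use metres).
#' @param clamp lower clamp for G before the log.
#' @return a [pairwise_matrix()].
#' @export
normalize_genetic_distance <- function(G, E, clamp = 1e-6) {
  if (!all(dim(G) == dim(E))) stop("matrices not conformable")
  off <- !diag(nrow(E))
  if (any(E[off] <= 1)) {
    stop("Euclidean distances must be > 1 (are coordinates in metres?)")
  }
  g <- pmax(as.matrix(G), clamp)
  out <- matrix(0, nrow(g), ncol(g), dimnames = dimnames(g))
  out[off] <- log(g[off]) / log(as.matrix(E)[off])
  pairwise_matrix(out, paste0("log", attr(G, "statistic"), "_by_logE"))
}
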