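#' Maximum-likelihood population-effects (MLPE) model for pairwise distances
#'
#' Fits the mixed model
#' \deqn{y_{ij} = \beta_0 + \sum_m \beta_m x_{m,ij} + u_i + u_j + \epsilon_{ij}}
#' where \eqn{u_k \sim N(0, \sigma^2_u)} is a random effect per population
#' shared by every pair containing it, and \eqn{\epsilon \sim N(0,
#' \sigma^2_e)}. The covariance of the pair vector is
#' \eqn{\Sigma = \sigma^2_e I + \sigma^2_u Z Z^\top} with Z the pair-
#' population incidence matrix. Estimation is full maximum likelihood (not
#' REML) so that log-likelihoods are comparable across fixed-effect
#' structures: the variance ratio \eqn{\phi = \sigma^2_u/\sigma^2_e} is
#' profiled out and optimized numerically, with generalized least squares
#' for \eqn{\beta} at each \eqn{\phi}.
#'
#' @param y response [pairwise_matrix()] (e.g. normalized genetic distance).
#' @param X named list of predictor [pairwise_matrix()] objects (possibly
#'   empty for an intercept-only model).
#' @param log_predictors log-transform predictors before fitting (default
#'   `TRUE`; pairwise distances are typically right-skewed).
#' @param vif_threshold with >= 2 predictors, iteratively drop the
#'   predictor with the largest variance inflation factor until all VIF
#'   fall below this threshold (default 4). Use `Inf` to disable.
#' @param fix_sigma_u optionally fix \eqn{\sigma^2_u} (e.g. `0` collapses
#'   the model to OLS). Default `NULL` (estimated).
#' @return an `mlpe_fit` list: `beta` (estimates, se, 95% Wald CI),
#'   `sigma2_u`, `sigma2_e`, `logLik`, `k` (estimated parameters:
#'   intercept + slopes + 2 variance components), `n` (pairs), `dropped`
#'   (predictors removed by the VIF screen), `model` (predictor names).
#' @export
mlpe_fit <- function(y, X = list(), log_predictors = TRUE,
                     vif_threshold = 4, fix_sigma_u = NULL) {
  labs <- rownames(y)
  npop <- length(labs)
  yv <- lower_vec(y)
  n <- length(yv)
  if (length(X) && is.null(names(X))) names(X) <- paste0("X", seq_along(X))
  xmat <- if (length(X)) {
    vapply(X, function(m) {
      v <- lower_vec(m)
      if (log_predictors) {
        if (any(v <= 0)) stop("cannot log-transform non-positive predictor")
        v <- log(v)
      }
      v
    }, numeric(n))
  } else matrix(0, n, 0)
  dropped <- character(0)
  while (ncol(xmat) >= 2 && is.finite(vif_threshold)) {
    vifs <- vapply(seq_len(ncol(xmat)), function(j) {
      r2 <- summary(stats::lm(xmat[, j] ~ xmat[, -j, drop = FALSE]))$r.squared
      1 / (1 - min(r2, 1 - 1e-12))
    }, 0)
    if (max(vifs) < vif_threshold) break
    worst <- which.max(vifs)
    dropped <- c(dropped, colnames(xmat)[worst])
    xmat <- xmat[, -worst, drop = FALSE]
  }
  # pair-population incidence
  pr <- which(lower.tri(matrix(0, npop, npop)), arr.ind = TRUE)
  Z <- matrix(0, n, npop)
  Z[cbind(seq_len(n), pr[, 1])] <- 1
  Z[cbind(seq_len(n), pr[, 2])] <- 1
  Xd <- cbind(`(Intercept)` = 1, xmat)
  ZZt <- Z %*% t(Z)

  prof <- function(phi) {
    V <- diag(n) + phi * ZZt
    ch <- chol(V)
    Xi <- backsolve(ch, forwardsolve(t(ch), Xd))
    yi <- backsolve(ch, forwardsolve(t(ch), yv))
    XtVX <- crossprod(Xd, Xi)
    beta <- solve(XtVX, crossprod(Xd, yi))
    r <- yv - Xd %*% beta
    ri <- backsolve(ch, forwardsolve(t(ch), r))
    q <- sum(r * ri)
    s2 <- q / n
    ll <- -n / 2 * log(2 * pi) - n / 2 * log(s2) -
      sum(log(diag(ch))) - n / 2
    list(ll = ll, beta = beta, s2e = s2, XtVX = XtVX)
  }
  if (!is.null(fix_sigma_u)) {
    if (fix_sigma_u == 0) {
      phi_hat <- 0
      best <- prof(0)
      s2u <- 0
    } else {
      # fixed sigma2_u: profile sigma2_e numerically
      obj <- function(ls2e) {
        s2e <- exp(ls2e)
        V <- s2e * diag(n) + fix_sigma_u * ZZt
        ch <- chol(V)
        Xi <- backsolve(ch, forwardsolve(t(ch), Xd))
        yi <- backsolve(ch, forwardsolve(t(ch), yv))
        beta <- solve(crossprod(Xd, Xi), crossprod(Xd, yi))
        r <- yv - Xd %*% beta
        ri <- backsolve(ch, forwardsolve(t(ch), r))
        n / 2 * log(2 * pi) + sum(log(diag(ch))) + sum(r * ri) / 2
      }
      op <- stats::optimize(obj, c(-20, 10))
      s2e0 <- exp(op$minimum)
      phi_hat <- fix_sigma_u / s2e0
      best <- prof(phi_hat)
      best$s2e <- s2e0
      best$ll <- -op$objective
      s2u <- fix_sigma_u
    }
  } else {
    op <- stats::optimize(function(lphi) -prof(exp(lphi))$ll, c(-15, 15),
                          tol = 1e-9)
    ll0 <- prof(0)$ll  # boundary: sigma2_u = 0
    if (ll0 >= -op$objective) {
      phi_hat <- 0
      best <- prof(0)
    } else {
      phi_hat <- exp(op$minimum)
      best <- prof(phi_hat)
    }
    s2u <- phi_hat * best$s2e
  }
  vb <- best$s2e * solve(best$XtVX)
  se <- sqrt(diag(vb))
  est <- drop(best$beta)
  # t quantile rather than 1.96: pair counts are small (10 pairs for 5
  # populations), and the ML residual variance underestimates otherwise
  tq <- stats::qt(0.975, df = max(1L, n - ncol(Xd)))
  beta <- data.frame(estimate = est, se = se,
                     ci_lower = est - tq * se, ci_upper = est + tq * se)
  rownames(beta) <- colnames(Xd)
  structure(list(beta = beta, sigma2_u = s2u, sigma2_e = best$s2e,
                 logLik = best$ll, k = ncol(Xd) + 2L, n = n,
                 dropped = dropped, model = colnames(xmat)),
            class = "mlpe_fit")
}

#' @export
print.mlpe_fit <- function(x, ...) {
  cat(sprintf("MLPE fit: %s; logLik %.3f, sigma2_u %.4g, sigma2_e %.4g\n",
              if (length(x$model)) paste(x$model, collapse = " + ") else "(intercept only)",
              x$logLik, x$sigma2_u, x$sigma2_e))
  print(round(x$beta, 5))
  invisible(x)
}

#' MLPE log-likelihood at given parameters
#'
#' Evaluates the exact multivariate-normal log-likelihood of the pair
#' vector under \eqn{y \sim N(X\beta, \sigma^2_e I + \sigma^2_u Z Z^\top)}.
#' Useful for cross-checking fits against independent dense-covariance
#' computations.
#'
#' @param y response [pairwise_matrix()].
#' @param X named list of predictor matrices (same transform conventions
#'   as [mlpe_fit()]).
#' @param beta coefficient vector (intercept first).
#' @param sigma2_u,sigma2_e variance components.
#' @param log_predictors as in [mlpe_fit()].
#' @return log-likelihood (numeric scalar).
#' @export
mlpe_loglik <- function(y, X, beta, sigma2_u, sigma2_e,
                        log_predictors = TRUE) {
  labs <- rownames(y)
  npop <- length(labs)
  yv <- lower_vec(y)
  n <- length(yv)
  xmat <- if (length(X)) {
    vapply(X, function(m) {
      v <- lower_vec(m)
      if (log_predictors) v <- log(v)
      v
    }, numeric(n))
  } else matrix(0, n, 0)
  pr <- which(lower.tri(matrix(0, npop, npop)), arr.ind = TRUE)
  Z <- matrix(0, n, npop)
  Z[cbind(seq_len(n), pr[, 1])] <- 1
  Z[cbind(seq_len(n), pr[, 2])] <- 1
  Sig <- sigma2_e * diag(n) + sigma2_u * Z %*% t(Z)
  r <- yv - cbind(1, xmat) %*% beta
  ch <- chol(Sig)
  -n / 2 * log(2 * pi) - sum(log(diag(ch))) -
    0.5 * sum(backsolve(ch, r, transpose = TRUE)^2)
}

#' Information-criterion comparison of MLPE hypotheses
#'
#' \eqn{AICc = -2LL + 2k + 2k(k+1)/(n-k-1)}, \eqn{BIC = -2LL + k \ln n},
#' with evidence weights \eqn{w_m = \exp(-\Delta_m/2)/\sum \exp(-\Delta/2)}
#' computed separately for AICc and BIC.
#'
#' @param fits named list of [mlpe_fit()] objects on the same response.
#' @return data frame with one row per hypothesis: `logLik`, `k`, `AICc`,
#'   `BIC`, `aicc_weight`, `bic_weight`, `rank` (by AICc), sorted by rank.
#' @export
model_compare <- function(fits) {
  if (is.null(names(fits))) names(fits) <- paste0("M", seq_along(fits))
  n <- unique(vapply(fits, `[[`, 0L, "n"))
  if (length(n) != 1L) stop("fits are not on the same response")
  k <- vapply(fits, `[[`, 0L, "k")
  ll <- vapply(fits, `[[`, 0, "logLik")
  if (any(n <= k + 1)) stop("AICc undefined: n <= k + 1 for some model")
  aicc <- -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  bic <- -2 * ll + k * log(n)
  wa <- exp(-(aicc - min(aicc)) / 2); wa <- wa / sum(wa)
  wb <- exp(-(bic - min(bic)) / 2); wb <- wb / sum(wb)
  out <- data.frame(hypothesis = names(fits), logLik = ll, k = k,
                    AICc = aicc, BIC = bic, aicc_weight = wa,
                    bic_weight = wb, rank = rank(aicc, ties.method = "min"),
                    stringsAsFactors = FALSE)
  out[order(out$AICc), ]
}
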