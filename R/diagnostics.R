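#' MCMC convergence and model-checking toolkit
#'
#' These functions implement the model-fit checks used throughout the
#' pipeline: split R-hat, bulk and tail effective sample size,
#' Fisher-Pearson skewness posterior predictive checks, and
#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#' (PSIS-LOO). Draw matrices are oriented iterations x chains.
#'
#' @name diagnostics
NULL

as_draws_matrix <- function(draws) {
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1L)
  if (!is.matrix(draws) || !is.numeric(draws)) {
    abort("`draws` must be an iterations x chains numeric matrix",
          class = "trampler_diag_error")
  }
  draws
}

# Split each chain in half, doubling the chain count.
split_chains <- function(draws) {
  n <- nrow(draws)
  if (n %% 2L == 1L) draws <- draws[-n, , drop = FALSE]
  half <- nrow(draws) / 2L
  cbind(draws[seq_len(half), , drop = FALSE],
        draws[half + seq_len(half), , drop = FALSE])
}

#' Split R-hat for one parameter
#'
#' Each chain is split in half and the potential scale reduction factor
#' `sqrt(((n-1)/n * W + B/n) / W)` is computed over the split chains,
#' where `W` is the mean within-chain variance and `B` the between-chain
#' variance of the half-chain means. Values near 1 indicate that the
#' chains have mixed; the pipeline's convergence-failure threshold is 1.1.
#' Constant draws return 1.0 by convention with attribute
#' `degenerate = TRUE`.
#'
#' @param draws An iterations x chains matrix (>= 2 chains, >= 4
#'   iterations).
#' @return A scalar R-hat.
#' @export
split_rhat <- function(draws) {
  draws <- as_draws_matrix(draws)
  if (ncol(draws) < 2L || nrow(draws) < 4L) {
    abort("split_rhat needs >= 2 chains and >= 4 iterations",
          class = "trampler_diag_error")
  }
  sp <- split_chains(draws)
  if (max(sp) - min(sp) == 0) {
    return(structure(1.0, degenerate = TRUE))
  }
  n <- nrow(sp)
  chain_means <- colMeans(sp)
  chain_vars <- apply(sp, 2, var)
  w <- mean(chain_vars)
  b <- n * var(chain_means)
  if (w == 0) return(structure(Inf, degenerate = TRUE))
  sqrt(((n - 1) / n * w + b / n) / w)
}

# Core ESS from split chains via chain-averaged autocovariance and Geyer's
# initial-monotone positive-sequence truncation.
ess_core <- function(draws) {
  sp <- split_chains(as_draws_matrix(draws))
  m <- ncol(sp); n <- nrow(sp)
  if (n < 4L) {
    abort("ess needs >= 4 iterations", class = "trampler_diag_error")
  }
  if (max(sp) - min(sp) == 0) return(structure(m * n, degenerate = TRUE))
  acov <- vapply(seq_len(m), function(j) {
    drop(acf(sp[, j], lag.max = n - 1L, type = "covariance",
             plot = FALSE, demean = TRUE)$acf)
  }, numeric(n))
  mean_acov <- rowMeans(acov)
  chain_vars <- acov[1, ] * n / (n - 1)
  w <- mean(chain_vars)
  b <- if (m > 1) n * var(colMeans(sp)) else 0
  var_plus <- w * (n - 1) / n + b / n
  if (var_plus <= 0) return(structure(m * n, degenerate = TRUE))
  rho <- 1 - (w - mean_acov) / var_plus
  rho[1] <- 1
  # Geyer pairs P_k = rho_{2k} + rho_{2k+1}
  max_pairs <- floor(length(rho) / 2)
  tau <- 0
  prev <- Inf
  for (k in seq_len(max_pairs)) {
    p <- rho[2 * k - 1] + rho[2 * k]
    if (!is.finite(p) || p < 0) break
    p <- min(p, prev)
    tau <- tau + p
    prev <- p
  }
  tau <- max(2 * tau - 1, 1 / (m * n))
  min(m * n / tau, m * n)
}

#' Bulk effective sample size
#'
#' Rank-normalizes the pooled draws (average ranks mapped through the
#' normal quantile function with the (r - 3/8)/(S + 1/4) adjustment) and
#' computes the effective sample size via chain-averaged autocorrelations
#' with Geyer initial-monotone truncation. Capped at the pooled draw
#' count.
#'
#' @inheritParams split_rhat
#' @return A scalar ESS.
#' @export
ess_bulk <- function(draws) {
  draws <- as_draws_matrix(draws)
  s <- length(draws)
  z <- qnorm((rank(draws, ties.method = "average") - 3 / 8) / (s + 1 / 4))
  ess_core(matrix(z, nrow = nrow(draws)))
}

#' Tail effective sample size
#'
#' The minimum of the effective sample sizes of the 5% and 95% exceedance
#' indicators, measuring how well the chains resolve the distribution
#' tails.
#'
#' @inheritParams split_rhat
#' @return A scalar ESS.
#' @export
ess_tail <- function(draws) {
  draws <- as_draws_matrix(draws)
  qs <- quantile(draws, c(0.05, 0.95), names = FALSE)
  ess_q <- vapply(qs, function(q) {
    ind <- matrix(as.numeric(draws <= q), nrow = nrow(draws))
    ess_core(ind)
  }, numeric(1))
  min(ess_q)
}

#' Both effective sample sizes
#'
#' @inheritParams split_rhat
#' @return A one-row tibble with `ess_bulk` and `ess_tail`.
#' @export
ess <- function(draws) {
  tibble::tibble(ess_bulk = ess_bulk(draws), ess_tail = ess_tail(draws))
}

#' Fisher-Pearson coefficient of skewness
#'
#' The unadjusted moment coefficient `g1 = m3 / m2^(3/2)` with central
#' moments `m_k = mean((x - mean(x))^k)`; the test statistic used in the
#' posterior predictive check for response skewness.
#'
#' @param sample Numeric vector, length >= 3, nonzero variance.
#' @return A scalar.
#' @export
#' @examples
#' fisher_pearson_skew(c(-1, 0, 1)) # 0
fisher_pearson_skew <- function(sample) {
  if (!is.numeric(sample) || length(sample) < 3L || anyNA(sample)) {
    abort("`sample` must be numeric, length >= 3, without NAs",
          class = "trampler_diag_error")
  }
  m <- mean(sample)
  m2 <- mean((sample - m)^2)
  if (m2 == 0) {
    abort("zero variance: skewness undefined", class = "trampler_diag_error")
  }
  mean((sample - m)^3) / m2^1.5
}

# Simulate one replicated response vector from the fitted family at a
# posterior draw.
simulate_response <- function(params, data, spec) {
  p <- unpack_params(params, data$J)
  eta <- drop(data$X %*% p$beta) + p$u[data$group]
  if (spec$family == "negbin") {
    rnbinom(data$n, size = exp(p$aux_log), mu = exp(eta))
  } else if (spec$family == "beta") {
    mu <- if (spec$mean_link == "logit") plogis(eta) else exp(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    phi <- exp(p$aux_log)
    rbeta(data$n, mu * phi, (1 - mu) * phi)
  } else {
    rnorm(data$n, eta, exp(p$aux_log))
  }
}

#' Posterior predictive check on response skewness
#'
#' Draws `ndraws` parameter vectors from the posterior, simulates a
#' replicated response vector from the fitted family for each (conditional
#' on the fitted pair intercepts), computes the Fisher-Pearson skewness of
#' every replicate, and locates the observed skewness within that
#' replicate distribution. A two-sided tail probability near 0 means the
#' model fails to reproduce the skewness of the data.
#'
#' @param fit A [sample_posterior()] fit.
#' @param ndraws Number of posterior draws to replicate (default 1000).
#' @param seed Integer seed.
#' @return An object of class `trample_ppc`: list with `statistic`
#'   (`"skew"`), `observed`, `replicated` (length `ndraws`), and
#'   `tail_prob`.
#' @export
posterior_predictive <- function(fit, ndraws = 1000, seed = 1) {
  if (!inherits(fit, "trample_fit")) {
    abort("`fit` must be a trample_fit", class = "trampler_diag_error")
  }
  stopifnot_scalar_count(ndraws, "ndraws")
  pooled <- pooled_draws(fit)
  # Draws are stored on the raw elevation scale, which matches data$X.
  rep_skew <- with_seed(seed, {
    take <- sample.int(nrow(pooled), ndraws, replace = ndraws > nrow(pooled))
    vapply(take, function(s) {
      yrep <- simulate_response(pooled[s, ], fit$data, fit$spec)
      if (var(yrep) == 0) 0 else fisher_pearson_skew(yrep)
    }, numeric(1))
  })
  obs <- fisher_pearson_skew(fit$data$y)
  p_low <- mean(rep_skew <= obs)
  p_high <- mean(rep_skew >= obs)
  structure(list(statistic = "skew", observed = obs, replicated = rep_skew,
                 tail_prob = min(1, 2 * min(p_low, p_high))),
            class = "trample_ppc")
}

#' @export
print.trample_ppc <- function(x, ...) {
  cat(sprintf("<trample_ppc> %s: observed %.3f | replicated %.3f (%.3f, %.3f)\n",
              x$statistic, x$observed, median(x$replicated),
              quantile(x$replicated, 0.025), quantile(x$replicated, 0.975)))
  cat(sprintf("  two-sided tail probability: %.3f\n", x$tail_prob))
  invisible(x)
}

# Zhang & Stephens (2009)-style empirical-Bayes fit of a generalized
# Pareto distribution to tail excesses, with the weak-prior shrinkage of
# the shape towards 0.5 that stabilises small tails.
gpd_fit <- function(z) {
  z <- sort(z)
  n <- length(z)
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  theta <- 1 / z[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * z[max(1L, floor(n / 4 + 0.5))])
  k_of <- function(th) vapply(th, function(t) -mean(log1p(-t * z)), numeric(1))
  kk <- k_of(theta)
  ll <- n * (log(theta / kk) + kk - 1)
  ll[!is.finite(ll)] <- -Inf
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  theta_hat <- sum(theta * w)
  # shape on the standard xi convention (positive = heavy tail)
  k_hat <- mean(log1p(-theta_hat * z))
  sigma <- -k_hat / theta_hat
  # regularise towards 0.5 with a 10-observation pseudo-prior
  k_hat <- (n * k_hat + 5) / (n + 10)
  list(k = k_hat, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma * expm1(-k * log1p(-p)) / k
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' For each observation, forms raw importance ratios from the negative
#' pointwise log-likelihood, fits a generalized Pareto distribution to the
#' largest 20% of the weights, replaces that tail with the fitted
#' quantiles (truncated at the raw maximum), and computes the LOO expected
#' log predictive density from the smoothed weights. The fitted shape `k`
#' per observation diagnoses the reliability of the estimate: `k < 0.5`
#' is reliable; `k > 0.7` unreliable.
#'
#' @param log_lik An S x n matrix of pointwise log-likelihood values over
#'   S posterior draws (S >= 400; see [pointwise_loglik()]).
#' @return A list: `elpd_loo`, `pointwise` tibble (`elpd`, `pareto_k`),
#'   `n_k_gt_05`, `n_k_gt_07`.
#' @export
psis_loo <- function(log_lik) {
  if (!is.matrix(log_lik) || any(!is.finite(log_lik))) {
    abort("`log_lik` must be a finite S x n matrix",
          class = "trampler_diag_error")
  }
  S <- nrow(log_lik)
  if (S < 400L) {
    abort("PSIS-LOO needs >= 400 draws", class = "trampler_diag_error")
  }
  M <- ceiling(0.2 * S)
  if (M < 5L) {
    abort("tail too small for the generalized Pareto fit",
          class = "trampler_diag_error")
  }
  n <- ncol(log_lik)
  elpd <- numeric(n)
  k_vec <- numeric(n)
  for (i in seq_len(n)) {
    lw <- -log_lik[, i]
    lw <- lw - max(lw)
    w <- exp(lw)
    ord <- order(w)
    tail_idx <- ord[(S - M + 1L):S]
    cutoff <- w[ord[S - M]]
    z <- w[tail_idx] - cutoff
    pos <- z > 0
    if (sum(pos) >= 5L && sd(z[pos]) > 0) {
      fit <- gpd_fit(z[pos])
      k_vec[i] <- fit$k
      p_grid <- (seq_len(M) - 0.5) / M
      smoothed <- cutoff + qgpd(p_grid, fit$k, fit$sigma)
      smoothed <- pmin(smoothed, max(w))
      w[tail_idx[order(w[tail_idx])]] <- smoothed
    } else {
      k_vec[i] <- -Inf  # degenerate tail; nothing to smooth
    }
    lw_s <- log(w)
    elpd[i] <- log_sum_exp(lw_s + log_lik[, i]) - log_sum_exp(lw_s)
  }
  list(elpd_loo = sum(elpd),
       pointwise = tibble::tibble(elpd = elpd, pareto_k = k_vec),
       n_k_gt_05 = sum(k_vec > 0.5),
       n_k_gt_07 = sum(k_vec > 0.7))
}

#' Full diagnostics report for a fitted model
#'
#' Assembles the fit checks applied to every model in the pipeline:
#' per-parameter split R-hat and bulk/tail ESS against configurable
#' thresholds, the skewness posterior predictive check, and PSIS-LOO
#' Pareto-k counts.
#'
#' @param fit A [sample_posterior()] fit.
#' @param ndraws Posterior predictive replicates (default 1000).
#' @param seed Integer seed for the replicates.
#' @param thresholds List with elements `rhat` (default 1.1), `ess`
#'   (default 1000) and `pareto_k` (default 0.5).
#' @param loo Compute PSIS-LOO (default TRUE; the costliest check).
#' @return An object of class `trample_diagnostics`: list with
#'   `parameters` (tibble of R-hat/ESS per parameter), `ppc`, `psis`
#'   (NULL when `loo = FALSE`), `thresholds`, and logical `converged`
#'   (all R-hat below threshold).
#' @export
diagnose <- function(fit, ndraws = 1000, seed = 1,
                     thresholds = list(rhat = 1.1, ess = 1000,
                                       pareto_k = 0.5),
                     loo = TRUE) {
  s <- summarize_fit(fit)
  pars <- tibble::tibble(
    parameter = s$parameter, rhat = s$rhat,
    ess_bulk = s$ess_bulk, ess_tail = s$ess_tail,
    rhat_ok = s$rhat < thresholds$rhat,
    ess_ok = s$ess_bulk > thresholds$ess & s$ess_tail > thresholds$ess
  )
  ppc <- posterior_predictive(fit, ndraws = ndraws, seed = seed)
  psis <- if (loo) psis_loo(pointwise_loglik(fit)) else NULL
  structure(list(parameters = pars, ppc = ppc, psis = psis,
                 thresholds = thresholds,
                 converged = all(pars$rhat_ok)),
            class = "trample_diagnostics")
}

#' @export
print.trample_diagnostics <- function(x, ...) {
  cat("<trample_diagnostics>\n")
  cat(sprintf("  max R-hat %.3f (threshold %.2f) | min bulk ESS %.0f | min tail ESS %.0f\n",
              max(x$parameters$rhat), x$thresholds$rhat,
              min(x$parameters$ess_bulk), min(x$parameters$ess_tail)))
  cat(sprintf("  skew PPC tail probability %.3f\n", x$ppc$tail_prob))
  if (!is.null(x$psis)) {
    cat(sprintf("  elpd_loo %.1f | Pareto-k > %.1f: %d | > 0.7: %d\n",
                x$psis$elpd_loo, x$thresholds$pareto_k, x$psis$n_k_gt_05,
                x$psis$n_k_gt_07))
  }
  invisible(x)
}

#' Serialize a diagnostics report to JSON
#'
#' @param x A `trample_diagnostics` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(x, path) {
  out <- list(
    parameters = x$parameters,
    ppc = list(statistic = x$ppc$statistic, observed = x$ppc$observed,
               tail_prob = x$ppc$tail_prob),
    thresholds = x$thresholds,
    converged = x$converged
  )
  if (!is.null(x$psis)) {
    out$psis <- list(elpd_loo = x$psis$elpd_loo,
                     n_k_gt_05 = x$psis$n_k_gt_05,
                     n_k_gt_07 = x$psis$n_k_gt_07,
                     pareto_k = x$psis$pointwise$pareto_k)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
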