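iid_chains <- function(n, m, seed, mean = 0, sd = 1) {
  trampler:::with_seed(seed, matrix(rnorm(n * m, mean, sd), ncol = m))
}

ar1_chains <- function(n, m, rho, seed) {
  trampler:::with_seed(seed, {
    vapply(seq_len(m), function(j) {
      x <- numeric(n)
      x[1] <- rnorm(1)
      for (t in 2:n) x[t] <- rho * x[t - 1] + sqrt(1 - rho^2) * rnorm(1)
      x
    }, numeric(n))
  })
}

test_that("split R-hat separates mixed from unmixed chains", {
  good <- iid_chains(2000, 2, seed = 1)
  expect_gte(split_rhat(good), sqrt(999 / 1000))  # finite-sample floor
  expect_lt(split_rhat(good), 1.01)
  bad <- cbind(iid_chains(500, 1, seed = 2, mean = 0),
               iid_chains(500, 1, seed = 3, mean = 10))
  expect_gt(split_rhat(bad), 1.1)
  const <- matrix(5, 100, 3)
  r <- split_rhat(const)
  expect_equal(as.numeric(r), 1.0)
  expect_true(attr(r, "degenerate"))
  expect_error(split_rhat(matrix(1:4, ncol = 1)),
               class = "trampler_diag_error")
})

test_that("ESS matches iid and AR(1) references and respects its bound", {
  good <- iid_chains(2000, 2, seed = 11)
  b <- ess_bulk(good)
  expect_gt(b, 4000 * 0.8)
  expect_lte(b, 4000)
  rho <- 0.9
  ar <- ar1_chains(4000, 2, rho, seed = 12)
  target <- 8000 * (1 - rho) / (1 + rho)
  expect_lt(abs(ess_bulk(ar) - target) / target, 0.3)
  # bound holds across assorted chain shapes
  for (s in 1:5) {
    x <- ar1_chains(400, 2, runif(1, 0, 0.95), seed = 20 + s)
    e <- ess(x)
    expect_lte(e$ess_bulk, 800)
    expect_lte(e$ess_tail, 800)
  }
})

test_that("Fisher-Pearson skewness matches the moment definition", {
  expect_equal(fisher_pearson_skew(c(-1, 0, 1)), 0)
  x <- c(0, 0, 0, 1)
  m <- mean(x)
  oracle <- mean((x - m)^3) / mean((x - m)^2)^1.5
  expect_equal(fisher_pearson_skew(x), oracle)
  expect_gt(oracle, 0)
  y <- trampler:::with_seed(3, rexp(100))
  expect_equal(fisher_pearson_skew(-y), -fisher_pearson_skew(y))
  expect_error(fisher_pearson_skew(rep(2, 10)),
               class = "trampler_diag_error")
  expect_error(fisher_pearson_skew(c(1, 2)), class = "trampler_diag_error")
})

test_that("skew PPC is calibrated when the model is true", {
  # point-mass posterior at the truth, data simulated from that truth:
  # the observed skew should rarely sit in the replicate tails
  inside <- 0
  for (s in 1:10) {
    md <- structure(list(
      y = NULL, n = 60L, J = 2L,
      X = cbind(1, rep(0:1, 30), 0, 0), group = rep(1:2, 30),
      pair_levels = c("A", "B"),
      spec = model_spec("y", "negbin"), unidentifiable = FALSE
    ), class = "glmm_data")
    truth <- c(1.5, -0.5, 0, 0, log(4), log(0.3), 0.1, -0.1)
    md$y <- trampler:::with_seed(100 + s, {
      trampler:::simulate_response(truth, md, md$spec)
    })
    iter <- 150
    draws <- array(rep(truth, each = iter * 2),
                   dim = c(iter, 2, length(truth)),
                   dimnames = list(NULL, NULL, c(
                     "(Intercept)", "disturbance", "elevation",
                     "disturbance:elevation", "log_shape", "log_sigma_pair",
                     "u[A]", "u[B]")))
    fit <- structure(list(draws = draws, data = md, spec = md$spec,
                          chains = 2, iter = iter, warmup = 0, seed = 1,
                          accept = matrix(0.3, 2, 8),
                          par_names = dimnames(draws)[[3]],
                          elevation_center = 0),
                     class = "trample_fit")
    ppc <- posterior_predictive(fit, ndraws = 400, seed = 7)
    if (ppc$tail_prob > 0.05) inside <- inside + 1
    if (s == 1) {
      expect_identical(posterior_predictive(fit, ndraws = 400, seed = 7)$replicated,
                       ppc$replicated)
      one <- posterior_predictive(fit, ndraws = 1, seed = 8)
      expect_length(one$replicated, 1)
    }
  }
  expect_gte(inside, 8)
})

test_that("PSIS-LOO behaves on a well-specified conjugate model", {
  # y ~ N(mu, 1), mu ~ N(0, 1): exact posterior draws, no MCMC involved
  n <- 50; S <- 1000
  y <- trampler:::with_seed(5, rnorm(n))
  post_var <- 1 / (n + 1)
  post_mean <- sum(y) * post_var
  mu_s <- trampler:::with_seed(6, rnorm(S, post_mean, sqrt(post_var)))
  ll <- vapply(seq_len(n), function(i) dnorm(y[i], mu_s, 1, log = TRUE),
               numeric(S))
  res <- psis_loo(ll)
  expect_true(all(res$pointwise$pareto_k < 0.5))
  expect_identical(res$n_k_gt_05, 0L)
  # LOO penalization: elpd_loo below the in-sample log predictive density
  lpd <- sum(log(colMeans(exp(ll))))
  expect_lt(res$elpd_loo, lpd)
  # locality: duplicating one observation barely changes its k
  y2 <- c(y, y[1])
  pv2 <- 1 / (n + 2)
  mu_s2 <- trampler:::with_seed(6, rnorm(S, sum(y2) * pv2, sqrt(pv2)))
  ll2 <- vapply(seq_len(n + 1), function(i) dnorm(y2[i], mu_s2, 1, log = TRUE),
                numeric(S))
  res2 <- psis_loo(ll2)
  expect_lt(abs(res2$pointwise$pareto_k[1] - res$pointwise$pareto_k[1]), 0.2)
  expect_error(psis_loo(ll[1:300, ]), class = "trampler_diag_error")
})

test_that("diagnose assembles a full report and serializes it", {
  md <- toy_height_data(91, 92, abundance_mean = 1.2)
  fit <- sample_posterior(md, chains = 2, iter = 500, warmup = 200, seed = 14)
  dg <- diagnose(fit, ndraws = 200, seed = 3, loo = TRUE)
  expect_s3_class(dg, "trample_diagnostics")
  expect_equal(nrow(dg$parameters), length(fit$par_names))
  expect_true(all(dg$parameters$rhat >= sqrt(1 - 1 / 150)))
  expect_true(is.finite(dg$psis$elpd_loo))
  expect_gte(dg$ppc$tail_prob, 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_diagnostics(dg, path)
  parsed <- jsonlite::read_json(path)
  expect_named(parsed, c("parameters", "ppc", "thresholds", "converged",
                         "psis"), ignore.order = TRUE)
})
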