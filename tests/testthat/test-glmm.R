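# Minimal hand-built fit object for summary-level tests.
make_fake_fit <- function(pooled, chains = 2) {
  J <- 2
  par_names <- c("(Intercept)", "disturbance", "elevation",
                 "disturbance:elevation", "log_shape", "log_sigma_pair",
                 "u[A]", "u[B]")
  iter <- nrow(pooled) / chains
  draws <- array(0, dim = c(iter, chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  for (p in seq_along(par_names)) {
    draws[, , p] <- matrix(pooled[, p], nrow = iter)
  }
  dat <- list(n = 10L, J = J, X = cbind(1, rep(0:1, 5), 1700, rep(0:1, 5) * 1700),
              group = rep(1:2, 5), pair_levels = c("A", "B"))
  structure(list(draws = draws, data = dat,
                 spec = model_spec("y", "negbin"), chains = chains,
                 iter = iter, warmup = 0, seed = 1,
                 accept = matrix(0.3, chains, length(par_names)),
                 par_names = par_names, elevation_center = 0),
            class = "trample_fit")
}

test_that("build_model_data assembles the design matrix and indices", {
  dat <- tibble::tibble(
    y = c(3L, 1L, 4L, 2L), disturbed = c(0, 1, 0, 1),
    elevation_m = c(1600, 1600, 1900, 1900), pair_id = c("A", "A", "C", "C")
  )
  md <- build_model_data(dat, model_spec("y", "negbin"))
  expect_equal(dim(md$X), c(4, 4))
  expect_equal(unname(md$X[, 4]), dat$disturbed * dat$elevation_m)
  expect_equal(md$group, c(1, 1, 2, 2))   # "A","C" -> 1,2
  expect_equal(md$J, 2)
  expect_false(md$unidentifiable)
})

test_that("family preconditions and degenerate designs are caught", {
  base <- tibble::tibble(disturbed = c(0, 1), elevation_m = 1700,
                         pair_id = "A")
  nb_bad <- dplyr::mutate(base, y = c(1.5, 2))
  expect_error(build_model_data(nb_bad, model_spec("y", "negbin")),
               "round_for_nb")
  beta_bad <- dplyr::mutate(base, y = c(0, 0.5))
  expect_error(build_model_data(beta_bad, model_spec("y", "beta")),
               "adjust_unit_interval")
  flat <- tibble::tibble(y = c(1L, 2L), disturbed = 0, elevation_m = 1700,
                         pair_id = c("A", "B"))
  expect_warning(md <- build_model_data(flat, model_spec("y", "negbin")),
                 class = "trampler_design_warning")
  expect_true(md$unidentifiable)
})

test_that("pointwise log-likelihood sums to the total and matches the pmf", {
  dat <- tibble::tibble(y = c(0L, 2L, 5L, 1L, 3L), disturbed = c(0, 0, 1, 1, 0),
                        elevation_m = 1700, pair_id = c("A", "A", "B", "B", "A"))
  md <- build_model_data(dat, model_spec("y", "negbin"))
  params <- c(1.2, -0.4, 0.001, 0, log(3), log(0.5), 0.2, -0.1)
  ll <- log_likelihood(params, md)
  expect_equal(sum(ll$pointwise), ll$total)
  # independent NB pmf from the gamma-function definition
  eta <- drop(md$X %*% params[1:4]) + params[7:8][md$group]
  mu <- exp(eta); phi <- 3
  manual <- lgamma(md$y + phi) - lgamma(phi) - lfactorial(md$y) +
    phi * log(phi / (phi + mu)) + md$y * log(mu / (phi + mu))
  expect_equal(ll$pointwise, manual, tolerance = 1e-10)
})

test_that("negative binomial approaches Poisson as the shape grows", {
  dat <- tibble::tibble(y = c(2L, 4L, 0L, 7L), disturbed = c(0, 1, 0, 1),
                        elevation_m = 1700, pair_id = "A")
  md <- build_model_data(dat, model_spec("y", "negbin"))
  params <- c(1, 0.3, 0, 0, log(1e6), log(0.5), 0)
  nb <- log_likelihood(params, md)$pointwise
  eta <- drop(md$X %*% params[1:4])
  pois <- dpois(md$y, exp(eta), log = TRUE)
  expect_lt(max(abs(nb - pois)), 1e-3)
})

test_that("Beta mean links behave at the origin and out of range", {
  dat <- tibble::tibble(y = c(0.2, 0.5, 0.9), disturbed = c(0, 1, 0),
                        elevation_m = 1700, pair_id = "A")
  md <- build_model_data(dat, model_spec("y", "beta"))
  # all-zero parameters under logit: mu = 0.5 exactly
  params <- c(0, 0, 0, 0, log(5), log(0.5), 0)
  mu_half <- dbeta(dat$y, 0.5 * 5, 0.5 * 5, log = TRUE)
  expect_equal(log_likelihood(params, md)$pointwise, mu_half)
  # log mean link with mu >= 1 is rejected at -Inf, not an exception
  md_log <- build_model_data(dat, model_spec("y", "beta", mean_link = "log"))
  bad <- c(0.5, 0, 0, 0, log(5), log(0.5), 0)   # mu = exp(0.5) > 1
  expect_identical(log_likelihood(bad, md_log)$total, -Inf)
})

test_that("log posterior equals likelihood plus the analytic prior", {
  dat <- tibble::tibble(y = c(2L, 3L), disturbed = c(0, 1),
                        elevation_m = 1700, pair_id = "A")
  md <- build_model_data(dat, model_spec("y", "negbin"))
  pr <- prior_config()
  params <- c(0.5, -1, 0.002, 0, log(2), log(0.7), 0.3)
  beta <- params[1:4]; la <- params[5]; ls <- params[6]; u <- params[7]
  sigma <- exp(ls)
  lp <- sum(dt(beta / 10, 3, log = TRUE) - log(10)) +
    log(2) + dt(sigma / 2.5, 3, log = TRUE) - log(2.5) + ls +
    dnorm(la, 0, 2.5, log = TRUE) +
    dnorm(u, 0, sigma, log = TRUE)
  expect_equal(log_posterior(params, md) - log_likelihood(params, md)$total,
               lp)
  # prior-only evaluation: finite for any finite parameters, symmetric in
  # the sign of the disturbance coefficient
  empty <- md; empty$n <- 0L
  expect_true(is.finite(log_posterior(params, empty)))
  flip <- params; flip[2] <- -flip[2]
  expect_equal(log_posterior(params, empty), log_posterior(flip, empty))
})

test_that("the adaptive sampler recovers a conjugate normal posterior", {
  y <- trampler:::with_seed(31, rnorm(50, mean = 3, sd = 1))
  prior_sd <- 10
  post_var <- 1 / (length(y) + 1 / prior_sd^2)
  post_mean <- post_var * sum(y)
  log_post <- function(th) {
    sum(dnorm(y, th, 1, log = TRUE)) + dnorm(th, 0, prior_sd, log = TRUE)
  }
  out <- trampler:::adaptive_mwg(log_post, init = 0, iter = 4000,
                                 warmup = 1000, prop_sd = 0.5, seed = 77)
  draws <- out$draws[, 1]
  mcse <- sd(draws) / sqrt(ess_bulk(matrix(draws, ncol = 1)))
  expect_lt(abs(mean(draws) - post_mean), 3 * mcse)
  expect_equal(sd(draws), sqrt(post_var), tolerance = 0.15)
})

test_that("same seed reproduces draws exactly and chains require >= 2", {
  md <- toy_height_data(61, 62)
  f1 <- sample_posterior(md, chains = 2, iter = 200, warmup = 100, seed = 5)
  f2 <- sample_posterior(md, chains = 2, iter = 200, warmup = 100, seed = 5)
  expect_identical(f1$draws, f2$draws)
  expect_error(sample_posterior(md, chains = 1, iter = 200, warmup = 100,
                                seed = 5), class = "trampler_model_error")
})

test_that("the posterior is invariant to pair relabelling", {
  cfg <- sim_config(seed = 71, n_pairs = 6, abundance_mean = 3)
  d <- make_design(cfg)
  tr <- simulate_traits(d, toy_params(), seed = 72)
  tr$height <- round_for_nb(tr$height_cm)
  spec <- model_spec("height", "negbin")
  fit1 <- sample_posterior(build_model_data(tr, spec),
                           chains = 2, iter = 800, warmup = 300, seed = 9)
  relabel <- setNames(sprintf("Z%02d", 6:1), unique(tr$pair_id))
  tr2 <- tr; tr2$pair_id <- unname(relabel[tr$pair_id])
  fit2 <- sample_posterior(build_model_data(tr2, spec),
                           chains = 2, iter = 800, warmup = 300, seed = 10)
  e1 <- disturbance_effect(fit1); e2 <- disturbance_effect(fit2)
  expect_lt(abs(e1$estimate - e2$estimate),
            3 * sqrt(e1$sd^2 / 500 + e2$sd^2 / 500 + 1e-8) + 0.05)
})

test_that("summaries, effect flags and tidiers are consistent", {
  S <- 400
  pooled <- matrix(0, S, 8)
  pooled[, 1] <- 2                        # constant draws
  pooled[, 2] <- trampler:::with_seed(8, rnorm(S))
  fit <- make_fake_fit(pooled)
  s <- summarize_fit(fit)
  expect_equal(s$mean[1], 2)
  expect_equal(s$lower[1], 2)
  expect_equal(s$upper[1], 2)
  expect_true(s$effect[1])                # CI [2,2] excludes 0
  expect_equal(s$lower[2], qnorm(0.025), tolerance = 0.3)
  expect_false(s$effect[2])
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "conf.low",
                     "conf.high", "rhat", "ess_bulk", "ess_tail", "effect"))
  expect_equal(nrow(td), 4)
  g <- glance(fit)
  expect_equal(g$nobs, 10L)
  expect_equal(g$chains, 2)
})

test_that("disturbance_effect evaluates the contrast at an elevation", {
  S <- 200
  pooled <- matrix(0, S, 8)
  pooled[, 2] <- -3          # bD
  pooled[, 4] <- 0.001       # bDE
  fit <- make_fake_fit(pooled)
  eff <- disturbance_effect(fit, elevation = 1700)
  expect_equal(eff$estimate, -3 + 0.001 * 1700)
  expect_true(eff$effect)
})

test_that("large-draw normal posterior flags no effect", {
  md <- toy_height_data(81, 82, bD = 0, abundance_mean = 1)
  expect_error(summarize_fit(
    sample_posterior(md, chains = 2, iter = 120, warmup = 100, seed = 3)),
    "100 pooled")
})
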