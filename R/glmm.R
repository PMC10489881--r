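#' Specify a hierarchical disturbance x elevation model
#'
#' All models share the fixed-effect structure
#' `response ~ disturbance * elevation` with a random intercept per
#' transect pair. Size traits (integer cm) use a negative binomial family
#' with log mean link and log-scale shape; proportions (relative
#' reproduction, percent cover) use a Beta family with a logit mean link by
#' default (a log mean link is selectable, with means outside (0,1)
#' rejected at -Inf during sampling) and log-scale precision. A Gaussian
#' identity-link family (auxiliary parameter = log residual sd) is included
#' as a reference family for sampler validation.
#'
#' @param response Name of the response column (e.g. `"height_cm"`,
#'   `"relative_repro"`, `"green_fraction"`).
#' @param family `"negbin"`, `"beta"`, or `"gaussian"`.
#' @param mean_link Mean link; defaults to `"log"` for negative binomial,
#'   `"logit"` for Beta, `"identity"` for Gaussian.
#' @param priors A list as returned by [prior_config()].
#' @param center_elevation Centre elevation internally during sampling (the
#'   reported draws are always back-transformed exactly to the raw metre
#'   scale). Recommended: raw elevations near 1800 m make the intercept and
#'   slope almost collinear.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response,
                       family = c("negbin", "beta", "gaussian"),
                       mean_link = NULL,
                       priors = prior_config(),
                       center_elevation = TRUE) {
  family <- match.arg(family)
  default_link <- switch(family, negbin = "log", beta = "logit",
                         gaussian = "identity")
  if (is.null(mean_link)) mean_link <- default_link
  ok <- switch(family,
               negbin = mean_link == "log",
               beta = mean_link %in% c("logit", "log"),
               gaussian = mean_link == "identity")
  if (!ok) {
    abort(sprintf("mean link '%s' is not supported for family '%s'",
                  mean_link, family), class = "trampler_model_error")
  }
  if (!is.character(response) || length(response) != 1L) {
    abort("`response` must be a single column name",
          class = "trampler_model_error")
  }
  structure(list(response = response, family = family,
                 mean_link = mean_link, priors = priors,
                 center_elevation = isTRUE(center_elevation)),
            class = "model_spec")
}

#' Prior configuration
#'
#' Weakly informative priors wide enough for coefficients on the scale of
#' the reported disturbance effects (magnitudes up to ~20): each fixed
#' effect gets a Student-t(df, 0, scale) prior, the random-intercept sd a
#' half-Student-t, and the log auxiliary parameter (log NB shape or log
#' Beta precision) a Normal(0, aux_sd). `beta_df = Inf` gives Normal
#' priors on the fixed effects.
#'
#' @param beta_df,beta_scale Student-t degrees of freedom and scale for the
#'   fixed effects (default t(3, 0, 10)).
#' @param sigma_df,sigma_scale Half-Student-t parameters for the pair
#'   random-intercept sd (default half-t(3, 0, 2.5)).
#' @param aux_sd Normal sd for the log auxiliary parameter (default 2.5).
#' @return A named list of class `prior_config`.
#' @export
prior_config <- function(beta_df = 3, beta_scale = 10,
                         sigma_df = 3, sigma_scale = 2.5, aux_sd = 2.5) {
  if (beta_scale <= 0 || sigma_scale <= 0 || aux_sd <= 0) {
    abort("prior scales must be positive", class = "trampler_model_error")
  }
  structure(list(beta_df = beta_df, beta_scale = beta_scale,
                 sigma_df = sigma_df, sigma_scale = sigma_scale,
                 aux_sd = aux_sd),
            class = "prior_config")
}

#' Assemble model data from a trait or cover table
#'
#' Extracts the response vector, the n x 4 design matrix
#' `[1, D, E, D*E]` (D = disturbed indicator, on-trail = 1; E = elevation
#' in metres) and contiguous transect-pair indices. Family preconditions
#' are enforced here: negative binomial responses must already be
#' non-negative integers (see [round_for_nb()]) and Beta responses must lie
#' strictly inside (0,1) (see [adjust_unit_interval()]).
#'
#' @param data A tibble containing the response column plus `disturbed`,
#'   `elevation_m` and `pair_id`. Rows with missing response are dropped.
#' @param spec A [model_spec()].
#' @return An object of class `glmm_data`: list with `y`, `X`, `group`
#'   (1..J), `pair_levels`, `n`, `J`, `spec`, and an `unidentifiable` flag
#'   set when the disturbance column is constant.
#' @export
build_model_data <- function(data, spec) {
  if (!inherits(spec, "model_spec")) {
    abort("`spec` must be a model_spec", class = "trampler_model_error")
  }
  required <- c(spec$response, "disturbed", "elevation_m", "pair_id")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("data is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "trampler_model_error")
  }
  keep <- !is.na(data[[spec$response]])
  data <- data[keep, , drop = FALSE]
  y <- data[[spec$response]]
  if (nrow(data) == 0L) {
    abort("no non-missing responses", class = "trampler_model_error")
  }
  if (spec$family == "negbin") {
    if (any(y < 0) || any(y != floor(y))) {
      abort(paste0("negative binomial responses must be non-negative ",
                   "integers; apply round_for_nb() first"),
            class = "trampler_model_error")
    }
  } else if (spec$family == "beta") {
    if (any(y <= 0) || any(y >= 1)) {
      abort(paste0("Beta responses must lie strictly in (0,1); apply ",
                   "adjust_unit_interval() first"),
            class = "trampler_model_error")
    }
  }
  D <- as.numeric(data$disturbed)
  if (!all(D %in% c(0, 1))) {
    abort("`disturbed` must be coded 0/1", class = "trampler_model_error")
  }
  E <- as.numeric(data$elevation_m)
  X <- cbind(`(Intercept)` = 1, disturbance = D, elevation = E,
             `disturbance:elevation` = D * E)
  pair_levels <- unique(data$pair_id)
  group <- match(data$pair_id, pair_levels)
  unident <- length(unique(D)) < 2L
  if (unident) {
    warn("disturbance indicator is constant: its effect is unidentifiable",
         class = "trampler_design_warning")
  }
  structure(list(y = as.numeric(y), X = X, group = group,
                 pair_levels = pair_levels, n = length(y),
                 J = length(pair_levels), spec = spec,
                 unidentifiable = unident),
            class = "glmm_data")
}

# Family log-likelihood on the linear-predictor scale. Returns a pointwise
# vector; non-finite values signal an invalid parameter point (rejected at
# -Inf), never an exception.
pointwise_ll <- function(y, eta, aux_log, spec) {
  if (spec$family == "negbin") {
    mu <- exp(eta)
    ll <- dnbinom(y, size = exp(aux_log), mu = mu, log = TRUE)
  } else if (spec$family == "beta") {
    mu <- if (spec$mean_link == "logit") plogis(eta) else exp(eta)
    phi <- exp(aux_log)
    ll <- suppressWarnings(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
    ll[mu <= 0 | mu >= 1] <- -Inf
  } else {
    ll <- dnorm(y, mean = eta, sd = exp(aux_log), log = TRUE)
  }
  ll[!is.finite(ll)] <- -Inf
  ll
}

unpack_params <- function(params, J) {
  if (length(params) != 6L + J) {
    abort(sprintf("expected %d parameters (4 beta, log aux, log sigma, %d u)",
                  6L + J, J), class = "trampler_model_error")
  }
  list(beta = params[1:4], aux_log = params[5], log_sigma = params[6],
       u = params[seq_len(J) + 6L])
}

#' Hierarchical model log-likelihood
#'
#' Evaluates the likelihood at a parameter vector ordered as
#' `(b0, bD, bE, bDE, log aux, log sigma_pair, u_1..u_J)`, where the
#' auxiliary parameter is the NB shape or Beta precision. The linear
#' predictor is `X beta + u[group]`. The total equals the sum of the
#' pointwise vector exactly; the pointwise vector feeds PSIS-LOO.
#'
#' @param params Numeric parameter vector (see above).
#' @param data A [build_model_data()] object.
#' @param spec Optional [model_spec()]; defaults to `data$spec`.
#' @return List with elements `total` and `pointwise`.
#' @export
log_likelihood <- function(params, data, spec = NULL) {
  if (is.null(spec)) spec <- data$spec
  p <- unpack_params(params, data$J)
  eta <- drop(data$X %*% p$beta) + p$u[data$group]
  ll <- pointwise_ll(data$y, eta, p$aux_log, spec)
  list(total = sum(ll), pointwise = ll)
}

# Analytic log prior; the Jacobian of the log transform for sigma_pair is
# included (the auxiliary parameter's prior is placed directly on the log
# scale, so it needs none).
log_prior <- function(beta, aux_log, log_sigma, u, priors) {
  sigma <- exp(log_sigma)
  lp_beta <- sum(dt(beta / priors$beta_scale, df = priors$beta_df,
                    log = TRUE) - log(priors$beta_scale))
  lp_sigma <- log(2) + dt(sigma / priors$sigma_scale, df = priors$sigma_df,
                          log = TRUE) - log(priors$sigma_scale) + log_sigma
  lp_aux <- dnorm(aux_log, 0, priors$aux_sd, log = TRUE)
  lp_u <- sum(dnorm(u, 0, sigma, log = TRUE))
  lp_beta + lp_sigma + lp_aux + lp_u
}

#' Hierarchical model log-posterior
#'
#' Log-likelihood plus log-priors: Student-t(df, 0, scale) on each fixed
#' effect, half-Student-t on the pair sd (with the log-scale Jacobian),
#' Normal on the log auxiliary parameter, and Normal(0, sigma_pair) on the
#' pair intercepts. With zero-row data this is the (finite) log prior.
#'
#' @inheritParams log_likelihood
#' @return A scalar.
#' @export
log_posterior <- function(params, data, spec = NULL) {
  if (is.null(spec)) spec <- data$spec
  p <- unpack_params(params, data$J)
  lp <- log_prior(p$beta, p$aux_log, p$log_sigma, p$u, spec$priors)
  if (data$n == 0L) return(lp)
  log_likelihood(params, data, spec)$total + lp
}

# Generic adaptive scalar Metropolis-within-Gibbs, used for sampler
# validation against closed-form targets. `log_post` maps a parameter
# vector to a scalar. Proposal scales adapt towards ~30% acceptance in
# batches during warmup, then freeze.
adaptive_mwg <- function(log_post, init, iter, warmup, prop_sd, seed,
                         batch = 25L, target = 0.3) {
  set.seed(seed)
  npar <- length(init)
  cur <- init
  lp_cur <- log_post(cur)
  if (!is.finite(lp_cur)) {
    abort(paste0("log posterior is non-finite at the initial values; ",
                 "re-seed or rescale the data"),
          class = "trampler_sampler_error")
  }
  keep <- matrix(NA_real_, nrow = iter - warmup, ncol = npar)
  acc <- int_acc <- integer(npar)
  for (it in seq_len(iter)) {
    for (k in seq_len(npar)) {
      prop <- cur
      prop[k] <- cur[k] + rnorm(1, 0, prop_sd[k])
      lp_prop <- log_post(prop)
      if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp_cur) {
        cur <- prop; lp_cur <- lp_prop
        acc[k] <- acc[k] + 1L; int_acc[k] <- int_acc[k] + 1L
      }
    }
    if (it <= warmup && it %% batch == 0L) {
      rate <- int_acc / batch
      prop_sd <- pmin(pmax(prop_sd * exp(rate - target), 1e-7), 50)
      int_acc[] <- 0L
    }
    if (it > warmup) keep[it - warmup, ] <- cur
  }
  list(draws = keep, accept = acc / iter, prop_sd = prop_sd)
}

#' Draw from the posterior with an adaptive Metropolis-within-Gibbs sampler
#'
#' Runs `chains` independent chains of scalar random-walk
#' Metropolis-within-Gibbs updates over the blocks (fixed effects), (pair
#' intercepts), (log pair sd), (log auxiliary). Proposal scales adapt
#' towards a 20-40% acceptance window during warmup and are frozen
#' afterwards; only post-warmup draws are returned. Elevation is centred
#' internally when the spec requests it and every draw is back-transformed
#' exactly to the raw metre scale, so reported coefficients are always on
#' the data scale. Fully reproducible given `seed`.
#'
#' Initial values follow the published fitting protocol: Beta-family
#' chains start all parameters at zero on the sampling scale; negative
#' binomial (and Gaussian) chains start at data-informed values.
#'
#' @param data A [build_model_data()] object.
#' @param spec Optional [model_spec()] override; defaults to `data$spec`.
#' @param chains Number of chains (>= 2; default 3).
#' @param iter Total iterations per chain including warmup (default 5000).
#' @param warmup Warmup iterations discarded and used for adaptation
#'   (default 1000).
#' @param seed Integer seed.
#' @return An object of class `trample_fit`: `draws` is an
#'   (iter - warmup) x chains x parameters array with parameters ordered
#'   `(Intercept)`, `disturbance`, `elevation`, `disturbance:elevation`,
#'   `log_shape`/`log_precision`/`log_residual_sd`, `log_sigma_pair`,
#'   `u[...]`; plus the data, spec, acceptance rates and sampler metadata.
#' @export
sample_posterior <- function(data, spec = NULL, chains = 3, iter = 5000,
                             warmup = 1000, seed = 1) {
  if (!inherits(data, "glmm_data")) {
    abort("`data` must come from build_model_data()",
          class = "trampler_model_error")
  }
  if (is.null(spec)) spec <- data$spec
  stopifnot_scalar_count(chains, "chains")
  if (chains < 2) {
    abort("at least 2 chains are required for convergence diagnostics",
          class = "trampler_model_error")
  }
  stopifnot_scalar_count(iter, "iter")
  stopifnot_scalar_count(warmup, "warmup")
  if (warmup >= iter) {
    abort("`warmup` must be smaller than `iter`",
          class = "trampler_model_error")
  }
  if (data$unidentifiable) {
    warn("fitting with a constant disturbance column; bD is prior-driven",
         class = "trampler_design_warning")
  }
  y <- data$y; J <- data$J; group <- data$group
  idx_by_group <- split(seq_len(data$n), group)
  X <- data$X
  e_center <- 0
  if (spec$center_elevation) {
    e_center <- mean(X[, 3])
    X <- cbind(X[, 1], X[, 2], X[, 3] - e_center, X[, 2] * (X[, 3] - e_center))
  }
  priors <- spec$priors

  init_state <- function() {
    beta <- numeric(4)
    if (spec$family == "negbin") {
      beta[1] <- log(mean(y) + 0.5)
      la <- 0; ls <- log(0.5)
    } else if (spec$family == "gaussian") {
      beta[1] <- mean(y)
      la <- log(sd(y) + 1e-6); ls <- log(0.5)
    } else {
      la <- 0; ls <- 0
    }
    list(beta = beta, u = numeric(J), ls = ls, la = la)
  }
  col_sd <- apply(X, 2, sd)
  prop0 <- list(beta = 0.5 / pmax(col_sd, 0.5), u = 0.5, ls = 0.3, la = 0.3)

  n_keep <- iter - warmup
  par_names <- c("(Intercept)", "disturbance", "elevation",
                 "disturbance:elevation",
                 switch(spec$family, negbin = "log_shape",
                        beta = "log_precision", gaussian = "log_residual_sd"),
                 "log_sigma_pair",
                 paste0("u[", data$pair_levels, "]"))
  draws <- array(NA_real_, dim = c(n_keep, chains, 6L + J),
                 dimnames = list(NULL, NULL, par_names))
  accept <- matrix(NA_real_, nrow = chains, ncol = 6L + J)

  lp_beta_k <- function(b) {
    dt(b / priors$beta_scale, df = priors$beta_df, log = TRUE) -
      log(priors$beta_scale)
  }

  # group-level mean of the (possibly centred) elevation column, used by
  # the joint translation move that trades the elevation slope against the
  # pair intercepts
  ec_group <- vapply(idx_by_group, function(idx) mean(X[idx, 3]), numeric(1))

  for (ch in seq_len(chains)) {
    set.seed(sub_seed(seed, 7000L + ch))
    st <- init_state()
    s_beta <- prop0$beta
    s_u <- rep(prop0$u, J)
    s_ls <- prop0$ls; s_la <- prop0$la
    s_mv <- c(prop0$beta[1], prop0$beta[3])
    eta <- drop(X %*% st$beta) + st$u[group]
    ll_vec <- pointwise_ll(y, eta, st$la, spec)
    ll_tot <- sum(ll_vec)
    if (!is.finite(ll_tot)) {
      # fall back to prior-ish start for degenerate inits
      st$beta <- st$beta * 0
      eta <- drop(X %*% st$beta) + st$u[group]
      ll_vec <- pointwise_ll(y, eta, st$la, spec)
      ll_tot <- sum(ll_vec)
    }
    if (!is.finite(ll_tot)) {
      abort(paste0("posterior is non-finite at the initial values; re-seed ",
                   "or rescale the data"), class = "trampler_sampler_error")
    }
    acc <- int_acc <- numeric(6L + J)
    acc_mv <- int_mv <- numeric(2L)
    # adaptive joint block over (beta, log aux): empirical covariance
    # learned during warmup (Haario-style), frozen afterwards
    joint_hist <- matrix(NA_real_, nrow = warmup, ncol = 5L)
    joint_chol <- NULL
    s_joint <- 1
    acc_joint <- int_joint <- 0
    s_sc <- 0.3
    acc_sc <- int_sc <- 0
    for (it in seq_len(iter)) {
      # -- fixed effects ------------------------------------------------
      for (k in 1:4) {
        delta <- rnorm(1, 0, s_beta[k])
        eta_p <- eta + delta * X[, k]
        ll_p <- sum(pointwise_ll(y, eta_p, st$la, spec))
        logr <- ll_p - ll_tot +
          lp_beta_k(st$beta[k] + delta) - lp_beta_k(st$beta[k])
        if (is.finite(logr) && log(runif(1)) < logr) {
          st$beta[k] <- st$beta[k] + delta
          eta <- eta_p; ll_tot <- ll_p
          acc[k] <- acc[k] + 1; int_acc[k] <- int_acc[k] + 1
        }
      }
      # -- pair intercepts ----------------------------------------------
      sigma <- exp(st$ls)
      for (j in seq_len(J)) {
        idx <- idx_by_group[[j]]
        delta <- rnorm(1, 0, s_u[j])
        u_new <- st$u[j] + delta
        eta_sub <- eta[idx] + delta
        ll_sub_old <- sum(pointwise_ll(y[idx], eta[idx], st$la, spec))
        ll_sub_new <- sum(pointwise_ll(y[idx], eta_sub, st$la, spec))
        logr <- ll_sub_new - ll_sub_old +
          dnorm(u_new, 0, sigma, log = TRUE) -
          dnorm(st$u[j], 0, sigma, log = TRUE)
        if (is.finite(logr) && log(runif(1)) < logr) {
          st$u[j] <- u_new
          eta[idx] <- eta_sub
          ll_tot <- ll_tot + (ll_sub_new - ll_sub_old)
          acc[4L + 2L + j] <- acc[4L + 2L + j] + 1
          int_acc[4L + 2L + j] <- int_acc[4L + 2L + j] + 1
        }
      }
      # -- joint (beta, log aux) block ----------------------------------
      if (!is.null(joint_chol)) {
        step <- s_joint * drop(joint_chol %*% rnorm(5))
        beta_p <- st$beta + step[1:4]
        la_p <- st$la + step[5]
        eta_p <- eta + drop(X %*% step[1:4])
        ll_p <- sum(pointwise_ll(y, eta_p, la_p, spec))
        logr <- ll_p - ll_tot +
          sum(lp_beta_k(beta_p) - lp_beta_k(st$beta)) +
          dnorm(la_p, 0, priors$aux_sd, log = TRUE) -
          dnorm(st$la, 0, priors$aux_sd, log = TRUE)
        if (is.finite(logr) && log(runif(1)) < logr) {
          st$beta <- beta_p; st$la <- la_p
          eta <- eta_p; ll_tot <- ll_p
          acc_joint <- acc_joint + 1; int_joint <- int_joint + 1
        }
      }
      # -- joint translation moves --------------------------------------
      # Shift the intercept (or elevation slope) and compensate through
      # the pair intercepts; this breaks the strong posterior correlation
      # between the location-type fixed effects and the random effects
      # that scalar updates mix through only slowly.
      sigma <- exp(st$ls)
      for (mv in 1:2) {
        delta <- rnorm(1, 0, s_mv[mv])
        k0 <- if (mv == 1L) 1L else 3L
        beta_p <- st$beta
        beta_p[k0] <- beta_p[k0] + delta
        u_p <- if (mv == 1L) st$u - delta else st$u - delta * ec_group
        eta_p <- drop(X %*% beta_p) + u_p[group]
        ll_p <- sum(pointwise_ll(y, eta_p, st$la, spec))
        logr <- ll_p - ll_tot +
          lp_beta_k(beta_p[k0]) - lp_beta_k(st$beta[k0]) +
          sum(dnorm(u_p, 0, sigma, log = TRUE)) -
          sum(dnorm(st$u, 0, sigma, log = TRUE))
        if (is.finite(logr) && log(runif(1)) < logr) {
          st$beta <- beta_p; st$u <- u_p
          eta <- eta_p; ll_tot <- ll_p
          acc_mv[mv] <- acc_mv[mv] + 1; int_mv[mv] <- int_mv[mv] + 1
        }
      }
      # -- funnel scale move: shift log sigma and rescale the u's -------
      # (log sigma, u) -> (log sigma + delta, u * e^delta); the Jacobian
      # e^(J delta) makes this a valid move that traverses the funnel at
      # small sigma much faster than separate updates.
      {
        delta <- rnorm(1, 0, s_sc)
        ls_n <- st$ls + delta
        u_n <- st$u * exp(delta)
        eta_p <- eta + (u_n - st$u)[group]
        ll_p <- sum(pointwise_ll(y, eta_p, st$la, spec))
        lp_old <- log(2) + dt(exp(st$ls) / priors$sigma_scale,
                              df = priors$sigma_df, log = TRUE) + st$ls +
          sum(dnorm(st$u, 0, exp(st$ls), log = TRUE))
        lp_new <- log(2) + dt(exp(ls_n) / priors$sigma_scale,
                              df = priors$sigma_df, log = TRUE) + ls_n +
          sum(dnorm(u_n, 0, exp(ls_n), log = TRUE))
        logr <- ll_p - ll_tot + lp_new - lp_old + J * delta
        if (is.finite(logr) && log(runif(1)) < logr) {
          st$ls <- ls_n; st$u <- u_n
          eta <- eta_p; ll_tot <- ll_p
          acc_sc <- acc_sc + 1; int_sc <- int_sc + 1
        }
      }
      # -- log pair sd (prior-only conditional) -------------------------
      ls_new <- st$ls + rnorm(1, 0, s_ls)
      lp_old <- log(2) + dt(exp(st$ls) / priors$sigma_scale,
                            df = priors$sigma_df, log = TRUE) + st$ls +
        sum(dnorm(st$u, 0, exp(st$ls), log = TRUE))
      lp_new <- log(2) + dt(exp(ls_new) / priors$sigma_scale,
                            df = priors$sigma_df, log = TRUE) + ls_new +
        sum(dnorm(st$u, 0, exp(ls_new), log = TRUE))
      if (is.finite(lp_new) && log(runif(1)) < lp_new - lp_old) {
        st$ls <- ls_new
        acc[6L] <- acc[6L] + 1; int_acc[6L] <- int_acc[6L] + 1
      }
      # -- log auxiliary ------------------------------------------------
      la_new <- st$la + rnorm(1, 0, s_la)
      ll_p <- sum(pointwise_ll(y, eta, la_new, spec))
      logr <- ll_p - ll_tot +
        dnorm(la_new, 0, priors$aux_sd, log = TRUE) -
        dnorm(st$la, 0, priors$aux_sd, log = TRUE)
      if (is.finite(logr) && log(runif(1)) < logr) {
        st$la <- la_new; ll_tot <- ll_p
        acc[5L] <- acc[5L] + 1; int_acc[5L] <- int_acc[5L] + 1
      }
      # -- warmup adaptation -------------------------------------------
      if (it <= warmup && it %% 25L == 0L) {
        rate <- int_acc / 25
        s_beta <- pmin(pmax(s_beta * exp(rate[1:4] - 0.3), 1e-7), 50)
        s_la <- pmin(pmax(s_la * exp(rate[5] - 0.3), 1e-7), 50)
        s_ls <- pmin(pmax(s_ls * exp(rate[6] - 0.3), 1e-7), 50)
        s_u <- pmin(pmax(s_u * exp(rate[7:(6 + J)] - 0.3), 1e-7), 50)
        s_mv <- pmin(pmax(s_mv * exp(int_mv / 25 - 0.3), 1e-7), 50)
        if (!is.null(joint_chol)) {
          s_joint <- pmin(pmax(s_joint * exp(int_joint / 25 - 0.25), 1e-6),
                          50)
        }
        s_sc <- pmin(pmax(s_sc * exp(int_sc / 25 - 0.3), 1e-7), 50)
        int_acc[] <- 0; int_mv[] <- 0; int_joint <- 0; int_sc <- 0
      }
      if (it <= warmup) {
        joint_hist[it, ] <- c(st$beta, st$la)
        if (it %% 100L == 0L && it >= 200L) {
          hist_part <- joint_hist[seq(floor(it / 2), it), , drop = FALSE]
          cv <- stats::cov(hist_part)
          cf <- tryCatch(chol(cv + diag(1e-10, 5L)), error = function(e) NULL)
          if (!is.null(cf)) {
            joint_chol <- t(cf) * (2.38 / sqrt(5))
            s_joint <- 1
          }
        }
      }
      if (it > warmup) {
        b <- st$beta
        if (spec$center_elevation) {
          b <- c(b[1] - b[3] * e_center, b[2] - b[4] * e_center, b[3], b[4])
        }
        draws[it - warmup, ch, ] <- c(b, st$la, st$ls, st$u)
      }
    }
    accept[ch, ] <- acc / iter
  }
  structure(list(draws = draws, data = data, spec = spec, chains = chains,
                 iter = iter, warmup = warmup, seed = seed,
                 accept = accept, par_names = par_names,
                 elevation_center = e_center),
            class = "trample_fit")
}

#' @export
print.trample_fit <- function(x, ...) {
  cat(sprintf("<trample_fit> %s model for '%s'\n", x$spec$family,
              x$spec$response))
  cat(sprintf("  %d obs, %d transect pairs, %d chains x %d post-warmup draws\n",
              x$data$n, x$data$J, x$chains, dim(x$draws)[1]))
  print(summarize_fit(x)[1:6, c("parameter", "mean", "lower", "upper",
                                "effect")])
  invisible(x)
}

# Pooled draws matrix (S x P).
pooled_draws <- function(fit) {
  d <- fit$draws
  matrix(aperm(d, c(1, 2, 3)), nrow = dim(d)[1] * dim(d)[2],
         dimnames = list(NULL, dimnames(d)[[3]]))
}

# iter x chain matrix for one parameter.
param_matrix <- function(fit, par) {
  fit$draws[, , par, drop = TRUE]
}

#' Summarize a fitted model the way the published table reports it
#'
#' Pools draws across chains and reports, per parameter, the posterior
#' mean, the equal-tailed 95% credible interval (2.5% and 97.5%
#' quantiles), split R-hat, bulk and tail effective sample sizes, and the
#' effect flag: `TRUE` when the credible interval excludes zero, the
#' criterion used to infer an effect.
#'
#' @param fit A [sample_posterior()] fit.
#' @param prob Credible-interval mass (default 0.95).
#' @return A tibble with one row per parameter.
#' @export
summarize_fit <- function(fit, prob = 0.95) {
  if (!inherits(fit, "trample_fit")) {
    abort("`fit` must be a trample_fit", class = "trampler_model_error")
  }
  pooled <- pooled_draws(fit)
  if (nrow(pooled) < 100L) {
    abort("fewer than 100 pooled draws; increase iterations",
          class = "trampler_model_error")
  }
  a <- (1 - prob) / 2
  qs <- apply(pooled, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  rhat <- vapply(fit$par_names, function(p) split_rhat(param_matrix(fit, p)),
                 numeric(1))
  essb <- vapply(fit$par_names, function(p) ess_bulk(param_matrix(fit, p)),
                 numeric(1))
  esst <- vapply(fit$par_names, function(p) ess_tail(param_matrix(fit, p)),
                 numeric(1))
  tibble::tibble(
    parameter = fit$par_names,
    mean = unname(colMeans(pooled)),
    sd = unname(apply(pooled, 2, sd)),
    lower = unname(qs[1, ]),
    upper = unname(qs[2, ]),
    rhat = unname(rhat),
    ess_bulk = unname(essb),
    ess_tail = unname(esst),
    effect = unname(qs[1, ] > 0 | qs[2, ] < 0),
    n = fit$data$n
  )
}

#' Pointwise log-likelihood matrix over posterior draws
#'
#' @param fit A [sample_posterior()] fit.
#' @param max_draws Upper bound on the number of (evenly thinned) pooled
#'   draws used (default 4000).
#' @return An S x n matrix of pointwise log-likelihood values.
#' @export
pointwise_loglik <- function(fit, max_draws = 4000) {
  pooled <- pooled_draws(fit)
  S <- nrow(pooled)
  take <- if (S > max_draws) round(seq(1, S, length.out = max_draws)) else
    seq_len(S)
  out <- matrix(NA_real_, nrow = length(take), ncol = fit$data$n)
  for (s in seq_along(take)) {
    out[s, ] <- log_likelihood(pooled[take[s], ], fit$data, fit$spec)$pointwise
  }
  out
}

#' Fit one disturbance x elevation model from a table
#'
#' Convenience wrapper: builds the model spec and data, applies the
#' family's response preparation ([round_for_nb()] for negative binomial,
#' [adjust_unit_interval()] for Beta) unless `prepare = FALSE`, and
#' samples the posterior.
#'
#' @param data Tibble with the response plus `disturbed`, `elevation_m`,
#'   `pair_id`.
#' @param response Response column name.
#' @param family `"negbin"` or `"beta"`.
#' @param prepare Apply the family's response preparation (default TRUE).
#' @param mean_link,priors Passed to [model_spec()].
#' @param chains,iter,warmup,seed Passed to [sample_posterior()].
#' @return A `trample_fit`.
#' @export
fit_trample_model <- function(data, response,
                              family = c("negbin", "beta"),
                              prepare = TRUE, mean_link = NULL,
                              priors = prior_config(),
                              chains = 3, iter = 5000, warmup = 1000,
                              seed = 1) {
  family <- match.arg(family)
  spec <- model_spec(response, family, mean_link = mean_link,
                     priors = priors)
  if (prepare) {
    if (family == "negbin") {
      data[[response]] <- round_for_nb(data[[response]])
    } else {
      data[[response]] <- adjust_unit_interval(data[[response]])
    }
  }
  md <- build_model_data(data, spec)
  sample_posterior(md, chains = chains, iter = iter, warmup = warmup,
                   seed = seed)
}

#' Posterior disturbance effect at a given elevation
#'
#' The model's disturbance contrast on the link scale is
#' `bD + bDE * elevation`; because the survey's raw elevations (~1600-2000
#' m) make `bD` an extrapolation to elevation 0, the scientifically
#' interpretable disturbance effect is this contrast evaluated at an
#' elevation inside the survey range. Defaults to the mean elevation of
#' the fitted data.
#'
#' @param fit A [sample_posterior()] fit.
#' @param elevation Elevation (m) at which to evaluate the contrast;
#'   default: mean of the data's elevation column.
#' @param prob Credible-interval mass (default 0.95).
#' @return A one-row tibble: `elevation`, `estimate` (posterior mean),
#'   `sd`, `lower`, `upper`, `effect` (CI excludes zero).
#' @export
disturbance_effect <- function(fit, elevation = NULL, prob = 0.95) {
  if (!inherits(fit, "trample_fit")) {
    abort("`fit` must be a trample_fit", class = "trampler_model_error")
  }
  if (is.null(elevation)) elevation <- mean(fit$data$X[, 3])
  pooled <- pooled_draws(fit)
  eff <- pooled[, "disturbance"] +
    pooled[, "disturbance:elevation"] * elevation
  a <- (1 - prob) / 2
  q <- quantile(eff, c(a, 1 - a), names = FALSE)
  tibble::tibble(elevation = elevation, estimate = mean(eff), sd = sd(eff),
                 lower = q[1], upper = q[2],
                 effect = q[1] > 0 | q[2] < 0)
}

#' Tidy a fitted trampling model
#'
#' @param x A `trample_fit`.
#' @param effects `"fixed"` (default) restricts to the four fixed effects;
#'   `"all"` includes the auxiliary, pair-sd and pair-intercept rows.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `rhat`, `ess_bulk`, `ess_tail`, `effect`.
#' @export
tidy.trample_fit <- function(x, effects = c("fixed", "all"), ...) {
  effects <- match.arg(effects)
  s <- summarize_fit(x)
  if (effects == "fixed") s <- s[1:4, ]
  tibble::tibble(term = s$parameter, estimate = s$mean, std.error = s$sd,
                 conf.low = s$lower, conf.high = s$upper, rhat = s$rhat,
                 ess_bulk = s$ess_bulk, ess_tail = s$ess_tail,
                 effect = s$effect)
}

#' One-row model overview
#'
#' @param x A `trample_fit`.
#' @param ... Unused.
#' @return A one-row tibble: observations, groups, family, chains, draws,
#'   worst R-hat, smallest bulk/tail ESS and mean acceptance rate.
#' @export
glance.trample_fit <- function(x, ...) {
  s <- summarize_fit(x)
  tibble::tibble(nobs = x$data$n, n_pairs = x$data$J,
                 family = x$spec$family, chains = x$chains,
                 draws = dim(x$draws)[1] * x$chains,
                 max_rhat = max(s$rhat, na.rm = TRUE),
                 min_ess_bulk = min(s$ess_bulk, na.rm = TRUE),
                 min_ess_tail = min(s$ess_tail, na.rm = TRUE),
                 mean_accept = mean(x$accept))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
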