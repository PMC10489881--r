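# Shared fixtures, built in code at test time.

# A random RGB image with integer DNs in [0, 255].
random_image <- function(h, w, seed) {
  trampler:::with_seed(seed, {
    array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
  })
}

# A random image whose every pixel has three pairwise-distinct channel
# values (no ties anywhere).
distinct_channel_image <- function(h, w, seed) {
  trampler:::with_seed(seed, {
    img <- array(0, dim = c(h, w, 3))
    for (i in seq_len(h * w)) {
      px <- sample(0:255, 3)          # without replacement: distinct
      img[((i - 1) %% h) + 1, ((i - 1) %/% h) + 1, ] <- px
    }
    img
  })
}

# Nested-loop reference classifier, deliberately naive.
oracle_green_mask <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  mask <- matrix(0L, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      r <- img[i, j, 1]; g <- img[i, j, 2]; b <- img[i, j, 3]
      if (g > r && g > b) mask[i, j] <- 1L
    }
  }
  mask
}

# Small single-species survey parameters for sampler tests.
toy_params <- function(b0 = 2, bD = -0.5, bE = 0, bDE = 0, phi = 5,
                       sigma_pair = 0.5) {
  survey_params(
    species = list(test = species_params(
      height = trait_params(c(b0, bD, bE, bDE), phi),
      diameter = trait_params(c(b0, 0, 0, 0), phi),
      lambda_rep = 0)),
    sigma_pair = sigma_pair
  )
}

# Simulate one survey and return NB-ready model data for the height trait.
toy_height_data <- function(sim_seed, trait_seed, bD = -0.5,
                            abundance_mean = 2.5) {
  cfg <- sim_config(seed = sim_seed, abundance_mean = abundance_mean)
  d <- make_design(cfg)
  tr <- simulate_traits(d, toy_params(bD = bD), seed = trait_seed)
  tr$height <- round_for_nb(tr$height_cm)
  build_model_data(tr, model_spec("height", "negbin"))
}
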