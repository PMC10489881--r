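test_that("make_design lays out the paired-transect survey", {
  d <- make_design(sim_config(seed = 1))
  expect_equal(nrow(d), 280)                       # 14 x 2 x 10 quadrats
  expect_equal(length(unique(d$transect_id)), 28)
  expect_equal(length(unique(d$pair_id)), 14)
  # one disturbed and one undisturbed transect per pair
  per_pair <- tapply(d$disturbed, d$pair_id, function(x) sort(unique(x)))
  expect_true(all(vapply(per_pair, identical, logical(1), c(0L, 1L))))
  # elevation shared within a pair and inside the configured range
  ranges <- tapply(d$elevation_m, d$pair_id, function(x) diff(range(x)))
  expect_true(all(ranges == 0))
  expect_true(all(d$elevation_m >= 1580 & d$elevation_m <= 1980))
})

test_that("minimal designs and invalid configs behave", {
  d <- make_design(sim_config(seed = 3, n_pairs = 1, n_quadrats = 1))
  expect_equal(nrow(d), 2)
  expect_equal(length(unique(d$elevation_m)), 1)
  expect_error(sim_config(seed = 1, n_pairs = 0), class = "trampler_config_error")
  expect_error(sim_config(seed = 1, n_quadrats = -2),
               class = "trampler_config_error")
  expect_error(sim_config(n_pairs = 3), class = "trampler_config_error")
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(seed = 42, n_pairs = 3, n_quadrats = 2,
                    image_size = c(16, 16))
  p <- table1_defaults()
  expect_identical(make_design(cfg), make_design(cfg))
  d <- make_design(cfg)
  expect_identical(simulate_traits(d, p, seed = 9),
                   simulate_traits(d, p, seed = 9))
  expect_identical(simulate_cover_images(d, p, seed = 9),
                   simulate_cover_images(d, p, seed = 9))
})

test_that("trait draws follow the generative mean law", {
  # empirical mean ratio disturbed/undisturbed converges to exp(bD)
  cfg <- sim_config(seed = 7, n_pairs = 50, n_quadrats = 20,
                    max_per_quadrat = 10, abundance_mean = 6)
  d <- make_design(cfg)
  pars <- toy_params(b0 = 2, bD = -0.5, phi = 5, sigma_pair = 0)
  tr <- simulate_traits(d, pars, seed = 8)
  expect_gt(nrow(tr), 1e4)
  m1 <- mean(tr$height_cm[tr$disturbed == 1])
  m0 <- mean(tr$height_cm[tr$disturbed == 0])
  # each arm's mean is within 3 Monte-Carlo SEs of its target
  se0 <- sd(tr$height_cm[tr$disturbed == 0]) / sqrt(sum(tr$disturbed == 0))
  se1 <- sd(tr$height_cm[tr$disturbed == 1]) / sqrt(sum(tr$disturbed == 1))
  expect_lt(abs(m0 - exp(2)), 3 * se0)
  expect_lt(abs(m1 - exp(1.5)), 3 * se1)
  expect_equal(m1 / m0, exp(-0.5), tolerance = 0.05)
})

test_that("null effects and zero reproduction rates are honoured", {
  cfg <- sim_config(seed = 5, n_pairs = 10)
  d <- make_design(cfg)
  pars <- survey_params(
    species = list(a = species_params(
      height = trait_params(c(2, 0, 0, 0), 5),
      diameter = trait_params(c(2, 0, 0, 0), 5),
      lambda_rep = 0)),
    sigma_pair = 0
  )
  tr <- simulate_traits(d, pars, seed = 6)
  expect_true(all(tr$buds == 0 & tr$flowers == 0 & tr$fruits == 0))
  # null disturbance effect: two-sample mean difference small
  t_stat <- t.test(height_cm ~ disturbed, data = tr)$statistic
  expect_lt(abs(t_stat), 4)
})

test_that("per-quadrat selection is capped at the configured maximum", {
  cfg <- sim_config(seed = 11, n_pairs = 4, abundance_mean = 12,
                    max_per_quadrat = 5)
  d <- make_design(cfg)
  tr <- simulate_traits(d, table1_defaults(), seed = 12)
  counts <- dplyr::count(tr, species, pair_id, disturbed, quadrat)
  expect_true(all(counts$n <= 5))
})

test_that("sedge-like species carry no reproduction counts", {
  cfg <- sim_config(seed = 13, n_pairs = 3)
  tr <- simulate_traits(make_design(cfg), table1_defaults(), seed = 14)
  cx <- tr[tr$species == "Carex_spp", ]
  expect_gt(nrow(cx), 0)
  expect_true(all(is.na(cx$buds)))
  sh <- tr[tr$species == "P_empetriformis", ]
  expect_true(all(!is.na(sh$buds)))
})

test_that("painted images contain exactly the requested green pixels", {
  cfg <- sim_config(seed = 21, n_pairs = 2, n_quadrats = 2,
                    image_size = c(32, 32))
  d <- make_design(cfg)
  imgs <- simulate_cover_images(d, table1_defaults(), seed = 22)
  for (i in seq_len(nrow(imgs))) {
    img <- imgs$image[[i]]
    mask <- (img[, , 2] > img[, , 1]) & (img[, , 2] > img[, , 3])
    expect_identical(sum(mask), as.integer(round(imgs$true_cover[i] * 1024)))
    expect_identical(sum(mask), imgs$n_green[i])
  }
})

test_that("preset fixed effects match the reported estimates", {
  p <- table1_defaults()
  expect_equal(p$cover_beta[1:2], c(6.58, -8.38))
  expect_equal(p$species$C_mertensiana$height$beta[2], 0.66)
  expect_equal(p$species$V_ovalifolium$diameter$beta[2], -9.18)
  expect_equal(p$species$V_ovalifolium$height$beta[2], -4.58)
  expect_equal(p$species$Carex_spp$height$beta[c(2, 4)], c(-19.89, 0.01))
  expect_false(p$species$Carex_spp$reproduction)
})

test_that("parameters and plant tables round-trip through disk formats", {
  p <- table1_defaults()
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_survey_params(p, yml)
  expect_equal(read_survey_params(yml), p)

  cfg <- sim_config(seed = 31, n_pairs = 2, n_quadrats = 2)
  tr <- simulate_traits(make_design(cfg), p, seed = 32)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_plant_table(tr, csv)
  back <- read_plant_table(csv)
  expect_equal(as.data.frame(back), as.data.frame(tr))
})

test_that("written quadrat images read back losslessly", {
  cfg <- sim_config(seed = 41, n_pairs = 1, n_quadrats = 2,
                    image_size = c(16, 16))
  d <- make_design(cfg)
  imgs <- simulate_cover_images(d, table1_defaults(), seed = 42)
  dir <- withr::local_tempdir()
  write_quadrat_images(imgs, dir)
  f <- file.path(dir, paste0(imgs$quadrat_id[1], ".png"))
  expect_true(file.exists(f))
  expect_identical(read_quadrat_image(f), imgs$image[[1]] * 1)
})
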