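test_that("saturation boost preserves gray and saturated pixels", {
  gray <- array(c(120, 120, 120), dim = c(1, 1, 3))
  expect_equal(boost_saturation(gray)[1, 1, ], c(120, 120, 120))
  sat <- array(c(0, 255, 0), dim = c(1, 1, 3))
  expect_equal(boost_saturation(sat)[1, 1, ], c(0, 255, 0))
})

test_that("saturation boost matches the HSV round-trip oracle", {
  # (100,110,100): s = 10/110 -> boosted to 1, hue 1/3, value 110/255;
  # grDevices::hsv()/col2rgb() is the independent round-trip
  px <- array(c(100, 110, 100), dim = c(1, 1, 3))
  got <- boost_saturation(px, 30)[1, 1, ]
  hsv <- grDevices::rgb2hsv(matrix(c(100, 110, 100), 3), maxColorValue = 255)
  oracle <- drop(grDevices::col2rgb(
    grDevices::hsv(hsv[1], min(1, 30 * hsv[2]), hsv[3])))
  expect_equal(got, as.numeric(oracle))
  expect_equal(got, c(0, 110, 0))
  # rank order preserved and gap widened on random distinct-channel pixels
  img <- distinct_channel_image(8, 8, seed = 99)
  boosted <- boost_saturation(img, 30)
  rank_before <- apply(matrix(img, ncol = 3), 1, order)
  rank_after <- apply(matrix(boosted, ncol = 3), 1, order)
  expect_identical(rank_before, rank_after)
})

test_that("boost_saturation validates its arguments", {
  img <- random_image(4, 4, seed = 1)
  expect_error(boost_saturation(img, factor = 0),
               class = "trampler_image_error")
  expect_error(boost_saturation(img, factor = -3),
               class = "trampler_image_error")
  expect_error(boost_saturation(array(300, dim = c(1, 1, 3))),
               class = "trampler_image_error")
})

test_that("classify_green implements strict green dominance", {
  expect_identical(classify_green(array(c(10, 20, 5), dim = c(1, 1, 3)))[1, 1], 1L)
  expect_identical(classify_green(array(c(50, 50, 50), dim = c(1, 1, 3)))[1, 1], 0L)
  expect_identical(classify_green(array(c(0, 0, 255), dim = c(1, 1, 3)))[1, 1], 0L)
  # ties are non-green
  expect_identical(classify_green(array(c(80, 80, 10), dim = c(1, 1, 3)))[1, 1], 0L)
  all_green <- array(rep(c(10, 200, 30), each = 25), dim = c(5, 5, 3))
  expect_true(all(classify_green(all_green) == 1L))
})

test_that("classify_green equals the nested-loop oracle", {
  for (s in 1:10) {
    img <- random_image(32, 32, seed = 200 + s)
    expect_identical(classify_green(img), oracle_green_mask(img))
  }
})

test_that("estimate_cover returns the exact pixel fraction", {
  img <- trampler:::with_seed(5, trampler:::paint_quadrat_image(64, 64, 1024))
  rec <- estimate_cover(img)
  expect_equal(rec$green_fraction, 0.25)
  expect_identical(rec$n_green, 1024L)
  expect_identical(rec$n_total, 4096L)
  gray <- array(128, dim = c(8, 8, 3))
  expect_equal(estimate_cover(gray)$green_fraction, 0)
  expect_error(estimate_cover(array(0, dim = c(0, 4, 3))),
               class = "trampler_image_error")
})

test_that("adding one green pixel raises the fraction by exactly 1/n", {
  img <- array(100, dim = c(10, 10, 3))       # all gray
  base <- estimate_cover(img, boost = FALSE)$green_fraction
  img[1, 1, ] <- c(10, 200, 30)
  one <- estimate_cover(img, boost = FALSE)$green_fraction
  expect_equal(one - base, 1 / 100)
})

test_that("classification is invariant to the boost on tie-free images", {
  for (s in 1:5) {
    img <- distinct_channel_image(16, 16, seed = 300 + s)
    expect_identical(classify_green(boost_saturation(img, 30)),
                     classify_green(img))
    expect_equal(estimate_cover(img, boost = TRUE)$green_fraction,
                 estimate_cover(img, boost = FALSE)$green_fraction)
  }
})

test_that("batch_estimate processes a directory and skips corrupt files", {
  dir <- withr::local_tempdir()
  for (k in 1:3) {
    img <- random_image(8, 8, seed = 400 + k)
    png::writePNG(img / 255, file.path(dir, sprintf("q%02d.png", k)))
  }
  writeLines("not a png", file.path(dir, "broken.png"))
  out <- suppressMessages(batch_estimate(dir))
  expect_equal(nrow(out), 3)
  expect_identical(attr(out, "skipped"), 1L)
  expect_equal(out$quadrat_id, c("q01", "q02", "q03"))
  # determinism: identical CSV on re-run
  csv1 <- withr::local_tempfile(fileext = ".csv")
  csv2 <- withr::local_tempfile(fileext = ".csv")
  suppressMessages(batch_estimate(dir, output_csv = csv1))
  suppressMessages(batch_estimate(dir, output_csv = csv2))
  expect_identical(readLines(csv1), readLines(csv2))
  expect_error(batch_estimate(withr::local_tempdir()),
               class = "trampler_image_error")
})
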