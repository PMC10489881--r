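#' Validate and coerce a quadrat image
#'
#' A quadrat image is an `H x W x 3` numeric array of 8-bit digital numbers
#' (DN, 0-255) in R,G,B channel order, pre-cropped to the quadrat frame.
#'
#' @param img An array.
#' @return The validated array.
#' @keywords internal
as_quadrat_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    abort("a quadrat image must be an H x W x 3 array (R,G,B channels)",
          class = "trampler_image_error")
  }
  if (dim(img)[1] < 1L || dim(img)[2] < 1L || length(img) == 0L) {
    abort("image has zero pixels", class = "trampler_image_error")
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 255) {
    abort("image digital numbers must lie in [0, 255]",
          class = "trampler_image_error")
  }
  img
}

#' Read a quadrat photograph into an 8-bit RGB array
#'
#' Reads PNG (via the png package) or JPEG (via the jpeg package, if
#' installed). Grayscale images are replicated across channels and alpha
#' channels are dropped; intensities are scaled to 0-255 digital numbers.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An `H x W x 3` array of DNs in 0-255.
#' @export
read_quadrat_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE)) {
      abort("reading JPEG requires the 'jpeg' package",
            class = "trampler_image_error")
    }
    jpeg::readJPEG(path)
  } else {
    abort(sprintf("unsupported image format: '%s'", ext),
          class = "trampler_image_error")
  }
  if (length(dim(raw)) == 2L) {
    raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  } else if (dim(raw)[3] == 2L) {          # gray + alpha
    raw <- array(rep(raw[, , 1], 3L), dim = c(dim(raw)[1:2], 3L))
  } else if (dim(raw)[3] >= 4L) {          # drop alpha
    raw <- raw[, , 1:3, drop = FALSE]
  }
  as_quadrat_image(round(raw * 255))
}

# Vectorised HSV -> RGB on [0,1] scale; h in [0,1).
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- numeric(length(h)); g <- numeric(length(h)); b <- numeric(length(h))
  pick <- function(i0, rr, gg, bb) {
    sel <- i == i0
    r[sel] <<- rr[sel]; g[sel] <<- gg[sel]; b[sel] <<- bb[sel]
  }
  pick(0, v, t, p); pick(1, q, v, p); pick(2, p, v, t)
  pick(3, p, q, v); pick(4, t, p, v); pick(5, v, p, q)
  list(r = r, g = g, b = b)
}

#' Standardize lighting by boosting image saturation
#'
#' Converts each pixel to HSV, multiplies saturation by `factor` (clipping
#' at 1), and converts back, rounding to 8-bit digital numbers. Hue and
#' value are preserved, so the rank order of a pixel's channels is
#' unchanged: boosting pushes the minor channels down towards zero,
#' widening the gap between the dominant channel and the others. Gray
#' pixels (saturation 0) are unchanged. The default factor of 30
#' effectively maximises saturation for any pixel that is not almost
#' perfectly gray, which suppresses shading differences across the quadrat
#' before green classification.
#'
#' @param img An `H x W x 3` quadrat image (DNs 0-255).
#' @param factor Positive saturation multiplier (default 30).
#' @return The boosted image, same dimensions, integer DNs 0-255.
#' @export
#' @examples
#' px <- array(c(100, 110, 100), dim = c(1, 1, 3))
#' boost_saturation(px)[1, 1, ] # fully saturated green: 0, 110, 0
boost_saturation <- function(img, factor = 30) {
  img <- as_quadrat_image(img)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    abort("`factor` must be a positive number", class = "trampler_image_error")
  }
  d <- dim(img)
  rgb <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
               as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  s2 <- pmin(1, factor * hsv[2, ])
  out <- hsv_to_rgb(hsv[1, ], s2, hsv[3, ])
  res <- array(0, dim = d)
  res[, , 1] <- round(255 * out$r)
  res[, , 2] <- round(255 * out$g)
  res[, , 3] <- round(255 * out$b)
  pmin(pmax(res, 0), 255)
}

#' Classify green-dominant pixels
#'
#' A pixel is green vegetation when its green-channel digital number is
#' strictly greater than both the red and the blue DN. Gray pixels and
#' ties are classified non-green; logs and rocks (no green dominance)
#' therefore count as non-cover while moss counts as cover.
#'
#' @param img An `H x W x 3` quadrat image (DNs 0-255).
#' @return An `H x W` integer matrix of 0/1 (1 = green-dominant).
#' @export
#' @examples
#' img <- array(c(10, 20, 5), dim = c(1, 1, 3))
#' classify_green(img)[1, 1] # 1
classify_green <- function(img) {
  img <- as_quadrat_image(img)
  mask <- (img[, , 2] > img[, , 1]) & (img[, , 2] > img[, , 3])
  matrix(as.integer(mask), nrow = dim(img)[1], ncol = dim(img)[2])
}

#' Estimate percent plant cover of one quadrat image
#'
#' Applies the saturation boost ([boost_saturation()]) and then counts
#' green-dominant pixels ([classify_green()]); the fraction of qualifying
#' pixels out of the entire image is the cover estimate. Classification on
#' the unboosted image is available via `boost = FALSE`; because the boost
#' preserves channel rank order the two paths agree on any image free of
#' channel ties.
#'
#' @param img An `H x W x 3` quadrat image (DNs 0-255).
#' @param factor Saturation factor passed to [boost_saturation()].
#' @param boost Apply the saturation standardization first (default TRUE).
#' @param quadrat_id Optional identifier carried into the output.
#' @return A one-row tibble: `quadrat_id`, `green_fraction`
#'   (= `n_green / n_total` exactly), `n_green`, `n_total`.
#' @export
estimate_cover <- function(img, factor = 30, boost = TRUE,
                           quadrat_id = NA_character_) {
  img <- as_quadrat_image(img)
  work <- if (boost) boost_saturation(img, factor) else img
  mask <- classify_green(work)
  n_green <- sum(mask)
  n_total <- length(mask)
  tibble::tibble(quadrat_id = quadrat_id,
                 green_fraction = n_green / n_total,
                 n_green = as.integer(n_green),
                 n_total = as.integer(n_total))
}

#' Estimate cover for every image in a directory
#'
#' Processes all PNG/JPEG files in `input_dir` in filename order.
#' Unreadable files are skipped with a logged message and counted in the
#' `skipped` attribute of the result.
#'
#' @param input_dir Directory containing quadrat photographs.
#' @param output_csv Optional path; when given, the cover table is written
#'   there as CSV.
#' @param factor,boost Passed to [estimate_cover()].
#' @param save_masks Optional directory; when given, each classified mask
#'   is written as a grayscale PNG for visual checking.
#' @return A tibble of cover records, one row per readable image, ordered
#'   by filename; attribute `skipped` holds the number of unreadable files.
#' @export
batch_estimate <- function(input_dir, output_csv = NULL, factor = 30,
                           boost = TRUE, save_masks = NULL) {
  if (!dir.exists(input_dir)) {
    abort(sprintf("input directory '%s' does not exist", input_dir),
          class = "trampler_image_error")
  }
  files <- sort(list.files(input_dir, pattern = "\\.(png|jpe?g)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) {
    abort(sprintf("no PNG/JPEG images found in '%s'", input_dir),
          class = "trampler_image_error")
  }
  if (!is.null(save_masks) && !dir.exists(save_masks)) {
    dir.create(save_masks, recursive = TRUE)
  }
  records <- list()
  skipped <- 0L
  for (f in files) {
    id <- tools::file_path_sans_ext(basename(f))
    rec <- tryCatch({
      img <- read_quadrat_image(f)
      if (!is.null(save_masks)) {
        work <- if (boost) boost_saturation(img, factor) else img
        png::writePNG(classify_green(work) * 1.0,
                      file.path(save_masks, paste0(id, "_mask.png")))
      }
      estimate_cover(img, factor = factor, boost = boost, quadrat_id = id)
    }, error = function(e) {
      inform(sprintf("skipping unreadable image '%s': %s", basename(f),
                     conditionMessage(e)))
      NULL
    })
    if (is.null(rec)) skipped <- skipped + 1L else
      records[[length(records) + 1L]] <- rec
  }
  if (length(records) == 0L) {
    abort("no readable images in input directory",
          class = "trampler_image_error")
  }
  out <- dplyr::bind_rows(records)
  if (!is.null(output_csv)) {
    utils::write.csv(as.data.frame(out), output_csv, row.names = FALSE)
  }
  attr(out, "skipped") <- skipped
  out
}
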