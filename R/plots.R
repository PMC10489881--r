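#' Plot posterior estimates of a fitted model
#'
#' Point estimates with 95% credible intervals for the fixed effects;
#' intervals excluding zero are highlighted, mirroring how the estimates
#' table flags effects.
#'
#' @param object A `trample_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trample_fit <- function(object, ...) {
  td <- tidy(object)
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term,
                                   colour = .data$effect)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#b2182b", `FALSE` = "grey30"),
      labels = c(`TRUE` = "CI excludes 0", `FALSE` = "no effect"),
      name = NULL) +
    ggplot2::labs(x = "posterior estimate (95% CI)", y = NULL,
                  title = sprintf("%s model: %s", object$spec$family,
                                  object$spec$response)) +
    ggplot2::theme_minimal()
}

#' Plot a posterior predictive skewness check
#'
#' Histogram of replicated skewness values with the observed skewness
#' marked.
#'
#' @param object A `trample_ppc` from [posterior_predictive()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trample_ppc <- function(object, ...) {
  df <- tibble::tibble(skew = object$replicated)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$skew)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "#b2182b",
                        linewidth = 1) +
    ggplot2::labs(x = "Fisher-Pearson skewness of replicated responses",
                  y = "count",
                  title = sprintf("Skew PPC (tail probability %.3f)",
                                  object$tail_prob)) +
    ggplot2::theme_minimal()
}

#' Plot disturbance effects across all models of a pipeline run
#'
#' One point-interval per fitted model for the disturbance coefficient,
#' on the model's link scale.
#'
#' @param object A `trample_pipeline` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trample_pipeline <- function(object, ...) {
  r <- object$report
  r$model <- paste(r$species, r$trait)
  r$model <- factor(r$model, levels = rev(r$model))
  ggplot2::ggplot(r, ggplot2::aes(x = .data$dist_est, y = .data$model,
                                  colour = .data$dist_effect)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$dist_lo,
                                          xmax = .data$dist_hi)) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#b2182b", `FALSE` = "grey30"),
      labels = c(`TRUE` = "CI excludes 0", `FALSE` = "no effect"),
      name = NULL) +
    ggplot2::labs(x = "disturbance effect (link scale, 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Show a quadrat image and its green-classification mask side by side
#'
#' @param img An `H x W x 3` quadrat image (DNs 0-255).
#' @param factor,boost Passed to the classifier path (see
#'   [estimate_cover()]).
#' @return A ggplot object with the image pixels coloured by their RGB
#'   values and classified pixels outlined.
#' @export
plot_cover_mask <- function(img, factor = 30, boost = TRUE) {
  img <- as_quadrat_image(img)
  work <- if (boost) boost_saturation(img, factor) else img
  mask <- classify_green(work)
  h <- dim(img)[1]; w <- dim(img)[2]
  df <- tibble::tibble(
    row = rep(seq_len(h), times = w),
    col = rep(seq_len(w), each = h),
    colour = grDevices::rgb(as.vector(img[, , 1]), as.vector(img[, , 2]),
                            as.vector(img[, , 3]), maxColorValue = 255),
    green = as.vector(mask) == 1L
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$colour)) +
    ggplot2::geom_point(data = df[df$green, ], shape = ".",
                        colour = "white") +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("green fraction: %.3f",
                                  mean(df$green))) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
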