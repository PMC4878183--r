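#' Ratio image from a CypHer 5E / Alexa488 pair
#'
#' Forms the ratiometric image used for extracellular pH mapping. Both
#' channels are smoothed with a 7 x 7 Gaussian; a binary mask from the
#' pH-insensitive Alexa488 channel removes background pixels; the ratio
#' CypHer/Alexa488 is computed on masked-in pixels and is `NA` elsewhere.
#' CypHer 5E brightens at acidic pH, so the ratio decreases with increasing
#' pH. Masked-in pixels with a zero denominator are flagged undefined with a
#' warning.
#'
#' @param stack a [channel_stack()]; channel names given by `cypher`/`alexa`.
#' @param cypher,alexa channel names.
#' @param kernel_px smoothing kernel width (default 7).
#' @param method,value background thresholding rule on the Alexa channel
#'   (see [threshold_mask()]).
#' @return A `ratio_image`: list with `ratio` (matrix, `NA` = undefined),
#'   `background_mask` (TRUE = analysed pixel) and the Alexa threshold.
#' @export
ratio_image <- function(stack, cypher = "CypHer5E", alexa = "Alexa488",
                        kernel_px = 7, method = "otsu", value = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  cy <- gaussian_smooth(get_channel(stack, cypher), kernel_px)
  al <- gaussian_smooth(get_channel(stack, alexa), kernel_px)
  if (diff(range(al)) == 0 && method == "otsu") {
    mask <- new_binary_mask(matrix(FALSE, nrow(al), ncol(al)),
                            threshold = Inf, source_channel = alexa)
  } else {
    mask <- threshold_mask(al, method, value, source_channel = alexa)
  }
  ratio <- matrix(NA_real_, nrow(al), ncol(al))
  inside <- unclass_mask(mask)
  zero_den <- inside & al == 0
  if (any(zero_den)) {
    warn(sprintf("%d masked-in pixel(s) had zero Alexa intensity; flagged undefined.",
                 sum(zero_den)))
    inside <- inside & !zero_den
  }
  ratio[inside] <- cy[inside] / al[inside]
  structure(list(ratio = ratio, background_mask = inside,
                 threshold_alexa = attr(mask, "threshold"),
                 kernel_px = kernel_px),
            class = "ratio_image")
}

#' @export
print.ratio_image <- function(x, ...) {
  cat(sprintf("<ratio_image> %d x %d px, %.1f%% analysed (Alexa > %.4g)\n",
              nrow(x$ratio), ncol(x$ratio), 100 * mean(x$background_mask),
              x$threshold_alexa))
  invisible(x)
}

#' Fit a ratio-to-pH calibration curve from buffer standards
#'
#' Builds the monotone mapping from fluorescence ratio to pH from images
#' acquired in calibration buffers of known pH. Each standard contributes its
#' mean masked ratio (nuclear pixels excluded, since the two dyes accumulate
#' at different rates in the nucleus). The default model is piecewise-linear
#' interpolation between buffer means — robust and assumption-free; a
#' 4-parameter logistic (`"4pl"`) in pH is available with >= 4 standards.
#' Ratios must be strictly decreasing with pH; a violation is an error naming
#' the offending pair.
#'
#' @param standards a data frame with columns `ph` and `ratio` (one row per
#'   buffer), or a list of buffers, each `list(ph =, stack =, nuclear_mask =)`
#'   reduced via [ratio_image()] to its mean defined ratio.
#' @param model `"piecewise"` or `"4pl"`.
#' @param ... passed to [ratio_image()] when reducing buffer stacks.
#' @return A `calibration_curve` with the standards, model, fitted parameters
#'   (4PL) and the valid ratio range. Supports [predict()] (ratio to pH),
#'   [calibration_response()] (pH to ratio), [tidy()], [glance()] and
#'   [autoplot()].
#' @export
fit_calibration <- function(standards, model = c("piecewise", "4pl"), ...) {
  model <- match.arg(model)
  if (!is.data.frame(standards)) {
    standards <- purrr::map_dfr(standards, function(b) {
      ri <- ratio_image(b$stack, ...)
      ok <- !is.na(ri$ratio)
      if (!is.null(b$nuclear_mask)) ok <- ok & !b$nuclear_mask
      tibble::tibble(ph = b$ph, ratio = mean(ri$ratio[ok]))
    })
  }
  standards <- tibble::as_tibble(standards)[, c("ph", "ratio")]
  standards <- standards[order(standards$ph), ]
  if (nrow(standards) < 3)
    abort("at least 3 buffer standards are required.")
  if (anyDuplicated(standards$ph))
    abort("buffer pH values must be distinct.")
  dr <- diff(standards$ratio)
  if (any(dr >= 0)) {
    i <- which(dr >= 0)[1]
    abort(sprintf(
      "standards are not strictly decreasing in ratio: pH %.3g (ratio %.4g) vs pH %.3g (ratio %.4g).",
      standards$ph[i], standards$ratio[i], standards$ph[i + 1], standards$ratio[i + 1]))
  }
  params <- NULL
  residuals <- rep(0, nrow(standards))
  if (model == "4pl") {
    if (nrow(standards) < 4)
      abort("the 4PL model requires at least 4 standards.")
    a0 <- max(standards$ratio); d0 <- min(standards$ratio)
    fit <- minpack.lm::nlsLM(
      ratio ~ d + (a - d) / (1 + (ph / c)^b),
      data = standards,
      start = list(a = a0 * 1.05, d = d0 * 0.5,
                   c = median(standards$ph), b = 6),
      lower = c(a = 0, d = 0, c = 0.1, b = 0.1),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    params <- as.list(stats::coef(fit))
    residuals <- as.numeric(stats::resid(fit))
  }
  structure(list(standards = standards, model = model, params = params,
                 residuals = residuals,
                 ratio_range = rev(range(standards$ratio)),
                 ph_range = range(standards$ph)),
            class = "calibration_curve")
}

#' Forward calibration response: pH to expected ratio
#'
#' @param curve a [fit_calibration()] result.
#' @param ph numeric pH values.
#' @return Expected CypHer/Alexa ratios.
#' @export
calibration_response <- function(curve, ph) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$model == "4pl") {
    p <- curve$params
    p$d + (p$a - p$d) / (1 + (ph / p$c)^p$b)
  } else {
    approx(curve$standards$ph, curve$standards$ratio, xout = ph, rule = 2)$y
  }
}

#' Invert the calibration: ratio to pH
#'
#' @param object a `calibration_curve`.
#' @param ratio numeric ratios.
#' @param ... unused.
#' @return pH values; ratios outside the calibrated range are clamped to the
#'   domain ends.
#' @export
predict.calibration_curve <- function(object, ratio, ...) {
  hi <- max(object$standards$ratio); lo <- min(object$standards$ratio)
  r <- pmin(pmax(ratio, lo), hi)
  if (object$model == "4pl") {
    p <- object$params
    r <- pmin(pmax(r, p$d + 1e-12), p$a - 1e-12)
    p$c * ((p$a - p$d) / (r - p$d) - 1)^(1 / p$b)
  } else {
    # ratio decreases with pH; approx needs ascending x
    approx(rev(object$standards$ratio), rev(object$standards$ph),
           xout = r, rule = 2)$y
  }
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s, %d standards, pH %.3g-%.3g, ratio %.4g-%.4g\n",
              x$model, nrow(x$standards), x$ph_range[1], x$ph_range[2],
              min(x$standards$ratio), max(x$standards$ratio)))
  invisible(x)
}

#' @export
tidy.calibration_curve <- function(x, ...) {
  dplyr::mutate(x$standards, residual = x$residuals)
}

#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(model = x$model, n_standards = nrow(x$standards),
                 ph_min = x$ph_range[1], ph_max = x$ph_range[2],
                 rmse = sqrt(mean(x$residuals^2)))
}

#' @export
autoplot.calibration_curve <- function(object, n = 200, ...) {
  grid <- tibble::tibble(
    ph = seq(object$ph_range[1], object$ph_range[2], length.out = n))
  grid$ratio <- calibration_response(object, grid$ph)
  ggplot2::ggplot(object$standards, ggplot2::aes(x = .data$ph, y = .data$ratio)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point(size = 2, colour = "firebrick") +
    ggplot2::labs(x = "pH", y = "CypHer 5E / Alexa488 ratio",
                  title = "Ratio-to-pH calibration") +
    ggplot2::theme_minimal()
}

#' Pixel-wise pH map from a ratio image
#'
#' Converts a ratio image to pH by inverting the calibration curve at every
#' defined pixel. Nuclear pixels are excluded (undefined) because the two
#' dyes accumulate at different rates in the nucleus. Ratios outside the
#' calibrated range are clamped to the domain ends rather than dropped —
#' dropping would bias spatial means — and the clamped fraction is reported.
#'
#' @param ratio a [ratio_image()] result or a plain ratio matrix with `NA`
#'   for undefined pixels.
#' @param curve a [fit_calibration()] curve.
#' @param nuclear_mask optional logical matrix of nuclear pixels to exclude.
#' @return A `ph_map`: list with `ph` (matrix, `NA` = undefined),
#'   `clamp_fraction`, `defined_fraction` and a record of masks applied.
#' @export
ph_map <- function(ratio, curve, nuclear_mask = NULL) {
  stopifnot(inherits(curve, "calibration_curve"))
  rmat <- if (inherits(ratio, "ratio_image")) ratio$ratio else ratio
  if (!is.matrix(rmat)) abort("`ratio` must be a matrix or ratio_image.")
  if (!is.null(nuclear_mask)) {
    if (!identical(dim(nuclear_mask), dim(rmat)))
      abort("`nuclear_mask` shape does not match the ratio image.")
    rmat[nuclear_mask] <- NA_real_
  }
  defined <- !is.na(rmat)
  lo <- min(curve$standards$ratio); hi <- max(curve$standards$ratio)
  clamped <- defined & (rmat < lo | rmat > hi)
  ph <- matrix(NA_real_, nrow(rmat), ncol(rmat))
  ph[defined] <- predict(curve, rmat[defined])
  structure(list(ph = ph,
                 clamp_fraction = if (any(defined)) mean(clamped[defined]) else 0,
                 defined_fraction = mean(defined),
                 nuclear_excluded = !is.null(nuclear_mask)),
            class = "ph_map")
}

#' @export
print.ph_map <- function(x, ...) {
  cat(sprintf("<ph_map> %d x %d px, %.1f%% defined, mean pH %.3f, %.2f%% clamped\n",
              nrow(x$ph), ncol(x$ph), 100 * x$defined_fraction,
              mean(x$ph, na.rm = TRUE), 100 * x$clamp_fraction))
  invisible(x)
}

#' @export
glance.ph_map <- function(x, ...) {
  tibble::tibble(mean_ph = mean(x$ph, na.rm = TRUE),
                 defined_fraction = x$defined_fraction,
                 clamp_fraction = x$clamp_fraction)
}

#' @export
autoplot.ph_map <- function(object, ...) {
  nr <- nrow(object$ph); nc <- ncol(object$ph)
  df <- tibble::tibble(row = rep(seq_len(nr), nc),
                       col = rep(seq_len(nc), each = nr),
                       ph = as.vector(object$ph))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$ph)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85", name = "pH") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = "Extracellular pH map") +
    ggplot2::theme_minimal()
}
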