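# ggplot2 views of the main result types.

#' Plot a gradient profile
#'
#' Concentration against RI (corrected when available, raw otherwise).
#'
#' @param object A [gradient_profile()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.gradient_profile <- function(object, ...) {
  has_corr <- !all(is.na(object$corrected_concentration))
  df <- tibble(
    ri = object$ri,
    concentration = if (has_corr) object$corrected_concentration
                    else object$raw_concentration
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ri, y = .data$concentration)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(
      x = "Refractive index (20 °C)",
      y = paste0(if (has_corr) "Corrected" else "Raw",
                 " DNA concentration (ng/µl)"),
      title = attr(object, "label")
    )
}

#' Plot a mixture fit over its RI range
#'
#' Fitted individual components (dashed) and their sum (solid).
#'
#' @param object A [fit_mixture()] result.
#' @param profile Optional [gradient_profile()] to overlay as points.
#' @param n Curve resolution.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.mixture_fit <- function(object, profile = NULL, n = 400, ...) {
  comp <- object$components
  lo <- min(comp$mean - 4 * comp$sigma)
  hi <- max(comp$mean + 4 * comp$sigma)
  if (!is.null(profile)) {
    lo <- min(lo, min(profile$ri)); hi <- max(hi, max(profile$ri))
  }
  ri <- seq(lo, hi, length.out = n)
  curves <- purrr::map_dfr(seq_len(nrow(comp)), function(j) {
    tibble(ri = ri, component = paste0("component ", j),
           concentration = comp$amplitude[j] *
             exp(-(ri - comp$mean[j])^2 / (2 * comp$sigma[j]^2)))
  })
  total <- tibble(ri = ri, component = "combined",
                  concentration = predict(object, ri))
  p <- ggplot2::ggplot(
    dplyr::bind_rows(curves, total),
    ggplot2::aes(x = .data$ri, y = .data$concentration,
                 linetype = .data$component)) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::labs(x = "Refractive index (20 °C)",
                  y = "DNA concentration (ng/µl)")
  if (!is.null(profile)) {
    p <- p + ggplot2::geom_point(
      data = tibble(ri = profile$ri,
                    concentration = profile$corrected_concentration),
      ggplot2::aes(x = .data$ri, y = .data$concentration),
      inherit.aes = FALSE)
  }
  p
}

#' Plot a shuffle null distribution
#'
#' Histogram of shuffled overlap counts with the observed count marked.
#'
#' @param object A [shuffle_null_summary()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.shuffle_null <- function(object, ...) {
  ggplot2::ggplot(tibble(count = object$null_counts),
                  ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "Shuffled overlap count", y = "Shuffles",
                  title = sprintf("Observed = %d, null mean = %.1f",
                                  object$observed, object$null_mean))
}
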