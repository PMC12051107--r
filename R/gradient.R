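#' Construct a gradient profile
#'
#' A gradient profile holds the per-fraction measurements of one caesium
#' sulphate equilibrium density gradient: fraction index (1 = first fraction
#' pumped, i.e. the densest, since gradients are pumped bottom to top),
#' refractive index (RI, typically measured for odd-numbered fractions only)
#' and the blanked spectrophotometric DNA concentration reading.
#'
#' @param fractions A data frame with columns `fraction_index`,
#'   `refractive_index` (NA allowed — unmeasured fractions) and
#'   `dna_concentration` (ng/ul; may be negative after blanking).
#' @param label Free-text label for the gradient (e.g. "quiescent primary").
#' @return A `gradient_profile`: a tibble with columns `fraction_index`,
#'   `ri_measured`, `ri` (filled by [interpolate_ri()]), `raw_concentration`
#'   and `corrected_concentration` (filled by [correct_baseline()]), plus a
#'   `label` attribute.
#' @examples
#' gp <- gradient_profile(data.frame(
#'   fraction_index = 1:5,
#'   refractive_index = c(1.380, NA, 1.376, NA, 1.372),
#'   dna_concentration = c(0.1, 0.2, 5, 0.3, 0.1)
#' ))
#' @export
gradient_profile <- function(fractions, label = "") {
  fractions <- as_tibble(fractions)
  need <- c("fraction_index", "refractive_index", "dna_concentration")
  missing_cols <- setdiff(need, names(fractions))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "densigrad_parameter_error")
  }
  idx <- fractions$fraction_index
  if (any(idx < 1) || any(diff(idx) <= 0)) {
    abort("fraction indices must be >= 1 and strictly increasing",
          class = "densigrad_parameter_error")
  }
  ri <- fractions$refractive_index
  if (any(!is.na(ri) & (ri < 1.33 | ri > 1.40))) {
    abort("measured refractive indices must lie in [1.3300, 1.4000]",
          class = "densigrad_parameter_error")
  }
  out <- tibble(
    fraction_index = as.integer(idx),
    ri_measured = as.numeric(ri),
    ri = as.numeric(ri),
    raw_concentration = as.numeric(fractions$dna_concentration),
    corrected_concentration = NA_real_
  )
  new_gradient_profile(out, label = label)
}

new_gradient_profile <- function(x, label = "", ri_fit = NULL,
                                 baseline = NULL) {
  structure(x,
    class = c("gradient_profile", class(tibble())),
    label = label, ri_fit = ri_fit, baseline = baseline
  )
}

#' @export
print.gradient_profile <- function(x, ...) {
  lab <- attr(x, "label")
  cat("<gradient_profile>", if (nzchar(lab)) paste0(" ", lab), " (",
      nrow(x), " fractions)\n", sep = "")
  fit <- attr(x, "ri_fit")
  if (!is.null(fit)) {
    cat(sprintf("  RI fit: %.6g + %.6g * index\n", fit["intercept"],
                fit["slope"]))
  }
  NextMethod()
}

#' Fit the refractive-index to buoyant-density calibration line
#'
#' Caesium sulphate density is linear in refractive index over the working
#' range of the gradients, so a set of gravimetrically determined
#' (RI, density) pairs is summarised by an ordinary least-squares line
#' `density = slope * RI + intercept`.
#'
#' @param pairs A data frame with columns `ri` and `density_g_per_ml`
#'   (aliases `density` accepted).
#' @return An `ri_calibration` object with elements `slope` (g/ml per RI
#'   unit), `intercept` (g/ml), `n_points` and `r_squared`; supports
#'   [tidy()], [glance()] and [ri_to_density()].
#' @examples
#' pairs <- data.frame(ri = c(1.36, 1.37, 1.38),
#'                     density_g_per_ml = 12.46 * c(1.36, 1.37, 1.38) - 15.62)
#' cal <- fit_ri_density_calibration(pairs)
#' ri_to_density(cal, 1.3700)
#' @export
fit_ri_density_calibration <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (!"density_g_per_ml" %in% names(pairs) && "density" %in% names(pairs)) {
    pairs$density_g_per_ml <- pairs$density
  }
  if (!all(c("ri", "density_g_per_ml") %in% names(pairs))) {
    abort("`pairs` needs columns ri and density_g_per_ml",
          class = "densigrad_parameter_error")
  }
  pairs <- dplyr::filter(pairs, is.finite(.data$ri),
                         is.finite(.data$density_g_per_ml))
  if (length(unique(pairs$ri)) < 2) {
    abort("need at least 2 pairs with distinct RI values",
          class = "densigrad_degenerate_input")
  }
  fit <- lm(density_g_per_ml ~ ri, data = pairs)
  structure(
    list(
      slope = unname(coef(fit)[["ri"]]),
      intercept = unname(coef(fit)[["(Intercept)"]]),
      n_points = nrow(pairs),
      r_squared = summary(fit)$r.squared,
      residuals = unname(stats::residuals(fit))
    ),
    class = "ri_calibration"
  )
}

#' @export
print.ri_calibration <- function(x, ...) {
  cat(sprintf(
    "<ri_calibration> density = %.4f * RI %+.4f g/ml  (n = %d, R^2 = %.4f)\n",
    x$slope, x$intercept, x$n_points, x$r_squared))
  invisible(x)
}

#' @rdname fit_ri_density_calibration
#' @param x,... An `ri_calibration`; further arguments ignored.
#' @export
tidy.ri_calibration <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname fit_ri_density_calibration
#' @export
glance.ri_calibration <- function(x, ...) {
  tibble(n_points = x$n_points, r_squared = x$r_squared)
}

#' Convert refractive index to buoyant density
#'
#' @param cal An [ri_calibration][fit_ri_density_calibration] object, or any
#'   list with `slope` and `intercept`.
#' @param ri Refractive index value(s) at 20 degrees C.
#' @return Density in g/ml, `cal$slope * ri + cal$intercept`.
#' @export
ri_to_density <- function(cal, ri) {
  cal$slope * ri + cal$intercept
}

#' The calibration line of the reference gradient series
#'
#' The experimentally determined conversion used throughout:
#' density = 12.46 g/ml x RI - 15.62 g/ml (38 gravimetric points,
#' R^2 = 0.9945). The printed intercept is a magnitude; its sign is negative,
#' as forced by density ~ 1.43 g/ml at RI ~ 1.37.
#'
#' @return An `ri_calibration` object with the reference constants.
#' @export
reference_calibration <- function() {
  structure(
    list(slope = 12.46, intercept = -15.62, n_points = 38L,
         r_squared = 0.9945, residuals = numeric(0)),
    class = "ri_calibration"
  )
}

#' Interpolate refractive index across all fractions
#'
#' RI is measured with a hand refractometer on odd-numbered fractions only;
#' because the pumped gradient is linear in fraction index, a least-squares
#' line of RI against index fills in every fraction. Fitted-line values are
#' assigned to all fractions (measured readings are kept in `ri_measured`
#' for reporting) so downstream windows and integrals see a strictly
#' monotone RI axis.
#'
#' @param profile A [gradient_profile()].
#' @return The profile with `ri` filled for every fraction and an `ri_fit`
#'   attribute holding `c(slope, intercept)`.
#' @export
interpolate_ri <- function(profile) {
  measured <- !is.na(profile$ri_measured)
  if (sum(measured) < 2) {
    abort("need at least 2 measured RI values to interpolate",
          class = "densigrad_degenerate_input")
  }
  fit <- lm(ri_measured ~ fraction_index, data = profile[measured, ])
  slope <- unname(coef(fit)[["fraction_index"]])
  intercept <- unname(coef(fit)[["(Intercept)"]])
  if (slope == 0) {
    abort("measured RIs are constant; RI must be monotone in fraction index",
          class = "densigrad_degenerate_input")
  }
  profile$ri <- intercept + slope * profile$fraction_index
  attr(profile, "ri_fit") <- c(slope = slope, intercept = intercept)
  profile
}

#' Default signal exclusion windows for baseline fitting
#'
#' Fractions containing RNA (densest end, RI above 1.3780) or DNA
#' (RI 1.365 to 1.372) are excluded when regressing the instrumental
#' baseline.
#'
#' @return A list of two-element numeric RI intervals.
#' @export
default_signal_windows <- function() {
  list(c(1.3780, Inf), c(1.365, 1.372))
}

#' Correct a linear instrumental baseline
#'
#' Blanked spectrophotometric readings drift linearly across the gradient.
#' A least-squares line of raw concentration against RI is fitted over the
#' signal-free fractions (those outside every `signal_windows` interval) and
#' subtracted from every fraction. After correction, re-fitting the baseline
#' over the same fractions gives slope and intercept of zero, so the
#' operation is idempotent. Negative corrected readings are retained, not
#' clipped, to avoid biasing integrals.
#'
#' @param profile A [gradient_profile()] with RI defined on every fraction
#'   (run [interpolate_ri()] first if needed).
#' @param signal_windows List of RI intervals `c(lo, hi)` treated as
#'   signal-bearing and excluded from the baseline regression. Defaults to
#'   [default_signal_windows()].
#' @return The corrected profile, with `corrected_concentration` filled and
#'   a `baseline_fit` (fields `slope` per RI unit, `intercept`,
#'   `n_baseline_points`, `excluded_windows`, `abscissa = "ri"`) attached;
#'   retrieve it with [baseline_of()].
#' @export
correct_baseline <- function(profile, signal_windows = default_signal_windows()) {
  if (anyNA(profile$ri)) {
    abort("RI must be defined on all fractions; run interpolate_ri() first",
          class = "densigrad_parameter_error")
  }
  if (length(signal_windows) == 0) {
    abort("signal_windows must be non-empty",
          class = "densigrad_parameter_error")
  }
  in_signal <- Reduce(`|`, lapply(signal_windows, function(w) {
    profile$ri >= w[1] & profile$ri <= w[2]
  }))
  baseline_rows <- which(!in_signal)
  if (length(baseline_rows) < 2) {
    abort("fewer than 2 baseline fractions remain after exclusion",
          class = "densigrad_insufficient_baseline")
  }
  base <- profile[baseline_rows, ]
  fit <- lm(raw_concentration ~ ri, data = base)
  slope <- unname(coef(fit)[["ri"]])
  intercept <- unname(coef(fit)[["(Intercept)"]])
  profile$corrected_concentration <-
    profile$raw_concentration - (intercept + slope * profile$ri)
  baseline <- structure(
    list(slope = slope, intercept = intercept,
         n_baseline_points = length(baseline_rows),
         excluded_windows = signal_windows, abscissa = "ri"),
    class = "baseline_fit"
  )
  attr(profile, "baseline") <- baseline
  profile
}

#' @rdname correct_baseline
#' @export
baseline_of <- function(profile) {
  attr(profile, "baseline")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf(
    "<baseline_fit> conc = %.4g %+.4g * RI  (%d baseline fractions)\n",
    x$intercept, x$slope, x$n_baseline_points))
  invisible(x)
}

#' @rdname correct_baseline
#' @param x,... A `baseline_fit`; further arguments ignored.
#' @export
tidy.baseline_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"), estimate = c(x$intercept, x$slope))
}
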