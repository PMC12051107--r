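# End-to-end pipelines mirroring the two-consecutive-gradient experimental
# design: a raw DNA preparation is separated on a primary gradient, the
# dense pool is re-run on a secondary gradient, and the dense proportion is
# the integrated extended-dense area of the secondary over the total of the
# primary.

#' Pipeline configuration
#'
#' Collects the tunable constants of the density pipeline. Defaults are the
#' standard values: pooling windows from [pooling_window()], baseline
#' exclusion windows from [default_signal_windows()], the
#' [reference_calibration()] line, 0.025 Da MS tolerance, and the k = 2
#' acceptance rule (accept the two-component fit when it improves SSE by
#' more than `k2_sse_improvement` and its dense amplitude exceeds
#' `k2_min_amplitude_ratio` of the bulk amplitude).
#'
#' @param dense_window,bulk_window,light_window,dense_extended_window RI
#'   pooling windows, `c(lo, hi)`.
#' @param signal_windows Baseline exclusion windows.
#' @param calibration An [ri_calibration][fit_ri_density_calibration].
#' @param ms_tol MS matching tolerance, Da.
#' @param k2_sse_improvement Minimum relative SSE improvement of k = 2 over
#'   k = 1 for the two-component model to be selected.
#' @param k2_min_amplitude_ratio Minimum dense/bulk amplitude ratio.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(dense_window = pooling_window("dense"),
                            bulk_window = pooling_window("bulk"),
                            light_window = pooling_window("light"),
                            dense_extended_window =
                              pooling_window("dense_extended"),
                            signal_windows = default_signal_windows(),
                            calibration = reference_calibration(),
                            ms_tol = 0.025,
                            k2_sse_improvement = 0.20,
                            k2_min_amplitude_ratio = 0.05) {
  structure(
    list(dense_window = as_window(dense_window),
         bulk_window = as_window(bulk_window),
         light_window = as_window(light_window),
         dense_extended_window = as_window(dense_extended_window),
         signal_windows = signal_windows,
         calibration = calibration, ms_tol = ms_tol,
         k2_sse_improvement = k2_sse_improvement,
         k2_min_amplitude_ratio = k2_min_amplitude_ratio),
    class = "pipeline_config"
  )
}

#' Run the two-gradient density pipeline
#'
#' For each gradient: interpolate RI, correct the baseline, fit Gaussian
#' mixtures with k = 1 and k = 2 and select k by the configured rule; then
#' quantify percent dense DNA from the secondary over the primary. When the
#' two-component model is rejected on the secondary gradient, the result is
#' flagged: no distinct dense DNA distribution (the S-phase situation).
#'
#' @param primary,secondary [gradient_profile()]s (or file paths readable
#'   by [read_fraction_table()]) for the primary gradient and the secondary
#'   gradient of its re-run dense pool.
#' @param config A [pipeline_config()].
#' @return A `density_run_report` list: corrected `primary` and `secondary`
#'   profiles, their mixture fits (`primary_fit`, `secondary_fit`), the
#'   chosen `secondary_k`, `dense_detected`, `quantification` (the
#'   [percent_dense()] row), and `dense_component` (one-row tibble with
#'   mean RI, sigma, amplitude and mean density, or NULL).
#' @export
run_density_pipeline <- function(primary, secondary,
                                 config = pipeline_config()) {
  if (is.character(primary)) primary <- read_fraction_table(primary)
  if (is.character(secondary)) secondary <- read_fraction_table(secondary)

  prep <- function(p) {
    correct_baseline(interpolate_ri(p), signal_windows = config$signal_windows)
  }
  primary <- prep(primary)
  secondary <- prep(secondary)

  primary_fit <- fit_mixture(primary, k = 1)
  fit1 <- fit_mixture(secondary, k = 1)
  fit2 <- fit_mixture(secondary, k = 2)
  improvement <- if (fit1$sse > 0) 1 - fit2$sse / fit1$sse else 0
  amp <- fit2$components$amplitude
  amp_ratio <- if (max(amp) > 0) min(amp) / max(amp) else 0
  use_k2 <- improvement > config$k2_sse_improvement &&
    amp_ratio > config$k2_min_amplitude_ratio
  secondary_fit <- if (use_k2) fit2 else fit1

  dense_component <- NULL
  if (use_k2) {
    dc <- secondary_fit$components[which.max(secondary_fit$components$mean), ]
    dense_component <- dplyr::mutate(
      dc, mean_density = ri_to_density(config$calibration, .data$mean))
  }
  quantification <- percent_dense(secondary, primary,
                                  dense_window = config$dense_extended_window)
  structure(
    list(primary = primary, secondary = secondary,
         primary_fit = primary_fit, secondary_fit = secondary_fit,
         secondary_k = if (use_k2) 2L else 1L,
         dense_detected = use_k2,
         dense_component = dense_component,
         quantification = quantification,
         config = config),
    class = "density_run_report"
  )
}

#' @export
print.density_run_report <- function(x, ...) {
  cat("<density_run_report>\n")
  cat(sprintf("  secondary fit: k = %d%s\n", x$secondary_k,
              if (x$dense_detected) ""
              else " — no distinct dense DNA distribution"))
  if (!is.null(x$dense_component)) {
    cat(sprintf("  dense component: mean RI %.4f (%.3f g/ml), sigma %.4g\n",
                x$dense_component$mean, x$dense_component$mean_density,
                x$dense_component$sigma))
  }
  cat(sprintf("  percent dense DNA: %.2f%%\n",
              x$quantification$percent_dense))
  invisible(x)
}

#' @rdname run_density_pipeline
#' @param x,... A `density_run_report`; further arguments ignored.
#' @export
glance.density_run_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble(secondary_k = x$secondary_k, dense_detected = x$dense_detected,
           dense_mean_ri = if (is.null(x$dense_component)) NA_real_
                           else x$dense_component$mean),
    x$quantification
  )
}

#' Run the interval-overlap pipeline
#'
#' Computes the mutual overlap summary of two BED interval sets and the
#' per-chromosome shuffle null for the a-in-b count.
#'
#' @param a,b [interval_set()]s, or BED file paths.
#' @param genome Named chromosome lengths or a chrom.sizes path (required
#'   when `a`/`b` are file paths).
#' @param n_shuffles Number of shuffles for the null.
#' @param seed Integer seed.
#' @return An `overlap_run_report` list: `summary` (the [overlap_summary()]
#'   row), `null` (the [shuffle_null_summary()] object), `seed`.
#' @export
run_overlap_pipeline <- function(a, b, genome = NULL, n_shuffles = 100,
                                 seed = 1) {
  if (is.character(a)) a <- read_bed(a, genome)
  if (is.character(b)) b <- read_bed(b, genome)
  structure(
    list(summary = overlap_summary(a, b),
         null = shuffle_null_summary(a, b, n_shuffles = n_shuffles,
                                     seed = seed),
         seed = seed),
    class = "overlap_run_report"
  )
}

#' @export
print.overlap_run_report <- function(x, ...) {
  cat("<overlap_run_report>\n")
  print(x$summary)
  print(x$null)
  invisible(x)
}
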