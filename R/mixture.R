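# Gaussian mixture model of a corrected concentration profile:
#   c(ri) = sum_j A_j * exp(-(ri - mu_j)^2 / (2 sigma_j^2))
# The mean locates the buoyant density of a DNA population, the height is
# proportional to its amount, and sigma shrinks with fragment size.

mixture_predict <- function(par, ri) {
  k <- length(par) / 3
  out <- numeric(length(ri))
  for (j in seq_len(k)) {
    mu <- par[3 * j - 2]; sg <- par[3 * j - 1]; a <- par[3 * j]
    out <- out + a * exp(-(ri - mu)^2 / (2 * sg^2))
  }
  out
}

mixture_sse <- function(par, ri, conc) {
  sum((conc - mixture_predict(par, ri))^2)
}

# One bounded Levenberg-Marquardt run from a given start.
run_nlslm <- function(start, ri, conc, lower, upper) {
  res <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      lower = lower, upper = upper,
      fn = function(p) conc - mixture_predict(p, ri),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(res)) return(NULL)
  list(par = res$par, sse = sum(res$fvec^2),
       converged = res$info %in% 1:4)
}

#' Fit a one- or two-component Gaussian mixture to a gradient profile
#'
#' Minimises the sum of squared differences between the baseline-corrected
#' DNA concentrations and a superposition of `k` Gaussian distributions over
#' the RI axis, by bounded Levenberg-Marquardt least squares with
#' multi-start. For `k = 2` one start is the `k = 1` solution plus a second
#' component seeded at the centre of the dense pooling window, which also
#' guarantees SSE(k = 2) <= SSE(k = 1) up to optimiser tolerance.
#'
#' @param profile A baseline-corrected [gradient_profile()] (or any data
#'   frame with `ri` and `corrected_concentration` columns).
#' @param k Number of components, 1 or 2.
#' @param init Optional data frame of starting values with columns `mean`,
#'   `sigma`, `amplitude` (one row per component).
#' @param sigma_bounds Bounds on component sigma, in RI units.
#' @return A `mixture_fit` with `components` (tibble of `mean`, `sigma`,
#'   `amplitude`, sorted by ascending mean), `sse`, `n_points` and
#'   `converged`. The denser population is the larger-mean component.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_mixture <- function(profile, k = 1, init = NULL,
                        sigma_bounds = c(1e-4, 1e-2)) {
  if (!k %in% c(1, 2)) {
    abort("k must be 1 or 2", class = "densigrad_parameter_error")
  }
  ri <- profile$ri
  conc <- profile$corrected_concentration
  keep <- is.finite(ri) & is.finite(conc)
  ri <- ri[keep]; conc <- conc[keep]
  if (length(ri) < 3 * k + 1) {
    abort(sprintf("need at least %d points to fit k = %d", 3 * k + 1, k),
          class = "densigrad_degenerate_input")
  }
  rng <- range(ri)
  lower1 <- c(rng[1], sigma_bounds[1], 0)
  upper1 <- c(rng[2], sigma_bounds[2], Inf)

  pos <- pmax(conc, 0)
  w <- if (sum(pos) > 0) pos / sum(pos) else rep(1 / length(ri), length(ri))
  mu0 <- sum(w * ri)
  sg0 <- min(max(sqrt(sum(w * (ri - mu0)^2)), sigma_bounds[1] * 2),
             sigma_bounds[2] / 2)
  a0 <- max(conc, 0.1 * max(abs(conc)))

  starts1 <- list(c(mu0, sg0, a0))
  if (!is.null(init) && nrow(init) >= 1) {
    starts1 <- c(list(with(init[1, ], c(mean, sigma, amplitude))), starts1)
  }
  # extra starts at the mode and at the dense-window centre
  starts1 <- c(starts1, list(c(ri[which.max(conc)], sg0, a0),
                             c(1.3706, sg0, a0)))

  best1 <- NULL
  for (s in starts1) {
    s <- pmin(pmax(s, lower1 + 1e-12), c(upper1[1:2], s[3]))
    r <- run_nlslm(s, ri, conc, lower1, upper1)
    if (!is.null(r) && (is.null(best1) || r$sse < best1$sse)) best1 <- r
  }
  if (is.null(best1)) {
    best1 <- list(par = starts1[[1]], sse = mixture_sse(starts1[[1]], ri, conc),
                  converged = FALSE)
  }
  if (k == 1) {
    return(new_mixture_fit(best1$par, best1$sse, length(ri), best1$converged))
  }

  lower2 <- rep(lower1, 2)
  upper2 <- rep(upper1, 2)
  starts2 <- list()
  if (!is.null(init) && nrow(init) >= 2) {
    starts2 <- c(starts2, list(c(
      with(init[1, ], c(mean, sigma, amplitude)),
      with(init[2, ], c(mean, sigma, amplitude))
    )))
  }
  # k = 1 solution plus a small dense component at the dense-window centre
  dense_mu <- min(max(1.3706, rng[1]), rng[2])
  starts2 <- c(starts2,
    list(c(best1$par, dense_mu, 0.0013, 0.25 * best1$par[3])),
    # the same with a vanishing second amplitude: reproduces the k = 1 SSE
    list(c(best1$par, dense_mu, 0.0013, 1e-9)),
    # split the single component symmetrically
    list(c(best1$par[1] - best1$par[2], best1$par[2], best1$par[3] / 2,
           best1$par[1] + best1$par[2], best1$par[2], best1$par[3] / 2))
  )
  best2 <- NULL
  for (s in starts2) {
    s[c(1, 4)] <- pmin(pmax(s[c(1, 4)], rng[1]), rng[2])
    s[c(3, 6)] <- pmax(s[c(3, 6)], 0)
    s[c(2, 5)] <- pmin(pmax(s[c(2, 5)], sigma_bounds[1]), sigma_bounds[2])
    r <- run_nlslm(s, ri, conc, lower2, upper2)
    if (!is.null(r) && (is.null(best2) || r$sse < best2$sse)) best2 <- r
  }
  if (is.null(best2) || best2$sse > best1$sse) {
    # never worse than k = 1: degenerate second component
    par <- c(best1$par, dense_mu, 0.0013, 0)
    best2 <- list(par = par, sse = best1$sse,
                  converged = isTRUE(best1$converged))
  }
  new_mixture_fit(best2$par, best2$sse, length(ri), best2$converged)
}

new_mixture_fit <- function(par, sse, n_points, converged) {
  k <- length(par) / 3
  comp <- tibble(
    mean = par[3 * seq_len(k) - 2],
    sigma = par[3 * seq_len(k) - 1],
    amplitude = par[3 * seq_len(k)]
  )
  comp <- dplyr::arrange(comp, .data$mean)
  structure(
    list(components = comp, sse = sse, n_points = n_points,
         converged = converged),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k = %d, SSE = %.4g, n = %d%s\n",
              nrow(x$components), x$sse, x$n_points,
              if (x$converged) "" else " (NOT converged)"))
  print(x$components)
  invisible(x)
}

#' @rdname fit_mixture
#' @param x,object,... A `mixture_fit`; further arguments ignored.
#' @export
tidy.mixture_fit <- function(x, ...) {
  dplyr::mutate(x$components,
                component = dplyr::row_number(),
                role = if (nrow(x$components) == 2) c("bulk", "dense")
                       else "single",
                .before = 1)
}

#' @rdname fit_mixture
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(k = nrow(x$components), sse = x$sse, n_points = x$n_points,
         converged = x$converged)
}

#' Predict mixture concentrations at given RI values
#' @param object A `mixture_fit`.
#' @param ri RI values.
#' @param ... Ignored.
#' @export
predict.mixture_fit <- function(object, ri, ...) {
  par <- as.vector(t(as.matrix(object$components[, c("mean", "sigma",
                                                     "amplitude")])))
  mixture_predict(par, ri)
}

#' Standard RI pooling windows
#'
#' The RI windows used to pool fractions: bulk DNA 1.3670-1.3682, dense DNA
#' 1.3695-1.3715, light DNA 1.3630-1.3660 on primary gradients, and the
#' extended dense area 1.3700-1.3750 used for quantification on secondary
#' gradients. Bounds are inclusive on both ends.
#'
#' @param name One of "dense", "bulk", "light", "dense_extended".
#' @return A `pooling_window`: named numeric `c(ri_lo, ri_hi)`.
#' @export
pooling_window <- function(name = c("dense", "bulk", "light",
                                    "dense_extended")) {
  name <- match.arg(name)
  w <- switch(name,
    bulk = c(1.3670, 1.3682),
    dense = c(1.3695, 1.3715),
    light = c(1.3630, 1.3660),
    dense_extended = c(1.3700, 1.3750)
  )
  structure(setNames(w, c("ri_lo", "ri_hi")), name = name,
            class = "pooling_window")
}

as_window <- function(window) {
  if (inherits(window, "pooling_window")) return(unclass(window))
  if (is.character(window)) return(unclass(pooling_window(window)))
  if (is.numeric(window) && length(window) == 2 && window[1] < window[2]) {
    return(setNames(as.numeric(window), c("ri_lo", "ri_hi")))
  }
  abort("window must be a pooling_window, a window name, or c(lo, hi)",
        class = "densigrad_parameter_error")
}

#' Select the fractions inside an RI pooling window
#'
#' @param profile A [gradient_profile()] with RI defined.
#' @param window A [pooling_window()], a window name, or `c(ri_lo, ri_hi)`.
#' @return The sub-profile of fractions with RI in `[ri_lo, ri_hi]`
#'   (inclusive), order preserved. An empty selection warns.
#' @export
select_window <- function(profile, window) {
  w <- as_window(window)
  keep <- which(profile$ri >= w[1] & profile$ri <= w[2])
  if (length(keep) == 0) {
    warn("no fractions fall inside the window; returning an empty profile")
  }
  out <- profile[keep, ]
  for (a in c("label", "ri_fit", "baseline")) {
    attr(out, a) <- attr(profile, a)
  }
  out
}

trapz_ri <- function(ri, conc) {
  o <- order(ri)
  if (length(ri) < 2) return(0)
  pracma::trapz(ri[o], conc[o])
}

# Trapezoidal integral restricted to [lo, hi], with linearly interpolated
# samples inserted at the window bounds so the window edges are exact.
trapz_window <- function(ri, conc, lo, hi) {
  o <- order(ri)
  ri <- ri[o]; conc <- conc[o]
  lo <- max(lo, ri[1]); hi <- min(hi, ri[length(ri)])
  if (hi <= lo) return(0)
  inside <- ri > lo & ri < hi
  edge <- stats::approx(ri, conc, xout = c(lo, hi), ties = "ordered")
  x <- c(lo, ri[inside], hi)
  y <- c(edge$y[1], conc[inside], edge$y[2])
  pracma::trapz(x, y)
}

#' Quantify percent dense DNA
#'
#' The proportion of dense over total DNA: the trapezoidal integral of the
#' baseline-corrected secondary-gradient concentrations over the extended
#' dense RI window (1.3700-1.3750 by default), divided by the integral of
#' the total corrected DNA of the corresponding primary gradient.
#'
#' @param secondary,primary Baseline-corrected [gradient_profile()]s: the
#'   secondary gradient carrying the re-run dense pool, and the primary
#'   gradient it was pooled from.
#' @param dense_window RI window integrated on the secondary gradient;
#'   defaults to `pooling_window("dense_extended")`.
#' @return A one-row tibble: `dense_integral`, `total_integral`
#'   (concentration x RI units) and `percent_dense`.
#' @export
percent_dense <- function(secondary, primary,
                          dense_window = pooling_window("dense_extended")) {
  w <- as_window(dense_window)
  for (p in list(secondary, primary)) {
    if (anyNA(p$ri) || all(is.na(p$corrected_concentration))) {
      abort("profiles must be baseline-corrected with RI defined",
            class = "densigrad_parameter_error")
    }
  }
  dense_integral <- trapz_window(secondary$ri,
                                 secondary$corrected_concentration,
                                 w[1], w[2])
  total_integral <- trapz_ri(primary$ri, primary$corrected_concentration)
  if (!is.finite(total_integral) || total_integral <= 0) {
    abort("total integral of the primary gradient is not positive",
          class = "densigrad_quantification_error")
  }
  tibble(dense_integral = abs(dense_integral),
         total_integral = abs(total_integral),
         percent_dense = 100 * abs(dense_integral) / abs(total_integral))
}

#' Overlap length of fitted components with an RI window
#'
#' For each fitted component, the length of the intersection of its
#' `[mean - 2 sigma, mean + 2 sigma]` extent with a pooling window.
#'
#' @param fit A `mixture_fit`.
#' @param window A [pooling_window()] or `c(ri_lo, ri_hi)`.
#' @return A tibble with one row per component: `mean`, `sigma`,
#'   `overlap_length` (RI units).
#' @export
peak_window_overlap_length <- function(fit, window) {
  w <- as_window(window)
  dplyr::mutate(fit$components,
    overlap_length = pmax(0, pmin(.data$mean + 2 * .data$sigma, w[2]) -
                             pmax(.data$mean - 2 * .data$sigma, w[1])))
}
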