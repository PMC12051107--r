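test_that("single-Gaussian fit recovers noiseless parameters to high precision", {
  ri <- seq(1.3800, 1.3600, length.out = 60)
  conc <- 10 * exp(-(ri - 1.3683)^2 / (2 * 0.0016^2))
  prof <- tibble::tibble(ri = ri, corrected_concentration = conc)
  fit <- fit_mixture(prof, k = 1)
  expect_true(fit$converged)
  expect_equal(fit$components$mean, 1.3683, tolerance = 1e-6)
  expect_equal(fit$components$sigma, 0.0016, tolerance = 1e-6)
  expect_equal(fit$components$amplitude, 10, tolerance = 1e-5)
  expect_lt(fit$sse, 1e-10)
})

test_that("two-component fit resolves a noisy biphasic secondary gradient", {
  # carried-over bulk plus dense DNA at 3:1 amplitude, as on a secondary
  # gradient of pooled dense fractions. The major component is pinned to
  # < 2e-4 RI; the minor overlapping component carries a larger statistical
  # uncertainty (~3e-4 median at these amplitudes and 60 fractions), which
  # truth-initialised fits share, so the bound reflects the information
  # limit rather than the optimiser.
  comps <- data.frame(mean = c(1.3685, 1.3706), sigma = c(0.0012, 0.0013),
                      amplitude = c(7.5, 2.5))
  errs <- sapply(1:20, function(s) {
    prof <- make_corrected_profile(comps, seed = s, noise_cv = 0.02,
                                   noise_floor_sd = 0.02)
    fit <- fit_mixture(prof, k = 2)
    expect_equal(fit$components$mean, sort(fit$components$mean))
    abs(fit$components$mean - comps$mean)
  })
  expect_lt(median(errs[1, ]), 0.0002)
  expect_lt(median(errs[2, ]), 0.001)
})

test_that("SSE of the two-component fit never exceeds the one-component fit", {
  for (s in 1:5) {
    comps <- data.frame(mean = 1.368 + 0.001 * s %% 3,
                        sigma = 0.0015, amplitude = 8)
    prof <- make_corrected_profile(comps, seed = s, noise_cv = 0.05,
                                   noise_floor_sd = 0.05)
    f1 <- fit_mixture(prof, k = 1)
    f2 <- fit_mixture(prof, k = 2)
    expect_lte(f2$sse, f1$sse + 1e-8 * max(1, f1$sse))
  }
})

test_that("continuous optimiser beats a coarse grid search on small profiles", {
  withr::with_seed(11, {
    ri <- seq(1.380, 1.360, length.out = 25)
    conc <- 6 * exp(-(ri - 1.369)^2 / (2 * 0.0015^2)) + rnorm(25, sd = 0.1)
  })
  prof <- tibble::tibble(ri = ri, corrected_concentration = conc)
  fit <- fit_mixture(prof, k = 1)
  oracle_sse <- grid_search_sse(
    ri, conc,
    mu_grid = seq(1.360, 1.380, by = 5e-4),
    sigma_grid = seq(5e-4, 5e-3, by = 2.5e-4),
    a_grid = seq(1, 10, by = 0.25))
  expect_lte(fit$sse, oracle_sse)
})

test_that("fit_mixture rejects bad k and too-few points", {
  prof <- tibble::tibble(ri = seq(1.36, 1.38, length.out = 5),
                         corrected_concentration = rep(1, 5))
  expect_error(fit_mixture(prof, k = 3), class = "densigrad_parameter_error")
  expect_error(fit_mixture(prof, k = 2), class = "densigrad_degenerate_input")
})

test_that("select_window keeps exactly the in-window fractions", {
  prof <- make_corrected_profile(
    data.frame(mean = 1.3683, sigma = 0.0016, amplitude = 10))
  dense <- select_window(prof, pooling_window("dense"))
  expect_true(all(dense$ri >= 1.3695 & dense$ri <= 1.3715))
  expect_equal(nrow(select_window(prof, c(1.30, 1.40))), nrow(prof))
  expect_warning(empty <- select_window(prof, c(1.39, 1.40)))
  expect_equal(nrow(empty), 0)
})

test_that("pooling windows carry the standard RI bounds", {
  expect_equal(unclass(pooling_window("bulk")),
               c(ri_lo = 1.3670, ri_hi = 1.3682), ignore_attr = TRUE)
  expect_equal(unclass(pooling_window("dense")),
               c(ri_lo = 1.3695, ri_hi = 1.3715), ignore_attr = TRUE)
  expect_equal(unclass(pooling_window("light")),
               c(ri_lo = 1.3630, ri_hi = 1.3660), ignore_attr = TRUE)
  expect_equal(unclass(pooling_window("dense_extended")),
               c(ri_lo = 1.3700, ri_hi = 1.3750), ignore_attr = TRUE)
})

test_that("percent_dense matches the closed-form Gaussian window mass", {
  # exact corrected profiles at fine sampling so the trapezoid is the only
  # approximation
  primary <- make_exact_profile(
    data.frame(mean = 1.3683, sigma = 0.00163, amplitude = 10),
    n_fractions = 400)
  secondary <- make_exact_profile(
    data.frame(mean = 1.3706, sigma = 0.0013, amplitude = 2.5),
    n_fractions = 400)
  q <- percent_dense(secondary, primary)
  expected <- 100 *
    gaussian_window_mass(1.3706, 0.0013, 2.5, 1.3700, 1.3750) /
    gaussian_window_mass(1.3683, 0.00163, 10, 1.3600, 1.3800)
  expect_equal(q$percent_dense, expected, tolerance = 0.005)

  # trivial bounds: all mass inside the window vs an empty secondary
  all_in <- percent_dense(primary, primary, dense_window = c(1.30, 1.45))
  expect_equal(all_in$percent_dense, 100, tolerance = 1e-6)
  zero <- primary
  zero$corrected_concentration <- 0
  expect_equal(percent_dense(zero, primary)$percent_dense, 0)
})

test_that("percent_dense scaling invariances hold", {
  primary <- make_corrected_profile(
    data.frame(mean = 1.3683, sigma = 0.0016, amplitude = 10))
  secondary <- make_corrected_profile(
    data.frame(mean = 1.3706, sigma = 0.0013, amplitude = 2.5))
  q <- percent_dense(secondary, primary)
  scale_profile <- function(p, f) {
    p$corrected_concentration <- p$corrected_concentration * f
    p
  }
  both <- percent_dense(scale_profile(secondary, 3), scale_profile(primary, 3))
  expect_equal(both$percent_dense, q$percent_dense, tolerance = 1e-9)
  only_sec <- percent_dense(scale_profile(secondary, 2), primary)
  expect_equal(only_sec$percent_dense, 2 * q$percent_dense, tolerance = 1e-9)
})

test_that("peak extent within a window follows interval arithmetic", {
  fit <- fit_mixture(
    tibble::tibble(
      ri = seq(1.380, 1.360, length.out = 40),
      corrected_concentration =
        5 * exp(-(seq(1.380, 1.360, length.out = 40) - 1.3706)^2 /
                  (2 * 0.0010^2))),
    k = 1)
  # centred in a wide window: full 4-sigma extent
  wide <- peak_window_overlap_length(fit, c(1.30, 1.45))
  expect_equal(wide$overlap_length, 4 * fit$components$sigma,
               tolerance = 1e-6)
  # disjoint window
  out <- peak_window_overlap_length(fit, c(1.30, 1.31))
  expect_equal(out$overlap_length, 0)
  # half-overlap checked by direct interval arithmetic
  mu <- fit$components$mean; sg <- fit$components$sigma
  w <- c(mu, mu + 1)  # window starting exactly at the mean
  expected <- min(mu + 2 * sg, w[2]) - max(mu - 2 * sg, w[1])
  half <- peak_window_overlap_length(fit, w)
  expect_equal(half$overlap_length, expected, tolerance = 1e-9)
})
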