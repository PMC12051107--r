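# Independent oracles, deliberately naive, used to cross-check the package
# implementations.

# Closed-form ordinary least squares via the normal equations.
ols_oracle <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  r2 <- 1 - sum((y - slope * x - intercept)^2) / sum((y - yb)^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# All-pairs O(n*m) overlap check on half-open intervals: rows of `a`
# overlapping >= 1 bp with any row of `b`.
brute_force_hits <- function(a, b) {
  hit <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && a$end[i] > b$start[j]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  which(hit)
}

# Naive sliding-window CCGG scan, 0-based positions.
ccgg_oracle <- function(sequence) {
  n <- nchar(sequence)
  if (n < 4) return(integer(0))
  pos <- integer(0)
  for (i in seq_len(n - 3)) {
    if (substr(sequence, i, i + 3) == "CCGG") pos <- c(pos, i - 1L)
  }
  pos
}

# Exhaustive coarse grid search for the best single-Gaussian SSE.
grid_search_sse <- function(ri, conc, mu_grid, sigma_grid, a_grid) {
  best <- Inf
  for (mu in mu_grid) for (sg in sigma_grid) for (a in a_grid) {
    sse <- sum((conc - a * exp(-(ri - mu)^2 / (2 * sg^2)))^2)
    if (sse < best) best <- sse
  }
  best
}

# Monoisotopic mass from a simple CxHyNzOw formula string, summed from
# atomic masses.
formula_mass_oracle <- function(formula) {
  atomic <- c(C = 12.000000, H = 1.0078250319, N = 14.0030740052,
              O = 15.9949146221)
  parts <- regmatches(formula, gregexpr("([CHNO])([0-9]*)", formula))[[1]]
  total <- 0
  for (p in parts) {
    el <- substr(p, 1, 1)
    n <- suppressWarnings(as.integer(substr(p, 2, nchar(p))))
    if (is.na(n)) n <- 1L
    total <- total + n * atomic[[el]]
  }
  total
}

# Closed-form Gaussian window mass: integral of A*exp(-(x-mu)^2/(2 s^2))
# over [lo, hi].
gaussian_window_mass <- function(mean, sigma, amplitude, lo, hi) {
  amplitude * sigma * sqrt(2 * pi) *
    (pnorm((hi - mean) / sigma) - pnorm((lo - mean) / sigma))
}

# A corrected profile built directly from exact Gaussian values, bypassing
# the baseline step (used where the quantity under test is integration or
# fitting alone).
make_exact_profile <- function(components, n_fractions = 60,
                               ri_start = 1.3800, ri_end = 1.3600) {
  ri <- seq(ri_start, ri_end, length.out = n_fractions)
  conc <- rowSums(sapply(seq_len(nrow(components)), function(j) {
    components$amplitude[j] *
      exp(-(ri - components$mean[j])^2 / (2 * components$sigma[j]^2))
  }))
  tibble::tibble(ri = ri, corrected_concentration = conc)
}

# A noiseless-noise gradient pair used by several tests.
make_corrected_profile <- function(components, seed = 1, noise_cv = 0,
                                   noise_floor_sd = 0, n_fractions = 60,
                                   ...) {
  prof <- simulate_gradient(components, seed = seed, noise_cv = noise_cv,
                            noise_floor_sd = noise_floor_sd,
                            n_fractions = n_fractions, ...)
  correct_baseline(interpolate_ri(prof))
}
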