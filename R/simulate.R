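# Seeded forward models of every input the pipeline consumes. Each
# generator is a pure function of its parameters and seed (bit-identical
# reruns), and a noiseless run composed with the matching analysis stage is
# the identity on parameters.

#' Simulate a density-gradient fraction table
#'
#' Forward model of a pumped caesium sulphate gradient: RI falls linearly
#' with fraction index from `ri_start` (fraction 1, densest) to `ri_end`;
#' the DNA concentration profile is a sum of Gaussian components over RI
#' plus a linear instrumental baseline, with heteroscedastic Gaussian noise
#' (sd = `noise_cv` x |signal| + `noise_floor_sd`, mimicking blanked
#' spectrophotometer readings that can dip below zero). Only odd-numbered
#' fractions carry a "measured" RI, mirroring hand-refractometer practice,
#' so [interpolate_ri()] is exercised on realistic inputs.
#'
#' @param components Data frame with columns `mean`, `sigma` (RI units) and
#'   `amplitude` (ng/ul peak height), one row per DNA population.
#' @param n_fractions Number of fractions (>= 10), default 60.
#' @param ri_start,ri_end RI of the first and last fraction;
#'   `ri_start > ri_end` (dense pumped first). Defaults span the plotted
#'   range 1.3800-1.3600.
#' @param baseline_slope,baseline_intercept The instrumental baseline line
#'   `intercept + slope * RI`, ng/ul. Defaults give a slight tilt of
#'   ~0.5 ng/ul across the gradient around a 0.9 ng/ul offset.
#' @param noise_cv Coefficient of variation of the signal-proportional
#'   noise; default 0.02.
#' @param noise_floor_sd Additive noise floor, ng/ul.
#' @param seed Integer seed.
#' @param label Label for the profile.
#' @return A [gradient_profile()] with raw concentrations filled.
#' @examples
#' prof <- simulate_gradient(
#'   data.frame(mean = 1.3683, sigma = 0.00163, amplitude = 10), seed = 1)
#' @export
simulate_gradient <- function(components,
                              n_fractions = 60,
                              ri_start = 1.3800, ri_end = 1.3600,
                              baseline_slope = 25,
                              baseline_intercept = 0.9 - 25 * 1.37,
                              noise_cv = 0.02, noise_floor_sd = 0.02,
                              seed = 1, label = "simulated") {
  components <- as_tibble(components)
  if (n_fractions < 10) {
    abort("n_fractions must be >= 10", class = "densigrad_parameter_error")
  }
  if (ri_start <= ri_end) {
    abort("ri_start must exceed ri_end (dense fractions pumped first)",
          class = "densigrad_parameter_error")
  }
  if (noise_cv < 0 || noise_floor_sd < 0) {
    abort("noise parameters must be >= 0",
          class = "densigrad_parameter_error")
  }
  if (any(components$sigma <= 0) || any(components$amplitude < 0)) {
    abort("components require sigma > 0 and amplitude >= 0",
          class = "densigrad_parameter_error")
  }
  idx <- seq_len(n_fractions)
  ri <- ri_start + (ri_end - ri_start) * (idx - 1) / (n_fractions - 1)
  par <- as.vector(t(as.matrix(components[, c("mean", "sigma",
                                              "amplitude")])))
  signal <- mixture_predict(par, ri)
  baseline <- baseline_intercept + baseline_slope * ri
  withr::local_seed(seed)
  noise_sd <- noise_cv * abs(signal) + noise_floor_sd
  conc <- signal + baseline + rnorm(n_fractions, sd = noise_sd)
  gradient_profile(
    tibble(
      fraction_index = idx,
      refractive_index = ifelse(idx %% 2 == 1, ri, NA_real_),
      dna_concentration = conc
    ),
    label = label
  )
}

#' Simulate gravimetric (RI, density) calibration pairs
#'
#' @param n Number of pairs (>= 2).
#' @param slope,intercept True calibration line, g/ml; defaults are the
#'   reference constants 12.46 and -15.62.
#' @param noise_sd Gaussian noise on density, g/ml.
#' @param seed Integer seed.
#' @return A tibble with columns `ri`, `density_g_per_ml`.
#' @export
simulate_calibration_pairs <- function(n = 38, slope = 12.46,
                                       intercept = -15.62, noise_sd = 0,
                                       seed = 1) {
  if (n < 2) abort("n must be >= 2", class = "densigrad_parameter_error")
  withr::local_seed(seed)
  ri <- runif(n, 1.360, 1.380)
  tibble(ri = ri,
         density_g_per_ml = slope * ri + intercept + rnorm(n, sd = noise_sd))
}

#' Simulate a pair of interval sets with controlled overlap
#'
#' Places `n_b` disjoint intervals uniformly on the genome, then places
#' `n_a` intervals such that exactly `floor(overlap_fraction * n_a)` of
#' them overlap some b interval by >= 1 bp and the remainder avoid b
#' entirely, giving a construction-exact overlap count.
#'
#' @param genome Named numeric vector of chromosome lengths; defaults to
#'   [toy_genome()].
#' @param n_a,n_b Interval counts.
#' @param len_range `c(min, max)` interval length in bp.
#' @param overlap_fraction Fraction of a intervals placed to overlap b.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling budget per interval.
#' @return A list with [interval_set()]s `a` and `b` and `n_overlapping`,
#'   the constructed exact count.
#' @export
simulate_peak_sets <- function(genome = toy_genome(), n_a = 200, n_b = 100,
                               len_range = c(200, 1000),
                               overlap_fraction = 0.5, seed = 1,
                               max_tries = 10000) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    abort("overlap_fraction must be in [0, 1]",
          class = "densigrad_parameter_error")
  }
  withr::local_seed(seed)
  chroms <- names(genome)
  draw_len <- function(n) {
    floor(runif(n, len_range[1], len_range[2] + 1))
  }
  # b: uniform placement, no mutual overlap, chromosome chosen
  # length-proportionally
  b_chrom <- sample(chroms, n_b, replace = TRUE, prob = genome)
  b_rows <- dplyr::bind_rows(lapply(chroms, function(chr) {
    n <- sum(b_chrom == chr)
    if (n == 0) return(NULL)
    lens <- draw_len(n)
    starts <- place_lengths(lens, genome[[chr]], no_overlap = TRUE,
                            max_tries = max_tries)
    tibble(chrom = chr, start = starts, end = starts + lens)
  }))
  b <- interval_set(b_rows, genome)

  n_over <- floor(overlap_fraction * n_a)
  a_rows <- vector("list", n_a)
  for (i in seq_len(n_a)) {
    len <- draw_len(1)
    if (i <= n_over) {
      # anchor to a random b interval and force >= 1 bp overlap
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        j <- sample.int(nrow(b), 1)
        chr <- b$chrom[j]
        lo <- max(0, b$start[j] - len + 1)
        hi <- min(genome[[chr]] - len, b$end[j] - 1)
        if (hi < lo) next
        s <- floor(runif(1, lo, hi + 1))
        if (s > hi) s <- hi
        a_rows[[i]] <- tibble(chrom = chr, start = s, end = s + len)
        placed <- TRUE
        break
      }
      if (!placed) {
        abort("could not place an overlapping a interval",
              class = "densigrad_packing_error")
      }
    } else {
      # avoid b entirely
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        chr <- sample(chroms, 1, prob = genome)
        hi <- genome[[chr]] - len
        if (hi < 0) next
        s <- floor(runif(1, 0, hi + 1))
        if (s > hi) s <- hi
        bc <- b[b$chrom == chr, ]
        if (!any(s < bc$end & s + len > bc$start)) {
          a_rows[[i]] <- tibble(chrom = chr, start = s, end = s + len)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort("could not place a non-overlapping a interval",
              class = "densigrad_packing_error")
      }
    }
  }
  a <- interval_set(dplyr::bind_rows(a_rows), genome)
  list(a = a, b = b, n_overlapping = n_over)
}

#' A small three-chromosome toy genome
#'
#' Small enough that brute-force all-pairs overlap checks stay fast.
#'
#' @return Named numeric vector of chromosome lengths.
#' @export
toy_genome <- function() {
  c(chrT1 = 1e6, chrT2 = 5e5, chrT3 = 2e5)
}

#' Simulate an LC-MS nucleoside peak table
#'
#' For each deoxycytidine form with nonzero composition, emits an H- and a
#' Na-adduct peak at the expected m/z plus Gaussian mass error, with the
#' form's share of the total intensity split between the adducts.
#'
#' @param composition Percentages for the five dC forms in the order of
#'   [nucleoside_references()] (dC, 5me-dC, 5hm-dC, 5f-dC, 5ca-dC); must sum
#'   to 100.
#' @param total_intensity Total detector counts distributed over all peaks.
#' @param adduct_split Fraction of each form's intensity on the H adduct.
#' @param mass_error_sd Gaussian m/z error sd, Da.
#' @param seed Integer seed.
#' @return A tibble with columns `mz`, `intensity` (plus the generating
#'   `nucleoside`/`adduct` as columns `true_nucleoside`, `true_adduct`).
#' @export
simulate_ms_peaks <- function(composition, total_intensity = 1e6,
                              adduct_split = 0.7, mass_error_sd = 0.005,
                              seed = 1) {
  if (length(composition) != 5 || abs(sum(composition) - 100) > 1e-9) {
    abort("composition must be 5 percentages summing to 100",
          class = "densigrad_parameter_error")
  }
  if (mass_error_sd < 0) {
    abort("mass_error_sd must be >= 0", class = "densigrad_parameter_error")
  }
  refs <- nucleoside_references()
  withr::local_seed(seed)
  rows <- purrr::pmap_dfr(
    list(refs$name, refs$neutral_mass, composition),
    function(name, mass, pct) {
      if (pct <= 0) return(NULL)
      tibble(
        true_nucleoside = name,
        true_adduct = c("H", "Na"),
        mz = unname(ADDUCT_OFFSETS) + mass + rnorm(2, sd = mass_error_sd),
        intensity = total_intensity * pct / 100 *
          c(adduct_split, 1 - adduct_split)
      )
    }
  )
  dplyr::select(rows, "mz", "intensity", "true_nucleoside", "true_adduct")
}

#' Simulate a random DNA fragment of given GC content
#'
#' Bases are i.i.d. with P(G or C) = `gc_target`, split evenly between G/C
#' and between A/T.
#'
#' @param length Fragment length in bp (>= 1).
#' @param gc_target Target GC fraction in `[0, 1]`; 0.41 is the human
#'   genome average.
#' @param seed Integer seed.
#' @return A single A/C/G/T string.
#' @export
simulate_fragment <- function(length, gc_target = 0.41, seed = 1) {
  if (length < 1) abort("length must be >= 1",
                        class = "densigrad_parameter_error")
  if (gc_target < 0 || gc_target > 1) {
    abort("gc_target must be in [0, 1]", class = "densigrad_parameter_error")
  }
  withr::local_seed(seed)
  paste(sample(c("G", "C", "A", "T"), length, replace = TRUE,
               prob = c(gc_target / 2, gc_target / 2,
                        (1 - gc_target) / 2, (1 - gc_target) / 2)),
        collapse = "")
}
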