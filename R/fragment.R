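# Per-residue monoisotopic mass added to a deoxycytidine by each
# modification, relative to unmodified dC: methyl +CH2, hydroxymethyl +CH2O,
# formyl +CHO-H (= +CO), carboxy +CO2H-H (= +CO2).
MOD_MASS_DELTAS <- c(none = 0, `5me` = 14.01565, `5hm` = 30.010565,
                     `5f` = 27.994915, `5ca` = 43.989829)

# Average-mass variants for work at unit resolution.
MOD_MASS_DELTAS_AVG <- c(none = 0, `5me` = 14.0266, `5hm` = 30.026,
                         `5f` = 28.0101, `5ca` = 44.0095)

validate_sequence <- function(sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1) {
    abort("empty sequence", class = "densigrad_parameter_error")
  }
  if (grepl("[^ACGT]", sequence)) {
    abort("sequence must contain only A/C/G/T (ambiguity codes rejected)",
          class = "densigrad_parameter_error")
  }
  sequence
}

#' GC fraction of a sequence
#'
#' @param sequence An A/C/G/T string (upper or lower case).
#' @return Fraction of G + C bases, in `[0, 1]`.
#' @export
gc_fraction <- function(sequence) {
  sequence <- validate_sequence(sequence)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  mean(bases %in% c("G", "C"))
}

#' Positions of CCGG (MspI) sites
#'
#' All, possibly overlapping, occurrences of the MspI recognition site CCGG
#' on the given strand. CCGG is its own reverse complement, so
#' opposite-strand occurrences coincide and are not double-counted.
#' Glucosylation of 5hm-dC within this site blocks MspI cleavage, which is
#' the basis of the T4-BGT/MspI hydroxymethylation assay.
#'
#' @param sequence An A/C/G/T string.
#' @return Integer vector of 0-based site start positions (possibly empty).
#' @examples
#' find_ccgg_sites("AACCGGTT")  # 2
#' @export
find_ccgg_sites <- function(sequence) {
  sequence <- validate_sequence(sequence)
  hits <- gregexpr("(?=CCGG)", sequence, perl = TRUE)[[1]]
  if (hits[1] == -1) return(integer(0))
  as.integer(hits) - 1L
}

#' Modification mass loading of a double-stranded fragment
#'
#' When every dC of a PCR product is replaced by a modified deoxycytidine,
#' the added molecular mass per fragment is the number of substituted
#' residues times the per-residue mass delta. On the duplex, the top strand
#' carries one C per top-strand `C`, and the bottom strand one C per
#' top-strand `G`; full modification substitutes both strands, hemi
#' modification exactly one.
#'
#' @param sequence Top-strand A/C/G/T sequence of the fragment.
#' @param modification One of `"none"`, `"5me"`, `"5hm"`, `"5f"`, `"5ca"`.
#' @param mode `"full"` (both strands), `"hemi_top"` or `"hemi_bottom"`.
#' @param average_mass Use average instead of monoisotopic mass deltas.
#' @return A one-row tibble: `n_dC_top`, `n_dC_bottom`,
#'   `modified_dC_count`, `added_mass_total` (Da), `added_mass_per_bp`
#'   (Da/bp), `modification`, `mode`.
#' @export
modification_mass_loading <- function(sequence,
                                      modification = c("none", "5me", "5hm",
                                                       "5f", "5ca"),
                                      mode = c("full", "hemi_top",
                                               "hemi_bottom"),
                                      average_mass = FALSE) {
  modification <- match.arg(modification)
  mode <- match.arg(mode)
  sequence <- validate_sequence(sequence)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n_top <- sum(bases == "C")
  n_bottom <- sum(bases == "G")
  n_mod <- switch(mode, full = n_top + n_bottom, hemi_top = n_top,
                  hemi_bottom = n_bottom)
  delta <- if (average_mass) MOD_MASS_DELTAS_AVG[[modification]]
           else MOD_MASS_DELTAS[[modification]]
  tibble(
    n_dC_top = n_top, n_dC_bottom = n_bottom,
    modified_dC_count = n_mod,
    added_mass_total = n_mod * delta,
    added_mass_per_bp = n_mod * delta / nchar(sequence),
    modification = modification, mode = mode
  )
}

#' Empirical density-shift calibration
#'
#' Least-squares line relating the mean RI at which a fragment bands to its
#' modification mass loading (Da/bp). This is an empirical calibration
#' layer: buoyant density is not predicted from first principles, only
#' interpolated between measured fragments.
#'
#' @param observations Data frame with columns `added_mass_per_bp` and
#'   `mean_ri`.
#' @return A `density_shift_model` with `slope`, `intercept`, `n`; supports
#'   [predict()] and [tidy()].
#' @export
fit_density_shift_model <- function(observations) {
  observations <- as_tibble(observations)
  if (length(unique(observations$added_mass_per_bp)) < 2) {
    abort("need >= 2 observations with distinct loadings",
          class = "densigrad_degenerate_input")
  }
  fit <- lm(mean_ri ~ added_mass_per_bp, data = observations)
  structure(
    list(slope = unname(coef(fit)[["added_mass_per_bp"]]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         n = nrow(observations)),
    class = "density_shift_model"
  )
}

#' @rdname fit_density_shift_model
#' @param object A `density_shift_model`.
#' @param loading Mass loadings (Da/bp) to predict mean RI for.
#' @param ... Ignored.
#' @export
predict.density_shift_model <- function(object, loading, ...) {
  object$intercept + object$slope * loading
}

#' @rdname fit_density_shift_model
#' @param x,... A `density_shift_model`; further arguments ignored.
#' @export
tidy.density_shift_model <- function(x, ...) {
  tibble(term = c("intercept", "slope"), estimate = c(x$intercept, x$slope))
}
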