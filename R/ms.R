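# Deoxycytidine and its DNMT/TET modification states, with monoisotopic
# neutral masses summed from atomic masses (C 12, H 1.0078250319,
# N 14.0030740052, O 15.9949146221). Positive-mode adducts carry the cation
# mass minus the electron: [M+H]+ = +1.00728 Da, [M+Na]+ = +22.98922 Da;
# the nominal "+1" / "+23" labels are shorthand for these.

ADDUCT_OFFSETS <- c(H = 1.00728, Na = 22.98922)

DC_FORMS <- c("dC", "5me-dC", "5hm-dC", "5f-dC", "5ca-dC")

#' Reference table of deoxycytidine-derived nucleosides
#'
#' Monoisotopic neutral masses of deoxycytidine (dC) and its four modified
#' forms: 5-methyl (5me-dC), 5-hydroxymethyl (5hm-dC), 5-formyl (5f-dC) and
#' 5-carboxy (5ca-dC) deoxycytidine.
#'
#' @return A tibble with columns `name`, `formula`, `neutral_mass` (Da).
#' @export
nucleoside_references <- function() {
  tibble(
    name = DC_FORMS,
    formula = c("C9H13N3O4", "C10H15N3O4", "C10H15N3O5", "C10H13N3O5",
                "C10H13N3O6"),
    neutral_mass = c(227.090606, 241.106256, 257.101171, 255.085521,
                     271.080435)
  )
}

#' Expected m/z of a nucleoside adduct
#'
#' @param ref One row of [nucleoside_references()] (or any list with
#'   `neutral_mass`), or a nucleoside name.
#' @param adduct `"H"` for `[M+H]+` or `"Na"` for `[M+Na]+`.
#' @return Expected m/z in Da: neutral mass plus the adduct offset.
#' @examples
#' expected_mz("5hm-dC", "H") # 258.1085
#' @export
expected_mz <- function(ref, adduct = c("H", "Na")) {
  adduct <- match.arg(adduct)
  if (is.character(ref)) {
    refs <- nucleoside_references()
    if (!ref %in% refs$name) {
      abort(paste0("unknown nucleoside: ", ref),
            class = "densigrad_parameter_error")
    }
    ref <- refs[refs$name == ref, ]
  }
  ref$neutral_mass + ADDUCT_OFFSETS[[adduct]]
}

#' Assign LC-MS peaks to nucleoside adducts
#'
#' Each observed peak is assigned to the (nucleoside, adduct) slot whose
#' expected m/z is nearest, provided the absolute mass difference is within
#' `tol` (default 0.025 Da, i.e. < 0.01% at these masses). Peaks with no
#' expected m/z within tolerance are left unassigned. Should two reference
#' m/z values be within `tol` of one peak, the nearest wins; exact ties go
#' to the earlier reference row, with a warning.
#'
#' @param peaks Data frame with columns `mz` (Da) and `intensity` (detector
#'   counts, >= 0).
#' @param refs Reference table, by default [nucleoside_references()].
#' @param tol Absolute mass tolerance in Da.
#' @return The peaks tibble with added columns `nucleoside`, `adduct`,
#'   `expected_mz`, `delta_mz` (NA for unassigned peaks).
#' @export
match_peaks <- function(peaks, refs = nucleoside_references(), tol = 0.025) {
  check_number(tol, "tol", lo = 1e-12)
  peaks <- as_tibble(peaks)
  if (nrow(peaks) == 0) {
    return(dplyr::mutate(peaks, nucleoside = character(0),
                         adduct = character(0), expected_mz = numeric(0),
                         delta_mz = numeric(0)))
  }
  if (any(peaks$mz <= 0) || any(peaks$intensity < 0)) {
    abort("peaks require mz > 0 and intensity >= 0",
          class = "densigrad_parameter_error")
  }
  slots <- tidyr::crossing(refs, adduct = names(ADDUCT_OFFSETS)) |>
    dplyr::mutate(expected_mz = .data$neutral_mass +
                    ADDUCT_OFFSETS[.data$adduct])
  # overlapping assignment windows are possible in principle; note them
  emz <- sort(slots$expected_mz)
  if (any(diff(emz) < 2 * tol)) {
    rlang::inform("some reference m/z windows overlap at this tolerance",
                  class = "densigrad_overlap_note")
  }
  assigned <- purrr::pmap_dfr(
    list(peaks$mz),
    function(mz) {
      d <- abs(slots$expected_mz - mz)
      i <- which.min(d)
      if (d[i] <= tol) {
        if (sum(d == d[i]) > 1) {
          warn("tied peak assignment broken by reference listing order")
        }
        tibble(nucleoside = slots$name[i], adduct = slots$adduct[i],
               expected_mz = slots$expected_mz[i], delta_mz = mz - slots$expected_mz[i])
      } else {
        tibble(nucleoside = NA_character_, adduct = NA_character_,
               expected_mz = NA_real_, delta_mz = NA_real_)
      }
    }
  )
  dplyr::bind_cols(peaks, assigned)
}

#' Percent composition over deoxycytidine forms
#'
#' Combines the H- and Na-adduct intensities per nucleoside (multiple peaks
#' landing in the same slot are summed) and expresses each of the five
#' dC-derived forms as a percentage of their total.
#'
#' @param assignments Output of [match_peaks()].
#' @return A tibble with one row per dC form: `nucleoside`, `intensity`,
#'   `percent` (NA for all if the total intensity is zero), plus attributes
#'   `unassigned_peaks` (count) and `total_intensity`.
#' @export
composition_percent <- function(assignments) {
  per_nuc <- assignments |>
    dplyr::filter(!is.na(.data$nucleoside)) |>
    dplyr::group_by(.data$nucleoside) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")
  out <- tibble(nucleoside = DC_FORMS) |>
    dplyr::left_join(per_nuc, by = "nucleoside") |>
    dplyr::mutate(intensity = dplyr::coalesce(.data$intensity, 0))
  total <- sum(out$intensity)
  out$percent <- if (total > 0) 100 * out$intensity / total else NA_real_
  if (total <= 0) {
    warn("total assigned intensity is zero; percentages undefined")
  }
  structure(out,
            unassigned_peaks = sum(is.na(assignments$nucleoside)),
            total_intensity = total)
}

#' Average composition tables across repeat measurements
#'
#' Averages at the per-percentage level: each repeat's composition is
#' normalised first, then percentages are averaged across repeats. (Whether
#' averaging is better done on raw intensities is measurement-design
#' dependent; this utility commits to per-percentage averaging.)
#'
#' @param compositions List of [composition_percent()] tibbles.
#' @return A tibble with `nucleoside`, `percent` (mean), `percent_sd`,
#'   `n_repeats`.
#' @export
average_compositions <- function(compositions) {
  dplyr::bind_rows(compositions, .id = "repeat_id") |>
    dplyr::group_by(.data$nucleoside) |>
    dplyr::summarise(percent_sd = sd(.data$percent),
                     percent = mean(.data$percent),
                     n_repeats = dplyr::n(), .groups = "drop") |>
    dplyr::select("nucleoside", "percent", "percent_sd", "n_repeats")
}
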