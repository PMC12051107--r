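# Readers and writers for the delimited-text formats the pipeline consumes:
# fraction tables, calibration pairs, BED3+, UCSC chrom.sizes, LC-MS peak
# tables and FASTA fragments. CSV vs TSV is autodetected from the file
# extension.

delim_for <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read and write gradient fraction tables
#'
#' Delimited text with a header row and columns `fraction_index`,
#' `refractive_index` (blank for unmeasured fractions) and
#' `dna_concentration`; `.csv` comma- and `.tsv`/`.txt` tab-delimited.
#'
#' @param path File path.
#' @param label Label for the resulting profile.
#' @return [read_fraction_table()]: a [gradient_profile()].
#' @export
read_fraction_table <- function(path, label = basename(path)) {
  x <- readr::read_delim(path, delim = delim_for(path),
                         show_col_types = FALSE)
  gradient_profile(x, label = label)
}

#' @rdname read_fraction_table
#' @param profile A [gradient_profile()].
#' @export
write_fraction_table <- function(profile, path) {
  out <- tibble(fraction_index = profile$fraction_index,
                refractive_index = profile$ri_measured,
                dna_concentration = profile$raw_concentration)
  readr::write_delim(out, path, delim = delim_for(path), na = "")
  invisible(path)
}

#' Read RI-density calibration pairs
#'
#' Two-column delimited text (`ri`, `density_g_per_ml`), header required.
#'
#' @param path File path.
#' @return A tibble suitable for [fit_ri_density_calibration()].
#' @export
read_calibration_pairs <- function(path) {
  readr::read_delim(path, delim = delim_for(path), show_col_types = FALSE)
}

#' Read and write BED interval files
#'
#' Tab-delimited BED3+ without header; `track`/`browser`/comment lines are
#' skipped. Only the first three columns (chrom, start, end) are
#' interpreted; a fourth column, when present, is kept as `name`.
#'
#' @param path BED file path.
#' @param genome Named numeric vector of chromosome lengths, or the path to
#'   a chrom.sizes file (passed through [read_chrom_sizes()]).
#' @return [read_bed()]: an [interval_set()].
#' @export
read_bed <- function(path, genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_chrom_sizes(genome)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(interval_set(tibble(chrom = character(0), start = numeric(0),
                               end = numeric(0)), genome))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  df <- tibble(
    chrom = vapply(parts, `[[`, "", 1),
    start = as.numeric(vapply(parts, `[[`, "", 2)),
    end = as.numeric(vapply(parts, `[[`, "", 3))
  )
  if (all(lengths(parts) >= 4)) {
    df$name <- vapply(parts, `[[`, "", 4)
  }
  interval_set(df, genome)
}

#' @rdname read_bed
#' @param x An [interval_set()].
#' @export
write_bed <- function(x, path) {
  df <- as.data.frame(x)[, intersect(c("chrom", "start", "end", "name"),
                                     names(x)), drop = FALSE]
  readr::write_tsv(as_tibble(df), path, col_names = FALSE)
  invisible(path)
}

#' Read a UCSC chrom.sizes file
#'
#' Two tab-separated columns: chromosome name, length.
#'
#' @param path File path.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       show_col_types = FALSE)
  setNames(as.numeric(x$length), x$chrom)
}

#' Read an LC-MS peak table
#'
#' Delimited text with columns `mz` and `intensity`.
#'
#' @param path File path.
#' @return A tibble for [match_peaks()].
#' @export
read_peak_table <- function(path) {
  readr::read_delim(path, delim = delim_for(path), show_col_types = FALSE)
}

#' Read DNA fragments from a FASTA file
#'
#' @param path FASTA file path.
#' @return A tibble with columns `id`, `sequence`, `length`.
#' @export
read_fragment_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble(id = names(seqs),
         sequence = unname(toupper(as.character(seqs))),
         length = Biostrings::width(seqs))
}

#' @rdname read_fragment_fasta
#' @param fragments Tibble with `id` and `sequence` columns.
#' @export
write_fragment_fasta <- function(fragments, path) {
  x <- Biostrings::DNAStringSet(setNames(fragments$sequence, fragments$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a mixture-fit report
#'
#' One row per fitted component (`mean_ri`, `sigma`, `amplitude`, and
#' `mean_density` when a calibration is supplied) plus the fit SSE, as
#' delimited text or JSON.
#'
#' @param fit A [fit_mixture()] result.
#' @param path Output path; `.json` selects the JSON variant.
#' @param calibration Optional [ri_calibration][fit_ri_density_calibration]
#'   used to add `mean_density`.
#' @export
write_fit_report <- function(fit, path, calibration = NULL) {
  comp <- dplyr::rename(fit$components, mean_ri = "mean")
  if (!is.null(calibration)) {
    comp$mean_density <- ri_to_density(calibration, comp$mean_ri)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(components = comp, sse = fit$sse, n_points = fit$n_points,
           converged = fit$converged),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    comp$sse <- fit$sse
    readr::write_delim(comp, path, delim = delim_for(path))
  }
  invisible(path)
}
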