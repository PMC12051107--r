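# Genomic intervals are tibbles with columns chrom, start, end (0-based,
# half-open, BED convention) and an attached genome: a named vector of
# chromosome lengths. "Overlap" always means >= 1 shared bp, matching
# `bedtools intersect -u` with an intersect distance of 0 bp.

#' Construct an interval set
#'
#' @param intervals Data frame with columns `chrom`, `start` (0-based,
#'   inclusive), `end` (exclusive) and optionally `name`/`score`.
#' @param genome Named numeric vector of chromosome lengths (bp), or a
#'   two-column data frame (`chrom`, `length`).
#' @return An `interval_set`: a tibble sorted by (chrom, start, end) with a
#'   `genome` attribute.
#' @examples
#' iv <- interval_set(
#'   data.frame(chrom = "chr1", start = c(100, 500), end = c(200, 800)),
#'   genome = c(chr1 = 1000)
#' )
#' @export
interval_set <- function(intervals, genome) {
  intervals <- as_tibble(intervals)
  if (is.data.frame(genome)) {
    genome <- setNames(as.numeric(genome[[2]]), as.character(genome[[1]]))
  }
  if (any(genome <= 0)) {
    abort("genome lengths must be positive",
          class = "densigrad_parameter_error")
  }
  if (nrow(intervals) > 0) {
    if (any(intervals$start < 0) || any(intervals$start >= intervals$end)) {
      abort("intervals require 0 <= start < end",
            class = "densigrad_parameter_error")
    }
    unknown <- setdiff(unique(intervals$chrom), names(genome))
    if (length(unknown) > 0) {
      abort(paste0("chromosome(s) not in genome: ",
                   paste(unknown, collapse = ", ")),
            class = "densigrad_context_error")
    }
    beyond <- intervals$end > genome[as.character(intervals$chrom)]
    if (any(beyond)) {
      abort("interval(s) extend beyond chromosome end",
            class = "densigrad_context_error")
    }
    intervals <- dplyr::arrange(intervals, .data$chrom, .data$start,
                                .data$end)
  }
  structure(intervals, class = c("interval_set", class(tibble())),
            genome = genome)
}

#' @rdname interval_set
#' @param x An `interval_set`.
#' @export
genome_of <- function(x) {
  attr(x, "genome")
}

reconstruct_set <- function(rows, template) {
  interval_set(as_tibble(as.data.frame(rows)), genome_of(template))
}

# Row indices of intervals in a overlapping >= 1 bp with any interval in b.
overlap_hit_rows <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(integer(0))
  hits <- logical(nrow(a))
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- which(a$chrom == chr)
    bi <- which(b$chrom == chr)
    # half-open [start, end) -> closed integer ranges [start, end - 1]
    ar <- IRanges::IRanges(start = a$start[ai] + 1L, end = a$end[ai])
    br <- IRanges::IRanges(start = b$start[bi] + 1L, end = b$end[bi])
    hit <- IRanges::overlapsAny(ar, br, minoverlap = 1L)
    hits[ai] <- hit
  }
  which(hits)
}

#' Intervals of `a` overlapping any interval of `b`
#'
#' Reports each interval of `a` (at most once) that shares at least one bp
#' with some interval of `b` — the semantics of `bedtools intersect -u`.
#'
#' @param a,b [interval_set()]s over the same genome.
#' @return An `interval_set` holding the overlapping subset of `a`.
#' @export
intersect_unique <- function(a, b) {
  reconstruct_set(a[overlap_hit_rows(a, b), , drop = FALSE], a)
}

#' Overlap summary between two interval sets
#'
#' Mutual overlap counts and percentages: how many `a` intervals touch `b`,
#' how many `b` intervals touch `a`, and the ratio of the two (the average
#' number of `a` peaks per overlapped `b` zone).
#'
#' @param a,b [interval_set()]s over the same genome.
#' @return A one-row tibble: `n_a`, `n_b`, `n_a_in_b`, `n_b_in_a`,
#'   `pct_a_in_b`, `pct_b_in_a`, `peaks_per_zone` (NA when `n_b_in_a` is 0).
#' @export
overlap_summary <- function(a, b) {
  n_a_in_b <- length(overlap_hit_rows(a, b))
  n_b_in_a <- length(overlap_hit_rows(b, a))
  tibble(
    n_a = nrow(a), n_b = nrow(b),
    n_a_in_b = n_a_in_b, n_b_in_a = n_b_in_a,
    pct_a_in_b = if (nrow(a) > 0) 100 * n_a_in_b / nrow(a) else 0,
    pct_b_in_a = if (nrow(b) > 0) 100 * n_b_in_a / nrow(b) else 0,
    peaks_per_zone = if (n_b_in_a > 0) n_a_in_b / n_b_in_a else NA_real_
  )
}

# Place lengths on [0, chrom_len) uniformly; rejection sampling against
# `occupied` (a list of start/end vectors) when no_overlap.
place_lengths <- function(lens, chrom_len, no_overlap, max_tries,
                          occupied_start = integer(0),
                          occupied_end = integer(0)) {
  starts <- integer(length(lens))
  os <- as.numeric(occupied_start); oe <- as.numeric(occupied_end)
  for (i in seq_along(lens)) {
    len <- lens[i]
    hi <- chrom_len - len
    if (hi < 0) {
      abort("interval longer than its chromosome",
            class = "densigrad_packing_error")
    }
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      s <- floor(runif(1, min = 0, max = hi + 1))
      if (s > hi) s <- hi  # guard the open upper edge
      if (!no_overlap || !any(s < oe & s + len > os)) {
        starts[i] <- s
        if (no_overlap) {
          os <- c(os, s); oe <- c(oe, s + len)
        }
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf("could not place an interval of length %d after %d tries",
                    len, max_tries),
            class = "densigrad_packing_error")
    }
  }
  starts
}

#' Randomise interval positions within each chromosome
#'
#' Each interval is relocated uniformly at random within its own chromosome,
#' preserving its length — the null model of `bedtools shuffle -chrom
#' -noOverlapping`. With `no_overlap`, placements are pairwise disjoint by
#' rejection sampling; intervals are placed in random order to reduce
#' packing bias.
#'
#' @param s An [interval_set()].
#' @param seed Integer seed; the result is a pure function of `s` and `seed`.
#' @param no_overlap Require placed intervals to be pairwise disjoint.
#' @param max_tries Rejection-sampling attempts per interval before a
#'   packing error naming the chromosome is raised.
#' @return A shuffled `interval_set` over the same genome.
#' @export
shuffle_per_chromosome <- function(s, seed, no_overlap = TRUE,
                                   max_tries = 10000) {
  genome <- genome_of(s)
  withr::local_seed(seed)
  pieces <- lapply(unique(s$chrom), function(chr) {
    rows <- s[s$chrom == chr, , drop = FALSE]
    lens <- rows$end - rows$start
    ord <- sample.int(length(lens))
    starts <- tryCatch(
      place_lengths(lens[ord], genome[[chr]], no_overlap, max_tries),
      densigrad_packing_error = function(e) {
        abort(sprintf("packing failed on chromosome %s", chr),
              class = "densigrad_packing_error")
      }
    )
    tibble(chrom = chr, start = starts, end = starts + lens[ord])
  })
  interval_set(dplyr::bind_rows(pieces), genome)
}

#' Empirical shuffle null for an overlap count
#'
#' Shuffles `a` per chromosome `n_shuffles` times and records the number of
#' shuffled `a` intervals overlapping `b`, giving an empirical null for the
#' observed count and the fold enrichment observed / mean(null).
#'
#' @param a,b [interval_set()]s over the same genome.
#' @param n_shuffles Number of shuffles.
#' @param seed Integer seed (each shuffle uses a distinct derived seed).
#' @param no_overlap,max_tries Passed to [shuffle_per_chromosome()].
#' @return A `shuffle_null` list: `observed`, `null_counts`
#'   (length `n_shuffles`), `null_mean`, `fold_change` (NA when the null
#'   mean is 0). Supports [glance()] and [autoplot()].
#' @export
shuffle_null_summary <- function(a, b, n_shuffles, seed, no_overlap = TRUE,
                                 max_tries = 10000) {
  observed <- length(overlap_hit_rows(a, b))
  withr::local_seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_shuffles)
  null_counts <- purrr::map_int(sub_seeds, function(s2) {
    shuffled <- shuffle_per_chromosome(a, seed = s2, no_overlap = no_overlap,
                                       max_tries = max_tries)
    length(overlap_hit_rows(shuffled, b))
  })
  null_mean <- mean(null_counts)
  structure(
    list(observed = observed, null_counts = null_counts,
         null_mean = null_mean,
         fold_change = if (null_mean > 0) observed / null_mean else NA_real_,
         n_shuffles = n_shuffles, seed = seed),
    class = "shuffle_null"
  )
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat(sprintf(
    "<shuffle_null> observed = %d, null mean = %.2f over %d shuffles, fold = %s\n",
    x$observed, x$null_mean, x$n_shuffles,
    if (is.na(x$fold_change)) "undefined" else sprintf("%.2f", x$fold_change)))
  invisible(x)
}

#' @rdname shuffle_null_summary
#' @param x,... A `shuffle_null`; further arguments ignored.
#' @export
glance.shuffle_null <- function(x, ...) {
  tibble(observed = x$observed, null_mean = x$null_mean,
         null_sd = sd(x$null_counts), fold_change = x$fold_change,
         n_shuffles = x$n_shuffles)
}
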