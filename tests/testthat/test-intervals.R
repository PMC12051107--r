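toy_set <- function(df, genome = c(chr1 = 1000)) {
  interval_set(df, genome)
}

test_that("intersect_unique implements >= 1 bp overlap on half-open intervals", {
  a <- toy_set(data.frame(chrom = "chr1", start = 100, end = 200))
  b1 <- toy_set(data.frame(chrom = "chr1", start = 199, end = 300))
  b2 <- toy_set(data.frame(chrom = "chr1", start = 200, end = 300))
  expect_equal(nrow(intersect_unique(a, b1)), 1)   # 1 bp shared
  expect_equal(nrow(intersect_unique(a, b2)), 0)   # half-open abutment
})

test_that("intersect and overlap counts equal the brute-force oracle on random sets", {
  genome <- toy_genome()
  for (s in 1:8) {
    sets <- simulate_peak_sets(genome, n_a = 200, n_b = 120,
                               overlap_fraction = runif(1), seed = s)
    hits <- brute_force_hits(sets$a, sets$b)
    got <- intersect_unique(sets$a, sets$b)
    key <- function(df) sort(paste(df$chrom, df$start, df$end))
    expect_equal(key(got), key(as.data.frame(sets$a)[hits, ]))
    summ <- overlap_summary(sets$a, sets$b)
    expect_equal(summ$n_a_in_b, length(hits))
    expect_equal(summ$n_b_in_a, length(brute_force_hits(sets$b, sets$a)))
  }
})

test_that("overlap_summary handles self-overlap, disjoint and empty sets", {
  sets <- simulate_peak_sets(n_a = 100, n_b = 50, overlap_fraction = 0,
                             seed = 2)
  self <- overlap_summary(sets$a, sets$a)
  expect_equal(self$pct_a_in_b, 100)
  expect_equal(self$pct_b_in_a, 100)
  expect_equal(self$peaks_per_zone, 1)

  disj <- overlap_summary(sets$a, sets$b)
  expect_equal(disj$n_a_in_b, 0)
  expect_true(is.na(disj$peaks_per_zone))

  empty <- toy_set(data.frame(chrom = character(0), start = numeric(0),
                              end = numeric(0)))
  e <- overlap_summary(empty, empty)
  expect_equal(e$pct_a_in_b, 0)
})

test_that("intersect is idempotent on self and monotone in b", {
  sets <- simulate_peak_sets(n_a = 150, n_b = 80, overlap_fraction = 0.5,
                             seed = 3)
  self <- intersect_unique(sets$a, sets$a)
  expect_equal(nrow(self), nrow(sets$a))
  small <- intersect_unique(sets$a, sets$b)
  bigger_b <- interval_set(
    rbind(as.data.frame(sets$b)[, c("chrom", "start", "end")],
          data.frame(chrom = "chrT3", start = 0, end = 2e5)),
    genome_of(sets$b))
  big <- intersect_unique(sets$a, bigger_b)
  expect_gte(nrow(big), nrow(small))
})

test_that("per-chromosome shuffle conserves counts and lengths and is seeded", {
  sets <- simulate_peak_sets(n_a = 120, n_b = 10, overlap_fraction = 0.5,
                             seed = 4)
  sh1 <- shuffle_per_chromosome(sets$a, seed = 99)
  sh2 <- shuffle_per_chromosome(sets$a, seed = 99)
  expect_identical(as.data.frame(sh1), as.data.frame(sh2))
  sh3 <- shuffle_per_chromosome(sets$a, seed = 100)
  expect_false(identical(as.data.frame(sh1), as.data.frame(sh3)))

  for (chr in unique(sets$a$chrom)) {
    orig <- sets$a[sets$a$chrom == chr, ]
    shuf <- sh1[sh1$chrom == chr, ]
    expect_equal(nrow(shuf), nrow(orig))
    expect_equal(sort(shuf$end - shuf$start), sort(orig$end - orig$start))
    expect_true(all(shuf$start >= 0))
    expect_true(all(shuf$end <= genome_of(sets$a)[[chr]]))
  }
  # no_overlap placements are pairwise disjoint
  for (chr in unique(sh1$chrom)) {
    x <- sh1[sh1$chrom == chr, ]
    x <- x[order(x$start), ]
    if (nrow(x) > 1) expect_true(all(x$start[-1] >= x$end[-nrow(x)]))
  }
})

test_that("shuffling intervals that tile a tiny chromosome permutes the tiling", {
  tiling <- interval_set(
    data.frame(chrom = "mini", start = c(0, 2, 4, 6, 8),
               end = c(2, 4, 6, 8, 10)),
    c(mini = 10))
  res <- tryCatch(shuffle_per_chromosome(tiling, seed = 5, max_tries = 5000),
                  densigrad_packing_error = function(e) e)
  if (!inherits(res, "error")) {
    expect_equal(sort(res$start), c(0, 2, 4, 6, 8))
  } else {
    expect_s3_class(res, "densigrad_packing_error")
  }
})

test_that("shuffle null reproduces analytic expectations and detects enrichment", {
  # b covering a whole one-chromosome genome: every shuffle hits
  genome <- c(solo = 1e5)
  a <- interval_set(data.frame(chrom = "solo",
                               start = seq(0, 9e4, by = 1e4), end = seq(0, 9e4, by = 1e4) + 500),
                    genome)
  b_all <- interval_set(data.frame(chrom = "solo", start = 0, end = 1e5),
                        genome)
  null_all <- shuffle_null_summary(a, b_all, n_shuffles = 5, seed = 1)
  expect_true(all(null_all$null_counts == nrow(a)))
  expect_equal(null_all$fold_change, 1)

  # empty b: null all zeros, fold change undefined
  b_none <- interval_set(data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0)), genome)
  null_none <- shuffle_null_summary(a, b_none, n_shuffles = 5, seed = 1)
  expect_true(all(null_none$null_counts == 0))
  expect_true(is.na(null_none$fold_change))

  # constructed enrichment: observed far above the shuffle null
  sets <- simulate_peak_sets(genome = c(big = 1e6), n_a = 100, n_b = 20,
                             len_range = c(100, 300),
                             overlap_fraction = 0.9, seed = 6)
  null_enr <- shuffle_null_summary(sets$a, sets$b, n_shuffles = 30, seed = 7)
  expect_equal(null_enr$observed, 90)
  expect_gte(null_enr$fold_change, 10)
})

test_that("expected shuffled overlap approaches the analytic coverage rate", {
  # single-bp a intervals against b covering fraction p of one chromosome:
  # P(hit) = p for a uniformly placed bp, so E[count] = n_a * p
  genome <- c(solo = 1e5)
  p <- 0.2
  b <- interval_set(data.frame(chrom = "solo", start = 0, end = p * 1e5),
                    genome)
  a <- interval_set(data.frame(chrom = "solo",
                               start = seq(5e4, 9e4, length.out = 50),
                               end = seq(5e4, 9e4, length.out = 50) + 1),
                    genome)
  null <- shuffle_null_summary(a, b, n_shuffles = 200, seed = 8)
  se <- sd(null$null_counts) / sqrt(length(null$null_counts))
  expect_lt(abs(mean(null$null_counts) - 50 * p), 3 * max(se, 1e-9))
})

test_that("interval_set validates coordinates and genome context", {
  expect_error(toy_set(data.frame(chrom = "chr1", start = 10, end = 10)),
               class = "densigrad_parameter_error")
  expect_error(toy_set(data.frame(chrom = "chrX", start = 0, end = 10)),
               class = "densigrad_context_error")
  expect_error(toy_set(data.frame(chrom = "chr1", start = 0, end = 2000)),
               class = "densigrad_context_error")
})
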