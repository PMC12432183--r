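test_that("binning respects half-open bin boundaries and conserves reads", {
  gl <- make_genome(1, 20000, 10000)
  reads <- manual_reads("chr1", c(0, 9999, 10000))
  track <- count_reads_in_bins(reads, gl)
  expect_equal(track$counts, c(2, 1))
  expect_equal(track$library_size, 3)

  empty <- count_reads_in_bins(manual_reads(character(0), numeric(0)), gl)
  expect_equal(empty$counts, c(0, 0))
  expect_equal(empty$library_size, 0)

  lib <- small_library(n_reads = 5000)
  expect_equal(sum(count_reads_in_bins(lib, small_genome())$counts), nrow(lib))
})

test_that("vectorized binning matches the naive per-read oracle", {
  gl <- make_genome(3, c(120000, 95000, 50000), bin_size = 7000)  # <= 50 bins
  set.seed(42)
  n <- 1000
  ci <- sample(3, n, replace = TRUE)
  reads <- manual_reads(gl$chrom_names[ci],
                        floor(runif(n) * gl$chrom_lengths[ci]))
  track <- count_reads_in_bins(reads, gl)
  expect_equal(track$counts, oracle_bin_counts(reads, gl), tolerance = 1e-12)
})

test_that("unknown chromosomes are rejected, or skipped and counted when lenient", {
  gl <- make_genome(1, 50000, 10000)
  reads <- manual_reads(c("chr1", "chrMT"), c(100, 200))
  expect_error(count_reads_in_bins(reads, gl), "chrMT")
  expect_message(track <- count_reads_in_bins(reads, gl, lenient = TRUE), "skipped 1")
  expect_equal(track$library_size, 1)
  expect_equal(track$n_skipped, 1L)
})

test_that("rebinned fine counts aggregate exactly to coarse counts", {
  gl <- small_genome(bin_size = 10000)
  reads <- small_library(gl, n_reads = 20000)
  coarse <- count_reads_in_bins(reads, gl)
  fine <- rebin_reads(reads, gl, 1000)
  expect_equal(length(fine$counts), 10 * length(coarse$counts))
  agg <- tapply(fine$counts, rep(seq_along(coarse$counts), each = 10), sum)
  expect_equal(as.numeric(agg), coarse$counts, tolerance = 0)

  # 1-kb boundary membership
  r2 <- manual_reads(c("chr1", "chr1"), c(0, 999))
  expect_equal(rebin_reads(r2, gl, 1000)$counts[1], 2)

  expect_equal(sum(rebin_reads(manual_reads(character(0), numeric(0)), gl, 1000)$counts), 0)
})

test_that("library normalization scales, is idempotent, and rejects empty libraries", {
  tr <- manual_normalized_track(c(2, 0, 4))
  tr$normalized <- FALSE
  tr$library_size <- 6
  n1 <- normalize_library(tr, norm_target = 3)
  expect_equal(n1$counts, c(1, 0, 2))
  expect_true(n1$normalized)
  expect_identical(normalize_library(n1, norm_target = 3), n1)
  # identity when target equals library size
  tr2 <- tr
  expect_equal(normalize_library(tr2, norm_target = 6)$counts, c(2, 0, 4))
  tr$counts <- rep(0, 3); tr$library_size <- 0
  expect_error(normalize_library(tr, 3), "empty")
})

test_that("sigma equals normalized counts over the population SD", {
  tr <- manual_normalized_track(c(0, 0, 0, 4))
  st <- compute_sigma(tr)
  expect_equal(st$sd_used, sqrt(3))
  expect_equal(st$sigma, c(0, 0, 0, 4 / sqrt(3)))
  expect_equal(st$sigma[4], 2.309, tolerance = 1e-3)
})

test_that("sigma is invariant to a common rescaling of the track", {
  vals <- c(1, 3, 0, 8, 2, 2)
  s1 <- compute_sigma(manual_normalized_track(vals))$sigma
  s2 <- compute_sigma(manual_normalized_track(vals * 7.3))$sigma
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("constant tracks are a degenerate-track error", {
  expect_error(compute_sigma(manual_normalized_track(rep(5, 10))), "degenerate")
  tr <- manual_normalized_track(c(1, 2, 3))
  tr$normalized <- FALSE
  expect_error(compute_sigma(tr), "normalized")
})

test_that("trimmed SD scope excludes peak bins from the divisor but divides all bins", {
  set.seed(1)
  vals <- c(rpois(500, 20), 500, 700)  # noisy background plus two peak bins
  tr <- manual_normalized_track(vals)
  all_scope <- compute_sigma(tr, sd_scope = "all_bins")
  trimmed <- compute_sigma(tr, sd_scope = "trimmed")
  expect_lt(trimmed$sd_used, all_scope$sd_used)
  expect_lt(trimmed$sd_used, 2 * sqrt(20))  # near the background dispersion
  expect_equal(length(trimmed$sigma), length(vals))
  expect_equal(trimmed$sigma, vals / trimmed$sd_used)
  # an exactly flat background trims to a constant scope -> degenerate error
  expect_error(compute_sigma(manual_normalized_track(c(rep(2, 20), 100)),
                             sd_scope = "trimmed"),
               "degenerate")
})

test_that("tracks export to bedGraph and TSV with half-open coordinates", {
  gl <- make_genome(1, 25000, 10000)
  reads <- manual_reads(rep("chr1", 4), c(0, 1, 10001, 24000))
  track <- count_reads_in_bins(reads, gl)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_track_tsv(track, tsv)
  tab <- read.delim(tsv)
  expect_equal(tab$start, c(0, 10000, 20000))
  expect_equal(tab$end, c(10000, 20000, 25000))  # partial last bin
  expect_equal(tab$count, c(2, 1, 1))
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  st <- compute_sigma(normalize_library(track, 4))
  write_track_bedgraph(st, bg)
  gr <- rtracklayer::import(bg, format = "bedGraph")
  expect_equal(GenomicRanges::start(gr) - 1, c(0, 10000, 20000))
  expect_equal(gr$score, st$sigma, tolerance = 1e-6)
})
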