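test_that("peak calling follows the run-merge rule (hand traces)", {
  # all sub-threshold -> empty set
  empty <- call_peaks(manual_sigma_track(rep(0, 6)), threshold = 3)
  expect_equal(nrow(empty), 0)

  pk <- call_peaks(manual_sigma_track(c(0, 0, 5, 7, 6, 0)), threshold = 3,
                   merge_gap = 0)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$peak_sigma, 7)
  expect_equal(pk$peak_bin, 3)          # 0-based index of the max bin
  expect_equal(pk$summit, 35000)        # midpoint of bin [30000, 40000)
  expect_equal(pk$span, 3)

  # gap-merge boundary: two runs separated by two sub-threshold bins
  two <- call_peaks(manual_sigma_track(c(5, 0, 0, 5)), threshold = 3, merge_gap = 1)
  expect_equal(nrow(two), 2)
  one <- call_peaks(manual_sigma_track(c(5, 0, 0, 5)), threshold = 3, merge_gap = 2)
  expect_equal(nrow(one), 1)
  expect_equal(one$span, 4)

  # ties on the maximum resolve to the leftmost bin
  tie <- call_peaks(manual_sigma_track(c(0, 6, 6, 0)), threshold = 3)
  expect_equal(tie$peak_bin, 1)
})

test_that("raising the threshold never increases the peak count on separated unimodal signal", {
  # origin-style signal: well-separated single-summit bumps over a low floor;
  # within one bump the above-threshold bins stay contiguous, so higher
  # thresholds can only drop bumps, never split them
  gl <- small_genome()
  st <- sigma_track(small_library(gl, n_reads = 2e5), gl)
  counts <- vapply(c(2, 4, 6, 9, 14), function(th) {
    nrow(call_peaks(st, threshold = th))
  }, numeric(1))
  expect_gt(counts[1], 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("ranking selects by decreasing sigma with summit exclusion", {
  peaks <- data.frame(
    chrom = c("chrT", "chrT", "chrT"),
    peak_bin = c(2, 10, 20), summit = c(25000, 105000, 205000),
    peak_sigma = c(9, 7, 5), span = 1, rank = NA_integer_)
  class(peaks) <- c("origin_set", "data.frame")
  top2 <- rank_and_select(peaks, n_top = 2, min_separation = 30000)
  expect_equal(top2$peak_sigma, c(9, 7))
  expect_equal(top2$rank, c(1, 2))

  # a lower peak within min_separation of a selected summit is skipped
  near <- peaks
  near$summit <- c(25000, 40000, 205000)
  near$peak_sigma <- c(9, 8, 5)
  expect_warning(sel <- rank_and_select(near, n_top = 3, min_separation = 30000),
                 "2 of the requested 3")
  expect_equal(sel$peak_sigma, c(9, 5))

  # exhaustion: fewer peaks than requested returns all, with a warning
  expect_warning(all3 <- rank_and_select(peaks, n_top = 1000), "3 of the requested 1000")
  expect_equal(nrow(all3), 3)
  expect_equal(all3$rank, 1:3)
})

test_that("selection is deterministic and invariant to input permutation", {
  gl <- small_genome()
  st <- sigma_track(small_library(gl, n_reads = 1e5), gl)
  peaks <- call_peaks(st)
  sel1 <- rank_and_select(peaks, n_top = 10)
  perm <- peaks[sample(nrow(peaks)), ]
  class(perm) <- c("origin_set", "data.frame")
  sel2 <- rank_and_select(perm, n_top = 10, chrom_order = gl$chrom_names)
  rownames(sel2) <- NULL
  expect_equal(sel1$summit, sel2$summit)
  expect_equal(sel1$peak_sigma, sel2$peak_sigma)
})

test_that("truth matching is one-to-one nearest within tolerance", {
  truth <- data.frame(chrom = "chrT",
                      position = c(10000, 50000, 90000, 130000),
                      efficiency = 1)
  class(truth) <- c("origin_catalog", "data.frame")
  calls_df <- function(summit) {
    n <- length(summit)
    d <- data.frame(chrom = rep("chrT", n), peak_bin = rep(0, n),
                    summit = summit, peak_sigma = rep(5, n), span = rep(1, n),
                    rank = rep(NA_integer_, n))
    class(d) <- c("origin_set", "data.frame")
    d
  }
  # identical calls -> perfect recall and precision
  m <- match_to_truth(calls_df(truth$position), truth, tolerance = 0)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  # empty calls -> recall 0, precision reported 0 with flag
  m0 <- match_to_truth(calls_df(numeric(0)), truth, tolerance = 1000)
  expect_equal(m0$recall, 0)
  expect_equal(m0$precision, 0)
  expect_false(m0$precision_defined)
  # 2 of 4 truth origins called within tolerance -> recall 0.5 (oracle:
  # exhaustive matching on this instance pairs 11000->10000, 52000->50000)
  m2 <- match_to_truth(calls_df(c(11000, 52000)), truth, tolerance = 5000)
  expect_equal(m2$recall, 0.5)
  expect_equal(m2$precision, 1)
  # one call cannot match two truth origins
  m3 <- match_to_truth(calls_df(c(30000)), truth, tolerance = 20000)
  expect_equal(m3$n_matched, 1L)
})

test_that("origin recovery on simulated data stays high under subsetting of depth", {
  gl <- small_genome()
  cat0 <- small_catalog(gl)
  reads <- small_library(gl, cat0, n_reads = 4e5, seed = 12)
  sel <- rank_and_select(call_peaks(sigma_track(reads, gl)), n_top = nrow(cat0))
  m <- match_to_truth(sel, cat0, tolerance = 10000)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("origin sets export as BED6 with rank names and sigma scores", {
  gl <- small_genome()
  sel <- rank_and_select(call_peaks(sigma_track(small_library(gl), gl)), n_top = 5)
  path <- withr::local_tempfile(fileext = ".bed")
  write_origins_bed(sel, path)
  gr <- rtracklayer::import(path, format = "BED")
  expect_equal(length(gr), 5)
  expect_equal(gr$name, as.character(1:5))
  expect_equal(gr$score, round(sel$peak_sigma))
})
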