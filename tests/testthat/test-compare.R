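test_that("meta-profile of summit-anchored reads concentrates at offset zero", {
  gl <- make_genome(1, 1e6, 10000)
  origins <- data.frame(chrom = "chr1", peak_bin = 20, summit = 205000,
                        peak_sigma = 10, span = 1, rank = 1L)
  class(origins) <- c("origin_set", "data.frame")
  # delta input: every read exactly at the summit, plus a thin uniform floor
  # elsewhere so the SD is defined
  reads <- manual_reads(rep("chr1", 120),
                        c(rep(205000, 100), seq(1500, 975000, length.out = 20)))
  prof <- meta_profile(reads, origins, gl, half_window = 5000, resolution = 1000)
  expect_equal(prof$offset, seq(-5000, 5000, 1000))
  central <- prof$mean_sigma[prof$offset == 0]
  expect_gt(central, 50 * max(prof$mean_sigma[prof$offset != 0]))
})

test_that("single-origin profile equals the direct sigma window (oracle)", {
  gl <- make_genome(1, 200000, 10000)
  origins <- data.frame(chrom = "chr1", peak_bin = 10, summit = 105500,
                        peak_sigma = 1, span = 1, rank = 1L)
  class(origins) <- c("origin_set", "data.frame")
  set.seed(11)
  reads <- manual_reads(rep("chr1", 20), floor(runif(20, 95000, 115000)))
  prof <- meta_profile(reads, origins, gl, half_window = 3000, resolution = 1000)
  # oracle: extract the sigma values of the bins containing summit + offset
  st <- sigma_track(reads, gl, bin_size = 1000)
  expected <- st$sigma[floor((105500 + seq(-3000, 3000, 1000)) / 1000) + 1]
  expect_equal(prof$mean_sigma, expected, tolerance = 1e-12)
  expect_equal(prof$n, rep(1L, 7), ignore_attr = TRUE)
})

test_that("simulator profiles are symmetric and windows are clipped at chromosome ends", {
  gl <- make_genome(1, 2e7, 10000)
  cat0 <- place_origins(gl, 8, min_spacing = 1e6, seed = 21)
  reads <- simulate_eduseq_reads(gl, cat0, treatment_schedule(), 3e5,
                                 bg_fraction = 0.2, seed = 22)
  sel <- rank_and_select(call_peaks(sigma_track(reads, gl)), n_top = 8)
  prof <- meta_profile(reads, sel, gl, half_window = 30000, resolution = 1000,
                       sd_scope = "trimmed")
  left <- prof$mean_sigma[prof$offset < 0]
  right <- rev(prof$mean_sigma[prof$offset > 0])
  expect_gt(cor(left, right), 0.9)

  # an origin 10 kb from the chromosome start contributes only valid offsets
  edge <- data.frame(chrom = "chr1", peak_bin = 1, summit = 10000,
                     peak_sigma = 1, span = 1, rank = 1L)
  class(edge) <- c("origin_set", "data.frame")
  prof_edge <- meta_profile(reads, edge, gl, half_window = 30000, resolution = 1000)
  expect_equal(prof_edge$n[prof_edge$offset < -10000], rep(0L, 20), ignore_attr = TRUE)
  expect_true(all(is.nan(prof_edge$mean_sigma[prof_edge$offset < -10000])))
  expect_error(meta_profile(reads, sel[0, ], gl), "empty")
  expect_error(meta_profile(reads, sel, gl, half_window = 5000, resolution = 3000),
               "divide")
})

test_that("average origin activity is the central-window mean", {
  prof <- data.frame(offset = seq(-2000, 2000, 1000),
                     mean_sigma = c(1, 0, 10, 0, 1), n = 5L)
  class(prof) <- c("meta_profile", "data.frame")
  attr(prof, "half_window") <- 2000
  expect_equal(average_origin_activity(prof, central_window = 1000), 10 / 3)
  expect_equal(average_origin_activity(prof, central_window = 0), 10)
  flat <- prof; flat$mean_sigma <- rep(4.2, 5)
  expect_equal(average_origin_activity(flat, central_window = 2000), 4.2)
  expect_error(average_origin_activity(prof, central_window = 3000), "half_window")
})

test_that("percent reduction follows 100*(1 - treated/control)", {
  expect_equal(percent_reduction(20, 20), 0)
  expect_equal(percent_reduction(0, 20), 100)
  expect_equal(percent_reduction(3, 20), 85)
  expect_equal(percent_reduction(30, 20), -50)  # enrichment, not clamped
  expect_error(percent_reduction(1, 0), "positive")
  # invariance to common depth rescaling
  expect_equal(percent_reduction(3 * 7, 20 * 7), percent_reduction(3, 20))
})

test_that("per-origin signal takes the maximum sigma within the window", {
  st <- manual_sigma_track(c(0, 4, 7, 0, 0, 2))
  origins <- data.frame(chrom = "chrT", peak_bin = c(1, 5),
                        summit = c(15000, 55000), peak_sigma = NA, span = 1,
                        rank = 1:2)
  class(origins) <- c("origin_set", "data.frame")
  expect_equal(per_origin_signal(st, origins, window = 10000), c(7, 2))
  # all origins on an empty track -> zeros
  zero <- manual_sigma_track(rep(0, 6))
  expect_equal(per_origin_signal(zero, origins, window = 10000), c(0, 0))
  expect_error(per_origin_signal(st, origins, window = 500), "at least one bin")
})

test_that("condition comparison matches the closed-form OLS oracle", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 5, 8)
  cmp <- compare_conditions(x, y)
  orc <- oracle_ols(x, y)
  expect_equal(cmp$slope, 2)
  expect_equal(cmp$intercept, -0.5)
  expect_equal(cmp$r_squared, orc$r_squared, tolerance = 1e-12)
  expect_equal(cmp$r_squared, 100 / 105, tolerance = 1e-12)
  expect_equal(cmp$t_statistic, orc$t_statistic, tolerance = 1e-10)
  expect_equal(cmp$p_value, orc$p_value, tolerance = 1e-10)
  expect_equal(cmp$df, 2L)

  # y identical to x -> slope 1, R^2 1
  ident <- compare_conditions(1:10, 1:10)
  expect_equal(ident$slope, 1)
  expect_equal(ident$r_squared, 1)
  # constant y -> slope 0, R^2 0
  flat <- compare_conditions(1:10, rep(3, 10))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_equal(flat$percent_reduction, 100 * (1 - 3 / 5.5))

  expect_error(compare_conditions(1:3, 1:4), "equal length")
  expect_error(compare_conditions(c(2, 2, 2), 1:3), "degenerate")
  expect_error(compare_conditions(1:2, 1:2), "at least 3")
})

test_that("OLS matches the brute-force normal-equations solve on random inputs", {
  set.seed(33)
  for (i in 1:5) {
    n <- sample(5:20, 1)
    x <- rnorm(n, sd = 3)
    y <- 2 * x + rnorm(n)
    cmp <- compare_conditions(x, y)
    orc <- oracle_ols(x, y)
    expect_equal(cmp$slope, orc$slope, tolerance = 1e-10)
    expect_equal(cmp$intercept, orc$intercept, tolerance = 1e-10)
    expect_equal(cmp$r_squared, orc$r_squared, tolerance = 1e-10)
    expect_equal(cmp$t_statistic, orc$t_statistic, tolerance = 1e-10)
  }
})
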