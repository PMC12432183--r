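# Shared fixture builders; every fixture is generated in code under a fixed
# seed so suites are reproducible and the repository stays text-only.

small_genome <- function(bin_size = 10000) {
  make_genome(2, c(5e7, 3e7), bin_size = bin_size)
}

small_catalog <- function(genome = small_genome(), n = 20, seed = 1,
                          min_spacing = 1e6) {
  place_origins(genome, n, min_spacing = min_spacing, seed = seed)
}

small_library <- function(genome = small_genome(), catalog = small_catalog(genome),
                          schedule = treatment_schedule(), n_reads = 2e5,
                          bg_fraction = 0.2, seed = 2) {
  simulate_eduseq_reads(genome, catalog, schedule, n_reads,
                        bg_fraction = bg_fraction, seed = seed)
}

# Hand-built read set on one small chromosome.
manual_reads <- function(chrom, start) {
  r <- data.frame(chrom = chrom, start = start,
                  strand = rep("+", length(start)), stringsAsFactors = FALSE)
  class(r) <- c("read_set", "data.frame")
  r
}

# A normalized track with prescribed per-bin values (for sigma arithmetic).
manual_normalized_track <- function(values, bin_size = 10000) {
  layout <- genome_layout(c(chrT = length(values) * bin_size), bin_size = bin_size)
  structure(
    list(layout = layout, counts = as.numeric(values), library_size = sum(values),
         normalized = TRUE, norm_target = sum(values), n_skipped = 0L),
    class = "binned_track"
  )
}

# A sigma track with prescribed per-bin sigma values (for peak-call traces).
manual_sigma_track <- function(sigma, bin_size = 10000) {
  layout <- genome_layout(c(chrT = length(sigma) * bin_size), bin_size = bin_size)
  structure(
    list(layout = layout, sigma = as.numeric(sigma), sd_used = 1,
         sd_scope = "all_bins", source_library_size = NA_real_),
    class = "sigma_track"
  )
}

# Brute-force per-read binning oracle: naive loop, no tabulate.
oracle_bin_counts <- function(reads, layout) {
  counts <- numeric(total_bins(layout))
  for (i in seq_len(nrow(reads))) {
    ci <- match(reads$chrom[i], layout$chrom_names)
    k <- floor(reads$start[i] / layout$bin_size)
    counts[layout$bin_offset[ci] + k + 1] <- counts[layout$bin_offset[ci] + k + 1] + 1
  }
  counts
}

# Closed-form OLS oracle via normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  t_stat <- slope / se
  list(slope = slope, intercept = intercept, r_squared = r2,
       t_statistic = t_stat, p_value = 2 * pt(-abs(t_stat), n - 2))
}
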