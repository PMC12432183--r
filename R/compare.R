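#' Meta-origin activity profile
#'
#' Recomputes sigma from the reads at a fine resolution (1 kb by default) and
#' averages it, offset by offset, across a fixed origin set: for each offset
#' `o` in `-half_window .. +half_window` (steps of `resolution`) the profile
#' value is the mean sigma of the bins containing `summit + o`, with equal
#' weight per origin. Origins whose window runs off a chromosome end contribute
#' only their valid offsets. Sigma is recomputed at the profile resolution with
#' its own SD divisor, never interpolated from a coarser track.
#'
#' @param reads A `read_set`.
#' @param origins An `origin_set` (uses `chrom`, `summit`).
#' @param layout A [genome_layout()] for the fine-resolution recount.
#' @param half_window Window half-width in bases (default 50 kb).
#' @param resolution Profile step in bases (default 1 kb); must divide
#'   `half_window`.
#' @param sd_scope,mad_k,norm_target Passed to the sigma computation; see
#'   [compute_sigma()]. Treatment-comparison pipelines typically use
#'   `sd_scope = "trimmed"` so the divisor estimates background dispersion
#'   rather than being dominated by the peaks under comparison.
#' @return A `meta_profile` data frame (`offset`, `mean_sigma`, `n`) with
#'   attributes `n_origins`, `half_window`, `resolution`, `sd_scope`,
#'   `sd_used`.
#' @export
meta_profile <- function(reads, origins, layout, half_window = 50000,
                         resolution = 1000, sd_scope = "all_bins", mad_k = 5,
                         norm_target = 1e7) {
  if (nrow(origins) == 0) stop("origin set is empty", call. = FALSE)
  if (half_window %% resolution != 0) {
    stop("resolution must divide half_window", call. = FALSE)
  }
  st <- sigma_track(reads, layout, bin_size = resolution,
                    norm_target = norm_target, sd_scope = sd_scope,
                    mad_k = mad_k)
  offsets <- seq(-half_window, half_window, by = resolution)
  chrom_idx <- match(origins$chrom, layout$chrom_names)
  if (anyNA(chrom_idx)) stop("origin chromosome not in layout", call. = FALSE)
  lens <- layout$chrom_lengths[chrom_idx]
  # origins x offsets matrix of genomic positions
  pos <- outer(origins$summit, offsets, `+`)
  valid <- pos >= 0 & pos < matrix(lens, nrow(origins), length(offsets))
  fine <- st$layout
  val <- matrix(NA_real_, nrow(origins), length(offsets))
  if (any(valid)) {
    rows <- row(pos)[valid]
    idx <- flat_bin_index(fine, origins$chrom[rows], pos[valid])
    val[valid] <- st$sigma[idx]
  }
  mean_sigma <- colMeans(val, na.rm = TRUE)
  n <- colSums(valid)
  prof <- data.frame(offset = offsets, mean_sigma = mean_sigma, n = n)
  class(prof) <- c("meta_profile", "data.frame")
  attr(prof, "n_origins") <- nrow(origins)
  attr(prof, "half_window") <- half_window
  attr(prof, "resolution") <- resolution
  attr(prof, "sd_scope") <- sd_scope
  attr(prof, "sd_used") <- st$sd_used
  prof
}

#' Average origin activity
#'
#' The scalar compared across treatments: the unweighted mean of the
#' meta-profile over offsets within `±central_window` of the summit.
#'
#' @param profile A `meta_profile`.
#' @param central_window Half-width in bases of the averaging window (default
#'   10 kb); must not exceed the profile's half-window.
#' @return Mean sigma, a scalar.
#' @export
average_origin_activity <- function(profile, central_window = 10000) {
  stopifnot(inherits(profile, "meta_profile"))
  if (central_window > attr(profile, "half_window")) {
    stop("central_window exceeds the profile half_window", call. = FALSE)
  }
  keep <- abs(profile$offset) <= central_window
  mean(profile$mean_sigma[keep])
}

#' Percent reduction of a treated value relative to control
#'
#' `100 * (1 - treated / control)`. Negative values (enrichment under
#' treatment) are reported as-is, not clamped.
#'
#' @param treated Scalar activity under treatment.
#' @param control Scalar activity under the mock/control condition; must be
#'   positive.
#' @return Percent reduction.
#' @export
percent_reduction <- function(treated, control) {
  if (!is.finite(control) || control <= 0) {
    stop("control activity must be positive", call. = FALSE)
  }
  100 * (1 - treated / control)
}

#' Per-origin signal values
#'
#' One value per origin: the maximum sigma over bins overlapping
#' `summit ± window`. The maximum (rather than the mean) is robust to one-bin
#' summit jitter between libraries.
#'
#' @param sigma A `sigma_track`.
#' @param origins An `origin_set`.
#' @param window Half-width in bases (default 10 kb); at least one bin.
#' @return Numeric vector, one entry per origin (in input order).
#' @export
per_origin_signal <- function(sigma, origins, window = 10000) {
  stopifnot(inherits(sigma, "sigma_track"))
  layout <- sigma$layout
  if (window < layout$bin_size) {
    stop("window must be at least one bin", call. = FALSE)
  }
  vapply(seq_len(nrow(origins)), function(i) {
    chrom <- origins$chrom[i]
    len <- layout$chrom_lengths[[chrom]]
    lo <- max(0, origins$summit[i] - window)
    hi <- min(len - 1, origins$summit[i] + window)
    idx <- flat_bin_index(layout, rep(chrom, 2), c(lo, hi))
    max(sigma$sigma[idx[1]:idx[2]])
  }, numeric(1))
}

#' Compare per-origin signal between two conditions
#'
#' Ordinary least squares `y ~ a + b x` over the per-origin pairs, with the
#' coefficient of determination, a two-tailed t-test of the slope against zero
#' (`n - 2` degrees of freedom, no multiple-testing adjustment), and the
#' percent reduction of the mean signal in `y` relative to `x`.
#'
#' @param x Per-origin values in the reference condition.
#' @param y Per-origin values in the comparison condition, same origin order.
#' @return A `comparison_result` list: `n`, `slope`, `intercept`, `r_squared`,
#'   `t_statistic`, `df`, `p_value`, `mean_x`, `mean_y`, `percent_reduction`
#'   (`NA` if `mean(x) <= 0`).
#' @export
compare_conditions <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 origins", call. = FALSE)
  if (stats::var(x) == 0) stop("degenerate x: zero variance", call. = FALSE)
  if (stats::var(y) == 0) {
    # a constant response carries no trend: report the zero fit exactly
    # rather than lm()'s numerical noise
    return(structure(
      list(n = n, slope = 0, intercept = mean(y), r_squared = 0,
           t_statistic = 0, df = n - 2L, p_value = 1,
           mean_x = mean(x), mean_y = mean(y),
           percent_reduction = if (mean(x) > 0)
             percent_reduction(mean(y), mean(x)) else NA_real_),
      class = "comparison_result"))
  }
  fit <- stats::lm(y ~ x)
  # an exact linear relation (e.g. self-comparison checks) is a valid input;
  # silence summary.lm's perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  structure(
    list(
      n = n,
      slope = unname(co["x", "Estimate"]),
      intercept = unname(co["(Intercept)", "Estimate"]),
      r_squared = sm$r.squared,
      t_statistic = unname(co["x", "t value"]),
      df = n - 2L,
      p_value = unname(co["x", "Pr(>|t|)"]),
      mean_x = mean(x),
      mean_y = mean(y),
      percent_reduction = if (mean(x) > 0) percent_reduction(mean(y), mean(x)) else NA_real_
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "comparison_result: n = %d origins\n  slope %.4f, intercept %.4f, R^2 %.4f\n  slope t = %.3f (df %d), two-tailed p = %.3g\n  mean x %.3f, mean y %.3f -> percent reduction %.1f%%\n",
    x$n, x$slope, x$intercept, x$r_squared, x$t_statistic, x$df, x$p_value,
    x$mean_x, x$mean_y, x$percent_reduction))
  invisible(x)
}

#' Write a meta-profile as TSV
#' @param profile A `meta_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meta_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
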