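#' Count reads into genome bins
#'
#' Assigns every read to the half-open bin containing its 5' position
#' (`floor(start / bin_size)`), ignoring strand, and returns the per-bin counts.
#'
#' @param reads A `read_set` data frame (`chrom`, `start`).
#' @param layout A [genome_layout()] defining the bins.
#' @param lenient If `TRUE`, reads on chromosomes absent from the layout (or
#'   out of bounds) are skipped and counted in the `n_skipped` attribute instead
#'   of raising an error.
#' @return A `binned_track`: the layout, a flat numeric `counts` vector (one
#'   entry per bin in layout order), `library_size` (= sum of counts),
#'   `normalized = FALSE`.
#' @export
count_reads_in_bins <- function(reads, layout, lenient = FALSE) {
  stopifnot(inherits(layout, "genome_layout"))
  chrom <- reads$chrom
  start <- reads$start
  n_skipped <- 0L
  if (lenient) {
    ci <- match(chrom, layout$chrom_names)
    ok <- !is.na(ci) & start >= 0 & start < layout$chrom_lengths[ifelse(is.na(ci), 1, ci)]
    n_skipped <- sum(!ok)
    if (n_skipped > 0) {
      message("count_reads_in_bins: skipped ", n_skipped,
              " read(s) outside the layout")
    }
    chrom <- chrom[ok]
    start <- start[ok]
  }
  nb <- total_bins(layout)
  counts <- if (length(start) == 0) {
    numeric(nb)
  } else {
    as.numeric(tabulate(flat_bin_index(layout, chrom, start), nbins = nb))
  }
  structure(
    list(layout = layout, counts = counts, library_size = sum(counts),
         normalized = FALSE, norm_target = NA_real_, n_skipped = n_skipped),
    class = "binned_track"
  )
}

#' Re-count reads at a different bin size
#'
#' Identical contract to [count_reads_in_bins()] at the new resolution: counts
#' are recomputed from the read positions, never interpolated from coarser bins.
#'
#' @param reads A `read_set`.
#' @param layout A [genome_layout()] (its `bin_size` is replaced).
#' @param new_bin New bin width in bases.
#' @param lenient Passed to [count_reads_in_bins()].
#' @return A `binned_track` at `new_bin` resolution.
#' @export
rebin_reads <- function(reads, layout, new_bin, lenient = FALSE) {
  if (!is.finite(new_bin) || new_bin <= 0) {
    stop("new_bin must be positive", call. = FALSE)
  }
  fine <- genome_layout(layout$chrom_lengths, bin_size = new_bin)
  count_reads_in_bins(reads, fine, lenient = lenient)
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track: %d bins @ %g bp, library %g reads%s\n",
              length(x$counts), x$layout$bin_size, x$library_size,
              if (isTRUE(x$normalized))
                sprintf(", normalized to %g", x$norm_target) else ""))
  invisible(x)
}

#' Scale a track to a reference library size
#'
#' Multiplies every bin by `norm_target / library_size` so tracks from
#' libraries of different depths share a scale. Renormalizing an
#' already-normalized track rescales relative to its current target
#' (idempotent for an unchanged target).
#'
#' @param track A `binned_track`.
#' @param norm_target Reference library size (default 1e7 reads, an arbitrary
#'   fixed reference so magnitudes are cross-library comparable).
#' @return The normalized `binned_track`.
#' @export
normalize_library <- function(track, norm_target = 1e7) {
  stopifnot(inherits(track, "binned_track"))
  if (!is.finite(norm_target) || norm_target <= 0) {
    stop("norm_target must be positive", call. = FALSE)
  }
  if (isTRUE(track$normalized)) {
    if (track$norm_target == norm_target) return(track)
    track$counts <- track$counts * norm_target / track$norm_target
    track$norm_target <- norm_target
    return(track)
  }
  if (track$library_size <= 0) {
    stop("cannot normalize an empty library", call. = FALSE)
  }
  track$counts <- track$counts * norm_target / track$library_size
  track$normalized <- TRUE
  track$norm_target <- norm_target
  track
}

#' Compute the sigma track
#'
#' Sigma is the per-bin normalized read count divided by one genome-wide
#' standard deviation of the normalized counts, making signal comparable across
#' chromosomes and libraries. The divisor is the population SD, pooled over all
#' bins of the layout by default. The `"trimmed"` scope first excludes bins
#' above `median + mad_k * MAD` — an estimate of the background dispersion for
#' peak-dense libraries whose signal bins would otherwise inflate the divisor —
#' then still divides every bin.
#'
#' @param track A normalized `binned_track` (see [normalize_library()]).
#' @param sd_scope `"all_bins"` (default) or `"trimmed"`.
#' @param mad_k Cap multiplier for the trimmed scope (default 5).
#' @return A `sigma_track`: layout, per-bin `sigma`, `sd_used`, `sd_scope`,
#'   `source_library_size`.
#' @export
compute_sigma <- function(track, sd_scope = c("all_bins", "trimmed"), mad_k = 5) {
  stopifnot(inherits(track, "binned_track"))
  sd_scope <- match.arg(sd_scope)
  if (!isTRUE(track$normalized)) {
    stop("track must be normalized first (see normalize_library())", call. = FALSE)
  }
  x <- track$counts
  if (length(x) < 2) stop("need at least 2 bins to compute sigma", call. = FALSE)
  scope <- if (sd_scope == "trimmed") {
    cap <- stats::median(x) + mad_k * stats::mad(x)
    x[x <= cap]
  } else {
    x
  }
  if (length(scope) < 2) {
    stop("trimmed scope left fewer than 2 bins", call. = FALSE)
  }
  sd_used <- sqrt(mean((scope - mean(scope))^2))  # population SD
  if (sd_used == 0) {
    stop("degenerate track: standard deviation over the SD scope is zero",
         call. = FALSE)
  }
  structure(
    list(layout = track$layout, sigma = x / sd_used, sd_used = sd_used,
         sd_scope = sd_scope, source_library_size = track$library_size),
    class = "sigma_track"
  )
}

#' @export
print.sigma_track <- function(x, ...) {
  cat(sprintf(
    "sigma_track: %d bins @ %g bp, sd_used %.4g (%s scope), max sigma %.2f\n",
    length(x$sigma), x$layout$bin_size, x$sd_used, x$sd_scope, max(x$sigma)))
  invisible(x)
}

#' One-call sigma track from reads
#'
#' Convenience wrapper: count, normalize, divide by the SD.
#'
#' @param reads A `read_set`.
#' @param layout A [genome_layout()].
#' @param bin_size Bin width (defaults to the layout's).
#' @param norm_target See [normalize_library()].
#' @param sd_scope,mad_k See [compute_sigma()].
#' @param lenient See [count_reads_in_bins()].
#' @return A `sigma_track`.
#' @export
sigma_track <- function(reads, layout, bin_size = layout$bin_size,
                        norm_target = 1e7, sd_scope = "all_bins", mad_k = 5,
                        lenient = FALSE) {
  track <- rebin_reads(reads, layout, bin_size, lenient = lenient)
  compute_sigma(normalize_library(track, norm_target), sd_scope = sd_scope,
                mad_k = mad_k)
}

# Track values as a per-bin data frame (chrom, start, end, value).
track_frame <- function(layout, value) {
  bc <- bin_coordinates(layout)
  data.frame(chrom = bc$chrom, start = bc$start, end = bc$end, value = value,
             stringsAsFactors = FALSE)
}

#' Export a track as bedGraph
#'
#' Writes per-bin values in 0-based half-open bedGraph records.
#'
#' @param x A `binned_track` or `sigma_track`.
#' @param path Output `.bedgraph` path.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(x, path) {
  value <- if (inherits(x, "sigma_track")) x$sigma else x$counts
  df <- track_frame(x$layout, value)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    score = df$value
  )
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' Export a track as TSV
#' @param x A `binned_track` or `sigma_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(x, path) {
  value <- if (inherits(x, "sigma_track")) x$sigma else x$counts
  df <- track_frame(x$layout, value)
  names(df)[4] <- if (inherits(x, "sigma_track")) "sigma" else "count"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
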