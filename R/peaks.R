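#' Call origin peaks from a sigma track
#'
#' A peak is a maximal run of bins with `sigma >= threshold` on one chromosome;
#' runs separated by at most `merge_gap` sub-threshold bins are merged into one
#' peak. Each peak records its maximum sigma, the summit (midpoint of the
#' leftmost bin attaining the maximum) and its span in bins.
#'
#' @param sigma A `sigma_track` from [compute_sigma()].
#' @param threshold Minimum sigma for a bin to enter a peak (default 5).
#' @param merge_gap Maximum number of consecutive sub-threshold bins bridged
#'   between runs (default 1).
#' @return An unranked `origin_set` data frame: `chrom`, `peak_bin` (0-based
#'   bin index of the summit bin within its chromosome), `summit` (base),
#'   `peak_sigma`, `span` (bins from first to last above-threshold bin,
#'   inclusive), `rank` (`NA` until [rank_and_select()]).
#' @export
call_peaks <- function(sigma, threshold = 5, merge_gap = 1) {
  stopifnot(inherits(sigma, "sigma_track"))
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  if (merge_gap < 0) stop("merge_gap must be >= 0", call. = FALSE)
  layout <- sigma$layout
  out <- list()
  for (chrom in layout$chrom_names) {
    off <- layout$bin_offset[[chrom]]
    nb <- layout$n_bins[[chrom]]
    s <- sigma$sigma[(off + 1):(off + nb)]
    above <- s >= threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    # merge runs separated by <= merge_gap sub-threshold bins
    merged <- list()
    cur <- runs[1, ]
    for (i in seq_len(nrow(runs))[-1]) {
      if (runs$start[i] - cur$end - 1 <= merge_gap) {
        cur$end <- runs$end[i]
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- runs[i, ]
      }
    }
    merged[[length(merged) + 1]] <- cur
    for (m in merged) {
      idx <- m$start:m$end
      peak_sigma <- max(s[idx])
      max_bin <- idx[which.max(s[idx])]  # which.max: leftmost on ties
      bin0 <- max_bin - 1               # 0-based bin index
      bin_start <- bin0 * layout$bin_size
      bin_end <- min(bin_start + layout$bin_size, layout$chrom_lengths[[chrom]])
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, peak_bin = bin0,
        summit = floor((bin_start + bin_end) / 2),
        peak_sigma = peak_sigma, span = m$end - m$start + 1,
        stringsAsFactors = FALSE
      )
    }
  }
  peaks <- if (length(out) == 0) {
    data.frame(chrom = character(0), peak_bin = integer(0), summit = numeric(0),
               peak_sigma = numeric(0), span = integer(0))
  } else {
    do.call(rbind, out)
  }
  peaks$rank <- rep(NA_integer_, nrow(peaks))
  rownames(peaks) <- NULL
  class(peaks) <- c("origin_set", "data.frame")
  attr(peaks, "threshold") <- threshold
  attr(peaks, "merge_gap") <- merge_gap
  attr(peaks, "bin_size") <- layout$bin_size
  peaks
}

#' Rank peaks and select the top N origins
#'
#' Greedy selection in order of decreasing peak sigma (ties broken by leftmost
#' chromosome-order coordinate): a peak is skipped if its summit lies within
#' `min_separation` of an already-selected summit on the same chromosome.
#' Selection stops at `n_top` peaks or when candidates are exhausted, and ranks
#' 1..k are assigned. The result is the fixed "predefined most active origins"
#' set held constant across treatment comparisons.
#'
#' @param peaks An `origin_set` from [call_peaks()].
#' @param n_top Number of origins to retain (default 1000).
#' @param min_separation Minimum distance in bases between selected summits
#'   (default 30 kb).
#' @param chrom_order Chromosome ordering used for deterministic tie-breaks
#'   (default: order of first appearance).
#' @return The selected `origin_set`, ranked 1..k by non-increasing
#'   `peak_sigma`. Warns if fewer than `n_top` peaks survive.
#' @export
rank_and_select <- function(peaks, n_top = 1000, min_separation = 30000,
                            chrom_order = unique(peaks$chrom)) {
  stopifnot(inherits(peaks, "origin_set"))
  if (n_top < 1) stop("n_top must be >= 1", call. = FALSE)
  if (nrow(peaks) == 0) {
    warning("no peaks to select from")
    return(peaks)
  }
  ord <- order(-peaks$peak_sigma, match(peaks$chrom, chrom_order), peaks$summit)
  cand <- peaks[ord, ]
  sel <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(sel) >= n_top) break
    ok <- TRUE
    if (length(sel) > 0) {
      same <- cand$chrom[sel] == cand$chrom[i]
      if (any(same) && any(abs(cand$summit[sel][same] - cand$summit[i]) < min_separation)) {
        ok <- FALSE
      }
    }
    if (ok) sel <- c(sel, i)
  }
  out <- cand[sel, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("origin_set", "data.frame")
  attr(out, "min_separation") <- min_separation
  if (nrow(out) < n_top) {
    warning(sprintf("only %d of the requested %d origins available",
                    nrow(out), n_top))
  }
  out
}

#' Match called origins to a ground-truth catalog
#'
#' One-to-one nearest matching: candidate (call, truth) pairs on the same
#' chromosome within `tolerance` are accepted greedily by increasing distance,
#' each call and each truth origin matching at most once. Recall is the matched
#' fraction of truth origins, precision the matched fraction of calls.
#'
#' @param calls An `origin_set` (uses `summit`).
#' @param truth An `origin_catalog` (uses `position`).
#' @param tolerance Maximum summit-to-origin distance in bases.
#' @return List with `recall`, `precision`, `n_matched`, `n_calls`, `n_truth`
#'   and `precision_defined` (`FALSE` when there are no calls; precision is
#'   then reported as 0).
#' @export
match_to_truth <- function(calls, truth, tolerance) {
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  n_calls <- nrow(calls)
  n_truth <- nrow(truth)
  if (n_truth == 0) stop("truth catalog is empty", call. = FALSE)
  if (n_calls == 0) {
    return(list(recall = 0, precision = 0, n_matched = 0L, n_calls = 0L,
                n_truth = n_truth, precision_defined = FALSE))
  }
  pairs <- list()
  for (i in seq_len(n_calls)) {
    j <- which(truth$chrom == calls$chrom[i] &
                 abs(truth$position - calls$summit[i]) <= tolerance)
    if (length(j)) {
      pairs[[length(pairs) + 1]] <- data.frame(
        call = i, truth = j, dist = abs(truth$position[j] - calls$summit[i]))
    }
  }
  n_matched <- 0L
  if (length(pairs)) {
    pairs <- do.call(rbind, pairs)
    pairs <- pairs[order(pairs$dist, pairs$call, pairs$truth), ]
    used_call <- logical(n_calls)
    used_truth <- logical(n_truth)
    for (k in seq_len(nrow(pairs))) {
      ci <- pairs$call[k]; ti <- pairs$truth[k]
      if (!used_call[ci] && !used_truth[ti]) {
        used_call[ci] <- TRUE
        used_truth[ti] <- TRUE
        n_matched <- n_matched + 1L
      }
    }
  }
  list(recall = n_matched / n_truth, precision = n_matched / n_calls,
       n_matched = n_matched, n_calls = n_calls, n_truth = n_truth,
       precision_defined = TRUE)
}

#' Write an origin set as BED6
#'
#' One record per origin at its summit bin; name = rank, score = rounded peak
#' sigma.
#'
#' @param origins An `origin_set`.
#' @param path Output `.bed` path.
#' @return `path`, invisibly.
#' @export
write_origins_bed <- function(origins, path) {
  bin_size <- attr(origins, "bin_size") %||% 10000
  gr <- GenomicRanges::GRanges(
    seqnames = origins$chrom,
    ranges = IRanges::IRanges(start = origins$peak_bin * bin_size + 1,
                              width = bin_size),
    strand = "*"
  )
  gr$name <- as.character(ifelse(is.na(origins$rank),
                                 seq_len(nrow(origins)), origins$rank))
  gr$score <- round(origins$peak_sigma)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}
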