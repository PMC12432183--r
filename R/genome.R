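#' Define a genome layout
#'
#' A genome layout fixes the coordinate frame for every binned track: an ordered
#' set of chromosomes with lengths, and a bin size. Bins are 0-based half-open
#' intervals `[k*bin_size, (k+1)*bin_size)`; the last bin of a chromosome may be
#' partial.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bases.
#'   Unnamed vectors get names `chr1`, `chr2`, ...
#' @param bin_size Bin width in bases (default 10 kb, the working resolution for
#'   genome-wide origin signal).
#' @return An object of class `genome_layout` with elements `chrom_names`,
#'   `chrom_lengths`, `bin_size`, `n_bins` (per chromosome) and `bin_offset`
#'   (0-based offset of each chromosome's first bin in the flattened bin vector).
#' @examples
#' gl <- genome_layout(c(chrA = 105000), bin_size = 10000)
#' total_bins(gl)  # 11: ten full bins plus a 5-kb partial bin
#' @export
genome_layout <- function(chrom_lengths, bin_size = 10000) {
  if (length(chrom_lengths) < 1) {
    stop("at least one chromosome is required", call. = FALSE)
  }
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stop("chromosome lengths must be positive and finite", call. = FALSE)
  }
  if (!is.finite(bin_size) || bin_size <= 0) {
    stop("bin_size must be a positive number of bases", call. = FALSE)
  }
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  if (anyDuplicated(names(chrom_lengths))) {
    stop("chromosome names must be unique", call. = FALSE)
  }
  n_bins <- as.integer(ceiling(chrom_lengths / bin_size))
  structure(
    list(
      chrom_names = names(chrom_lengths),
      chrom_lengths = chrom_lengths,
      bin_size = bin_size,
      n_bins = stats::setNames(n_bins, names(chrom_lengths)),
      bin_offset = stats::setNames(
        cumsum(c(0, n_bins[-length(n_bins)])), names(chrom_lengths)
      )
    ),
    class = "genome_layout"
  )
}

#' Build a genome layout from counts and lengths
#'
#' Convenience constructor mirroring the simulator's parameterisation.
#'
#' @param n_chrom Number of chromosomes.
#' @param lengths Vector of chromosome lengths (recycled if scalar).
#' @param bin_size Bin width in bases.
#' @return A [genome_layout()].
#' @export
make_genome <- function(n_chrom, lengths, bin_size = 10000) {
  if (n_chrom < 1) stop("n_chrom must be >= 1", call. = FALSE)
  if (length(lengths) == 1) lengths <- rep(lengths, n_chrom)
  if (length(lengths) != n_chrom) {
    stop("lengths must have one entry per chromosome", call. = FALSE)
  }
  genome_layout(stats::setNames(lengths, paste0("chr", seq_len(n_chrom))),
                bin_size = bin_size)
}

#' Total number of bins in a layout
#' @param layout A [genome_layout()].
#' @return Integer bin count summed over chromosomes.
#' @export
total_bins <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(layout$n_bins)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chrom_names), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bases,",
      "bin_size", x$bin_size, "->", total_bins(x), "bins\n")
  invisible(x)
}

# Flat 1-based bin index for (chrom, 0-based base position); positions must lie
# within the chromosome. Used by every counting routine so the half-open bin
# convention lives in exactly one place.
flat_bin_index <- function(layout, chrom, pos) {
  idx <- match(chrom, layout$chrom_names)
  if (anyNA(idx)) {
    bad <- unique(chrom[is.na(idx)])
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(pos < 0) || any(pos >= layout$chrom_lengths[idx])) {
    stop("position(s) outside chromosome bounds", call. = FALSE)
  }
  as.integer(layout$bin_offset[idx] + pos %/% layout$bin_size + 1)
}

# Genomic start (0-based) and width of every bin, as parallel vectors; used by
# track exporters.
bin_coordinates <- function(layout) {
  chrom <- rep(layout$chrom_names, layout$n_bins)
  k <- unlist(lapply(layout$n_bins, function(n) seq_len(n) - 1), use.names = FALSE)
  start <- k * layout$bin_size
  end <- pmin(start + layout$bin_size, rep(layout$chrom_lengths, layout$n_bins))
  list(chrom = chrom, start = start, end = end)
}

#' Read a UCSC chrom.sizes file
#'
#' @param path Two-column TSV (chromosome name, length).
#' @param bin_size Bin width for the resulting layout.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path, bin_size = 10000) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  genome_layout(stats::setNames(tab$length, tab$chrom), bin_size = bin_size)
}

#' Write a UCSC chrom.sizes file
#' @param layout A [genome_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(layout, path) {
  utils::write.table(
    data.frame(layout$chrom_names, format(layout$chrom_lengths, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
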