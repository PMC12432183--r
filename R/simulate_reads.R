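# Run expr with a private RNG stream: seed the generator, evaluate, then
# restore whatever global .Random.seed existed before. Keeps every simulator
# deterministic in its seed argument without leaking state between calls.
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed)) stop("an integer seed is required", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Place ground-truth replication origins on a genome
#'
#' Samples origin positions uniformly over the genome (chromosomes weighted by
#' length) subject to a minimum pairwise spacing on the same chromosome, and
#' assigns each origin a firing efficiency drawn from `efficiency_law`.
#'
#' @param genome A [genome_layout()].
#' @param n_origins Number of origins to place.
#' @param efficiency_law A list describing the per-origin efficiency
#'   distribution: `list(dist = "constant", value = v)`,
#'   `list(dist = "uniform", min = a, max = b)` or
#'   `list(dist = "beta", shape1 = a, shape2 = b)`. Default `uniform(0.2, 1)`:
#'   real early-firing origins differ severalfold in efficiency, and a
#'   heterogeneous catalog is what makes per-origin cross-library regression
#'   informative.
#' @param min_spacing Minimum distance in bases between origins on one
#'   chromosome (default 100 kb).
#' @param seed Integer seed; the catalog is a deterministic function of it.
#' @param max_tries Rejection-sampling attempts per origin before giving up.
#' @return An `origin_catalog` data frame with columns `chrom`, `position`
#'   (0-based base), `efficiency`.
#' @export
place_origins <- function(genome, n_origins,
                          efficiency_law = list(dist = "uniform", min = 0.2, max = 1),
                          min_spacing = 100000, seed, max_tries = 1000L) {
  stopifnot(inherits(genome, "genome_layout"))
  if (n_origins < 1) stop("n_origins must be >= 1", call. = FALSE)
  if (n_origins * min_spacing > sum(genome$chrom_lengths)) {
    stop("infeasible origin placement: n_origins * min_spacing exceeds genome size",
         call. = FALSE)
  }
  with_seed(seed, {
    chrom_prob <- genome$chrom_lengths / sum(genome$chrom_lengths)
    pos <- numeric(n_origins)
    chrom <- character(n_origins)
    placed_by_chrom <- stats::setNames(
      vector("list", length(genome$chrom_names)), genome$chrom_names)
    for (i in seq_len(n_origins)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand_chrom <- sample(genome$chrom_names, 1, prob = chrom_prob)
        cand_pos <- floor(stats::runif(1, 0, genome$chrom_lengths[[cand_chrom]]))
        prev <- placed_by_chrom[[cand_chrom]]
        if (is.null(prev) || all(abs(prev - cand_pos) >= min_spacing)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("origin placement failed after ", max_tries,
             " attempts; relax min_spacing or n_origins", call. = FALSE)
      }
      chrom[i] <- cand_chrom
      pos[i] <- cand_pos
      placed_by_chrom[[cand_chrom]] <- c(placed_by_chrom[[cand_chrom]], cand_pos)
    }
    eff <- draw_efficiencies(efficiency_law, n_origins)
    out <- data.frame(chrom = chrom, position = pos, efficiency = eff,
                      stringsAsFactors = FALSE)
    out <- out[order(match(out$chrom, genome$chrom_names), out$position), ]
    rownames(out) <- NULL
    class(out) <- c("origin_catalog", "data.frame")
    attr(out, "min_spacing") <- min_spacing
    attr(out, "seed") <- seed
    out
  })
}

draw_efficiencies <- function(law, n) {
  dist <- law$dist %||% "uniform"
  eff <- switch(dist,
    constant = rep(law$value %||% 1, n),
    uniform = stats::runif(n, law$min %||% 0.2, law$max %||% 1),
    beta = stats::rbeta(n, law$shape1, law$shape2),
    stop("unknown efficiency_law dist: ", dist, call. = FALSE)
  )
  if (any(eff < 0 | eff > 1)) stop("efficiencies must lie in [0,1]", call. = FALSE)
  eff
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an EdU-seq-HU read library
#'
#' Models the read pileups produced when cells are released into S phase in
#' hydroxyurea with EdU: replication forks stall within a bounded span of each
#' fired origin, so nascent-DNA reads concentrate symmetrically around origins
#' over a uniform background. Each of `n_reads` attempted incorporation events
#' is background with probability `bg_fraction` (uniform over the genome);
#' otherwise it targets an origin chosen with probability proportional to its
#' efficiency and is retained with probability equal to the schedule's firing
#' proficiency (`licensed_fraction^licensing_exponent`). Attempts at
#' unlicensed origins yield no read, so licensing blocks shrink the origin
#' component of the library the way they shrink nascent-DNA yield; the realized
#' library size is the number of retained reads.
#'
#' Retained origin reads are placed at `origin_position + offset` with `offset`
#' drawn from a symmetric triangular distribution on `[-fork_span, +fork_span]`
#' (sharp symmetric peaks without modelling fork kinetics), clamped to the
#' chromosome. Reads carry only their 5' position and a strand that downstream
#' binning ignores.
#'
#' @param genome A [genome_layout()].
#' @param catalog An `origin_catalog` from [place_origins()].
#' @param schedule A [treatment_schedule()].
#' @param n_reads Attempted incorporation events (the library size under an
#'   unblocked schedule).
#' @param fork_span Maximum distance in bases a fork travels from its origin
#'   under hydroxyurea arrest (default 25 kb).
#' @param bg_fraction Probability that an attempt is background (default 0.2).
#' @param seed Integer seed.
#' @return A `read_set` data frame (`chrom`, `start`, `strand`) with attributes
#'   `total_reads`, `n_attempted`, `seed` and the generating parameters.
#' @export
simulate_eduseq_reads <- function(genome, catalog, schedule, n_reads,
                                  fork_span = 25000, bg_fraction = 0.2, seed) {
  stopifnot(inherits(genome, "genome_layout"),
            inherits(catalog, "origin_catalog"),
            inherits(schedule, "treatment_schedule"))
  if (bg_fraction < 0 || bg_fraction > 1) {
    stop("bg_fraction must lie in [0,1]", call. = FALSE)
  }
  if (fork_span <= 0) stop("fork_span must be positive", call. = FALSE)
  proficiency <- firing_proficiency(schedule)
  weights <- catalog$efficiency * proficiency
  if (all(weights == 0) && bg_fraction < 1) {
    stop("degenerate origin weights: no origin can fire and bg_fraction < 1; ",
         "use bg_fraction = 1 for a background-only library", call. = FALSE)
  }
  with_seed(seed, {
    is_bg <- stats::runif(n_reads) < bg_fraction
    n_bg <- sum(is_bg)
    n_attempt <- n_reads - n_bg

    # background: uniform over the concatenated genome
    bg_chrom_idx <- sample.int(length(genome$chrom_names), n_bg, replace = TRUE,
                               prob = genome$chrom_lengths)
    bg_pos <- floor(stats::runif(n_bg) * genome$chrom_lengths[bg_chrom_idx])

    # origin attempts: categorical by efficiency, thinned by proficiency
    if (n_attempt > 0 && any(catalog$efficiency > 0)) {
      o_idx <- sample.int(nrow(catalog), n_attempt, replace = TRUE,
                          prob = catalog$efficiency)
      keep <- stats::runif(n_attempt) < proficiency
      o_idx <- o_idx[keep]
    } else {
      o_idx <- integer(0)
    }
    n_o <- length(o_idx)
    offset <- round(fork_span * (stats::runif(n_o) + stats::runif(n_o) - 1))
    o_chrom <- catalog$chrom[o_idx]
    o_len <- genome$chrom_lengths[o_chrom]
    o_pos <- pmin(pmax(catalog$position[o_idx] + offset, 0), o_len - 1)

    chrom <- c(genome$chrom_names[bg_chrom_idx], o_chrom)
    start <- c(bg_pos, o_pos)
    strand <- sample(c("+", "-"), n_bg + n_o, replace = TRUE)

    reads <- data.frame(chrom = chrom, start = as.numeric(start),
                        strand = strand, stringsAsFactors = FALSE)
    rownames(reads) <- NULL
    class(reads) <- c("read_set", "data.frame")
    attr(reads, "total_reads") <- nrow(reads)
    attr(reads, "n_attempted") <- n_reads
    attr(reads, "seed") <- seed
    attr(reads, "params") <- list(fork_span = fork_span,
                                  bg_fraction = bg_fraction,
                                  proficiency = proficiency)
    reads
  })
}

#' Write a read set as 6-column BED
#'
#' Each read becomes a 1-base interval at its 5' position (BED is 0-based
#' half-open, matching the internal convention), name `read<i>`, score 0.
#'
#' @param reads A `read_set`.
#' @param path Output `.bed` path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = reads$start + 1, width = 1),
    strand = reads$strand
  )
  gr$name <- paste0("read", seq_along(gr))
  gr$score <- 0L
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read aligned read positions from BED
#'
#' Imports a BED file and keeps each record's 5' position (interval start,
#' 0-based) and strand.
#'
#' @param path BED file of aligned reads.
#' @return A `read_set` data frame.
#' @export
read_reads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  reads <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  reads$strand[!reads$strand %in% c("+", "-")] <- "+"
  class(reads) <- c("read_set", "data.frame")
  attr(reads, "total_reads") <- nrow(reads)
  reads
}

#' Write an origin catalog as TSV
#' @param catalog An `origin_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_origin_catalog <- function(catalog, path) {
  utils::write.table(as.data.frame(catalog), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
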