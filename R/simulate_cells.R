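#' Simulate a per-cell cytometry population
#'
#' Generates the per-nucleus integrated-intensity table (DAPI, EdU, Cyclin A2)
#' that quantitative image-based cytometry or flow cytometry would produce from
#' an asynchronous population released from mitosis. G1 cells sit at the 2N DAPI
#' mode and G2/M at 4N (mode ratio 2); S-phase DNA content is uniform between
#' the two. EdU is at a low background mode in G1/G2M; S-phase cells add a high
#' mode whose amplitude scales with the schedule's firing proficiency, so a
#' fully blocked licensing schedule leaves S-phase EdU indistinguishable from
#' background. Cyclin A2 rises from G1 through S to G2/M. All channels carry
#' multiplicative lognormal noise.
#'
#' @param schedule A [treatment_schedule()].
#' @param n_cells Number of cells (default 2000).
#' @param phase_fractions Named fractions for `G1`, `S`, `G2M` (default
#'   0.5/0.3/0.2); `S` is the true S-entry fraction the gating statistics
#'   should recover.
#' @param noise List with `sdlog`, the lognormal sd applied per channel
#'   (default 0.15).
#' @param baselines List of channel location parameters: `dapi_2n`,
#'   `edu_background`, `edu_amplitude` (full-proficiency S-phase increment),
#'   `cyclin_g1`, `cyclin_s` (range), `cyclin_g2m`. Arbitrary units.
#' @param seed Integer seed; the table is byte-identical for a fixed seed.
#' @return A `cell_table` data frame: `cell_id`, `dapi`, `edu`, `cyclin_a2`,
#'   `true_phase`.
#' @export
simulate_cell_population <- function(schedule, n_cells = 2000,
                                     phase_fractions = c(G1 = 0.5, S = 0.3, G2M = 0.2),
                                     noise = list(sdlog = 0.15),
                                     baselines = list(dapi_2n = 100,
                                                      edu_background = 50,
                                                      edu_amplitude = 1500,
                                                      cyclin_g1 = 30,
                                                      cyclin_s = c(60, 150),
                                                      cyclin_g2m = 200),
                                     seed) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  pf <- phase_fractions[c("G1", "S", "G2M")]
  if (anyNA(pf) || any(pf < 0) || abs(sum(pf) - 1) > 1e-8) {
    stop("phase_fractions must be non-negative, named G1/S/G2M and sum to 1",
         call. = FALSE)
  }
  sdlog <- noise$sdlog %||% 0.15
  proficiency <- firing_proficiency(schedule)
  with_seed(seed, {
    phase <- sample(c("G1", "S", "G2M"), n_cells, replace = TRUE, prob = pf)
    n <- n_cells
    noise_mult <- function() exp(stats::rnorm(n, 0, sdlog))

    dapi_base <- ifelse(phase == "G1", baselines$dapi_2n,
                 ifelse(phase == "G2M", 2 * baselines$dapi_2n,
                        stats::runif(n, baselines$dapi_2n, 2 * baselines$dapi_2n)))
    edu_base <- baselines$edu_background +
      ifelse(phase == "S", baselines$edu_amplitude * proficiency, 0)
    cyc_base <- ifelse(phase == "G1", baselines$cyclin_g1,
                ifelse(phase == "G2M", baselines$cyclin_g2m,
                       stats::runif(n, baselines$cyclin_s[1], baselines$cyclin_s[2])))

    cells <- data.frame(
      cell_id = sprintf("cell%05d", seq_len(n)),
      dapi = dapi_base * noise_mult(),
      edu = edu_base * noise_mult(),
      cyclin_a2 = cyc_base * noise_mult(),
      true_phase = phase,
      stringsAsFactors = FALSE
    )
    class(cells) <- c("cell_table", "data.frame")
    attr(cells, "seed") <- seed
    attr(cells, "proficiency") <- proficiency
    attr(cells, "phase_fractions") <- pf
    cells
  })
}

#' Write a cell table as TSV
#' @param cells A `cell_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.table(as.data.frame(cells), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-cell intensity table
#'
#' Accepts TSV or CSV (sniffed from the header line) with required columns
#' `dapi` and `edu`; `cell_id`, `cyclin_a2` and `true_phase` are optional. The
#' DNA-content column may be named differently (e.g. propidium iodide) and
#' remapped via `dna_column`.
#'
#' @param path Input table.
#' @param dna_column Name of the DNA-content column (default `"dapi"`).
#' @return A `cell_table` data frame.
#' @export
read_cell_table <- function(path, dna_column = "dapi") {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  if (!dna_column %in% names(tab)) {
    stop("missing DNA-content column '", dna_column, "'", call. = FALSE)
  }
  names(tab)[names(tab) == dna_column] <- "dapi"
  if (!"edu" %in% names(tab)) stop("missing 'edu' column", call. = FALSE)
  if (!"cell_id" %in% names(tab)) tab$cell_id <- sprintf("cell%05d", seq_len(nrow(tab)))
  if (any(tab$dapi < 0) || any(tab$edu < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  class(tab) <- c("cell_table", "data.frame")
  tab
}
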