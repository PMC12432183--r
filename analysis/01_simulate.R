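#!/usr/bin/env Rscript
# Generate the synthetic study: genome, origin catalog, treatment libraries
# and cytometry populations. Ground truth is written alongside so later
# scripts can score themselves against it.

source("analysis/00_conditions.R")

write_chrom_sizes(genome, "results/genome.chrom.sizes")
write_origin_catalog(catalog, "results/origin_catalog_truth.tsv")

message("genome: ", format(sum(genome$chrom_lengths), big.mark = ","),
        " bases; ", nrow(catalog), " planted origins, efficiency ",
        sprintf("%.2f-%.2f", min(catalog$efficiency), max(catalog$efficiency)))

for (name in names(schedules)) {
  reads <- simulate_library(name)
  message(sprintf("%-8s licensed fraction %.3f -> %s reads retained of %s attempted",
                  name, licensed_fraction(schedules[[name]]),
                  format(nrow(reads), big.mark = ","), format(1e6, big.mark = ",")))
}

# an example mock library on disk for external browsing (down-sampled)
example <- simulate_library("mock")
keep <- seq(1, nrow(example), by = 500)
sub <- example[keep, ]
class(sub) <- c("read_set", "data.frame")
write_reads_bed(sub, "results/mock_reads_subsample.bed")

cells <- simulate_cell_population(schedules$mock, n_cells = 2000, seed = SEED + 50)
write_cell_table(cells, "results/mock_cells.tsv")
message("cytometry: wrote ", nrow(cells), " mock cells (true S fraction ",
        sprintf("%.2f", mean(cells$true_phase == "S")), ")")
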