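# Shared study conditions for the analysis scripts. Desk-scale stand-in for a
# genome-wide experiment: one 50-Mb chromosome, 100 planted origins, 1e6
# attempted incorporations per library. All randomness is seeded here so every
# script is reproducible in isolation.

library(oriact)

SEED <- 20260930 %% 2^31

genome <- make_genome(1, 5e7, bin_size = 10000)
catalog <- place_origins(genome, 100, min_spacing = 3e5, seed = SEED + 1)

# treatment outlines mirror a 12-h G1 between mitotic release (M) and S entry:
# mock (untreated), licensing blocked for the first 4 h / first 8 h / last 4 h /
# last 8 h of G1, and throughout G1
schedules <- list(
  mock     = treatment_schedule(12),
  M_to_4   = treatment_schedule(12, licensing_block_windows = list(c(0, 4))),
  M_to_8   = treatment_schedule(12, licensing_block_windows = list(c(0, 8))),
  h8_to_S  = treatment_schedule(12, licensing_block_windows = list(c(8, 12))),
  h4_to_S  = treatment_schedule(12, licensing_block_windows = list(c(4, 12)))
)

simulate_library <- function(name, seed_offset = 0) {
  simulate_eduseq_reads(genome, catalog, schedules[[name]], 1e6,
                        bg_fraction = 0.1,
                        seed = SEED + 100 + seed_offset + match(name, names(schedules)))
}

dir.create("results", showWarnings = FALSE)
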