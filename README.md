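# oriact — time-resolved replication-origin activity from EdU-seq-HU

`oriact` is an R package plus analysis workflow for quantifying DNA
replication **origin firing** from EdU-seq-HU experiments: cells synchronised
by mitotic shake-off are released into S phase in hydroxyurea with EdU, forks
stall near the origins where they fired, and sequencing the EdU-labelled
nascent DNA produces read pileups over early-firing origins. Combined with
drug treatments that block **origin licensing** during chosen G1 windows
(CDC6/CDT1 degradation, CDK4/6 inhibition), this measures when in G1
licensing occurs and how much firing capacity each window contributes. The
package is aimed at analysts of such time-resolved licensing experiments and
at anyone who needs its core statistic on binned genomic signal.

## What it computes

* **Sigma tracks** — reads are counted into 10-kb half-open bins, scaled to a
  reference depth, and each bin is divided by one genome-wide standard
  deviation of the scaled counts: `σ_b = normalized count_b / SD`. Sigma is
  invariant to sequencing depth, comparable across chromosomes and libraries.
  An optional trimmed SD scope (`median + 5·MAD` cap) estimates background
  dispersion for peak-dense libraries.
* **Origin calling and ranking** — threshold/merge peak calling on sigma,
  greedy top-N selection with a minimum summit separation; the ranked set
  from the mock condition becomes the fixed "most active origins" panel for
  all comparisons.
* **Meta-origin profiles and average origin activity** — sigma recomputed at
  1 kb and averaged across origins by offset from the summit; the mean over a
  central ±10 kb window is the scalar "average origin activity", and
  treatments are summarised as `100·(1 − treated/control)` percent reduction.
* **Per-origin comparisons** — OLS of treated on control per-origin signal
  with R² and a two-tailed slope t-test.
* **Cytometry statistics** — EdU-positive fraction by valley/Otsu gating on
  log intensities, DAPI/Cyclin A2 cell-cycle staging, replicate summaries and
  paired two-tailed t-tests.
* **A synthetic generator** — G1 licensing schedules (blocked-window union,
  firing proficiency `licensed_fraction^exponent`), origin-anchored read
  pileups with triangular fork spans over uniform background, and per-cell
  DAPI/EdU/Cyclin A2 tables — all seeded and bit-reproducible, providing
  planted ground truth for every pipeline stage.

Standard formats are used throughout: BED for reads and origins, bedGraph/TSV
for tracks, UCSC chrom.sizes for genomes, TSV/CSV for cell tables.

## Worked example

The `analysis/` directory is a numbered workflow over the package; running it
end to end simulates a licensing time-course on a 50-Mb chromosome
(100 planted origins, 10⁶ reads per library) and analyses it:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_sigma_tracks.R
Rscript analysis/03_call_origins.R
Rscript analysis/04_treatment_comparison.R
Rscript analysis/05_cytometry.R
```

`04_treatment_comparison.R` prints (abridged):

```
mock average origin activity: 273.4 sigma (central +/-10 kb)
 condition licensed_fraction avg_activity percent_reduction slope r_squared
    M_to_4             0.667        120.3              56.0 0.978     0.944
    M_to_8             0.333         29.3              89.3 0.976     0.911
   h8_to_S             0.667        121.0              55.7 0.965     0.952
   h4_to_S             0.333         29.2              89.3 0.891     0.839
```

Read: blocking licensing during the first 4 h of a 12-h G1 (`M_to_4`) leaves
a licensed fraction of 2/3 and suppresses average origin activity by 56%
under the default quadratic licensing→firing dose-response; blocking the
first 8 h suppresses it by 89%; blocks at the start and end of G1 of equal
length act identically, and the high per-origin R² shows all origins are
suppressed proportionally — no subset is licensed preferentially early or
late in G1. `05_cytometry.R` shows the flow-style readout: the EdU-positive
fraction stays at ~30% (the S-entry fraction) for partial blocks but falls to
0% when licensing is blocked throughout G1 (paired t = 39.1, df = 3,
p = 3.7×10⁻⁵ vs mock), and DAPI/Cyclin A2 staging agrees with simulated truth
for 98% of cells.

Each step writes its tables under `results/`.

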