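---
title: "Measuring replication-origin activity from EdU-seq-HU data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring replication-origin activity from EdU-seq-HU data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriact)
```

## The measurement problem

DNA replication starts at origins that are *licensed* in G1 phase — MCM2-7
helicases loaded by ORC, CDC6 and CDT1 — and *fired* at S-phase entry. EdU-seq-HU
makes early origin firing visible genome-wide: cells synchronised by mitotic
shake-off are released into S phase in hydroxyurea (HU) plus EdU, HU stalls
forks close to the origins where they started, and sequencing of the
EdU-labelled nascent DNA yields read pileups centred on early-firing origins.
Comparing such libraries between a mock condition and treatments that block
licensing during defined G1 windows (degron-mediated CDC6/CDT1 degradation, or
CDK4/6 inhibition) measures *when* in G1 licensing happens and how much firing
capacity each window contributes.

`oriact` implements the quantitative side of that design: the per-bin **sigma**
statistic, origin calling and ranking, 1-kb meta-origin profiles, the
**average origin activity** scalar and its percent reduction between
conditions, per-origin regression across libraries, and the cytometry gating
statistics (EdU-positive fraction, DAPI/Cyclin A2 staging, paired t-tests)
that accompany the sequencing readout. A synthetic generator produces read
sets and cell populations with planted ground truth so every stage is testable
at desk scale.

## The sigma statistic

Reads (5' positions; read length is negligible against bin width) are counted
into 0-based half-open bins, 10 kb by default. Counts are scaled to a
reference library size (10 M reads) and each bin is divided by **one**
genome-wide standard deviation of the scaled counts:

$$\sigma_b = \frac{n_b \cdot T / N}{\mathrm{SD}\left(\{n_j \cdot T / N\}_j\right)}$$

with $n_b$ the bin count, $N$ the library size and $T$ the reference. The SD
is the population SD pooled across all chromosomes, so sigma values share one
scale along the whole genome. Two consequences matter:

* **Scale invariance.** Sigma is unchanged by any uniform depth rescaling —
  doubling every read, or the normalisation itself, cancels exactly. This is
  what makes tracks from libraries of very different depths comparable, and it
  is asserted exactly in the test suite.
* **Self-normalisation at the all-bins scope.** If peak bins dominate the
  genome-wide variance, a treatment that scales every peak by a common factor
  also scales the SD by nearly that factor, and peak *sigma* barely moves.
  For peak calling this is harmless (positions and ranks are preserved); for
  treatment comparisons it would hide the effect being measured.

For the second reason `compute_sigma()` exposes an `sd_scope` option:
`"all_bins"` (default) and `"trimmed"`, which excludes bins above
`median + 5·MAD` before computing the divisor (all bins are still divided).
The trimmed divisor estimates the *background* dispersion, so peak sigma
scales linearly with the origin-read yield. The comparison pipeline
(`meta_profile()` and everything built on it in the analysis scripts) uses
`sd_scope = "trimmed"` at 1-kb resolution; peak calling keeps the all-bins
default. Both choices are recorded in the returned objects (`sd_scope`,
`sd_used`) so real-data runs are auditable.

## Origin calling and the fixed origin set

`call_peaks()` takes maximal runs of bins at or above a sigma threshold
(default 5), bridging runs separated by at most `merge_gap` (default 1)
sub-threshold bins; the summit is the midpoint of the leftmost maximal bin.
`rank_and_select()` then greedily retains the top `n_top` peaks by peak sigma,
skipping summits within `min_separation` (default 30 kb) of an already
selected one — ties always resolve to the leftmost coordinate, so selection is
deterministic and permutation-invariant. The threshold and count are exposed
because no canonical values exist; the origin set is defined **once, from the
mock condition**, and held fixed for every treatment comparison, so that
treatment effects are measured at the same loci rather than at whatever
survives calling in a depleted library.

One caveat is worth stating: with gap-bridging, raising the threshold can in
principle split a bridged run into two peaks, so "higher threshold, fewer
peaks" is guaranteed only for signal composed of well-separated single-summit
pileups — which is what origin-anchored pileups look like, and what the
property test asserts it on.

## Average origin activity and treatment comparisons

`meta_profile()` re-counts the reads at 1 kb (never interpolating from the
10-kb track), computes sigma at that resolution with its own SD divisor, and
averages it origin-by-origin at each offset within ±50 kb of the summits;
origins near chromosome ends contribute only their valid offsets. The
**average origin activity** is the unweighted mean of the profile over a
central ±10 kb window — wide enough to be robust to summit jitter, narrow
enough to stay signal-dominated; the window is configurable and persisted.
Treatments are summarised by
`percent_reduction = 100·(1 − treated/control)` of this scalar (negative
values report enrichment and are not clamped), and per-origin by ordinary
least squares of treated on control per-origin signal (maximum sigma within
±10 kb of each summit — the maximum, not the mean, to tolerate one-bin summit
drift between libraries), with $R^2$ and a two-tailed slope t-test on $n-2$
degrees of freedom, unadjusted for multiple comparisons.

## The licensing-schedule model behind the simulator

The generator encodes the licensing biology the analysis assumes, no more:

* **Cumulative licensing.** Licensing capacity accrues uniformly over a G1 of
  `g1_duration` (default 12 h — S entry 12–14 h after mitotic release in the
  synchronised system this emulates). Any moment covered by a
  licensing-block window (CDC6/CDT1 degradation) or a CDK4/6-inhibition
  window contributes nothing; the two kinds act in one pathway, so blocked
  time is the *union* of the windows, and already-loaded helicases are never
  unloaded. `licensed_fraction()` is the unblocked share of G1.
* **Firing proficiency.** Downstream firing scales as
  `licensed_fraction^licensing_exponent`. The exponent (default 2, minimum 1)
  supplies the observed super-proportional suppression of firing by partial
  licensing windows without asserting a mechanism; the real dose–response
  between loaded MCM and firing is not quantified anywhere we know of, so the
  default is an explicit placeholder, and the linear case (exponent 1) is
  what the parameter-recovery validation pins down.
* **Reads.** Each of `n_reads` attempted incorporations is background with
  probability `bg_fraction` (uniform over the genome) or targets an origin
  drawn proportionally to catalog efficiency, *retained* with probability
  equal to the firing proficiency. Thinning — rather than renormalising the
  origin choice — is deliberate: a licensing block reduces nascent-DNA yield,
  so the origin component of the library shrinks while background is
  unaffected, and with exponent 1 the percent reduction of average origin
  activity recovers the blocked G1 fraction. Retained reads land at
  `origin ± offset` with a symmetric triangular offset on
  `[−fork_span, +fork_span]` (default 25 kb): sharp symmetric peaks without a
  fork-kinetics model. A schedule under which no origin can fire is rejected
  as degenerate unless the library is declared background-only.
* **Cells.** Populations draw a true phase (G1/S/G2M, default 0.5/0.3/0.2),
  put G1 at the 2N DAPI mode and G2M at 4N with S uniform in between, give S
  cells an EdU increment proportional to firing proficiency above a common
  background mode, let Cyclin A2 rise G1 → S → G2M, and apply multiplicative
  lognormal noise (sdlog 0.15) per channel. A fully blocked schedule therefore
  collapses S-phase EdU onto background while leaving DNA content and Cyclin
  A2 intact — the signature used to distinguish "cells enter S" from "origins
  fire".

Seeds are explicit arguments everywhere, simulations are bit-reproducible,
and the generators restore the global RNG state on exit.

What the simulator does **not** emulate: GC/mappability bias, copy-number
variation, late-S or dormant-origin firing, replication-stress signalling,
fork collapse, re-replication, MCM turnover, or imaging segmentation error.
Passing tests therefore validate the statistical machinery against the stated
generative model, not the full messiness of real libraries; real-data claims
still require the benchmarks run on actual sequencing.

## Cytometry gating

All gating operates on log10 intensities with Silverman-bandwidth kernel
density estimates, which makes every decision invariant to multiplicative
channel rescaling (gain changes). `gate_edu_positive()` thresholds at the
density valley between the two largest EdU modes; if no credible second mode
exists it falls back to an Otsu split of the binned log intensities, accepted
only when the between-class variance fraction reaches 0.8 — a single
log-normal mode tops out near 0.64, so an all-background population (complete
licensing block) is correctly reported as 0% EdU-positive rather than split
in half. `classify_cell_cycle()` finds the 2N DAPI mode as the largest
density mode `m`, stages EdU-negative cells with DAPI in `[0.75m, 1.5m)` as
G1 and at or above `1.5m` as G2/M, and assigns everything else to S; mid-S
cells are flagged as S cells inside the interquartile Cyclin A2 band of the
S population (a stated surrogate for drawing a box on intermediate Cyclin A2
levels). Replicate summaries use sample SD and SEM; paired comparisons use
the closed-form paired two-tailed t-test with defined behaviour for
zero-variance differences (identical vectors give t = 0, p = 1).

## Numerical choices and degenerate inputs

* Population (not sample) SD for sigma; the divisor must be positive, so a
  constant track is an error, as is a trimmed scope left with no variation.
* Half-open bin arithmetic lives in one internal function; a read at a bin
  boundary belongs to the right-hand bin, and the last bin of a chromosome
  may be partial.
* Reads on chromosomes absent from the layout are an error by default; a
  `lenient` flag skips and counts them instead.
* OLS with a degenerate predictor is an error; a constant response returns
  the zero fit exactly (slope 0, R² 0) instead of `lm()`'s numerical noise.
* Ties everywhere (peak maxima, ranking, matching) resolve to the leftmost
  coordinate.
* Truth matching is one-to-one nearest-first within tolerance; with zero
  calls, precision is undefined and reported as 0 with a flag.

## Problem sizes used in validation

The shipped analyses and tests run at desk scale, chosen once as realistic
miniatures of a genome-wide experiment: origin recovery and cross-library
regression on a 2-Gb genome (4 × 500 Mb) with 200 planted origins and 2×10⁶
reads at background fraction 0.2; treatment comparisons on a 50-Mb chromosome
with 100 origins and 10⁶ attempted reads at background 0.1 (bin-level
background ≈ 2 reads/kb, enough for a stable trimmed SD); cytometry on 2,000
cells per population. Origin efficiencies default to Uniform(0.2, 1):
severalfold heterogeneity is what real early-origin sets show, and it is what
makes per-origin regression across libraries informative. Under these
conditions the pipeline recovers planted origins with recall and precision
≥ 0.95, recovers blocked-G1 fractions of 1/3 and 2/3 as percent reductions
within 3 points at exponent 1, and self-comparisons of independent libraries
give slope ≈ 1 with R² > 0.9 — each asserted by the acceptance test suite and
recomputed by `scripts/acceptance.R`.

## Known limitations

* The licensing exponent is a placeholder for an unmeasured dose–response;
  conclusions that depend on its exact value should be treated as
  qualitative.
* Average origin activity includes the small background sigma level inside
  the central window, biasing percent reductions toward zero by roughly
  `background / (signal + background)` — under the shipped conditions well
  under one percentage point, but worth remembering for shallow libraries.
* The all-bins SD becomes peak-dominated at fine resolution; use the trimmed
  scope for any cross-condition magnitude comparison (the meta-profile
  pipeline already does).
* Gating assumes roughly lognormal intensity modes; strongly skewed
  autofluorescence or segmentation artefacts are not modelled.
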