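---
title: "Time-resolved ChEC-seq analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved ChEC-seq analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(checseq)
```

## The measurement and its model

ChEC-seq maps protein–DNA interactions by fusing a transcription factor (TF)
to micrococcal nuclease (MNase). Adding calcium to permeabilized cells
activates the nuclease, which cuts DNA near wherever the fusion protein
sits; small protected fragments are sequenced in paired-end mode at a series
of digestion times. Two properties of the data drive everything in this
package:

1. **Fragment ends are cut sites.** The informative observable is the
   terminal base of each fragment, not its midpoint. `end_counts()` adds one
   count at `start` and one at `end − 1` of every fragment (0-based
   half-open coordinates: `end` itself is outside the fragment, so the last
   base is `end − 1`; a length-one fragment contributes 2 at its single
   position). The track sum is exactly twice the fragment count, and the
   test suite asserts this conservation everywhere.

2. **Time is a dimension.** Sites bound stably by the TF are cleaved within
   seconds of calcium addition; sites the TF only samples transiently
   accumulate cleavage over minutes. Classifying sites by the time at which
   their signal peaks separates these two modes of DNA recognition.

## Normalization

Two schemes serve two purposes, and they are deliberately not
interchangeable:

- **Depth-scaled** (`depth_normalize()`): divide by the sample's total
  mapped read ends, multiply by its total mapped bases. Used for track
  display and for the composite maximum, where time points of different
  sequencing depth must be comparable. It is linear and preserves
  positionwise ratios.
- **Genome-scaled** (`genome_scale_normalize()`): multiply by
  genome size / fragments mapped. Used for cleavage profiles, where values
  should read as cuts per genome equivalent. The default genome size is
  12,495,000 bp (budding yeast); every function takes it as an argument, and
  the pipeline substitutes the actual genome total when analysing simulated
  genomes.

"Total mapped bases" is the sum of fragment lengths — the only reading of
that quantity consistent with paired-end fragment input. Free-MNase control
signal is subtracted after normalization, and negative values are *kept*:
profiles average differences across sites, and flooring at zero would bias
those averages upward.

## Peak calling

Peaks are called on the per-position maximum across all (depth-normalized)
time-point tracks, so a site qualifies whenever it is strong at *any* time.
The threshold is `fold × mean`, with `fold = 10` and the mean taken over
every base of every chromosome **including zeros** — with a sparse cleavage
track this zero-inclusive mean is small, which is what makes a simple 10×
rule workable. Qualifying positions at most `merge_dist = 30` bp apart merge
into one peak, reported half-open with midpoint `floor((start + end)/2)`.
Comparisons are inclusive (`≥ threshold`, gap `≤ 30`). The caller is tested
against an independent exhaustive scan-and-merge implementation on 1,000
random tracks, plus the boundary cases (gap of exactly 30 and 31; uniform
tracks, which can never reach 10× their own mean; all-zero tracks).

Peak-level specificity is summarized by an empirical FDR: the percentage of
TF peaks sharing ≥ 1 bp with any peak called on the free-MNase control,
which models untargeted mass-action cleavage. Replicate agreement is the
Spearman correlation of per-peak occupancy sums.

## Kinetic classification

`build_time_matrix()` sums cleavage in 50-bp windows around each peak
midpoint per time point; rows are Z-scored with the **population** (divide
by *n*) standard deviation — the convention of the classic clustering tools
this matrix format targets; either denominator is defensible, one had to be
fixed. Constant rows become all-zero and are flagged. k-means with k = 2
(Euclidean, 10 restarts, seeded) partitions the rows, and classes are
*named* by the data: the cluster whose members reach their row maximum
earlier on average is "fast". Ties in a row's maximum resolve to the
earliest time point, which is the conservative direction for calling a site
fast. Degenerate (constant) rows go to the slow class: they show no
detectable early maximum.

## Motif scoring with exact p-values

Peak windows (50 bp around the midpoint) are scored on both strands at
every offset against a position frequency matrix. Counts become
probabilities with a total pseudocount of 0.1 distributed by the background
(`(count + 0.1·bg) / (total + 0.1)`), then log₂-odds against a zero-order
background estimated from the genome's base composition (uniform available
by argument). Scores are discretized to 1,000 integer bins across the
attainable range; the exact null distribution of a background-generated
w-mer's integer score is built by convolving per-position distributions,
and the p-value of a score is the tail mass at or above it. Because
scanning sums the same integer cells, scan p-values and the DP distribution
agree *exactly*, and the test suite checks them against brute-force
enumeration of all 4^w words for w ≤ 6. A letter with zero probability
(possible only with a zero pseudocount) scores −∞; its null mass drops
below every finite score and any window offset containing it is skipped.

The best match per window is the highest-scoring offset/strand, ties broken
leftmost then + strand; windows with no N-free offset yield a no-match
sentinel and are dropped from class analyses with a logged count. Sites
with best-match p < 0.001 (strict) are "high-scoring"; all others,
including no-match windows, are "low-scoring". Matched random control sites
are drawn uniformly (chromosomes weighted by placeable length) with
rejection against ≥ 1 bp overlap of any excluded interval.

## Cleavage profiles and directionality

`oriented_end_profile()` averages the fragment-end track over 100-bp
windows centered on motif-match centers, reversing minus-strand windows so
offsets run 5′→3′ along the motif. The center of a width-w match is
`start + floor(w/2)` (the right-of-center base for even w, matching the
peak-midpoint convention). Profiles are genome-scale normalized per sample
and control-subtracted. Sites whose window would cross a chromosome edge
are skipped and counted, so the profile is a mean over included sites (for
interior sites this equals pooled-count averaging).

Directionality is quantified as `(U − D)/(U + D)` over summed upstream and
downstream signal, excluding the match interior — interior cleavage (e.g.
within the linker of a bipartite motif) is a separate phenomenon. The index
is computed on the raw count profile, whose sums are nonnegative, keeping
it in [−1, 1]; on a control-subtracted profile a near-zero negative
downstream sum can push the ratio outside its range. Reflecting every
site's strand negates the index exactly for even motif widths.

One empirical subtlety dictated where the pipeline measures this index.
Orientation comes from the best motif match, and for degenerate sites the
best match can genuinely lie on the wrong strand (a two-mismatch instance
may read closer to the reverse complement of the consensus than to the
consensus itself). Such sites enter the high-scoring class near the p-value
boundary, and their mis-oriented signal dilutes a directionality index
computed over all high-scoring sites. The pipeline therefore reports the
index over high-scoring sites in the **fast** kinetic class — sites whose
orientation is trustworthy — at that subset's maximal-signal time point;
per-motif-class profiles are still computed and exported. This matches the
biology the index is meant to capture: directional cleavage is a property
of genuinely bound consensus sites.

For mean-signal figures, `average_signal_ci()` provides a percentile
bootstrap band (default 200 resamples, 95%), resampling sites; site signal
distributions are heavy-tailed, so a normal approximation would be
anti-conservative.

## DNA shape

Shape features are predicted by sliding-pentamer lookup: each pentamer's
table entry supplies minor groove width (Å) and propeller twist (degrees)
for its center base, and roll/helix twist (degrees) for the two steps
flanking the center; each interior step averages the contributions of the
two pentamers that flank it. This step-assignment convention is documented
here precisely because it is a choice: it is the standard sliding-window
treatment, and it preserves the physical reverse-complement symmetry
(base-centered features equal for a pentamer and its reverse complement;
step features swap), which the suite verifies on 1,000 random sequences.
Pentamers containing N, or absent from a partial table, yield missing
values that are excluded from class averages with per-offset counts
tracked.

The pentamer value table is consumed as data (TSV: pentamer, MGW, ProT,
Roll1, Roll2, HelT1, HelT2), not derived; published tables can be supplied
in that dialect. The package ships a generator for a *synthetic*,
symmetry-consistent table (`symmetric_shape_table()`), clearly labelled as
such, used by the tests and simulations.

Class profiles are compared per feature by Pearson correlation of the two
mean-profile vectors and a two-sample KS test on the same vectors treated
as value samples. Whether such comparisons should instead pool per-site
values is ambiguous; the mean-vector mode is the default and the per-site
values remain accessible for the other reading.

## Sequence vs shape discrimination

Sequence is one-hot encoded (4 columns per position); shape features are
concatenated per position and min-max scaled to [0, 1] per feature over the
training set, with scaling parameters stored — applied to held-out data the
values may leave [0, 1] and are retained unclipped. Models are linear
regression on 0/1 labels with an L2 penalty (λ = 1 by default; the solve is
closed-form with an unpenalized intercept). A linear rather than logistic
fit is intentional: AUROC is rank-based, so the monotone link is
immaterial. AUROC is computed from predictions pooled over 10-fold
cross-validation with seeded folds (the in-sample AUROC is also reported);
it equals the normalized Mann–Whitney statistic, ties counted half, and the
suite checks it against exhaustive pair counting and an independent
implementation. At the null (permuted labels, 1,000 sites) the
cross-validated AUROC sits within 0.5 ± 0.05; as λ → ∞ predictions collapse
to the training-label mean.

## The simulator: what it emulates and what it does not

`simulate_genome()`/`simulate_timecourse()` define the package's reference
study conditions; all defaults were fixed as part of the generator's design
and are not tuned per analysis:

- **Genome**: 100 kb, single chromosome, i.i.d. bases at GC 0.38
  (budding-yeast-like). 200 *fast* sites carry the exact consensus of a
  strong 8-bp motif (85% consensus counts per position); 200 *slow* sites
  carry instances with 2 mismatches, on random strands, at non-overlapping
  positions (≥ 160 bp apart) recorded in a manifest.
- **Kinetics**: a 6-point time course (10, 30, 60, 150, 600, 1200 s)
  spanning seconds to 20 minutes. Expected fragments per site are
  `A(1 − e^{−t/15 s})` for fast sites and
  `A(1 − e^{−(t−150 s)/350 s})₊` for slow ones, with saturation amplitude
  A = 300 modulated by a per-site lognormal factor (log-sd 0.25). Slow
  kinetics are *delayed onset*, not reduced amplitude: a slow site's
  detectability is a matter of when, not whether, and the time of maximal
  signal is what the classifier exploits.
- **Cut geometry**: cut positions fall ~8 ± 2 bp outside the motif edges.
  `symmetric` mode protects the motif (one cut each side); `upstream_only`
  mode places both fragment ends 5′ of the motif in its own orientation,
  emulating a fusion whose nuclease reaches only one side.
- **Background and control**: 20,000 uniform background fragments per
  sample (~0.4 ends/bp, putting integer-count thresholding in a realistic
  regime) plus 30 shared mass-action hotspots with lognormal amplitudes
  (median 120) placed away from planted sites; hotspot cleavage ramps with
  digestion time in TF samples and appears at full strength in the
  free-MNase control, which contains no site-targeted signal.

The simulator does **not** model MNase sequence preference, nucleosome
occupancy, chromatin accessibility, fragment-length biases of library
preparation, or the late-time decay of fast-site signal seen when bound
sites are digested away (fast-site expected counts here are monotone
saturating). Passing the recovery, kinetic-agreement and classification
properties on these fixtures therefore demonstrates the correctness of the
computational machinery under a controlled generative model — not
performance on real chromatin, where thresholds and classes interact with
biases the simulator deliberately omits.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline at the
reference conditions above (≈ 400 planted sites, ≈ 500k fragments across
samples), the peak-caller/oracle comparison on 1,000 random tracks up to
10 kb, exhaustive motif-p-value enumeration up to w = 6, and
reverse-complement shape symmetry on 1,000 random sequences — sizes chosen
so the whole suite completes in a couple of minutes while still exercising
every stage end to end. Every stochastic step takes an explicit seed; one
master seed derives all stage seeds, and identical configurations reproduce
identical results bit for bit (asserted in the suite).

## Known limitations

- Peak counts and thresholds on real yeast data depend on masking of
  repetitive regions (telomeres, rDNA), which is not implemented.
- The k = 2 kinetic partition is the method's design; data with more than
  two temporal modes would need the exported matrix and a different k
  (supported by `cluster_kinetics()` but not by the fast/slow naming).
- Orientation of degenerate motif matches is inherently unreliable (see
  above); downstream strand-sensitive analyses should restrict to
  high-confidence sites.
- The KS test on mean-profile vectors treats offsets as exchangeable
  samples; it is a similarity summary, not a calibrated test of the
  per-site distributions.
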