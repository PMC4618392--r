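# checseq

Analysis of **ChEC-seq** (chromatin endogenous cleavage with high-throughput
sequencing) time courses. In ChEC, a transcription factor (TF) fused to
micrococcal nuclease (MNase) cleaves DNA near its binding sites when calcium
is added; sequencing the released fragments at several digestion time points
maps binding sites *and* their cleavage kinetics. `checseq` implements the
complete downstream analysis for such experiments, from mapped paired-end
fragments to kinetically classified, motif-scored, shape-profiled binding
sites — plus a synthetic time-course simulator so the whole pipeline runs at
desk scale, with no external data.

It is aimed at genomicists analysing ChEC-seq (or similar cleavage-mapping)
data in budding yeast or other compact genomes, and at method developers who
need a tested reference implementation of its statistical machinery.

## What it computes

- **Fragment-end tracks.** Each fragment contributes one count at each
  terminus (both are MNase cut sites). Two normalizations:
  depth-scaled, `v' = v / N_ends × N_mapped_bases`, for track display; and
  genome-scaled, `v' = v × G / N_fragments` (default
  `G` = 12,495,000 bp, the budding yeast genome), for profile analysis;
  free-MNase control subtraction, negatives retained.
- **Peak calling** on the per-position maximum over all time points:
  positions with signal ≥ 10 × the zero-inclusive genome-wide mean,
  merged when ≤ 30 bp apart.
- **Kinetic classes.** Peak × time-point occupancy matrix (50-bp windows),
  row Z-scores (population SD), k-means with k = 2; the class reaching
  maximal signal earlier is *fast*, the other *slow*. Peak-level FDR as the
  percentage of TF peaks overlapping free-MNase control peaks; replicate
  reproducibility by Spearman correlation of peak occupancies.
- **Motif scoring** of 50-bp peak windows against a position frequency
  matrix: log₂-odds with background-distributed pseudocount, and *exact*
  p-values by dynamic programming over the discretized null score
  distribution (the probability that a background w-mer scores at least as
  high). Sites split at p < 0.001 into high- and low-scoring classes.
- **Cleavage profiles**: strand-oriented average fragment-end profiles
  around motif-match centers, control-subtracted, with a scalar asymmetry
  index `(U − D)/(U + D)` quantifying upstream-vs-downstream cleavage.
- **DNA shape**: minor groove width, propeller twist, roll and helix twist
  predicted by sliding-pentamer lookup; class-average profiles compared by
  Pearson correlation and two-sample Kolmogorov–Smirnov test.
- **Sequence vs shape discrimination**: one-hot sequence and min-max-scaled
  shape encodings, L2-regularized (ridge) linear regression on 0/1 class
  labels, AUROC from cross-validated predictions (0.5 = random classifier).
- **Simulation**: genomes with planted consensus (fast) and degenerate
  (slow) motif instances, time-stamped cleavage fragments with
  class-dependent kinetics, symmetric or upstream-only cut geometry, and an
  untargeted free-MNase control.

## Worked example

```r
library(checseq)

cfg <- simulation_config()            # 100-kb genome, 200 fast + 200 slow sites
sim <- simulate_genome(cfg)
tc  <- simulate_timecourse(sim)

res <- run_pipeline(tc$fragments, tc$control, sim$seqs,
                    motif_counts = cfg$motif_counts,
                    shape_table  = symmetric_shape_table(7),
                    seed = 11)
res
#> <chec_pipeline>
#>   peaks:379 (threshold 887.69)
#>   FDR vs control: 1.06 %
#>   motif classes: high 254 / low 124

matched <- match_planted_sites(res$peaks, sim$manifest)
mean(matched$recovered)               # fraction of planted sites called
#> [1] 0.9425

glance(res$kinetics)                  # class sizes and mean time of max signal
#> # A tibble: 2 × 3
#>   class     n mean_argmax
#>   <chr> <int>       <dbl>
#> 1 fast    200        110.
#> 2 slow    179       1200

res$discrimination$high_vs_low$sequence$auroc   # sequence model
#> [1] 0.9110998
res$discrimination$high_vs_low$shape$auroc      # shape model
#> [1] 0.8100076
```

Interpretation: of 400 planted sites, 94% are recovered as peaks; the
k-means partition splits them into an early-maximum (fast) and a
late-maximum (slow) class; and a sequence encoding discriminates
high- from low-scoring sites better than a shape encoding, as expected when
class labels derive from motif score. `autoplot()` methods produce the
kinetic heatmap, profile and shape-profile figures;
`tidy()`/`glance()` return the clustering and ridge results as tibbles.

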