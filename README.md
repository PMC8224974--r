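# reservoiR

Promoter-centric integration of many DNA-binding-protein (DBP) ChIP-seq
experiments measured in a single cell state: replicate consensus peaks,
binary promoter × DBP occupancy, constrained permutation enrichment at
promoters and repeat families, TSS and element-centered coverage
metaprofiles, TPM expression quantification — and the classification of
**reservoir promoters**: promoters loaded with many DBPs that nonetheless
produce no steady-state RNA, split into **ghosts** (no nascent
transcription either, PRO-seq TPM < 0.001) and **zombies** (nascent but no
mature RNA).

## Who this is for

Anyone with per-replicate peak calls for dozens-to-hundreds of ChIP-seq
targets in one cell type (plus a gene annotation, RNA-seq/PRO-seq counts or
read intervals, and optionally repeat and super-enhancer annotations) who
wants reproducible, promoter-level answers to: which DBPs bind where, which
binding is more than chance, and which promoters break the
binding-expression rule.

## The core quantities

* **Consensus peak** — connected component of ≥ 1 bp overlaps containing a
  peak from *every* replicate, reported as the union span; DBPs are kept
  when their consensus count reaches `max(250, 15th percentile)`.
* **Occupancy** — binary promoter × DBP matrix over TSS ± 3 kb windows; a
  promoter's *binding events* is its row sum.
* **Enrichment Z** — `(observed − null mean)/null sd` where the null
  relocates peaks uniformly, preserving peak count, widths, and
  per-chromosome counts; a calibrated (mid-p, add-one) two-sided empirical
  p-value and a Fisher 2×2 p-value are reported alongside.
* **Reservoir** — binding events > 7 and total RNA-seq TPM < 0.001; ghosts
  additionally have PRO-seq window TPM < 0.001; the *conservative* subset
  has TPM < 0.001 in every total/polyA sample over the whole 6 kb window.

Every stage is validated on synthetic data with planted ground truth; the
generator (`sim_config()`, `write_synthetic_dataset()`) is part of the
package.

## Worked example

Simulate a small study (300 genes, 16 DBPs, 12 planted reservoirs), run the
pipeline from the written files, and inspect the results:

```r
library(reservoiR)

cfg <- sim_config(seed = 42, n_genes = 300, n_chromosomes = 2,
                  chrom_length = 3e6, n_dbps = 16, n_low_affinity = 3,
                  n_reservoirs = 12, bg_peaks_per_dbp = 60,
                  repeat_family_copies = 60, n_superenhancers = 6)
write_synthetic_dataset(cfg, "demo_ds", coverage = FALSE)

res <- run_pipeline("demo_ds", "demo_out",
                    thresholds = analysis_thresholds(min_consensus_peaks = 50,
                                                     peak_percentile = 0,
                                                     n_permutations = 200,
                                                     seed = 42),
                    stages = c("enrich", "reservoirs", "report"))

res$occupancy
#> OccupancyMatrix: 300 promoters x 16 DBPs; median binding events per promoter: 7

res$promoter_regression
#> RegressionFit: slope = 0.574, intercept = 27.23, r = 0.890, p = 3.98e-06 (n = 16)

res$reservoir_calls
#> ReservoirCalls: 300 promoters; 12 reservoirs ( 7 ghost / 5 zombie )

res$promoter_enrichment[["DBP16"]]
#> PermutationNull: DBP16 vs promoters - obs 181, null 96.4 +/- 7.52, z = 11.25, p_emp = 0.00995 (enriched)

round(sort(res$repeat_family$z["DBP16", ], decreasing = TRUE), 1)
#>  SVA  MIR  Alu   L1
#> 21.0  0.4 -1.4 -1.6
```

Reading the output: the 16-DBP panel shows the expected linear relation
between a DBP's peak count and the promoters it touches (slope 0.57 here);
all 12 planted reservoirs are recovered with the correct 7/5 ghost/zombie
split; DBP16 binds promoters ~11 SD above its shuffle null; and DBP16 — one
of the planted repeat-family binders — stands out on the planted SVA family
(Z = 21) while staying at chance on the background families. The
per-promoter summary (`demo_out/master_promoters.tsv`) has one row per
promoter with binding events, TPMs, expression bin, reservoir/ghost/zombie
calls, neighbor class, super-enhancer overlap and the conservative flag.

A thin command-line wrapper is provided at `inst/scripts/pipeline.R`
(`simulate` and `run` subcommands).

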