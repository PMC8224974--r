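---
title: "Methods: promoter occupancy, permutation enrichment and reservoir promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter occupancy, permutation enrichment and reservoir promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reservoiR)
```

## The problem

When dozens to hundreds of DNA-binding proteins (DBPs — transcription
factors, cofactors, Pol II machinery, chromatin modifiers) are each profiled
by ChIP-seq in the *same* cell state, the data can be turned around and read
promoter-centrically: for every annotated promoter, which DBPs sit on it,
and how does that combinatorial load relate to the promoter's
transcriptional output? Most promoters follow a simple monotone rule — more
distinct DBPs bound, more RNA produced. The interesting biology is in the
exceptions: promoters loaded with many DBPs that nonetheless produce no
steady-state RNA. This package calls such promoters **reservoirs**, splits
them by nascent transcription into **ghosts** (no PRO-seq signal either) and
**zombies** (nascent transcription without mature RNA), and provides the
supporting machinery: replicate consensus peaks, binary occupancy matrices,
constrained permutation enrichment (promoters and repeat families),
TSS/element metaprofiles, and TPM quantification.

Because the full analysis at genome scale depends on very large external
datasets, the package is validated end-to-end on synthetic data with planted
ground truth: every classifier and statistic is exercised against
configurations where the right answer is known by construction.

## Coordinate conventions

All on-disk formats the pipeline reads and writes (`chrom.sizes`, BED,
broadPeak, bedGraph, UCSC rmsk tables) are 0-based half-open; GTF is 1-based
closed. In memory everything is a `GRanges` (1-based closed), the canonical
container in this language's genomics stack. Conversion happens exactly once
at each I/O boundary (`read_peaks()`, `write_bed()`, ...), which is the same
"single convention" discipline that motivates fixing a coordinate system in
the first place.

A promoter window is `tss ± flank` with `flank = 3000` bp by default — the
"6 kb window". The TSS is the strand-aware 5' end of the annotated gene
span; on the minus strand that is the last covered base. Windows are clipped
at chromosome ends. The canonical chromosome set defaults to chr1–chr22,
chrX, chrY (intersected with the assembly; configurable), and peaks off it
are dropped with a logged count.

## Consensus peaks

A consensus peak requires support from **every** replicate: replicate peaks
are joined into an overlap graph (edge = at least 1 bp of overlap; abutting
intervals do not count), and each connected component containing at least
one peak from every replicate is reported as the component's union span.
Because interval overlap is transitive along a chain, components are exactly
the maximal merged regions, so the implementation is a sweep line over
sorted starts rather than an explicit graph; its equivalence to a
brute-force all-pairs/component-search oracle is asserted on hundreds of
random instances in the test suite. Chained, non-transitive overlaps (A–B
and B–C overlap, A and C do not) therefore merge into one region; the
alternative "every pair must mutually overlap" semantics is deliberately not
offered, because it is order-dependent.

A replicate with zero peaks makes its DBP unreproducible (empty consensus).
DBPs are then filtered by consensus peak count: the threshold is
`max(min_peaks, q)` with `min_peaks = 250` and `q` the nearest-rank 15th
percentile of the observed count distribution (the smallest count whose rank
is at least `ceiling(0.15 n)`). The nearest-rank rule is fixed because it is
exact on the data and involves no interpolation choice.

## Occupancy and simple fits

The occupancy matrix is binary: promoter × DBP, 1 when any consensus peak of
the DBP touches the window by at least 1 bp. Multiple peaks in one window
still contribute a single 1 — binding *events* are counted at the window
level, and a promoter's "binding events" is its row sum. The peak-count
versus promoter-overlap trend is an ordinary least-squares fit with
intercept (feature-unit overlap counts on the y axis). Peak feature
annotation assigns each peak by its midpoint with fixed precedence
promoter/TSS > TTS > exon > intron > intergenic; without exon models the
gene body counts as intronic. Binary profile clustering uses Euclidean
distance and complete linkage (configurable) — the choice of metric on
binary vectors is a genuine free parameter, and the defaults are recorded in
the output metadata.

## Permutation enrichment

The null model relocates peaks uniformly while preserving (i) the number of
peaks, (ii) the multiset of peak widths, and (iii) the per-chromosome peak
counts. Shuffled peaks may overlap each other; no rejection is applied —
this is the simplest null consistent with the three constraints. The test
statistic is, by default, the number of **peaks** overlapping at least one
feature (peak units make the Fisher 2×2 rows sum to the peak count); the
feature-unit statistic is available via `unit = "features"`.

From `n_perm` shuffles (default 1000) the package reports the Z-score
`(obs − mean)/sd` (undefined when `sd = 0`), a two-sided empirical p-value,
and a Fisher exact p-value on the documented 2×2 table
`[obs, n − obs; round(null mean), n − round(null mean)]`. The empirical
p-value uses an add-one correction (it can never be 0) and the **mid-p**
tie rule: draws equal to the observed count contribute half to each tail.
The overlap count is discrete, so full-weight ties make the p-value
conservative (stochastically larger than uniform, with an atom at 1);
the mid-p construction is the calibrated version of the same estimator, and
the test suite checks calibration directly — on 200 DBP × feature-set pairs
drawn from the same uniform null as the shuffle, the p-values pass a
Kolmogorov–Smirnov uniformity test and `|Z| > 3` is rare. For that check to
be meaningful the overlap statistic must have wide support; the calibration
fixture therefore uses 400 features × 3 kb and 500 peaks per DBP on a
2 × 10 Mb genome (a statistic with only a handful of attainable values
would fail a continuous-uniformity test for resolution reasons alone).

Every (DBP, feature-set) pair derives its own RNG substream from
`(master seed, dbp, feature-set id)` via a fixed string hash, so results are
independent of execution order and reproducible one pair at a time.

Biotype bias (lncRNA versus mRNA promoters) and reservoir-versus-rest DBP
bias use the plain chi-squared statistic on the 2×2 table without continuity
correction, with effects reported as log2(observed/expected) on the bound
cell and as the binding-rate fold change respectively. Over-representation
of a class among reservoirs uses the upper-tail hypergeometric probability.

## Metaprofiles

A TSS metaprofile is the per-offset mean of an oriented coverage slice over
anchors, offsets running −flank to flank−1 in transcription direction:
minus-strand windows are reversed so downstream always means
transcription-downstream. The slice is `[tss − flank, tss + flank − 1]` on
the plus strand and `[tss − flank + 1, tss + flank]` on the minus strand;
with an even window length this is the unique choice that makes profiles
exactly invariant under mirroring the genome (coordinates and strands
together), an invariance the tests assert to float precision along with
additivity over tracks. Windows truncated by chromosome ends are excluded by
default (`zero_pad` keeps them). The confidence band is the normal 95%
interval `mean ± 1.96 · sqrt(var/n)` per offset.

Element-centered profiles rescale variable-length element bodies to a fixed
bin count by linear interpolation of per-bp coverage at bin-center
fractional positions (robust for elements shorter than the bin count), with
fixed-width flanks binned by plain means. Profile-shape clustering uses
Euclidean distance and complete linkage with a configurable cut height
(default 65, retained for parity with common practice; it is meaningful only
when profiles share a scale — per-profile max-normalization is available but
off by default). Cluster labels are renumbered in order of first appearance
so labelling is deterministic.

## Expression

TPM is computed as `rate = count/length`, `TPM = 1e6 · rate / sum(rates)`;
each sample column sums to one million by construction, and the tests assert
this to 1e-6 relative tolerance. Promoter-window quantification uses
multi-overlap counting: a read increments every window it touches, and the
window width is the effective length. Expression bins on the TPM scale are
off `< 0.001`, low `(0.001, 0.137]`, medium `(0.137, 3]`, high `> 3`;
exactly 0.001 is "low" (the off rule is strict `<`). The binding–expression
correlation reports Pearson on `log10(TPM + 0.001)` (pseudocount = the off
threshold) together with Spearman, which needs no transform. Replicates are
averaged per assay before thresholding.

## Reservoir classification

A **reservoir** has strictly more than `min_dbps = 7` binding events and
total RNA-seq TPM strictly below `0.001`. The default threshold of 7 is
fixed; an optional "valley" mode locates the deepest density minimum between
the two largest modes of the (typically bimodal) binding-event distribution
and falls back to the fixed value with a warning when the distribution is
not bimodal.

Reservoirs are then characterized, never deleted:

* **Super-enhancer overlap** is a flag (≥ 1 bp window overlap with SE
  intervals already in the working assembly); SE-overlapping reservoirs are
  excluded from the neighborhood-window comparison only.
* **Neighbor classes** use TSS-to-TSS distances with strict `≤ 1000` bp and
  a fixed precedence — `multiple_nearby` (≥ 2 other TSSs within range, any
  strand), then `bidirectional` (opposite-strand TSS upstream), then
  `same_strand_nearby`, else `none`. The categories overlap as written
  prose; mutual exclusivity requires an order, and "multiple wins" is the
  choice here because reported category percentages only make sense
  disjointly. "Upstream" is measured against the query gene's own
  orientation. The implementation is validated against an exhaustive
  hand-written truth table over every configuration of up to 3 neighbors ×
  strands × offsets {250, 999, 1000, 1001} bp.
* **Neighborhood expression** uses 5-gene sliding windows per chromosome
  (full windows only): the mean TPM of the four flanking genes, center
  excluded, compared between reservoir-centered and other windows by
  two-sided Wilcoxon rank-sum.
* **Ghost/zombie** splits reservoirs by PRO-seq TPM quantified on the same
  promoter window: ghost when below 0.001, zombie otherwise.
* The **conservative** subset requires window TPM below 0.001 in *every*
  total and polyA RNA sample — no expression anywhere in the 6 kb window,
  not merely none attributed to the gene model. PRO-seq is deliberately not
  part of the conservative criterion; ghosts and conservative reservoirs
  remain independent annotations.
* **Pol II binding** is occupancy by any DBP on a configurable name list
  (empty by default — the synthetic panel has no Pol II).

## The synthetic-data generator

The generator is first-class, tested code, and its defaults define the
conditions under which the package validates itself: 2 chromosomes × 10 Mb;
1,000 genes on a regular grid of ~20 kb slots (TSS mid-slot, 8 kb spans, so
promoter windows never cross slots); 30% lncRNA; 40 DBPs × 2 replicates;
log-normal peak widths (median 300 bp, clamped to [150, 2500]); replicate
jitter up to ±50 bp and optional dropout; 300 background peaks per DBP kept
clear of promoter windows; a planted repeat family (200 × 1.5 kb copies in
slot tails, away from every window) bound by a dedicated 3-DBP subset; 20
super-enhancers (mostly over heavily-bound expressed promoters, two over
reservoirs so the overlap flag is exercised); and 50 planted reservoirs
(60% ghosts), over-sampling lncRNA promoters 3:1 to echo their real-data
over-representation.

Expression follows the planted log-linear model
`log10(TPM + 0.001) = 0.1 · n_dbps + Normal(0, 0.5)` for normal genes, with
two margins that make recovery unambiguous rather than probabilistic:
planted reservoirs have at least 12 binding events and exactly zero RNA in
every steady-state sample, and non-reservoir genes above the binding
threshold have TPM at least 0.01. Two further structural margins matter:
the minimum peak width (150 bp) exceeds twice the replicate jitter, so
jittered replicate copies always still overlap and consensus never loses a
planted peak; and reservoir DBP sets are drawn only from the high-affinity
block of the panel, so the bottom-percentile reproducibility filter (which
removes low-affinity DBPs) can never delete a planted reservoir's binding
events. Zombies receive strong PRO-seq reads over their windows; ghosts
receive none, and the grid layout guarantees no neighboring gene's reads can
bleed into a ghost's window. Everything derives from one master seed through
named substreams, and the emitted files are byte-identical across runs.

What the generator does **not** emulate: read-level sequencing noise,
mappability and GC structure, overlapping gene models, enhancer–promoter
contacts, and peak-caller artifacts. Tests passing on this generator
demonstrate that the pipeline's logic is correct under its stated
definitions — not that those definitions are robust to every artifact of
real data.

## Validation scale and runtime choices

The randomized equivalence and calibration checks use sizes chosen to give
stable statistics while keeping a full test run in the low minutes: 200
random consensus instances (2–4 replicates × ≤ 30 peaks) against the
brute-force oracle; 40 DBPs × 5 feature sets × 200 permutations for
calibration; 100 permutations for the planted-family recovery; the default
1,000-gene study for reservoir recovery, trend recovery and TPM
conservation; and a 120-gene study for byte-identical determinism. The
`scripts/acceptance.R` entry point recomputes all of these from scratch for
any seed.

## Known limitations

* The consensus rule is all-replicates intersection with union spans; it has
  no notion of peak score, and IDR-style reproducibility modelling is out of
  scope.
* The permutation null controls count, width and chromosome only; GC- or
  mappability-matched shuffles are out of scope.
* The Fisher 2×2 built from the rounded null mean is a pragmatic summary,
  not an exact test; the empirical p-value is the primary statistic and is
  always reported alongside.
* Peak feature annotation is midpoint-based with a fixed precedence; exact
  concordance with annotators that use full-interval logic is not promised.
* `ExpressionMatrix` columns are renormalized per sample; cross-sample
  comparisons inherit TPM's usual compositional caveats.
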