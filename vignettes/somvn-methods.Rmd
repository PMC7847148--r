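---
title: "Learning chromatin accessibility signal shapes with variable-neighborhood SOMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning chromatin accessibility signal shapes with variable-neighborhood SOMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somvn)
```

## The problem

Chromatin accessibility assays (DNase-seq, ATAC-seq) produce one genome-wide
signal track per sample. Assigning regulatory chromatin states — promoter,
enhancer, weak/quiescent — usually requires several histone-mark assays (as in
ChromHMM) or peak calling, which discards most of the genome. The premise of
this package is that the local *shape* of the accessibility signal alone
carries enough information to assign such states: promoters tend to show
single high summits, enhancers lower and often multimodal summits, and
quiescent chromatin stays near the floor.

The workflow learns a library of representative signal shapes from one
track, labels each shape with the regulatory-element (RE) class it overlaps
most, and then annotates unseen chromosomes by matching windows of signal
against the labeled shapes.

## The model

**Representation.** Signal is binned at 50 bp (RPKM per bin), clipped per
chromosome at its 99.9th percentile value and scaled to [0, 1]
(`normalize_signal()`). The exact scheme is a package design choice: clipping
caps sequencing-depth-driven outlier summits without altering shape, and
per-chromosome scaling keeps chromosomes with different signal-to-noise on a
common footing. Raw values are kept for magnitude-based evaluation (the
5 RPKM floor). Training regions are disjoint 4 kb windows (80 bins);
assignment windows are 8 kb, overlapping by 4 kb.

**Similarity.** All matching uses normalized cross-correlation (NCC): the
Pearson correlation of mean-centered, variance-normalized segments, maximized
over a small set of integer-bin lags where shifts are tolerated. NCC is
invariant to positive affine transforms of either vector, which makes merge
thresholds scale-free; its flip side — a faint bump correlates perfectly with
a tall one — drives several of the design choices below. Flat (zero-variance)
segments are defined as uncorrelated (score 0) so quiescent signal can never
spuriously match a flat template through the correlation route.

**SOM with variable neighborhoods.** Shapes are learned by a mini-batch
self-organizing map on a rectangular grid (default 10x10), each node holding
one 80-bin weight vector initialized from a sampled training region. Every
batch, regions map to their best node by lag-0 NCC, and each node moves
toward its neighborhood's data:

    w <- w + alpha(t) * hbar * (xbar - w)

where membership is *winner-centric*: a region reaches every node within its
winner's neighborhood radius, `xbar` is the kernel-weighted member mean and
`hbar` the mean Gaussian kernel weight `exp(-d^2 / (2 r^2))` over the
Chebyshev grid distance `d`. The radius of a winner scales with its summit:

    r(t) = r0 * exp(-t / T) * (1 + lambda * max_weight / global_max)

High-summit shapes therefore broadcast their pattern over a wider grid patch.
This is the variable-neighborhood mechanism: accessibility data are
overwhelmingly flat, and without the boost the rare high-summit patterns are
averaged away. At `lambda = 0` and `batch_size = 1` the rule reduces exactly
to the classic per-sample SOM update (a property the test suite checks
against an independently written scalar implementation).

## Numerical choices that mattered

These were all forced by observed failure modes on the package's own
synthetic benchmark, and each is config-exposed:

* **Radius end point** (`radius_end = 0.1`). The textbook schedule decays the
  radius from `r0` to 1 grid cell. With amplitude-invariant matching that is
  not enough: any node still receiving high-summit neighbors keeps a faint
  copy of their bump, faint copies correlate near 1 with the real thing, and
  the merge step then collapses the entire grid into one family. Letting the
  base radius decay below one cell gives every node a final phase in which it
  is shaped by its own winners only.
* **Learning-rate floor** (`alpha_min = 0.1`). The learning rate decays
  exponentially from `alpha0` to `alpha_min` rather than sharing the radius'
  exact time constant; otherwise the late, narrow-neighborhood phase has too
  little gain left to erase the blends accumulated while neighborhoods were
  wide.
* **Match-score quantization** (`match_resolution = 0.01`). Best-match scores
  are rounded to this resolution before the argmax, with ties going to the
  lowest node index. NCC differences below the noise level carry no
  information, and without quantization, near-identical regions scatter
  across near-identical nodes (in one diagnostic, 53 promoter regions claimed
  50 private nodes), starving the grid of clean low-signal nodes.
* **Dead-node pruning.** Nodes that win no region at the end of training
  retain frozen mid-training transients; they are dropped before merging,
  since their blended weights would bridge otherwise distinct shape families.

## Merging, association, assignment

**Merging** (`merge_shapes()`). Learned shapes are often shifted versions of
one another, because peaks sit at arbitrary phases relative to the
segmentation grid. Greedy agglomeration repeatedly merges the
highest-scoring pair with max-NCC at or above 0.75 within a +/-20-bin lag,
replacing the pair with its lag-aligned, support-weighted mean — weighting by
each shape's region support keeps a dominant shape's amplitude from being
diluted by a faint variant, approximating the mean over member regions. The
result is a flat library in which no pair reaches the threshold.

**Association** (`associate_shapes()`). Each training region is matched to
its best shape; per shape, the bp overlap between matched regions and the
simplified annotation classes is accumulated. The 15-state ChromHMM space is
simplified to promoter (TssA, TssAFlnk, TssBiv, BivFlnk), enhancer (EnhG,
Enh, EnhBiv), weak (Het, Quies), and other (transcription, ZNF/repeats,
Polycomb). `other` enters the coverage denominator but never wins a label.
The winning label must reach the association cutoff (default 0.5 of matched
bp), else the shape stays `unknown`. A magnitude-only baseline
(`associate_magnitudes()`) replaces shapes with equal-frequency quantile bins
of each region's maximum raw RPKM.

**Assignment** (`match_windows()`, `consolidate()`). Unseen signal is cut
into 8 kb windows stepped by 4 kb and scored by *containment*: the shape
slides along the window and the best start offset wins, so a 4 kb pattern
anywhere inside the window is found regardless of phase. Each window records
its best and second-best shapes and the ambiguity `second/best` (in [0, 1];
confident windows are near 0). The overlapping windows are then reduced by
weighted-interval-scheduling dynamic programming to a non-overlapping subset
that first maximizes covered bp — without that constraint the empty set would
trivially minimize ambiguity — and among coverage-maximal subsets minimizes
the ambiguity sum, with ties resolved toward earlier windows. Windows where
no shape scores positively (flat signal) fall back to the weak-associated
shape with the lowest summit, reflecting that flat signal is the quiescent
majority; the ambiguity ratio is direction-corrected (second-best over best)
so that minimizing its sum prefers confident windows.

## Null models and evaluation

Two permutation nulls validate that learned shapes are non-arbitrary:

* **Permuted signal**: bin values are shuffled per chromosome before
  segmentation, then shapes are learned and associated as usual. Matched
  NCC scores of real regions against the real versus the null library are
  compared with a one-sided Wilcoxon rank-sum test, grouped by the region's
  RE annotation, at a Bonferroni-adjusted level (0.05 divided by the number
  of comparable RE groups times the number of samples).
* **Permuted annotations**: interval positions are shuffled within each
  chromosome — the interval-length multiset, mnemonics, and the
  inter-interval gap-length multiset are all preserved exactly, so genome
  coverage is unchanged — and the association step is repeated.

Evaluation is region-level: a selected window's truth is the simplified
class covering most of its bp (ties broken promoter > enhancer > weak >
other); per class, precision `tp/(tp+fp)` and recall `tp/(tp+fn)` are
reported, with `NA` when a denominator is empty. An enhancer-vs-rest PR-AUC
over a containment-based ranking score, an optional 5 RPKM evaluation floor
on raw signal, optional promoter exclusion, and a Davies-Bouldin diagnostic
for region-size selection round out the toolkit.

## The synthetic benchmark

`simulate_genome()` generates the study conditions used throughout the
tests: regions laid end-to-end on one synthetic chromosome, class mix
promoter/enhancer/weak = 0.1/0.1/0.8 (weak-dominant, as in real genomes),
promoter summits of 20 RPKM (single Gaussian), enhancer summits of 10 RPKM
(two modes), background 0.5 RPKM, i.i.d. Gaussian noise at 5% of the class
summit, and annotations that exactly tile the regions (a boundary-jitter
option exercises partial-overlap paths). Summit positions are jittered
uniformly by up to +/-250 bp: real peaks sit at arbitrary phase relative to
the segmentation grid, and this structured diversity is also what lets each
summit position claim its own node rather than spreading degenerately.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: weak regions here are i.i.d. noise with no learnable
structure (real quiescent chromatin has low-frequency structure, so
weak-class separation in the signal-permutation null is only testable on the
structured classes here); read-level artifacts, mappability, GC and
fragment-length effects are absent; annotation boundaries in real
segmentations do not align with signal regions. Reported precision/recall on
this benchmark is therefore an upper bound on real-data behavior, and the
benchmark's role is mechanism verification, not performance claims.

Problem sizes used by the packaged experiments: the end-to-end benchmark
fits the default 10x10 grid, 100 epochs on a 500-region genome; the repeated
permutation experiments (100 runs each) use 300-region genomes with a 4x4
grid and 30 epochs, which preserves every mechanism while keeping each run
below a second.

## Worked example

```{r example, eval = FALSE}
genome <- simulate_genome(fixture_config(seed = 1))
fit <- somvn(genome$signal, genome$annotations, somvn_config(seed = 1))
fit
assignment <- predict(fit, genome$signal)
precision_recall(confusion(assignment, genome$annotations))
plot(fit)
```

## Known limitations

* The association cutoff (0.5), merge threshold (0.75) and grid size are set
  by observation, not optimization; a grid search over them is future work.
* Chain merging is greedy; an adversarial chain of intermediates can still
  bridge families that no single pair would merge.
* The ambiguity ratio is undefined at zero best score and is clamped; flat
  windows carry ambiguity 1 by convention when several shapes are available.
* Only the 15-state ChromHMM mnemonic set ships; the mapping table is a
  single named vector and easy to extend, but 18/25-state models are not
  recognized out of the box.
* Signal permutation is per chromosome; block permutations preserving
  autocorrelation are deliberately out of scope.
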