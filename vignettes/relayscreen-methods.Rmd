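---
title: "Calling enhancers and motif statistics from a chromatin-integrated reporter screen"
author: "relayscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling enhancers and motif statistics from a chromatin-integrated reporter screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relayscreen)
library(GenomicRanges)
```

## The assay this package models

A chromatin-integrated enhancer reporter screen clones open-chromatin (ATAC)
fragments from cells at successive differentiation stages — here labelled ES,
HB, HE1, HE2 and HP, the stages of blood progenitor specification from
embryonic stem cells — upstream of a minimal promoter driving a YFP
reporter, integrates one construct per cell at a defined genomic site, and
re-differentiates the library. Cells are FACS-sorted into four reporter
bins (negative, low, medium, high), and the cloned fragment in each sorted
cell is recovered by sequencing. Every *unique* fragment is one unit of
evidence: a fragment recovered from the low, medium or high bin stimulated
transcription; a fragment seen only in the negative bin did not.

The computational task is to turn tens of millions of read pairs into a
per-stage catalogue of enhancer-positive open-chromatin sites, and then to
ask which transcription-factor (TF) motif combinations, accessibility
changes and target genes go with stage-specific activity.

## Fragment reconstruction and filtering

Read pairs (BEDPE) are converted to fragments spanning
`min(start1, start2) .. max(end1, end2)`. We use the min/max rule rather
than a literal "start of read 1 to end of read 2" so that mate order does
not matter; pairs on different chromosomes or spanning more than the
library's insert cap (600 bp by default, matching a 350–650 bp
size-selected library) are dropped and counted in a ledger, never silently.
A mapping-quality filter (`mapq > 40`, strict) is applied when a mapq is
present; the strict inequality is a deliberate reading of "over 40" and is
exposed as a parameter for sensitivity analysis.

Filtering then proceeds in a fixed order, audited per stage and replicate by
a `FilterLedger` in which input = retained + removed at every step:

1. **Deduplication** — exactly one copy per `(chrom, start, end)` tuple.
2. **Background removal** — a separate PCR library built from untransfected
   DNA defines artifact fragments; any sample fragment with a *perfect*
   coordinate match in that library is removed. Partial overlaps are kept:
   only an exact match is evidence of a PCR artifact.
3. **Open-chromatin restriction** — a fragment is kept only if it overlaps
   (≥ 1 bp) an ATAC site of its *own* differentiation stage.
4. **Promoter/distal classification** — an element is promoter-proximal iff
   its midpoint lies within 1.5 kb (inclusive) of a TSS. Inclusivity at
   exactly 1500 bp is a tie-break choice made for determinism.

A site is **enhancer positive** in a replicate iff at least one positive-bin
fragment overlaps it; the screen's intensity gradation (low/medium/high) is
carried as metadata but does not enter the call, which is binary by design.
Consensus across replicates is a strict site-level intersection: positive in
both replicates or not positive. The per-stage consensus calls are merged
across stages by single-linkage overlap into one site universe and
binarized into an activity matrix whose rows carry a 5-character pattern
code (`"00111"` = active in HE1, HE2 and HP), sorted by pattern then
coordinates.

Coordinates are BED-convention (0-based, half-open) in every file read or
written; in memory all regions are `GRanges` (1-based, closed). The
conversion happens only at the `read_bed()`/`write_bed()` boundary, so all
overlap arithmetic is format-agnostic and `read_bed(write_bed(x))`
round-trips exactly.

## Motif-pair co-localization z-score

For a *specific* set of regions (e.g. the sites exclusively active at one
stage), `count_motif_pairs()` counts, over all hits lying in the set, every
unordered pair of distinct hit instances whose midpoints are within 50 bp of
each other. Two conventions matter:

* distance is midpoint-to-midpoint and inclusive — symmetric in motif width
  (an edge-to-edge gap mode is available via `anchor = "edge"`);
* coordinate-identical hit intervals are excluded: overlapping motif
  definitions otherwise generate degenerate self-pairs;
* homotypic pairs fall on the diagonal as instance pairs, so a clique of
  *k* hits of one motif contributes *k(k−1)/2* — the diagonal is therefore
  not expected to be uniform across motifs.

Significance comes from a resampling null: `resample_null()` repeatedly
(1000 times by default) draws the same *number* of sites uniformly without
replacement from the universe of all distal sites of that stage and
recounts. For observed count $x$ with resampled mean $\mu$ and sample
standard deviation $\sigma$ (divisor reps − 1),

$$z = \frac{x - \mu}{\sigma}.$$

A positive $z$ means the pair is co-localized in the specific set more often
than size-matched random site sets allow. Draws are count-matched, not
length-matched; because the null is recomputed per analysis, length-matched
sampling can be layered on by passing a pre-stratified universe. When
$\sigma = 0$ the z-score is 0 if $x = \mu$ and ±`cap` (default 10)
otherwise, with an explicit flag.

The implementation precomputes the genome-wide pair table and each hit's
universe-site membership once, so each resample is a membership mask rather
than a fresh overlap query; a test asserts that this fast path equals a
direct recount on sampled subsets.

## Relative motif enrichment

To compare motif content across peak sets (for instance, sites gained
vs lost after withdrawing a cytokine), the relative enrichment of motif $i$
in peak set $j$ is its per-site rate divided by the pooled rate:

$$S_{ij} = \frac{n_{ij} / m_j}{\sum_j n_{ij} / \sum_j m_j},$$

with $n_{ij}$ the number of instances of motif $i$ in set $j$ and $m_j$ the
number of sites in set $j$. Every defined row satisfies
$\sum_j (m_j/\sum m)\, S_{ij} = 1$, which the tests verify to $10^{-9}$;
motifs absent from all sets are flagged undefined rather than scored. For
display, matrices are z-scaled by row or column (`zscale()`) and ordered by
complete-linkage hierarchical clustering of Euclidean distances
(`hcluster_order()`, a thin wrapper over `stats::hclust` — the standard
tool for this standard step, cross-checked in the tests against a
hand-written agglomeration).

## Differential accessibility

Accessibility comparisons use a plain fold threshold, not a dispersion
model: peaks from the two conditions are merged into a union (the merged
summit is the higher peak's summit, ties to the leftmost), tags are counted
in a 400 bp window centred on each summit (half-open, clipped windows
flagged), each sample is normalized to counts-per-million and transformed as
$\log_2(\mathrm{CPM}+1)$, and replicate columns are averaged *after* the
transform. A site is gained iff the condition means differ by at least
$\log_2(\mathrm{fold})$ (fold = 2 by default) on that scale, lost iff by at
most $-\log_2(\mathrm{fold})$. Whether "two-fold different" should be a
log-scale difference or a raw CPM ratio is genuinely ambiguous; the
log-difference is the default because the +1 pseudo-count guards zeros, and
`method = "cpm_ratio"` exposes the alternative.

## Enhancer–gene assignment

The union of chromatin-interaction anchor pairs links an enhancer to a gene
whenever the enhancer overlaps one anchor and the gene's promoter window
(TSS ± 1.5 kb, reusing the pipeline's promoter definition) overlaps the
other, in either anchor order. Enhancers with no interaction link fall back
to the nearest TSS by midpoint distance, with ties broken to the smaller
coordinate and then the lexicographically smaller gene id so results are
reproducible. Every enhancer ends up with at least one link and the method
(interaction vs nearest) is recorded. `responsive_linkage_fraction()`
summarises, for a set of signalling-responsive enhancers, the fraction of
linked ones whose target gene is itself responsive — an enhancer with
several links counts once.

## What the synthetic screen emulates

`sim_config()` / `simulate_screen()` generate a complete screen with known
truth so that every stage of the pipeline can be scored exactly. Defaults
are the study conditions the package models, chosen once:

| parameter | default | rationale |
|---|---|---|
| stages | ES, HB, HE1, HE2, HP | the five differentiation stages assayed |
| fragment length | uniform 350–650 bp | the library's size-selection window |
| YFP bins | negative/low/medium/high, 2 replicates | the sort layout |
| `true_positive_fraction` | 0.4 | 30–50% of distal sites score in such screens |
| `frags_per_site_mean` | 4 | median positive fragments per distal site of 3–6 |
| `duplicate_rate` | 0.3 | a realistic PCR duplication load |
| `background_artifact_rate` | 0.01 | artifact abundance is not quantified anywhere; 1% is a free parameter |
| `nb_mean`, `nb_dispersion` | 100, 0.05 | well-covered sites with modest biological noise |
| `interaction_coverage` | 0.7 | most, not all, links are recoverable from interaction data |

Structural choices that make exact recovery well-defined:

* Sites are non-overlapping with gaps of at least 700 bp, larger than half
  the longest fragment, so a fragment can only overlap its source site and
  a noiseless run has zero false-positive calls by construction.
* Sites keep 2 kb clear of every TSS and TSS are spaced so that ±1.5 kb
  promoter windows never overlap; simulated candidate sites are therefore
  unambiguously distal and interaction anchors match exactly one gene.
  Promoter classification itself is exercised on constructed fixtures.
* Background artifacts are emitted both as a standalone library and as
  verbatim spike-ins to sample files, so the perfect-overlap filter is
  actually exercised.
* Planted motif pairs are *marginal-preserving*: each inserted co-located
  pair removes one baseline hit of each motif from the target sites when
  available. Per-motif hit rates stay at baseline, so only the pair
  co-localization — not every pair involving those motifs — is enriched.
  Insertions run at `(multiplier − 1) ×` the baseline pair rate, putting
  the total at `multiplier ×` baseline; a multiplier of 1 plants nothing.
* A site's true target gene is its nearest TSS with probability 0.7,
  otherwise a random same-chromosome gene, so interaction-based linking is
  meaningfully different from the nearest-TSS fallback.
* All randomness derives from one master seed through fixed per-stage
  offsets: re-running any generator stage under the same config is
  byte-identical.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: sequence content (no PWM scanning; hits are
coordinates), read-level errors and mapping ambiguity, fragment-length
biases of real tagmentation, sort impurity between YFP bins (bin labels are
noiseless), chromatin-contact noise, and overlapping or nested ATAC peaks.
Exact truth recovery is a correctness statement about the pipeline's logic
under clean labels, not a sensitivity claim for noisy screens.

## Numerical and testing choices

* Overlaps are half-open/BED arithmetic throughout; `min_bp` in
  `overlap_any()` is shared bases.
* Ordering is always (chromosome, start, end, name), so outputs are
  diff-stable; the calling pipeline is invariant under input permutation.
* The null's $\sigma$ uses the sample divisor (reps − 1); reps ≥ 2 is
  enforced.
* Zero-variance z-scores and constant vectors in `zscale()` are flagged,
  never silently propagated as `NaN`.
* Test problem sizes: pair-count brute-force equivalence at 500 hits ×
  100 regions for windows 10/50/200; calibration on a 5000-site universe
  with 500-site draws, 500 resamples and 10 draws; planted-pair recovery at
  200 resamples; screen recovery at 2000 sites/stage with 30% duplicates
  and 5% spike-ins; differential recovery on ~5000 sites with 10% planted
  4-fold sites; linking recovery on 900 sites/600 genes with the planted
  15% responsive fraction checked against its binomial confidence interval
  at n = 400.

## Known limitations

* Replicate consensus is defined at the site level; a fragment-level
  consensus can be composed from `call_sites()` on pooled fragments but is
  a different statistic.
* "Negative/unknown" conflates assayed-but-inactive sites with sites whose
  fragments were simply not recovered; without per-site assay coverage the
  two cannot be separated, and the generator mirrors that.
* The resampling null matches draw *counts*, not site length distributions;
  for universes with strongly heterogeneous site widths a length-stratified
  universe should be supplied.
* `hcluster_order()` inherits `stats::hclust` tie-breaking; ties in merge
  heights are resolved deterministically but not by the lowest-index rule
  some other implementations use.
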