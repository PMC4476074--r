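---
title: "Detecting differential intron retention from RNA-seq alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential intron retention from RNA-seq alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irdetect)
library(dplyr)
```

## The problem

Intron retention (IR) is the alternative-splicing outcome in which an intron
stays in the mature transcript instead of being spliced out. Detecting
*differential* IR between a treatment and a control condition from bulk
RNA-seq is harder than it looks: raw read counts over an intron rise for
several reasons that have nothing to do with retention. Three failure modes
recur in practice:

1. reads piling up at the exon–intron boundaries while the intron interior
   stays empty (incomplete splicing intermediates, mispriming);
2. a dense read cluster inside the intron covering only a small region
   (an unannotated feature, a repeat);
3. the gene as a whole being up-regulated in one condition, which inflates
   every intron-associated count proportionally.

`irdetect` addresses these by combining seven per-condition features per
intron and offering two detectors over them: a transparent **rank-based
caller** and a **vote-trained classifier** pair (decision tree and small
random forest).

## Features

For each intron and each condition the package extracts, from uniquely
mapped reads only:

| feature | definition |
|---|---|
| `Nintron` | unspliced reads fully contained in the intron |
| `Nexon` | reads fully contained in either flanking exon |
| `Njunc` | spliced reads whose gap matches the intron exactly, with ≥ 4 bp anchors |
| `N5ss`, `N3ss` | unspliced reads straddling the 5'/3' splice site with ≥ 1 bp on each side |
| `Ncoverage` | fraction of intron positions under at least one read |
| `Nexpression` | gene-level RPKM over the union exon model |

Containment — rather than mere overlap — keeps these features disjoint: a
boundary-straddling read is evidence of its own kind and never doubles as an
intronic read, and a spliced read never contributes to `Nintron`, `N5ss` or
`N3ss`. Uniqueness is taken from the `NH` tag when present, falling back to
a mapping-quality threshold (default 20); multimappers are a documented
source of false calls in intron quantification. Mates of paired-end
libraries are treated as independent single-end reads, and duplicates are
not removed.

Because library sizes differ, counts are put on a common scale before
conditions are compared: the smallest per-sample total is the **standard
normalization scale** (SNS), and every count is multiplied by
`sns / sample_total`. Replicates are then summed within a condition.
Coverage is a fraction, not a count, so it is computed on the pooled
(unscaled) replicate reads; expression uses the pooled normalized exonic
counts against an effective library of `sns × replicates`. Normalized counts
stay fractional — rounding would bias the small counts that matter most
here.

## The rank-based caller

Low-quality introns are removed first. An intron survives only if **all**
criteria hold (strict inequalities): treatment splice-site counts > 3 on
each side, treatment coverage > 0.9, treatment exon count > 1, treatment
intronic count > 1, both expressions > 10, control junction and exon counts
> 1, and the expression log-ratio `log2(T/C)` strictly inside
`(log2(2/3), log2(3/2))`. The band is the guard against failure mode (3):
if the gene's expression itself differs between conditions, count shifts
over its introns are uninterpretable as retention. A zero control
expression with non-zero treatment expression makes the ratio undefined and
is reported as its own drop reason. Every threshold is configurable through
`removal_criteria()`; the defaults are the package's committed operating
point, and the filter audit accounts for every input intron exactly once.

Surviving introns are summarized per condition by

- `IE = (Nintron + c) / (Nexon + c)` — intron-to-exon count ratio,
- `IJ = (Nintron + c) / (Njunc + c)` — intron-to-junction count ratio,
- `IC = exp(Ncoverage)`,

with pseudo-count `c = 1` by default. Taking the logarithm of a ratio of
counts cannot by itself survive empty denominators — control-side intron
counts of zero are routine — so the pseudo-count is applied to every count
entering `IE` and `IJ`; it is exposed as a parameter for sensitivity
checks. The condition contrasts are

`DIE = log2(IE_t / IE_c)`, `DIJ = log2(IJ_t / IJ_c)`,
`DIC = log2(IC_t / IC_c) = (Tcov − Ccov) · log2 e`.

A retained intron gains intronic signal in treatment on all three axes, so
any candidate with a non-positive delta is flagged as noise and set aside.
The three deltas live on different scales; each is divided by its maximum
over the surviving candidate set (not over all introns — normalizing
against filtered-out noise would compress the informative range), giving
`NDIE`, `NDIJ`, `NDIC` in (0, 1]. The final score is the weighted average

`IRScore = w1·NDIE + w2·NDIJ + w3·NDIC`, `w1 + w2 + w3 = 1`,

with equal weights by default. Candidates are ranked by score and the top
*n*% (ceiling, so any positive *n* returns at least one event) are
reported. Ties are broken by `DIC` descending and then intron id — an
arbitrary but fixed rule chosen so rankings are reproducible; with a single
candidate the normalization forces `IRScore = 1` exactly.

```{r caller}
sim <- simulate_ir_dataset(sim_config(seed = 1))
feats <- build_feature_table(sim$treatment, sim$control,
                             sim$catalog, sim$exons)
res <- run_ircall(feats, n_percent = 10)
glance(res)
res$audit
```

## The classifier pair

Where several independent IR predictors are available, their agreement can
substitute for hand-curated labels: introns hit by at least two of three
external prediction sets become positives, introns hit by none form the
negative pool (introns hit by exactly one are too ambiguous for either
class), and negatives are drawn uniformly at random at a default ratio of
3525/741 ≈ 4.76 negatives per positive with a mandatory seed. Matching
between external intervals and catalog introns is exact-coordinate by
default; a reciprocal-overlap mode (threshold 0.9) is available for
boundary-shifted inputs, since interval conventions differ across tools.

Each labeled intron is represented by 17 features: the 14 per-condition
counts plus `DIE`, `DIJ`, `DIC`. The deltas here use the same pseudo-count
policy as the caller but **no** positivity filter — negative examples
legitimately have non-positive deltas, and discarding them would leak the
label into the feature construction.

Two stock learners are wrapped: a single decision tree with
information-gain splits, pruned by cost-complexity at the
cross-validation-optimal strength (`rpart`), and a bagged forest of 10
trees drawing 5 candidate features per split with majority-vote
aggregation (`randomForest`). Evaluation is stratified 10-fold
cross-validation with pooled held-out predictions; AUC is computed from the
continuous yes-scores (forest vote fraction, tree leaf frequency) because
a vote-threshold label alone cannot order candidates.

```{r classifier}
mat_labels <- tibble::tibble(
  intron_id = sim$truth$intron_id,
  label = ifelse(sim$truth$class == "true_ir", "yes", "no"))
mat <- build_matrix(mat_labels, feats)
cv <- cross_validate(mat, kind = "forest", folds = 6, seed = 1)
glance(cv)
```

## Feature ranking

To ask which features carry the signal, each base feature is reduced to the
per-intron ratio `treatment / (control + 1)` — retention is a differential
phenomenon, so the contrast, not the absolute level, is informative — then
discretized into 10 equal-frequency bins and scored by information gain
(reduction in label entropy, in bits). Equal-frequency binning was chosen
over equal-width because the count ratios are heavy-tailed; with
equal-width bins a single extreme intron would absorb most of the range. A
constant feature collapses to one bin and scores exactly 0; a perfectly
separating binary feature on balanced labels scores exactly 1 bit.

```{r ranking}
information_gain_ranking(feats, mat_labels)
```

## What the simulator emulates — and what it does not

All tests run offline against `sim_config()` / `simulate_ir_dataset()`.
The default configuration — the package's fixed study condition — is 20
genes × 4 exons (60 introns) on one synthetic chromosome, exons of 200 bp,
introns of 150 bp, 50 bp single-end uniquely-mapped reads, 30 exonic reads
per exon per replicate, 2 replicates per condition, and planted classes at
10% each: true IR (near-complete treatment coverage via deterministic
tiling plus boundary reads, with junction support collapsing to ~2 reads
per replicate), boundary-only pile-ups (6 splice-site reads per site but a
single fixed interior read, so pooled coverage stays below 0.87 by
construction), interior clusters (15 reads confined to 40% of the intron),
and whole-gene 2× expression shifts applied proportionally to every count
of the gene — the only planted class whose treatment and control *pattern*
is identical. Expression-shift genes are chosen gene-wise because an
expression change is a property of the gene, not of one intron. Read
*placement* is uniform and seeded; read *counts* per feature are fixed at
their configured values, so class identity is never lost to sampling noise.

The simulator writes real SAM (convertible with samtools) and a truth
table, and identical configurations produce byte-identical files.

What it deliberately omits: sequencing errors and quality strings,
paired-end fragments, multimappers, overlapping genes, alternative
transcripts per gene, length variation, and depth profiles of any real
library. Passing the planted-recovery tests therefore demonstrates that the
implementation computes its own definitions correctly and separates its own
archetypes — not that the operating point is optimal for any particular
organism or library depth. On real data the removal criteria (especially
`coverage > 0.9` and `expression > 10 RPKM`) are aggressive and should be
tuned to depth.

## Numerical and design choices

- Coordinates are 0-based half-open internally; GFF3/GTF (1-based
  inclusive) are converted at the boundary, BED is native. Lengths are
  always `end − start`.
- Introns are deduplicated genome-wide by (chrom, start, end, strand);
  flanking exons of a shared intron come from the first defining
  transcript in annotation order. Catalog size is annotation-driven — no
  count is ever hard-coded.
- On the minus strand the 5' splice site sits at the intron's genomic end;
  unstranded annotations default the 5' site to the lower coordinate with
  a warning.
- Weight vectors must sum to 1 within 1e-6; empty candidate sets are an
  error at context construction but yield an empty, fully-audited result
  from the top-level caller.
- Problem sizes in the test-suite were chosen so the whole suite and the
  acceptance script each complete in a few minutes on one core: 60-intron
  simulations, ~3,000–3,700 reads per sample, n = 500 classifier matrices.

## Known limitations

- Gene expression is gene-level RPKM over the union exon model; no
  transcript-resolved estimate is attempted, so isoform switches that
  change exon usage without changing gene expression pass the ratio band.
- The caller is rank-based by design and attaches no p-values; the top-*n*%
  cut is a budget, not a significance statement.
- `Nexon` sums both flanking exons without length normalization, as the
  feature definitions specify; very asymmetric flanks shift `IE`
  accordingly.
- Vote labeling inherits the biases of the external predictors that cast
  the votes.
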