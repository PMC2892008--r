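---
title: "Methods: group-based scoring of S-nitrosylation sites"
author: "gpsno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group-based scoring of S-nitrosylation sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpsno)
```

## The scoring model

`gpsno` predicts which cysteines of a protein undergo *S*-nitrosylation.
The underlying hypothesis of the GPS ("group-based prediction system")
algorithm family is that short peptides with similar sequences adopt
similar local structure and chemistry, so a cysteine whose flanking
peptide resembles experimentally verified SNO sites is itself a plausible
site.

A site is the cysteine-centred window NSP($m$, $n$): $m$ residues
upstream, $n$ downstream, total length $m + 1 + n$. Windows overhanging a
protein terminus are padded with `*` rather than truncated, so every
peptide of a window class has equal length; `*` (and any non-standard
residue letter such as B, Z, X or U) scores zero against everything.
Coordinates are 1-based throughout, matching the C135-style site notation
used in the experimental literature.

Two peptides are compared position-wise through a substitution matrix,
initially BLOSUM62, with non-negative integer position weights $w_i$
(all 1 before training):

$$S'(A, B) = \max\Big(0, \sum_i w_i \,\mathrm{Score}(A_i, B_i)\Big).$$

The zero floor keeps scores non-negative, as in the original algorithm.
The score of a query against a trained cluster is the **arithmetic mean**
of $S'$ over the cluster's reference positives. The original description
leaves the aggregation implicit; the mean was chosen over the sum because
it keeps scores comparable across clusters with different numbers of
reference sites, consistent with the GPS-series scoring convention.

## Training pipeline

Training runs four stages in a fixed order — clustering, window selection
(PS), weight training (WT), matrix mutation (MaM) — with cluster
membership frozen after the first stage.

**Similarity k-means (k-medoids).** Positive sites are clustered at the
NSP(7, 7) window under the conserved-substitution similarity
$s(A, B)$ — the fraction of aligned positions whose BLOSUM62 score is
positive, a value in $[0, 1]$. The companion distance is $D = 1/s$
(infinite at $s = 0$); the implementation compares similarities directly,
so the infinity never needs materialising. Centroids are member peptides
(medoids): with only a pairwise similarity available, the "centroid with
the highest average similarity (HAS)" update is only meaningful for
members. Assignment ties break to the lowest medoid index; if an update
empties a cluster, its medoid is re-seeded with the peptide least similar
to its currently assigned medoid and assignment is recomputed, so exactly
$k$ non-empty clusters always survive. Convergence means an unchanged
assignment vector; a cap of 100 update rounds bounds the loop. $k$
defaults to 3 — more clusters can help but cost training time — and
clustering always uses unit weights and the unmutated matrix; later
per-cluster WT/MaM never feed back into membership. Negative sites attach
to the cluster with the highest mean similarity to its positives, and the
same rule assigns query peptides at prediction time (the minimal
consistent extension of the training-time rule).

**Peptide selection.** Per cluster, every window $m, n \in [1, 30]$
(configurable) is evaluated by re-extracting all peptides and computing
the leave-one-out sensitivity at the fixed specificity (below); the best
window wins, ties breaking to the smallest $m + n$ then the smallest $m$
(the cheapest equivalent model). The scan reuses cumulative per-offset
score contributions, so the full 900-window grid costs only a few vector
operations per window.

**Leave-one-out objective.** Each positive is scored against its cluster's
other positives (itself removed); each negative is scored once against the
full positive set. The cutoff is the smallest score $t$ such that the
fraction of the cluster's negative scores strictly below $t$ is at least
the fixed specificity (0.80 by default; decision rule "score ≥ cutoff ⇒
positive" everywhere). The objective is the sensitivity at that cutoff.
Specificity is fixed *per cluster* and the confusion counts are pooled
afterwards: cluster windows, weights and matrices differ, so raw scores
are not comparable across clusters and a single global cutoff would be
meaningless. A cluster reduced to a single positive has an empty LOO
reference set; its score is defined as 0 and flagged in the output.

**Hill climbs.** WT perturbs one uniformly drawn position weight by ±1
(proposals driving a weight below zero are rejected: a negative weight
would invert similarity semantics); MaM perturbs one uniformly drawn
unordered residue pair of the cluster's own matrix copy by ±1, applied
symmetrically, with the padding row untouchable and entries otherwise
unbounded. A proposal is accepted only if the LOO sensitivity *strictly*
increases — equal-objective proposals are rejected to prevent drift.
"Until convergence" is undecidable for stochastic proposals, so each climb
stops after a run of consecutive rejections (500 for WT, 2 000 for MaM by
default; both configurable). Per-cluster matrices (rather than one shared
matrix) are consistent with per-cluster PS/WT; a shared-matrix mode is
deliberately out of scope of the trainer's default path. Each proposal is
evaluated by a delta update of the cached raw score matrices, so even the
default stall budgets run in seconds at benchmark scale.

**Calibration.** The shipped high/medium/low cutoffs are calibrated per
cluster on the final LOO negative scores at specificity 0.90 (high),
0.85 (medium) and 0.80 (low) respectively (`calibration_levels`,
configurable). When ties or a
request of 1.0 make every observed negative fail, the cutoff is the
smallest representable value above the maximum negative score.

**Reproducibility.** One RNG stream is seeded once per training run and
consumed in documented order (clustering init, then per cluster in index
order WT then MaM), so `(dataset, config, seed)` fully determines the
model, and every CLI command is byte-reproducible under a fixed seed.

## Baselines

The PSSM baseline estimates per-position residue probabilities in the
positive and negative classes with add-one smoothing (pseudocount
configurable) and scores a peptide by summed log-odds; padding scores 0.
Positional (per-column) probabilities are the default — the classical
PSI-BLAST-style usage — with a composition-only variant behind a flag,
since prose descriptions of PSSM baselines are often ambiguous between
the two. The evaluation window defaults to NSP(7, 7) to match the GPS
comparison setting. The acid-base motif rule fires when the residue at
offset −1 is K/R/H/D/E and the residue at +1 is D or E; published
renderings of the pattern vary in whether the downstream acidic residue
is required, and the stricter table form (D/E required) is implemented.
The motif is interpreted at the immediate flanks only, so widening the
window never changes its verdict.

The single-group baseline trainer (`train_gps2_baseline`) is the exact
$k = 1$ reduction of the pipeline: fixed NSP(7, 7), unit weights, MaM
only — the GPS 2.0 configuration.

## The synthetic benchmark

`generate_dataset()` draws proteins residue-wise from a background
composition (uniform 1/20 by default: simple nulls and closed-form motif
frequencies; a UniProt-like composition can be supplied), plants
cysteines at well-separated positions, and for positive sites resamples
each profiled flanking offset from the signal profile with probability
`signal_strength`. The default profile places basic/acidic residues
(K/R/H/D/E) at offsets −2..−1 and acidic residues (D/E) at +1..+2 — the
acid-base recognition pattern discussed for SNO sites. Positives and
negatives co-occur on the same proteins, as unmodified cysteines of real
substrates do. Default sizes (200 proteins, 300 positive and 1 500
negative sites, mean length 300) mirror the shape of the curated training
set of this algorithm family (~1.5 modified and ~8 unmodified cysteines
per substrate).

What the generator does **not** emulate: homology structure between
proteins (real training sets need 40%-identity deduplication), organism
composition drift, length-biased site placement, or correlated flanking
positions. Passing recovery tests therefore demonstrates that the
pipeline can learn a planted local-composition signal — not that it
attains any particular accuracy on curated experimental data, whose
headline numbers also depend on the exact literature-derived training set
and on an optimisation run whose final matrices and weights were never
published.

Benchmark conditions used by the test-suite and the acceptance script:
signal strength 1.0 for the recovery check (held-out AROC), 0.7 for
method comparison — at 0.7 only about
$(0.7 + 0.3 \cdot \tfrac{5}{20})(0.7 + 0.3 \cdot \tfrac{2}{20}) \approx 0.57$
of true sites carry the exact −1/+1 motif, so the planted signal is
genuinely broader than the motif rule can see, which is the regime where
the grouped predictor, the single-group baseline, the PSSM and the motif
rule separate. The trainer runs with the window grid capped at
$m, n \le 8$ and stall budgets 100 (WT) / 200 (MaM) — the package's
desk-scale defaults for simulation studies; the planted signal lives
within ±2 residues, so the capped grid loses nothing.

**Negative control.** `shuffle_labels()` permutes labels uniformly across
all sites. Recovery experiments treat this as a standard permutation
test: the *entire world* is permuted — the model is trained on
permuted-label data and evaluated against permuted held-out labels — and
performance must sit at chance (AROC ≈ 0.5). Evaluating a
permuted-trained model against *true* held-out labels is not a clean
null: with ~1/6 of shuffled "positives" being genuine sites, the
reference set stays contaminated with real signal and the AROC would sit
measurably above 0.5 by construction.

## Numerical and design notes

- The exact equation renderings of $S(A,B)$, $S'(A,B)$ and $s(A,B)$ in
  the source literature are figures; the forms implemented here follow
  the accompanying prose (position-wise sums; conserved fraction).
  Whether released GPS tools normalise prediction scores (e.g. by window
  length) is not documented; no normalisation is applied.
- MCC is defined as 0 when its denominator vanishes and is clamped to
  $[-1, 1]$ against floating-point overshoot of the factorised
  denominator.
- ROC areas use the rank-based Mann–Whitney statistic (ties counted ½),
  which equals the trapezoidal area under the step curve.
- k-fold cross-validation stratifies by label (fold sizes differ by at
  most one per class) and retrains the full pipeline per fold; reusing
  the final model would leak the held-out fold through PS/WT/MaM. The
  training budgets are configurable so that CV remains desk-scale.
- Model files are versioned JSON; reading a file written by a different
  format version fails loudly rather than guessing.

## Limitations

Sequence windows are the only feature: no structure, accessibility or
conservation inputs. $k$ is a configuration knob, not auto-tuned. The
hill climbs are greedy single-seed searches — no restarts or annealing —
so different seeds give different (all locally optimal) models; the seed
is part of the model metadata. Only cysteine centres are supported
(selenocysteine is not).
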