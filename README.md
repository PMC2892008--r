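# gpsno — group-based prediction of protein S-nitrosylation sites

Protein *S*-nitrosylation (SNO) is a reversible post-translational
modification in which a nitric-oxide moiety attaches to a cysteine thiol.
Experimentally mapping which cysteines of a substrate are modified is slow
and low-throughput, so sequence-based predictors are used to shortlist
candidate sites for verification. `gpsno` implements a group-based
peptide-scoring predictor in the style of the GPS 3.0 algorithm family,
together with its training pipeline, two classical baselines, a full
evaluation protocol and a deterministic synthetic benchmark generator. It
is aimed at computational biologists studying PTM site prediction and at
anyone who needs a transparent, retrainable SNO-site scorer.

## The model

A candidate site is represented as a cysteine-centred peptide NSP(*m*, *n*)
— the central C with *m* residues upstream and *n* downstream; windows
overhanging a terminus are padded with `*`, which scores 0 against
everything. Two peptides *A*, *B* are compared with a substitution matrix
(initially BLOSUM62):

    S(A, B) = max(0, sum_i w_i * Score(A_i, B_i))

where the `w_i` are non-negative per-position weights. The score of a query
site against a trained group is the arithmetic mean of S(query, P) over the
group's reference positive peptides: similar short peptides are assumed to
bear similar structure and biochemistry, so proximity to known sites is
evidence of modifiability.

Training proceeds in four stages, each frozen before the next:

1. **k-means clustering** (k = 3 by default) of the positive NSP(7, 7)
   peptides under the conserved-substitution similarity *s*(*A*, *B*) — the
   fraction of aligned positions with a positive BLOSUM62 score — using
   medoid centroids updated by highest average similarity (HAS); negative
   sites attach to the cluster of highest mean similarity.
2. **Peptide selection (PS)**: per cluster, exhaustive search of the window
   grid (*m*, *n* up to 30 each) for the best leave-one-out (LOO)
   sensitivity at 80% specificity.
3. **Weight training (WT)**: stochastic hill-climb over the position
   weights (±1 steps, accepted only on strictly improved LOO Sn at fixed
   Sp).
4. **Matrix mutation (MaM)**: the same hill-climb over the entries of the
   cluster's own substitution-matrix copy, symmetry preserved.

Finally, high/medium/low prediction cutoffs are calibrated per cluster on
the LOO negative scores at specificity 0.90/0.85/0.80. Baselines: a
position-specific scoring matrix (PSSM, smoothed per-column log-odds) and
the acid-base motif rule K/R/H/D/E–C–D/E.

## Worked example

Everything below runs offline on the package's own synthetic benchmark,
which plants an acid-base flanking profile (K/R/H/D/E at offsets −2..−1,
D/E at +1..+2) around positive cysteines at a configurable strength:

```r
library(gpsno)

ds <- generate_dataset(simulation_config(n_proteins = 60, n_pos_sites = 90,
                                         n_neg_sites = 450,
                                         signal_strength = 0.7, seed = 42))
ds
#> sno_dataset: 60 proteins, 90 positive and 450 negative cysteine sites

config <- training_config(k = 3, ps_max_m = 8, ps_max_n = 8,
                          wt_max_stall = 100, mam_max_stall = 200, seed = 42)
model <- train_gps3(ds, config)
model
#> Group-based site predictor (gps3), 3 cluster(s)
#>   cluster A: NSP(1, 4), 14 reference positives, cutoffs high=8.429 medium=7.714 low=7.429
#>   cluster B: NSP(5, 4), 61 reference positives, cutoffs high=5.738 medium=5.393 low=4.426
#>   cluster C: NSP(5, 1), 15 reference positives, cutoffs high=8.333 medium=7.733 low=6.667

ev <- evaluate_sn_at_sp(loo_scores(ds, model), 0.80)
sprintf("LOO Sn at Sp 80%%: %.1f%% (Sp achieved %.1f%%)",
        100 * ev$metrics$sn, 100 * ev$metrics$sp)
#> "LOO Sn at Sp 80%: 98.9% (Sp achieved 80.9%)"

predict_sites(model, ds$sequences[1], level = "medium")[, c(1:5, 9)]
#>    protein_id position    peptide cluster     score  level
#> 1     SYN0001        7 IMMHDCADSV       B  6.622951   high
#> 2     SYN0001       37     TCRDPV       A  8.642857   high
#> ...
```

Each cluster learned its own window (e.g. NSP(5, 4) for the largest group),
its own weights and matrix, and its own cutoffs; at the `medium` threshold
every reported site scored at or above its cluster's medium cutoff, and the
`level` column shows the most stringent threshold each site passes.

The same workflow is available from the shell via the bundled CLI
(`exec/gpsno`): `simulate`, `train`, `predict` and `evaluate` subcommands
with seeds for byte-reproducible outputs.

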