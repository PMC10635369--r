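# tmcontact

Inter-helical residue contact prediction for alpha-helical transmembrane
(TM) proteins from atomic structures.

## What problem this solves, and for whom

A TM protein's inter-helical contact map — which residue pairs on distinct
membrane-spanning helices lie within 5.5 Å of each other (minimum heavy-atom
distance, pairs restricted to |i − j| > 5) — is a compact, rigid-motion
invariant summary of how the helices pack, useful for identifying
helix–helix binding sites and as a constraint in structure modeling. A
predicted structure (e.g. an AlphaFold-like model) implies a contact map
directly, but that binary annotation inherits every coordinate error. This
package is for structural bioinformaticians who have (i) experimentally
determined structures to learn from and (ii) predicted structures for
chains of interest, and want contact maps that are better than what the
predicted coordinates imply on their own.

## The method

For a candidate pair (i, j), five geometric features are computed for each
of the 8 positions of the 3×3 sequence window around it (center excluded):

* θ — inter-helical tilt angle between the two host helix axes, each axis
  the normalized mean of the O(i) → N(i+4) hydrogen-bond-register unit
  vectors;
* D1, SD(D1) — mean and population standard deviation of all M×N heavy-atom
  cross distances of the (neighbor) pair;
* Dα — the Cα–Cα distance;
* δ — angle between residue-plane normals, a plane being spanned by
  (N − Cα) and (C − Cα).

Concatenation gives the length-40 **SDF** (structurally derived features)
vector; a length-192 **CF** baseline concatenates the raw N/Cα/O/Cβ
coordinates of the same window instead. Features are min/max-scaled to
[−1, 1] on the training set; SDF passes through a frozen Xavier-uniform
40→192 linear projection; a 6-hidden-layer leaky-ReLU network with a
sigmoid output is trained with Adam (lr 1e-4, batches of 256, 400 epochs,
gradients clipped to [−1, 1]) on binary cross entropy, on features from
experimentally determined structures only. At test time the classifier
rescores the candidate pairs of a predicted structure (same features,
predicted coordinates; labels always from experiment); on the published
real-protein datasets this rescoring outperforms the predicted structure's
own binary annotation, whose average precision degenerates to
precision × recall. Evaluation is per sequence: average
precision, trapezoidal AUC-ROC, and top-L/L2/L5/L10 precision-recall, with
cross-validation grouped by sequence.

No deep-learning runtime is required: the MLP, Adam, clipping and the
frozen projection are implemented on base-R BLAS matrix operations, with
every source of randomness seeded.

## Worked example

Simulate a paired benchmark (clean "experimental" bundles plus σ = 0.5 Å
perturbed, randomly re-posed "predicted" surrogates), extract features, and
run the train-on-experimental / test-on-predicted protocol:

```r
library(tmcontact)

ds <- make_benchmark(n_sequences = 10, noise = noise_spec(0.5, seed = 90), seed = 11)
#> benchmark: 10 sequences, contact ratio 0.012-0.077 (median 0.036)

entries <- lapply(ds, function(e) {
  pairs <- candidate_pairs(e$experimental, e$annotation)
  cm    <- label_contacts(e$experimental, pairs)          # truth: experiment
  fe <- build_feature_matrix(e$experimental, e$annotation, pairs, "SDF", e$id)
  fp <- build_feature_matrix(e$predicted,    e$annotation, pairs, "SDF", e$id)
  list(id = e$id, features = fe, features_test = fp, labels = cm$labels[fe$kept],
       pred_labels = label_contacts(e$predicted, pairs)$labels[fe$kept])
})

cfg <- synthetic_model_config()        # capacity matched to desk-scale data
rep_pred <- cross_validate(entries, cfg, k = 5, repeats = 1, seed = 19)
print(rep_pred)
#> <MetricsReport | 10 rows | mean AP 0.6091 | mean AUC 0.9675>
#>   across repeats: AP 0.6091 +/- 0.0000, AUC 0.9675 +/- 0.0000

base <- annotation_baseline_report(entries)   # the predicted structure's own map
print(base)
#> <MetricsReport | 10 rows | mean AP 0.6889 | mean AUC 0.9488>

cmp <- compare_sources(NULL, rep_pred, base)
cmp$pct_improved
#> [1] 30
```

`mean AP` is the unweighted mean over held-out sequences of average
precision of the classifier scored on the *perturbed* structures' features;
the baseline row is the perturbed structures' own binary contact annotation
(AP = P × R per sequence); `pct_improved` is the percentage of sequences
where the classifier beats that annotation. Even at this desk scale the
classifier improves mean AUC over the annotation baseline (0.9675 vs
0.9488); in average precision it does not: on real datasets (~150 training
sequences) the published protocol reports AP above 0.9, while at 10
sequences the MLP sits below the information ceiling of its own features
(see the methods vignette's "Known limitations").

## Command line

The wrapper installs with the package; put it on your PATH or call it as
`Rscript "$(Rscript -e 'cat(system.file("exec","tmcontact",package="tmcontact"))')" ...`:

```sh
tmcontact simulate --out sim --n-sequences 10 --sigma 0.5 --seed 1
tmcontact features --manifest sim/manifest.tsv --out feat --feature-kind sdf --source experimental
tmcontact features --manifest sim/manifest.tsv --out feat --feature-kind sdf --source predicted
tmcontact train    --features-dir feat --out model.json --feature-kind sdf --epochs 400
tmcontact predict  --model model.json --features-dir feat --out scores --source predicted
tmcontact evaluate --features-dir feat --out report.tsv --feature-kind sdf --k 5 --repeats 1
```

Exit codes: 0 success, 2 configuration error, 3 data error. Each command
writes a run log with a config hash and seeds.

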