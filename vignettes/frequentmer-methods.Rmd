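---
title: "Frequentmers: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequentmers: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frequentmer)
```

## The model

A frequentmer of recurrency $r$ is a k-mer present in at least $r$ distinct
samples of one cohort and absent from every sample of the other cohort.
Both halves of the condition matter. Recurrent presence filters out k-mers
that appear in a cohort by chance (a single sample's private sequence, a
rare sequencing artifact); total absence from the opposite cohort makes the
feature group-exclusive, so a single detection of a patient frequentmer in
an unseen sample is already evidence about its label. The two catalogs are
disjoint by construction — a k-mer with even one occurrence in each cohort
qualifies for neither — and the catalog at $r + 1$ is nested inside the
catalog at $r$, so the recurrency threshold trades catalog size against
per-feature reliability monotonically.

Presence of a k-mer in a sample is itself filtered: a k-mer observed exactly
once in a sample's merged reads is discarded (the singleton filter,
`min_count = 2`). Substitution errors scatter reads into essentially random
k-mers, each unlikely to recur within a sample, so the singleton filter
removes the bulk of error-derived k-mers at the cost of genuinely rare ones.
This is the method's only error control; base qualities are ignored, and all
files are treated as single-end reads (pairing adds nothing to a presence
test).

Downstream, frequentmers become binary presence/absence features. By
construction every training control sample scores zero on all patient
frequentmer columns and vice versa, so the training feature matrix is
block-structured; test samples are free to violate the blocks, and the
violations are exactly the classification signal.

## Tunable parameters

* `k` (default 16 bases): the k-mer length. At $4^{16} \approx 4.3 \times
  10^9$ possible 16-mers, random collisions between unrelated genomes are
  rare while sensitivity to short variants is retained. Encoded 2 bits per
  base, a 16-mer fits one integer; codes travel through R as doubles (exact
  to $2^{53}$, i.e. $k \le 26$).
* `min_count` (default 2): the within-sample occurrence threshold. 1
  disables the singleton filter; the default implements it.
* `r` (recurrency, no single default): the sweep grid defaults to 5–20 and
  `recurrency_sweep()` reports catalog sizes across it. Values $r \le 1$
  degenerate to mere group-absence and are flagged with a warning rather
  than rejected.
* `canonical` (default `FALSE`): off, a k-mer and its reverse complement are
  distinct, matching forward-strand presence semantics; on, each window maps
  to the smaller of its code and its reverse-complement code. Results differ
  between modes and the conservative forward-strand reading is the default.
* Classifier settings: ridge logistic regression with inverse regularization
  strength $C = 0.01$ and an iteration cap of 2000 (on glmnet's scale,
  $\lambda = 1/(nC)$ with $\alpha = 0$), and XGBoost with max_depth 11,
  gamma 0.3, eta 0.2, L1 alpha 6, 100 rounds, single-threaded and seeded.
  Strong regularization suits the regime of many collinear binary features
  (all k-mers of one marker sequence rise and fall together).
* `n_folds` (default 10): stratified so each fold's patient fraction is
  within one sample of the global fraction. Frequentmers are re-derived
  from each fold's training split alone; nothing about the features leaks
  from test samples.

## What the synthetic generator emulates

`synthetic_spec()` / `generate_cohorts()` draw a shared background pool
(the common microbiome), rejection-sample marker sequences whose k-mers are
disjoint from the background and from each other, plant each marker into a
Bernoulli-chosen subset of one cohort's samples, and emit error-injected
reads. The defaults are the package's reference study conditions: 30
patients and 30 controls, one 5,000-bp background reference, ten 100-bp
patient markers at prevalence 0.5, 600 background reads of 100 bp per
sample, substitution error rate 0.5%, and marker coverage 3 (at least 2 is
needed to survive the singleton filter). The background scale gives roughly
12× coverage, so background k-mers are present in essentially every sample
of both cohorts and are excluded from catalogs by the absence condition,
while each marker contributes exactly `marker_len - k + 1` ground-truth
patient frequentmer candidates. These sizes keep a full ten-fold run in the
seconds range; they were chosen once as a realistic-but-small emulation and
are not tuned per analysis.

An explicit `inclusion` override matrix lets tests pin exact recurrency
counts (a marker in exactly 5 of 10 patients) instead of relying on
Bernoulli tails.

What the generator does **not** emulate: realistic community abundance
distributions, GC bias, indels, chimeras, quality-score structure, strain
variation, or batch effects. Passing synthetic tests therefore demonstrates
the correctness of the set algebra, the leakage-free derivation and the
classifier plumbing — not clinical performance on real stool mNGS, where
cohort-exclusive k-mers are rarer, noisier and confounded.

## Numerical and procedural choices

* **Index construction** is a heap-based multiway merge over the per-sample
  sorted k-mer vectors, emitting (k-mer, control count, patient count) in
  ascending order. The file backend reads `.kset` payloads and merges with
  the same kernel; both backends are contract-tested to produce identical
  indices. The `.kset` format is little-endian: magic, codec version, k, an
  8-byte count, a NUL-terminated sample id, then 8-byte ascending codes.
* **Recurrency counts distinct samples, never read counts** — a k-mer's
  within-sample multiplicity only matters to the singleton filter.
* **Majority-vote ties** (a recovered frequentmer seen in equally many
  control and patient test samples) are reported as `unassigned`; no
  tie-break is invented.
* **Patient ratio** in sweeps is `n_patient / (n_patient + n_control)`,
  reported as `NA` when no frequentmers exist at that threshold.
* **Jaccard of two empty sets** is 0 by convention and counted in the
  output so callers can see how often it fired. The within- vs cross-group
  comparison uses Welch's two-sample t-test by default; a paired mode
  exists but requires the caller to supply a defensible pairing, because
  within-group and cross-group pair sets have no natural correspondence.
* **Exposure-specific frequentmers** require presence in at least `r`
  exposure-positive patients and absence from exposure-negative patients
  *and* all controls (which makes them a subset of the patient catalog).
  Patients with unknown exposure are excluded with a warning, not treated
  as negative.
* **Top-N retraining** ranks features by absolute coefficient on the
  training fit only, restricts the same split to the top N with columns
  kept in their original order, and refits. Keeping the original column
  order makes N = all features reproduce the full model bit for bit
  (coordinate descent is order-sensitive). Ranking is per fold by default;
  an `average_ranks` mode uses the cross-fold mean signed coefficient, the
  same averaging used to pick the top/bottom frequentmers for read
  traceback.
* **Coefficient ties** are broken by encoded k-mer ascending, so rankings
  are total and reproducible.
* **AUC** is trapezoidal (via pROC, with a brute-force threshold-enumeration
  oracle in the tests); the fold summary reports both the mean-across-folds
  AUC with a normal-approximation 95% CI ($\pm 1.96\,s/\sqrt{n}$) and the
  pooled AUC over all concatenated test scores, since either convention is
  common. Confusion matrices use a 0.5 threshold. Single-class test folds
  are excluded from AUC aggregation with a warning.
* **PCA** is column-mean-centered without unit-variance scaling (the
  features are comparable 0/1 columns), up to 90 components.
* **Traceback** scans reads of all samples by default (restrictable),
  matching with the same 2-bit window encoding as extraction: all queries
  share one length k, so a window either is or is not in the sorted query
  set, and Aho–Corasick machinery is unnecessary. A read matching several
  queries is emitted once in the FASTA but tallied once per query.
* **Determinism**: every stochastic step (simulation, folds, booster) is
  seeded, and library code uses a private RNG stream that restores the
  caller's `.Random.seed`. Reruns of the pipeline at a fixed seed are
  byte-identical, including gzipped FASTQ output.

## Degenerate inputs

Empty k-mer sets, empty indices and empty sweeps are well-defined and
return empty results; an empty frequentmer catalog is an error at
feature-building time with advice to lower `r`. Reads shorter than k
contribute no windows; windows containing N are skipped everywhere
(extraction and traceback alike). Non-ACGTN input characters are mapped to
N at load. Mixed-k inputs, unknown samples, duplicate manifest ids and
truncated `.kset` files are hard errors.

## Known limitations

* Exact absence is a sharp condition: one stray opposite-cohort occurrence
  (contamination, index hopping) deletes a frequentmer. The method is
  deliberately exact — no sketches or Bloom filters — so this sensitivity
  is inherent.
* The in-memory cohort index scales with the k-mer universe of the cohort;
  the problem sizes this package targets (tens of samples, synthetic or
  downsampled read sets) fit comfortably, but population-scale runs would
  need the merge to stream from disk in bounded buffers.
* The substitution-only error model understates real error structure;
  indel-rich platforms would erode marker k-mers faster than the simulation
  suggests.
* Welch's test on all sample pairs treats pairwise Jaccard values as
  independent observations, which they are not (each sample participates in
  many pairs); the p-values are heuristic summaries, as is common for
  pairwise-similarity comparisons.
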