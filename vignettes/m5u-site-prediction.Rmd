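---
title: "Predicting RNA 5-methyluridine sites from multi-view sequence features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting RNA 5-methyluridine sites from multi-view sequence features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m5usite)
```

## The problem

5-methyluridine (m5U) is a post-transcriptional RNA modification installed at
the C5 position of uridine by pyrimidine methyltransferases. Experimentally
mapped m5U sites are costly to produce, so sequence-based classifiers are used
to triage candidate uridines. The standard framing, which this package
implements end to end, is a binary classification of fixed-length windows: a
41-nt fragment centered on a uridine (20 nt of flanking context on each side)
is labeled positive if the central U is modified. Negatives are unmodified
uridine windows drawn from the same transcripts. `m5usite` takes such windows
(as FASTA or extracted from transcripts with `extract_window()`), encodes them
under several complementary views, optimizes the feature space, trains and
evaluates an SVM, and interprets the fitted model.

Coordinates inside a window are signed, with the candidate site at position 0
and flanks at -20..+20; curated m5U data show a UUC consensus at positions
0..2, which is also what the synthetic generator plants by default.

## Feature views

Four physicochemical encoders turn a window $s = R_1 R_2 \ldots R_L$ over
$\{A,C,G,U\}$ into numeric vectors:

* **Kmer** — frequencies of all $4^k$ length-$k$ substrings,
  $f(t) = N_t / (L - k + 1)$. Dividing by the number of k-mer positions makes
  each block sum to exactly 1; the alternative convention of dividing by the
  sequence length $L$ is available via `denom = "length"`. Defaults use
  $k = 1, 2, 3$ (84 features).
* **ENAC** — mononucleotide frequencies inside a length-5 window slid 5'→3'
  with step 1, concatenated: $4 \times (L - 4) = 148$ features for $L = 41$.
  This is the position-resolved view; it is what picks up motif positions.
* **CKSNAP** — for each gap $k = 0..5$, frequencies of ordered nucleotide
  pairs $(R_i, R_{i+k+1})$, each 16-block divided by its pair count
  $N_\mathrm{total} = L - (k+1)$; $16 \times 6 = 96$ features.
* **PseDNC** — the 16 normalized dinucleotide frequencies $f_k$ augmented
  with $\lambda$ sequence-order correlation factors
  $\theta_j = \frac{1}{L-1-j} \sum_i \Theta(R_iR_{i+1}, R_{i+j}R_{i+j+1})$,
  where $\Theta$ is the mean squared difference of six standardized
  physicochemical dinucleotide indices (rise, roll, shift, slide, tilt,
  twist), all sharing the denominator $\sum_k f_k + w \sum_j \theta_j$ so the
  vector sums to 1. Defaults $\lambda = 3$, $w = 0.5$ give 19 features.

The six-index table shipped in `inst/extdata/` is compiled from the published
RNA dinucleotide step-parameter literature. Each index row is standardized to
mean 0 / sd 1 across the 16 dinucleotides before use — the established
pseudo-nucleotide-composition convention — which makes $\Theta$ scale-free,
so conclusions depend only weakly on the raw units of the table. A user table
can be supplied as TSV.

The fifth view is a **distributed representation**: windows are tiled into
overlapping k-mers (one "sentence" per window), a skip-gram model with
negative sampling learns one vector per k-mer from the co-occurrence
structure, and each window is represented by the unweighted mean of its
k-mer vectors. Defaults: $k = 3$, context window 4, 100 dimensions,
50 epochs, 5 negative samples, linearly decaying learning rate. The trainer
is written in C++ with a private seeded RNG and runs single-threaded, so
given the same corpus and seed the vectors are bit-identical — multi-worker
word2vec training is not reproducible, and reproducibility is part of this
package's contract. K-mers unseen at prediction time are skipped from the
mean (the embedding is trained on training windows only, which is the
leakage-safe choice; a window of entirely unseen k-mers embeds to the zero
vector with a warning).

## Two-step feature optimization

The four physicochemical views are fused (order: CKSNAP, ENAC, Kmer, PseDNC;
347 features at the defaults) and then optimized in two steps:

1. **Importance ranking** by one of: per-feature one-way ANOVA F,
   the classical feature-selection F-score
   $\frac{(\bar x^+ - \bar x)^2 + (\bar x^- - \bar x)^2}{s^2_+ + s^2_-}$,
   or gain importance from a seeded gradient-boosted tree ensemble
   (xgboost; 100 rounds, depth 4, learning rate 0.1). Ties are broken by
   original column order so rankings are stable.
2. **Incremental feature selection (IFS)**: prefixes of the ranking of size
   `step`, `2*step`, ... are each scored by mean stratified k-fold CV
   accuracy of the SVM, with one fixed seeded fold partition reused for every
   prefix (removing fold-resampling noise from the curve), and the smallest
   prefix attaining the maximum wins. The default step is 1 — the finest
   scan — with a `selection_step` knob for coarser, faster scans; the full
   feature set is always evaluated as the last prefix, so the procedure can
   never do worse (in CV accuracy) than no selection at any scanned size.

The embedding features deliberately bypass IFS: selection operates on the
fused physicochemical view only, and the embedding block is concatenated to
the selected features afterwards. This ordering is part of the method's
design, and `m5u_fit()` enforces it.

## Classifier and evaluation

The classifier is a soft-margin SVM (RBF kernel by default), delegated to
libsvm via e1071; this package owns the kernel/C/gamma surface, the grid
search and the seeding, not the quadratic program. The grid defaults follow
canonical practice — $C \in 2^{-5} \ldots 2^{15}$, $\gamma \in 2^{-15} \ldots
2^{3}$, both by powers of 4 — and each cell is scored by mean stratified
k-fold CV accuracy on one seeded partition, with ties resolved toward smaller
$C$ then smaller $\gamma$. Columns are standardized inside each fit
(`scale = TRUE`); the `"scale"` gamma heuristic $1/(p \cdot \mathrm{var})$ is
evaluated on the matrix the kernel actually sees, i.e. $1/p$ after
standardization.

Evaluation reports Sn, Sp, Acc, precision, F1 and MCC from the confusion
matrix at libsvm's default decision threshold, plus a ROC curve swept over
the signed decision values with trapezoidal AUC (ties grouped; a constant
score yields AUC 0.5 by construction). Metrics with an undefined denominator
are reported as 0 and flagged rather than dropped. Cross-validation emits
both fold-mean metrics and pooled-confusion metrics, since the two
conventions differ and reports in the field use either.

## Interpretation

Per-feature attributions are Shapley values of the decision score:
$\phi_i = \sum_{k \subseteq S \setminus \{i\}}
\frac{|k|!\,(p-|k|-1)!}{p!}\,(\mathrm{val}(k \cup \{i\}) - \mathrm{val}(k))$,
with $\mathrm{val}(k)$ the interventional mean — coalition features take the
explained sample's values, the rest are drawn from a background set, and the
model output is averaged over the background rows. Exact enumeration of all
$2^p$ coalitions is used up to $p = 15$ (the desk-scale ceiling); above that
a permutation estimator samples feature orderings, with coalition values
still computed as full background means so the only Monte-Carlo error is
over orderings. When the ordering space is small enough to enumerate
($p \le 8$ and enough draws), the estimator cycles all $p!$ orderings and is
exact. `shap_summary()` ranks features by mean $|\phi|$ and exports
(value, $\phi$) pairs for dependence plots. For a fitted model,
`interpret()` attributes over the post-selection multi-view features against
a training-matrix background (subsampled by default).

## Composition analysis

`enrichment()` compares positive and negative window sets per (position,
nucleotide) cell: class frequencies, their difference, and a Welch t-test on
the per-sequence presence indicator — the two-sample-logo convention. The
quoted criterion in this literature is an uncorrected $p < 0.05$, so no
multiple-testing correction is applied by default; a Bonferroni flag exists.
Structurally constant cells (the all-U center) yield $t = 0$, $p = 1$. A
signed $-\log_{10} p$ matrix for logo plotters is available via
`enrichment_logo_matrix()`.

## The synthetic generator, and what passing tests show

`simulate_windows()` emulates the *structure* of curated m5U window sets: a
fixed odd window length with the center forced to U, a position-specific
consensus motif (default UUC at positions 0..2, matching the consensus
reported for real m5U data) planted in positives with a configurable
probability over a uniform ACGU background, and uniform-background negatives.
The validation suite runs a planted-motif study at 300 windows per class with
a 0.9 planting probability — sizes comparable to the mature-mRNA-scale
datasets in this field and large enough that the planted positions are
unambiguous to a t-test.

Real transcript context is not uniform: it has dinucleotide autocorrelation,
GC structure, shared transcript provenance between positives and negatives,
and homology, none of which the generator reproduces. Passing the suite
therefore demonstrates that the machinery is correct (encoders match their
defining formulas, selection recovers planted signal, the classifier learns
a recoverable motif, attribution satisfies the Shapley axioms, the
enrichment test controls its type-I error) — not that any particular
accuracy will be attained on real data.

## Numerical and design choices

* Window invariants are hard errors, not warnings: even length, non-ACGU
  characters (after T→U and uppercasing) and a non-U center are rejected at
  construction. No edge padding is performed; windows that would run off the
  transcript are refused, because the encoders cannot represent ambiguity.
* All vector blocks with a frequency interpretation sum to 1 to 1e-9
  (ENAC per sliding window, CKSNAP per gap, PseDNC overall); this is used
  as a standing invariant in the tests.
* Tie-breaks are always toward the smaller/simpler object: smallest IFS
  prefix, smallest C then gamma in the grid, smaller k then w in embedding
  tuning. This keeps results unique and reproducible.
* Every stochastic stage (fold partitions, the generator, embedding
  training, tree ranking, background subsampling) takes an explicit seed,
  and helpers restore the caller's RNG state, so library code never
  perturbs a user's session RNG.
* Degenerate metric denominators report 0 with a flag; the lightgbm ranking
  backend is recognized but unavailable and raises a capability error
  naming the alternatives.
* Problem sizes in the shipped validation suite are deliberately desk-scale
  (hundreds of windows, coarse IFS steps, reduced embedding dimensions in
  the fast paths); all of them are knobs on `m5u_config()` and the defaults
  are the method's standard settings (step 1, 100-dimensional embeddings,
  tenfold CV).

## Known limitations

* Negatives in real datasets are drawn from the same transcripts as
  positives; the generator does not model per-transcript sampling structure
  (it exposes class counts directly).
* Homology reduction is out of scope — inputs are assumed deduplicated
  upstream (e.g. with CD-HIT).
* The exact Shapley path is exponential by nature; for fitted models with
  hundreds of features only the permutation estimator is practical, and its
  attributions carry Monte-Carlo error at small `n_perm`.
* The SVM probability surface is not calibrated; hard predictions use
  libsvm's default threshold and AUC uses the signed decision values.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
train <- simulate_windows(150, 150, motif = "UUC", motif_prob = 0.9, seed = 1)
cfg <- m5u_config(selection_step = 20, selection_folds = 5, folds = 5,
                  embed_dim = 32, embed_epochs = 10,
                  svm = svm_config(C_grid = c(1, 10, 100),
                                   gamma_grid = c(0.005, 0.05, 0.5)))
fit <- m5u_fit(train, cfg)
print(fit)
summary(fit)

test <- simulate_windows(50, 50, motif = "UUC", motif_prob = 0.9, seed = 2)
predict(fit, test, type = "report")

shap <- interpret(fit, n_samples = 10, seed = 1)
shap_summary(shap, top_n = 10)$ranking
```
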