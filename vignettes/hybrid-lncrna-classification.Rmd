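---
title: "Hybrid deep learning classification of plant lncRNAs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid deep learning classification of plant lncRNAs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(plncHDeep)
```

## The problem and the model

Long noncoding RNAs (lncRNAs) are transcripts longer than 200 nt with no
protein-coding role; distinguishing them from mRNAs using only the
nucleotide sequence is a standard binary classification task in plant
genomics, where tools trained on animal data transfer poorly. The
approach implemented here learns two complementary views of the same
transcript and fuses them at decision level:

* **Sentence view.** The sequence is tokenized into non-overlapping
  words of `p` nucleotides (default `p = 3`, i.e. codon-sized words;
  4^3 = 64 word types plus a padding token). A word-embedding layer
  followed by a bidirectional LSTM (64 units per direction, dropout
  0.4) and a sigmoid dense layer maps each transcript to a confidence
  probability `Cp_L` that it is a lncRNA. Training minimizes binary
  cross-entropy with Adam.
* **Image view.** The sequence is one-hot encoded as a 4 x N binary
  matrix (rows A, T, C, G; all-zero trailing columns pad shorter
  sequences). Two convolutional layers (32 then 64 filters), each
  followed by max-pooling, then dropout 0.4 and a two-way softmax give
  the pair `(1 - Cp_C, Cp_C)`. Training minimizes categorical
  cross-entropy with SGD.

The two confidence probabilities are combined per sample by one of three
*selection* strategies (the fused value is always one of the two inputs,
never an average), with decisiveness measured by the distance `|2Cp - 1|`
from the 0.5 fence:

* greedy: keep the more decisive of the two (ties go to the CNN);
* CNN-dominant: trust the CNN unless `|2Cp_C - 1| <= 0.5`, otherwise
  fall back to the LSTM;
* LSTM-dominant (the default): the mirror image, reflecting that the
  token/LSTM branch is the stronger single model.

The fused `Cp` is thresholded at 0.5 inclusive: `label = 1` iff
`Cp >= 0.5`.

## Dataset protocol

Class balance is controlled by clustering-based undersampling of the
majority (mRNA) class: negatives are embedded in the 20-dimensional
space of weighted 1-mer and 2-mer frequencies, clustered by k-means with
200 centers (k-means++-style seeding for reproducibility; the center
count is capped at the number of distinct samples for small runs), and
cluster `i` of size `x_i` contributes

    O_i = round(x_i / total * target)

randomly drawn samples, preserving the compositional structure of the
majority class. `round()` is implemented half-away-from-zero rather
than R's banker's rounding, matching the conventional rounded function.
Two numerical consequences are worth knowing:

* the raw rounded counts sum to the target only approximately (each
  cluster contributes at most 0.5 of rounding error, so the deviation is
  bounded by half the cluster count); `undersample_counts(...,
  exact_total = TRUE)` applies a largest-remainder correction when the
  exact total matters;
* when the cluster count is large relative to the number of negatives,
  many singleton clusters each round 0.5 up to 1, biasing the selected
  total upward. This is inherent to the per-cluster rounding rule; the
  exact-total option removes it.

Evaluation uses a stratified 80/20 split (stratification keeps a
balanced design balanced on both sides; the split is deterministic given
a seed), stratified 5-fold cross-validation, the threshold metrics
sensitivity, precision, accuracy, F1 and GM (geometric mean of
sensitivity and specificity, informative on imbalanced test sets),
trapezoidal ROC/AUC (equal to the normalized Mann-Whitney statistic
with rank-averaged ties), and Fisher's unprotected LSD test on per-fold
accuracies (pooled one-way-ANOVA error variance, two-sided t). Metrics
with zero denominators are reported as `NaN` with a warning rather than
silently as 0, so fold averages are not quietly corrupted. Fold metrics
are averaged per fold; pooled evaluation over concatenated predictions
is available by evaluating the pooled vector directly.

## Classical features

`feature_vector()` produces the 90-dimensional classical descriptor
used by shallow baselines and for clustering: 84 weighted k-mer
frequencies (`f_j = a_k c_j / s_k` with `s_k = L - k + 1`,
`a_k = 1/4^(3-k)`, k = 1, 2, 3, lexicographic form order with base
order A < T < C < G), three ORF features (integrity, coverage
`sum(l_m)/L`, normalized count `n/L`) and three structure features
(number of base pairs, GC content, normalized folding energy).

Two classical external tools are replaced by internal components, by
design:

* **ORF finder.** A three-forward-frame scanner: within a frame, the
  first ATG after the previous ORF's stop opens an ORF that runs to the
  next in-frame stop (inclusive), so every reported ORF is integrated;
  ORFs shorter than `min_codons` (default 30) are discarded. Transcripts
  are treated as sense-strand, so reverse-strand ORFs are deliberately
  not counted.
* **Folding engine.** A Nussinov dynamic program over Watson-Crick and
  GU wobble pairs with a minimum hairpin loop of 3 unpaired bases. The
  objective is lexicographic: maximize the number of pairs, break ties
  by the per-pair stability proxy 3 (GC) > 2 (AU) > 1 (GU); the reported
  energy is minus the optimal proxy score and `nmfe` divides it by the
  length. The proxy ranks stability sensibly but is **not** on the
  kcal/mol scale of a thermodynamic folder; `structure_features(...,
  engine = "external", fold_fun = ...)` accepts an adapter to any
  external tool when absolute energies are needed.

## The synthetic generator and what it does (not) show

`gen_dataset()` draws both classes from i.i.d. multinomial base
backgrounds with three controllable departures, which are exactly the
signals the two models can exploit:

* `gc_shift` moves mRNA-like background GC to `0.5 + gc_shift/2` and
  lncRNA-like GC to `0.5 - gc_shift/2` (coding sequence tends to be
  GC-richer than plant lncRNA);
* `orf_frac_mrna` sets the target coverage of the single ORF embedded in
  each mRNA-like sequence (ATG, interior sense codons, terminal stop, at
  a random in-frame offset);
* `periodicity_strength` in `[0, 1]` mixes the interior codon
  distribution between the background product distribution and a skewed
  positional profile, producing the codon-level 3-periodicity that
  distinguishes coding sequence.

One semantic choice deserves emphasis: **strength 0 is the exact null
model**. At `periodicity_strength = 0` no ORF is embedded and both
classes reduce to pure i.i.d. background, so with `gc_shift = 0` they
are statistically identical and any classifier's expected accuracy is
0.5. Embedding a stop-free ORF while claiming "no codon signal" would
be self-contradictory — stop-codon depletion *is* a detectable triplet
signal — so ORF embedding is tied to a positive periodicity strength.
For any strength > 0 the interior is sense-codons-only and the full ORF
is present.

The presets are fixed study conditions, chosen once: `strong`
(`gc_shift = 0.1`, `periodicity_strength = 0.9`, ORF coverage 0.9) gives
classes a scientist would call clearly separated but not trivially so
(single-feature rules do not reach the ~0.99 accuracy the trained
models do); `weak` (0.05, 0.4) and `none` (0, 0) cover the intermediate
and null regimes. Lengths default to 210–400 nt, respecting the
>200 nt lncRNA definition on both classes so length is not a
confound.

What passing tests on this generator shows: the encoders, training
loops, fusion rules and evaluation stack are correct and can recover
known signal at realistic effect sizes. What it does not show:
performance on real transcriptomes, whose UTR structure, splice
isoforms, repeat content and length/GC confounds the generator
deliberately omits.

## The neural-net engine and numerical choices

The package ships its own small neural-net engine in vectorized base R
(forward and backward passes for the embedding/BiLSTM/dense stack and
the conv/pool/softmax stack, Adam and momentum-SGD optimizers). Layer
types, unit/filter counts, dropout, activations, losses and optimizers
follow the reference architecture; sizes with no prescribed value are
exposed in `lstm_config()` / `cnn_config()`. Choices that matter:

* **Masking.** Padding tokens map to a frozen zero embedding and masked
  LSTM steps carry state through unchanged, so zero-padding injects no
  signal in either direction; all-padding inputs are valid and score
  near 0.5. The analytic gradients of both networks are verified against
  central finite differences in the test suite.
* **Schedules.** Defaults are Adam at 0.002 for the LSTM and SGD at
  0.03 with momentum 0.9 for the CNN; 0.03 was selected because the
  loss trajectory of the small CNN is stable there across seeds,
  whereas noticeably hotter rates occasionally diverge mid-run.
* **Determinism.** Every stochastic step (initialization, shuffling,
  dropout, splits, clustering, generation) flows through a local
  seeded RNG scope, so identical configs reproduce identical runs
  without touching the caller's RNG state, in single-threaded BLAS.
* **Widths.** Encoded widths (`floor(max L / p)` tokens, `max L` one-hot
  columns) are fixed on the training set; longer test-time sequences are
  truncated with a warning rather than silently re-deriving the width.
* **Tie-breaks.** Fusion boundaries use `<=` exactly as defined (ties
  at the decisiveness fence go to the deferred model); labels threshold
  at `Cp >= 0.5`; trailing partial words (`L mod p != 0`) are dropped by
  the stride-`p` window.

Problem sizes in the shipped tests and in `scripts/acceptance.R` are
desk-scale by design: 400 sequences per class (negatives undersampled
from 800), lengths 210–400 nt, an 8-unit LSTM and an 8/16-filter CNN
trained for about a dozen epochs. At these sizes a full pipeline run
takes well under a minute on one CPU, and both base models reach
held-out accuracy above 0.95 on strong-effect data; the reference-scale
architecture (64 units, 32/64 filters) is the default for real data.

## Known limitations

* The folding proxy is a maximum-pairing score, not free energy; use
  the external-engine adapter for thermodynamic values.
* Forward frames only in the ORF finder; antisense ORFs are invisible.
* Training is full-batch-shuffled minibatch gradient descent in plain R:
  fine for thousands of sequences, not for genome-scale corpora.
* The generator's i.i.d. background is a deliberate simplification; do
  not read synthetic accuracies as field performance.
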