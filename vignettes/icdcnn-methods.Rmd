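---
title: "Chapter-level ICD-10-CM coding with a multi-channel text CNN: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chapter-level ICD-10-CM coding with a multi-channel text CNN: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hospital discharge notes are free text, but reimbursement, surveillance and
research need them labeled with ICD-10-CM diagnosis codes. Truncated to the
first character level, the 2017 code system collapses to 21 chapter ranges
(`icd10_chapters()`), e.g. `C00-D49` Neoplasms, and a note typically carries
several of them, so the task is multi-label text classification. `icdcnn`
implements two families of pipelines for it and the tooling to compare them:

* **Classical**: token and n-gram phrase features in a bag-of-words
  document-term matrix, classified per chapter by an SVM (linear, degree-3
  polynomial, radial-basis or sigmoid kernel), a random forest, or a
  gradient boosting machine.
* **Embedding + CNN**: each note becomes an $n \times d$ matrix of
  pretrained word embeddings and is classified by a single-layer
  convolutional network with five filter-height channels.

Both are run one-vs-rest: 21 independent binary classifiers, one per
chapter, which matches per-task reporting and lets oversampling be tuned to
each task's prevalence.

## Encoding notes

Tokenization (`tokenize()`) lowercases and splits on non-alphanumeric
characters, keeping digit-bearing tokens intact — `h1n1` must survive,
because terms like it are exactly where embedding-based generalization
pays off. `encode_note()` stacks the embedding vectors of the in-vocabulary
tokens in note order. Two policies here are deliberate:

* **Out-of-vocabulary tokens are dropped**, not zero-filled: a zero row in
  the middle of a note would create convolution windows spanning words that
  were never adjacent.
* **Short notes are padded** with zero rows at the bottom up to `min_rows`
  (default 5, the tallest filter), so every channel always has at least one
  window. With non-positive biases a zero pad window contributes a zero
  activation and pooling is unaffected; with positive biases pad windows
  contribute `max(bias, 0)` — pooled features are taken over all windows,
  pads included, which is the simplest consistent rule and is asserted in
  the tests rather than hidden.

## The network

Channel $c$ applies $k_c$ filters of height $h_c$ (width $= d$). For filter
$f$ with weights $W_f$ and bias $b_f$, window $t$ of the note matrix $M$
gives $a_t = \mathrm{ReLU}(\langle M_{t:t+h-1}, W_f\rangle + b_f)$, and max
pooling keeps $\max_t a_t$ — a "concept detected anywhere in the note"
feature. The default geometry, `channel_spec()`, is
$(h,k) \in \{(1,40), (2,30), (3,15), (4,10), (5,5)\}$: 100 pooled features
per note. Dropout (rate 0.5, inverted scaling) is applied to the pooled
vector during training, and a logistic output unit turns it into a
probability; training minimizes cross-entropy plus an L2 penalty
($\lambda/2 \sum w^2$ over filter and output weights, not biases).

Optimization (`note_cnn()`) is minibatch gradient descent with momentum:
defaults are batch size 1000, learning rate 0.05, momentum 0.9,
$\lambda = 10^{-5}$, and early stopping when the monitored loss improves by
less than $10^{-4}$ over 100 iterations. The reference protocol does not
say what loss the tolerance is applied to; we monitor a 10% validation
split of the training notes (`validation_fraction`), evaluated without
dropout — monitoring the training batch loss would make the stopping rule
hostage to minibatch noise. Weights initialize uniform on $(-0.05, 0.05)$
with zero biases; the scheme is unremarkable and seeded
(`init_cnn_params()`). The forward/backward passes are C++
(RcppArmadillo); the gradients are validated against central differences to
$10^{-4}$ relative error in the test suite, and the forward pass against a
nested-loop oracle.

`desk_training_config()` keeps the optimizer settings but scales batch size
(100), iteration cap (200) and early-stop window (50) to the bundled
synthetic corpora of about 2000 notes, where a 1000-note minibatch would be
half the corpus; all experiments below and the package's acceptance script
use these sizes.

## Evaluation protocol

`evaluate_pipeline()` reproduces the full protocol per model family:
chapter labels derived from the codes field; either 5-fold cross-validation
(`split_kfold()`) or a date split (`split_temporal()`, train strictly
before the cutoff — the deployment rehearsal); minority-class oversampling
to balance (`oversample()`) applied to training parts only, never to test
folds; per-task AUC (`roc_auc()`, rank form of the Mann–Whitney statistic,
ties at half credit) and F-measure (`f_measure()`; threshold 0.5 for
probability outputs, 0 for SVM decision values — the reference leaves the
threshold unstated, so it is exposed as a parameter; precision is defined
as 0 when nothing is predicted positive). Reports aggregate per column with
the global mean and the mean of the 5 lowest task values
(`summarize_eval()`), the worst-case summary used in the field. Where the
fold-vs-task order of aggregation is ambiguous, we average over folds per
task first and take lowest-5 on the fold-averaged values.

Baseline vocabularies are built from the training part only: all unigrams,
n-gram phrases ($n$ 2–5) with corpus count strictly greater than 10, and —
as a stand-in for licensed clinical vocabularies — an optional pluggable
synonym dictionary mapping terms to category pseudo-tokens
(`toy_synonym_dictionary()`; one category token per matching term
occurrence). The count filter applies to phrases only, not unigrams.

## Filter interpretability

For a trained model, each filter's pooled activation is binarized by the
training-IG-maximizing threshold over midpoints of consecutive distinct
values (`binarize_activation()`; deterministic, first-best tie-break) and
scored by information gain $IG(C,F) = H(C) - H(C \mid F)$ in bits
(`information_gain()`). Transfer from training to test data is summarized
by the geometric mean of per-filter $IG_{test}/IG_{train}$ ratios, capped
at 1 (`ig_ratio_summary()`). Because the threshold search *maximizes*
training IG, a label-independent filter still shows a small positive
training IG at finite $n$; `ig_noise_floor()` estimates that chance level
by permuting labels and is the recommended eligibility floor for the
geometric mean. At a few thousand notes this matters: filters with
training IG barely above chance transfer poorly and would otherwise
dominate a geometric mean, while the genuinely informative filters in our
experiments transfer at ratios near 1. `top_filter_ngrams()` exposes what
a filter fires on: the highest pre-pool ReLU activations over all
height-$h$ windows of a corpus, with counts of notes where the n-gram is
the pooled (argmax) window.

## The synthetic corpus

Hospital discharge notes cannot be redistributed, so the package ships a
generator (`corpus_spec()`, `generate_embeddings()`, `generate_corpus()`)
that reproduces the statistical structure the method exploits, not clinical
language:

* **Concept-clustered embeddings**: one unit cluster center per label;
  signal (synonym) words are the center plus isotropic Gaussian noise
  (`sigma`, default 0.1 — within-concept cosines around 0.8 in $d = 20$,
  comparable to the similarity of real disease-term synonym pairs in
  published embeddings); background words are kept at absolute cosine
  below 0.5 from every center.
* **Keyword-driven multi-label assignment**: each note draws each label
  independently at its prevalence; the defaults
  (0.335, 0.282, 0.213, 0.130, 0.074, 0.037) mirror the spread of chapter
  prevalences in hospital data, from a dominant chapter to a rare one.
  A positive label injects each of its signal words with probability
  `p_signal` (default 0.25 of 12 words — a few synonyms per note, so no
  single term is individually necessary); tokens are background words with
  Zipf-distributed frequencies (exponent 1.1) in random order, 15–40 per
  note.
* **The emerging-synonym scenario**: with `emerging_fraction` $> 0$, that
  share of each label's signal words is reserved — it never appears before
  the cutoff date, and a post-cutoff positive note expresses its label
  through the reserved set with that probability. This reproduces the
  emerging-disease situation (a term like H1N1 absent from all historical
  notes but embedded near influenza terms): the reserved words have zero
  training counts, so term-count models cannot use them, while their
  embeddings lie in the trained concept cluster.

The packaged conditions (`small_corpus_spec()`: 2000 notes, 6 labels,
$d = 20$) were fixed once as the test-suite scale. What passing on them
shows is that the implementation is correct and that the embedding-CNN's
qualitative advantages (synonym pooling, robustness to train-unseen terms)
emerge under the structure that produces them; it does not show clinical
performance — real notes bring misspellings, negation, section structure
and label noise that the generator deliberately omits.

## Numerical choices and degenerate inputs

Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ before logs; a note
with no in-vocabulary token encodes to an all-pad matrix with a warning,
not an error; chapter mapping treats the 21 ranges as half-open intervals
on their ordered start bounds, so the gap prefixes between ranges (which
contain no billable 2017 codes) inherit the preceding chapter and mapping
is total on A00–Z99, while malformed codes are rejected by name; `O9A` is
handled as the one legal non-numeric third character. Constant pooled
activations binarize to an all-zero feature (IG 0). All randomness —
initialization, batching, dropout, oversampling, folds, generation — runs
through R's RNG under explicit seeds, and fits are reproducible to the bit.

## Limitations

One binary CNN per chapter (no parameter sharing, no multi-output head);
no spell correction, negation handling or sentence structure; baseline
hyperparameters are the backends' defaults, so their numbers characterize
the protocol, not the best attainable classical performance; and the
synthetic corpus is a mechanism model, not a language model.
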