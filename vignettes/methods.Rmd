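---
title: "Classifying cancer disease response from radiology conclusions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cancer disease response from radiology conclusions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task

Oncology follow-up imaging is summarized in the free-text conclusion section
of a radiology report. Reading that section, a clinician assigns one of four
disease-response classes relative to the prior comparison scan: **NED** (no
evidence of disease), **PR** (partial response), **SD** (stable disease) or
**PD** (progressive disease). Automating this assignment makes it possible to
derive progression-free survival in large retrospective cohorts and to offer
an automated second opinion in clinical workflows. `radresponse` implements
the full modeling stack for this task at desk scale: a corpus model with
patient-level splitting, classical TF-IDF baselines, small neural sequence
classifiers, sentence-permutation consistency training, cloze-prompt few-shot
fine-tuning of a masked language model, and an evaluation harness.

Real annotated report corpora of this kind are private. The package therefore
ships a synthetic corpus generator that reproduces the *structural* properties
the methods rely on, so that every stage is exercisable and testable end to
end.

## The synthetic corpus and its label oracle

The generator (`generate_corpus()`) emulates:

* **Population structure** — a configurable number of patients, each with
  `1 + Poisson(mean - 1)` reports; the default mean of 6 reports per patient
  matches the reference cohort average. The shifted Poisson guarantees at
  least one report per patient while hitting the stated mean.
* **Class marginals** — labels are drawn per report from the default
  NED/PR/SD/PD marginals 0.390/0.114/0.144/0.352, the reference population
  distribution. Sampling the label first and composing a compatible sentence
  bundle afterwards keeps the marginals exact in expectation with no
  rejection step.
* **Sentence structure** — each conclusion is a shuffled bundle of sentences
  drawn from a template bank (at least 8 templates per role, with site /
  lesion-type / size slots): class-defining cues (resolution statements,
  shrinking, stable, growing, or new lesions), benign incidental findings,
  label-neutral distractors (0–3 per report), and an occasional hedging
  sentence (probability 0.1). Slot filling prevents bag-of-words models from
  memorizing one string per class. Sizes are numerically consistent with the
  sentence's role (current < prior for shrinkage, and so on), although the
  label oracle currently uses roles only.
* **Labels** — `oracle_label()` maps the *multiset* of sentence roles to a
  class with a fixed precedence: any growth or new lesion means PD; else any
  shrinkage means PR; else any stable lesion means SD; else NED. Because the
  rule sees only the multiset, the label is invariant to sentence order by
  construction — exactly the premise of permutation augmentation. The oracle
  stands in for the (unavailable) consensus annotation guidelines of a human
  curation team; it is a plausible precedence rule, not a reconstruction.

The defining role is repeated `1 + Binomial(2, 0.5)` times, which keeps
single-sentence conclusions below 5% so that permutation augmentation almost
always has something to permute.

**What passing tests on this corpus do and do not show.** The generator's
language is templated and far easier than real radiology prose: cue words are
nearly unambiguous, there are no negation scope traps, no cross-sentence
coreference, and no indeterminate findings (the reference study excluded
those too). Results on it validate the *mechanics* of each method —
label-preservation of augmentation, the direction of the consistency effect,
the few-shot benefit of prompting — not clinical-grade accuracy. Absolute
accuracies reported by the reference study (around 0.89 with GPU-scale
pretrained encoders on 10,602 reports) are out of reach and out of scope
here.

## Corpus model

Corpora are JSON-lines files (one record per line) with patient-level split
assignment. `split_by_patient()` shuffles the sorted patient list with a
seeded generator and cuts it, apportioning patients to train/dev/test by
largest remainder — so 10 patients at fractions (0.8, 0.1, 0.1) give exactly
8/1/1 and the assignment is reproducible across platforms. The reference
study's realized patient counts are not an exact 80/10/10 split and its
apportionment rule is unstated; largest remainder was fixed here for
determinism. Patient-level (rather than report-level) splitting prevents
leakage: all reports of a patient stay in one fold, matching deployment on
unseen patients. The training entry points refuse train/dev pairs that share
patients.

## Sentence permutation and consistency training

`split_sentences()` segments a conclusion at sentence-final punctuation,
protecting common abbreviations ("approx.", "e.g.", …) and numbered-list
markers; joining the sentences with single spaces reproduces the
whitespace-normalized input, so permuted variants preserve the token multiset
exactly. `permute_conclusion()` draws up to `P` distinct non-identity orders
(all `n!` orders are enumerated for n ≤ 7; longer conclusions use bounded
rejection sampling), giving exactly `min(P, n! − 1)` variants; textual
duplicates arising from repeated sentences are dropped. The default `P = 10`
follows the reference recipe.

Consistency training (`train_with_consistency()`) adds to the cross-entropy
loss a mean-squared-error penalty between the model's label distributions on
an original and on one uniformly sampled permuted variant:

    L = alpha * L_CE + beta * L_MSE,   L_MSE = (1/C) * sum_c (y_c - y^P_c)^2,  C = 4

with defaults alpha = 1, beta = 10. Design choices that the source recipe
leaves open, and how they were fixed:

* **MSE on probabilities, not logits** — the tied quantity is the *output
  label distribution*, i.e. the post-softmax vector.
* **Gradient flows through both distributions** by default; a
  `stop_gradient_original` flag switches to a fixed-teacher variant.
* **Variants also enter the cross-entropy term** by default (they are
  additional labeled samples — augmentation is described as increasing the
  number of training samples); when enabled, the original and variant CE are
  averaged so the CE scale does not depend on the flag. Configurable off, and
  with `beta = 0` and variants excluded the trainer reduces *exactly* to
  plain training under the same seed (same RNG stream, verified bitwise in
  the tests).
* **One variant per step** (sampled uniformly each epoch) by default;
  averaging over all P variants is available (`average_all_variants`).
* No sharpening or confidence thresholding is applied to either
  distribution.

## Classifiers

**Classical baselines** (`fit_classical()`): TF-IDF bag-of-words features
(unigrams + bigrams, minimum document frequency 2, smooth idf, l2-normalized
— sub-settings the reference leaves unstated, fixed here and exposed in the
interface) feeding (a) a linear max-margin classifier, (b) multinomial ridge
logistic regression, (c) gradient-boosted trees (200 rounds, depth 6,
learning rate 0.1, single-threaded for determinism), and (d) a soft-voting
ensemble averaging the three members' probability vectors. Two deliberate
choices:

* n-grams never span a sentence boundary, so the feature vector — and hence
  every classical prediction — is *bit-identical* under sentence permutation.
  This makes the classical models an independent oracle for the
  augmentation module's label-preservation claim.
* The max-margin member needs probabilities for soft voting. The bundled
  libsvm probability machinery draws from a C random stream that R's seed
  does not control, so calibration is done manually: one-vs-rest linear
  SVMs, out-of-fold decision values from a seeded 3-fold refit, a sigmoid
  (Platt) fit per class, and normalization across classes. Everything is
  deterministic given the seed.

Argmax ties break toward the lowest class code (NED first) everywhere.

**Neural classifiers** (`train_supervised()`): a small transformer encoder
(default 2 layers, 4 heads, model dimension 64, feed-forward 128, standard
fixed sinusoidal positional encodings, learned CLS vector for pooling), a Bi-LSTM (embedding size 64; per-direction hidden
32 so the concatenated state feeds the classic 64-unit dense layer and
4-unit output), and a 1-d CNN with global max-pooling. All three are
implemented in base R with hand-derived reverse-mode gradients — verified
against central finite differences in the test suite — and trained with Adam
on per-batch accumulated gradients. Training is bit-reproducible given the
seed: sequences are processed one at a time (no padding enters the math),
and every random draw goes through R's seeded generator. The
`pretrained_adapter` encoder kind accepts any external text-to-vector
encoder and trains a linear head on top, so full-scale pretrained
checkpoints can be plugged in by users with the hardware; no test depends on
one. The CLS-vector design also gives a well-defined "classification
position" for attention saliency.

These dimensions are deliberately small. The reference models are
345M-parameter pretrained encoders; the package's contribution is the
training objectives and protocol, which are architecture-agnostic.

Positional information deserves a note. Consistency training suppresses a
model's sensitivity to sentence order, so the base encoder must be able to
*see* order in the first place — as the large pretrained checkpoints this
method targets do, through strong positional signals. The package therefore
uses the standard fixed sinusoidal positional encoding (unit scale) in the
transformer and the masked LM rather than small randomly initialized learned
positions: with near-zero positional signal a small transformer is already
almost permutation-invariant and the held-out original-vs-permuted
divergence is dominated by seed noise, which would make the consistency
comparison meaningless rather than merely harder.

## Prompt-based few-shot fine-tuning

`train_prompt()` implements cloze-prompt fine-tuning of a masked LM with a
decoupled label loss and a label-conditioned masked-LM loss. The default
prompt is `"[INPUT_TEXT] [SEP] In summary, this is a [MASK]"` and the default
verbalizer maps codes 0–3 to "no evidence of disease", "partial response",
"stable disease", "progressive disease". Overlong inputs are truncated from
the tail of the input text, never from the prompt suffix.

* **Scoring**: each class is scored by the mean per-token log-probability of
  its tokenized verbalization over the mask span (padded positions excluded);
  length normalization keeps two-token phrases from dominating the four-token
  one. Scores are softmax-normalized over the four classes.
* **Decoupled label loss**: per-token binary cross-entropy at the mask span,
  pushing true-label tokens toward 1 and the other candidates' tokens toward
  0, averaged over involved (position, token) pairs. The negative set is
  restricted to the competing verbalizations by default
  (`full_vocab_negatives` extends it to the whole vocabulary).
* **Label-conditioned MLM loss**: the mask span is filled with a candidate
  verbalization, 15% of the input tokens are masked, and the model
  reconstructs the originals with BCE targets inverted when the candidate is
  wrong. During training each step uses the true label and one sampled wrong
  candidate; at least one input token is always masked (the standalone loss
  function instead errors after one resampling attempt, making the degenerate
  configuration visible).
* **Mask-span length**: the reference recipe caps label tokens at 2, but its
  own four-class verbalizer contains a four-token phrase; how that conflict
  was resolved there is unknowable. The default here is the longest
  verbalization's token length (no truncation), with the shorter cap
  selectable via `max_label_tokens`.
* Reference hyperparameter defaults are kept (2000 batches, learning rate
  1e-5, evaluation every 100 batches); the desk-scale experiments below use
  fewer batches and a larger learning rate suited to the tiny MLM.

The few-shot comparator is `fit_mlm_head()`: the same pre-trained encoder,
frozen, with a multinomial logistic head on mean-pooled hidden states. The
package's few-shot claim mirrors the reference pattern directionally: with
100 labeled reports, prompt fine-tuning should match or beat head-only
tuning of the same encoder.

## Evaluation harness

`evaluate()` produces the 4×4 confusion matrix, accuracy, micro- and
macro-averaged precision/recall/F1 and per-class metrics; in single-label
multiclass classification accuracy, micro-precision, micro-recall and
micro-F1 coincide, and the property suite asserts that identity on random
instances. `aggregate_runs()` averages accuracies over seeds (the reference
protocol averages 3 runs). `paired_t_test()` pairs per-seed accuracies by
default — the reference's pairing unit is unstated; per-example pairing can
be had by passing correctness indicators — and flags zero-variance
differences instead of fabricating a p-value. `cohen_kappa()` and
`spearman_rho()` implement the agreement statistics used for inter-annotator
agreement and external response-criteria validation; the reference values of
those statistics depend on private data and are not reproduction targets, so
the package exercises them on synthetic annotation noise
(`inject_annotation_noise()`). `learning_curve()` runs the
stratified-subsample protocol (largest-remainder stratification per class)
over a size grid. `saliency()` renders per-token weights — mean final-layer
attention from the classification position for transformers (the extraction
recipe is a design choice; the reference does not state one), gradient ×
input for any architecture — and `render_saliency()` emits the familiar
red-shaded HTML.

## Numerical choices and problem sizes

* Tokenization for neural models: lowercased word + punctuation tokens, four
  reserved ids (padding, OOV, mask, separator), frequency-then-lexicographic
  vocabulary order for determinism.
* Losses are clamped at 1e-7 inside BCE logs; label distributions are
  validated to sum to 1 within 1e-6; layer norm uses epsilon 1e-5.
* The test suite and the acceptance script run everything at desk scale,
  chosen so the full stack (including six neural trainings and six
  prompt-model trainings) completes in minutes on one CPU: an 80-patient
  corpus (~480 reports) with an 80/10/10 patient split; 100-report few-shot
  training sets; a transformer of dimension 32 with 1 layer (8 epochs,
  learning rate 2e-3) for the consistency comparison; a masked LM of
  dimension 32 with 2 layers, 400 pre-training steps and 1000 prompt batches
  (learning rate 1e-3) for the prompt comparison; 3 seeds per comparison.
  These sizes are the package's reference experiment; users can scale any of
  them up through the configuration objects.

## Known limitations

* The synthetic language is templated; models trained on it do not transfer
  to real reports, and ceiling effects can compress differences between
  methods.
* The label oracle ignores lesion sizes and cannot express indeterminate or
  mixed-response subtleties beyond its precedence rule.
* The neural stack is CPU-oriented base R: correct and reproducible, but not
  fast; full-scale pretrained encoders enter only through the adapter seam.
* The consistency and few-shot comparisons are directional claims under the
  synthetic conditions, with small test splits; they are not estimates of
  effect sizes on clinical data.
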