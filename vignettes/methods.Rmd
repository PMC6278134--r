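---
title: "Methods: stroke-risk prediction from longitudinal health records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stroke-risk prediction from longitudinal health records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the prediction task and its assumptions, the synthetic data generator that
stands in for hospital records, the parameters that matter, the numerical
choices, and the limits of what the tests demonstrate.

## The prediction task

Given a patient's historical diagnoses and blood/biochemical exam results,
predict whether a first stroke diagnosis (ICD-10 I60–I69) occurs within
365 days of the last record. The horizon matches the annual-exam rhythm of
occupational health care: a one-year-ahead flag raised at a routine exam is
actionable. The task is framed as binary classification over *instances* —
snapshots of a patient's history anchored at each record — not over
patients, so one patient contributes many training examples with labels
that flip from 0 to 1 as the anchor approaches the stroke.

Three predictors are compared. Model 1 reads the diagnosis sequence with a
masked GRU; Model 2 reads the exam sequence with a shared per-timestep
dense transform followed by a dense stack; Model 3 fuses both branches'
penultimate representations, initialized by transferring the trained branch
weights of Models 1 and 2. If diagnoses and exams carry complementary
information, Model 3 should beat both single-input models.

## The synthetic EHR generator

The hospital data this class of analysis is usually built on is never
deposited, so the package generates populations with the statistical
structure the analysis assumes, plus a *planted*, controllable link between
history and outcome. What the generator emulates:

- **Demographics**: birth years 1920–1965, balanced gender.
- **Enrolment**: each patient's record begins at a first-contact date
  drawn uniformly over the first 80% of the 1996–2015 observation window;
  EHR coverage in reality starts when a patient first visits, not at the
  study window's opening. This also concentrates record anchors nearer to
  events, which keeps the instance-level positive prevalence within sight
  of the roughly 1-positive-in-8-to-9 regime typical for this design.
- **Diagnoses**: a Poisson stream (default 1.2/patient-year) over a
  30-code weighted background vocabulary of common primary-care codes.
  About 20% of emitted codes are spelled with a 5th character (half with a
  dot, "E11.6" style) so the 4-character truncation path is always
  exercised; real hospital feeds show such spellings at lower rates, the
  default exaggerates them for test coverage.
- **Exams**: panels at roughly annual intervals (Poisson per year with
  within-year jitter); each of the 20 catalog metrics is present with
  probability 0.85 and duplicated within a panel with probability 0.05.
  Metric values are Gaussian with gender-specific reference means/SDs from
  the catalog — plausible adult laboratory values, chosen because the
  pipeline needs standardizable real values, not clinical realism.
- **The planted hazard** has two arms so that both input modalities carry
  signal: (i) carriers of designated *risk codes* (hypertension I10,
  type-2 diabetes E11, atrial fibrillation I489; hazard ratios 3.0, 2.5,
  5.0) have their annual stroke probability multiplied from the year after
  onset; (ii) designated *signal metrics* drift linearly over the 3 years
  before the event (blood glucose +0.6 SD, HbA1c NGSP +0.6, platelet count
  +0.5, Hb −0.5, LDL-C +0.4 at the event). The baseline annual hazard is
  0.003. The hazard-ratio and drift magnitudes were calibrated once so
  that neither arm dominates — a lopsided generator would make the fusion
  comparison vacuous — and are not revisited.

Hazard is piecewise-constant per patient-year (a continuous-time hazard
would add nothing the downstream models can see at annual resolution). The
linear pre-event drift gives temporal models a learnable advantage over
last-value summaries, which is precisely the property the dual/temporal
architecture is supposed to exploit.

What the generator does **not** emulate: ICD-10 co-occurrence structure,
medication data, free text, seasonality, metric-metric correlations, and
measurement error models. Passing tests on this generator therefore show
that the pipeline recovers a planted signal of the stated form — they do
not show clinical-grade performance on real EHRs.

## Cohort construction

Case criteria, control matching (two stroke-free controls per case with
the same birth year and gender and records strictly before *and* after the
index date), and the grouped 70/15/15 split are implemented exactly as
described in the README. Design choices the source design left open:

- Control sampling among eligible candidates is uniform without
  replacement, seeded, with candidates ordered by patient id — so matching
  is invariant to the row order of the population.
- A control serves at most one case; reuse would copy identical records
  across matched triples and, worse, across splits.
- Matching is greedy in ascending index-date order. Optimal bipartite
  matching could retain slightly more cases but would buy determinism
  headaches for no inferential gain here.
- Age is index year minus birth year; the data model carries birth year
  only, which is also what the matching uses.

## Feature encoding

- Codes are truncated to 4 characters after dot removal; truncation is
  idempotent and tested against hand examples.
- Day gaps between consecutive records are bucketed into 6 categories with
  a *closed* upper edge at 365 (category 4 is [180, 365], category 5 is
  strictly longer than a year); the first or unknown gap is category 0.
  The tests pin this against a brute-force lookup for every gap 0..1000.
- Exams are summarized per age (newest value per metric-age pair; within a
  date the later-listed measurement wins, covering duplicated
  measurements), then imputed: roll-forward first, then training-split
  gender means for metrics the patient never had measured. The
  `indicator` strategy (zero-fill plus 20 presence flags, row length 48)
  and plain `roll_forward` are retained as alternatives because the
  strategy comparison is part of the analysis surface.
- Standardization always uses training-split means/SDs; fitting the scaler
  on anything else is impossible through the public API, and a test
  poisons the test-split labels to verify trained weights do not change.
- One instance is emitted per anchor position (every history prefix), with
  case anchors on/after the stroke date excluded. Each case's instance
  labels, ordered by anchor, switch 0 to 1 exactly once. The positive
  prevalence is therefore a generator property, not a resampling choice.
- Dual instances pair each exam anchor with the newest diagnosis instance
  anchored on or before it; the exam anchor provides the label. Exam gaps
  run between the retained per-age anchor dates (whether the source design
  measured gaps between raw panels or summarized rows is unstated; this
  choice is flagged, not asserted).

## The autoencoder

One hidden layer, tanh bottleneck (32 by default), softmax decoder,
categorical cross-entropy, full-batch Adam over the N one-hot codes
(optimizer unstated in the source design; full-batch Adam is the natural
choice at this problem size). "Perfect reconstruction" is argmax-exactness
— softmax cross-entropy never reaches zero loss exactly. Training stops at
accuracy 1 or `max_epochs` (warning, not error). With one-hot inputs the
encoder reduces to row selection, which gives the tests a one-line oracle.

## The imbalance loss

`custom_loss` is implemented literally as the three-term sum (alpha times
all log losses, beta times the negatives' sum, gamma times the positives'
sum); the weighted-cross-entropy identity is kept as an *independent*
closed form that the tests compare against to 1e-10, along with
finite-difference gradient checks. Probabilities are clipped at 1e-7
before logs (the surrogate diverges at 0). The loss is summed, not
averaged, per batch, matching its definition; Adam's scale adaptivity
makes the distinction benign. With beta = gamma the objective is exactly a
uniform rescaling of cross-entropy — the interesting regime is beta ≠
gamma, and the imbalance test uses gamma = 10 > beta = 5 to penalize
missed positives harder.

## Predictors and training

Hidden sizes are configurable; the package defaults (GRU 64, dense 64/32)
are modest CPU-trainable capacities, since the reference architectures'
exact layer sizes are not recoverable. Sequences are pre-padded with zero
rows to fixed length (35 diagnoses, 20 exams) with an explicit mask; the
GRU holds its state through masked steps, and a test verifies that
prepending all-zero padding never changes its output. Training is
mini-batch Adam (batch 32, step 1e-3, framework-default moments), seeded;
the checkpoint with the best validation F1 (argmax threshold, positive
class) is returned, keeping the *latest* best epoch among ties so a
flat-zero F1 trajectory still returns trained weights. Transferred branch
weights are fine-tuned by default; freezing is available via
`train_config(freeze = ...)`.

## Evaluation

AUC uses the rank formulation with half credit for ties, which equals
trapezoidal integration of the empirical ROC curve (both are asserted, and
pROC serves as an independent cross-check in the tests). CIs are
percentile intervals from a stratified bootstrap (positives and negatives
resampled separately; 2000 replicates by default, following the
convention of the standard ROC tooling), seeded. The exam ablation zeroes
a metric group's standardized values (0 = training mean) across all rows
and re-scores the trained dual model; the loss ablation reports the
2 + 2 + 4 grid of model x loss x transfer-source configurations.

## Desk-scale study conditions

The full protocol of the source design (5,000+ patients, 500 epochs for
single-input models, 100 for the dual model, 2000 bootstrap replicates) is
what `experiment_config()` defaults encode. The test suite and the
`analysis/` drivers run a desk-scale version chosen once for CPU
pragmatism and documented here:

- end-to-end recovery: 3,000 patients (data seed 101), widths GRU 32 /
  per-timestep 16 / dense 32,16 / fusion 16, epochs 25 (single) and 12
  (dual), five training seeds;
- the three models are compared on the *common* dual test set — Model 1
  scored on its diagnosis half, Model 2 on its exam half, Model 3 on both
  — because the models' own instance sets differ in composition and hence
  in attainable AUC, which would confound the integration question;
- the imbalance experiment: 800/400 train/validation instances at 1:21
  prevalence with a +0.5 SD shift on a 5-metric block of the positives'
  last 6 rows, 12 epochs. This sits deliberately in the escape-speed
  regime: plain cross-entropy has not left the all-negative optimum by
  epoch 12 on any tested seed, while the positively-weighted objective
  already fires on some — which is the pathology-and-rescue the loss
  exists for.

At these sizes the five-seed end-to-end block reproduces the qualitative
ordering the design predicts (fusion mean AUC at or above both single-input
means, everything well above chance), with all randomness seeded.

## Known limitations

- The generator's independence assumptions (metrics independent given
  gender and drift; codes i.i.d. given weights) make the synthetic task
  easier than real EHRs; absolute AUCs here say nothing about clinical
  performance.
- Checkpoint selection by F1 at the argmax threshold is noisy when
  positives are rare; it is kept because it is the protocol being
  reimplemented, but selection by validation AUC would be more stable.
- With beta = gamma the custom loss differs from cross-entropy only by a
  scale factor; any benefit then rides on optimizer scale-sensitivity.
  The implementation supports the asymmetric regime, which is where the
  mechanism has force.
- The GRU uses the classic (reset-before) gate formulation; frameworks
  differ in this detail, so transferred intuitions about exact
  hidden-state values do not carry across implementations.
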