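---
title: "Classifying dopaminergic motor states from Parkinsonian speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying dopaminergic motor states from Parkinsonian speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdvoice)
```

## The problem

People with Parkinson's disease fluctuate between a medicated **ON** motor
state and an unmedicated **OFF** state. The OFF state audibly degrades
speech: hypophonia (reduced loudness), hoarseness (lower
harmonic-to-noise ratio), hesitation, imprecise articulation, and a
characteristically hastened, festinating speaking rate. `pdvoice`
implements two speaker-independent classifiers that call a patient's
motor state from structured speech recordings (seven elicitation
protocols: digits, months, vowels, pataka, twisters, read, monologue),
together with the feature extraction front end, feature-level statistics,
and a leave-one-patient-out (LOOCV) evaluation harness. Because clinical
recordings of this kind cannot be redistributed, the package also ships a
fully synthetic cohort generator so that every stage is exercisable and
testable end to end.

## Feature extraction

Recordings arrive as mono 44.1-kHz float WAV and are downsampled to
16 kHz/16-bit. Downsampling is FFT-domain sinc resampling — the spectrum
is truncated at the 8-kHz target Nyquist before reconstruction — which is
ideal anti-aliasing by construction; a 16-bit quantization round trip
follows. Training audio of one state is concatenated and cut into
non-overlapping 10-s segments; test recordings are kept separate
(utterance-level evaluation) and each 10-s test segment is split into a
5-s validation half and a 5-s test half, each extended back to 10 s by
repetition when fed to the network.

The time-frequency representation is the magnitude of a complex STFT
with a 25-ms window and 7.5-ms overlap (hop 17.5 ms) over 201 one-sided
bins. With the no-padding frame convention `floor((N - win)/hop) + 1`, a
10-s 16-kHz segment yields exactly a 201 x 571 matrix; that arithmetic
identity is why the package fixes this convention. Two points the
analysis convention leaves open are resolved as config options with
defaults: the window function (Hamming; conventional for 25-ms speech
analysis) and linear rather than log magnitude. Each frequency channel is
z-scored with mean and standard deviation estimated **on the training
folds only**; the fitted statistics carry a provenance tag so
cross-validation hygiene is assertable.

The phonological front end is consumed, not trained, by this package: a
posterior stream is a frames x 21 matrix of class posteriors over 20
distinctive features plus silence, at a 10-ms frame period (a
conventional short-term rate; the package fixes it since nothing in the
method depends on its exact value). Streams are read and written as
strictly validated 21-column CSV.

## The PAC classifier

The Phone-Attribute Codebook method is instance-based: no model is
fitted. Posteriors are 1-bit quantized at 0.5 (the measure-zero boundary
value maps to 1, fixed for determinism), giving one 21-bit code per
frame. All training codes of one class and protocol form a codebook;
codes occurring in both classes are removed from both, so the unique ON
and OFF codebooks are disjoint by construction (asserted on every run).
A test sample is scored by exact set membership — per-frame counting by
default, since every frame of the test sample is matched and frequency
weighting preserves evidence mass; per-unique-code counting is a config
switch — and the class with more matches wins. When exact matching ties
(including the common no-match 0 = 0 case on small codebooks), the
fallback scores each test code by its maximum Jaccard similarity
`a/(a+b+c)` (joint absences ignored; two all-zero codes score 1) against
each codebook and sums over test codes; summing, rather than taking a
single nearest code, uses all frames and is the package's choice where
the method description is silent. A persistent tie abstains. Patient
calls are majority votes over protocol decisions, abstentions excluded,
label ties broken by the summed score margin.

## The CRNN classifier

The network consumes normalized spectrograms shaped time x frequency:
a temporal 1-D convolution (196 filters, kernel 15, stride 4 over time),
two stacked bidirectional recurrent layers (GRU or LSTM, 128 units per
direction), each followed by dropout (rate 0.8, read literally as the
fraction dropped) and batch normalization — the dropout-then-batch-norm
order is fixed and documented since the description does not specify it
— and a time-distributed single-unit sigmoid head. The stated "(4, 4)"
stride over time *and* frequency cannot be literal for a 1-D temporal
convolution, so the frequency stride is realized as 4x average-pooling
decimation of the frequency axis before the convolution
(`freq_mode = "pool"`); a pure-temporal mode keeping all 201 bins as
input channels is the alternative. The output length obeys
`m = floor((n - kernel)/stride) + 1`, i.e. 140 steps for 571 input
frames; per-timestep targets are the segment's state label repeated m
times. Training minimizes per-timestep binary cross-entropy with Adam
(optimizer and loss are unstated upstream; these are the standard pair
for sigmoid-per-timestep heads).

No deep-learning runtime is declared as a dependency: the forward and
backward passes are implemented directly on BLAS-backed matrix algebra,
and every layer's gradients are verified against finite differences in
the test suite (relative error below 1e-4 at tolerance; observed around
1e-9).

Decisions binarize the m per-step probabilities at a threshold
(probability >= threshold counts as ON) and call ON iff strictly more
than m/2 steps are ON — an exact m/2 split is OFF, because the voting
rule is a strict majority. The threshold is selected per fold on the
validation halves by a 0.01-step grid search (smallest maximizer on
ties) and averaged across folds; a replication mode returns the fixed
constant 0.44 regardless of data, and both interpretations (per-fold vs
global average) are available since the published description is
ambiguous between them.

## Personalization (p-CRNN)

The model stays speaker-independent; only the set of speech protocols
used at test time is personalized. A protocol is selected for a patient
iff its validation halves are classified correctly for **both** states
(strict-all rule; a per-state majority rule is a config option). If no
protocol qualifies the evaluation falls back to all protocols with a
flag, so every patient still receives a call. Selection granularity is
the protocol (pooling that protocol's segments), matching the natural
unit "the recording of one protocol". `loocv_paired_crnn()` evaluates
CRNN and p-CRNN on identical per-fold models so comparisons are paired.

## Feature statistics

`attribute_ttest()` is a paired t-test per attribute (the within-subject
design makes pairing the coherent reading of a "two-sample paired"
description), defaulting to patient x protocol mean posteriors as the
pairing unit; segment- or frame-level pairing can be substituted. Note
that published frame-level analyses can report vanishing p-values even
for |t| near 1 because the frame count is enormous; with per-patient
pairing the same effect sizes give modest t values — the package reports
Bonferroni-adjusted p alongside raw p for the 21 tests. The sign
convention is mean(ON) − mean(OFF). Zero-variance differences return
±Inf with p = 0 (flagged), and `attribute_correlation()` is the Pearson
correlation of two attributes' posterior trajectories concatenated over
recordings, returning a flagged NA for constant series.
`embed_protocol()` embeds per-segment mean posterior vectors with a
seeded exact t-SNE (perplexity calibration by bisection, momentum
gradient descent — written in-package and suitable for the tens of
points involved) and reports nearest-centroid accuracy in the plane as a
separability score.

## The synthetic cohort generator

The generator emulates the *statistical structure* the classifiers
assume, not German phonetics. Each protocol has a phone-string template
over a 24-phone inventory with canonical 21-bit attribute vectors; the
inventory is deliberately coarse but fixes the properties the analyses
rely on (e.g. *high* and *coronal* canonically co-active within the
pataka phone set, giving the strong ON-state trajectory correlation
between structurally dependent attributes; fricatives are the only
*fricative*-bearing phones; pataka varies in silence, continuant, tense
and voiced). Posteriors are the canonical vectors plus a smooth
logistic-squashed AR(1) Gaussian perturbation (scale 0.15 — DNN
posteriors are typically saturated), plus a small state-independent
"articulation slip" rate (0.03 per active attribute-frame) representing
momentary under-articulation in either state.

OFF corruption has five components, all scaled by a per-patient x
protocol effect multiplier:

* **consistent weakening** — with probability 0.5 per attribute, a
  canonically active attribute is suppressed throughout the stream, and
  with probability 0.6 its frames activate a fixed "confusion partner"
  instead (slurred substitution). Consistency is essential: it is what
  gives each state class-exclusive quantized codes, the premise of the
  codebook method. Purely frame-independent corruption would let every
  near-canonical code eventually appear in both classes of a large
  training pool, emptying the unique codebooks;
* **frame-wise dropout** (0.08) — residual imprecision;
* **silence intrusion** (0.12 per frame) — hesitation;
* **time compression** (rate factor 0.9) — festination; the effective
  stretch is `1 + (0.9 − 1) x effect`, so a zero-effect patient is
  distributionally identical to ON;
* **posterior offsets** — small ON−OFF shifts on fricative (0.12),
  continuant (0.10), tense and voiced (0.08), giving the t-test its
  designed directions (silence rises in OFF via intrusion, fricative
  falls).

Audio is a jittered harmonic source shaped by per-vowel formant
resonances, shaped noise for fricatives, and closure-plus-burst stops;
OFF applies a 6-dB gain reduction, added aspiration noise, extra pitch
jitter and the same time compression, each scaled by the patient effect.
Effect multipliers are log-normal per patient x protocol
(sdlog 0.5) times per-protocol informativeness weights (pataka 1.3,
vowels 1.2, twisters 1.1, digits/months 1.0, read 0.45, monologue 0.35),
so that reading and monologue analogs are weakly informative — mirroring
the qualitative observation that spontaneous and read speech separate
the states poorly — and so that protocol selection is consequential. A
`single-protocol` mode makes exactly one protocol informative per
patient, the regime in which personalization must pay off. The
clinical-style score table draws per-patient totals around 21 (ON) and
adds a delta that increases monotonically with the patient's mean effect
multiplier. Recording durations are desk-scale (10.5–20 s per protocol,
preserving the tasks' relative lengths); with a 10-ms frame period each
recording still contributes on the order of a thousand frames per
stream, which is the regime the codebook statistics need.

What the generator does *not* emulate: intelligible speech, real
phonetic coarticulation, microphone/room acoustics, non-motor symptoms,
session-to-session drift. Passing tests therefore demonstrate that the
algorithms recover the designed structure under controlled conditions —
not clinical performance; the published clinical accuracies cannot be
reproduced without the original cohort, which is not distributable.

## Numerical and design choices

* Quantization boundary 0.5 → bit 1; decision-threshold boundary
  probability = threshold → ON bit; exact m/2 timestep vote → OFF.
* Exact-match tie → Jaccard; persistent tie → abstain; all protocols
  abstaining is an undecidable-patient error.
* Normalizer floors zero-variance channels at 1e-8 with a warning.
* LOOCV metrics are macro-averaged over folds (with a pooled-confusion
  alternative always reported), ON is the positive class, and undefined
  ratios are flagged NA rather than zero.
* Evaluations at desk scale use a reduced network (24 filters, 12
  recurrent units, dropout 0.2, 3 epochs, batch 16) and cap training at
  20 segments per state per fold, sampled evenly over the concatenated
  pool so every training patient stays represented; these sizes are the
  package's scaled-down study conditions and are fixed in the
  acceptance script and tests.

## A worked example

```{r example, eval = FALSE}
cfg <- cohort_config(n_patients = 6, protocols = c("pataka", "vowels",
                                                   "digits"), seed = 1)
cohort <- generate_cohort(cfg, "cohort")
res <- loocv(cohort$manifest, method = "pac")
res$metrics_pooled
```

## Known limitations

The CRNN at published scale (196 filters, 128 units, dropout 0.8, many
epochs) is supported by the implementation but slow on a single CPU; the
desk-scale configuration above is the practical default for simulation
studies. The PAC method inherits the asymmetry of unique-codebook
matching: weakly affected patients and weakly informative protocols
yield near-empty ON evidence and bias those protocol votes toward OFF,
which is consistent with the method's published sensitivity being lower
than its specificity. Personalized PAC is intentionally absent: with 5-s
validation and test halves the codebooks are too small to match
reliably.
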