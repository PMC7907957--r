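---
title: "Admission prediction and queue prioritization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admission prediction and queue prioritization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`udnadmit` studies a triage problem: a program for patients with
undiagnosed diseases receives applications (demographics plus a free-text
referral letter), an expert committee reviews them in periodic sessions of
limited capacity, and the question is how much a classifier that predicts
the committee's accept/decline decision can shorten the wait of the
patients who will eventually be accepted. Because real application data of
this kind are private, the package pairs the analysis code with a
synthetic cohort generator that reproduces the *statistical shape* of such
a stream; every claim the test suite makes is a claim about that
generative model, exercised end to end.

This vignette records the models, the calibration choices, the parameters
that matter, and the design decisions that were genuinely open.

## 1. The synthetic cohort

`generate_cohort(cohort_config())` draws, per application: a submission
day, an admission label, four demographics, a symptom category, a
recorded review day, and a referral letter. Everything is a pure function
of the configuration, seed included; two calls with the same
`cohort_config` are byte-identical.

**Arrivals.** Monthly application counts are lognormal, moment-matched to
the configured mean/SD (default 55.0 (19.7) applications per month — the
published workload of the program this package emulates). The lognormal
is a deliberate choice over Poisson: the configured SD implies strong
overdispersion, and a two-parameter family lets both moments be matched
exactly. Counts are integerized by stochastic rounding (floor plus a
Bernoulli on the fractional part), which preserves the mean exactly.
Submission days are uniform within each month; one month is 30.44 days in
every day↔month conversion in the package.

**Demographics and the truncated-normal calibration.** Ages, durations
and processing times are non-negative, so each marginal is modelled as a
normal truncated at zero. Truncation shifts moments: a normal with mean
19.7 and SD 18.7 truncated at zero has mean ≈ 24.7, which would break the
headline property that the generator *recovers its configured summary
statistics*. The generator therefore solves, per marginal, for the
underlying (μ, σ) whose **truncated** mean equals the configured mean
exactly (`calibrate_tnorm()`; the mean equation always has a root) and
whose truncated SD is as close to the configured SD as the family allows.
The caveat matters: a normal truncated at zero cannot exceed a
coefficient of variation of about 1, while some configured marginals
(e.g. duration 8.89 (9.55), not-accepted processing time 4.73 (4.85)) sit
at or beyond that bound. For those, the calibrated distribution has the
exact mean and the closest attainable SD. The package's recovery tests —
and its acceptance checks — therefore assert mean recovery strictly (3
standard errors at n = 5000) and SD recovery only where the family can
attain it.

**Coherence of age, onset and duration.** Only marginals are published
for the cohort being emulated, so the joint law is a design decision: age
at application is drawn first; disease duration is drawn from its own
calibrated truncated normal additionally truncated to [0, age] per person
(the "resample until coherent" rule, implemented by inverse-CDF sampling
on the restricted window); and age at onset is `age − duration`. Because
per-person truncation at the age would deflate the duration mean,
`calibrate_tnorm_conditional()` re-solves the duration parameters against
a deterministic quantile grid of the age distribution so the *marginal*
duration mean still equals the configured value. A pleasant consistency
check falls out: the implied onset means (19.7 − 8.89 = 10.81 and
36.5 − 8.12 = 28.38 years) agree with the published onset means (10.8 and
28.4) to the printed precision, so the emulated table is internally
coherent with this construction.

**Counts and dates.** Prior-visit counts are integerized by stochastic
rounding (mean-exact). The recorded review day — used by the `udn_order`
heuristic — is the submission day plus a calibrated truncated-normal
processing time in months (default 3.29 (3.17) accepted, 4.73 (4.85) not
accepted), converted to days and stochastically rounded with a floor of
one day.

**Labels and symptom categories.** Labels are i.i.d. Bernoulli (default
fraction 0.5, matching the near-balanced reference cohort of 1209 vs
1212). Symptom categories are categorical per class, proportional to the
published per-class counts across 21 categories.

**Letters.** A letter is a token sequence drawn from a four-component
mixture: a shared Zipf-weighted background vocabulary (weight 0.55), the
symptom category's own token set (0.15), terms from the shipped concept
lexicon (0.20), and terms from the shipped objective/subjective symptom
checklist (0.10). Class separation is a single knob, `class_effect`
∈ [0, 1]: concept terms of the sign/symptom, disease/syndrome and
gene types are sampled with weight 1 + e in accepted letters and 1 − e in
not-accepted letters (procedure and body-part terms the reverse), and
checklist terms are tilted at half that magnitude with objective findings
enriched in accepted letters — mirroring the admission criterion that an
application needs at least one objective finding. At e = 0 the letter
distribution is exactly label-independent; at e = 1 the class-conditional
concept vocabularies are disjoint. Letter length is Poisson around a mean
of 90 tokens (the sampled unit count is scaled by the expected tokens per
unit so multi-word terms do not inflate the length). The default
`class_effect = 0.5` was chosen once, as a moderate-separation setting, at
design time.

**What the generator does not emulate.** Realistic clinical language
(letters are token soups, with no syntax, negation or ontology
structure); correlations between demographics and symptom category;
site-level referral patterns; seasonal arrival structure; label noise in
committee decisions. Passing tests therefore demonstrate that the
pipeline recovers structure *of this kind* from text and demographics —
not that any particular performance level transfers to real referral
letters.

## 2. Feature tiers

Six cumulative tiers, in fixed order: `baseline` ⊂ `walley` ⊂
`referral_letter` ⊂ `semantic_types` ⊂ `clinical_bert` ⊂
`omim_similarity`. Feature names are namespaced per block (`base_`,
`walley_`, `tfidf_`, `sem_`, `emb_`, `omim_`), so blocks can never
collide, and the assembled dimension is non-decreasing up the ladder.

* **baseline** — the four demographics, min-max scaled to [0, 1] using
  training-split bounds, out-of-range values clipped.
* **walley** — one binary feature per symptom-checklist term:
  case-insensitive whole-token phrase presence (presence, not count). The
  shipped 30-term objective/subjective checklist is a demonstration
  lexicon, replaceable by any two-column TSV via `read_lexicon()`.
* **referral_letter** — TF-IDF over adjacent-token bigrams. Tokenization
  is lowercase, split on non-alphanumerics — the simplest reproducible
  dialect. The TF-IDF variant is the de-facto standard smoothed form:
  tf = raw count, idf = ln((1 + n)/(1 + df)) + 1, vectors L2-normalized.
  Bigrams unseen at fit time are ignored at transform time. The fitted
  vocabulary keeps bigrams with document frequency ≥ 2 by default
  (`min_df`): synthetic letters otherwise produce a vocabulary dominated
  by df-1 bigrams that contribute no generalizable signal.
* **semantic_types** — exactly five binary features, one per concept
  type; a flag is 1 iff any lexicon term of that type occurs in the
  letter. The shipped ~100-term lexicon is an unlicensed demonstration
  dictionary preserving the presence/absence semantics of a concept
  tagger; it is user-replaceable.
* **clinical_bert** — the letter's embedding vector under a pluggable
  backend. The default, `hashed_embedding_backend(512)`, is deterministic
  signed feature hashing of unigram counts (FNV-1a; bucket from the low
  hash bits, sign from bit 16), L2-normalized. Any backend with the same
  contract — same text, same finite vector — can be plugged in; none of
  the package's tests require a trained encoder.
* **omim_similarity** — one feature per phenotype-corpus entry: the
  cosine between the letter embedding and the entry-description embedding
  (entry embeddings precomputed once per corpus).
  `generate_phenotype_corpus()` provides a synthetic stand-in corpus
  whose entries are anchored at symptom categories.

**Leakage discipline.** Every fitted statistic (normalizer bounds, TF-IDF
vocabulary and document frequencies, corpus embeddings) comes from the
training split only; `featurize()` is a pure transform. Whether the
original analysis fitted its bigram vocabulary on all applications or on
training data only is not recorded; the leakage-safe choice is made here,
and it is the conservative one when comparing feature-tier magnitudes.

## 3. The classifier

An L2-regularized linear logistic model (glmnet, `alpha = 0`). The grid
crosses inverse-regularization strengths C ∈ {10⁻³, …, 10³} with class
weighting (none vs balanced) — the two hyperparameters that matter for a
linear logistic model; glmnet's penalty is mapped by λ = 1/(C·n).
Selection maximizes validation AUROC; exact ties keep the more
regularized candidate. The decision threshold is a signed distance of 0
(predicted probability one half) — the canonical default absent a stated
operating point; `evaluate()` accepts any other threshold.

The ranking statistic is the signed distance s(x) = (w·x + b)/‖w‖:
its sign is the predicted class, its magnitude the queue priority, and it
is invariant to rescaling (w, b).

**Evaluation.** Accepted is the positive class throughout. Sensitivity =
TP/(TP+FN), specificity = TN/(TN+FP), balanced accuracy their mean
(an exact identity in `metrics_report`), and AUROC the Mann–Whitney pair
statistic with ties counted one half — hence invariant under strictly
monotone transforms of the scores.

**Comparing tiers.** The published comparison used a Wilcoxon signed-rank
test without recording its pairing unit; the standard protocol adopted
here pairs per-fold test AUROCs from repeated stratified cross-validation
(default 10 repeats × 5 folds) with folds shared between the two tiers.
When every paired difference is zero the statistic is undefined and
`wilcoxon_signed_rank()` reports p = 1.

**Splits.** 80/10/10 train/validation/test, stratified: largest-remainder
rounding of the fractions within each label keeps every split's label
proportion within one application of the cohort's (2421 applications
split 1937/242/242).

## 4. The review queue

All four heuristics are *static* rankings — FIFO (submission day, id),
classifier (−score, submission day, id), accept-first (class, then FIFO
within class), and `udn_order` (recorded review day) — so the simulator
serves a fixed priority order under eligibility and capacity constraints:

* sessions on days d, 2d, 3d, … (first session on day d, not day 0);
* an application is eligible at a session iff submitted **strictly
  before** the session day;
* each session reviews the `budget_a` highest-priority eligible
  applications; the loop runs until everyone is reviewed;
* processing time = (review day − submission day)/30.44 months;
* `udn_order` bypasses the session mechanics and reads the recorded
  review days directly.

The streaming form (applications become eligible as they arrive) is the
package's definition of the session mechanics; a purely static ranking of
a closed backlog is the special case in which all submissions precede the
first session. Tie-breaking is everywhere (submission day, then id), so a
simulation replays deterministically. Two structural properties anchor
the test suite: on tiny cohorts, accept-first attains the brute-force
minimum of the accepted-group mean over *all* static priority orders; and
when every session is saturated or empty, the overall mean processing
time is the same for every heuristic — ranking redistributes waiting
between classes, it cannot create or destroy it.

`sweep_schedule()` evaluates the full (heuristic, d, a) factorial
(defaults d ∈ {3, 6, 9, 12, 15, 30}, a ∈ {5, 10, 15, 20, 26, 30, 40},
which bracket a biweekly session of ~26 reviews at the default arrival
rate) and reports the (d, a) minimizing the accepted-group gap between
classifier and accept-first ranking, ties toward smaller a, then smaller
d.

## 5. Cohort statistics

`welch_t()` computes the unequal-variance t test directly from per-group
mean/SD/n — the form needed when only summary statistics are available.
Welch was chosen over the pooled test because it reproduces the reference
table's printed statistics from its printed summaries (age at application
−20.7, minimum duration 2.0, processing time −8.6). `chi2_2x2()` is the
closed-form Pearson statistic with optional Yates correction;
`summarize_cohort()` applies it per symptom category (category vs rest ×
accepted vs not) with a Bonferroni family size equal to the number of
categories tested. Degenerate inputs are explicit: zero margins and
all-zero variances are errors, one-observation groups drop the t test
with a warning.

## 6. Numerical choices and degenerate inputs

* Truncated-normal sampling is inverse-CDF (no rejection loops), with the
  probability window clamped away from 0/1; collapsed windows fall back
  to the nearest endpoint.
* The calibration solvers are deterministic (uniroot inside a univariate
  optimize over log σ); σ is capped so the mean equation stays solvable.
* Hash arithmetic is exact in doubles (16-bit split multiply mod 2³²),
  so embeddings and fingerprints are platform-independent.
* Zero vectors make cosine similarity undefined and are signalled, as are
  zero weight norms in the signed distance, single-class AUROC sets, and
  empty training corpora.
* Sparse design matrices (`Matrix::dgCMatrix`) throughout the TF-IDF and
  assembled tiers.

## 7. Problem sizes in the test suite

The suite runs end to end on generated data at sizes chosen to make the
statistical assertions sharp but the run economical: recovery checks at
n = 5000; the tier-ordering comparison on two 2000-application cohorts;
the dominance suite on twenty 400-application cohorts with out-of-fold
scoring under a reduced grid (C ∈ {10⁻², 1, 10²}, unweighted) — the full
grid is reserved for the criterion-level fits; null-calibration checks on
50 permutation fits and 100–replicate goodness-of-fit loops at n ≈ 120;
and the queue-optimality oracle on fifty cohorts of two to seven
applications against exhaustive enumeration of all priority orders.

## 8. Known limitations

* The synthetic letters carry no linguistic structure; tiers that exploit
  word order beyond bigrams cannot be differentiated on these data.
* The embedding tier's default backend is a bag-of-words hash: it is a
  contract stand-in for a contextual encoder, not an approximation of
  one.
* With near-balanced classes the `balanced` class-weight option is rarely
  selected; its code path is exercised, but imbalanced-cohort behaviour
  is not a tested headline property.
* The accept-first heuristic is an oracle bound, and its fairness cost is
  structural: those who will be declined wait longest. The package
  quantifies that cost (`sweep_schedule()`); it does not attempt
  fairness-constrained scheduling.
* Printed chi-squared statistics in the reference table are not
  reproducible from its printed counts under the plain Pearson formula
  (plausibly a missing-data denominator); the package pins its own
  formula against an independent implementation instead of those values.
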