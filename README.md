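# udnadmit

Machine-learning triage for undiagnosed-disease program applications:
predict admission outcomes from application materials, rank the review
queue by classifier confidence, and quantify how much ranking shortens the
wait of the patients who will eventually be accepted.

Programs such as the Undiagnosed Diseases Network (UDN) receive a steady
stream of applications — a form with demographics plus a free-text referral
letter — and a committee reviews them in periodic sessions with limited
capacity. `udnadmit` provides a tested, fully synthetic-data-driven
implementation of that analysis:

* a **synthetic cohort generator** that emulates the statistical shape of
  such an application stream (overdispersed monthly arrivals,
  class-conditional demographics and symptom categories, referral letters
  whose token distributions differ by class with a controllable effect
  size), so every downstream stage is testable without any private data;
* **six nested feature models** over letters and demographics:
  `baseline` (min-max-normalized age at application, age at onset, disease
  duration, prior visits) ⊂ `walley` (+ binary objective/subjective symptom
  checklist) ⊂ `referral_letter` (+ L2-normalized TF-IDF bigrams) ⊂
  `semantic_types` (+ five binary concept-type flags: sign/symptom,
  procedure, disease/syndrome, body part, gene) ⊂ `clinical_bert`
  (+ a pluggable text-embedding vector; the default backend is
  deterministic signed feature hashing) ⊂ `omim_similarity` (+ cosine
  similarity to every entry of a phenotype-description corpus);
* a **linear logistic classifier** (L2-regularized, hyperparameters chosen
  by grid search on validation AUROC) whose ranking statistic is the
  signed distance to the separating hyperplane,
  s(x) = (w·x + b) / ‖w‖;
* **out-of-fold confidence scoring** via stratified k-fold
  cross-validation (k = 5), so every application is scored by a model that
  never saw it;
* a **capacity-constrained queue simulator**: review sessions every *d*
  days, at most *a* applications per session, under four ranking
  heuristics — `fifo`, `udn_order` (recorded review dates), `classifier`
  (signed-distance ranking) and `accept_first` (oracle ranking, the lower
  bound on accepted-group waiting time) — plus a full (d, a) sweep;
* **cohort comparison statistics**: Welch t tests from group summaries,
  2×2 chi-squared tests with Bonferroni adjustment, and an
  accepted-vs-not-accepted summary table.

## Worked example

```r
library(udnadmit)

coh <- generate_cohort(cohort_config(n_total = 1200, seed = 2026))
sp  <- stratified_split(coh, seed = 2026)

fit <- admit_fit(sp$train, sp$validation, tier = "semantic_types")
fit
#> Linear logistic admission model
#>   tier:             semantic_types
#>   features:         10965
#>   C:                1000
#>   class weight:     none
#>   validation AUROC: 0.976

evaluate(fit, sp$test)
#> n = 119 | sensitivity 0.898 | specificity 0.867 | balanced accuracy 0.882 | AUROC 0.966

scores <- crossval_scores(coh, tier = "semantic_types", k = 5, seed = 2026)

simulate_queue(coh, "udn_order", period_d = 14, budget_a = 13)
#> Review-queue simulation: udn_order, d = 14 days, a = 13/session
#>   accepted      mean 3.39 (SD 3.26) months
#>   not_accepted  mean 4.65 (SD 4.53) months

simulate_queue(coh, "classifier", period_d = 14, budget_a = 13,
               scores = scores)
#> Review-queue simulation: classifier, d = 14 days, a = 13/session
#>   accepted      mean 1.00 (SD 2.81) months
#>   not_accepted  mean 17.37 (SD 10.80) months
```

Reading this: on a 1200-application synthetic cohort the semantic-types
model separates eventually-accepted from not-accepted applications with
test AUROC 0.966. Replaying the queue with biweekly sessions of 13 reviews,
ranking by classifier confidence cuts the mean wait of accepted applicants
from 3.39 to 1.00 months — `percent_reduction(3.39, 1.00)` ≈ 70.7% — at the
cost of a longer wait for those who would be declined anyway (the fairness
trade-off is inherent to any accept-first-style prioritization, not an
artifact of the implementation). `sweep_schedule()` maps this trade-off
over a grid of review periods and session budgets.

The full pipeline (simulate → train → retrospective + prospective
evaluation → out-of-fold ranking → queue simulation → sweep → cohort
table), with every artifact hashed and seed-stamped, is available as
`run_pipeline(pipeline_config(out_dir = "runs/demo"))`.

## Documentation

The methods vignette (`vignettes/udnadmit-methods.Rmd`) describes the
generative model and its calibration, the feature tiers, the classifier
and its hyperparameter grid, the queue-simulator semantics, and the design
decisions and limitations in detail.
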