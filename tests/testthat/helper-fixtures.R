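# Shared fixtures and small utilities. Cohorts are generated in code and
# memoized per test run so expensive suites can share them.

.fixtures <- new.env(parent = emptyenv())

fx_cohort <- function(n = 300, seed = 1, effect = 0.5, null_demo = FALSE) {
  key <- paste(n, seed, effect, null_demo, sep = "_")
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  cfg <- if (null_demo)
    cohort_config(n_total = n, seed = seed,
                  demo_params = null_demo_params(),
                  symptom_probs = null_symptom_probs(),
                  letter = letter_params(class_effect = effect))
  else
    cohort_config(n_total = n, seed = seed,
                  letter = letter_params(class_effect = effect))
  .fixtures[[key]] <- generate_cohort(cfg)
  .fixtures[[key]]
}

# identical marginals in both classes (the no-signal configuration)
null_demo_params <- function() {
  dp <- default_demo_params()
  dp$not_accepted <- dp$accepted
  dp
}

null_symptom_probs <- function() {
  sp <- default_symptom_probs()
  sp["not_accepted", ] <- sp["accepted", ]
  sp
}

# reduced hyperparameter grid for bulk simulation suites
grid_small <- function() list(C = 10^c(-2, 0, 2), class_weight = "none")

# all permutations of a vector (used for brute-force queue oracles)
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# accepted-group mean review delay (days) under an arbitrary static
# priority order, realized through the classifier heuristic with ranks as
# scores (highest score = first in the order)
static_order_accepted_mean <- function(apps, ord, d, a) {
  sc <- data.frame(id = apps$id[ord], score = rev(seq_len(nrow(apps))))
  sim <- simulate_queue(apps, "classifier", d, a, scores = sc)
  mean(sim$result$processing_months[apps$label == "accepted"])
}

# random tiny cohort for queue oracles: only fields the simulator needs
tiny_cohort <- function(n, seed) {
  set.seed(seed)
  lab <- c("accepted",
           sample(c("accepted", "not_accepted"), n - 1L, replace = TRUE))
  data.frame(id = sprintf("t%02d", seq_len(n)),
             submission_day = sample(0:20, n, replace = TRUE),
             label = factor(lab, levels = c("accepted", "not_accepted")),
             stringsAsFactors = FALSE)
}
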