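Package: udnadmit
Title: Admission Prediction and Review-Queue Prioritization for
    Undiagnosed-Disease Application Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying machine-learning triage of applications to
    an undiagnosed-diseases program. Generates synthetic application
    cohorts (demographics, symptom categories, referral-letter text,
    arrival process) with controllable class separation; builds six nested
    feature models over letters and demographics (demographic baseline,
    symptom checklists, TF-IDF bigrams, semantic-type concept flags,
    hashed text embeddings, phenotype-corpus cosine similarities); trains
    and evaluates a linear logistic classifier; ranks applications by
    out-of-fold signed distance to the decision hyperplane; and simulates
    capacity-constrained periodic review sessions under four queueing
    heuristics to quantify processing-time gains. Includes two-sample
    cohort comparison statistics (Welch t, chi-squared, Bonferroni).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    glmnet,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
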