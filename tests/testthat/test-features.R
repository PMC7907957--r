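make_app <- function(age = 30, onset = 20, duration = 10, visits = 1,
                     letter = "w001 w002") {
  data.frame(id = "a1", submission_day = 0L, recorded_review_day = 10L,
             label = factor("accepted", c("accepted", "not_accepted")),
             age_at_application = age, age_at_onset = onset,
             duration = duration, prior_visits = visits,
             symptom_category = "neurologic", letter = letter,
             stringsAsFactors = FALSE)
}

test_that("baseline features are min-max scaled with clipping", {
  train <- rbind(make_app(age = 10, onset = 0, duration = 0, visits = 0),
                 make_app(age = 50, onset = 40, duration = 20, visits = 4))
  nz <- fit_normalizer(train)
  expect_equal(unname(baseline_features(make_app(age = 10), nz)[1]), 0)
  expect_equal(unname(baseline_features(make_app(age = 50), nz)[1]), 1)
  expect_equal(unname(baseline_features(make_app(age = 30), nz)[1]), 0.5)
  # out-of-bound values clip to [0, 1]
  expect_equal(unname(baseline_features(make_app(age = 90), nz)[1]), 1)
  expect_equal(unname(baseline_features(make_app(age = 1), nz)[1]), 0)
  expect_length(baseline_features(make_app(), nz), 4)
  expect_error(baseline_features(make_app(), list()), "unfitted")
})

test_that("symptom-checklist features are binary presence, not counts", {
  lx <- default_symptom_lexicon()
  expect_equal(sum(walley_features("", lx)), 0)
  v <- walley_features("patient reports fever today", lx)
  expect_equal(sum(v), 1)
  expect_equal(unname(v["walley_fever"]), 1)
  v2 <- walley_features("fever and more fever", lx)
  expect_equal(unname(v2["walley_fever"]), 1)
  # phrase terms require the full token sequence
  v3 <- walley_features("acute abdominal pain noted", lx)
  expect_equal(unname(v3["walley_abdominal_pain"]), 1)
  expect_equal(sum(walley_features("abdominal discomfort", lx)), 0)
})

test_that("TF-IDF matches the closed form on a one-document corpus", {
  m <- fit_tfidf("severe ataxia severe ataxia")
  expect_setequal(m$vocabulary, c("severe_ataxia", "ataxia_severe"))
  expect_equal(unname(m$idf["severe_ataxia"]), log(2 / 2) + 1)
  v <- transform_tfidf(m, "severe ataxia severe ataxia")
  expect_equal(unname(v["severe_ataxia"]), 2 / sqrt(5), tolerance = 1e-12)
  expect_equal(unname(v["ataxia_severe"]), 1 / sqrt(5), tolerance = 1e-12)
  expect_equal(sum(transform_tfidf(m, "totally different words")^2), 0)
  expect_error(fit_tfidf(character(0)), "empty")
})

test_that("TF-IDF transform of a training document matches the fitted matrix", {
  letters <- c("a b c a b", "b c d", "a a a b")
  m <- fit_tfidf(letters)
  M <- udnadmit:::tfidf_matrix(m, letters)
  for (i in seq_along(letters))
    expect_equal(unname(as.numeric(M[i, ])),
                 unname(transform_tfidf(m, letters[i])), tolerance = 1e-12)
  nrm <- sqrt(Matrix::rowSums(M^2))
  expect_true(all(abs(nrm - 1) < 1e-12 | nrm == 0))
})

test_that("semantic-type features flag exactly the present types", {
  lx <- default_concept_lexicon()
  v <- semantic_type_features("patient reports seizure episodes", lx)
  expect_length(v, 5)
  expect_equal(unname(v["sem_sign_or_symptom"]), 1)
  expect_equal(sum(v), 1)
  expect_equal(sum(semantic_type_features("", lx)), 0)
  all5 <- "seizure mri epilepsy liver exon"
  expect_equal(sum(semantic_type_features(all5, lx)), 5)
})

test_that("cosine similarity matches hand computation and rejects zeros", {
  expect_equal(cosine_sim(c(1, 2), c(1, 2)), 1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(1:3, 4:6), 32 / sqrt(14 * 77), tolerance = 1e-12)
  expect_error(cosine_sim(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_sim(1:2, 1:3), "equal length")
})

test_that("hashed embedding backend is deterministic and sign-hashed", {
  be <- hashed_embedding_backend(64)
  expect_identical(be$embed("ataxia and tremor"), be$embed("ataxia and tremor"))
  expect_equal(length(be$embed("anything")), 64)
  expect_equal(sum(abs(be$embed(""))), 0)
  # a fresh backend instance gives the same vectors (no hidden state)
  expect_identical(hashed_embedding_backend(64)$embed("seizure"),
                   be$embed("seizure"))
})

test_that("phenotype-similarity features are cosines per corpus entry", {
  corpus <- data.frame(entry_id = c("E1", "E2"),
                       description = c("alpha beta gamma", "delta epsilon"),
                       stringsAsFactors = FALSE)
  be <- hashed_embedding_backend(512)
  v <- omim_similarity_features("alpha beta gamma", corpus, be)
  expect_length(v, 2)
  expect_equal(unname(v["omim_E1"]), 1, tolerance = 1e-12)
  # disjoint vocabularies with no shared hash buckets give exactly zero
  e1 <- be$embed("alpha beta gamma"); e2 <- be$embed("delta epsilon")
  if (sum(abs(e1) * abs(e2)) == 0)  # confirmed collision-free
    expect_equal(unname(v["omim_E2"]), 0)
  expect_error(omim_similarity_features("x", corpus[0, ], be), "empty")
})

test_that("tiers assemble cumulatively with namespaced features", {
  coh <- fx_cohort(n = 80, seed = 12)
  corpus <- generate_phenotype_corpus(20, seed = 1)
  dims <- integer(0)
  for (tier in c("baseline", "walley", "referral_letter", "semantic_types",
                 "clinical_bert", "omim_similarity")) {
    st <- fit_features(coh[1:60, ], tier, corpus = corpus,
                       backend = hashed_embedding_backend(64))
    X <- featurize(st, coh[61:80, ])
    expect_equal(nrow(X), 20)
    expect_false(anyDuplicated(colnames(X)) > 0)
    dims <- c(dims, ncol(X))
  }
  expect_equal(dims[1], 4)           # demographic block only
  expect_true(all(diff(dims) > 0))   # strictly growing up the ladder
  expect_true(all(is.finite(featurize(st, coh[61:80, ])@x)))
  # identical applications map to identical rows
  two <- coh[c(61, 61), ]
  X2 <- featurize(st, two)
  expect_equal(as.numeric(X2[1, ]), as.numeric(X2[2, ]))
  expect_error(fit_features(coh[1:60, ], "omim_similarity"), "corpus")
})

test_that("transforms use training statistics only (no leakage)", {
  coh <- fx_cohort(n = 120, seed = 13)
  train <- coh[1:80, ]; test <- coh[81:120, ]
  st_train <- fit_features(train, "semantic_types")
  st_leaky <- fit_features(coh, "semantic_types")
  X1 <- featurize(st_train, test)
  X2 <- featurize(st_train, test)
  expect_identical(as.numeric(X1), as.numeric(X2))  # transform is pure
  # refitting on train+test changes the fitted statistics and the vectors
  expect_false(identical(st_train$tfidf$vocabulary,
                         st_leaky$tfidf$vocabulary))
  Xl <- featurize(st_leaky, test)
  expect_false(identical(dim(X1), dim(Xl)) &&
                 identical(as.numeric(X1), as.numeric(Xl)))
})
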