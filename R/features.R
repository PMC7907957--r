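# The six cumulative feature tiers.
#
# baseline        four min-max-normalized demographics
# walley          + binary presence of each symptom-checklist term
# referral_letter + L2-normalized TF-IDF of letter bigrams
# semantic_types  + five binary semantic-type presence flags
# clinical_bert   + the letter's (unit-normalized) embedding vector
# omim_similarity + cosine similarity to every phenotype-corpus entry
#
# Every fitted statistic (min/max bounds, bigram vocabulary and document
# frequencies, corpus embeddings) comes from the training split only;
# transforming new applications never updates fitted state.

#' Lowercase alphanumeric tokenization
#' @param text character vector.
#' @return list of character token vectors.
#' @export
tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")
  lapply(toks, function(t) t[nzchar(t)])
}

bigrams_of <- function(tokens) {
  if (length(tokens) < 2L) return(character(0))
  paste(tokens[-length(tokens)], tokens[-1L], sep = "_")
}

# " tok tok " padded form for whole-token phrase matching
padded_text <- function(text) {
  paste0(" ", vapply(tokenize(text), paste, character(1), collapse = " "), " ")
}

term_presence <- function(letters, terms) {
  pad <- padded_text(letters)
  needles <- paste0(" ", vapply(tokenize(terms), paste, character(1),
                                collapse = " "), " ")
  m <- vapply(needles, function(nd) grepl(nd, pad, fixed = TRUE),
              logical(length(pad)))
  matrix(as.numeric(m), nrow = length(pad),
         dimnames = list(NULL, terms))
}

# ---- baseline ----------------------------------------------------------

BASELINE_VARS <- c("age_at_application", "age_at_onset", "duration",
                   "prior_visits")

#' Fit the demographic min-max normalizer on a training split
#' @param train data.frame with the four demographic columns.
#' @return object of class `demo_normalizer` holding per-feature bounds.
#' @export
fit_normalizer <- function(train) {
  stopifnot(all(BASELINE_VARS %in% names(train)))
  bounds <- lapply(BASELINE_VARS, function(v)
    c(min = min(train[[v]]), max = max(train[[v]])))
  names(bounds) <- BASELINE_VARS
  structure(list(bounds = bounds), class = "demo_normalizer")
}

#' Baseline demographic features
#'
#' Four features (age at application, age at onset, disease duration, prior
#' visits), each min-max scaled to `[0, 1]` by training-split bounds; values
#' outside the bounds are clipped.
#'
#' @param app one-row data.frame (or list) with the demographic fields.
#' @param normalizer a fitted [fit_normalizer()] object.
#' @return named numeric vector of length 4.
#' @export
baseline_features <- function(app, normalizer) {
  drop(baseline_matrix(as.data.frame(app), normalizer))
}

baseline_matrix <- function(apps, normalizer) {
  if (!inherits(normalizer, "demo_normalizer")) stop("unfitted normalizer")
  cols <- lapply(BASELINE_VARS, function(v) {
    b <- normalizer$bounds[[v]]
    rng <- b[["max"]] - b[["min"]]
    x <- as.numeric(apps[[v]])
    if (rng <= 0) rep(0, length(x))
    else pmin(1, pmax(0, (x - b[["min"]]) / rng))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- paste0("base_", BASELINE_VARS)
  m
}

# ---- symptom checklist (binary presence) --------------------------------

#' Symptom-checklist binary features
#'
#' One feature per lexicon term: 1 if the term occurs in the letter
#' (case-insensitive whole-token phrase match), else 0. Presence, not count.
#'
#' @param letter letter text (single string).
#' @param lexicon symptom lexicon, as from [default_symptom_lexicon()].
#' @return named numeric vector, one entry per term.
#' @export
walley_features <- function(letter, lexicon = default_symptom_lexicon()) {
  drop(walley_matrix(letter, lexicon))
}

walley_matrix <- function(letters, lexicon) {
  if (nrow(lexicon) == 0L) stop("empty symptom lexicon")
  m <- term_presence(letters, lexicon$term)
  colnames(m) <- paste0("walley_", gsub(" ", "_", lexicon$term))
  m
}

# ---- TF-IDF bigrams -----------------------------------------------------

#' Fit a bigram TF-IDF model on training letters
#'
#' Tokens are lowercase alphanumeric words; features are adjacent-token
#' bigrams; `idf = ln((1 + n_docs) / (1 + df)) + 1` (smoothed); transformed
#' vectors are L2-normalized. Bigrams unseen at fit time are ignored at
#' transform time.
#'
#' @param letters character vector of training letters.
#' @param min_df keep bigrams occurring in at least this many documents.
#' @return object of class `tfidf_model` with `vocabulary`, `df`, `idf`,
#'   `n_docs`.
#' @export
fit_tfidf <- function(letters, min_df = 1L) {
  if (length(letters) == 0L) stop("empty training corpus")
  big <- lapply(tokenize(letters), bigrams_of)
  df_tab <- table(unlist(lapply(big, unique)))
  keep <- names(df_tab)[df_tab >= min_df]
  vocab <- sort(keep)
  df <- as.numeric(df_tab[vocab])
  n <- length(letters)
  structure(list(vocabulary = vocab, df = setNames(df, vocab),
                 idf = setNames(log((1 + n) / (1 + df)) + 1, vocab),
                 n_docs = n, min_df = as.integer(min_df)),
            class = "tfidf_model")
}

#' Transform a letter under a fitted TF-IDF model
#' @param model a [fit_tfidf()] model.
#' @param letter single letter text.
#' @return named numeric vector over the model vocabulary (dense; use
#'   [featurize()] for sparse batch transforms).
#' @export
transform_tfidf <- function(model, letter) {
  m <- tfidf_matrix(model, letter)
  setNames(as.numeric(m[1L, ]), model$vocabulary)
}

tfidf_matrix <- function(model, letters) {
  stopifnot(inherits(model, "tfidf_model"))
  vocab_idx <- seq_along(model$vocabulary)
  names(vocab_idx) <- model$vocabulary
  big <- lapply(tokenize(letters), bigrams_of)
  ii <- jj <- xx <- vector("list", length(big))
  for (d in seq_along(big)) {
    tab <- table(big[[d]])
    j <- vocab_idx[names(tab)]
    ok <- !is.na(j)
    if (any(ok)) {
      ii[[d]] <- rep.int(d, sum(ok))
      jj[[d]] <- unname(j[ok])
      xx[[d]] <- as.numeric(tab[ok])
    }
  }
  m <- Matrix::sparseMatrix(i = unlist(ii) %||% integer(0),
                            j = unlist(jj) %||% integer(0),
                            x = unlist(xx) %||% numeric(0),
                            dims = c(length(big), length(model$vocabulary)))
  m <- m %*% Matrix::Diagonal(x = unname(model$idf))
  nrm <- sqrt(Matrix::rowSums(m^2))
  nrm[nrm == 0] <- 1
  m <- Matrix::Diagonal(x = 1 / nrm) %*% m
  colnames(m) <- paste0("tfidf_", model$vocabulary)
  methods::as(m, "CsparseMatrix")
}

# ---- semantic types -----------------------------------------------------

#' Semantic-type presence features
#'
#' Exactly five features, one per semantic type; a feature is 1 iff any
#' lexicon term of that type occurs in the letter.
#'
#' @param letter single letter text.
#' @param lexicon concept lexicon, as from [default_concept_lexicon()].
#' @return named numeric vector of length 5.
#' @export
semantic_type_features <- function(letter,
                                   lexicon = default_concept_lexicon()) {
  drop(semantic_matrix(letter, lexicon))
}

semantic_matrix <- function(letters, lexicon) {
  if (nrow(lexicon) == 0L) stop("empty concept lexicon")
  pres <- term_presence(letters, lexicon$term)
  m <- vapply(SEMANTIC_TYPES, function(st) {
    cols <- which(lexicon$label == st)
    if (!length(cols)) rep(0, nrow(pres))
    else as.numeric(rowSums(pres[, cols, drop = FALSE]) > 0)
  }, numeric(length(letters)))
  m <- matrix(m, nrow = length(letters))
  colnames(m) <- paste0("sem_", SEMANTIC_TYPES)
  m
}

# ---- embeddings and phenotype similarity --------------------------------

#' Cosine similarity between two vectors
#' @param u,v equal-length numeric vectors, each with a nonzero norm.
#' @return `dot(u, v) / (||u|| ||v||)`, in `[-1, 1]`.
#' @export
cosine_sim <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

embed_matrix <- function(backend, texts, normalize = TRUE) {
  m <- t(vapply(texts, backend$embed, numeric(backend$dimension),
                USE.NAMES = FALSE))
  if (normalize) {
    nrm <- sqrt(rowSums(m^2))
    nrm[nrm == 0] <- 1
    m <- m / nrm
  }
  m
}

#' Phenotype-corpus similarity features
#'
#' One feature per corpus entry: the cosine similarity between the letter's
#' embedding and the entry description's embedding under the given backend.
#'
#' @param letter single letter text.
#' @param corpus a [generate_phenotype_corpus()] data.frame (or any frame
#'   with `entry_id` and `description`).
#' @param backend an embedding backend, default
#'   [hashed_embedding_backend()].
#' @return named numeric vector, one entry per corpus entry.
#' @export
omim_similarity_features <- function(letter, corpus,
                                     backend = hashed_embedding_backend()) {
  if (nrow(corpus) == 0L) stop("empty phenotype corpus")
  E <- embed_matrix(backend, corpus$description)
  if (any(rowSums(E^2) == 0)) stop("zero embedding in phenotype corpus")
  le <- backend$embed(letter)
  n <- sqrt(sum(le^2))
  if (n == 0) stop("zero embedding for letter")
  setNames(as.numeric(E %*% (le / n)),
           paste0("omim_", corpus$entry_id))
}

# ---- fitted feature state and assembly ----------------------------------

#' Fit all feature components required by a tier on a training split
#'
#' @param train training applications (`udn_cohort`-shaped data.frame).
#' @param tier one of `"baseline"`, `"walley"`, `"referral_letter"`,
#'   `"semantic_types"`, `"clinical_bert"`, `"omim_similarity"`; each tier
#'   includes all lower tiers' features.
#' @param concept_lexicon,symptom_lexicon term lexicons.
#' @param corpus phenotype corpus; required for the `omim_similarity` tier.
#' @param backend embedding backend; used from the `clinical_bert` tier up.
#' @param min_df minimum bigram document frequency for the TF-IDF
#'   vocabulary.
#' @return object of class `feature_state`.
#' @export
fit_features <- function(train, tier = "semantic_types",
                         concept_lexicon = default_concept_lexicon(),
                         symptom_lexicon = default_symptom_lexicon(),
                         corpus = NULL,
                         backend = hashed_embedding_backend(),
                         min_df = 2L) {
  ti <- tier_index(tier)
  st <- list(tier = TIERS[ti], tier_index = ti,
             normalizer = fit_normalizer(train),
             symptom_lexicon = if (ti >= 2) validate_lexicon(symptom_lexicon,
                                                             "symptom"),
             tfidf = if (ti >= 3) fit_tfidf(train$letter, min_df = min_df),
             concept_lexicon = if (ti >= 4) validate_lexicon(concept_lexicon,
                                                             "concept"),
             backend = if (ti >= 5) backend)
  if (ti >= 6) {
    if (is.null(corpus) || nrow(corpus) == 0L)
      stop("omim_similarity tier requires a phenotype corpus")
    E <- embed_matrix(backend, corpus$description)
    if (any(rowSums(E^2) == 0)) stop("zero embedding in phenotype corpus")
    st$corpus_ids <- corpus$entry_id
    st$corpus_embeddings <- E
  }
  structure(st, class = "feature_state")
}

#' Assemble the design matrix for a set of applications
#'
#' Produces the union of all feature blocks up to the fitted tier, using
#' only statistics fitted on the training split. Feature names are
#' namespaced by block, so blocks can never collide.
#'
#' @param state a [fit_features()] object.
#' @param apps applications to transform.
#' @return sparse `dgCMatrix`, one row per application.
#' @export
featurize <- function(state, apps) {
  stopifnot(inherits(state, "feature_state"))
  ti <- state$tier_index
  blocks <- list(methods::as(baseline_matrix(apps, state$normalizer),
                             "CsparseMatrix"))
  if (ti >= 2)
    blocks <- c(blocks, list(methods::as(
      walley_matrix(apps$letter, state$symptom_lexicon), "CsparseMatrix")))
  if (ti >= 3)
    blocks <- c(blocks, list(tfidf_matrix(state$tfidf, apps$letter)))
  if (ti >= 4)
    blocks <- c(blocks, list(methods::as(
      semantic_matrix(apps$letter, state$concept_lexicon), "CsparseMatrix")))
  if (ti >= 5) {
    E <- embed_matrix(state$backend, apps$letter)
    colnames(E) <- sprintf("emb_%04d", seq_len(ncol(E)))
    blocks <- c(blocks, list(methods::as(E, "CsparseMatrix")))
    if (ti >= 6) {
      S <- E %*% Matrix::t(state$corpus_embeddings)
      colnames(S) <- paste0("omim_", state$corpus_ids)
      blocks <- c(blocks, list(methods::as(S, "CsparseMatrix")))
    }
  }
  out <- Reduce(cbind, blocks)
  rownames(out) <- apps$id
  out
}
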