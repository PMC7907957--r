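# Serialization: applications as JSONL or CSV, phenotype corpus as JSONL,
# confidence scores and sweep grids as CSV, model artifacts as JSON.
# All text is UTF-8; dates are integer day indices.

APP_COLUMNS <- c("id", "submission_day", "recorded_review_day", "label",
                 "age_at_application", "age_at_onset", "duration",
                 "prior_visits", "symptom_category", "letter")

validate_applications <- function(df, where = "applications") {
  miss <- setdiff(setdiff(APP_COLUMNS, "recorded_review_day"), names(df))
  if (length(miss))
    stop(where, ": missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$recorded_review_day))
    df$recorded_review_day <- NA_integer_
  df <- df[, APP_COLUMNS]
  df$label <- factor(as.character(df$label),
                     levels = c("accepted", "not_accepted"))
  if (anyNA(df$label)) stop(where, ": invalid admission labels")
  for (v in c("submission_day", "recorded_review_day", "prior_visits"))
    df[[v]] <- as.integer(df[[v]])
  bad <- which(!is.na(df$recorded_review_day) &
                 df$recorded_review_day <= df$submission_day)
  if (length(bad))
    stop(where, ": recorded_review_day not after submission_day at record ",
         bad[1])
  class(df) <- c("udn_cohort", "data.frame")
  df
}

#' Write applications to JSONL or CSV
#' @param apps applications data.frame.
#' @param path output path; format inferred from the extension
#'   (`.jsonl`/`.json` vs `.csv`) unless given.
#' @param format `"jsonl"` or `"csv"`.
#' @export
write_applications <- function(apps, path,
                               format = infer_format(path)) {
  apps <- validate_applications(as.data.frame(apps))
  if (format == "jsonl") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(apps))) {
      rec <- as.list(apps[i, ])
      rec$label <- as.character(rec$label)
      if (is.na(rec$recorded_review_day)) rec$recorded_review_day <- NULL
      writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                               digits = NA)), con)
    }
  } else {
    write.csv(as.data.frame(apps), path, row.names = FALSE,
              fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read applications from JSONL or CSV
#' @param path input path (schema as written by [write_applications()]).
#' @param format `"jsonl"` or `"csv"`.
#' @return `udn_cohort` data.frame (empty input gives an empty frame).
#' @export
read_applications <- function(path, format = infer_format(path)) {
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
      return(validate_applications(empty_applications()))
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      recs[[i]] <- tryCatch(jsonlite::fromJSON(lines[i]),
                            error = function(e)
                              stop("parse error at line ", i, " of ", path,
                                   ": ", conditionMessage(e)))
      if (is.null(recs[[i]]$recorded_review_day))
        recs[[i]]$recorded_review_day <- NA_integer_
      for (v in c("submission_day", "age_at_application"))
        if (is.null(recs[[i]][[v]]) || !is.numeric(recs[[i]][[v]]))
          stop("schema violation at line ", i, " of ", path,
               ": bad or missing field '", v, "'")
    }
    df <- do.call(rbind, lapply(recs, function(r)
      as.data.frame(r[APP_COLUMNS], stringsAsFactors = FALSE)))
    validate_applications(df, where = path)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    if (nrow(df) == 0L) return(validate_applications(empty_applications()))
    validate_applications(df, where = path)
  }
}

empty_applications <- function() {
  data.frame(id = character(0), submission_day = integer(0),
             recorded_review_day = integer(0),
             label = factor(character(0),
                            levels = c("accepted", "not_accepted")),
             age_at_application = numeric(0), age_at_onset = numeric(0),
             duration = numeric(0), prior_visits = integer(0),
             symptom_category = character(0), letter = character(0),
             stringsAsFactors = FALSE)
}

infer_format <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
}

#' Write / read a phenotype corpus as JSONL
#' @param corpus a [generate_phenotype_corpus()] frame.
#' @param path file path.
#' @export
write_phenotype_corpus <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus)))
    writeLines(as.character(jsonlite::toJSON(as.list(corpus[i, ]),
                                             auto_unbox = TRUE, digits = NA)),
               con)
  invisible(path)
}

#' @rdname write_phenotype_corpus
#' @export
read_phenotype_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  df <- do.call(rbind, lapply(seq_along(lines), function(i) {
    r <- tryCatch(jsonlite::fromJSON(lines[i]),
                  error = function(e) stop("parse error at line ", i, " of ",
                                           path, ": ", conditionMessage(e)))
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  if (is.null(df$entry_id) || is.null(df$description) ||
      any(!nzchar(df$description)))
    stop("invalid phenotype corpus: ", path)
  class(df) <- c("phenotype_corpus", "data.frame")
  df
}

# Serializable fingerprint of everything a fitted feature state depends on.
feature_state_fingerprint <- function(state) {
  object_hash(list(
    tier = state$tier,
    bounds = state$normalizer$bounds,
    symptom_lexicon = state$symptom_lexicon,
    tfidf = if (!is.null(state$tfidf))
      list(vocab = state$tfidf$vocabulary, df = unname(state$tfidf$df),
           n_docs = state$tfidf$n_docs),
    concept_lexicon = state$concept_lexicon,
    backend = if (!is.null(state$backend))
      list(name = state$backend$name, dimension = state$backend$dimension),
    corpus_ids = state$corpus_ids,
    corpus_emb = if (!is.null(state$corpus_embeddings))
      round(as.numeric(state$corpus_embeddings), 10)))
}

#' Save / load a trained model artifact (JSON)
#'
#' The artifact records the decision function (weights by feature name,
#' intercept), the tier, the chosen hyperparameters and a fingerprint of
#' the fitted feature state, so that downstream scoring can verify it uses
#' an unchanged model.
#'
#' @param model an [admit_fit()] model.
#' @param path JSON file path.
#' @export
save_model <- function(model, path) {
  nz <- model$weights  # keep all named weights, zeros included
  jsonlite::write_json(list(
    format = "udnadmit-model-1",
    tier = model$tier,
    intercept = model$intercept,
    weights = as.list(nz),
    hyperparameters = model$hyperparameters,
    validation_auroc = model$validation_auroc,
    feature_state_hash = feature_state_fingerprint(model$feature_state)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format, "udnadmit-model-1"))
    stop("not a model artifact: ", path)
  obj$weights <- unlist(obj$weights)
  class(obj) <- "admit_model_artifact"
  obj
}

#' Write / read confidence scores as CSV
#' @param scores a [crossval_scores()] table.
#' @param path CSV path.
#' @export
write_scores <- function(scores, path) {
  write.csv(as.data.frame(scores), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "score") %in% names(df))) stop("invalid scores file")
  class(df) <- c("confidence_table", "data.frame")
  df
}
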