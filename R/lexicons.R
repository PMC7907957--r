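# Term lexicons: small curated dictionaries mapping lowercase terms (single
# words or short phrases) to a label. Two kinds are used:
#   * concept lexicon  -- label is one of the five semantic types
#     (sign_or_symptom, procedure, disease_or_syndrome, body_part,
#     gene_or_genome); drives the semantic-type presence features.
#   * symptom lexicon  -- label is objective/subjective; drives the
#     symptom-checklist (Walley-style) binary features.
# Both ship as demo TSVs under extdata and can be replaced by any
# user-supplied two-column TSV.

#' Read a two-column term lexicon from TSV
#'
#' @param path TSV file with header columns `term` and `label`.
#' @param kind `"concept"` restricts labels to the five semantic types;
#'   `"symptom"` to objective/subjective; `"any"` performs no label check.
#' @return data.frame with columns `term` (lowercase) and `label`.
#' @export
read_lexicon <- function(path, kind = c("any", "concept", "symptom")) {
  kind <- match.arg(kind)
  lx <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  if (!all(c("term", "label") %in% names(lx)))
    stop("lexicon file must have columns 'term' and 'label': ", path)
  lx <- lx[, c("term", "label")]
  validate_lexicon(lx, kind)
}

validate_lexicon <- function(lx, kind = "any") {
  lx$term <- tolower(trimws(lx$term))
  lx$label <- trimws(lx$label)
  if (nrow(lx) == 0L) stop("lexicon is empty")
  if (anyDuplicated(lx$term)) stop("lexicon terms must be unique")
  allowed <- switch(kind,
    concept = SEMANTIC_TYPES,
    symptom = c("objective", "subjective"),
    any = unique(lx$label))
  bad <- setdiff(unique(lx$label), allowed)
  if (length(bad))
    stop("invalid lexicon labels: ", paste(bad, collapse = ", "))
  lx
}

#' Built-in demo concept lexicon (term to semantic type)
#'
#' About 100 common clinical terms labelled with one of the five semantic
#' types used as presence/absence features. A demonstration dictionary, not
#' a licensed terminology; replace via [read_lexicon()] for real analyses.
#' @return data.frame with columns `term`, `label`.
#' @export
default_concept_lexicon <- function() {
  read_lexicon(system.file("extdata", "concept_lexicon.tsv",
                           package = "udnadmit", mustWork = TRUE),
               kind = "concept")
}

#' Built-in demo symptom lexicon (term to objective/subjective)
#'
#' A small checklist of findings labelled objective (ascertainable by
#' examination or testing) or subjective (patient-reported), used as binary
#' presence features.
#' @return data.frame with columns `term`, `label`.
#' @export
default_symptom_lexicon <- function() {
  read_lexicon(system.file("extdata", "symptom_lexicon.tsv",
                           package = "udnadmit", mustWork = TRUE),
               kind = "symptom")
}

# Synthetic per-category token lexicon for letter generation: each symptom
# category gets a disjoint set of plain alphanumeric tokens.
category_lexicon <- function(categories, tokens_per_category = 8L) {
  stopifnot(tokens_per_category >= 1)
  out <- lapply(categories, function(cat) {
    stem <- gsub("[^a-z0-9]", "", tolower(cat))
    if (!nzchar(stem)) stem <- "misc"
    paste0(stem, "sign", seq_len(tokens_per_category))
  })
  names(out) <- categories
  out
}
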