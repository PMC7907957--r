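# Synthetic application-cohort generator.
#
# Emulates the statistical shape of an undiagnosed-disease application
# stream: overdispersed monthly arrivals, class-conditional demographics,
# class-conditional symptom-category frequencies, and free-text referral
# letters whose token distributions differ by class with controllable
# separation. Everything is a pure function of the configuration, seed
# included.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Precomputed token pools + class-conditional sampling weights for letters.
letter_machinery <- function(params, concept_lexicon = default_concept_lexicon(),
                             symptom_lexicon = default_symptom_lexicon(),
                             categories = SYMPTOM_CATEGORIES) {
  stopifnot(inherits(params, "letter_params"))
  if (nrow(concept_lexicon) == 0L || nrow(symptom_lexicon) == 0L)
    stop("empty vocabulary")
  e <- params$class_effect
  bg <- paste0("w", sprintf("%03d", seq_len(params$background_vocab_size)))
  bg_p <- (1 / seq_along(bg)) / sum(1 / seq_along(bg))  # Zipf background
  cat_lex <- category_lexicon(categories, params$tokens_per_category)
  # concept tilt: accepted letters over-represent sign/disease/gene terms,
  # under-represent procedure/body-part terms (and vice versa), scaled by e
  cs <- ifelse(concept_lexicon$label %in%
                 c("sign_or_symptom", "disease_or_syndrome", "gene_or_genome"),
               1, -1)
  ws <- ifelse(symptom_lexicon$label == "objective", 1, -1)
  wts <- list(
    accepted = list(concept = 1 + e * cs, walley = 1 + 0.5 * e * ws),
    not_accepted = list(concept = 1 - e * cs, walley = 1 - 0.5 * e * ws))
  list(params = params, background = bg, background_p = bg_p,
       category = cat_lex, concept_terms = concept_lexicon$term,
       walley_terms = symptom_lexicon$term, weights = wts)
}

#' Generate one synthetic referral letter
#'
#' Draws a token sequence from a mixture of a shared background vocabulary,
#' the symptom-category token set, class-tilted concept terms and
#' symptom-checklist terms; the tilt magnitude is proportional to
#' `class_effect` (zero tilt makes the letter distribution independent of
#' the label). Length is Poisson around the configured mean. Uses the
#' current RNG state; identical state gives an identical letter.
#'
#' @param label `"accepted"` or `"not_accepted"`.
#' @param symptom_category one of the configured categories.
#' @param params a [letter_params()] object.
#' @param machinery precomputed pools from the default lexicons; supply
#'   once when generating many letters.
#' @return a single string of space-separated lowercase tokens.
#' @export
generate_letter <- function(label, symptom_category, params = letter_params(),
                            machinery = letter_machinery(params)) {
  lm <- machinery
  label <- match.arg(label, c("accepted", "not_accepted"))
  cat_tokens <- lm$category[[symptom_category]]
  if (is.null(cat_tokens)) stop("unknown symptom category: ", symptom_category)
  w <- lm$weights[[label]]
  # expected tokens per sampled unit (lexicon terms may be multi-word)
  ntok <- function(terms, wt) {
    k <- lengths(strsplit(terms, " ", fixed = TRUE))
    sum(k * wt) / sum(wt)
  }
  mix <- lm$params$mix
  e_tok <- mix[["background"]] + mix[["category"]] +
    mix[["concept"]] * ntok(lm$concept_terms, w$concept) +
    mix[["walley"]] * ntok(lm$walley_terms, w$walley)
  n_units <- max(3L, round(rpois(1, lm$params$mean_length) / e_tok))
  src <- sample.int(4L, n_units, replace = TRUE, prob = mix)
  units <- character(n_units)
  if (any(src == 1L))
    units[src == 1L] <- sample(lm$background, sum(src == 1L), replace = TRUE,
                               prob = lm$background_p)
  if (any(src == 2L))
    units[src == 2L] <- sample(cat_tokens, sum(src == 2L), replace = TRUE)
  if (any(src == 3L))
    units[src == 3L] <- sample(lm$concept_terms, sum(src == 3L),
                               replace = TRUE, prob = w$concept)
  if (any(src == 4L))
    units[src == 4L] <- sample(lm$walley_terms, sum(src == 4L),
                               replace = TRUE, prob = w$walley)
  paste(unlist(strsplit(units, " ", fixed = TRUE)), collapse = " ")
}

#' Generate a synthetic application cohort
#'
#' Monthly arrival counts are lognormal, moment-matched to the configured
#' monthly mean/SD, with submission days placed uniformly within each
#' 30.44-day month. Labels are i.i.d. Bernoulli. Demographics are drawn per
#' class from zero-truncated normals calibrated so the configured means are
#' recovered exactly in expectation; disease duration is truncated to
#' `[0, age]` per person (with the calibration compensating for that
#' conditioning) and age at onset is `age - duration`. A recorded review
#' day is sampled so that per-class processing time matches the configured
#' mean/SD in months. Letters come from [generate_letter()].
#'
#' @param config a [cohort_config()].
#' @return data.frame of class `udn_cohort`, one row per application, with
#'   columns `id`, `submission_day`, `recorded_review_day`, `label`,
#'   `age_at_application`, `age_at_onset`, `duration`, `prior_visits`,
#'   `symptom_category`, `letter`. The configuration is attached as
#'   attribute `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_total = 50, seed = 7))
#' table(coh$label)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_total
  cal <- calibrate_cohort(config)
  with_seed(config$seed, {
    # --- arrivals ---------------------------------------------------------
    cv2 <- (config$arrival_rate_sd / config$arrival_rate_mean)^2
    sdlog <- sqrt(log1p(cv2))
    meanlog <- log(config$arrival_rate_mean) - sdlog^2 / 2
    days <- integer(0)
    month <- 0L
    while (length(days) < n) {
      k <- max(0L, as.integer(sround(rlnorm(1, meanlog, sdlog))))
      if (k > 0)
        days <- c(days, as.integer(floor((month + runif(k)) * DAYS_PER_MONTH)))
      month <- month + 1L
      if (month > 10000L) stop("arrival process failed to produce applications")
    }
    days <- sort(days)[seq_len(n)]
    label <- ifelse(runif(n) < config$accepted_fraction,
                    "accepted", "not_accepted")
    label <- factor(label, levels = c("accepted", "not_accepted"))

    age <- duration <- visits <- proc_days <- numeric(n)
    symptom <- character(n)
    for (cl in c("accepted", "not_accepted")) {
      idx <- which(label == cl)
      if (!length(idx)) next
      cc <- cal[[cl]]
      age[idx] <- rtnorm(length(idx), cc$age$mu, cc$age$sigma, 0)
      duration[idx] <- rtnorm(length(idx), cc$duration$mu, cc$duration$sigma,
                              0, age[idx])
      visits[idx] <- sround(rtnorm(length(idx), cc$visits$mu,
                                   cc$visits$sigma, 0))
      pm <- rtnorm(length(idx), cc$processing$mu, cc$processing$sigma, 0)
      proc_days[idx] <- pmax(1, sround(pm * DAYS_PER_MONTH))
      symptom[idx] <- sample(colnames(config$symptom_probs), length(idx),
                             replace = TRUE,
                             prob = config$symptom_probs[cl, ])
    }
    lm <- letter_machinery(config$letter)
    letters <- character(n)
    for (i in seq_len(n))
      letters[i] <- generate_letter(as.character(label[i]), symptom[i],
                                    machinery = lm)
    out <- data.frame(
      id = sprintf("app%06d", seq_len(n)),
      submission_day = days,
      recorded_review_day = as.integer(days + proc_days),
      label = label,
      age_at_application = age,
      age_at_onset = age - duration,
      duration = duration,
      prior_visits = as.integer(visits),
      symptom_category = symptom,
      letter = letters,
      stringsAsFactors = FALSE)
    class(out) <- c("udn_cohort", "data.frame")
    attr(out, "config") <- config
    out
  })
}

# One calibration pass per class; deterministic, no RNG involved.
calibrate_cohort <- function(config) {
  out <- list()
  for (cl in c("accepted", "not_accepted")) {
    dp <- config$demo_params[[cl]]
    age <- calibrate_tnorm(dp$age_at_application[["mean"]],
                           dp$age_at_application[["sd"]])
    dur <- calibrate_tnorm_conditional(dp$duration[["mean"]],
                                       dp$duration[["sd"]], age)
    vis <- calibrate_tnorm(dp$prior_visits[["mean"]], dp$prior_visits[["sd"]])
    prc <- calibrate_tnorm(dp$processing_months[["mean"]],
                           dp$processing_months[["sd"]])
    out[[cl]] <- list(age = age, duration = dur, visits = vis,
                      processing = prc)
  }
  out
}

#' Generate a synthetic phenotype-description corpus
#'
#' A stand-in for a catalogue of phenotype entries: each entry's description
#' is drawn mostly from one symptom-category token set (plus shared
#' background tokens), so letters of a category are nearer, under any
#' token-overlap-respecting embedding, to entries anchored at the same
#' category.
#'
#' @param n_entries number of entries (>= 1).
#' @param params a [letter_params()].
#' @param categories symptom categories to anchor entries at (cycled).
#' @param seed RNG seed.
#' @return data.frame of class `phenotype_corpus` with columns `entry_id`,
#'   `category`, `description`.
#' @export
generate_phenotype_corpus <- function(n_entries = 200L,
                                      params = letter_params(),
                                      categories = SYMPTOM_CATEGORIES,
                                      seed = 1L) {
  if (n_entries < 1) stop("n_entries must be >= 1")
  n_entries <- as.integer(n_entries)
  bg <- paste0("w", sprintf("%03d", seq_len(params$background_vocab_size)))
  bg_p <- (1 / seq_along(bg)) / sum(1 / seq_along(bg))
  cat_lex <- category_lexicon(categories, params$tokens_per_category)
  with_seed(seed, {
    anchor <- categories[(seq_len(n_entries) - 1L) %% length(categories) + 1L]
    desc <- vapply(seq_len(n_entries), function(i) {
      L <- max(5L, rpois(1, 40))
      from_cat <- runif(L) < 0.7
      toks <- character(L)
      toks[from_cat] <- sample(cat_lex[[anchor[i]]], sum(from_cat),
                               replace = TRUE)
      toks[!from_cat] <- sample(bg, sum(!from_cat), replace = TRUE,
                                prob = bg_p)
      paste(toks, collapse = " ")
    }, character(1))
    out <- data.frame(entry_id = sprintf("PHEN%05d", seq_len(n_entries)),
                      category = anchor, description = desc,
                      stringsAsFactors = FALSE)
    class(out) <- c("phenotype_corpus", "data.frame")
    out
  })
}
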