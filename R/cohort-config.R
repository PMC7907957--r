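# Cohort configuration and the truncated-normal calibration behind it.
#
# All non-negative continuous marginals (ages, durations, processing times)
# are modelled as normals truncated at zero. Truncation shifts moments, so
# the generator does not use the configured mean/SD as the underlying
# (mu, sigma) directly: it solves for parameters whose *truncated* mean
# equals the configured mean exactly, and whose truncated SD is as close to
# the configured SD as the family allows. (A normal truncated at zero cannot
# exceed a coefficient of variation of ~1; configurations beyond that bound
# get the closest attainable SD, with the mean still exact.)

# ---- truncated-normal moments ------------------------------------------

tn_mean <- function(mu, sigma, lo = 0, hi = Inf) {
  if (sigma <= 0) return(pmin(pmax(mu, lo), hi))
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  da <- dnorm(a)
  db <- ifelse(is.finite(b), dnorm(b), 0)
  m <- mu + sigma * (da - db) / Z
  # collapsed window: fall back to nearest endpoint
  bad <- !is.finite(m) | Z < 1e-300
  if (any(bad)) m[bad] <- pmin(pmax(mu, lo), ifelse(is.finite(hi), hi, lo))[bad]
  m
}

tn_var <- function(mu, sigma, lo = 0, hi = Inf) {
  if (sigma <= 0) return(rep(0, max(length(mu), length(hi))))
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  da <- dnorm(a)
  db <- ifelse(is.finite(b), dnorm(b), 0)
  bdb <- ifelse(is.finite(b), b * db, 0)
  v <- sigma^2 * (1 + (a * da - bdb) / Z - ((da - db) / Z)^2)
  bad <- !is.finite(v) | Z < 1e-300 | v < 0
  v[bad] <- 0
  v
}

# Inverse-CDF sampler; lo/hi may be vectors (per-draw truncation windows).
rtnorm <- function(n, mu, sigma, lo = 0, hi = Inf) {
  if (sigma <= 0) return(rep(pmin(pmax(mu, lo), hi), length.out = n))
  p_lo <- pnorm((lo - mu) / sigma)
  p_hi <- pnorm((pmin(hi, mu + 40 * sigma) - mu) / sigma)
  u <- runif(n, pmin(p_lo, p_hi), p_hi)
  x <- qnorm(pmin(pmax(u, 1e-300), 1 - 1e-16)) * sigma + mu
  pmin(pmax(x, lo), hi)
}

# Stochastic rounding: integer-valued, preserves the expectation exactly.
sround <- function(x) {
  f <- floor(x)
  f + (runif(length(x)) < (x - f))
}

# ---- calibration --------------------------------------------------------

# Solve mu so that the lo-truncated mean equals target_mean at this sigma.
solve_tn_mu <- function(target_mean, sigma, lo = 0) {
  if (sigma <= 0) return(target_mean)
  f <- function(mu) tn_mean(mu, sigma, lo) - target_mean
  lower <- lo - 12 * sigma
  upper <- target_mean + 4 * sigma
  if (f(lower) > 0) return(lower)  # sigma too large for this mean; boundary
  uniroot(f, c(lower, upper), tol = 1e-10)$root
}

#' Calibrate a zero-truncated normal to a target mean and SD
#'
#' Finds `(mu, sigma)` such that the normal truncated below at `lo` has mean
#' exactly `target_mean` and standard deviation as close as possible to
#' `target_sd`. Used for every non-negative continuous marginal so that
#' configured summary statistics are recovered by the generator.
#'
#' @param target_mean,target_sd desired moments of the truncated variable.
#' @param lo lower truncation point (default 0).
#' @return list with `mu`, `sigma`, `lo`, plus achieved `mean` and `sd`.
#' @export
calibrate_tnorm <- function(target_mean, target_sd, lo = 0) {
  if (!is.finite(target_mean) || !is.finite(target_sd) || target_sd < 0)
    stop("invalid moment targets")
  if (target_mean <= lo)
    stop("impossible truncation: target mean ", target_mean,
         " not above truncation point ", lo)
  if (target_sd == 0)
    return(list(mu = target_mean, sigma = 0, lo = lo,
                mean = target_mean, sd = 0))
  span <- target_mean - lo
  sig_hi <- min(4 * target_sd, 11 * span)
  obj <- function(lsig) {
    sigma <- exp(lsig)
    mu <- solve_tn_mu(target_mean, sigma, lo)
    (sqrt(tn_var(mu, sigma, lo)) - target_sd)^2
  }
  opt <- optimize(obj, c(log(target_sd / 20), log(sig_hi)), tol = 1e-8)
  sigma <- exp(opt$minimum)
  mu <- solve_tn_mu(target_mean, sigma, lo)
  list(mu = mu, sigma = sigma, lo = lo,
       mean = tn_mean(mu, sigma, lo), sd = sqrt(tn_var(mu, sigma, lo)))
}

# Calibrate duration parameters so that, after per-person truncation to
# [0, age_i], the marginal duration mean still equals the target. The age
# distribution enters through a deterministic quantile grid.
calibrate_tnorm_conditional <- function(target_mean, target_sd, age_pars,
                                        grid_size = 256L) {
  pr <- (seq_len(grid_size) - 0.5) / grid_size
  a0 <- (0 - age_pars$mu) / max(age_pars$sigma, 1e-12)
  ages <- if (age_pars$sigma <= 0) rep(age_pars$mu, grid_size) else
    qnorm(pnorm(a0) + pr * (1 - pnorm(a0))) * age_pars$sigma + age_pars$mu
  ages <- pmax(ages, 1e-8)
  mixed_mean <- function(mu, sigma) mean(tn_mean(mu, sigma, 0, ages))
  solve_mu <- function(sigma) {
    f <- function(mu) mixed_mean(mu, sigma) - target_mean
    lower <- -12 * sigma
    upper <- target_mean + 6 * sigma
    if (f(lower) > 0) return(lower)
    if (f(upper) < 0) return(upper)  # ages cap the mean; boundary solution
    uniroot(f, c(lower, upper), tol = 1e-9)$root
  }
  obj <- function(lsig) {
    sigma <- exp(lsig)
    mu <- solve_mu(sigma)
    m_i <- tn_mean(mu, sigma, 0, ages)
    v <- mean(tn_var(mu, sigma, 0, ages)) + mean((m_i - mean(m_i))^2)
    (sqrt(v) - target_sd)^2
  }
  opt <- optimize(obj, c(log(target_sd / 20), log(4 * target_sd)), tol = 1e-7)
  sigma <- exp(opt$minimum)
  mu <- solve_mu(sigma)
  list(mu = mu, sigma = sigma,
       mean = mean(tn_mean(mu, sigma, 0, ages)))
}

# ---- defaults -----------------------------------------------------------

#' Default per-class demographic parameters
#'
#' Mean/SD per admission class for age at application, minimum disease
#' duration, prior program visits and application processing time (months),
#' matching the published cohort summary this package emulates. Age at
#' symptom onset is implied (onset = age - duration) and listed for
#' reference only.
#' @return nested list `accepted` / `not_accepted`, each a list of
#'   `c(mean, sd)` pairs.
#' @export
default_demo_params <- function() {
  list(
    accepted = list(
      age_at_application = c(mean = 19.7, sd = 18.7),
      duration = c(mean = 8.89, sd = 9.55),
      age_at_onset = c(mean = 10.8, sd = 16.9),
      prior_visits = c(mean = 0.49, sd = 0.56),
      processing_months = c(mean = 3.29, sd = 3.17)),
    not_accepted = list(
      age_at_application = c(mean = 36.5, sd = 21.1),
      duration = c(mean = 8.12, sd = 9.58),
      age_at_onset = c(mean = 28.4, sd = 20.1),
      prior_visits = c(mean = 0.30, sd = 0.68),
      processing_months = c(mean = 4.73, sd = 4.85))
  )
}

SYMPTOM_CATEGORIES <- c(
  "neurologic", "musculoskeletal", "allergic", "gastroenterologic",
  "rheumatologic", "cardiologic", "endocrinologic", "pulmonologic",
  "hematologic", "infectious_disease", "dermatologic", "nephrologic",
  "ophthalmologic", "oncologic", "dental", "psychiatric", "urologic",
  "gynecologic", "toxicologic", "other", "not_reported")

#' Default per-class symptom-category probabilities
#'
#' Class-conditional categorical distributions over 21 symptom categories,
#' proportional to the published per-class counts.
#' @return matrix with rows `accepted`, `not_accepted`; columns categories;
#'   each row sums to 1.
#' @export
default_symptom_probs <- function() {
  acc <- c(575, 151, 59, 47, 35, 54, 27, 26, 22, 2, 13, 18, 14, 6, 8, 5,
           1, 2, 0, 115, 29)
  not <- c(413, 117, 94, 92, 91, 29, 45, 23, 23, 36, 15, 8, 8, 10, 6, 5,
           6, 2, 5, 130, 54)
  m <- rbind(accepted = acc / sum(acc), not_accepted = not / sum(not))
  colnames(m) <- SYMPTOM_CATEGORIES
  m
}

#' Letter-generation parameters
#'
#' Controls the synthetic referral letters: a shared Zipf-weighted background
#' vocabulary, a per-symptom-category token set, concept terms from the
#' semantic-type lexicon whose class-conditional frequencies are tilted by
#' `class_effect`, and symptom-checklist terms with half that tilt.
#' `class_effect = 0` makes letter text independent of the admission label;
#' `1` makes the class-conditional concept vocabularies disjoint.
#'
#' @param background_vocab_size shared background vocabulary size.
#' @param mean_length Poisson mean letter length in tokens.
#' @param class_effect class separation in `[0, 1]`.
#' @param mix mixture weights over token sources
#'   (background/category/concept/walley); must sum to 1.
#' @param tokens_per_category size of each symptom-category token set.
#' @return list of class `letter_params`.
#' @export
letter_params <- function(background_vocab_size = 400L, mean_length = 90,
                          class_effect = 0.5,
                          mix = c(background = 0.55, category = 0.15,
                                  concept = 0.20, walley = 0.10),
                          tokens_per_category = 8L) {
  stopifnot(background_vocab_size >= 1, mean_length > 0,
            class_effect >= 0, class_effect <= 1,
            length(mix) == 4, abs(sum(mix)) > 0)
  if (abs(sum(mix) - 1) > 1e-9) stop("mix weights must sum to 1")
  structure(list(background_vocab_size = as.integer(background_vocab_size),
                 mean_length = mean_length, class_effect = class_effect,
                 mix = mix,
                 tokens_per_category = as.integer(tokens_per_category)),
            class = "letter_params")
}

#' Cohort configuration
#'
#' Bundles everything [generate_cohort()] needs: cohort size, class balance,
#' monthly arrival process (lognormal, moment-matched), per-class demographic
#' mean/SD pairs, per-class symptom-category probabilities, letter
#' parameters and the seed. Defaults reproduce the published cohort summary
#' (n = 2421, ~50/50 classes, 55.0 (19.7) applications/month).
#'
#' @param n_total number of applications.
#' @param accepted_fraction expected accepted proportion, in (0, 1).
#' @param arrival_rate_mean,arrival_rate_sd monthly application count
#'   mean/SD.
#' @param demo_params see [default_demo_params()].
#' @param symptom_probs see [default_symptom_probs()].
#' @param letter see [letter_params()].
#' @param seed integer RNG seed; every generator output is a pure function
#'   of the configuration including this seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_total = 2421L, accepted_fraction = 0.5,
                          arrival_rate_mean = 55.0, arrival_rate_sd = 19.7,
                          demo_params = default_demo_params(),
                          symptom_probs = default_symptom_probs(),
                          letter = letter_params(), seed = 1L) {
  if (!is.numeric(n_total) || n_total < 1) stop("n_total must be positive")
  if (accepted_fraction <= 0 || accepted_fraction >= 1)
    stop("accepted_fraction must be in (0, 1)")
  if (arrival_rate_mean <= 0 || arrival_rate_sd < 0)
    stop("invalid arrival rate parameters")
  stopifnot(inherits(letter, "letter_params"))
  if (!all(rownames(symptom_probs) == c("accepted", "not_accepted")))
    stop("symptom_probs must have rows accepted / not_accepted")
  if (any(symptom_probs < 0) ||
      any(abs(rowSums(symptom_probs) - 1) > 1e-9))
    stop("symptom_probs rows must be non-negative and sum to 1")
  for (cl in c("accepted", "not_accepted")) {
    for (p in names(demo_params[[cl]])) {
      v <- demo_params[[cl]][[p]]
      if (v[["sd"]] < 0) stop("negative SD for ", cl, "/", p)
    }
  }
  structure(list(n_total = as.integer(n_total),
                 accepted_fraction = accepted_fraction,
                 arrival_rate_mean = arrival_rate_mean,
                 arrival_rate_sd = arrival_rate_sd,
                 demo_params = demo_params,
                 symptom_probs = symptom_probs,
                 letter = letter,
                 seed = as.integer(seed)),
            class = "cohort_config")
}
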