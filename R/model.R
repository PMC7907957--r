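# Linear logistic classifier over the feature tiers.
#
# The model is an L2-regularized logistic regression (glmnet, alpha = 0)
# whose inverse-regularization strength C and class weighting are chosen by
# grid search on validation AUROC; the ranking statistic everywhere is the
# signed distance (w.x + b)/||w|| to the separating hyperplane.

#' Default hyperparameter grid
#'
#' Inverse regularization strengths `10^-3 .. 10^3` crossed with class
#' weighting (`"none"` or `"balanced"`).
#' @return list with elements `C` and `class_weight`.
#' @export
default_hyper_grid <- function() {
  list(C = 10^seq(-3, 3), class_weight = c("none", "balanced"))
}

split_sizes <- function(n, fractions) {
  q <- n * fractions
  base <- floor(q)
  left <- n - sum(base)
  add <- integer(length(q))
  if (left > 0) {
    ord <- order(-(q - base), seq_along(q))
    add[ord[seq_len(left)]] <- 1L
  }
  as.integer(base + add)
}

#' Stratified train/validation/test split
#'
#' Sizes follow largest-remainder rounding of the fractions, applied within
#' each label so every split's label proportion is within one application
#' of the cohort's.
#'
#' @param apps applications data.frame with a `label` column.
#' @param fractions named fractions summing to 1.
#' @param stratified stratify by label (degenerates to a plain split when
#'   only one label is present).
#' @param seed RNG seed for the shuffle.
#' @return named list of disjoint, exhaustive data.frames.
#' @export
stratified_split <- function(apps,
                             fractions = c(train = 0.8, validation = 0.1,
                                           test = 0.1),
                             stratified = TRUE, seed = 1L) {
  if (nrow(apps) < 10L) stop("too few applications to split")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  groups <- if (stratified && length(unique(apps$label)) > 1L)
    split(seq_len(nrow(apps)), apps$label) else list(all = seq_len(nrow(apps)))
  assign_idx <- rep(NA_integer_, nrow(apps))
  with_seed(seed, {
    for (g in groups) {
      g <- g[sample.int(length(g))]
      sz <- split_sizes(length(g), fractions)
      assign_idx[g] <- rep(seq_along(fractions), sz)
    }
  })
  out <- lapply(seq_along(fractions), function(s) apps[assign_idx == s, ,
                                                       drop = FALSE])
  names(out) <- names(fractions)
  out
}

# Round-robin stratified fold assignment; every fold's complement keeps
# both classes provided k <= min class count.
stratified_folds <- function(labels, k, seed) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > min(table(labels))) stop("k exceeds the smallest class count")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (g in split(seq_along(labels), labels)) {
      g <- g[sample.int(length(g))]
      fold[g] <- rep_len(seq_len(k), length(g))
    }
  })
  fold
}

# ---- fitting ------------------------------------------------------------

#' Fit the admission classifier for one feature tier
#'
#' Fits all feature components on the training split, then an
#' L2-regularized linear logistic model, selecting `C` and class weighting
#' on validation AUROC (ties resolved toward stronger regularization).
#'
#' @param train,validation application data.frames; features are fitted on
#'   `train` only.
#' @param tier feature tier (see [fit_features()]).
#' @param grid hyperparameter grid, see [default_hyper_grid()].
#' @param concept_lexicon,symptom_lexicon,corpus,backend,min_df passed to
#'   [fit_features()].
#' @return object of class `admit_model` with elements `weights` (named),
#'   `intercept`, `hyperparameters`, `tier`, `feature_state`,
#'   `validation_auroc`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_total = 120, seed = 3))
#' sp <- stratified_split(coh, seed = 3)
#' fit <- admit_fit(sp$train, sp$validation, tier = "walley")
#' summary(fit)
#' @export
admit_fit <- function(train, validation, tier = "semantic_types",
                      grid = default_hyper_grid(),
                      concept_lexicon = default_concept_lexicon(),
                      symptom_lexicon = default_symptom_lexicon(),
                      corpus = NULL,
                      backend = hashed_embedding_backend(),
                      min_df = 2L) {
  if (length(unique(train$label)) < 2L)
    stop("training set must contain both classes")
  state <- fit_features(train, tier, concept_lexicon, symptom_lexicon,
                        corpus, backend, min_df)
  X <- featurize(state, train)
  Xv <- featurize(state, validation)
  y <- as.numeric(train$label == "accepted")
  yv <- validation$label
  n <- length(y)
  lam <- sort(1 / (grid$C * n), decreasing = TRUE)
  Cs <- 1 / (lam * n)  # ascending C = descending lambda
  best <- NULL
  for (cw in grid$class_weight) {
    w <- if (cw == "balanced") {
      tab <- table(factor(y, levels = c(0, 1)))
      as.numeric(n / (2 * tab[as.character(y)]))
    } else rep(1, n)
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = lam, weights = w, standardize = FALSE)
    link <- predict(fit, Xv, s = lam, type = "link")
    for (j in seq_along(lam)) {
      au <- auroc(link[, j], yv)
      # ascending C within each cw: strict improvement required, so ties
      # keep the earlier (more regularized) candidate
      if (is.null(best) || au > best$auroc + 1e-12) {
        co <- as.numeric(predict(fit, s = lam[j], type = "coefficients"))
        best <- list(auroc = au, C = Cs[j], lambda = lam[j],
                     class_weight = cw,
                     intercept = co[1L],
                     weights = setNames(co[-1L], colnames(X)))
      }
    }
  }
  structure(list(weights = best$weights, intercept = best$intercept,
                 hyperparameters = list(C = best$C, lambda = best$lambda,
                                        class_weight = best$class_weight),
                 tier = tier, feature_state = state,
                 validation_auroc = best$auroc,
                 n_train = n),
            class = "admit_model")
}

#' Signed distance to the separating hyperplane
#'
#' `(w.x + b) / ||w||`; positive scores point toward the accepted class and
#' the magnitude is the ranking priority. Feature names absent from `x`
#' contribute zero.
#'
#' @param model an [admit_fit()] model.
#' @param x named numeric feature vector, or a matrix with named columns.
#' @return numeric score(s).
#' @export
decision_score <- function(model, x) {
  w <- model$weights
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("zero weight vector: signed distance undefined")
  if (is.matrix(x) || inherits(x, "Matrix")) {
    common <- intersect(colnames(x), names(w))
    as.numeric(x[, common, drop = FALSE] %*% w[common] + model$intercept) / nw
  } else {
    common <- intersect(names(x), names(w))
    (sum(w[common] * x[common]) + model$intercept) / nw
  }
}

#' @export
predict.admit_model <- function(object, newdata, type = c("score", "class",
                                                          "response"), ...) {
  type <- match.arg(type)
  X <- featurize(object$feature_state, newdata)
  s <- decision_score(object, X)
  switch(type,
    score = s,
    class = factor(ifelse(s > 0, "accepted", "not_accepted"),
                   levels = c("accepted", "not_accepted")),
    response = {
      nw <- sqrt(sum(object$weights^2))
      stats::plogis(s * nw)
    })
}

#' @export
coef.admit_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' @export
print.admit_model <- function(x, ...) {
  cat("Linear logistic admission model\n")
  cat("  tier:            ", x$tier, "\n")
  cat("  features:        ", length(x$weights), "\n")
  cat("  C:               ", format(x$hyperparameters$C), "\n")
  cat("  class weight:    ", x$hyperparameters$class_weight, "\n")
  cat("  validation AUROC:", round(x$validation_auroc, 3), "\n")
  invisible(x)
}

#' @export
summary.admit_model <- function(object, n_top = 10L, ...) {
  print(object)
  w <- sort(abs(object$weights), decreasing = TRUE)
  top <- head(names(w), n_top)
  cat("  top weighted features:\n")
  for (f in top)
    cat(sprintf("    %-32s %+.4f\n", f, object$weights[[f]]))
  invisible(object)
}

# ---- evaluation ---------------------------------------------------------

#' Area under the ROC curve (rank statistic)
#'
#' Probability that a random accepted application outscores a random
#' not-accepted one, with ties counted one half (Mann-Whitney definition);
#' invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric scores.
#' @param labels labels; `"accepted"` (or 1 / TRUE) is the positive class.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  pos <- labels_to_logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: evaluation set contains a single class")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

labels_to_logical <- function(labels) {
  if (is.logical(labels)) labels
  else if (is.numeric(labels)) labels > 0
  else labels == "accepted"
}

#' Evaluate a model on labelled applications
#'
#' @param model an [admit_fit()] model.
#' @param apps labelled applications containing both classes.
#' @param threshold decision threshold on the signed distance (default 0,
#'   i.e. predicted probability one half).
#' @return object of class `metrics_report`: sensitivity, specificity,
#'   balanced accuracy, AUROC and the confusion counts (accepted is the
#'   positive class).
#' @export
evaluate <- function(model, apps, threshold = 0) {
  s <- predict(model, apps, type = "score")
  metrics_from_scores(s, apps$label, threshold)
}

metrics_from_scores <- function(scores, labels, threshold = 0) {
  pos <- labels_to_logical(labels)
  pred <- scores > threshold
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(list(sensitivity = sens, specificity = spec,
                 balanced_accuracy = balanced_accuracy(sens, spec),
                 auroc = auroc(scores, labels),
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 n = length(scores), threshold = threshold),
            class = "metrics_report")
}

#' Balanced accuracy
#' @param sensitivity,specificity class-conditional accuracies.
#' @return their arithmetic mean.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "n = %d | sensitivity %.3f | specificity %.3f | balanced accuracy %.3f | AUROC %.3f\n",
    x$n, x$sensitivity, x$specificity, x$balanced_accuracy, x$auroc))
  invisible(x)
}

# ---- model comparison ---------------------------------------------------

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Thin wrapper that reports p = 1 when every paired difference is zero
#' (the test statistic is otherwise undefined).
#' @param x,y paired numeric vectors.
#' @return list with `p_value` and `statistic`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  if (all(d == 0)) return(list(p_value = 1, statistic = 0))
  wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic))
}

#' Compare two feature tiers by repeated cross-validated AUROC
#'
#' Runs repeated stratified k-fold cross-validation with folds shared
#' between the two tiers, collects per-fold test AUROCs, and applies the
#' two-sided Wilcoxon signed-rank test to the paired fold AUROCs.
#'
#' @param apps labelled applications.
#' @param tier_a,tier_b feature tiers to compare.
#' @param k folds per repeat; `repeats` repeats.
#' @param seed base seed (each repeat derives its own fold shuffle).
#' @param ... passed to [admit_fit()] (grid, lexicons, corpus, ...).
#' @return object of class `tier_comparison` with the p-value and the
#'   paired per-fold AUROCs.
#' @export
compare_models <- function(apps, tier_a, tier_b, k = 5L, repeats = 10L,
                           seed = 1L, ...) {
  au_a <- au_b <- numeric(0)
  for (r in seq_len(repeats)) {
    fold_seed <- as.integer(seed) + r - 1L
    folds <- stratified_folds(apps$label, k, fold_seed)
    for (f in seq_len(k)) {
      tr <- apps[folds != f, , drop = FALSE]
      te <- apps[folds == f, , drop = FALSE]
      inner <- stratified_split(tr, c(train = 0.9, validation = 0.1),
                                seed = fold_seed + 1000L * f)
      fa <- admit_fit(inner$train, inner$validation, tier = tier_a, ...)
      fb <- admit_fit(inner$train, inner$validation, tier = tier_b, ...)
      au_a <- c(au_a, auroc(predict(fa, te, type = "score"), te$label))
      au_b <- c(au_b, auroc(predict(fb, te, type = "score"), te$label))
    }
  }
  if (length(au_a) < 6L) stop("need at least 6 paired folds")
  wt <- wilcoxon_signed_rank(au_a, au_b)
  structure(list(tier_a = tier_a, tier_b = tier_b,
                 fold_auroc_a = au_a, fold_auroc_b = au_b,
                 mean_auroc_a = mean(au_a), mean_auroc_b = mean(au_b),
                 p_value = wt$p_value, statistic = wt$statistic),
            class = "tier_comparison")
}

#' @export
print.tier_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: mean fold AUROC %.3f vs %.3f, Wilcoxon p = %.4g (n = %d folds)\n",
              x$tier_a, x$tier_b, x$mean_auroc_a, x$mean_auroc_b,
              x$p_value, length(x$fold_auroc_a)))
  invisible(x)
}
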