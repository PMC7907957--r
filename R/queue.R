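# Out-of-fold confidence ranking and the capacity-constrained review-queue
# simulator.
#
# Review sessions occur every `period_d` days (first session on day d, not
# day 0); at each session the `budget_a` highest-priority applications
# among those submitted strictly before the session day are reviewed. All
# four heuristics are static rankings, so the simulator reduces to serving
# a fixed priority order under eligibility and capacity constraints.
# Processing time is (review day - submission day) / 30.44 months.

#' Out-of-fold confidence scores via stratified k-fold cross-validation
#'
#' Each application is scored (signed distance) exactly once, by a model
#' whose training fold excluded it; feature components are refit for every
#' fold, and hyperparameters are selected on an inner validation split of
#' the fold's training data.
#'
#' @param apps labelled applications.
#' @param tier feature tier.
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param ... passed to [admit_fit()].
#' @return data.frame (`confidence_table`) with columns `id`, `fold`,
#'   `score`, one row per application.
#' @export
crossval_scores <- function(apps, tier = "semantic_types", k = 5L, seed = 1L,
                            ...) {
  folds <- stratified_folds(apps$label, k, seed)
  score <- numeric(nrow(apps))
  for (f in seq_len(k)) {
    tr <- apps[folds != f, , drop = FALSE]
    te <- apps[folds == f, , drop = FALSE]
    inner <- stratified_split(tr, c(train = 0.9, validation = 0.1),
                              seed = as.integer(seed) + 1000L * f)
    fit <- admit_fit(inner$train, inner$validation, tier = tier, ...)
    score[folds == f] <- predict(fit, te, type = "score")
  }
  out <- data.frame(id = apps$id, fold = folds, score = score,
                    stringsAsFactors = FALSE)
  class(out) <- c("confidence_table", "data.frame")
  out
}

# Static priority order (permutation of row indices, best first) for a
# heuristic; ties broken by submission day then id for deterministic replay.
priority_order <- function(apps, heuristic, scores = NULL) {
  heuristic <- match.arg(heuristic, HEURISTICS)
  switch(heuristic,
    fifo = order(apps$submission_day, apps$id),
    classifier = {
      s <- lookup_scores(apps, scores)
      order(-s, apps$submission_day, apps$id)
    },
    accept_first = order(apps$label != "accepted", apps$submission_day,
                         apps$id),
    udn_order = {
      if (is.null(apps$recorded_review_day) ||
          anyNA(apps$recorded_review_day))
        stop("udn_order requires recorded_review_day for every application")
      order(apps$recorded_review_day, apps$id)
    })
}

lookup_scores <- function(apps, scores) {
  if (is.null(scores)) stop("classifier heuristic requires confidence scores")
  s <- scores$score[match(apps$id, scores$id)]
  if (anyNA(s)) stop("missing confidence score for some applications")
  if (any(!is.finite(s))) stop("non-finite confidence scores")
  s
}

#' Priority key of one application under a ranking heuristic
#'
#' Returns the lexicographic sort key (ascending) used by the simulator:
#' `fifo` (submission day, id); `classifier` (-score, submission day, id);
#' `accept_first` (not-accepted flag, submission day, id); `udn_order`
#' (recorded review day, id).
#'
#' @param heuristic one of `"fifo"`, `"udn_order"`, `"classifier"`,
#'   `"accept_first"`.
#' @param app single-row application data.frame.
#' @param scores confidence table (for `classifier`).
#' @return list of key components, ascending lexicographic order.
#' @export
priority <- function(heuristic, app, scores = NULL) {
  heuristic <- match.arg(heuristic, HEURISTICS)
  switch(heuristic,
    fifo = list(app$submission_day, app$id),
    classifier = list(-lookup_scores(app, scores), app$submission_day,
                      app$id),
    accept_first = list(as.numeric(app$label != "accepted"),
                        app$submission_day, app$id),
    udn_order = {
      if (is.null(app$recorded_review_day) || anyNA(app$recorded_review_day))
        stop("udn_order requires recorded_review_day")
      list(app$recorded_review_day, app$id)
    })
}

#' Simulate capacity-constrained review sessions
#'
#' Sessions are held on days `d, 2d, 3d, ...`; at each session the pending
#' set is every application submitted strictly before the session day and
#' not yet reviewed, and the `budget_a` highest-priority pending
#' applications are reviewed on that day. The simulation runs until every
#' application is reviewed. The `udn_order` heuristic bypasses the session
#' mechanics and uses the recorded review days directly.
#'
#' @param apps applications.
#' @param heuristic ranking heuristic (see [priority()]).
#' @param period_d days between sessions (integer >= 1).
#' @param budget_a applications reviewable per session (integer >= 1).
#' @param scores confidence table for the `classifier` heuristic.
#' @return object of class `queue_sim`: per-application `review_day` and
#'   `processing_months`, plus mean/SD processing time by label.
#' @examples
#' coh <- generate_cohort(cohort_config(n_total = 60, seed = 2))
#' simulate_queue(coh, "accept_first", period_d = 14, budget_a = 5)
#' @export
simulate_queue <- function(apps, heuristic, period_d, budget_a,
                           scores = NULL) {
  heuristic <- match.arg(heuristic, HEURISTICS)
  period_d <- as.integer(period_d); budget_a <- as.integer(budget_a)
  if (period_d < 1L || budget_a < 1L)
    stop("period_d and budget_a must be positive integers")
  n <- nrow(apps)
  if (heuristic == "udn_order") {
    ord <- priority_order(apps, heuristic)  # validates recorded days
    review_day <- apps$recorded_review_day
  } else {
    ord <- priority_order(apps, heuristic, scores)
    sub_sorted <- apps$submission_day[ord]
    review_sorted <- rep(NA_integer_, n)
    reviewed <- logical(n)
    n_done <- 0L
    session <- period_d
    while (n_done < n) {
      elig <- which(!reviewed & sub_sorted < session)
      if (length(elig)) {
        take <- elig[seq_len(min(budget_a, length(elig)))]
        review_sorted[take] <- session
        reviewed[take] <- TRUE
        n_done <- n_done + length(take)
      }
      session <- session + period_d
    }
    review_day <- integer(n)
    review_day[ord] <- review_sorted
  }
  months <- (review_day - apps$submission_day) / DAYS_PER_MONTH
  if (any(review_day <= apps$submission_day))
    stop("internal error: review on or before submission")
  by_label <- lapply(split(months, apps$label), function(m)
    c(mean = mean(m), sd = if (length(m) > 1L) sd(m) else NA_real_))
  structure(list(heuristic = heuristic, period_d = period_d,
                 budget_a = budget_a,
                 result = data.frame(id = apps$id, label = apps$label,
                                     submission_day = apps$submission_day,
                                     review_day = review_day,
                                     processing_months = months,
                                     stringsAsFactors = FALSE),
                 by_label = by_label),
            class = "queue_sim")
}

#' @export
print.queue_sim <- function(x, ...) {
  cat(sprintf("Review-queue simulation: %s, d = %d days, a = %d/session\n",
              x$heuristic, x$period_d, x$budget_a))
  for (lb in names(x$by_label))
    cat(sprintf("  %-13s mean %.2f (SD %.2f) months\n", lb,
                x$by_label[[lb]][["mean"]], x$by_label[[lb]][["sd"]]))
  invisible(x)
}

#' Sweep review period and session budget
#'
#' Full factorial grid of (heuristic, d, a); reports mean/SD processing
#' time by label per cell, and the (d, a) minimizing the accepted-group
#' mean-time gap between the classifier and accept-first rankings (ties
#' toward smaller a, then smaller d).
#'
#' @param apps applications.
#' @param heuristics heuristics to include.
#' @param d_values,a_values review periods (days) and session budgets.
#' @param scores confidence table (needed when `classifier` is included).
#' @return data.frame of class `schedule_sweep` (columns heuristic, d, a,
#'   label, mean_months, sd_months) with the optimum as attribute
#'   `optimum`.
#' @export
sweep_schedule <- function(apps, heuristics = c("fifo", "classifier",
                                                "accept_first"),
                           d_values = c(3, 6, 9, 12, 15, 30),
                           a_values = c(5, 10, 15, 20, 26, 30, 40),
                           scores = NULL) {
  if (!length(d_values) || !length(a_values) || !length(heuristics))
    stop("empty sweep grid")
  rows <- list()
  for (h in heuristics) for (d in d_values) for (a in a_values) {
    sim <- simulate_queue(apps, h, d, a, scores)
    for (lb in names(sim$by_label))
      rows[[length(rows) + 1L]] <- data.frame(
        heuristic = h, d = d, a = a, label = lb,
        mean_months = sim$by_label[[lb]][["mean"]],
        sd_months = sim$by_label[[lb]][["sd"]],
        stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, rows)
  opt <- NULL
  if (all(c("classifier", "accept_first") %in% heuristics)) {
    acc <- grid[grid$label == "accepted", ]
    cl <- acc[acc$heuristic == "classifier", ]
    af <- acc[acc$heuristic == "accept_first", ]
    key <- paste(cl$d, cl$a)
    gap <- abs(cl$mean_months - af$mean_months[match(key, paste(af$d, af$a))])
    best <- order(gap, cl$a, cl$d)[1L]
    opt <- list(d = cl$d[best], a = cl$a[best], gap_months = gap[best])
  }
  structure(grid, class = c("schedule_sweep", "data.frame"), optimum = opt)
}

#' Percent reduction in mean processing time
#' @param baseline_mean,new_mean mean processing times (months);
#'   `baseline_mean` must be positive.
#' @return `100 * (baseline_mean - new_mean) / baseline_mean`.
#' @export
percent_reduction <- function(baseline_mean, new_mean) {
  if (any(baseline_mean <= 0)) stop("baseline mean must be positive")
  100 * (baseline_mean - new_mean) / baseline_mean
}
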