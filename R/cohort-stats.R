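# Cohort-comparison statistics: Welch two-sample t from group summaries,
# Pearson chi-squared on 2x2 tables, Bonferroni adjustment, and the
# accepted-vs-not-accepted summary table.

#' Group summary (mean, SD, n)
#' @param mean,sd,n group mean, standard deviation (>= 0) and size (>= 2).
#' @return list of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  if (sd < 0 || n < 2) stop("invalid group summary: need sd >= 0, n >= 2")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' Welch two-sample t test from group summaries
#'
#' Unequal-variance t test computed directly from per-group mean/SD/n:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value.
#'
#' @param g1,g2 [group_summary()] objects.
#' @return list with `t`, `df`, `p_value`.
#' @examples
#' welch_t(group_summary(19.7, 18.7, 1209), group_summary(36.5, 21.1, 1212))
#' @export
welch_t <- function(g1, g2) {
  stopifnot(inherits(g1, "group_summary"), inherits(g2, "group_summary"))
  v1 <- g1$sd^2 / g1$n
  v2 <- g2$sd^2 / g2$n
  if (v1 + v2 == 0) stop("both group variances are zero")
  t <- (g1$mean - g2$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' `chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, optionally with the
#' Yates continuity correction; two-sided p from the chi-squared(1)
#' distribution.
#'
#' @param a,b,c,d non-negative cell counts (rows: group; columns: outcome).
#' @param correction apply the Yates continuity correction.
#' @return list with `statistic`, `p_value`.
#' @export
chi2_2x2 <- function(a, b, c, d, correction = FALSE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || sum(cells) == 0) stop("invalid 2x2 counts")
  n <- sum(cells)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0)) stop("chi-squared undefined: zero margin")
  num <- abs(a * d - b * c)
  if (correction) num <- max(0, num - n / 2)
  stat <- n * num^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE))
}

#' Bonferroni adjustment with explicit family size
#' @param p_values p-values in `[0, 1]`.
#' @param m number of tests in the family (>= number of p-values).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  if (m < length(p_values)) stop("m must be at least the number of p-values")
  pmin(1, m * p_values)
}

#' Accepted-vs-not-accepted cohort summary table
#'
#' Per-label mean (SD) for the five continuous indicators (age at
#' application, age at onset, minimum duration, prior visits, processing
#' time in months), Welch t per indicator, per-label symptom-category
#' counts/percentages, and per-category 2x2 chi-squared tests with a
#' Bonferroni adjustment over the number of categories tested.
#'
#' @param apps labelled applications (a `udn_cohort` or compatible frame).
#' @return object of class `cohort_table`.
#' @export
summarize_cohort <- function(apps) {
  if (nrow(apps) == 0L) stop("empty cohort")
  labs <- c("accepted", "not_accepted")
  if (!all(labs %in% apps$label)) stop("cohort must contain both labels")
  apps$processing_months <-
    (apps$recorded_review_day - apps$submission_day) / DAYS_PER_MONTH
  vars <- c("age_at_application", "age_at_onset", "duration",
            "prior_visits", "processing_months")
  cont <- lapply(vars, function(v) {
    out <- list()
    for (lb in labs) {
      x <- apps[[v]][apps$label == lb]
      x <- x[!is.na(x)]
      out[[lb]] <- list(mean = mean(x),
                        sd = if (length(x) > 1L) sd(x) else NA_real_,
                        n = length(x))
    }
    if (out$accepted$n >= 2 && out$not_accepted$n >= 2 &&
        !is.na(out$accepted$sd) && !is.na(out$not_accepted$sd) &&
        out$accepted$sd + out$not_accepted$sd > 0) {
      wt <- welch_t(group_summary(out$accepted$mean, out$accepted$sd,
                                  out$accepted$n),
                    group_summary(out$not_accepted$mean,
                                  out$not_accepted$sd,
                                  out$not_accepted$n))
      out$t <- wt$t; out$p_value <- wt$p_value
    } else {
      warning("degenerate groups for ", v, "; t test omitted")
      out$t <- NA_real_; out$p_value <- NA_real_
    }
    out
  })
  names(cont) <- vars

  cats <- sort(unique(apps$symptom_category))
  n_by <- table(factor(apps$label, levels = labs))
  sym <- lapply(cats, function(ct) {
    k <- vapply(labs, function(lb)
      sum(apps$label == lb & apps$symptom_category == ct), numeric(1))
    res <- list(count = k, percent = 100 * k / as.numeric(n_by))
    chi <- tryCatch(chi2_2x2(k[1], n_by[[1]] - k[1],
                             k[2], n_by[[2]] - k[2]),
                    error = function(e) list(statistic = NA_real_,
                                             p_value = NA_real_))
    res$chi2 <- chi$statistic
    res$p_value <- chi$p_value
    res
  })
  names(sym) <- cats
  p_raw <- vapply(sym, `[[`, numeric(1), "p_value")
  p_adj <- rep(NA_real_, length(p_raw))
  ok <- !is.na(p_raw)
  p_adj[ok] <- bonferroni(p_raw[ok], m = length(cats))
  for (i in seq_along(sym)) sym[[i]]$p_adjusted <- p_adj[i]

  structure(list(n = as.integer(n_by), labels = labs, continuous = cont,
                 symptoms = sym, m_tests = length(cats)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort summary: accepted n = %d, not accepted n = %d\n",
              x$n[1], x$n[2]))
  cat(sprintf("%-22s %18s %18s %8s\n", "Indicator", "Accepted",
              "Not accepted", "t"))
  for (v in names(x$continuous)) {
    ct <- x$continuous[[v]]
    cat(sprintf("%-22s %10.2f (%5.2f) %10.2f (%5.2f) %8.1f\n", v,
                ct$accepted$mean, ct$accepted$sd,
                ct$not_accepted$mean, ct$not_accepted$sd, ct$t))
  }
  cat("Symptoms, No. (%):\n")
  for (ct in names(x$symptoms)) {
    s <- x$symptoms[[ct]]
    star <- if (!is.na(s$p_adjusted) && s$p_adjusted < 0.05) " *" else ""
    cat(sprintf("  %-20s %6d (%4.1f) %8d (%4.1f)%s\n", ct,
                s$count[1], s$percent[1], s$count[2], s$percent[2], star))
  }
  invisible(x)
}
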