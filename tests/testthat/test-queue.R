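test_that("priority keys implement the four heuristics", {
  apps <- data.frame(id = c("a", "b"),
                     submission_day = c(9L, 1L),
                     recorded_review_day = c(30L, 40L),
                     label = factor(c("accepted", "not_accepted"),
                                    c("accepted", "not_accepted")),
                     stringsAsFactors = FALSE)
  # accept-first: accepted ahead despite later submission
  ka <- priority("accept_first", apps[1, ])
  kb <- priority("accept_first", apps[2, ])
  expect_lt(ka[[1]], kb[[1]])
  # fifo equals submission-day order
  expect_equal(udnadmit:::priority_order(apps, "fifo"), c(2L, 1L))
  # classifier: higher score first, submission day breaks ties
  sc <- data.frame(id = c("a", "b"), score = c(1, 1))
  expect_equal(udnadmit:::priority_order(apps, "classifier", sc), c(2L, 1L))
  sc2 <- data.frame(id = c("a", "b"), score = c(2, 1))
  expect_equal(udnadmit:::priority_order(apps, "classifier", sc2), c(1L, 2L))
  expect_equal(udnadmit:::priority_order(apps, "udn_order"), c(1L, 2L))
  expect_error(priority("classifier", apps[1, ]), "scores")
})

test_that("the event loop matches hand simulation", {
  apps <- data.frame(id = c("a1", "a2", "a3", "a4"),
                     submission_day = c(0L, 0L, 0L, 0L),
                     label = factor(c("accepted", "not_accepted",
                                      "accepted", "not_accepted"),
                                    c("accepted", "not_accepted")),
                     stringsAsFactors = FALSE)
  sc <- data.frame(id = apps$id, score = c(2, -1, 1, -2))
  sim <- simulate_queue(apps, "classifier", 7, 1, scores = sc)
  expect_equal(sim$result$review_day, c(7L, 21L, 14L, 28L))
  expect_equal(sim$by_label$accepted[["mean"]],
               mean(c(7, 14)) / 30.44)
  # fifo with id tie-breaks interleaves the classes
  simf <- simulate_queue(apps, "fifo", 7, 1)
  expect_equal(simf$result$review_day, c(7L, 14L, 21L, 28L))
  expect_equal(simf$by_label$accepted[["mean"]], mean(c(7, 21)) / 30.44)
  # single application, d = 14
  one <- apps[1, ]
  s1 <- simulate_queue(one, "fifo", 14, 1)
  expect_equal(s1$result$review_day, 14L)
  expect_equal(s1$result$processing_months, 14 / 30.44)
  expect_error(simulate_queue(apps, "fifo", 0, 1), "positive")
})

test_that("every application is reviewed once within the session budget", {
  coh <- fx_cohort(n = 250, seed = 22)
  for (h in c("fifo", "accept_first")) {
    sim <- simulate_queue(coh, h, 7, 9)
    r <- sim$result
    expect_equal(nrow(r), nrow(coh))
    expect_true(all(r$review_day > r$submission_day))
    expect_true(all(r$review_day %% 7 == 0))
    expect_true(all(table(r$review_day) <= 9))
    # eligibility is strict: nothing reviewed at the session of its
    # submission day
    expect_true(all(r$review_day > r$submission_day))
  }
})

test_that("without contention all heuristics coincide", {
  coh <- fx_cohort(n = 60, seed = 23)
  sc <- data.frame(id = coh$id, score = seq_len(60))
  sims <- lapply(c("fifo", "classifier", "accept_first"), function(h)
    simulate_queue(coh, h, 7, nrow(coh), scores = sc)$result$review_day)
  expect_equal(sims[[1]], sims[[2]])
  expect_equal(sims[[1]], sims[[3]])
})

test_that("overall mean time is heuristic-free when sessions saturate", {
  # 40 applications all submitted before day 1, budget 5: every session
  # is exactly full until the queue drains
  apps <- data.frame(id = sprintf("s%02d", 1:40),
                     submission_day = 0L,
                     label = factor(rep(c("accepted", "not_accepted"), 20),
                                    c("accepted", "not_accepted")),
                     stringsAsFactors = FALSE)
  sc <- data.frame(id = apps$id, score = stats::rnorm(40))
  overall <- vapply(c("fifo", "classifier", "accept_first"), function(h)
    mean(simulate_queue(apps, h, 10, 5, scores = sc)$result$review_day),
    numeric(1))
  expect_true(all(abs(overall - overall[1]) < 1e-9))
})

test_that("recorded review days reproduce the configured processing times", {
  coh <- generate_cohort(cohort_config(n_total = 4000, seed = 24))
  sim <- simulate_queue(coh, "udn_order", 14, 26)
  dp <- default_demo_params()
  for (cl in c("accepted", "not_accepted")) {
    m <- sim$result$processing_months[coh$label == cl]
    tgt <- dp[[cl]]$processing_months
    expect_lt(abs(mean(m) - tgt[["mean"]]),
              3 * tgt[["sd"]] / sqrt(length(m)) + 1 / 30.44)
  }
})

test_that("out-of-fold scores cover each application exactly once", {
  coh <- fx_cohort(n = 150, seed = 25)
  cs <- crossval_scores(coh, tier = "walley", k = 5, seed = 25,
                        grid = grid_small())
  expect_setequal(cs$id, coh$id)
  expect_equal(anyDuplicated(cs$id), 0L)
  expect_equal(sort(unique(cs$fold)), 1:5)
  expect_true(all(is.finite(cs$score)))
  expect_error(crossval_scores(coh[1:8, ], k = 7), "class count")
})

test_that("strong class separation yields near-perfect out-of-fold ranking", {
  coh <- fx_cohort(n = 400, seed = 26, effect = 1)
  cs <- crossval_scores(coh, tier = "semantic_types", k = 5, seed = 26,
                        grid = grid_small())
  expect_gt(auroc(cs$score, coh$label), 0.95)
})

test_that("null cohorts rank at chance out of fold", {
  for (s in 1:3) {
    coh <- fx_cohort(n = 250, seed = 40 + s, effect = 0, null_demo = TRUE)
    cs <- crossval_scores(coh, tier = "walley", k = 5, seed = s,
                          grid = grid_small())
    expect_lt(abs(auroc(cs$score, coh$label) - 0.5), 0.1)
  }
})

test_that("sweep returns the full grid and a well-defined optimum", {
  coh <- fx_cohort(n = 200, seed = 27)
  cs <- crossval_scores(coh, tier = "walley", k = 5, seed = 27,
                        grid = grid_small())
  sw <- sweep_schedule(coh, d_values = c(7, 14), a_values = c(5, 200),
                       scores = cs)
  expect_equal(nrow(sw), 3 * 2 * 2 * 2)  # heuristics x d x a x labels
  opt <- attr(sw, "optimum")
  # with a budget that never binds the classifier/accept-first gap is zero
  nocont <- sw[sw$a == 200 & sw$label == "accepted", ]
  gap <- abs(nocont$mean_months[nocont$heuristic == "classifier"] -
               nocont$mean_months[nocont$heuristic == "accept_first"])
  expect_true(all(gap < 1e-9))
  expect_equal(opt$gap_months, 0)
  # both a = 200 cells tie at zero gap; the smaller d wins the tie-break
  expect_equal(opt$a, 200)
  expect_equal(opt$d, 7)
  expect_error(sweep_schedule(coh, d_values = numeric(0)), "empty")
})

test_that("percent reduction is plain arithmetic with a guarded baseline", {
  expect_equal(percent_reduction(4, 1), 75)
  expect_equal(percent_reduction(3.29, 3.29), 0)
  expect_error(percent_reduction(0, 1), "positive")
})
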