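test_that("stratified split uses largest-remainder sizes and balances labels", {
  coh <- fx_cohort(n = 2421, seed = 8)
  sp <- stratified_split(coh, seed = 8)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 1937L, validation = 242L, test = 242L))
  expect_equal(sum(vapply(sp, nrow, integer(1))), nrow(coh))
  expect_false(any(duplicated(unlist(lapply(sp, `[[`, "id")))))
  gl <- mean(coh$label == "accepted")
  for (s in sp)
    expect_lt(abs(sum(s$label == "accepted") - gl * nrow(s)), 1 + 1e-9)
  # identical seed, identical partition
  sp2 <- stratified_split(coh, seed = 8)
  expect_identical(lapply(sp, `[[`, "id"), lapply(sp2, `[[`, "id"))
})

test_that("single-label input degenerates to a plain split", {
  coh <- fx_cohort(n = 100, seed = 9)
  coh$label <- factor("accepted", c("accepted", "not_accepted"))
  sp <- stratified_split(coh, seed = 1)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 80L, validation = 10L, test = 10L))
})

test_that("AUROC equals the Mann-Whitney pair count", {
  # brute force over the 4 accepted/not-accepted pairs
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.1),
                     c("accepted", "accepted", "not_accepted",
                       "not_accepted")), 1)
  expect_equal(auroc(c(0.9, 0.7, 0.8, 0.1),
                     c("accepted", "accepted", "not_accepted",
                       "not_accepted")), 0.75)
  expect_equal(auroc(rep(1, 6), rep(c("accepted", "not_accepted"), 3)), 0.5)
  expect_error(auroc(1:3, rep("accepted", 3)), "single class")
  # invariant under strictly monotone transforms
  set.seed(4)
  s <- rnorm(40); lb <- sample(c("accepted", "not_accepted"), 40, TRUE,
                               prob = c(0.5, 0.5))
  expect_equal(auroc(s, lb), auroc(exp(2 * s) + 5, lb))
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  s <- c(rnorm(60, 0.5), rnorm(60))
  lb <- rep(c("accepted", "not_accepted"), each = 60)
  expect_equal(auroc(s, lb),
               as.numeric(pROC::auc(pROC::roc(lb, s, levels =
                 c("not_accepted", "accepted"), direction = "<",
                 quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("metrics report is internally consistent", {
  s <- c(2, 1, -1, 0.5, -2, -0.3)
  lb <- c("accepted", "accepted", "accepted",
          "not_accepted", "not_accepted", "not_accepted")
  m <- udnadmit:::metrics_from_scores(s, lb)
  expect_equal(m$balanced_accuracy,
               (m$sensitivity + m$specificity) / 2)
  expect_equal(sum(m$counts), 6)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 2 / 3)
})

test_that("a separable toy problem is fit perfectly at weak regularization", {
  n <- 60
  coh <- fx_cohort(n = 200, seed = 14)[1:n, ]
  coh$label <- factor(rep(c("accepted", "not_accepted"), each = n / 2),
                      c("accepted", "not_accepted"))
  coh$age_at_application <- ifelse(coh$label == "accepted", 10, 60) +
    runif(n)
  coh$age_at_onset <- coh$age_at_application / 2
  coh$duration <- coh$age_at_application - coh$age_at_onset
  fit <- admit_fit(coh, coh, tier = "baseline")
  expect_equal(as.character(predict(fit, coh, type = "class")),
               as.character(coh$label))
  expect_error(admit_fit(coh[coh$label == "accepted", ], coh,
                         tier = "baseline"), "both classes")
})

test_that("signed distance matches the normalized hyperplane formula", {
  fit <- list(weights = c(f1 = 3, f2 = 4), intercept = 0)
  class(fit) <- "admit_model"
  expect_equal(decision_score(fit, c(f1 = 1, f2 = 1)), 7 / 5)
  # scaling (w, b) leaves the signed distance unchanged
  fit2 <- fit; fit2$weights <- fit$weights * 2; fit2$intercept <- 0
  expect_equal(decision_score(fit2, c(f1 = 1, f2 = 1)), 7 / 5)
  # a point on the hyperplane scores zero; unknown features contribute zero
  expect_equal(decision_score(fit, c(f1 = 4, f2 = -3, junk = 9)), 0)
  fit$weights <- c(f1 = 0, f2 = 0)
  expect_error(decision_score(fit, c(f1 = 1)), "zero weight")
})

test_that("permuted labels give chance-level validation AUROC", {
  coh <- fx_cohort(n = 200, seed = 15)
  aucs <- numeric(50)
  for (r in 1:50) {
    set.seed(300 + r)
    coh$label <- sample(coh$label)
    sp <- stratified_split(coh, seed = r)
    fit <- admit_fit(sp$train, sp$validation, tier = "baseline",
                     grid = grid_small())
    aucs[r] <- auroc(predict(fit, sp$test, type = "score"), sp$test$label)
  }
  # each test split holds ~20 applications, so the null SD of a single
  # AUROC is ~0.09; bound individual folds loosely and the mean tightly
  expect_true(all(abs(aucs - 0.5) < 0.35))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("letter features outperform the demographic baseline", {
  coh <- fx_cohort(n = 600, seed = 16)
  sp <- stratified_split(coh, seed = 16)
  au <- vapply(c("baseline", "semantic_types"), function(tier)
    evaluate(admit_fit(sp$train, sp$validation, tier = tier), sp$test)$auroc,
    numeric(1))
  expect_gt(au["semantic_types"], au["baseline"])
})

test_that("Wilcoxon comparison reproduces exact enumeration", {
  x <- c(1, 2, 3, 4, 5, 6); y <- c(2, 4, 6, 8, 10, 12)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value, 2 / 64)
  expect_equal(wilcoxon_signed_rank(x, x)$p_value, 1)
})

test_that("tier self-comparison yields p = 1 and strong tiers win often", {
  coh <- fx_cohort(n = 240, seed = 17, effect = 0.7)
  cmp_self <- compare_models(coh, "baseline", "baseline", k = 3,
                             repeats = 2, seed = 5, grid = grid_small())
  expect_equal(cmp_self$p_value, 1)
  hits <- 0L
  for (s in 1:8) {
    coh_s <- fx_cohort(n = 240, seed = 100 + s, effect = 0.7)
    cmp <- compare_models(coh_s, "semantic_types", "baseline", k = 3,
                          repeats = 2, seed = s, grid = grid_small())
    if (cmp$p_value < 0.05 && cmp$mean_auroc_a > cmp$mean_auroc_b)
      hits <- hits + 1L
  }
  expect_gte(hits, 7)
})

test_that("a frozen model scores a later batch without refitting", {
  coh <- fx_cohort(n = 300, seed = 18)
  sp <- stratified_split(coh, seed = 18)
  fit <- admit_fit(sp$train, sp$validation, tier = "walley")
  path <- tempfile(fileext = ".json")
  save_model(fit, path)
  h1 <- unname(tools::md5sum(path))
  later <- generate_cohort(cohort_config(n_total = 288, seed = 19))
  ev <- evaluate(fit, later)
  expect_true(is.finite(ev$auroc))
  save_model(fit, path)  # model object untouched by scoring
  expect_identical(h1, unname(tools::md5sum(path)))
})
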