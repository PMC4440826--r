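test_that("stratified splits reproduce the study partition sizes", {
  co <- generate_cohort(cohort_spec(n_sclc = 145, n_nsclc = 0,
                                    n_control = 155), seed = 1)
  lab <- gepdx:::label_cases(co, "SCLC", "CONTROL")
  sp <- split_cohort(lab, "class", 0.8, seed = 4)
  expect_equal(nrow(sp$train), 240)
  expect_equal(nrow(sp$test), 60)
  # per-class proportions within one subject of the target fraction
  for (cl in 0:1) {
    n_cl <- sum(lab$class == cl)
    expect_lte(abs(sum(sp$train$class == cl) - 0.8 * n_cl), 1)
  }
  # exact historical 115/125 allocation via train_counts
  sp2 <- split_cohort(lab, "class", 0.8, seed = 4,
                      train_counts = c("1" = 115, "0" = 125))
  expect_equal(sum(sp2$train$class == 1), 115)
  expect_equal(sum(sp2$train$class == 0), 125)

  # partition: disjoint and exhaustive
  ids <- c(sp$train$subject_id, sp$test$subject_id)
  expect_setequal(ids, lab$subject_id)
  expect_equal(anyDuplicated(ids), 0L)

  co2 <- generate_cohort(cohort_spec(n_sclc = 0, n_nsclc = 130,
                                     n_control = 130), seed = 2)
  lab2 <- gepdx:::label_cases(co2, "NSCLC", "CONTROL")
  sp3 <- split_cohort(lab2, "class", 0.8, seed = 1)
  expect_equal(nrow(sp3$train), 208)
  expect_equal(nrow(sp3$test), 52)

  expect_error(split_cohort(lab[1, ], "class"),
               class = "gepdx_parameter_error")
})

test_that("confusion counts enumerate prediction outcomes", {
  expect_equal(unlist(confusion_counts(c(1, 1, 0), c(1, 0, 0))),
               c(tp = 1, fn = 1, tn = 0, fp = 0) + c(0, 0, 1, 0))
  allc <- confusion_counts(rep(c(1, 0), 5), rep(c(1, 0), 5))
  expect_equal(allc$fp + allc$fn, 0)
  set.seed(8)
  for (k in 1:20) {
    t <- rbinom(30, 1, 0.5); p <- rbinom(30, 1, 0.5)
    expect_equal(sum(unlist(confusion_counts(t, p))), 30)
  }
  expect_error(confusion_counts(c(1, 0), c(1)),
               class = "gepdx_parameter_error")
})

test_that("the metric panel reproduces the worked examples", {
  # training split: 115 patients (106 recovered), 125 controls (119)
  lab <- c(rep(1, 115), rep(0, 125))
  scores <- c(rep(1, 106), rep(0, 9), rep(0, 119), rep(1, 6))
  m <- panel_metrics(lab, scores)
  expect_equal(m$accuracy, 0.9375)
  expect_equal(round(100 * m$sensitivity, 2), 92.17)
  expect_equal(round(100 * m$specificity, 2), 95.20)
  expect_equal(m$error, 0.0625)

  # four-marker model test split: 26/30 patients, 29/30 controls
  lab2 <- c(rep(1, 30), rep(0, 30))
  scores2 <- c(rep(1, 26), rep(0, 4), rep(0, 29), rep(1, 1))
  m2 <- panel_metrics(lab2, scores2)
  expect_equal(round(100 * m2$accuracy, 2), 91.67)
  expect_equal(round(100 * m2$sensitivity, 2), 86.67)
  expect_equal(round(100 * m2$specificity, 2), 96.67)

  # scores equal to labels: perfect regression diagnostics
  mp <- panel_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(mp$mse, 0)
  expect_equal(mp$mae, 0)
  expect_equal(mp$cc, 1)

  # accuracy + error = 1 and counts sum to N on random panels
  set.seed(5)
  for (k in 1:10) {
    t <- rbinom(40, 1, 0.5); s <- runif(40)
    mm <- panel_metrics(t, s)
    expect_equal(mm$accuracy + mm$error, 1)
    expect_equal(mm$tp + mm$fn + mm$tn + mm$fp, 40L)
    expect_equal(mm$rmse, sqrt(mm$mse))
  }

  # zero-variance labels leave CC undefined
  expect_true(is.na(panel_metrics(c(1, 1, 1), c(0.2, 0.6, 0.9))$cc))
})

test_that("ROC curves integrate to the Mann-Whitney AUC identity", {
  set.seed(12)
  for (k in 1:10) {
    labels <- rbinom(60, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(60), 1)  # ties on purpose
    r <- roc_curve(scores, labels)
    u <- mann_whitney(scores[labels == 1], scores[labels == 0])$statistic
    expect_equal(attr(r, "auc"),
                 u / (sum(labels == 1) * sum(labels == 0)),
                 tolerance = 1e-10)
    # negating scores mirrors the curve
    r_neg <- roc_curve(-scores, labels)
    expect_equal(attr(r_neg, "auc"), 1 - attr(r, "auc"), tolerance = 1e-10)
  }
  # perfect separation
  expect_equal(attr(roc_curve(c(3, 4, 5, 0, 1, 2),
                              c(1, 1, 1, 0, 0, 0)), "auc"), 1)
  expect_error(roc_curve(1:5, rep(1, 5)), class = "gepdx_parameter_error")
  r <- roc_curve(c(3, 4, 1, 2), c(1, 1, 0, 0))
  expect_s3_class(autoplot(r), "ggplot")
  expect_equal(glance(r)$auc, 1)
  expect_identical(names(tidy(r)), c("threshold", "fpr", "tpr"))
})

test_that("ROC orientation is preserved for markers lower in cases", {
  co <- generate_cohort(cohort_spec(n_sclc = 400, n_nsclc = 0,
                                    n_control = 400), seed = 9)
  lab <- gepdx:::label_cases(co, "SCLC", "CONTROL")
  auc_na <- attr(roc_curve(lab$na, lab$class), "auc")
  auc_nse <- attr(roc_curve(lab$nse, lab$class), "auc")
  expect_lt(auc_na, 0.5)   # sodium depressed in cases
  expect_gt(auc_nse, 0.5)  # NSE elevated in cases
})

test_that("experiments compose split, scoring and metrics", {
  co <- generate_cohort(cohort_spec(n_sclc = 60, n_nsclc = 0,
                                    n_control = 60), seed = 6)
  rep <- run_experiment(co, model = "published1", seed = 2)
  expect_setequal(rep$set, c("train", "test"))
  expect_equal(rep$n[rep$set == "train"], 96)
  expect_equal(rep$n[rep$set == "test"], 24)

  # report equals panel_metrics on the same fixed predictions
  lab <- gepdx:::label_cases(co, "SCLC", "CONTROL")
  sp <- split_cohort(lab, "class", 0.8, seed = gepdx:::derive_seed(2, 301L))
  manual <- panel_metrics(sp$train$class,
                          score_published(sp$train, 1)$score)
  expect_equal(rep[rep$set == "train",
                   names(manual)], manual)

  # triplicate: three reports, best-by-training-accuracy flagged once
  rep3 <- run_experiment(co, model = "published2", seed = 2, replicates = 3)
  expect_equal(nrow(rep3), 6)
  expect_equal(sum(rep3$best[rep3$set == "train"]), 1)
  best_rep <- unique(rep3$replicate[rep3$best])
  train_rows <- rep3[rep3$set == "train", ]
  expect_equal(train_rows$accuracy[train_rows$replicate == best_rep],
               max(train_rows$accuracy))
})

test_that("stage-stratified experiments reproduce the sub-cohort sizes", {
  co <- generate_cohort(cohort_spec(), seed = 13)
  # emulate the limited-stage comparison: cases with LIMITED stage vs a
  # seeded subsample of 74 controls
  n_lim <- sum(co$stage == "LIMITED", na.rm = TRUE)
  rep <- run_experiment(co, model = "published1", stage = "LIMITED",
                        n_negative = 74, seed = 3)
  expect_equal(rep$n[rep$set == "train"] + rep$n[rep$set == "test"],
               n_lim + 74)
  expect_equal(rep$n[rep$set == "train"],
               round(0.8 * n_lim) + round(0.8 * 74))
})
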