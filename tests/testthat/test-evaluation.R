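test_that("LOSO folds hold out one super-trial for every subject", {
  ds <- toy_windows(n_subjects = 8, trials = 5, per_trial = 2, W = 4, C = 2)
  plan <- loso_split(ds)
  expect_equal(plan$n_super_trials, 5)
  all_test <- integer(0)
  for (f in plan$folds) {
    held <- ds$meta[f$test, ]
    expect_setequal(unique(held$trial), f$trial)
    # every subject contributes to the held-out super-trial
    expect_setequal(unique(held$subject), unique(ds$meta$subject))
    expect_length(f$test, 8 * 2)
    expect_setequal(c(f$test, f$train), seq_len(nrow(ds$meta)))
    all_test <- c(all_test, f$test)
  }
  # partition: jointly exhaustive, pairwise disjoint
  expect_setequal(all_test, seq_len(nrow(ds$meta)))
  expect_equal(anyDuplicated(all_test), 0)

  # T = 2, 2 subjects: folds enumerate exactly as expected
  ds2 <- toy_windows(n_subjects = 2, trials = 2, per_trial = 1, W = 4, C = 2)
  plan2 <- loso_split(ds2)
  expect_equal(lapply(plan2$folds, `[[`, "test"), list(c(1L, 3L), c(2L, 4L)))

  # ragged trials are refused (drop one subject's whole first trial)
  ds3 <- ds
  drop <- which(ds3$meta$subject == "S01" & ds3$meta$trial == 1)
  ds3$meta <- ds3$meta[-drop, ]
  ds3$x <- ds3$x[-drop, , , drop = FALSE]
  expect_error(loso_split(ds3), "ragged")
})

test_that("expert recall follows its definition, including the undefined case", {
  lv <- c("novice", "expert")
  cm <- confusion_matrix(rep(c("expert", "novice"), c(10, 5)),
                         c(rep("expert", 9), "novice", rep("novice", 5)), lv)
  expect_equal(expert_recall(cm), 0.9)
  cm0 <- confusion_matrix(rep("expert", 4), rep("novice", 4), lv)
  expect_equal(expert_recall(cm0), 0)
  cm1 <- confusion_matrix(rep("expert", 4), rep("expert", 4), lv)
  expect_equal(expert_recall(cm1), 1)
  none <- confusion_matrix(rep("novice", 4), rep("novice", 4), lv)
  expect_true(is.na(expert_recall(none)))  # missing, not zero
})

test_that("confusion-matrix accuracy equals the direct label comparison", {
  set.seed(8)
  lv <- c("novice", "intermediate", "expert")
  for (i in 1:10) {
    truth <- sample(lv, 30, replace = TRUE)
    pred <- sample(lv, 30, replace = TRUE)
    expect_equal(cm_accuracy(confusion_matrix(truth, pred, lv)),
                 mean(truth == pred))
  }
})

test_that("zero true/false positive census counts degenerate matrices", {
  lv <- c("novice", "expert")
  perfect <- confusion_matrix(rep(lv, 5), rep(lv, 5), lv)
  no_expert_pred <- confusion_matrix(rep(lv, 5), rep("novice", 10), lv)
  cms <- list(perfect, perfect, no_expert_pred)
  cen <- zero_tp_census(cms)
  expect_equal(cen$zero_tp[cen$class == "expert"], 1)
  expect_equal(cen$zero_tp[cen$class == "novice"], 0)
  # a perfect matrix has zero false positives everywhere
  expect_equal(cen$zero_fp[cen$class == "expert"], 3)  # incl. no_expert_pred
  expect_equal(cen$zero_fp[cen$class == "novice"], 2)
  expect_true(all(cen$zero_tp <= cen$n_matrices))
  expect_error(zero_tp_census(list()), "no confusion")
})

test_that("the 5x5 protocol books 25 accuracies and summarises per definition", {
  ds <- toy_windows(n_subjects = 4, trials = 5, per_trial = 2, W = 16, C = 8, seed = 12)
  pr <- run_protocol(ds, stub_oracle(), n_runs = 5, base_seed = 0)
  expect_equal(nrow(pr$accuracies), 25)
  expect_length(pr$confusions, 25)
  g <- glance(pr)
  expect_equal(g$mean, 100)
  expect_equal(g$best_run, 100)
  expect_equal(g$best_trial, 100)
  expect_equal(g$sd, 0)

  # majority stub on an imbalanced dataset: per-fold accuracy equals the
  # fold's majority share
  ds2 <- toy_windows(n_subjects = 4, trials = 3, per_trial = 1, W = 4, C = 2,
                     seed = 13,
                     sd_by_class = c(novice = 1, novice2 = 1, expert = 1))
  ds2$meta$skill[ds2$meta$skill == "novice2"] <- "novice"  # 3:1 imbalance
  pr2 <- run_protocol(ds2, stub_constant("novice"), n_runs = 2, base_seed = 0)
  share <- vapply(loso_split(ds2)$folds, function(f) {
    100 * mean(ds2$meta$skill[f$test] == "novice")
  }, numeric(1))
  expect_equal(pr2$accuracies$accuracy, rep(share, 2))
  # hand-computed summary statistics
  expect_equal(glance(pr2)$mean, mean(share))
  expect_equal(glance(pr2)$best_run, mean(share))
  expect_equal(glance(pr2)$best_trial, max(share))
  expect_equal(glance(pr2)$sd, 0)

  # result_table mirrors the per-protocol summaries
  tbl <- result_table(list(pr, pr2))
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$mean, c(100, mean(share)))
})

test_that("protocol results are reproducible and tidy/autoplot work", {
  ds <- toy_windows(n_subjects = 4, trials = 2, per_trial = 2, W = 8, C = 4, seed = 14)
  cfg <- classifier_config(n_peaks = 3L)
  a <- run_protocol(ds, "dft", head = "svm", n_runs = 2, base_seed = 5, config = cfg)
  b <- run_protocol(ds, "dft", head = "svm", n_runs = 2, base_seed = 5, config = cfg)
  expect_identical(tidy(a), tidy(b))
  expect_s3_class(tidy(a), "tbl_df")
  expect_named(glance(a),
               c("parameters", "method", "evaluation", "mean", "sd",
                 "best_run", "best_trial"))
  expect_s3_class(autoplot(a), "ggplot")
})

test_that("a failing method aborts its run but leaves other runs intact", {
  ds <- toy_windows(n_subjects = 4, trials = 2, per_trial = 1, W = 4, C = 2, seed = 15)
  flaky_env <- new.env()
  flaky_env$calls <- 0L
  flaky <- skill_method(
    fit = function(x, y, seed) {
      flaky_env$calls <- flaky_env$calls + 1L
      if (seed == 1) stop("synthetic training failure")
      1.5
    },
    predict = function(model, x) ifelse(apply(x, 1, mean) > model, "expert", "novice"),
    id = "flaky")
  pr <- run_protocol(ds, flaky, n_runs = 2, base_seed = 0)
  expect_equal(nrow(pr$failures), 1)
  expect_match(pr$failures$message, "synthetic training failure")
  expect_equal(unique(pr$accuracies$run), 2L)
  expect_equal(nrow(pr$accuracies), 2)
})
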