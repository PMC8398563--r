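# Leave-one-super-trial-out cross-validation, the 5-runs x 5-folds
# protocol, confusion-matrix accounting, expert recall, and the summary
# statistics (Mean / SD / Best run / Best trial) reported per method.

#' Leave-one-super-trial-out fold plan
#'
#' Fold `i` holds out super-trial `i`: all samples from trial repetition
#' `i` of every subject form the test set, everything else trains. Every
#' subject therefore appears in both the training and the test side of
#' every fold — it is the repetition, not the subject, that is held out.
#' Requires every subject to have the same number of trials.
#'
#' @param dataset An `sf_windows` dataset.
#' @return An `sf_folds` list: `n_super_trials`, `folds` (per fold:
#'   `trial`, `test` and `train` sample indices).
#' @export
loso_split <- function(dataset) {
  meta <- dataset$meta
  per_subj <- tapply(meta$trial, meta$subject, function(t) sort(unique(t)))
  trials <- per_subj[[1]]
  same <- all(vapply(per_subj, function(t) identical(t, trials), logical(1)))
  if (!same) {
    stop("ragged trial counts across subjects; every subject needs the same ",
         "super-trials for LOSO")
  }
  folds <- lapply(trials, function(tr) {
    test <- which(meta$trial == tr)
    list(trial = tr, test = test, train = setdiff(seq_len(nrow(meta)), test))
  })
  structure(list(n_super_trials = length(trials), folds = folds),
            class = "sf_folds")
}

#' @export
print.sf_folds <- function(x, ...) {
  cat("<sf_folds> ", x$n_super_trials, " leave-one-super-trial-out folds\n", sep = "")
  invisible(x)
}

#' Confusion matrix with fixed class levels
#'
#' @param truth,pred Label vectors.
#' @param levels Class levels fixing row/column order.
#' @return A square `table` (rows = truth, columns = predicted).
#' @export
confusion_matrix <- function(truth, pred, levels) {
  table(truth = factor(truth, levels = levels),
        pred = factor(pred, levels = levels))
}

#' Accuracy from a confusion matrix
#'
#' @param cm Square confusion matrix (truth x predicted).
#' @return Fraction of correctly classified samples (trace / total).
#' @export
cm_accuracy <- function(cm) {
  sum(diag(cm)) / sum(cm)
}

#' Expert recall of one test fold
#'
#' `ExpertTruePositive / NumOfExpertsInTrial`: the fraction of true
#' experts in the fold that were classified as experts. Undefined when the
#' fold contains no experts — reported as `NA`, never as 0.
#'
#' @param cm Confusion matrix (truth x predicted) whose dimnames contain
#'   `expert_label`.
#' @param expert_label Name of the expert class.
#' @return A fraction in `[0, 1]`, or `NA_real_` with zero experts.
#' @export
expert_recall <- function(cm, expert_label = "expert") {
  if (!expert_label %in% rownames(cm)) return(NA_real_)
  n_expert <- sum(cm[expert_label, ])
  if (n_expert == 0) return(NA_real_)
  cm[expert_label, expert_label] / n_expert
}

#' Census of degenerate confusion matrices
#'
#' Counts, per class, how many confusion matrices show zero true
#' positives (the class was never correctly recognised) and how many show
#' zero false positives (nothing was wrongly assigned to the class) — the
#' reliability bookkeeping used to vet accuracy summaries.
#'
#' @param matrices Non-empty list of same-shaped confusion matrices.
#' @return Tibble: `class`, `zero_tp`, `zero_fp`, `n_matrices`.
#' @export
zero_tp_census <- function(matrices) {
  if (length(matrices) == 0) stop("no confusion matrices given")
  classes <- rownames(matrices[[1]])
  purrr::map_dfr(classes, function(cl) {
    tp <- vapply(matrices, function(cm) cm[cl, cl], numeric(1))
    fp <- vapply(matrices, function(cm) sum(cm[, cl]) - cm[cl, cl], numeric(1))
    tibble::tibble(class = cl, zero_tp = sum(tp == 0), zero_fp = sum(fp == 0),
                   n_matrices = length(matrices))
  })
}

#' Majority-class baseline accuracy
#'
#' @param labels Vector of labels.
#' @return Largest class share, as a fraction.
#' @export
majority_baseline <- function(labels) {
  max(table(labels)) / length(labels)
}

#' Wrap fit/predict functions as a protocol method
#'
#' Lets [run_protocol()] evaluate an arbitrary classifier (e.g. a stub
#' with known behaviour, for verifying the protocol bookkeeping).
#'
#' @param fit `function(x, y, seed)` returning a model object.
#' @param predict `function(model, x)` returning labels.
#' @param id Method name used in result tables.
#' @return An `sf_method` object.
#' @export
skill_method <- function(fit, predict, id = "custom") {
  structure(list(fit = fit, predict = predict, id = id), class = "sf_method")
}

#' Run the repeated LOSO evaluation protocol
#'
#' The full benchmark protocol for one method: `n_runs` independent runs
#' (run `r` seeds all of its training with `base_seed + r`), each run
#' cross-validating over all super-trial folds. For every (run, fold)
#' pair the classifier is trained on the training folds, test-fold
#' accuracy is recorded, and the full confusion matrix is kept. The
#' summary follows the benchmark's table columns: `mean` is the average
#' of the per-run mean accuracies, `sd` is taken over the same per-run
#' means, `best_run` is the highest per-run mean, and `best_trial` the
#' single highest fold accuracy. Accuracies are percentages on
#' `[0, 100]`. A training failure aborts that run and is recorded in
#' `$failures`; completed runs still summarise.
#'
#' @param dataset An `sf_windows` dataset.
#' @param method Architecture name (see [build_classifier()]) or an
#'   [skill_method()] object.
#' @param head `"model"` (softmax) or `"svm"` (penultimate-feature SVM);
#'   autoencoder and DFT/DCT always use their SVM head.
#' @param n_runs Number of repeated runs (benchmark default 5).
#' @param base_seed Base seed; run `r` uses `base_seed + r`.
#' @param config [classifier_config()] hyperparameters.
#' @param epochs Optional override of `config$epochs` (e.g. reduced
#'   training for quick evaluations).
#' @param aggregate `"window"` scores every window independently
#'   (default); `"trial"` majority-votes windows per (subject, trial)
#'   before scoring.
#' @param center_positions Center absolute-position channels per window at
#'   training/prediction time (translation invariance; default `TRUE`).
#'   Channels are identified from the dataset's feature names via
#'   [position_mask()]; layouts without position columns are unaffected.
#' @return An `sf_protocol` object; see [tidy.sf_protocol()],
#'   [glance.sf_protocol()], [result_table()].
#' @export
run_protocol <- function(dataset, method, head = c("model", "svm"),
                         n_runs = 5L, base_seed = 0L,
                         config = classifier_config(), epochs = NULL,
                         aggregate = c("window", "trial"),
                         center_positions = TRUE) {
  head <- match.arg(head)
  aggregate <- match.arg(aggregate)
  center <- if (center_positions && !is.null(dataset$feature_names)) {
    position_mask(dataset$feature_names)
  } else {
    NULL
  }
  plan <- loso_split(dataset)
  levels <- skill_levels_of(dataset)
  input_shape <- dim(dataset$x)[2:3]
  n_classes <- length(levels)
  accs <- list()
  cms <- list()
  recalls <- list()
  failures <- list()
  for (r in seq_len(n_runs)) {
    seed_r <- base_seed + r
    run_ok <- TRUE
    run_rows <- list()
    run_cms <- list()
    for (f in seq_along(plan$folds)) {
      fold <- plan$folds[[f]]
      x_tr <- dataset$x[fold$train, , , drop = FALSE]
      y_tr <- dataset$meta$skill[fold$train]
      x_te <- dataset$x[fold$test, , , drop = FALSE]
      y_te <- dataset$meta$skill[fold$test]
      pred <- tryCatch({
        if (inherits(method, "sf_method")) {
          model <- method$fit(x_tr, y_tr, seed_r)
          method$predict(model, x_te)
        } else {
          clf <- build_classifier(method, input_shape, n_classes,
                                  config = config, seed = seed_r)
          clf <- fit(clf, x_tr, y_tr, seed = seed_r, epochs = epochs,
                     center = center)
          predict(clf, x_te, head = head)
        }
      }, error = function(e) e)
      if (inherits(pred, "error")) {
        failures[[length(failures) + 1L]] <- tibble::tibble(
          run = r, trial = fold$trial, message = conditionMessage(pred))
        run_ok <- FALSE
        break
      }
      if (aggregate == "trial") {
        key <- paste(dataset$meta$subject[fold$test], dataset$meta$trial[fold$test])
        vote <- tapply(as.character(pred), key, function(p) names(which.max(table(p))))
        truth <- tapply(y_te, key, function(s) s[1])
        pred <- vote[names(truth)]
        y_te <- truth
      }
      cm <- confusion_matrix(y_te, pred, levels)
      run_rows[[f]] <- tibble::tibble(run = r, trial = fold$trial,
                                      accuracy = 100 * cm_accuracy(cm),
                                      expert_recall = expert_recall(cm))
      run_cms[[f]] <- cm
    }
    if (run_ok) {
      accs <- c(accs, run_rows)
      cms <- c(cms, run_cms)
    }
  }
  acc_tbl <- dplyr::bind_rows(accs)
  method_id <- if (inherits(method, "sf_method")) method$id else method
  structure(list(
    accuracies = acc_tbl,
    confusions = cms,
    failures = dplyr::bind_rows(failures),
    method = method_id, head = head,
    window = dataset$window, step = dataset$step,
    class_mode = dataset$class_mode,
    n_runs = n_runs, n_folds = plan$n_super_trials,
    base_seed = base_seed),
    class = "sf_protocol")
}

protocol_summary <- function(x) {
  if (nrow(x$accuracies) == 0) {
    return(tibble::tibble(parameters = paste0(x$window, "x", x$step),
                          method = x$method, evaluation = x$head,
                          mean = NA_real_, sd = NA_real_,
                          best_run = NA_real_, best_trial = NA_real_))
  }
  per_run <- dplyr::summarise(dplyr::group_by(x$accuracies, .data$run),
                              run_mean = mean(.data$accuracy), .groups = "drop")
  tibble::tibble(
    parameters = paste0(x$window, "x", x$step),
    method = x$method,
    evaluation = if (x$head == "model") "Model" else "SVM",
    mean = mean(per_run$run_mean),
    sd = stats::sd(per_run$run_mean),
    best_run = max(per_run$run_mean),
    best_trial = max(x$accuracies$accuracy))
}

#' @describeIn run_protocol Per-(run, fold) accuracies and expert recall.
#' @param x An `sf_protocol`.
#' @param ... Unused.
#' @method tidy sf_protocol
#' @export
tidy.sf_protocol <- function(x, ...) x$accuracies

#' @describeIn run_protocol One-row summary: mean, sd, best run, best trial.
#' @method glance sf_protocol
#' @export
glance.sf_protocol <- function(x, ...) protocol_summary(x)

#' @export
print.sf_protocol <- function(x, ...) {
  cat("<sf_protocol> ", x$method, " (", x$head, " head), ",
      x$n_runs, " runs x ", x$n_folds, " folds\n", sep = "")
  print(as.data.frame(protocol_summary(x)))
  if (nrow(x$failures) > 0) cat(nrow(x$failures), "run failure(s) recorded\n")
  invisible(x)
}

#' Benchmark result table across methods
#'
#' Stacks the one-row summaries of several protocol results into the
#' standard report: Parameters (window x step), Evaluation (Model/SVM),
#' Mean, Standard Deviation, Best run, Best trial.
#'
#' @param protocols List of `sf_protocol` objects.
#' @return A tibble, one row per protocol.
#' @export
result_table <- function(protocols) {
  dplyr::bind_rows(lapply(protocols, protocol_summary))
}

#' Box plot of protocol accuracies
#'
#' @param object An `sf_protocol`.
#' @param ... Unused.
#' @return A ggplot: per-fold accuracies grouped by run.
#' @method autoplot sf_protocol
#' @export
autoplot.sf_protocol <- function(object, ...) {
  d <- object$accuracies
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$run), y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$trial))) +
    ggplot2::labs(x = "run", y = "accuracy (%)", colour = "held-out trial",
                  title = paste0(object$method, " (", object$head, " head)")) +
    ggplot2::ylim(0, 100)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
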