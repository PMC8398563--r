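# Sliding-window preprocessing: cut each video's feature matrix into
# uniformly sized W x 240 samples, keyed by (subject, task, trial, skill)
# so super-trial cross-validation folds stay well defined. Windows never
# mix rows from two videos; trailing rows not covered by a full window are
# discarded (uniform size is required downstream).

#' Slide a fixed window over a feature matrix
#'
#' Windows start at rows `0, step, 2*step, ...` (0-based), each `window`
#' rows long; the count is `floor((L - window) / step) + 1` for `L` input
#' rows. Overlapping windows arise when `step < window`.
#'
#' @param m Feature matrix (or tibble/data.frame) with `L >= window` rows.
#' @param window Window size W in rows (frames).
#' @param step Step size S in rows (>= 1).
#' @return List of `window x ncol(m)` numeric matrices.
#' @examples
#' length(slide(matrix(0, 100, 4), window = 60, step = 20))  # 3
#' @export
slide <- function(m, window, step) {
  m <- as.matrix(m)
  L <- nrow(m)
  if (window < 1 || step < 1) stop("window and step must be at least 1")
  if (L < window) {
    stop("matrix has L = ", L, " rows, fewer than the window size W = ", window)
  }
  n_win <- (L - window) %/% step + 1L
  lapply(seq_len(n_win), function(i) {
    m[(i - 1L) * step + seq_len(window), , drop = FALSE]
  })
}

#' Assemble labelled window datasets from a cohort's feature matrices
#'
#' Applies [slide()] per video and groups samples by task: the result is
#' one dataset per task, each sample carrying its source subject, trial
#' and skill. In `"two_class"` mode all trials of intermediate subjects
#' are dropped before windowing, leaving only novice and expert labels
#' (the intermediate class is the one most prone to misclassification and
#' is excluded from the main evaluation); `"three_class"` keeps all
#' three.
#'
#' @param manifest Tibble with columns `subject`, `task`, `trial`,
#'   `skill` (one row per video), as produced by [generate_cohort()].
#' @param features Named list of feature matrices (names =
#'   `subject_task_trial` keys from [video_key()]), or a directory of
#'   per-video CSV files named `<key>.csv`.
#' @param window,step Sliding-window parameters W and S.
#' @param class_mode `"three_class"` or `"two_class"`.
#' @return Named list (one element per task) of `sf_windows` objects:
#'   `x` (`N x W x C` array), `meta` (tibble: subject, task, trial,
#'   skill, window index), `window`, `step`, `class_mode`.
#' @export
assemble_windows <- function(manifest, features, window, step,
                             class_mode = c("three_class", "two_class")) {
  class_mode <- match.arg(class_mode)
  if (anyNA(manifest$skill)) {
    bad <- unique(manifest$subject[is.na(manifest$skill)])
    stop("skill label missing for subject(s): ", paste(bad, collapse = ", "))
  }
  if (class_mode == "two_class") {
    manifest <- dplyr::filter(manifest, .data$skill != "intermediate")
  }
  get_feat <- function(key) {
    if (is.character(features)) {
      path <- file.path(features, paste0(key, ".csv"))
      if (!file.exists(path)) stop("no feature file for video ", key, ": ", path)
      as.matrix(utils::read.csv(path, check.names = FALSE))
    } else {
      if (is.null(features[[key]])) stop("no feature matrix for video ", key)
      as.matrix(features[[key]])
    }
  }
  out <- list()
  for (task in unique(manifest$task)) {
    rows <- manifest[manifest$task == task, ]
    samples <- list()
    meta <- list()
    for (i in seq_len(nrow(rows))) {
      key <- video_key(rows$subject[i], rows$task[i], rows$trial[i])
      wins <- slide(get_feat(key), window, step)
      for (j in seq_along(wins)) {
        samples[[length(samples) + 1L]] <- wins[[j]]
        meta[[length(meta) + 1L]] <- tibble::tibble(
          subject = rows$subject[i], task = task, trial = rows$trial[i],
          skill = rows$skill[i], window_index = j)
      }
    }
    cc <- ncol(samples[[1]])
    x <- array(0, c(length(samples), window, cc))
    for (s in seq_along(samples)) x[s, , ] <- samples[[s]]
    out[[task]] <- structure(
      list(x = x, meta = dplyr::bind_rows(meta),
           window = as.integer(window), step = as.integer(step),
           class_mode = class_mode,
           feature_names = colnames(samples[[1]])),
      class = "sf_windows")
  }
  out
}

#' Key identifying one video of a cohort
#'
#' @param subject,task,trial Manifest fields.
#' @return Character key `subject_task_T<trial>`.
#' @export
video_key <- function(subject, task, trial) {
  sprintf("%s_%s_T%02d", subject, task, trial)
}

#' @export
print.sf_windows <- function(x, ...) {
  cat("<sf_windows> ", dim(x$x)[1], " samples of ", x$window, "x", dim(x$x)[3],
      " (step ", x$step, ", ", x$class_mode, ")\n", sep = "")
  print(table(skill = x$meta$skill))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Window metadata as a tibble
#'
#' @param x An `sf_windows` dataset.
#' @param ... Unused.
#' @return The per-sample metadata tibble.
#' @method tidy sf_windows
#' @export
tidy.sf_windows <- function(x, ...) x$meta

skill_levels_of <- function(ds) {
  lv <- c("novice", "intermediate", "expert")
  present <- lv[lv %in% unique(ds$meta$skill)]
  if (length(present) == 0) unique(ds$meta$skill) else present
}
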