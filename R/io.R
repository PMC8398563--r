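# Disk formats: videos as PNG frame directories, feature matrices as CSV
# with a JSON parameter sidecar, manifests as CSV. All pixel coordinates
# on disk are 0-based; ROIs are half-open [x, x+w) x [y, y+h).

#' Write / read a video as a PNG frame directory
#'
#' Frames are stored as `frame_000001.png`, ... so a directory listing
#' sorts in time order.
#'
#' @param frames `height x width x n` array in `[0, 1]`.
#' @param dir Directory (created if missing).
#' @return `write_frames()` the directory path, invisibly;
#'   `read_frames()` a list of grayscale matrices.
#' @export
write_frames <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_len(dim(frames)[3])) {
    png::writePNG(frames[, , t], file.path(dir, sprintf("frame_%06d.png", t)))
  }
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG frames found in ", dir)
  lapply(files, function(f) to_gray(png::readPNG(f)))
}

#' Write / read a feature matrix with its JSON sidecar
#'
#' The CSV holds the 240 named feature columns, one row per processed
#' frame; `<path>.json` records the start frame, per-frame lost-point
#' counts and the full extraction parameter block, so every output can be
#' traced to its configuration.
#'
#' @param features An `sf_features` tibble from [extract_features()].
#' @param path CSV output path.
#' @return `write_features()` the path, invisibly; `read_features()` the
#'   feature tibble with `start_frame`, `lost_log` and `params`
#'   attributes restored.
#' @export
write_features <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE, quote = FALSE)
  side <- list(start_frame = attr(features, "start_frame"),
               lost_log = attr(features, "lost_log"),
               params = attr(features, "params"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "start_frame") <- side$start_frame
    attr(out, "lost_log") <- tibble::as_tibble(side$lost_log)
    attr(out, "params") <- side$params
  }
  class(out) <- c("sf_features", class(out))
  out
}

#' Read a cohort manifest CSV
#'
#' @param path Path to `manifest.csv` (columns as written by
#'   [generate_cohort()]).
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE,
                                    stringsAsFactors = FALSE))
}

manifest_rois <- function(row) {
  list(left = roi("left", row$roi_left_x, row$roi_left_y, row$roi_left_w, row$roi_left_h),
       right = roi("right", row$roi_right_x, row$roi_right_y, row$roi_right_w, row$roi_right_h))
}
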