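# Data-generation stage: preprocess frames, seed corners with Shi-Tomasi
# inside the two tool ROIs, track them with pyramidal Lucas-Kanade sparse
# optical flow, and emit one 240-feature row per processed frame (positions
# and per-frame displacements of 30 sub-pixel points per tool).
#
# Conventions: grayscale frames are height x width matrices in [0, 1];
# pixel coordinates are 0-based, x rightward (columns), y downward (rows),
# sub-pixel floats. ROIs are half-open [x, x+w) x [y, y+h). Corner seeding
# runs on the binarised frame; tracking runs on the unmodified grayscale
# frames (the thresholding only serves detection).

#' Region of interest around one tool
#'
#' @param tool_id `"left"` or `"right"`.
#' @param x,y Top-left corner, 0-based px.
#' @param w,h Width and height in px (positive).
#' @return An `sf_roi` list.
#' @export
roi <- function(tool_id = c("left", "right"), x, y, w, h) {
  tool_id <- match.arg(tool_id)
  if (w <= 0 || h <= 0) stop("ROI width and height must be positive")
  structure(list(tool_id = tool_id, x = x, y = y, w = w, h = h), class = "sf_roi")
}

roi_in_frame <- function(r, dim_hw) {
  r$x >= 0 && r$y >= 0 && r$x + r$w <= dim_hw[2] && r$y + r$h <= dim_hw[1]
}

rois_disjoint <- function(a, b) {
  a$x + a$w <= b$x || b$x + b$w <= a$x || a$y + a$h <= b$y || b$y + b$h <= a$y
}

to_gray <- function(frame) {
  if (length(dim(frame)) == 3L) {
    0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
  } else {
    frame
  }
}

#' Preprocess a frame for corner detection
#'
#' Grayscale conversion, median blur (odd kernel) and adaptive
#' thresholding against the local mean — the denoising chain that makes
#' tool texture stand out for the corner detector. The output is a binary
#' single-channel image with values in `{0, 1}`.
#'
#' @param frame `height x width` matrix in `[0, 1]`, or an
#'   `height x width x 3` RGB array.
#' @param median_size Odd median-filter kernel size; `0` or `1` skips the
#'   blur.
#' @param block_size Odd side of the local-mean window of the adaptive
#'   threshold.
#' @param offset Threshold offset subtracted from the local mean.
#' @return Binary matrix of the same height/width, values 0 or 1.
#' @export
preprocess_frame <- function(frame, median_size = 5L, block_size = 11L, offset = 0.02) {
  if (length(frame) == 0 || any(dim(frame)[1:2] == 0)) stop("frame has zero size")
  g <- to_gray(frame)
  g <- pmin(pmax(g, 0), 1)
  if (median_size >= 3) {
    if (median_size %% 2 == 0) stop("median_size must be odd")
    g <- EBImage::medianFilter(g, size = (median_size - 1L) / 2L)
  }
  if (block_size %% 2 == 0) stop("block_size must be odd")
  half <- (block_size - 1L) / 2L
  b <- EBImage::thresh(g, w = half, h = half, offset = offset)
  b <- as.numeric(b > 0)
  b[is.na(b)] <- 0  # border pixels outside the local-mean window
  matrix(b, nrow(g), ncol(g))
}

# ---- Shi-Tomasi corner seeding ---------------------------------------------

# centered finite-difference gradients with replicated borders
image_gradients <- function(img) {
  h <- nrow(img); w <- ncol(img)
  xr <- img[, c(2:w, w)]; xl <- img[, c(1, 1:(w - 1))]
  yd <- img[c(2:h, h), ]; yu <- img[c(1, 1:(h - 1)), ]
  list(gx = (xr - xl) / 2, gy = (yd - yu) / 2)
}

# sliding box sum with half-width `half` via integral image
box_sum <- function(img, half) {
  h <- nrow(img); w <- ncol(img)
  padded <- matrix(0, h + 2 * half, w + 2 * half)
  padded[half + 1:h, half + 1:w] <- img
  ii <- apply(apply(padded, 2, cumsum), 1, cumsum)  # transposed integral
  ii <- t(ii)
  ii <- rbind(0, cbind(0, ii))
  k <- 2 * half + 1
  r1 <- 1:h; c1 <- 1:w
  ii[r1 + k, c1 + k] - ii[r1, c1 + k] - ii[r1 + k, c1] + ii[r1, c1]
}

# min-eigenvalue score of the 2x2 gradient structure tensor, summed over a
# (2*half+1)^2 window
shi_tomasi_score <- function(img, half = 1L) {
  gr <- image_gradients(img)
  sxx <- box_sum(gr$gx * gr$gx, half)
  syy <- box_sum(gr$gy * gr$gy, half)
  sxy <- box_sum(gr$gx * gr$gy, half)
  ((sxx + syy) - sqrt((sxx - syy)^2 + 4 * sxy^2)) / 2
}

#' Seed trackable corners inside an ROI
#'
#' Shi-Tomasi "good features to track": corners are ranked by the
#' minimum eigenvalue of the local gradient structure tensor, thresholded
#' at `quality` times the strongest score in the ROI, and thinned by a
#' greedy minimum-distance suppression in score order. The pipeline
#' requires a full point budget, so finding fewer than `n_points`
#' acceptable corners is an error naming the shortfall.
#'
#' @param binary_frame Preprocessed frame from [preprocess_frame()] (any
#'   single-channel image works).
#' @param roi An [roi()] fully inside the frame.
#' @param n_points Number of corners to return (default 30 per tool).
#' @param min_distance Minimum Euclidean distance between kept corners, px.
#' @param quality Quality level relative to the best ROI score.
#' @return An `sf_points` list: `tool_id`, `coords` (`n_points x 2`,
#'   0-based px), `status` (all `TRUE` at seeding).
#' @export
detect_initial_points <- function(binary_frame, roi, n_points = 30L,
                                  min_distance = 3, quality = 0.02) {
  if (n_points < 1) stop("n_points must be at least 1")
  if (!roi_in_frame(roi, dim(binary_frame))) stop("ROI lies outside the frame")
  score <- shi_tomasi_score(binary_frame)
  # candidate pixels strictly inside the half-open ROI
  xs <- roi$x:(roi$x + roi$w - 1L)
  ys <- roi$y:(roi$y + roi$h - 1L)
  sub <- score[ys + 1L, xs + 1L, drop = FALSE]
  smax <- max(sub)
  if (smax <= 0) {
    stop("no corners detectable in ROI '", roi$tool_id, "' (0 of ", n_points, " required)")
  }
  cand <- which(sub >= quality * smax, arr.ind = TRUE)
  ord <- order(sub[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  px <- xs[cand[, 2]]
  py <- ys[cand[, 1]]
  keep_x <- numeric(0)
  keep_y <- numeric(0)
  md2 <- min_distance^2
  for (i in seq_along(px)) {
    if (length(keep_x) == 0 ||
        min((keep_x - px[i])^2 + (keep_y - py[i])^2) >= md2) {
      keep_x <- c(keep_x, px[i])
      keep_y <- c(keep_y, py[i])
      if (length(keep_x) == n_points) break
    }
  }
  if (length(keep_x) < n_points) {
    stop("only ", length(keep_x), " of ", n_points,
         " corners detectable in ROI '", roi$tool_id, "'")
  }
  structure(list(tool_id = roi$tool_id,
                 coords = cbind(x = keep_x, y = keep_y),
                 status = rep(TRUE, n_points)),
            class = "sf_points")
}

# ---- pyramidal Lucas-Kanade -------------------------------------------------

#' Lucas-Kanade tracker parameters
#'
#' Standard pyramidal settings: `levels` pyramid levels (downsampled by 2
#' each), a `window x window` integration window, and per-level iteration
#' until the update falls below `eps` or `max_iter` is reached.
#'
#' @param levels,window,max_iter,eps,min_det Tracker settings; `min_det`
#'   is the determinant floor below which the normal matrix is considered
#'   singular and the point lost.
#' @return An `lk_params` list.
#' @export
lk_params <- function(levels = 3L, window = 15L, max_iter = 10L, eps = 0.03,
                      min_det = 1e-7) {
  if (window %% 2 == 0) stop("window must be odd")
  structure(list(levels = as.integer(levels), window = as.integer(window),
                 max_iter = as.integer(max_iter), eps = eps, min_det = min_det),
            class = "lk_params")
}

# 2x downsample by 2x2 block average
pyr_down <- function(img) {
  h2 <- nrow(img) %/% 2L
  w2 <- ncol(img) %/% 2L
  a <- img[seq_len(2L * h2), seq_len(2L * w2)]
  (a[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2)] + a[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2)] +
     a[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2)] + a[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2)]) / 4
}

build_pyramid <- function(img, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- img
  for (l in seq_len(levels - 1L)) {
    if (min(dim(pyr[[l]])) < 16) {
      pyr <- pyr[seq_len(l)]
      break
    }
    pyr[[l + 1L]] <- pyr_down(pyr[[l]])
  }
  pyr
}

# bilinear sampling at 0-based coords: index/weight preparation shared
# between several images of the same size
bil_prep <- function(h, w, x, y) {
  x <- pmin(pmax(x, 0), w - 1 - 1e-9)
  y <- pmin(pmax(y, 0), h - 1 - 1e-9)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  list(i00 = (y0 + 1) + x0 * h, h = h,
       w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy),
       w01 = (1 - fx) * fy, w11 = fx * fy)
}

bil_apply <- function(img, p) {
  p$w00 * img[p$i00] + p$w10 * img[p$i00 + p$h] +
    p$w01 * img[p$i00 + 1] + p$w11 * img[p$i00 + p$h + 1]
}

bilinear <- function(img, x, y) {
  bil_apply(img, bil_prep(nrow(img), ncol(img), x, y))
}

# pyramid with per-level gradients, reusable across consecutive frame pairs
lk_pyramid <- function(img, levels) {
  pyr <- build_pyramid(img, levels)
  lapply(pyr, function(im) c(list(im = im), image_gradients(im)))
}

#' Track points between two frames (pyramidal Lucas-Kanade)
#'
#' Estimates, for each point, the sub-pixel displacement solving the
#' optical-flow constraint `Ix vx + Iy vy + It = 0` over a local window
#' (brightness constancy + local motion constancy), refined coarse to
#' fine over an image pyramid with Newton iterations per level. Points
#' whose normal matrix is (near) singular or whose new position leaves
#' the frame are flagged lost; lost points keep their previous position
#' and report zero displacement.
#'
#' @param prev_gray,next_gray Same-shape grayscale frames.
#' @param points An `sf_points` set (from [detect_initial_points()] or a
#'   previous `track_step()`).
#' @param params [lk_params()].
#' @return A list: `points` (updated `sf_points`, `status` FALSE where
#'   lost) and `displacement` (`n x 2`, exactly `new - old` per tracked
#'   point, zero for lost points).
#' @export
track_step <- function(prev_gray, next_gray, points, params = lk_params()) {
  if (!identical(dim(prev_gray), dim(next_gray))) {
    stop("prev and next frames have different shapes: ",
         paste(dim(prev_gray), collapse = "x"), " vs ",
         paste(dim(next_gray), collapse = "x"))
  }
  track_lk(lk_pyramid(prev_gray, params$levels),
           lk_pyramid(next_gray, params$levels),
           points, params, dim(prev_gray))
}

# core tracker on precomputed pyramids (lk_pyramid); extract_features reuses
# each frame's pyramid for two consecutive steps
track_lk <- function(pyr_a, pyr_b, points, params, dim_hw) {
  old <- points$coords
  n <- nrow(old)
  hw <- (params$window - 1L) / 2L
  lv <- min(length(pyr_a), length(pyr_b))
  offs <- expand.grid(dx = -hw:hw, dy = -hw:hw)
  g <- matrix(0, n, 2)  # accumulated guess, in the current level's units
  lost <- !points$status
  for (l in rev(seq_len(lv))) {
    A <- pyr_a[[l]]
    B <- pyr_b[[l]]$im
    hA <- nrow(A$im); wA <- ncol(A$im)
    scale <- 2^(l - 1)
    X <- outer(old[, 1] / scale, offs$dx, "+")
    Y <- outer(old[, 2] / scale, offs$dy, "+")
    bp <- bil_prep(hA, wA, X, Y)
    Iw <- bil_apply(A$im, bp)
    Ix <- bil_apply(A$gx, bp)
    Iy <- bil_apply(A$gy, bp)
    gxx <- rowSums(Ix * Ix)
    gxy <- rowSums(Ix * Iy)
    gyy <- rowSums(Iy * Iy)
    det <- gxx * gyy - gxy * gxy
    sing <- det < params$min_det
    # a singular window at a coarse level only skips that level's
    # refinement; losing the point requires singularity at full resolution
    if (l == 1L) lost <- lost | sing
    det[sing] <- 1
    v <- matrix(0, n, 2)
    active <- which(!sing)
    for (it in seq_len(params$max_iter)) {
      if (length(active) == 0) break
      a <- active
      bp2 <- bil_prep(hA, wA,
                      X[a, , drop = FALSE] + g[a, 1] + v[a, 1],
                      Y[a, , drop = FALSE] + g[a, 2] + v[a, 2])
      dI <- Iw[a, , drop = FALSE] - bil_apply(B, bp2)
      bx <- rowSums(dI * Ix[a, , drop = FALSE])
      by <- rowSums(dI * Iy[a, , drop = FALSE])
      ex <- (gyy[a] * bx - gxy[a] * by) / det[a]
      ey <- (gxx[a] * by - gxy[a] * bx) / det[a]
      v[a, 1] <- v[a, 1] + ex
      v[a, 2] <- v[a, 2] + ey
      active <- a[abs(ex) >= params$eps | abs(ey) >= params$eps]
    }
    g <- g + v
    if (l > 1) g <- 2 * g
  }
  newc <- old + g
  oob <- newc[, 1] < 0 | newc[, 1] > dim_hw[2] - 1 |
    newc[, 2] < 0 | newc[, 2] > dim_hw[1] - 1
  lost <- lost | oob | !is.finite(newc[, 1]) | !is.finite(newc[, 2])
  newc[lost, ] <- old[lost, ]
  disp <- newc - old
  disp[lost, ] <- 0
  out <- points
  out$coords <- newc
  out$status <- !lost
  list(points = out, displacement = disp)
}

# ---- feature rows -----------------------------------------------------------

feature_colnames <- function(n_points = 30L) {
  per_tool <- function(tag) {
    pos <- as.vector(rbind(sprintf("%s_x%02d", tag, seq_len(n_points)),
                           sprintf("%s_y%02d", tag, seq_len(n_points))))
    dis <- as.vector(rbind(sprintf("%s_dx%02d", tag, seq_len(n_points)),
                           sprintf("%s_dy%02d", tag, seq_len(n_points))))
    c(pos, dis)
  }
  c(per_tool("left"), per_tool("right"))
}

#' Assemble one 240-feature row
#'
#' Fixed column order: all left-tool values, then all right-tool values;
#' within a tool, the point-major position block (`x1, y1, ..., x30,
#' y30`) followed by the point-major displacement block (`dx1, dy1, ...,
#' dx30, dy30`). With the default 30 points per tool the row length is
#' `2 * 30 * 4 = 240`.
#'
#' @param record A list with elements `left` and `right`, each holding
#'   `positions` and `displacements` (`n_points x 2` matrices).
#' @param n_points Configured point budget per tool.
#' @return Named numeric vector of length `8 * n_points`.
#' @export
build_feature_row <- function(record, n_points = 30L) {
  for (tool in c("left", "right")) {
    tl <- record[[tool]]
    if (is.null(tl) || nrow(tl$positions) != n_points || nrow(tl$displacements) != n_points) {
      stop(tool, " tool does not carry the configured point count (", n_points, ")")
    }
  }
  row <- c(as.vector(t(record$left$positions)),
           as.vector(t(record$left$displacements)),
           as.vector(t(record$right$positions)),
           as.vector(t(record$right$displacements)))
  names(row) <- feature_colnames(n_points)
  row
}

as_frame_list <- function(video) {
  if (is.character(video)) return(read_frames(video))
  if (is.array(video) && length(dim(video)) == 3L) {
    return(lapply(seq_len(dim(video)[3]), function(t) video[, , t]))
  }
  if (is.list(video)) return(video)
  stop("video must be a height x width x frames array, a list of frames, ",
       "or a path to a PNG frame directory")
}

#' Extract the optical-flow feature matrix of a video
#'
#' The full data-generation pass for one video: binarise the start frame,
#' seed 30 Shi-Tomasi corners in each tool ROI, then track all 60 points
#' frame to frame with pyramidal Lucas-Kanade on the raw grayscale
#' frames, emitting one row of 240 features (positions + per-frame
#' displacements) per frame after the start frame. Only positions and
#' displacements are recorded — no derived kinematics (acceleration,
#' jerk, ...). Points lost by the tracker carry their last known position
#' forward with zero displacement and are counted in the lost-point log;
#' there is no re-detection.
#'
#' @param video Frame array (`height x width x frames`), list of frames,
#'   or path to a PNG frame directory.
#' @param roi_left,roi_right [roi()]s valid on the start frame.
#' @param start_frame 1-based index of the initial frame where both tools
#'   are visible.
#' @param n_points Point budget per tool (30 keeps the 240-column contract).
#' @param lk [lk_params()].
#' @param median_size,block_size,offset Preprocessing parameters, see
#'   [preprocess_frame()].
#' @param min_distance,quality Corner-seeding parameters, see
#'   [detect_initial_points()].
#' @return An `sf_features` tibble with `8 * n_points` columns and
#'   `frames - start_frame` rows. Attributes: `buffer` (raw tracking
#'   array `rows x (2 n_points) x 2 x 2`: point, position/displacement,
#'   x/y), `lost_log` (per-frame lost-point counts per tool),
#'   `start_frame`, `params`.
#' @export
extract_features <- function(video, roi_left, roi_right, start_frame = 1L,
                             n_points = 30L, lk = lk_params(),
                             median_size = 5L, block_size = 11L, offset = 0.02,
                             min_distance = 3, quality = 0.02) {
  frames <- as_frame_list(video)
  nf <- length(frames)
  if (start_frame < 1 || start_frame >= nf) {
    stop("start_frame ", start_frame, " leaves no frames to track (video has ",
         nf, " frames)")
  }
  dim_hw <- dim(frames[[start_frame]])[1:2]
  for (r in list(roi_left, roi_right)) {
    if (!roi_in_frame(r, dim_hw)) stop("ROI '", r$tool_id, "' lies outside the frame")
  }
  if (!rois_disjoint(roi_left, roi_right)) stop("left and right ROIs overlap")
  gray <- lapply(frames, to_gray)
  binary <- preprocess_frame(gray[[start_frame]], median_size, block_size, offset)
  pl <- detect_initial_points(binary, roi_left, n_points, min_distance, quality)
  pr <- detect_initial_points(binary, roi_right, n_points, min_distance, quality)
  pts <- structure(list(tool_id = "both",
                        coords = rbind(pl$coords, pr$coords),
                        status = c(pl$status, pr$status)),
                   class = "sf_points")
  n_rows <- nf - start_frame
  buffer <- array(0, c(n_rows, 2L * n_points, 2L, 2L),
                  dimnames = list(NULL, NULL, c("position", "displacement"), c("x", "y")))
  lost_left <- integer(n_rows)
  lost_right <- integer(n_rows)
  rows <- matrix(0, n_rows, 8L * n_points)
  dim_hw <- dim(gray[[start_frame]])
  pyr_prev <- lk_pyramid(gray[[start_frame]], lk$levels)
  for (k in seq_len(n_rows)) {
    t <- start_frame + k
    pyr_next <- lk_pyramid(gray[[t]], lk$levels)
    st <- track_lk(pyr_prev, pyr_next, pts, lk, dim_hw)
    pyr_prev <- pyr_next
    # lost-point policy: carry position forward, zero displacement, keep
    # the point in the set so the 240-column contract holds
    pts$coords <- st$points$coords
    lost_now <- !st$points$status
    lost_left[k] <- sum(lost_now[seq_len(n_points)])
    lost_right[k] <- sum(lost_now[n_points + seq_len(n_points)])
    buffer[k, , 1L, ] <- pts$coords
    buffer[k, , 2L, ] <- st$displacement
    rec <- list(
      left = list(positions = pts$coords[seq_len(n_points), , drop = FALSE],
                  displacements = st$displacement[seq_len(n_points), , drop = FALSE]),
      right = list(positions = pts$coords[n_points + seq_len(n_points), , drop = FALSE],
                   displacements = st$displacement[n_points + seq_len(n_points), , drop = FALSE]))
    rows[k, ] <- build_feature_row(rec, n_points)
  }
  out <- tibble::as_tibble(as.data.frame(rows))
  names(out) <- feature_colnames(n_points)
  attr(out, "buffer") <- buffer
  attr(out, "lost_log") <- tibble::tibble(
    frame = start_frame + seq_len(n_rows),
    lost_left = lost_left, lost_right = lost_right)
  attr(out, "start_frame") <- as.integer(start_frame)
  attr(out, "params") <- list(n_points = n_points, lk = unclass(lk),
                              median_size = median_size, block_size = block_size,
                              offset = offset, min_distance = min_distance,
                              quality = quality)
  class(out) <- c("sf_features", class(out))
  out
}
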