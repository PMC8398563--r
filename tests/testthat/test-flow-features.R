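test_that("preprocessing binarises, denoises and respects degenerate inputs", {
  flat <- matrix(0.5, 40, 50)
  b <- preprocess_frame(flat)
  expect_true(all(b %in% c(0, 1)))
  expect_equal(length(unique(as.vector(b))), 1)  # uniform input, uniform output

  # salt noise on a constant background: the median blur removes isolated
  # bright pixels before thresholding; without it they survive
  set.seed(1)
  sp <- flat
  idx <- sample(length(sp), 40)
  sp[idx] <- 1
  with_median <- preprocess_frame(sp, median_size = 5)
  no_median <- preprocess_frame(sp, median_size = 0)
  expect_gt(sum(no_median), 0)
  expect_lt(sum(with_median), sum(no_median) / 4)

  # an already high-contrast checkerboard keeps its structure
  cb <- matrix(0, 48, 48)
  on <- (((row(cb) - 1) %/% 8) + ((col(cb) - 1) %/% 8)) %% 2 == 1
  cb[on] <- 1
  bb <- preprocess_frame(cb, median_size = 3)
  expect_gt(mean(bb), 0.25)
  expect_lt(mean(bb), 0.75)

  expect_error(preprocess_frame(matrix(numeric(0), 0, 0)), "zero size")
  expect_error(preprocess_frame(flat, median_size = 4), "odd")
})

test_that("corner seeding matches checkerboard geometry and brute-force scores", {
  cb <- matrix(0, 64, 64)
  on <- (((row(cb) - 1) %/% 8) + ((col(cb) - 1) %/% 8)) %% 2 == 1
  cb[on] <- 1
  r <- roi("left", 4, 4, 56, 56)
  pts <- detect_initial_points(cb, r, n_points = 20, min_distance = 4)
  expect_equal(nrow(pts$coords), 20)
  # all inside the half-open ROI
  expect_true(all(pts$coords[, 1] >= 4 & pts$coords[, 1] < 60))
  expect_true(all(pts$coords[, 2] >= 4 & pts$coords[, 2] < 60))
  # every corner within 1 px of a true square intersection (multiples of 8,
  # offset by the 0-based pixel grid: boundaries at 7.5, 15.5, ...)
  grid_dist <- function(z) abs((z + 0.5) %% 8 - 0) # distance to nearest multiple of 8
  gd <- function(z) pmin((z + 0.5) %% 8, 8 - (z + 0.5) %% 8)
  expect_true(all(gd(pts$coords[, 1]) <= 1))
  expect_true(all(gd(pts$coords[, 2]) <= 1))

  # single bright square: the sole requested corner has the max brute score
  img <- matrix(0, 30, 30)
  img[12:17, 14:19] <- 1
  p1 <- detect_initial_points(img, roi("left", 2, 2, 26, 26), n_points = 1)
  scores <- outer(2:27, 2:27, Vectorize(function(y, x) brute_shi_tomasi(img, x, y)))
  got <- brute_shi_tomasi(img, p1$coords[1, 1], p1$coords[1, 2])
  expect_equal(got, max(scores), tolerance = 1e-9)

  # uniform ROI: error naming the shortfall
  expect_error(detect_initial_points(matrix(0, 40, 40), roi("left", 0, 0, 40, 40), 5),
               "no corners")
  expect_error(detect_initial_points(img, roi("left", 2, 2, 26, 26), 30),
               "of 30 corners")
})

test_that("Lucas-Kanade recovers zero and rigid motion, and flags losses", {
  fr <- rigid_scene(n_frames = 2, shift = c(0, 0))
  b <- preprocess_frame(fr[[1]], median_size = 0, offset = 0.01)
  pts <- detect_initial_points(b, roi("left", 20, 20, 60, 50), 15)
  st <- track_step(fr[[1]], fr[[1]], pts)
  expect_true(all(st$points$status))
  expect_true(all(st$displacement == 0))

  fr3 <- rigid_scene(n_frames = 2, shift = c(3, 0))
  st3 <- track_step(fr3[[1]], fr3[[2]], pts)
  expect_lt(max(abs(colMeans(st3$displacement) - c(3, 0))), 0.5)

  expect_error(track_step(fr[[1]], matrix(0, 10, 10), pts), "different shapes")

  # previously-lost points stay lost and report zero displacement
  pts_lost <- pts
  pts_lost$status[1] <- FALSE
  st4 <- track_step(fr3[[1]], fr3[[2]], pts_lost)
  expect_false(st4$points$status[1])
  expect_equal(st4$displacement[1, ], c(x = 0, y = 0))
})

test_that("feature rows have the 240-column contract and exact displacements", {
  set.seed(5)
  pos_prev <- list(left = matrix(runif(60, 10, 50), 30, 2),
                   right = matrix(runif(60, 80, 120), 30, 2))
  pos_now <- list(left = pos_prev$left + matrix(rnorm(60), 30, 2),
                  right = pos_prev$right + matrix(rnorm(60), 30, 2))
  rec <- list(left = list(positions = pos_now$left,
                          displacements = pos_now$left - pos_prev$left),
              right = list(positions = pos_now$right,
                           displacements = pos_now$right - pos_prev$right))
  row <- build_feature_row(rec)
  expect_length(row, 240)
  expect_identical(names(row)[1:2], c("left_x01", "left_y01"))
  # displacement block equals the elementwise position difference
  expect_identical(unname(row[61:120]),
                   as.vector(t(pos_now$left - pos_prev$left)))
  # zero-motion record: displacement entries all zero, positions = seeds
  rec0 <- list(left = list(positions = pos_prev$left,
                           displacements = pos_prev$left * 0),
               right = list(positions = pos_prev$right,
                            displacements = pos_prev$right * 0))
  row0 <- build_feature_row(rec0)
  expect_true(all(row0[c(61:120, 181:240)] == 0))
  expect_identical(unname(row0[1:60]), as.vector(t(pos_prev$left)))

  bad <- rec
  bad$left$positions <- bad$left$positions[1:10, ]
  expect_error(build_feature_row(bad), "point count")
})

test_that("extraction emits frames-1 rows of 240 features with exact bookkeeping", {
  v <- fixture("video30", function() small_tool_video(n_frames = 30))
  fm <- fixture("features30", function() {
    v <- fixture("video30", function() small_tool_video(n_frames = 30))
    extract_features(v$frames, v$roi_left, v$roi_right)
  })
  expect_s3_class(fm, "sf_features")
  expect_equal(dim(fm), c(29L, 240L))
  buf <- attr(fm, "buffer")
  expect_equal(dim(buf), c(29L, 60L, 2L, 2L))
  # flow/position consistency, bit-exact for tracked points (lost points
  # carry forward: position difference 0 equals stored displacement 0)
  for (k in 2:29) {
    expect_identical(buf[k, , 1, ] - buf[k - 1, , 1, ], buf[k, , 2, ])
  }
  # the tibble mirrors the buffer (left tool positions, point-major)
  expect_identical(unname(as.matrix(fm)[5, 1:2]), unname(buf[5, 1, 1, ]))
  # seeding containment (half-open)
  expect_true(all(buf[1, 1:30, 1, 1] - buf[1, 1:30, 2, 1] >= v$roi_left$x))
  expect_true(all(buf[1, 1:30, 1, 1] - buf[1, 1:30, 2, 1] < v$roi_left$x + v$roi_left$w))

  expect_error(extract_features(v$frames, v$roi_left, v$roi_right, start_frame = 30),
               "no frames")
  expect_error(extract_features(v$frames, v$roi_left,
                                roi("right", 15, 30, 60, 60)),
               "overlap")
})

test_that("static scenes give zero flow and rigid scenes the commanded flow", {
  sc <- scene_spec(n_frames = 8, background_noise_sd = 0, seed = 3)
  static <- matrix(rep(c(45, 60), each = 8), 8, 2)
  static_r <- matrix(rep(c(115, 60), each = 8), 8, 2)
  v <- render_video(static, static_r, sc)
  fm <- extract_features(v$frames, roi("left", 15, 30, 60, 60),
                         roi("right", 85, 30, 60, 60))
  dcols <- grepl("_d", names(fm))
  expect_true(all(as.matrix(fm)[, dcols] == 0))

  # rigid (1.5, 0) translation: displacement columns near the truth
  fr <- rigid_scene(n_frames = 20, shift = c(1.5, 0))
  fmr <- extract_features(fr, roi("left", 10, 10, 45, 45),
                          roi("right", 70, 30, 45, 45))
  dx <- as.matrix(fmr)[, grepl("_dx", names(fmr))]
  dy <- as.matrix(fmr)[, grepl("_dy", names(fmr))]
  expect_lt(median(abs(dx - 1.5)), 0.1)
  expect_lt(median(abs(dy)), 0.1)
})

test_that("a tool leaving the frame loses points which carry forward", {
  sc <- scene_spec(n_frames = 25, background_noise_sd = 0, seed = 5)
  # drive the left tool off the left edge
  exit <- cbind(seq(40, -40, length.out = 25), rep(60, 25))
  static_r <- matrix(rep(c(115, 60), each = 25), 25, 2)
  v <- render_video(exit, static_r, sc)
  fm <- extract_features(v$frames, roi("left", 10, 30, 60, 60),
                         roi("right", 85, 30, 60, 60))
  log <- attr(fm, "lost_log")
  expect_gt(sum(log$lost_left), 0)
  expect_equal(sum(log$lost_right), 0)
  # carry-forward policy: positions never leave the frame even though the
  # commanded center ends far outside it
  buf <- attr(fm, "buffer")
  expect_true(all(buf[, , 1, 1] >= 0 & buf[, , 1, 1] <= sc$width - 1))
  expect_true(all(buf[, , 1, 2] >= 0 & buf[, , 1, 2] <= sc$height - 1))
})
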