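test_that("motion presets encode skill and reject invalid parameters", {
  nov <- motion_params("novice")
  exp_ <- motion_params("expert")
  expect_lt(exp_$jitter_sd, nov$jitter_sd)
  expect_gt(exp_$path_directness, nov$path_directness)
  expect_gte(nov$jitter_sd, 5 * exp_$jitter_sd)
  expect_error(motion_params("novice", jitter_sd = NaN), "finite")
  expect_error(motion_params("novice", jitter_sd = -1), "non-negative")
  expect_error(motion_params("novice", path_directness = 1.5), "\\[0, 1\\]")
  expect_error(motion_params("novice", pause_prob = 2), "\\[0, 1\\]")
})

test_that("noise-free direct trajectory is a straight line and paths are seeded", {
  p <- motion_params("expert", jitter_sd = 0, pause_prob = 0, path_directness = 1)
  start <- c(10, 20)
  goal <- c(70, 60)
  path <- generate_trajectory(p, 40, start, goal, seed = 3)
  expect_equal(path[1, ], c(x = 10, y = 20))
  # collinearity: cross product of every step with the start-goal direction
  d <- goal - start
  steps <- diff(path)
  cross <- steps[, 1] * d[2] - steps[, 2] * d[1]
  expect_lt(max(abs(cross)), 1e-9)
  expect_identical(generate_trajectory(p, 40, start, goal, seed = 3), path)
  expect_error(generate_trajectory(p, 1, start, goal), "at least 2")
  expect_error(generate_trajectory(p, 10, start, start), "differ")
})

test_that("expert paths are shorter and class displacement distributions separate", {
  n <- 300
  len <- function(params, seed) {
    sum(sqrt(rowSums(diff(generate_trajectory(params, n, c(20, 20), c(120, 90),
                                              seed = seed))^2)))
  }
  seeds <- 1:50
  len_e <- vapply(seeds, function(s) len(motion_params("expert"), s), numeric(1))
  len_n <- vapply(seeds, function(s) len(motion_params("novice"), s), numeric(1))
  expect_lt(mean(len_e), mean(len_n))
  # disjoint at the 5th/95th percentiles (jitter ratio >= 5x)
  expect_lt(stats::quantile(len_e, 0.95), stats::quantile(len_n, 0.05))
})

test_that("rendering is deterministic and ground truth follows commanded motion", {
  sc <- scene_spec(n_frames = 6, background_noise_sd = 0, seed = 2)
  static <- matrix(rep(c(45, 60), each = 6), 6, 2)
  static_r <- matrix(rep(c(115, 60), each = 6), 6, 2)
  v <- render_video(static, static_r, sc)
  for (t in 2:6) expect_identical(v$frames[, , t], v$frames[, , 1])

  # pure translation: ground truth shifts by exactly (3, 0) per frame
  tl <- cbind(40 + 3 * (0:5), rep(60, 6))
  v2 <- render_video(tl, static_r, sc)
  pts <- v2$ground_truth$left$points
  for (t in 2:6) {
    expect_equal(pts[t, , 1] - pts[t - 1, , 1], rep(3, dim(pts)[2]))
    expect_equal(pts[t, , 2] - pts[t - 1, , 2], rep(0, dim(pts)[2]))
  }
  expect_false(v2$ground_truth$left$out_of_bounds)

  # ground-truth differencing reproduces arbitrary commanded displacements
  p <- motion_params("novice")
  traj <- generate_trajectory(p, 6, c(50, 55), c(80, 70), seed = 9)
  v3 <- render_video(traj, static_r, sc)
  gt <- v3$ground_truth$left$points
  for (t in 2:6) {
    expect_equal(gt[t, , 1] - gt[t - 1, , 1],
                 rep(unname(traj[t, 1] - traj[t - 1, 1]), dim(gt)[2]))
  }

  # leaving the frame flags, but does not error
  out_traj <- cbind(seq(10, -40, length.out = 6), rep(60, 6))
  v4 <- render_video(out_traj, static_r, sc)
  expect_true(v4$ground_truth$left$out_of_bounds)

  expect_error(render_video(static[1:3, ], static_r, sc), "n_frames")
})

test_that("cohort manifests count, label and reproduce correctly", {
  co <- generate_cohort(n_subjects = 8, trials_per_subject = 5, seed = 4)
  m <- co$manifest
  expect_equal(nrow(m), 40)
  expect_equal(nrow(dplyr::distinct(m, subject, task, trial)), 40)
  # one skill per subject, default proportions 4/2/2
  per_subj <- dplyr::distinct(m, subject, skill)
  expect_equal(nrow(per_subj), 8)
  expect_equal(sort(as.vector(table(per_subj$skill))), c(2, 2, 4))
  # byte-identical regeneration
  co2 <- generate_cohort(n_subjects = 8, trials_per_subject = 5, seed = 4)
  expect_identical(serialize(co$manifest, NULL), serialize(co2$manifest, NULL))
  # errors
  expect_error(generate_cohort(trials_per_subject = 1), "at least 2")
  expect_error(generate_cohort(n_subjects = 3, seed = 1,
                               skill_counts = c(novice = 2, expert = 1)),
               "at least 2 subjects")
})

test_that("cohort ROIs contain their tool disc on the start frame", {
  co <- generate_cohort(n_subjects = 4, trials_per_subject = 2, seed = 6,
                        skill_counts = c(novice = 2, expert = 2))
  r <- co$scene$tool_radius
  for (i in seq_len(nrow(co$manifest))) {
    v <- cohort_video(co, i)
    row <- co$manifest[i, ]
    for (tool in c("left", "right")) {
      ctr <- v$ground_truth[[tool]]$centers[1, ]
      x0 <- row[[paste0("roi_", tool, "_x")]]
      y0 <- row[[paste0("roi_", tool, "_y")]]
      expect_gte(ctr[1] - r, x0)
      expect_lte(ctr[1] + r, x0 + row[[paste0("roi_", tool, "_w")]])
      expect_gte(ctr[2] - r, y0)
      expect_lte(ctr[2] + r, y0 + row[[paste0("roi_", tool, "_h")]])
    }
  }
})
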