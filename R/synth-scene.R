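# Seeded generator of synthetic endoscopy-like scenes: two textured,
# corner-rich tool blobs move over a noisy background along skill-dependent
# trajectories. Skill is expressed only through motion statistics (jitter,
# path directness, pauses) — never through appearance — so classifiers must
# learn motion. All outputs are pure functions of (parameters, seed).

#' Motion parameters of a simulated tool
#'
#' Bundles the per-frame motion statistics that encode operator skill:
#' `jitter_sd` (px/frame of isotropic Gaussian hand tremor), `speed_mean`
#' (px/frame of goal-directed drift), `path_directness` (in `[0, 1]`; 1 =
#' head straight for the goal, lower values blend in a wandering heading)
#' and `pause_prob` (per-frame probability of a hesitation during which
#' only tremor moves the tool). `motion_params("expert")` etc. return the
#' built-in presets; presets keep `speed_mean` equal across classes so
#' skill shows up as smoothness and path efficiency, not speed. The expert
#' preset has strictly lower `jitter_sd` and higher `path_directness` than
#' the novice one.
#'
#' @param skill `"novice"`, `"intermediate"` or `"expert"`.
#' @param jitter_sd,speed_mean,path_directness,pause_prob Optional
#'   overrides of the preset values.
#' @return A `motion_params` list.
#' @examples
#' motion_params("expert")
#' motion_params("novice", jitter_sd = 3)
#' @export
motion_params <- function(skill = c("novice", "intermediate", "expert"),
                          jitter_sd = NULL, speed_mean = NULL,
                          path_directness = NULL, pause_prob = NULL) {
  skill <- match.arg(skill)
  presets <- list(
    novice = list(jitter_sd = 2.0, speed_mean = 2.0, path_directness = 0.55, pause_prob = 0.15),
    intermediate = list(jitter_sd = 1.0, speed_mean = 2.0, path_directness = 0.80, pause_prob = 0.08),
    expert = list(jitter_sd = 0.3, speed_mean = 2.0, path_directness = 0.95, pause_prob = 0.02))
  p <- presets[[skill]]
  if (!is.null(jitter_sd)) p$jitter_sd <- jitter_sd
  if (!is.null(speed_mean)) p$speed_mean <- speed_mean
  if (!is.null(path_directness)) p$path_directness <- path_directness
  if (!is.null(pause_prob)) p$pause_prob <- pause_prob
  vals <- unlist(p)
  if (any(!is.finite(vals))) stop("motion parameters must be finite")
  if (p$jitter_sd < 0) stop("jitter_sd must be non-negative")
  if (p$path_directness < 0 || p$path_directness > 1) stop("path_directness must lie in [0, 1]")
  if (p$pause_prob < 0 || p$pause_prob > 1) stop("pause_prob must lie in [0, 1]")
  structure(c(list(skill = skill), p), class = "motion_params")
}

#' Scene geometry and rendering parameters
#'
#' @param width,height Frame size in px (at least 64 each).
#' @param n_frames Number of frames (at least 2).
#' @param tool_radius Radius of each tool blob in px.
#' @param background_noise_sd Gaussian intensity noise of the background.
#' @param texture_contrast Peak-to-trough contrast of the tool texture.
#' @param checker_cell Cell size (px) of the smoothed checkerboard texture.
#' @param seed Integer seed fixing all randomness of the render.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width = 160L, height = 120L, n_frames = 100L,
                       tool_radius = 26, background_noise_sd = 0.03,
                       texture_contrast = 0.5, checker_cell = 12, seed = 1L) {
  if (width < 64 || height < 64) stop("frame must be at least 64x64 px")
  if (n_frames < 2) stop("a scene needs at least 2 frames")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_frames = as.integer(n_frames), tool_radius = tool_radius,
                 background_noise_sd = background_noise_sd,
                 texture_contrast = texture_contrast,
                 checker_cell = checker_cell, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Simulate one tool-tip trajectory
#'
#' Generates a goal-directed path with skill-dependent roughness: at each
#' frame the heading blends the direction to the goal (weight
#' `path_directness`) with a smoothly wandering unit vector, the tool
#' advances `speed_mean` px unless pausing, and isotropic Gaussian jitter
#' of sd `jitter_sd` is added. On (near) arrival the goal and start are
#' swapped, so the tool works back and forth for the whole clip. The path
#' is a pure function of the arguments; in the noise-free limit
#' (`jitter_sd = 0`, `pause_prob = 0`, `path_directness = 1`) it is a
#' straight line through start and goal.
#'
#' @param params A [motion_params()] object.
#' @param n_frames Number of frames (at least 2).
#' @param start,goal Numeric `(x, y)` endpoints in px; must differ.
#' @param seed Integer seed.
#' @return An `n_frames x 2` matrix of `(x, y)` centers; row 1 is `start`.
#' @export
generate_trajectory <- function(params, n_frames, start, goal, seed = 1L) {
  stopifnot(inherits(params, "motion_params"))
  if (n_frames < 2) stop("n_frames must be at least 2")
  if (!all(is.finite(c(start, goal)))) stop("start/goal must be finite")
  if (all(start == goal)) stop("start and goal must differ")
  set.seed(seed)
  pos <- as.numeric(start)
  g <- as.numeric(goal)
  s0 <- pos
  path <- matrix(0, n_frames, 2, dimnames = list(NULL, c("x", "y")))
  path[1, ] <- pos
  theta <- stats::runif(1, 0, 2 * pi)
  arrive <- max(2, params$speed_mean)
  for (t in 2:n_frames) {
    d <- g - pos
    nd <- sqrt(sum(d * d))
    if (nd < arrive) {  # reached: turn around
      tmp <- g; g <- s0; s0 <- tmp
      d <- g - pos
      nd <- sqrt(sum(d * d))
    }
    dir_goal <- if (nd > 1e-9) d / nd else c(1, 0)
    theta <- theta + stats::rnorm(1, 0, 0.4)
    u <- params$path_directness * dir_goal +
      (1 - params$path_directness) * c(cos(theta), sin(theta))
    nu <- sqrt(sum(u * u))
    if (nu < 1e-9) u <- dir_goal else u <- u / nu
    paused <- stats::runif(1) < params$pause_prob
    step <- if (paused) c(0, 0) else params$speed_mean * u
    pos <- pos + step + stats::rnorm(2, 0, params$jitter_sd)
    path[t, ] <- pos
  }
  path
}

# smoothed checkerboard texture, a function of coordinates relative to the
# blob center so it translates rigidly with the tool
tool_texture <- function(u, v, cell, contrast) {
  # sharp plateaus (sign-like but differentiable) so the median blur of the
  # preprocessing keeps the checker squares intact
  0.5 + 0.5 * contrast * tanh(6 * sin(2 * pi * u / cell) * sin(2 * pi * v / cell))
}

# lattice of texture-corner offsets inside the blob (the checker zero
# crossings, where the Shi-Tomasi score peaks)
corner_offsets <- function(radius, cell, margin = 5) {
  half <- cell / 2
  k <- floor((radius - margin) / half)
  g <- half * (-k:k)
  off <- as.matrix(expand.grid(du = g, dv = g))
  off[sqrt(rowSums(off^2)) <= radius - margin, , drop = FALSE]
}

#' Render a two-tool scene
#'
#' Draws two textured blobs (smoothed checkerboard over a soft disc) onto
#' a noisy gray background, one per trajectory, and returns the frames
#' together with exact ground truth: per-frame true centers and the
#' coordinates of texture-corner points that follow each blob rigidly.
#' Ground-truth bookkeeping is analytic (center plus fixed offsets), so
#' differencing consecutive ground-truth positions reproduces the
#' commanded per-frame displacement exactly. A trajectory leaving the
#' frame bounds sets `out_of_bounds` in the ground truth, it is not an
#' error.
#'
#' @param traj_left,traj_right `n_frames x 2` center paths (px, 0-based
#'   coordinates: x rightward, y downward).
#' @param scene A [scene_spec()].
#' @return A list with `frames` (array `height x width x n_frames`, values
#'   in `[0, 1]`) and `ground_truth`: per tool, `centers` (`n x 2`),
#'   `points` (array `n_frames x n_points x 2` of corner tracks) and
#'   `out_of_bounds`.
#' @export
render_video <- function(traj_left, traj_right, scene = scene_spec()) {
  n <- scene$n_frames
  if (nrow(traj_left) != n || nrow(traj_right) != n) {
    stop("both trajectories must have length n_frames = ", n)
  }
  set.seed(scene$seed)
  h <- scene$height; w <- scene$width; r <- scene$tool_radius
  frames <- array(0, c(h, w, n))
  offs <- corner_offsets(r, scene$checker_cell)
  gt <- lapply(list(left = traj_left, right = traj_right), function(traj) {
    pts <- array(0, c(n, nrow(offs), 2))
    for (t in seq_len(n)) {
      pts[t, , 1] <- traj[t, 1] + offs[, 1]
      pts[t, , 2] <- traj[t, 2] + offs[, 2]
    }
    oob <- any(traj[, 1] < 0 | traj[, 1] >= w | traj[, 2] < 0 | traj[, 2] >= h)
    list(centers = traj, points = pts, offsets = offs, out_of_bounds = oob)
  })
  for (t in seq_len(n)) {
    fr <- matrix(0.45, h, w)
    if (scene$background_noise_sd > 0) {
      fr <- fr + matrix(stats::rnorm(h * w, 0, scene$background_noise_sd), h, w)
    }
    for (traj in list(traj_left, traj_right)) {
      cx <- traj[t, 1]; cy <- traj[t, 2]
      x0 <- max(0L, floor(cx - r - 2)); x1 <- min(w - 1L, ceiling(cx + r + 2))
      y0 <- max(0L, floor(cy - r - 2)); y1 <- min(h - 1L, ceiling(cy + r + 2))
      if (x0 > x1 || y0 > y1) next
      px <- x0:x1; py <- y0:y1
      u <- matrix(px, length(py), length(px), byrow = TRUE) - cx
      v <- matrix(py, length(py), length(px)) - cy
      rad <- sqrt(u * u + v * v)
      mask <- pmin(pmax((r - rad) / 1.5, 0), 1)
      tex <- tool_texture(u, v, scene$checker_cell, scene$texture_contrast)
      sub <- fr[py + 1L, px + 1L, drop = FALSE]
      fr[py + 1L, px + 1L] <- sub * (1 - mask) + tex * mask
    }
    frames[, , t] <- pmin(pmax(fr, 0), 1)
  }
  list(frames = frames, ground_truth = gt)
}

#' Generate a cohort of synthetic training videos
#'
#' Creates the manifest (and, lazily, the videos) of a subjects-by-trials
#' cohort mirroring the layout of bench-training datasets: each subject
#' has one skill level across all of their repeated trials, so
#' leave-one-super-trial-out folds are well defined. Start/goal points
#' keep the left tool in the left half of the frame and the right tool in
#' the right half; square regions of interest are centered on the frame-0
#' tool positions, so the ROIs are guaranteed to contain the tools at the
#' start frame. Per-trial seeds are derived from `seed`, making the
#' manifest (and every video) byte-identical across re-runs.
#'
#' @param n_subjects Number of subjects; every represented skill class
#'   must get at least 2 subjects.
#' @param trials_per_subject Repetitions per subject and task (>= 2, so
#'   super-trial folds exist).
#' @param task_names Character vector of task names.
#' @param seed Integer master seed.
#' @param skill_counts Named integer vector distributing subjects over
#'   skill classes; defaults to 4 novice / 2 intermediate / 2 expert for
#'   8 subjects (scaled proportionally otherwise).
#' @param scene A [scene_spec()] shared by all videos.
#' @param roi_size Side length (px) of the square ROIs.
#' @param out_dir If given, render all videos as PNG frame directories
#'   under `out_dir` and write `manifest.csv` there.
#' @return An `sf_cohort` list with `manifest` (tibble: subject, task,
#'   trial, skill, ROI columns, video_path, video_seed), `scene`, `seed`.
#'   Use [cohort_video()] to materialise one trial's frames.
#' @export
generate_cohort <- function(n_subjects = 8L, trials_per_subject = 5L,
                            task_names = "synthetic_task", seed = 1L,
                            skill_counts = NULL, scene = scene_spec(),
                            roi_size = 60L, out_dir = NULL) {
  if (trials_per_subject < 2) {
    stop("trials_per_subject must be at least 2 (super-trial folds need >= 2 trials)")
  }
  if (is.null(skill_counts)) {
    # default mix leans toward novices; intermediates appear only when the
    # cohort is large enough to give them >= 2 subjects
    expert <- max(2L, round(n_subjects / 4))
    inter <- if (round(n_subjects / 4) >= 2) round(n_subjects / 4) else 0L
    skill_counts <- c(novice = n_subjects - expert - inter,
                      intermediate = inter, expert = expert)
  }
  skill_counts <- skill_counts[skill_counts > 0]
  if (sum(skill_counts) != n_subjects) stop("skill_counts must sum to n_subjects")
  if (any(skill_counts < 2)) {
    stop("every represented skill class needs at least 2 subjects")
  }
  skills <- rep(names(skill_counts), skill_counts)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  grid <- tidyr::expand_grid(subject = subjects, task = task_names,
                             trial = seq_len(trials_per_subject))
  grid$skill <- skills[match(grid$subject, subjects)]
  grid$video_seed <- (as.integer(seed) * 7919L +
                        seq_len(nrow(grid)) * 104729L) %% 2147483647L
  w <- scene$width; h <- scene$height
  m <- roi_size / 2
  # deterministic per-trial geometry from the trial seed
  geo <- lapply(grid$video_seed, function(s) {
    set.seed(s)
    sl <- c(stats::runif(1, 0.22 * w, 0.30 * w), stats::runif(1, 0.45 * h, 0.55 * h))
    gl <- c(stats::runif(1, 0.12 * w, 0.40 * w), stats::runif(1, 0.25 * h, 0.75 * h))
    sr <- c(stats::runif(1, 0.70 * w, 0.78 * w), stats::runif(1, 0.45 * h, 0.55 * h))
    gr <- c(stats::runif(1, 0.60 * w, 0.88 * w), stats::runif(1, 0.25 * h, 0.75 * h))
    list(sl = sl, gl = gl, sr = sr, gr = gr)
  })
  clampx <- function(x) pmin(pmax(round(x - m), 0), w - roi_size)
  clampy <- function(y) pmin(pmax(round(y - m), 0), h - roi_size)
  grid$roi_left_x <- vapply(geo, function(g) clampx(g$sl[1]), numeric(1))
  grid$roi_left_y <- vapply(geo, function(g) clampy(g$sl[2]), numeric(1))
  grid$roi_left_w <- roi_size
  grid$roi_left_h <- roi_size
  grid$roi_right_x <- vapply(geo, function(g) clampx(g$sr[1]), numeric(1))
  grid$roi_right_y <- vapply(geo, function(g) clampy(g$sr[2]), numeric(1))
  grid$roi_right_w <- roi_size
  grid$roi_right_h <- roi_size
  grid$video_path <- NA_character_
  cohort <- structure(list(manifest = grid, scene = scene, seed = as.integer(seed)),
                      class = "sf_cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      vid <- cohort_video(cohort, i)
      rel <- sprintf("%s_%s_T%02d", grid$subject[i], grid$task[i], grid$trial[i])
      write_frames(vid$frames, file.path(out_dir, rel))
      paths[i] <- rel
    }
    cohort$manifest$video_path <- paths
    utils::write.csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  cohort
}

#' Materialise one cohort trial as frames + ground truth
#'
#' Regenerates trajectories and frames for row `i` of the cohort manifest
#' from the stored per-trial seed; repeated calls are identical.
#'
#' @param cohort An `sf_cohort` from [generate_cohort()].
#' @param i Manifest row index.
#' @return As [render_video()], plus `row` (the manifest row).
#' @export
cohort_video <- function(cohort, i) {
  row <- cohort$manifest[i, ]
  sc <- cohort$scene
  s <- row$video_seed
  set.seed(s)
  w <- sc$width; h <- sc$height
  sl <- c(stats::runif(1, 0.22 * w, 0.30 * w), stats::runif(1, 0.45 * h, 0.55 * h))
  gl <- c(stats::runif(1, 0.12 * w, 0.40 * w), stats::runif(1, 0.25 * h, 0.75 * h))
  sr <- c(stats::runif(1, 0.70 * w, 0.78 * w), stats::runif(1, 0.45 * h, 0.55 * h))
  gr <- c(stats::runif(1, 0.60 * w, 0.88 * w), stats::runif(1, 0.25 * h, 0.75 * h))
  mp <- motion_params(row$skill)
  tl <- generate_trajectory(mp, sc$n_frames, sl, gl, seed = s + 1L)
  tr <- generate_trajectory(mp, sc$n_frames, sr, gr, seed = s + 2L)
  sc$seed <- s + 3L
  out <- render_video(tl, tr, sc)
  out$row <- row
  out
}

#' @export
print.sf_cohort <- function(x, ...) {
  m <- x$manifest
  cat("<sf_cohort> ", dplyr::n_distinct(m$subject), " subjects x ",
      max(m$trial), " trials x ", dplyr::n_distinct(m$task), " task(s): ",
      nrow(m), " videos\n", sep = "")
  print(table(skill = m$skill[!duplicated(m$subject)]))
  invisible(x)
}
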