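# Fixtures are generated in code, cached per test session.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# analytic rigid-translation scene: a smooth random-looking texture shifted
# by `shift` px per frame, exact to machine precision at any sub-pixel phase
rigid_scene <- function(n_frames = 20, shift = c(1.5, 0), h = 90, w = 130) {
  xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
  yy <- matrix(0:(h - 1), h, w)
  tex <- function(x, y) {
    0.5 + 0.16 * sin(0.55 * x) * sin(0.62 * y) +
      0.12 * sin(0.31 * x + 0.21 * y) + 0.08 * sin(0.17 * y - 0.12 * x)
  }
  lapply(seq_len(n_frames) - 1L, function(t) tex(xx - shift[1] * t, yy - shift[2] * t))
}

# a small rendered two-tool video plus its ROIs and ground truth
small_tool_video <- function(n_frames = 30, seed = 7,
                             left_skill = "expert", right_skill = "novice") {
  sc <- scene_spec(n_frames = n_frames, seed = seed)
  tl <- generate_trajectory(motion_params(left_skill), n_frames, c(40, 60), c(30, 45),
                            seed = seed + 1)
  tr <- generate_trajectory(motion_params(right_skill), n_frames, c(120, 60), c(130, 75),
                            seed = seed + 2)
  v <- render_video(tl, tr, sc)
  v$roi_left <- roi("left", 10, 30, 60, 60)
  v$roi_right <- roi("right", 90, 30, 60, 60)
  v
}

# class-separated synthetic window datasets for classifier/evaluation tests
# (no rendering: gaussian channels whose variance depends on the class)
toy_windows <- function(n_subjects = 4, trials = 3, per_trial = 2, W = 16, C = 8,
                        seed = 1, sd_by_class = c(novice = 3, expert = 1),
                        mean_shift = 3) {
  set.seed(seed)
  skills <- rep(names(sd_by_class), length.out = n_subjects)
  meta <- list()
  xs <- list()
  for (s in seq_len(n_subjects)) for (tr in seq_len(trials)) for (k in seq_len(per_trial)) {
    skill <- skills[s]
    xs[[length(xs) + 1L]] <- matrix(rnorm(W * C, mean = mean_shift *
                                            (skill == "expert"),
                                          sd = sd_by_class[[skill]]), W, C)
    meta[[length(meta) + 1L]] <- tibble::tibble(
      subject = sprintf("S%02d", s), task = "toy", trial = tr,
      skill = skill, window_index = k)
  }
  x <- array(0, c(length(xs), W, C))
  for (i in seq_along(xs)) x[i, , ] <- xs[[i]]
  structure(list(x = x, meta = dplyr::bind_rows(meta), window = W, step = W,
                 class_mode = "two_class", feature_names = paste0("f", seq_len(C))),
            class = "sf_windows")
}

# stub protocol methods with known behaviour: the oracle recovers the class
# from the planted mean shift (perfect by construction), the constant stub
# always predicts one label
stub_oracle <- function(threshold = 1.5) {
  skill_method(
    fit = function(x, y, seed) threshold,
    predict = function(model, x) {
      m <- apply(x, 1, mean)
      ifelse(m > model, "expert", "novice")
    },
    id = "oracle")
}
stub_constant <- function(label) {
  skill_method(fit = function(x, y, seed) label,
               predict = function(model, x) rep(model, dim(x)[1]),
               id = paste0("always_", label))
}
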