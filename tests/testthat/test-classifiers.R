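test_that("activations obey their defining identities", {
  expect_equal(relu(c(-2, 3)), c(0, 3))
  expect_equal(sigmoid(0), 0.5)
  expect_equal(softmax(c(1, 1, 1)), rep(1 / 3, 3))
  set.seed(1)
  z <- matrix(rnorm(40, sd = 4), 8, 5)
  p <- softmax(z)
  expect_equal(rowSums(p), rep(1, 8))
  expect_true(all(p > 0))
  expect_true(all(sigmoid(z) > 0 & sigmoid(z) < 1))
})

test_that("lstm_step has the analytic limits of the gate equations", {
  H <- 4
  zero_cell <- lapply(random_lstm_cell(3, H, 1), function(m) m * 0)
  zero_cell$c <- matrix(c(0.4, -0.2, 1, 0.3), 1, H)
  step <- lstm_step(zero_cell, rep(0, 3))
  # all pre-activations zero: i = f = o = 1/2, candidate tanh(0) = 0
  expect_equal(drop(step$c), 0.5 * drop(zero_cell$c))
  expect_equal(drop(step$h), 0.5 * tanh(0.5 * drop(zero_cell$c)))

  # saturated gates: forget ~ 1 and input ~ 0 preserve the memory cell
  mem <- zero_cell
  mem$bf <- rep(100, H)
  mem$bi <- rep(-100, H)
  step2 <- lstm_step(mem, rep(1, 3))
  expect_equal(drop(step2$c), drop(mem$c), tolerance = 1e-12)
})

test_that("lstm_step matches a literal transcription of the gate equations", {
  for (s in 1:5) {
    cell <- random_lstm_cell(c_in = 6, H = 5, seed = s)
    x_t <- rnorm(6)
    got <- lstm_step(cell, x_t)
    want <- lstm_step_literal(cell, x_t)
    expect_lt(max(abs(drop(got$h) - want$h)), 1e-6)
    expect_lt(max(abs(drop(got$c) - want$c)), 1e-6)
  }
})

test_that("frequency features match naive transforms and exhaustive peak sorts", {
  set.seed(9)
  for (L in c(16, 33, 64)) {
    x <- matrix(rnorm(3 * L), 3, L)
    # full-matrix agreement with the double-loop oracles; DFT magnitudes
    # come in exactly tied conjugate pairs (|Y_k| = |Y_(L-k)|), so the
    # selected sets are compared as sorted value multisets
    got_dft <- freq_features(x, "dft", n_peaks = L - 1)
    got_dct <- freq_features(x, "dct", n_peaks = L - 1)
    for (r in 1:3) {
      Yd <- naive_dft(x[r, ])
      Yc <- naive_dct(x[r, ])
      top_d <- sort(Mod(Yd), decreasing = TRUE)[seq_len(L - 1)]
      keep_c <- sort(order(-abs(Yc), seq_len(L))[seq_len(L - 1)])
      expect_lt(max(abs(sort(got_dft[(r - 1) * (L - 1) + seq_len(L - 1)],
                             decreasing = TRUE) - top_d)), 1e-9)
      expect_lt(max(abs(got_dct[(r - 1) * (L - 1) + seq_len(L - 1)] - Yc[keep_c])), 1e-9)
    }
  }

  # constant series: only the DC coefficient survives the DFT
  cst <- matrix(2.5, 1, 32)
  Y <- naive_dft(cst[1, ])
  expect_lt(max(Mod(Y[-1])), 1e-9)
  expect_equal(Mod(Y[1]), 2.5 * 32, tolerance = 1e-9)
  expect_equal(freq_features(cst, "dft", 1), 80, tolerance = 1e-9)

  # pure cosine of frequency 3 on L = 32: peaks at k = 3 and k = 29
  l <- 0:31
  cosr <- matrix(cos(2 * pi * 3 * l / 32), 1, 32)
  Yc <- naive_dft(cosr[1, ])
  expect_setequal(order(-Mod(Yc))[1:2], c(4, 30))  # 1-based indices of k = 3, 29
  expect_equal(freq_features(cosr, "dft", 2), c(16, 16), tolerance = 1e-9)

  expect_error(freq_features(cosr, "dft", 32), "smaller than L")
  expect_error(freq_features(cosr, "dft", 0), "at least 1")
})

test_that("classifier skeletons have the contracted heads and shapes", {
  set.seed(2)
  x <- array(rnorm(2 * 60 * 240), c(2, 60, 240))
  cnn3 <- build_cnn(c(60, 240), 3)
  sf <- asNamespace("skillflow")
  p3 <- softmax(sf$nn_forward_stack(cnn3$layers, x)$out)
  expect_equal(ncol(p3), 3)
  expect_equal(rowSums(p3), rep(1, 2))
  cnn2 <- build_cnn(c(60, 240), 2)
  p2 <- softmax(sf$nn_forward_stack(cnn2$layers, x)$out)
  expect_equal(ncol(p2), 2)
  expect_error(build_cnn(c(60, 240), 1), "at least 2")

  # cnn_lstm runs end to end and returns normalised probabilities
  cl <- build_cnn_lstm(c(60, 240), 3)
  pl <- softmax(sf$nn_forward_stack(cl$layers, x)$out)
  expect_equal(rowSums(pl), rep(1, 2))

  # every instantiated conv layer obeys the same-padding output-size law
  for (arch in c("cnn", "cnn_lstm", "resnet", "convauto")) {
    clf <- build_classifier(arch, c(60, 240), 2)
    geo <- conv_geometry(clf)
    expect_gt(nrow(geo), 0)
    expect_equal(geo$out_len, ceiling(geo$in_len / geo$stride))
  }

  # autoencoder: reconstruction shape equals input shape; must compress
  ae <- build_conv_autoencoder(c(60, 240), latent_dim = 32)
  out <- sf$nn_forward_stack(ae$layers, x)$out
  expect_equal(dim(out), dim(x))
  expect_error(build_conv_autoencoder(c(60, 240), latent_dim = 60 * 240),
               "compress")
})

test_that("fitting is seed-deterministic and separable data reach full accuracy", {
  ds <- toy_windows(W = 16, C = 8, seed = 3)
  cfg <- classifier_config(filters = c(8L, 8L), kernels = c(5L, 3L),
                           lstm_hidden = c(8L, 8L), resnet_filters = 8L,
                           lr = 5e-3, batch_size = 8, n_peaks = 5L)
  clf <- build_cnn(c(16, 8), 2, cfg)
  f1 <- fit(clf, ds$x, ds$meta$skill, seed = 11, epochs = 25)
  f2 <- fit(clf, ds$x, ds$meta$skill, seed = 11, epochs = 25)
  expect_identical(predict(f1, ds$x), predict(f2, ds$x))
  expect_identical(predict(f1, ds$x, head = "svm"), predict(f2, ds$x, head = "svm"))
  # linearly separable training set: the SVM head is perfect on it
  expect_equal(mean(predict(f1, ds$x, head = "svm") == ds$meta$skill), 1)
  expect_gt(mean(predict(f1, ds$x) == ds$meta$skill), 0.9)

  # both heads consume identical penultimate features
  pa <- penultimate_features(f1, ds$x)
  pb <- penultimate_features(f1, ds$x)
  expect_identical(pa, pb)
  expect_equal(ncol(pa), 8)

  # single-class training set is rejected
  one <- ds$meta$skill == "novice"
  expect_error(fit(clf, ds$x[one, , , drop = FALSE], ds$meta$skill[one]),
               "single class")
})

test_that("frequency and autoencoder methods classify through their SVM heads", {
  ds <- toy_windows(W = 16, C = 8, seed = 5)
  cfg <- classifier_config(n_peaks = 5L, ae_filters = c(6L, 4L), latent_dim = 12L,
                           lr = 5e-3, batch_size = 8)
  for (arch in c("dft", "dct")) {
    clf <- fit(build_classifier(arch, c(16, 8), 2, cfg), ds$x, ds$meta$skill, seed = 1)
    expect_equal(mean(predict(clf, ds$x) == ds$meta$skill), 1)
    # model head silently falls back to the only head these methods have
    expect_identical(predict(clf, ds$x, head = "model"), predict(clf, ds$x, head = "svm"))
  }
  ae <- fit(build_classifier("convauto", c(16, 8), 2, cfg), ds$x, ds$meta$skill,
            seed = 1, epochs = 15)
  expect_equal(dim(reconstruct(ae, ds$x)), dim(ds$x))
  expect_gt(mean(predict(ae, ds$x) == ds$meta$skill), 0.9)
  expect_equal(ncol(penultimate_features(ae, ds$x)), 12)
})
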