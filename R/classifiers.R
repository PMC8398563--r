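# The six benchmark classifiers for W x 240 optical-flow windows:
# 1-D CNN, LSTM, CNN+LSTM, residual network, convolutional autoencoder with
# an SVM head, and DFT/DCT frequency-peak features with an SVM. The neural
# architectures are built from the layer core in nn-core.R; SVM heads use
# e1071. Unprinted hyperparameters live in `classifier_config()` so every
# run can serialise the exact configuration it used.

ARCHITECTURES <- c("cnn", "lstm", "cnn_lstm", "resnet", "convauto", "dft", "dct")
SVM_ONLY <- c("convauto", "dft", "dct")

#' Default classifier hyperparameters
#'
#' One versioned bundle of every tunable the benchmark leaves open:
#' convolution filter counts and kernel sizes, LSTM hidden sizes, training
#' schedule (Adam learning rate, epochs, early-stopping patience, batch
#' size), L2 strength, autoencoder latent dimension, linear-SVM cost, and
#' the number `F` of frequency peaks kept per series. Override any entry
#' via `...`.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of hyperparameters.
#' @export
classifier_config <- function(...) {
  cfg <- list(
    filters = c(64L, 64L), kernels = c(7L, 5L),
    lstm_hidden = c(64L, 32L),
    cnn_lstm_strides = c(2L, 2L),
    resnet_filters = 64L,
    latent_dim = 64L, ae_filters = c(32L, 16L), ae_kernel = 5L,
    epochs = 100L, batch_size = 16L, lr = 1e-3, l2 = 1e-4,
    patience = 10L, min_delta = 1e-5,
    svm_cost = 1, n_peaks = 10L,
    peephole = TRUE, normalize = TRUE)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

new_skill_classifier <- function(architecture, input_shape, n_classes, config, layers,
                                 extra = list()) {
  structure(
    c(list(architecture = architecture,
           input_shape = as.integer(input_shape),
           n_classes = as.integer(n_classes),
           config = config,
           layers = layers,
           trained = FALSE,
           class_levels = NULL, norm = NULL, svm = NULL, seed = NULL),
      extra),
    class = "skill_classifier")
}

check_input_shape <- function(input_shape) {
  if (length(input_shape) != 2L || any(input_shape < 1)) {
    stop("input_shape must be (window length, feature count)")
  }
}

# ---- architecture builders --------------------------------------------------

#' Build a benchmark classifier skeleton
#'
#' Constructors for the six evaluation methods, all taking windows of shape
#' `input_shape = c(W, C)` (frames x features, C = 240 by default pipeline
#' output):
#'
#' * `build_cnn()`: two 1-D convolution blocks (conv -> batch norm -> ReLU),
#'   global average pooling over time, dense softmax head.
#' * `build_lstm()`: two LSTM blocks (peephole gates by default, see
#'   [lstm_step()]), softmax head on the final hidden state.
#' * `build_cnn_lstm()`: two convolution blocks followed by two LSTM blocks
#'   and a softmax head.
#' * `build_resnet()`: three residual blocks (each two convolution blocks
#'   plus a shortcut, projected by a width-1 convolution when the channel
#'   count changes), global average pooling, softmax head.
#' * `build_conv_autoencoder()`: strided convolutional encoder to a latent
#'   code, mirrored decoder back to the input shape, trained on
#'   reconstruction error; classification only ever happens through an SVM
#'   fitted on the latent codes.
#' * `build_freq_svm()`: no network — frequency-peak features
#'   ([freq_features()]) with a linear SVM.
#'
#' All convolutions use "same" padding, so each layer's output length is
#' `ceiling(input_length / stride)` (see [conv_out_len_same()]).
#'
#' @param input_shape Integer pair `c(W, C)`: window length and features.
#' @param n_classes Number of skill classes (2 or 3).
#' @param config Hyperparameters from [classifier_config()].
#' @param seed Integer seed for the weight initialisation.
#' @param latent_dim Autoencoder bottleneck width; must be smaller than the
#'   flattened input `W * C`.
#' @param transform `"dft"` or `"dct"` for `build_freq_svm()`.
#' @return An untrained `skill_classifier`; fit it with [fit()].
#' @seealso [fit.skill_classifier()], [predict.skill_classifier()]
#' @export
build_cnn <- function(input_shape, n_classes, config = classifier_config(), seed = 0L) {
  check_input_shape(input_shape)
  if (n_classes < 2) stop("n_classes must be at least 2")
  set.seed(seed)
  f <- config$filters; k <- config$kernels
  cc <- input_shape[2]
  layers <- list(
    nn_conv1d(cc, f[1], k[1]), nn_batchnorm(f[1]), nn_relu(),
    nn_conv1d(f[1], f[2], k[2]), nn_batchnorm(f[2]), nn_relu(),
    nn_gap(),
    nn_dense(f[2], n_classes))
  new_skill_classifier("cnn", input_shape, n_classes, config, layers)
}

#' @rdname build_cnn
#' @export
build_lstm <- function(input_shape, n_classes, config = classifier_config(), seed = 0L) {
  check_input_shape(input_shape)
  if (n_classes < 2) stop("n_classes must be at least 2")
  set.seed(seed)
  h <- config$lstm_hidden
  layers <- list(
    nn_lstm(input_shape[2], h[1], return_seq = TRUE, peephole = config$peephole),
    nn_lstm(h[1], h[2], return_seq = FALSE, peephole = config$peephole),
    nn_dense(h[2], n_classes))
  new_skill_classifier("lstm", input_shape, n_classes, config, layers)
}

#' @rdname build_cnn
#' @export
build_cnn_lstm <- function(input_shape, n_classes, config = classifier_config(), seed = 0L) {
  check_input_shape(input_shape)
  if (n_classes < 2) stop("n_classes must be at least 2")
  set.seed(seed)
  f <- config$filters; k <- config$kernels; h <- config$lstm_hidden
  s <- config$cnn_lstm_strides
  # strided convolutions shorten the sequence the LSTM blocks must span
  # (e.g. 60 -> 15 steps), which conditions the recurrent training far
  # better at small sample sizes
  layers <- list(
    nn_conv1d(input_shape[2], f[1], k[1], stride = s[1]),
    nn_batchnorm(f[1]), nn_relu(),
    nn_conv1d(f[1], f[2], k[2], stride = s[2]),
    nn_batchnorm(f[2]), nn_relu(),
    nn_lstm(f[2], h[1], return_seq = TRUE, peephole = config$peephole),
    nn_lstm(h[1], h[2], return_seq = FALSE, peephole = config$peephole),
    nn_dense(h[2], n_classes))
  new_skill_classifier("cnn_lstm", input_shape, n_classes, config, layers)
}

resnet_block <- function(c_in, c_out, kernels = c(7L, 5L)) {
  branch <- list(
    nn_conv1d(c_in, c_out, kernels[1]), nn_batchnorm(c_out), nn_relu(),
    nn_conv1d(c_out, c_out, kernels[2]), nn_batchnorm(c_out))
  shortcut <- if (c_in != c_out) {
    list(nn_conv1d(c_in, c_out, 1L), nn_batchnorm(c_out))
  } else {
    list()
  }
  nn_residual(branch, shortcut)
}

#' @rdname build_cnn
#' @export
build_resnet <- function(input_shape, n_classes, config = classifier_config(), seed = 0L) {
  check_input_shape(input_shape)
  if (n_classes < 2) stop("n_classes must be at least 2")
  set.seed(seed)
  f <- config$resnet_filters
  layers <- list(
    resnet_block(input_shape[2], f),
    resnet_block(f, f),
    resnet_block(f, f),
    nn_gap(),
    nn_dense(f, n_classes))
  new_skill_classifier("resnet", input_shape, n_classes, config, layers)
}

#' @rdname build_cnn
#' @export
build_conv_autoencoder <- function(input_shape, latent_dim = NULL,
                                   config = classifier_config(), seed = 0L) {
  check_input_shape(input_shape)
  if (is.null(latent_dim)) latent_dim <- config$latent_dim
  w <- input_shape[1]; cc <- input_shape[2]
  if (latent_dim >= w * cc) {
    stop("latent_dim (", latent_dim, ") must be smaller than the flattened input (",
         w * cc, "): the encoder must compress")
  }
  if (w %% 4 != 0) stop("autoencoder requires a window length divisible by 4")
  set.seed(seed)
  f <- config$ae_filters; k <- config$ae_kernel
  w4 <- w %/% 4L
  enc <- list(
    nn_conv1d(cc, f[1], k, stride = 2L), nn_relu(),
    nn_conv1d(f[1], f[2], k, stride = 2L), nn_relu(),
    nn_flatten(),
    nn_dense(w4 * f[2], latent_dim))
  dec <- list(
    nn_dense(latent_dim, w4 * f[2]), nn_relu(),
    nn_reshape(w4, f[2]),
    nn_upsample(2L), nn_conv1d(f[2], f[1], k), nn_relu(),
    nn_upsample(2L), nn_conv1d(f[1], cc, k))
  new_skill_classifier("convauto", input_shape, 0L, config, c(enc, dec),
                       extra = list(latent_dim = as.integer(latent_dim),
                                    latent_index = length(enc)))
}

#' @rdname build_cnn
#' @export
build_freq_svm <- function(input_shape, n_classes, transform = c("dft", "dct"),
                           config = classifier_config()) {
  check_input_shape(input_shape)
  if (n_classes < 2) stop("n_classes must be at least 2")
  transform <- match.arg(transform)
  if (config$n_peaks >= input_shape[1]) {
    stop("n_peaks (F = ", config$n_peaks, ") must be smaller than the window length L = ",
         input_shape[1])
  }
  new_skill_classifier(transform, input_shape, n_classes, config, list())
}

#' @rdname build_cnn
#' @param architecture One of `"cnn"`, `"lstm"`, `"cnn_lstm"`, `"resnet"`,
#'   `"convauto"`, `"dft"`, `"dct"`.
#' @export
build_classifier <- function(architecture, input_shape, n_classes,
                             config = classifier_config(), seed = 0L) {
  architecture <- match.arg(architecture, ARCHITECTURES)
  switch(architecture,
         cnn = build_cnn(input_shape, n_classes, config, seed),
         lstm = build_lstm(input_shape, n_classes, config, seed),
         cnn_lstm = build_cnn_lstm(input_shape, n_classes, config, seed),
         resnet = build_resnet(input_shape, n_classes, config, seed),
         convauto = build_conv_autoencoder(input_shape, config = config, seed = seed),
         dft = build_freq_svm(input_shape, n_classes, "dft", config),
         dct = build_freq_svm(input_shape, n_classes, "dct", config))
}

# ---- single LSTM step (exported for direct inspection) ----------------------

#' One step of the LSTM cell
#'
#' Applies the gate equations of the peephole LSTM to a single time step:
#' input gate `i = sigmoid(Wxi x + Whi h + wci * c + bi)`, forget gate
#' `f = sigmoid(Wxf x + Whf h + wcf * c + bf)`, cell update
#' `c' = f * c + i * tanh(Wxc x + Whc h + bc)`, output gate
#' `o = sigmoid(Wxo x + Who h + wco * c' + bo)` and hidden state
#' `h' = o * tanh(c')`. Peephole weights (`wci`, `wcf`, `wco`) are
#' per-cell scalars; with `peephole = FALSE` those terms are dropped,
#' giving the framework-standard cell.
#'
#' @param cell A list with weight matrices `Wxi, Whi, Wxf, Whf, Wxc, Whc,
#'   Wxo, Who`, bias vectors `bi, bf, bc, bo`, peephole vectors
#'   `wci, wcf, wco`, and the current state `h` (hidden) and `c` (memory),
#'   both `n x H` matrices.
#' @param x_t Input at this time step: an `n x C` matrix (or length-C
#'   vector for a single sample).
#' @param peephole Include the peephole terms? Default `TRUE`.
#' @return The cell list with `h` and `c` advanced by one step.
#' @export
lstm_step <- function(cell, x_t, peephole = TRUE) {
  if (is.null(dim(x_t))) x_t <- matrix(x_t, 1L)
  n <- nrow(x_t)
  h <- cell$h; cs <- cell$c
  ai <- x_t %*% cell$Wxi + h %*% cell$Whi + bcast_rows(cell$bi, n)
  af <- x_t %*% cell$Wxf + h %*% cell$Whf + bcast_rows(cell$bf, n)
  if (peephole) {
    ai <- ai + cs * bcast_rows(cell$wci, n)
    af <- af + cs * bcast_rows(cell$wcf, n)
  }
  ig <- sigmoid(ai)
  fg <- sigmoid(af)
  g <- tanh(x_t %*% cell$Wxc + h %*% cell$Whc + bcast_rows(cell$bc, n))
  c_new <- fg * cs + ig * g
  ao <- x_t %*% cell$Wxo + h %*% cell$Who + bcast_rows(cell$bo, n)
  if (peephole) ao <- ao + c_new * bcast_rows(cell$wco, n)
  og <- sigmoid(ao)
  h_new <- og * tanh(c_new)
  if (anyNA(h_new) || anyNA(c_new)) stop("NaN in LSTM state")
  cell$h <- h_new
  cell$c <- c_new
  cell
}

# ---- frequency features -----------------------------------------------------

dct_matrix <- function(L) {
  # Y_k = x_0 / 2 + sum_{l=1}^{L-1} x_l cos[(pi / L) * l * (k + 1/2)]
  M <- matrix(0, L, L)
  k <- 0:(L - 1)
  M[1, ] <- 0.5
  for (l in 1:(L - 1)) M[l + 1, ] <- cos(pi / L * l * (k + 0.5))
  M
}

#' Frequency-peak features of a multivariate window
#'
#' Treats each row of `x` as a univariate series of length `L`, transforms
#' it to the frequency domain — DFT `Y_k = sum_l x_l exp(-i 2 pi k l / L)`
#' or DCT `Y_k = x_0/2 + sum_{l>=1} x_l cos[(pi/L) l (k + 1/2)]` — and
#' keeps, per row, the `n_peaks` coefficients of largest magnitude (ties
#' broken toward the lower frequency index). The kept values (magnitudes
#' for the DFT, signed coefficients for the DCT) are returned in ascending
#' frequency order, concatenated row-major into one real vector of length
#' `nrow(x) * n_peaks` — the input the SVM head trains on.
#'
#' @param x Numeric matrix, one univariate series per row (a feature
#'   window is passed transposed: 240 rows x W columns).
#' @param transform `"dft"` or `"dct"`.
#' @param n_peaks Number of peaks `F` kept per row; must satisfy `F < L`.
#' @return Numeric vector of length `nrow(x) * n_peaks`.
#' @examples
#' w <- matrix(rnorm(8 * 16), 8, 16)
#' length(freq_features(w, "dft", 4))  # 32
#' @export
freq_features <- function(x, transform = c("dft", "dct"), n_peaks) {
  transform <- match.arg(transform)
  x <- as.matrix(x)
  L <- ncol(x)
  if (n_peaks >= L) stop("n_peaks (F = ", n_peaks, ") must be smaller than L = ", L)
  if (n_peaks < 1) stop("n_peaks must be at least 1")
  Y <- if (transform == "dft") {
    t(stats::mvfft(t(x)))
  } else {
    x %*% dct_matrix(L)
  }
  mag <- Mod(Y)
  out <- matrix(0, nrow(x), n_peaks)
  for (r in seq_len(nrow(x))) {
    keep <- sort(order(-mag[r, ], seq_len(L))[seq_len(n_peaks)])
    out[r, ] <- if (transform == "dft") mag[r, keep] else Re(Y[r, keep])
  }
  as.vector(t(out))
}

windows_to_freq <- function(x, transform, n_peaks) {
  # x: (N, W, C) -> matrix N x (C * n_peaks); each window transposed so rows
  # are univariate per-feature series
  n <- dim(x)[1]
  t(vapply(seq_len(n), function(i) {
    w <- x[i, , , drop = TRUE]
    dim(w) <- dim(x)[2:3]
    freq_features(t(w), transform, n_peaks)
  }, numeric(dim(x)[3] * n_peaks)))
}

# ---- normalization ----------------------------------------------------------

# subtract the within-window mean of selected channels (position columns):
# absolute image coordinates are camera-frame artifacts, only the motion
# relative to the window's own centroid generalises across trials
apply_center <- function(x, mask) {
  if (is.null(mask) || !any(mask)) return(x)
  idx <- which(mask)
  W <- dim(x)[2]
  for (i in seq_len(dim(x)[1])) {
    sl <- x[i, , idx]
    dim(sl) <- c(W, length(idx))
    x[i, , idx] <- sweep(sl, 2, colMeans(sl))
  }
  x
}

#' Channel mask of absolute-position features
#'
#' Identifies the position (x, y) columns of a feature layout by name, for
#' per-window centering at training time (see [fit.skill_classifier()]).
#'
#' @param feature_names Column names as produced by the feature extractor.
#' @return Logical vector, `TRUE` for position channels.
#' @export
position_mask <- function(feature_names) {
  grepl("_(x|y)[0-9]+$", feature_names)
}

norm_stats <- function(x) {
  cc <- dim(x)[3]
  xm <- x
  dim(xm) <- c(dim(x)[1] * dim(x)[2], cc)
  mu <- colMeans(xm)
  sd_ <- apply(xm, 2L, stats::sd)
  sd_[!is.finite(sd_) | sd_ < 1e-8] <- 1
  list(mu = mu, sd = sd_)
}

apply_norm <- function(x, norm) {
  if (is.null(norm)) return(x)
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3])
  xm <- (xm - bcast_rows(norm$mu, nrow(xm))) / bcast_rows(norm$sd, nrow(xm))
  dim(xm) <- d
  xm
}

as_window_array <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (is.list(x)) {
    w <- dim(x[[1]])
    out <- array(0, c(length(x), w[1], w[2]))
    for (i in seq_along(x)) out[i, , ] <- x[[i]]
    return(out)
  }
  stop("samples must be a (N, W, C) array or a list of W x C matrices")
}

# ---- fit / predict ----------------------------------------------------------

#' @importFrom generics fit
#' @export
generics::fit

#' Fit a benchmark classifier
#'
#' Trains a built classifier on labelled windows. Training is fully
#' deterministic given `seed`: the seed re-initialises the weights,
#' fixes the minibatch shuffling, and the SVM fit is itself
#' deterministic. Per-feature z-score normalisation statistics are
#' computed from the training windows only (disable with
#' `classifier_config(normalize = FALSE)`) and reused at prediction time.
#' Along with its softmax ("model") head, every network also gets an SVM
#' head fitted on its penultimate-layer features (global-average-pooled
#' channels for CNN/ResNet, the final hidden state for the LSTM variants,
#' latent codes for the autoencoder, frequency vectors for DFT/DCT).
#'
#' @param object An untrained `skill_classifier` from [build_classifier()].
#' @param x Windows: `(N, W, C)` array or list of `W x C` matrices.
#' @param y Skill labels, one per window (factor or character).
#' @param seed Integer seed controlling initialisation and shuffling.
#' @param epochs Optional override of `config$epochs`.
#' @param center Optional logical channel mask (length C): masked channels
#'   (absolute positions, see [position_mask()]) are centered per window
#'   before normalisation, making the representation translation
#'   invariant. Applied identically at prediction time.
#' @param ... Unused.
#' @return The fitted `skill_classifier`.
#' @method fit skill_classifier
#' @export
fit.skill_classifier <- function(object, x, y, seed = 0L, epochs = NULL,
                                 center = NULL, ...) {
  x <- as_window_array(x)
  y <- factor(y)
  if (nlevels(y) < 2) {
    stop("training set contains a single class ('", levels(y)[1],
         "'); at least one sample per class is required")
  }
  if (dim(x)[1] != length(y)) stop("number of windows and labels differ")
  cfg <- object$config
  if (!is.null(epochs)) cfg$epochs <- as.integer(epochs)
  set.seed(seed)
  object$seed <- as.integer(seed)
  object$class_levels <- levels(y)
  y_int <- as.integer(y)
  object$center_mask <- center
  x <- apply_center(x, center)
  if (cfg$normalize) {
    object$norm <- norm_stats(x)
    x <- apply_norm(x, object$norm)
  }
  arch <- object$architecture
  if (arch %in% c("dft", "dct")) {
    feats <- windows_to_freq(x, arch, cfg$n_peaks)
    object$svm <- e1071::svm(feats, y, kernel = "linear", cost = cfg$svm_cost,
                             scale = FALSE, type = "C-classification")
    object$trained <- TRUE
    return(object)
  }
  # fresh seed-dependent weights (the builder's seed only served the skeleton)
  object$layers <- build_classifier_layers(object, cfg)
  if (arch == "convauto") {
    tr <- nn_train(object$layers, x, y_int = NULL, target = x,
                   epochs = cfg$epochs, batch_size = cfg$batch_size,
                   lr = cfg$lr, l2 = cfg$l2,
                   patience = cfg$patience, min_delta = cfg$min_delta)
    object$layers <- tr$layers
    object$history <- tr$history
    object$trained <- TRUE
    lat <- penultimate_features(object, x, .normalized = TRUE)
    object$svm <- e1071::svm(lat, y, kernel = "linear", cost = cfg$svm_cost,
                             scale = FALSE, type = "C-classification")
    return(object)
  }
  tr <- nn_train(object$layers, x, y_int = y_int,
                 epochs = cfg$epochs, batch_size = cfg$batch_size,
                 lr = cfg$lr, l2 = cfg$l2,
                 patience = cfg$patience, min_delta = cfg$min_delta)
  object$layers <- tr$layers
  object$history <- tr$history
  object$trained <- TRUE
  pen <- penultimate_features(object, x, .normalized = TRUE)
  object$svm <- e1071::svm(pen, y, kernel = "linear", cost = cfg$svm_cost,
                           scale = FALSE, type = "C-classification")
  object
}

# rebuild the layer list of a classifier from its config using the current RNG
build_classifier_layers <- function(object, cfg) {
  tmp <- switch(object$architecture,
                cnn = build_cnn(object$input_shape, object$n_classes, cfg,
                                seed = sample.int(2^30, 1)),
                lstm = build_lstm(object$input_shape, object$n_classes, cfg,
                                  seed = sample.int(2^30, 1)),
                cnn_lstm = build_cnn_lstm(object$input_shape, object$n_classes, cfg,
                                          seed = sample.int(2^30, 1)),
                resnet = build_resnet(object$input_shape, object$n_classes, cfg,
                                      seed = sample.int(2^30, 1)),
                convauto = build_conv_autoencoder(object$input_shape, object$latent_dim,
                                                  cfg, seed = sample.int(2^30, 1)))
  tmp$layers
}

#' Penultimate-layer features
#'
#' The representation the SVM head trains on: global-average-pooled
#' channels (CNN, ResNet), the last LSTM hidden state (LSTM, CNN+LSTM),
#' the latent code (autoencoder) or the frequency-peak vector (DFT/DCT).
#'
#' @param object A `skill_classifier`.
#' @param x Windows: `(N, W, C)` array or list of matrices.
#' @param .normalized Internal: set when `x` is already normalised.
#' @return Numeric matrix, one row per window.
#' @export
penultimate_features <- function(object, x, .normalized = FALSE) {
  x <- as_window_array(x)
  if (!.normalized) {
    x <- apply_center(x, object$center_mask)
    x <- apply_norm(x, object$norm)
  }
  arch <- object$architecture
  if (arch %in% c("dft", "dct")) {
    return(windows_to_freq(x, arch, object$config$n_peaks))
  }
  fw <- nn_forward_stack(object$layers, x, training = FALSE, keep_outputs = TRUE)
  idx <- if (arch == "convauto") object$latent_index else length(object$layers) - 1L
  out <- fw$outputs[[idx]]
  if (length(dim(out)) == 3L) dim(out) <- c(dim(out)[1], prod(dim(out)[2:3]))
  out
}

#' Predict skill labels (or probabilities)
#'
#' @param object A fitted `skill_classifier`.
#' @param newdata Windows: `(N, W, C)` array or list of `W x C` matrices.
#' @param head `"model"` uses the network's softmax output; `"svm"` uses
#'   the SVM fitted on penultimate features. The autoencoder and DFT/DCT
#'   methods only have an SVM head.
#' @param type `"class"` for hard labels (default) or `"prob"` for the
#'   softmax probability matrix (model head only).
#' @param ... Unused.
#' @return A factor of labels, or a probability matrix for `type = "prob"`.
#' @export
predict.skill_classifier <- function(object, newdata, head = c("model", "svm"),
                                     type = c("class", "prob"), ...) {
  head <- match.arg(head)
  type <- match.arg(type)
  if (!object$trained) stop("classifier has not been fitted")
  if (object$architecture %in% SVM_ONLY) {
    if (identical(head, "model")) head <- "svm"
  }
  x <- as_window_array(newdata)
  x <- apply_center(x, object$center_mask)
  x <- apply_norm(x, object$norm)
  if (head == "svm") {
    feats <- penultimate_features(object, x, .normalized = TRUE)
    p <- stats::predict(object$svm, feats)
    return(factor(as.character(p), levels = object$class_levels))
  }
  fw <- nn_forward_stack(object$layers, x, training = FALSE)
  probs <- softmax(fw$out)
  colnames(probs) <- object$class_levels
  if (type == "prob") return(probs)
  factor(object$class_levels[max.col(probs, ties.method = "first")],
         levels = object$class_levels)
}

#' Reconstruct windows with a fitted autoencoder
#'
#' @param object A fitted `"convauto"` classifier.
#' @param x Windows: `(N, W, C)` array or list of matrices.
#' @return The reconstructed `(N, W, C)` array, on the normalised scale
#'   used for training.
#' @export
reconstruct <- function(object, x) {
  stopifnot(object$architecture == "convauto")
  x <- as_window_array(x)
  x <- apply_center(x, object$center_mask)
  x <- apply_norm(x, object$norm)
  nn_forward_stack(object$layers, x, training = FALSE)$out
}

#' Convolution geometry of a classifier on given input
#'
#' Runs a forward pass and reports, for every convolution layer actually
#' instantiated (including those inside residual blocks and the decoder),
#' its input length, kernel, stride, total padding and output length —
#' for verifying the same-padding output-size law.
#'
#' @param object A `skill_classifier` with network layers.
#' @param n Batch size of the probe input.
#' @return A tibble with columns `in_len`, `kernel`, `stride`,
#'   `pad_total`, `out_len`.
#' @export
conv_geometry <- function(object, n = 2L) {
  x <- array(stats::rnorm(n * prod(object$input_shape)),
             c(n, object$input_shape[1], object$input_shape[2]))
  fw <- nn_forward_stack(object$layers, x, training = FALSE)
  nn_conv_geometry(fw$layers, fw$caches)
}

#' @export
print.skill_classifier <- function(x, ...) {
  cat("<skill_classifier> ", x$architecture,
      "  input ", paste(x$input_shape, collapse = "x"),
      if (x$n_classes > 0) paste0("  classes ", x$n_classes) else "",
      if (x$trained) "  [trained]" else "  [untrained]", "\n", sep = "")
  invisible(x)
}
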