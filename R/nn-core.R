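# Minimal neural-network core for the classifier benchmark.
#
# Sequence batches are arrays of dim (N, W, C): N samples, W time steps
# (frames), C channels (features). Layers are plain lists tagged by $kind;
# forward passes return caches that the matching backward passes consume.
# Every backward pass is verified against numerical differentiation in the
# test suite. Training uses Adam with classic L2 regularisation folded into
# the gradient of the weight matrices (never biases or normalisation
# parameters).

bcast_rows <- function(v, m) matrix(v, m, length(v), byrow = TRUE)

# ---- convolution geometry (output-size laws) --------------------------------

#' Convolution output length
#'
#' Output size of a 1-D/2-D convolution along one axis:
#' `(W - F + 2P) / S + 1` for explicit padding `P`, and `ceil(W / S)` under
#' "same" padding (where the padding is chosen so the input is covered).
#'
#' @param input Input length (frames or pixels).
#' @param filter Filter (kernel) length along the axis.
#' @param pad Number of zero rows/columns padded on each side.
#' @param stride Stride along the axis.
#' @return Integer output length.
#' @examples
#' conv_out_len(60, 7, pad = 3, stride = 1)  # 60
#' conv_out_len_same(60, stride = 2)         # 30
#' @export
conv_out_len <- function(input, filter, pad = 0L, stride = 1L) {
  stopifnot(input >= 1, filter >= 1, stride >= 1, pad >= 0)
  out <- (input - filter + 2 * pad) / stride + 1
  if (out != floor(out)) {
    stop("convolution geometry does not tile: (", input, " - ", filter,
         " + 2*", pad, ") / ", stride, " + 1 is not an integer")
  }
  as.integer(out)
}

#' @rdname conv_out_len
#' @param input,stride Input length and stride.
#' @export
conv_out_len_same <- function(input, stride = 1L) {
  as.integer(ceiling(input / stride))
}

same_pad_total <- function(input, filter, stride) {
  out <- conv_out_len_same(input, stride)
  max((out - 1L) * stride + filter - input, 0L)
}

# ---- layer constructors -----------------------------------------------------

nn_conv1d <- function(c_in, c_out, kernel, stride = 1L, pad = "same") {
  sdv <- sqrt(2 / (kernel * c_in))
  list(kind = "conv1d",
       W = matrix(stats::rnorm(kernel * c_in * c_out, sd = sdv), kernel * c_in, c_out),
       b = numeric(c_out),
       kernel = as.integer(kernel), stride = as.integer(stride), pad = pad,
       c_in = as.integer(c_in), c_out = as.integer(c_out))
}

nn_batchnorm <- function(c_out, eps = 1e-5, momentum = 0.9) {
  list(kind = "batchnorm", gamma = rep(1, c_out), beta = numeric(c_out),
       run_mean = numeric(c_out), run_var = rep(1, c_out),
       eps = eps, momentum = momentum)
}

nn_relu <- function() list(kind = "relu")
nn_reshape <- function(w, c) list(kind = "reshape", w = as.integer(w), c = as.integer(c))
nn_gap <- function() list(kind = "gap")
nn_flatten <- function() list(kind = "flatten")
nn_upsample <- function(factor = 2L) list(kind = "upsample", factor = as.integer(factor))

nn_dense <- function(c_in, c_out) {
  sdv <- sqrt(2 / c_in)
  list(kind = "dense",
       W = matrix(stats::rnorm(c_in * c_out, sd = sdv), c_in, c_out),
       b = numeric(c_out), c_in = c_in, c_out = c_out)
}

nn_lstm <- function(c_in, hidden, return_seq = FALSE, peephole = TRUE) {
  g <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(1 / nr)), nr, nc)
  list(kind = "lstm", H = as.integer(hidden), c_in = as.integer(c_in),
       return_seq = return_seq, peephole = peephole,
       Wxi = g(c_in, hidden), Whi = g(hidden, hidden), wci = numeric(hidden), bi = numeric(hidden),
       Wxf = g(c_in, hidden), Whf = g(hidden, hidden), wcf = numeric(hidden),
       bf = rep(1, hidden),  # forget bias 1: standard retention-friendly init
       Wxc = g(c_in, hidden), Whc = g(hidden, hidden), bc = numeric(hidden),
       Wxo = g(c_in, hidden), Who = g(hidden, hidden), wco = numeric(hidden), bo = numeric(hidden))
}

nn_residual <- function(branch, shortcut = list()) {
  list(kind = "residual", branch = branch, shortcut = shortcut)
}

# ---- parameter trees --------------------------------------------------------

PARAM_NAMES <- c("W", "b", "gamma", "beta", "Wxi", "Whi", "wci", "bi",
                 "Wxf", "Whf", "wcf", "bf", "Wxc", "Whc", "bc",
                 "Wxo", "Who", "wco", "bo")
DECAY_NAMES <- c("W", "Wxi", "Whi", "Wxf", "Whf", "Wxc", "Whc", "Wxo", "Who")

layer_params <- function(layer) {
  if (layer$kind == "residual") {
    return(list(branch = lapply(layer$branch, layer_params),
                shortcut = lapply(layer$shortcut, layer_params)))
  }
  layer[intersect(names(layer), PARAM_NAMES)]
}

layer_set_params <- function(layer, params) {
  if (layer$kind == "residual") {
    layer$branch <- Map(layer_set_params, layer$branch, params$branch)
    layer$shortcut <- Map(layer_set_params, layer$shortcut, params$shortcut)
    return(layer)
  }
  for (nm in names(params)) layer[[nm]] <- params[[nm]]
  layer
}

# map a function over two parallel parameter trees (leaves are numeric)
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- Map(function(x, y) tree_map2(f, x, y), a, b)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

tree_zeros <- function(a) {
  if (is.list(a)) lapply(a, tree_zeros) else a * 0
}

# ---- forward / backward per layer ------------------------------------------

fwd_conv1d <- function(layer, x, training) {
  d <- dim(x); n <- d[1]; w_in <- d[2]; c_in <- d[3]
  k <- layer$kernel; s <- layer$stride
  pt <- if (identical(layer$pad, "same")) same_pad_total(w_in, k, s) else 2L * layer$pad
  pl <- pt %/% 2L
  wp <- w_in + pt
  w_out <- (wp - k) %/% s + 1L
  xp <- array(0, c(n, wp, c_in))
  xp[, pl + seq_len(w_in), ] <- x
  cols <- matrix(0, n * w_out, k * c_in)
  for (j in seq_len(k)) {
    idx <- j + s * (0:(w_out - 1L))
    sl <- xp[, idx, , drop = FALSE]
    dim(sl) <- c(n * w_out, c_in)
    cols[, (j - 1L) * c_in + seq_len(c_in)] <- sl
  }
  out <- cols %*% layer$W + bcast_rows(layer$b, n * w_out)
  dim(out) <- c(n, w_out, layer$c_out)
  cache <- list(cols = cols, n = n, w_in = w_in, w_out = w_out, wp = wp,
                pl = pl, c_in = c_in, s = s, k = k, pad_total = pt)
  list(out = out, cache = cache, layer = layer)
}

bwd_conv1d <- function(layer, cache, dout) {
  n <- cache$n; w_out <- cache$w_out; c_in <- cache$c_in
  dmat <- dout
  dim(dmat) <- c(n * w_out, layer$c_out)
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(layer$W)
  dxp <- array(0, c(n, cache$wp, c_in))
  for (j in seq_len(cache$k)) {
    idx <- j + cache$s * (0:(w_out - 1L))
    blk <- dcols[, (j - 1L) * c_in + seq_len(c_in)]
    dim(blk) <- c(n, w_out, c_in)
    dxp[, idx, ] <- dxp[, idx, , drop = FALSE] + blk
  }
  dx <- dxp[, cache$pl + seq_len(cache$w_in), , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

fwd_batchnorm <- function(layer, x, training) {
  d <- dim(x)
  cc <- d[length(d)]
  xm <- x
  dim(xm) <- c(prod(d[-length(d)]), cc)
  m <- nrow(xm)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - bcast_rows(mu, m)
    va <- colMeans(xc * xc)
    layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
    layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * va
  } else {
    mu <- layer$run_mean
    va <- layer$run_var
    xc <- xm - bcast_rows(mu, m)
  }
  ivar <- 1 / sqrt(va + layer$eps)
  xhat <- xc * bcast_rows(ivar, m)
  out <- xhat * bcast_rows(layer$gamma, m) + bcast_rows(layer$beta, m)
  dim(out) <- d
  list(out = out,
       cache = list(xhat = xhat, ivar = ivar, d = d, m = m, training = training),
       layer = layer)
}

bwd_batchnorm <- function(layer, cache, dout) {
  d <- cache$d; m <- cache$m
  dm <- dout
  dim(dm) <- c(m, d[length(d)])
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- dm * bcast_rows(layer$gamma, m)
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dx <- (dxhat - bcast_rows(s1 / m, m) - cache$xhat * bcast_rows(s2 / m, m)) *
      bcast_rows(cache$ivar, m)
  } else {
    dx <- dxhat * bcast_rows(cache$ivar, m)
  }
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

fwd_relu <- function(layer, x, training) {
  mask <- x > 0
  list(out = x * mask, cache = list(mask = mask), layer = layer)
}

bwd_relu <- function(layer, cache, dout) {
  list(dx = dout * cache$mask, grads = list())
}

fwd_gap <- function(layer, x, training) {
  d <- dim(x); n <- d[1]; w <- d[2]; cc <- d[3]
  out <- matrix(0, n, cc)
  for (t in seq_len(w)) {
    sl <- x[, t, , drop = FALSE]
    dim(sl) <- c(n, cc)
    out <- out + sl
  }
  out <- out / w
  list(out = out, cache = list(d = d), layer = layer)
}

bwd_gap <- function(layer, cache, dout) {
  d <- cache$d
  dx <- array(0, d)
  g <- dout / d[2]
  for (t in seq_len(d[2])) dx[, t, ] <- g
  list(dx = dx, grads = list())
}

fwd_flatten <- function(layer, x, training) {
  d <- dim(x)
  out <- x
  dim(out) <- c(d[1], prod(d[-1]))
  list(out = out, cache = list(d = d), layer = layer)
}

bwd_flatten <- function(layer, cache, dout) {
  dim(dout) <- cache$d
  list(dx = dout, grads = list())
}

fwd_upsample <- function(layer, x, training) {
  d <- dim(x); f <- layer$factor
  out <- array(0, c(d[1], d[2] * f, d[3]))
  for (j in seq_len(f)) out[, f * (seq_len(d[2]) - 1L) + j, ] <- x
  list(out = out, cache = list(d = d), layer = layer)
}

bwd_upsample <- function(layer, cache, dout) {
  d <- cache$d; f <- layer$factor
  dx <- array(0, d)
  for (j in seq_len(f)) dx <- dx + dout[, f * (seq_len(d[2]) - 1L) + j, , drop = FALSE]
  dim(dx) <- d
  list(dx = dx, grads = list())
}

fwd_reshape <- function(layer, x, training) {
  d <- dim(x)
  out <- x
  dim(out) <- c(d[1], layer$w, layer$c)
  list(out = out, cache = list(d = d), layer = layer)
}

bwd_reshape <- function(layer, cache, dout) {
  dim(dout) <- cache$d
  list(dx = dout, grads = list())
}

fwd_dense <- function(layer, x, training) {
  out <- x %*% layer$W + bcast_rows(layer$b, nrow(x))
  list(out = out, cache = list(x = x), layer = layer)
}

bwd_dense <- function(layer, cache, dout) {
  list(dx = dout %*% t(layer$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

# LSTM with the peephole gate equations (input and forget gates see
# c_{t-1}; the output gate sees the freshly updated c_t). Peephole weights
# are diagonal (one scalar per memory cell). peephole = FALSE drops those
# terms, giving the framework-standard cell.
fwd_lstm <- function(layer, x, training) {
  d <- dim(x); n <- d[1]; w <- d[2]; H <- layer$H
  h <- matrix(0, n, H); cs <- matrix(0, n, H)
  steps <- vector("list", w)
  hseq <- if (layer$return_seq) array(0, c(n, w, H)) else NULL
  pe <- layer$peephole
  for (t in seq_len(w)) {
    xt <- x[, t, , drop = TRUE]
    if (is.null(dim(xt))) xt <- matrix(xt, n, layer$c_in)
    cprev <- cs
    hprev <- h
    ai <- xt %*% layer$Wxi + hprev %*% layer$Whi + bcast_rows(layer$bi, n)
    af <- xt %*% layer$Wxf + hprev %*% layer$Whf + bcast_rows(layer$bf, n)
    if (pe) {
      ai <- ai + cprev * bcast_rows(layer$wci, n)
      af <- af + cprev * bcast_rows(layer$wcf, n)
    }
    ig <- sigmoid(ai)
    fg <- sigmoid(af)
    g <- tanh(xt %*% layer$Wxc + hprev %*% layer$Whc + bcast_rows(layer$bc, n))
    cs <- fg * cprev + ig * g
    ao <- xt %*% layer$Wxo + hprev %*% layer$Who + bcast_rows(layer$bo, n)
    if (pe) ao <- ao + cs * bcast_rows(layer$wco, n)
    og <- sigmoid(ao)
    tc <- tanh(cs)
    h <- og * tc
    if (anyNA(h)) stop("NaN in LSTM state at step ", t)
    steps[[t]] <- list(xt = xt, hprev = hprev, cprev = cprev,
                       i = ig, f = fg, g = g, o = og, c = cs, tc = tc)
    if (layer$return_seq) hseq[, t, ] <- h
  }
  out <- if (layer$return_seq) hseq else h
  list(out = out, cache = list(steps = steps, d = d), layer = layer)
}

bwd_lstm <- function(layer, cache, dout) {
  d <- cache$d; n <- d[1]; w <- d[2]; H <- layer$H
  pe <- layer$peephole
  z <- function(a, b) matrix(0, a, b)
  gr <- list(Wxi = 0 * layer$Wxi, Whi = 0 * layer$Whi, wci = 0 * layer$wci, bi = 0 * layer$bi,
             Wxf = 0 * layer$Wxf, Whf = 0 * layer$Whf, wcf = 0 * layer$wcf, bf = 0 * layer$bf,
             Wxc = 0 * layer$Wxc, Whc = 0 * layer$Whc, bc = 0 * layer$bc,
             Wxo = 0 * layer$Wxo, Who = 0 * layer$Who, wco = 0 * layer$wco, bo = 0 * layer$bo)
  dx <- array(0, d)
  dh_next <- z(n, H)
  dc_next <- z(n, H)
  for (t in rev(seq_len(w))) {
    st <- cache$steps[[t]]
    dh <- dh_next
    if (layer$return_seq) dh <- dh + dout[, t, ]
    else if (t == w) dh <- dh + dout
    do_ <- dh * st$tc
    dao <- do_ * st$o * (1 - st$o)
    dc <- dh * st$o * (1 - st$tc^2) + dc_next
    if (pe) dc <- dc + dao * bcast_rows(layer$wco, n)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$cprev
    dai <- di * st$i * (1 - st$i)
    daf <- df * st$f * (1 - st$f)
    dag <- dg * (1 - st$g^2)
    dc_next <- dc * st$f
    if (pe) dc_next <- dc_next + dai * bcast_rows(layer$wci, n) +
        daf * bcast_rows(layer$wcf, n)
    gr$Wxi <- gr$Wxi + crossprod(st$xt, dai)
    gr$Whi <- gr$Whi + crossprod(st$hprev, dai)
    gr$bi <- gr$bi + colSums(dai)
    gr$Wxf <- gr$Wxf + crossprod(st$xt, daf)
    gr$Whf <- gr$Whf + crossprod(st$hprev, daf)
    gr$bf <- gr$bf + colSums(daf)
    gr$Wxc <- gr$Wxc + crossprod(st$xt, dag)
    gr$Whc <- gr$Whc + crossprod(st$hprev, dag)
    gr$bc <- gr$bc + colSums(dag)
    gr$Wxo <- gr$Wxo + crossprod(st$xt, dao)
    gr$Who <- gr$Who + crossprod(st$hprev, dao)
    gr$bo <- gr$bo + colSums(dao)
    if (pe) {
      gr$wci <- gr$wci + colSums(dai * st$cprev)
      gr$wcf <- gr$wcf + colSums(daf * st$cprev)
      gr$wco <- gr$wco + colSums(dao * st$c)
    }
    dxt <- dai %*% t(layer$Wxi) + daf %*% t(layer$Wxf) +
      dag %*% t(layer$Wxc) + dao %*% t(layer$Wxo)
    dh_next <- dai %*% t(layer$Whi) + daf %*% t(layer$Whf) +
      dag %*% t(layer$Whc) + dao %*% t(layer$Who)
    dx[, t, ] <- dxt
  }
  # non-peephole cells keep their (unused) peephole slots with zero grads so
  # the parameter and gradient trees stay aligned
  keep <- intersect(names(layer), names(gr))
  list(dx = dx, grads = gr[keep])
}

fwd_residual <- function(layer, x, training) {
  br <- nn_forward_stack(layer$branch, x, training)
  if (length(layer$shortcut) > 0) {
    sc <- nn_forward_stack(layer$shortcut, x, training)
    s <- br$out + sc$out
    sc_caches <- sc$caches
    layer$shortcut <- sc$layers
  } else {
    s <- br$out + x
    sc_caches <- NULL
  }
  layer$branch <- br$layers
  mask <- s > 0
  list(out = s * mask,
       cache = list(branch = br$caches, shortcut = sc_caches, mask = mask),
       layer = layer)
}

bwd_residual <- function(layer, cache, dout) {
  ds <- dout * cache$mask
  br <- nn_backward_stack(layer$branch, cache$branch, ds)
  if (!is.null(cache$shortcut)) {
    sc <- nn_backward_stack(layer$shortcut, cache$shortcut, ds)
    dx <- br$dx + sc$dx
    grads <- list(branch = br$grads, shortcut = sc$grads)
  } else {
    dx <- br$dx + ds
    grads <- list(branch = br$grads, shortcut = list())
  }
  list(dx = dx, grads = grads)
}

FWD <- list(conv1d = fwd_conv1d, batchnorm = fwd_batchnorm, relu = fwd_relu,
            gap = fwd_gap, dense = fwd_dense, lstm = fwd_lstm,
            flatten = fwd_flatten, reshape = fwd_reshape,
            upsample = fwd_upsample, residual = fwd_residual)
BWD <- list(conv1d = bwd_conv1d, batchnorm = bwd_batchnorm, relu = bwd_relu,
            gap = bwd_gap, dense = bwd_dense, lstm = bwd_lstm,
            flatten = bwd_flatten, reshape = bwd_reshape,
            upsample = bwd_upsample, residual = bwd_residual)

# ---- stack traversal --------------------------------------------------------

nn_forward_stack <- function(layers, x, training = FALSE, keep_outputs = FALSE) {
  caches <- vector("list", length(layers))
  outputs <- if (keep_outputs) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    r <- FWD[[layers[[i]]$kind]](layers[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
    if (keep_outputs) outputs[[i]] <- x
  }
  list(out = x, caches = caches, layers = layers, outputs = outputs)
}

nn_backward_stack <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- BWD[[layers[[i]]$kind]](layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dout, grads = grads)
}

# Walk a forward pass and report geometry of every conv layer encountered
# (incl. inside residual blocks), for checking the output-size laws.
nn_conv_geometry <- function(layers, caches) {
  rows <- list()
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    ca <- caches[[i]]
    if (ly$kind == "conv1d") {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        in_len = ca$w_in, kernel = ca$k, stride = ca$s,
        pad_total = ca$pad_total, out_len = ca$w_out)
    } else if (ly$kind == "residual") {
      rows[[length(rows) + 1L]] <- nn_conv_geometry(ly$branch, ca$branch)
      if (!is.null(ca$shortcut)) {
        rows[[length(rows) + 1L]] <- nn_conv_geometry(ly$shortcut, ca$shortcut)
      }
    }
  }
  dplyr::bind_rows(rows)
}

# ---- losses -----------------------------------------------------------------

softmax_ce <- function(logits, y_int) {
  p <- softmax(logits)
  n <- nrow(p)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(n), y_int)] + eps))
  dlog <- p
  dlog[cbind(seq_len(n), y_int)] <- dlog[cbind(seq_len(n), y_int)] - 1
  list(loss = loss, dout = dlog / n, probs = p)
}

mse_loss <- function(out, target) {
  d <- out - target
  list(loss = mean(d * d), dout = 2 * d / length(d))
}

# ---- training ---------------------------------------------------------------

adam_init <- function(params) list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)

# one Adam step over a whole parameter tree; l2 applies only to leaves whose
# name is in DECAY_NAMES (weight matrices)
adam_step <- function(params, grads, state, lr, l2,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v, decay_ok) {
    if (is.list(p)) {
      nm <- names(p)
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]],
                  if (is.null(nm)) decay_ok else nm[k] %in% DECAY_NAMES)
        p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (isTRUE(decay_ok)) g <- g + l2 * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v, FALSE)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

slice_batch <- function(x, idx) {
  if (length(dim(x)) == 3L) x[idx, , , drop = FALSE] else x[idx, , drop = FALSE]
}

# Train a layer stack. y_int: integer labels (softmax loss) or NULL with
# target = x (autoencoder MSE). Returns updated layers + loss history.
nn_train <- function(layers, x, y_int = NULL, target = NULL,
                     epochs = 100L, batch_size = 16L, lr = 1e-3, l2 = 1e-4,
                     patience = 10L, min_delta = 1e-5, verbose = FALSE) {
  n <- dim(x)[1]
  params <- lapply(layers, layer_params)
  st <- adam_init(params)
  best <- Inf
  stale <- 0L
  history <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- slice_batch(x, idx)
      fw <- nn_forward_stack(layers, xb, training = TRUE)
      layers <- fw$layers
      if (is.null(y_int)) {
        ls <- mse_loss(fw$out, slice_batch(target, idx))
      } else {
        ls <- softmax_ce(fw$out, y_int[idx])
      }
      bw <- nn_backward_stack(layers, fw$caches, ls$dout)
      params <- lapply(layers, layer_params)
      up <- adam_step(params, bw$grads, st, lr = lr, l2 = l2)
      st <- up$state
      layers <- Map(layer_set_params, layers, up$params)
      ep_loss <- ep_loss + ls$loss
      nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb
    history <- c(history, ep_loss)
    if (verbose && ep %% 10 == 0) message("epoch ", ep, " loss ", signif(ep_loss, 4))
    if (ep_loss < best - min_delta) {
      best <- ep_loss
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  list(layers = layers, history = history)
}
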