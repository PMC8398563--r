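# Independent oracles, deliberately written as plain transcriptions and
# brute-force loops, never sharing code with the implementation.

# DFT: Y_k = sum_{l=0}^{L-1} x_l * exp(-i 2 pi k l / L), double loop
naive_dft <- function(x) {
  L <- length(x)
  Y <- complex(L)
  for (k in 0:(L - 1)) {
    acc <- 0 + 0i
    for (l in 0:(L - 1)) {
      acc <- acc + x[l + 1] * exp(-1i * 2 * pi * k * l / L)
    }
    Y[k + 1] <- acc
  }
  Y
}

# DCT: Y_k = x_0 / 2 + sum_{l=1}^{L-1} x_l * cos[(pi / L) * l * (k + 1/2)]
naive_dct <- function(x) {
  L <- length(x)
  Y <- numeric(L)
  for (k in 0:(L - 1)) {
    acc <- x[1] / 2
    for (l in 1:(L - 1)) {
      acc <- acc + x[l + 1] * cos(pi / L * l * (k + 0.5))
    }
    Y[k + 1] <- acc
  }
  Y
}

# literal transcription of the peephole LSTM gate equations, one sample
lstm_step_literal <- function(cell, x_t) {
  sig <- function(z) 1 / (1 + exp(-z))
  x <- as.numeric(x_t)
  h <- as.numeric(cell$h)
  c_prev <- as.numeric(cell$c)
  i_t <- sig(drop(x %*% cell$Wxi) + drop(h %*% cell$Whi) + cell$wci * c_prev + cell$bi)
  f_t <- sig(drop(x %*% cell$Wxf) + drop(h %*% cell$Whf) + cell$wcf * c_prev + cell$bf)
  c_t <- f_t * c_prev + i_t * tanh(drop(x %*% cell$Wxc) + drop(h %*% cell$Whc) + cell$bc)
  o_t <- sig(drop(x %*% cell$Wxo) + drop(h %*% cell$Who) + cell$wco * c_t + cell$bo)
  list(h = o_t * tanh(c_t), c = c_t)
}

# window count by explicit enumeration of start rows
enum_window_count <- function(L, W, S) {
  starts <- 0L
  s <- 0L
  while (s + W <= L) {
    starts <- starts + 1L
    s <- s + S
  }
  starts
}

# brute-force Shi-Tomasi score at a single pixel: 3x3-window structure
# tensor from central-difference gradients, smallest eigenvalue
brute_shi_tomasi <- function(img, px, py) {
  h <- nrow(img); w <- ncol(img)
  gx <- function(x, y) {
    xr <- min(x + 1, w - 1); xl <- max(x - 1, 0)
    (img[y + 1, xr + 1] - img[y + 1, xl + 1]) / 2
  }
  gy <- function(x, y) {
    yd <- min(y + 1, h - 1); yu <- max(y - 1, 0)
    (img[yd + 1, x + 1] - img[yu + 1, x + 1]) / 2
  }
  sxx <- sxy <- syy <- 0
  for (dx in -1:1) for (dy in -1:1) {
    x <- px + dx; y <- py + dy
    if (x < 0 || x >= w || y < 0 || y >= h) next
    a <- gx(x, y); b <- gy(x, y)
    sxx <- sxx + a * a; sxy <- sxy + a * b; syy <- syy + b * b
  }
  min(eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)$values)
}

random_lstm_cell <- function(c_in, H, seed, n = 1L) {
  set.seed(seed)
  g <- function(a, b) matrix(rnorm(a * b, sd = 0.4), a, b)
  list(Wxi = g(c_in, H), Whi = g(H, H), wci = rnorm(H, sd = 0.3), bi = rnorm(H, sd = 0.2),
       Wxf = g(c_in, H), Whf = g(H, H), wcf = rnorm(H, sd = 0.3), bf = rnorm(H, sd = 0.2),
       Wxc = g(c_in, H), Whc = g(H, H), bc = rnorm(H, sd = 0.2),
       Wxo = g(c_in, H), Who = g(H, H), wco = rnorm(H, sd = 0.3), bo = rnorm(H, sd = 0.2),
       h = matrix(rnorm(n * H, sd = 0.5), n, H),
       c = matrix(rnorm(n * H, sd = 0.5), n, H))
}
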