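# Low-level network layers.  Feature maps are [H, W, C] arrays; convolutions
# are lowered to matrix products through the im2col/col2im kernels in src/.
# Weight layout for a convolution: matrix (kh*kw*Cin) x Cout whose row order
# matches the im2col column order (ki fastest, then kj, then channel).

new_conv <- function(cin, cout, k = 3L, stride = 1L, gain = sqrt(2)) {
  fan_in <- k * k * cin
  list(type = "conv",
       W = matrix(rnorm(fan_in * cout, sd = gain / sqrt(fan_in)), fan_in, cout),
       b = numeric(cout),
       k = as.integer(k), stride = as.integer(stride),
       pad = as.integer((k - 1L) %/% 2L), cin = cin, cout = cout)
}

conv_forward <- function(layer, x) {
  d <- dim(x)
  M <- im2col_cpp(as.numeric(x), d[1], d[2], d[3],
                  layer$k, layer$k, layer$stride, layer$pad)
  Ho <- (d[1] + 2 * layer$pad - layer$k) %/% layer$stride + 1L
  Wo <- (d[2] + 2 * layer$pad - layer$k) %/% layer$stride + 1L
  y <- M %*% layer$W
  y <- sweep(y, 2, layer$b, "+")
  list(out = array(y, dim = c(Ho, Wo, layer$cout)),
       cache = list(M = M, din = d))
}

conv_backward <- function(layer, cache, dout) {
  do_ <- dim(dout)
  dY <- matrix(dout, do_[1] * do_[2], do_[3])
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dX <- col2im_cpp(dY %*% t(layer$W), cache$din[1], cache$din[2], cache$din[3],
                   layer$k, layer$k, layer$stride, layer$pad)
  list(dx = array(dX, dim = cache$din), grads = list(W = dW, b = db))
}

# Transposed convolution used for learned upsampling by integer factor f:
# kernel 2f, stride f, pad f/2, initialised to bilinear interpolation.
# Weight layout mirrors the downsampling conv it is the adjoint of:
# matrix (k*k*Cout) x Cin.
bilinear_kernel <- function(k, f) {
  c0 <- if (k %% 2 == 1) (k - 1) / 2 else k / 2 - 0.5  # 0-based center
  w <- 1 - abs(seq_len(k) - 1 - c0) / f
  outer(w, w)
}

new_convt <- function(cin, cout, factor) {
  f <- as.integer(factor)
  k <- 2L * f
  W <- matrix(0, k * k * cout, cin)
  filt <- bilinear_kernel(k, f)
  for (c in seq_len(min(cin, cout))) {
    rows <- (c - 1L) * k * k + seq_len(k * k)
    W[rows, c] <- as.numeric(filt)
  }
  list(type = "convt", W = W, b = numeric(cout),
       k = k, stride = f, pad = f %/% 2L, cin = cin, cout = cout)
}

convt_forward <- function(layer, x) {
  d <- dim(x)
  Hb <- d[1] * layer$stride; Wb <- d[2] * layer$stride
  Xmat <- matrix(x, d[1] * d[2], d[3])
  cols <- Xmat %*% t(layer$W)
  y <- col2im_cpp(cols, Hb, Wb, layer$cout,
                  layer$k, layer$k, layer$stride, layer$pad)
  y <- array(y, dim = c(Hb, Wb, layer$cout))
  y <- sweep(y, 3, layer$b, "+")
  list(out = y, cache = list(Xmat = Xmat, din = d, dout = c(Hb, Wb, layer$cout)))
}

convt_backward <- function(layer, cache, dout) {
  do_ <- cache$dout
  Mg <- im2col_cpp(as.numeric(dout), do_[1], do_[2], do_[3],
                   layer$k, layer$k, layer$stride, layer$pad)
  dX <- Mg %*% layer$W
  dW <- crossprod(Mg, cache$Xmat)
  db <- apply(dout, 3, sum)
  list(dx = array(dX, dim = cache$din), grads = list(W = dW, b = db))
}

new_maxpool <- function(k = 3L, stride = 2L) {
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer((k - 1L) %/% 2L))
}

maxpool_forward <- function(layer, x) {
  d <- dim(x)
  r <- maxpool_cpp(as.numeric(x), d[1], d[2], d[3], layer$k, layer$stride, layer$pad)
  list(out = array(r$out, dim = c(r$Ho, r$Wo, d[3])),
       cache = list(argmax = r$argmax, n_in = length(x), din = d))
}

maxpool_backward <- function(layer, cache, dout) {
  dx <- maxpool_backward_cpp(as.numeric(dout), cache$argmax, cache$n_in)
  list(dx = array(dx, dim = cache$din), grads = NULL)
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(cache, dout) dout * cache

sigmoid <- function(z) 1 / (1 + exp(-z))

# --- Adam over a flat list of parameter arrays -------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
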