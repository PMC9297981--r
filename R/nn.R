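# Layer-level primitives for the U-Net engine. Tensors are (H, W, C, N)
# arrays; convolution kernels live in C++ (src/nn_ops.cpp), the pointwise
# layers and batch normalization are vectorized R.

conv_fw <- function(x, W, b) cpp_conv2d_fw(x, dim(x), W, dim(W), b)

conv_bw <- function(x, W, dout) cpp_conv2d_bw(x, dim(x), W, dim(W), dout)

convt_fw <- function(x, W, b) cpp_convt2_fw(x, dim(x), W, b)

convt_bw <- function(x, W, dout) cpp_convt2_bw(x, dim(x), W, dout)

relu_fw <- function(x) { x[x < 0] <- 0; x }

relu_bw <- function(dout, x) { dout[x <= 0] <- 0; dout }

sigmoid_fw <- function(x) 1 / (1 + exp(-x))

# channel-wise batch normalization; in training mode statistics are computed
# over (H, W, N) per channel and running statistics updated in place by the
# caller; in inference mode the stored statistics are used
bn_fw <- function(x, gamma, beta, rmean, rvar, training, eps = 1e-5) {
  d <- dim(x); C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2L, mu)^2)
  } else {
    mu <- rmean; va <- rvar
  }
  xh <- sweep(sweep(xm, 2L, mu), 2L, sqrt(va + eps), `/`)
  y <- sweep(sweep(xh, 2L, gamma, `*`), 2L, beta, `+`)
  out <- aperm(array(y, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(out = out, xhat = xh, mu = mu, va = va, eps = eps)
}

bn_bw <- function(dout, cache, gamma) {
  d <- dim(dout); C <- d[3]
  dy <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = C)
  m <- nrow(dy)
  xh <- cache$xhat
  dgamma <- colSums(dy * xh)
  dbeta <- colSums(dy)
  dxh <- sweep(dy, 2L, gamma, `*`)
  inv_sd <- 1 / sqrt(cache$va + cache$eps)
  dx <- sweep(dxh - matrix(dbeta_term <- colMeans(dxh), m, C, byrow = TRUE) -
                xh * matrix(colMeans(dxh * xh), m, C, byrow = TRUE),
              2L, inv_sd, `*`)
  dx <- aperm(array(dx, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# inference-mode batch norm has a simple elementwise gradient
bn_bw_frozen <- function(dout, cache, gamma) {
  d <- dim(dout); C <- d[3]
  dy <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = C)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dx <- sweep(dy, 2L, gamma / sqrt(cache$va + cache$eps), `*`)
  dx <- aperm(array(dx, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dropout_fw <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  mask <- array(runif(length(x)) >= rate, dim = dim(x)) / (1 - rate)
  list(out = x * mask, mask = mask)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_ch <- function(d, c1) {
  list(a = d[, , seq_len(c1), , drop = FALSE],
       b = d[, , -seq_len(c1), , drop = FALSE])
}
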