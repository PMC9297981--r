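# Forward and backward passes of the U-Net (paired bottleneck arrangement).
# A processing block is conv -> ReLU -> BN -> dropout -> conv -> ReLU -> BN.
# Frozen blocks run batch normalization in inference mode (stored statistics,
# no updates), so they are strictly inert under fine-tuning.

block_fw <- function(prefix, x, params, trainable, training, dropout_rate) {
  p1 <- params[[paste0(prefix, "_conv1")]]
  p2 <- params[[paste0(prefix, "_conv2")]]
  b1 <- params[[paste0(prefix, "_bn1")]]
  b2 <- params[[paste0(prefix, "_bn2")]]
  bn_train <- training && trainable
  c1 <- conv_fw(x, p1$W, p1$b)
  r1 <- relu_fw(c1)
  n1 <- bn_fw(r1, b1$gamma, b1$beta, b1$rmean, b1$rvar, bn_train)
  dp <- dropout_fw(n1$out, dropout_rate, training)
  c2 <- conv_fw(dp$out, p2$W, p2$b)
  r2 <- relu_fw(c2)
  n2 <- bn_fw(r2, b2$gamma, b2$beta, b2$rmean, b2$rvar, bn_train)
  list(out = n2$out,
       cache = list(x = x, c1 = c1, n1 = n1, mask = dp$mask, dp_out = dp$out,
                    c2 = c2, n2 = n2, bn_train = bn_train))
}

block_bw <- function(prefix, dout, cache, params, dropout_rate) {
  p1 <- params[[paste0(prefix, "_conv1")]]
  p2 <- params[[paste0(prefix, "_conv2")]]
  b1 <- params[[paste0(prefix, "_bn1")]]
  b2 <- params[[paste0(prefix, "_bn2")]]
  bnb <- if (cache$bn_train) bn_bw else bn_bw_frozen
  g2 <- bnb(dout, cache$n2, b2$gamma)
  dr2 <- relu_bw(g2$dx, cache$c2)
  cv2 <- conv_bw(cache$dp_out, p2$W, dr2)
  dn1 <- cv2$dx
  if (!is.null(cache$mask)) dn1 <- dn1 * cache$mask
  g1 <- bnb(dn1, cache$n1, b1$gamma)
  dr1 <- relu_bw(g1$dx, cache$c1)
  cv1 <- conv_bw(cache$x, p1$W, dr1)
  grads <- list()
  grads[[paste0(prefix, "_conv1")]] <- list(W = cv1$dW, b = cv1$db)
  grads[[paste0(prefix, "_conv2")]] <- list(W = cv2$dW, b = cv2$db)
  grads[[paste0(prefix, "_bn1")]] <- list(gamma = g1$dgamma, beta = g1$dbeta)
  grads[[paste0(prefix, "_bn2")]] <- list(gamma = g2$dgamma, beta = g2$dbeta)
  list(dx = cv1$dx, grads = grads)
}

block_bn_updates <- function(prefix, cache, momentum = 0.9) {
  if (!cache$bn_train) return(list())
  upd <- list()
  upd[[paste0(prefix, "_bn1")]] <- list(mu = cache$n1$mu, va = cache$n1$va)
  upd[[paste0(prefix, "_bn2")]] <- list(mu = cache$n2$mu, va = cache$n2$va)
  upd
}

trainable_map <- function(spec) {
  m <- setNames(spec$layers$trainable, spec$layers$name)
  # block-level flag: a block is trainable iff its layers are
  m
}

block_trainable <- function(spec, prefix) {
  nm <- paste0(prefix, "_conv1")
  spec$layers$trainable[spec$layers$name == nm]
}

#' Forward pass of a U-Net model
#'
#' @param net a `unet` from [unet_init()].
#' @param x input tensor, `(H, W, 1, N)` array (or an `H x W` matrix, which
#'   is promoted); `H` and `W` must be divisible by `2^n_blocks`.
#' @param training training mode: batch statistics, dropout active.
#' @return list with `out` (same shape as `x`, values in `[0, 1]`) and,
#'   for `training = TRUE`, the backward `cache` and pending `bn_updates`.
#' @export
unet_forward <- function(net, x, training = FALSE) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  sp <- net$spec; p <- net$params
  n <- sp$n_blocks
  if (any(dim(x)[1:2] %% 2^n != 0))
    stop(sprintf("input size must be divisible by 2^%d", n))
  skips <- vector("list", n)
  caches <- list()
  cur <- x
  for (i in seq_len(n)) {
    bf <- block_fw(sprintf("d%d", i), cur, p, block_trainable(sp, sprintf("d%d", i)),
                   training, sp$dropout_rate)
    skips[[i]] <- bf$out
    caches[[sprintf("d%d", i)]] <- bf$cache
    mp <- cpp_maxpool2_fw(bf$out, dim(bf$out))
    caches[[sprintf("pool%d", i)]] <- list(arg = mp$arg, xdim = dim(bf$out))
    cur <- mp$out
  }
  bf <- block_fw("b", cur, p, block_trainable(sp, "b"), training,
                 sp$dropout_rate)
  caches[["b"]] <- bf$cache
  cur <- bf$out
  for (lvl in rev(seq_len(n))) {
    tn <- sprintf("u%d_tconv", lvl)
    caches[[paste0(tn, "_in")]] <- cur
    cur <- convt_fw(cur, p[[tn]]$W, p[[tn]]$b)
    cat_in <- concat_ch(cur, skips[[lvl]])
    caches[[sprintf("cat%d", lvl)]] <- dim(cur)[3]
    if (lvl > 1) {
      bf <- block_fw(sprintf("u%d", lvl - 1), cat_in, p,
                     block_trainable(sp, sprintf("u%d", lvl - 1)), training,
                     sp$dropout_rate)
      caches[[sprintf("u%d", lvl - 1)]] <- bf$cache
      cur <- bf$out
    } else {
      pf <- p[["final_conv"]]
      z <- conv_fw(cat_in, pf$W, pf$b)
      caches[["final_in"]] <- cat_in
      caches[["final_z"]] <- z
      out <- sigmoid_fw(z)
      caches[["out"]] <- out
    }
  }
  if (training) list(out = out, cache = caches)
  else list(out = out)
}

#' Backward pass (gradients of a scalar loss wrt all parameters)
#'
#' @param net a `unet`.
#' @param cache forward cache from `unet_forward(..., training = TRUE)`.
#' @param dout gradient of the loss wrt the network output (same shape).
#' @return named list of per-layer gradients plus pending batch-norm
#'   statistic updates.
#' @keywords internal
unet_backward <- function(net, cache, dout) {
  sp <- net$spec; p <- net$params
  n <- sp$n_blocks
  grads <- list()
  bn_upd <- list()
  # output head
  dz <- dout * cache$out * (1 - cache$out)
  cvf <- conv_bw(cache$final_in, p$final_conv$W, dz)
  grads$final_conv <- list(W = cvf$dW, b = cvf$db)
  dcat <- cvf$dx
  dskip <- vector("list", n)
  for (lvl in seq_len(n)) {
    ch <- cache[[sprintf("cat%d", lvl)]]
    sp_ <- split_ch(dcat, ch)
    dskip[[lvl]] <- sp_$b
    tn <- sprintf("u%d_tconv", lvl)
    tb <- convt_bw(cache[[paste0(tn, "_in")]], p[[tn]]$W, sp_$a)
    grads[[tn]] <- list(W = tb$dW, b = tb$db)
    dcur <- tb$dx
    if (lvl < n) {
      bb <- block_bw(sprintf("u%d", lvl), dcur, cache[[sprintf("u%d", lvl)]],
                     p, sp$dropout_rate)
      grads <- c(grads, bb$grads)
      bn_upd <- c(bn_upd, block_bn_updates(sprintf("u%d", lvl),
                                           cache[[sprintf("u%d", lvl)]]))
      dcat <- bb$dx
    } else {
      bb <- block_bw("b", dcur, cache$b, p, sp$dropout_rate)
      grads <- c(grads, bb$grads)
      bn_upd <- c(bn_upd, block_bn_updates("b", cache$b))
      dpool <- bb$dx
    }
  }
  for (i in rev(seq_len(n))) {
    pc <- cache[[sprintf("pool%d", i)]]
    dblk <- cpp_maxpool2_bw(dpool, pc$arg, pc$xdim) + dskip[[i]]
    bb <- block_bw(sprintf("d%d", i), dblk, cache[[sprintf("d%d", i)]], p,
                   sp$dropout_rate)
    grads <- c(grads, bb$grads)
    bn_upd <- c(bn_upd, block_bn_updates(sprintf("d%d", i),
                                         cache[[sprintf("d%d", i)]]))
    dpool <- bb$dx
  }
  list(grads = grads, bn_updates = bn_upd)
}

#' Predict corrected slices with a trained model
#'
#' Runs the network in inference mode on one slice or a stack of slices.
#'
#' @param net a trained `unet`.
#' @param x matrix (`H x W`) or `(H, W, 1, N)` array, normalized `[0, 1]`.
#' @return same shape as the input.
#' @export
unet_predict <- function(net, x) {
  was_mat <- is.matrix(x)
  out <- unet_forward(net, x, training = FALSE)$out
  if (was_mat) out <- out[, , 1L, 1L]
  out
}

#' Apply shading correction to a CBCT slice
#'
#' Runs the network on a normalized padded slice and composites the result
#' with the input: the correction is defined only inside the reconstructed
#' field of view, so pixels outside the FOV circle pass through unchanged.
#'
#' @param net a trained `unet`.
#' @param slice normalized padded input slice (square matrix centered on
#'   the isocenter).
#' @param fov_diameter FOV diameter in mm (default 208).
#' @param spacing pixel size in mm.
#' @return corrected slice, same shape, normalized scale.
#' @export
correct_slice <- function(net, slice, fov_diameter = 208, spacing = 1) {
  pred <- unet_predict(net, slice)
  d <- dim(slice)
  ci <- (d[1] + 1) / 2; cj <- (d[2] + 1) / 2
  xs <- ((1:d[1]) - ci) * spacing
  ys <- ((1:d[2]) - cj) * spacing
  outside <- outer(xs^2, ys^2, `+`) > (fov_diameter / 2)^2
  pred[outside] <- slice[outside]
  pred
}
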