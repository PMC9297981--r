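#' Training configuration
#'
#' ADAM hyperparameters follow the restoration task's defaults: learning
#' rate 0.001, beta1 0.9, beta2 0.999, mean-absolute-error loss on
#' normalized patches, checkpoint on maximum validation SSIM.
#'
#' @param learning_rate ADAM step size (default 0.001).
#' @param beta1,beta2 ADAM moment decay rates (defaults 0.9 / 0.999).
#' @param batch_size patches per optimization step (default 8).
#' @param epochs training epochs (default 30).
#' @param patch_size square crop fed to the network (default 128).
#' @param patches_per_slice fresh random crops drawn from every training
#'   slice per epoch (default 4); with runtime augmentation an epoch is
#'   several passes over the slices, each with new transforms.
#' @param seed master seed for shuffling, augmentation, and dropout.
#' @param verbose print per-epoch progress.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 8, epochs = 30, patch_size = 128,
                         patches_per_slice = 4, seed = 1L, verbose = FALSE) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (beta1 <= 0 || beta1 >= 1 || beta2 <= 0 || beta2 >= 1)
    stop("beta1 and beta2 must lie in (0, 1)")
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = batch_size, epochs = epochs,
                 patch_size = patch_size, patches_per_slice = patches_per_slice,
                 seed = seed, verbose = verbose),
            class = "train_config")
}

#' Runtime augmentation of a slice pair
#'
#' Draws one random `patch_size` crop window, a rotation by a multiple of
#' 90 degrees, and a horizontal flip, and applies the identical transform
#' to the input and label slices.
#'
#' @param pair a `slice_pair` (or any `list(input =, label =)` of equal
#'   matrices).
#' @param seed integer seed.
#' @param patch_size crop edge (default 128); must not exceed the slice.
#' @return a `slice_pair` of `patch_size` x `patch_size` matrices.
#' @export
augment <- function(pair, seed = 1L, patch_size = 128) {
  d <- dim(pair$input)
  if (patch_size > min(d)) stop("patch larger than the slice")
  with_seed(seed, {
    oi <- sample.int(d[1] - patch_size + 1L, 1L) - 1L
    oj <- sample.int(d[2] - patch_size + 1L, 1L) - 1L
    k <- sample.int(4L, 1L) - 1L
    fl <- runif(1) < 0.5
    tf <- function(s) {
      s <- s[oi + seq_len(patch_size), oj + seq_len(patch_size)]
      for (r in seq_len(k)) s <- t(s[nrow(s):1, , drop = FALSE])
      if (fl) s <- s[nrow(s):1, , drop = FALSE]
      s
    }
    out <- pair
    out$input <- tf(pair$input)
    out$label <- tf(pair$label)
    out
  })
}

adam_init <- function(params) {
  lapply(params, function(p)
    lapply(p[names(p) %in% c("W", "b", "gamma", "beta")],
           function(t) list(m = t * 0, v = t * 0)))
}

adam_step <- function(net, grads, state, t, cfg) {
  sp <- net$spec
  tr <- setNames(sp$layers$trainable, sp$layers$name)
  for (nm in names(grads)) {
    if (!isTRUE(tr[[nm]])) next
    for (fld in names(grads[[nm]])) {
      pf <- switch(fld, W = "W", b = "b", gamma = "gamma", beta = "beta")
      g <- grads[[nm]][[fld]]
      st <- state[[nm]][[pf]]
      st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
      st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * g^2
      mhat <- st$m / (1 - cfg$beta1^t)
      vhat <- st$v / (1 - cfg$beta2^t)
      net$params[[nm]][[pf]] <- net$params[[nm]][[pf]] -
        cfg$learning_rate * mhat / (sqrt(vhat) + 1e-8)
      state[[nm]][[pf]] <- st
    }
  }
  list(net = net, state = state)
}

apply_bn_updates <- function(net, upd, momentum = 0.9) {
  for (nm in names(upd)) {
    net$params[[nm]]$rmean <- momentum * net$params[[nm]]$rmean +
      (1 - momentum) * upd[[nm]]$mu
    net$params[[nm]]$rvar <- momentum * net$params[[nm]]$rvar +
      (1 - momentum) * upd[[nm]]$va
  }
  net
}

stack_pairs <- function(pairs) {
  ps <- dim(pairs[[1]]$input)[1]
  x <- array(0, dim = c(ps, ps, 1L, length(pairs)))
  y <- array(0, dim = c(ps, ps, 1L, length(pairs)))
  for (i in seq_along(pairs)) {
    x[, , 1L, i] <- pairs[[i]]$input
    y[, , 1L, i] <- pairs[[i]]$label
  }
  list(x = x, y = y)
}

validate_net <- function(net, val_pairs, max_slices = 6L) {
  if (length(val_pairs) == 0L)
    return(list(mae = NA_real_, ssim = NA_real_, psnr = NA_real_))
  if (length(val_pairs) > max_slices)
    val_pairs <- val_pairs[seq_len(max_slices)]
  maes <- ssims <- psnrs <- numeric(length(val_pairs))
  for (i in seq_along(val_pairs)) {
    pred <- unet_predict(net, val_pairs[[i]]$input)
    lab <- val_pairs[[i]]$label
    maes[i] <- mean(abs(pred - lab))
    ssims[i] <- ssim(lab, pred)
    psnrs[i] <- psnr(lab, pred)
  }
  list(mae = mean(maes), ssim = mean(ssims),
       psnr = mean(psnrs[is.finite(psnrs)]))
}

#' Train a U-Net on a slice-pair dataset
#'
#' Minimizes mean absolute error on augmented `patch_size` crops with ADAM.
#' Validation metrics are computed each epoch on full, un-augmented slices;
#' the returned model carries the weights of the epoch with the highest
#' validation SSIM. Fresh augmentation transforms are drawn every epoch
#' from a per-epoch seed stream, so the network never sees the same crop
#' twice. Layers outside an active fine-tune scope are not updated and
#' their batch-norm statistics stay fixed.
#'
#' @param net a `unet` from [unet_init()] (possibly with a fine-tune scope).
#' @param data a `dataset_split` from [build_dataset()].
#' @param cfg a [train_config()].
#' @param stage tag recorded in the history (`"single"`, `"pretrain"`,
#'   `"finetune"`).
#' @return list with `net` (best-checkpoint model) and `history`
#'   (per-epoch data.frame: train MAE, validation MAE/SSIM/PSNR, stage,
#'   and `best_epoch` attribute).
#' @export
train_model <- function(net, data, cfg = train_config(), stage = "single") {
  if (length(data$train) == 0L) stop("empty training set")
  n_tr <- length(data$train)
  pps <- max(1L, cfg$patches_per_slice %||% 1L)
  n_draw <- n_tr * pps
  steps <- max(1L, ceiling(n_draw / cfg$batch_size))
  state <- adam_init(net$params)
  hist <- data.frame()
  best <- list(ssim = -Inf, params = net$params, epoch = 0L)
  t_glob <- 0L
  epoch_seeds <- derive_seeds(cfg$seed, cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    sseed <- epoch_seeds[ep]
    order <- with_seed(sseed, sample.int(n_draw))
    aug_seeds <- derive_seeds(sseed + 1L, n_draw)
    ep_loss <- 0; ep_n <- 0
    for (st in seq_len(steps)) {
      ids <- order[((st - 1L) * cfg$batch_size + 1L):min(st * cfg$batch_size, n_draw)]
      patches <- lapply(seq_along(ids), function(j)
        augment(data$train[[(ids[j] - 1L) %% n_tr + 1L]],
                seed = aug_seeds[ids[j]], patch_size = cfg$patch_size))
      ba <- stack_pairs(patches)
      fw <- with_seed(sseed + st, unet_forward(net, ba$x, training = TRUE))
      err <- fw$out - ba$y
      loss <- mean(abs(err))
      dout <- sign(err) / length(err)
      bw <- unet_backward(net, fw$cache, dout)
      t_glob <- t_glob + 1L
      upd <- adam_step(net, bw$grads, state, t_glob, cfg)
      net <- upd$net; state <- upd$state
      net <- apply_bn_updates(net, bw$bn_updates)
      ep_loss <- ep_loss + loss * length(ids); ep_n <- ep_n + length(ids)
    }
    vm <- validate_net(net, data$val)
    hist <- rbind(hist, data.frame(epoch = ep, stage = stage,
                                   train_mae = ep_loss / ep_n,
                                   val_mae = vm$mae, val_ssim = vm$ssim,
                                   val_psnr = vm$psnr))
    if (is.finite(vm$ssim) && vm$ssim > best$ssim)
      best <- list(ssim = vm$ssim, params = net$params, epoch = ep)
    if (cfg$verbose)
      message(sprintf("[%s] epoch %d/%d train MAE %.5f val MAE %.5f val SSIM %.4f",
                      stage, ep, cfg$epochs, ep_loss / ep_n, vm$mae, vm$ssim))
  }
  if (is.finite(best$ssim)) net$params <- best$params
  attr(hist, "best_epoch") <- if (is.finite(best$ssim)) best$epoch else NA_integer_
  list(net = net, history = hist)
}

#' Run a training protocol (single-stage or two-stage transfer learning)
#'
#' `noFT`: a fresh network is trained in one stage on the target dataset.
#' `FTx`: a fresh network is first trained end to end on the synthetic
#' dataset (the Synth model), then the `x` deepest symmetric block pairs
#' are fine-tuned on the target dataset with everything else frozen.
#'
#' @param protocol `"noft"` or `"ftx"`.
#' @param ds_synth synthetic-pair `dataset_split` (required for `ftx`).
#' @param ds_target target-pair `dataset_split`.
#' @param x number of deepest block pairs to retrain (1-3 in the study
#'   grid), used by `ftx`.
#' @param spec a `unet_spec`.
#' @param cfg a [train_config()]; `pretrain_epochs` optionally overrides
#'   `cfg$epochs` for the synthetic stage.
#' @param pretrain_epochs epochs for the synthetic stage (default
#'   `cfg$epochs`).
#' @param init_seed weight initialization seed.
#' @return list with `net`, `histories` (list of per-stage histories tagged
#'   `single` or `pretrain`/`finetune`), and for `ftx` also `synth_net`
#'   (the pretrained model before fine-tuning).
#' @export
run_protocol <- function(protocol = c("noft", "ftx"), ds_synth = NULL,
                         ds_target, x = 2, spec = build_unet(),
                         cfg = train_config(), pretrain_epochs = NULL,
                         init_seed = 1L) {
  protocol <- match.arg(protocol)
  if (protocol == "noft") {
    net <- unet_init(spec, seed = init_seed)
    res <- train_model(net, ds_target, cfg, stage = "single")
    return(list(net = res$net, histories = list(single = res$history)))
  }
  if (is.null(ds_synth) || length(ds_synth$train) == 0L)
    stop("the ftx protocol requires a non-empty synthetic dataset")
  if (x < 1 || x > spec$n_blocks)
    stop("x must be between 1 and n_blocks")
  net <- unet_init(spec, seed = init_seed)
  pre_cfg <- cfg
  if (!is.null(pretrain_epochs)) pre_cfg$epochs <- pretrain_epochs
  pre <- train_model(net, ds_synth, pre_cfg, stage = "pretrain")
  synth_net <- pre$net
  ft_net <- set_finetune_scope(synth_net, x)
  ft_cfg <- cfg
  ft_cfg$seed <- cfg$seed + 1L
  ft <- train_model(ft_net, ds_target, ft_cfg, stage = "finetune")
  list(net = ft$net, synth_net = synth_net,
       histories = list(pretrain = pre$history, finetune = ft$history))
}

#' Leave-one-out cross-validation over scan pairs
#'
#' One fold per CBCT/CT pair: the pretrained Synth model is fine-tuned on
#' all pairs except the held-out one and evaluated on it; a single-stage
#' model trained from scratch on the same folds serves as the `noFT`
#' reference, and the unprocessed CBCT as `Base`. Per-fold median PSNR,
#' SSIM, and MAE (HU) are reported for each model tag.
#'
#' @param pairs list of `list(cbct =, ct =)` aligned [cbct_volume] pairs
#'   (>= 2).
#' @param base_net pretrained Synth `unet` used as the fine-tuning start.
#' @param cfg a [train_config()].
#' @param x fine-tune depth (default 2).
#' @param include_noft also train the single-stage reference per fold
#'   (default TRUE; skip to halve the runtime).
#' @param fov_diameter FOV passed to dataset assembly.
#' @param pad_size padded slice edge for dataset assembly (default 256).
#' @param train_fn training routine `function(net, ds, cfg, stage)`
#'   returning `list(net =, history =)`; injectable so the harness can be
#'   exercised with a stubbed trainer.
#' @return data.frame with one row per fold x model tag: `fold`, `tag`
#'   (`Base` / `noFT` / `FTx`), `psnr_median`, `ssim_median`,
#'   `mae_median_hu`, `width_mm`.
#' @export
run_loocv <- function(pairs, base_net, cfg = train_config(), x = 2,
                      include_noft = TRUE, fov_diameter = 208,
                      pad_size = 256, train_fn = train_model) {
  if (length(pairs) < 2L) stop("need at least 2 pairs for cross-validation")
  n <- length(pairs)
  rows <- list()
  for (fold in seq_len(n)) {
    tr_pairs <- pairs[-fold]
    ds <- build_dataset(tr_pairs, ratios = c(0.8, 0.2, 0), seed = cfg$seed,
                        split_level = if (length(tr_pairs) >= 3) "volume" else "slice",
                        fov_diameter = fov_diameter, pad_size = pad_size)
    ft_net <- set_finetune_scope(base_net, x)
    ft <- train_fn(ft_net, ds, cfg, stage = "finetune")
    nets <- setNames(list(ft$net), sprintf("FT%d", x))
    if (include_noft) {
      fresh <- unet_init(base_net$spec, seed = cfg$seed + fold)
      no <- train_fn(fresh, ds, cfg, stage = "single")
      nets$noFT <- no$net
    }
    held <- build_dataset(pairs[fold], ratios = c(0, 0, 1), seed = cfg$seed,
                          split_level = "slice", fov_diameter = fov_diameter,
                          pad_size = pad_size)
    test_pairs <- held$test
    models <- c(list(Base = NULL), nets)
    for (nm in names(models)) {
      ps <- sapply(test_pairs, slice_pair_metrics, net = models[[nm]])
      rows[[length(rows) + 1L]] <- data.frame(
        fold = fold, tag = nm,
        psnr_median = median(ps["psnr", ]),
        ssim_median = median(ps["ssim", ]),
        mae_median_hu = median(ps["mae_hu", ]),
        width_mm = attr(pairs[[fold]]$cbct, "width_mm") %||% NA_real_)
    }
  }
  do.call(rbind, rows)
}
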