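test_that("augmentation applies one shared transform to input and label", {
  p <- toy_pair(1, n = 40)
  a <- augment(p, seed = 3, patch_size = 24)
  expect_identical(dim(a$input), c(24L, 24L))
  a2 <- augment(p, seed = 3, patch_size = 24)
  expect_identical(a$input, a2$input)
  # a pair whose input equals its label stays equal after augmentation
  pe <- p; pe$input <- pe$label
  ae <- augment(pe, seed = 7, patch_size = 24)
  expect_identical(ae$input, ae$label)
  # full-slice patch: rotation/flip only, pixel multiset preserved
  af <- augment(p, seed = 11, patch_size = 40)
  expect_identical(sort(as.vector(af$input)), sort(as.vector(p$input)))
  expect_error(augment(p, 1, patch_size = 64), "patch")
})

test_that("training reduces the loss and returns the best-SSIM checkpoint", {
  ds <- toy_dataset(n_train = 10, n_val = 3)
  net <- unet_init(build_unet(2, 4), seed = 1)
  cfg <- train_config(epochs = 6, patch_size = 16, batch_size = 4,
                      patches_per_slice = 3, seed = 2)
  res <- train_model(net, ds, cfg)
  h <- res$history
  expect_identical(nrow(h), 6L)
  expect_lt(h$train_mae[6], h$train_mae[1])
  # checkpoint rule: returned weights reproduce the maximum validation SSIM
  vm <- cbctshade:::validate_net(res$net, ds$val)
  expect_equal(vm$ssim, max(h$val_ssim), tolerance = 1e-10)
  expect_identical(attr(h, "best_epoch"), which.max(h$val_ssim))
  expect_error(train_model(net, structure(list(train = list(), val = list(),
                                               test = list()),
                                          class = "dataset_split"), cfg),
               "empty")
})

test_that("out-of-scope weights stay bit-identical under fine-tuning", {
  ds <- toy_dataset(n_train = 6, n_val = 2)
  pre <- train_model(unet_init(build_unet(3, 4), seed = 2), ds,
                     train_config(epochs = 2, patch_size = 16,
                                  batch_size = 4, seed = 3),
                     stage = "pretrain")
  ft <- set_finetune_scope(pre$net, 1)
  res <- train_model(ft, ds, train_config(epochs = 2, patch_size = 16,
                                          batch_size = 4, seed = 4),
                     stage = "finetune")
  frozen <- c("d1_conv1", "d1_bn1", "d2_conv2", "u1_conv1", "u1_tconv",
              "u2_conv2", "u2_bn2", "u2_tconv")
  for (nm in frozen)
    expect_identical(res$net$params[[nm]], pre$net$params[[nm]])
  expect_false(identical(res$net$params$b_conv1$W, pre$net$params$b_conv1$W))
})

test_that("protocols wire the stages, scopes, and tags correctly", {
  ds_s <- toy_dataset(n_train = 6, n_val = 2)
  ds_t <- toy_dataset(n_train = 4, n_val = 2, seed_off = 50)
  spec <- build_unet(4, 2)
  cfg <- train_config(epochs = 1, patch_size = 16, batch_size = 4, seed = 5)
  no <- run_protocol("noft", ds_target = ds_t, spec = spec, cfg = cfg)
  expect_named(no$histories, "single")
  expect_identical(unique(no$histories$single$stage), "single")
  ft <- run_protocol("ftx", ds_s, ds_t, x = 2, spec = spec, cfg = cfg)
  expect_named(ft$histories, c("pretrain", "finetune"))
  # FT2 on the 4-block net retrains exactly the 64-128-128-64 blocks
  tr <- ft$net$spec$layers
  blocks_trained <- unique(sub("_(conv|bn|tconv).*", "", tr$name[tr$trainable]))
  expect_setequal(blocks_trained, c("d3", "d4", "b", "u3", "u4", "final"))
  # out-of-scope weights equal the Synth model's
  for (nm in c("d1_conv1", "d2_conv2", "u1_conv2", "u2_conv1", "u1_tconv"))
    expect_identical(ft$net$params[[nm]], ft$synth_net$params[[nm]])
  expect_error(run_protocol("ftx", NULL, ds_t, spec = spec, cfg = cfg),
               "synthetic")
})

test_that("a pretrained start converges at least as fast as scratch", {
  # average over three seeds of first-epoch validation MAE on the target
  # task: transfer initialization should not start worse than random
  deltas <- sapply(1:3, function(s) {
    ds_s <- toy_dataset(n_train = 8, n_val = 2, seed_off = 100 * s)
    ds_t <- toy_dataset(n_train = 6, n_val = 2, seed_off = 100 * s + 30)
    spec <- build_unet(2, 4)
    cfg1 <- train_config(epochs = 4, patch_size = 16, batch_size = 4,
                         seed = s)
    pre <- train_model(unet_init(spec, seed = s), ds_s, cfg1, "pretrain")
    cfg2 <- train_config(epochs = 1, patch_size = 16, batch_size = 4,
                         seed = s + 7)
    ftr <- train_model(set_finetune_scope(pre$net, 2), ds_t, cfg2, "finetune")
    scr <- train_model(unet_init(spec, seed = s + 13), ds_t, cfg2, "single")
    scr$history$val_mae[1] - ftr$history$val_mae[1]
  })
  expect_gt(mean(deltas), 0)
})
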