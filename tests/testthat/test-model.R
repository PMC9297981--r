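test_that("the builder mirrors level widths and ends in one sigmoid map", {
  spec <- build_unet(4, 16)
  expect_identical(spec$widths, c(16, 32, 64, 128))
  final <- spec$layers[spec$layers$name == "final_conv", ]
  expect_identical(final$cout, 1)
  # the deepest pair is two 128-wide blocks; expanding widths mirror down
  expect_identical(spec$layers$cout[spec$layers$name == "b_conv2"], 128)
  expect_identical(spec$layers$cout[spec$layers$name == "u3_conv2"], 64)
  expect_identical(spec$layers$cout[spec$layers$name == "u1_conv2"], 16)
  # degenerate minimal network builds and runs
  mini <- unet_init(build_unet(1, 1), seed = 1)
  out <- unet_forward(mini, matrix(0.5, 16, 16))$out
  expect_identical(dim(out), c(16L, 16L, 1L, 1L))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("parameter counting matches closed forms", {
  # one 3x3 conv 1 -> 16 plus its batch norm
  spec1 <- build_unet(1, 16)
  ly <- spec1$layers
  expect_identical(cbctshade:::layer_param_count(ly[ly$name == "d1_conv1", ]),
                   1 * 16 * 9 + 16)
  expect_identical(cbctshade:::layer_param_count(ly[ly$name == "d1_bn1", ]),
                   2 * 16)
  # full count is the sum over layers, invariant to any input size
  spec <- build_unet(2, 8)
  manual <- sum(vapply(seq_len(nrow(spec$layers)), function(i)
    cbctshade:::layer_param_count(spec$layers[i, ]), numeric(1)))
  expect_identical(count_trainable_parameters(spec), manual)
})

test_that("fine-tune scope selects the deepest symmetric pairs", {
  spec <- build_unet(4, 16)
  s1 <- set_finetune_scope(spec, 1)
  tr <- s1$layers$name[s1$layers$trainable]
  # only the 128-128 level (deepest contracting block + its expanding twin,
  # the transpose that follows it) plus the always-trainable output conv
  expect_setequal(tr, c("d4_conv1", "d4_bn1", "d4_conv2", "d4_bn2",
                        "b_conv1", "b_bn1", "b_conv2", "b_bn2",
                        "u4_tconv", "final_conv"))
  expect_identical(count_trainable_parameters(set_finetune_scope(spec, 0)), 0L)
  expect_identical(count_trainable_parameters(set_finetune_scope(spec, 4)),
                   count_trainable_parameters(spec, scoped = FALSE))
  expect_error(set_finetune_scope(spec, 5), "scope")
})

test_that("specifications round-trip through YAML with their scope", {
  spec <- set_finetune_scope(build_unet(3, 8, final_kernel = 3), 2)
  tmp <- tempfile(fileext = ".yaml")
  write_unet_spec(spec, tmp)
  back <- read_unet_spec(tmp)
  expect_identical(back$layers, spec$layers)
  expect_identical(back$finetune_scope, spec$finetune_scope)
  expect_identical(count_trainable_parameters(back),
                   count_trainable_parameters(spec))
})

test_that("forward pass is shape-preserving and bounded at any valid size", {
  net <- unet_init(build_unet(2, 4), seed = 3)
  for (sz in c(16, 32, 64)) {
    x <- array(runif(sz * sz * 2), dim = c(sz, sz, 1, 2))
    out <- unet_forward(net, x)$out
    expect_identical(dim(out), dim(x))
    expect_true(all(out >= 0 & out <= 1))
  }
  expect_error(unet_forward(net, matrix(0, 15, 15)), "divisible")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(4)
  net <- unet_init(build_unet(2, 3, dropout_rate = 0), seed = 5)
  x <- array(runif(16 * 16 * 2), dim = c(16, 16, 1, 2))
  y <- array(runif(16 * 16 * 2), dim = c(16, 16, 1, 2))
  loss_of <- function(n) mean(abs(unet_forward(n, x, training = TRUE)$out - y))
  fw <- unet_forward(net, x, training = TRUE)
  bw <- cbctshade:::unet_backward(net, fw$cache,
                                  sign(fw$out - y) / length(y))
  eps <- 1e-6
  for (nm in c("d1_conv1", "b_conv2", "u1_conv1", "u2_tconv", "final_conv",
               "d2_bn2")) {
    for (fld in intersect(names(net$params[[nm]]),
                          c("W", "b", "gamma", "beta"))) {
      ii <- sample(length(net$params[[nm]][[fld]]),
                   min(2, length(net$params[[nm]][[fld]])))
      for (i in ii) {
        np <- net; np$params[[nm]][[fld]][i] <- np$params[[nm]][[fld]][i] + eps
        nn <- net; nn$params[[nm]][[fld]][i] <- nn$params[[nm]][[fld]][i] - eps
        num <- (loss_of(np) - loss_of(nn)) / (2 * eps)
        expect_lt(abs(num - bw$grads[[nm]][[fld]][i]),
                  1e-4 * max(1, abs(num)))
      }
    }
  }
})
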