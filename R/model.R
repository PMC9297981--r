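#' Declarative U-Net specification
#'
#' Describes the symmetric encoder-decoder used for slice-to-slice HU
#' restoration: `n_blocks` contracting processing blocks (each two 3x3
#' convolutions with ReLU, batch normalization after every convolution and
#' dropout between them) joined by 2x2 max pooling, a mirrored expanding
#' path with transpose-convolution upsampling and skip concatenations at
#' matching widths, and a single-feature-map convolution with sigmoid
#' output. Level widths double per level (`first_filters * 2^(level-1)`).
#'
#' Two bottleneck arrangements are supported. `"paired"` (default): the
#' deepest contracting block is pooled into an equal-width expanding block
#' (the `w_n`-`w_n` pair), transpose convolutions preserve their channel
#' count, and each expanding block halves the width after the skip
#' concatenation, so a 4-block/16-filter network reads
#' 16-32-64-128-128-64-32-16. `"pooled"`: the classic arrangement in which
#' every transpose convolution maps to the level width and each expanding
#' block keeps it.
#'
#' @param n_blocks number of processing blocks per path (the tuning grid
#'   uses 4 or 5).
#' @param first_filters feature maps of the first block (16/32/64 in the
#'   grid).
#' @param dropout_rate dropout fraction between the two convolutions of a
#'   block (default 0.10).
#' @param transpose_kernel transpose-convolution kernel size, 2 or 3
#'   (counting supports both; the runtime engine executes 2).
#' @param final_kernel kernel of the output convolution, 1 or 3.
#' @param bottleneck `"paired"` or `"pooled"` (see above).
#' @param finetune_final should the output convolution stay trainable under
#'   a fine-tune scope (default TRUE).
#' @return an object of class `unet_spec` with a `layers` table (name,
#'   type, kernel, cin, cout, level, trainable) from which parameter counts
#'   and freeze scopes derive.
#' @export
build_unet <- function(n_blocks = 4, first_filters = 16, dropout_rate = 0.10,
                       transpose_kernel = 2, final_kernel = 1,
                       bottleneck = c("paired", "pooled"),
                       finetune_final = TRUE) {
  bottleneck <- match.arg(bottleneck)
  if (n_blocks < 1 || first_filters < 1)
    stop("n_blocks and first_filters must be >= 1")
  if (!transpose_kernel %in% c(2, 3) || !final_kernel %in% c(1, 3))
    stop("transpose_kernel must be 2 or 3; final_kernel 1 or 3")
  w <- first_filters * 2^(seq_len(n_blocks) - 1)
  L <- list()
  add <- function(name, type, k, cin, cout, level)
    L[[length(L) + 1L]] <<- data.frame(name = name, type = type, k = k,
                                       cin = cin, cout = cout, level = level,
                                       stringsAsFactors = FALSE)
  cin <- 1L
  for (i in seq_len(n_blocks)) {
    add(sprintf("d%d_conv1", i), "conv", 3, cin, w[i], i)
    add(sprintf("d%d_bn1", i), "bn", 0, w[i], w[i], i)
    add(sprintf("d%d_conv2", i), "conv", 3, w[i], w[i], i)
    add(sprintf("d%d_bn2", i), "bn", 0, w[i], w[i], i)
    cin <- w[i]
  }
  n <- n_blocks
  if (bottleneck == "paired") {
    # expanding block paired with the deepest contracting block, same width
    add("b_conv1", "conv", 3, w[n], w[n], n)
    add("b_bn1", "bn", 0, w[n], w[n], n)
    add("b_conv2", "conv", 3, w[n], w[n], n)
    add("b_bn2", "bn", 0, w[n], w[n], n)
    add(sprintf("u%d_tconv", n), "convt", transpose_kernel, w[n], w[n], n)
    cur <- w[n]
    for (i in rev(seq_len(n))) {
      cin_up <- cur + w[i]                  # skip concat at matching width
      if (i > 1) {
        add(sprintf("u%d_conv1", i - 1), "conv", 3, cin_up, w[i - 1], i - 1)
        add(sprintf("u%d_bn1", i - 1), "bn", 0, w[i - 1], w[i - 1], i - 1)
        add(sprintf("u%d_conv2", i - 1), "conv", 3, w[i - 1], w[i - 1], i - 1)
        add(sprintf("u%d_bn2", i - 1), "bn", 0, w[i - 1], w[i - 1], i - 1)
        add(sprintf("u%d_tconv", i - 1), "convt", transpose_kernel,
            w[i - 1], w[i - 1], i - 1)
        cur <- w[i - 1]
      } else {
        add("final_conv", "conv", final_kernel, cin_up, 1, 0)
      }
    }
  } else {
    # classic arrangement: pool below the deepest block, transpose back to
    # the level width, each expanding block keeps it
    cur <- w[n]
    for (i in rev(seq_len(n))) {
      add(sprintf("u%d_tconv", i), "convt", transpose_kernel, cur, w[i], i)
      add(sprintf("u%d_conv1", i), "conv", 3, 2 * w[i], w[i], i)
      add(sprintf("u%d_bn1", i), "bn", 0, w[i], w[i], i)
      add(sprintf("u%d_conv2", i), "conv", 3, w[i], w[i], i)
      add(sprintf("u%d_bn2", i), "bn", 0, w[i], w[i], i)
      cur <- w[i]
    }
    add("final_conv", "conv", final_kernel, w[1], 1, 0)
  }
  layers <- do.call(rbind, L)
  layers$trainable <- TRUE
  structure(list(n_blocks = n_blocks, first_filters = first_filters,
                 widths = w, dropout_rate = dropout_rate,
                 transpose_kernel = transpose_kernel,
                 final_kernel = final_kernel, bottleneck = bottleneck,
                 finetune_final = finetune_final, finetune_scope = NULL,
                 layers = layers),
            class = "unet_spec")
}

#' @export
print.unet_spec <- function(x, ...) {
  seq_txt <- paste(c(x$widths, rev(x$widths)), collapse = "-")
  cat(sprintf("<unet_spec> %d blocks, widths %s (%s bottleneck), %s trainable parameters\n",
              x$n_blocks, seq_txt, x$bottleneck,
              format(count_trainable_parameters(x), big.mark = ",")))
  if (!is.null(x$finetune_scope))
    cat(sprintf("  fine-tune scope: %d deepest block pair(s)\n",
                x$finetune_scope))
  invisible(x)
}

layer_param_count <- function(l) {
  switch(l$type,
         conv = l$k^2 * l$cin * l$cout + l$cout,
         convt = l$k^2 * l$cin * l$cout + l$cout,
         bn = 2 * l$cout)
}

#' Count trainable parameters of a network specification
#'
#' Sums weight and bias counts of convolution and transpose-convolution
#' layers plus per-channel scale/shift of batch normalization; moving batch
#' statistics are excluded. When a fine-tune scope is active (see
#' [set_finetune_scope()]) only trainable layers are counted.
#'
#' @param spec a `unet_spec` (or a `unet` model, whose spec is used).
#' @param scoped honor the trainable flags (default TRUE; FALSE counts the
#'   full network regardless of scope).
#' @return integer parameter count.
#' @export
count_trainable_parameters <- function(spec, scoped = TRUE) {
  if (inherits(spec, "unet")) spec <- spec$spec
  ly <- spec$layers
  if (scoped) ly <- ly[ly$trainable, , drop = FALSE]
  if (nrow(ly) == 0L) return(0L)
  sum(vapply(seq_len(nrow(ly)),
             function(i) layer_param_count(ly[i, ]), numeric(1)))
}

#' Restrict training to the deepest symmetric block pairs
#'
#' Marks the `x` deepest levels (contracting block, its paired expanding
#' block, and the transpose convolution that follows the latter) as
#' trainable and freezes everything shallower. `x = 0` freezes the whole
#' network; `x = n_blocks` restores full end-to-end training. The output
#' convolution follows the spec's `finetune_final` option (trainable by
#' default).
#'
#' @param spec a `unet_spec` (or `unet` model; the contained spec is
#'   updated and the model returned).
#' @param x number of deepest block pairs to retrain, `0 <= x <= n_blocks`.
#' @return the updated object.
#' @export
set_finetune_scope <- function(spec, x) {
  if (inherits(spec, "unet")) {
    spec$spec <- set_finetune_scope(spec$spec, x)
    return(spec)
  }
  if (x < 0 || x > spec$n_blocks)
    stop(sprintf("fine-tune scope must be in [0, %d]", spec$n_blocks))
  lv <- spec$layers$level
  deep <- lv >= spec$n_blocks - x + 1 & lv >= 1
  spec$layers$trainable <- deep
  spec$layers$trainable[lv == 0] <- isTRUE(spec$finetune_final) && x > 0
  spec$finetune_scope <- as.integer(x)
  spec
}

#' Enumerate structural U-Net variants and their parameter counts
#'
#' Crosses the open structural options (transpose kernel, final kernel,
#' bottleneck arrangement) for a given depth/width and reports each
#' variant's full trainable parameter count, e.g. to identify the variant
#' closest to a reference count.
#'
#' @param n_blocks,first_filters architecture size.
#' @return data.frame of variants with a `params` column.
#' @export
enumerate_unet_variants <- function(n_blocks = 4, first_filters = 16) {
  grid <- expand.grid(transpose_kernel = c(2, 3), final_kernel = c(1, 3),
                      bottleneck = c("paired", "pooled"),
                      stringsAsFactors = FALSE)
  grid$params <- vapply(seq_len(nrow(grid)), function(i)
    count_trainable_parameters(
      build_unet(n_blocks, first_filters,
                 transpose_kernel = grid$transpose_kernel[i],
                 final_kernel = grid$final_kernel[i],
                 bottleneck = grid$bottleneck[i])), numeric(1))
  grid
}

#' Write a network specification to YAML
#'
#' Persists the constructor arguments (and any active fine-tune scope) so
#' the identical specification can be rebuilt with [read_unet_spec()].
#'
#' @param spec a `unet_spec`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_unet_spec <- function(spec, path) {
  yaml::write_yaml(list(
    n_blocks = spec$n_blocks, first_filters = spec$first_filters,
    dropout_rate = spec$dropout_rate,
    transpose_kernel = spec$transpose_kernel,
    final_kernel = spec$final_kernel, bottleneck = spec$bottleneck,
    finetune_final = spec$finetune_final,
    finetune_scope = spec$finetune_scope), path)
  invisible(path)
}

#' Read a network specification from YAML
#'
#' @param path YAML file written by [write_unet_spec()].
#' @return a `unet_spec`.
#' @export
read_unet_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  scope <- cfg$finetune_scope
  cfg$finetune_scope <- NULL
  spec <- do.call(build_unet, cfg)
  if (!is.null(scope)) spec <- set_finetune_scope(spec, scope)
  spec
}

#' Instantiate network weights for a specification
#'
#' He-style seeded initialization: convolution weights
#' `N(0, 2 / (k^2 cin))`, zero biases, batch-norm scale 1 / shift 0 with
#' zero/unit running statistics.
#'
#' @param spec a `unet_spec`.
#' @param seed integer seed.
#' @return an object of class `unet`: `list(spec, params)`.
#' @export
unet_init <- function(spec, seed = 1L) {
  if (spec$transpose_kernel != 2)
    stop("the runtime engine executes transpose kernel 2 only")
  params <- with_seed(seed, {
    p <- list()
    for (i in seq_len(nrow(spec$layers))) {
      l <- spec$layers[i, ]
      p[[l$name]] <- switch(l$type,
        conv = list(W = array(rnorm(l$k^2 * l$cin * l$cout,
                                    sd = sqrt(2 / (l$k^2 * l$cin))),
                              dim = c(l$k, l$k, l$cin, l$cout)),
                    b = numeric(l$cout)),
        convt = list(W = array(rnorm(4 * l$cin * l$cout,
                                     sd = sqrt(2 / (4 * l$cin))),
                               dim = c(2, 2, l$cin, l$cout)),
                     b = numeric(l$cout)),
        bn = list(gamma = rep(1, l$cout), beta = numeric(l$cout),
                  rmean = numeric(l$cout), rvar = rep(1, l$cout)))
    }
    p
  })
  structure(list(spec = spec, params = params), class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  print(x$spec)
  invisible(x)
}
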