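#' Architecture configuration
#'
#' Collects every hyperparameter of the hybrid classifier.  Defaults follow
#' the published architecture: a 33-residue window over a 21-token alphabet
#' embedded in 21 dimensions; residual blocks with 32 and 64 filters (kernel
#' 3, concatenation skip); inception kernels 1, 3, 5, 7, 9, 11 with 32
#' filters per parallel branch; a 1024-wide language-model vector feeding a
#' 32-unit dense branch; a 32-unit head; 30% dropout throughout; max-pool of
#' size 2 with floor length division.
#'
#' @param branch Word-branch kind: `"resnet"`, `"conv"` or `"inception"`.
#' @param window_length Window length (odd; default 33).
#' @param vocab Token alphabet size (default 21).
#' @param embed_dim Learned embedding width d (default 21).
#' @param conv_filters Two filter counts for the conv/resnet blocks
#'   (default `c(32, 64)`).
#' @param conv_kernel Kernel size of the plain-conv and residual-block
#'   convolutions (default 3).
#' @param inception_kernels Kernel sizes of the parallel inception
#'   convolutions (default `c(1, 3, 5, 7, 9, 11)`).
#' @param inception_filters Filters per inception branch (default 32).
#' @param plm_width Width of the language-model embedding (default 1024).
#' @param branch_dense Units of each branch's dense layer (default 32).
#' @param head_dense Units of the combined head's dense layer (default 32).
#' @param dropout Dropout rate (default 0.30).
#' @param pool_size Max-pool size and stride (default 2).
#' @return Object of class `succnet_config`.
#' @export
succnet_config <- function(branch = c("resnet", "conv", "inception"),
                           window_length = 33L, vocab = 21L, embed_dim = 21L,
                           conv_filters = c(32L, 64L), conv_kernel = 3L,
                           inception_kernels = c(1L, 3L, 5L, 7L, 9L, 11L),
                           inception_filters = 32L, plm_width = 1024L,
                           branch_dense = 32L, head_dense = 32L,
                           dropout = 0.30, pool_size = 2L) {
  branch <- match.arg(branch)
  if (window_length %% 2 == 0) stop("window_length must be odd")
  if (embed_dim < 1) stop("embed_dim must be >= 1")
  if (any(c(conv_filters, inception_filters, branch_dense, head_dense) < 1))
    stop("all filter and unit counts must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(
    list(branch = branch, window_length = as.integer(window_length),
         vocab = as.integer(vocab), embed_dim = as.integer(embed_dim),
         conv_filters = as.integer(conv_filters),
         conv_kernel = as.integer(conv_kernel),
         inception_kernels = as.integer(inception_kernels),
         inception_filters = as.integer(inception_filters),
         plm_width = as.integer(plm_width),
         branch_dense = as.integer(branch_dense),
         head_dense = as.integer(head_dense),
         dropout = dropout, pool_size = as.integer(pool_size)),
    class = "succnet_config"
  )
}

#' @export
print.succnet_config <- function(x, ...) {
  cat("succnet config:", x$branch, "branch, window", x$window_length,
      ", embed", x$embed_dim, ", PLM width", x$plm_width, "\n")
  invisible(x)
}

#' Build the word-embedding branch
#'
#' Learned token embedding followed by the configured convolutional stack:
#' `"conv"` — two length-preserving convolutions (32 then 64 filters), each
#' followed by ReLU and max-pool; `"resnet"` — two residual-concatenation
#' blocks (32 then 64 filters), each followed by max-pool; `"inception"` —
#' one inception module (parallel kernels plus a pooled 1x1-conv branch,
#' channel concat) followed by max-pool.  All variants end with flatten,
#' a `branch_dense`-unit ReLU layer and dropout, so the branch maps a
#' `(batch, 33)` token matrix to `(batch, 32)` features.
#'
#' @param config A [succnet_config()].
#' @return Object of class `succnet_branch` (layer stack plus input/output
#'   widths); supports [count_parameters()].
#' @export
build_word_branch <- function(config) {
  stopifnot(inherits(config, "succnet_config"))
  L <- config$window_length
  p <- config$pool_size
  layers <- list(layer_embedding(config$vocab, config$embed_dim))
  ch <- config$embed_dim
  if (config$branch == "conv") {
    layers <- c(layers, list(
      layer_conv1d(config$conv_kernel, ch, config$conv_filters[1]),
      layer_relu(), layer_maxpool(p),
      layer_conv1d(config$conv_kernel, config$conv_filters[1], config$conv_filters[2]),
      layer_relu(), layer_maxpool(p)
    ))
    ch <- config$conv_filters[2]
    L <- (L %/% p) %/% p
  } else if (config$branch == "resnet") {
    b1 <- layer_resblock(ch, config$conv_filters[1], config$conv_kernel)
    ch1 <- config$conv_filters[1] + ch
    b2 <- layer_resblock(ch1, config$conv_filters[2], config$conv_kernel)
    layers <- c(layers, list(b1, layer_maxpool(p), b2, layer_maxpool(p)))
    ch <- config$conv_filters[2] + ch1
    L <- (L %/% p) %/% p
  } else if (config$branch == "inception") {
    layers <- c(layers, list(
      layer_inception(ch, config$inception_kernels, config$inception_filters),
      layer_maxpool(p)
    ))
    ch <- (length(config$inception_kernels) + 1L) * config$inception_filters
    L <- L %/% p
  } else stop("unknown branch kind: ", config$branch)
  layers <- c(layers, list(
    layer_flatten(),
    layer_dense(L * ch, config$branch_dense),
    layer_relu(),
    layer_dropout(config$dropout)
  ))
  structure(
    list(layers = layers, flat_width = L * ch, out_width = config$branch_dense,
         config = config),
    class = "succnet_branch"
  )
}

#' Build the language-model (MLP) branch
#'
#' A single `branch_dense`-unit dense layer with ReLU and dropout over the
#' `plm_width`-dimensional target-site embedding.
#'
#' @inheritParams build_word_branch
#' @return Object of class `succnet_branch`.
#' @export
build_mlp_branch <- function(config) {
  stopifnot(inherits(config, "succnet_config"))
  structure(
    list(layers = list(
      layer_dense(config$plm_width, config$branch_dense),
      layer_relu(),
      layer_dropout(config$dropout)
    ), flat_width = config$plm_width, out_width = config$branch_dense,
    config = config),
    class = "succnet_branch"
  )
}

#' Build the full hybrid classifier
#'
#' Concatenates the two branch outputs (32 + 32), applies a
#' `head_dense`-unit ReLU layer with dropout and a final 1-unit sigmoid
#' layer.  Weights are drawn from the active RNG stream; seed the build for
#' reproducibility.
#'
#' @inheritParams build_word_branch
#' @return Object of class `succnet_model` with components `word`, `mlp`,
#'   `head` and `config`.
#' @export
build_hybrid <- function(config) {
  word <- build_word_branch(config)
  mlp <- build_mlp_branch(config)
  head <- list(
    layer_dense(2L * config$branch_dense, config$head_dense),
    layer_relu(),
    layer_dropout(config$dropout),
    layer_dense(config$head_dense, 1L),
    layer_sigmoid()
  )
  structure(list(word = word$layers, mlp = mlp$layers, head = head,
                 config = config),
            class = "succnet_model")
}

# Forward pass of the hybrid model.  `train_word` / `train_mlp` allow frozen
# branches to run in inference mode while the head trains.
net_forward <- function(model, tokens, plm, training = FALSE,
                        train_word = training, train_mlp = training) {
  fw <- seq_fwd(model$word, tokens, train_word)
  fm <- seq_fwd(model$mlp, plm, train_mlp)
  p <- seq_fwd(model$head, cbind(fw, fm), training)
  as.numeric(p)
}

# Backward pass from the pre-sigmoid gradient dz (B x 1).  Skips frozen
# branches entirely.
net_backward <- function(model, dz, skip_word = FALSE, skip_mlp = FALSE) {
  nh <- length(model$head)
  dh <- model$head[[nh - 1L]]$bwd(dz) # into the last dense layer
  for (i in (nh - 2L):1L) dh <- model$head[[i]]$bwd(dh)
  w <- model$config$branch_dense
  if (!skip_word) seq_bwd(model$word, dh[, seq_len(w), drop = FALSE])
  if (!skip_mlp) seq_bwd(model$mlp, dh[, w + seq_len(w), drop = FALSE])
  invisible(NULL)
}

#' Count trainable parameters
#'
#' Counts every trainable scalar — embedding table, convolution and dense
#' weights, and all biases.  The default residual hybrid has 93,082.
#'
#' @param x A `succnet_model`, `succnet_branch`, or fitted [succnet()] object.
#' @return Integer parameter count.
#' @export
count_parameters <- function(x) UseMethod("count_parameters")

#' @export
count_parameters.succnet_model <- function(x) {
  .count_layers(c(x$word, x$mlp, x$head))
}

#' @export
count_parameters.succnet_branch <- function(x) .count_layers(x$layers)

#' @export
count_parameters.succnet <- function(x) count_parameters(x$model)

.count_layers <- function(layers) {
  sum(vapply(flatten_param_layers(layers),
             function(ly) sum(vapply(ly$par, length, integer(1))), numeric(1)))
}
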