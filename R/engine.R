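# Minimal neural-network engine: plain-R layers with explicit forward/backward
# passes and an Adam optimiser.  Sequence activations are 3-d arrays
# (batch, length, channels); dense activations are (batch, features) matrices.
# Convolutions are realised as im2col matrix products, which keeps the whole
# engine inside BLAS-backed matrix algebra.
#
# Each layer is an environment holding its parameters (`par`), gradients
# (`grad`), optional sub-layers (`sub`), a `frozen` flag, and closures
# `fwd(x, training)` / `bwd(dy)`.  Environments give reference semantics so
# the optimiser can update weights in place.

new_layer <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$par <- list()
  e$grad <- list()
  e$sub <- list()
  e$frozen <- FALSE
  e
}

# Glorot/Xavier uniform initialisation; draws from the active RNG stream.
.glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

layer_embedding <- function(vocab, d) {
  ly <- new_layer("embedding")
  ly$par$E <- .glorot(vocab, d, c(vocab, d))
  ly$fwd <- function(x, training) {
    # x: integer matrix (B, L), values in [0, vocab-1]
    ly$x <- x
    B <- nrow(x); L <- ncol(x)
    idx <- as.integer(x) + 1L
    y <- ly$par$E[idx, , drop = FALSE]
    dim(y) <- c(B, L, ncol(ly$par$E))
    y
  }
  ly$bwd <- function(dy) {
    B <- nrow(ly$x); L <- ncol(ly$x); d <- ncol(ly$par$E)
    dm <- dy
    dim(dm) <- c(B * L, d)
    idx <- as.integer(ly$x) + 1L
    gE <- matrix(0, nrow(ly$par$E), d)
    acc <- rowsum(dm, group = idx)
    gE[as.integer(rownames(acc)), ] <- acc
    ly$grad$E <- gE
    NULL # tokens carry no gradient
  }
  ly
}

# Length-preserving ("same"-padded) 1-d convolution, odd kernel size.
layer_conv1d <- function(kernel, c_in, filters) {
  stopifnot(kernel %% 2 == 1)
  ly <- new_layer("conv1d")
  ly$kernel <- kernel; ly$c_in <- c_in; ly$filters <- filters
  ly$par$W <- .glorot(kernel * c_in, filters, c(kernel * c_in, filters))
  ly$par$b <- numeric(filters)
  ly$fwd <- function(x, training) {
    B <- dim(x)[1]; L <- dim(x)[2]; C <- dim(x)[3]
    P <- (ly$kernel - 1L) %/% 2L
    xp <- array(0, c(B, L + 2L * P, C))
    xp[, P + seq_len(L), ] <- x
    xcol <- matrix(0, B * L, ly$kernel * C)
    for (j in seq_len(ly$kernel)) {
      sl <- xp[, j:(j + L - 1L), , drop = FALSE]
      dim(sl) <- c(B * L, C)
      xcol[, ((j - 1L) * C + 1L):(j * C)] <- sl
    }
    ly$xcol <- xcol
    ly$dims <- c(B, L, C)
    y <- xcol %*% ly$par$W
    y <- sweep(y, 2L, ly$par$b, "+")
    dim(y) <- c(B, L, ly$filters)
    y
  }
  ly$bwd <- function(dy) {
    B <- ly$dims[1]; L <- ly$dims[2]; C <- ly$dims[3]
    dm <- dy
    dim(dm) <- c(B * L, ly$filters)
    ly$grad$W <- crossprod(ly$xcol, dm)
    ly$grad$b <- colSums(dm)
    dxcol <- tcrossprod(dm, ly$par$W)
    P <- (ly$kernel - 1L) %/% 2L
    dxp <- array(0, c(B, L + 2L * P, C))
    for (j in seq_len(ly$kernel)) {
      sl <- dxcol[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
      dim(sl) <- c(B, L, C)
      dxp[, j:(j + L - 1L), ] <- dxp[, j:(j + L - 1L), , drop = FALSE] + sl
    }
    dxp[, P + seq_len(L), , drop = FALSE]
  }
  ly
}

layer_relu <- function() {
  ly <- new_layer("relu")
  ly$fwd <- function(x, training) {
    ly$mask <- x > 0
    x * ly$mask
  }
  ly$bwd <- function(dy) dy * ly$mask
  ly
}

layer_sigmoid <- function() {
  ly <- new_layer("sigmoid")
  ly$fwd <- function(x, training) {
    y <- 1 / (1 + exp(-x))
    ly$y <- y
    y
  }
  ly$bwd <- function(dy) dy * ly$y * (1 - ly$y)
  ly
}

# Non-overlapping max pool along the length axis, stride == size, floor length
# division (33 -> 16 -> 8 at size 2).  Ties go to the earliest position.
layer_maxpool <- function(size = 2L) {
  ly <- new_layer("maxpool")
  ly$size <- as.integer(size)
  ly$fwd <- function(x, training) {
    B <- dim(x)[1]; L <- dim(x)[2]; C <- dim(x)[3]
    s <- ly$size
    L2 <- L %/% s
    base <- (seq_len(L2) - 1L) * s
    y <- x[, base + 1L, , drop = FALSE]
    am <- array(1L, c(B, L2, C))
    if (s > 1L) for (j in 2:s) {
      xj <- x[, base + j, , drop = FALSE]
      upd <- xj > y
      y[upd] <- xj[upd]
      am[upd] <- j
    }
    ly$am <- am
    ly$inL <- L
    y
  }
  ly$bwd <- function(dy) {
    B <- dim(dy)[1]; L2 <- dim(dy)[2]; C <- dim(dy)[3]
    dx <- array(0, c(B, ly$inL, C))
    base <- (seq_len(L2) - 1L) * ly$size
    for (j in seq_len(ly$size)) {
      sel <- ly$am == j
      if (!any(sel)) next
      tmp <- array(0, c(B, L2, C))
      tmp[sel] <- dy[sel]
      dx[, base + j, ] <- tmp
    }
    dx
  }
  ly
}

# Stride-1 same-padded max pool (used by the inception pool branch); length is
# preserved so channel concatenation stays well-defined.
layer_maxpool_same <- function(window = 3L) {
  stopifnot(window %% 2 == 1)
  ly <- new_layer("maxpool_same")
  ly$window <- as.integer(window)
  ly$fwd <- function(x, training) {
    B <- dim(x)[1]; L <- dim(x)[2]; C <- dim(x)[3]
    P <- (ly$window - 1L) %/% 2L
    xp <- array(-Inf, c(B, L + 2L * P, C))
    xp[, P + seq_len(L), ] <- x
    y <- xp[, 1:L, , drop = FALSE]
    am <- array(1L, c(B, L, C))
    for (j in 2:ly$window) {
      xj <- xp[, j:(j + L - 1L), , drop = FALSE]
      upd <- xj > y
      y[upd] <- xj[upd]
      am[upd] <- j
    }
    ly$am <- am
    ly$L <- L
    y
  }
  ly$bwd <- function(dy) {
    B <- dim(dy)[1]; L <- ly$L; C <- dim(dy)[3]
    P <- (ly$window - 1L) %/% 2L
    dxp <- array(0, c(B, L + 2L * P, C))
    for (j in seq_len(ly$window)) {
      sel <- ly$am == j
      if (!any(sel)) next
      tmp <- array(0, c(B, L, C))
      tmp[sel] <- dy[sel]
      dxp[, j:(j + L - 1L), ] <- dxp[, j:(j + L - 1L), , drop = FALSE] + tmp
    }
    dxp[, P + seq_len(L), , drop = FALSE]
  }
  ly
}

layer_flatten <- function() {
  ly <- new_layer("flatten")
  ly$fwd <- function(x, training) {
    ly$d <- dim(x)
    dim(x) <- c(ly$d[1], prod(ly$d[-1]))
    x
  }
  ly$bwd <- function(dy) {
    dim(dy) <- ly$d
    dy
  }
  ly
}

layer_dense <- function(n_in, n_out) {
  ly <- new_layer("dense")
  ly$par$W <- .glorot(n_in, n_out, c(n_in, n_out))
  ly$par$b <- numeric(n_out)
  ly$fwd <- function(x, training) {
    ly$x <- x
    sweep(x %*% ly$par$W, 2L, ly$par$b, "+")
  }
  ly$bwd <- function(dy) {
    ly$grad$W <- crossprod(ly$x, dy)
    ly$grad$b <- colSums(dy)
    tcrossprod(dy, ly$par$W)
  }
  ly
}

# Inverted dropout: active only in training mode, identity at inference.
layer_dropout <- function(rate) {
  ly <- new_layer("dropout")
  ly$rate <- rate
  ly$fwd <- function(x, training) {
    if (!training || ly$rate <= 0) {
      ly$mask <- NULL
      return(x)
    }
    m <- array(as.numeric(stats::runif(length(x)) >= ly$rate), dim = dim(x) %||% length(x)) /
      (1 - ly$rate)
    if (is.matrix(x)) dim(m) <- dim(x)
    ly$mask <- m
    x * m
  }
  ly$bwd <- function(dy) if (is.null(ly$mask)) dy else dy * ly$mask
  ly
}

# Residual block, concatenation variant: conv -> ReLU -> conv -> ReLU, then the
# block input is concatenated back along the channel axis (no post-concat
# activation).  Output channels = filters + input channels.
layer_resblock <- function(c_in, filters, kernel = 3L) {
  ly <- new_layer("resblock")
  ly$c_in <- c_in; ly$filters <- filters
  ly$sub <- list(
    conv1 = layer_conv1d(kernel, c_in, filters),
    relu1 = layer_relu(),
    conv2 = layer_conv1d(kernel, filters, filters),
    relu2 = layer_relu()
  )
  ly$fwd <- function(x, training) {
    h <- ly$sub$relu1$fwd(ly$sub$conv1$fwd(x, training), training)
    h2 <- ly$sub$relu2$fwd(ly$sub$conv2$fwd(h, training), training)
    B <- dim(x)[1]; L <- dim(x)[2]
    y <- array(0, c(B, L, ly$filters + ly$c_in))
    y[, , seq_len(ly$filters)] <- h2
    y[, , ly$filters + seq_len(ly$c_in)] <- x
    y
  }
  ly$bwd <- function(dy) {
    d2 <- dy[, , seq_len(ly$filters), drop = FALSE]
    dskip <- dy[, , ly$filters + seq_len(ly$c_in), drop = FALSE]
    dh <- ly$sub$conv2$bwd(ly$sub$relu2$bwd(d2))
    dx <- ly$sub$conv1$bwd(ly$sub$relu1$bwd(dh))
    dx + dskip
  }
  ly
}

# Inception module: parallel length-preserving convolutions with kernel sizes
# `kernels`, each with `filters` channels and ReLU, plus a stride-1 max-pool
# branch followed by a 1x1 convolution.  Outputs concatenate to
# (L, (length(kernels) + 1) * filters).
layer_inception <- function(c_in, kernels = c(1L, 3L, 5L, 7L, 9L, 11L),
                            filters = 32L, pool_window = 3L) {
  ly <- new_layer("inception")
  ly$c_in <- c_in; ly$filters <- filters; ly$kernels <- kernels
  sub <- list()
  for (k in kernels) {
    sub[[paste0("conv", k)]] <- layer_conv1d(k, c_in, filters)
    sub[[paste0("relu", k)]] <- layer_relu()
  }
  sub$pool <- layer_maxpool_same(pool_window)
  sub$pool_conv <- layer_conv1d(1L, c_in, filters)
  sub$pool_relu <- layer_relu()
  ly$sub <- sub
  ly$fwd <- function(x, training) {
    B <- dim(x)[1]; L <- dim(x)[2]
    nb <- length(ly$kernels) + 1L
    y <- array(0, c(B, L, nb * ly$filters))
    for (i in seq_along(ly$kernels)) {
      k <- ly$kernels[i]
      h <- ly$sub[[paste0("relu", k)]]$fwd(
        ly$sub[[paste0("conv", k)]]$fwd(x, training), training)
      y[, , ((i - 1L) * ly$filters + 1L):(i * ly$filters)] <- h
    }
    hp <- ly$sub$pool_relu$fwd(
      ly$sub$pool_conv$fwd(ly$sub$pool$fwd(x, training), training), training)
    y[, , (length(ly$kernels) * ly$filters + 1L):(nb * ly$filters)] <- hp
    y
  }
  ly$bwd <- function(dy) {
    dx <- NULL
    for (i in seq_along(ly$kernels)) {
      k <- ly$kernels[i]
      d <- dy[, , ((i - 1L) * ly$filters + 1L):(i * ly$filters), drop = FALSE]
      dxi <- ly$sub[[paste0("conv", k)]]$bwd(ly$sub[[paste0("relu", k)]]$bwd(d))
      dx <- if (is.null(dx)) dxi else dx + dxi
    }
    nb <- length(ly$kernels) + 1L
    dp <- dy[, , (length(ly$kernels) * ly$filters + 1L):(nb * ly$filters), drop = FALSE]
    dxp <- ly$sub$pool$bwd(ly$sub$pool_conv$bwd(ly$sub$pool_relu$bwd(dp)))
    dx + dxp
  }
  ly
}

# ---- traversal, sequencing, optimiser ----

# Depth-first list of every layer that owns parameters.
flatten_param_layers <- function(layers) {
  out <- list()
  for (ly in layers) {
    if (length(ly$sub)) out <- c(out, flatten_param_layers(ly$sub))
    if (length(ly$par)) out <- c(out, list(ly))
  }
  out
}

seq_fwd <- function(layers, x, training) {
  for (ly in layers) x <- ly$fwd(x, training)
  x
}

seq_bwd <- function(layers, dy) {
  for (ly in rev(layers)) dy <- ly$bwd(dy)
  invisible(dy)
}

adam_new <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps; e$t <- 0L
  e
}

adam_step <- function(opt, param_layers) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (ly in param_layers) {
    if (isTRUE(ly$frozen)) next
    if (is.null(ly$optstate)) ly$optstate <- list()
    for (nm in names(ly$par)) {
      g <- ly$grad[[nm]]
      st <- ly$optstate[[nm]]
      if (is.null(st)) st <- list(m = 0 * g, v = 0 * g)
      st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
      st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g * g
      ly$par[[nm]] <- ly$par[[nm]] - opt$lr * (st$m / c1) / (sqrt(st$v / c2) + opt$eps)
      ly$optstate[[nm]] <- st
    }
  }
  invisible(NULL)
}

get_weights <- function(param_layers) lapply(param_layers, function(ly) ly$par)

set_weights <- function(param_layers, weights) {
  stopifnot(length(param_layers) == length(weights))
  for (i in seq_along(param_layers)) param_layers[[i]]$par <- weights[[i]]
  invisible(NULL)
}
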