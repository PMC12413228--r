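test_that("residual word branch follows the published channel trace", {
  set.seed(1)
  cfg <- succnet_config("resnet")
  wb <- build_word_branch(cfg)
  # 21 -> 32+21=53 -> pool -> 53 -> 64+53=117, lengths 33 -> 16 -> 8
  tok <- encode_windows(random_window(3))
  x <- wb$layers[[1]]$fwd(tok, FALSE)
  expect_equal(dim(x), c(3, 33, 21))
  x <- wb$layers[[2]]$fwd(x, FALSE) # first residual block
  expect_equal(dim(x), c(3, 33, 53))
  x <- wb$layers[[3]]$fwd(x, FALSE)
  expect_equal(dim(x), c(3, 16, 53))
  x <- wb$layers[[4]]$fwd(x, FALSE)
  expect_equal(dim(x), c(3, 16, 117))
  x <- wb$layers[[5]]$fwd(x, FALSE)
  expect_equal(dim(x), c(3, 8, 117))
  expect_equal(wb$flat_width, 8 * 117)
  out <- seq_len(0) # silence lints
  y <- x
  for (i in 6:length(wb$layers)) y <- wb$layers[[i]]$fwd(y, FALSE)
  expect_equal(dim(y), c(3, 32))
})

test_that("inception module concatenates 7 branches at preserved length", {
  set.seed(2)
  cfg <- succnet_config("inception")
  wb <- build_word_branch(cfg)
  tok <- encode_windows(random_window(2))
  x <- wb$layers[[1]]$fwd(tok, FALSE)
  x <- wb$layers[[2]]$fwd(x, FALSE)
  expect_equal(dim(x), c(2, 33, 7 * 32))
})

test_that("conv branch output width is the branch dense width", {
  set.seed(3)
  for (bd in c(8L, 32L)) {
    cfg <- succnet_config("conv", branch_dense = bd, plm_width = 16)
    wb <- build_word_branch(cfg)
    tok <- encode_windows(random_window(4))
    y <- tok
    for (ly in wb$layers) y <- ly$fwd(y, FALSE)
    expect_equal(dim(y), c(4, bd))
  }
})

test_that("convolutions preserve length for any kernel in use", {
  set.seed(4)
  for (k in c(1L, 3L, 7L, 11L)) {
    ly <- succnet:::layer_conv1d(k, 5L, 3L)
    x <- array(rnorm(2 * 19 * 5), c(2, 19, 5))
    expect_equal(dim(ly$fwd(x, FALSE)), c(2, 19, 3))
  }
})

test_that("residual block output channels equal filters plus input channels", {
  set.seed(5)
  for (cin in c(4L, 21L)) for (f in c(8L, 32L)) {
    blk <- succnet:::layer_resblock(cin, f)
    x <- array(rnorm(2 * 11 * cin), c(2, 11, cin))
    y <- blk$fwd(x, FALSE)
    expect_equal(dim(y), c(2, 11, f + cin))
    # skip path carries the input through unchanged
    expect_equal(y[, , f + seq_len(cin)], x)
  }
})

test_that("MLP branch maps the language-model vector to 32 ReLU units", {
  set.seed(6)
  cfg <- succnet_config("resnet")
  mb <- build_mlp_branch(cfg)
  x <- matrix(rnorm(3 * 1024), 3, 1024)
  y <- x
  for (ly in mb$layers) y <- ly$fwd(y, FALSE)
  expect_equal(dim(y), c(3, 32))
  expect_true(all(y >= 0))
  # dense layer parameters: 1024 * 32 + 32
  expect_equal(count_parameters(mb), 1024 * 32 + 32)
  # zero input -> ReLU(bias), weights irrelevant
  z <- matrix(0, 1, 1024)
  y0 <- z
  for (ly in mb$layers) y0 <- ly$fwd(y0, FALSE)
  expect_equal(as.numeric(y0), pmax(mb$layers[[1]]$par$b, 0))
})

test_that("parameter counts match the closed-form oracle across configs", {
  set.seed(7)
  for (branch in c("conv", "resnet", "inception")) {
    expect_equal(count_parameters(build_hybrid(succnet_config(branch))),
                 oracle_param_count(branch))
  }
  # a non-default configuration
  cfg <- succnet_config("resnet", embed_dim = 12, conv_filters = c(16L, 24L),
                        plm_width = 256, branch_dense = 20, head_dense = 10)
  expect_equal(count_parameters(build_hybrid(cfg)),
               oracle_param_count("resnet", d = 12, f1 = 16, f2 = 24,
                                  plm = 256, bd = 20, hd = 10))
  cfg2 <- succnet_config("inception", inception_kernels = c(1L, 3L, 5L),
                         inception_filters = 8L, plm_width = 64)
  expect_equal(count_parameters(build_hybrid(cfg2)),
               oracle_param_count("inception", inc_kernels = c(1, 3, 5),
                                  incF = 8, plm = 64))
  # embedding table alone
  wb <- build_word_branch(succnet_config("resnet"))
  expect_equal(length(wb$layers[[1]]$par$E), 21 * 21)
})

test_that("hybrid forward yields probabilities, deterministic in eval mode", {
  set.seed(8)
  cfg <- tiny_config("resnet")
  m <- build_hybrid(cfg)
  tok <- encode_windows(random_window(4))
  plm <- matrix(rnorm(4 * 32), 4, 32)
  p1 <- succnet:::net_forward(m, tok, plm, FALSE)
  p2 <- succnet:::net_forward(m, tok, plm, FALSE)
  expect_length(p1, 4)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, p2)
  # head consumes the 64-wide concatenation
  m64 <- build_hybrid(succnet_config("resnet"))
  expect_equal(dim(m64$head[[1]]$par$W), c(64L, 32L))
  # probability is monotone in the final logit
  zs <- seq(-4, 4, length.out = 9)
  sig <- succnet:::layer_sigmoid()
  expect_true(all(diff(as.numeric(sig$fwd(matrix(zs), FALSE))) > 0))
})

test_that("backpropagation matches finite differences on all branch kinds", {
  for (branch in c("conv", "resnet", "inception")) {
    set.seed(42)
    cfg <- succnet_config(branch, window_length = 9, embed_dim = 4,
                          conv_filters = c(3L, 4L),
                          inception_kernels = c(1L, 3L),
                          inception_filters = 2L, plm_width = 5,
                          branch_dense = 3L, head_dense = 3L, dropout = 0)
    m <- build_hybrid(cfg)
    n <- 6
    tok <- matrix(sample(0:20, n * 9, TRUE), n)
    plm <- matrix(rnorm(n * 5), n)
    y <- sample(0:1, n, TRUE)
    loss <- function() bce_loss(y, succnet:::net_forward(m, tok, plm, FALSE))
    p <- succnet:::net_forward(m, tok, plm, TRUE)
    succnet:::net_backward(m, matrix((p - y) / n, ncol = 1))
    plyrs <- succnet:::flatten_param_layers(c(m$word, m$mlp, m$head))
    for (ly in plyrs) for (nm in names(ly$par)) {
      for (i in sample(length(ly$par[[nm]]), min(2, length(ly$par[[nm]])))) {
        eps <- 1e-5
        v0 <- ly$par[[nm]][i]
        ly$par[[nm]][i] <- v0 + eps; lp <- loss()
        ly$par[[nm]][i] <- v0 - eps; lm <- loss()
        ly$par[[nm]][i] <- v0
        num <- (lp - lm) / (2 * eps)
        expect_lt(abs(num - ly$grad[[nm]][i]) /
                    max(1e-8, abs(num) + abs(ly$grad[[nm]][i])), 1e-5)
      }
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(succnet_config(window_length = 32), "odd")
  expect_error(succnet_config(dropout = 1), "dropout")
  expect_error(succnet_config(embed_dim = 0), "embed_dim")
})
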