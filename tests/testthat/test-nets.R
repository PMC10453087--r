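test_that("channel shuffle is the group-interleaving permutation", {
  m <- matrix(rnorm(5 * 6), 5, 6)
  expect_identical(channel_shuffle(m, 1), m)          # g = 1
  expect_identical(channel_shuffle(m, 6), m)          # one channel per group

  # C = 6, g = 2 against the explicit reshape-transpose oracle
  expect_equal(channel_shuffle_perm(6, 2), c(1L, 4L, 2L, 5L, 3L, 6L))
  for (case in list(c(6, 2), c(6, 3), c(12, 4), c(24, 3), c(8, 2)))
    expect_equal(channel_shuffle_perm(case[1], case[2]),
                 shuffle_perm_oracle(case[1], case[2]))

  # bijection and inverse: shuffling with g then C/g restores the input
  for (case in list(c(6, 2), c(12, 3), c(24, 4))) {
    C <- case[1]; g <- case[2]
    expect_setequal(channel_shuffle_perm(C, g), seq_len(C))
    x <- matrix(rnorm(3 * C), 3, C)
    expect_equal(channel_shuffle(channel_shuffle(x, g), C / g), x)
  }

  # 3D arrays shuffle the channel axis only
  a <- array(rnorm(2 * 4 * 6), c(2, 4, 6))
  s <- channel_shuffle(a, 3)
  expect_equal(s[, , 1], a[, , 1])
  expect_equal(s[, , 2], a[, , 3])

  expect_error(channel_shuffle(m, 4), "divisible")
})

test_that("fire block arithmetic: concatenation, length, parameter count", {
  set.seed(1)
  for (c_in in c(3, 8)) {
    blk <- block_init(fire_block(c_in, squeeze_filters = 2,
                                 expand_filters = 8))
    x <- array(rnorm(2 * 20 * c_in), c(2, 20, c_in))
    y <- block_forward(blk, x)
    expect_equal(dim(y), c(2, 20, 16))  # 2 * expand channels, same length
  }
  # hand count for (C_in, s, e) = (4, 2, 3):
  # weights C_in*s + s*e + 3*s*e = 8 + 6 + 18 = 32; biases s + 2e = 8
  blk <- fire_block(4, 2, 3)
  expect_equal(count_params(blk, "weight"), 32)
  expect_equal(count_params(blk), 40)
  expect_error(fire_block(4, 0, 3), "positive")
})

test_that("depthwise-separable block saves parameters and rectifies output", {
  blk <- dsc_block(8, 16)
  # 3*C_in + C_in*C_out = 24 + 128 = 152 weights, vs 3*8*16 = 384 dense
  expect_equal(count_params(blk, "weight"), 152)
  expect_lt(count_params(blk, "weight"), 3 * 8 * 16)

  set.seed(2)
  block_init(blk)
  x <- array(rnorm(3 * 15 * 8), c(3, 15, 8))
  y <- block_forward(blk, x, training = TRUE)
  expect_equal(dim(y), c(3, 15, 16))
  expect_true(all(y >= 0))  # ends in a ReLU
})

test_that("shuffle unit keeps shape, is identity at zero weights", {
  blk <- shuffle_unit(6, 3)        # weights all zero before init
  x <- array(rnorm(2 * 9 * 6), c(2, 9, 6))
  expect_equal(block_forward(blk, x), x)  # residual with a dead branch

  set.seed(3)
  block_init(blk)
  y <- block_forward(blk, x)
  expect_equal(dim(y), dim(x))

  # grouped 1x1 conv carries 1/g the weights of a dense 1x1 conv:
  # C = 12, g = 3 -> 3 * (4*4) = 48 vs 144
  gp <- sersnet:::gconv1d_layer(12, 12, 3)
  expect_equal(sum(sersnet:::sn_info(gp)$n[sersnet:::sn_info(gp)$kind ==
                                             "weight"]), 48)
  expect_error(shuffle_unit(10, 3), "divisible")
})

# independent layer-by-layer arithmetic for each default architecture
arch_param_oracle <- function(arch, L = 751, n_classes = 4) {
  dense1d <- function(ci, co, k) k * ci * co + co
  if (arch == "squeezenet1d") {
    L1 <- ceiling(L / 2)             # conv stride 2
    L2 <- L1 %/% 2                   # maxpool
    conv <- dense1d(1, 16, 7)
    fire <- (16 * 16 + 16) + (16 * 32 + 32) + (3 * 16 * 32 + 32)
    head <- L2 * 64 * n_classes + n_classes
    conv + fire + head
  } else if (arch == "mobilenet1d") {
    conv <- dense1d(1, 16, 3)
    dsc <- function(ci, co) (3 * ci + ci) + 2 * ci + (ci * co + co) + 2 * co
    head <- (L %/% 2) * 64 * 64 + 64 + 64 * n_classes + n_classes
    conv + dsc(16, 32) + dsc(32, 64) + head
  } else {
    conv <- dense1d(1, 24, 3)
    unit <- 2 * (3 * (8 * 8) + 24) + (3 * 24 + 24)
    head <- (L %/% 2) * 24 * 64 + 64 + 64 * n_classes + n_classes
    conv + 2 * unit + head
  }
}

test_that("built networks match the structural audit and parameter oracles", {
  for (arch in c("squeezenet1d", "mobilenet1d", "shufflenet1d")) {
    model <- build_network(network_config(arch, seed = 3))
    expect_equal(count_params(model), arch_param_oracle(arch))

    # softmax head: probabilities sum to one for every spectrum
    set.seed(8)
    x <- matrix(runif(5 * 751), 5, 751)
    p <- predict(model, x, type = "prob")
    expect_equal(dim(p), c(5, 4))
    expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
    expect_true(all(p >= 0))
  }

  # squeezenet block order: conv -> pool -> fire -> flatten -> dropout -> dense
  sq <- build_network(network_config("squeezenet1d"))
  seq_types <- sq$audit$block[sq$audit$block != "relu"]
  expect_equal(seq_types,
               c("conv1d", "maxpool", "fire", "flatten", "dropout", "dense"))

  sh <- build_network(network_config("shufflenet1d"))
  expect_equal(sum(sh$audit$block == "shuffle_unit"), 2)
  expect_equal(sh$audit$block[1], "conv1d")
  expect_equal(utils::tail(sh$audit$block, 1), "dense")

  mb <- build_network(network_config("mobilenet1d"))
  expect_equal(sum(mb$audit$block == "dsc"), 2)

  expect_error(network_config("resnet"), "arg")
  expect_error(network_config("shufflenet1d", conv_filters = 25), "divisible")
})

test_that("each lightweight net undercuts a dense-conv network of equal width", {
  # replace every structured block by a dense kernel-3 convolution of the
  # same input/output channels, keeping the identical head
  dense1d <- function(ci, co, k = 3) k * ci * co + co
  sq <- count_params(build_network(network_config("squeezenet1d")))
  sq_dense <- arch_param_oracle("squeezenet1d") -
    ((16 * 16 + 16) + (16 * 32 + 32) + (3 * 16 * 32 + 32)) + dense1d(16, 64)
  expect_lt(sq, sq_dense)

  mb <- count_params(build_network(network_config("mobilenet1d")))
  dsc_w <- function(ci, co) (3 * ci + ci) + 2 * ci + (ci * co + co) + 2 * co
  mb_dense <- arch_param_oracle("mobilenet1d") - dsc_w(16, 32) - dsc_w(32, 64) +
    dense1d(16, 32) + dense1d(32, 64)
  expect_lt(mb, mb_dense)

  sh <- count_params(build_network(network_config("shufflenet1d")))
  unit_w <- 2 * (3 * (8 * 8) + 24) + (3 * 24 + 24)
  sh_dense <- arch_param_oracle("shufflenet1d") - 2 * unit_w +
    2 * dense1d(24, 24)
  expect_lt(sh, sh_dense)
})

test_that("weight initialization and forward passes reproduce under a seed", {
  a <- build_network(network_config("shufflenet1d", seed = 12))
  b <- build_network(network_config("shufflenet1d", seed = 12))
  pa <- sersnet:::sn_params(a$layers)
  pb <- sersnet:::sn_params(b$layers)
  expect_equal(length(pa), length(pb))
  for (i in seq_along(pa))
    expect_identical(pa[[i]]$env[[pa[[i]]$name]], pb[[i]]$env[[pb[[i]]$name]])
  set.seed(0)
  x <- matrix(runif(3 * 751), 3, 751)
  expect_identical(predict(a, x), predict(b, x))
})

# input channel count of a block, for the gradient test below
blk_cin <- function(blk) {
  if (!is.null(blk$sublayers)) {
    first <- blk$sublayers[[1]]
    if (!is.null(first$layers)) first <- first$layers[[1]]
    return(first$c_in)
  }
  if (!is.null(blk$layers)) return(blk$layers[[1]]$c_in)
  blk$c_in
}

test_that("block gradients match numeric differentiation", {
  ns <- asNamespace("sersnet")
  set.seed(21)
  for (make in list(function() fire_block(4, 3, 4),
                    function() dsc_block(4, 6),
                    function() shuffle_unit(6, 3),
                    function() ns$conv1d_layer(3, 4, 7, 2))) {
    blk <- block_init(make())
    # keep activations away from the ReLU kink at exactly zero
    for (p in ns$sn_params(blk))
      if (p$name == "b") p$env$b <- runif(length(p$env$b), 0.05, 0.2)
    x <- array(runif(2 * 10 * blk_cin(blk)), c(2, 10, blk_cin(blk)))
    loss <- function() sum(ns$sn_forward(blk, x, TRUE)^2) / 2
    y <- ns$sn_forward(blk, x, TRUE)
    ns$sn_backward(blk, y)
    for (p in ns$sn_params(blk)) {
      W <- p$env[[p$name]]
      G <- p$env[[paste0("g", p$name)]]
      for (i in sample(length(W), min(4, length(W)))) {
        o <- W[i]; eps <- 1e-6
        p$env[[p$name]][i] <- o + eps; lp <- loss()
        p$env[[p$name]][i] <- o - eps; lm <- loss()
        p$env[[p$name]][i] <- o
        gn <- (lp - lm) / (2 * eps)
        expect_lt(abs(gn - G[i]) / max(1e-4, abs(gn) + abs(G[i])), 1e-4)
      }
    }
  }
})
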