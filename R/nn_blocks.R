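#' Channel-shuffle permutation
#'
#' The reshape-(g, C/g)-transpose-flatten permutation that interleaves
#' channels across groups so that consecutive grouped convolutions exchange
#' information. Output channel `i` (1-based) takes input channel
#' `((i-1) mod g) * (C/g) + (i-1) div g + 1`.
#'
#' @param channels Total channel count `C`.
#' @param groups Group count `g`; must divide `channels`.
#' @return Integer vector `src` of length `C`: output channel `i` is input
#'   channel `src[i]`.
#' @export
channel_shuffle_perm <- function(channels, groups) {
  channels <- as.integer(channels); groups <- as.integer(groups)
  if (channels < 1 || groups < 1 || channels %% groups != 0)
    stop("channel_shuffle: channels must be divisible by groups")
  i0 <- 0:(channels - 1L)
  (i0 %% groups) * (channels %/% groups) + i0 %/% groups + 1L
}

#' Shuffle the channels of a feature map
#'
#' @param x A feature map: matrix `[length, channels]` or array
#'   `[batch, length, channels]`.
#' @param groups Group count; must divide the channel count.
#' @return Object of the same shape with channels permuted; positions along
#'   the length axis are untouched.
#' @examples
#' m <- matrix(1:12, nrow = 2)  # 6 channels
#' channel_shuffle(m, groups = 2)
#' @export
channel_shuffle <- function(x, groups) {
  if (is.matrix(x)) {
    src <- channel_shuffle_perm(ncol(x), groups)
    return(x[, src, drop = FALSE])
  }
  if (is.array(x) && length(dim(x)) == 3) {
    src <- channel_shuffle_perm(dim(x)[3], groups)
    return(x[, , src, drop = FALSE])
  }
  stop("channel_shuffle: x must be a [L, C] matrix or [B, L, C] array")
}

shuffle_layer <- function(channels, groups) {
  src <- channel_shuffle_perm(channels, groups)
  .layer_env("shuffle", list(groups = as.integer(groups), src = src,
                             inv = order(src)))
}

#' @export
sn_forward.sn_shuffle <- function(layer, x, training = FALSE)
  x[, , layer$src, drop = FALSE]

#' @export
sn_backward.sn_shuffle <- function(layer, dy)
  dy[, , layer$inv, drop = FALSE]

#' Fire block
#'
#' SqueezeNet building block: a kernel-size-1 "squeeze" convolution reduces
#' the channel count to `squeeze_filters`, then two parallel "expand"
#' convolutions (kernel sizes 1 and 3, same padding) are applied and their
#' outputs concatenated along the channel axis, giving
#' `2 * expand_filters` output channels. ReLU follows the squeeze and the
#' concatenated expand.
#'
#' @param in_channels Input channel count.
#' @param squeeze_filters,expand_filters Positive filter counts.
#' @return A network block usable in [build_network()] models and directly
#'   via [block_forward()].
#' @export
fire_block <- function(in_channels, squeeze_filters, expand_filters) {
  if (squeeze_filters < 1 || expand_filters < 1)
    stop("fire_block: filter counts must be positive")
  .layer_env("fire", list(
    e = as.integer(expand_filters),
    sublayers = list(sq = conv1d_layer(in_channels, squeeze_filters, 1L),
                     e1 = conv1d_layer(squeeze_filters, expand_filters, 1L),
                     e3 = conv1d_layer(squeeze_filters, expand_filters, 3L))))
}

#' @export
sn_forward.sn_fire <- function(layer, x, training = FALSE) {
  s <- layer$sublayers
  a <- sn_forward(s$sq, x, training)
  layer$mask_s <- a > 0
  a <- a * layer$mask_s
  y1 <- sn_forward(s$e1, a, training)
  y3 <- sn_forward(s$e3, a, training)
  d <- dim(y1); e <- layer$e
  y <- array(0, c(d[1], d[2], 2L * e))
  y[, , 1:e] <- y1
  y[, , (e + 1L):(2L * e)] <- y3
  layer$mask_o <- y > 0
  y * layer$mask_o
}

#' @export
sn_backward.sn_fire <- function(layer, dy) {
  s <- layer$sublayers; e <- layer$e
  dy <- dy * layer$mask_o
  da <- sn_backward(s$e1, dy[, , 1:e, drop = FALSE]) +
    sn_backward(s$e3, dy[, , (e + 1L):(2L * e), drop = FALSE])
  sn_backward(s$sq, da * layer$mask_s)
}

#' @export
sn_shape.sn_fire <- function(layer, shape) c(shape[1], 2L * layer$e)

#' Depthwise-separable convolution block
#'
#' Depthwise convolution (one kernel of size `kernel` per input channel)
#' followed by a pointwise kernel-size-1 convolution, each followed by batch
#' normalization and ReLU. Weight count (excluding batch-norm parameters and
#' biases) is `kernel * c_in + c_in * c_out` versus
#' `kernel * c_in * c_out` for a dense convolution of the same shape.
#'
#' @param in_channels,out_channels Channel counts.
#' @param kernel Depthwise kernel size (default 3).
#' @return A network block.
#' @export
dsc_block <- function(in_channels, out_channels, kernel = 3L) {
  seq_block("dsc", list(dwconv1d_layer(in_channels, kernel),
                        bn_layer(in_channels),
                        relu_layer(),
                        conv1d_layer(in_channels, out_channels, 1L),
                        bn_layer(out_channels),
                        relu_layer()))
}

#' Shuffle unit
#'
#' ShuffleNet building block with a residual connection: 1x1 grouped
#' convolution, channel shuffle, kernel-3 depthwise convolution, 1x1 grouped
#' convolution, then element-wise addition of the block's input. Channel
#' count is preserved (required by the residual addition) and must be
#' divisible by `groups`.
#'
#' @param channels Input = output channel count.
#' @param groups Group count for the grouped convolutions and the shuffle.
#' @return A network block.
#' @export
shuffle_unit <- function(channels, groups) {
  if (channels %% groups != 0)
    stop("shuffle_unit: channels must be divisible by groups")
  .layer_env("shuffle_unit", list(
    sublayers = list(branch = seq_block("branch", list(
      gconv1d_layer(channels, channels, groups),
      relu_layer(),
      shuffle_layer(channels, groups),
      dwconv1d_layer(channels, 3L),
      relu_layer(),
      gconv1d_layer(channels, channels, groups))))))
}

#' @export
sn_forward.sn_shuffle_unit <- function(layer, x, training = FALSE) {
  if (dim(x)[3] != layer$sublayers$branch$layers[[1]]$c_in)
    stop("shuffle_unit: input channel count does not match the residual")
  x + sn_forward(layer$sublayers$branch, x, training)
}

#' @export
sn_backward.sn_shuffle_unit <- function(layer, dy)
  dy + sn_backward(layer$sublayers$branch, dy)

#' Apply a network block to a feature map
#'
#' Runs a single block (from [fire_block()], [dsc_block()],
#' [shuffle_unit()], ...) forward in inference mode, mainly for inspection
#' and testing of block arithmetic.
#'
#' @param block A network block.
#' @param x Feature map array `[batch, length, channels]`.
#' @param training Logical; use batch statistics and dropout when `TRUE`.
#' @return The block's output feature map.
#' @export
block_forward <- function(block, x, training = FALSE) {
  stopifnot(inherits(block, "sn_layer"), is.array(x), length(dim(x)) == 3)
  sn_forward(block, x, training)
}

#' Initialize a block's weights from the current RNG
#'
#' @param block A network block.
#' @return The block, with weights drawn uniformly at fan-in scale.
#' @export
block_init <- function(block) {
  stopifnot(inherits(block, "sn_layer"))
  sn_init(block)
  block
}

#' Count block or model parameters
#'
#' @param x A network block or a model from [build_network()].
#' @param kind `"all"` for every trainable parameter, `"weight"` for
#'   convolution/dense weights only (excluding biases and batch-norm
#'   parameters).
#' @return Integer parameter count.
#' @export
count_params <- function(x, kind = c("all", "weight")) {
  kind <- match.arg(kind)
  layers <- if (inherits(x, "sersnet_model")) x$layers else list(x)
  info <- do.call(rbind, lapply(layers, sn_info))
  if (is.null(info) || nrow(info) == 0) return(0L)
  if (kind == "weight") info <- info[info$kind == "weight", , drop = FALSE]
  as.integer(sum(info$n))
}
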