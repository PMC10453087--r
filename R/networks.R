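#' Network configuration
#'
#' Hyperparameters of one of the three lightweight 1D architectures. Widths
#' default to the smallest configuration consistent with each architecture's
#' block inventory; every value can be overridden through `...`.
#'
#' Architecture-specific fields and defaults:
#' \describe{
#'   \item{squeezenet1d}{`conv_filters` 16, `conv_kernel` 7, `conv_stride` 2,
#'     `squeeze` 16, `expand` 32, `dropout` 0.5. Block order: conv, maxpool,
#'     fire, flatten, dropout, dense. The pooling sits after a stride-2
#'     convolution so the fire module still sees a large feature map.}
#'   \item{mobilenet1d}{`conv_filters` 16, `conv_kernel` 3, `dsc1` 32,
#'     `dsc2` 64, `hidden` 64. Block order: conv, two depthwise-separable
#'     blocks, maxpool, flatten, two dense layers.}
#'   \item{shufflenet1d}{`conv_filters` 24, `conv_kernel` 3, `groups` 3,
#'     `n_units` 2, `hidden` 64, `dropout` 0.5. Block order: conv, maxpool,
#'     two shuffle units, flatten, dropout, two dense layers.}
#' }
#'
#' @param architecture One of `"shufflenet1d"`, `"squeezenet1d"`,
#'   `"mobilenet1d"`.
#' @param input_length Length of the input spectrum vector (default 751,
#'   the 300--1800 cm^-1 grid at 2 cm^-1 spacing).
#' @param n_classes Number of mixture classes (>= 2; default 4).
#' @param seed Seed for weight initialization.
#' @param ... Architecture-specific overrides (see Details).
#' @return An object of class `network_config`.
#' @export
network_config <- function(architecture = c("shufflenet1d", "squeezenet1d",
                                            "mobilenet1d"),
                           input_length = 751, n_classes = 4, seed = 1, ...) {
  architecture <- match.arg(architecture)
  defaults <- switch(architecture,
    squeezenet1d = list(conv_filters = 16L, conv_kernel = 7L,
                        conv_stride = 2L, squeeze = 16L, expand = 32L,
                        dropout = 0.5),
    mobilenet1d = list(conv_filters = 16L, conv_kernel = 3L, dsc1 = 32L,
                       dsc2 = 64L, hidden = 64L),
    shufflenet1d = list(conv_filters = 24L, conv_kernel = 3L, groups = 3L,
                        n_units = 2L, hidden = 64L, dropout = 0.5))
  dots <- list(...)
  bad <- setdiff(names(dots), names(defaults))
  if (length(bad))
    stop(sprintf("network_config: unknown option(s) for %s: %s",
                 architecture, paste(bad, collapse = ", ")))
  defaults[names(dots)] <- dots
  input_length <- as.integer(input_length)
  n_classes <- as.integer(n_classes)
  if (n_classes < 2) stop("network_config: n_classes must be >= 2")
  if (input_length < 16)
    stop("network_config: input_length below the smallest receptive field")
  if (architecture == "shufflenet1d" &&
      defaults$conv_filters %% defaults$groups != 0)
    stop("network_config: shufflenet channel count must be divisible by groups")
  structure(c(list(architecture = architecture, input_length = input_length,
                   n_classes = n_classes, seed = seed), defaults),
            class = "network_config")
}

.arch_layers <- function(config) {
  a <- config$architecture
  if (a == "squeezenet1d") {
    list(conv1d_layer(1L, config$conv_filters, config$conv_kernel,
                      config$conv_stride),
         relu_layer(),
         maxpool_layer(),
         fire_block(config$conv_filters, config$squeeze, config$expand),
         flatten_layer(),
         dropout_layer(config$dropout),
         dense_layer(NA, config$n_classes))
  } else if (a == "mobilenet1d") {
    list(conv1d_layer(1L, config$conv_filters, config$conv_kernel),
         relu_layer(),
         dsc_block(config$conv_filters, config$dsc1),
         dsc_block(config$dsc1, config$dsc2),
         maxpool_layer(),
         flatten_layer(),
         dense_layer(NA, config$hidden),
         relu_layer(),
         dense_layer(config$hidden, config$n_classes))
  } else {
    c(list(conv1d_layer(1L, config$conv_filters, config$conv_kernel),
           relu_layer(),
           maxpool_layer()),
      lapply(seq_len(config$n_units), function(i)
        shuffle_unit(config$conv_filters, config$groups)),
      list(flatten_layer(),
           dropout_layer(config$dropout),
           dense_layer(NA, config$hidden),
           relu_layer(),
           dense_layer(config$hidden, config$n_classes)))
  }
}

#' Build a lightweight 1D network
#'
#' Constructs the classifier described by a [network_config()]: the layer
#' sequence of the selected architecture with weights initialized uniformly
#' at fan-in scale from `config$seed`. The final dense layer has `n_classes`
#' outputs; [predict.sersnet_model()] applies a softmax so each spectrum maps
#' to a probability vector.
#'
#' @param config A [network_config()].
#' @return Object of class `sersnet_model` with elements `layers`, `config`,
#'   and `audit` (per-block output shapes and parameter counts).
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  layers <- .arch_layers(config)
  shape <- c(config$input_length, 1L)
  audit <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "dense" && is.na(l$n_in)) {
      if (shape[2] != 0L)
        stop("build_network: dense layer requires flattened input")
      layers[[i]] <- l <- dense_layer(shape[1], l$n_out)
    }
    shape <- sn_shape(l, shape)
    audit[[i]] <- data.frame(block = l$type, out_length = shape[1],
                             out_channels = shape[2], params = 0L)
  }
  audit <- do.call(rbind, audit)
  set.seed(config$seed)
  for (i in seq_along(layers)) {
    sn_init(layers[[i]])
    audit$params[i] <- count_params(layers[[i]])
  }
  structure(list(layers = layers, config = config,
                 input_length = config$input_length,
                 n_classes = config$n_classes, audit = audit,
                 class_names = NULL),
            class = "sersnet_model")
}

#' @export
print.sersnet_model <- function(x, ...) {
  cat(sprintf("<sersnet_model> %s: input %d -> %d classes, %d parameters\n",
              x$config$architecture, x$input_length, x$n_classes,
              count_params(x)))
  print(x$audit, row.names = FALSE)
  invisible(x)
}

# forward pass over a [N, L] intensity matrix in chunks; returns logits.
# The chunk bounds the size of intermediate feature maps, which for the
# widest architecture reach ~25 MB per layer at 64 rows.
.model_logits <- function(model, x, training = FALSE, chunk = 64L) {
  stopifnot(is.matrix(x))
  if (ncol(x) != model$input_length)
    stop(sprintf("model expects input length %d, got %d",
                 model$input_length, ncol(x)))
  if (training || nrow(x) <= chunk) {
    a <- array(x, c(nrow(x), ncol(x), 1L))
    for (l in model$layers) a <- sn_forward(l, a, training)
    return(a)
  }
  idx <- split(seq_len(nrow(x)), ceiling(seq_len(nrow(x)) / chunk))
  do.call(rbind, lapply(idx, function(i)
    .model_logits(model, x[i, , drop = FALSE], FALSE, chunk)))
}

#' Predict from a built (or trained) network
#'
#' @param object A `sersnet_model`.
#' @param x Matrix of spectra, one row per spectrum, already normalized the
#'   way the training inputs were.
#' @param type `"prob"` for the softmax probability matrix, `"class"` for
#'   the argmax class (factor when class names are known).
#' @param ... Unused.
#' @return Probability matrix `[n, n_classes]` or class vector.
#' @export
predict.sersnet_model <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- .softmax(.model_logits(object, x))
  if (!is.null(object$class_names)) colnames(p) <- object$class_names
  if (type == "prob") return(p)
  k <- max.col(p, ties.method = "first")
  if (is.null(object$class_names)) k
  else factor(object$class_names[k], levels = object$class_names)
}

#' Architecture audit
#'
#' Per-block output shapes and parameter counts plus totals, suitable for
#' JSON serialization next to a checkpoint.
#'
#' @param model A `sersnet_model`.
#' @return List with `architecture`, `input_length`, `n_classes`, `blocks`
#'   (data frame), `total_params`, `weight_params`.
#' @export
model_audit <- function(model) {
  stopifnot(inherits(model, "sersnet_model"))
  list(architecture = model$config$architecture,
       input_length = model$input_length,
       n_classes = model$n_classes,
       blocks = model$audit,
       total_params = count_params(model),
       weight_params = count_params(model, "weight"))
}
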