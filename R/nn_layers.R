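# Minimal reverse-mode engine for 1D convolutional networks.
#
# Feature maps are arrays [batch, length, channels]; after flattening,
# matrices [batch, features]. Layers are environments so parameters and
# optimizer state can be updated in place; each layer type implements the
# sn_forward / sn_backward / sn_init / sn_shape / sn_info generics.
# Column-major array order (batch fastest) lets im2col and reshapes be
# plain dim<- assignments with no data movement beyond slicing.

.layer_env <- function(type, fields = list()) {
  e <- new.env(parent = emptyenv())
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$type <- type
  if (is.null(e$param_names)) e$param_names <- character(0)
  class(e) <- c(paste0("sn_", type), "sn_layer")
  e
}

sn_forward <- function(layer, x, training = FALSE) UseMethod("sn_forward")
sn_backward <- function(layer, dy) UseMethod("sn_backward")
sn_init <- function(layer) UseMethod("sn_init")
sn_shape <- function(layer, shape) UseMethod("sn_shape")
sn_info <- function(layer) UseMethod("sn_info")

#' @export
sn_init.default <- function(layer) invisible(layer)
#' @export
sn_shape.default <- function(layer, shape) shape
#' @export
sn_info.default <- function(layer)
  data.frame(name = character(), n = integer(), kind = character())

# list of list(env, name) pairs for every trainable array in a layer tree
sn_params <- function(layer) {
  if (is.list(layer) && !is.environment(layer))
    return(do.call(c, lapply(layer, sn_params)))
  own <- lapply(layer$param_names, function(nm) list(env = layer, name = nm))
  if (!is.null(layer$layers)) own <- c(own, sn_params(layer$layers))
  if (!is.null(layer$sublayers)) own <- c(own, sn_params(layer$sublayers))
  own
}

.uniform_init <- function(dims, fan_in) {
  lim <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -lim, lim), dims)
}

.same_pad <- function(L, k, stride) {
  L_out <- as.integer(ceiling(L / stride))
  pt <- max((L_out - 1L) * stride + k - L, 0L)
  list(left = pt %/% 2L, right = pt - pt %/% 2L, L_out = L_out)
}

.pad_length <- function(x, left, right) {
  d <- dim(x)
  if (left == 0 && right == 0) return(x)
  xp <- array(0, c(d[1], d[2] + left + right, d[3]))
  xp[, (left + 1):(left + d[2]), ] <- x
  xp
}

# ---- dense 1D convolution (im2col) ----------------------------------------

conv1d_layer <- function(c_in, c_out, k, stride = 1L) {
  if (c_in < 1 || c_out < 1 || k < 1)
    stop("conv1d_layer: filter counts and kernel size must be positive")
  .layer_env("conv1d", list(c_in = as.integer(c_in), c_out = as.integer(c_out),
                            k = as.integer(k), stride = as.integer(stride),
                            W = array(0, c(k * c_in, c_out)),
                            b = numeric(c_out),
                            param_names = c("W", "b")))
}

#' @export
sn_init.sn_conv1d <- function(layer) {
  layer$W <- .uniform_init(dim(layer$W), layer$k * layer$c_in)
  layer$b <- numeric(layer$c_out)
  invisible(layer)
}

#' @export
sn_forward.sn_conv1d <- function(layer, x, training = FALSE) {
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
  stopifnot(C == layer$c_in)
  p <- .same_pad(L, layer$k, layer$stride)
  xp <- .pad_length(x, p$left, p$right)
  X2 <- matrix(0, B * p$L_out, layer$k * C)
  for (j in seq_len(layer$k)) {
    pos <- seq.int(j, by = layer$stride, length.out = p$L_out)
    X2[, ((j - 1L) * C + 1L):(j * C)] <- xp[, pos, , drop = FALSE]
  }
  Y <- X2 %*% layer$W
  Y <- Y + rep(layer$b, each = B * p$L_out)
  layer$cache <- list(X2 = X2, B = B, L = L, Lp = dim(xp)[2], p = p)
  array(Y, c(B, p$L_out, layer$c_out))
}

#' @export
sn_backward.sn_conv1d <- function(layer, dy) {
  cc <- layer$cache; B <- cc$B; L_out <- cc$p$L_out; C <- layer$c_in
  dY <- matrix(dy, B * L_out, layer$c_out)
  layer$gW <- crossprod(cc$X2, dY)
  layer$gb <- colSums(dY)
  dX2 <- tcrossprod(dY, layer$W)
  dxp <- array(0, c(B, cc$Lp, C))
  for (j in seq_len(layer$k)) {
    pos <- seq.int(j, by = layer$stride, length.out = L_out)
    dxp[, pos, ] <- dxp[, pos, , drop = FALSE] +
      array(dX2[, ((j - 1L) * C + 1L):(j * C)], c(B, L_out, C))
  }
  dxp[, (cc$p$left + 1L):(cc$p$left + cc$L), , drop = FALSE]
}

#' @export
sn_shape.sn_conv1d <- function(layer, shape)
  c(as.integer(ceiling(shape[1] / layer$stride)), layer$c_out)

#' @export
sn_info.sn_conv1d <- function(layer)
  data.frame(name = c("W", "b"), n = c(length(layer$W), length(layer$b)),
             kind = c("weight", "bias"))

# ---- depthwise convolution (kernel along length, one filter per channel) ---

dwconv1d_layer <- function(c_in, k = 3L) {
  if (c_in < 1 || k < 1) stop("dwconv1d_layer: invalid shape")
  .layer_env("dwconv1d", list(c_in = as.integer(c_in), k = as.integer(k),
                              W = array(0, c(k, c_in)), b = numeric(c_in),
                              param_names = c("W", "b")))
}

#' @export
sn_init.sn_dwconv1d <- function(layer) {
  layer$W <- .uniform_init(dim(layer$W), layer$k)
  layer$b <- numeric(layer$c_in)
  invisible(layer)
}

#' @export
sn_forward.sn_dwconv1d <- function(layer, x, training = FALSE) {
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
  stopifnot(C == layer$c_in)
  p <- .same_pad(L, layer$k, 1L)
  xp <- .pad_length(x, p$left, p$right)
  y <- array(0, c(B, L, C))
  for (j in seq_len(layer$k))
    y <- y + xp[, j:(j + L - 1L), , drop = FALSE] *
      rep(layer$W[j, ], each = B * L)
  y <- y + rep(layer$b, each = B * L)
  layer$cache <- list(xp = xp, B = B, L = L, p = p)
  y
}

#' @export
sn_backward.sn_dwconv1d <- function(layer, dy) {
  cc <- layer$cache; B <- cc$B; L <- cc$L; C <- layer$c_in
  gW <- array(0, dim(layer$W))
  dxp <- array(0, dim(cc$xp))
  for (j in seq_len(layer$k)) {
    sl <- cc$xp[, j:(j + L - 1L), , drop = FALSE]
    gW[j, ] <- colSums(matrix(dy * sl, B * L, C))
    dxp[, j:(j + L - 1L), ] <- dxp[, j:(j + L - 1L), , drop = FALSE] +
      dy * rep(layer$W[j, ], each = B * L)
  }
  layer$gW <- gW
  layer$gb <- colSums(matrix(dy, B * L, C))
  dxp[, (cc$p$left + 1L):(cc$p$left + L), , drop = FALSE]
}

#' @export
sn_info.sn_dwconv1d <- function(layer)
  data.frame(name = c("W", "b"), n = c(length(layer$W), length(layer$b)),
             kind = c("weight", "bias"))

# ---- grouped 1x1 convolution ----------------------------------------------

gconv1d_layer <- function(c_in, c_out, groups) {
  if (c_in %% groups != 0 || c_out %% groups != 0)
    stop("gconv1d_layer: channel counts must be divisible by the group count")
  .layer_env("gconv1d", list(
    c_in = as.integer(c_in), c_out = as.integer(c_out),
    groups = as.integer(groups),
    W = array(0, c(c_in %/% groups, c_out %/% groups, groups)),
    b = numeric(c_out), param_names = c("W", "b")))
}

#' @export
sn_init.sn_gconv1d <- function(layer) {
  layer$W <- .uniform_init(dim(layer$W), layer$c_in %/% layer$groups)
  layer$b <- numeric(layer$c_out)
  invisible(layer)
}

#' @export
sn_forward.sn_gconv1d <- function(layer, x, training = FALSE) {
  d <- dim(x); B <- d[1]; L <- d[2]
  stopifnot(d[3] == layer$c_in)
  g <- layer$groups; ci <- layer$c_in %/% g; co <- layer$c_out %/% g
  y <- array(0, c(B, L, layer$c_out))
  Xg <- vector("list", g)
  for (gi in seq_len(g)) {
    ic <- ((gi - 1L) * ci + 1L):(gi * ci)
    oc <- ((gi - 1L) * co + 1L):(gi * co)
    Xg[[gi]] <- matrix(x[, , ic, drop = FALSE], B * L, ci)
    y[, , oc] <- array(Xg[[gi]] %*% layer$W[, , gi], c(B, L, co))
  }
  y <- y + rep(layer$b, each = B * L)
  layer$cache <- list(Xg = Xg, B = B, L = L)
  y
}

#' @export
sn_backward.sn_gconv1d <- function(layer, dy) {
  cc <- layer$cache; B <- cc$B; L <- cc$L
  g <- layer$groups; ci <- layer$c_in %/% g; co <- layer$c_out %/% g
  gW <- array(0, dim(layer$W))
  dx <- array(0, c(B, L, layer$c_in))
  for (gi in seq_len(g)) {
    ic <- ((gi - 1L) * ci + 1L):(gi * ci)
    oc <- ((gi - 1L) * co + 1L):(gi * co)
    dYg <- matrix(dy[, , oc, drop = FALSE], B * L, co)
    gW[, , gi] <- crossprod(cc$Xg[[gi]], dYg)
    dx[, , ic] <- array(tcrossprod(dYg, layer$W[, , gi]), c(B, L, ci))
  }
  layer$gW <- gW
  layer$gb <- colSums(matrix(dy, B * L, layer$c_out))
  dx
}

#' @export
sn_shape.sn_gconv1d <- function(layer, shape) c(shape[1], layer$c_out)

#' @export
sn_info.sn_gconv1d <- function(layer)
  data.frame(name = c("W", "b"), n = c(length(layer$W), length(layer$b)),
             kind = c("weight", "bias"))

# ---- batch normalization (per channel over batch x length) -----------------

bn_layer <- function(c_in, momentum = 0.9, eps = 1e-5) {
  .layer_env("bn", list(c_in = as.integer(c_in), momentum = momentum,
                        eps = eps, gamma = rep(1, c_in), beta = numeric(c_in),
                        running_mean = numeric(c_in), running_var = rep(1, c_in),
                        param_names = c("gamma", "beta")))
}

#' @export
sn_init.sn_bn <- function(layer) {
  layer$gamma <- rep(1, layer$c_in); layer$beta <- numeric(layer$c_in)
  layer$running_mean <- numeric(layer$c_in)
  layer$running_var <- rep(1, layer$c_in)
  invisible(layer)
}

#' @export
sn_forward.sn_bn <- function(layer, x, training = FALSE) {
  d <- dim(x); N <- d[1] * d[2]; C <- d[3]
  xm <- matrix(x, N, C)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    layer$running_mean <- layer$momentum * layer$running_mean +
      (1 - layer$momentum) * mu
    layer$running_var <- layer$momentum * layer$running_var +
      (1 - layer$momentum) * v
  } else {
    mu <- layer$running_mean; v <- layer$running_var
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- (xm - rep(mu, each = N)) * rep(invstd, each = N)
  y <- xhat * rep(layer$gamma, each = N) + rep(layer$beta, each = N)
  layer$cache <- list(xhat = xhat, invstd = invstd, d = d, N = N)
  array(y, d)
}

#' @export
sn_backward.sn_bn <- function(layer, dy) {
  cc <- layer$cache; N <- cc$N; C <- layer$c_in
  dym <- matrix(dy, N, C)
  layer$ggamma <- colSums(dym * cc$xhat)
  layer$gbeta <- colSums(dym)
  dxhat <- dym * rep(layer$gamma, each = N)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cc$xhat)
  dx <- (rep(cc$invstd, each = N) / N) *
    (N * dxhat - rep(s1, each = N) - cc$xhat * rep(s2, each = N))
  array(dx, cc$d)
}

#' @export
sn_info.sn_bn <- function(layer)
  data.frame(name = c("gamma", "beta"),
             n = c(length(layer$gamma), length(layer$beta)),
             kind = c("bn", "bn"))

# ---- parameter-free layers -------------------------------------------------

relu_layer <- function() .layer_env("relu")

#' @export
sn_forward.sn_relu <- function(layer, x, training = FALSE) {
  layer$mask <- x > 0
  x * layer$mask
}

#' @export
sn_backward.sn_relu <- function(layer, dy) dy * layer$mask

maxpool_layer <- function(pool = 2L) {
  stopifnot(pool == 2L)
  .layer_env("maxpool", list(pool = 2L))
}

#' @export
sn_forward.sn_maxpool <- function(layer, x, training = FALSE) {
  d <- dim(x); L2 <- d[2] %/% 2L
  a <- x[, seq.int(1L, 2L * L2, 2L), , drop = FALSE]
  b <- x[, seq.int(2L, 2L * L2, 2L), , drop = FALSE]
  m <- a >= b
  layer$cache <- list(m = m, d = d, L2 = L2)
  a * m + b * !m
}

#' @export
sn_backward.sn_maxpool <- function(layer, dy) {
  cc <- layer$cache
  dx <- array(0, cc$d)
  dx[, seq.int(1L, 2L * cc$L2, 2L), ] <- dy * cc$m
  dx[, seq.int(2L, 2L * cc$L2, 2L), ] <- dy * !cc$m
  dx
}

#' @export
sn_shape.sn_maxpool <- function(layer, shape)
  c(shape[1] %/% 2L, shape[2])

flatten_layer <- function() .layer_env("flatten")

#' @export
sn_forward.sn_flatten <- function(layer, x, training = FALSE) {
  d <- dim(x)
  layer$cache <- d
  # [B, L, C] -> [B, L*C]; column-major order keeps batch as the row index
  dim(x) <- c(d[1], d[2] * d[3])
  x
}

#' @export
sn_backward.sn_flatten <- function(layer, dy) {
  dim(dy) <- layer$cache
  dy
}

#' @export
sn_shape.sn_flatten <- function(layer, shape)
  c(as.integer(shape[1] * shape[2]), 0L)

dropout_layer <- function(p = 0.5) {
  stopifnot(p >= 0, p < 1)
  .layer_env("dropout", list(p = p))
}

#' @export
sn_forward.sn_dropout <- function(layer, x, training = FALSE) {
  if (!training || layer$p == 0) {
    layer$mask <- NULL
    return(x)
  }
  m <- (stats::runif(length(x)) >= layer$p) / (1 - layer$p)
  dim(m) <- dim(x)
  layer$mask <- m
  x * m
}

#' @export
sn_backward.sn_dropout <- function(layer, dy)
  if (is.null(layer$mask)) dy else dy * layer$mask

dense_layer <- function(n_in, n_out) {
  n_in <- as.integer(n_in)  # may be NA: size resolved when the model is built
  W <- if (is.na(n_in)) NULL else array(0, c(n_in, n_out))
  .layer_env("dense", list(n_in = n_in, n_out = as.integer(n_out),
                           W = W, b = numeric(n_out),
                           param_names = c("W", "b")))
}

#' @export
sn_init.sn_dense <- function(layer) {
  layer$W <- .uniform_init(dim(layer$W), layer$n_in)
  layer$b <- numeric(layer$n_out)
  invisible(layer)
}

#' @export
sn_forward.sn_dense <- function(layer, x, training = FALSE) {
  stopifnot(ncol(x) == layer$n_in)
  layer$cache <- x
  x %*% layer$W + rep(layer$b, each = nrow(x))
}

#' @export
sn_backward.sn_dense <- function(layer, dy) {
  layer$gW <- crossprod(layer$cache, dy)
  layer$gb <- colSums(dy)
  tcrossprod(dy, layer$W)
}

#' @export
sn_shape.sn_dense <- function(layer, shape) c(layer$n_out, 0L)

#' @export
sn_info.sn_dense <- function(layer)
  data.frame(name = c("W", "b"), n = c(length(layer$W), length(layer$b)),
             kind = c("weight", "bias"))

# ---- sequential composite --------------------------------------------------

seq_block <- function(type, layers) {
  .layer_env(type, list(layers = layers, composite = "seq"))
}

#' @export
sn_forward.sn_layer <- function(layer, x, training = FALSE) {
  if (is.null(layer$layers))
    stop(sprintf("no forward method for layer type %s", layer$type))
  for (l in layer$layers) x <- sn_forward(l, x, training)
  x
}

#' @export
sn_backward.sn_layer <- function(layer, dy) {
  if (is.null(layer$layers))
    stop(sprintf("no backward method for layer type %s", layer$type))
  for (l in rev(layer$layers)) dy <- sn_backward(l, dy)
  dy
}

#' @export
sn_init.sn_layer <- function(layer) {
  if (!is.null(layer$layers)) for (l in layer$layers) sn_init(l)
  if (!is.null(layer$sublayers)) for (l in layer$sublayers) sn_init(l)
  invisible(layer)
}

#' @export
sn_shape.sn_layer <- function(layer, shape) {
  if (is.null(layer$layers)) return(shape)
  for (l in layer$layers) shape <- sn_shape(l, shape)
  shape
}

#' @export
sn_info.sn_layer <- function(layer) {
  subs <- c(layer$layers, layer$sublayers)
  if (is.null(subs)) return(sn_info.default(layer))
  do.call(rbind, lapply(subs, sn_info))
}

# ---- softmax / cross-entropy ----------------------------------------------

.softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# labels: integer class indices in 1..K; returns loss and dlogits
.softmax_xent <- function(logits, labels) {
  B <- nrow(logits)
  p <- .softmax(logits)
  idx <- cbind(seq_len(B), labels)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  d <- p
  d[idx] <- d[idx] - 1
  list(loss = loss, dlogits = d / B)
}
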