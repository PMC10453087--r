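#' Stratified training/validation/prediction split
#'
#' Random partition of spectra into a prediction subset of
#' `round(prediction_frac * N)` spectra, with the remainder divided 3:1 into
#' training and validation. Allocation is stratified by class with
#' largest-remainder rounding, so the global subset sizes are exact (400
#' spectra give 120 prediction, 210 training, 70 validation) and per-class
#' counts are as even as the arithmetic allows.
#'
#' Spectra are split individually, so replicates of one sample can land in
#' different subsets; pass `group` (e.g. the sample id) to keep whole groups
#' together, at the price of approximate subset sizes.
#'
#' @param labels Class label per spectrum (factor or character).
#' @param seed Integer seed; the partition is a pure function of
#'   `(labels, seed)`.
#' @param prediction_frac Fraction held out for prediction (default 0.30).
#' @param val_frac_of_rest Validation fraction of the non-prediction
#'   remainder (default 0.25, i.e. a 3:1 training:validation ratio).
#' @param group Optional grouping vector of the same length as `labels`.
#' @return Object of class `sersnet_split`: list of integer index vectors
#'   `training`, `validation`, `prediction`, plus `seed`.
#' @export
split_dataset <- function(labels, seed = 1, prediction_frac = 0.30,
                          val_frac_of_rest = 0.25, group = NULL) {
  labels <- factor(labels)
  n <- length(labels)
  if (n < 8) stop("split_dataset: need at least 8 spectra")
  n_pred <- round(prediction_frac * n)
  n_rem <- n - n_pred
  n_train <- round((1 - val_frac_of_rest) * n_rem)
  n_val <- n_rem - n_train
  counts <- table(labels)
  if (any(counts < 3))
    stop("split_dataset: every class needs at least 3 spectra to appear in all subsets")
  pred_k <- .largest_remainder(n_pred * as.numeric(counts) / n, n_pred)
  rem_k <- as.numeric(counts) - pred_k
  val_k <- .largest_remainder(n_val * rem_k / n_rem, n_val)
  train_k <- rem_k - val_k
  if (any(pred_k < 1 | val_k < 1 | train_k < 1))
    stop("split_dataset: a class has too few members to appear in all subsets")
  set.seed(seed)
  training <- validation <- prediction <- integer(0)
  for (i in seq_along(levels(labels))) {
    idx <- which(labels == levels(labels)[i])
    if (is.null(group)) {
      idx <- sample(idx)
      prediction <- c(prediction, idx[seq_len(pred_k[i])])
      validation <- c(validation, idx[pred_k[i] + seq_len(val_k[i])])
      training <- c(training, idx[(pred_k[i] + val_k[i] + 1):length(idx)])
    } else {
      gs <- sample(unique(group[idx]))
      sizes <- vapply(gs, function(g) sum(group[idx] == g), 1L)
      cum <- cumsum(sizes)
      np <- which.min(abs(cum - pred_k[i]))
      nv <- which.min(abs(cum - (pred_k[i] + val_k[i])))
      nv <- max(nv, np + 1L)
      pg <- gs[seq_len(np)]
      vg <- gs[(np + 1):nv]
      prediction <- c(prediction, idx[group[idx] %in% pg])
      validation <- c(validation, idx[group[idx] %in% vg])
      training <- c(training, idx[!(group[idx] %in% c(pg, vg))])
    }
  }
  structure(list(training = sort(training), validation = sort(validation),
                 prediction = sort(prediction), seed = seed),
            class = "sersnet_split")
}

# integer allocation matching a real-valued quota vector and an exact total
.largest_remainder <- function(quota, total) {
  base <- floor(quota)
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' @export
print.sersnet_split <- function(x, ...) {
  cat(sprintf("<sersnet_split> training %d / validation %d / prediction %d (seed %s)\n",
              length(x$training), length(x$validation), length(x$prediction),
              format(x$seed)))
  invisible(x)
}

# ---- Adam ------------------------------------------------------------------

.adam_step <- function(params, lr, beta1, beta2, eps, t) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  for (p in params) {
    env <- p$env; nm <- p$name
    g <- env[[paste0("g", nm)]]
    if (is.null(g)) next
    st <- env$.opt[[nm]]
    if (is.null(st)) st <- list(m = g * 0, v = g * 0)
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    if (is.null(env$.opt)) env$.opt <- list()
    env$.opt[[nm]] <- st
    env[[nm]] <- env[[nm]] - lr * (st$m / corr1) / (sqrt(st$v / corr2) + eps)
  }
}

.snapshot_params <- function(params)
  lapply(params, function(p) p$env[[p$name]])

.restore_params <- function(params, snap) {
  for (i in seq_along(params))
    params[[i]]$env[[params[[i]]$name]] <- snap[[i]]
  # batch-norm running statistics travel with the snapshot owner already
  invisible(NULL)
}

.normalize_rows <- function(x, method) {
  if (method == "none") return(x)
  if (method == "minmax") {
    lo <- apply(x, 1, min); hi <- apply(x, 1, max)
    if (any(hi - lo <= 0)) stop("constant spectrum cannot be min-max normalized")
    return((x - lo) / (hi - lo))
  }
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop("zero spectrum cannot be vector normalized")
  x / nrm
}

.model_acc <- function(model, x, yi) {
  p <- .model_logits(model, x)
  mean(max.col(p, ties.method = "first") == yi) * 100
}

#' Train a network
#'
#' Minimizes softmax cross-entropy on the training subset with Adam,
#' tracking training and validation accuracy each epoch. The returned model
#' is the epoch with the highest validation accuracy (earliest on ties);
#' training stops early when validation accuracy has not improved for
#' `patience` epochs. With a fixed `seed` (governing minibatch order and
#' dropout) the run is reproducible on a given platform.
#'
#' @param model A freshly built [build_network()] model (its weights are
#'   updated in place).
#' @param x Spectra matrix `[N, input_length]`, raw intensities.
#' @param labels Class label per row.
#' @param split A [split_dataset()] partition.
#' @param epochs Maximum epochs (default 200).
#' @param batch_size Minibatch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param beta1,beta2,eps Adam moment parameters.
#' @param patience Early-stopping patience in epochs (default 30).
#' @param seed Seed for minibatch shuffling and dropout.
#' @param normalize Per-spectrum input scaling applied before training and
#'   stored with the fit: `"minmax"` (default), `"vector"`, or `"none"`.
#' @param verbose Print per-epoch progress.
#' @return Object of class `sersnet_fit`: list with `model`, `history`
#'   (data frame of epoch, loss, training/validation accuracy),
#'   `best_epoch`, `class_names`, `normalize`, `split`, `seed`.
#' @export
train_network <- function(model, x, labels, split, epochs = 200,
                          batch_size = 32, lr = 1e-3, beta1 = 0.9,
                          beta2 = 0.999, eps = 1e-8, patience = 30,
                          seed = 1, normalize = c("minmax", "vector", "none"),
                          verbose = FALSE) {
  stopifnot(inherits(model, "sersnet_model"), inherits(split, "sersnet_split"))
  normalize <- match.arg(normalize)
  if (!is.matrix(x) || ncol(x) != model$input_length)
    stop(sprintf("train_network: spectra length %s does not match model input length %d",
                 if (is.matrix(x)) ncol(x) else "?", model$input_length))
  labels <- factor(labels)
  if (nlevels(labels) != model$n_classes)
    stop("train_network: number of classes does not match the model head")
  x <- .normalize_rows(x, normalize)
  yi <- as.integer(labels)
  tr <- split$training; va <- split$validation
  params <- sn_params(model$layers)
  set.seed(seed)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        acc_train = numeric(), acc_val = numeric())
  best_acc <- -Inf; best_epoch <- 0L; best_snap <- NULL; t <- 0L
  for (epoch in seq_len(epochs)) {
    ord <- sample(tr)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      logits <- .model_logits(model, x[b, , drop = FALSE], training = TRUE)
      sx <- .softmax_xent(logits, yi[b])
      losses[bi] <- sx$loss
      dy <- sx$dlogits
      for (l in rev(model$layers)) dy <- sn_backward(l, dy)
      t <- t + 1L
      .adam_step(params, lr, beta1, beta2, eps, t)
    }
    acc_tr <- .model_acc(model, x[tr, , drop = FALSE], yi[tr])
    acc_va <- .model_acc(model, x[va, , drop = FALSE], yi[va])
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = mean(losses),
                                         acc_train = acc_tr,
                                         acc_val = acc_va))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc_T %.2f  acc_V %.2f",
                      epoch, mean(losses), acc_tr, acc_va))
    if (acc_va > best_acc) {
      best_acc <- acc_va
      best_epoch <- epoch
      best_snap <- .snapshot_params(params)
      best_bn <- lapply(.bn_layers(model$layers), function(l)
        list(m = l$running_mean, v = l$running_var))
    }
    # selection is by validation accuracy: once both subsets are perfect
    # there is nothing left to select between
    if (acc_tr == 100 && acc_va == 100) break
    if (epoch - best_epoch >= patience) break
  }
  .restore_params(params, best_snap)
  bns <- .bn_layers(model$layers)
  for (i in seq_along(bns)) {
    bns[[i]]$running_mean <- best_bn[[i]]$m
    bns[[i]]$running_var <- best_bn[[i]]$v
  }
  model$class_names <- levels(labels)
  structure(list(model = model, history = history, best_epoch = best_epoch,
                 class_names = levels(labels), normalize = normalize,
                 split = split, seed = seed),
            class = "sersnet_fit")
}

.bn_layers <- function(layers) {
  out <- list()
  rec <- function(l) {
    if (is.list(l) && !is.environment(l)) { lapply(l, rec); return(invisible()) }
    if (inherits(l, "sn_bn")) out[[length(out) + 1L]] <<- l
    if (!is.null(l$layers)) rec(l$layers)
    if (!is.null(l$sublayers)) rec(l$sublayers)
    invisible()
  }
  rec(layers)
  out
}

#' @export
print.sersnet_fit <- function(x, ...) {
  last <- x$history[x$best_epoch, ]
  cat(sprintf("<sersnet_fit> %s, %d epochs (best %d): acc_T %.2f%%, acc_V %.2f%%\n",
              x$model$config$architecture, nrow(x$history), x$best_epoch,
              last$acc_train, last$acc_val))
  invisible(x)
}

#' Predict classes or probabilities from a fit
#'
#' Applies the fit's stored input normalization, then the network.
#'
#' @param object A `sersnet_fit`.
#' @param x Raw spectra matrix `[N, input_length]`.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Factor of predicted classes, or probability matrix.
#' @export
predict.sersnet_fit <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- .normalize_rows(x, object$normalize)
  predict(object$model, x, type = type)
}

#' Evaluate a fit on the split subsets
#'
#' Argmax-of-softmax class assignment and a full [classification_metrics()]
#' report for each subset of the fit's (or a supplied) split.
#'
#' @param fit A `sersnet_fit`.
#' @param x Raw spectra matrix.
#' @param labels True class labels per row.
#' @param split A [split_dataset()] partition; defaults to the one stored in
#'   the fit.
#' @return Object of class `sersnet_evaluation`: list of
#'   `classification_report`s under `training`, `validation`, `prediction`,
#'   plus `acc` (named vector `acc_t`, `acc_v`, `acc_p`).
#' @export
evaluate_network <- function(fit, x, labels, split = fit$split) {
  stopifnot(inherits(fit, "sersnet_fit"))
  labels <- factor(labels, levels = fit$class_names)
  pred <- predict(fit, x)
  reports <- lapply(list(training = split$training,
                         validation = split$validation,
                         prediction = split$prediction), function(idx) {
    if (length(idx) == 0) stop("evaluate_network: empty subset")
    classification_metrics(confusion_matrix(labels[idx], pred[idx],
                                            classes = fit$class_names))
  })
  acc <- c(acc_t = reports$training$accuracy,
           acc_v = reports$validation$accuracy,
           acc_p = reports$prediction$accuracy)
  structure(c(reports, list(acc = acc)), class = "sersnet_evaluation")
}

#' @export
print.sersnet_evaluation <- function(x, ...) {
  cat(sprintf("ACC_T = %.2f%%  ACC_V = %.2f%%  ACC_P = %.2f%%\n",
              x$acc["acc_t"], x$acc["acc_v"], x$acc["acc_p"]))
  cat("Prediction subset:\n")
  print(x$prediction)
  invisible(x)
}
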