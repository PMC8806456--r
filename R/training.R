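## Loss, bespoke momentum-SGD update, layer freezing, transfer
## initialization, and the mini-batch training loop.

#' Mean binary cross-entropy (logistic) loss
#'
#' `L = -(1/n) * sum_i [ y_i log p_i + (1 - y_i) log(1 - p_i) ]`, with
#' predictions clipped into `[eps, 1 - eps]` before the logarithms.
#'
#' @param predictions Predicted positive-class probabilities in `[0, 1]`.
#' @param labels Binary labels (0/1), same length.
#' @param eps Clipping constant guarding the logarithms (default 1e-7).
#' @return Non-negative scalar loss.
#' @examples
#' logistic_loss(c(0.5, 0.5), c(0, 1))  # log(2)
#' @export
logistic_loss <- function(predictions, labels, eps = 1e-7) {
  n <- length(predictions)
  if (n == 0 || length(labels) != n)
    stop("predictions and labels must be non-empty and of equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  p <- pmin(pmax(predictions, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Create an optimizer state
#'
#' Houses the hyperparameters and per-parameter velocities of the momentum
#' SGD update `v' = mu * v - lambda * eps * w - eps * grad; w' = w + v'`.
#' Defaults are the transfer-learning settings used throughout the package:
#' learning rate 1e-4, momentum 0.95, weight decay 1e-6.
#'
#' @param learning_rate Step size `eps > 0`.
#' @param momentum Momentum coefficient `mu` in `[0, 1)`.
#' @param weight_decay Per-step weight decay `lambda >= 0`.
#' @return An object of class `optimizer_state` with zero velocities
#'   (allocated lazily per parameter) and iteration index 0.
#' @export
optimizer_state <- function(learning_rate = 1e-4, momentum = 0.95,
                            weight_decay = 1e-6) {
  stopifnot(learning_rate >= 0, momentum >= 0, momentum < 1, weight_decay >= 0)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, v = list(), iteration = 0L),
            class = "optimizer_state")
}

#' One momentum-SGD update of a single parameter tensor
#'
#' Applies `v' = mu * v - lambda * eps * w - eps * grad` followed by
#' `w' = w + v'`, where `eps` is the learning rate, `mu` the momentum and
#' `lambda` the weight decay, and increments the iteration index.
#'
#' @param state An [optimizer_state()].
#' @param w Parameter tensor.
#' @param grad Batch-averaged gradient, same shape as `w`.
#' @param name Key under which the velocity is stored (default `"w"`).
#' @return `list(state, w)` with the updated velocity and weights.
#' @examples
#' st <- optimizer_state(learning_rate = 1e-4, momentum = 0.95,
#'                       weight_decay = 1e-6)
#' momentum_step(st, w = 1, grad = 0.5)$w  # 1 - (1e-6*1e-4*1 + 1e-4*0.5)
#' @export
momentum_step <- function(state, w, grad, name = "w") {
  stopifnot(inherits(state, "optimizer_state"))
  if (length(w) != length(grad))
    stop(sprintf("momentum_step: weight has %d elements, gradient %d",
                 length(w), length(grad)))
  v <- state$v[[name]]
  if (is.null(v)) v <- w * 0
  v <- state$momentum * v - state$weight_decay * state$learning_rate * w -
    state$learning_rate * grad
  w <- w + v
  state$v[[name]] <- v
  state$iteration <- state$iteration + 1L
  list(state = state, w = w)
}

#' Freeze the first n convolutional layers
#'
#' Marks the kernels and biases of conv layers `1..n` non-trainable and
#' everything else (remaining conv layers, merged projection, dense and
#' classifier layers) trainable — the transfer-learning recipe where the
#' general early features are kept fixed.
#'
#' @param model An `fmc_model`.
#' @param n Number of leading conv layers to freeze, in `0..5`.
#' @return The model with its `trainable` mask set.
#' @export
apply_freeze <- function(model, n = 3L) {
  stopifnot(inherits(model, "fmc_model"))
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n > 5)
    stop("freeze count must be in 0..5")
  nm <- names(model$param_shapes)
  tr <- stats::setNames(rep(TRUE, length(nm)), nm)
  if (n >= 1) {
    frozen <- paste0("conv", seq_len(n))
    tr[sub("\\.(W|b)$", "", nm) %in% frozen] <- FALSE
  }
  model$trainable <- tr
  model
}

#' Initialize a model from a weights file
#'
#' Loads parameters from a checkpoint written by [save_checkpoint()] wherever
#' names and shapes match; remaining parameters come from the scaled-Gaussian
#' scheme.  When a skip connection has widened a conv layer's input channel
#' count relative to the checkpoint (e.g. conv5 in the FMC wiring), the
#' checkpoint kernels are copied into the leading input-channel slice and the
#' extra slice is scheme-initialized, preserving the transferred features.
#'
#' @param model An `fmc_model` (weights need not be initialized).
#' @param weights_file Optional path to a checkpoint; `NULL` means pure
#'   scheme initialization.
#' @param seed Seed for the scheme-initialized remainder.
#' @return The initialized model; `attr(model, "init_report")` is a
#'   `data.frame` (param, status) with status one of `matched`,
#'   `sliced`, `unmatched`.
#' @export
load_initial_weights <- function(model, weights_file = NULL, seed = 1L) {
  model <- init_model_weights(model, seed = seed)
  report <- data.frame(param = names(model$params),
                       status = "unmatched", stringsAsFactors = FALSE)
  if (is.null(weights_file)) {
    attr(model, "init_report") <- report
    return(model)
  }
  ck <- tryCatch(suppressWarnings(readRDS(weights_file)),
                 error = function(e) stop("cannot read weights file '",
                                          weights_file, "': ", conditionMessage(e)))
  src <- if (!is.null(ck$params)) ck$params else ck
  if (!is.list(src)) stop("weights file does not contain a parameter list")
  matched <- 0L
  for (nm in names(model$params)) {
    sw <- src[[nm]]
    if (is.null(sw)) next
    tgt <- model$params[[nm]]
    if (identical(dim(sw), dim(tgt)) ||
        (is.null(dim(tgt)) && is.null(dim(sw)) && length(sw) == length(tgt))) {
      model$params[[nm]] <- sw
      report$status[report$param == nm] <- "matched"
      matched <- matched + 1L
    } else if (length(dim(sw)) == 4 && length(dim(tgt)) == 4 &&
               all(dim(sw)[c(1, 2, 4)] == dim(tgt)[c(1, 2, 4)]) &&
               dim(sw)[3] < dim(tgt)[3]) {
      ## widened input channels: copy checkpoint into the leading slice
      model$params[[nm]][, , seq_len(dim(sw)[3]), ] <- sw
      report$status[report$param == nm] <- "sliced"
      matched <- matched + 1L
    }
  }
  if (matched == 0L)
    warning("no checkpoint parameter matched the model; using scheme initialization")
  attr(model, "init_report") <- report
  model
}

#' Training configuration
#'
#' @param epochs Number of passes over the training split (default 200).
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate,momentum,weight_decay Momentum-SGD hyperparameters
#'   (defaults 1e-4, 0.95, 1e-6).
#' @param freeze_first_n_conv Leading conv layers to freeze (default 3).
#' @param seed Seed controlling shuffling (and initialization when the
#'   trainer initializes the model itself).
#' @param verbose Print per-epoch progress to stderr.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 32L,
                         learning_rate = 1e-4, momentum = 0.95,
                         weight_decay = 1e-6, freeze_first_n_conv = 3L,
                         seed = 1L, verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1,
            freeze_first_n_conv >= 0, freeze_first_n_conv <= 5)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay,
                 freeze_first_n_conv = as.integer(freeze_first_n_conv),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Train a model
#'
#' Mini-batch training with the bespoke momentum-SGD update and mean binary
#' cross-entropy loss.  The first `freeze_first_n_conv` conv layers are
#' frozen; all randomness (shuffling) flows from `config$seed`, so a fixed
#' seed and config reproduce the run exactly.  The returned model is the
#' epoch checkpoint with the highest validation accuracy (earliest epoch on
#' ties).
#'
#' @param model An initialized `fmc_model`.
#' @param splits A list with elements `train` and `validation`, each a
#'   `list(x = (H,W,C,N) array, y = 0/1 vector)`.
#' @param config A [train_config()].
#' @return `list(model, history)`; `history` is a `data.frame` with columns
#'   `epoch`, `loss`, `train_acc`, `val_acc`.
#' @export
train <- function(model, splits, config = train_config()) {
  stopifnot(inherits(model, "fmc_model"), inherits(config, "train_config"))
  tr <- splits$train; va <- splits$validation
  if (is.null(tr$x) || is.null(tr$y) || length(tr$y) == 0)
    stop("empty training split")
  if (is.null(model$params)) model <- init_model_weights(model, seed = config$seed)
  model <- apply_freeze(model, config$freeze_first_n_conv)
  opt <- optimizer_state(config$learning_rate, config$momentum, config$weight_decay)
  n <- length(tr$y)
  set.seed(config$seed)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     train_acc = numeric(0), val_acc = numeric(0))
  best <- list(acc = -Inf, params = model$params, epoch = 0L)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    at <- 1L
    while (at <= n) {
      hi <- min(n, at + config$batch_size - 1L)
      ix <- ord[at:hi]
      xb <- tr$x[, , , ix, drop = FALSE]
      yb <- tr$y[ix]
      nb <- length(ix)
      fw <- fmc_forward(model, xb, want_acts = TRUE)
      loss_b <- logistic_loss(fw$prob, yb)
      if (!is.finite(loss_b))
        stop(sprintf("training diverged at epoch %d (non-finite loss)", ep))
      ep_loss <- ep_loss + loss_b * nb
      ep_correct <- ep_correct + sum((fw$prob >= 0.5) == (yb == 1))
      ## d loss / d logits for softmax + BCE on the positive-class probability
      dz <- (fw$prob - yb) / nb
      dlogits <- rbind(-dz, dz, deparse.level = 0)
      grads <- fmc_backward(model, fw$acts, dlogits)
      for (nm in names(grads)) {
        st <- momentum_step(opt, model$params[[nm]], grads[[nm]], name = nm)
        opt <- st$state
        model$params[[nm]] <- st$w
      }
      at <- hi + 1L
    }
    val_acc <- NA_real_
    if (!is.null(va$x) && length(va$y) > 0) {
      vp <- predict(model, va$x, batch_size = config$batch_size)
      val_acc <- mean((vp >= 0.5) == (va$y == 1))
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n,
                                   train_acc = ep_correct / n, val_acc = val_acc))
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.4f  train_acc %.3f  val_acc %s",
                      ep, ep_loss / n, ep_correct / n,
                      ifelse(is.na(val_acc), "NA", sprintf("%.3f", val_acc))))
    if (!is.na(val_acc) && val_acc > best$acc)
      best <- list(acc = val_acc, params = model$params, epoch = ep)
  }
  if (is.finite(best$acc)) {
    model$params <- best$params
    attr(model, "best_epoch") <- best$epoch
  }
  list(model = model, history = hist)
}

#' Save / load a model checkpoint
#'
#' The checkpoint container is an RDS file holding the named parameter
#' tensors plus (optionally) the architecture spec, trainability mask,
#' optimizer state, training config and history.
#'
#' @param model An `fmc_model`.
#' @param path Destination file.
#' @param optimizer,config,history Optional state to store alongside.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, optimizer = NULL, config = NULL,
                            history = NULL) {
  saveRDS(list(spec = model$spec, params = model$params,
               trainable = model$trainable, optimizer = optimizer,
               config = config, history = history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ck <- readRDS(path)
  if (is.null(ck$spec) || is.null(ck$params))
    stop("corrupt checkpoint: ", path)
  model <- build_architecture(ck$spec)
  model$params <- ck$params
  model$trainable <- ck$trainable
  attr(model, "history") <- ck$history
  model
}

#' Checksums of parameter tensors
#'
#' MD5 checksums of each parameter's serialized values — used to verify that
#' frozen layers are bit-identical before and after training.
#'
#' @param model An initialized `fmc_model`.
#' @param params Optional subset of parameter names.
#' @return Named character vector of checksums.
#' @export
param_checksums <- function(model, params = NULL) {
  nm <- if (is.null(params)) names(model$params) else params
  vapply(nm, function(p) {
    tf <- tempfile()
    on.exit(unlink(tf), add = TRUE)
    writeBin(serialize(as.vector(model$params[[p]]), NULL), tf)
    unname(tools::md5sum(tf))
  }, character(1))
}
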