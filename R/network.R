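## Forward and backward passes through the model graph.  The graph is small
## and fixed up to the wiring table, so both passes are written out
## explicitly; gradients for tensors consumed by several layers (e.g. conv3
## in the FMC wiring) are accumulated.

fc_forward <- function(x, W, b) {
  ## x: (d_in, N); W: (d_in, d_out); returns (d_out, N)
  crossprod(W, x) + b
}

#' Forward pass
#'
#' Runs a batch of input tensors through the model and returns class logits
#' and positive-class probabilities.  Identical weights and input always give
#' identical outputs.
#'
#' @param model An initialized `fmc_model`.
#' @param x Input batch, (H, W, C, N) array (a single (H, W, C) image is
#'   promoted to a batch of one).
#' @param want_acts If `TRUE`, all intermediate activations are returned
#'   (needed for backpropagation and class-activation maps).
#' @return A list with `logits` (n_classes x N), `prob` (length-N vector of
#'   positive-class probabilities) and, if requested, `acts`.
#' @export
fmc_forward <- function(model, x, want_acts = FALSE) {
  stopifnot(inherits(model, "fmc_model"))
  if (is.null(model$params)) stop("model has no weights; call init_model_weights()")
  x <- as_batch(x)
  spec <- model$spec
  d <- dim(x)
  if (d[1] != spec$input_size || d[2] != spec$input_size || d[3] != spec$n_channels)
    stop(sprintf("input is %dx%dx%d, model expects %dx%dx%d", d[1], d[2], d[3],
                 spec$input_size, spec$input_size, spec$n_channels))
  P <- model$params
  g <- spec$conv_geom
  a <- list(input = x)

  a$conv1 <- relu(conv2d(x, P$conv1.W, P$conv1.b, g[[1]]$stride, g[[1]]$pad))
  a$lrn1 <- lrn(a$conv1, spec$lrn)
  pl1 <- maxpool(a$lrn1, spec$pool$size, spec$pool$stride)
  a$pool1 <- pl1$out; a$pool1_idx <- pl1$idx
  a$conv2 <- relu(conv2d(a$pool1, P$conv2.W, P$conv2.b, g[[2]]$stride, g[[2]]$pad))
  a$lrn2 <- lrn(a$conv2, spec$lrn)
  pl2 <- maxpool(a$lrn2, spec$pool$size, spec$pool$stride)
  a$pool2 <- pl2$out; a$pool2_idx <- pl2$idx
  a$conv3 <- relu(conv2d(a$pool2, P$conv3.W, P$conv3.b, g[[3]]$stride, g[[3]]$pad))
  a$conv4 <- relu(conv2d(a$conv3, P$conv4.W, P$conv4.b, g[[4]]$stride, g[[4]]$pad))
  conv5_in <- if (length(model$wiring$conv5_in) == 1) a[[model$wiring$conv5_in]]
              else concat_merge(a[model$wiring$conv5_in])
  a$conv5_in <- conv5_in
  a$conv5 <- relu(conv2d(conv5_in, P$conv5.W, P$conv5.b, g[[5]]$stride, g[[5]]$pad))

  N <- d[4]
  if (spec$variant == "base") {
    pl5 <- maxpool(a$conv5, spec$pool$size, spec$pool$stride)
    a$pool5 <- pl5$out; a$pool5_idx <- pl5$idx
    flat <- a$pool5
    dim(flat) <- c(prod(dim(a$pool5)[1:3]), N)
    a$flat <- flat
    a$fc1 <- relu(fc_forward(flat, P$fc1.W, P$fc1.b))
  } else {
    a$ftotal <- concat_merge(a[model$wiring$merge_in])
    a$fpool <- lp_reduce(a$ftotal, spec$reduction_p)   # (C_total, N)
    a$merged <- relu(fc_forward(a$fpool, P$merge.W, P$merge.b))
    a$fc1 <- relu(fc_forward(a$merged, P$fc1.W, P$fc1.b))
  }
  a$fc2 <- relu(fc_forward(a$fc1, P$fc2.W, P$fc2.b))
  logits <- fc_forward(a$fc2, P$cls.W, P$cls.b)        # (n_classes, N)
  ## probability of the positive class (class index 2)
  z <- logits[2, ] - logits[1, ]
  prob <- 1 / (1 + exp(-z))
  out <- list(logits = logits, prob = as.numeric(prob))
  if (want_acts) out$acts <- a
  out
}

## split a channel-concatenated gradient back onto its source tensors
.split_concat_grad <- function(dg, sources, out_ch, grads) {
  at <- 0L
  for (srcnm in sources) {
    ci <- out_ch[[srcnm]]
    block <- dg[, , (at + 1L):(at + ci), , drop = FALSE]
    grads[[srcnm]] <- if (is.null(grads[[srcnm]])) block else grads[[srcnm]] + block
    at <- at + ci
  }
  grads
}

## Backward pass.  dlogits: (n_classes, N).  Returns gradients for every
## trainable parameter.  Propagation below conv3 is skipped when conv1-3 are
## all frozen (their weight gradients are never needed in that case).
fmc_backward <- function(model, acts, dlogits) {
  spec <- model$spec
  P <- model$params
  tr <- model$trainable
  if (is.null(tr)) tr <- stats::setNames(rep(TRUE, length(P)), names(P))
  g <- spec$conv_geom
  G <- list()

  ## classifier and dense stack
  dfc2 <- (P$cls.W %*% dlogits) * (acts$fc2 > 0)
  if (tr[["cls.W"]]) { G$cls.W <- acts$fc2 %*% t(dlogits); G$cls.b <- rowSums(dlogits) }
  dfc1 <- (P$fc2.W %*% dfc2) * (acts$fc1 > 0)
  if (tr[["fc2.W"]]) { G$fc2.W <- acts$fc1 %*% t(dfc2); G$fc2.b <- rowSums(dfc2) }

  tgrad <- list()   # gradients wrt named activation tensors
  if (spec$variant == "base") {
    dflat <- P$fc1.W %*% dfc1
    if (tr[["fc1.W"]]) { G$fc1.W <- acts$flat %*% t(dfc1); G$fc1.b <- rowSums(dfc1) }
    dpool5 <- dflat
    dim(dpool5) <- dim(acts$pool5)
    dconv5 <- maxpool_backward_cpp(dpool5, acts$pool5_idx, dim(acts$conv5))
    tgrad$conv5 <- dconv5
  } else {
    dmerged <- (P$fc1.W %*% dfc1) * (acts$merged > 0)
    if (tr[["fc1.W"]]) { G$fc1.W <- acts$merged %*% t(dfc1); G$fc1.b <- rowSums(dfc1) }
    dfpool <- P$merge.W %*% dmerged
    if (tr[["merge.W"]]) { G$merge.W <- acts$fpool %*% t(dmerged); G$merge.b <- rowSums(dmerged) }
    dftotal <- lp_reduce_backward(dfpool, acts$ftotal, acts$fpool, spec$reduction_p)
    tgrad <- .split_concat_grad(dftotal, model$wiring$merge_in, model$out_ch, tgrad)
  }

  ## conv5
  dpre5 <- tgrad$conv5 * (acts$conv5 > 0)
  need_dx5 <- TRUE   # conv5's input always involves conv3/conv4 activations
  bw5 <- conv2d_backward_cpp(acts$conv5_in, P$conv5.W, dpre5,
                             g[[5]]$stride, g[[5]]$pad, need_dx5, tr[["conv5.W"]])
  if (tr[["conv5.W"]]) { G$conv5.W <- bw5$dw; G$conv5.b <- bw5$db }
  if (length(model$wiring$conv5_in) == 1) {
    src <- model$wiring$conv5_in
    tgrad[[src]] <- if (is.null(tgrad[[src]])) bw5$dx else tgrad[[src]] + bw5$dx
  } else {
    tgrad <- .split_concat_grad(bw5$dx, model$wiring$conv5_in, model$out_ch, tgrad)
  }

  ## conv4 (input conv3)
  dpre4 <- tgrad$conv4 * (acts$conv4 > 0)
  need_dx4 <- tr[["conv3.W"]] || tr[["conv2.W"]] || tr[["conv1.W"]]
  ## conv3's activation gradient is also needed if conv3 feeds skip paths and
  ## conv3 itself is trainable; if everything below is frozen we can stop.
  bw4 <- conv2d_backward_cpp(acts$conv3, P$conv4.W, dpre4,
                             g[[4]]$stride, g[[4]]$pad, need_dx4, tr[["conv4.W"]])
  if (tr[["conv4.W"]]) { G$conv4.W <- bw4$dw; G$conv4.b <- bw4$db }
  if (need_dx4) {
    tgrad$conv3 <- if (is.null(tgrad$conv3)) bw4$dx else tgrad$conv3 + bw4$dx
  }
  if (!need_dx4) return(G)

  ## conv3 (input pool2)
  dpre3 <- tgrad$conv3 * (acts$conv3 > 0)
  need_dx3 <- tr[["conv2.W"]] || tr[["conv1.W"]]
  bw3 <- conv2d_backward_cpp(acts$pool2, P$conv3.W, dpre3,
                             g[[3]]$stride, g[[3]]$pad, need_dx3, tr[["conv3.W"]])
  if (tr[["conv3.W"]]) { G$conv3.W <- bw3$dw; G$conv3.b <- bw3$db }
  if (!need_dx3) return(G)

  ## pool2 <- lrn2 <- conv2 <- pool1 <- lrn1 <- conv1
  dlrn2 <- maxpool_backward_cpp(bw3$dx, acts$pool2_idx, dim(acts$lrn2))
  dconv2 <- lrn_backward(dlrn2, acts$conv2, spec$lrn)
  dpre2 <- dconv2 * (acts$conv2 > 0)
  need_dx2 <- tr[["conv1.W"]]
  bw2 <- conv2d_backward_cpp(acts$pool1, P$conv2.W, dpre2,
                             g[[2]]$stride, g[[2]]$pad, need_dx2, tr[["conv2.W"]])
  if (tr[["conv2.W"]]) { G$conv2.W <- bw2$dw; G$conv2.b <- bw2$db }
  if (!need_dx2) return(G)

  dlrn1 <- maxpool_backward_cpp(bw2$dx, acts$pool1_idx, dim(acts$lrn1))
  dconv1 <- lrn_backward(dlrn1, acts$conv1, spec$lrn)
  dpre1 <- dconv1 * (acts$conv1 > 0)
  bw1 <- conv2d_backward_cpp(acts$input, P$conv1.W, dpre1,
                             g[[1]]$stride, g[[1]]$pad, FALSE, TRUE)
  G$conv1.W <- bw1$dw; G$conv1.b <- bw1$db
  G
}

#' Predict class probabilities
#'
#' @param object An initialized `fmc_model`.
#' @param x Input batch, (H, W, C, N) array.
#' @param batch_size Forward-pass chunk size (memory control).
#' @param ... Unused.
#' @return Numeric vector of positive-class probabilities, length N.
#' @export
predict.fmc_model <- function(object, x, batch_size = 64L, ...) {
  x <- as_batch(x)
  N <- dim(x)[4]
  out <- numeric(N)
  at <- 1L
  while (at <= N) {
    hi <- min(N, at + batch_size - 1L)
    out[at:hi] <- fmc_forward(object, x[, , , at:hi, drop = FALSE])$prob
    at <- hi + 1L
  }
  out
}
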