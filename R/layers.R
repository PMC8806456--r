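## Layer primitives.  Activations are numeric arrays of shape (H, W, C) for a
## single feature map or (H, W, C, N) for a batch; all layer functions accept
## either and preserve the batch dimension.

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || !length(d) %in% c(3L, 4L))
    stop("expected an (H, W, C) or (H, W, C, N) array")
  if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
    attr(x, "was_single") <- TRUE
  }
  x
}

unbatch_like <- function(x, template) {
  if (isTRUE(attr(template, "was_single"))) dim(x) <- dim(x)[1:3]
  attr(x, "was_single") <- NULL
  x
}

#' Local response normalization parameters
#'
#' Hyperparameters of cross-channel local response normalization:
#' `b[i] = a[i] / (k + alpha * sum_j a[j]^2)^beta`, the sum running over the
#' `n`-channel neighbourhood centred on channel `i` and clipped at the tensor
#' edges.  Defaults are the values used throughout the package:
#' `k = 2`, `n = 5`, `alpha = 0.0004`, `beta = 0.75`.
#'
#' @param k Additive offset inside the normalizer, `>= 0`.
#' @param n Neighbourhood size in channels, `>= 1`; the window spans
#'   `floor(n/2)` channels on each side.
#' @param alpha Scale of the squared-activation sum, `> 0`.
#' @param beta Exponent of the normalizer, `> 0`.
#' @return An object of class `lrn_params`.
#' @export
lrn_params <- function(k = 2, n = 5, alpha = 0.0004, beta = 0.75) {
  stopifnot(k >= 0, n >= 1, alpha > 0, beta > 0)
  structure(list(k = k, n = n, alpha = alpha, beta = beta),
            class = "lrn_params")
}

## windowed channel sum of a (H*W, C, N)-reshaped array
.channel_window_sum <- function(x, half) {
  d <- dim(x)
  C <- d[2]
  out <- array(0, d)
  for (i in seq_len(C)) {
    lo <- max(1L, i - half)
    hi <- min(C, i + half)
    out[, i, ] <- x[, lo, ]
    if (hi > lo) for (j in (lo + 1L):hi) out[, i, ] <- out[, i, ] + x[, j, ]
  }
  out
}

#' Local response normalization
#'
#' Normalizes each activation by the summed squares of activations at the
#' same spatial position in neighbouring channels.  The output has the shape
#' of the input.
#'
#' @param a Feature map, an (H, W, C) or (H, W, C, N) array with finite
#'   entries.
#' @param params An [lrn_params()] object.
#' @return The normalized array, same shape as `a`.
#' @examples
#' a <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
#' b <- lrn(a)
#' stopifnot(identical(dim(a), dim(b)))
#' @export
lrn <- function(a, params = lrn_params()) {
  if (!all(is.finite(a))) stop("lrn: input contains non-finite values")
  x <- as_batch(a)
  d <- dim(x)
  half <- params$n %/% 2L
  xr <- x
  dim(xr) <- c(d[1] * d[2], d[3], d[4])
  s <- params$k + params$alpha * .channel_window_sum(xr^2, half)
  br <- xr / s^params$beta
  out <- br
  dim(out) <- d
  unbatch_like(out, x)
}

## gradient of lrn wrt its input; a is the forward input (batched)
lrn_backward <- function(db, a, params) {
  d <- dim(a)
  half <- params$n %/% 2L
  ar <- a; dim(ar) <- c(d[1] * d[2], d[3], d[4])
  dbr <- db; dim(dbr) <- c(d[1] * d[2], d[3], d[4])
  s <- params$k + params$alpha * .channel_window_sum(ar^2, half)
  t1 <- dbr * s^(-params$beta)
  t2 <- .channel_window_sum(dbr * ar * s^(-params$beta - 1), half)
  da <- t1 - 2 * params$alpha * params$beta * ar * t2
  dim(da) <- d
  da
}

#' Concatenate feature maps along the channel axis
#'
#' Merges an ordered list of feature maps sharing spatial (and batch)
#' dimensions into one map whose channel count is the sum of the inputs'.
#' Channel blocks appear in input order, so slicing the output recovers each
#' input exactly.
#'
#' @param features A non-empty list of (H, W, C) or (H, W, C, N) arrays with
#'   identical H, W (and N).
#' @return The concatenated array.
#' @examples
#' f1 <- array(1, c(4, 4, 3)); f2 <- array(2, c(4, 4, 5))
#' dim(concat_merge(list(f1, f2)))  # 4 4 8
#' @export
concat_merge <- function(features) {
  stopifnot(is.list(features), length(features) >= 1)
  xs <- lapply(features, as_batch)
  dims <- lapply(xs, dim)
  sp <- dims[[1]][c(1, 2, 4)]
  for (i in seq_along(dims)) {
    if (!identical(dims[[i]][c(1, 2, 4)], sp))
      stop(sprintf("concat_merge: input %d has spatial/batch dims (%s), expected (%s)",
                   i, paste(dims[[i]][c(1, 2, 4)], collapse = "x"),
                   paste(sp, collapse = "x")))
  }
  ctot <- sum(vapply(dims, `[`, integer(1), 3))
  out <- array(0, c(sp[1], sp[2], ctot, sp[3]))
  at <- 0L
  for (i in seq_along(xs)) {
    ci <- dims[[i]][3]
    out[, , (at + 1L):(at + ci), ] <- xs[[i]]
    at <- at + ci
  }
  if (isTRUE(attr(xs[[1]], "was_single"))) dim(out) <- dim(out)[1:3]
  out
}

#' Lp reduction of a feature map to a channel vector
#'
#' Collapses the spatial dimensions of a feature map into one value per
#' channel via a generalized Lp aggregation,
#' `out[c] = (sum_xy |F[x, y, c]|^p)^(1/p)`.  `p = 1` gives the per-channel
#' sum of activation magnitudes; large `p` approaches the per-channel
#' maximum.  Absolute values keep the root real for non-even `p`; on the
#' non-negative post-ReLU maps this reduction is applied to, they are a
#' no-op.
#'
#' @param f Feature map, (H, W, C) array (or (H, W, C, N); then a (C, N)
#'   matrix is returned).
#' @param p Aggregation exponent, `>= 1`.
#' @return Numeric vector of length C (or a C x N matrix for batched input).
#' @examples
#' f <- array(runif(3 * 3 * 2), c(3, 3, 2))
#' lp_reduce(f, p = 1)  # per-channel sums
#' @export
lp_reduce <- function(f, p = 2) {
  if (!is.numeric(p) || length(p) != 1 || !is.finite(p) || p < 1)
    stop("lp_reduce: p must be a single number >= 1")
  x <- as_batch(f)
  d <- dim(x)
  xr <- abs(x)^p
  dim(xr) <- c(d[1] * d[2], d[3] * d[4])
  out <- colSums(xr)^(1 / p)
  if (isTRUE(attr(x, "was_single"))) out else matrix(out, d[3], d[4])
}

## gradient of lp_reduce wrt f; dout is (C, N), f the batched forward input,
## out the forward output (C, N)
lp_reduce_backward <- function(dout, f, out, p) {
  d <- dim(f)
  scale <- dout * ifelse(out > 0, out^(1 - p), 0)   # (C, N)
  sc <- array(rep(as.vector(scale), each = d[1] * d[2]), d)
  sign(f) * abs(f)^(p - 1) * sc
}

relu <- function(x) { x[x < 0] <- 0; x }

conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  conv2d_forward_cpp(x, w, b, as.integer(stride), as.integer(pad))
}

maxpool <- function(x, size, stride) {
  maxpool_forward_cpp(x, as.integer(size), as.integer(stride))
}
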