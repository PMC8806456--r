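## Architecture family: a five-conv AlexNet-style backbone plus a set of
## skip-wiring variants that route conv3/conv4/conv5 outputs forward into a
## merged layer.  Every variant keeps the backbone's depth (5 conv layers)
## and per-layer widths; only the wiring differs.

VARIANTS <- c("base", "A", "B", "C", "D", "E", "FMC")

## per-profile convolution / pooling geometry
.profile_geometry <- function(profile, input_size) {
  if (profile == "full") {
    list(
      input_size = if (is.null(input_size)) 227L else as.integer(input_size),
      conv_widths = c(96L, 256L, 384L, 384L, 256L),
      conv_geom = list(
        list(kernel = 11L, stride = 4L, pad = 0L),
        list(kernel = 5L,  stride = 1L, pad = 2L),
        list(kernel = 3L,  stride = 1L, pad = 1L),
        list(kernel = 3L,  stride = 1L, pad = 1L),
        list(kernel = 3L,  stride = 1L, pad = 1L)),
      pool = list(size = 3L, stride = 2L),
      dense_widths = c(4096L, 4096L),
      merged_width = 1024L
    )
  } else {
    list(
      input_size = if (is.null(input_size)) 64L else as.integer(input_size),
      conv_widths = c(16L, 32L, 48L, 48L, 32L),
      conv_geom = list(
        list(kernel = 7L, stride = 2L, pad = 3L),
        list(kernel = 5L, stride = 1L, pad = 2L),
        list(kernel = 3L, stride = 1L, pad = 1L),
        list(kernel = 3L, stride = 1L, pad = 1L),
        list(kernel = 3L, stride = 1L, pad = 1L)),
      pool = list(size = 2L, stride = 2L),
      dense_widths = c(64L, 64L),
      merged_width = 128L
    )
  }
}

#' Declare a backbone + wiring variant
#'
#' An `architecture_spec` fully describes one member of the architecture
#' family: the backbone geometry (a `full` AlexNet-scale profile with conv
#' widths 96/256/384/384/256, or a CPU-scale `tiny` profile with widths
#' 16/32/48/48/32), the skip-wiring variant, and the merged-layer
#' hyperparameters.
#'
#' Variants differ only in wiring; all have exactly five convolutional
#' layers of identical widths:
#' \describe{
#'   \item{base}{plain sequential backbone, no merged layer.}
#'   \item{A}{conv5 additionally receives conv3's output
#'     (input = concat(conv4, conv3)); merged layer fed by conv5 alone.}
#'   \item{B}{merged layer fed by concat(conv5, conv3).}
#'   \item{C}{merged layer fed by concat(conv4, conv5).}
#'   \item{D}{as C (see the methods vignette for why the extra conv4 input
#'     collapses onto C's wiring).}
#'   \item{E}{merged layer fed by concat(conv3, conv4, conv5).}
#'   \item{FMC}{conv5 input = concat(conv3, conv4); merged layer fed by
#'     concat(conv3, conv4, conv5) — the full multi-connection pattern.}
#' }
#'
#' @param variant One of `"base"`, `"A"`–`"E"`, `"FMC"`.
#' @param profile `"full"` (input 227, AlexNet widths) or `"tiny"`
#'   (input 64, reduced widths; meant for CPU-scale work and tests).
#' @param input_size Optional square input size in pixels (profile default
#'   otherwise).
#' @param merged_width Width D of the merged layer's linear projection
#'   (default 1024 full / 128 tiny).
#' @param reduction_p Exponent of the Lp spatial reduction feeding the
#'   merged projection, `>= 1` (default 2).
#' @param conv_widths,dense_widths Optional overrides of the per-layer
#'   channel counts (length 5) and dense widths (length 2).
#' @param n_channels Input channels (default 3: grayscale replicated).
#' @param n_classes Number of classes (2).
#' @param lrn An [lrn_params()] object; LRN follows conv1 and conv2.
#' @return An object of class `architecture_spec`.
#' @examples
#' spec <- architecture_spec("FMC", profile = "tiny")
#' spec$merged_width
#' @export
architecture_spec <- function(variant = "FMC",
                              profile = c("full", "tiny"),
                              input_size = NULL,
                              merged_width = NULL,
                              reduction_p = 2,
                              conv_widths = NULL,
                              dense_widths = NULL,
                              n_channels = 3L,
                              n_classes = 2L,
                              lrn = lrn_params()) {
  variant <- match.arg(variant, VARIANTS)
  profile <- match.arg(profile)
  geom <- .profile_geometry(profile, input_size)
  if (!is.null(conv_widths)) {
    stopifnot(length(conv_widths) == 5, all(conv_widths >= 1))
    geom$conv_widths <- as.integer(conv_widths)
  }
  if (!is.null(dense_widths)) {
    stopifnot(length(dense_widths) == 2, all(dense_widths >= 1))
    geom$dense_widths <- as.integer(dense_widths)
  }
  if (!is.null(merged_width)) {
    if (merged_width < 1) stop("merged_width must be >= 1")
    geom$merged_width <- as.integer(merged_width)
  }
  if (!is.numeric(reduction_p) || reduction_p < 1)
    stop("reduction_p must be >= 1")
  structure(list(
    variant = variant, profile = profile,
    input_size = geom$input_size, n_channels = as.integer(n_channels),
    conv_widths = geom$conv_widths, conv_geom = geom$conv_geom,
    pool = geom$pool, dense_widths = geom$dense_widths,
    merged_width = geom$merged_width, reduction_p = reduction_p,
    n_classes = as.integer(n_classes), lrn = lrn
  ), class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("architecture_spec: variant %s, profile %s, input %dx%dx%d\n",
              x$variant, x$profile, x$input_size, x$input_size, x$n_channels))
  cat(sprintf("  conv widths %s; merged width %d (p = %g); dense %s\n",
              paste(x$conv_widths, collapse = "/"), x$merged_width,
              x$reduction_p, paste(x$dense_widths, collapse = "/")))
  invisible(x)
}

## wiring table: sources of conv5's input and of the merged layer's input
.wiring <- function(variant) {
  switch(variant,
    base = list(conv5_in = "conv4", merge_in = NULL),
    A    = list(conv5_in = c("conv4", "conv3"), merge_in = "conv5"),
    B    = list(conv5_in = "conv4", merge_in = c("conv5", "conv3")),
    C    = list(conv5_in = "conv4", merge_in = c("conv4", "conv5")),
    D    = list(conv5_in = "conv4", merge_in = c("conv4", "conv5")),
    E    = list(conv5_in = "conv4", merge_in = c("conv3", "conv4", "conv5")),
    FMC  = list(conv5_in = c("conv3", "conv4"), merge_in = c("conv3", "conv4", "conv5")),
    stop("unknown variant: ", variant))
}

.conv_out_size <- function(s, g) (s + 2L * g$pad - g$kernel) %/% g$stride + 1L
.pool_out_size <- function(s, p) (s - p$size) %/% p$stride + 1L

#' Build a model graph from an architecture spec
#'
#' Instantiates the layer graph for the given spec: computes spatial sizes
#' and input channel counts through the wiring table, verifies that all
#' merged feature maps share spatial dimensions (skip connections never
#' resample), and optionally initializes weights.
#'
#' @param spec An [architecture_spec()].
#' @param seed If non-`NULL`, weights are initialized (scaled-Gaussian He
#'   scheme) deterministically from this seed; otherwise the graph is
#'   structural only and [init_model_weights()] must be called before a
#'   forward pass.
#' @return An object of class `fmc_model`: the spec, a layer table, the
#'   wiring, parameter shapes, and (if seeded) the parameter store.
#' @examples
#' m <- build_architecture(architecture_spec("FMC", profile = "tiny"), seed = 1)
#' summarize_depth_width(m)
#' @export
build_architecture <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "architecture_spec"))
  wire <- .wiring(spec$variant)
  s <- spec$input_size
  sizes <- integer(5)
  ## conv1 -> lrn -> pool, conv2 -> lrn -> pool, conv3, conv4, conv5
  s1 <- .conv_out_size(s, spec$conv_geom[[1]]);  p1 <- .pool_out_size(s1, spec$pool)
  s2 <- .conv_out_size(p1, spec$conv_geom[[2]]); p2 <- .pool_out_size(s2, spec$pool)
  s3 <- .conv_out_size(p2, spec$conv_geom[[3]])
  s4 <- .conv_out_size(s3, spec$conv_geom[[4]])
  s5 <- .conv_out_size(s4, spec$conv_geom[[5]])
  sizes <- c(s1, s2, s3, s4, s5)
  if (any(sizes < 1)) stop("input size too small for the convolution geometry")

  conv_spatial <- c(conv1 = s1, conv2 = s2, conv3 = s3, conv4 = s4, conv5 = s5)
  w <- spec$conv_widths
  out_ch <- c(conv1 = w[1], conv2 = w[2], conv3 = w[3], conv4 = w[4], conv5 = w[5])
  conv_in <- c(conv1 = spec$n_channels, conv2 = w[1], conv3 = w[2], conv4 = w[3],
               conv5 = sum(out_ch[wire$conv5_in]))
  ## skip edges are only legal between maps of equal spatial size
  if (length(wire$conv5_in) > 1) {
    sp <- conv_spatial[wire$conv5_in]
    if (length(unique(sp)) != 1)
      stop(sprintf("conv5 skip inputs have unequal spatial sizes: %s",
                   paste(sprintf("%s=%d", names(sp), sp), collapse = ", ")))
  }
  merge_channels <- NA_integer_
  if (!is.null(wire$merge_in)) {
    sp <- conv_spatial[wire$merge_in]
    if (length(unique(sp)) != 1)
      stop(sprintf("merged-layer inputs have unequal spatial sizes: %s",
                   paste(sprintf("%s=%d", names(sp), sp), collapse = ", ")))
    merge_channels <- sum(out_ch[wire$merge_in])
  }

  param_shapes <- list()
  for (i in 1:5) {
    g <- spec$conv_geom[[i]]
    nm <- paste0("conv", i)
    param_shapes[[paste0(nm, ".W")]] <-
      c(g$kernel, g$kernel, unname(conv_in[nm]), unname(out_ch[nm]))
    param_shapes[[paste0(nm, ".b")]] <- unname(out_ch[nm])
  }
  if (spec$variant == "base") {
    p5 <- .pool_out_size(s5, spec$pool)
    flat <- p5 * p5 * w[5]
    param_shapes[["fc1.W"]] <- c(flat, spec$dense_widths[1])
  } else {
    param_shapes[["merge.W"]] <- c(merge_channels, spec$merged_width)
    param_shapes[["merge.b"]] <- spec$merged_width
    param_shapes[["fc1.W"]] <- c(spec$merged_width, spec$dense_widths[1])
  }
  param_shapes[["fc1.b"]] <- spec$dense_widths[1]
  param_shapes[["fc2.W"]] <- c(spec$dense_widths[1], spec$dense_widths[2])
  param_shapes[["fc2.b"]] <- spec$dense_widths[2]
  param_shapes[["cls.W"]] <- c(spec$dense_widths[2], spec$n_classes)
  param_shapes[["cls.b"]] <- spec$n_classes

  ## skip edges beyond the sequential chain, for structural summaries
  seq_conv5 <- "conv4"
  skip_edges <- character(0)
  extra5 <- setdiff(wire$conv5_in, seq_conv5)
  if (length(extra5)) skip_edges <- c(skip_edges, paste0(extra5, "->conv5"))
  if (!is.null(wire$merge_in))
    skip_edges <- c(skip_edges, paste0(wire$merge_in, "->merged"))

  model <- structure(list(
    spec = spec, wiring = wire,
    conv_spatial = conv_spatial, conv_in = conv_in, out_ch = out_ch,
    pool_spatial = c(pool1 = p1, pool2 = p2,
                     pool5 = if (spec$variant == "base") .pool_out_size(s5, spec$pool) else NA_integer_),
    merge_channels = merge_channels,
    skip_edges = skip_edges,
    param_shapes = param_shapes,
    params = NULL,
    trainable = NULL
  ), class = "fmc_model")
  if (!is.null(seed)) model <- init_model_weights(model, seed = seed)
  model
}

#' Initialize model weights
#'
#' Fills the parameter store with the scaled-Gaussian scheme
#' (sd = sqrt(2 / fan_in) for kernels and projection matrices, zero biases),
#' deterministically under `seed`.  The merged projection's effective fan-in
#' includes the spatial extent collapsed by the Lp reduction (whose output
#' scales like sqrt(H*W) times the activation scale for p = 2), keeping the
#' initial logits at unit order instead of deep in saturation.  All
#' parameters start trainable.
#'
#' @param model An `fmc_model` from [build_architecture()].
#' @param seed Integer seed for the initialization stream.
#' @return The model with `params` filled and `trainable` all `TRUE`.
#' @export
init_model_weights <- function(model, seed = 1L) {
  stopifnot(inherits(model, "fmc_model"))
  set.seed(seed)
  params <- list()
  for (nm in names(model$param_shapes)) {
    shp <- model$param_shapes[[nm]]
    if (grepl("\\.b$", nm)) {
      params[[nm]] <- numeric(shp)
    } else {
      fan_in <- prod(shp[-length(shp)])
      if (nm == "merge.W")
        fan_in <- fan_in * unname(model$conv_spatial["conv5"])^2
      params[[nm]] <- array(rnorm(prod(shp), sd = sqrt(2 / fan_in)), shp)
    }
  }
  model$params <- params
  model$trainable <- stats::setNames(rep(TRUE, length(params)), names(params))
  model
}

#' Structural summary of a model graph
#'
#' Reports, per layer, its type and output channel count, plus the number of
#' convolutional layers and skip edges — enough to assert that a wiring
#' variant changes neither the depth nor the width of the backbone.
#'
#' @param model An `fmc_model`.
#' @return A `data.frame` with columns `layer`, `type`, `out_channels`,
#'   `spatial`, and attributes `n_conv_layers` and `n_skip_edges`.
#' @export
summarize_depth_width <- function(model) {
  stopifnot(inherits(model, "fmc_model"))
  spec <- model$spec
  rows <- data.frame(
    layer = c(paste0("conv", 1:5),
              if (spec$variant != "base") "merged" else NULL,
              "fc1", "fc2", "classifier"),
    type = c(rep("conv", 5),
             if (spec$variant != "base") "merged" else NULL,
             "dense", "dense", "classifier"),
    out_channels = c(unname(model$out_ch),
                     if (spec$variant != "base") spec$merged_width else NULL,
                     spec$dense_widths, spec$n_classes),
    spatial = c(unname(model$conv_spatial),
                if (spec$variant != "base") 1L else NULL,
                1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
  attr(rows, "n_conv_layers") <- 5L
  attr(rows, "n_skip_edges") <- length(model$skip_edges)
  attr(rows, "variant") <- spec$variant
  rows
}

#' @export
print.fmc_model <- function(x, ...) {
  cat(sprintf("fmc_model: %s (%s profile), input %dx%dx%d, %s\n",
              x$spec$variant, x$spec$profile, x$spec$input_size,
              x$spec$input_size, x$spec$n_channels,
              if (is.null(x$params)) "uninitialized" else
                sprintf("%d parameter tensors", length(x$params))))
  if (length(x$skip_edges))
    cat("  skip edges:", paste(x$skip_edges, collapse = ", "), "\n")
  invisible(x)
}
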