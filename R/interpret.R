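## Class-activation heat maps: weighted sums of final convolutional feature
## maps, upsampled and blended over the input image.

#' Class activation map
#'
#' `M_c(x, y) = sum_k w[k] * f[ , , k]` — the per-class weighted sum of the
#' feature maps.  The raw (unnormalized) map is returned at the feature
#' maps' spatial resolution.
#'
#' @param feature_maps (H, W, C) array of feature maps.
#' @param class_weights Numeric vector of length C.
#' @return H x W numeric matrix.
#' @examples
#' f <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
#' cam(f, c(1, -1))  # f[,,1] - f[,,2]
#' @export
cam <- function(feature_maps, class_weights) {
  d <- dim(feature_maps)
  if (length(d) != 3) stop("cam expects an (H, W, C) feature map array")
  if (length(class_weights) != d[3])
    stop(sprintf("%d class weights for %d channels", length(class_weights), d[3]))
  m <- matrix(as.vector(feature_maps), d[1] * d[2], d[3])
  matrix(m %*% class_weights, d[1], d[2])
}

#' Effective class weights of the final feature maps
#'
#' Composes the linear path from the Lp-pooled channel vector to the class
#' logit — merged projection, the two dense layers, and the classifier —
#' ignoring the intervening nonlinearities (the standard class-activation
#' assumption).  The result is one weight per channel of the merged feature
#' map, suitable for [cam()].
#'
#' @param model An initialized `fmc_model` with a merged layer (the base
#'   variant has no pooled path and is not supported).
#' @param class_index Class column of the classifier (2 = positive).
#' @return Numeric vector, one weight per merged-map channel.
#' @export
class_weight_vector <- function(model, class_index = 2L) {
  stopifnot(inherits(model, "fmc_model"))
  if (model$spec$variant == "base")
    stop("class_weight_vector requires a merged-layer architecture")
  if (is.null(model$params)) stop("model has no weights")
  P <- model$params
  v <- P$cls.W[, class_index]
  v <- P$fc2.W %*% v
  v <- P$fc1.W %*% v
  as.numeric(P$merge.W %*% v)
}

#' Overlay a heat map on a grayscale image
#'
#' Min-max normalizes the heat map to [0, 1] (a constant map normalizes to
#' all zeros, with a warning), bilinearly upsamples it to the image size,
#' maps it through a jet-like colormap with red at the high end, and
#' alpha-blends it over the grayscale image.
#'
#' @param image H x W grayscale matrix in [0, 1].
#' @param heatmap Numeric matrix (any spatial size).
#' @param alpha Blend weight in [0, 1]; 0 returns the (colorized-grayscale)
#'   image unchanged.
#' @return (H, W, 3) RGB array in [0, 1].
#' @export
overlay <- function(image, heatmap, alpha = 0.45) {
  stopifnot(is.matrix(image), alpha >= 0, alpha <= 1)
  rng <- range(heatmap)
  if (rng[1] == rng[2]) {
    warning("constant heat map normalized to all zeros")
    hm <- matrix(0, nrow(heatmap), ncol(heatmap))
  } else {
    hm <- (heatmap - rng[1]) / (rng[2] - rng[1])
  }
  if (!all(dim(hm) == dim(image)))
    hm <- matrix(as.numeric(EBImage::resize(hm, w = nrow(image), h = ncol(image),
                                            filter = "bilinear")),
                 nrow(image), ncol(image))
  hm <- pmin(pmax(hm, 0), 1)
  ramp <- colorRamp(c("#000080", "#0000ff", "#00ffff", "#ffff00", "#ff0000"))
  cols <- ramp(as.vector(hm)) / 255
  out <- array(0, c(nrow(image), ncol(image), 3))
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * image + alpha * matrix(cols[, ch], nrow(image))
  pmin(pmax(out, 0), 1)
}

#' Heat map for one input image
#'
#' Runs the forward pass, takes the merged concatenated feature map (or the
#' conv5 block of it), and weights it by the composed class weights.
#'
#' @param model An initialized merged-layer `fmc_model`.
#' @param x Preprocessed input tensor (H, W, C) or (H, W, C, 1).
#' @param class_index Class of interest (2 = positive).
#' @param source `"merged"` (default; all transmitted feature maps) or
#'   `"conv5"` (the final convolutional layer only).
#' @return Raw heat map matrix at feature-map resolution.
#' @export
heatmap_for_input <- function(model, x, class_index = 2L,
                              source = c("merged", "conv5")) {
  source <- match.arg(source)
  fw <- fmc_forward(model, x, want_acts = TRUE)
  ft <- fw$acts$ftotal
  if (is.null(ft)) stop("model has no merged layer")
  d <- dim(ft)
  fmaps <- array(ft, d[1:3])
  wts <- class_weight_vector(model, class_index)
  if (source == "conv5") {
    merge_in <- model$wiring$merge_in
    offs <- cumsum(c(0, model$out_ch[merge_in]))
    k <- which(merge_in == "conv5")
    sel <- (offs[k] + 1):offs[k + 1]
    fmaps <- fmaps[, , sel, drop = FALSE]
    wts <- wts[sel]
  }
  cam(fmaps, wts)
}

#' Original / heat map / superimposed triptych
#'
#' Produces the three-panel visualization for one image: the original
#' grayscale patch, the colorized heat map, and the alpha-blended overlay,
#' side by side in one RGB array of equal-size panels.
#'
#' @param model An initialized merged-layer `fmc_model`.
#' @param image Raw grayscale image matrix in [0, 1].
#' @param stats Dataset standardization statistics for [preprocess()].
#' @param alpha Blend weight for the overlay panel.
#' @param class_index Class of interest.
#' @param path Optional PNG output path.
#' @return (H, 3W, 3) RGB array, invisibly if written to `path`.
#' @export
heatmap_triptych <- function(model, image, stats = NULL, alpha = 0.45,
                             class_index = 2L, path = NULL) {
  x <- preprocess(image, target_size = model$spec$input_size,
                  n_channels = model$spec$n_channels, stats = stats)
  hm <- heatmap_for_input(model, x, class_index)
  disp <- if (!all(dim(image) == rep(model$spec$input_size, 2)))
    matrix(as.numeric(EBImage::resize(image, w = model$spec$input_size,
                                      h = model$spec$input_size,
                                      filter = "bilinear")),
           model$spec$input_size, model$spec$input_size) else image
  left <- array(rep(disp, 3), c(nrow(disp), ncol(disp), 3)) # original only
  mid <- overlay(disp * 0, hm, alpha = 1)                    # pure heat map
  right <- overlay(disp, hm, alpha = alpha)
  S <- nrow(disp)
  out <- array(0, c(S, 3 * S, 3))
  out[, 1:S, ] <- left
  out[, (S + 1):(2 * S), ] <- mid
  out[, (2 * S + 1):(3 * S), ] <- right
  if (!is.null(path)) {
    png::writePNG(out, path)
    return(invisible(out))
  }
  out
}
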