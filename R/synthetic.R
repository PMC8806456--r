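## Synthetic lymph-node-like patches.  Positive (metastatic) and negative
## (benign) classes differ in three radiological criteria: border
## irregularity, internal intensity heterogeneity, and roundness.  The
## generator is a pure function of (config, seed).

## truncated-normal draw via inverse-CDF; consumes the global RNG stream
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd < 0) stop("negative standard deviation in phenotype model")
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  u <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(pmax(stats::qnorm(u, mean, sd), lo), hi)
}

#' Synthetic dataset configuration
#'
#' Defines the statistical model of the generator.  Class-conditional
#' phenotype distributions are truncated normals; the positive-class means
#' are interpolated away from the negative-class means by the `separation`
#' factor, so `separation = 0` makes the two classes identically distributed
#' (no signal) and larger values make the task easier.  Defaults emulate the
#' structure of the motivating clinical dataset: 3,364 patches with 1,646
#' positives, each containing a single node whose diameter exceeds a minimum
#' size threshold.
#'
#' @param n_samples Number of patches.
#' @param positive_fraction Proportion of positives in (0, 1).
#' @param image_size Square patch size in pixels.
#' @param min_diameter_px Minimum node diameter in pixels (the pixel analog
#'   of the clinical 3 mm minimum node size).
#' @param max_diameter_frac Largest node diameter as a fraction of
#'   `image_size`.
#' @param separation Class-separation multiplier (>= 0, default 1).
#' @param irregularity,heterogeneity,roundness Length-2 numeric vectors
#'   `c(negative, positive)` of class means for the three criteria.
#' @param irregularity_sd,heterogeneity_sd,roundness_sd Length-2 vectors of
#'   class standard deviations (must be non-negative).
#' @param node_contrast Mean interior minus background intensity (intensity
#'   units on the [0, 1] scale).
#' @param background_level Background intensity.
#' @param background_noise_sd Additive Gaussian background noise sd.
#' @param seed Integer seed; identical config + seed give a bit-identical
#'   dataset.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 3364L,
                             positive_fraction = 1646 / 3364,
                             image_size = 64L,
                             min_diameter_px = 16,
                             max_diameter_frac = 0.7,
                             separation = 1,
                             irregularity = c(0.03, 0.11),
                             heterogeneity = c(0.05, 0.20),
                             roundness = c(0.75, 0.92),
                             irregularity_sd = c(0.02, 0.04),
                             heterogeneity_sd = c(0.03, 0.06),
                             roundness_sd = c(0.10, 0.05),
                             node_contrast = 0.4,
                             background_level = 0.25,
                             background_noise_sd = 0.05,
                             seed = 1L) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stop("positive_fraction must be in (0, 1)")
  if (min_diameter_px <= 0 || min_diameter_px >= image_size)
    stop("min_diameter_px must be positive and smaller than image_size")
  if (separation < 0) stop("separation must be >= 0")
  for (v in list(irregularity_sd, heterogeneity_sd, roundness_sd))
    if (any(v < 0)) stop("phenotype standard deviations must be >= 0")
  for (v in list(irregularity, heterogeneity, roundness))
    if (length(v) != 2) stop("class means must be length-2 (negative, positive)")
  structure(list(
    n_samples = as.integer(n_samples), positive_fraction = positive_fraction,
    image_size = as.integer(image_size), min_diameter_px = min_diameter_px,
    max_diameter_frac = max_diameter_frac, separation = separation,
    irregularity = irregularity, heterogeneity = heterogeneity,
    roundness = roundness, irregularity_sd = irregularity_sd,
    heterogeneity_sd = heterogeneity_sd, roundness_sd = roundness_sd,
    node_contrast = node_contrast, background_level = background_level,
    background_noise_sd = background_noise_sd, seed = as.integer(seed)
  ), class = "synthetic_config")
}

## class-conditional (mean, sd) after applying the separation factor
.class_moments <- function(config, what, label) {
  mu <- config[[what]]
  sdv <- config[[paste0(what, "_sd")]]
  if (label == 1) {
    list(mean = mu[1] + config$separation * (mu[2] - mu[1]),
         sd = sdv[1] + config$separation * (sdv[2] - sdv[1]))
  } else {
    list(mean = mu[1], sd = sdv[1])
  }
}

#' Draw a node phenotype
#'
#' Samples the three radiological criteria and a node diameter from the
#' class-conditional distributions.  Positives have stochastically higher
#' border irregularity and heterogeneity and roundness nearer 1.  Consumes
#' the global RNG stream, so a fixed seed gives a fixed phenotype.
#'
#' @param config A [synthetic_config()].
#' @param label Class label, 0 (negative) or 1 (positive).
#' @return An object of class `node_phenotype` with fields `label`,
#'   `border_irregularity`, `heterogeneity`, `roundness`, `diameter_px`.
#' @export
sample_phenotype <- function(config, label) {
  stopifnot(inherits(config, "synthetic_config"), label %in% c(0, 1))
  irr <- .class_moments(config, "irregularity", label)
  het <- .class_moments(config, "heterogeneity", label)
  rnd <- .class_moments(config, "roundness", label)
  structure(list(
    label = as.integer(label),
    border_irregularity = rtrunc_norm(1, irr$mean, irr$sd, lo = 0, hi = 0.5),
    heterogeneity = rtrunc_norm(1, het$mean, het$sd, lo = 0, hi = 1),
    roundness = rtrunc_norm(1, rnd$mean, rnd$sd, lo = 0.05, hi = 1),
    diameter_px = runif(1, config$min_diameter_px,
                        config$max_diameter_frac * config$image_size)
  ), class = "node_phenotype")
}

#' Render a node phenotype as a grayscale patch
#'
#' Draws one elliptical node on a flat background: the boundary is an
#' ellipse with axis ratio `roundness` whose radius is perturbed by a sum of
#' low-order sinusoids (`k = 3..8`, random phases) with RMS amplitude
#' `border_irregularity`; the interior intensity is the base level modulated
#' by multiplicative Gaussian speckle smoothed with a small kernel and
#' scaled so its std/mean contrast equals `heterogeneity`; background noise
#' is additive Gaussian.  Intensities are clipped to [0, 1].  Consumes the
#' global RNG stream (phases, speckle, noise, small center jitter).
#'
#' @param phenotype A `node_phenotype`.
#' @param config A [synthetic_config()].
#' @param with_mask If `TRUE`, the binary node mask is attached as
#'   `attr(img, "mask")`.
#' @return `image_size` x `image_size` numeric matrix in [0, 1].
#' @export
render_patch <- function(phenotype, config, with_mask = FALSE) {
  stopifnot(inherits(phenotype, "node_phenotype"),
            inherits(config, "synthetic_config"))
  S <- config$image_size
  if (phenotype$diameter_px >= S)
    stop(sprintf("node diameter (%.1f px) does not fit the %d px image",
                 phenotype$diameter_px, S))
  a <- phenotype$diameter_px / 2          # semi-major axis
  b <- a * phenotype$roundness            # semi-minor axis
  jit <- 0.5 * (S - phenotype$diameter_px) * 0.25
  cx <- (S + 1) / 2 + runif(1, -jit, jit)
  cy <- (S + 1) / 2 + runif(1, -jit, jit)
  phi <- runif(1, 0, pi)                  # orientation

  xs <- matrix(rep(seq_len(S), each = S), S, S)   # column index
  ys <- matrix(rep(seq_len(S), times = S), S, S)  # row index
  xr <- (xs - cx) * cos(phi) + (ys - cy) * sin(phi)
  yr <- -(xs - cx) * sin(phi) + (ys - cy) * cos(phi)
  u <- xr / a
  v <- yr / b
  rho <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)

  ks <- 3:8
  gk <- rnorm(length(ks))
  ph <- runif(length(ks), 0, 2 * pi)
  pert <- 0
  if (phenotype$border_irregularity > 0) {
    scale <- phenotype$border_irregularity / sqrt(sum(gk^2) / 2)
    amp <- scale * gk
    pert <- matrix(0, S, S)
    for (i in seq_along(ks)) pert <- pert + amp[i] * sin(ks[i] * theta + ph[i])
  }
  mask <- rho <= 1 + pert

  img <- matrix(config$background_level, S, S)
  base <- config$background_level + config$node_contrast
  interior <- rep(base, sum(mask))
  speck <- matrix(rnorm(S * S), S, S)     # drawn regardless, for stream stability
  if (phenotype$heterogeneity > 0 && sum(mask) >= 2) {
    sm <- EBImage::gblur(speck, sigma = 1)
    z <- sm[mask]
    if (sd(z) > 0) {
      z <- (z - mean(z)) / sd(z)
      interior <- base * (1 + phenotype$heterogeneity * z)
    }
  }
  img[mask] <- interior
  if (config$background_noise_sd > 0)
    img <- img + matrix(rnorm(S * S, sd = config$background_noise_sd), S, S)
  img <- pmin(pmax(img, 0), 1)
  if (with_mask) attr(img, "mask") <- mask
  img
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes one 8-bit grayscale PNG per sample plus a CSV manifest with header
#' `path,label,border_irregularity,heterogeneity,roundness,diameter_px`.
#' Class counts are exactly `round(n_samples * positive_fraction)` positives
#' and the complement; the whole dataset is a deterministic function of the
#' config (including its seed).
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest `data.frame`, invisibly; its `manifest_path`
#'   attribute holds the CSV location.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  set.seed(config$seed)
  n <- config$n_samples
  n_pos <- round(n * config$positive_fraction)
  labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- sample_phenotype(config, labels[i])
    img <- render_patch(ph, config)
    img <- round(img * 255) / 255          # 8-bit quantization
    fname <- sprintf("sample_%05d.png", i)
    ok <- tryCatch({
      png::writePNG(img, file.path(out_dir, fname)); TRUE
    }, error = function(e) {
      stop("failed to write ", file.path(out_dir, fname), ": ",
           conditionMessage(e))
    })
    rows[[i]] <- data.frame(
      path = fname, label = labels[i],
      border_irregularity = ph$border_irregularity,
      heterogeneity = ph$heterogeneity,
      roundness = ph$roundness,
      diameter_px = ph$diameter_px,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  attr(manifest, "manifest_path") <- mpath
  invisible(manifest)
}
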