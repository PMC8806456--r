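## Manifest reading, stratified train/validation/test splitting, and
## preprocessing of image patches into network input tensors.

#' Load a CSV manifest of image samples
#'
#' Reads a manifest with at least the columns `path` and `label`; labels
#' must parse as 0/1.  Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path CSV file with header `path,label,...`.
#' @return A `data.frame` of sample records (possibly zero rows).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(df)))
    stop("manifest must have columns 'path' and 'label'")
  if (nrow(df) == 0) return(df)
  lab <- suppressWarnings(as.numeric(df$label))
  bad <- which(is.na(lab) | !(lab %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("manifest row %d has unparseable label '%s' (must be 0 or 1)",
                 bad[1], df$label[bad[1]]))
  df$label <- as.integer(lab)
  base <- dirname(path)
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(base, df$path[rel])
  df
}

#' Split specification
#'
#' @param fractions Length-3 numeric vector `(train, validation, test)`,
#'   each in (0, 1), summing to 1 (within 1e-9).
#' @param seed Integer seed for the split permutation.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3 || any(fractions <= 0) || any(fractions >= 1))
    stop("fractions must be three values in (0, 1)")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1")
  structure(list(fractions = fractions, seed = as.integer(seed)),
            class = "split_spec")
}

## largest-remainder apportionment of n into length(fractions) parts;
## ties broken by position order (train, validation, test)
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    rem <- raw - counts
    give <- order(-rem, seq_along(rem))[seq_len(short)]
    counts[give] <- counts[give] + 1
  }
  as.integer(counts)
}

#' Assign train/validation/test splits
#'
#' Stratified random assignment with exact global counts: the per-split
#' totals equal the largest-remainder rounding of `fractions * n` (ties
#' broken in train, validation, test order), and within each label stratum
#' the allocation is the floor of the proportional share, topped up (in
#' stratum remainder order, subject to the global totals) by at most one —
#' so every record lands in exactly one split and each split's positive
#' count is within one sample of its proportional share.  The permutation
#' within each stratum is determined by `spec$seed`.
#'
#' @param records A `data.frame` with a `label` column (from
#'   [load_manifest()] or [generate_dataset()]).
#' @param spec A [split_spec()].
#' @return `records` with a `split` column (`train`/`validation`/`test`).
#' @examples
#' rec <- data.frame(path = sprintf("s%02d.png", 1:10),
#'                   label = rep(c(0, 1), 5))
#' table(make_splits(rec, split_spec(seed = 7))$split)
#' @export
make_splits <- function(records, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  n <- nrow(records)
  if (n < 3) stop("need at least 3 records to split")
  names_s <- c("train", "validation", "test")
  global <- largest_remainder(n, spec$fractions)
  strata <- sort(unique(records$label))
  ## per-stratum floors, then top-ups by remainder preference under the
  ## global-count constraint (controlled rounding)
  alloc <- matrix(0L, length(strata), 3)
  for (si in seq_along(strata)) {
    ns <- sum(records$label == strata[si])
    alloc[si, ] <- as.integer(floor(ns * spec$fractions))
  }
  left <- global - colSums(alloc)
  for (si in seq_along(strata)) {
    ns <- sum(records$label == strata[si])
    short <- ns - sum(alloc[si, ])
    if (short == 0) next
    rem <- ns * spec$fractions - floor(ns * spec$fractions)
    pref <- order(-rem, seq_along(rem))
    for (j in pref) {
      if (short == 0) break
      if (left[j] > 0) {
        alloc[si, j] <- alloc[si, j] + 1L
        left[j] <- left[j] - 1L
        short <- short - 1L
      }
    }
  }
  set.seed(spec$seed)
  split <- character(n)
  for (si in seq_along(strata)) {
    ix <- which(records$label == strata[si])
    ix <- ix[sample.int(length(ix))]
    split[ix] <- rep(names_s, alloc[si, ])
  }
  records$split <- split
  records
}

#' Preprocess an image into a network input tensor
#'
#' Rescales intensities to [0, 1] (8-bit inputs are divided by 255),
#' bilinearly resizes to `target_size` x `target_size`, standardizes by the
#' supplied dataset mean/sd (or, if none is given, by the image's own
#' statistics), and replicates the result to `n_channels` channels.  A
#' zero-variance image cannot be standardized; it falls back to
#' mean-centering with a warning.
#'
#' @param image 2-D grayscale numeric matrix.
#' @param target_size Output spatial size in pixels.
#' @param n_channels Number of replicated channels (default 3).
#' @param stats Optional `list(mean =, sd =)` dataset statistics (computed
#'   on the training split by [load_split_tensors()]).
#' @return A `(target_size, target_size, n_channels)` array.
#' @export
preprocess <- function(image, target_size = 227L, n_channels = 3L,
                       stats = NULL) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("preprocess expects a 2-D grayscale numeric matrix")
  if (max(image) > 1) image <- image / 255
  if (!all(dim(image) == c(target_size, target_size)))
    image <- EBImage::resize(image, w = target_size, h = target_size,
                             filter = "bilinear")
  image <- matrix(as.numeric(image), target_size, target_size)
  if (is.null(stats)) {
    s <- sd(image)
    if (is.na(s) || s == 0) {
      warning("zero-variance image: standardization fell back to mean-centering")
      image <- image - mean(image)
    } else {
      image <- (image - mean(image)) / s
    }
  } else {
    if (stats$sd == 0) {
      warning("zero-variance dataset statistics: mean-centering only")
      image <- image - stats$mean
    } else {
      image <- (image - stats$mean) / stats$sd
    }
  }
  array(rep(image, n_channels), c(target_size, target_size, n_channels))
}

read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Load split manifests into input tensors
#'
#' Reads every image referenced by a split-assigned manifest, computes the
#' dataset standardization statistics on the training split only (no
#' test-set leakage), and preprocesses all splits with those statistics.
#'
#' @param records Manifest `data.frame` with `path`, `label`, `split`.
#' @param target_size,n_channels Passed to [preprocess()].
#' @return A list with `train`, `validation`, `test` (each
#'   `list(x = (H,W,C,N) array, y = integer labels)`) and `stats`.
#' @export
load_split_tensors <- function(records, target_size = 64L, n_channels = 3L) {
  stopifnot(all(c("path", "label", "split") %in% names(records)))
  imgs <- lapply(records$path, read_gray_png)
  tr_ix <- which(records$split == "train")
  if (!length(tr_ix)) stop("no training records")
  trv <- unlist(lapply(imgs[tr_ix], as.numeric))
  stats <- list(mean = mean(trv), sd = sd(trv))
  out <- list(stats = stats)
  for (sp in c("train", "validation", "test")) {
    ix <- which(records$split == sp)
    if (!length(ix)) { out[[sp]] <- list(x = NULL, y = integer(0)); next }
    x <- array(0, c(target_size, target_size, n_channels, length(ix)))
    for (j in seq_along(ix))
      x[, , , j] <- preprocess(imgs[[ix[j]]], target_size, n_channels, stats)
    out[[sp]] <- list(x = x, y = records$label[ix])
  }
  out
}
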