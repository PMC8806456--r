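# Shared fixtures.  Everything is generated in code at test time; expensive
# artifacts (a trained tiny model) are memoized for the session.

.fixture_env <- new.env(parent = emptyenv())

# a micro architecture for fast engine tests: 32 px input, narrow layers
micro_spec <- function(variant = "FMC", merged_width = 6L) {
  architecture_spec(variant, profile = "tiny", input_size = 32,
                    conv_widths = c(2, 3, 4, 4, 3), dense_widths = c(5, 4),
                    merged_width = merged_width)
}

# synthetic dataset written to a temp dir, split, loaded as tensors
make_synth_tensors <- function(n = 60, separation = 1.5, seed = 1,
                               image_size = 32, target_size = 32,
                               min_diameter_px = 8) {
  dir <- tempfile("synth")
  cfg <- synthetic_config(n_samples = n, positive_fraction = 0.5,
                          separation = separation, seed = seed,
                          image_size = image_size,
                          min_diameter_px = min_diameter_px)
  man <- generate_dataset(cfg, dir)
  rec <- make_splits(man, split_spec(seed = seed))
  rec$path <- file.path(dir, rec$path)
  tens <- load_split_tensors(rec, target_size = target_size)
  tens$records <- rec
  tens$dir <- dir
  tens
}

# one end-to-end run of the study protocol: 400 patches, 80/10/10 split,
# tiny-profile FMC trained from scratch
run_e2e <- function(seed, separation = 1.5, epochs = 15, n = 400) {
  tens <- make_synth_tensors(n = n, separation = separation, seed = seed,
                             image_size = 64, target_size = 64,
                             min_diameter_px = 16)
  model <- build_architecture(architecture_spec("FMC", profile = "tiny"),
                              seed = seed)
  tc <- train_config(epochs = epochs, batch_size = 32, learning_rate = 0.01,
                     momentum = 0.95, weight_decay = 1e-6,
                     freeze_first_n_conv = 0, seed = seed)
  fit <- train(model, tens, tc)
  rep_ <- evaluate_model(fit$model, tens$test$x, tens$test$y)
  list(model = fit$model, history = fit$history, report = rep_, tensors = tens)
}

# memoized high-separation trained run (seed 1), shared across test files
cached_highsep_run <- function() {
  if (is.null(.fixture_env$highsep)) .fixture_env$highsep <- run_e2e(seed = 1)
  .fixture_env$highsep
}

# triple-loop oracle for local response normalization
lrn_loop_oracle <- function(a, params) {
  d <- dim(a)
  half <- params$n %/% 2
  out <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (i in seq_len(d[3])) {
    lo <- max(1, i - half)
    hi <- min(d[3], i + half)
    s <- 0
    for (j in lo:hi) s <- s + a[x, y, j]^2
    out[x, y, i] <- a[x, y, i] / (params$k + params$alpha * s)^params$beta
  }
  out
}

random_confusion <- function() {
  cc <- confusion(runif(40), sample(c(0, 1), 40, replace = TRUE))
  cc
}
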