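test_that("logistic loss matches hand-computed values", {
  # maximum-entropy prediction costs log(2) per sample
  expect_equal(logistic_loss(rep(0.5, 7), c(1, 0, 1, 1, 0, 0, 1)), log(2))
  # perfect (clipped) predictions cost ~0
  expect_lt(logistic_loss(c(1, 0, 1), c(1, 0, 1)), 1e-5)
  # two-sample hand evaluation
  expect_equal(logistic_loss(c(0.9, 0.2), c(1, 0)),
               -0.5 * (log(0.9) + log(0.8)))
  # clipping keeps the loss finite at the boundary
  expect_true(is.finite(logistic_loss(c(0, 1), c(1, 0))))
  expect_error(logistic_loss(numeric(0), numeric(0)))
  expect_error(logistic_loss(c(0.5), c(2)), "0/1")
})

test_that("loss is permutation-invariant over the batch", {
  set.seed(6)
  p <- runif(20); y <- sample(c(0, 1), 20, replace = TRUE)
  ord <- sample(20)
  expect_equal(logistic_loss(p, y), logistic_loss(p[ord], y[ord]))
})

test_that("momentum update matches direct substitution", {
  # null update: zero velocity, zero gradient, zero decay
  st <- optimizer_state(learning_rate = 1e-4, momentum = 0.95, weight_decay = 0)
  r <- momentum_step(st, w = 2.5, grad = 0)
  expect_identical(r$w, 2.5)
  # direct substitution: v1 = -(lambda*eps*w0 + eps*g), w1 = w0 + v1
  st <- optimizer_state(learning_rate = 1e-4, momentum = 0.95, weight_decay = 1e-6)
  r <- momentum_step(st, w = 1, grad = 0.5)
  v1 <- -(1e-6 * 1e-4 * 1 + 1e-4 * 0.5)
  expect_equal(r$state$v$w, v1)
  expect_equal(r$w, 1 + v1)
  expect_identical(r$state$iteration, 1L)
  expect_error(momentum_step(st, w = c(1, 2), grad = 1), "elements")
})

test_that("unrolled momentum steps match the hand recurrence", {
  mu <- 0.95; eps <- 1e-4; lam <- 1e-6; g <- 0.3; w <- 2
  st <- optimizer_state(eps, mu, lam)
  v <- 0
  for (k in 1:3) {
    v <- mu * v - lam * eps * w - eps * g
    w <- w + v
    r <- momentum_step(st, if (k == 1) 2 else r$w, g)
    st <- r$state
    expect_identical(r$w, w)   # exact floating-point agreement
    expect_identical(st$v$w, v)
  }
})

test_that("freezing marks exactly the first n conv layers non-trainable", {
  m <- build_architecture(micro_spec("FMC"), seed = 1)
  m3 <- apply_freeze(m, 3)
  frozen <- names(m3$trainable)[!m3$trainable]
  expect_setequal(frozen, c("conv1.W", "conv1.b", "conv2.W", "conv2.b",
                            "conv3.W", "conv3.b"))
  expect_true(all(m3$trainable[c("conv4.W", "conv5.W", "merge.W",
                                 "fc1.W", "fc2.W", "cls.W")]))
  m0 <- apply_freeze(m, 0)
  expect_true(all(m0$trainable))
  expect_error(apply_freeze(m, 6), "0..5")
})

test_that("weight loading honors name matching and the input-slice rule", {
  # deterministic scheme init without a file
  spec <- micro_spec("FMC")
  m1 <- load_initial_weights(build_architecture(spec), seed = 3)
  m2 <- load_initial_weights(build_architecture(spec), seed = 3)
  expect_identical(m1$params, m2$params)
  expect_true(all(attr(m1, "init_report")$status == "unmatched"))

  # partial checkpoint: only conv1 matches
  ck <- tempfile(fileext = ".rds")
  saveRDS(list(params = list(conv1.W = m1$params$conv1.W,
                             conv1.b = m1$params$conv1.b)), ck)
  m3 <- load_initial_weights(build_architecture(spec), weights_file = ck, seed = 9)
  rep_ <- attr(m3, "init_report")
  expect_setequal(rep_$param[rep_$status == "matched"], c("conv1.W", "conv1.b"))
  expect_identical(m3$params$conv1.W, m1$params$conv1.W)

  # widened conv5 input: base checkpoint kernels land in the leading slice
  base_m <- build_architecture(micro_spec("base"), seed = 5)
  ckb <- tempfile(fileext = ".rds")
  save_checkpoint(base_m, ckb)
  fmc_m <- load_initial_weights(build_architecture(micro_spec("FMC")),
                                weights_file = ckb, seed = 11)
  repb <- attr(fmc_m, "init_report")
  expect_identical(repb$status[repb$param == "conv5.W"], "sliced")
  n_base_in <- dim(base_m$params$conv5.W)[3]
  expect_identical(fmc_m$params$conv5.W[, , seq_len(n_base_in), ],
                   base_m$params$conv5.W)
  expect_error(load_initial_weights(build_architecture(spec),
                                    weights_file = tempfile()), "cannot read")
})

test_that("a zero learning rate with zero decay leaves weights untouched", {
  tens <- make_synth_tensors(n = 12, seed = 2)
  m <- build_architecture(micro_spec("FMC"), seed = 2)
  before <- m$params
  tc <- train_config(epochs = 1, batch_size = 4, learning_rate = 0,
                     weight_decay = 0, freeze_first_n_conv = 0, seed = 2)
  fit <- train(m, tens, tc)
  expect_identical(fit$model$params, before)
})

test_that("training history is reproducible under a fixed seed and config", {
  tens <- make_synth_tensors(n = 24, seed = 8)
  tc <- train_config(epochs = 2, batch_size = 8, learning_rate = 0.005,
                     freeze_first_n_conv = 0, seed = 8)
  f1 <- train(build_architecture(micro_spec("FMC"), seed = 8), tens, tc)
  f2 <- train(build_architecture(micro_spec("FMC"), seed = 8), tens, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(nrow(f1$history), 2L)
  expect_identical(names(f1$history), c("epoch", "loss", "train_acc", "val_acc"))
})

test_that("checkpoints round-trip a trained model's predictions", {
  tens <- make_synth_tensors(n = 24, seed = 13)
  tc <- train_config(epochs = 1, batch_size = 8, learning_rate = 0.005,
                     freeze_first_n_conv = 0, seed = 13)
  fit <- train(build_architecture(micro_spec("FMC"), seed = 13), tens, tc)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(fit$model, ck, history = fit$history)
  m2 <- load_checkpoint(ck)
  expect_identical(predict(m2, tens$test$x), predict(fit$model, tens$test$x))
  expect_error(load_checkpoint(tempfile()), "not found")
})
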