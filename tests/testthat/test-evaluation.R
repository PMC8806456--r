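test_that("confusion counts follow the >= threshold convention", {
  cc <- confusion(c(0.9, 0.1), c(1, 0))
  expect_identical(c(cc$TP, cc$TN, cc$FP, cc$FN), c(1L, 1L, 0L, 0L))
  # scores exactly at the threshold are positive calls
  cc2 <- confusion(rep(0.5, 4), c(1, 0, 1, 0))
  expect_identical(cc2$TP + cc2$FP, 4L)
  expect_identical(cc2$TN + cc2$FN, 0L)
  # degenerate single-class labels
  cc3 <- confusion(c(0.2, 0.8), c(1, 1))
  expect_identical(cc3$TN + cc3$FP, 0L)
  expect_error(confusion(numeric(0), numeric(0)))
})

test_that("the metric panel matches its closed forms", {
  cc <- structure(list(TP = 87L, FP = 13L, TN = 87L, FN = 13L),
                  class = "confusion_counts")
  m <- metric_panel(cc)
  expect_equal(m$sensitivity, 0.87)
  expect_equal(m$specificity, 0.87)
  expect_equal(m$ppv, 0.87)
  expect_equal(m$npv, 0.87)
  expect_equal(m$accuracy, 0.87)
  # corner case
  cc2 <- structure(list(TP = 1L, FP = 1L, TN = 0L, FN = 0L),
                   class = "confusion_counts")
  m2 <- metric_panel(cc2)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$specificity, 0)
  # zero denominators are undefined, not zero
  cc3 <- structure(list(TP = 0L, FP = 0L, TN = 5L, FN = 0L),
                   class = "confusion_counts")
  m3 <- metric_panel(cc3)
  expect_true(is.na(m3$sensitivity))
  expect_true(is.na(m3$ppv))
  expect_true(all(c("sensitivity", "ppv") %in% m3$undefined))
})

test_that("panels on random confusion matrices satisfy the closed forms and the weighted-mean identity", {
  set.seed(31)
  for (rep in 1:50) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1)
    tn <- sample(0:50, 1); fn <- sample(0:50, 1)
    if (tp + fp + tn + fn == 0) tp <- 1
    cc <- structure(list(TP = tp, FP = fp, TN = tn, FN = fn),
                    class = "confusion_counts")
    m <- metric_panel(cc)
    if (tp + fn > 0) expect_equal(m$sensitivity, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
    if (tp + fp > 0) expect_equal(m$ppv, tp / (tp + fp))
    if (tn + fn > 0) expect_equal(m$npv, tn / (tn + fn))
    expect_equal(m$accuracy, (tp + tn) / (tp + fp + tn + fn))
    if (tp + fn > 0 && tn + fp > 0) {
      expect_gte(m$accuracy, min(m$sensitivity, m$specificity) - 1e-12)
      expect_lte(m$accuracy, max(m$sensitivity, m$specificity) + 1e-12)
    }
  }
})

test_that("ROC curves are anchored, monotone, and integrate to the rank AUC", {
  # perfectly separated scores
  expect_equal(roc_auc(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0))$auc, 1)
  # random scores with heavy ties: trapezoid equals the rank statistic
  set.seed(32)
  for (rep in 1:10) {
    s <- sample(seq(0, 1, by = 0.1), 60, replace = TRUE)
    y <- sample(c(0, 1), 60, replace = TRUE)
    if (length(unique(y)) < 2) next
    r <- roc_auc(s, y)
    expect_lt(abs(r$auc - auc_rank(s, y)), 1e-10)
    expect_equal(r$curve$fpr[1], 0)
    expect_equal(r$curve$tpr[1], 0)
    expect_equal(r$curve$fpr[nrow(r$curve)], 1)
    expect_equal(r$curve$tpr[nrow(r$curve)], 1)
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
  }
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  s <- round(runif(100), 2)
  y <- sample(c(0, 1), 100, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
  expect_lt(abs(roc_auc(s, y)$auc - ref), 1e-10)
})

test_that("label-permuted scores give chance-level AUC", {
  set.seed(34)
  s <- runif(2000)
  y <- sample(c(0, 1), 2000, replace = TRUE)
  expect_lt(abs(roc_auc(s, y)$auc - 0.5), 0.05)
})

test_that("width search selects the argmax with smallest-width tie-break", {
  oracle <- function(w) c(`32` = 0.7, `64` = 0.9, `128` = 0.9)[as.character(w)]
  res <- width_search(NULL, NULL, NULL, widths = c(32L, 64L, 128L),
                      accuracy_fn = oracle)
  expect_identical(attr(res, "selected"), 64L)
  expect_identical(res$val_accuracy, c(0.7, 0.9, 0.9))
  # the default sweep is the eight powers of two from 32 to 4096
  expect_identical(default_width_candidates(),
                   as.integer(c(32, 64, 128, 256, 512, 1024, 2048, 4096)))
  expect_error(width_search(NULL, NULL, NULL, widths = integer(0)), "candidate")
})

test_that("width search over real trainings is reproducible", {
  tens <- make_synth_tensors(n = 40, seed = 21)
  tc <- train_config(epochs = 1, batch_size = 8, learning_rate = 0.005,
                     freeze_first_n_conv = 0, seed = 21)
  r1 <- width_search(tens, micro_spec("FMC"), tc, widths = c(4L, 8L))
  r2 <- width_search(tens, micro_spec("FMC"), tc, widths = c(4L, 8L))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_true(attr(r1, "selected") %in% c(4L, 8L))
})

test_that("the ablation harness reports one row per variant, deterministically", {
  tens <- make_synth_tensors(n = 40, seed = 22, image_size = 64,
                             target_size = 64, min_diameter_px = 16)
  tc <- train_config(epochs = 1, batch_size = 8, learning_rate = 0.005,
                     freeze_first_n_conv = 0, seed = 22)
  variants <- c("A", "B", "C", "D", "E", "FMC")
  base_spec <- architecture_spec("FMC", profile = "tiny")
  t1 <- run_ablation(tens, tc, variants = variants, base_spec = base_spec)
  expect_identical(nrow(t1), 6L)
  expect_identical(t1$variant, variants)
  expect_identical(names(t1), c("variant", "sensitivity", "specificity",
                                "ppv", "npv", "accuracy", "auc"))
  t2 <- run_ablation(tens, tc, variants = variants, base_spec = base_spec)
  expect_identical(t1, t2)
})
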