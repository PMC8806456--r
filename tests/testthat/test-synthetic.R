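test_that("class-conditional phenotypes separate in the stated direction", {
  cfg <- synthetic_config(separation = 1)
  set.seed(101)
  pos <- replicate(1000, unlist(sample_phenotype(cfg, 1)[
    c("border_irregularity", "heterogeneity", "roundness")]))
  neg <- replicate(1000, unlist(sample_phenotype(cfg, 0)[
    c("border_irregularity", "heterogeneity", "roundness")]))
  expect_gt(mean(pos["border_irregularity", ]), mean(neg["border_irregularity", ]))
  expect_gt(mean(pos["heterogeneity", ]), mean(neg["heterogeneity", ]))
  # positives are rounder (minor/major ratio nearer 1)
  expect_gt(mean(pos["roundness", ]), mean(neg["roundness", ]))
})

test_that("zero separation makes the class distributions identical", {
  cfg0 <- synthetic_config(separation = 0)
  set.seed(7)
  a <- sample_phenotype(cfg0, 1)
  set.seed(7)
  b <- sample_phenotype(cfg0, 0)
  expect_identical(a$border_irregularity, b$border_irregularity)
  expect_identical(a$heterogeneity, b$heterogeneity)
  expect_identical(a$roundness, b$roundness)
  expect_identical(a$diameter_px, b$diameter_px)
})

test_that("phenotype sampling is deterministic and validates its config", {
  cfg <- synthetic_config()
  set.seed(3); p1 <- sample_phenotype(cfg, 1)
  set.seed(3); p2 <- sample_phenotype(cfg, 1)
  expect_identical(p1, p2)
  expect_error(synthetic_config(irregularity_sd = c(-0.1, 0.2)),
               "standard deviations")
  expect_error(synthetic_config(positive_fraction = 1.2))
})

test_that("phenotype invariants hold over many draws", {
  cfg <- synthetic_config(image_size = 48, min_diameter_px = 10)
  set.seed(5)
  for (i in 1:200) {
    ph <- sample_phenotype(cfg, i %% 2)
    expect_gte(ph$diameter_px, cfg$min_diameter_px)
    expect_true(ph$roundness > 0 && ph$roundness <= 1)
    expect_gte(ph$border_irregularity, 0)
    expect_gte(ph$heterogeneity, 0)
  }
})

make_phenotype <- function(label = 1, irr = 0, het = 0, round_ = 1, diam = 20) {
  structure(list(label = label, border_irregularity = irr, heterogeneity = het,
                 roundness = round_, diameter_px = diam),
            class = "node_phenotype")
}

test_that("a zero-perturbation render is a constant-intensity ellipse", {
  cfg <- synthetic_config(image_size = 48, min_diameter_px = 10,
                          background_noise_sd = 0)
  set.seed(9)
  img <- render_patch(make_phenotype(irr = 0, het = 0, round_ = 0.7), cfg,
                      with_mask = TRUE)
  mask <- attr(img, "mask")
  expect_true(sum(mask) > 0)
  expect_equal(length(unique(img[mask])), 1L)
  expect_equal(length(unique(img[!mask])), 1L)
})

test_that("roundness 1 with no irregularity renders a circle", {
  cfg <- synthetic_config(image_size = 64, min_diameter_px = 16,
                          background_noise_sd = 0)
  set.seed(10)
  img <- render_patch(make_phenotype(round_ = 1, diam = 36), cfg, with_mask = TRUE)
  mask <- attr(img, "mask")
  # boundary pixels: inside the mask but touching the outside
  S <- nrow(mask)
  inner <- mask[2:(S - 1), 2:(S - 1)] &
    !(mask[1:(S - 2), 2:(S - 1)] & mask[3:S, 2:(S - 1)] &
      mask[2:(S - 1), 1:(S - 2)] & mask[2:(S - 1), 3:S])
  bd <- which(inner, arr.ind = TRUE) + 1L
  ctr <- colMeans(which(mask, arr.ind = TRUE))
  dist <- sqrt((bd[, 1] - ctr[1])^2 + (bd[, 2] - ctr[2])^2)
  expect_lt(sd(dist) / mean(dist), 0.02)
})

test_that("interior and background means differ by the configured contrast", {
  cfg <- synthetic_config(image_size = 48, min_diameter_px = 10,
                          background_noise_sd = 0, node_contrast = 0.4)
  # heterogeneity small enough that no interior pixel clips at 1
  set.seed(11)
  img <- render_patch(make_phenotype(het = 0.05, diam = 24), cfg, with_mask = TRUE)
  mask <- attr(img, "mask")
  expect_equal(mean(img[mask]) - mean(img[!mask]), 0.4, tolerance = 1e-6)
})

test_that("a node larger than the image is a geometry error", {
  cfg <- synthetic_config(image_size = 32, min_diameter_px = 10)
  expect_error(render_patch(make_phenotype(diam = 40), cfg), "does not fit")
})

test_that("generate_dataset writes exact class counts and a valid manifest", {
  dir <- tempfile("gd")
  cfg <- synthetic_config(n_samples = 100, positive_fraction = 0.5,
                          image_size = 24, min_diameter_px = 6, seed = 4)
  man <- generate_dataset(cfg, dir)
  expect_identical(sum(man$label == 1), 50L)
  expect_identical(sum(man$label == 0), 50L)
  expect_true(all(file.exists(file.path(dir, man$path))))
  got <- read.csv(file.path(dir, "manifest.csv"))
  expect_identical(names(got), c("path", "label", "border_irregularity",
                                 "heterogeneity", "roundness", "diameter_px"))
  unlink(dir, recursive = TRUE)
})

test_that("the emulated clinical cohort has 1646 positives of 3364 samples", {
  dir <- tempfile("gd")
  cfg <- synthetic_config(n_samples = 3364, positive_fraction = 1646 / 3364,
                          image_size = 16, min_diameter_px = 5, seed = 1)
  man <- generate_dataset(cfg, dir)
  expect_identical(sum(man$label == 1), 1646L)
  expect_identical(sum(man$label == 0), 1718L)
  unlink(dir, recursive = TRUE)
})

test_that("dataset generation is a pure function of config and seed", {
  cfg <- synthetic_config(n_samples = 20, positive_fraction = 0.5,
                          image_size = 24, min_diameter_px = 6, seed = 12)
  d1 <- tempfile("gd1"); d2 <- tempfile("gd2")
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  unlink(c(d1, d2), recursive = TRUE)
})
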