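# Unit tests for the loss module: analytic examples computed by hand or by
# the double-loop oracles in helper-oracles.R, plus the structural
# invariants of each loss.

test_that("dice loss matches analytic cases", {
  expect_equal(dice_loss(c(1, 1, 1, 1), c(1, 1, 1, 1)), 0)
  expect_equal(dice_loss(c(1, 1, 1, 1), c(0, 0, 0, 0)), 1,
               tolerance = 1e-6)
  expect_equal(dice_loss(c(1, 0, 1, 0), c(0.8, 0.2, 0.6, 0.4)), 0.3,
               tolerance = 1e-6)
  # empty mask + empty prediction is a perfect score via eps smoothing
  expect_equal(dice_loss(rep(0, 8), rep(0, 8)), 0)
})

test_that("dice loss is symmetric under joint pixel permutation", {
  set.seed(1)
  y <- rbinom(16, 1, 0.5); p <- runif(16)
  for (k in 1:5) {
    o <- sample(16)
    expect_equal(dice_loss(y[o], p[o]), dice_loss(y, p))
  }
})

test_that("entropy minimization matches analytic cases and is maximal at 0.5", {
  expect_equal(entropy_min_loss(rep(1, 6)), 0)
  expect_equal(entropy_min_loss(rep(0, 6)), 0)
  expect_equal(entropy_min_loss(matrix(0.5, 3, 5)), -0.5 * log(0.5),
               tolerance = 1e-9)
  expect_equal(entropy_min_loss(matrix(0.5, 2, 2), entropy = "full_binary"),
               log(2), tolerance = 1e-9)
  set.seed(2)
  for (p in runif(10))
    expect_lte(entropy_min_loss(rep(p, 4), entropy = "full_binary"),
               entropy_min_loss(rep(0.5, 4), entropy = "full_binary"))
})

test_that("segmentation and translated-source losses share the composite form", {
  y <- c(1, 0, 1, 0); p <- c(0.8, 0.2, 0.6, 0.4)
  expect_equal(segmentation_loss(y, p),
               dice_loss(y, p) + entropy_min_loss(p))
  expect_equal(translated_source_loss(y, p), segmentation_loss(y, p))
  # confident perfect prediction scores exactly zero
  expect_equal(segmentation_loss(c(1, 0), c(1, 0)), 0)
  expect_equal(segmentation_loss(rep(0, 4), rep(0, 4)), 0)
})

test_that("adversarial generator loss matches analytic cases and decreases in d", {
  expect_equal(adversarial_generator_loss(rep(1, 4)), 0)
  expect_equal(adversarial_generator_loss(array(0.5, c(2, 2))), log(2),
               tolerance = 1e-9)
  expect_equal(adversarial_generator_loss(c(0.5, 0.25)),
               (log(2) + log(4)) / 2, tolerance = 1e-9)
  d <- seq(0.05, 0.95, by = 0.1)
  vals <- vapply(d, function(v)
    adversarial_generator_loss(rep(v, 3)), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("reconstruction loss matches analytic cases", {
  x <- array(runif(2 * 2 * 3 * 2), c(2, 2, 3, 2))
  expect_equal(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(array(0.75, c(2, 2, 3, 1)),
                                   array(0.25, c(2, 2, 3, 1))), 0.25)
  a <- array(0, c(2, 2, 1, 1)); b <- a; b[1, 1, 1, 1] <- 1
  expect_equal(reconstruction_loss(a, b), 0.25)
})

test_that("discriminator loss matches analytic cases and the shared -log d form", {
  expect_equal(discriminator_loss(rep(1, 4), 1), 0)
  expect_equal(discriminator_loss(rep(0, 4), 0), 0)
  expect_equal(discriminator_loss(array(0.5, c(2, 3)), 1), log(2),
               tolerance = 1e-9)
  set.seed(3)
  d <- array(runif(12, 0.05, 0.95), c(2, 2, 3))
  expect_equal(discriminator_loss(d, 1), adversarial_generator_loss(d))
})

test_that("class centroids match direct means and flag absent classes", {
  cc <- class_centroids(matrix(c(1, 3, 1, 3), 2), c(0, 1))
  expect_equal(cc$centroids[1, ], c(1, 1))
  expect_equal(cc$centroids[2, ], c(3, 3))
  cc <- class_centroids(matrix(c(0, 2, 10, 12), ncol = 1), c(0, 0, 1, 1))
  expect_equal(cc$centroids[, 1], c(1, 11))
  f <- matrix(rnorm(8), ncol = 2)
  cc <- class_centroids(f, rep(1, 4))
  expect_false(cc$present[1])
  expect_true(all(is.na(cc$centroids[1, ])))
  expect_equal(cc$centroids[2, ], colMeans(f))
})

test_that("clustering loss matches the toy value and its structural properties", {
  f <- matrix(c(0, 2, 10, 12), ncol = 1)
  l <- c(0, 0, 1, 1)
  expect_equal(clustering_loss(f, NULL, l, NULL), -9) # tight 1, repel 10
  # identical features, single class: zero
  expect_equal(clustering_loss(matrix(1, 5, 2), NULL, rep(1, 5), NULL), 0)
  # L1 positive homogeneity: scaling features doubles the loss
  expect_equal(clustering_loss(2 * f, NULL, l, NULL),
               2 * clustering_loss(f, NULL, l, NULL))
  # single class present: only the tightening term contributes
  f1 <- matrix(c(0, 4), ncol = 1)
  expect_equal(clustering_loss(f1, NULL, c(1, 1), NULL), 2)
})

test_that("clustering loss responds to tightening and repulsion (finite differences)", {
  f <- matrix(c(0, 2, 10, 12), ncol = 1)
  l <- c(0, 0, 1, 1)
  base <- clustering_loss(f, NULL, l, NULL)
  # tighten class 0 around its (unmoved) centroid: loss decreases
  f2 <- f; f2[1:2, 1] <- c(0.5, 1.5)
  expect_lt(clustering_loss(f2, NULL, l, NULL), base)
  # move class-1 block away from class-0: centroids separate, loss decreases
  f3 <- f; f3[3:4, 1] <- f3[3:4, 1] + 5
  expect_lt(clustering_loss(f3, NULL, l, NULL), base)
})

test_that("clustering loss pools source and target features", {
  fs <- matrix(c(0, 2), ncol = 1)
  ft <- matrix(c(10, 12), ncol = 1)
  expect_equal(clustering_loss(fs, ft, c(0, 0), c(1, 1)), -9)
})

test_that("downsampling predictions yields hard nearest-neighbour classes", {
  p <- array(0, c(4, 4, 1, 1))
  p[1:2, , 1, 1] <- 0.9 # top half foreground
  l <- downsample_preds(p, 2, 2)
  expect_equal(l, c(1L, 0L, 1L, 0L)) # column-major: rows 1,2 per column
  expect_true(all(downsample_preds(array(0.49, c(4, 4, 1, 1)), 2, 2) == 0))
})

test_that("weighted totals reproduce the published operating point", {
  comp <- list(seg = 1, advP = 1, recons = 1, advI = 1, trans = 1, cl = 1)
  expect_equal(total_uda_loss(comp, loss_weights()), 1.015)
  expect_equal(total_uda_loss(comp, loss_weights(0, 0, 0, 0, 0)), 1)
  # linearity: each component enters with exactly its lambda
  w <- loss_weights()
  for (nm in c("advP", "recons", "advI", "trans", "cl")) {
    c2 <- comp; c2[[nm]] <- 0
    expect_equal(total_uda_loss(comp, w) - total_uda_loss(c2, w),
                 w[[nm]], tolerance = 1e-12)
  }
  # absent components contribute zero (ablation)
  expect_equal(total_uda_loss(list(seg = 0.5), w), 0.5)
})

test_that("SSDA total adds the unweighted labeled-target term", {
  comp <- list(seg = 1, advP = 1, recons = 1, advI = 1, trans = 1, cl = 1)
  expect_equal(total_ssda_loss(c(comp, seg_tl = 1)), 2.015)
  expect_equal(total_ssda_loss(c(comp, seg_tl = 0)),
               total_uda_loss(comp))
  expect_warning(v <- total_ssda_loss(comp), "falling back")
  expect_equal(v, total_uda_loss(comp))
})

test_that("losses reject contract violations", {
  expect_error(dice_loss(c(1, 0), c(0.5, 0.5, 0.5)), "shape mismatch")
  expect_error(dice_loss(c(1, 2), c(0.5, 0.5)), "binary")
  expect_error(entropy_min_loss(c(-0.1, 0.5)), "outside")
  expect_error(reconstruction_loss(array(0, c(2, 2, 3, 1)),
                                   array(0, c(2, 2, 1, 1))),
               "shape mismatch")
  expect_error(discriminator_loss(0.5, 2), "single 0 or 1")
  expect_error(loss_weights(advP = -1), "non-negative")
})

test_that("all losses match the double-loop oracles on random tensors", {
  worst <- run_loss_oracle_suite(n_cases = 60, seed = 7)
  expect_lt(worst, 1e-6)
})

test_that("losses stay finite and correctly signed on eps-clamped inputs", {
  set.seed(9)
  for (k in 1:20) {
    h <- sample(2:6, 1); w <- sample(2:6, 1)
    y <- rand_mask_batch(h, w, 1)
    p <- array(runif(h * w, 0, 1), c(h, w, 1, 1)) # includes exact 0/1 region
    d <- array(runif(h * w), c(h, w))
    vals <- c(dice_loss(y, p), entropy_min_loss(p),
              adversarial_generator_loss(d), discriminator_loss(d, 1),
              reconstruction_loss(y, p))
    expect_true(all(is.finite(vals)))
    expect_true(all(vals >= 0))
  }
})
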