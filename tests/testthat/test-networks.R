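# Network contracts (shapes, ranges, determinism) and finite-difference
# validation of the backward passes that power the training loops.

unet_fw <- nucadapt:::unet_forward
unet_bw <- nucadapt:::unet_backward
disc_fw <- nucadapt:::disc_forward
disc_bw <- nucadapt:::disc_backward

test_that("segmentation network satisfies its shape/range/determinism contract", {
  set.seed(1)
  S <- build_segmentation_network(depth = 4, base = 4)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  y1 <- network_forward(S, x)
  expect_equal(dim(y1), c(64L, 64L, 1L, 2L))
  expect_true(all(y1 > 0 & y1 < 1))
  f <- network_features(S, x)
  expect_equal(dim(f)[1:2], c(64L / 2^4, 64L / 2^4))
  expect_identical(y1, network_forward(S, x)) # eval-mode determinism
  expect_error(network_forward(S, array(0.5, c(60, 60, 3, 1))),
               "pad to 64x64")
  expect_error(build_segmentation_network(backbone = "unetpp"),
               "not built in")
})

test_that("reconstruction network maps predictions to images in [0,1]", {
  set.seed(2)
  R <- build_reconstruction_network(depth = 3, base = 4)
  p <- array(runif(32 * 32), c(32, 32, 1, 1))
  img <- network_forward(R, p)
  expect_equal(dim(img), c(32L, 32L, 3L, 1L))
  expect_true(all(img >= 0 & img <= 1))
})

test_that("patch discriminator has a five-layer stride-2 receptive field", {
  set.seed(3)
  DP <- build_discriminator(1, base = 4)
  DI <- build_discriminator(3, base = 4)
  d1 <- network_forward(DP, array(runif(64 * 64), c(64, 64, 1, 2)))
  expect_equal(dim(d1), c(2L, 2L, 1L, 2L)) # 64 / 2^5
  d3 <- network_forward(DI, array(runif(64 * 64 * 3), c(64, 64, 3, 1)))
  expect_equal(dim(d3)[1:2], c(2L, 2L))
  expect_true(all(d1 > 0 & d1 < 1))
  expect_error(build_discriminator(2), "must be 1 .* or 3")
})

test_that("U-Net backward matches finite differences", {
  set.seed(4)
  S <- build_segmentation_network(in_channels = 2, depth = 2, base = 3)
  x <- array(runif(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  fw <- unet_fw(S, x)
  gout <- array(rnorm(length(fw$out)), dim(fw$out))
  gfeat <- array(rnorm(length(fw$features)), dim(fw$features))
  bk <- unet_bw(S, fw$cache, gout, gfeat)
  loss_of <- function(net) {
    f <- unet_fw(net, x)
    sum(f$out * gout) + sum(f$features * gfeat)
  }
  for (nm in c("enc1_c1_w", "enc2_c2_b", "bot_c1_w", "dec2_c1_w",
               "dec1_c2_b", "head_w")) {
    i <- sample(length(S$params[[nm]]), 1)
    up <- S; up$params[[nm]][i] <- up$params[[nm]][i] + 1e-6
    dn <- S; dn$params[[nm]][i] <- dn$params[[nm]][i] - 1e-6
    num <- (loss_of(up) - loss_of(dn)) / 2e-6
    expect_equal(bk$grads[[nm]][i], num, tolerance = 1e-4,
                 label = paste("grad", nm))
  }
  # input gradient (needed when S's output feeds a frozen discriminator)
  i <- sample(length(x), 3)
  for (k in i) {
    up <- x; up[k] <- up[k] + 1e-6
    dn <- x; dn[k] <- dn[k] - 1e-6
    xl <- function(z) { f <- unet_fw(S, z)
      sum(f$out * gout) + sum(f$features * gfeat) }
    expect_equal(bk$gx[k], (xl(up) - xl(dn)) / 2e-6, tolerance = 1e-4)
  }
})

test_that("discriminator backward matches finite differences", {
  set.seed(5)
  D <- build_discriminator(1, base = 3)
  x <- array(runif(32 * 32), c(32, 32, 1, 2))
  fw <- disc_fw(D, x)
  gout <- array(rnorm(length(fw$out)), dim(fw$out))
  bk <- disc_bw(D, fw$cache, gout)
  loss_of <- function(net) sum(disc_fw(net, x)$out * gout)
  for (nm in c("d1_w", "d3_b", "d5_w")) {
    i <- sample(length(D$params[[nm]]), 1)
    up <- D; up$params[[nm]][i] <- up$params[[nm]][i] + 1e-6
    dn <- D; dn$params[[nm]][i] <- dn$params[[nm]][i] - 1e-6
    expect_equal(bk$grads[[nm]][i], (loss_of(up) - loss_of(dn)) / 2e-6,
                 tolerance = 1e-4, label = paste("grad", nm))
  }
  k <- sample(length(x), 2)
  for (i in k) {
    up <- x; up[i] <- up[i] + 1e-6
    dn <- x; dn[i] <- dn[i] - 1e-6
    expect_equal(bk$gx[i],
                 (sum(disc_fw(D, up)$out * gout) -
                    sum(disc_fw(D, dn)$out * gout)) / 2e-6,
                 tolerance = 1e-4)
  }
})

test_that("gradient flows from the reconstruction into the segmentation net", {
  set.seed(6)
  S <- build_segmentation_network(depth = 2, base = 3)
  R <- build_reconstruction_network(depth = 2, base = 3)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3, 1))
  fs <- unet_fw(S, x)
  fr <- unet_fw(R, fs$out)
  grec <- nucadapt:::reconstruction_loss_grad(x, fr$out)
  g_pt <- unet_bw(R, fr$cache, grec)$gx # autoencoder chain into S's output
  gS <- unet_bw(S, fs$cache, g_pt)$grads
  expect_gt(max(abs(gS$enc1_c1_w)), 0)
  # finite-difference check of the composed path on one S parameter
  i <- which.max(abs(gS$head_w))
  comp_loss <- function(net) {
    ps <- unet_fw(net, x)$out
    reconstruction_loss(x, unet_fw(R, ps)$out)
  }
  up <- S; up$params$head_w[i] <- up$params$head_w[i] + 1e-6
  dn <- S; dn$params$head_w[i] <- dn$params$head_w[i] - 1e-6
  expect_equal(gS$head_w[i], (comp_loss(up) - comp_loss(dn)) / 2e-6,
               tolerance = 1e-4)
})

test_that("translation preserves shape and range", {
  set.seed(7)
  S <- build_segmentation_network(depth = 2, base = 3)
  R <- build_reconstruction_network(depth = 2, base = 3)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  xst <- translate_source_to_target(S, R, x)
  expect_equal(dim(xst), dim(x))
  expect_true(all(xst >= 0 & xst <= 1))
})

test_that("parameter counts and summaries are consistent", {
  set.seed(8)
  S <- build_segmentation_network(depth = 2, base = 4)
  expect_identical(count_parameters(S),
                   sum(vapply(S$params, length, integer(1))))
  sm <- summary(S)
  expect_length(sm, length(S$params) + 1)
  expect_output(print(S), "unet network")
})

test_that("checkpoints round-trip all networks and optimizer state", {
  set.seed(9)
  st <- init_train_state(tiny_config())
  path <- tempfile(fileext = ".rds")
  save_checkpoint(st, path)
  st2 <- load_checkpoint(path)
  expect_identical(st2$nets$S$params, st$nets$S$params)
  expect_identical(st2$opt$DP, st$opt$DP)
})
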