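# Training-loop contracts: loss-record keys, determinism, supervised
# reduction, SSDA behaviour and the fit() bookkeeping.

make_batches <- function(bench, n = 4) {
  list(s = list(images = bench$source$train$images[, , , 1:n, drop = FALSE],
                masks = bench$source$train$masks[, , , 1:n, drop = FALSE]),
       t = bench$target$train$images[, , , 1:n, drop = FALSE],
       tl = list(images = bench$target$train$images[, , , 5:(4 + n),
                                                    drop = FALSE],
                 masks = bench$target$train$masks[, , , 5:(4 + n),
                                                  drop = FALSE]))
}

bench <- tiny_benchmark()
batches <- make_batches(bench)

test_that("UDA step returns the full finite loss record and updates all nets", {
  st <- init_train_state(tiny_config())
  out <- uda_train_step(st, batches$s, batches$t)
  expect_setequal(names(out$losses),
                  c("seg", "advP", "recons", "advI", "trans", "cl",
                    "disP", "disI"))
  expect_true(all(vapply(out$losses, is.finite, logical(1))))
  for (nm in c("S", "R", "DP", "DI"))
    expect_false(identical(out$state$nets[[nm]]$params,
                           st$nets[[nm]]$params))
})

test_that("UDA step is bitwise deterministic given state and batches", {
  st <- init_train_state(tiny_config())
  out1 <- uda_train_step(st, batches$s, batches$t)
  out2 <- uda_train_step(st, batches$s, batches$t)
  expect_identical(out1$losses, out2$losses)
  expect_identical(out1$state$nets$S$params, out2$state$nets$S$params)
})

test_that("with all lambdas zero the UDA step reduces to a supervised step", {
  cfg <- tiny_config(weights = loss_weights(0, 0, 0, 0, 0),
                     use_adv_i = FALSE, use_trans = FALSE, use_cl = FALSE)
  st <- init_train_state(cfg)
  out <- uda_train_step(st, batches$s, batches$t)
  expect_identical(names(out$losses), "seg")
  # independent supervised reference: seg gradients + one Adam step
  fw <- nucadapt:::unet_forward(st$nets$S, batches$s$images)
  g <- nucadapt:::segmentation_loss_grad(
    nucadapt:::as_map(batches$s$masks), fw$out, cfg$entropy)
  grads <- nucadapt:::unet_backward(st$nets$S, fw$cache, g)$grads
  up <- nucadapt:::adam_step(st$nets$S$params, grads, st$opt$S, cfg$lr_seg)
  expect_equal(out$state$nets$S$params, up$params, tolerance = 1e-12)
  # discriminators and R untouched
  expect_identical(out$state$nets$DP$params, st$nets$DP$params)
  expect_identical(out$state$nets$R$params, st$nets$R$params)
})

test_that("SSDA step adds seg_tl and reduces to UDA without labeled data", {
  st <- init_train_state(tiny_config())
  out_uda <- uda_train_step(st, batches$s, batches$t)
  out_empty <- ssda_train_step(st, batches$s, NULL, batches$t)
  expect_identical(out_empty$losses, out_uda$losses)
  out_ssda <- ssda_train_step(st, batches$s, batches$tl, batches$t)
  expect_setequal(names(out_ssda$losses),
                  c(names(out_uda$losses), "seg_tl"))
  expect_true(is.finite(out_ssda$losses$seg_tl))
  # the labeled-target pass changes the segmentation update
  expect_false(identical(out_ssda$state$nets$S$params,
                         out_uda$state$nets$S$params))
})

test_that("fit produces consistent history and best-checkpoint bookkeeping", {
  cfg <- tiny_config(epochs = 2)
  st <- fit(cfg, bench$source, bench$target)
  expect_equal(nrow(st$history), 2)
  expect_true(all(c("seg", "advP", "recons", "advI", "trans", "cl",
                    "disP", "disI", "val_iou", "epoch") %in%
                    names(st$history)))
  expect_true(all(is.finite(as.matrix(st$history))))
  expect_equal(st$best$iou, max(st$history$val_iou))
  # fixed seed reproducibility end to end
  st2 <- fit(cfg, bench$source, bench$target)
  expect_identical(st$history, st2$history)
})

test_that("ablation switches remove their loss terms from the history", {
  cfg <- tiny_config(epochs = 1, use_adv_i = FALSE)
  st <- fit(cfg, bench$source, bench$target)
  expect_false(any(c("advI", "disI") %in% names(st$history)))
  expect_true("trans" %in% names(st$history))
  cfg <- tiny_config(epochs = 1, use_trans = FALSE, use_cl = FALSE)
  st <- fit(cfg, bench$source, bench$target)
  expect_false(any(c("trans", "cl") %in% names(st$history)))
})

test_that("SSDA fit uses the labeled fraction and logs seg_tl", {
  cfg <- tiny_config(epochs = 1, ssda_labeled_fraction = 0.5)
  st <- fit(cfg, bench$source, bench$target)
  expect_true("seg_tl" %in% names(st$history))
  expect_true(is.finite(st$history$seg_tl))
})

test_that("fit rejects empty datasets and bad configs", {
  empty <- bench$target
  empty$train$images <- empty$train$images[, , , 0, drop = FALSE]
  expect_error(fit(tiny_config(), bench$source, empty), "empty")
  expect_error(train_config(lr_seg = 0), "positive")
  expect_error(train_config(ssda_labeled_fraction = 1.5), "0,1")
})

test_that("training log is reproducible minus timestamps", {
  cfg <- tiny_config(epochs = 1)
  f1 <- tempfile(); f2 <- tempfile()
  fit(cfg, bench$source, bench$target, log_file = f1)
  fit(cfg, bench$source, bench$target, log_file = f2)
  expect_identical(readLines(f1), readLines(f2))
})
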