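# Alternating generator/discriminator optimization of the UDA and SSDA
# objectives. Per step: one Adam update of the generators (segmentation net S
# and reconstruction net R) against the full weighted objective with both
# discriminators frozen, then one update each of the prediction
# discriminator D_P (real = source prediction) and the image discriminator
# D_I (real = original target image, fake = reconstruction). Inputs to a
# frozen network contribute gradients through it; translated images X_{s->t}
# are detached before the L_trans pass, so that pass trains S only.

#' Training configuration
#'
#' Bundles optimizer settings (Adam, DCGAN-style \eqn{\beta_1 = 0.5}),
#' loss weights, network sizes and the semi-supervised labeled fraction.
#' The per-network learning rates default to the published schedule:
#' segmentation 1e-4; reconstruction and both discriminators 1e-3.
#'
#' @param lr_seg,lr_recons,lr_dp,lr_di Adam learning rates.
#' @param weights a [loss_weights()] object.
#' @param epochs training epochs (one pass over the larger domain).
#' @param batch_size images per domain per step.
#' @param seed integer; seeds weight init and batch order.
#' @param ssda_labeled_fraction fraction of target-train images whose labels
#'   may be used (0 = fully unsupervised).
#' @param use_adv_i,use_trans,use_cl ablation switches for the image
#'   adversarial, translated-source and clustering terms.
#' @param entropy entropy-minimization form, see [entropy_min_loss()].
#' @param em_warmup fraction of the epochs during which the
#'   entropy-minimization term is left out of the supervised losses (dice
#'   only). The dice + entropy objective is bistable from a fresh
#'   initialization — depending on batch order it can collapse to a
#'   saturated all-foreground/all-background state — while dice alone has no
#'   such attractor; sharpening is switched on once the network
#'   discriminates. Set 0 to train the printed objective from step one.
#' @param em_gate competence gate for the entropy term: after the warm-up
#'   fraction, the term engages (stickily) only once the previous epoch's
#'   mean dice loss falls below this value, i.e. once the model actually
#'   discriminates. \code{NULL} disables the gate (schedule only).
#' @param trans_warmup fraction of the epochs during which the
#'   translated-source term is skipped (early translations are noise);
#'   default 0, i.e. active from the first epoch.
#' @param cl_normalize compute the clustering loss on L2-normalized feature
#'   vectors (default). The raw loss is positively homogeneous in the
#'   features and its centroid-repulsion term is unbounded below, so on raw
#'   features a scale-free optimizer can drive the encoder's feature norms
#'   to explode; clustering directions on the unit sphere (standard in
#'   feature-clustering domain adaptation) bounds it. \code{FALSE} feeds
#'   raw features, the literal printed form.
#' @param depth,base U-Net depth and base width (kept small for CPU-scale
#'   experiments).
#' @param disc_base first-layer width of the discriminators.
#' @return object of class \code{"train_config"}.
#' @export
train_config <- function(lr_seg = 1e-4, lr_recons = 1e-3, lr_dp = 1e-3,
                         lr_di = 1e-3, weights = loss_weights(),
                         epochs = 10L, batch_size = 4L, seed = 1L,
                         ssda_labeled_fraction = 0,
                         use_adv_i = TRUE, use_trans = TRUE, use_cl = TRUE,
                         entropy = "single", em_warmup = 0.25,
                         em_gate = 0.3,
                         trans_warmup = 0, cl_normalize = TRUE,
                         depth = 3L, base = 8L, disc_base = 16L) {
  lrs <- c(lr_seg, lr_recons, lr_dp, lr_di)
  if (any(lrs <= 0)) stop("learning rates must be positive")
  if (ssda_labeled_fraction < 0 || ssda_labeled_fraction > 1)
    stop("ssda_labeled_fraction must lie in [0,1]")
  if (em_warmup < 0 || em_warmup > 1 || trans_warmup < 0 ||
      trans_warmup > 1)
    stop("warm-up fractions must lie in [0,1]")
  if (!inherits(weights, "loss_weights"))
    weights <- do.call(loss_weights, as.list(weights))
  structure(list(lr_seg = lr_seg, lr_recons = lr_recons, lr_dp = lr_dp,
                 lr_di = lr_di, weights = weights,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 ssda_labeled_fraction = ssda_labeled_fraction,
                 use_adv_i = use_adv_i, use_trans = use_trans,
                 use_cl = use_cl, entropy = entropy,
                 em_warmup = em_warmup, em_gate = em_gate,
                 trans_warmup = trans_warmup,
                 cl_normalize = cl_normalize,
                 depth = as.integer(depth), base = as.integer(base),
                 disc_base = as.integer(disc_base)),
            class = "train_config")
}

#' Initialize a training state
#'
#' Builds the four networks (S, R, D_P, D_I) with seeded weights and fresh
#' Adam states.
#'
#' @param config a [train_config()].
#' @return object of class \code{"train_state"}.
#' @export
init_train_state <- function(config) {
  stopifnot(inherits(config, "train_config"))
  with_seed(config$seed, {
    S <- build_segmentation_network(depth = config$depth, base = config$base)
    R <- build_reconstruction_network(depth = config$depth,
                                      base = config$base)
    DP <- build_discriminator(1L, base = config$disc_base)
    DI <- build_discriminator(3L, base = config$disc_base)
    structure(list(
      nets = list(S = S, R = R, DP = DP, DI = DI),
      opt = list(S = adam_init(S$params), R = adam_init(R$params),
                 DP = adam_init(DP$params), DI = adam_init(DI$params)),
      epoch = 0L, step = 0L, config = config, history = NULL,
      best = NULL), class = "train_state")
  })
}

check_finite_losses <- function(rec) {
  bad <- names(rec)[!vapply(rec, is.finite, logical(1))]
  if (length(bad))
    stop("non-finite training loss in term(s): ",
         paste(bad, collapse = ", "))
  invisible(rec)
}

need_recon <- function(cfg)
  cfg$weights$recons > 0 || (cfg$use_adv_i && cfg$weights$advI > 0)

# Core shared by the UDA and SSDA steps. batch_tl may be NULL.
adapt_train_step <- function(state, batch_s, batch_t, batch_tl = NULL) {
  cfg <- state$config
  w <- cfg$weights
  S <- state$nets$S; R <- state$nets$R
  DP <- state$nets$DP; DI <- state$nets$DI
  xs <- as_batch(batch_s$images, 3L)
  ys <- as_map(batch_s$masks)
  xt <- as_batch(batch_t, 3L)
  rec <- list()

  # entropy/trans warm-up state is set by fit(); standalone steps train the
  # full printed objective
  em_on <- state$em_active %||% TRUE
  trans_on <- state$trans_active %||% TRUE
  sup_loss <- function(y, p) {
    dice_loss(y, p) +
      if (em_on) entropy_min_loss(p, entropy = cfg$entropy) else 0
  }
  sup_grad <- function(y, p) {
    g <- dice_loss_grad(y, p)
    if (em_on) g <- g + entropy_min_loss_grad(p, cfg$entropy)
    g
  }

  ## ---- generator phase (D_P, D_I frozen) ----
  fw_s <- unet_forward(S, xs)
  dice_s <- dice_loss(ys, fw_s$out)
  rec$seg <- dice_s +
    (if (em_on) entropy_min_loss(fw_s$out, entropy = cfg$entropy) else 0)
  g_ps <- sup_grad(ys, fw_s$out)

  do_advP <- w$advP > 0
  do_cl <- cfg$use_cl && w$cl > 0
  # the target pass feeds the adversarial, reconstruction and clustering
  # terms; when all are off (supervised reduction) it is skipped entirely
  need_t <- do_advP || need_recon(cfg) || do_cl
  fw_t <- if (need_t) unet_forward(S, xt)
  g_pt <- if (need_t) array(0, dim(fw_t$out))
  grads_R <- NULL
  if (do_advP) {
    fw_dp <- disc_forward(DP, fw_t$out)
    rec$advP <- adversarial_generator_loss(fw_dp$out)
    gd <- adversarial_generator_loss_grad(fw_dp$out)
    g_pt <- g_pt + w$advP * disc_backward(DP, fw_dp$cache, gd)$gx
  }

  xrt <- NULL
  if (need_recon(cfg)) {
    fw_rt <- unet_forward(R, fw_t$out)
    xrt <- fw_rt$out
    rec$recons <- reconstruction_loss(xt, xrt)
    g_xrt <- w$recons * reconstruction_loss_grad(xt, xrt)
    if (cfg$use_adv_i && w$advI > 0) {
      fw_di <- disc_forward(DI, xrt)
      rec$advI <- adversarial_generator_loss(fw_di$out)
      gd <- adversarial_generator_loss_grad(fw_di$out)
      g_xrt <- g_xrt + w$advI * disc_backward(DI, fw_di$cache, gd)$gx
    }
    bw_r <- unet_backward(R, fw_rt$cache, g_xrt)
    grads_R <- bw_r$grads
    g_pt <- g_pt + bw_r$gx
  }

  # translated-source supervision on detached X_{s->t}
  grads_S_trans <- NULL
  if (cfg$use_trans && w$trans > 0 && trans_on) {
    ps_det <- fw_s$out
    xst <- unet_forward(R, ps_det, keep_cache = FALSE)$out
    fw_st <- unet_forward(S, xst)
    rec$trans <- sup_loss(ys, fw_st$out)
    g_pst <- w$trans * sup_grad(ys, fw_st$out)
    grads_S_trans <- unet_backward(S, fw_st$cache, g_pst)$grads
  }

  # labeled-target supervision (SSDA)
  grads_S_tl <- NULL
  fw_tl <- NULL
  xtl <- NULL; ytl <- NULL
  if (!is.null(batch_tl) && !is.null(batch_tl$images) &&
      batch_size(as_batch(batch_tl$images)) > 0) {
    xtl <- as_batch(batch_tl$images, 3L)
    ytl <- as_map(batch_tl$masks)
    fw_tl <- unet_forward(S, xtl)
    rec$seg_tl <- sup_loss(ytl, fw_tl$out)
    g_ptl <- sup_grad(ytl, fw_tl$out)
  }

  # feature clustering over all available domains
  gfeat_s <- gfeat_t <- gfeat_tl <- NULL
  if (do_cl) {
    fd_s <- dim(fw_s$features); fd_t <- dim(fw_t$features)
    f_s <- flatten_features(fw_s$features)
    f_t <- flatten_features(fw_t$features)
    l_s <- downsample_preds(fw_s$out, fd_s[1], fd_s[2])
    l_t <- downsample_preds(fw_t$out, fd_t[1], fd_t[2])
    f_all <- rbind(f_s, f_t); l_all <- c(l_s, l_t)
    n_s <- nrow(f_s); n_t <- nrow(f_t)
    if (!is.null(fw_tl)) {
      f_tl <- flatten_features(fw_tl$features)
      fd_tl <- dim(fw_tl$features)
      l_tl <- downsample_preds(fw_tl$out, fd_tl[1], fd_tl[2])
      f_all <- rbind(f_all, f_tl); l_all <- c(l_all, l_tl)
    }
    if (cfg$cl_normalize) {
      # cluster directions on the unit sphere; backprop through f/|f|
      r <- sqrt(rowSums(f_all^2)) + 1e-8
      u <- f_all / r
      rec$cl <- cluster_loss_flat(u, l_all)$loss
      g_u <- cluster_loss_grad_flat(u, l_all)
      g_all <- w$cl * (g_u - u * rowSums(u * g_u)) / r
    } else {
      rec$cl <- cluster_loss_flat(f_all, l_all)$loss
      g_all <- w$cl * cluster_loss_grad_flat(f_all, l_all)
    }
    gfeat_s <- unflatten_features(g_all[seq_len(n_s), , drop = FALSE], fd_s)
    gfeat_t <- unflatten_features(g_all[n_s + seq_len(n_t), , drop = FALSE],
                                  fd_t)
    if (!is.null(fw_tl))
      gfeat_tl <- unflatten_features(
        g_all[n_s + n_t + seq_len(nrow(f_all) - n_s - n_t), ,
              drop = FALSE], dim(fw_tl$features))
  }

  grads_S <- unet_backward(S, fw_s$cache, g_ps, gfeat_s)$grads
  if (need_t)
    grads_S <- add_grads(grads_S,
                         unet_backward(S, fw_t$cache, g_pt, gfeat_t)$grads)
  if (!is.null(fw_tl))
    grads_S <- add_grads(grads_S,
                         unet_backward(S, fw_tl$cache, g_ptl,
                                       gfeat_tl)$grads)
  grads_S <- add_grads(grads_S, grads_S_trans)

  up <- adam_step(S$params, grads_S, state$opt$S, cfg$lr_seg)
  S$params <- up$params; state$opt$S <- up$state
  if (!is.null(grads_R)) {
    up <- adam_step(R$params, grads_R, state$opt$R, cfg$lr_recons)
    R$params <- up$params; state$opt$R <- up$state
  }
  state$nets$S <- S; state$nets$R <- R

  ## ---- discriminator phase (generators frozen, detached inputs) ----
  if (do_advP) {
    fw_real <- disc_forward(DP, fw_s$out)
    fw_fake <- disc_forward(DP, fw_t$out)
    rec$disP <- 0.5 * (discriminator_loss(fw_real$out, 1) +
                       discriminator_loss(fw_fake$out, 0))
    g1 <- 0.5 * discriminator_loss_grad(fw_real$out, 1)
    g0 <- 0.5 * discriminator_loss_grad(fw_fake$out, 0)
    gDP <- add_grads(disc_backward(DP, fw_real$cache, g1)$grads,
                     disc_backward(DP, fw_fake$cache, g0)$grads)
    up <- adam_step(DP$params, gDP, state$opt$DP, cfg$lr_dp)
    DP$params <- up$params; state$opt$DP <- up$state
    state$nets$DP <- DP
  }
  if (cfg$use_adv_i && w$advI > 0 && !is.null(xrt)) {
    fw_real <- disc_forward(DI, xt)
    fw_fake <- disc_forward(DI, xrt)
    rec$disI <- 0.5 * (discriminator_loss(fw_real$out, 1) +
                       discriminator_loss(fw_fake$out, 0))
    g1 <- 0.5 * discriminator_loss_grad(fw_real$out, 1)
    g0 <- 0.5 * discriminator_loss_grad(fw_fake$out, 0)
    gDI <- add_grads(disc_backward(DI, fw_real$cache, g1)$grads,
                     disc_backward(DI, fw_fake$cache, g0)$grads)
    up <- adam_step(DI$params, gDI, state$opt$DI, cfg$lr_di)
    DI$params <- up$params; state$opt$DI <- up$state
    state$nets$DI <- DI
  }

  state$step <- state$step + 1L
  check_finite_losses(rec)
  list(state = state, losses = rec, dice = dice_s)
}

#' One unsupervised domain-adaptation training step
#'
#' @param state a [init_train_state()] object.
#' @param batch_s source batch: list with \code{images (H,W,3,N)} and
#'   \code{masks (H,W,1,N)}.
#' @param batch_t target image batch \code{(H,W,3,N)} (no masks).
#' @return list with the updated \code{state} and the \code{losses} record
#'   (keys among \code{seg, advP, recons, advI, trans, cl, disP, disI};
#'   ablated terms are absent).
#' @export
uda_train_step <- function(state, batch_s, batch_t)
  adapt_train_step(state, batch_s, batch_t)

#' One semi-supervised domain-adaptation training step
#'
#' As [uda_train_step()] plus an unweighted supervised segmentation loss on
#' a labeled target batch (\code{seg_tl} in the record); unlabeled-target
#' terms use \code{batch_tu} only, and the clustering loss pools features
#' from all three batches. An empty \code{batch_tl} reduces the step to the
#' UDA step.
#'
#' @inheritParams uda_train_step
#' @param batch_tl labeled target batch (list with images and masks), may be
#'   \code{NULL} or empty.
#' @param batch_tu unlabeled target image batch.
#' @return list with updated \code{state} and \code{losses} record.
#' @export
ssda_train_step <- function(state, batch_s, batch_tl, batch_tu)
  adapt_train_step(state, batch_s, batch_tu, batch_tl = batch_tl)

# cycle a permuted index vector to length len
cycle_idx <- function(idx, len) rep_len(idx, len)

rbind_fill <- function(a, b) {
  if (is.null(a)) return(b)
  cols <- union(names(a), names(b))
  for (m in setdiff(cols, names(a))) a[[m]] <- NA_real_
  for (m in setdiff(cols, names(b))) b[[m]] <- NA_real_
  rbind(a[cols], b[cols])
}

#' Fit the adaptation model on a two-domain benchmark
#'
#' Runs the alternating optimization for \code{config$epochs} epochs (an
#' epoch is one pass over the larger of the two training sets; the smaller
#' one is cycled). With \code{ssda_labeled_fraction > 0}, a seeded subset of
#' target-train images keeps its labels and the semi-supervised objective is
#' used. After each epoch the segmentation network is scored (IoU%) on the
#' target validation split when it carries masks, else on source validation,
#' and the best-scoring weights are retained in \code{state$best}.
#'
#' @param config a [train_config()].
#' @param source_ds,target_ds \code{nucadapt_dataset} objects (see
#'   [make_benchmark()] / [load_dataset()]).
#' @param log_file optional path for a JSON-lines log (one record per step).
#' @param verbose print one line per epoch.
#' @return a \code{train_state} with \code{history} (one row per epoch) and
#'   \code{best} (list: \code{S}, \code{iou}, \code{epoch}).
#' @export
fit <- function(config, source_ds, target_ds, log_file = NULL,
                verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  ns <- batch_size(as_batch(source_ds$train$images))
  nt <- batch_size(as_batch(target_ds$train$images))
  if (ns == 0 || nt == 0) stop("empty training split")
  state <- init_train_state(config)
  bs <- config$batch_size
  frac <- config$ssda_labeled_fraction
  log_con <- if (!is.null(log_file)) file(log_file, open = "wt")
  on.exit(if (!is.null(log_con)) close(log_con))

  with_seed(config$seed + 1L, {
    n_lab <- floor(frac * nt)
    lab_idx <- if (n_lab > 0) sort(sample.int(nt, n_lab)) else integer(0)
    unlab_idx <- setdiff(seq_len(nt), lab_idx)
    # degenerate SSDA splits fall back to using all target images unlabeled
    if (length(unlab_idx) == 0) unlab_idx <- seq_len(nt)
    history <- NULL
    em_engaged <- FALSE
    last_dice <- Inf
    for (ep in seq_len(config$epochs)) {
      if (!em_engaged && ep > floor(config$em_warmup * config$epochs) &&
          (is.null(config$em_gate) || last_dice < config$em_gate))
        em_engaged <- TRUE
      state$em_active <- em_engaged
      state$trans_active <- ep > floor(config$trans_warmup * config$epochs)
      steps <- ceiling(max(ns, length(unlab_idx)) / bs)
      ord_s <- cycle_idx(sample(ns), steps * bs)
      ord_t <- cycle_idx(sample(unlab_idx), steps * bs)
      ord_l <- if (n_lab > 0) cycle_idx(sample(lab_idx), steps * bs)
      ep_rec <- list()
      for (st in seq_len(steps)) {
        ii <- (st - 1) * bs + seq_len(bs)
        batch_s <- list(
          images = source_ds$train$images[, , , ord_s[ii], drop = FALSE],
          masks = source_ds$train$masks[, , , ord_s[ii], drop = FALSE])
        batch_t <- target_ds$train$images[, , , ord_t[ii], drop = FALSE]
        batch_tl <- if (n_lab > 0) {
          jj <- ord_l[ii]
          list(images = target_ds$train$images[, , , jj, drop = FALSE],
               masks = target_ds$train$masks[, , , jj, drop = FALSE])
        }
        out <- adapt_train_step(state, batch_s, batch_t, batch_tl)
        state <- out$state
        ep_rec[[st]] <- c(out$losses, .dice = out$dice)
        if (!is.null(log_con))
          writeLines(jsonlite::toJSON(
            c(list(epoch = ep, step = state$step), out$losses),
            auto_unbox = TRUE, digits = NA), log_con)
      }
      last_dice <- mean(vapply(ep_rec, function(r) r$.dice, numeric(1)))
      keys <- setdiff(unique(unlist(lapply(ep_rec, names))), ".dice")
      means <- vapply(keys, function(k)
        mean(vapply(ep_rec, function(r) r[[k]] %||% NA_real_, numeric(1)),
             na.rm = TRUE), numeric(1))
      val <- if (!is.null(target_ds$val) && !is.null(target_ds$val$masks))
        target_ds$val else source_ds$val
      rep_val <- evaluate_model(state$nets$S, val)
      row <- as.data.frame(as.list(means))
      row$epoch <- ep
      row$val_iou <- unname(rep_val$means["iou_percent"])
      history <- rbind_fill(history, row)
      if (is.null(state$best) || row$val_iou >= state$best$iou)
        state$best <- list(S = state$nets$S, iou = row$val_iou, epoch = ep)
      if (verbose)
        message(sprintf("epoch %d/%d  seg %.4f  val IoU %.2f", ep,
                        config$epochs, means[["seg"]], row$val_iou))
    }
    state$epoch <- config$epochs
    state$history <- history[order(history$epoch), , drop = FALSE]
  })
  state
}
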