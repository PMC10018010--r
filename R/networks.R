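# Network architectures. A network is a plain list: metadata plus a flat
# named list of parameter arrays. Forward passes return the output together
# with a cache of intermediate activations; the matching *_backward()
# consumes the cache and returns parameter gradients (and the gradient with
# respect to the input, needed when losses are chained through a frozen
# network). Everything is deterministic given (weights, input).

unet_channels <- function(depth, base) base * 2^(seq_len(depth) - 1)

#' Build a U-Net segmentation network
#'
#' Encoder-decoder with skip connections: \code{depth} levels of two 3x3
#' convolutions + ReLU followed by 2x2 max pooling, a two-convolution
#' bottleneck (whose activation is the feature map used for feature-space
#' adaptation), nearest-neighbour upsampling with skip concatenation on the
#' way up, and a 1x1 convolution + sigmoid head producing a one-channel
#' nucleus-probability map. One shared instance segments both domains.
#'
#' @param in_channels input channels (3 for RGB images).
#' @param out_channels output channels (1 for a binary probability map).
#' @param depth number of pooling levels; inputs must be divisible by
#'   \code{2^depth}.
#' @param base filters in the first level; doubled at each level. The default
#'   is kept small so CPU training at desk scale is feasible.
#' @param backbone backbone identifier; \code{"unet"} is the supported
#'   backbone (the plug-in slot exists so alternative encoders can be
#'   registered, but none ship with the package).
#' @param head_bias initial bias of the output head. The default -2 starts
#'   predictions near the nucleus-foreground prior (sigmoid(-2) ~ 0.12).
#'   This matters because the dice + entropy-minimization objective has a
#'   degenerate all-foreground local minimum that captures a network whose
#'   initial predictions are uniformly above 1/e; starting below it keeps
#'   the early dynamics healthy (see the methods vignette).
#' @return object of class \code{"nucadapt_network"}.
#' @export
build_segmentation_network <- function(in_channels = 3L, out_channels = 1L,
                                       depth = 4L, base = 16L,
                                       backbone = "unet", head_bias = -2) {
  if (!identical(backbone, "unet"))
    stop(sprintf("backbone '%s' is not built in; only 'unet' ships with ",
                 backbone), "this package")
  ch <- unet_channels(depth, base)
  params <- list()
  add_block <- function(params, nm, cin, cout) {
    cc <- init_conv(3, 3, cin, cout)
    params[[paste0(nm, "_w")]] <- cc$w
    params[[paste0(nm, "_b")]] <- cc$b
    params[[paste0(nm, "_g")]] <- rep(1, cout)  # instance-norm gain
    params[[paste0(nm, "_n")]] <- rep(0, cout)  # instance-norm shift
    params
  }
  prev <- in_channels
  for (i in seq_len(depth)) {
    params <- add_block(params, paste0("enc", i, "_c1"), prev, ch[i])
    params <- add_block(params, paste0("enc", i, "_c2"), ch[i], ch[i])
    prev <- ch[i]
  }
  cb <- base * 2^depth
  params <- add_block(params, "bot_c1", prev, cb)
  params <- add_block(params, "bot_c2", cb, cb)
  above <- cb
  for (i in rev(seq_len(depth))) {
    params <- add_block(params, paste0("dec", i, "_c1"), above + ch[i],
                        ch[i])
    params <- add_block(params, paste0("dec", i, "_c2"), ch[i], ch[i])
    above <- ch[i]
  }
  hd <- init_conv(1, 1, ch[1], out_channels, gain = 1)
  params$head_w <- hd$w; params$head_b <- hd$b + head_bias
  structure(list(type = "unet", in_channels = in_channels,
                 out_channels = out_channels, depth = depth, base = base,
                 backbone = backbone, params = params),
            class = "nucadapt_network")
}

#' Build the reconstruction network
#'
#' A U-Net that maps a one-channel segmentation prediction back to a
#' three-channel image in \code{[0,1]}. Composed with the segmentation
#' network it forms an autoencoder, and applied to source predictions it
#' yields target-translated source images.
#'
#' @inheritParams build_segmentation_network
#' @return object of class \code{"nucadapt_network"}.
#' @export
build_reconstruction_network <- function(in_channels = 1L, out_channels = 3L,
                                         depth = 4L, base = 16L) {
  net <- build_segmentation_network(in_channels, out_channels,
                                    depth = depth, base = base,
                                    head_bias = 0) # mid-range image output
  net$type <- "unet_recon"
  net
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

unet_forward <- function(net, x, keep_cache = TRUE) {
  x <- as_batch(x, net$in_channels)
  d <- dim(x)
  if (d[1] %% 2^net$depth != 0 || d[2] %% 2^net$depth != 0)
    stop(sprintf(paste0("input %dx%d not divisible by 2^depth = %d; pad to ",
                        "%dx%d"), d[1], d[2], 2^net$depth,
                 2^net$depth * ceiling(d[1] / 2^net$depth),
                 2^net$depth * ceiling(d[2] / 2^net$depth)))
  p <- net$params
  cache <- list(x = x, skips = list(), pool_idx = list(), pre = list())
  # one conv + instance-norm + relu unit; cache carries what backward needs
  cir <- function(a, nm) {
    z <- conv2d(a, p[[paste0(nm, "_w")]], p[[paste0(nm, "_b")]], pad = 1L)
    inr <- instnorm_fwd(z, p[[paste0(nm, "_g")]], p[[paste0(nm, "_n")]])
    list(out = relu_fwd(inr$y), cache = list(a = a, zdim = dim(z),
                                             inr = inr))
  }
  a <- x
  for (i in seq_len(net$depth)) {
    b1 <- cir(a, paste0("enc", i, "_c1"))
    b2 <- cir(b1$out, paste0("enc", i, "_c2"))
    pl <- .maxpool2_forward_cpp(b2$out)
    cache$pre[[paste0("enc", i)]] <- list(b1 = b1$cache, b2 = b2$cache)
    cache$skips[[i]] <- b2$out
    cache$pool_idx[[i]] <- pl$idx
    a <- pl$y
  }
  b1 <- cir(a, "bot_c1")
  b2 <- cir(b1$out, "bot_c2")
  feat <- b2$out
  cache$pre$bot <- list(b1 = b1$cache, b2 = b2$cache)
  a <- feat
  for (i in rev(seq_len(net$depth))) {
    u <- .upsample2_forward_cpp(a)
    cat_ <- concat_ch(u, cache$skips[[i]])
    b1 <- cir(cat_, paste0("dec", i, "_c1"))
    b2 <- cir(b1$out, paste0("dec", i, "_c2"))
    cache$pre[[paste0("dec", i)]] <- list(b1 = b1$cache, b2 = b2$cache,
                                          up_ch = dim(u)[3])
    a <- b2$out
  }
  logits <- conv2d(a, p$head_w, p$head_b)
  out <- sigmoid_fwd(logits)
  cache$pre$head <- list(a = a)
  cache$out <- out
  cache$feat <- feat
  list(out = out, features = feat, cache = if (keep_cache) cache else NULL)
}

# gout: gradient wrt the sigmoid output; gfeat: optional extra gradient
# injected at the bottleneck feature map (feature-space clustering loss).
unet_backward <- function(net, cache, gout, gfeat = NULL) {
  p <- net$params
  g <- list()
  # backward through one conv + instance-norm + relu unit
  cir_bwd <- function(ga, nm, cc) {
    gy <- relu_bwd(ga, cc$inr$y)
    inb <- instnorm_bwd(gy, cc$inr, p[[paste0(nm, "_g")]], cc$zdim)
    bw <- conv2d_grad(cc$a, p[[paste0(nm, "_w")]], inb$dx, pad = 1L)
    g[[paste0(nm, "_w")]] <<- bw$gw
    g[[paste0(nm, "_b")]] <<- bw$gb
    g[[paste0(nm, "_g")]] <<- inb$dgamma
    g[[paste0(nm, "_n")]] <<- inb$dbeta
    bw$gx
  }
  gz <- sigmoid_bwd(gout, cache$out)
  bw <- conv2d_grad(cache$pre$head$a, p$head_w, gz)
  g$head_w <- bw$gw; g$head_b <- bw$gb
  ga <- bw$gx
  gskips <- vector("list", net$depth)
  for (i in seq_len(net$depth)) {
    pr <- cache$pre[[paste0("dec", i)]]
    ga1 <- cir_bwd(ga, paste0("dec", i, "_c2"), pr$b2)
    gcat <- cir_bwd(ga1, paste0("dec", i, "_c1"), pr$b1)
    nu <- pr$up_ch
    gu <- gcat[, , seq_len(nu), , drop = FALSE]
    gskips[[i]] <- gcat[, , nu + seq_len(dim(gcat)[3] - nu), ,
                        drop = FALSE]
    ga <- .upsample2_backward_cpp(gu)
  }
  if (!is.null(gfeat)) ga <- ga + gfeat
  pr <- cache$pre$bot
  ga <- cir_bwd(cir_bwd(ga, "bot_c2", pr$b2), "bot_c1", pr$b1)
  for (i in rev(seq_len(net$depth))) {
    pr <- cache$pre[[paste0("enc", i)]]
    gr2 <- .maxpool2_backward_cpp(ga, cache$pool_idx[[i]],
                                  dim(cache$skips[[i]])) + gskips[[i]]
    ga <- cir_bwd(cir_bwd(gr2, paste0("enc", i, "_c2"), pr$b2),
                  paste0("enc", i, "_c1"), pr$b1)
  }
  list(grads = g, gx = ga)
}

#' Build a patch discriminator
#'
#' DCGAN-style classifier with five 4x4 stride-2 convolutions (leaky ReLU
#' slope 0.2 between layers, sigmoid on the last) producing a patch-wise
#' real/fake probability map whose spatial size is the input size divided by
#' \eqn{2^5}. Use one input channel for the prediction discriminator and
#' three for the image discriminator.
#'
#' @param in_channels 1 (prediction maps) or 3 (images).
#' @param base filters in the first layer.
#' @return object of class \code{"nucadapt_network"}.
#' @export
build_discriminator <- function(in_channels, base = 16L) {
  if (!in_channels %in% c(1L, 3L))
    stop("in_channels must be 1 (prediction) or 3 (image) discriminator")
  ch <- c(base, 2L * base, 4L * base, 4L * base, 1L)
  params <- list()
  prev <- in_channels
  for (i in seq_along(ch)) {
    ci <- init_conv(4, 4, prev, ch[i], gain = if (i == 5) 1 else 2)
    params[[paste0("d", i, "_w")]] <- ci$w
    params[[paste0("d", i, "_b")]] <- ci$b
    prev <- ch[i]
  }
  structure(list(type = "disc", in_channels = in_channels, base = base,
                 n_layers = 5L, params = params),
            class = "nucadapt_network")
}

disc_forward <- function(net, x, keep_cache = TRUE) {
  x <- as_batch(x, net$in_channels)
  if (any(dim(x)[1:2] %% 32L != 0))
    stop("discriminator input must be divisible by 2^5 = 32")
  p <- net$params
  cache <- list(pre = vector("list", net$n_layers))
  a <- x
  for (i in seq_len(net$n_layers)) {
    z <- conv2d(a, p[[paste0("d", i, "_w")]], p[[paste0("d", i, "_b")]],
                stride = 2L, pad = 1L)
    cache$pre[[i]] <- list(a = a, z = z)
    a <- if (i < net$n_layers) lrelu_fwd(z) else sigmoid_fwd(z)
  }
  cache$out <- a
  list(out = a, cache = if (keep_cache) cache else NULL)
}

disc_backward <- function(net, cache, gout) {
  p <- net$params
  g <- list()
  ga <- sigmoid_bwd(gout, cache$out)
  for (i in rev(seq_len(net$n_layers))) {
    pr <- cache$pre[[i]]
    gz <- if (i < net$n_layers) lrelu_bwd(ga, pr$z) else ga
    bw <- conv2d_grad(pr$a, p[[paste0("d", i, "_w")]], gz,
                      stride = 2L, pad = 1L)
    g[[paste0("d", i, "_w")]] <- bw$gw
    g[[paste0("d", i, "_b")]] <- bw$gb
    ga <- bw$gx
  }
  list(grads = g, gx = ga)
}

# ---- generic front-ends -----------------------------------------------------

#' Run a network forward
#'
#' @param net a \code{nucadapt_network}.
#' @param x input batch in \code{(H, W, C, N)} layout (2-D/3-D arrays are
#'   promoted).
#' @return output array: probability/image map for U-Nets, patch map for
#'   discriminators.
#' @export
network_forward <- function(net, x) {
  if (net$type == "disc") disc_forward(net, x, keep_cache = FALSE)$out
  else unet_forward(net, x, keep_cache = FALSE)$out
}

#' Deepest encoder feature map of a segmentation network
#'
#' @inheritParams network_forward
#' @return feature array \code{(H/2^depth, W/2^depth, d, N)}.
#' @export
network_features <- function(net, x)
  unet_forward(net, x, keep_cache = FALSE)$features

#' Translate source images toward the target domain
#'
#' Pushes source images through the segmentation network then the
#' reconstruction network, \eqn{X_{s\to t} = R(S(X_s))}. After adversarial
#' training of R against the image discriminator, the result keeps the source
#' nuclei layout but adopts target-domain appearance. The output is a plain
#' array (no gradient bookkeeping): downstream supervision treats it as a
#' fixed input.
#'
#' @param seg_net segmentation network S.
#' @param recon_net reconstruction network R.
#' @param x_s source image batch.
#' @return translated image batch, same shape as \code{x_s}, values in
#'   \code{[0,1]}.
#' @export
translate_source_to_target <- function(seg_net, recon_net, x_s)
  network_forward(recon_net, network_forward(seg_net, x_s))

#' Number of learnable parameters
#' @param net a \code{nucadapt_network}.
#' @return integer count.
#' @export
count_parameters <- function(net)
  sum(vapply(net$params, length, integer(1)))

#' @export
print.nucadapt_network <- function(x, ...) {
  cat(sprintf("<nucadapt %s network> in=%d channels, %s parameters\n",
              x$type, x$in_channels,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Architecture summary
#' @param object a \code{nucadapt_network}.
#' @param ... unused.
#' @return character vector, one line per parameter tensor.
#' @export
summary.nucadapt_network <- function(object, ...) {
  lines <- vapply(names(object$params), function(nm)
    sprintf("%-12s (%s)", nm,
            paste(dim(object$params[[nm]]) %||% length(object$params[[nm]]),
                  collapse = "x")), character(1))
  c(sprintf("%s network, %d parameters", object$type,
            count_parameters(object)), lines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a training checkpoint
#'
#' Single-file serialization of all networks and optimizer states.
#'
#' @param state a training state (see [init_train_state()]) or any list of
#'   networks/optimizers.
#' @param path file path.
#' @return \code{load_checkpoint} returns the restored object.
#' @export
save_checkpoint <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
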