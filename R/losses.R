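# Training losses for adversarial domain-adaptive nuclei segmentation.
#
# All losses operate on arrays in (H, W, C, N) layout (plain vectors and
# 2-D/3-D arrays are promoted, so `dice_loss(c(1,0,1,0), c(.8,.2,.6,.4))`
# works for quick checks). Every loss reduces to a scalar by averaging over
# the batch; per-image reductions follow the printed formulas. Natural
# logarithms throughout.

.EPS <- 1e-7

as_map <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(1L, length(x), 1L, 1L)
  as_batch(x)
}

check_prob <- function(p, what = "probability map") {
  if (any(p < 0 | p > 1))
    stop(sprintf("%s contains values outside [0,1]", what))
  invisible(TRUE)
}

check_mask <- function(y, what = "mask") {
  if (!all(y %in% c(0, 1)))
    stop(sprintf("%s must be binary {0,1}", what))
  invisible(TRUE)
}

#' Dice-coefficient loss
#'
#' Complement of the soft Dice overlap between a binary ground-truth mask and
#' a soft prediction, \eqn{1 - 2 \sum y\hat y / (\sum y + \sum \hat y)},
#' computed per image on the flattened maps and averaged over the batch. A
#' small smoothing constant \code{eps} is added to numerator and denominator
#' so that an empty mask with an empty prediction scores 0 loss.
#'
#' @param y_true binary mask, any of (H,W), (H,W,1), (H,W,1,N) or a vector.
#' @param y_pred soft prediction in \code{[0,1]}, same shape.
#' @param eps smoothing constant.
#' @return scalar loss in \code{[0,1]} (up to \code{eps}).
#' @examples
#' dice_loss(c(1, 0, 1, 0), c(0.8, 0.2, 0.6, 0.4)) # 0.3
#' @export
dice_loss <- function(y_true, y_pred, eps = .EPS) {
  y <- as_map(y_true); p <- as_map(y_pred)
  check_same_shape(y, p, "mask and prediction")
  check_mask(y); check_prob(p)
  n <- batch_size(y)
  per <- vapply(seq_len(n), function(i) {
    yi <- y[, , , i]; pi <- p[, , , i]
    1 - (2 * sum(yi * pi) + eps) / (sum(yi) + sum(pi) + eps)
  }, numeric(1))
  mean(per)
}

#' Entropy-minimization loss
#'
#' Sharpens soft predictions toward confident values:
#' \eqn{-(1/HW)\sum \hat y \log \hat y} per image, batch-averaged, with the
#' convention \eqn{0\log 0 = 0}. The default follows the single-term form;
#' \code{entropy = "full_binary"} adds the complementary
#' \eqn{-(1-\hat y)\log(1-\hat y)} term of the full binary entropy.
#'
#' @param y_pred soft prediction in \code{[0,1]}.
#' @param entropy \code{"single"} (default) or \code{"full_binary"}.
#' @param eps clamp inside the logarithms.
#' @return scalar loss (natural-log units).
#' @examples
#' entropy_min_loss(matrix(0.5, 4, 4)) # -0.5 * log(0.5) ~ 0.3466
#' @export
entropy_min_loss <- function(y_pred, entropy = c("single", "full_binary"),
                             eps = .EPS) {
  entropy <- match.arg(entropy)
  p <- as_map(y_pred)
  check_prob(p, "prediction")
  h <- -p * log(pmax(p, eps))
  if (entropy == "full_binary")
    h <- h - (1 - p) * log(pmax(1 - p, eps))
  mean(h) # images share one size: global mean == batch mean of image means
}

#' Supervised segmentation loss (dice + entropy minimization)
#'
#' The sum \code{dice_loss + entropy_min_loss}, the supervised objective used
#' for labeled source (and, in the semi-supervised setting, labeled target)
#' images.
#'
#' @inheritParams dice_loss
#' @inheritParams entropy_min_loss
#' @return scalar loss.
#' @export
segmentation_loss <- function(y_true, y_pred,
                              entropy = c("single", "full_binary"),
                              eps = .EPS) {
  dice_loss(y_true, y_pred, eps = eps) +
    entropy_min_loss(y_pred, entropy = entropy, eps = eps)
}

#' Target-translated source supervision loss
#'
#' Identical in form to [segmentation_loss()], applied to the prediction of a
#' target-translated source image (the source image pushed through the
#' segmentation network then the reconstruction network) against the original
#' source mask, which remains valid because nuclei masks are domain-invariant.
#'
#' @param y_true_s source-domain binary mask.
#' @param y_pred_trans prediction for the translated image.
#' @inheritParams segmentation_loss
#' @return scalar loss.
#' @export
translated_source_loss <- function(y_true_s, y_pred_trans,
                                   entropy = c("single", "full_binary"),
                                   eps = .EPS) {
  segmentation_loss(y_true_s, y_pred_trans, entropy = entropy, eps = eps)
}

#' Adversarial generator loss
#'
#' \eqn{-\mathrm{mean}(\log D(\cdot))} over all patch cells of a
#' discriminator output map. Used both in output space (prediction
#' discriminator on target predictions) and image space (image discriminator
#' on reconstructed images); the generator minimizes it to fool the
#' discriminator.
#'
#' @param d_out discriminator output map in \code{(0,1)}, any array shape.
#' @param eps clamp inside the logarithm.
#' @return scalar loss \eqn{\ge 0}.
#' @examples
#' adversarial_generator_loss(array(0.5, c(2, 2))) # log(2)
#' @export
adversarial_generator_loss <- function(d_out, eps = .EPS) {
  d <- unlist(d_out, use.names = FALSE)
  check_prob(d, "discriminator output")
  mean(-log(pmax(d, eps)))
}

#' Image reconstruction loss
#'
#' Mean squared error \eqn{(1/HWC)\sum (x - \tilde x)^2} per image, averaged
#' over the batch, between an image and its reconstruction from the
#' segmentation prediction.
#'
#' @param x original image batch in \code{[0,1]}.
#' @param x_recon reconstructed batch, same shape.
#' @return scalar loss \eqn{\ge 0}.
#' @export
reconstruction_loss <- function(x, x_recon) {
  a <- as_map(x); b <- as_map(x_recon)
  check_same_shape(a, b, "image and reconstruction")
  mean((a - b)^2)
}

#' Discriminator cross-entropy loss
#'
#' \eqn{-\mathrm{mean}[z \log d + (1-z)\log(1-d)]} over all patch cells,
#' where the domain label \code{z} is 1 for the "real" class (source-domain
#' prediction for the output-space discriminator; original image for the
#' image discriminator) and 0 for the "fake" class (target prediction /
#' reconstructed image).
#'
#' @param d_out discriminator output map in \code{(0,1)}.
#' @param z domain label, a single 0 or 1.
#' @param eps clamp inside the logarithms.
#' @return scalar loss \eqn{\ge 0}.
#' @export
discriminator_loss <- function(d_out, z, eps = .EPS) {
  if (length(z) != 1L || !(z %in% c(0, 1))) stop("z must be a single 0 or 1")
  d <- unlist(d_out, use.names = FALSE)
  check_prob(d, "discriminator output")
  mean(-(z * log(pmax(d, eps)) + (1 - z) * log(pmax(1 - d, eps))))
}

# ---- feature clustering -----------------------------------------------------

# features: n x d matrix (one row per spatial location); labels: integer 0/1.
flatten_features <- function(features) {
  if (is.matrix(features)) return(features)
  f <- features
  if (is.null(dim(f))) return(matrix(f, ncol = 1L))
  if (length(dim(f)) == 3L) dim(f) <- c(dim(f), 1L)
  stopifnot(length(dim(f)) == 4L)
  d <- dim(f)
  f <- aperm(f, c(1, 2, 4, 3)) # feature channel last -> rows are locations
  dim(f) <- c(d[1] * d[2] * d[4], d[3])
  f
}

#' Per-class feature centroids
#'
#' Mean feature vector of every semantic class (background 0, nucleus 1)
#' present in a batch of encoder features, with hard class assignments taken
#' from a downsampled prediction map.
#'
#' @param features either an \code{n x d} matrix of feature vectors or a 4-D
#'   feature map \code{(Hf, Wf, d, N)}.
#' @param labels hard class per feature vector (0/1), length \code{n} (any
#'   array shape is flattened in the matching order).
#' @return list with \code{centroids} (2 x d matrix, rows = classes 0 and 1;
#'   \code{NA} rows for absent classes), \code{present} (logical 2-vector)
#'   and \code{counts}.
#' @export
class_centroids <- function(features, labels) {
  f <- flatten_features(features)
  l <- as.integer(round(unlist(labels, use.names = FALSE)))
  if (length(l) != nrow(f))
    stop("labels length does not match number of feature vectors")
  if (!all(l %in% c(0L, 1L))) stop("labels must be in {0,1}")
  cen <- matrix(NA_real_, 2L, ncol(f))
  counts <- c(sum(l == 0L), sum(l == 1L))
  for (j in 0:1) if (counts[j + 1] > 0)
    cen[j + 1, ] <- colMeans(f[l == j, , drop = FALSE])
  list(centroids = cen, present = counts > 0, counts = counts)
}

# L1 clustering loss on flat features; also returns pieces for the gradient.
cluster_loss_flat <- function(f, l) {
  cc <- class_centroids(f, l)
  n <- nrow(f)
  tight <- 0
  for (j in 0:1) if (cc$present[j + 1]) {
    fj <- f[l == j, , drop = FALSE]
    tight <- tight + sum(abs(sweep(fj, 2, cc$centroids[j + 1, ])))
  }
  tight <- tight / n
  repel <- if (all(cc$present))
    sum(abs(cc$centroids[1, ] - cc$centroids[2, ])) else 0
  list(loss = tight - repel, tight = tight, repel = repel, centroids = cc)
}

#' Class-conditional feature clustering loss
#'
#' Tightens encoder features of each semantic class around their pooled
#' (source + target) class centroid and pushes the two class centroids apart:
#' \deqn{L = \frac{1}{|F|}\sum_i \|f_i - c_{\hat y_i}\|_1 -
#'       \frac{1}{|C|(|C|-1)}\sum_{j \ne k} \|c_j - c_k\|_1}
#' with \eqn{C = \{0, 1\}}, so the repulsion term is simply
#' \eqn{\|c_0 - c_1\|_1}. Hard classes \eqn{\hat y_i} come from the
#' predictions downsampled (nearest-neighbour on the 0.5-thresholded map) to
#' the feature resolution. If only one class is present the repulsion term is
#' dropped. The loss may be negative.
#'
#' @param features_s,features_t encoder feature maps \code{(Hf, Wf, d, N)}
#'   (or \code{n x d} matrices); \code{features_t} may be \code{NULL}.
#' @param preds_s,preds_t matching soft prediction maps at image resolution
#'   (or hard label vectors when features are given as matrices).
#' @return scalar loss.
#' @examples
#' f <- matrix(c(0, 2, 10, 12), ncol = 1)
#' clustering_loss(f, NULL, c(0, 0, 1, 1), NULL) # -9
#' @export
clustering_loss <- function(features_s, features_t, preds_s, preds_t) {
  fl <- features_labels(features_s, features_t, preds_s, preds_t)
  cluster_loss_flat(fl$f, fl$l)$loss
}

# build the pooled (flat features, hard labels) pair from up to two domains
features_labels <- function(features_s, features_t, preds_s, preds_t) {
  one <- function(feat, pred) {
    f <- flatten_features(feat)
    if (is.matrix(feat) || is.null(dim(pred)))
      l <- as.integer(round(unlist(pred, use.names = FALSE)))
    else {
      fd <- dim(as_batch(feat))
      l <- downsample_preds(as_map(pred), fd[1], fd[2])
    }
    list(f = f, l = l)
  }
  a <- one(features_s, preds_s)
  if (is.null(features_t)) return(a)
  b <- one(features_t, preds_t)
  list(f = rbind(a$f, b$f), l = c(a$l, b$l))
}

#' Downsample a prediction map to hard classes at feature resolution
#'
#' Thresholds a soft prediction at 0.5 and picks the nearest-neighbour pixel
#' for every cell of the \code{hf x wf} target grid.
#'
#' @param preds soft prediction batch \code{(H, W, 1, N)}.
#' @param hf,wf target spatial size.
#' @return integer vector of 0/1 labels, location-major then batch.
#' @export
downsample_preds <- function(preds, hf, wf) {
  p <- as_map(preds)
  d <- dim(p)
  ih <- ceiling((seq_len(hf) - 0.5) * d[1] / hf)
  iw <- ceiling((seq_len(wf) - 0.5) * d[2] / wf)
  hard <- (p >= 0.5)[ih, iw, 1, , drop = FALSE]
  as.integer(hard)
}

# ---- weighted totals --------------------------------------------------------

#' Loss weights for the adaptation objective
#'
#' The \eqn{\lambda} multipliers balancing the adversarial, reconstruction,
#' translated-source and clustering terms against the supervised segmentation
#' loss. Defaults are the published operating point.
#'
#' @param advP weight of the prediction (output-space) adversarial loss.
#' @param recons weight of the image reconstruction loss.
#' @param advI weight of the image (reconstruction-space) adversarial loss.
#' @param trans weight of the translated-source supervision loss.
#' @param cl weight of the feature clustering loss.
#' @return object of class \code{"loss_weights"}.
#' @export
loss_weights <- function(advP = 0.001, recons = 0.01, advI = 0.001,
                         trans = 0.001, cl = 0.002) {
  w <- c(advP = advP, recons = recons, advI = advI,
         trans = trans, cl = cl)
  if (any(!is.finite(w)) || any(w < 0))
    stop("loss weights must be finite and non-negative")
  structure(as.list(w), class = "loss_weights")
}

component_or_zero <- function(components, nm) {
  if (is.null(components[[nm]]) || is.na(components[[nm]])) 0
  else components[[nm]]
}

#' Total unsupervised domain-adaptation objective
#'
#' The weighted sum
#' \eqn{L_{seg} + \lambda_{advP} L_{advP} + \lambda_{recons} L_{recons} +
#'      \lambda_{advI} L_{advI} + \lambda_{trans} L_{trans} +
#'      \lambda_{cl} L_{cl}}.
#' Components absent from the list (ablated terms) contribute zero.
#'
#' @param components named list/vector with entries \code{seg}, \code{advP},
#'   \code{recons}, \code{advI}, \code{trans}, \code{cl}.
#' @param w a [loss_weights()] object.
#' @return scalar total loss.
#' @examples
#' total_uda_loss(list(seg = 1, advP = 1, recons = 1, advI = 1,
#'                     trans = 1, cl = 1), loss_weights()) # 1.015
#' @export
total_uda_loss <- function(components, w = loss_weights()) {
  if (!inherits(w, "loss_weights")) w <- do.call(loss_weights, as.list(w))
  component_or_zero(components, "seg") +
    w$advP   * component_or_zero(components, "advP") +
    w$recons * component_or_zero(components, "recons") +
    w$advI   * component_or_zero(components, "advI") +
    w$trans  * component_or_zero(components, "trans") +
    w$cl     * component_or_zero(components, "cl")
}

#' Total semi-supervised domain-adaptation objective
#'
#' The UDA objective of [total_uda_loss()] plus an unweighted supervised
#' segmentation loss on the labeled target images (\code{seg_tl}). If
#' \code{seg_tl} is missing the function warns and falls back to the UDA
#' objective.
#'
#' @inheritParams total_uda_loss
#' @return scalar total loss.
#' @export
total_ssda_loss <- function(components, w = loss_weights()) {
  base <- total_uda_loss(components, w)
  if (is.null(components[["seg_tl"]])) {
    warning("no labeled-target segmentation loss supplied; ",
            "falling back to the UDA objective")
    return(base)
  }
  base + components[["seg_tl"]]
}
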