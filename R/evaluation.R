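# Segmentation metrics: IoU%, Dice score, Hausdorff distance, and
# dataset-level reports. Predictions are binarized at 0.5 before scoring;
# per-image metrics are averaged (not pixel-pooled) across a test set.

binarize <- function(p, threshold = 0.5) (as_map(p) >= threshold) * 1L

#' Intersection-over-union (Jaccard), in percent
#'
#' \eqn{100 |A \cap B| / |A \cup B|} per image. Two empty masks score 100.
#'
#' @param y_true binary ground-truth mask(s).
#' @param y_pred_bin binary predicted mask(s) (threshold soft maps first).
#' @return numeric vector, one value in \code{[0,100]} per image.
#' @export
iou <- function(y_true, y_pred_bin) {
  a <- as_map(y_true); b <- as_map(y_pred_bin)
  check_same_shape(a, b, "masks")
  check_mask(a); check_mask(b, "prediction mask")
  vapply(seq_len(batch_size(a)), function(i) {
    ai <- a[, , , i]; bi <- b[, , , i]
    u <- sum(ai | bi)
    if (u == 0) 100 else 100 * sum(ai & bi) / u
  }, numeric(1))
}

#' Dice score between binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)} per image. Two empty masks score 1.
#'
#' @inheritParams iou
#' @return numeric vector in \code{[0,1]}, one value per image.
#' @export
dice_score <- function(y_true, y_pred_bin) {
  a <- as_map(y_true); b <- as_map(y_pred_bin)
  check_same_shape(a, b, "masks")
  check_mask(a); check_mask(b, "prediction mask")
  vapply(seq_len(batch_size(a)), function(i) {
    ai <- a[, , , i]; bi <- b[, , , i]
    s <- sum(ai) + sum(bi)
    if (s == 0) 1 else 2 * sum(ai & bi) / s
  }, numeric(1))
}

#' Hausdorff distance between binary masks
#'
#' Symmetric Hausdorff distance (Euclidean, in pixels) between the
#' foreground pixel sets. The default is the classic full Hausdorff
#' distance; \code{percentile < 1} gives the robust percentile variant
#' (e.g. 0.95). Two empty masks are identical sets and score 0; if exactly
#' one mask is empty the image diagonal is returned as a sentinel (with a
#' warning).
#'
#' @inheritParams iou
#' @param percentile quantile of the directed nearest-neighbour distances;
#'   1 (default) is the classic maximum.
#' @return numeric vector (pixels), one value per image.
#' @export
hausdorff_distance <- function(y_true, y_pred_bin, percentile = 1) {
  a <- as_map(y_true); b <- as_map(y_pred_bin)
  check_same_shape(a, b, "masks")
  check_mask(a); check_mask(b, "prediction mask")
  d <- dim(a)
  vapply(seq_len(batch_size(a)), function(i) {
    pa <- which(a[, , 1, i] == 1, arr.ind = TRUE)
    pb <- which(b[, , 1, i] == 1, arr.ind = TRUE)
    if (nrow(pa) == 0 && nrow(pb) == 0) return(0)
    if (nrow(pa) == 0 || nrow(pb) == 0) {
      warning("empty foreground: returning image-diagonal sentinel")
      return(sqrt(d[1]^2 + d[2]^2))
    }
    if (percentile >= 1)
      return(.hausdorff_cpp(pa * 1.0, pb * 1.0))
    dm <- sqrt(pmax(outer(rowSums(pa^2), rowSums(pb^2), "+") -
                      2 * pa %*% t(pb), 0))
    max(stats::quantile(apply(dm, 1, min), percentile),
        stats::quantile(apply(dm, 2, min), percentile))
  }, numeric(1))
}

#' Evaluate a segmentation network on a labeled split
#'
#' Runs the network over a split, binarizes predictions at
#' \code{threshold}, and reports per-image and mean IoU%, Dice score and
#' Hausdorff distance.
#'
#' @param model a segmentation \code{nucadapt_network}.
#' @param data a list with \code{images (H,W,3,N)} and \code{masks
#'   (H,W,1,N)} — e.g. one split of a \code{nucadapt_dataset}.
#' @param threshold binarization threshold for the soft predictions.
#' @param batch forward-pass batch size.
#' @param percentile Hausdorff percentile (see [hausdorff_distance()]).
#' @return object of class \code{"metrics_report"}: a list with
#'   \code{per_image} (data.frame) and \code{means}.
#' @export
evaluate_model <- function(model, data, threshold = 0.5, batch = 8L,
                           percentile = 1) {
  imgs <- as_batch(data$images)
  masks <- as_map(data$masks)
  n <- batch_size(imgs)
  preds <- array(0, dim(masks))
  for (i0 in seq(1, n, by = batch)) {
    ii <- i0:min(n, i0 + batch - 1)
    preds[, , , ii] <- network_forward(model, imgs[, , , ii, drop = FALSE])
  }
  pb <- binarize(preds, threshold)
  per <- data.frame(
    image = seq_len(n),
    iou_percent = iou(masks, pb),
    dice_score = dice_score(masks, pb),
    hausdorff = suppressWarnings(
      hausdorff_distance(masks, pb, percentile = percentile)))
  structure(list(per_image = per,
                 means = c(iou_percent = mean(per$iou_percent),
                           dice_score = mean(per$dice_score),
                           hausdorff = mean(per$hausdorff))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Segmentation metrics over %d images:\n  IoU%%  %6.2f\n  Dice  %6.4f\n  HD    %6.4f px\n",
    nrow(x$per_image), x$means["iou_percent"], x$means["dice_score"],
    x$means["hausdorff"]))
  invisible(x)
}

#' Write a metrics report to CSV (per image + summary row) and JSON summary
#'
#' @param report a \code{metrics_report}.
#' @param csv,json output paths (either may be \code{NULL} to skip).
#' @return invisibly, the report.
#' @export
write_metrics_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) {
    df <- report$per_image
    df$image <- as.character(df$image)
    df <- rbind(df, data.frame(image = "mean",
                               iou_percent = report$means["iou_percent"],
                               dice_score = report$means["dice_score"],
                               hausdorff = report$means["hausdorff"]))
    utils::write.csv(df, csv, row.names = FALSE)
  }
  if (!is.null(json))
    jsonlite::write_json(as.list(report$means), json, auto_unbox = TRUE,
                         digits = NA)
  invisible(report)
}
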