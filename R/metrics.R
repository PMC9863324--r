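#' Confusion counts between two binary masks
#' @param pred,gt binary matrices of identical shape.
#' @return Named vector with `tp`, `fp`, `fn`, `tn` pixel counts.
#' @export
confusion_counts <- function(pred, gt) {
  stop_if(!identical(dim(pred), dim(gt)), "mask shapes differ")
  p <- pred > 0.5; g <- gt > 0.5
  c(tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g), tn = sum(!p & !g))
}

#' Dice coefficient
#'
#' `2TP / (2TP + FP + FN)` between a predicted and a ground-truth binary
#' mask. Two empty masks count as perfect agreement (1).
#'
#' @inheritParams confusion_counts
#' @return Value in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, gt) {
  n <- confusion_counts(pred, gt)
  den <- 2 * n["tp"] + n["fp"] + n["fn"]
  if (den == 0) return(1)
  unname(2 * n["tp"] / den)
}

#' Intersection over union (Jaccard index)
#'
#' `TP / (TP + FP + FN)`; two empty masks give 1.
#'
#' @inheritParams confusion_counts
#' @return Value in `[0, 1]`.
#' @export
iou <- function(pred, gt) {
  n <- confusion_counts(pred, gt)
  den <- n["tp"] + n["fp"] + n["fn"]
  if (den == 0) return(1)
  unname(n["tp"] / den)
}

#' Precision and recall
#'
#' `TP/(TP+FP)` and `TP/(TP+FN)`. An empty denominator scores 1 when the
#' corresponding reference (truth for precision, prediction for recall) is
#' also empty, otherwise 0.
#'
#' @inheritParams confusion_counts
#' @return Named vector `c(precision = , recall = )`.
#' @export
precision_recall <- function(pred, gt) {
  n <- confusion_counts(pred, gt)
  prec <- if (n["tp"] + n["fp"] == 0) {
    if (n["fn"] == 0) 1 else 0
  } else n["tp"] / (n["tp"] + n["fp"])
  rec <- if (n["tp"] + n["fn"] == 0) {
    if (n["fp"] == 0) 1 else 0
  } else n["tp"] / (n["tp"] + n["fn"])
  c(precision = unname(prec), recall = unname(rec))
}

# Boundary pixels: mask pixels with at least one non-mask 4-neighbor
# (image border counts as outside).
boundary_pixels <- function(mask) {
  m <- mask > 0.5
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  interior <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  which(m & !interior, arr.ind = TRUE)
}

#' Hausdorff distance between mask boundaries, in mm
#'
#' The symmetric (100th percentile) Hausdorff distance between the boundary
#' pixel sets of two masks: the larger of the two directed maximum
#' nearest-neighbor distances, Euclidean, with each image axis scaled by
#' its own pixel spacing.
#'
#' @inheritParams confusion_counts
#' @param spacing length-2 (row, col) pixel spacing in mm/pixel; a single
#'   value is recycled.
#' @param percentile boundary distance percentile (100 = true Hausdorff;
#'   95 gives the robust HD95 variant).
#' @return Distance in mm.
#' @export
hausdorff_mm <- function(pred, gt, spacing, percentile = 100) {
  stop_if(!identical(dim(pred), dim(gt)), "mask shapes differ")
  stop_if(sum(pred > 0.5) == 0 || sum(gt > 0.5) == 0,
          "Hausdorff distance is undefined for an empty mask")
  spacing <- rep_len(as.numeric(spacing), 2L)
  a <- boundary_pixels(pred); b <- boundary_pixels(gt)
  a <- sweep(a, 2, spacing, `*`); b <- sweep(b, 2, spacing, `*`)
  directed <- function(p, q) {
    # max over p of min over q, chunked to bound memory
    mins <- numeric(nrow(p))
    step <- max(1L, floor(2e6 / nrow(q)))
    for (s in seq(1, nrow(p), by = step)) {
      idx <- s:min(s + step - 1, nrow(p))
      d2 <- outer(p[idx, 1], q[, 1], `-`)^2 + outer(p[idx, 2], q[, 2], `-`)^2
      mins[idx] <- apply(d2, 1, min)
    }
    if (percentile >= 100) max(mins)
    else stats::quantile(mins, percentile / 100, names = FALSE)
  }
  sqrt(max(directed(a, b), directed(b, a)))
}

#' Evaluate a predicted mask sequence against ground truth
#'
#' Computes Dice, IoU, precision, recall and the Hausdorff distance for
#' every frame and aggregates them as mean and standard deviation over
#' frames (sample SD, n-1 denominator), mirroring per-image evaluation
#' tables. Frames where either mask is empty get `NA` Hausdorff and are
#' dropped from its aggregate.
#'
#' @param pred,gt `mask_sequence` objects of identical shape.
#' @param spacing pixel spacing mm/px; defaults to the ground truth's.
#' @return An object of class `segmentation_metrics`: `per_frame`
#'   data.frame and `aggregate` data.frame (metric, mean, sd).
#' @export
segmentation_metrics <- function(pred, gt, spacing = NULL) {
  stopifnot(inherits(pred, "mask_sequence"), inherits(gt, "mask_sequence"))
  stop_if(!identical(dim(pred$frames), dim(gt$frames)),
          "mask sequence shapes differ")
  spacing <- spacing %||% gt$pixel_spacing
  nt <- dim(gt$frames)[1]
  per <- do.call(rbind, lapply(seq_len(nt), function(t) {
    p <- pred$frames[t, , ]; g <- gt$frames[t, , ]
    pr <- precision_recall(p, g)
    hd <- if (sum(p) > 0 && sum(g) > 0) hausdorff_mm(p, g, spacing) else NA_real_
    data.frame(frame = t, dice = dice_coefficient(p, g), iou = iou(p, g),
               hausdorff_mm = hd, precision = pr["precision"],
               recall = pr["recall"], row.names = NULL)
  }))
  metrics <- c("dice", "iou", "hausdorff_mm", "precision", "recall")
  agg <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per[[m]], na.rm = TRUE), 0),
    sd = vapply(metrics, function(m) stats::sd(per[[m]], na.rm = TRUE), 0),
    row.names = NULL)
  structure(list(per_frame = per, aggregate = agg, exam_id = gt$exam_id),
            class = "segmentation_metrics")
}

#' @export
print.segmentation_metrics <- function(x, ...) {
  cat(sprintf("<segmentation_metrics '%s' over %d frames>\n",
              x$exam_id, nrow(x$per_frame)))
  print(x$aggregate, digits = 4)
  invisible(x)
}

#' Write segmentation metrics as CSV (per frame) and JSON (aggregate)
#' @param x a `segmentation_metrics`; @param prefix output path prefix.
#' @return Paths written, invisibly.
#' @export
write_segmentation_metrics <- function(x, prefix) {
  csv <- paste0(prefix, "_per_frame.csv")
  js <- paste0(prefix, "_aggregate.json")
  utils::write.csv(x$per_frame, csv, row.names = FALSE)
  agg <- stats::setNames(
    lapply(seq_len(nrow(x$aggregate)),
           function(i) list(mean = x$aggregate$mean[i], sd = x$aggregate$sd[i])),
    x$aggregate$metric)
  jsonlite::write_json(agg, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
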