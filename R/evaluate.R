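# Segmentation and recovery metrics: per-class accuracy and IoU, instance
# average precision under point-set IoU, and R^2 / RMSE agreement between
# extracted and reference parameter values.

#' Per-class semantic segmentation metrics
#'
#' For each class present in the ground truth, points are scored one-vs-rest
#' (TP: correctly given the class; TN: correctly not given it; FP/FN: the
#' two error types), yielding `ACC = (TP+TN)/(TP+TN+FP+FN)` and
#' `IoU = TP/(TP+FP+FN)`; `mIoU` is the unweighted mean IoU over classes
#' present in the truth.
#'
#' @param pred,truth Equal-length label vectors.
#' @return List with `per_class` (data.frame: class, TP, TN, FP, FN, ACC,
#'   IoU), `overall_acc` and `mIoU`.
#' @export
semantic_metrics <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("label vectors have different lengths")
  n <- length(truth)
  classes <- sort(unique(truth))
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    tn <- n - tp - fp - fn
    data.frame(class = cl, TP = tp, TN = tn, FP = fp, FN = fn,
               ACC = (tp + tn) / n, IoU = tp / (tp + fp + fn))
  }))
  list(per_class = per,
       overall_acc = mean(pred == truth),
       mIoU = mean(per$IoU))
}

set_iou <- function(a, b) {
  i <- length(intersect(a, b))
  i / (length(a) + length(b) - i)
}

ap_single_class <- function(preds, truths, thr) {
  nt <- length(truths)
  if (!length(preds))
    return(list(AP = 0, recall = if (nt) 0 else NA_real_))
  conf <- vapply(preds, `[[`, numeric(1), "confidence")
  ord <- order(-conf)
  matched <- rep(FALSE, nt)
  tp <- fp <- numeric(length(preds))
  for (r in seq_along(ord)) {
    p <- preds[[ord[r]]]
    ious <- if (nt) vapply(truths, function(t) set_iou(p$points, t$points),
                           numeric(1)) else numeric(0)
    ious[matched] <- -1
    best <- if (length(ious)) which.max(ious) else 0L
    if (nt && length(ious) && ious[best] >= thr) {
      matched[best] <- TRUE
      tp[r] <- 1
    } else fp[r] <- 1
  }
  ctp <- cumsum(tp); cfp <- cumsum(fp)
  rec <- if (nt) ctp / nt else rep(0, length(ctp))
  prec <- ctp / (ctp + cfp)
  # all-point interpolation: area under the precision envelope
  mrec <- c(0, rec, 1)
  mpre <- c(0, prec, 0)
  for (i in rev(seq_len(length(mpre) - 1L)))
    mpre[i] <- max(mpre[i], mpre[i + 1L])
  idx <- which(diff(mrec) > 0)
  list(AP = sum((mrec[idx + 1L] - mrec[idx]) * mpre[idx + 1L]),
       recall = if (nt) max(rec) else NA_real_)
}

#' Instance-segmentation average precision and recall
#'
#' Greedy confidence-ordered matching of predicted to true instances under
#' point-set IoU. Reports AP50 and AP25 (IoU thresholds 0.50 / 0.25), the
#' comprehensive AP averaged over thresholds 0.50 to 0.95 in steps of 0.05,
#' and the recalls RC50 / RC25, per class and macro-averaged.
#'
#' @param pred List of predicted instances: each
#'   `list(points = <index vector>, class = <label>, confidence = <0-1>)`.
#' @param truth List of true instances: `list(points =, class =)`.
#' @return List with `per_class` data.frame (`class`, `AP`, `AP50`, `AP25`,
#'   `RC50`, `RC25`) and `mean` (macro averages).
#' @export
instance_ap <- function(pred, truth) {
  classes <- sort(unique(vapply(truth, `[[`, character(1), "class")))
  comp_thr <- seq(0.50, 0.95, by = 0.05)
  per <- do.call(rbind, lapply(classes, function(cl) {
    pr <- Filter(function(p) p$class == cl, pred)
    tr <- Filter(function(t) t$class == cl, truth)
    ap_comp <- mean(vapply(comp_thr, function(th)
      ap_single_class(pr, tr, th)$AP, numeric(1)))
    a50 <- ap_single_class(pr, tr, 0.50)
    a25 <- ap_single_class(pr, tr, 0.25)
    data.frame(class = cl, AP = ap_comp, AP50 = a50$AP, AP25 = a25$AP,
               RC50 = a50$recall, RC25 = a25$recall)
  }))
  list(per_class = per,
       mean = colMeans(per[, -1, drop = FALSE]))
}

#' Agreement between extracted and reference parameter values
#'
#' `R^2 = 1 - sum((x - xhat)^2) / sum((x - mean(x))^2)` and
#' `RMSE = sqrt(mean((x - xhat)^2))`, where `x` are the reference
#' (manually measured or ground-truth) values and `xhat` the extracted
#' ones. Note this is agreement with the identity line, not a correlation:
#' a constant bias lowers it.
#'
#' @param x Reference values (n >= 2).
#' @param xhat Extracted values.
#' @return List with `r2`, `rmse` and `n`. Zero variance in `x` leaves `r2`
#'   as `NA` with a warning; `rmse` is still returned.
#' @export
recovery_metrics <- function(x, xhat) {
  stopifnot(length(x) == length(xhat), length(x) >= 2L)
  ok <- is.finite(x) & is.finite(xhat)
  x <- x[ok]; xhat <- xhat[ok]
  if (length(x) < 2L) stop("fewer than 2 finite pairs")
  sstot <- sum((x - mean(x))^2)
  ssres <- sum((x - xhat)^2)
  r2 <- if (sstot == 0) {
    warning("zero variance in reference values: R^2 undefined")
    NA_real_
  } else 1 - ssres / sstot
  list(r2 = r2, rmse = sqrt(mean((x - xhat)^2)), n = length(x))
}
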