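# Segmentation evaluation: pixel confusion matrices and the derived
# per-class IoU / precision / recall / F1 metrics, with mIoU as the mean
# of per-class IoU over all classes (background included).

#' Pixel confusion matrix between predicted and true label masks
#'
#' @param pred,truth integer matrices (or arrays) of identical shape with
#'   class labels in `0..C-1`.
#' @param n_classes number of classes C.
#' @return C x C matrix of class `confusion_matrix`; rows = true class,
#'   columns = predicted class, entry `[t, p]` = number of pixels with
#'   truth `t` and prediction `p` (labels offset by 1 for indexing).
#' @export
confusion_counts <- function(pred, truth, n_classes = 3) {
  check_that(length(pred) == length(truth) &&
               all(dim(pred) == dim(truth)),
             "pred and truth must have identical shape")
  pv <- as.vector(pred); tv <- as.vector(truth)
  check_that(all(pv >= 0 & pv < n_classes & tv >= 0 & tv < n_classes),
             "labels out of range 0..C-1")
  cm <- matrix(tabulate(tv * n_classes + pv + 1L, nbins = n_classes^2),
               n_classes, n_classes, byrow = TRUE)
  dimnames(cm) <- list(truth = 0:(n_classes - 1),
                       pred = 0:(n_classes - 1))
  structure(cm, class = "confusion_matrix")
}

#' Per-class segmentation metrics from a confusion matrix
#'
#' For class c: `TP = cm[c,c]`, `FP = sum over t != c of cm[t,c]`,
#' `FN = sum over p != c of cm[c,p]`; then
#' `IoU = TP/(TP+FP+FN)`, `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)` and `F1 = 2*precision*recall/(precision+recall)`
#' (the harmonic mean). Classes absent from both prediction and truth
#' (`TP+FP+FN = 0`) are reported as `NA` with a warning and excluded from
#' the mean IoU.
#'
#' @param cm a [confusion_counts()] matrix (or plain C x C count matrix).
#' @return object of class `metrics_report`: list with `per_class`
#'   (tibble: class, iou, precision, recall, f1), `miou`,
#'   `confusion` (counts) and `confusion_norm` (row-normalized fractions).
#' @export
class_metrics <- function(cm) {
  cm <- unclass(cm)
  check_that(is.matrix(cm) && nrow(cm) == ncol(cm) && sum(cm) > 0,
             "confusion matrix is empty")
  C <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  denom <- tp + fp + fn
  iou <- ifelse(denom > 0, tp / denom, NA_real_)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp),
                      ifelse(denom > 0, 0, NA_real_))
  recall <- ifelse(tp + fn > 0, tp / (tp + fn),
                   ifelse(denom > 0, 0, NA_real_))
  f1 <- ifelse(is.na(precision) | is.na(recall), NA_real_,
               ifelse(precision + recall > 0,
                      2 * precision * recall / (precision + recall), 0))
  if (any(denom == 0)) {
    warning(sprintf("class(es) %s absent from both prediction and truth; %s",
                    paste(which(denom == 0) - 1, collapse = ", "),
                    "excluded from mIoU"))
  }
  rs <- rowSums(cm)
  cm_norm <- cm / ifelse(rs > 0, rs, 1)
  structure(list(per_class = tibble::tibble(class = 0:(C - 1), iou = iou,
                                            precision = precision,
                                            recall = recall, f1 = f1),
                 miou = mean(iou, na.rm = TRUE),
                 confusion = cm, confusion_norm = cm_norm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation metrics\n")
  print(x$per_class)
  cat(sprintf("mIoU: %.4f\n", x$miou))
  invisible(x)
}

#' Tidy a metrics report into a per-class tibble
#' @param x a `metrics_report`.
#' @param ... unused.
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' One-row summary of a metrics report
#' @param x a `metrics_report`.
#' @param ... unused.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(miou = x$miou,
                 mean_precision = mean(x$per_class$precision, na.rm = TRUE),
                 mean_recall = mean(x$per_class$recall, na.rm = TRUE),
                 mean_f1 = mean(x$per_class$f1, na.rm = TRUE),
                 n_pixels = sum(x$confusion))
}

#' Evaluate directories of predicted and true masks
#'
#' @param pred_dir,truth_dir directories of mask PNGs with matching
#'   filenames.
#' @param n_classes number of classes.
#' @return a `metrics_report` accumulated over all shared files.
#' @export
evaluate_mask_dirs <- function(pred_dir, truth_dir, n_classes = 3) {
  files <- intersect(list.files(pred_dir, pattern = "\\.png$"),
                     list.files(truth_dir, pattern = "\\.png$"))
  check_that(length(files) > 0, "no shared mask files")
  cm <- matrix(0, n_classes, n_classes)
  for (f in files) {
    cm <- cm + unclass(confusion_counts(read_mask_png(file.path(pred_dir, f)),
                                        read_mask_png(file.path(truth_dir, f)),
                                        n_classes))
  }
  class_metrics(cm)
}
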