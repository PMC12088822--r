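#' Confusion matrix from binary labels
#'
#' @param y_true,y_pred equal-length binary 0/1 vectors.
#' @return a `confusion_matrix` list with counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(c(y_true, y_pred) %in% c(0, 1))) stop("labels must be binary 0/1")
  structure(list(tp = sum(y_true == 1 & y_pred == 1),
                 fp = sum(y_true == 0 & y_pred == 1),
                 fn = sum(y_true == 1 & y_pred == 0),
                 tn = sum(y_true == 0 & y_pred == 0)),
            class = "confusion_matrix")
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,fn,tn nonnegative counts.
#' @return a `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn > 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("pos", "neg"),
                              predicted = c("pos", "neg")))
  print(m)
  invisible(x)
}

# Rates with zero denominators are reported as NA_real_, the explicit
# undefined marker, never silently as 0.
safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Accuracy, precision, recall and specificity
#'
#' @param cm a [confusion_matrix()] or [confusion_counts()].
#' @return named list; undefined rates (zero denominator) are `NA`.
#' @export
basic_rates <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  list(accuracy = safe_ratio(cm$tp + cm$tn, n),
       precision = safe_ratio(cm$tp, cm$tp + cm$fp),
       recall = safe_ratio(cm$tp, cm$tp + cm$fn),
       specificity = safe_ratio(cm$tn, cm$tn + cm$fp))
}

#' False positive, false negative and false discovery rates
#'
#' FPR = FP/(FP+TN): the proportion of actual negatives misclassified as
#' positive. FNR = FN/(FN+TP): actual positives misclassified as negative.
#' FDR = FP/(FP+TP): predicted positives that are false (the classifier
#' sense, not the multiple-testing procedure).
#'
#' @inheritParams basic_rates
#' @return named list; undefined rates are `NA`.
#' @export
error_rates <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  list(fpr = safe_ratio(cm$fp, cm$fp + cm$tn),
       fnr = safe_ratio(cm$fn, cm$fn + cm$tp),
       fdr = safe_ratio(cm$fp, cm$fp + cm$tp))
}

#' Matthews correlation coefficient
#'
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), a balanced summary
#' of the whole 2x2 table in `[-1, 1]`. When any denominator factor is zero
#' the conventional value 0 is returned.
#'
#' @inheritParams basic_rates
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  f <- c(cm$tp + cm$fp, cm$tp + cm$fn, cm$tn + cm$fp, cm$tn + cm$fn)
  if (any(f == 0)) return(0)
  (cm$tp * cm$tn - cm$fp * cm$fn) / sqrt(prod(f))
}

#' Full classification report
#'
#' All eight classification metrics from one confusion matrix. Percentages
#' are also provided rounded half-up to the whole percent and the error
#' rates to 4 decimals, matching the conventional table precision.
#'
#' @inheritParams basic_rates
#' @return a `classification_report` list.
#' @export
classification_report <- function(cm) {
  b <- basic_rates(cm); e <- error_rates(cm)
  out <- c(b, e, list(mcc = mcc(cm)))
  out$rounded <- c(lapply(b, function(v) round_half_up(100 * v)),
                   lapply(e, function(v) round_half_up(v, 4)),
                   list(mcc = round_half_up(out$mcc, 4)))
  structure(out, class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("accuracy %s%%  precision %s%%  recall %s%%  specificity %s%%\n",
              x$rounded$accuracy, x$rounded$precision, x$rounded$recall,
              x$rounded$specificity))
  cat(sprintf("FPR %.4f  FNR %.4f  FDR %.4f  MCC %.4f\n",
              x$fpr, x$fnr, x$fdr, x$mcc))
  invisible(x)
}

#' Dice similarity coefficient of two binary masks
#'
#' 2|A intersect B| / (|A| + |B|); defined as 1 when both masks are empty.
#'
#' @param mask_a,mask_b binary matrices of equal shape.
#' @return value in `[0, 1]`.
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) stop("shape mismatch")
  a <- sum(mask_a); b <- sum(mask_b)
  if (a + b == 0) return(1)
  2 * sum(mask_a * mask_b) / (a + b)
}

# Separable Gaussian filtering with symmetric ("reflect") boundary handling.
gaussian_filter <- function(img, sd = 1.5, size = 11L) {
  half <- (size - 1L) / 2L
  k <- stats::dnorm(seq(-half, half), sd = sd)
  k <- k / sum(k)
  reflect_idx <- function(i, n) {
    i <- ((i - 1) %% (2 * n))
    ifelse(i < n, i + 1, 2 * n - i)
  }
  conv1 <- function(m) {     # along rows (dimension 1)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in seq_along(k)) {
      idx <- reflect_idx(seq_len(n) + (o - half - 1L), n)
      out <- out + k[o] * m[idx, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img))))
}

#' Structural similarity index of two grayscale images
#'
#' Mean local SSIM with the standard constants K1 = 0.01, K2 = 0.03, an
#' 11x11 Gaussian window with sd 1.5, and dynamic range taken from the data
#' (1 for binary or unit-scaled images).
#'
#' @param img_a,img_b numeric matrices of equal shape, at least 11x11.
#' @param dynamic_range value range L; default max range observed in the
#'   pair (1 if both constant).
#' @return value in `[-1, 1]`.
#' @export
ssim_index <- function(img_a, img_b, dynamic_range = NULL) {
  if (!all(dim(img_a) == dim(img_b))) stop("shape mismatch")
  if (any(dim(img_a) < 11)) stop("image smaller than the 11x11 window")
  img_a <- img_a * 1; img_b <- img_b * 1
  if (is.null(dynamic_range)) {
    dynamic_range <- max(img_a, img_b) - min(img_a, img_b)
    if (dynamic_range == 0) dynamic_range <- 1
  }
  C1 <- (0.01 * dynamic_range)^2
  C2 <- (0.03 * dynamic_range)^2
  mu_a <- gaussian_filter(img_a); mu_b <- gaussian_filter(img_b)
  sig_a <- gaussian_filter(img_a^2) - mu_a^2
  sig_b <- gaussian_filter(img_b^2) - mu_b^2
  sig_ab <- gaussian_filter(img_a * img_b) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * sig_ab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (sig_a + sig_b + C2))
  mean(s)
}

#' Proportion of correctly segmented patches
#'
#' Masks are zero-padded to a multiple of `patch_size`, divided into
#' non-overlapping square tiles, and a tile counts as correct when its
#' pixelwise agreement is at least `agreement_threshold`. The patch size and
#' threshold defaults (16 and 0.9) are this package's convention — the
#' metric has no universal operational definition.
#'
#' @param mask_a,mask_b binary matrices of equal shape.
#' @param patch_size positive tile side length.
#' @param agreement_threshold required within-tile agreement fraction.
#' @return fraction of correct tiles, in `[0, 1]`.
#' @export
patch_proportion <- function(mask_a, mask_b, patch_size = 16L,
                             agreement_threshold = 0.9) {
  if (!all(dim(mask_a) == dim(mask_b))) stop("shape mismatch")
  if (patch_size <= 0) stop("patch_size must be positive")
  h <- ceiling(nrow(mask_a) / patch_size) * patch_size
  w <- ceiling(ncol(mask_a) / patch_size) * patch_size
  pad <- function(m) {
    out <- matrix(0, h, w)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  A <- pad(mask_a); B <- pad(mask_b)
  agree <- A == B
  ok <- 0L; total <- 0L
  for (i in seq_len(h / patch_size)) for (j in seq_len(w / patch_size)) {
    tile <- agree[(i - 1) * patch_size + seq_len(patch_size),
                  (j - 1) * patch_size + seq_len(patch_size)]
    total <- total + 1L
    if (mean(tile) >= agreement_threshold) ok <- ok + 1L
  }
  ok / total
}

#' Segmentation report for a mask pair
#'
#' @param mask_a,mask_b binary masks (truth, prediction).
#' @param ... passed to [patch_proportion()].
#' @return list with `dice`, `ssim`, `patch_proportion`.
#' @export
segmentation_report <- function(mask_a, mask_b, ...) {
  list(dice = dice_coefficient(mask_a, mask_b),
       ssim = ssim_index(mask_a, mask_b),
       patch_proportion = patch_proportion(mask_a, mask_b, ...))
}
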