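# Segmentation evaluation: Dice similarity coefficient, sensitivity,
# specificity (all from pixel confusion counts) and the Hausdorff distance
# between mask boundaries.

#' Pixelwise confusion counts
#'
#' @param pred,gold Binary masks of identical shape.
#' @return List of class `"confusion_counts"` with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(pred, gold) {
  pred <- as.matrix(pred); gold <- as.matrix(gold)
  check_same_shape(pred, gold)
  if (!all(pred %in% c(0, 1)) || !all(gold %in% c(0, 1)))
    stop("masks must be binary", call. = FALSE)
  structure(list(TP = sum(pred == 1 & gold == 1),
                 FP = sum(pred == 1 & gold == 0),
                 FN = sum(pred == 0 & gold == 1),
                 TN = sum(pred == 0 & gold == 0)),
            class = "confusion_counts")
}

#' Dice similarity coefficient
#'
#' `DSC = 2TP / (2TP + FP + FN)`. When both masks are empty the comparison is
#' a perfect agreement; 1 is returned with a warning.
#'
#' @param c A [confusion_counts()] object (or compatible list).
#' @return Scalar in `[0, 1]`.
#' @export
dsc <- function(c) {
  den <- 2 * c$TP + c$FP + c$FN
  if (den == 0) {
    warning("both masks empty: DSC defined as 1")
    return(1)
  }
  2 * c$TP / den
}

#' Sensitivity (true positive rate)
#'
#' `Se = TP / (TP + FN)`.
#'
#' @inheritParams dsc
#' @return Scalar in `[0, 1]`.
#' @export
sensitivity <- function(c) {
  if (c$TP + c$FN == 0) stop("sensitivity undefined: gold mask empty", call. = FALSE)
  c$TP / (c$TP + c$FN)
}

#' Specificity (true negative rate)
#'
#' `Sp = TN / (TN + FP)`.
#'
#' @inheritParams dsc
#' @return Scalar in `[0, 1]`.
#' @export
specificity <- function(c) {
  if (c$TN + c$FP == 0) stop("specificity undefined: gold covers whole image", call. = FALSE)
  c$TN / (c$TN + c$FP)
}

#' Boundary pixels of a binary mask
#'
#' A positive pixel is a boundary point when at least one 4-neighbor is
#' non-positive or the pixel lies on the image edge.
#'
#' @param mask Binary matrix.
#' @return Two-column matrix of `(row, col)` coordinates.
#' @export
boundary_points <- function(mask) {
  mask <- as.matrix(mask)
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  core <- pad[2:(H + 1), 2:(W + 1)]
  nb_min <- pmin(pad[1:H, 2:(W + 1)], pad[3:(H + 2), 2:(W + 1)],
                 pad[2:(H + 1), 1:W], pad[2:(H + 1), 3:(W + 2)])
  which(core == 1 & nb_min == 0, arr.ind = TRUE)
}

#' Hausdorff distance between two masks
#'
#' The maximum over both directions of the furthest nearest-neighbor
#' Euclidean distance between the masks' boundary point sets, in pixel units
#' (multiplied by `spacing` when given).
#'
#' @param pred,gold Nonempty binary masks of identical shape.
#' @param spacing Pixel spacing (isotropic scalar).
#' @return Nonnegative scalar.
#' @export
hausdorff <- function(pred, gold, spacing = 1) {
  pred <- as.matrix(pred); gold <- as.matrix(gold)
  check_same_shape(pred, gold)
  if (sum(pred) == 0 || sum(gold) == 0)
    stop("Hausdorff undefined for empty mask", call. = FALSE)
  P <- boundary_points(pred); G <- boundary_points(gold)
  d2 <- outer(rowSums(P^2), rowSums(G^2), "+") - 2 * P %*% t(G)
  d2 <- pmax(d2, 0)
  h_pg <- max(apply(d2, 1, min))
  h_gp <- max(apply(d2, 2, min))
  spacing * sqrt(max(h_pg, h_gp))
}

#' Score one predicted mask against its gold standard
#'
#' @inheritParams hausdorff
#' @return List of class `"seg_score"` with `dsc`, `se`, `sp`, `hd`.
#' @export
seg_score <- function(pred, gold, spacing = 1) {
  cc <- confusion_counts(pred, gold)
  structure(list(dsc = dsc(cc), se = sensitivity(cc), sp = specificity(cc),
                 hd = if (sum(pred) > 0) hausdorff(pred, gold, spacing) else NA_real_),
            class = "seg_score")
}

#' Evaluate a paired collection of masks
#'
#' Per-metric mean and sample standard deviation (n - 1 denominator) across
#' cases, the usual "mean +/- sd" results-table format. DSC, Se and Sp are
#' reported in percent, HD in pixels. Predictions that are entirely empty
#' yield an undefined Hausdorff distance; those cases are dropped from the HD
#' row (their count is reported in `n`).
#'
#' @param preds,golds Equal-length lists of binary masks.
#' @param spacing Pixel spacing forwarded to [hausdorff()].
#' @return Data frame with `metric`, `mean`, `sd`, `n` and a formatted
#'   `display` column.
#' @export
evaluate_dataset <- function(preds, golds, spacing = 1) {
  if (length(preds) != length(golds))
    stop("preds and golds have different lengths", call. = FALSE)
  if (length(preds) == 0L) stop("no cases to evaluate", call. = FALSE)
  scores <- mapply(function(p, g) unlist(seg_score(p, g, spacing)),
                   preds, golds)
  scale <- c(dsc = 100, se = 100, sp = 100, hd = 1)
  rows <- lapply(c("dsc", "se", "sp", "hd"), function(m) {
    v <- scores[m, ] * scale[[m]]
    v <- v[!is.na(v)]
    data.frame(metric = m, mean = mean(v),
               sd = if (length(v) > 1) sd(v) else 0,
               n = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$display <- sprintf("%.2f ± %.2f", out$mean, out$sd)
  out
}
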