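# ROC construction, AUC (Mann-Whitney convention, ties get half credit),
# the Youden-index operating point, and the DeLong test for comparing two
# correlated AUCs measured on the same subjects.

as_binary_labels <- function(labels) {
  if (is.numeric(labels)) as.numeric(labels != 0)
  else as.numeric(labels == "case")
}

#' ROC curve, AUC and Youden operating point
#'
#' Thresholds are the distinct score values (plus one above the maximum); a
#' subject is called positive when `score >= threshold`. The AUC equals the
#' Mann-Whitney U statistic scaled by `n1 * n0`, ties contributing 1/2. The
#' Youden point maximizes `sensitivity + specificity - 1`; ties break to the
#' lowest threshold.
#'
#' @param scores Numeric score vector.
#' @param labels Binary labels (nonzero/`"case"` = positive); both classes
#'   must be present.
#' @return Object of class `"roc_result"`: `curve` (threshold, sensitivity,
#'   specificity), `auc`, `youden_point`, class counts.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("length mismatch", call. = FALSE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # average ranks: ties get half credit
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(sort(unique(scores)), max(scores) + 1)
  sens <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, 0)
  spec <- vapply(thr, function(t) sum(scores < t & y == 0) / n0, 0)
  j <- sens + spec - 1
  k <- which.max(j)  # which.max returns the first (lowest-threshold) maximum
  structure(list(curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec),
                 auc = auc,
                 youden_point = list(threshold = thr[k], sensitivity = sens[k],
                                     specificity = spec[k], youden = j[k]),
                 n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  yp <- x$youden_point
  cat(sprintf("<roc_result> AUC %.3f (%d cases / %d controls)\n",
              x$auc, x$n_pos, x$n_neg))
  cat(sprintf("  Youden point: threshold %.4g, sensitivity %.1f%%, specificity %.1f%%\n",
              yp$threshold, 100 * yp$sensitivity, 100 * yp$specificity))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(1 - x$curve$specificity, x$curve$sensitivity, type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Youden operating point of a fitted ROC
#'
#' @param roc A `"roc_result"`.
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_operating_point <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  roc$youden_point
}

# DeLong structural components: V10 (one per positive), V01 (one per negative)
delong_components <- function(scores, y) {
  xs <- scores[y == 1]; ys <- scores[y == 0]
  m <- length(xs); n <- length(ys)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  V10 <- vapply(xs, function(x) mean(psi(x, ys)), 0)
  V01 <- vapply(ys, function(yv) mean(psi(xs, yv)), 0)
  list(auc = mean(V10), V10 = V10, V01 = V01, m = m, n = n)
}

#' DeLong test for two correlated AUCs
#'
#' Nonparametric z-test for the difference of the AUCs of two score vectors
#' measured on the same subjects, using the structural-components estimate of
#' the variance of the AUC difference; the p-value is two-sided normal.
#'
#' @param scores_a,scores_b Paired score vectors on identical subjects.
#' @param labels Binary labels; both classes must be present.
#' @return Object of class `"delong_result"`: `auc_a`, `auc_b`,
#'   `var_diff`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as_binary_labels(labels)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(y))
    stop("scores and labels must be paired (equal lengths)", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  S10 <- stats::cov(cbind(ca$V10, cb$V10))
  S01 <- stats::cov(cbind(ca$V01, cb$V01))
  # var(auc_a - auc_b) via l = (1, -1)
  vd <- (S10[1, 1] - 2 * S10[1, 2] + S10[2, 2]) / ca$m +
        (S01[1, 1] - 2 * S01[1, 2] + S01[2, 2]) / ca$n
  dauc <- ca$auc - cb$auc
  z <- if (vd <= 0) 0 else dauc / sqrt(vd)
  p <- if (vd <= 0 && dauc == 0) 1 else 2 * pnorm(-abs(z))
  structure(list(auc_a = ca$auc, auc_b = cb$auc, var_diff = vd, z = z, p = p),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("<delong_result> AUC %.3f vs %.3f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$z, x$p))
  invisible(x)
}

#' Partition-restricted ROC evaluation
#'
#' Evaluates a score vector within partitions (e.g. FIGO stage groups among
#' cases, or control subgroups). For each partition level: if the level
#' contains both classes, only its own rows are evaluated; if it contains a
#' single class (the usual case for stage tags on cases or subgroup tags on
#' controls), all rows of the opposite class are added, so "early-stage cases
#' vs all controls" and "cases vs benign controls" both come out naturally.
#' Levels that still contain one class are skipped with a warning.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param partition Tag vector (same length); `NA` rows belong to no level.
#' @return Named list of `"roc_result"` objects (one per evaluable level).
#' @export
evaluate_by_partition <- function(scores, labels, partition) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y), length(partition) == length(y))
  out <- list()
  for (lv in unique(partition[!is.na(partition)])) {
    rows <- which(partition == lv)
    cls <- unique(y[rows])
    if (length(cls) == 1L)
      rows <- union(rows, which(y != cls))
    if (length(unique(y[rows])) < 2L || length(rows) == 0L) {
      warning(sprintf("partition '%s' has a single class; skipped", lv))
      next
    }
    out[[as.character(lv)]] <- roc_curve(scores[rows], y[rows])
  }
  out
}
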