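# End-to-end diagnostic model: one fitting function tying the pipeline
# together (standardize on training rows -> correlation PCA, top 3 components
# -> append demographics -> GA-optimised BP classifier), with test-set ROC
# evaluation built in.

#' Fit the multi-indicator diagnostic model
#'
#' Runs the full pipeline on a cohort table: stratified 2/3-1/3 split,
#' z-score standardization of the indicator panel fitted on the training
#' rows, correlation PCA keeping the three leading components, optional
#' unreduced demographics (age and pregnancies z-scored, menopausal as 0/1)
#' appended to the component scores, and a genetic-algorithm optimised
#' back-propagation classifier. The held-out test rows are scored and an ROC
#' with Youden operating point is computed.
#'
#' @param cohort Cohort data frame (see [generate_cohort()]); indicator
#'   columns are all columns before `age`.
#' @param seed Seed for the split and the GA.
#' @param ga A [ga_config()].
#' @param include_demographics Append `age`, `menopausal`, `pregnancies` to
#'   the classifier inputs.
#' @param n_components Leading principal components kept.
#' @param split_fraction Training fraction of the stratified split.
#' @return Object of class `"ovadx_model"` with the fitted `std` parameters,
#'   `pca`, `net`, `split`, per-row `scores` and the test-set `roc`.
#' @export
diagnostic_model <- function(cohort, seed = 1L, ga = ga_config(seed = seed),
                             include_demographics = TRUE,
                             n_components = 3L,
                             split_fraction = 2 / 3) {
  split <- stratified_split(cohort, fraction = split_fraction, seed = seed)
  std <- zscore_standardize(cohort, fit_rows = split$train_ids)
  pca <- fit_pca(std, n_selected = n_components)
  pcs <- project_scores(pca, std)
  feats <- pcs
  demo_center <- demo_scale <- NULL
  if (include_demographics) {
    demo <- cbind(age = cohort$age, menopausal = cohort$menopausal,
                  pregnancies = cohort$pregnancies)
    mu <- colMeans(demo[split$train_ids, , drop = FALSE])
    sdev <- apply(demo[split$train_ids, , drop = FALSE], 2, sd)
    sdev[sdev == 0] <- 1
    sdev["menopausal"] <- 1; mu["menopausal"] <- 0
    demo_center <- mu; demo_scale <- sdev
    feats <- cbind(pcs, sweep(sweep(demo, 2, mu, "-"), 2, sdev, "/"))
  }
  y <- as.numeric(cohort$label == "case")
  net <- ga_optimize_bp(feats[split$train_ids, , drop = FALSE],
                        y[split$train_ids], ga = ga)
  scores <- predict_scores(net, feats)
  roc <- roc_curve(scores[split$test_ids], y[split$test_ids])
  structure(list(std = std, pca = pca, net = net, split = split,
                 features = feats, scores = scores, labels = y, roc = roc,
                 include_demographics = include_demographics,
                 demo_center = demo_center, demo_scale = demo_scale,
                 seed = seed),
            class = "ovadx_model")
}

#' @export
print.ovadx_model <- function(x, ...) {
  cat(sprintf("<ovadx_model> %d train / %d test rows, %d classifier inputs\n",
              length(x$split$train_ids), length(x$split$test_ids),
              ncol(x$features)))
  print(x$roc)
  invisible(x)
}

#' @export
summary.ovadx_model <- function(object, ...) {
  share <- sum(object$pca$values[1:3]) / sum(object$pca$values)
  yp <- object$roc$youden_point
  out <- list(auc = object$roc$auc,
              sensitivity = yp$sensitivity, specificity = yp$specificity,
              threshold = yp$threshold,
              pc_variance_share = share,
              hidden_size = object$net$hidden_size,
              counts = object$split$counts)
  class(out) <- "summary.ovadx_model"
  out
}

#' @export
print.summary.ovadx_model <- function(x, ...) {
  cat(sprintf("Test-set AUC %.3f; Youden point: sensitivity %.1f%%, specificity %.1f%% (threshold %.3f)\n",
              x$auc, 100 * x$sensitivity, 100 * x$specificity, x$threshold))
  cat(sprintf("Top-3 principal components explain %.1f%% of indicator variance; hidden layer size %d\n",
              100 * x$pc_variance_share, x$hidden_size))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' @export
predict.ovadx_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  std_cols <- object$std$columns
  X <- as.matrix(as.data.frame(newdata, check.names = FALSE)[, std_cols, drop = FALSE])
  z <- sweep(sweep(X, 2, object$std$center, "-"), 2, object$std$scale, "/")
  pcs <- z %*% object$pca$vectors[, seq_len(object$pca$n_selected), drop = FALSE]
  feats <- pcs
  if (object$include_demographics) {
    demo <- cbind(age = newdata$age, menopausal = newdata$menopausal,
                  pregnancies = newdata$pregnancies)
    feats <- cbind(pcs, sweep(sweep(demo, 2, object$demo_center, "-"),
                              2, object$demo_scale, "/"))
  }
  predict_scores(object$net, feats)
}

#' @export
plot.ovadx_model <- function(x, ...) plot(x$roc, ...)
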