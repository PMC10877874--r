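# Training loop and the two experiment harnesses: an architecture comparison
# table (per-system mean +/- sd of all four metrics with pairwise mean
# differences) and the loss x ROI-size grid.

#' Training configuration
#'
#' @param loss_name One of `"cbce"`, `"ce"`, `"dice"`.
#' @param roi_size ROI side length in pixels (>= 32); slices are normalized
#'   then cropped to this size around the tumor centroid before training.
#' @param epochs Passes over the training set.
#' @param batch_size Slices per gradient step (gradients are averaged).
#' @param learning_rate Adam step size.
#' @param seed Seed controlling initialisation, the train/validation split
#'   and shuffling.
#' @param split_fraction Fraction of slices used for training; the remainder
#'   is the held-out validation split.
#' @param network Optional [network_config()]; defaults to the `reduced`
#'   backbone at `roi_size`.
#' @param augment Apply [augment_five_fold()] to the training split.
#' @param average_loss Average (rather than sum) the loss over pixels inside
#'   the optimizer; the reported metric scale is unaffected.
#' @param keep Which parameters the fit returns: `"best"` (default) keeps the
#'   epoch with the lowest mean training loss — a checkpoint-selection guard
#'   against late-epoch divergence — while `"final"` keeps the last epoch.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(loss_name = c("cbce", "ce", "dice"),
                         roi_size = 96L,
                         epochs = 10L,
                         batch_size = 4L,
                         learning_rate = 3e-3,
                         seed = 1L,
                         split_fraction = 0.8,
                         network = NULL,
                         augment = FALSE,
                         average_loss = TRUE,
                         keep = c("best", "final")) {
  loss_name <- match.arg(loss_name)
  keep <- match.arg(keep)
  roi_size <- as.integer(roi_size)
  if (roi_size < 32L) stop("roi_size must be >= 32", call. = FALSE)
  if (split_fraction <= 0 || split_fraction > 1)
    stop("split_fraction must be in (0, 1]", call. = FALSE)
  structure(list(loss_name = loss_name, roi_size = roi_size,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 split_fraction = split_fraction, network = network,
                 augment = isTRUE(augment), average_loss = isTRUE(average_loss),
                 keep = keep),
            class = "train_config")
}

# normalize + centroid crop each pair to the configured ROI
prep_pairs <- function(pairs, roi_size) {
  lapply(pairs, function(p) {
    q <- slice_pair(normalize_intensity(p$image), p$mask, p$id)
    crop_roi(q, roi_size)
  })
}

#' Train the segmentation network
#'
#' Normalizes and crops every slice to the configured ROI, splits off a
#' held-out validation set, and minimises the chosen loss with Adam. Training
#' aborts with a diagnostic if the loss becomes non-finite. The whole run is
#' a pure function of `(data, config)`.
#'
#' @param config A [train_config()].
#' @param data A `"phantom_dataset"` (or list of [slice_pair()]s with the
#'   same structure).
#' @return An object of class `"edgenet_fit"`: the trained `net`, the
#'   `config`, per-epoch mean training `loss` history, and the indices of the
#'   held-out validation slices.
#' @export
train_model <- function(config, data) {
  stopifnot(inherits(config, "train_config"))
  pairs <- if (inherits(data, "phantom_dataset")) data$pairs else data
  if (length(pairs) == 0L) stop("training data are empty", call. = FALSE)
  netcfg <- config$network %||%
    network_config("reduced", input_size = config$roi_size, seed = config$seed)
  if (netcfg$input_size != config$roi_size)
    stop("network input_size must equal roi_size", call. = FALSE)
  prepped <- prep_pairs(pairs, config$roi_size)

  with_seed(config$seed, {
    n <- length(prepped)
    n_train <- max(1L, floor(config$split_fraction * n))
    perm <- sample.int(n)
    train_idx <- sort(perm[seq_len(n_train)])
    val_idx <- sort(setdiff(perm, train_idx))
    train_set <- prepped[train_idx]
    if (config$augment) {
      ds <- structure(list(pairs = train_set, N = length(train_set),
                           shape_class = rep("", length(train_set))),
                      class = "phantom_dataset")
      train_set <- augment_five_fold(ds)$pairs
    }
    net <- build_network(netcfg)
    flat <- net_flat_params(net)
    opt <- adam_init(flat)
    history <- numeric(config$epochs)
    best_loss <- Inf
    best_params <- NULL
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(train_set))
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        gacc <- NULL
        for (i in idx) {
          p <- train_set[[i]]
          fw <- edgenet_forward_full(net, p$image)
          lv <- loss_value(config$loss_name, fw$prob, p$mask,
                           average = config$average_loss)
          if (!is.finite(lv))
            stop(sprintf("non-finite loss (%s) at epoch %d; try a lower learning rate",
                         config$loss_name, ep), call. = FALSE)
          dz <- loss_grad_logit(config$loss_name, fw$prob, p$mask,
                                average = config$average_loss)
          g <- grads_flat(net, edgenet_backward(net, fw$caches, dz))
          gacc <- if (is.null(gacc)) g else Map(`+`, gacc, g)
        }
        gacc <- lapply(gacc, function(g) g / length(idx))
        st <- adam_step(net_flat_params(net), gacc, opt, lr = config$learning_rate)
        opt <- st$state
        net <- net_set_flat_params(net, st$params)
      }
      # post-epoch training loss: the quantity logged and used for
      # checkpoint selection, measured with the epoch's final parameters
      history[ep] <- mean(vapply(train_set, function(p)
        loss_value(config$loss_name, edgenet_forward(net, p$image), p$mask,
                   average = config$average_loss), 0))
      if (!is.finite(history[ep]))
        stop(sprintf("non-finite loss (%s) at epoch %d; try a lower learning rate",
                     config$loss_name, ep), call. = FALSE)
      if ((config$keep %||% "best") == "best" && history[ep] < best_loss) {
        best_loss <- history[ep]
        best_params <- net_flat_params(net)
      }
    }
    if (!is.null(best_params)) net <- net_set_flat_params(net, best_params)
    structure(list(net = net, config = config, loss = history,
                   train_idx = train_idx, val_idx = val_idx,
                   kept_epoch = if (is.null(best_params)) config$epochs
                                else which.min(history)),
              class = "edgenet_fit")
  })
}

#' @export
print.edgenet_fit <- function(x, ...) {
  cat(sprintf("<edgenet_fit> %s loss, ROI %d, %d epochs (final loss %.4g)\n",
              x$config$loss_name, x$config$roi_size, x$config$epochs,
              x$loss[length(x$loss)]))
  invisible(x)
}

#' @export
predict.edgenet_fit <- function(object, image, ...) {
  predict(object$net, image, ...)
}

#' Evaluate a fitted model on slices
#'
#' Runs the forward pass on each (normalized, cropped) slice, binarizes at
#' `threshold` and scores against the gold masks.
#'
#' @param fit An `"edgenet_fit"`.
#' @param pairs List of [slice_pair()]s; defaults handled by caller.
#' @param threshold Binarization cut point.
#' @return List with per-case `preds`, `golds` and the [evaluate_dataset()]
#'   table.
#' @export
evaluate_model <- function(fit, pairs, threshold = 0.5) {
  prepped <- prep_pairs(pairs, fit$config$roi_size)
  preds <- lapply(prepped, function(p)
    binarize(edgenet_forward(fit$net, p$image), threshold))
  golds <- lapply(prepped, function(p) p$mask)
  list(preds = preds, golds = golds,
       table = evaluate_dataset(preds, golds))
}

#' Loss x ROI-size experiment grid
#'
#' Trains one network per (loss, ROI size) combination on the same dataset
#' and scores each on its held-out split, reproducing the experiment design
#' in which nine networks (3 losses x 3 sizes) are compared. Cell failures
#' are recorded in the `error` column rather than dropped.
#'
#' @param losses Character vector of loss names.
#' @param sizes Integer vector of ROI sizes.
#' @param data A `"phantom_dataset"` whose slices are at least as large as
#'   `max(sizes)`.
#' @param base_config A [train_config()] template supplying epochs, batch
#'   size, learning rate and seed for every cell.
#' @return A `"grid_result"` data frame: one row per combination with mean
#'   DSC/Se/Sp (percent), HD (pixels) and any error message.
#' @export
run_loss_roi_grid <- function(losses = c("cbce", "ce", "dice"),
                              sizes = c(96L, 192L, 320L),
                              data,
                              base_config = train_config()) {
  rows <- list()
  for (loss in losses) {
    for (size in sizes) {
      cfg <- base_config
      cfg$loss_name <- loss
      cfg$roi_size <- as.integer(size)
      cfg$network <- NULL
      res <- tryCatch({
        fit <- train_model(cfg, data)
        ev <- evaluate_model(fit,
                             (if (inherits(data, "phantom_dataset")) data$pairs
                              else data)[fit$val_idx])
        tb <- ev$table
        data.frame(loss_name = loss, roi_size = size,
                   dsc = tb$mean[tb$metric == "dsc"],
                   se = tb$mean[tb$metric == "se"],
                   sp = tb$mean[tb$metric == "sp"],
                   hd = tb$mean[tb$metric == "hd"],
                   error = NA_character_, stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(loss_name = loss, roi_size = size, dsc = NA_real_,
                   se = NA_real_, sp = NA_real_, hd = NA_real_,
                   error = conditionMessage(e), stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("grid_result", class(out))
  out
}

#' Compare segmentation systems on the same cases
#'
#' Produces a results-table-shaped report: per-system mean +/- sd of DSC, Se,
#' Sp (percent) and HD, plus pairwise differences of means. Systems may be
#' given either as lists of predicted masks (scored against `golds`) or as
#' precomputed per-case score data frames with columns `dsc`, `se`, `sp`,
#' `hd` (already on the reported scale).
#'
#' @param model_outputs Named list of >= 2 systems.
#' @param golds Gold-standard masks (required when systems are mask lists).
#' @return List of class `"model_comparison"` with `per_system` (metric table
#'   per system) and `differences` (pairwise mean differences, first minus
#'   second).
#' @export
compare_models <- function(model_outputs, golds = NULL) {
  if (length(model_outputs) < 2L) stop("need at least two systems", call. = FALSE)
  if (is.null(names(model_outputs)))
    names(model_outputs) <- paste0("system", seq_along(model_outputs))
  per_system <- lapply(model_outputs, function(sys) {
    if (is.data.frame(sys)) {
      rows <- lapply(c("dsc", "se", "sp", "hd"), function(m) {
        v <- sys[[m]]
        data.frame(metric = m, mean = mean(v),
                   sd = if (length(v) > 1) sd(v) else 0,
                   n = length(v), stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, rows)
      out$display <- sprintf("%.2f ± %.2f", out$mean, out$sd)
      out
    } else {
      if (is.null(golds)) stop("`golds` required for mask inputs", call. = FALSE)
      if (length(sys) != length(golds))
        stop("case mismatch between system outputs and golds", call. = FALSE)
      evaluate_dataset(sys, golds)
    }
  })
  nm <- names(per_system)
  diffs <- list()
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i == j) next
    a <- per_system[[i]]; b <- per_system[[j]]
    diffs[[paste(nm[i], "-", nm[j])]] <-
      data.frame(metric = a$metric, difference = a$mean - b$mean,
                 stringsAsFactors = FALSE)
  }
  structure(list(per_system = per_system, differences = diffs),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  for (nm in names(x$per_system)) {
    cat(nm, ":\n")
    print(x$per_system[[nm]][, c("metric", "display")], row.names = FALSE)
  }
  for (nm in names(x$differences)) {
    cat("difference", nm, ":\n")
    print(x$differences[[nm]], row.names = FALSE)
  }
  invisible(x)
}
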