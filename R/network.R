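# The edge-output segmentation network: a truncated residual backbone with
# three side branches ("edge output modules") tapping intermediate stages,
# each reducing channels then upsampling to input resolution with a
# transposed convolution, fused and classified by a two-convolution head with
# a sigmoid per-pixel output.
#
# Two backbones are available: "resnet50" (bottleneck blocks 1-13, i.e. the
# standard 16-block layout with the last three stride-32 blocks, global pool
# and fully connected layer removed; taps at blocks 3, 7, 13 = ends of the
# stride-4/8/16 stages) and "reduced", a shallow basic-block backbone with
# the same three-tap structure at desk scale.

#' Network configuration
#'
#' @param backbone `"reduced"` (shallow basic-block backbone, default) or
#'   `"resnet50"` (bottleneck blocks with the stride-32 stage truncated).
#' @param input_size Input side length in pixels (must be divisible by the
#'   deepest tap stride: 16 for `resnet50`, 4 for `reduced`).
#' @param tap_points Strictly increasing residual-block indices carrying edge
#'   outputs; defaults `(3, 7, 13)` for `resnet50` and `(2, 4, 6)` for
#'   `reduced`. All taps must precede the truncation point.
#' @param reduction_channels Channels after the per-branch reduction
#'   convolution (default 128 for `resnet50`, 16 for `reduced`).
#' @param head_channels Channel counts of the two fusion convolutions; the
#'   second must be 1 (the probability map).
#' @param widths Stage widths of the `reduced` backbone.
#' @param blocks_per_stage Blocks per stage of the `reduced` backbone.
#' @param pretrained Hook for initialising the backbone from stored weights;
#'   no weights ship with the package, so `TRUE` falls back to random
#'   initialisation with a warning.
#' @param seed Seed for weight initialisation.
#' @return An object of class `"network_config"`.
#' @export
network_config <- function(backbone = c("reduced", "resnet50"),
                           input_size = 96L,
                           tap_points = NULL,
                           reduction_channels = NULL,
                           head_channels = NULL,
                           widths = c(8L, 16L, 32L),
                           blocks_per_stage = c(2L, 2L, 2L),
                           pretrained = FALSE,
                           seed = 1L) {
  backbone <- match.arg(backbone)
  input_size <- as.integer(input_size)
  if (backbone == "resnet50") {
    blocks_per_stage <- c(3L, 4L, 6L)
    tap_points <- tap_points %||% c(3L, 7L, 13L)
    reduction_channels <- reduction_channels %||% 128L
    head_channels <- head_channels %||% c(64L, 1L)
    deepest <- 16L
  } else {
    tap_points <- tap_points %||% cumsum(blocks_per_stage)
    reduction_channels <- reduction_channels %||% 16L
    head_channels <- head_channels %||% c(16L, 1L)
    deepest <- 4L
  }
  n_blocks <- sum(blocks_per_stage)
  tap_points <- as.integer(tap_points)
  if (any(diff(tap_points) <= 0))
    stop("tap_points must be strictly increasing", call. = FALSE)
  if (max(tap_points) > n_blocks)
    stop(sprintf("tap index %d beyond truncation point (%d blocks)",
                 max(tap_points), n_blocks), call. = FALSE)
  if (reduction_channels < 1L) stop("reduction_channels must be >= 1", call. = FALSE)
  if (length(head_channels) != 2L || head_channels[2] != 1L)
    stop("head_channels must be two counts ending in 1", call. = FALSE)
  if (input_size %% deepest != 0L)
    stop(sprintf("input_size must be divisible by %d for backbone '%s'",
                 deepest, backbone), call. = FALSE)
  structure(list(backbone = backbone, input_size = input_size,
                 tap_points = tap_points,
                 reduction_channels = as.integer(reduction_channels),
                 head_channels = as.integer(head_channels),
                 widths = as.integer(widths),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 pretrained = isTRUE(pretrained), seed = as.integer(seed)),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> %s, input %dx%d, taps (%s), reduction %d\n",
              x$backbone, x$input_size, x$input_size,
              paste(x$tap_points, collapse = ", "), x$reduction_channels))
  invisible(x)
}

# Per-block stage membership, stride and channel bookkeeping.
backbone_plan <- function(config) {
  bps <- config$blocks_per_stage
  stage_of <- rep(seq_along(bps), bps)
  if (config$backbone == "resnet50") {
    mids <- c(64L, 128L, 256L); outs <- c(256L, 512L, 1024L)
    stem_out <- 64L
    stem_stride <- 4L                       # 7x7/2 conv + 3x3/2 maxpool
    stage_stride_in <- c(1L, 2L, 2L)        # stride of first block per stage
  } else {
    mids <- config$widths; outs <- config$widths
    stem_out <- config$widths[1]
    stem_stride <- 1L
    stage_stride_in <- c(1L, 2L, 2L)
  }
  n <- sum(bps)
  first_of_stage <- c(1L, head(cumsum(bps), -1) + 1L)
  plan <- vector("list", n)
  cin <- stem_out
  cum_stride <- stem_stride
  for (i in seq_len(n)) {
    s <- stage_of[i]
    stride <- if (i %in% first_of_stage) stage_stride_in[s] else 1L
    cum_stride <- cum_stride * stride
    plan[[i]] <- list(stage = s, stride = stride, cin = cin,
                      mid = mids[s], cout = outs[s], cum_stride = cum_stride)
    cin <- outs[s]
  }
  list(blocks = plan, stem_out = stem_out, stem_stride = stem_stride,
       bottleneck = config$backbone == "resnet50")
}

#' Build the edge-output network
#'
#' Constructs all trainable parameters: backbone stem and residual blocks,
#' one edge branch per tap point (1x1 channel reduction + bilinear-initialised
#' transposed-convolution upsampling to input resolution), and the
#' two-convolution fusion head.
#'
#' @param config A [network_config()].
#' @return An object of class `"edgenet"`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  if (config$pretrained)
    warning("no pretrained backbone weights are bundled; using random initialisation")
  plan <- backbone_plan(config)
  with_seed(config$seed, {
    L <- list()
    if (config$backbone == "resnet50") {
      L[["stem.conv"]] <- new_conv(1L, plan$stem_out, k = 7L, stride = 2L)
      L[["stem.pool"]] <- new_maxpool(3L, 2L)
    } else {
      L[["stem.conv"]] <- new_conv(1L, plan$stem_out, k = 3L, stride = 1L)
    }
    for (i in seq_along(plan$blocks)) {
      p <- plan$blocks[[i]]
      nm <- paste0("block", i)
      if (plan$bottleneck) {
        L[[paste0(nm, ".conv1")]] <- new_conv(p$cin, p$mid, k = 1L)
        L[[paste0(nm, ".conv2")]] <- new_conv(p$mid, p$mid, k = 3L, stride = p$stride)
        L[[paste0(nm, ".conv3")]] <- new_conv(p$mid, p$cout, k = 1L)
      } else {
        L[[paste0(nm, ".conv1")]] <- new_conv(p$cin, p$cout, k = 3L, stride = p$stride)
        L[[paste0(nm, ".conv2")]] <- new_conv(p$cout, p$cout, k = 3L)
      }
      if (p$stride != 1L || p$cin != p$cout)
        L[[paste0(nm, ".proj")]] <- new_conv(p$cin, p$cout, k = 1L, stride = p$stride,
                                             gain = 1)
    }
    rc <- config$reduction_channels
    for (bi in seq_along(config$tap_points)) {
      tp <- config$tap_points[bi]
      p <- plan$blocks[[tp]]
      nm <- paste0("branch", bi)
      L[[paste0(nm, ".reduce")]] <- new_conv(p$cout, rc, k = 1L)
      if (p$cum_stride > 1L)
        L[[paste0(nm, ".up")]] <- new_convt(rc, rc, factor = p$cum_stride)
    }
    # two 1x1 fusion convolutions: dimensionality reduction of the fused
    # multi-scale features down to the single-channel segmentation output
    hc <- config$head_channels
    L[["head.conv1"]] <- new_conv(rc * length(config$tap_points), hc[1], k = 1L)
    L[["head.conv2"]] <- new_conv(hc[1], 1L, k = 1L, gain = 1)
    structure(list(config = config, layers = L, plan = plan),
              class = "edgenet")
  })
}

#' @export
print.edgenet <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(paste0("<edgenet> %s backbone, %d residual blocks, ",
                     "%d edge branches (%d channels), %d-conv head, %d parameters\n"),
              x$config$backbone, s$n_blocks, s$n_branches,
              s$reduction_channels[1], s$head_convs, s$n_parameters))
  invisible(x)
}

#' Structural audit of a built network
#'
#' Walks the parameter graph and reports branch count, post-reduction channel
#' widths, head convolution count, block count and total parameter count.
#'
#' @param net An `"edgenet"`.
#' @return A list of structural facts.
#' @export
network_summary <- function(net) {
  nms <- names(net$layers)
  branches <- grep("^branch[0-9]+\\.reduce$", nms, value = TRUE)
  list(n_blocks = length(unique(sub("\\..*$", "", grep("^block", nms, value = TRUE)))),
       n_branches = length(branches),
       reduction_channels = vapply(net$layers[branches], function(l) l$cout, 1L),
       upsample_factors = vapply(seq_along(branches), function(bi) {
         up <- net$layers[[paste0("branch", bi, ".up")]]
         if (is.null(up)) 1L else up$stride
       }, 1L),
       head_convs = length(grep("^head\\.conv", nms)),
       n_parameters = sum(vapply(net$layers, function(l)
         length(l$W %||% numeric(0)) + length(l$b %||% numeric(0)), 0)))
}

block_forward <- function(net, i, x) {
  L <- net$layers
  nm <- paste0("block", i)
  cache <- list()
  if (net$plan$bottleneck) {
    c1 <- conv_forward(L[[paste0(nm, ".conv1")]], x); cache$c1 <- c1$cache
    r1 <- relu_forward(c1$out); cache$r1 <- r1$cache
    c2 <- conv_forward(L[[paste0(nm, ".conv2")]], r1$out); cache$c2 <- c2$cache
    r2 <- relu_forward(c2$out); cache$r2 <- r2$cache
    c3 <- conv_forward(L[[paste0(nm, ".conv3")]], r2$out); cache$c3 <- c3$cache
    main <- c3$out
  } else {
    c1 <- conv_forward(L[[paste0(nm, ".conv1")]], x); cache$c1 <- c1$cache
    r1 <- relu_forward(c1$out); cache$r1 <- r1$cache
    c2 <- conv_forward(L[[paste0(nm, ".conv2")]], r1$out); cache$c2 <- c2$cache
    main <- c2$out
  }
  pj <- L[[paste0(nm, ".proj")]]
  if (!is.null(pj)) {
    pr <- conv_forward(pj, x); cache$proj <- pr$cache
    short <- pr$out
  } else short <- x
  ro <- relu_forward(main + short); cache$rout <- ro$cache
  list(out = ro$out, cache = cache)
}

block_backward <- function(net, i, cache, dout, grads) {
  L <- net$layers
  nm <- paste0("block", i)
  d <- relu_backward(cache$rout, dout)
  # shortcut path
  pj <- L[[paste0(nm, ".proj")]]
  if (!is.null(pj)) {
    bwp <- conv_backward(pj, cache$proj, d)
    grads[[paste0(nm, ".proj")]] <- bwp$grads
    dshort <- bwp$dx
  } else dshort <- d
  # main path
  if (net$plan$bottleneck) {
    bw3 <- conv_backward(L[[paste0(nm, ".conv3")]], cache$c3, d)
    grads[[paste0(nm, ".conv3")]] <- bw3$grads
    d2 <- relu_backward(cache$r2, bw3$dx)
    bw2 <- conv_backward(L[[paste0(nm, ".conv2")]], cache$c2, d2)
    grads[[paste0(nm, ".conv2")]] <- bw2$grads
    d1 <- relu_backward(cache$r1, bw2$dx)
    bw1 <- conv_backward(L[[paste0(nm, ".conv1")]], cache$c1, d1)
    grads[[paste0(nm, ".conv1")]] <- bw1$grads
    dmain <- bw1$dx
  } else {
    bw2 <- conv_backward(L[[paste0(nm, ".conv2")]], cache$c2, d)
    grads[[paste0(nm, ".conv2")]] <- bw2$grads
    d1 <- relu_backward(cache$r1, bw2$dx)
    bw1 <- conv_backward(L[[paste0(nm, ".conv1")]], cache$c1, d1)
    grads[[paste0(nm, ".conv1")]] <- bw1$grads
    dmain <- bw1$dx
  }
  list(dx = dmain + dshort, grads = grads)
}

edgenet_forward_full <- function(net, image) {
  cfg <- net$config
  L <- net$layers
  image <- as.matrix(image)
  if (nrow(image) != cfg$input_size || ncol(image) != cfg$input_size)
    stop(sprintf("input is %dx%d but the network expects %dx%d",
                 nrow(image), ncol(image), cfg$input_size, cfg$input_size),
         call. = FALSE)
  caches <- list()
  x <- array(image, dim = c(dim(image), 1L))
  cv <- conv_forward(L[["stem.conv"]], x); caches[["stem.conv"]] <- cv$cache
  r <- relu_forward(cv$out); caches[["stem.relu"]] <- r$cache
  h <- r$out
  if (!is.null(L[["stem.pool"]])) {
    mp <- maxpool_forward(L[["stem.pool"]], h)
    caches[["stem.pool"]] <- mp$cache
    h <- mp$out
  }
  n_blocks <- length(net$plan$blocks)
  taps <- list()
  for (i in seq_len(n_blocks)) {
    fb <- block_forward(net, i, h)
    caches[[paste0("block", i)]] <- fb$cache
    h <- fb$out
    if (i %in% cfg$tap_points) taps[[as.character(i)]] <- h
    if (i == max(cfg$tap_points)) break  # layers past the last tap are unused
  }
  rc <- cfg$reduction_channels
  fused <- array(0, dim = c(cfg$input_size, cfg$input_size,
                            rc * length(cfg$tap_points)))
  for (bi in seq_along(cfg$tap_points)) {
    nm <- paste0("branch", bi)
    t <- taps[[as.character(cfg$tap_points[bi])]]
    cv <- conv_forward(L[[paste0(nm, ".reduce")]], t)
    caches[[paste0(nm, ".reduce")]] <- cv$cache
    r <- relu_forward(cv$out); caches[[paste0(nm, ".relu")]] <- r$cache
    u <- r$out
    up <- L[[paste0(nm, ".up")]]
    if (!is.null(up)) {
      ct <- convt_forward(up, u); caches[[paste0(nm, ".up")]] <- ct$cache
      u <- ct$out
    }
    fused[, , (bi - 1L) * rc + seq_len(rc)] <- u
  }
  cv1 <- conv_forward(L[["head.conv1"]], fused); caches[["head.conv1"]] <- cv1$cache
  hr <- relu_forward(cv1$out); caches[["head.relu"]] <- hr$cache
  cv2 <- conv_forward(L[["head.conv2"]], hr$out); caches[["head.conv2"]] <- cv2$cache
  z <- cv2$out[, , 1]
  list(prob = sigmoid(z), logit = z, caches = caches)
}

# dlogit: gradient of the loss w.r.t. the pre-sigmoid logit (H x W matrix).
edgenet_backward <- function(net, caches, dlogit) {
  cfg <- net$config
  L <- net$layers
  grads <- list()
  d <- array(dlogit, dim = c(dim(dlogit), 1L))
  bw <- conv_backward(L[["head.conv2"]], caches[["head.conv2"]], d)
  grads[["head.conv2"]] <- bw$grads
  d <- relu_backward(caches[["head.relu"]], bw$dx)
  bw <- conv_backward(L[["head.conv1"]], caches[["head.conv1"]], d)
  grads[["head.conv1"]] <- bw$grads
  dconcat <- bw$dx
  rc <- cfg$reduction_channels
  tap_grads <- list()
  for (bi in seq_along(cfg$tap_points)) {
    nm <- paste0("branch", bi)
    d <- dconcat[, , (bi - 1L) * rc + seq_len(rc), drop = FALSE]
    up <- L[[paste0(nm, ".up")]]
    if (!is.null(up)) {
      bwu <- convt_backward(up, caches[[paste0(nm, ".up")]], d)
      grads[[paste0(nm, ".up")]] <- bwu$grads
      d <- bwu$dx
    }
    d <- relu_backward(caches[[paste0(nm, ".relu")]], d)
    bwr <- conv_backward(L[[paste0(nm, ".reduce")]], caches[[paste0(nm, ".reduce")]], d)
    grads[[paste0(nm, ".reduce")]] <- bwr$grads
    key <- as.character(cfg$tap_points[bi])
    tap_grads[[key]] <- if (is.null(tap_grads[[key]])) bwr$dx else tap_grads[[key]] + bwr$dx
  }
  d <- NULL  # gradient w.r.t. output of current block
  for (i in rev(seq_len(max(cfg$tap_points)))) {
    tg <- tap_grads[[as.character(i)]]
    if (!is.null(tg)) d <- if (is.null(d)) tg else d + tg
    bb <- block_backward(net, i, caches[[paste0("block", i)]], d, grads)
    grads <- bb$grads
    d <- bb$dx
  }
  if (!is.null(L[["stem.pool"]]))
    d <- maxpool_backward(L[["stem.pool"]], caches[["stem.pool"]], d)$dx
  d <- relu_backward(caches[["stem.relu"]], d)
  bw <- conv_backward(L[["stem.conv"]], caches[["stem.conv"]], d)
  grads[["stem.conv"]] <- bw$grads
  grads
}

#' Forward pass: per-pixel tumor probabilities
#'
#' @param net An `"edgenet"` from [build_network()] or [train_model()].
#' @param image Normalized intensity matrix of the configured input size.
#' @return Probability matrix in `[0, 1]`, same shape as the input.
#' @export
edgenet_forward <- function(net, image) {
  stopifnot(inherits(net, "edgenet"))
  edgenet_forward_full(net, image)$prob
}

#' @export
predict.edgenet <- function(object, image, type = c("prob", "mask"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  p <- edgenet_forward(object, image)
  if (type == "mask") binarize(p, threshold) else p
}

#' Threshold a probability map into a binary mask
#'
#' @param map Probability matrix in `[0, 1]`.
#' @param threshold Cut point in `(0, 1)`; pixels with `map >= threshold`
#'   become 1. Idempotent on already-binary input for the default 0.5.
#' @return Binary matrix.
#' @export
binarize <- function(map, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)", call. = FALSE)
  (as.matrix(map) >= threshold) + 0
}

#' Save / load a model checkpoint
#'
#' One serialized file embedding the [network_config()] and all parameters;
#' reloading reproduces forward outputs bitwise.
#'
#' @param net An `"edgenet"`.
#' @param path Checkpoint file path.
#' @return `path` invisibly (`save_checkpoint`); the `"edgenet"`
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "edgenet"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "edgenet"))
  net
}

# Flatten trainable parameters to a named list of arrays (and back).
net_flat_params <- function(net) {
  out <- list()
  for (nm in names(net$layers)) {
    l <- net$layers[[nm]]
    if (!is.null(l$W)) {
      out[[paste0(nm, ".W")]] <- l$W
      out[[paste0(nm, ".b")]] <- l$b
    }
  }
  out
}

net_set_flat_params <- function(net, flat) {
  for (nm in names(net$layers)) {
    if (!is.null(net$layers[[nm]]$W)) {
      net$layers[[nm]]$W <- flat[[paste0(nm, ".W")]]
      net$layers[[nm]]$b <- flat[[paste0(nm, ".b")]]
    }
  }
  net
}

grads_flat <- function(net, grads) {
  out <- list()
  for (nm in names(net$layers)) {
    l <- net$layers[[nm]]
    if (!is.null(l$W)) {
      g <- grads[[nm]]
      out[[paste0(nm, ".W")]] <- if (is.null(g)) l$W * 0 else g$W
      out[[paste0(nm, ".b")]] <- if (is.null(g)) l$b * 0 else g$b
    }
  }
  out
}
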