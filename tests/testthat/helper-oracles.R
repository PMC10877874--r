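# Independent brute-force oracles used to check the fast implementations.
# Everything here is written as plainly as possible (explicit double loops),
# deliberately sharing no code with the package internals.

bf_confusion <- function(pred, gold) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j]; g <- gold[i, j]
    if (p == 1 && g == 1) tp <- tp + 1L
    else if (p == 1 && g == 0) fp <- fp + 1L
    else if (p == 0 && g == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

bf_boundary <- function(mask) {
  pts <- NULL
  H <- nrow(mask); W <- ncol(mask)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] != 1) next
    edge <- i == 1 || i == H || j == 1 || j == W
    if (!edge) {
      nb <- c(mask[i - 1, j], mask[i + 1, j], mask[i, j - 1], mask[i, j + 1])
      edge <- any(nb == 0)
    }
    if (edge) pts <- rbind(pts, c(i, j))
  }
  pts
}

bf_hausdorff <- function(pred, gold) {
  P <- bf_boundary(pred); G <- bf_boundary(gold)
  directed <- function(A, B) {
    worst <- 0
    for (i in seq_len(nrow(A))) {
      best <- Inf
      for (j in seq_len(nrow(B)))
        best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
      worst <- max(worst, best)
    }
    worst
  }
  max(directed(P, G), directed(G, P))
}

bf_cbce <- function(pred, gold, eps = 1e-7) {
  n <- length(gold); npos <- sum(gold == 1)
  beta <- (n - npos) / n
  tot <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- min(max(pred[i, j], eps), 1 - eps)
    if (gold[i, j] == 1) tot <- tot - beta * log(p)
    else tot <- tot - (1 - beta) * log(1 - p)
  }
  tot
}

bf_ce <- function(pred, gold, eps = 1e-7) {
  tot <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- min(max(pred[i, j], eps), 1 - eps)
    tot <- tot - ifelse(gold[i, j] == 1, log(p), log(1 - p))
  }
  tot
}

bf_dice <- function(pred, gold, s = 1) {
  num <- 0; sp <- 0; sg <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    num <- num + pred[i, j] * gold[i, j]
    sp <- sp + pred[i, j]; sg <- sg + gold[i, j]
  }
  1 - (2 * num + s) / (sp + sg + s)
}

bf_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

bf_youden <- function(scores, y) {
  best <- list(j = -Inf, threshold = NA)
  for (t in sort(unique(c(scores, max(scores) + 1)))) {
    sens <- sum(scores >= t & y == 1) / sum(y == 1)
    spec <- sum(scores < t & y == 0) / sum(y == 0)
    if (sens + spec - 1 > best$j + 1e-12) {
      best <- list(j = sens + spec - 1, threshold = t, sens = sens, spec = spec)
    }
  }
  best
}

mask_centroid_for_test <- function(mask) {
  w <- which(mask == 1, arr.ind = TRUE)
  round(colMeans(w))
}

# small random binary mask with at least one positive and one negative pixel
random_mask <- function(n, p = 0.35) {
  m <- matrix(rbinom(n * n, 1, p), n, n)
  if (sum(m) == 0) m[sample(n^2, 1)] <- 1
  if (sum(m) == n^2) m[sample(n^2, 1)] <- 0
  m
}

# tiny network config for fast structural / determinism tests
tiny_net_config <- function(input_size = 32L, seed = 1L) {
  network_config("reduced", input_size = input_size, widths = c(4L, 8L, 16L),
                 seed = seed)
}

easy_phantoms <- function(N = 8, size = 64, seed = 11) {
  generate_phantom_dataset(
    phantom_spec(image_size = size, tumor_intensity_contrast = 0.6,
                 noise_sd = 0.05, seed = seed), N = N)
}
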