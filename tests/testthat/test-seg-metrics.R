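test_that("confusion counts are exact on constructed and random masks", {
  set.seed(1)
  gold <- random_mask(5)
  cc <- confusion_counts(gold, gold)
  expect_equal(cc$TP, sum(gold))
  expect_equal(cc$TN, 25 - sum(gold))
  expect_equal(cc$FP + cc$FN, 0)
  inv <- confusion_counts(1 - gold, gold)
  expect_equal(inv$TP + inv$TN, 0)
  for (seed in 1:10) {
    set.seed(seed)
    p <- random_mask(8); g <- random_mask(8)
    expect_equal(unclass(confusion_counts(p, g)), bf_confusion(p, g))
  }
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("DSC, sensitivity and specificity follow their formulas and policies", {
  expect_equal(dsc(list(TP = 2, FP = 1, FN = 1, TN = 0)), 2 / 3)
  expect_warning(v <- dsc(list(TP = 0, FP = 0, FN = 0, TN = 9)), "empty")
  expect_equal(v, 1)
  expect_equal(sensitivity(list(TP = 8, FN = 2, FP = 0, TN = 0)), 0.8)
  expect_equal(specificity(list(TN = 9, FP = 1, TP = 0, FN = 0)), 0.9)
  set.seed(2)
  g <- random_mask(6)
  cc <- confusion_counts(g, g)
  expect_equal(dsc(cc), 1)
  expect_equal(sensitivity(cc), 1)
  expect_equal(specificity(cc), 1)
  miss <- confusion_counts(g * 0, g)
  expect_equal(sensitivity(miss), 0)
  allpos <- confusion_counts(g * 0 + 1, g)
  expect_equal(specificity(allpos), 0)
  expect_error(sensitivity(confusion_counts(g, g * 0)), "undefined")
  expect_error(specificity(confusion_counts(g, g * 0 + 1)), "undefined")
})

test_that("DSC equals the harmonic mean of sensitivity and precision", {
  for (seed in 1:10) {
    set.seed(seed)
    cc <- confusion_counts(random_mask(8), random_mask(8))
    if (cc$TP == 0) next
    prec <- cc$TP / (cc$TP + cc$FP)
    se <- sensitivity(cc)
    expect_equal(dsc(cc), 2 * se * prec / (se + prec), tolerance = 1e-12)
  }
})

test_that("Hausdorff distance matches its definition on point masks and oracles", {
  g <- matrix(0, 8, 8); g[1, 1] <- 1
  p <- matrix(0, 8, 8); p[4, 5] <- 1          # offset (3, 4) -> distance 5
  expect_equal(hausdorff(p, g), 5)
  set.seed(3)
  m <- random_mask(8)
  expect_equal(hausdorff(m, m), 0)
  for (seed in 1:10) {
    set.seed(seed)
    a <- random_mask(10); b <- random_mask(10)
    h <- hausdorff(a, b)
    expect_equal(h, bf_hausdorff(a, b), tolerance = 1e-9)
    expect_equal(h, hausdorff(b, a))     # symmetry
  }
  expect_error(hausdorff(matrix(0, 3, 3), random_mask(3)), "empty")
})

test_that("Hausdorff distance is translation invariant", {
  base <- matrix(0, 12, 12); base[3:5, 3:6] <- 1
  other <- matrix(0, 12, 12); other[4:7, 5:7] <- 1
  h <- hausdorff(base, other)
  shift <- function(m, di, dj) {
    out <- matrix(0, 12, 12)
    w <- which(m == 1, arr.ind = TRUE)
    out[cbind(w[, 1] + di, w[, 2] + dj)] <- 1
    out
  }
  expect_equal(hausdorff(shift(base, 2, 3), shift(other, 2, 3)), h)
})

test_that("dataset evaluation reports mean and sample sd in results-table form", {
  set.seed(4)
  golds <- lapply(1:4, function(i) random_mask(10))
  tab <- evaluate_dataset(golds, golds)
  expect_equal(tab$mean[tab$metric == "dsc"], 100)
  expect_equal(tab$sd[tab$metric == "dsc"], 0)
  expect_equal(tab$mean[tab$metric == "hd"], 0)
  # sample-sd convention against stats::sd on hand-built scores
  preds <- list(golds[[1]], 1 - golds[[2]], golds[[3]], golds[[4]])
  tab2 <- evaluate_dataset(preds, golds)
  percase <- sapply(seq_along(preds), function(i)
    dsc(confusion_counts(preds[[i]], golds[[i]])) * 100)
  expect_equal(tab2$mean[tab2$metric == "dsc"], mean(percase))
  expect_equal(tab2$sd[tab2$metric == "dsc"], sd(percase))
  expect_error(evaluate_dataset(golds[1:2], golds), "length")
})

test_that("model comparison reproduces printed mean differences from degenerate scores", {
  # two systems given as per-case constant scores equal to published means
  unet <- data.frame(dsc = rep(67.59, 5), se = rep(83.52, 5),
                     sp = rep(91.20, 5), hd = rep(16.81, 5))
  prop <- data.frame(dsc = rep(83.62, 5), se = rep(89.11, 5),
                     sp = rep(96.37, 5), hd = rep(8.50, 5))
  cmp <- compare_models(list(proposed = prop, unet = unet))
  d <- cmp$differences[["proposed - unet"]]
  expect_equal(d$difference[d$metric == "dsc"], 16.03, tolerance = 1e-9)
  expect_equal(d$difference[d$metric == "se"], 5.59, tolerance = 1e-9)
  expect_equal(d$difference[d$metric == "sp"], 5.17, tolerance = 1e-9)
  expect_equal(d$difference[d$metric == "hd"], -8.31, tolerance = 1e-9)
  # antisymmetry under order swap
  d2 <- cmp$differences[["unet - proposed"]]
  expect_equal(d2$difference, -d$difference)
  # self comparison is all-zero
  self <- compare_models(list(a = prop, b = prop))
  expect_true(all(self$differences[["a - b"]]$difference == 0))
})
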