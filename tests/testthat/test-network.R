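test_that("the default architecture audit matches the specified structure", {
  net <- build_network(network_config("resnet50", input_size = 96, seed = 1))
  s <- network_summary(net)
  expect_equal(s$n_branches, 3L)
  expect_true(all(s$reduction_channels == 128L))
  expect_equal(s$head_convs, 2L)
  expect_equal(s$n_blocks, 13L)                 # last three residual blocks removed
  expect_equal(s$upsample_factors, c(4L, 8L, 16L))
})

test_that("tap points beyond the truncation point are a configuration error", {
  expect_error(network_config("resnet50", tap_points = c(3, 7, 14)), "truncation")
  expect_error(network_config("reduced", tap_points = c(2, 2, 4)), "increasing")
})

test_that("the forward pass returns a deterministic probability map of input shape", {
  cfg <- tiny_net_config(32, seed = 2)
  net <- build_network(cfg)
  set.seed(5)
  img <- matrix(runif(32 * 32), 32, 32)
  p1 <- edgenet_forward(net, img)
  expect_equal(dim(p1), c(32L, 32L))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, edgenet_forward(net, img))
  expect_error(edgenet_forward(net, matrix(0, 16, 16)), "32x32")
})

test_that("building twice with the same seed gives identical parameters", {
  n1 <- build_network(tiny_net_config(32, seed = 7))
  n2 <- build_network(tiny_net_config(32, seed = 7))
  expect_identical(n1, n2)
  n3 <- build_network(tiny_net_config(32, seed = 8))
  expect_false(identical(n1$layers[["stem.conv"]]$W, n3$layers[["stem.conv"]]$W))
})

test_that("a resnet50 forward pass also honours the probability contract", {
  net <- build_network(network_config("resnet50", input_size = 96, seed = 3))
  set.seed(1)
  p <- edgenet_forward(net, matrix(runif(96 * 96), 96, 96))
  expect_equal(dim(p), c(96L, 96L))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("checkpoint save/load round trip reproduces forward outputs bitwise", {
  net <- build_network(tiny_net_config(32, seed = 4))
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, f)
  net2 <- load_checkpoint(f)
  set.seed(2)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(edgenet_forward(net, img), edgenet_forward(net2, img))
})

test_that("binarization follows the threshold rule and is idempotent", {
  expect_equal(binarize(matrix(0.7, 2, 2), 0.5), matrix(1, 2, 2))
  expect_equal(binarize(matrix(c(0.49, 0.51), 1), 0.5), matrix(c(0, 1), 1))
  m <- matrix(c(0.2, 0.8, 0.5, 0.6), 2)
  expect_equal(binarize(binarize(m, 0.5), 0.5), binarize(m, 0.5))
  expect_error(binarize(m, 0), "threshold")
  expect_error(binarize(m, 1), "threshold")
})

test_that("analytic backpropagation matches numerical gradients", {
  cfg <- network_config("reduced", input_size = 8, widths = c(2, 3, 4),
                        blocks_per_stage = c(1, 1, 1), tap_points = c(1, 2, 3),
                        reduction_channels = 2, head_channels = c(3, 1), seed = 2)
  net <- build_network(cfg)
  set.seed(9)
  img <- matrix(runif(64), 8, 8)
  gold <- matrix(rbinom(64, 1, 0.3), 8, 8)
  fw <- ovadx:::edgenet_forward_full(net, img)
  dz <- ovadx:::loss_grad_logit("cbce", fw$prob, gold, average = TRUE)
  g <- ovadx:::grads_flat(net, ovadx:::edgenet_backward(net, fw$caches, dz))
  flat <- ovadx:::net_flat_params(net)
  lossfun <- function(n) cbce_loss(ovadx:::edgenet_forward_full(n, img)$prob,
                                   gold, average = TRUE)
  set.seed(1)
  for (nm in sample(names(flat), 10)) {
    i <- sample(length(flat[[nm]]), 1)
    eps <- 1e-6
    f1 <- flat; f1[[nm]][i] <- f1[[nm]][i] + eps
    f2 <- flat; f2[[nm]][i] <- f2[[nm]][i] - eps
    num <- (lossfun(ovadx:::net_set_flat_params(net, f1)) -
            lossfun(ovadx:::net_set_flat_params(net, f2))) / (2 * eps)
    expect_equal(g[[nm]][i], num, tolerance = 1e-5)
  }
})

test_that("bilinear-initialised upsampling interpolates a constant map exactly inside", {
  ct <- ovadx:::new_convt(1, 1, 2)
  out <- ovadx:::convt_forward(ct, array(1, c(4, 4, 1)))$out
  expect_equal(dim(out), c(8L, 8L, 1L))
  expect_true(all(abs(out[3:6, 3:6, 1] - 1) < 1e-12))  # interior preserved
})
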