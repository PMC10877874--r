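test_that("z-score standardization centers, scales and transfers to test rows", {
  x <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "a"))
  st <- zscore_standardize(x)
  expect_equal(as.numeric(st$z), c(-1, 0, 1))
  # training columns of a larger fit: mean ~0, sd ~1
  set.seed(1)
  X <- matrix(rnorm(200, mean = 5, sd = 2), 50, 4,
              dimnames = list(NULL, letters[1:4]))
  st <- zscore_standardize(X, fit_rows = 1:30)
  expect_lt(max(abs(colMeans(st$z[1:30, ]))), 1e-10)
  expect_equal(apply(st$z[1:30, ], 2, sd), rep(1, 4), ignore_attr = TRUE)
  # test rows use training parameters
  manual <- (X[31, ] - st$center) / st$scale
  expect_equal(st$z[31, ], manual)
  # idempotence
  st2 <- zscore_standardize(st$z, fit_rows = 1:30)
  expect_equal(st2$z, st$z, tolerance = 1e-12)
  # constant column policy
  Xc <- cbind(X, k = 1)
  expect_warning(stc <- zscore_standardize(Xc, fit_rows = 1:30), "constant")
  expect_true(all(stc$z[, "k"] == 0))
})

test_that("correlation PCA matches an independent solver and its algebraic facts", {
  set.seed(2)
  # two perfectly correlated features
  a <- rnorm(40)
  st <- zscore_standardize(cbind(x = a, y = 2 * a + 3))
  pm <- fit_pca(st, n_selected = 1)
  expect_equal(pm$values, c(2, 0), tolerance = 1e-10)
  # general case: eigenvalues sum to the trace, loadings match prcomp up to sign
  set.seed(3)
  X <- matrix(rnorm(300), 60, 5, dimnames = list(NULL, paste0("v", 1:5)))
  st <- zscore_standardize(X)
  pm <- fit_pca(st)
  expect_equal(sum(pm$values), 5, tolerance = 1e-10)
  ref <- prcomp(st$z, center = FALSE, scale. = FALSE)
  for (k in 1:5) {
    v1 <- pm$vectors[, k]; v2 <- ref$rotation[, k]
    expect_equal(abs(sum(v1 * v2)), 1, tolerance = 1e-8)
  }
  # orthonormality and the sign convention
  expect_equal(crossprod(pm$vectors), diag(5), tolerance = 1e-10, ignore_attr = TRUE)
  for (k in 1:5) expect_gt(pm$vectors[which.max(abs(pm$vectors[, k])), k], 0)
})

test_that("full-rank PCA reconstruction reproduces the standardized matrix", {
  set.seed(4)
  X <- matrix(rnorm(240), 40, 6)
  colnames(X) <- paste0("v", 1:6)
  st <- zscore_standardize(X)
  pm <- fit_pca(st)
  recon <- st$z %*% pm$vectors %*% t(pm$vectors)
  expect_lt(max(abs(recon - st$z)), 1e-8)
})

test_that("projected scores have eigenvalue variance and are uncorrelated", {
  co <- generate_cohort(cohort_spec(seed = 6))
  st <- zscore_standardize(co)
  pm <- fit_pca(st)
  sc <- project_scores(pm, st)
  expect_equal(ncol(sc), 3L)
  expect_equal(apply(sc, 2, var), pm$values[1:3], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(abs(cor(sc[, 1], sc[, 2])), 1e-8)
  expect_equal(as.numeric(matrix(0, 1, 25) %*% pm$vectors[, 1:3]), rep(0, 3))
  bad <- st; colnames(bad$z)[1] <- "XXX"
  expect_error(project_scores(pm, bad), "XXX")
})

test_that("the stratified split reproduces the published case allocation", {
  co <- generate_cohort(cohort_spec(seed = 5))
  sp <- stratified_split(co, seed = 11)
  cnt <- sp$counts
  expect_equal(cnt$n_train[cnt$stratum == "case"], 123L)
  expect_equal(cnt$n_test[cnt$stratum == "case"], 62L)
  # disjoint and exhaustive
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), seq_len(nrow(co)))
  # floor rule per stratum
  for (r in seq_len(nrow(cnt)))
    expect_equal(cnt$n_train[r], floor(2 / 3 * cnt$n[r]))
  # reproducible
  sp2 <- stratified_split(co, seed = 11)
  expect_identical(sp$train_ids, sp2$train_ids)
  sp3 <- stratified_split(co, seed = 12)
  expect_false(identical(sp$train_ids, sp3$train_ids))
})

test_that("the GA-optimised BP classifier separates a separable toy problem", {
  set.seed(21)
  n <- 120
  X <- rbind(cbind(rnorm(n, -2), rnorm(n, -2)), cbind(rnorm(n, 2), rnorm(n, 2)))
  y <- rep(c(0, 1), each = n)
  hold <- sample(nrow(X), 60)
  ga <- ga_config(population_size = 20, generations = 15,
                  hidden_size_range = c(2, 6), fine_tune_steps = 100, seed = 3)
  net <- ga_optimize_bp(X[-hold, ], y[-hold], ga)
  acc <- mean((predict_scores(net, X[hold, ]) >= 0.5) == (y[hold] == 1))
  expect_gte(acc, 0.95)
  # structural contracts
  expect_true(net$hidden_size >= 2 && net$hidden_size <= 6)
  expect_true(all(diff(net$history) <= 1e-12))  # elitism: error never worsens
  expect_error(ga_optimize_bp(X, rep(1, nrow(X)), ga), "single class")
})

test_that("BP predictions obey the [0,1] contract and the closed form", {
  net <- structure(list(W1 = matrix(c(0.5, -1), 2, 1), b1 = 0.2,
                        W2 = matrix(2, 1, 1), b2 = -1, hidden_size = 1L,
                        activation = "logistic", history = 0),
                   class = "bp_net")
  x <- c(0.3, 0.7)
  h <- 1 / (1 + exp(-(0.5 * 0.3 - 1 * 0.7 + 0.2)))
  expect_equal(predict_scores(net, matrix(x, 1)), 1 / (1 + exp(-(2 * h - 1))),
               tolerance = 1e-10)
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2)
  ga <- ga_config(population_size = 10, generations = 3,
                  hidden_size_range = c(2, 4), fine_tune_steps = 10, seed = 1)
  net2 <- ga_optimize_bp(X, rep(c(0, 1), 10), ga)
  p <- predict_scores(net2, X)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(predict_scores(net2, X[c(1, 1), ])[1],
               predict_scores(net2, X[c(1, 1), ])[2])
  expect_error(predict_scores(net2, matrix(0, 2, 5)), "features")
})

test_that("group mean profiles equal direct column averages", {
  co <- generate_cohort(cohort_spec(n_cases = 40L,
                                    n_controls_by_subgroup = c(20L, 20L, 10L),
                                    seed = 9))
  prof <- group_mean_profile(co)
  cases <- co$label == "case"
  expect_equal(prof$case_mean, as.numeric(colMeans(co[cases, 1:25])))
  expect_equal(prof$control_mean, as.numeric(colMeans(co[!cases, 1:25])))
  # identical groups give all-zero directions
  co2 <- co
  co2[!cases, 1:25] <- co2[cases, 1:25][seq_len(sum(!cases)) %% sum(cases) + 1, ]
  co3 <- rbind(co[cases, ], co[cases, ])
  co3$label[seq_len(sum(cases))] <- "control"
  expect_true(all(group_mean_profile(co3)$direction == 0))
  expect_error(group_mean_profile(co[cases, ]), "nonempty")
})
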