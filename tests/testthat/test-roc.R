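test_that("ROC handles perfect separation and degenerate ties", {
  y <- rep(c(1, 0), each = 5)
  r <- roc_curve(c(6:10, 1:5), y)
  expect_equal(r$auc, 1)
  expect_equal(r$youden_point$sensitivity, 1)
  expect_equal(r$youden_point$specificity, 1)
  expect_equal(roc_curve(rep(3, 10), y)$auc, 0.5)
  expect_error(roc_curve(1:5, rep(1, 5)), "both classes")
})

test_that("AUC equals the brute-force pairwise comparison statistic", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 25
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n, mean = y), 1)   # rounding forces ties
    expect_equal(roc_curve(s, y)$auc, bf_auc(s, y), tolerance = 1e-12)
  }
})

test_that("the Youden point matches an exhaustive threshold scan", {
  for (seed in 1:10) {
    set.seed(seed)
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(30, y), 1)
    r <- roc_curve(s, y)
    ref <- bf_youden(s, y)
    expect_equal(r$youden_point$youden, ref$j, tolerance = 1e-12)
    expect_equal(r$youden_point$threshold, ref$threshold)  # lowest-threshold tie-break
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(2)
  y <- rbinom(40, 1, 0.5)
  s <- rnorm(40, y)
  a <- roc_curve(s, y)$auc
  expect_equal(roc_curve(exp(s), y)$auc, a)
  expect_equal(roc_curve(2 * s - 7, y)$auc, a)
  # reversing scores complements the AUC
  expect_equal(roc_curve(-s, y)$auc, 1 - a)
})

test_that("the DeLong test is null on identical scores and antisymmetric", {
  set.seed(3)
  y <- rep(c(1, 0), each = 20)
  s <- rnorm(40, y)
  d0 <- delong_test(s, s, y)
  expect_equal(d0$z, 0)
  expect_equal(d0$p, 1)
  s2 <- rnorm(40, 0.5 * y)
  d1 <- delong_test(s, s2, y)
  d2 <- delong_test(s2, s, y)
  expect_equal(d1$z, -d2$z)
  expect_equal(d1$p, d2$p)
  expect_true(d1$p >= 0 && d1$p <= 1)
  expect_error(delong_test(s, s2[1:10], y), "paired")
})

test_that("the DeLong variance agrees with a paired bootstrap", {
  set.seed(7)
  n <- 120
  y <- rep(c(1, 0), each = n / 2)
  sig <- rnorm(n)
  a <- y + 0.8 * sig + 0.6 * rnorm(n)
  b <- 0.7 * y + 0.8 * sig + 0.6 * rnorm(n)
  dl <- delong_test(a, b, y)
  boot <- replicate(2000, {
    i <- c(sample(which(y == 1), n / 2, TRUE), sample(which(y == 0), n / 2, TRUE))
    roc_curve(a[i], y[i])$auc - roc_curve(b[i], y[i])$auc
  })
  expect_lt(abs(var(boot) - dl$var_diff) / dl$var_diff, 0.15)
})

test_that("the DeLong z agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  y <- rep(c(1, 0), each = 30)
  sig <- rnorm(60)
  a <- y + sig + 0.5 * rnorm(60)
  b <- 0.5 * y + sig + 0.5 * rnorm(60)
  dl <- delong_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE), method = "delong")
  expect_equal(abs(dl$z), abs(as.numeric(ref$statistic)), tolerance = 1e-8)
  expect_equal(dl$p, as.numeric(ref$p.value), tolerance = 1e-8)
})

test_that("partition-restricted evaluation composes single-class levels correctly", {
  set.seed(4)
  n <- 80
  y <- rep(c(1, 0), each = n / 2)
  s <- rnorm(n, y)
  # one partition covering everything reduces to the plain curve
  whole <- evaluate_by_partition(s, y, rep("all", n))
  expect_equal(whole$all$auc, roc_curve(s, y)$auc)
  # stage tags on cases only: each level is evaluated against all controls
  stage <- ifelse(y == 1, rep(c("early", "advanced"), n / 4), NA)
  by_stage <- evaluate_by_partition(s, y, stage)
  expect_setequal(names(by_stage), c("early", "advanced"))
  early_rows <- which(stage == "early" | y == 0)
  expect_equal(by_stage$early$auc, roc_curve(s[early_rows], y[early_rows])$auc)
  # a single-class partition that cannot be completed is skipped with a warning
  expect_warning(res <- evaluate_by_partition(s[y == 1], y[y == 1],
                                              rep("only", n / 2)),
                 "single class")
  expect_length(res, 0)
})
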