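test_that("phantom generation is deterministic and respects its geometry contracts", {
  sp <- phantom_spec(image_size = 64, tumor_shape = "ellipse", seed = 4)
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1, p2)
  expect_identical(dim(p1$image), dim(p1$mask))
  expect_true(all(p1$mask %in% c(0, 1)))
  expect_gt(sum(p1$mask), 0)
  expect_true(all(p1$image >= 0))
  # mask fully inside the frame: no positives on the border
  expect_equal(sum(p1$mask[c(1, 64), ]) + sum(p1$mask[, c(1, 64)]), 0)
})

test_that("ring phantoms have a hole inside the tumor bounding box", {
  for (seed in 1:5) {
    p <- generate_phantom(phantom_spec(image_size = 64, tumor_shape = "ring",
                                       seed = seed))
    w <- which(p$mask == 1, arr.ind = TRUE)
    box <- p$mask[min(w[, 1]):max(w[, 1]), min(w[, 2]):max(w[, 2])]
    expect_gt(sum(box == 0), 0)
  }
})

test_that("noise-free phantoms hit the requested tumor/background contrast", {
  for (shape in c("ellipse", "ring")) {
    p <- generate_phantom(phantom_spec(image_size = 64, tumor_shape = shape,
                                       tumor_intensity_contrast = 0.5,
                                       noise_sd = 0, seed = 2))
    diff <- mean(p$image[p$mask == 1]) - mean(p$image[p$mask == 0])
    expect_lt(abs(diff - 0.5), 0.05)
  }
})

test_that("invalid phantom shape names are rejected", {
  expect_error(phantom_spec(tumor_shape = "cube"))
  expect_error(phantom_spec(image_size = 16), "32")
})

test_that("phantom datasets honour N, shape mix, uniqueness and determinism", {
  sp <- phantom_spec(image_size = 48, seed = 9)
  ds <- generate_phantom_dataset(sp, N = 30, shape_mix = c(1, 1, 1) / 3)
  expect_equal(ds$N, 30)
  expect_equal(as.integer(table(ds$shape_class)[c("ellipse", "ring", "fuzzy")]),
               c(10L, 10L, 10L))
  ids <- vapply(ds$pairs, function(p) p$id, "")
  expect_equal(anyDuplicated(ids), 0L)
  expect_true(all(vapply(ds$pairs, function(p) sum(p$mask) > 0, TRUE)))
  ds2 <- generate_phantom_dataset(sp, N = 30, shape_mix = c(1, 1, 1) / 3)
  expect_identical(ds, ds2)
  expect_error(generate_phantom_dataset(sp, N = 0), "empty")
})

test_that("phantom export writes PNG pairs and a readable manifest", {
  dir <- withr::local_tempdir()
  ds <- generate_phantom_dataset(phantom_spec(image_size = 48, seed = 3), N = 3)
  man <- write_phantom_dataset(ds, dir)
  expect_true(all(file.exists(man$image_path)))
  expect_true(all(file.exists(man$mask_path)))
  man2 <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man2), 3)
  expect_setequal(names(man2), c("id", "image_path", "mask_path", "shape_class"))
  m <- png::readPNG(man$mask_path[1])
  expect_setequal(unique(as.numeric(m)), c(0, 1))  # {0,255} bytes -> {0,1}
  expect_equal((m > 0.5) + 0, ds$pairs[[1]]$mask, ignore_attr = TRUE)
})

test_that("synthetic cohorts reproduce the study sizes and the label contract", {
  spec <- cohort_spec(seed = 5)
  co <- generate_cohort(spec)
  expect_equal(nrow(co), 754)
  expect_equal(sum(co$label == "case"), 185)
  expect_equal(as.integer(table(co$subgroup)[c("other_malignant", "benign", "healthy")]),
               c(138L, 339L, 92L))
  expect_equal(co$label == "case", co$subgroup == "case")
  expect_false(anyNA(co))
  expect_equal(ncol(co), 30)  # 25 indicators + 3 demographics + label + subgroup
  expect_identical(names(co)[1:25], default_indicators())
  expect_identical(co, generate_cohort(spec))
})

test_that("null cohorts show no systematic case/control differences", {
  spec <- cohort_spec(case_effect_size = 0, noise_sd = 1, seed = 8)
  co <- generate_cohort(spec)
  prof <- group_mean_profile(co)
  expect_lt(max(abs(prof$case_mean - prof$control_mean)), 0.4)
  expect_true(any(prof$direction > 0) && any(prof$direction < 0))
})

test_that("default cohorts recover the five stated negative directions", {
  co <- generate_cohort(cohort_spec(seed = 5))
  prof <- group_mean_profile(co)
  expect_setequal(prof$indicator[prof$direction < 0],
                  c("E2", "P", "AGR", "PA", "TC"))
  expect_gt(prof$direction[prof$indicator == "CA125"], 0)
})

test_that("unknown indicators in the loadings are rejected by name", {
  L <- default_factor_loadings()
  rownames(L)[1] <- "NOT_AN_INDICATOR"
  expect_error(cohort_spec(latent_factor_loadings = L), "NOT_AN_INDICATOR")
})

test_that("cohort CSV round trip preserves the column roster and values", {
  co <- generate_cohort(cohort_spec(n_cases = 20L,
                                    n_controls_by_subgroup = c(10L, 10L, 5L),
                                    seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  co2 <- read_cohort_csv(f)
  expect_identical(names(co2), names(co))
  expect_equal(co2[, 1:25], co[, 1:25], tolerance = 1e-12)
})
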