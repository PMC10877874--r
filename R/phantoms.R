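# Synthetic T2W-like phantom slices ------------------------------------------
#
# Stands in for clinical MRI slices: an elliptical, ring-shaped or
# fuzzy-boundary "tumor" with a controlled intensity contrast over a textured
# background, plus additive Gaussian noise.  The three shape classes cover the
# difficulty regimes segmentation networks are judged on: clean boundary,
# topology with a hole, and a blurred demarcation line.

#' Phantom specification
#'
#' Describes one synthetic grayscale slice with a binary gold-standard tumor
#' mask. Intensities are in arbitrary units on roughly a `[0, 1]` scale before
#' noise.
#'
#' @param image_size Pixels per side of the square slice (>= 32).
#' @param tumor_shape One of `"ellipse"`, `"ring"`, `"fuzzy"`.
#' @param tumor_intensity_contrast Mean intensity offset between tumor and
#'   background before noise (dimensionless).
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param background_texture_scale Correlation length of the smooth background
#'   texture, in pixels.
#' @param tumor_axes_frac Range of the tumor's ellipse semi-axes as a
#'   fraction of the image side. The default scales the tumor with the
#'   image; pass a smaller range (e.g. `c(0.04, 0.08)` on a 320-pixel slice)
#'   to keep tumors at a fixed absolute size while the field of view grows,
#'   as in ROI-size experiments.
#' @param seed Integer seed; the only source of randomness.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(image_size = 96L,
                         tumor_shape = c("ellipse", "ring", "fuzzy"),
                         tumor_intensity_contrast = 0.5,
                         noise_sd = 0.1,
                         background_texture_scale = 8,
                         tumor_axes_frac = c(0.12, 0.22),
                         seed = 1L) {
  tumor_shape <- match.arg(tumor_shape)
  image_size <- as.integer(image_size)
  if (is.na(image_size) || image_size < 32L)
    stop("`image_size` must be an integer >= 32", call. = FALSE)
  if (tumor_intensity_contrast < 0) stop("contrast must be nonnegative", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  if (length(tumor_axes_frac) != 2L || any(tumor_axes_frac <= 0) ||
      tumor_axes_frac[1] > tumor_axes_frac[2] || tumor_axes_frac[2] > 0.4)
    stop("`tumor_axes_frac` must be an increasing range within (0, 0.4]", call. = FALSE)
  structure(list(image_size = image_size, tumor_shape = tumor_shape,
                 tumor_intensity_contrast = tumor_intensity_contrast,
                 noise_sd = noise_sd,
                 background_texture_scale = background_texture_scale,
                 tumor_axes_frac = tumor_axes_frac,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%d %s, contrast %.2f, noise %.2f, seed %d\n",
              x$image_size, x$image_size, x$tumor_shape,
              x$tumor_intensity_contrast, x$noise_sd, x$seed))
  invisible(x)
}

#' Slice/mask pair constructor
#'
#' @param image 2D nonnegative intensity matrix.
#' @param mask 2D binary matrix of identical shape (1 = tumor).
#' @param id Identifier string.
#' @return An object of class `"slice_pair"`.
#' @export
slice_pair <- function(image, mask, id = "slice") {
  image <- as.matrix(image); mask <- as.matrix(mask)
  if (!identical(dim(image), dim(mask)))
    stop("image and mask shapes differ", call. = FALSE)
  if (!all(mask %in% c(0, 1)))
    stop("mask must contain only 0/1 values", call. = FALSE)
  structure(list(image = image, mask = mask, id = as.character(id)),
            class = "slice_pair")
}

#' @export
print.slice_pair <- function(x, ...) {
  cat(sprintf("<slice_pair> '%s' %dx%d, %d tumor px (%.1f%%)\n", x$id,
              nrow(x$image), ncol(x$image), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

# Separable Gaussian blur as banded-matrix products; zero padding is
# corrected by dividing by the blurred all-ones image so borders keep their
# mean level.
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- exp(-((-r:r)^2) / (2 * sigma^2)); g <- g / sum(g)
  band <- function(n) {
    B <- matrix(0, n, n)
    idx <- abs(row(B) - col(B)) <= r
    B[idx] <- g[row(B)[idx] - col(B)[idx] + r + 1L]
    B
  }
  Bh <- band(nrow(x)); Bw <- band(ncol(x))
  (Bh %*% x %*% t(Bw)) / (Bh %*% matrix(1, nrow(x), ncol(x)) %*% t(Bw))
}

# Ellipse interior indicator for centre (ci, cj), semi-axes (a, b), angle th.
ellipse_mask <- function(n, ci, cj, a, b, th) {
  i <- matrix(seq_len(n), n, n) - ci         # row offsets
  j <- matrix(seq_len(n), n, n, byrow = TRUE) - cj
  u <- cos(th) * i + sin(th) * j
  v <- -sin(th) * i + cos(th) * j
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate one phantom slice
#'
#' Draws tumor geometry, background texture and noise from the spec's seed.
#' The tumor mean exceeds the background mean by approximately
#' `tumor_intensity_contrast` before noise (exactly for the binary-intensity
#' `ellipse` and `ring` shapes; the `fuzzy` shape carries a smooth intensity
#' ramp whose gold mask is the ramp thresholded at 0.5).
#'
#' @param spec A [phantom_spec()].
#' @return A [slice_pair()]; identical spec (including seed) gives an
#'   identical result.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size
  with_seed(spec$seed, {
    # geometry: semi-axes drawn from the configured range, fully inside the frame
    a <- runif(1, spec$tumor_axes_frac[1], spec$tumor_axes_frac[2]) * n
    b <- runif(1, spec$tumor_axes_frac[1], spec$tumor_axes_frac[2]) * n
    th <- runif(1, 0, pi)
    margin <- max(a, b) + 2
    ci <- runif(1, margin, n - margin)
    cj <- runif(1, margin, n - margin)

    outer_m <- ellipse_mask(n, ci, cj, a, b, th)
    if (spec$tumor_shape == "ellipse") {
      mask <- outer_m
      ramp <- outer_m + 0
    } else if (spec$tumor_shape == "ring") {
      inner <- ellipse_mask(n, ci, cj, 0.5 * a, 0.5 * b, th)
      mask <- outer_m & !inner
      ramp <- mask + 0
    } else {  # fuzzy: blurred indicator; gold mask = ramp >= 0.5
      ramp <- gauss_blur(outer_m + 0, sigma = 0.035 * n)
      mask <- ramp >= 0.5
    }
    mask <- mask + 0  # logical -> numeric 0/1

    tex <- gauss_blur(matrix(rnorm(n * n), n, n),
                      sigma = spec$background_texture_scale / 2)
    tex <- 0.05 * tex / max(sd(as.numeric(tex)), 1e-12)
    # center the texture within tumor and background separately so the
    # requested contrast is the exact region mean offset before noise
    tex[mask == 1] <- tex[mask == 1] - mean(tex[mask == 1])
    tex[mask == 0] <- tex[mask == 0] - mean(tex[mask == 0])
    img <- 0.35 + tex + spec$tumor_intensity_contrast * ramp
    if (spec$noise_sd > 0) img <- img + spec$noise_sd * matrix(rnorm(n * n), n, n)
    img <- pmax(img, 0)
    slice_pair(img, mask, id = sprintf("phantom-%s-seed%d", spec$tumor_shape, spec$seed))
  })
}

#' Generate a phantom dataset
#'
#' @param spec A [phantom_spec()] used as a template; each slice receives its
#'   own sub-seed derived from `spec$seed` so the dataset is reproducible.
#' @param N Number of slices (>= 1).
#' @param shape_mix Named or unnamed proportions for
#'   `(ellipse, ring, fuzzy)`; must sum to 1. Counts are apportioned by
#'   largest remainder so they match the proportions within rounding.
#' @return An object of class `"phantom_dataset"`: a list with `pairs` (list
#'   of [slice_pair()]), `N`, and `shape_class` (character vector).
#' @export
generate_phantom_dataset <- function(spec, N, shape_mix = c(1, 1, 1) / 3) {
  stopifnot(inherits(spec, "phantom_spec"))
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("`N` must be >= 1 (empty dataset requested)", call. = FALSE)
  if (length(shape_mix) != 3L || abs(sum(shape_mix) - 1) > 1e-8)
    stop("`shape_mix` must be 3 proportions summing to 1", call. = FALSE)
  shapes <- c("ellipse", "ring", "fuzzy")
  # largest-remainder apportionment
  raw <- shape_mix * N
  counts <- floor(raw)
  rem <- N - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  assign_shapes <- rep(shapes, times = counts)
  pairs <- vector("list", N)
  for (i in seq_len(N)) {
    si <- phantom_spec(image_size = spec$image_size,
                       tumor_shape = assign_shapes[i],
                       tumor_intensity_contrast = spec$tumor_intensity_contrast,
                       noise_sd = spec$noise_sd,
                       background_texture_scale = spec$background_texture_scale,
                       tumor_axes_frac = spec$tumor_axes_frac,
                       seed = spec$seed + i)
    p <- generate_phantom(si)
    p$id <- sprintf("phantom-%04d-%s", i, assign_shapes[i])
    pairs[[i]] <- p
  }
  structure(list(pairs = pairs, N = N, shape_class = assign_shapes),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d slices (%s)\n", x$N,
              paste(sprintf("%s:%d", names(table(x$shape_class)),
                            as.integer(table(x$shape_class))), collapse = ", ")))
  invisible(x)
}

#' @export
length.phantom_dataset <- function(x) x$N

#' Write a phantom dataset to disk
#'
#' Images as grayscale PNG (intensities rescaled to the full range), masks as
#' `{0, 255}` PNG, plus a
#' manifest CSV (`id`, `image_path`, `mask_path`, `shape_class`). Optionally
#' also NIfTI volumes (one slice each) when `nifti = TRUE` and the RNifti
#' package is available.
#'
#' @param dataset A `"phantom_dataset"`.
#' @param dir Output directory (created if needed).
#' @param nifti Also write `.nii.gz` copies.
#' @return The manifest data frame, invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir, nifti = FALSE) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset$pairs, function(p) {
    ipath <- file.path(dir, paste0(p$id, "_image.png"))
    mpath <- file.path(dir, paste0(p$id, "_mask.png"))
    img <- p$image / max(p$image, 1e-12)
    png::writePNG(img, ipath)
    png::writePNG(p$mask, mpath)
    if (nifti && requireNamespace("RNifti", quietly = TRUE)) {
      RNifti::writeNifti(array(p$image, dim = c(dim(p$image), 1L)),
                         file.path(dir, paste0(p$id, "_image.nii.gz")))
      RNifti::writeNifti(array(p$mask, dim = c(dim(p$mask), 1L)),
                         file.path(dir, paste0(p$id, "_mask.nii.gz")))
    }
    data.frame(id = p$id, image_path = ipath, mask_path = mpath,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest$shape_class <- dataset$shape_class
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
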