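# Preprocessing: intensity normalization, tumor-covering ROI crops, and the
# five-fold geometric augmentation.
#
# Coordinate convention used throughout: matrices are row-major in meaning
# (row = image row), indices 1-based, crop windows are `size` consecutive
# rows/columns fully inside the image (clamped at borders rather than padded,
# so cropped pixels keep their true intensities).

#' Min-max intensity normalization
#'
#' Rescales an image to `[0, 1]` as `(I - Imin) / (Imax - Imin)`. A constant
#' image (the formula's degenerate case) maps to all zeros with a warning.
#'
#' @param image 2D intensity matrix, nonempty.
#' @return Matrix with minimum 0 and maximum 1 (when the input had at least
#'   two distinct values).
#' @export
normalize_intensity <- function(image) {
  image <- as.matrix(image)
  if (length(image) == 0L) stop("empty image", call. = FALSE)
  lo <- min(image); hi <- max(image)
  if (hi == lo) {
    warning("constant image: normalization undefined, returning all zeros")
    return(array(0, dim = dim(image)))
  }
  (image - lo) / (hi - lo)
}

# centroid of positive pixels (row, col), rounded
mask_centroid <- function(mask) {
  w <- which(mask == 1, arr.ind = TRUE)
  round(colMeans(w))
}

#' Crop a tumor-covering ROI
#'
#' Extracts a `size x size` window from image and mask congruently. By
#' default the window is centered on the tumor centroid; it is shifted
#' (clamped) to stay fully inside the image near borders.
#'
#' @param pair A [slice_pair()] with nonempty mask.
#' @param size ROI side length in pixels (the study sizes are 96, 192, 320,
#'   but any value up to the image side is accepted).
#' @param center Optional `(row, col)` center; defaults to the tumor centroid.
#' @return A [slice_pair()] of shape `size x size`.
#' @export
crop_roi <- function(pair, size, center = NULL) {
  stopifnot(inherits(pair, "slice_pair"))
  if (sum(pair$mask) == 0) stop("ROI must cover tumor: mask is empty", call. = FALSE)
  size <- as.integer(size)
  H <- nrow(pair$image); W <- ncol(pair$image)
  if (size > H || size > W)
    stop(sprintf("ROI size %d exceeds image size %dx%d", size, H, W), call. = FALSE)
  if (is.null(center)) center <- mask_centroid(pair$mask)
  r0 <- min(max(1L, as.integer(center[1]) - size %/% 2L), H - size + 1L)
  c0 <- min(max(1L, as.integer(center[2]) - size %/% 2L), W - size + 1L)
  rows <- r0:(r0 + size - 1L); cols <- c0:(c0 + size - 1L)
  slice_pair(pair$image[rows, cols], pair$mask[rows, cols],
             id = sprintf("%s-roi%d", pair$id, size))
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
rot180 <- function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]
flip_v <- function(m) m[nrow(m):1, , drop = FALSE]   # up-down
flip_h <- function(m) m[, ncol(m):1, drop = FALSE]   # left-right

#' Five-fold geometric augmentation
#'
#' Expands a dataset to five times its size with the variant set
#' `{original, rot90, rot180, vertical flip, horizontal flip}`, applied
#' congruently to image and mask. Augmentation changes geometry only, never
#' intensity values.
#'
#' @param dataset A `"phantom_dataset"` (or any list-of-[slice_pair()] with
#'   the same structure).
#' @return A `"phantom_dataset"` of size `5 * N`.
#' @export
augment_five_fold <- function(dataset) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  if (dataset$N == 0L) stop("empty dataset", call. = FALSE)
  ops <- list(orig = identity, rot90 = rot90cw, rot180 = rot180,
              flipv = flip_v, fliph = flip_h)
  pairs <- vector("list", 5L * dataset$N)
  shape <- character(5L * dataset$N)
  k <- 0L
  for (i in seq_len(dataset$N)) {
    p <- dataset$pairs[[i]]
    for (nm in names(ops)) {
      k <- k + 1L
      f <- ops[[nm]]
      pairs[[k]] <- slice_pair(f(p$image), f(p$mask),
                               id = sprintf("%s-%s", p$id, nm))
      shape[k] <- dataset$shape_class[i]
    }
  }
  structure(list(pairs = pairs, N = 5L * dataset$N, shape_class = shape),
            class = "phantom_dataset")
}
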