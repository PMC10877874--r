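# The tabular diagnostic pipeline: z-score standardization fitted on training
# rows, correlation PCA with top-3 component selection, a stratified 2/3-1/3
# split, and a one-hidden-layer back-propagation classifier whose hidden size,
# weights and thresholds are chosen by a genetic algorithm.

#' Z-score standardization
#'
#' Centers and scales the given columns using means and sample standard
#' deviations computed on `fit_rows` only, then transforms every row with
#' those parameters (so test rows never leak into the fit). Constant columns
#' map to zeros with a warning.
#'
#' @param table Data frame or matrix.
#' @param columns Columns to standardize; defaults to all numeric columns up
#'   to (excluding) `age` for a cohort table, else all columns.
#' @param fit_rows Row indices used to estimate means/sds (default: all).
#' @return Object of class `"std_table"`: `z` (matrix of all rows,
#'   standardized), `center`, `scale`, `columns`, `fit_rows`.
#' @export
zscore_standardize <- function(table, columns = NULL, fit_rows = NULL) {
  if (is.null(columns)) {
    if (is.data.frame(table) && "age" %in% names(table)) {
      columns <- names(table)[seq_len(match("age", names(table)) - 1L)]
    } else columns <- colnames(table) %||% seq_len(ncol(table))
  }
  X <- as.matrix(as.data.frame(table, check.names = FALSE)[, columns, drop = FALSE])
  storage.mode(X) <- "double"
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(X))
  if (length(fit_rows) < 2L) stop("need >= 2 fit rows", call. = FALSE)
  mu <- colMeans(X[fit_rows, , drop = FALSE])
  sdev <- apply(X[fit_rows, , drop = FALSE], 2, sd)
  const <- sdev == 0
  if (any(const)) {
    warning("constant column(s) standardized to zero: ",
            paste(columns[const], collapse = ", "))
    sdev[const] <- 1
    mu[const] <- X[fit_rows[1], const]
  }
  z <- sweep(sweep(X, 2, mu, "-"), 2, sdev, "/")
  structure(list(z = z, center = mu, scale = sdev, columns = columns,
                 fit_rows = fit_rows),
            class = "std_table")
}

#' Correlation PCA
#'
#' Eigen-decomposition of the correlation matrix of the standardized fit
#' rows (z-scored input makes covariance equal correlation). Eigenvector
#' signs are fixed so each component's largest-magnitude loading is positive,
#' making loading tables reproducible run to run.
#'
#' @param std A `"std_table"` from [zscore_standardize()] (or a plain
#'   z-scored matrix).
#' @param n_selected Number of leading components retained for scores.
#' @return Object of class `"pca_model"`: orthonormal `vectors` (loadings),
#'   descending `values`, `n_selected`, `columns`.
#' @export
fit_pca <- function(std, n_selected = 3L) {
  z <- if (inherits(std, "std_table")) std$z[std$fit_rows, , drop = FALSE] else as.matrix(std)
  if (nrow(z) < 2L) stop("need >= 2 rows", call. = FALSE)
  R <- crossprod(z) / (nrow(z) - 1)
  if (any(!is.finite(R))) stop("degenerate correlation matrix", call. = FALSE)
  e <- eigen(R, symmetric = TRUE)
  V <- e$vectors
  for (k in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, k])), k] < 0) V[, k] <- -V[, k]
  }
  cols <- colnames(z) %||% paste0("x", seq_len(ncol(z)))
  rownames(V) <- cols
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  structure(list(vectors = V, values = pmax(e$values, 0),
                 n_selected = as.integer(n_selected), columns = cols),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  share <- sum(x$values[seq_len(x$n_selected)]) / sum(x$values)
  cat(sprintf("<pca_model> %d variables, top %d components explain %.1f%% of variance\n",
              length(x$columns), x$n_selected, 100 * share))
  invisible(x)
}

#' Principal-component scores
#'
#' Projects standardized rows onto the selected leading eigenvectors — the
#' linear forms `P_k = v_k1 x_1 + v_k2 x_2 + ...` of a loadings table.
#'
#' @param model A `"pca_model"`.
#' @param std A `"std_table"` or z-scored matrix with matching columns.
#' @return Matrix with `n_selected` score columns.
#' @export
project_scores <- function(model, std) {
  z <- if (inherits(std, "std_table")) std$z else as.matrix(std)
  cols <- colnames(z) %||% paste0("x", seq_len(ncol(z)))
  if (!identical(cols, model$columns)) {
    bad <- c(setdiff(cols, model$columns), setdiff(model$columns, cols))
    stop("column roster mismatch: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  z %*% model$vectors[, seq_len(model$n_selected), drop = FALSE]
}

#' Stratified 2/3-1/3 split
#'
#' Per-stratum seeded shuffle; `floor(fraction * n)` rows go to training,
#' the remainder to testing. With the published cohort sizes this reproduces
#' 123 training / 62 testing cases.
#'
#' @param table Data frame with a stratum column.
#' @param fraction Training fraction (default 2/3).
#' @param seed Integer seed.
#' @param strata Column name holding the stratum tags (default `"subgroup"`).
#' @return Object of class `"split_result"`: `train_ids`, `test_ids`
#'   (row indices), and a per-stratum `counts` table.
#' @export
stratified_split <- function(table, fraction = 2 / 3, seed = 1L,
                             strata = "subgroup") {
  tags <- as.character(table[[strata]])
  if (any(is.na(tags))) stop("missing stratum tags", call. = FALSE)
  with_seed(seed, {
    train <- integer(0)
    for (lv in unique(tags)) {
      rows <- which(tags == lv)
      if (length(rows) == 0L) next
      k <- floor(fraction * length(rows))
      train <- c(train, sample(rows)[seq_len(k)])
    }
    train <- sort(train)
    test <- setdiff(seq_len(nrow(table)), train)
    counts <- do.call(rbind, lapply(unique(tags), function(lv) {
      rows <- which(tags == lv)
      data.frame(stratum = lv, n = length(rows),
                 n_train = sum(rows %in% train),
                 n_test = sum(rows %in% test), stringsAsFactors = FALSE)
    }))
    structure(list(train_ids = train, test_ids = test, counts = counts,
                   fraction = fraction, seed = seed),
              class = "split_result")
  })
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d train / %d test (fraction %.3f)\n",
              length(x$train_ids), length(x$test_ids), x$fraction))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

# --- BP network --------------------------------------------------------------

bp_forward <- function(net, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(net$W1))
    stop(sprintf("input has %d features but the network expects %d",
                 ncol(X), nrow(net$W1)), call. = FALSE)
  H <- stats::plogis(sweep(X %*% net$W1, 2, net$b1, "+"))
  as.numeric(stats::plogis(H %*% net$W2 + net$b2))
}

#' Predict continuous diagnostic scores
#'
#' One-hidden-layer feed-forward network with logistic squashing at both
#' layers; outputs are continuous values in `[0, 1]`.
#'
#' @param net A `"bp_net"`.
#' @param scores Feature matrix (rows = subjects).
#' @return Numeric vector in `[0, 1]`.
#' @export
predict_scores <- function(net, scores) {
  stopifnot(inherits(net, "bp_net"))
  bp_forward(net, scores)
}

#' @export
predict.bp_net <- function(object, newdata, ...) predict_scores(object, newdata)

#' @export
print.bp_net <- function(x, ...) {
  cat(sprintf("<bp_net> %d inputs -> %d hidden (logistic) -> 1, GA fitness %.4f\n",
              nrow(x$W1), x$hidden_size,
              x$history[length(x$history)]))
  invisible(x)
}

#' Genetic-algorithm configuration
#'
#' @param population_size Individuals per generation.
#' @param generations Number of generations.
#' @param crossover_rate,mutation_rate Rates in `[0, 1]`.
#' @param hidden_size_range Inclusive integer range for the hidden layer.
#' @param elitism_count Best individuals copied unchanged each generation.
#' @param fitness Validation-error definition: `"logloss"`, `"mse"` or
#'   `"misclass"`.
#' @param fine_tune_steps Full-batch gradient back-propagation steps applied
#'   to the best individual after the GA (0 disables fine-tuning).
#' @param fine_tune_lr Learning rate for fine-tuning.
#' @param seed Integer seed.
#' @return An object of class `"ga_config"`.
#' @export
ga_config <- function(population_size = 40L, generations = 100L,
                      crossover_rate = 0.8, mutation_rate = 0.05,
                      hidden_size_range = c(2L, 20L), elitism_count = 2L,
                      fitness = c("logloss", "mse", "misclass"),
                      fine_tune_steps = 200L, fine_tune_lr = 0.1,
                      seed = 1L) {
  fitness <- match.arg(fitness)
  if (crossover_rate < 0 || crossover_rate > 1 || mutation_rate < 0 || mutation_rate > 1)
    stop("rates must be in [0, 1]", call. = FALSE)
  if (length(hidden_size_range) != 2L || hidden_size_range[1] > hidden_size_range[2])
    stop("hidden_size_range must be a nonempty integer range", call. = FALSE)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 hidden_size_range = as.integer(hidden_size_range),
                 elitism_count = as.integer(elitism_count), fitness = fitness,
                 fine_tune_steps = as.integer(fine_tune_steps),
                 fine_tune_lr = fine_tune_lr, seed = as.integer(seed)),
            class = "ga_config")
}

# decode a chromosome into a bp_net; chromosome = [h_gene, W1 genes (d x Hmax),
# b1 genes (Hmax), W2 genes (Hmax), b2]
decode_chromosome <- function(chrom, d, range) {
  Hmax <- range[2]
  h <- range[1] + round(stats::plogis(chrom[1]) * (range[2] - range[1]))
  h <- max(range[1], min(range[2], h))
  off <- 1L
  W1 <- matrix(chrom[off + seq_len(d * Hmax)], d, Hmax)[, seq_len(h), drop = FALSE]
  off <- off + d * Hmax
  b1 <- chrom[off + seq_len(Hmax)][seq_len(h)]
  off <- off + Hmax
  W2 <- matrix(chrom[off + seq_len(Hmax)][seq_len(h)], h, 1)
  off <- off + Hmax
  b2 <- chrom[off + 1L]
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, hidden_size = h,
                 activation = "logistic"),
            class = "bp_net")
}

fitness_error <- function(pred, y, kind) {
  eps <- 1e-12
  switch(kind,
         logloss = -mean(y * log(pmax(pred, eps)) + (1 - y) * log(pmax(1 - pred, eps))),
         mse = mean((pred - y)^2),
         misclass = mean((pred >= 0.5) != (y == 1)))
}

bp_finetune <- function(net, X, y, steps, lr) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  for (s in seq_len(steps)) {
    A <- sweep(X %*% net$W1, 2, net$b1, "+")
    H <- stats::plogis(A)
    p <- as.numeric(stats::plogis(H %*% net$W2 + net$b2))
    dz2 <- (p - y) / n                       # d(logloss)/d(output logit)
    gW2 <- crossprod(H, dz2)
    gb2 <- sum(dz2)
    dH <- outer(dz2, as.numeric(net$W2)) * H * (1 - H)
    gW1 <- crossprod(X, dH)
    gb1 <- colSums(dH)
    net$W2 <- net$W2 - lr * gW2
    net$b2 <- net$b2 - lr * gb2
    net$W1 <- net$W1 - lr * gW1
    net$b1 <- net$b1 - lr * gb1
  }
  net
}

#' Genetic-algorithm optimisation of the BP classifier
#'
#' A real-valued chromosome encodes the hidden-layer size together with all
#' connection weights and thresholds. Tournament selection, arithmetic
#' crossover and Gaussian mutation evolve the population; elitism guarantees
#' the best validation error never worsens across generations. Fitness is the
#' error on an internal 75/25 validation split of the training rows. The best
#' individual is optionally polished by full-batch gradient back-propagation.
#'
#' @param train_scores Feature matrix (e.g. 3 PC scores + demographics).
#' @param labels Binary labels (1 = case) or a factor/character vector where
#'   `"case"` is the positive class.
#' @param ga A [ga_config()].
#' @return A `"bp_net"` with `history` (best validation error per
#'   generation, non-increasing) and the realised `hidden_size`.
#' @export
ga_optimize_bp <- function(train_scores, labels, ga = ga_config()) {
  stopifnot(inherits(ga, "ga_config"))
  X <- as.matrix(train_scores)
  y <- if (is.numeric(labels)) as.numeric(labels) else as.numeric(labels == "case")
  if (length(unique(y)) < 2L) stop("labels contain a single class", call. = FALSE)
  d <- ncol(X)
  Hmax <- ga$hidden_size_range[2]
  clen <- 1L + d * Hmax + Hmax + Hmax + 1L

  with_seed(ga$seed, {
    n <- nrow(X)
    val <- sample.int(n, max(1L, round(0.25 * n)))
    # guarantee both classes in both halves where possible
    if (length(unique(y[val])) < 2L || length(unique(y[-val])) < 2L) {
      pos <- which(y == 1); neg <- which(y == 0)
      val <- c(sample(pos, max(1L, round(0.25 * length(pos)))),
               sample(neg, max(1L, round(0.25 * length(neg)))))
    }
    tr <- setdiff(seq_len(n), val)

    evaluate <- function(chrom) {
      net <- decode_chromosome(chrom, d, ga$hidden_size_range)
      fitness_error(bp_forward(net, X[val, , drop = FALSE]), y[val], ga$fitness)
    }
    pop <- matrix(rnorm(ga$population_size * clen, sd = 0.5),
                  ga$population_size, clen)
    fit <- apply(pop, 1, evaluate)
    best_hist <- numeric(ga$generations)
    for (g in seq_len(ga$generations)) {
      ord <- order(fit)
      newpop <- pop[ord[seq_len(ga$elitism_count)], , drop = FALSE]
      while (nrow(newpop) < ga$population_size) {
        pick <- function() {
          cand <- sample.int(ga$population_size, 2L)
          cand[which.min(fit[cand])]
        }
        p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
        if (runif(1) < ga$crossover_rate) {
          a <- runif(1)
          child <- a * p1 + (1 - a) * p2
        } else child <- p1
        mut <- runif(clen) < ga$mutation_rate
        child[mut] <- child[mut] + rnorm(sum(mut), sd = 0.3)
        newpop <- rbind(newpop, child)
      }
      pop <- newpop
      fit <- apply(pop, 1, evaluate)
      best_hist[g] <- min(fit)
    }
    best <- decode_chromosome(pop[which.min(fit), ], d, ga$hidden_size_range)
    if (ga$fine_tune_steps > 0L)
      best <- bp_finetune(best, X[tr, , drop = FALSE], y[tr],
                          ga$fine_tune_steps, ga$fine_tune_lr)
    best$history <- best_hist  # elitism + deterministic fitness => non-increasing
    best$ga <- ga
    best
  })
}
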