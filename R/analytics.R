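# Whole-curve shape analytics: peak-aligned daily matrices, PCA ordination,
# PERMANOVA, random-forest strain classification, and correlations.

#' Peak-aligned daily fluorescence matrix
#'
#' Shifts each curve so its fluorescence peak sits at relative day 0, bins
#' observations into half-open one-day bins `[d, d+1)` labelled by integer
#' day `d` over `window` (default 10 days before the peak to 80 days after),
#' averages observations within a bin, linearly interpolates interior gaps,
#' and extends the edges with the nearest observed bin value. Curves with no
#' observation inside their window are excluded with a warning.
#'
#' @param es an [experiment_set()].
#' @param window integer `c(first, last)` relative days (default `c(-10, 80)`).
#' @return numeric matrix (class `aligned_matrix`), one row per culture,
#'   columns named by relative day; attributes `grid`, `standardized`,
#'   `peaks`.
#' @export
align_and_grid <- function(es, window = c(-10L, 80L)) {
  grid <- seq.int(window[1], window[2])
  ids <- unique(es$curves$culture_id)
  rows <- list()
  for (id in ids) {
    curve <- get_curve(es, id)
    peak <- tryCatch(find_peak(curve), error = function(e) NULL)
    if (is.null(peak)) {
      warning("curve '", id, "' excluded from alignment: no signal", call. = FALSE)
      next
    }
    rel <- curve$day - peak$tmax
    bin <- floor(rel)
    inw <- bin >= window[1] & bin <= window[2] & is.finite(curve$fluorescence)
    if (!any(inw)) {
      warning("curve '", id, "' excluded from alignment: no points in window",
              call. = FALSE)
      next
    }
    means <- tapply(curve$fluorescence[inw], bin[inw], mean)
    days <- as.integer(names(means))
    filled <- if (length(days) == 1L) rep(unname(means), length(grid))
              else stats::approx(days, as.numeric(means), xout = grid,
                                 method = "linear", rule = 2)$y
    rows[[id]] <- filled
  }
  if (length(rows) == 0L) stop("no curves with in-window points", call. = FALSE)
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), as.character(grid))
  structure(m, grid = grid, standardized = FALSE, class = c("aligned_matrix", "matrix"))
}

#' Standardize an aligned matrix per day
#'
#' Column-wise z-scores using the population standard deviation (divisor
#' `n`), as in standard-scaler preprocessing. Constant columns are set to 0
#' and recorded in the `constant_cols` attribute. Idempotent.
#'
#' @param m an [align_and_grid()] matrix (or any numeric matrix with at
#'   least 2 rows).
#' @return the standardized matrix with attribute `standardized = TRUE`.
#' @export
standardize_matrix <- function(m) {
  stopifnot(nrow(m) >= 2L)
  mu <- colMeans(m)
  sdp <- sqrt(colMeans(sweep(m, 2, mu)^2))
  constant <- sdp == 0
  sdp[constant] <- 1
  out <- sweep(sweep(m, 2, mu), 2, sdp, "/")
  out[, constant] <- 0
  attrs <- attributes(m)
  for (a in setdiff(names(attrs), c("dim", "dimnames"))) attr(out, a) <- attrs[[a]]
  dimnames(out) <- dimnames(m)
  attr(out, "standardized") <- TRUE
  attr(out, "constant_cols") <- colnames(m)[constant]
  class(out) <- c("aligned_matrix", "matrix")
  out
}

#' PCA ordination of standardized curves
#'
#' Principal component analysis of the row-samples; component signs are
#' fixed by forcing the largest-magnitude loading of each component
#' positive, so output is deterministic across runs and platforms.
#'
#' @param m standardized [align_and_grid()] matrix.
#' @param k number of components (default 2).
#' @return list of class `curve_pca`: `scores` (samples x k),
#'   `explained` (variance ratios, non-increasing, sum over all components
#'   is 1), `loadings` (features x k).
#' @export
pca_curves <- function(m, k = 2L) {
  if (k > min(nrow(m) - 1L, ncol(m))) {
    stop("k exceeds min(samples - 1, features)", call. = FALSE)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  explained_all <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, explained = explained_all[seq_len(k)],
                 explained_all = explained_all, loadings = loadings),
            class = "curve_pca")
}

#' @export
print.curve_pca <- function(x, ...) {
  cat(sprintf("<curve_pca> %d samples, %d components; explained: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' @export
plot.curve_pca <- function(x, labels = NULL, ...) {
  col <- if (is.null(labels)) 1 else as.integer(factor(labels))
  graphics::plot(x$scores[, 1], x$scores[, 2],
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2]),
                 col = col, pch = 19, ...)
  invisible(x)
}

#' Distance-based PERMANOVA on curve shapes
#'
#' Permutational multivariate ANOVA on the Euclidean distance matrix of the
#' standardized curves: sums of squares are computed from squared pairwise
#' distances (Gower decomposition), pseudo-F is
#' `(SS_between / (k-1)) / (SS_within / (N-k))`, `R2 = SS_between /
#' SS_total`, and the p-value is `(1 + #permuted F >= observed F) /
#' (1 + n_perm)` under random label permutation (so p never reaches 0).
#'
#' @param m standardized [align_and_grid()] matrix (or any numeric matrix).
#' @param labels group labels, one per row; every group needs >= 2 samples.
#' @param n_perm number of permutations (default 999).
#' @param seed optional seed for the permutation stream.
#' @return list of class `curve_permanova`: `pseudo_F`, `R2`, `p`,
#'   `n_permutations`, `df_between`, `df_within`.
#' @export
permanova_curves <- function(m, labels, n_perm = 999L, seed = NULL) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(m))
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("singleton group(s): ", paste(names(sizes)[sizes < 2L], collapse = ", "),
         call. = FALSE)
  }
  d2 <- as.matrix(stats::dist(m))^2
  N <- nrow(m)
  k <- length(sizes)
  ss_total <- sum(d2) / (2 * N)
  ss_within_for <- function(lab) {
    s <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  ssw <- ss_within_for(labels)
  ssb <- ss_total - ssw
  f_obs <- (ssb / (k - 1)) / (ssw / (N - k))
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      lab <- sample(labels)
      ssw_p <- ss_within_for(lab)
      f_p <- ((ss_total - ssw_p) / (k - 1)) / (ssw_p / (N - k))
      if (f_p >= f_obs) cnt <- cnt + 1L
    }
    cnt
  })
  structure(list(pseudo_F = f_obs, R2 = ssb / ss_total,
                 p = (1 + exceed) / (1 + n_perm),
                 n_permutations = n_perm,
                 df_between = k - 1L, df_within = N - k),
            class = "curve_permanova")
}

#' @export
print.curve_permanova <- function(x, ...) {
  cat(sprintf("<curve_permanova> F(%d,%d) = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$df_between, x$df_within, x$pseudo_F, x$R2, x$p, x$n_permutations))
  invisible(x)
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin across folds
stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- sample(which(labels == g))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Random-forest classification of curve shapes
#'
#' Stratified k-fold cross-validated classification of the aligned curves by
#' a strain label, plus per-day feature importance (mean decrease in Gini
#' impurity) averaged over `n_repeats` refits on the full matrix.
#' Deterministic given `seed`. If the smallest class has fewer members than
#' `folds`, the fold count is reduced with a warning.
#'
#' @param m standardized [align_and_grid()] matrix.
#' @param labels class labels, one per row (>= 2 classes).
#' @param folds cross-validation folds (default 10).
#' @param n_repeats refits for importance averaging (default 30).
#' @param seed optional seed.
#' @param ntree trees per forest (default 500).
#' @return list of class `curve_rf`: `fold_accuracy`, `mean_accuracy`,
#'   `confusion` (table), `importance` (named by relative day), `folds`.
#' @export
rf_classify <- function(m, labels, folds = 10L, n_repeats = 30L, seed = NULL,
                        ntree = 500L) {
  labels <- factor(as.character(labels))
  stopifnot(length(labels) == nrow(m))
  if (nlevels(labels) < 2L) stop("need at least 2 classes", call. = FALSE)
  min_class <- min(table(labels))
  if (min_class < folds) {
    warning("smallest class has ", min_class, " members; reducing folds to ",
            min_class, call. = FALSE)
    folds <- min_class
  }
  x <- as.data.frame(unclass(as.matrix(m)))
  names(x) <- paste0("d", colnames(m))
  with_seed(seed, {
    fold_of <- stratified_folds(as.character(labels), folds)
    fold_acc <- numeric(folds)
    confusion <- table(truth = labels[0], pred = labels[0])
    preds <- factor(rep(levels(labels)[1], length(labels)), levels = levels(labels))
    for (f in seq_len(folds)) {
      test <- fold_of == f
      rf <- randomForest::randomForest(x[!test, , drop = FALSE], labels[!test],
                                       ntree = ntree)
      p <- stats::predict(rf, x[test, , drop = FALSE])
      preds[test] <- p
      fold_acc[f] <- mean(p == labels[test])
    }
    confusion <- table(truth = labels, pred = preds)
    imp <- matrix(0, nrow = ncol(m), ncol = n_repeats)
    for (r in seq_len(n_repeats)) {
      rf <- randomForest::randomForest(x, labels, ntree = ntree, importance = FALSE)
      imp[, r] <- rf$importance[, "MeanDecreaseGini"]
    }
    importance <- rowMeans(imp)
    names(importance) <- colnames(m)
    structure(list(fold_accuracy = fold_acc, mean_accuracy = mean(fold_acc),
                   confusion = confusion, importance = importance,
                   folds = folds, n_repeats = n_repeats),
              class = "curve_rf")
  })
}

#' @export
print.curve_rf <- function(x, ...) {
  cat(sprintf("<curve_rf> %d-fold CV mean accuracy %.3f (folds: %s)\n",
              x$folds, x$mean_accuracy,
              paste(sprintf("%.2f", x$fold_accuracy), collapse = " ")))
  top <- names(sort(x$importance, decreasing = TRUE))[1:5]
  cat("  top importance days:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Pearson correlation between two per-culture scalars
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return list with `r` (Pearson product-moment correlation) and `p`
#'   (two-sided).
#' @export
correlate <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
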