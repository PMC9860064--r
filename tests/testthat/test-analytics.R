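# helper: experiment set with given per-culture (day, fluorescence) tables
es_from_curves <- function(curve_list) {
  curves <- do.call(rbind, lapply(names(curve_list), function(id) {
    cbind(data.frame(culture_id = id), curve_list[[id]])
  }))
  metadata <- data.frame(culture_id = names(curve_list), experiment = "E1",
                         pro_strain = "MED4", alt_strain = "HOT1A3",
                         replicate = seq_along(curve_list))
  experiment_set(curves, metadata)
}

test_that("alignment bins, averages, interpolates and edge-fills as specified", {
  # peak at day 0; observations at relative days 0, 2, 6 with a gap
  c1 <- data.frame(day = c(0, 2, 6), fluorescence = c(20, 10, 4))
  # same curve shifted by 13 days (peak-relative alignment must undo this)
  c2 <- data.frame(day = c(0, 2, 6) + 13, fluorescence = c(20, 10, 4))
  m <- align_and_grid(es_from_curves(list(a = c1, b = c2)))
  expect_equal(dim(m), c(2L, 91L))
  expect_equal(colnames(m)[1], "-10")
  # raw daily bins pass through
  expect_equal(m["a", "0"], 20)
  expect_equal(m["a", "2"], 10)
  expect_equal(m["a", "6"], 4)
  # linear interpolation across the day 3-5 gap between 10 and 4
  expect_equal(unname(m["a", c("3", "4", "5")]), c(8.5, 7, 5.5))
  # nearest-value edge fill
  expect_equal(unname(m["a", "-10"]), 20)
  expect_equal(unname(m["a", "80"]), 4)
  # shift invariance
  expect_equal(unname(m["b", ]), unname(m["a", ]))

  # two observations within one day-bin are averaged
  c3 <- data.frame(day = c(0, 3.2, 3.7, 5), fluorescence = c(9, 4, 6, 2))
  m3 <- align_and_grid(es_from_curves(list(a = c3, b = c3)))
  expect_equal(unname(m3["a", "3"]), 5)
})

test_that("standardization gives population z-scores, idempotently", {
  m <- matrix(c(1, 3, 10, 10, 2, 8), nrow = 2)
  colnames(m) <- c("-1", "0", "1")
  s <- standardize_matrix(m)
  expect_equal(unname(s[, 1]), c(-1, 1))   # population SD convention
  expect_equal(unname(s[, 2]), c(0, 0))    # constant column zeroed
  expect_identical(attr(s, "constant_cols"), "0")
  expect_equal(unname(standardize_matrix(s)), unname(s))
  # column means ~0 and population SDs ~1
  m2 <- matrix(rnorm(60), nrow = 6)
  colnames(m2) <- as.character(1:10)
  s2 <- standardize_matrix(m2)
  expect_lt(max(abs(colMeans(s2))), 1e-9)
  expect_lt(max(abs(sqrt(colMeans(sweep(s2, 2, colMeans(s2))^2)) - 1)), 1e-9)
})

test_that("PCA explains rank-1 data fully and preserves distances at full rank", {
  u <- c(1, 2, 3, 4); v <- c(2, -1, 0.5)
  r1 <- u %*% t(v)
  colnames(r1) <- as.character(1:3)
  p1 <- pca_curves(r1, k = 2)
  expect_equal(p1$explained[1], 1, tolerance = 1e-10)

  set.seed(9)
  m <- matrix(rnorm(24), nrow = 6)
  colnames(m) <- as.character(1:4)
  p <- pca_curves(m, k = 4)
  expect_equal(as.matrix(dist(p$scores)),
               as.matrix(dist(scale(m, scale = FALSE))), tolerance = 1e-10)
  # explained-variance ratios non-increasing, sum to <= 1
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-12)
  # deterministic sign: the largest-|loading| entry of each PC is positive
  for (j in 1:4) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  expect_error(pca_curves(m, k = 6), "k exceeds")
})

test_that("total variance of a standardized matrix equals its non-constant columns", {
  m <- default_aligned()
  nonconst <- ncol(m) - length(attr(m, "constant_cols"))
  total_var <- sum(colMeans(sweep(m, 2, colMeans(m))^2))
  expect_equal(total_var, nonconst, tolerance = 1e-8)
})

test_that("permanova matches exhaustive enumeration on a 6-sample instance", {
  set.seed(14)
  m <- matrix(rnorm(12), nrow = 6)
  labels <- rep(c("A", "B"), each = 3)
  # brute-force oracle over all 20 label assignments
  d2 <- as.matrix(dist(m))^2
  ss_total <- sum(d2) / 12
  f_of <- function(lab) {
    ssw <- sum(vapply(unique(lab), function(g) {
      i <- which(lab == g); sum(d2[i, i]) / (2 * length(i))
    }, 0))
    ((ss_total - ssw) / 1) / (ssw / 4)
  }
  f_obs <- f_of(labels)
  combos <- combn(6, 3)
  f_all <- apply(combos, 2, function(idx) {
    lab <- rep("B", 6); lab[idx] <- "A"; f_of(lab)
  })
  p_exact <- mean(f_all >= f_obs - 1e-12)
  res <- permanova_curves(m, labels, n_perm = 9999, seed = 77)
  expect_equal(res$pseudo_F, f_obs, tolerance = 1e-12)
  expect_equal(res$p, p_exact, tolerance = 0.05)
  expect_equal(res$R2 + (1 - res$R2), 1, tolerance = 1e-10)
})

test_that("permanova separates distant groups at the minimal p and matches adonis2", {
  set.seed(21)
  m <- rbind(matrix(rnorm(10 * 4), nrow = 10),
             matrix(rnorm(10 * 4, mean = 10), nrow = 10))
  colnames(m) <- as.character(1:4)
  labels <- rep(c("A", "B"), each = 10)
  res <- permanova_curves(m, labels, n_perm = 999, seed = 5)
  expect_equal(res$p, 0.001)
  expect_gte(res$p, 1 / (res$n_permutations + 1))
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 18L)

  # independent cross-check of F and R2 against vegan's adonis2
  skip_if_not_installed("vegan")
  set.seed(33)
  m2 <- matrix(rnorm(15 * 6), nrow = 15)
  lab2 <- rep(c("A", "B", "C"), each = 5)
  mine <- permanova_curves(m2, lab2, n_perm = 99, seed = 1)
  df <- data.frame(g = lab2)
  ad <- vegan::adonis2(dist(m2) ~ g, data = df, permutations = 99)
  expect_equal(mine$pseudo_F, ad$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ad$R2[1], tolerance = 1e-10)
  expect_error(permanova_curves(m2[1:6, ], c("A", "A", "A", "A", "A", "B")),
               "singleton")
})

test_that("random-forest CV is at chance for shuffled labels and deterministic", {
  set.seed(44)
  m <- matrix(rnorm(40 * 8), nrow = 40)
  colnames(m) <- as.character(1:8)
  labels <- sample(rep(c("A", "B"), each = 20))
  res <- rf_classify(m, labels, folds = 5, n_repeats = 3, seed = 10, ntree = 200)
  se <- sd(res$fold_accuracy) / sqrt(res$folds)
  expect_lt(abs(res$mean_accuracy - 0.5), 3 * se + 0.05)

  res2 <- rf_classify(m, labels, folds = 5, n_repeats = 3, seed = 10, ntree = 200)
  expect_identical(res$fold_accuracy, res2$fold_accuracy)
  expect_identical(res$importance, res2$importance)

  expect_error(rf_classify(m, rep("A", 40)), "2 classes")
  expect_warning(rf_classify(m[1:9, ], c(rep("A", 5), rep("B", 4)),
                             folds = 5, n_repeats = 1, seed = 1, ntree = 50),
                 "reducing folds")
})

test_that("classes defined by decline shape are recovered from the decline days", {
  # synthetic aligned curves: identical rise, class-specific post-peak decline
  set.seed(60)
  grid <- -10:80
  mk_row <- function(rate) {
    y <- ifelse(grid < 0, exp(0.5 * (grid + 10)) / exp(5),
                exp(-rate * grid))
    y * rlnorm(length(grid), 0, 0.05)
  }
  rates <- c(A = 0.02, B = 0.1, C = 0.4)
  labels <- rep(names(rates), each = 10)
  m <- do.call(rbind, lapply(labels, function(g) mk_row(rates[[g]])))
  colnames(m) <- as.character(grid)
  s <- standardize_matrix(m)
  res <- rf_classify(s, labels, folds = 5, n_repeats = 5, seed = 3, ntree = 300)
  expect_gt(res$mean_accuracy, 0.9)
  top_days <- as.integer(names(sort(res$importance, decreasing = TRUE))[1:5])
  expect_true(all(top_days > 0))
})

test_that("correlate recovers exact and stochastic correlations", {
  x <- c(1, 2, 5, 7, 9)
  expect_equal(correlate(x, -x)$r, -1, tolerance = 1e-12)
  expect_equal(correlate(x, 2 * x + 3)$r, 1, tolerance = 1e-12)
  expect_error(correlate(x, rep(1, 5)), "zero variance")

  set.seed(100)
  hits <- replicate(500, {
    x <- rnorm(70)
    y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(70)
    abs(correlate(x, y)$r - 0.6) <= 0.2
  })
  expect_gte(mean(hits), 0.95)
})
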