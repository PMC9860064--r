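test_that("model curves match analytic values and start at 1", {
  expect_equal(model_eval("weibull", c(a = 0.01, n = 2), 10), exp(-1))
  expect_equal(model_eval("harmonic", c(a = 1), 1), 0.5)
  tau <- seq(0, 40, by = 0.5)
  expect_equal(model_eval("biexponential", c(f = 1, a1 = 0.2, a2 = 7), tau),
               model_eval("exponential", c(a = 0.2), tau))
  # y(0) = 1 and monotone non-increasing for random valid parameters
  set.seed(3)
  for (i in 1:25) {
    pars <- list(
      exponential = c(a = runif(1, 0, 5)),
      biexponential = c(f = runif(1), a1 = runif(1, 0, 5), a2 = runif(1, 0, 5)),
      harmonic = c(a = runif(1, 0, 5)),
      weibull = c(a = runif(1, 0.01, 2), n = runif(1, 0.1, 5)))
    for (m in names(pars)) {
      y <- model_eval(m, pars[[m]], tau)
      expect_equal(y[1], 1)
      expect_true(all(diff(y) <= 1e-12))
    }
  }
})

test_that("extract_decline normalizes by the peak and drops flagged points", {
  days <- 0:30
  fl <- ifelse(days <= 10, 10 * 2^days / 2^10 * 100, 1000 * exp(-0.2 * (days - 10)))
  curve <- data.frame(day = days, fluorescence = fl)
  ph <- extract_decline(curve)
  expect_s3_class(ph, "decline_phase")
  expect_equal(ph$tau[1], 0)
  expect_equal(ph$y[1], 1)
  expect_equal(ph$n_points, 21L)

  # below-detection points mid-decline are excluded, the tau gap remains
  curve$below_detection <- c(rep(FALSE, 15), TRUE, TRUE, rep(FALSE, 14))
  ph2 <- extract_decline(curve)
  expect_equal(ph2$n_points, 19L)
  expect_false(any(ph2$tau %in% c(5, 6)))

  riser <- data.frame(day = 0:10, fluorescence = exp(0.4 * (0:10)))
  expect_error(extract_decline(riser), "decline not detected")
})

test_that("rmse matches hand computation and a brute-force oracle", {
  ph <- make_phase(c(0, 1), c(1, 1))
  expect_equal(decline_rmse("exponential", c(a = log(2)), ph),
               sqrt(mean(c(0, 0.5)^2)), tolerance = 1e-12)
  expect_equal(decline_rmse("exponential", c(a = log(2)), ph), 0.3536,
               tolerance = 1e-3)
  # perfect fit
  tau <- 0:20
  expect_equal(decline_rmse("harmonic", c(a = 0.3),
                            make_phase(tau, 1 / (1 + 0.3 * tau))), 0)
  # random instances against an independent elementwise recomputation
  set.seed(8)
  for (i in 1:1000) {
    tau <- sort(runif(8, 0, 50))
    y <- runif(8, 0, 1.2)
    a <- runif(1, 0, 2)
    got <- decline_rmse("exponential", c(a = a), make_phase(tau, y))
    resid2 <- vapply(seq_along(tau), function(j) (y[j] - exp(-a * tau[j]))^2, 0)
    expect_equal(got, sqrt(sum(resid2) / 8), tolerance = 1e-12)
  }
})

test_that("BIC arithmetic penalizes parameters as expected", {
  # equal RSS, k = 1 vs 3, m = 30: difference is 2 log(30)
  tau <- 0:29
  y <- exp(-0.1 * tau) + 0.01 * sin(tau)  # imperfect for both
  ph <- make_phase(tau, y)
  b1 <- decline_bic("exponential", c(a = 0.1), ph)
  b3 <- decline_bic("biexponential", c(f = 1, a1 = 0.1, a2 = 0.1), ph)
  expect_equal(b3 - b1, 2 * log(30), tolerance = 1e-10)

  # k = 1, m = 10, RSS = 0.1 -> 10 log(0.01) + log(10)
  tau2 <- 0:9
  y2 <- exp(-0.2 * tau2) + sqrt(0.01)  # RSS = 10 * 0.01 = 0.1
  ph2 <- make_phase(tau2, y2)
  expect_equal(decline_bic("exponential", c(a = 0.2), ph2),
               10 * log(0.01) + log(10), tolerance = 1e-10)
  expect_equal(10 * log(0.01) + log(10), -43.75, tolerance = 1e-3)

  # exact zero residual: -Inf sentinel with flag
  ph3 <- make_phase(tau2, exp(-0.2 * tau2))
  b <- decline_bic("exponential", c(a = 0.2), ph3)
  expect_identical(as.numeric(b), -Inf)
  expect_true(attr(b, "perfect_fit"))
})

test_that("BIC selects the bi-exponential on well-separated two-population data", {
  set.seed(31)
  tau <- seq(0, 40, length.out = 30)
  y_true <- model_eval("biexponential", c(f = 0.6, a1 = 1.0, a2 = 0.03), tau)
  wins <- 0L
  n_sim <- 100
  for (i in seq_len(n_sim)) {
    y <- y_true * rlnorm(30, 0, 0.05)
    fa <- fit_all_models(make_phase(tau, y), seed = i, n_random_starts = 8L)
    if (fa$best_bic == "biexponential") wins <- wins + 1L
  }
  expect_gte(wins / n_sim, 0.8)
})

test_that("weibull_td matches analytic and root-solving oracles and inverts the model", {
  # n = 1 exponential limit: two decades in 20 days
  expect_equal(weibull_td(c(a = log(100) / 20, n = 1), d = 2), 20, tolerance = 1e-12)
  # numeric root-solve oracle
  td_oracle <- function(a, n, d) {
    uniroot(function(x) exp(-a * x^n) - 10^(-d), c(1e-9, 1e6), tol = 1e-12)$root
  }
  expect_equal(weibull_td(c(a = 0.01, n = 2), d = 2), td_oracle(0.01, 2, 2),
               tolerance = 1e-8)
  expect_equal(weibull_td(c(a = 0.01, n = 2), d = 2), sqrt(log(100) / 0.01),
               tolerance = 1e-12)
  set.seed(12)
  for (i in 1:50) {
    p <- c(a = runif(1, 0.001, 2), n = runif(1, 0.1, 5))
    d <- runif(1, 0.5, 4)
    td <- weibull_td(p, d)
    # inversion: model value at td is exactly 10^-d
    expect_equal(model_eval("weibull", p, td), 10^(-d),
                 tolerance = 1e-10)
    # monotone in d
    expect_gt(weibull_td(p, d + 1), td)
  }
  # scale-form conversion describes the same curve
  p <- c(a = 0.05, n = 0.7)
  ap <- weibull_scale(p)
  tau <- seq(0.1, 60, by = 0.7)
  expect_equal(exp(-(tau / ap)^p[["n"]]), model_eval("weibull", p, tau),
               tolerance = 1e-12)
})

test_that("noiseless data from each model is recovered to 1e-4 and BIC picks the generator", {
  tau <- seq(0, 60, length.out = 40)
  truths <- list(
    exponential = c(a = 0.1),
    biexponential = c(f = 0.7, a1 = 1.2, a2 = 0.05),
    harmonic = c(a = 0.3),
    weibull = c(a = 0.02, n = 0.5))
  for (m in names(truths)) {
    ph <- make_phase(tau, model_eval(m, truths[[m]], tau))
    fit <- fit_decline(ph, m, seed = 2)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$params - truths[[m]])), 1e-4)
    expect_lt(fit$rmse, 1e-6)
    fa <- fit_all_models(ph, seed = 3, n_random_starts = 20L)
    expect_identical(fa$best_bic, m)
  }
})

test_that("the fitted Weibull optimum beats a dense grid search", {
  tau <- seq(0, 120, by = 2)
  ph <- make_phase(tau, model_eval("weibull", c(a = 0.02, n = 0.5), tau))
  fit <- fit_decline(ph, "weibull", seed = 4)
  expect_lt(max(abs(fit$params - c(0.02, 0.5))), 1e-4)
  grid <- expand.grid(a = seq(0.001, 0.2, length.out = 60),
                      n = seq(0.05, 3, length.out = 60))
  grid_rmse <- vapply(seq_len(nrow(grid)), function(i) {
    decline_rmse("weibull", c(a = grid$a[i], n = grid$n[i]), ph)
  }, 0)
  expect_lte(fit$rmse, min(grid_rmse))
})

test_that("nested models agree where they coincide", {
  set.seed(17)
  tau <- seq(0, 50, length.out = 35)
  y <- exp(-0.15 * tau) * rlnorm(35, 0, 0.03)
  ph <- make_phase(tau, y)
  fe <- fit_decline(ph, "exponential", seed = 21)
  fw <- fit_decline(ph, "weibull", seed = 22)
  fb <- fit_decline(ph, "biexponential", seed = 23)
  # Weibull at n ~ 1 and bi-exponential cannot do worse than exponential
  expect_lte(fw$rmse, fe$rmse + 1e-8)
  expect_lte(fb$rmse, fe$rmse + 1e-8)
  expect_equal(fw$params[["n"]], 1, tolerance = 0.05)
  # bi-exponential labelling convention
  expect_gte(fb$params[["a1"]], fb$params[["a2"]])
})

test_that("fits are deterministic given the seed", {
  set.seed(71)
  tau <- seq(0, 80, length.out = 50)
  y <- model_eval("weibull", c(a = 0.1, n = 0.8), tau) * rlnorm(50, 0, 0.05)
  ph <- make_phase(tau, y)
  f1 <- fit_all_models(ph, seed = 9, n_random_starts = 10L)
  f2 <- fit_all_models(ph, seed = 9, n_random_starts = 10L)
  expect_identical(f1$fits$weibull$params, f2$fits$weibull$params)
  expect_identical(vapply(f1$fits, `[[`, 0, "rmse"),
                   vapply(f2$fits, `[[`, 0, "rmse"))
  # RNG state of the caller is untouched
  state <- .Random.seed
  fit_decline(ph, "exponential", seed = 5)
  expect_identical(state, .Random.seed)
})

test_that("noiseless harmonic data makes harmonic the lowest-RMSE model", {
  tau <- seq(0, 60, length.out = 40)
  ph <- make_phase(tau, model_eval("harmonic", c(a = 0.5), tau))
  fa <- fit_all_models(ph, seed = 13, n_random_starts = 20L)
  expect_identical(fa$best_rmse, "harmonic")

  # exponential data: exponential and Weibull both essentially perfect,
  # BIC prefers the 1-parameter exponential
  ph2 <- make_phase(tau, model_eval("exponential", c(a = 0.12), tau))
  fa2 <- fit_all_models(ph2, seed = 14, n_random_starts = 20L)
  expect_lt(fa2$fits$exponential$rmse, 1e-6)
  expect_lt(fa2$fits$weibull$rmse, 1e-6)
  expect_identical(fa2$best_bic, "exponential")
})

test_that("Weibull shape is recovered within 0.15 on most noisy declines", {
  set.seed(55)
  errs <- vapply(1:20, function(i) {
    n_true <- runif(1, 0.3, 2.5)
    a_true <- 2 * log(10) / runif(1, 15, 100)^n_true
    tau <- seq(0, 100, length.out = 60)
    y <- model_eval("weibull", c(a = a_true, n = n_true), tau) * rlnorm(60, 0, 0.05)
    fit <- fit_decline(make_phase(tau, y), "weibull", seed = 100 + i,
                       n_random_starts = 20L)
    abs(fit$params[["n"]] - n_true)
  }, 0)
  expect_lte(median(errs), 0.15)
})

test_that("summarize_fits reports group shape statistics and passes td2 through", {
  fits <- data.frame(
    culture_id = sprintf("c%d", 1:8), model = "weibull",
    a = 0.1, f = NA, a1 = NA, a2 = NA,
    n = c(2.0, 2.2, 1.9, 2.3, 0.4, 0.5, 0.35, 0.45),
    rmse = 0.1, bic = -100,
    td2 = c(rep(12, 4), rep(300, 4)), converged = TRUE, status = "ok",
    pro_strain = "MED4", alt_strain = c(rep("none", 4), rep("AltDE", 4)),
    replicate = 1:8,
    treatment = c(rep("axenic_pro", 4), rep("coculture", 4)))
  s <- summarize_fits(fits)
  ax <- s$by_treatment[s$by_treatment$group == "axenic_pro", ]
  co <- s$by_treatment[s$by_treatment$group == "coculture", ]
  expect_equal(ax$shape_mean, mean(c(2.0, 2.2, 1.9, 2.3)))
  expect_equal(ax$td2_mean, 12)
  expect_equal(co$td2_mean, 300)
  expect_lt(s$shape_ttest$p.value, 0.001)
  # all-identical fits: SD 0
  fits2 <- fits; fits2$n <- 1.5; fits2$td2 <- 50
  s2 <- summarize_fits(fits2)
  expect_equal(s2$by_treatment$shape_sd, c(0, 0))
  # td2 pass-through of the exponential-limit fit
  expect_equal(weibull_td(c(a = log(100) / 20, n = 1), 2), 20, tolerance = 1e-10)
})
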