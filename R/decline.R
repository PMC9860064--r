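# Mortality-model fitting for the decline phase of batch cultures.
#
# Four descriptive models of culture mortality are supported, all expressed
# on peak-normalized fluorescence y = FL / FLmax as a function of time since
# decline onset tau = t - tmax:
#
#   exponential     y = exp(-a tau)                     1 free parameter
#   biexponential   y = f exp(-a1 tau) + (1-f) exp(-a2 tau)   3
#   harmonic        y = 1 / (1 + a tau)                 1
#   weibull         y = exp(-a tau^n)                   2
#
# The Weibull model is fitted in rate form exp(-a tau^n); the equivalent
# scale form exp(-(tau/a')^n) has a' = a^(-1/n) (see weibull_scale()).

#' Names of the supported mortality models
#' @return character vector of the four model names.
#' @export
decline_model_names <- function() c("exponential", "biexponential", "harmonic", "weibull")

model_par_names <- function(model) {
  switch(model,
         exponential = "a",
         biexponential = c("f", "a1", "a2"),
         harmonic = "a",
         weibull = c("a", "n"),
         stop("unknown model: ", model, call. = FALSE))
}

# free-parameter counts used by the BIC penalty
model_k <- function(model) {
  c(exponential = 1L, biexponential = 3L, harmonic = 1L, weibull = 2L)[[model]]
}

model_bounds <- function(model) {
  switch(model,
         exponential = list(lower = c(a = 0), upper = c(a = 50)),
         biexponential = list(lower = c(f = 0, a1 = 0, a2 = 0),
                              upper = c(f = 1, a1 = 50, a2 = 50)),
         harmonic = list(lower = c(a = 0), upper = c(a = 50)),
         weibull = list(lower = c(a = 0, n = 0.01), upper = c(a = 50, n = 10)),
         stop("unknown model: ", model, call. = FALSE))
}

#' Extract the decline phase of a curve
#'
#' Restricts the curve to days at or after the fluorescence peak, converts
#' days to time-since-decline-onset `tau = t - tmax` and normalizes
#' fluorescence by the peak value, so `y(0) = 1` by construction. Points
#' flagged below detection are excluded (not clamped); the gaps remain in
#' `tau`.
#'
#' @param curve data.frame with columns `day`, `fluorescence` and optionally
#'   `below_detection`.
#' @param peak list with `flmax`, `tmax` as returned by [find_peak()].
#' @param min_points minimum number of usable decline points (default 5).
#' @return Object of class `decline_phase`: list with `tau`, `y`, `n_points`,
#'   `flmax`, `tmax`.
#' @export
extract_decline <- function(curve, peak = find_peak(curve), min_points = 5L) {
  bd <- if ("below_detection" %in% names(curve)) curve$below_detection
        else (!is.finite(curve$fluorescence) | curve$fluorescence <= 0)
  keep <- curve$day >= peak$tmax & !bd
  if (sum(keep) < min_points) {
    stop("decline not detected: fewer than ", min_points,
         " above-detection points at or after the peak", call. = FALSE)
  }
  tau <- curve$day[keep] - peak$tmax
  y <- curve$fluorescence[keep] / peak$flmax
  structure(list(tau = tau, y = y, n_points = length(tau),
                 flmax = peak$flmax, tmax = peak$tmax),
            class = "decline_phase")
}

#' @export
print.decline_phase <- function(x, ...) {
  cat(sprintf("<decline_phase> %d points, tau 0..%.3g days, peak %.3g au at day %.3g\n",
              x$n_points, max(x$tau), x$flmax, x$tmax))
  invisible(x)
}

#' Evaluate a mortality model on normalized fluorescence
#'
#' All models satisfy `y(0) = 1` for any valid parameters and are
#' non-increasing in `tau` when rates are non-negative.
#'
#' @param model one of [decline_model_names()].
#' @param params named numeric vector with the model's parameters
#'   (`a`; or `f`, `a1`, `a2`; or `a`, `n`).
#' @param tau numeric vector of days since decline onset (`>= 0`).
#' @return numeric vector of model values on the normalized scale.
#' @export
model_eval <- function(model, params, tau) {
  p <- as.list(params)
  switch(model,
         exponential = exp(-p$a * tau),
         biexponential = p$f * exp(-p$a1 * tau) + (1 - p$f) * exp(-p$a2 * tau),
         harmonic = 1 / (1 + p$a * tau),
         weibull = exp(-p$a * tau^p$n),
         stop("unknown model: ", model, call. = FALSE))
}

#' Root mean square error of a mortality model on a decline phase
#'
#' Plain (unweighted) residuals on the normalized-fluorescence scale,
#' independent of the robust loss used during optimization.
#'
#' @inheritParams model_eval
#' @param phase a [extract_decline()] result.
#' @return non-negative scalar.
#' @export
decline_rmse <- function(model, params, phase) {
  r <- phase$y - model_eval(model, params, phase$tau)
  sqrt(mean(r^2))
}

#' Gaussian BIC of a mortality model on a decline phase
#'
#' `BIC = m log(RSS/m) + k log(m)` with `m` the number of points and `k` the
#' model's free-parameter count. The residual variance `RSS/m` is floored at
#' 1e-12 (RMSE 1e-6 on the normalized scale) so that among numerically
#' perfect fits the parameter-count term decides; an exactly zero RMSE
#' returns `-Inf` with attribute `perfect_fit = TRUE`.
#'
#' @inheritParams decline_rmse
#' @return scalar BIC (smaller is better).
#' @export
decline_bic <- function(model, params, phase) {
  m <- phase$n_points
  k <- model_k(model)
  rss <- sum((phase$y - model_eval(model, params, phase$tau))^2)
  if (rss == 0) {
    out <- -Inf
    attr(out, "perfect_fit") <- TRUE
    return(out)
  }
  m * log(max(rss / m, 1e-12)) + k * log(m)
}

# soft-L1 robust cost of residual vector r at scale fscale:
# fscale^2 * sum(2 (sqrt(1 + (r/fscale)^2) - 1)); quadratic near 0,
# linear for |r| >> fscale.
soft_l1_cost <- function(r, fscale = 0.1) {
  z <- (r / fscale)^2
  fscale^2 * sum(2 * (sqrt(1 + z) - 1))
}

# partial derivatives of the model curve w.r.t. its parameters,
# columns in the parameter order of model_par_names()
model_grad <- function(model, params, tau) {
  p <- as.list(params)
  switch(model,
         exponential = cbind(a = -tau * exp(-p$a * tau)),
         biexponential = {
           e1 <- exp(-p$a1 * tau); e2 <- exp(-p$a2 * tau)
           cbind(f = e1 - e2, a1 = -p$f * tau * e1, a2 = -(1 - p$f) * tau * e2)
         },
         harmonic = cbind(a = -tau / (1 + p$a * tau)^2),
         weibull = {
           tn <- tau^p$n
           m <- exp(-p$a * tn)
           dlog <- ifelse(tau > 0, log(tau), 0)  # tau^n log(tau) -> 0 as tau -> 0
           cbind(a = -tn * m, n = -p$a * tn * dlog * m)
         })
}

#' Fit one mortality model to a decline phase
#'
#' Bounded nonlinear least squares of the model against normalized
#' fluorescence under a smooth-L1 (soft-L1) robust loss with residual scale
#' 0.1, minimized by multi-start L-BFGS-B. The start set is the all-0.5
#' parameter vector plus `n_random_starts` draws uniform within the bounds;
#' the start achieving the lowest plain RMSE wins, ties broken by earlier
#' start index. Bounds: rates in \[0, 50\], Weibull shape `n` in
#' \[0.01, 10\], subpopulation fraction `f` in \[0, 1\]. For the
#' bi-exponential model the labelling `a1 >= a2` is enforced by a post-hoc
#' swap of `(f, a1)` and `(1 - f, a2)`.
#'
#' @param phase a [extract_decline()] result.
#' @param model one of [decline_model_names()].
#' @param n_random_starts number of random starts in addition to the 0.5
#'   start (default 50).
#' @param seed optional integer; fixes the random starts without disturbing
#'   the caller's RNG.
#' @param fscale residual scale of the soft-L1 loss (default 0.1).
#' @return Object of class `decline_fit`: list with `model`, `params` (named),
#'   `rmse`, `bic`, `converged`, `n_starts_used`, `seed`, `phase`.
#' @export
fit_decline <- function(phase, model, n_random_starts = 50L, seed = NULL,
                        fscale = 0.1) {
  stopifnot(inherits(phase, "decline_phase"), n_random_starts >= 1L)
  bounds <- model_bounds(model)
  npar <- length(bounds$lower)
  obj <- function(p) {
    soft_l1_cost(phase$y - model_eval(model, p, phase$tau), fscale)
  }
  gr <- function(p) {
    r <- phase$y - model_eval(model, p, phase$tau)
    w <- 2 * r / sqrt(1 + (r / fscale)^2)  # d cost / d r
    -drop(crossprod(model_grad(model, p, phase$tau), w))
  }
  # random starts: fractions uniform on [0, 1]; rate and shape parameters
  # log-uniform across their bounds, since decay rates spanning orders of
  # magnitude make uniform draws land almost surely in the flat large-rate
  # region where the fit cannot escape
  starts <- with_seed(seed, {
    rand <- sapply(seq_len(npar), function(j) {
      lo <- bounds$lower[j]; hi <- bounds$upper[j]
      if (names(bounds$lower)[j] == "f") {
        stats::runif(n_random_starts, lo, hi)
      } else {
        exp(stats::runif(n_random_starts, log(max(lo, 1e-3)), log(hi)))
      }
    })
    rand <- matrix(rand, nrow = n_random_starts)
    rbind(rep(0.5, npar), rand)
  })
  colnames(starts) <- names(bounds$lower)
  best <- NULL
  best_rmse <- Inf
  any_converged <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], obj, gr, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok <- fit$convergence == 0L
    any_converged <- any_converged || ok
    r <- decline_rmse(model, fit$par, phase)
    if (r < best_rmse) {  # strict: ties keep the earlier start
      best_rmse <- r
      best <- fit
    }
  }
  if (is.null(best)) {
    params <- structure(rep(NA_real_, npar), names = names(bounds$lower))
    return(structure(list(model = model, params = params, rmse = NA_real_,
                          bic = NA_real_, converged = FALSE,
                          n_starts_used = nrow(starts), seed = seed,
                          phase = phase),
                     class = "decline_fit"))
  }
  # polish the winning start with a tighter tolerance
  polished <- tryCatch(
    stats::optim(best$par, obj, gr, method = "L-BFGS-B",
                 lower = bounds$lower, upper = bounds$upper,
                 control = list(maxit = 2000L, factr = 1, pgtol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(polished) &&
      decline_rmse(model, polished$par, phase) <= best_rmse) {
    best <- polished
    best_rmse <- decline_rmse(model, best$par, phase)
  }
  params <- best$par
  if (model == "biexponential" && params[["a1"]] < params[["a2"]]) {
    params <- c(f = 1 - params[["f"]], a1 = params[["a2"]], a2 = params[["a1"]])
  }
  structure(list(model = model, params = params, rmse = best_rmse,
                 bic = decline_bic(model, params, phase),
                 converged = any_converged, n_starts_used = nrow(starts),
                 seed = seed, phase = phase),
            class = "decline_fit")
}

#' @export
print.decline_fit <- function(x, ...) {
  cat(sprintf("<decline_fit> %s model%s\n", x$model,
              if (!x$converged) " (NOT converged)" else ""))
  cat("  ", paste(sprintf("%s = %.5g", names(x$params), x$params), collapse = ", "), "\n")
  cat(sprintf("  rmse = %.5g, bic = %.5g, %d points\n",
              x$rmse, x$bic, x$phase$n_points))
  if (x$model == "weibull" && all(is.finite(x$params)) && x$params[["a"]] > 0) {
    cat(sprintf("  td2 = %.4g days, shape class: %s\n",
                weibull_td(x$params, d = 2), weibull_shape_class(x$params[["n"]])))
  }
  invisible(x)
}

#' @export
coef.decline_fit <- function(object, ...) object$params

#' @export
predict.decline_fit <- function(object, newdata = NULL, ...) {
  tau <- if (is.null(newdata)) object$phase$tau
         else if (is.list(newdata)) newdata$tau else newdata
  model_eval(object$model, object$params, tau)
}

#' @export
residuals.decline_fit <- function(object, ...) {
  object$phase$y - predict(object)
}

#' @export
summary.decline_fit <- function(object, ...) {
  out <- as.data.frame(as.list(object$params))
  out <- cbind(data.frame(model = object$model), out,
               data.frame(rmse = object$rmse, bic = object$bic,
                          converged = object$converged,
                          n_points = object$phase$n_points))
  if (object$model == "weibull" && all(is.finite(object$params))) {
    out$td2 <- weibull_td(object$params, d = 2)
    out$shape_class <- weibull_shape_class(object$params[["n"]])
  }
  class(out) <- c("summary.decline_fit", "data.frame")
  out
}

#' @export
plot.decline_fit <- function(x, ...) {
  graphics::plot(x$phase$tau, x$phase$y, xlab = "days since decline onset",
                 ylab = "FL / FLmax", ...)
  tt <- seq(0, max(x$phase$tau), length.out = 200)
  graphics::lines(tt, model_eval(x$model, x$params, tt), col = "red3")
  invisible(x)
}

#' Simulate normalized decline observations from a fitted model
#'
#' Draws multiplicative lognormal noise around the fitted curve at the
#' observed time points, the same error model the synthetic-data generator
#' uses.
#'
#' @param object a `decline_fit`.
#' @param nsim number of replicate series.
#' @param seed optional seed.
#' @param cv coefficient of variation of the multiplicative noise.
#' @param ... unused.
#' @return data.frame with columns `sim`, `tau`, `y`.
#' @export
simulate.decline_fit <- function(object, nsim = 1, seed = NULL, cv = 0.05, ...) {
  mu <- predict(object)
  sdlog <- sqrt(log(1 + cv^2))
  with_seed(seed, {
    out <- lapply(seq_len(nsim), function(s) {
      data.frame(sim = s, tau = object$phase$tau,
                 y = mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog))
    })
    do.call(rbind, out)
  })
}

#' Weibull decimal reduction time
#'
#' Time for the population signal to fall by `d` factors of 10 under the
#' rate-form Weibull model `y = exp(-a tau^n)`:
#' `td = (log(10^d) / a)^(1/n)`. It satisfies
#' `model_eval("weibull", params, td) = 10^-d` exactly and is monotone
#' increasing in `d`. `td2` (two decades) is the headline mortality
#' statistic.
#'
#' @param params named vector with `a > 0` and `n > 0`.
#' @param d number of decades of reduction (positive real; default 2).
#' @return time in days.
#' @export
weibull_td <- function(params, d = 2) {
  a <- params[["a"]]; n <- params[["n"]]
  stopifnot(a > 0, n > 0, d > 0)
  (d * log(10) / a)^(1 / n)
}

#' Convert a rate-form Weibull coefficient to the scale form
#'
#' The same curve can be written `exp(-a tau^n)` (rate form, used for
#' fitting) or `exp(-(tau/a')^n)` (scale form); `a' = a^(-1/n)`.
#'
#' @inheritParams weibull_td
#' @return the scale parameter `a'` in days.
#' @export
weibull_scale <- function(params) {
  params[["a"]]^(-1 / params[["n"]])
}

#' Classify a Weibull shape parameter
#'
#' `n > 1`: mortality rate accelerates as starvation proceeds (damage
#' accumulation); `n < 1`: the rate decelerates (acclimation / increasing
#' resistance); `n` within `tol` of 1 is labelled constant (exponential
#' limit).
#'
#' @param n Weibull shape value.
#' @param tol half-width of the "constant" band around 1 (default 0.05).
#' @return one of `"accelerating"`, `"decelerating"`, `"constant"`.
#' @export
weibull_shape_class <- function(n, tol = 0.05) {
  ifelse(abs(n - 1) <= tol, "constant",
         ifelse(n > 1, "accelerating", "decelerating"))
}

#' Fit all four mortality models to one decline phase
#'
#' Runs [fit_decline()] for each model with per-model seeds derived from the
#' base seed (deterministic given `seed`), and labels the winners by RMSE
#' and by BIC.
#'
#' @inheritParams fit_decline
#' @return Object of class `decline_fit_all`: list with `fits` (named list of
#'   `decline_fit`), `best_rmse`, `best_bic` (model names).
#' @export
fit_all_models <- function(phase, seed = NULL, n_random_starts = 50L) {
  models <- decline_model_names()
  fits <- lapply(seq_along(models), function(i) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, i)
    fit_decline(phase, models[i], n_random_starts = n_random_starts, seed = s)
  })
  names(fits) <- models
  rmses <- vapply(fits, function(f) ifelse(is.finite(f$rmse), f$rmse, Inf), 0)
  bics <- vapply(fits, function(f) ifelse(is.na(f$bic), Inf, f$bic), 0)
  structure(list(fits = fits,
                 best_rmse = models[which.min(rmses)],
                 best_bic = models[which.min(bics)]),
            class = "decline_fit_all")
}

#' @export
print.decline_fit_all <- function(x, ...) {
  cat("<decline_fit_all>\n")
  for (m in names(x$fits)) {
    f <- x$fits[[m]]
    cat(sprintf("  %-14s rmse = %.4g  bic = %.4g%s\n", m, f$rmse, f$bic,
                if (!f$converged) " (not converged)" else ""))
  }
  cat(sprintf("  best by RMSE: %s; best by BIC: %s\n", x$best_rmse, x$best_bic))
  invisible(x)
}

#' Fit mortality models to every culture of an experiment set
#'
#' Anchors each curve's decline at its global fluorescence peak, fits the
#' requested models, and returns a long table with one row per
#' (culture, model). Cultures without a usable decline phase are reported
#' with `status` `"decline_undetected"`.
#'
#' @param es an [experiment_set()].
#' @param models model names (default all four).
#' @param n_random_starts random starts per fit.
#' @param seed base seed; per-culture, per-model seeds are derived from it.
#' @return data.frame with columns `culture_id`, `model`, `a`, `f`, `a1`,
#'   `a2`, `n`, `rmse`, `bic`, `td2`, `converged`, `status`, plus metadata
#'   columns.
#' @export
decline_fits <- function(es, models = decline_model_names(),
                         n_random_starts = 50L, seed = 1L) {
  ids <- unique(es$curves$culture_id)
  par_cols <- c("a", "f", "a1", "a2", "n")
  rows <- list()
  for (ci in seq_along(ids)) {
    id <- ids[ci]
    curve <- get_curve(es, id)
    phase <- tryCatch(extract_decline(curve), error = function(e) NULL)
    if (is.null(phase)) {
      row <- as.data.frame(as.list(structure(rep(NA_real_, 5), names = par_cols)))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(culture_id = id, model = NA_character_), row,
              data.frame(rmse = NA_real_, bic = NA_real_, td2 = NA_real_,
                         converged = NA, status = "decline_undetected"))
      next
    }
    for (mi in seq_along(models)) {
      m <- models[mi]
      f <- fit_decline(phase, m, n_random_starts = n_random_starts,
                       seed = derive_seed(seed, ci * 11L + mi))
      vals <- structure(rep(NA_real_, 5), names = par_cols)
      vals[names(f$params)] <- f$params
      td2 <- if (m == "weibull" && is.finite(vals[["a"]]) && vals[["a"]] > 0)
        weibull_td(f$params, d = 2) else NA_real_
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(culture_id = id, model = m),
              as.data.frame(as.list(vals)),
              data.frame(rmse = f$rmse, bic = f$bic, td2 = td2,
                         converged = f$converged, status = "ok"))
    }
  }
  out <- do.call(rbind, rows)
  merge(out, es$metadata[, c("culture_id", "pro_strain", "alt_strain",
                             "replicate", "treatment")],
        by = "culture_id", sort = FALSE)
}

#' Group-level summary of mortality fits
#'
#' Summarizes a [decline_fits()] table per treatment group and per phototroph
#' strain: mean and SD of the Weibull shape `n` and `td2`, RMSE per model,
#' shape-class counts, and a two-sample t-test of the Weibull shape between
#' axenic phototroph cultures and co-cultures.
#'
#' @param fits data.frame from [decline_fits()].
#' @return list of class `decline_summary` with elements `by_treatment`,
#'   `by_strain`, `rmse_by_model`, `shape_classes`, `shape_ttest`.
#' @export
summarize_fits <- function(fits) {
  w <- fits[fits$model %in% "weibull" & fits$status == "ok", , drop = FALSE]
  agg <- function(df, by) {
    res <- lapply(split(df, df[[by]]), function(g) {
      data.frame(group = g[[by]][1], n_curves = nrow(g),
                 shape_mean = mean(g$n), shape_sd = stats::sd(g$n),
                 td2_mean = mean(g$td2), td2_sd = stats::sd(g$td2),
                 rmse_mean = mean(g$rmse))
    })
    out <- do.call(rbind, res); rownames(out) <- NULL; out
  }
  by_treatment <- agg(w, "treatment")
  by_strain <- agg(w[w$treatment == "coculture", , drop = FALSE], "pro_strain")
  ok <- fits[fits$status == "ok", , drop = FALSE]
  rmse_by_model <- do.call(rbind, lapply(split(ok, list(ok$model, ok$treatment), drop = TRUE),
    function(g) data.frame(model = g$model[1], treatment = g$treatment[1],
                           rmse_mean = mean(g$rmse), rmse_sd = stats::sd(g$rmse),
                           n_curves = nrow(g))))
  rownames(rmse_by_model) <- NULL
  shape_classes <- table(treatment = w$treatment, class = weibull_shape_class(w$n))
  ax <- w$n[w$treatment == "axenic_pro"]
  co <- w$n[w$treatment == "coculture"]
  shape_ttest <- if (length(ax) >= 2 && length(co) >= 2)
    tryCatch(stats::t.test(ax, co), error = function(e) NULL) else NULL
  structure(list(by_treatment = by_treatment, by_strain = by_strain,
                 rmse_by_model = rmse_by_model, shape_classes = shape_classes,
                 shape_ttest = shape_ttest),
            class = "decline_summary")
}

#' @export
print.decline_summary <- function(x, ...) {
  cat("<decline_summary>\n  Weibull shape and td2 by treatment:\n")
  print(x$by_treatment, row.names = FALSE)
  cat("  RMSE by model and treatment:\n")
  print(x$rmse_by_model, row.names = FALSE)
  if (!is.null(x$shape_ttest)) {
    cat(sprintf("  shape t-test (axenic vs co-culture): t = %.3f, p = %.3g\n",
                x$shape_ttest$statistic, x$shape_ttest$p.value))
  }
  invisible(x)
}
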