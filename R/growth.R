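# Growth-phase parameter extraction: peak detection, exponential-window
# search, log-linear regression, and group comparisons.

#' Locate the fluorescence peak of a curve
#'
#' The peak anchors both the growth window (which ends at the peak) and the
#' decline phase (which starts there). Ties are broken to the earliest day so
#' the decline window starts as early as possible.
#'
#' @param curve data.frame with columns `day` and `fluorescence` (as returned
#'   by [get_curve()]), days strictly increasing.
#' @return list with `flmax` (peak fluorescence, arbitrary units) and
#'   `tmax` (day of the peak).
#' @export
find_peak <- function(curve) {
  fl <- curve$fluorescence
  if (!any(is.finite(fl) & fl > 0)) {
    stop("no positive fluorescence values: no signal to locate a peak",
         call. = FALSE)
  }
  i <- which.max(fl)  # which.max returns the first maximum: earliest-day tie-break
  list(flmax = fl[i], tmax = curve$day[i])
}

#' Find the exponential growth window of a curve
#'
#' Searches the contiguous run of positive-fluorescence points ending at the
#' peak for the exponential segment, shrinking from the front (dropping
#' early lag points one at a time), matching the lag-exponential-peak
#' structure of a batch culture. A window is accepted when its log-linear
#' regression attains r^2 above `r2_threshold` with positive slope, dropping
#' one more leading point would not improve r^2 by more than `improve_tol`,
#' and the leading point is not a clear outlier against the rest of the
#' window (studentized against the remaining residuals); the last two rules
#' stop lag points that leave r^2 above the threshold from leaking into the
#' window, so on noiseless data the recovered rate is exact. Windows shorter
#' than `min_points` are not considered.
#'
#' @inheritParams find_peak
#' @param r2_threshold minimum coefficient of determination for acceptance.
#' @param min_points minimum window length (default 4; r^2 on 3 points is
#'   uninformative).
#' @param improve_tol keep shrinking while dropping the leading point gains
#'   more than this much r^2 (default 0.005).
#' @return integer vector `c(first, last)` of row indices into `curve`.
#' @export
detect_growth_phase <- function(curve, r2_threshold = 0.9, min_points = 4L,
                                improve_tol = 0.005) {
  fl <- curve$fluorescence
  peak <- find_peak(curve)
  i_peak <- which(curve$day == peak$tmax)[1]
  # maximal run of positive values ending at the peak
  first <- i_peak
  while (first > 1L && is.finite(fl[first - 1L]) && fl[first - 1L] > 0) {
    first <- first - 1L
  }
  if (i_peak - first + 1L < min_points) {
    stop("growth not detected: fewer than ", min_points,
         " positive points ending at the peak", call. = FALSE)
  }
  win_fit <- function(s) {
    ly <- log(fl[s:i_peak])
    f <- stats::lm(ly ~ curve$day[s:i_peak])
    sst <- sum((ly - mean(ly))^2)
    r <- stats::residuals(f)
    # direct r2 avoids summary.lm's perfect-fit warning on noiseless data
    list(mu = stats::coef(f)[[2]],
         r2 = if (sst > 0) 1 - sum(r^2) / sst else 0,
         resid = r)
  }
  for (s in seq.int(first, i_peak - min_points + 1L)) {
    f <- win_fit(s)
    if (!is.finite(f$mu) || f$mu <= 0 || f$r2 <= r2_threshold) next
    if (s < i_peak - min_points + 1L) {
      nxt <- win_fit(s + 1L)
      if (is.finite(nxt$mu) && nxt$mu > 0 && nxt$r2 - f$r2 > improve_tol) next
      sd_rest <- stats::sd(f$resid[-1])
      if (abs(f$resid[1]) > 3 * max(sd_rest, 1e-12)) next
    }
    return(c(first = s, last = i_peak))
  }
  stop("growth not detected: no window of length >= ", min_points,
       " with r2 > ", r2_threshold, " and positive slope", call. = FALSE)
}

#' Fit the exponential growth model to a window of a curve
#'
#' Ordinary least squares of `ln(FL)` on day over the window, following the
#' batch growth model `N_t = N_0 exp(mu (t - L))`: the slope is the growth
#' rate `mu` (per day) and the lag `L` (days) is recovered from the intercept
#' `b` as `L = (ln(FL_first) - b) / mu`, clipped below at 0, where `FL_first`
#' is the first observed positive fluorescence of the curve.
#'
#' @inheritParams find_peak
#' @param window indices from [detect_growth_phase()].
#' @return Object of class `growth_fit` with components `mu`, `lag`,
#'   `N0_fit` (exp of the intercept), `flmax`, `tmax`, `r2`, `window`, and the
#'   regression data.
#' @export
fit_growth <- function(curve, window = detect_growth_phase(curve)) {
  idx <- seq.int(window[1], window[2])
  t <- curve$day[idx]
  fl <- curve$fluorescence[idx]
  if (length(unique(t)) < 2L) stop("singular design: all days equal", call. = FALSE)
  if (any(!is.finite(fl) | fl <= 0)) {
    stop("growth window contains non-positive fluorescence", call. = FALSE)
  }
  ly <- log(fl)
  f <- stats::lm(ly ~ t)
  b <- stats::coef(f)[[1]]
  mu <- stats::coef(f)[[2]]
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(f)^2) / sst else 0
  peak <- find_peak(curve)
  fl_first <- curve$fluorescence[which(curve$fluorescence > 0)[1]]
  lag <- max(0, (log(fl_first) - b) / mu)
  structure(list(mu = mu, lag = lag, N0_fit = exp(b),
                 flmax = peak$flmax, tmax = peak$tmax, r2 = r2,
                 window = window, intercept = b,
                 data = data.frame(day = t, fluorescence = fl)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit>\n")
  cat(sprintf("  mu = %.4f /day, lag = %.2f days, r2 = %.4f\n", x$mu, x$lag, x$r2))
  cat(sprintf("  peak %.3g au at day %.3g; window points %d..%d\n",
              x$flmax, x$tmax, x$window[1], x$window[2]))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(mu = object$mu, lag = object$lag, N0_fit = object$N0_fit)
}

#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$day else newdata$day
  exp(object$intercept + object$mu * t)
}

#' @export
residuals.growth_fit <- function(object, ...) {
  log(object$data$fluorescence) - (object$intercept + object$mu * object$data$day)
}

#' @export
summary.growth_fit <- function(object, ...) {
  out <- data.frame(mu = object$mu, lag = object$lag, N0_fit = object$N0_fit,
                    flmax = object$flmax, tmax = object$tmax, r2 = object$r2,
                    n_points = nrow(object$data))
  class(out) <- c("summary.growth_fit", "data.frame")
  out
}

#' @export
plot.growth_fit <- function(x, curve = NULL, ...) {
  d <- if (is.null(curve)) x$data else curve
  graphics::plot(d$day, d$fluorescence, log = "y", xlab = "day",
                 ylab = "fluorescence (au)", ...)
  tt <- seq(min(x$data$day), max(x$data$day), length.out = 50)
  graphics::lines(tt, exp(x$intercept + x$mu * tt), col = "red3")
  invisible(x)
}

#' Growth features for every culture in an experiment set
#'
#' Runs peak detection, growth-window search and log-linear fitting on each
#' culture, returning one row per culture. Cultures where no window with
#' r^2 > 0.9 exists are reported with `status` `"growth_undetected"` (or
#' `"no_signal"`) and NA parameters rather than being dropped silently.
#'
#' @param es an [experiment_set()].
#' @return data.frame with columns `culture_id`, `mu`, `lag`, `flmax`, `tmax`,
#'   `r2`, `status`, merged with the metadata strain columns.
#' @export
growth_features <- function(es) {
  ids <- unique(es$curves$culture_id)
  rows <- lapply(ids, function(id) {
    curve <- get_curve(es, id)
    res <- tryCatch({
      gf <- fit_growth(curve)
      data.frame(culture_id = id, mu = gf$mu, lag = gf$lag, flmax = gf$flmax,
                 tmax = gf$tmax, r2 = gf$r2, status = "ok")
    }, error = function(e) {
      status <- if (grepl("no positive fluorescence", conditionMessage(e)))
        "no_signal" else "growth_undetected"
      peak <- tryCatch(find_peak(curve), error = function(e) list(flmax = NA_real_, tmax = NA_real_))
      data.frame(culture_id = id, mu = NA_real_, lag = NA_real_,
                 flmax = peak$flmax, tmax = peak$tmax, r2 = NA_real_, status = status)
    })
    res
  })
  out <- do.call(rbind, rows)
  merge(out, es$metadata[, c("culture_id", "experiment", "pro_strain",
                             "alt_strain", "replicate", "treatment")],
        by = "culture_id", sort = FALSE)
}

#' Compare a per-culture scalar across strain groups
#'
#' One-way ANOVA followed by all pairwise two-sample t-tests (pooled
#' variance) with Bonferroni correction: each pairwise p-value is multiplied
#' by the number of pairs and capped at 1. Groups with fewer than 2 values
#' are dropped with a warning.
#'
#' @param values numeric vector, one value per culture.
#' @param groups group labels (e.g. phototroph strain), same length.
#' @return list of class `group_comparison` with `anova` (data.frame: `df1`,
#'   `df2`, `F`, `p`) and `pairwise` (data.frame: `group1`, `group2`, `diff`,
#'   `p`, `p_bonferroni`).
#' @export
compare_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0L) {
    warning("dropping group(s) with fewer than 2 values: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !groups %in% small
    values <- values[keep]; groups <- groups[keep]
  }
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups with >= 2 values each", call. = FALSE)
  a <- stats::anova(stats::lm(values ~ g))
  anova_tab <- data.frame(df1 = a$Df[1], df2 = a$Df[2],
                          F = a$`F value`[1], p = a$`Pr(>F)`[1])
  pairs <- utils::combn(levels(g), 2)
  n_pairs <- ncol(pairs)
  pw <- lapply(seq_len(n_pairs), function(j) {
    x <- values[g == pairs[1, j]]; y <- values[g == pairs[2, j]]
    tt <- stats::t.test(x, y, var.equal = TRUE)
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               diff = mean(x) - mean(y), p = tt$p.value,
               p_bonferroni = min(1, tt$p.value * n_pairs))
  })
  structure(list(anova = anova_tab, pairwise = do.call(rbind, pw)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  cat(sprintf("  one-way ANOVA: F(%d,%d) = %.3f, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  cat("  pairwise (Bonferroni-corrected):\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
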