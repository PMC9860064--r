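# Nitrogen-quota biomass accounting: cell counts -> N biomass (umol N/L),
# carrying-capacity feasibility against the supplied N, and synergy
# (log2 fold change) classification of co-culture vs axenic controls.

#' Default cellular nitrogen quotas
#'
#' fg N per cell used to convert flow-cytometry counts to nitrogen biomass:
#' 7 for the high-light phototroph strains (MED4, MIT9312, MIT0604), 10.5
#' for NATL2A (LLI), 14 for MIT9313 (LLIV), and 13 for all *Alteromonas*
#' strains. These sit at the lower end of measured values (up to ~20 fg for
#' low-light phototrophs and ~25 fg for the heterotroph under replete
#' growth), reflecting reduced cell N content under long-term N stress.
#'
#' @return named numeric vector, fg N per cell.
#' @export
default_quotas <- function() {
  c(MED4 = 7, MIT9312 = 7, MIT0604 = 7, NATL2A = 10.5, MIT9313 = 14,
    HOT1A3 = 13, BS11 = 13, ATCC27126 = 13, AltDE1 = 13, AltDE = 13)
}

#' Convert a cell count to nitrogen biomass
#'
#' `biomass (umol N / L) = X (cells/ml) * Q_N (fg N/cell) * 1e-6 / MW_N`,
#' the chain fg -> umol (1e-9) and ml -> L (1e-3) collapsed into 1e-6.
#'
#' @param x cells per ml (non-negative).
#' @param q_n nitrogen quota, fg N per cell (positive).
#' @param mw_n molecular weight of nitrogen, g/mol (default 14).
#' @return biomass in umol N per litre; linear in both `x` and `q_n`.
#' @export
cells_to_biomass <- function(x, q_n, mw_n = 14) {
  stopifnot(all(x >= 0), all(q_n > 0), mw_n > 0)
  x * q_n * 1e-6 / mw_n
}

#' Nitrogen budget of one culture at one sampled day
#'
#' Converts the per-population cell counts to biomass through the strain
#' quotas, totals them, and checks feasibility against the total available
#' nitrogen (100 umol/L in low-N media unless overridden).
#'
#' @param counts data.frame with columns `population`
#'   (`"prochlorococcus"`/`"alteromonas"`) and `cells_per_ml` for one
#'   culture-day.
#' @param pro_strain,alt_strain strain labels (`"none"` for axenic arms).
#' @param quotas named quota vector as [default_quotas()].
#' @param total_available_n total N supplied, umol/L (default 100).
#' @param mw_n molecular weight of N, g/mol.
#' @return list of class `n_budget`: `pro_biomass`, `alt_biomass`, `total`,
#'   `fraction_alt`, `total_available_n`, `feasible`.
#' @export
n_budget <- function(counts, pro_strain, alt_strain, quotas = default_quotas(),
                     total_available_n = 100, mw_n = 14) {
  get_quota <- function(strain) {
    if (!strain %in% names(quotas)) {
      stop("no nitrogen quota for strain '", strain, "'", call. = FALSE)
    }
    quotas[[strain]]
  }
  pro_cells <- sum(counts$cells_per_ml[counts$population == "prochlorococcus"])
  alt_cells <- sum(counts$cells_per_ml[counts$population == "alteromonas"])
  pro_biomass <- if (pro_cells > 0 || pro_strain != "none") {
    if (pro_strain == "none" && pro_cells > 0)
      stop("prochlorococcus counts present but pro_strain is 'none'", call. = FALSE)
    if (pro_strain == "none") 0 else cells_to_biomass(pro_cells, get_quota(pro_strain), mw_n)
  } else 0
  alt_biomass <- if (alt_cells > 0 || alt_strain != "none") {
    if (alt_strain == "none" && alt_cells > 0)
      stop("alteromonas counts present but alt_strain is 'none'", call. = FALSE)
    if (alt_strain == "none") 0 else cells_to_biomass(alt_cells, get_quota(alt_strain), mw_n)
  } else 0
  total <- pro_biomass + alt_biomass
  feasible <- total <= total_available_n
  if (!feasible) {
    warning(sprintf("total N biomass %.3g umol/L exceeds available %.3g umol/L",
                    total, total_available_n), call. = FALSE)
  }
  structure(list(pro_biomass = pro_biomass, alt_biomass = alt_biomass,
                 total = total,
                 fraction_alt = if (total > 0) alt_biomass / total else 0,
                 total_available_n = total_available_n, feasible = feasible),
            class = "n_budget")
}

#' @export
print.n_budget <- function(x, ...) {
  cat(sprintf("<n_budget> total %.4g umol N/L (pro %.4g + alt %.4g), fraction_alt %.3f, %s\n",
              x$total, x$pro_biomass, x$alt_biomass, x$fraction_alt,
              if (x$feasible) "feasible" else "EXCEEDS available N"))
  invisible(x)
}

#' Nitrogen budgets for every culture-day of an experiment set
#'
#' @param es an [experiment_set()] with counts.
#' @inheritParams n_budget
#' @return data.frame with one row per (culture_id, day): biomasses, total,
#'   `fraction_alt`, `feasible`, plus metadata columns.
#' @export
n_budget_table <- function(es, quotas = default_quotas(),
                           total_available_n = 100, mw_n = 14) {
  if (is.null(es$counts)) stop("experiment set has no counts", call. = FALSE)
  keys <- unique(es$counts[, c("culture_id", "day")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    id <- keys$culture_id[i]; day <- keys$day[i]
    md <- es$metadata[es$metadata$culture_id == id, ]
    cnt <- es$counts[es$counts$culture_id == id & es$counts$day == day, ]
    b <- withCallingHandlers(
      n_budget(cnt, md$pro_strain, md$alt_strain, quotas, total_available_n, mw_n),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(culture_id = id, day = day, pro_biomass = b$pro_biomass,
               alt_biomass = b$alt_biomass, total = b$total,
               fraction_alt = b$fraction_alt, feasible = b$feasible,
               pro_strain = md$pro_strain, alt_strain = md$alt_strain,
               replicate = md$replicate, treatment = md$treatment)
  })
  out <- do.call(rbind, rows); rownames(out) <- NULL; out
}

#' Budget sensitivity to the assumed nitrogen quotas
#'
#' Recomputes a culture-day budget over a grid of phototroph and heterotroph
#' quota values and reports which combinations keep the total biomass within
#' the available nitrogen. Biomass is linear in each quota, so the
#' feasibility boundary is monotone in each.
#'
#' @inheritParams n_budget
#' @param pro_quotas,alt_quotas numeric vectors of quota values to try
#'   (fg N per cell).
#' @return data.frame with columns `pro_quota`, `alt_quota`, `total`,
#'   `feasible`; empty if either range is empty.
#' @export
quota_sensitivity <- function(counts, pro_strain, alt_strain,
                              pro_quotas, alt_quotas,
                              total_available_n = 100, mw_n = 14) {
  stopifnot(all(pro_quotas > 0), all(alt_quotas > 0))
  if (length(pro_quotas) == 0L || length(alt_quotas) == 0L) {
    return(data.frame(pro_quota = numeric(0), alt_quota = numeric(0),
                      total = numeric(0), feasible = logical(0)))
  }
  grid <- expand.grid(pro_quota = pro_quotas, alt_quota = alt_quotas)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    q <- default_quotas()
    if (pro_strain != "none") q[pro_strain] <- grid$pro_quota[i]
    if (alt_strain != "none") q[alt_strain] <- grid$alt_quota[i]
    b <- withCallingHandlers(
      n_budget(counts, pro_strain, alt_strain, q, total_available_n, mw_n),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(pro_quota = grid$pro_quota[i], alt_quota = grid$alt_quota[i],
               total = b$total, feasible = b$feasible)
  })
  do.call(rbind, rows)
}

#' Synergy call from co-culture vs axenic biomass replicates
#'
#' `log2FC = log2(mean(co) / mean(ax))`; significance from a two-sample
#' t-test on log2 biomass, Bonferroni-multiplied by `n_family` (the number
#' of strain-pair comparisons in the family) and capped at 1. The call is
#' `synergistic` when significant with positive log2FC, `competitive` when
#' significant with negative log2FC, otherwise `neutral` (with a
#' `negative_trend` flag when the non-significant fold change is negative).
#' Non-positive biomass values are excluded with a warning.
#'
#' @param co_biomass per-replicate biomass in co-culture, umol N/L.
#' @param ax_biomass per-replicate biomass of the axenic control, umol N/L.
#' @param n_family Bonferroni family size (default 1 = single comparison).
#' @param alpha significance level on the corrected p (default 0.05).
#' @param pooled_var,pooled_df optional pooled within-arm variance of log2
#'   biomass and its residual degrees of freedom (ANOVA-style, as used by
#'   [synergy_analysis()]); when supplied the pairwise test uses them
#'   instead of the two-sample Welch variance, giving the comparisons the
#'   power of the full design.
#' @return list of class `synergy_call`: `log2fc`, `p`, `p_corrected`,
#'   `call`, `negative_trend`.
#' @export
synergy_log2fc <- function(co_biomass, ax_biomass, n_family = 1L, alpha = 0.05,
                           pooled_var = NULL, pooled_df = NULL) {
  drop_bad <- function(v, label) {
    bad <- !is.finite(v) | v <= 0
    if (any(bad)) {
      warning("excluding ", sum(bad), " non-positive ", label, " biomass value(s)",
              call. = FALSE)
    }
    v[!bad]
  }
  co <- drop_bad(co_biomass, "co-culture")
  ax <- drop_bad(ax_biomass, "axenic")
  if (length(co) < 2L || length(ax) < 2L) {
    stop("need at least 2 positive replicates in each arm", call. = FALSE)
  }
  log2fc <- log2(mean(co) / mean(ax))
  identical_arms <- stats::var(log2(co)) == 0 && stats::var(log2(ax)) == 0 &&
    mean(log2(co)) == mean(log2(ax))
  p <- if (identical_arms) {
    1
  } else if (!is.null(pooled_var)) {
    se <- sqrt(pooled_var * (1 / length(co) + 1 / length(ax)))
    tt <- (mean(log2(co)) - mean(log2(ax))) / se
    2 * stats::pt(-abs(tt), df = pooled_df)
  } else {
    stats::t.test(log2(co), log2(ax))$p.value
  }
  p_corrected <- min(1, p * n_family)
  significant <- p_corrected < alpha
  call <- if (significant && log2fc > 0) "synergistic"
          else if (significant && log2fc < 0) "competitive"
          else "neutral"
  structure(list(log2fc = log2fc, p = p, p_corrected = p_corrected,
                 call = call,
                 negative_trend = !significant && log2fc < 0),
            class = "synergy_call")
}

#' @export
print.synergy_call <- function(x, ...) {
  cat(sprintf("<synergy_call> log2FC = %.3f, corrected p = %.3g -> %s%s\n",
              x$log2fc, x$p_corrected, x$call,
              if (x$negative_trend) " (negative trend)" else ""))
  invisible(x)
}

#' Strain-pair synergy analysis of an experiment set
#'
#' For each co-cultured strain pair and sampled day, compares a population's
#' biomass against its same-strain axenic control: `pro_on_alt` compares the
#' heterotroph's biomass in co-culture vs axenic heterotroph, `alt_on_pro`
#' the phototroph's biomass vs axenic phototroph. Bonferroni correction uses
#' the number of pairs tested per day and direction as the family, and the
#' pairwise tests share the pooled within-arm variance of log2 biomass over
#' all arms of that day and direction (the ANOVA residual, as in
#' Bonferroni-corrected ANOVA pairwise testing), so significance has the
#' power of the full design rather than of two triplicate arms.
#'
#' @param budget_tab data.frame from [n_budget_table()].
#' @param direction `"pro_on_alt"` or `"alt_on_pro"`.
#' @param days which sampled days to analyse (default: all in the table).
#' @return data.frame with one row per (day, pro_strain, alt_strain):
#'   `log2fc`, `p`, `p_corrected`, `call`, `negative_trend`.
#' @export
synergy_analysis <- function(budget_tab, direction = c("pro_on_alt", "alt_on_pro"),
                             days = sort(unique(budget_tab$day))) {
  direction <- match.arg(direction)
  rows <- list()
  for (d in days) {
    tab <- budget_tab[budget_tab$day == d, , drop = FALSE]
    co <- tab[tab$treatment == "coculture", , drop = FALSE]
    pairs <- unique(co[, c("pro_strain", "alt_strain")])
    n_family <- nrow(pairs)
    # pooled within-arm variance of log2 biomass across every arm measuring
    # the target population on this day (ANOVA residual variance)
    target_col <- if (direction == "pro_on_alt") "alt_biomass" else "pro_biomass"
    rel <- tab[tab$treatment == "coculture" |
                 tab$treatment == (if (direction == "pro_on_alt") "axenic_alt"
                                   else "axenic_pro"), , drop = FALSE]
    rel <- rel[is.finite(rel[[target_col]]) & rel[[target_col]] > 0, , drop = FALSE]
    arm <- interaction(rel$pro_strain, rel$alt_strain, rel$treatment, drop = TRUE)
    sse <- 0; df_resid <- 0L
    for (g in levels(arm)) {
      v <- log2(rel[[target_col]][arm == g])
      if (length(v) >= 2L) {
        sse <- sse + sum((v - mean(v))^2)
        df_resid <- df_resid + length(v) - 1L
      }
    }
    pooled_var <- if (df_resid > 0L) sse / df_resid else NULL
    pooled_df <- if (df_resid > 0L) df_resid else NULL
    for (i in seq_len(nrow(pairs))) {
      ps <- pairs$pro_strain[i]; as <- pairs$alt_strain[i]
      co_i <- co[co$pro_strain == ps & co$alt_strain == as, , drop = FALSE]
      if (direction == "pro_on_alt") {
        ax <- tab[tab$treatment == "axenic_alt" & tab$alt_strain == as, , drop = FALSE]
        co_v <- co_i$alt_biomass; ax_v <- ax$alt_biomass
      } else {
        ax <- tab[tab$treatment == "axenic_pro" & tab$pro_strain == ps, , drop = FALSE]
        co_v <- co_i$pro_biomass; ax_v <- ax$pro_biomass
      }
      res <- tryCatch(
        withCallingHandlers(
          synergy_log2fc(co_v, ax_v, n_family = n_family,
                         pooled_var = pooled_var, pooled_df = pooled_df),
          warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <-
        data.frame(day = d, pro_strain = ps, alt_strain = as,
                   direction = direction, log2fc = res$log2fc, p = res$p,
                   p_corrected = res$p_corrected, call = res$call,
                   negative_trend = res$negative_trend)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}
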