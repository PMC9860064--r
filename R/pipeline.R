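# One-command orchestration: growth features -> mortality fits -> group
# summaries -> nitrogen budgets and synergy -> ordination, PERMANOVA,
# classification -> shape/biomass correlations, with a machine-readable
# report and a per-stage log.

#' Run the full co-culture analysis on an experiment set
#'
#' Executes every analysis stage on an [experiment_set()] (real or
#' simulated) with a single base seed from which all stage seeds are
#' derived, so two runs with the same inputs and seed produce an identical
#' report. Shape-level analytics (PCA, PERMANOVA, random forest) run on the
#' co-culture curves, classified both by phototroph and by heterotroph
#' strain. Stages that need counts are skipped when the set has none.
#'
#' @param es an [experiment_set()].
#' @param seed integer base seed (mandatory).
#' @param out_dir optional directory; when given, result tables, the JSON
#'   report and the run log are written there (partial outputs are preserved
#'   if a stage fails).
#' @param models mortality models to fit.
#' @param n_random_starts random starts per mortality fit.
#' @param quotas nitrogen quota table.
#' @param total_available_n available N, umol/L.
#' @param window alignment window in days relative to the peak.
#' @param folds,n_repeats random-forest CV folds and importance repeats.
#' @param n_perm PERMANOVA permutations.
#' @return list of class `coculture_report`: `tables` (features, fits,
#'   budget, synergy, pca scores, importances), `stats` (headline numbers),
#'   `log` (per-stage timing and warning counts), `exclusions`.
#' @export
run_pipeline <- function(es, seed, out_dir = NULL,
                         models = decline_model_names(), n_random_starts = 50L,
                         quotas = default_quotas(), total_available_n = 100,
                         window = c(-10L, 80L), folds = 10L, n_repeats = 30L,
                         n_perm = 999L) {
  stopifnot(inherits(es, "experiment_set"), !missing(seed))
  tables <- list(); stats <- list()
  log_rows <- list(); exclusions <- list()
  stage_i <- 0L
  run_stage <- function(name, expr) {
    stage_i <<- stage_i + 1L
    warns <- character(0)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      withCallingHandlers(expr, warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        if (!is.null(out_dir)) {
          try(write_results(tables, out_dir, config = list(seed = seed),
                            seed = seed), silent = TRUE)
        }
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    log_rows[[length(log_rows) + 1L]] <<-
      data.frame(stage = name, seconds = proc.time()[["elapsed"]] - t0,
                 n_warnings = length(warns))
    if (length(warns) > 0L) {
      exclusions[[length(exclusions) + 1L]] <<-
        data.frame(stage = name, reason = warns)
    }
    res
  }

  features <- run_stage("growth_features", growth_features(es))
  tables$features <- features
  bad <- features[features$status != "ok", , drop = FALSE]
  if (nrow(bad) > 0L) {
    exclusions[[length(exclusions) + 1L]] <-
      data.frame(stage = "growth_features",
                 reason = paste0(bad$culture_id, ": ", bad$status))
  }
  stats$n_cultures <- nrow(features)
  stats$n_growth_ok <- sum(features$status == "ok")
  ok <- features[features$status == "ok", , drop = FALSE]
  stats$mu_mean <- mean(ok$mu)
  stats$lag_mean <- mean(ok$lag)

  fits <- run_stage("decline_fits",
                    decline_fits(es, models = models,
                                 n_random_starts = n_random_starts,
                                 seed = derive_seed(seed, 2L)))
  tables$fits <- fits
  bad <- fits[fits$status != "ok", , drop = FALSE]
  if (nrow(bad) > 0L) {
    exclusions[[length(exclusions) + 1L]] <-
      data.frame(stage = "decline_fits",
                 reason = paste0(unique(bad$culture_id), ": decline_undetected"))
  }
  fit_summary <- run_stage("summarize_fits", summarize_fits(fits))
  bt <- fit_summary$by_treatment
  for (i in seq_len(nrow(bt))) {
    g <- bt$group[i]
    stats[[paste0("weibull_shape_mean_", g)]] <- bt$shape_mean[i]
    stats[[paste0("weibull_shape_sd_", g)]] <- bt$shape_sd[i]
    stats[[paste0("td2_mean_", g)]] <- bt$td2_mean[i]
  }
  if (!is.null(fit_summary$shape_ttest)) {
    stats$shape_ttest_p <- fit_summary$shape_ttest$p.value
  }
  rb <- fit_summary$rmse_by_model
  stats$rmse_by_model <- lapply(split(rb, seq_len(nrow(rb))), function(r)
    list(model = r$model, treatment = r$treatment, rmse_mean = r$rmse_mean,
         rmse_sd = r$rmse_sd, n = r$n_curves))
  names(stats$rmse_by_model) <- paste(rb$model, rb$treatment, sep = "_")

  if (!is.null(es$counts)) {
    budget <- run_stage("n_budget",
                        n_budget_table(es, quotas = quotas,
                                       total_available_n = total_available_n))
    tables$budget <- budget
    co60 <- budget[budget$treatment == "coculture" & budget$day == 60, ]
    if (nrow(co60) > 0) {
      stats$coculture_total_biomass_day60_mean <- mean(co60$total)
      stats$coculture_fraction_alt_day60_mean <- mean(co60$fraction_alt)
    }
    ax60 <- budget[budget$treatment == "axenic_alt" & budget$day == 60, ]
    if (nrow(ax60) > 0) stats$axenic_alt_total_biomass_day60_mean <- mean(ax60$total)
    synergy <- run_stage("synergy", rbind(
      synergy_analysis(budget, direction = "pro_on_alt"),
      synergy_analysis(budget, direction = "alt_on_pro")))
    tables$synergy <- synergy
    s60 <- synergy[synergy$day == 60 & synergy$direction == "pro_on_alt", ]
    if (nrow(s60) > 0) {
      stats$alt_log2fc_day60_mean <- mean(s60$log2fc)
      stats$n_synergistic_day60 <- sum(s60$call == "synergistic")
      stats$n_competitive_day60 <- sum(s60$call == "competitive")
    }
  }

  co_ids <- es$metadata$culture_id[es$metadata$treatment == "coculture"]
  if (length(co_ids) >= 4L) {
    co_es <- es
    co_es$curves <- es$curves[es$curves$culture_id %in% co_ids, , drop = FALSE]
    m <- run_stage("align_and_grid",
                   standardize_matrix(align_and_grid(co_es, window = window)))
    md <- es$metadata[match(rownames(m), es$metadata$culture_id), ]
    pca <- run_stage("pca", pca_curves(m, k = 2L))
    tables$pca_scores <- data.frame(culture_id = rownames(m),
                                    PC1 = pca$scores[, 1], PC2 = pca$scores[, 2],
                                    pro_strain = md$pro_strain,
                                    alt_strain = md$alt_strain)
    stats$pca_explained <- as.list(structure(pca$explained,
                                             names = c("PC1", "PC2")))
    for (target in c("pro_strain", "alt_strain")) {
      labels <- md[[target]]
      pm <- run_stage(paste0("permanova_", target),
                      permanova_curves(m, labels, n_perm = n_perm,
                                       seed = derive_seed(seed, 3L + match(target, c("pro_strain", "alt_strain")))))
      stats[[paste0("permanova_", target)]] <-
        list(pseudo_F = pm$pseudo_F, R2 = pm$R2, p = pm$p,
             df_between = pm$df_between, df_within = pm$df_within)
      rf <- run_stage(paste0("rf_", target),
                      rf_classify(m, labels, folds = folds,
                                  n_repeats = n_repeats,
                                  seed = derive_seed(seed, 5L + match(target, c("pro_strain", "alt_strain")))))
      stats[[paste0("rf_accuracy_", target)]] <- rf$mean_accuracy
      if (target == "pro_strain") {
        tables$importance <- data.frame(day = as.integer(names(rf$importance)),
                                        importance = unname(rf$importance))
      }
    }
  }

  if (!is.null(tables$budget)) {
    w <- fits[fits$model %in% "weibull" & fits$status == "ok" &
                fits$treatment == "coculture", ]
    b60 <- tables$budget[tables$budget$day == 60, c("culture_id", "total")]
    j <- merge(w, b60, by = "culture_id")
    if (nrow(j) >= 3L && stats::var(j$n) > 0 && stats::var(j$total) > 0) {
      cn <- run_stage("correlations", list(
        shape_vs_biomass = correlate(j$total, j$n),
        rmse_vs_biomass = correlate(j$total, j$rmse)))
      stats$cor_shape_vs_biomass_day60 <- cn$shape_vs_biomass
      stats$cor_rmse_vs_biomass_day60 <- cn$rmse_vs_biomass
    }
  }

  report <- structure(list(tables = tables, stats = stats,
                           log = do.call(rbind, log_rows),
                           exclusions = if (length(exclusions) > 0)
                             do.call(rbind, exclusions) else
                             data.frame(stage = character(0), reason = character(0)),
                           seed = seed),
                      class = "coculture_report")
  if (!is.null(out_dir)) {
    write_results(tables, out_dir, config = list(seed = seed, n_perm = n_perm,
                                                 folds = folds,
                                                 n_random_starts = n_random_starts),
                  seed = seed)
    jsonlite::write_json(stats, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(report$log, file.path(out_dir, "run_log.csv"), row.names = FALSE)
    utils::write.csv(report$exclusions, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.coculture_report <- function(x, ...) {
  cat("<coculture_report> seed", x$seed, "\n")
  cat(sprintf("  %d cultures, %d growth fits ok\n",
              x$stats$n_cultures, x$stats$n_growth_ok))
  if (!is.null(x$stats$weibull_shape_mean_axenic_pro)) {
    cat(sprintf("  Weibull shape: axenic %.2f +- %.2f, co-culture %.2f +- %.2f (t-test p = %.2g)\n",
                x$stats$weibull_shape_mean_axenic_pro, x$stats$weibull_shape_sd_axenic_pro,
                x$stats$weibull_shape_mean_coculture, x$stats$weibull_shape_sd_coculture,
                x$stats$shape_ttest_p))
    cat(sprintf("  td2: axenic %.3g d, co-culture %.3g d\n",
                x$stats$td2_mean_axenic_pro, x$stats$td2_mean_coculture))
  }
  if (!is.null(x$stats$rf_accuracy_pro_strain)) {
    cat(sprintf("  RF accuracy: phototroph %.2f, heterotroph %.2f\n",
                x$stats$rf_accuracy_pro_strain, x$stats$rf_accuracy_alt_strain))
    cat(sprintf("  PERMANOVA (phototroph): F(%d,%d) = %.1f, R2 = %.2f, p = %.3g\n",
                x$stats$permanova_pro_strain$df_between,
                x$stats$permanova_pro_strain$df_within,
                x$stats$permanova_pro_strain$pseudo_F,
                x$stats$permanova_pro_strain$R2, x$stats$permanova_pro_strain$p))
  }
  invisible(x)
}
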