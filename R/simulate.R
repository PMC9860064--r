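# Synthetic experiment generator with known ground truth, emulating the
# study design: a 5 x 5 phototroph-heterotroph strain grid plus axenic
# controls in triplicate, near-daily fluorescence sampling over ~140 days,
# exponential growth to a peak followed by strain-specific mortality, and
# flow-cytometry counts at days 60/100/140 generated budget-downward so the
# closed nitrogen budget holds by construction.

#' Default simulation configuration
#'
#' @param seed integer seed (mandatory; every stochastic step derives its
#'   stream from it).
#' @param replicates biological replicates per culture (default 3).
#' @param duration experiment length in days (default 140).
#' @param sampling_interval days between measurements (default 1).
#' @param jitter uniform sampling-time jitter half-width in days
#'   (default 0.15; day 0 is exact).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise (default 0.05).
#' @param detection_floor fluorescence detection limit in arbitrary units;
#'   values below it are reported at the floor and flagged (default 1).
#' @param n_total total available nitrogen, umol/L (default 100, low-N media).
#' @param count_days days with flow-cytometry counts (default 60, 100, 140).
#' @param second_growth if TRUE, synergistic co-cultures get a "second
#'   growth" bump in the decline phase (log-space Gaussian bumps near 45 and
#'   100 days after decline onset), emulating the non-monotonic declines of
#'   strongly recycling co-cultures.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed, replicates = 3L, duration = 140, sampling_interval = 1,
                       jitter = 0.15, noise_cv = 0.05, detection_floor = 1,
                       n_total = 100, count_days = c(60, 100, 140),
                       second_growth = FALSE) {
  stopifnot(!missing(seed), is.finite(seed))
  stopifnot(replicates >= 1, duration > 0, sampling_interval > 0,
            jitter >= 0, noise_cv >= 0, detection_floor >= 0, n_total > 0)
  structure(list(seed = as.integer(seed), replicates = as.integer(replicates),
                 duration = duration, sampling_interval = sampling_interval,
                 jitter = jitter, noise_cv = noise_cv,
                 detection_floor = detection_floor, n_total = n_total,
                 count_days = count_days, second_growth = second_growth),
            class = "sim_config")
}

#' Default strain profile library
#'
#' Ten profiles: five phototrophs whose mortality parameters are drawn
#' around the study-scale group statistics — axenic Weibull shape around
#' 2.1 (SD 0.9, clipped above 1.1) with two-decade reduction time around
#' 12.6 days, and co-culture shape below 1 (synergistic strains around 0.36,
#' competitive around 0.52, pooling to roughly 0.4; clipped above 0.05)
#' with td2 around 316 days — and five heterotrophs with a null effect on
#' phototroph decline (any heterotroph partner yields the phototroph's
#' co-culture decline law). The MIT9313-like profile carries a 10-day
#' co-culture lag penalty ("delayed growth" phenotype); MED4, MIT0604 and
#' NATL2A are flagged synergistic (heterotroph biomass benefit, log2FC
#' around 1.3 at day 60), MIT9312 and MIT9313 competitive (around -0.2).
#'
#' @param seed seed for the profile draws (fixed default so the default
#'   library is reproducible).
#' @return list of class `strain_library` with elements `pro` and `alt`,
#'   each a named list of profiles.
#' @export
default_library <- function(seed = 202211L) {
  pro_names <- c("MED4", "MIT9312", "MIT0604", "NATL2A", "MIT9313")
  alt_names <- c("HOT1A3", "BS11", "ATCC27126", "AltDE1", "AltDE")
  synergistic <- c("MED4", "MIT0604", "NATL2A")
  with_seed(seed, {
    pro <- lapply(seq_along(pro_names), function(i) {
      nm <- pro_names[i]
      mu <- max(0.25, stats::rnorm(1, 0.5, 0.08))
      lag <- stats::runif(1, 1, 4)
      flmax <- stats::runif(1, 300, 800)
      n_ax <- max(1.1, stats::rnorm(1, 2.1, 0.9))
      td2_ax <- max(5, stats::rnorm(1, 12.58, 3.85))
      # co-culture shapes are lower for the strains whose heterotroph
      # partner benefits (strong N recycling) than for the competitive ones
      n_co <- if (nm %in% synergistic) max(0.05, stats::rnorm(1, 0.36, 0.14))
              else max(0.05, stats::rnorm(1, 0.52, 0.16))
      # td2 of co-cultures is strongly right-skewed (mean 316, SD 337 days):
      # lognormal with matching first two moments
      sdlog <- sqrt(log(1 + (337 / 316)^2))
      td2_co <- min(1500, max(60, stats::rlnorm(1, log(316) - sdlog^2 / 2, sdlog)))
      list(strain = nm, role = "phototroph",
           growth = list(mu = mu, lag = lag, flmax = flmax, fl0 = 5),
           decline_axenic = list(model = "weibull",
                                 params = c(a = 2 * log(10) / td2_ax^n_ax, n = n_ax)),
           decline_coculture = list(model = "weibull",
                                    params = c(a = 2 * log(10) / td2_co^n_co, n = n_co)),
           coculture_lag_penalty = if (nm == "MIT9313") 10 else 0,
           synergistic = nm %in% synergistic)
    })
    names(pro) <- pro_names
    alt <- lapply(alt_names, function(nm) {
      list(strain = nm, role = "heterotroph",
           # axenic heterotroph N biomass at day 60 (umol/L); no effect on
           # the phototroph decline law (null effect by design)
           ax_biomass_day60 = min(90, stats::rlnorm(1, log(32), 0.35)),
           day100_synergy = nm != "BS11")
    })
    names(alt) <- alt_names
    structure(list(pro = pro, alt = alt), class = "strain_library")
  })
}

#' @export
print.strain_library <- function(x, ...) {
  cat("<strain_library>\n  phototrophs:\n")
  for (p in x$pro) {
    cat(sprintf("    %-8s mu %.2f, FLmax %.0f, shape ax %.2f / co %.2f%s%s\n",
                p$strain, p$growth$mu, p$growth$flmax,
                p$decline_axenic$params[["n"]], p$decline_coculture$params[["n"]],
                if (p$coculture_lag_penalty > 0) sprintf(", +%g d co-culture lag", p$coculture_lag_penalty) else "",
                if (p$synergistic) ", synergistic" else ", competitive"))
  }
  cat("  heterotrophs:", paste(names(x$alt), collapse = ", "), "\n")
  invisible(x)
}

# noiseless fluorescence trajectory of a phototroph profile at times t
closed_form_curve <- function(pro, t, coculture = FALSE, second_growth = FALSE) {
  g <- pro$growth
  lag <- g$lag + if (coculture) pro$coculture_lag_penalty else 0
  tmax <- lag + log(g$flmax / g$fl0) / g$mu
  dec <- if (coculture) pro$decline_coculture else pro$decline_axenic
  fl <- ifelse(t < lag, g$fl0,
        ifelse(t <= tmax, g$fl0 * exp(g$mu * (t - lag)),
               g$flmax * model_eval(dec$model, dec$params, pmax(0, t - tmax))))
  if (second_growth && coculture) {
    tau <- pmax(0, t - tmax)
    bump <- 0.8 * exp(-(tau - 45)^2 / (2 * 8^2)) + 0.5 * exp(-(tau - 100)^2 / (2 * 10^2))
    fl <- ifelse(t > tmax, fl * exp(bump), fl)
  }
  list(fl = fl, tmax = tmax, lag = lag, decline = dec)
}

#' Simulate one culture's fluorescence curve
#'
#' Piecewise trajectory: flat at the initial level until the lag ends,
#' exponential rise at rate `mu` to the peak, then decline under the
#' profile's (axenic or co-culture) mortality law; multiplicative lognormal
#' noise; values below the detection floor are reported at the floor and
#' flagged. Axenic heterotroph cultures (`pro = NULL`) produce only
#' floor-level noise, since chlorophyll fluorescence does not track the
#' heterotroph.
#'
#' @param pro phototroph profile from [default_library()], or `NULL` for an
#'   axenic heterotroph culture.
#' @param alt heterotroph profile or `NULL` for an axenic phototroph
#'   culture.
#' @param config a [sim_config()].
#' @param seed seed for this curve's noise and sampling jitter.
#' @return list with `curve` (data.frame `day`, `fluorescence`,
#'   `below_detection`) and `truth` (generating parameters, including the
#'   true peak time).
#' @export
simulate_curve <- function(pro, alt, config, seed) {
  coculture <- !is.null(pro) && !is.null(alt)
  with_seed(seed, {
    k <- seq(0, config$duration, by = config$sampling_interval)
    t <- k + c(0, stats::runif(length(k) - 1, -config$jitter, config$jitter))
    t <- pmax(0, t)
    stopifnot(all(diff(t) > 0))
    if (is.null(pro)) {
      true_fl <- rep(config$detection_floor * 0.5, length(t))
      truth <- list(model = "none", tmax = NA_real_)
    } else {
      cf <- closed_form_curve(pro, t, coculture = coculture,
                              second_growth = config$second_growth)
      true_fl <- cf$fl
      truth <- list(model = cf$decline$model, params = cf$decline$params,
                    mu = pro$growth$mu, lag = cf$lag, flmax = pro$growth$flmax,
                    fl0 = pro$growth$fl0, tmax = cf$tmax)
    }
    noise <- if (config$noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$noise_cv^2))
      stats::rlnorm(length(t), -sdlog^2 / 2, sdlog)
    } else 1
    fl <- true_fl * noise
    below <- fl < config$detection_floor
    fl[below] <- config$detection_floor
    truth$seed <- seed
    truth$noise_cv <- config$noise_cv
    list(curve = data.frame(day = t, fluorescence = fl, below_detection = below),
         truth = truth)
  })
}

# expected N biomass (umol/L) for one culture at one count day; pair_fx is
# the pair-level heterotroph log2FC at day 60
expected_biomass <- function(treatment, pro, alt, day, pair_fx, n_total) {
  if (treatment == "axenic_pro") {
    pro_b <- c(`60` = 0.01, `100` = 0.005, `140` = 0.001)[[as.character(day)]]
    return(c(pro = pro_b, alt = 0))
  }
  if (treatment == "axenic_alt") {
    base <- alt$ax_biomass_day60
    alt_b <- switch(as.character(day), `60` = base, `100` = base * 0.25,
                    `140` = base * 0.01)
    return(c(pro = 0, alt = alt_b))
  }
  # co-culture: phototroph benefits in every pairing (log2FC ~10 over the
  # axenic control); the heterotroph benefit depends on the phototroph strain
  if (day == 60) {
    pro_b <- 0.01 * 2^10
    alt_b <- alt$ax_biomass_day60 * 2^pair_fx
  } else if (day == 100) {
    pro_b <- 0.005 * 2^10
    alt_b <- alt$ax_biomass_day60 * 0.25 * if (alt$day100_synergy) 2^3 else 1
  } else {
    pro_b <- if (pro$strain == "MIT0604") 1.46 else 0.26
    alt_b <- 0.5
  }
  c(pro = pro_b, alt = alt_b)
}

#' Simulate a full experiment set
#'
#' Generates the 25 co-culture combinations plus 5 axenic phototroph and 5
#' axenic heterotroph controls, each in `config$replicates` replicates, with
#' fluorescence curves from [simulate_curve()] and flow-cytometry counts at
#' the configured count days. Counts are generated budget-downward: expected
#' nitrogen biomass per population is drawn first (with 10% within-arm
#' replicate variation), rescaled if needed so the total never exceeds the
#' available N, and then converted to cells/ml through the quotas — so the
#' closed-budget constraint and quota round-trip hold by construction.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param library a [default_library()] (or a modified profile library).
#' @return An [experiment_set()] whose `provenance` holds the config and a
#'   `truth` list: per-curve generating parameters (`curves`), expected
#'   biomasses (`counts`), and the profile library.
#' @export
simulate_experiment <- function(config, library = default_library()) {
  stopifnot(inherits(config, "sim_config"))
  quotas <- default_quotas()
  pro_names <- names(library$pro)
  alt_names <- names(library$alt)
  design <- rbind(
    expand.grid(pro = pro_names, alt = alt_names, stringsAsFactors = FALSE),
    data.frame(pro = pro_names, alt = "none"),
    data.frame(pro = "none", alt = alt_names))
  meta_rows <- list(); curve_rows <- list(); count_rows <- list()
  truth_curves <- list(); truth_counts <- list()
  cid <- 0L
  for (i in seq_len(nrow(design))) {
    pro_nm <- design$pro[i]; alt_nm <- design$alt[i]
    pro <- if (pro_nm == "none") NULL else library$pro[[pro_nm]]
    alt <- if (alt_nm == "none") NULL else library$alt[[alt_nm]]
    treatment <- derive_treatment(pro_nm, alt_nm)
    # pair-level heterotroph benefit at day 60, deterministic per pair
    pair_fx <- if (treatment == "coculture") {
      base <- if (pro$synergistic) 1.3 else -0.2
      with_seed(derive_seed(config$seed, 9000L + i), stats::rnorm(1, base, 0.3))
    } else NA_real_
    for (r in seq_len(config$replicates)) {
      cid <- cid + 1L
      id <- sprintf("E1_%s_%s_r%d", pro_nm, alt_nm, r)
      meta_rows[[cid]] <- data.frame(culture_id = id, experiment = "E1",
                                     pro_strain = pro_nm, alt_strain = alt_nm,
                                     replicate = r)
      sc <- simulate_curve(pro, alt, config, seed = derive_seed(config$seed, cid))
      curve_rows[[cid]] <- cbind(data.frame(culture_id = id), sc$curve)
      truth_curves[[cid]] <- data.frame(
        culture_id = id, pro_strain = pro_nm, alt_strain = alt_nm,
        treatment = treatment,
        model = sc$truth$model,
        mu = if (is.null(pro)) NA_real_ else sc$truth$mu,
        lag = if (is.null(pro)) NA_real_ else sc$truth$lag,
        flmax = if (is.null(pro)) NA_real_ else sc$truth$flmax,
        tmax = sc$truth$tmax,
        a = if (is.null(pro)) NA_real_ else sc$truth$params[["a"]],
        n = if (is.null(pro)) NA_real_ else sc$truth$params[["n"]],
        pair_log2fc_day60 = pair_fx)
      for (d in config$count_days) {
        eb <- expected_biomass(treatment, pro, alt, d, pair_fx, config$n_total)
        noisy <- with_seed(derive_seed(config$seed, cid * 1000L + d), {
          eb * stats::rlnorm(2, -log(1 + 0.1^2) / 2, sqrt(log(1 + 0.1^2)))
        })
        if (sum(noisy) > config$n_total) {
          noisy <- noisy * 0.98 * config$n_total / sum(noisy)
        }
        if (pro_nm != "none") {
          count_rows[[length(count_rows) + 1L]] <- data.frame(
            culture_id = id, day = d, population = "prochlorococcus",
            cells_per_ml = noisy[["pro"]] * 14 / (quotas[[pro_nm]] * 1e-6))
        }
        if (alt_nm != "none") {
          count_rows[[length(count_rows) + 1L]] <- data.frame(
            culture_id = id, day = d, population = "alteromonas",
            cells_per_ml = noisy[["alt"]] * 14 / (quotas[[alt_nm]] * 1e-6))
        }
        truth_counts[[length(truth_counts) + 1L]] <- data.frame(
          culture_id = id, day = d, pro_biomass = noisy[["pro"]],
          alt_biomass = noisy[["alt"]])
      }
    }
  }
  experiment_set(
    curves = do.call(rbind, curve_rows),
    metadata = do.call(rbind, meta_rows),
    counts = do.call(rbind, count_rows),
    provenance = list(generator = "simulate_experiment", config = unclass(config),
                      truth = list(curves = do.call(rbind, truth_curves),
                                   counts = do.call(rbind, truth_counts),
                                   library = library)))
}
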