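# Shared fixtures, all built in code.

# a decline phase directly from model coordinates (tau, normalized y)
make_phase <- function(tau, y) {
  structure(list(tau = tau, y = y, n_points = length(tau), flmax = 1, tmax = 0),
            class = "decline_phase")
}

# minimal 3-culture experiment: one co-culture, one axenic phototroph,
# one axenic heterotroph
toy_tables <- function() {
  days <- 0:20
  fl <- function(mu, lag, flmax, a) {
    tmax <- lag + log(flmax / 5) / mu
    ifelse(days < lag, 5,
    ifelse(days <= tmax, 5 * exp(mu * (days - lag)),
           flmax * exp(-a * (days - tmax))))
  }
  curves <- rbind(
    data.frame(culture_id = "c1", day = days, fluorescence = fl(0.5, 2, 200, 0.05)),
    data.frame(culture_id = "c2", day = days, fluorescence = fl(0.6, 1, 300, 0.3)),
    data.frame(culture_id = "c3", day = days, fluorescence = 0.4))
  metadata <- data.frame(
    culture_id = c("c1", "c2", "c3"),
    experiment = "E1",
    pro_strain = c("MED4", "NATL2A", "none"),
    alt_strain = c("HOT1A3", "none", "AltDE"),
    replicate = 1L)
  counts <- data.frame(
    culture_id = c("c1", "c1", "c2", "c3"),
    day = 20,
    population = c("prochlorococcus", "alteromonas", "prochlorococcus", "alteromonas"),
    cells_per_ml = c(1e6, 1e7, 2e5, 5e6))
  list(curves = curves, metadata = metadata, counts = counts)
}

# memoised default simulated experiment shared across test files
sim_cache <- new.env(parent = emptyenv())

default_sim <- function(seed = 42L) {
  key <- paste0("es_", seed)
  if (is.null(sim_cache[[key]])) {
    sim_cache[[key]] <- simulate_experiment(sim_config(seed = seed))
  }
  sim_cache[[key]]
}

# Weibull fits of every culture of the default sim (slowest shared fixture)
default_weibull_fits <- function(seed = 42L) {
  key <- paste0("wfits_", seed)
  if (is.null(sim_cache[[key]])) {
    sim_cache[[key]] <- decline_fits(default_sim(seed), models = "weibull",
                                     n_random_starts = 50L, seed = seed)
  }
  sim_cache[[key]]
}

# standardized aligned matrix of the default sim's co-culture curves
default_aligned <- function(seed = 42L) {
  key <- paste0("mat_", seed)
  if (is.null(sim_cache[[key]])) {
    es <- default_sim(seed)
    co <- es$metadata$culture_id[es$metadata$treatment == "coculture"]
    es$curves <- es$curves[es$curves$culture_id %in% co, , drop = FALSE]
    sim_cache[[key]] <- standardize_matrix(align_and_grid(es))
  }
  sim_cache[[key]]
}
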