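#' @keywords internal
#' @importFrom stats simulate coef predict residuals
"_PACKAGE"

#' Recognised strain names
#'
#' The five *Prochlorococcus* (phototroph) and five *Alteromonas* (heterotroph)
#' strains of the study design, plus `"none"` for axenic cultures.
#'
#' @return Character vector of valid strain labels.
#' @export
pro_strains <- function() c("MED4", "MIT9312", "MIT0604", "NATL2A", "MIT9313", "none")

#' @rdname pro_strains
#' @export
alt_strains <- function() c("HOT1A3", "BS11", "ATCC27126", "AltDE1", "AltDE", "none")

# derived treatment label from the two strain columns
derive_treatment <- function(pro, alt) {
  ifelse(pro != "none" & alt != "none", "coculture",
         ifelse(pro != "none", "axenic_pro", "axenic_alt"))
}

validate_metadata <- function(metadata) {
  required <- c("culture_id", "experiment", "pro_strain", "alt_strain", "replicate")
  missing <- setdiff(required, names(metadata))
  if (length(missing) > 0L) {
    stop("metadata is missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  metadata$culture_id <- as.character(metadata$culture_id)
  bad_pro <- !metadata$pro_strain %in% pro_strains()
  bad_alt <- !metadata$alt_strain %in% alt_strains()
  if (any(bad_pro)) {
    stop("unknown pro_strain value(s): ",
         paste(unique(metadata$pro_strain[bad_pro]), collapse = ", "), call. = FALSE)
  }
  if (any(bad_alt)) {
    stop("unknown alt_strain value(s): ",
         paste(unique(metadata$alt_strain[bad_alt]), collapse = ", "), call. = FALSE)
  }
  both_none <- metadata$pro_strain == "none" & metadata$alt_strain == "none"
  if (any(both_none)) {
    stop("culture(s) with neither strain present: ",
         paste(metadata$culture_id[both_none], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(metadata$culture_id)) {
    stop("duplicated culture_id in metadata: ",
         paste(unique(metadata$culture_id[duplicated(metadata$culture_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(metadata$replicate)) || any(metadata$replicate < 1)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  metadata$treatment <- derive_treatment(metadata$pro_strain, metadata$alt_strain)
  metadata
}

# Per-culture curve checks. Returns list(curves = kept rows, rejected = ids).
validate_curves <- function(curves, metadata) {
  required <- c("culture_id", "day", "fluorescence")
  missing <- setdiff(required, names(curves))
  if (length(missing) > 0L) {
    stop("curves table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  curves$culture_id <- as.character(curves$culture_id)
  orphans <- setdiff(unique(curves$culture_id), metadata$culture_id)
  if (length(orphans) > 0L) {
    stop("curves reference culture_id(s) absent from metadata: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  keep <- rep(TRUE, nrow(curves))
  rejected <- character(0)
  for (id in unique(curves$culture_id)) {
    idx <- which(curves$culture_id == id)
    d <- curves$day[idx]
    if (any(!is.finite(d)) || any(d < 0) || any(diff(d) <= 0)) {
      warning("curve '", id, "' rejected: days must be non-negative and strictly increasing",
              call. = FALSE)
      keep[idx] <- FALSE
      rejected <- c(rejected, id)
    }
  }
  curves <- curves[keep, , drop = FALSE]
  # values at or below zero are kept but flagged: log-domain steps must skip
  # them. A pre-existing flag (e.g. a generator's floor clamp) is kept.
  prior <- if ("below_detection" %in% names(curves)) curves$below_detection else FALSE
  curves$below_detection <- prior |
    !is.finite(curves$fluorescence) | curves$fluorescence <= 0
  rownames(curves) <- NULL
  list(curves = curves, rejected = rejected)
}

validate_counts <- function(counts, metadata) {
  required <- c("culture_id", "day", "population", "cells_per_ml")
  missing <- setdiff(required, names(counts))
  if (length(missing) > 0L) {
    stop("counts table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  counts$culture_id <- as.character(counts$culture_id)
  orphans <- setdiff(unique(counts$culture_id), metadata$culture_id)
  if (length(orphans) > 0L) {
    stop("counts reference culture_id(s) absent from metadata: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  bad_pop <- !counts$population %in% c("prochlorococcus", "alteromonas")
  if (any(bad_pop)) {
    stop("unknown population value(s): ",
         paste(unique(counts$population[bad_pop]), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(counts$cells_per_ml)) || any(counts$cells_per_ml < 0)) {
    stop("cells_per_ml must be finite and non-negative", call. = FALSE)
  }
  counts
}

#' Assemble a validated experiment set
#'
#' Bundles a curve table, a culture metadata table and (optionally) a
#' flow-cytometry count table into a single validated object. The `treatment`
#' column (`axenic_pro`, `axenic_alt`, `coculture`) is derived from the strain
#' columns. Curves with non-monotone or negative days are dropped with a
#' warning; fluorescence values at or below zero are retained but flagged
#' `below_detection` so that log-domain operations can exclude them.
#'
#' @param curves data.frame with columns `culture_id`, `day`, `fluorescence`.
#' @param metadata data.frame with columns `culture_id`, `experiment`,
#'   `pro_strain`, `alt_strain`, `replicate`.
#' @param counts optional data.frame with columns `culture_id`, `day`,
#'   `population` (`"prochlorococcus"` or `"alteromonas"`), `cells_per_ml`.
#' @param provenance free-form list recording how the set was produced
#'   (seed, generator parameters, input paths).
#'
#' @return An object of class `experiment_set`: a list with elements
#'   `curves`, `metadata`, `counts`, `provenance`.
#' @export
experiment_set <- function(curves, metadata, counts = NULL, provenance = list()) {
  metadata <- validate_metadata(as.data.frame(metadata))
  cv <- validate_curves(as.data.frame(curves), metadata)
  if (!is.null(counts)) counts <- validate_counts(as.data.frame(counts), metadata)
  structure(list(curves = cv$curves, metadata = metadata, counts = counts,
                 provenance = provenance, rejected_curves = cv$rejected),
            class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  n_cult <- length(unique(x$curves$culture_id))
  cat("<experiment_set>\n")
  cat(sprintf("  %d cultures with curves (%d observations), %d metadata rows\n",
              n_cult, nrow(x$curves), nrow(x$metadata)))
  tr <- table(x$metadata$treatment)
  cat("  treatments:", paste(sprintf("%s=%d", names(tr), tr), collapse = ", "), "\n")
  if (!is.null(x$counts)) {
    cat(sprintf("  counts: %d records on day(s) %s\n", nrow(x$counts),
                paste(sort(unique(x$counts$day)), collapse = ", ")))
  }
  if (length(x$rejected_curves) > 0L) {
    cat("  rejected curves:", paste(x$rejected_curves, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read an experiment set from delimited files
#'
#' Reads the canonical long-format CSV dialect: `curves.csv` with header
#' `culture_id,day,fluorescence`, `metadata.csv` with header
#' `culture_id,experiment,pro_strain,alt_strain,replicate`, and optionally
#' `counts.csv` with header `culture_id,day,population,cells_per_ml`.
#' Days are real numbers measured from inoculation.
#'
#' @param curves_path path to the curves CSV.
#' @param metadata_path path to the metadata CSV.
#' @param counts_path optional path to the counts CSV.
#' @return A validated [experiment_set()].
#' @export
read_experiment <- function(curves_path, metadata_path, counts_path = NULL) {
  for (p in c(curves_path, metadata_path, counts_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  curves <- utils::read.csv(curves_path, stringsAsFactors = FALSE)
  metadata <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  counts <- if (!is.null(counts_path)) utils::read.csv(counts_path, stringsAsFactors = FALSE)
  experiment_set(curves, metadata, counts,
                 provenance = list(curves_path = curves_path,
                                   metadata_path = metadata_path,
                                   counts_path = counts_path))
}

#' Extract one culture's fluorescence series
#'
#' @param es an [experiment_set()].
#' @param culture_id culture identifier.
#' @return data.frame with columns `day`, `fluorescence`, `below_detection`,
#'   ordered by day.
#' @export
get_curve <- function(es, culture_id) {
  cv <- es$curves[es$curves$culture_id == culture_id, , drop = FALSE]
  if (nrow(cv) == 0L) stop("no curve for culture_id '", culture_id, "'", call. = FALSE)
  rownames(cv) <- NULL
  cv[, c("day", "fluorescence", "below_detection")]
}

#' Write result tables plus a run manifest
#'
#' Writes each named table as `<name>.csv` under `out_dir` and a
#' `manifest.json` recording the file list, package version, seed and any
#' configuration passed. Reals are written with 15 significant digits so a
#' round trip reproduces them to at least 12 significant digits.
#'
#' @param tables named list of data.frames (may be empty).
#' @param out_dir output directory, created if needed.
#' @param config optional list stored verbatim in the manifest.
#' @param seed optional seed recorded in the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, mode = 2) != 0) {
    stop("output directory not writable: ", out_dir, call. = FALSE)
  }
  stopifnot(is.list(tables))
  files <- character(0)
  old <- options(digits = 15); on.exit(options(old))
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(format(tables[[nm]], digits = 15, trim = TRUE, scientific = NA),
                     path, row.names = FALSE, quote = TRUE)
    files <- c(files, basename(path))
  }
  manifest <- list(files = as.list(files),
                   package = "cocultx",
                   version = as.character(utils::packageVersion("cocultx")),
                   seed = seed,
                   config = config,
                   written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write an experiment set to the canonical CSV files
#'
#' Inverse of [read_experiment()]: writes `curves.csv`, `metadata.csv` and,
#' if counts are present, `counts.csv` under `out_dir`.
#'
#' @param es an [experiment_set()].
#' @param out_dir output directory.
#' @return Invisibly, the manifest from [write_results()].
#' @export
write_experiment <- function(es, out_dir) {
  curve_cols <- c("culture_id", "day", "fluorescence")
  if (any(es$curves$below_detection)) curve_cols <- c(curve_cols, "below_detection")
  tables <- list(
    curves = es$curves[, curve_cols],
    metadata = es$metadata[, c("culture_id", "experiment", "pro_strain",
                               "alt_strain", "replicate")]
  )
  if (!is.null(es$counts)) {
    tables$counts <- es$counts[, c("culture_id", "day", "population", "cells_per_ml")]
  }
  write_results(tables, out_dir, config = es$provenance)
}
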