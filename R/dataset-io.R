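# Dataset persistence: one CSV per measurement class plus a YAML manifest
# recording the generating configuration and seed, so a written dataset can be
# reloaded (or regenerated) exactly.

dataset_files <- c(meteorology = "meteorology.csv",
                   sensors = "sensors.csv",
                   water_potential = "water_potential.csv",
                   soil_moisture = "soil_moisture.csv",
                   isotopes = "isotopes.csv",
                   gas_exchange = "gas_exchange.csv",
                   leaf_loss = "leaf_loss.csv",
                   trees = "trees.csv")

required_columns <- list(
  meteorology = c("timestamp", "day", "temperature", "rh", "irradiance", "vpd"),
  sensors = c("timestamp", "day", "tree", "heat_velocity",
              "stem_water_content"),
  water_potential = c("day", "tree", "psi_pd", "psi_md"),
  soil_moisture = c("day", "tree", "depth_cm", "vwc"),
  isotopes = c("day", "tree", "medium", "depth_cm", "dD", "d18O"),
  gas_exchange = c("day", "tree", "stomatal_conductance", "assimilation"),
  leaf_loss = c("day", "tree", "area_cm2"),
  trees = c("tree", "sapwood_area_cm2"))

#' Write a dataset to a directory of CSV files
#'
#' Writes one RFC-4180 CSV (UTF-8, ISO-8601 timestamps) per measurement class
#' plus `manifest.yml` holding the generating configuration and seed. The
#' written form round-trips losslessly through [load_dataset()]. When `truth`
#' is supplied its daily table is written as `truth_daily.csv` (labelled
#' synthetic ground truth, not a measurement).
#'
#' @param dataset a `drydown_dataset` (from [simulate_drydown()] or
#'   [load_dataset()]).
#' @param directory output directory (created if absent).
#' @param truth optional `synthetic_truth` whose daily summary should be
#'   persisted alongside the observations.
#' @return invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, directory, truth = NULL) {
  if (!inherits(dataset, "drydown_dataset")) {
    stop("`dataset` must be a drydown_dataset")
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  written <- character(0)
  for (nm in names(dataset_files)) {
    path <- file.path(directory, dataset_files[[nm]])
    readr::write_csv(dataset[[nm]], path, progress = FALSE)
    written <- c(written, path)
  }
  manifest <- list(format = "drydownr-dataset", version = 1L,
                   seed = dataset$seed,
                   config = config_to_list(dataset$config),
                   files = unname(dataset_files))
  manifest_path <- file.path(directory, "manifest.yml")
  yaml::write_yaml(manifest, manifest_path)
  written <- c(written, manifest_path)
  if (!is.null(truth)) {
    tp <- file.path(directory, "truth_daily.csv")
    readr::write_csv(truth$daily, tp, progress = FALSE)
    written <- c(written, tp)
  }
  invisible(written)
}

#' Load a dataset from a directory written by [write_dataset()]
#'
#' Validates the manifest and the required columns of every table (errors name
#' the offending file and column); unknown extra columns are preserved
#' untouched.
#'
#' @param directory directory containing `manifest.yml` and the CSV tables.
#' @return a `drydown_dataset`.
#' @export
load_dataset <- function(directory) {
  manifest_path <- file.path(directory, "manifest.yml")
  if (!file.exists(manifest_path)) {
    stop("no manifest.yml in ", directory,
         ": not a dataset directory (write one with write_dataset())")
  }
  manifest <- yaml::read_yaml(manifest_path)
  if (!identical(manifest$format, "drydownr-dataset")) {
    stop("manifest.yml in ", directory, " is not a drydownr dataset manifest")
  }
  cfg <- config_from_list(manifest$config)
  out <- list()
  for (nm in names(dataset_files)) {
    path <- file.path(directory, dataset_files[[nm]])
    if (!file.exists(path)) stop("missing dataset file: ", path)
    tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    missing_cols <- setdiff(required_columns[[nm]], names(tbl))
    if (length(missing_cols) > 0) {
      stop(sprintf("file %s is missing column(s): %s", path,
                   paste(missing_cols, collapse = ", ")))
    }
    out[[nm]] <- tbl
  }
  out$config <- cfg
  out$seed <- manifest$seed
  structure(out, class = "drydown_dataset")
}

#' @export
print.drydown_dataset <- function(x, ...) {
  cat(sprintf(paste0(
    "drydown-rewatering dataset: %d trees, %d days (rewatered day %d)\n",
    "  %d sensor rows, %d sampling-day isotope samples, seed %s\n"),
    x$config$n_trees, x$config$n_days, x$config$rewater_day,
    nrow(x$sensors), nrow(x$isotopes), format(x$seed)))
  invisible(x)
}
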