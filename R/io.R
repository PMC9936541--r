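#' Write / read a plate dataset as plain-text CSV
#'
#' A dataset directory holds `timeseries.csv` (`plate_id`, `well`,
#' `time_s`, `fluorescence_au`; time in seconds, long format),
#' `plate_map.csv`, and optionally `truth.csv` (ground-truth sidecar)
#' and `annotations.csv`. The round-trip is lossless: times are written
#' at full double precision.
#'
#' @param ds A `plate_dataset`.
#' @param path Directory to write into (created if needed).
#' @param plate_id Plate label written to the time-series table.
#' @return `write_dataset` returns `path` invisibly; `read_dataset`
#'   returns a `plate_dataset`.
#' @export
write_dataset <- function(ds, path, plate_id = "plate1") {
  stopifnot(inherits(ds, "plate_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ts <- data.frame(plate_id = plate_id, well = ds$wells$well,
                   time_s = format(ds$wells$time * 3600, digits = 17,
                                   scientific = FALSE, trim = TRUE),
                   fluorescence_au = format(ds$wells$value, digits = 17,
                                            trim = TRUE))
  utils::write.csv(ts, file.path(path, "timeseries.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(ds$plate_map, file.path(path, "plate_map.csv"),
                   row.names = FALSE)
  if (!is.null(ds$truth))
    utils::write.csv(format(ds$truth, digits = 17, trim = TRUE),
                     file.path(path, "truth.csv"), row.names = FALSE,
                     quote = FALSE)
  if (!is.null(ds$annotations))
    utils::write.csv(ds$annotations, file.path(path, "annotations.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  f_ts <- file.path(path, "timeseries.csv")
  f_map <- file.path(path, "plate_map.csv")
  if (!file.exists(f_ts) || !file.exists(f_map))
    stop_input(sprintf("'%s' is not a dataset directory (need timeseries.csv and plate_map.csv)",
                       path))
  ts <- utils::read.csv(f_ts, stringsAsFactors = FALSE)
  wells <- data.frame(well = ts$well, time = ts$time_s / 3600,
                      value = ts$fluorescence_au)
  map <- utils::read.csv(f_map, stringsAsFactors = FALSE)
  truth <- NULL
  if (file.exists(file.path(path, "truth.csv")))
    truth <- utils::read.csv(file.path(path, "truth.csv"),
                             stringsAsFactors = FALSE)
  ann <- NULL
  if (file.exists(file.path(path, "annotations.csv")))
    ann <- utils::read.csv(file.path(path, "annotations.csv"),
                           stringsAsFactors = FALSE)
  plate_dataset(wells, map, annotations = ann, truth = truth)
}

#' Packaged vitamin-metabolite annotation table
#'
#' Loads the packaged table of 18 fat- and water-soluble vitamin
#' metabolites with their qualitative effect on Abeta42 aggregation
#' (`acceleration`, `inhibition`, `no effect`), used to drive the
#' synthetic screen scenario.
#'
#' @param path Optional path to an alternative annotation CSV with
#'   columns `metabolite`, `vitamin_group`, `effect`.
#' @return A data.frame with columns `metabolite`, `vitamin_group`,
#'   `effect`.
#' @export
read_metabolite_annotations <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "vitamin_metabolites.csv",
                        package = "amylokin", mustWork = TRUE)
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "effect")
  if (!all(need %in% names(ann)))
    stop_input("annotation table needs columns metabolite and effect")
  ann
}

#' Read a flat run-configuration file
#'
#' YAML configuration with flat keys (`k_n`, `k_2`, `k_plus`, `n_c`,
#' `n_2`, `m_total_uM`, `seed_mass_fraction`, `seed_length`) describing
#' one aggregation reaction; unspecified keys fall back to the package
#' defaults.
#'
#' @param path YAML file path.
#' @return A `kinetic_params` object.
#' @export
read_params_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_input("the 'yaml' package is required to read configuration files")
  cfg <- yaml::read_yaml(path)
  def <- default_params()
  m_total <- cfg$m_total_uM %||% def$m_total
  sf <- cfg$seed_mass_fraction %||% 0
  L <- cfg$seed_length %||% 500
  M0 <- sf * m_total
  kinetic_params(
    k_n = cfg$k_n %||% def$k_n, k_2 = cfg$k_2 %||% def$k_2,
    k_plus = cfg$k_plus %||% def$k_plus,
    n_c = cfg$n_c %||% def$n_c, n_2 = cfg$n_2 %||% def$n_2,
    m_total = m_total, M_0 = M0, P_0 = if (M0 > 0) M0 / L else 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
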