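#' Write a calibration dataset as CSV plus JSON sidecar
#'
#' The CSV holds the points (columns \code{abscissa}, \code{value},
#' \code{weight}); the sidecar holds the metadata (observable, abscissa
#' kind, normalization, protocol or ligand configuration, provenance).
#'
#' @param dataset A [calibration_dataset()].
#' @param dir Output directory.
#' @return Invisible character vector of the two file paths.
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(dataset$id, ".csv"))
  side <- file.path(dir, paste0(dataset$id, ".json"))
  utils::write.csv(dataset$points, csv, row.names = FALSE)
  meta <- dataset[c("id", "observable", "abscissa", "normalization",
                    "ligand", "summary", "at_time", "t_end", "source",
                    "truth")]
  if (!is.null(dataset$protocol)) {
    pr <- dataset$protocol
    meta$protocol <- list(events = pr$events, t_end = pr$t_end,
                          output_grid = range(pr$output_grid))
  }
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(csv, side))
}

#' Read a calibration dataset written by [write_dataset_csv()]
#'
#' @param path Path to the CSV file (the JSON sidecar is found by
#'   replacing the extension).
#' @return A [calibration_dataset()].
#' @export
read_dataset_csv <- function(path) {
  side <- sub("\\.csv$", ".json", path)
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(side)) stop("missing JSON sidecar: ", side)
  pts <- utils::read.csv(path, colClasses = "character")
  need <- c("abscissa", "value", "weight")
  if (!identical(names(pts)[seq_along(need)], need))
    stop("malformed header in ", path, ": expected columns ",
         paste(need, collapse = ", "))
  for (col in need) {
    v <- suppressWarnings(as.numeric(pts[[col]]))
    bad <- which(is.na(v) & !is.na(pts[[col]]))
    if (length(bad))
      stop("non-numeric cell in ", path, ", column '", col, "', row ",
           bad[1])
    pts[[col]] <- v
  }
  bad <- which(pts$weight <= 0)
  if (length(bad))
    stop("non-positive weight in ", path, ", row ", bad[1])
  meta <- jsonlite::read_json(side)
  protocol <- NULL
  if (!is.null(meta$protocol)) {
    ev <- lapply(meta$protocol$events, function(e)
      list(time = e$time, ligand = e$ligand, amount = e$amount,
           unit = e$unit %||% "ng/mL"))
    protocol <- stimulus_protocol(ev, t_end = meta$protocol$t_end)
  }
  calibration_dataset(
    id = meta$id, observable = meta$observable, abscissa = meta$abscissa,
    points = pts, normalization = meta$normalization, protocol = protocol,
    ligand = meta$ligand, summary = meta$summary %||% "at_time",
    at_time = meta$at_time %||% 15, t_end = meta$t_end %||% 60,
    source = meta$source %||% "file", truth = meta$truth)
}

#' Write a simulation result as tidy CSV
#'
#' Long format: one row per (time, observable, value).
#'
#' @param result A \code{simulation_result}.
#' @param path Output CSV path.
#' @return Invisible path.
#' @export
write_results_csv <- function(result, path) {
  obs <- result$observables
  df <- data.frame(
    time = rep(result$times, times = ncol(obs)),
    observable = rep(colnames(obs), each = nrow(obs)),
    value = as.vector(obs))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Every pipeline output directory carries exactly one manifest recording
#' the command, configuration hash, package version, seed, timestamps and
#' output file list, so that identical config + seed reruns are
#' identifiable.
#'
#' @param dir Output directory.
#' @param command Command or function name.
#' @param config Configuration object (hashed into the manifest).
#' @param seed Seed used for all randomness in the run.
#' @param outputs Character vector of output files (relative to dir).
#' @return Invisible manifest list.
#' @export
write_manifest <- function(dir, command, config = list(), seed = NA,
                           outputs = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    command = command,
    config_hash = .config_hash(config),
    package_version = as.character(utils::packageVersion("endonet")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

.config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  h <- 0
  for (ch in utf8ToInt(as.character(s))) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Read a model/run configuration file
#'
#' YAML is the canonical format; JSON is accepted (any file parseable by
#' the JSON reader is treated as JSON first).
#'
#' @param path Path to a .yaml/.yml/.json file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  if (grepl("\\.json$", path)) return(jsonlite::read_json(path))
  yaml::read_yaml(path)
}
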