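# Configuration files, CSV readers/writers for landscapes and weather,
# and run outputs (metrics CSV, path GeoJSON, run-metadata JSON).
#
# Conventions: dates ISO-8601; node ids 0-based in files; distances km,
# energies kJ, masses kg, temperatures degC, snow cm, pressure Pa.

#' Load a simulation configuration from YAML
#'
#' Unknown keys are rejected by name; missing keys take the study
#' defaults of [sim_config()] (an empty file yields the full default
#' configuration: N0 = 19,856,514, WSI threshold 7.5, 21 classes, ...).
#'
#' @param path YAML file path.
#' @return a `flyway_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  for (nm in c("forage_density", "decay_weights"))
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  do.call(sim_config, vals)
}

#' Save a configuration to YAML
#' @param cfg a `flyway_config`.
#' @param path output file.
#' @export
save_config <- function(cfg, path) {
  out <- unclass(cfg)
  for (nm in c("forage_density", "decay_weights"))
    out[[nm]] <- as.list(out[[nm]])   # keep names through YAML
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write / read a landscape as CSV
#'
#' One row per node: `node_id`, `x`, `y`, `area`, the cover proportion
#' columns, `breeding`, and roosting quality `R` if present. Grid
#' metadata (resolution, coordinate mode, dimensions) travels in a
#' header comment line.
#'
#' @param grid a `flyway_grid`.
#' @param path CSV file path.
#' @export
write_landscape <- function(grid, path) {
  hdr <- sprintf("# flyway_grid resolution=%.10g coords=%s n_x=%d n_y=%d",
                 grid$resolution, grid$coords, grid$n_x, grid$n_y)
  writeLines(hdr, path)
  suppressWarnings(
    data.table::fwrite(grid$nodes, path, append = TRUE, col.names = TRUE))
  invisible(path)
}

#' @rdname write_landscape
#' @return `read_landscape`: a `flyway_grid`.
#' @export
read_landscape <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  kv <- strsplit(meta, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  nodes <- as.data.frame(data.table::fread(path, skip = 1))
  structure(list(nodes = nodes,
                 resolution = as.numeric(vals[["resolution"]]),
                 coords = vals[["coords"]],
                 n_x = as.integer(vals[["n_x"]]),
                 n_y = as.integer(vals[["n_y"]])),
            class = "flyway_grid")
}

#' Write / read daily weather as long CSV
#'
#' Columns `date` (ISO-8601), `node_id` (0-based), `T` (degC), `S`
#' (cm), `P` (Pa). Reading validates the date column and reshapes to
#' the days x nodes matrices of [derive_weather()].
#'
#' @param weather a `flyway_weather`.
#' @param path CSV file path.
#' @param start_date first day (default "2000-09-01").
#' @export
write_weather <- function(weather, path, start_date = "2000-09-01") {
  n_days <- nrow(weather$T_air); n_nodes <- ncol(weather$T_air)
  dt <- data.table::data.table(
    date = rep(format(as.Date(start_date) + seq_len(n_days) - 1), n_nodes),
    node_id = rep(seq_len(n_nodes) - 1L, each = n_days),
    T = as.vector(weather$T_air),
    S = as.vector(weather$S),
    P = if (is.null(weather$P)) NA_real_ else as.vector(weather$P))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_weather
#' @param threshold WSI availability threshold for re-derivation.
#' @return `read_weather`: a `flyway_weather`.
#' @export
read_weather <- function(path, threshold = 7.5) {
  dt <- data.table::fread(path)
  need <- c("date", "node_id", "T", "S")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("weather CSV is missing columns: ", paste(miss, collapse = ", "))
  dates <- tryCatch(as.Date(as.character(dt$date)),
                    error = function(e) NA)
  if (anyNA(dates)) stop("malformed date column (expect ISO-8601 dates)")
  dt$date <- dates
  data.table::setorderv(dt, c("node_id", "date"))
  days <- sort(unique(dt$date))
  nodes <- sort(unique(dt$node_id))
  n_days <- length(days); n_nodes <- length(nodes)
  if (nrow(dt) != n_days * n_nodes)
    stop("weather CSV is not a complete day x node grid")
  shape <- function(x) matrix(x, n_days, n_nodes)
  P <- if ("P" %in% names(dt) && !anyNA(dt$P)) shape(dt$P) else NULL
  derive_weather(shape(dt$T), shape(dt$S), P, threshold)
}

#' Write the outputs of a run
#'
#' Writes `metrics.csv` (one row per day), `path.geojson` (the
#' center-of-mass track as a LineString), `top_nodes.csv` (day, node
#' id), and `run_metadata.json` (config snapshot, seed, decision-switch
#' values, package version) sufficient to reproduce the run
#' bit-identically.
#'
#' @param run a `flyway_run`.
#' @param dir output directory (created if needed).
#' @export
write_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(run$metrics, file.path(dir, "metrics.csv"))
  tn <- data.table::data.table(
    day = rep(run$metrics$day, lengths(run$top_nodes)),
    node_id = unlist(run$top_nodes))
  data.table::fwrite(tn, file.path(dir, "top_nodes.csv"))
  com <- run$metrics[, c("com_x", "com_y")]
  gj <- list(type = "Feature",
             properties = list(name = "population center-of-mass path",
                               units = if (run$ctx$planar %||% TRUE)
                                 "km" else "degrees"),
             geometry = list(type = "LineString",
                             coordinates = unname(
                               lapply(seq_len(nrow(com)),
                                      function(i) as.numeric(com[i, ])))))
  jsonlite::write_json(gj, file.path(dir, "path.geojson"),
                       auto_unbox = TRUE, digits = NA)
  cfg_out <- unclass(run$cfg)
  for (nm in c("forage_density", "decay_weights"))
    cfg_out[[nm]] <- as.list(cfg_out[[nm]])   # keep names through JSON
  meta <- list(
    config = cfg_out,
    seed = run$cfg$seed,
    n0 = run$n0,
    inflection_day = run$inflection,
    decisions = list(combine_rule = run$cfg$combine_rule,
                     decay_order = run$cfg$decay_order,
                     roost_rule = run$cfg$roost_rule,
                     wsi_exponent = run$cfg$wsi_exponent,
                     starvation = run$cfg$starvation),
    package_version = as.character(utils::packageVersion("flywaysim")),
    written = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
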