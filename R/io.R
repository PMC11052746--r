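#' Write a region to a directory of CSV files
#'
#' Emits `zones.csv` (id, municipality_id, lon, lat, population,
#' surface_km2), `municipalities.csv` (id, name, area_class,
#' candidate_location_id), `hospitals.csv` (id, lon, lat, kind),
#' `candidates.csv` (id, lon, lat), and the travel matrices
#' `travel_time.csv` / `travel_dist.csv` (first column `location`, one
#' column per location id).
#'
#' @param region An [ems_region()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_region <- function(region, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(
    dplyr::select(region$zones, "id", "municipality_id", "lon", "lat",
                  "population", "surface_km2"),
    file.path(dir, "zones.csv")
  )
  readr::write_csv(region$municipalities, file.path(dir, "municipalities.csv"))
  readr::write_csv(region$hospitals, file.path(dir, "hospitals.csv"))
  readr::write_csv(region$candidates, file.path(dir, "candidates.csv"))
  write_matrix_csv(region$travel_time, file.path(dir, "travel_time.csv"))
  write_matrix_csv(region$travel_dist, file.path(dir, "travel_dist.csv"))
  invisible(dir)
}

write_matrix_csv <- function(m, path) {
  df <- tibble::as_tibble(m)
  df <- dplyr::bind_cols(tibble::tibble(location = rownames(m)), df)
  readr::write_csv(df, path)
}

read_matrix_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$location
  storage.mode(m) <- "double"
  m
}

#' Read a region from a directory of CSV files
#'
#' Inverse of [write_region()]; the loaded structures are re-validated.
#'
#' @param dir Directory holding the region CSVs.
#' @return An [ems_region()].
#' @export
read_region <- function(dir) {
  rd <- function(f) readr::read_csv(file.path(dir, f), show_col_types = FALSE)
  ems_region(
    zones = rd("zones.csv"),
    municipalities = rd("municipalities.csv"),
    hospitals = rd("hospitals.csv"),
    candidates = rd("candidates.csv"),
    travel_time = read_matrix_csv(file.path(dir, "travel_time.csv")),
    travel_dist = read_matrix_csv(file.path(dir, "travel_dist.csv"))
  )
}

#' Read / write an emergency stream
#'
#' CSV with columns `id`, `t_call`, `lon`, `lat`, `code`, `hospital_kind`,
#' `needs_transport`.
#'
#' @param emergencies Tibble of emergencies.
#' @param path CSV file path.
#' @return `read_emergencies` returns the tibble sorted by `t_call`.
#' @export
write_emergencies <- function(emergencies, path) {
  readr::write_csv(emergencies, path)
  invisible(path)
}

#' @rdname write_emergencies
#' @export
read_emergencies <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_integer(), t_call = readr::col_double(),
      lon = readr::col_double(), lat = readr::col_double(),
      code = readr::col_character(), hospital_kind = readr::col_character(),
      needs_transport = readr::col_logical()
    )
  ) |>
    dplyr::arrange(.data$t_call)
}

#' Read / write a fleet
#'
#' CSV with columns `id`, `type`, `shift`, `station`.
#'
#' @param fleet An [ems_fleet()].
#' @param path CSV file path.
#' @param region Optional region used to validate stations when reading.
#' @export
write_fleet <- function(fleet, path) {
  readr::write_csv(fleet, path)
  invisible(path)
}

#' @rdname write_fleet
#' @export
read_fleet <- function(path, region = NULL) {
  ems_fleet(readr::read_csv(path, show_col_types = FALSE), region)
}

#' Export an event log
#'
#' `write_event_log` writes JSON-lines (one object per emergency, all
#' timestamps and assignments); a tidy CSV of the same records is written
#' alongside when `csv = TRUE`.
#'
#' @param sim An `ems_simulation` (or its tidy log).
#' @param path Output `.jsonl` path.
#' @param csv Also write `<path>.csv`.
#' @export
write_event_log <- function(sim, path, csv = TRUE) {
  log <- if (inherits(sim, "ems_simulation")) sim$log else tibble::as_tibble(sim)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE, digits = NA, na = "null"), con)
  }
  if (csv) readr::write_csv(log, paste0(path, ".csv"))
  invisible(path)
}

#' Export a Pareto front
#'
#' JSON (per solution: the location vectors and the seven cost components)
#' plus a flat CSV of the cost components for radar-plot tooling.
#'
#' @param front An `ems_front` from [plahc()].
#' @param path Output `.json` path.
#' @export
write_front <- function(front, path) {
  recs <- lapply(seq_len(nrow(front)), function(i) {
    c(list(solution = front$solution[[i]]),
      as.list(front[i, setdiff(names(front), "solution")]))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  readr::write_csv(front[, setdiff(names(front), "solution")], paste0(path, ".csv"))
  invisible(path)
}

#' Export cumulative response-time curves
#'
#' One two-column CSV (`minutes`, `cum_freq`) per urgency code.
#'
#' @param stats An `ems_response_stats` from [response_time_stats()].
#' @param dir Output directory.
#' @export
write_response_curves <- function(stats, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(nrow(stats))) {
    cv <- stats$curve[[i]]
    if (length(cv) == 0) next
    readr::write_csv(
      tibble::tibble(minutes = cv, cum_freq = seq_along(cv) / length(cv)),
      file.path(dir, paste0("response_curve_", stats$code[i], ".csv"))
    )
  }
  invisible(dir)
}

#' Run configuration file
#'
#' A single YAML file bundling KPI, dispatch and duration parameters plus the
#' root seed; every generated artifact embeds this seed so a run can be
#' reproduced end to end.
#'
#' @param path YAML file path.
#' @return A named list with `kpi` ([kpi_config()]), `dispatch`
#'   ([dispatch_config()]), `durations` ([duration_model()]) and `seed`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  list(
    kpi = do.call(kpi_config, y$kpi %||% list()),
    dispatch = do.call(dispatch_config, y$dispatch %||% list()),
    durations = do.call(duration_model, y$durations %||% list()),
    seed = y$seed %||% 1L
  )
}
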