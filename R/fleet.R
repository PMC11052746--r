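VEHICLE_TYPES <- c("ALS", "BLS", "MC")
SHIFTS <- c("day", "night", "allday")

#' Define an emergency vehicle fleet
#'
#' A fleet is a tibble with one row per vehicle: Advanced Life Support
#' ambulances (`ALS`, staffed with a registered nurse), Basic Life Support
#' ambulances (`BLS`, staffed by trained volunteers), and medical cars
#' (`MC`, carrying a doctor and dispatched jointly with an ambulance for
#' the most urgent calls; they never transport patients). Each vehicle works
#' a `day` (08:00--20:00), `night` (20:00--08:00) or `allday` shift and is
#' based at a station, which must be a location of the region travel model.
#'
#' @param fleet Data frame with columns `id`, `type`, `shift`, `station`.
#' @param region Optional [ems_region()]; when given, stations are checked
#'   against the travel model.
#' @return A tibble of class `ems_fleet`.
#' @export
ems_fleet <- function(fleet, region = NULL) {
  fleet <- tibble::as_tibble(fleet)
  stopifnot(all(c("id", "type", "shift", "station") %in% names(fleet)))
  if (anyDuplicated(fleet$id)) stop("vehicle ids must be unique", call. = FALSE)
  if (!all(fleet$type %in% VEHICLE_TYPES)) {
    stop("vehicle type must be one of: ", paste(VEHICLE_TYPES, collapse = ", "), call. = FALSE)
  }
  if (!all(fleet$shift %in% SHIFTS)) {
    stop("shift must be one of: ", paste(SHIFTS, collapse = ", "), call. = FALSE)
  }
  if (!is.null(region)) {
    locs <- rownames(region$travel_time)
    if (!all(fleet$station %in% locs)) {
      bad <- setdiff(fleet$station, locs)
      stop("station(s) not in travel model: ", paste(utils::head(bad, 3), collapse = ", "),
           call. = FALSE)
    }
  }
  class(fleet) <- c("ems_fleet", class(fleet))
  fleet
}

#' Vehicles rostered on a shift
#'
#' All-day vehicles are counted in both the day and the night roster.
#'
#' @param fleet An [ems_fleet()].
#' @param shift `"day"` or `"night"`.
#' @return The subset of fleet rows active on that shift.
#' @export
fleet_roster <- function(fleet, shift = c("day", "night")) {
  shift <- match.arg(shift)
  dplyr::filter(fleet, .data$shift %in% c(!!shift, "allday"))
}

# shift windows in minutes-of-day; day = [480, 1200)
shift_window <- function(shift) {
  switch(shift,
    day = c(480, 1200),
    night = c(1200, 480),
    allday = c(0, 1440)
  )
}

in_shift_at <- function(shift, t) {
  m <- t %% 1440
  switch(shift,
    day = m >= 480 & m < 1200,
    night = m >= 1200 | m < 480,
    allday = rep(TRUE, length(m))
  )
}
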