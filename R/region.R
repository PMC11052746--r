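#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6371 km, the metric used to
#' pre-filter candidate vehicles before exact road-network lookups and to
#' compute travel times from off-road (interpolated) vehicle positions.
#'
#' @param a,b Coordinates as `c(lon, lat)` in decimal degrees (WGS84), or
#'   two-column matrices of such pairs (recycled row-wise).
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_km(c(13.23, 46.06), c(13.77, 45.65))
#' @export
haversine_km <- function(a, b) {
  a <- coerce_lonlat(a)
  b <- coerce_lonlat(b)
  if (any(abs(a[, 2]) > 90, na.rm = TRUE) || any(abs(b[, 2]) > 90, na.rm = TRUE)) {
    stop("invalid latitude: |lat| must be <= 90 degrees", call. = FALSE)
  }
  if (any(abs(a[, 1]) > 360, na.rm = TRUE) || any(abs(b[, 1]) > 360, na.rm = TRUE)) {
    stop("invalid longitude", call. = FALSE)
  }
  geosphere::distHaversine(a, b, r = 6371000) / 1000
}

coerce_lonlat <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 2) stop("coordinates must be c(lon, lat)", call. = FALSE)
    x <- matrix(as.numeric(x), ncol = 2)
  }
  x
}

AREA_CLASSES <- c("city", "rural", "mountain", "seaside")
HOSPITAL_KINDS <- c("hub", "spoke", "primary_care")

#' Assemble and validate an EMS region
#'
#' A region bundles the demographic units (municipalities and their census
#' zones), the hospital network, the candidate ambulance station locations,
#' and a travel model (time and road-distance matrices over every location).
#' All downstream computations -- isochrone coverage, KPIs, the simulator and
#' the optimizer -- read travel times from the matrices, so no road network
#' or GIS layer is needed.
#'
#' @param zones Tibble with columns `id`, `municipality_id`, `lon`, `lat`,
#'   `population` (>= 0), `surface_km2` (> 0).
#' @param municipalities Tibble with columns `id`, `name`, `area_class`
#'   (one of `"city"`, `"rural"`, `"mountain"`, `"seaside"`) and
#'   `candidate_location_id`.
#' @param hospitals Tibble with columns `id`, `lon`, `lat`, `kind` (one of
#'   `"hub"`, `"spoke"`, `"primary_care"`).
#' @param candidates Tibble with columns `id`, `lon`, `lat`: possible
#'   ambulance station locations (typically one per municipality).
#' @param travel_time,travel_dist Square numeric matrices (minutes and road
#'   km) with identical dimnames covering every candidate, hospital and zone
#'   id. Non-negative with a zero diagonal.
#' @return An object of class `ems_region`.
#' @export
ems_region <- function(zones, municipalities, hospitals, candidates,
                       travel_time, travel_dist) {
  zones <- tibble::as_tibble(zones)
  municipalities <- tibble::as_tibble(municipalities)
  hospitals <- tibble::as_tibble(hospitals)
  candidates <- tibble::as_tibble(candidates)

  stopifnot(
    all(c("id", "municipality_id", "lon", "lat", "population", "surface_km2") %in% names(zones)),
    all(c("id", "name", "area_class", "candidate_location_id") %in% names(municipalities)),
    all(c("id", "lon", "lat", "kind") %in% names(hospitals)),
    all(c("id", "lon", "lat") %in% names(candidates))
  )
  if (any(zones$population < 0)) stop("zone population must be >= 0", call. = FALSE)
  if (any(zones$surface_km2 <= 0)) stop("zone surface must be > 0", call. = FALSE)
  if (!all(municipalities$area_class %in% AREA_CLASSES)) {
    stop("area_class must be one of: ", paste(AREA_CLASSES, collapse = ", "), call. = FALSE)
  }
  if (!all(hospitals$kind %in% HOSPITAL_KINDS)) {
    stop("hospital kind must be one of: ", paste(HOSPITAL_KINDS, collapse = ", "), call. = FALSE)
  }
  if (!all(zones$municipality_id %in% municipalities$id)) {
    stop("every zone must belong to a known municipality", call. = FALSE)
  }
  if (!all(municipalities$candidate_location_id %in% candidates$id)) {
    stop("unknown candidate_location_id in municipalities", call. = FALSE)
  }
  ids <- c(candidates$id, hospitals$id, zones$id)
  if (anyDuplicated(ids)) stop("location ids (candidates, hospitals, zones) must be distinct", call. = FALSE)

  for (m in list(travel_time, travel_dist)) {
    if (!is.matrix(m) || nrow(m) != ncol(m)) stop("travel matrices must be square", call. = FALSE)
    if (is.null(rownames(m)) || !setequal(rownames(m), colnames(m))) {
      stop("travel matrices need matching row/col location names", call. = FALSE)
    }
    if (!all(ids %in% rownames(m))) stop("travel matrices must cover all locations", call. = FALSE)
    if (any(m < 0)) stop("travel matrices must be non-negative", call. = FALSE)
    if (any(abs(diag(m)) > 1e-9)) stop("travel matrix diagonal must be zero", call. = FALSE)
  }

  # area_class carried onto zones for convenience
  zones$area_class <- municipalities$area_class[match(zones$municipality_id, municipalities$id)]

  structure(
    list(
      zones = zones, municipalities = municipalities, hospitals = hospitals,
      candidates = candidates, travel_time = travel_time, travel_dist = travel_dist
    ),
    class = "ems_region"
  )
}

#' @export
print.ems_region <- function(x, ...) {
  cat(
    "<ems_region> ", nrow(x$municipalities), " municipalities, ",
    nrow(x$zones), " zones, ", nrow(x$hospitals), " hospitals, ",
    nrow(x$candidates), " candidate stations\n",
    "  population ", format(sum(x$zones$population), big.mark = ","),
    " over ", format(round(sum(x$zones$surface_km2)), big.mark = ","), " km2\n",
    sep = ""
  )
  invisible(x)
}

travel_time_from <- function(region, from, to) {
  tt <- region$travel_time
  if (!from %in% rownames(tt)) stop("unknown location id: ", from, call. = FALSE)
  tt[from, to]
}

#' Zones reachable within a travel-time threshold
#'
#' The matrix-based surrogate of an isochrone query: a census zone counts as
#' reached when the travel time from `location` to the zone centroid does not
#' exceed `threshold` minutes. (Polygon/zone intersections of true road
#' isochrones are approximated by centroid membership.)
#'
#' @param region An [ems_region()].
#' @param location A location id present in the travel model (candidate
#'   station, hospital, or zone centroid).
#' @param threshold Travel-time threshold in minutes (> 0 or `Inf`; 0 is
#'   allowed and returns only co-located zones).
#' @return Character vector of zone ids, ordered as in `region$zones`.
#' @export
isochrone_zones <- function(region, location, threshold) {
  stopifnot(inherits(region, "ems_region"), length(location) == 1, threshold >= 0)
  tt <- travel_time_from(region, location, region$zones$id)
  region$zones$id[tt <= threshold]
}

#' Population, surface and density by area class
#'
#' Aggregates the region by its four area classes (cities, rural, mountain,
#' seaside) plus a total row: number of municipalities, resident population,
#' surface in km2, and density in inhabitants per km2 (rounded to one decimal
#' for reporting, as customary in regional statistics).
#'
#' @param region An [ems_region()].
#' @return A tibble with one row per represented area class and a `"total"` row.
#' @export
area_summary <- function(region) {
  stopifnot(inherits(region, "ems_region"))
  if (sum(region$zones$surface_km2) <= 0) stop("zero total surface", call. = FALSE)
  per_mun <- region$zones |>
    dplyr::group_by(.data$municipality_id) |>
    dplyr::summarise(
      population = sum(.data$population),
      surface_km2 = sum(.data$surface_km2), .groups = "drop"
    ) |>
    dplyr::left_join(
      dplyr::select(region$municipalities, id, area_class = "area_class"),
      by = c(municipality_id = "id")
    )
  by_class <- per_mun |>
    dplyr::group_by(area_class = factor(.data$area_class, levels = AREA_CLASSES)) |>
    dplyr::summarise(
      municipalities = dplyr::n(),
      population = sum(.data$population),
      surface_km2 = sum(.data$surface_km2), .groups = "drop"
    ) |>
    dplyr::mutate(area_class = as.character(.data$area_class))
  total <- tibble::tibble(
    area_class = "total",
    municipalities = nrow(per_mun),
    population = sum(per_mun$population),
    surface_km2 = sum(per_mun$surface_km2)
  )
  dplyr::bind_rows(by_class, total) |>
    dplyr::mutate(density = round(ifelse(.data$surface_km2 > 0,
                                         .data$population / .data$surface_km2, 0), 1))
}
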