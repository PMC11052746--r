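#' KPI configuration
#'
#' Parameters shared by all coverage and fairness indicators.
#'
#' @param response_threshold Timeliness threshold in minutes within which a
#'   response is considered on time (regulatory default 18).
#' @param bls_weight Fraction of the corresponding ALS service credited to a
#'   BLS ambulance in the coverage indicators (default 0.70): BLS crews offer
#'   basic care only and are used for critical emergencies only when no
#'   alternative vehicle is available.
#' @param second_ambulance_metric `"distance"` (road km, default) or `"time"`
#'   (road minutes) for the second-ambulance indicator.
#' @param fair_denominator How the per-zone reach share is normalized:
#'   `"fleet"` (default) divides the weighted number of ambulances reaching a
#'   zone by the total weighted fleet of the shift; `"reachable_population"`
#'   credits each ambulance with the fraction of its own reachable population
#'   that lies in the municipality.
#' @return A list of class `ems_kpi_config`.
#' @export
kpi_config <- function(response_threshold = 18, bls_weight = 0.70,
                       second_ambulance_metric = c("distance", "time"),
                       fair_denominator = c("fleet", "reachable_population")) {
  stopifnot(response_threshold > 0, bls_weight > 0, bls_weight <= 1)
  structure(
    list(
      response_threshold = response_threshold,
      bls_weight = bls_weight,
      second_ambulance_metric = match.arg(second_ambulance_metric),
      fair_denominator = match.arg(fair_denominator)
    ),
    class = "ems_kpi_config"
  )
}

#' Gini index of a non-negative distribution
#'
#' Normalized mean absolute difference: `G = sum_ij |x_i - x_j| / (2 n sum(x))`.
#' Zero means perfect equality; the maximum for `n` values is `1 - 1/n`.
#' The index is scale-invariant and, by convention, 0 for an all-zero vector
#' (degenerate perfect equality).
#'
#' @param x Numeric vector, all values >= 0, length >= 1.
#' @return A number in `[0, 1)`.
#' @export
gini <- function(x) {
  if (length(x) < 1) stop("gini needs at least one value", call. = FALSE)
  if (any(x < 0)) stop("gini is defined for non-negative values", call. = FALSE)
  s <- sum(x)
  if (s == 0) return(0)
  n <- length(x)
  # sorted closed form: sum_ij |xi - xj| = 2 * sum_i (2i - n - 1) x_(i)
  xs <- sort(x)
  sum((2 * seq_len(n) - n - 1) * xs) / (n * s)
}

transport_roster <- function(fleet, shift) {
  r <- fleet_roster(fleet, shift)
  dplyr::filter(r, .data$type %in% c("ALS", "BLS"))
}

# weighted reach of each transport ambulance to each zone; returns list with
# per-zone share r_z and supporting pieces
zone_reach_shares <- function(region, fleet, shift, config) {
  tr <- transport_roster(fleet, shift)
  if (nrow(tr) == 0) {
    stop("no transport (ALS/BLS) vehicles rostered on the ", shift, " shift", call. = FALSE)
  }
  w <- ifelse(tr$type == "ALS", 1, config$bls_weight)
  tt <- region$travel_time[tr$station, region$zones$id, drop = FALSE]
  reach <- tt <= config$response_threshold   # ambulances x zones
  if (config$fair_denominator == "fleet") {
    r_z <- as.numeric(crossprod(reach, w)) / sum(w)
  } else {
    # each ambulance contributes, to every zone it reaches, the zone's share of
    # the population that the ambulance can reach at all
    pop <- region$zones$population
    pop_reached <- as.numeric(reach %*% pop)
    contrib <- reach * (w / pmax(pop_reached, 1))  # per-person credit
    r_z <- as.numeric(crossprod(contrib, rep(1, nrow(tr)))) * pop / sum(w)
    r_z <- r_z / max(r_z, 1e-12)
  }
  list(r_z = r_z, zones = region$zones)
}

#' Per-municipality ambulance reach shares
#'
#' For each census zone, the proportion of the shift's transport fleet
#' (ALS weight 1, BLS weight `bls_weight`, medical cars excluded) that can
#' reach the zone centroid within the response threshold; municipality shares
#' are the population-weighted means of their zones' proportions.
#'
#' @param region An [ems_region()].
#' @param fleet An [ems_fleet()].
#' @param shift `"day"` or `"night"`.
#' @param config A [kpi_config()].
#' @return A tibble with columns `municipality_id`, `share`.
#' @export
municipality_reach_shares <- function(region, fleet, shift = c("day", "night"),
                                      config = kpi_config()) {
  shift <- match.arg(shift)
  zr <- zone_reach_shares(region, fleet, shift, config)
  zr$zones |>
    dplyr::mutate(r_z = zr$r_z) |>
    dplyr::group_by(.data$municipality_id) |>
    dplyr::summarise(
      share = if (sum(.data$population) > 0) {
        stats::weighted.mean(.data$r_z, .data$population)
      } else {
        mean(.data$r_z)
      },
      .groups = "drop"
    )
}

#' Fair coverage: Gini index of municipality reach shares
#'
#' The fairness objective: the Gini index of the per-municipality reach
#' shares, with day and night combined as the unweighted mean of the two
#' shift shares. Lower is fairer; 0 means every municipality enjoys the same
#' proportion of reachable ambulances.
#'
#' @inheritParams municipality_reach_shares
#' @return A number in `[0, 1)`.
#' @export
fair_coverage <- function(region, fleet, config = kpi_config()) {
  d <- municipality_reach_shares(region, fleet, "day", config)
  n <- municipality_reach_shares(region, fleet, "night", config)
  shares <- dplyr::inner_join(d, n, by = "municipality_id", suffix = c("_day", "_night"))
  gini((shares$share_day + shares$share_night) / 2)
}

zone_coverage_credit <- function(region, fleet, shift, config) {
  tr <- transport_roster(fleet, shift)
  if (nrow(tr) == 0) return(rep(0, nrow(region$zones)))
  tt <- region$travel_time[tr$station, region$zones$id, drop = FALSE]
  reach <- tt <= config$response_threshold
  als <- tr$type == "ALS"
  has_als <- if (any(als)) colSums(reach[als, , drop = FALSE]) > 0 else rep(FALSE, ncol(reach))
  has_bls <- if (any(!als)) colSums(reach[!als, , drop = FALSE]) > 0 else rep(FALSE, ncol(reach))
  ifelse(has_als, 1, ifelse(has_bls, config$bls_weight, 0))
}

#' Population covered within the response threshold
#'
#' Fraction of residents living in zones reachable within the threshold:
#' a zone counts fully when at least one ALS ambulance reaches it,
#' `bls_weight` when only BLS ambulances do, and 0 otherwise.
#'
#' @inheritParams municipality_reach_shares
#' @return Covered fraction in `[0, 1]`.
#' @export
population_coverage <- function(region, fleet, shift = c("day", "night"),
                                config = kpi_config()) {
  shift <- match.arg(shift)
  p <- region$zones$population
  if (sum(p) == 0) stop("zero total population", call. = FALSE)
  credit <- zone_coverage_credit(region, fleet, shift, config)
  sum(p * credit) / sum(p)
}

#' Surface covered within the response threshold
#'
#' As [population_coverage()] with zone surfaces replacing populations:
#' guards service quality in extensive but sparsely populated areas.
#'
#' @inheritParams municipality_reach_shares
#' @return Covered fraction in `[0, 1]`.
#' @export
surface_coverage <- function(region, fleet, shift = c("day", "night"),
                             config = kpi_config()) {
  shift <- match.arg(shift)
  s <- region$zones$surface_km2
  credit <- zone_coverage_credit(region, fleet, shift, config)
  sum(s * credit) / sum(s)
}

#' Worst-case second-ambulance distance
#'
#' For each zone, the road distance to the station of the second-nearest
#' transport ambulance (counting multiplicity: two ambulances at one station
#' provide first and second cover from the same distance). The indicator is
#' the maximum over zones, capturing the worst case when the nearest
#' ambulance is already busy.
#'
#' @inheritParams municipality_reach_shares
#' @return Kilometres (or minutes when `second_ambulance_metric = "time"`).
#' @export
second_ambulance_max <- function(region, fleet, shift = c("day", "night"),
                                 config = kpi_config()) {
  shift <- match.arg(shift)
  tr <- transport_roster(fleet, shift)
  if (nrow(tr) < 2) stop("second-ambulance distance needs >= 2 transport vehicles", call. = FALSE)
  m <- if (config$second_ambulance_metric == "distance") region$travel_dist else region$travel_time
  d <- m[tr$station, region$zones$id, drop = FALSE]  # ambulances x zones
  second <- apply(d, 2, function(col) sort(col, partial = 2)[2])
  max(second)
}

#' Multi-objective cost vector of a fleet deployment
#'
#' The seven components, all oriented for minimization, that drive the
#' location optimizer: the fair-coverage Gini (computed overall across
#' shifts), and -- separately for the day and night rosters, since daytime
#' resources far exceed night-time ones -- the uncovered population fraction,
#' the uncovered surface fraction, and the worst-case second-ambulance
#' distance.
#'
#' @inheritParams municipality_reach_shares
#' @return A one-row tibble with columns `fair_coverage_gini`,
#'   `pop_uncovered_day`, `pop_uncovered_night`, `surf_uncovered_day`,
#'   `surf_uncovered_night`, `second_amb_max_day`, `second_amb_max_night`.
#' @export
cost_vector <- function(region, fleet, config = kpi_config()) {
  tibble::tibble(
    fair_coverage_gini = fair_coverage(region, fleet, config),
    pop_uncovered_day = 1 - population_coverage(region, fleet, "day", config),
    pop_uncovered_night = 1 - population_coverage(region, fleet, "night", config),
    surf_uncovered_day = 1 - surface_coverage(region, fleet, "day", config),
    surf_uncovered_night = 1 - surface_coverage(region, fleet, "night", config),
    second_amb_max_day = second_ambulance_max(region, fleet, "day", config),
    second_amb_max_night = second_ambulance_max(region, fleet, "night", config)
  )
}

COST_COMPONENTS <- c(
  "fair_coverage_gini",
  "pop_uncovered_day", "pop_uncovered_night",
  "surf_uncovered_day", "surf_uncovered_night",
  "second_amb_max_day", "second_amb_max_night"
)

#' Response-time statistics from an event log
#'
#' The response time of an emergency is the time elapsed between the call
#' and the first vehicle arriving on scene. Statistics are reported per
#' urgency code; emergencies never reached (still queued or in service at
#' horizon end) are counted in `n_unserved`, never silently dropped.
#'
#' @param log A tidy event log: tibble with at least `code`, `t_call`,
#'   `t_scene_arrival` (NA when unserved), as produced by [simulate_ems()].
#' @param config A [kpi_config()].
#' @return A tibble of class `ems_response_stats`: one row per urgency code
#'   with `n`, `n_served`, `n_unserved`, `mean_minutes`, `p90_minutes`,
#'   `frac_within_threshold`, and a list-column `curve` holding the sorted
#'   response times (the cumulative-frequency curve support).
#' @export
response_time_stats <- function(log, config = kpi_config()) {
  log <- tibble::as_tibble(log)
  if (nrow(log) == 0) {
    out <- tibble::tibble(
      code = character(), n = integer(), n_served = integer(),
      n_unserved = integer(), mean_minutes = numeric(), p90_minutes = numeric(),
      frac_within_threshold = numeric(), curve = list()
    )
    class(out) <- c("ems_response_stats", class(out))
    return(out)
  }
  out <- log |>
    dplyr::mutate(
      response = .data$t_scene_arrival - .data$t_call,
      code = factor(.data$code, levels = URGENCY_CODES)
    ) |>
    dplyr::group_by(.data$code, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_served = sum(!is.na(.data$response)),
      n_unserved = sum(is.na(.data$response)),
      mean_minutes = mean(.data$response, na.rm = TRUE),
      p90_minutes = unname(stats::quantile(.data$response, 0.9, na.rm = TRUE, names = FALSE)),
      frac_within_threshold = if (any(!is.na(.data$response))) {
        mean(.data$response[!is.na(.data$response)] <= config$response_threshold)
      } else {
        NA_real_
      },
      curve = list(sort(.data$response[!is.na(.data$response)])),
      .groups = "drop"
    ) |>
    dplyr::mutate(code = as.character(.data$code))
  attr(out, "threshold") <- config$response_threshold
  class(out) <- c("ems_response_stats", class(out))
  out
}
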