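#' Parameters for the synthetic region generator
#'
#' Defaults reproduce the structure of a large heterogeneous north-Italian
#' region: 5 city, 125 rural, 83 mountain and 2 seaside municipalities with
#' class populations 413,647 / 613,074 / 155,930 / 14,644 and surfaces
#' 242 / 3,233 / 4,322 / 135 km2 (total 1,197,295 inhabitants over
#' 7,932 km2). Travel times are derived from great-circle distances scaled
#' by class-dependent road-winding and speed factors, so the mountain area
#' is markedly slower to traverse than the cities.
#'
#' @param n_municipalities Named integer vector (city/rural/mountain/seaside).
#' @param population,surface_km2 Named totals per class.
#' @param zones_per_municipality Census zones per municipality (default 2).
#' @param speed_kmh Named average road speed per class (mountain slowest).
#' @param winding Named road-winding factor (road km per great-circle km).
#' @param hospitals Named counts `c(hub=, spoke=, primary_care=)`.
#' @return A list of class `ems_region_params`.
#' @export
region_params <- function(
    n_municipalities = c(city = 5, rural = 125, mountain = 83, seaside = 2),
    population = c(city = 413647, rural = 613074, mountain = 155930, seaside = 14644),
    surface_km2 = c(city = 242, rural = 3233, mountain = 4322, seaside = 135),
    zones_per_municipality = 2,
    speed_kmh = c(city = 40, rural = 60, mountain = 30, seaside = 50),
    winding = c(city = 1.2, rural = 1.25, mountain = 1.6, seaside = 1.2),
    hospitals = c(hub = 4, spoke = 9, primary_care = 6)) {
  stopifnot(
    all(n_municipalities > 0), all(population >= 0), all(surface_km2 > 0),
    zones_per_municipality >= 1, all(speed_kmh > 0), all(winding >= 1)
  )
  structure(
    list(
      n_municipalities = n_municipalities, population = population,
      surface_km2 = surface_km2, zones_per_municipality = zones_per_municipality,
      speed_kmh = speed_kmh, winding = winding, hospitals = hospitals
    ),
    class = "ems_region_params"
  )
}

# split `total` into n positive parts with moderate dispersion, preserving
# the total exactly (integer = TRUE rounds and fixes the remainder)
split_total <- function(total, n, shape = 4, integer = FALSE) {
  if (n == 1) return(total)
  w <- stats::rgamma(n, shape = shape)
  x <- total * w / sum(w)
  if (integer) {
    xi <- floor(x)
    rem <- round(total - sum(xi))
    if (rem > 0) {
      add <- utils::head(order(x - xi, decreasing = TRUE), rem)
      xi[add] <- xi[add] + 1
    }
    xi
  } else {
    x
  }
}

# latitude bands per class inside a compact bounding box (~75 x 110 km)
CLASS_BANDS <- list(
  mountain = c(46.20, 46.60),
  rural = c(45.80, 46.20),
  city = c(45.88, 46.08),
  seaside = c(45.62, 45.70)
)
LON_RANGE <- c(12.90, 13.90)

#' Generate a synthetic region
#'
#' Places municipalities on a plane (small WGS84 bounding box, so both
#' great-circle and road metrics remain meaningful) in class-specific
#' latitude bands -- mountains north, cities central, seaside south --
#' splits class population and surface totals across municipalities and
#' zones, locates one candidate ambulance station per municipality (its
#' "town hall" = the municipality centre), assigns hub / spoke /
#' primary-care hospitals to the most populous city, rural and mountain
#' municipalities respectively, and builds the travel model: road distance =
#' great-circle distance x class winding factor, travel time = road distance
#' / class road speed (factors averaged between the two endpoint classes).
#' Deterministic for a fixed seed.
#'
#' @param params An [region_params()].
#' @param seed Integer seed.
#' @return An [ems_region()].
#' @export
generate_region <- function(params = region_params(), seed = 1) {
  stopifnot(inherits(params, "ems_region_params"))
  set.seed(seed)

  classes <- rep(names(params$n_municipalities), params$n_municipalities)
  nm <- length(classes)
  mun <- tibble::tibble(
    id = sprintf("M%03d", seq_len(nm)),
    name = sprintf("%s-%03d", classes, seq_len(nm)),
    area_class = classes,
    lat = unname(vapply(classes, function(cl) {
      stats::runif(1, CLASS_BANDS[[cl]][1], CLASS_BANDS[[cl]][2])
    }, numeric(1))),
    lon = stats::runif(nm, LON_RANGE[1], LON_RANGE[2])
  )
  pop_m <- unlist(lapply(names(params$n_municipalities), function(cl) {
    split_total(params$population[[cl]], params$n_municipalities[[cl]], integer = TRUE)
  }))
  surf_m <- unlist(lapply(names(params$n_municipalities), function(cl) {
    s <- split_total(params$surface_km2[[cl]], params$n_municipalities[[cl]])
    pmax(s, 1e-3)
  }))
  mun$population <- pop_m
  mun$surface_km2 <- surf_m

  zpm <- params$zones_per_municipality
  zone_rows <- lapply(seq_len(nm), function(i) {
    radius_deg <- sqrt(mun$surface_km2[i]) / 111 / 2
    tibble::tibble(
      id = sprintf("Z%04d", (i - 1) * zpm + seq_len(zpm)),
      municipality_id = mun$id[i],
      lon = mun$lon[i] + stats::runif(zpm, -radius_deg, radius_deg),
      lat = mun$lat[i] + stats::runif(zpm, -radius_deg, radius_deg),
      population = split_total(mun$population[i], zpm, integer = TRUE),
      surface_km2 = pmax(split_total(mun$surface_km2[i], zpm), 1e-4)
    )
  })
  zones <- dplyr::bind_rows(zone_rows)

  candidates <- tibble::tibble(
    id = sprintf("C%03d", seq_len(nm)),
    lon = mun$lon, lat = mun$lat
  )
  municipalities <- tibble::tibble(
    id = mun$id, name = mun$name, area_class = mun$area_class,
    candidate_location_id = candidates$id
  )

  hosp_host <- function(cl, k) {
    pool <- which(mun$area_class == cl)
    if (length(pool) == 0) pool <- seq_len(nm)
    pool[order(-mun$population[pool])][seq_len(min(k, length(pool)))]
  }
  hh <- hosp_host("city", params$hospitals[["hub"]])
  hs <- hosp_host("rural", params$hospitals[["spoke"]])
  hp <- hosp_host("mountain", params$hospitals[["primary_care"]])
  hosts <- c(hh, hs, hp)
  hospitals <- tibble::tibble(
    id = sprintf("H%02d", seq_along(hosts)),
    lon = mun$lon[hosts] + 0.002,   # nudge off the town hall so ids stay distinct points
    lat = mun$lat[hosts] + 0.002,
    kind = rep(c("hub", "spoke", "primary_care"), c(length(hh), length(hs), length(hp)))
  )

  all_lon <- c(candidates$lon, hospitals$lon, zones$lon)
  all_lat <- c(candidates$lat, hospitals$lat, zones$lat)
  all_ids <- c(candidates$id, hospitals$id, zones$id)
  all_class <- c(
    mun$area_class,
    mun$area_class[hosts],
    zones$municipality_id |> match(mun$id) |> (\(i) mun$area_class[i])()
  )
  gc_km <- geosphere::distm(cbind(all_lon, all_lat), fun = geosphere::distHaversine) / 1000 *
    (6371 / 6378.137)   # rescale to the 6371 km sphere used throughout
  wind <- params$winding[all_class]
  spd <- params$speed_kmh[all_class]
  wind_m <- outer(wind, wind, `+`) / 2
  spd_m <- outer(spd, spd, `+`) / 2
  dist_km <- gc_km * wind_m
  time_min <- dist_km / spd_m * 60
  dimnames(dist_km) <- dimnames(time_min) <- list(all_ids, all_ids)
  diag(dist_km) <- 0; diag(time_min) <- 0

  ems_region(zones, municipalities, hospitals, candidates, time_min, dist_km)
}

#' Parameters for the synthetic emergency stream
#'
#' The temporal profile has mid-morning and early-evening peaks and a night
#' trough; spatially, calls follow zone population scaled by a class-season
#' multiplier (winter boosts the mountain area through ski tourism, summer
#' boosts mountain and seaside). The urgency mix defaults (red 10%, yellow
#' 35%, green 45%, white 10%) and the hospital-need/transport probabilities
#' are plausible placeholders rather than estimates from any real dispatch dataset.
#'
#' @param annual_calls Expected calls per year (default 108,000, roughly
#'   consistent with a region of 1.2 M inhabitants).
#' @param hour_profile Length-24 non-negative weights for the hour of day.
#' @param urgency_mix Named probabilities over red/yellow/green/white.
#' @param seasonal Matrix (4 classes x 4 seasons: winter, spring, summer,
#'   autumn) of per-capita multipliers.
#' @param p_transport Probability an emergency needs hospital transport.
#' @param p_hub_given_transport Probability the transport requires a hub.
#' @return A list of class `ems_demand_params`.
#' @export
demand_params <- function(
    annual_calls = 108000,
    hour_profile = default_hour_profile(),
    urgency_mix = c(red = 0.10, yellow = 0.35, green = 0.45, white = 0.10),
    seasonal = default_seasonal(),
    p_transport = 0.75,
    p_hub_given_transport = 0.30) {
  stopifnot(
    annual_calls > 0, length(hour_profile) == 24, all(hour_profile >= 0),
    abs(sum(urgency_mix) - 1) < 1e-9, all(urgency_mix >= 0),
    p_transport >= 0, p_transport <= 1
  )
  structure(
    list(
      annual_calls = annual_calls, hour_profile = hour_profile,
      urgency_mix = urgency_mix, seasonal = seasonal,
      p_transport = p_transport, p_hub_given_transport = p_hub_given_transport
    ),
    class = "ems_demand_params"
  )
}

#' @rdname demand_params
#' @export
default_hour_profile <- function() {
  h <- 0:23
  0.35 + 0.8 * exp(-((h - 10) / 2.5)^2) + 0.6 * exp(-((h - 18) / 2.5)^2) -
    0.25 * exp(-((h - 3) / 3)^2)
}

#' @rdname demand_params
#' @export
default_seasonal <- function() {
  m <- matrix(1, 4, 4, dimnames = list(AREA_CLASSES, c("winter", "spring", "summer", "autumn")))
  m["mountain", "winter"] <- 1.5
  m["mountain", "summer"] <- 1.3
  m["seaside", "summer"] <- 1.8
  m
}

season_of_day <- function(day) {
  doy <- day %% 365
  # meteorological seasons, day 0 = 1 January
  cut(doy, c(-1, 58, 150, 242, 333, 365),
      labels = c("winter", "spring", "summer", "autumn", "winter2")) |>
    as.character() |>
    (\(s) ifelse(s == "winter2", "winter", s))()
}

#' Generate a synthetic emergency stream
#'
#' Draws a non-homogeneous Poisson process: daily counts are Poisson with
#' mean `annual_calls / 365`, call times within the day follow the hourly
#' intensity profile, and locations are drawn across zones with probability
#' proportional to zone population times the class-season multiplier (so
#' zero-population zones receive no calls). Urgency codes, hospital needs
#' and transport flags are i.i.d. from the configured mixes. The stream is
#' sorted by call time and deterministic for a fixed seed.
#'
#' @param region An [ems_region()].
#' @param demand An [demand_params()].
#' @param horizon_days Length of the stream in days (>= 1).
#' @param seed Integer seed.
#' @param start_day Day offset from 1 January (affects the season).
#' @return A tibble ready for [simulate_ems()].
#' @export
generate_emergencies <- function(region, demand = demand_params(),
                                 horizon_days = 7, seed = 1, start_day = 0) {
  stopifnot(inherits(region, "ems_region"), horizon_days >= 1)
  set.seed(seed)
  zones <- region$zones
  daily <- demand$annual_calls / 365
  hp <- demand$hour_profile / sum(demand$hour_profile)

  days <- seq_len(horizon_days) - 1
  n_day <- stats::rpois(horizon_days, daily)
  total <- sum(n_day)
  if (total == 0) {
    return(tibble::tibble(
      id = integer(), t_call = numeric(), lon = numeric(), lat = numeric(),
      code = character(), hospital_kind = character(), needs_transport = logical()
    ))
  }

  day_of <- rep(days, n_day)
  hour <- sample.int(24, total, replace = TRUE, prob = hp) - 1
  t_call <- day_of * 1440 + hour * 60 + stats::runif(total, 0, 60)

  season <- season_of_day(start_day + day_of)
  # per-season zone weights, precomputed once per season present in the stream
  zsel <- integer(total)
  for (s in unique(season)) {
    w <- zones$population * demand$seasonal[zones$area_class, s]
    idx <- which(season == s)
    zsel[idx] <- sample.int(nrow(zones), length(idx), replace = TRUE, prob = w)
  }

  code <- sample(names(demand$urgency_mix), total, replace = TRUE, prob = demand$urgency_mix)
  transport <- stats::runif(total) < demand$p_transport
  hub_need <- stats::runif(total) < demand$p_hub_given_transport
  hospital_kind <- ifelse(!transport, "none", ifelse(hub_need, "hub", "spoke"))

  out <- tibble::tibble(
    t_call = t_call,
    lon = zones$lon[zsel], lat = zones$lat[zsel],
    code = code, hospital_kind = hospital_kind, needs_transport = transport
  ) |>
    dplyr::arrange(.data$t_call) |>
    dplyr::mutate(id = dplyr::row_number(), .before = 1)
  out
}

#' Fleet preset for a large heterogeneous region
#'
#' The reference fleet roster: 17 day / 5 night / 26 all-day ALS ambulances,
#' 6 / 1 / 3 BLS, and 3 / 1 / 3 medical cars (helicopters are outside the
#' model). All-day vehicles belong to both the day and the night roster.
#' ALS and BLS stations are assigned to candidate locations of the most
#' populous municipalities (round-robin, so large towns are staffed first);
#' medical cars are stationed at hospitals.
#'
#' @param region An [ems_region()].
#' @param counts Named list of `c(day, night, allday)` counts per type.
#' @return An [ems_fleet()].
#' @export
fvg_like_fleet <- function(region,
                           counts = list(ALS = c(17, 5, 26), BLS = c(6, 1, 3), MC = c(3, 1, 3))) {
  mun <- region$municipalities
  pop <- region$zones |>
    dplyr::group_by(.data$municipality_id) |>
    dplyr::summarise(population = sum(.data$population), .groups = "drop")
  ord <- pop$municipality_id[order(-pop$population)]
  stations_by_pop <- mun$candidate_location_id[match(ord, mun$id)]

  rows <- list()
  for (type in names(counts)) {
    k <- counts[[type]]
    rows[[type]] <- tibble::tibble(
      type = type,
      shift = rep(c("day", "night", "allday"), k)
    )
  }
  fleet <- dplyr::bind_rows(rows)
  amb <- fleet$type != "MC"
  fleet$station <- NA_character_
  fleet$station[amb] <- rep_len(stations_by_pop, sum(amb))
  if (any(!amb)) {
    hosp_ids <- region$hospitals$id
    fleet$station[!amb] <- rep_len(hosp_ids, sum(!amb))
  }
  fleet$id <- sprintf("%s%02d", fleet$type, stats::ave(seq_len(nrow(fleet)), fleet$type, FUN = seq_along))
  ems_fleet(fleet[, c("id", "type", "shift", "station")], region)
}
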