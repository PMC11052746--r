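# Shared fixture builders and independent oracles. All fixtures are built in
# code; nothing is read from disk.

# A minimal hand-specified region: one zone per municipality, candidate
# stations C1..Ck, one hub hospital co-located with the first candidate.
# `cand_zone_time` is the (stations x zones) road-time matrix in minutes;
# everything else in the travel model is left at the values below.
toy_region <- function(cand_zone_time,
                       pops = rep(100, ncol(cand_zone_time)),
                       surfs = rep(10, ncol(cand_zone_time)),
                       cand_zone_dist = cand_zone_time,
                       hosp_cand_time = rep(0, nrow(cand_zone_time)),
                       zone_hosp_time = rep(0, ncol(cand_zone_time)),
                       classes = "rural") {
  k <- nrow(cand_zone_time); nz <- ncol(cand_zone_time)
  cand_ids <- sprintf("C%d", seq_len(k))
  zone_ids <- sprintf("Z%d", seq_len(nz))
  ids <- c(cand_ids, "H1", zone_ids)
  nn <- length(ids)
  # compact geometry: everything within a couple of km so the 20 km
  # Haversine pre-filter never excludes a vehicle unless a test wants it to
  lon <- 13 + seq_len(nn) * 0.001
  lat <- rep(46, nn)
  tt <- matrix(0, nn, nn, dimnames = list(ids, ids))
  tt[cand_ids, zone_ids] <- cand_zone_time
  tt[zone_ids, cand_ids] <- t(cand_zone_time)
  tt["H1", cand_ids] <- hosp_cand_time
  tt[cand_ids, "H1"] <- hosp_cand_time
  tt[zone_ids, "H1"] <- zone_hosp_time
  tt["H1", zone_ids] <- zone_hosp_time
  td <- matrix(0, nn, nn, dimnames = list(ids, ids))
  td[cand_ids, zone_ids] <- cand_zone_dist
  td[zone_ids, cand_ids] <- t(cand_zone_dist)

  zones <- tibble::tibble(
    id = zone_ids, municipality_id = sprintf("M%d", seq_len(nz)),
    lon = lon[match(zone_ids, ids)], lat = lat[match(zone_ids, ids)],
    population = pops, surface_km2 = surfs
  )
  municipalities <- tibble::tibble(
    id = sprintf("M%d", seq_len(nz)), name = sprintf("mun-%d", seq_len(nz)),
    area_class = rep_len(classes, nz),
    candidate_location_id = rep_len(cand_ids, nz)
  )
  hospitals <- tibble::tibble(
    id = "H1", lon = lon[match("H1", ids)], lat = lat[match("H1", ids)], kind = "hub"
  )
  candidates <- tibble::tibble(
    id = cand_ids, lon = lon[match(cand_ids, ids)], lat = lat[match(cand_ids, ids)]
  )
  ems_region(zones, municipalities, hospitals, candidates, tt, td)
}

toy_fleet <- function(region, types = "ALS", shifts = "allday", stations = NULL) {
  n <- max(length(types), length(shifts), if (is.null(stations)) 1 else length(stations))
  types <- rep_len(types, n); shifts <- rep_len(shifts, n)
  if (is.null(stations)) stations <- rep_len(region$candidates$id, n)
  ems_fleet(tibble::tibble(
    id = sprintf("V%02d", seq_len(n)), type = types, shift = shifts, station = stations
  ), region)
}

toy_emergencies <- function(region, t_call, code = "green",
                            zone = 1, needs_transport = FALSE,
                            hospital_kind = ifelse(needs_transport, "spoke", "none")) {
  n <- length(t_call)
  zi <- rep_len(zone, n)
  tibble::tibble(
    id = seq_len(n), t_call = t_call,
    lon = region$zones$lon[zi], lat = region$zones$lat[zi],
    code = rep_len(code, n),
    hospital_kind = rep_len(hospital_kind, n),
    needs_transport = rep_len(needs_transport, n)
  )
}

# single point, zero travel everywhere: the M/M/c test bench
mmc_region <- function() {
  toy_region(matrix(0, 1, 1), pops = 100, surfs = 1)
}

# --- independent oracles --------------------------------------------------

# O(n^2) pairwise mean-absolute-difference Gini
gini_oracle <- function(x) {
  if (sum(x) == 0) return(0)
  sum(abs(outer(x, x, "-"))) / (2 * length(x) * sum(x))
}

# naive double-loop Pareto front
brute_front_idx <- function(m) {
  n <- nrow(m)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(m[j, ] <= m[i, ]) && any(m[j, ] < m[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

# Erlang-C expected wait in queue for an M/M/c system
erlang_c_wq <- function(lambda, mu, c) {
  a <- lambda / mu
  rho <- a / c
  stopifnot(rho < 1)
  p0 <- 1 / (sum(a^(0:(c - 1)) / factorial(0:(c - 1))) +
               a^c / (factorial(c) * (1 - rho)))
  pc <- a^c / (factorial(c) * (1 - rho)) * p0
  pc / (c * mu - lambda)
}

# canonical string form of a cost matrix for front comparisons
front_key <- function(m) sort(apply(round(as.matrix(m), 9), 1, paste, collapse = ","))

# 2 all-day ALS over 8 candidate stations on a small generated region:
# the enumerable location problem (36 ordered configurations)
toy8_problem <- function() {
  p <- region_params(
    n_municipalities = c(city = 1, rural = 4, mountain = 2, seaside = 1),
    population = c(city = 20000, rural = 12000, mountain = 3000, seaside = 1500),
    surface_km2 = c(city = 20, rural = 200, mountain = 300, seaside = 15),
    hospitals = c(hub = 1, spoke = 1, primary_care = 1)
  )
  region <- generate_region(p, seed = 2)
  fleet <- ems_fleet(tibble::tibble(
    id = c("A1", "A2"), type = "ALS", shift = "allday",
    station = region$candidates$id[1:2]
  ), region)
  ems_location_problem(region, fleet)
}

toy8_true_front <- function(problem) {
  configs <- rbind(t(utils::combn(8, 2)), cbind(1:8, 1:8))
  costs <- t(apply(configs, 1, function(sr) problem$eval(list(ALS.allday = sort(sr)))))
  colnames(costs) <- problem$objectives
  costs[brute_front_idx(costs), , drop = FALSE]
}

# small heterogeneous region + lean fleet used for policy experiments
policy_bench <- function(seed = 11) {
  p <- region_params(
    n_municipalities = c(city = 1, rural = 5, mountain = 3, seaside = 1),
    population = c(city = 30000, rural = 24000, mountain = 6000, seaside = 2000),
    surface_km2 = c(city = 25, rural = 260, mountain = 400, seaside = 12),
    hospitals = c(hub = 1, spoke = 1, primary_care = 1)
  )
  region <- generate_region(p, seed = seed)
  fleet <- ems_fleet(tibble::tibble(
    id = c("ALS1", "ALS2", "ALS3", "BLS1", "MC1"),
    type = c("ALS", "ALS", "ALS", "BLS", "MC"),
    shift = c("allday", "allday", "day", "allday", "allday"),
    station = c(region$candidates$id[c(1, 2, 6)], region$candidates$id[3],
                region$hospitals$id[1])
  ), region)
  list(region = region, fleet = fleet, demand = demand_params(annual_calls = 9000))
}
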