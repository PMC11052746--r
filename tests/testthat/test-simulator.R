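no_delay <- function() duration_model(0, 0, 0, 0)

test_that("an empty stream yields an empty, closed log", {
  r <- toy_region(matrix(5, 1, 1))
  fl <- toy_fleet(r)
  sim <- simulate_ems(r, fl, toy_emergencies(r, numeric(0)), no_delay(), seed = 1)
  expect_equal(nrow(tidy(sim)), 0)
  expect_equal(sim$n_closed, 0)
})

test_that("with zero travel the response time is exactly the triage sample", {
  r <- mmc_region()
  fl <- toy_fleet(r)
  dm <- duration_model(triage_mean = 1.5, scene_mean = 0,
                       dropoff_mean = 0, cleaning_mean = 0)
  sim <- simulate_ems(r, fl, toy_emergencies(r, 0), dm, seed = 99)
  set.seed(99)
  expected_triage <- rexp(1, 1 / 1.5)  # first draw of the duration stream
  expect_equal(tidy(sim)$response_time, expected_triage)
  expect_equal(tidy(sim)$t_dispatch, expected_triage)
})

test_that("identical seeds give identical logs; streams must be time-sorted", {
  b <- policy_bench()
  em <- generate_emergencies(b$region, b$demand, horizon_days = 2, seed = 5)
  s1 <- simulate_ems(b$region, b$fleet, em, seed = 3)
  s2 <- simulate_ems(b$region, b$fleet, em, seed = 3)
  expect_identical(tidy(s1), tidy(s2))
  s3 <- simulate_ems(b$region, b$fleet, em, seed = 4)
  expect_false(identical(tidy(s1)$response_time, tidy(s3)$response_time))
  expect_error(simulate_ems(b$region, b$fleet, em[rev(seq_len(nrow(em))), ], seed = 1),
               "sorted")
})

test_that("every emergency is closed or explicitly queued, never lost", {
  b <- policy_bench()
  em <- generate_emergencies(b$region, b$demand, horizon_days = 3, seed = 9)
  for (pol in c("no_preemption", "preemption")) {
    sim <- simulate_ems(b$region, b$fleet, em, seed = 2,
                        dispatch = dispatch_config(pol), horizon = 2 * 1440)
    log <- tidy(sim)
    expect_equal(nrow(log), nrow(em))
    expect_true(all(log$status %in% c("closed", "queued", "in_service")))
    expect_equal(sum(log$status == "closed"), sim$n_closed)
    expect_equal(sim$n_closed + sim$n_open, nrow(em))
  }
})

test_that("per-emergency timestamps are monotone in process order", {
  b <- policy_bench()
  em <- generate_emergencies(b$region, b$demand, horizon_days = 3, seed = 13)
  sim <- simulate_ems(b$region, b$fleet, em, seed = 6,
                      dispatch = dispatch_config("preemption"))
  log <- dplyr::filter(tidy(sim), .data$status == "closed")
  expect_gt(nrow(log), 0)
  eps <- 1e-9
  expect_true(all(log$t_dispatch >= log$t_call - eps))
  expect_true(all(log$t_scene_arrival >= log$t_dispatch - eps))
  expect_true(all(log$t_scene_departure >= log$t_scene_arrival - eps))
  tr <- dplyr::filter(log, .data$needs_transport)
  expect_true(all(tr$t_hospital_arrival >= tr$t_scene_departure - eps))
  expect_true(all(tr$t_closed >= tr$t_hospital_arrival - eps))
  expect_true(all(log$response_time >= -eps))
})

test_that("a vehicle never serves two emergencies at once", {
  b <- policy_bench()
  em <- generate_emergencies(b$region, b$demand, horizon_days = 3, seed = 17)
  sim <- simulate_ems(b$region, b$fleet, em, seed = 8,
                      dispatch = dispatch_config("preemption"))
  log <- dplyr::filter(tidy(sim), .data$status == "closed")
  overlaps <- log |>
    dplyr::group_by(.data$vehicle) |>
    dplyr::arrange(.data$t_dispatch, .by_group = TRUE) |>
    dplyr::summarise(
      bad = any(utils::head(.data$t_closed, -1) > utils::tail(.data$t_dispatch, -1) + 1e-9),
      .groups = "drop"
    )
  expect_false(any(overlaps$bad))
})

test_that("dispatch picks the nearest compatible vehicle, ties by vehicle id", {
  r <- toy_region(matrix(c(7, 9), 2, 1))   # C1 at 7 min, C2 at 9 min from Z1
  fl <- toy_fleet(r, types = c("ALS", "ALS"), stations = c("C2", "C1"))
  sim <- simulate_ems(r, fl, toy_emergencies(r, 0, code = "yellow"), no_delay(), seed = 1)
  expect_equal(tidy(sim)$vehicle, "V02")   # V02 sits at C1, 7 min away
  expect_equal(tidy(sim)$response_time, 7)
  # co-located tie broken by lower vehicle id
  fl2 <- toy_fleet(r, types = c("ALS", "ALS"), stations = c("C1", "C1"))
  sim2 <- simulate_ems(r, fl2, toy_emergencies(r, 0, code = "yellow"), no_delay(), seed = 1)
  expect_equal(tidy(sim2)$vehicle, "V01")
})

test_that("urgency-dependent vehicle type preference and fallbacks apply", {
  r <- toy_region(matrix(c(5, 6), 2, 1))
  flab <- toy_fleet(r, types = c("BLS", "ALS"), stations = c("C1", "C2"))
  # red prefers ALS even though the BLS is closer
  sim_red <- simulate_ems(r, flab, toy_emergencies(r, 0, code = "red"),
                          no_delay(), seed = 1)
  expect_equal(tidy(sim_red)$vehicle_type, "ALS")
  # green prefers BLS
  sim_grn <- simulate_ems(r, flab, toy_emergencies(r, 0, code = "green"),
                          no_delay(), seed = 1)
  expect_equal(tidy(sim_grn)$vehicle_type, "BLS")
  # green falls back to ALS when no BLS exists
  flaa <- toy_fleet(r, types = "ALS", stations = "C1")
  sim_g2 <- simulate_ems(r, flaa, toy_emergencies(r, 0, code = "green"),
                         no_delay(), seed = 1)
  expect_equal(tidy(sim_g2)$vehicle_type, "ALS")
})

test_that("red codes pair with the nearest available medical car", {
  r <- toy_region(matrix(c(5, 6), 2, 1))
  fl <- ems_fleet(tibble::tibble(
    id = c("A1", "M1"), type = c("ALS", "MC"), shift = "allday",
    station = c("C1", "C2")
  ), r)
  sim <- simulate_ems(r, fl, toy_emergencies(r, 0, code = "red"), no_delay(), seed = 1)
  expect_equal(tidy(sim)$medical_car, "M1")
  sim_y <- simulate_ems(r, fl, toy_emergencies(r, 0, code = "yellow"), no_delay(), seed = 1)
  expect_true(is.na(tidy(sim_y)$medical_car))
})

test_that("busy fleets queue non-urgent calls and pop by urgency then waiting time", {
  # one ALS; first call occupies it (transport 30 min + return); three calls
  # arrive while it is busy: white (waiting longest), then two reds
  r <- toy_region(matrix(5, 1, 1), zone_hosp_time = 30, hosp_cand_time = 10)
  fl <- toy_fleet(r, types = "ALS")
  em <- tibble::tibble(
    id = 1:4, t_call = c(0, 1, 2, 3),
    lon = r$zones$lon[1], lat = r$zones$lat[1],
    code = c("green", "white", "red", "red"),
    hospital_kind = c("spoke", "none", "none", "none"),
    needs_transport = c(TRUE, FALSE, FALSE, FALSE)
  )
  sim <- simulate_ems(r, fl, em, no_delay(), dispatch_config("no_preemption"), seed = 1)
  log <- tidy(sim)
  # vehicle timeline: to scene 0-5, to hospital 5-35, return 35-45
  expect_equal(log$t_dispatch[1], 0)
  ord <- order(log$t_dispatch[2:4]) + 1
  expect_equal(log$code[ord], c("red", "red", "white"))
  # among equal codes, the longer-waiting red (earlier call) goes first
  expect_lt(log$t_dispatch[3], log$t_dispatch[4])
  # nothing moves before the vehicle is back at the station
  expect_true(all(log$t_dispatch[2:4] >= 45 - 1e-9))
})

test_that("returning vehicles are available only under preemption", {
  # call 1 transports to hospital; return leg is long; call 2 (red) arrives
  # while the vehicle is returning
  r <- toy_region(matrix(5, 1, 1), zone_hosp_time = 10, hosp_cand_time = 60)
  fl <- toy_fleet(r, types = "ALS")
  em <- tibble::tibble(
    id = 1:2, t_call = c(0, 20),
    lon = r$zones$lon[1], lat = r$zones$lat[1],
    code = c("green", "red"),
    hospital_kind = c("spoke", "none"),
    needs_transport = c(TRUE, FALSE)
  )
  # service 1: scene 0-5(arrive)-5(depart), hospital at 15, return 15-75
  sim_np <- simulate_ems(r, fl, em, no_delay(), dispatch_config("no_preemption"), seed = 1)
  sim_pr <- simulate_ems(r, fl, em, no_delay(), dispatch_config("preemption"), seed = 1)
  expect_gte(tidy(sim_np)$t_dispatch[2], 75)     # waits for station arrival
  expect_equal(tidy(sim_pr)$t_dispatch[2], 20)   # grabbed while returning
  expect_lt(tidy(sim_pr)$response_time[2], tidy(sim_np)$response_time[2])
})

test_that("urgent calls preempt en-route non-urgent services within proximity", {
  # vehicle heads to a green call far away (long leg); a red call arrives at
  # the same location while the vehicle is en route
  r <- toy_region(matrix(c(40, 5), 1, 2))
  fl <- toy_fleet(r, types = "ALS")
  em <- tibble::tibble(
    id = 1:2, t_call = c(0, 10),
    lon = r$zones$lon[c(1, 2)], lat = r$zones$lat[c(1, 2)],
    code = c("green", "red"),
    hospital_kind = "none", needs_transport = FALSE
  )
  sim <- simulate_ems(r, fl, em, no_delay(), dispatch_config("preemption"), seed = 1)
  log <- tidy(sim)
  expect_equal(log$preemptions[1], 1L)           # green interrupted once
  expect_equal(log$preemptions[2], 0L)
  expect_lt(log$t_scene_arrival[2], 40)          # red served before green leg ends
  expect_gt(log$t_scene_arrival[1], log$t_scene_arrival[2])  # green requeued
  expect_equal(log$status, c("closed", "closed"))
  # a red service is never interrupted
  em2 <- em; em2$code <- c("red", "red")
  sim2 <- simulate_ems(r, fl, em2, no_delay(), dispatch_config("preemption"), seed = 1)
  expect_equal(tidy(sim2)$preemptions, c(0L, 0L))
  # under no_preemption the operation is unreachable
  sim3 <- simulate_ems(r, fl, em, no_delay(), dispatch_config("no_preemption"), seed = 1)
  expect_equal(tidy(sim3)$preemptions, c(0L, 0L))
})

test_that("hospital choice honours the hub/spoke hierarchy", {
  r <- toy_region(matrix(5, 1, 1))
  expect_equal(choose_hospital(r, "Z1", "hub"), "H1")
  expect_equal(choose_hospital(r, "Z1", "spoke"), "H1")  # hub satisfies spoke need
  expect_equal(choose_hospital(r, "Z1", "none"), NA_character_)
  # a nearer hub beats a farther spoke for a spoke-level need
  r2 <- generate_region(region_params(
    n_municipalities = c(city = 1, rural = 2, mountain = 1, seaside = 1),
    population = c(city = 5000, rural = 2000, mountain = 500, seaside = 300),
    surface_km2 = c(city = 10, rural = 80, mountain = 100, seaside = 8),
    hospitals = c(hub = 1, spoke = 1, primary_care = 1)
  ), seed = 4)
  tt <- r2$travel_time
  z <- r2$zones$id[1]
  hubs <- r2$hospitals$id[r2$hospitals$kind == "hub"]
  eligible <- r2$hospitals$id[r2$hospitals$kind %in% c("hub", "spoke")]
  expect_equal(choose_hospital(r2, z, "spoke"), eligible[which.min(tt[z, eligible])])
  expect_equal(choose_hospital(r2, z, "hub"), hubs[which.min(tt[z, hubs])])
  # primary-care-only network cannot satisfy transport needs
  r3 <- toy_region(matrix(5, 1, 1))
  r3$hospitals$kind <- "primary_care"
  expect_error(choose_hospital(r3, "Z1", "spoke"), "no hospital")
})

test_that("off-shift vehicles are never dispatched and finish ongoing services", {
  r <- toy_region(matrix(5, 1, 1), zone_hosp_time = 10, hosp_cand_time = 5)
  fl <- toy_fleet(r, types = "ALS", shifts = "day")
  # night call waits for the 08:00 shift opening
  em_night <- toy_emergencies(r, 60, code = "green")
  sim_n <- simulate_ems(r, fl, em_night, no_delay(), seed = 1)
  expect_gte(tidy(sim_n)$t_dispatch[1], 480)
  # a service started minutes before shift end runs to completion
  em_edge <- tibble::tibble(
    id = 1, t_call = 1195, lon = r$zones$lon[1], lat = r$zones$lat[1],
    code = "yellow", hospital_kind = "spoke", needs_transport = TRUE
  )
  sim_e <- simulate_ems(r, fl, em_edge, no_delay(), seed = 1)
  log <- tidy(sim_e)
  expect_equal(log$status, "closed")
  expect_gt(log$t_closed, 1200)   # completed after shift end
})
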