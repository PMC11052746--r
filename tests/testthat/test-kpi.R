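test_that("gini matches hand values and elementary properties", {
  expect_equal(gini(c(3, 3, 3)), 0)
  expect_equal(gini(c(0, 1)), 0.5)
  expect_equal(gini(c(5)), 0)
  expect_equal(gini(rep(0, 4)), 0)          # all-zero convention
  expect_equal(gini(c(1, 2, 7)), gini(10 * c(1, 2, 7)))  # scale invariance
  expect_error(gini(c(1, -1)), "non-negative")
  expect_error(gini(numeric(0)), "at least one")
})

test_that("gini equals the pairwise oracle and respects its upper bound", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(1:200, 1)
    x <- rexp(n) * sample(c(1, 100), 1)
    expect_equal(gini(x), gini_oracle(x), tolerance = 1e-12)
    expect_lt(gini(x), 1 - 1 / n + 1e-12)
  }
})

test_that("reach shares follow the weighted reachable-fleet formula", {
  cfg <- kpi_config()
  # every ambulance reaches every zone
  r <- toy_region(matrix(5, 2, 3))
  fl <- toy_fleet(r, types = c("ALS", "ALS"), stations = c("C1", "C2"))
  sh <- municipality_reach_shares(r, fl, "day", cfg)
  expect_true(all(sh$share == 1))
  expect_equal(fair_coverage(r, fl, cfg), 0)
  # 2 ALS, only one of them reaches zone 3 (its municipality M3)
  r2 <- toy_region(matrix(c(5, 5, 5, 5, 10, 30), 2, 3, byrow = TRUE))
  fl2 <- toy_fleet(r2, types = c("ALS", "ALS"), stations = c("C1", "C2"))
  sh2 <- municipality_reach_shares(r2, fl2, "day", cfg)
  expect_equal(sh2$share[sh2$municipality_id == "M3"], 0.5)
  # unreachable municipality gets share 0
  r3 <- toy_region(matrix(c(5, 40), 1, 2))
  fl3 <- toy_fleet(r3, types = "ALS", stations = "C1")
  sh3 <- municipality_reach_shares(r3, fl3, "day", cfg)
  expect_equal(sh3$share[sh3$municipality_id == "M2"], 0)
  # BLS contribution is weighted
  flb <- toy_fleet(r, types = c("ALS", "BLS"), stations = c("C1", "C2"))
  shb <- municipality_reach_shares(r, flb, "day", cfg)
  expect_true(all(abs(shb$share - 1) < 1e-12))  # both reach all: share still 1
  r4 <- toy_region(matrix(c(5, 5, 40, 5), 2, 2, byrow = TRUE))
  fl4 <- toy_fleet(r4, types = c("ALS", "BLS"), stations = c("C1", "C2"))
  sh4 <- municipality_reach_shares(r4, fl4, "day", cfg)
  expect_equal(sh4$share[sh4$municipality_id == "M1"], 1 / 1.7)  # ALS only
  expect_equal(sh4$share[sh4$municipality_id == "M2"], 1)        # both reach
  expect_error(municipality_reach_shares(r, toy_fleet(r, types = "MC"), "day", cfg),
               "no transport")
})

test_that("population coverage credits ALS fully and BLS at its weight", {
  cfg <- kpi_config()
  # two zones, pop 100 and 300, only the second zone covered and only by BLS
  r <- toy_region(matrix(c(40, 5), 1, 2), pops = c(100, 300))
  fl <- toy_fleet(r, types = "BLS", stations = "C1")
  expect_equal(population_coverage(r, fl, "day", cfg), 0.7 * 300 / 400)
  # with an ALS instead, full credit
  fla <- toy_fleet(r, types = "ALS", stations = "C1")
  expect_equal(population_coverage(r, fla, "day", cfg), 300 / 400)
  # bls_weight = 1 removes the ALS/BLS distinction
  cfg1 <- kpi_config(bls_weight = 1)
  expect_equal(population_coverage(r, fl, "day", cfg1),
               population_coverage(r, fla, "day", cfg1))
  # surface mirrors population with surfaces as weights
  rs <- toy_region(matrix(c(40, 5), 1, 2), pops = c(100, 300), surfs = c(30, 10))
  expect_equal(surface_coverage(rs, fl, "day", cfg), 0.7 * 10 / 40)
})

test_that("coverage is monotone under fleet enlargement", {
  cfg <- kpi_config()
  set.seed(5)
  r <- toy_region(matrix(runif(12, 0, 40), 3, 4), pops = c(50, 10, 200, 80))
  small <- toy_fleet(r, types = "BLS", stations = "C2")
  big <- toy_fleet(r, types = c("BLS", "ALS", "ALS"), stations = c("C2", "C1", "C3"))
  expect_gte(population_coverage(r, big, "day", cfg),
             population_coverage(r, small, "day", cfg))
  expect_gte(surface_coverage(r, big, "day", cfg),
             surface_coverage(r, small, "day", cfg))
  expect_true(population_coverage(r, big, "day", cfg) <= 1)
})

test_that("second-ambulance distance equals the exhaustive computation", {
  cfg <- kpi_config()
  d <- matrix(c(3, 8, 12, 6, 2, 9), 2, 3, byrow = TRUE)  # stations x zones
  r <- toy_region(cand_zone_time = d, cand_zone_dist = d)
  fl <- toy_fleet(r, types = c("ALS", "ALS"), stations = c("C1", "C2"))
  # brute force: for each zone the 2nd smallest distance over ambulances
  exp2 <- max(apply(d, 2, function(col) sort(col)[2]))
  expect_equal(second_ambulance_max(r, fl, "day", cfg), exp2)
  # co-located pair: 1st and 2nd coincide
  flc <- toy_fleet(r, types = c("ALS", "ALS"), stations = c("C1", "C1"))
  expect_equal(second_ambulance_max(r, flc, "day", cfg), max(d[1, ]))
  # adding an ambulance never increases the indicator
  fl3 <- toy_fleet(r, types = c("ALS", "ALS", "BLS"), stations = c("C1", "C2", "C2"))
  expect_lte(second_ambulance_max(r, fl3, "day", cfg),
             second_ambulance_max(r, fl, "day", cfg))
  expect_error(second_ambulance_max(r, toy_fleet(r, types = "ALS"), "day", cfg), ">= 2")
})

test_that("the cost vector composes the individual indicators", {
  cfg <- kpi_config()
  set.seed(9)
  r <- toy_region(matrix(runif(8, 0, 30), 2, 4), pops = c(10, 40, 5, 100))
  fl <- toy_fleet(r, types = c("ALS", "BLS", "ALS"),
                  shifts = c("allday", "day", "night"), stations = c("C1", "C2", "C2"))
  cv <- cost_vector(r, fl, cfg)
  expect_named(cv, c("fair_coverage_gini", "pop_uncovered_day", "pop_uncovered_night",
                     "surf_uncovered_day", "surf_uncovered_night",
                     "second_amb_max_day", "second_amb_max_night"))
  expect_equal(cv$fair_coverage_gini, fair_coverage(r, fl, cfg))
  expect_equal(cv$pop_uncovered_day, 1 - population_coverage(r, fl, "day", cfg))
  expect_equal(cv$pop_uncovered_night, 1 - population_coverage(r, fl, "night", cfg))
  expect_equal(cv$surf_uncovered_day, 1 - surface_coverage(r, fl, "day", cfg))
  expect_equal(cv$second_amb_max_night, second_ambulance_max(r, fl, "night", cfg))
})

test_that("full even coverage attains the lower bound except the 2nd-ambulance terms", {
  cfg <- kpi_config()
  r <- toy_region(matrix(5, 2, 3))
  fl <- toy_fleet(r, types = c("ALS", "ALS"), shifts = "allday", stations = c("C1", "C2"))
  cv <- cost_vector(r, fl, cfg)
  expect_equal(as.numeric(cv[1, 1:5]), rep(0, 5))
  expect_equal(cv$second_amb_max_day, 5)   # distance to the other station
  expect_equal(cv$second_amb_max_day, cv$second_amb_max_night)
})

test_that("response-time statistics tally served and unserved emergencies", {
  cfg <- kpi_config()
  # single emergency: call at 0, on scene at 12
  one <- tibble::tibble(code = "red", t_call = 0, t_scene_arrival = 12)
  s1 <- response_time_stats(one, cfg)
  expect_equal(s1$mean_minutes[s1$code == "red"], 12)
  expect_equal(s1$frac_within_threshold[s1$code == "red"], 1)
  # all arrivals beyond the threshold
  late <- tibble::tibble(code = c("green", "green"), t_call = c(0, 5),
                         t_scene_arrival = c(30, 40))
  s2 <- response_time_stats(late, cfg)
  expect_equal(s2$frac_within_threshold[s2$code == "green"], 0)
  # mixed hand-computed log of 5 records, one unserved
  log5 <- tibble::tibble(
    code = c("red", "red", "yellow", "green", "green"),
    t_call = c(0, 10, 0, 0, 100),
    t_scene_arrival = c(8, 40, 18, NA, 110)
  )
  s3 <- response_time_stats(log5, cfg)
  red <- s3[s3$code == "red", ]
  expect_equal(red$n, 2L)
  expect_equal(red$mean_minutes, mean(c(8, 30)))
  expect_equal(red$frac_within_threshold, 0.5)
  grn <- s3[s3$code == "green", ]
  expect_equal(grn$n_unserved, 1L)
  expect_equal(grn$n_served, 1L)
  expect_equal(grn$curve[[1]], 10)
  # curves are sorted (non-decreasing cumulative support)
  expect_true(all(vapply(s3$curve, function(cv) !is.unsorted(cv), logical(1))))
  # empty log yields an empty stats object
  expect_equal(nrow(response_time_stats(tibble::tibble(), cfg)), 0)
})
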