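URGENCY_CODES <- c("red", "yellow", "green", "white")
URGENCY_PRIORITY <- c(red = 4, yellow = 3, green = 2, white = 1)

#' Duration model for service phases
#'
#' Phase durations are drawn from exponential distributions: triage (call
#' qualification by the operator, before dispatch), on-scene treatment
#' (the stay-and-play stabilization), patient drop-off at the hospital, and
#' ambulance cleaning (which ends the service). Means are in minutes; a mean
#' of 0 makes the phase instantaneous (useful for stylized queueing
#' scenarios). The defaults are plausible order-of-magnitude values, not
#' estimates from any specific EMS dataset.
#'
#' @param triage_mean,scene_mean,dropoff_mean,cleaning_mean Mean durations
#'   in minutes (>= 0).
#' @return A list of class `ems_duration_model`.
#' @export
duration_model <- function(triage_mean = 1.5, scene_mean = 18,
                           dropoff_mean = 10, cleaning_mean = 5) {
  means <- c(triage = triage_mean, scene = scene_mean,
             dropoff = dropoff_mean, cleaning = cleaning_mean)
  if (any(means < 0)) stop("duration means must be >= 0", call. = FALSE)
  structure(list(means = means), class = "ems_duration_model")
}

#' Dispatching configuration
#'
#' @param policy `"no_preemption"` (a vehicle is available only while idle
#'   at a station) or `"preemption"` (additionally, a vehicle serving a
#'   green/white emergency that has not yet reached the scene can be
#'   diverted to a nearby red/yellow call, and a vehicle returning to its
#'   station after a service is available).
#' @param prefilter_km Haversine radius for the initial candidate-vehicle
#'   filter (default 20 km); red/yellow calls with no vehicle in range
#'   escalate to a region-wide search.
#' @param preemption_km "Close proximity" radius within which an ongoing
#'   non-urgent service may be interrupted; defaults to `prefilter_km`.
#' @param offroad_speed_kmh Speed used to convert Haversine distances into
#'   travel times for vehicles redirected from a mid-leg position.
#' @param pair_medical_car Attempt to couple the nearest available medical
#'   car with the ambulance on red-code calls (default TRUE).
#' @return A list of class `ems_dispatch_config`.
#' @export
dispatch_config <- function(policy = c("no_preemption", "preemption"),
                            prefilter_km = 20, preemption_km = prefilter_km,
                            offroad_speed_kmh = 50, pair_medical_car = TRUE) {
  stopifnot(prefilter_km > 0, preemption_km > 0, offroad_speed_kmh > 0)
  structure(
    list(
      policy = match.arg(policy), prefilter_km = prefilter_km,
      preemption_km = preemption_km, offroad_speed_kmh = offroad_speed_kmh,
      pair_medical_car = pair_medical_car
    ),
    class = "ems_dispatch_config"
  )
}

#' Nearest suitable hospital for an emergency
#'
#' Selects the hospital closest by road time whose kind satisfies the
#' clinical need: a hub requirement is satisfied only by hubs; a spoke
#' requirement by spokes or hubs (a hub provides everything a spoke does).
#'
#' @param region An [ems_region()].
#' @param from Location id the transport starts from (usually the emergency
#'   zone centroid).
#' @param kind_needed `"hub"`, `"spoke"`, or `"none"` (no transport).
#' @return A hospital id, or `NA_character_` when no transport is needed.
#' @export
choose_hospital <- function(region, from, kind_needed) {
  if (kind_needed == "none") return(NA_character_)
  ok <- switch(kind_needed,
    hub = region$hospitals$kind == "hub",
    spoke = region$hospitals$kind %in% c("hub", "spoke"),
    stop("unknown hospital kind needed: ", kind_needed, call. = FALSE)
  )
  if (!any(ok)) stop("no hospital of required kind in region", call. = FALSE)
  h <- region$hospitals[ok, ]
  tt <- region$travel_time[from, h$id]
  h$id[which.min(tt)]  # which.min breaks ties at the first (lowest id order)
}

# vehicle state codes
ST_IDLE <- 0L; ST_TO_SCENE <- 1L; ST_AT_SCENE <- 2L; ST_TO_HOSP <- 3L
ST_AT_HOSP <- 4L; ST_RETURN <- 5L
# vehicle event codes
EV_ARRIVE_SCENE <- 1L; EV_SCENE_END <- 2L; EV_ARRIVE_HOSP <- 3L
EV_SERVICE_END <- 4L; EV_ARRIVE_STATION <- 5L

#' Simulate EMS operations over an emergency stream
#'
#' Discrete-event digital twin of the dispatch process: each call undergoes
#' triage, is assigned a vehicle by a hierarchical rule (vehicle type by
#' urgency, then a 20 km Haversine pre-filter, then the nearest vehicle by
#' road time; red/yellow calls escalate region-wide when the pre-filter is
#' empty; red calls additionally attempt to pair the nearest available
#' medical car), is treated on scene, transported to the nearest suitable
#' hospital when needed, and closed after drop-off and cleaning, upon which
#' the vehicle returns to its station. Calls with no available vehicle wait
#' in a queue ordered by urgency, waiting time and proximity. Two
#' dispatching policies are supported (see [dispatch_config()]).
#'
#' The run is deterministic for a fixed seed: all phase durations are
#' pre-sampled per emergency from a single stream, so the same stream and
#' seed yield comparable runs across policies.
#'
#' @param region An [ems_region()].
#' @param fleet An [ems_fleet()] (stations must be travel-model locations).
#' @param emergencies Tibble with columns `id`, `t_call` (minutes from
#'   horizon start; day 1 starts at midnight), `lon`, `lat`, `code`
#'   (red/yellow/green/white), `hospital_kind` (hub/spoke/none),
#'   `needs_transport` (logical). Must be sorted by `t_call`.
#' @param durations An [duration_model()].
#' @param dispatch An [dispatch_config()].
#' @param seed Integer seed for the duration sampling.
#' @param horizon Minutes after which no further event is processed
#'   (default `Inf`: run until every emergency is closed). Emergencies not
#'   closed by then are reported with status `"queued"` or `"in_service"`.
#' @return An `ems_simulation` object; `tidy()` extracts the per-emergency
#'   event log, `glance()` a one-row summary.
#' @export
simulate_ems <- function(region, fleet, emergencies,
                         durations = duration_model(),
                         dispatch = dispatch_config(),
                         seed = 1, horizon = Inf) {
  fleet <- ems_fleet(fleet, region)
  em <- tibble::as_tibble(emergencies)
  stopifnot(all(c("id", "t_call", "lon", "lat", "code", "hospital_kind",
                  "needs_transport") %in% names(em)))
  if (is.unsorted(em$t_call)) stop("emergencies must be sorted by t_call", call. = FALSE)
  if (!all(em$code %in% URGENCY_CODES)) stop("unknown urgency code", call. = FALSE)
  n <- nrow(em)

  loc_lon <- stats::setNames(
    c(region$candidates$lon, region$hospitals$lon, region$zones$lon),
    c(region$candidates$id, region$hospitals$id, region$zones$id)
  )
  loc_lat <- stats::setNames(
    c(region$candidates$lat, region$hospitals$lat, region$zones$lat),
    c(region$candidates$id, region$hospitals$id, region$zones$id)
  )
  TT <- region$travel_time

  # snap each emergency to the nearest zone centroid for road-time lookups
  em_loc <- snap_to_zones(region, em$lon, em$lat)
  if (anyNA(em_loc)) stop("emergency outside region travel model", call. = FALSE)

  # pre-sample all phase durations (single stream, fixed order => runs are
  # reproducible and policy changes do not shift the random draws)
  set.seed(seed)
  mns <- durations$means
  draw <- function(mean) if (mean == 0) numeric(n) else stats::rexp(n, 1 / mean)
  d_triage <- draw(mns[["triage"]]); d_scene <- draw(mns[["scene"]])
  d_drop <- draw(mns[["dropoff"]]); d_clean <- draw(mns[["cleaning"]])

  nv <- nrow(fleet)
  v_type <- fleet$type; v_shift <- fleet$shift; v_station <- fleet$station
  v_state <- rep(ST_IDLE, nv)
  v_loc <- v_station                       # location id when parked at one, NA mid-leg
  v_leg <- matrix(NA_real_, nv, 6,
                  dimnames = list(NULL, c("f_lon", "f_lat", "t_lon", "t_lat", "t0", "t1")))
  v_em <- rep(NA_integer_, nv)             # emergency index being served
  v_ev_t <- rep(Inf, nv); v_ev_type <- rep(0L, nv)
  v_is_mc_for <- rep(NA_integer_, nv)      # for MCs: paired emergency

  e_status <- rep(0L, n)   # 0 pending triage, 1 queued, 2 assigned, 3 closed
  e_ready <- rep(Inf, n)   # dispatch-ready time (after triage)
  e_disp <- rep(NA_real_, n); e_scene <- rep(NA_real_, n); e_dep <- rep(NA_real_, n)
  e_hosp_t <- rep(NA_real_, n); e_closed <- rep(NA_real_, n)
  e_veh <- rep(NA_integer_, n); e_mc <- rep(NA_integer_, n)
  e_hosp <- rep(NA_character_, n); e_pre <- rep(0L, n)
  queue <- integer(0)

  prio <- URGENCY_PRIORITY[em$code]
  off_speed <- dispatch$offroad_speed_kmh
  preemptive <- dispatch$policy == "preemption"

  v_pos <- function(v, t) {
    if (!is.na(v_loc[v])) return(c(loc_lon[[v_loc[v]]], loc_lat[[v_loc[v]]]))
    lg <- v_leg[v, ]
    if (t >= lg[["t1"]]) return(c(lg[["t_lon"]], lg[["t_lat"]]))
    frac <- (t - lg[["t0"]]) / (lg[["t1"]] - lg[["t0"]])
    c(lg[["f_lon"]] + frac * (lg[["t_lon"]] - lg[["f_lon"]]),
      lg[["f_lat"]] + frac * (lg[["t_lat"]] - lg[["f_lat"]]))
  }
  time_to <- function(v, t, dest_loc) {
    if (!is.na(v_loc[v])) return(TT[v_loc[v], dest_loc])
    p <- v_pos(v, t)
    haversine_km(p, c(loc_lon[[dest_loc]], loc_lat[[dest_loc]])) / off_speed * 60
  }
  dist_to_point <- function(v, t, lon, lat) {
    p <- v_pos(v, t)
    haversine_km(p, c(lon, lat))
  }

  start_leg <- function(v, t, dest_loc, dur) {
    p <- v_pos(v, t)
    v_leg[v, ] <<- c(p[1], p[2], loc_lon[[dest_loc]], loc_lat[[dest_loc]], t, t + dur)
    v_loc[v] <<- NA_character_
  }

  # availability of vehicle v for emergency e at time t (type already matched)
  avail_for <- function(v, e, t) {
    if (!in_shift_at(v_shift[v], t)) return(FALSE)
    st <- v_state[v]
    if (st == ST_IDLE) return(TRUE)
    if (!preemptive) return(FALSE)
    if (st == ST_RETURN) return(TRUE)
    if (st == ST_TO_SCENE) {
      o <- v_em[v]
      if (is.na(o)) return(FALSE)                 # MC en route: not divertible
      if (prio[o] >= 3) return(FALSE)             # never interrupt red/yellow
      if (prio[e] < 3) return(FALSE)              # only red/yellow may preempt
      return(dist_to_point(v, t, em$lon[e], em$lat[e]) <= dispatch$preemption_km)
    }
    FALSE
  }

  pick_vehicle <- function(e, t, types_pref) {
    for (tier in seq_along(types_pref)) {
      cand <- which(v_type == types_pref[tier])
      cand <- cand[vapply(cand, avail_for, logical(1), e = e, t = t)]
      if (length(cand) == 0) next
      dd <- vapply(cand, dist_to_point, numeric(1), t = t, lon = em$lon[e], lat = em$lat[e])
      near <- cand[dd <= dispatch$prefilter_km]
      pool <- if (length(near) > 0) near else if (prio[e] >= 3) cand else integer(0)
      if (length(pool) == 0) next
      rt <- vapply(pool, time_to, numeric(1), t = t, dest_loc = em_loc[e])
      return(pool[order(rt, pool)][1])   # nearest by road time, ties by lower id
    }
    NA_integer_
  }

  assign_vehicle <- function(v, e, t) {
    # preempt an ongoing non-urgent service if needed
    if (v_state[v] == ST_TO_SCENE && !is.na(v_em[v])) {
      o <- v_em[v]
      e_pre[o] <<- e_pre[o] + 1L
      e_disp[o] <<- NA_real_; e_veh[o] <<- NA_integer_
      e_status[o] <<- 1L
      queue <<- c(queue, o)
      release_mc(o, t)
    }
    dur <- time_to(v, t, em_loc[e])
    start_leg(v, t, em_loc[e], dur)   # handles mid-leg redirection via v_pos()
    v_state[v] <<- ST_TO_SCENE; v_em[v] <<- e
    v_ev_t[v] <<- t + dur; v_ev_type[v] <<- EV_ARRIVE_SCENE
    e_status[e] <<- 2L; e_disp[e] <<- t; e_veh[e] <<- v
  }

  pair_mc <- function(e, t) {
    if (!dispatch$pair_medical_car) return()
    mcs <- which(v_type == "MC" & is.na(v_is_mc_for))
    ok <- mcs[vapply(mcs, function(v) {
      in_shift_at(v_shift[v], t) && (v_state[v] == ST_IDLE ||
        (preemptive && v_state[v] == ST_RETURN))
    }, logical(1))]
    if (length(ok) == 0) return()
    rt <- vapply(ok, time_to, numeric(1), t = t, dest_loc = em_loc[e])
    v <- ok[order(rt, ok)][1]
    dur <- rt[match(v, ok)]
    start_leg(v, t, em_loc[e], dur)
    v_state[v] <<- ST_TO_SCENE; v_is_mc_for[v] <<- e
    v_ev_t[v] <<- t + dur; v_ev_type[v] <<- EV_ARRIVE_SCENE
    e_mc[e] <<- v
  }

  release_mc <- function(e, t) {
    v <- e_mc[e]
    if (is.na(v)) return()
    if (!is.na(v_is_mc_for[v]) && v_is_mc_for[v] == e) {
      dur <- time_to(v, t, v_station[v])
      start_leg(v, t, v_station[v], dur)
      v_state[v] <<- ST_RETURN; v_is_mc_for[v] <<- NA_integer_
      v_ev_t[v] <<- t + dur; v_ev_type[v] <<- EV_ARRIVE_STATION
    }
  }

  try_dispatch <- function(e, t) {
    pref <- if (prio[e] >= 3) c("ALS", "BLS") else c("BLS", "ALS")
    v <- pick_vehicle(e, t, pref)
    if (is.na(v)) {
      e_status[e] <<- 1L
      queue <<- c(queue, e)
      return(invisible(FALSE))
    }
    assign_vehicle(v, e, t)
    if (em$code[e] == "red") pair_mc(e, t)
    invisible(TRUE)
  }

  # freed (or newly in-shift) vehicle scans the queue
  serve_queue <- function(v, t) {
    if (length(queue) == 0 || v_type[v] == "MC") return()
    if (!avail_for_queue(v, t)) return()
    cand <- queue
    if (v_type[v] == "BLS") {
      # BLS takes red/yellow from the queue only as a fallback, i.e. when no
      # ALS is currently available anywhere
      als_free <- any(vapply(which(v_type == "ALS"), function(w) {
        in_shift_at(v_shift[w], t) && v_state[w] == ST_IDLE
      }, logical(1)))
      if (als_free) cand <- cand[prio[cand] < 3]
    }
    if (length(cand) == 0) return()
    rt <- vapply(cand, function(e) time_to(v, t, em_loc[e]), numeric(1))
    ord <- order(-prio[cand], em$t_call[cand], rt, cand)
    e <- cand[ord[1]]
    queue <<- setdiff(queue, e)
    assign_vehicle(v, e, t)
    if (em$code[e] == "red") pair_mc(e, t)
  }
  avail_for_queue <- function(v, t) {
    in_shift_at(v_shift[v], t) && v_state[v] == ST_IDLE
  }

  handle_vehicle_event <- function(v, t) {
    type <- v_ev_type[v]
    v_ev_t[v] <<- Inf; v_ev_type[v] <<- 0L
    if (type == EV_ARRIVE_SCENE) {
      if (!is.na(v_is_mc_for[v])) {            # medical car reaches the scene
        v_loc[v] <<- em_loc[v_is_mc_for[v]]
        v_state[v] <<- ST_AT_SCENE
        return()
      }
      e <- v_em[v]
      v_loc[v] <<- em_loc[e]; v_state[v] <<- ST_AT_SCENE
      e_scene[e] <<- t
      v_ev_t[v] <<- t + d_scene[e]; v_ev_type[v] <<- EV_SCENE_END
    } else if (type == EV_SCENE_END) {
      e <- v_em[v]
      e_dep[e] <<- t
      release_mc(e, t)
      if (em$needs_transport[e]) {
        h <- choose_hospital(region, em_loc[e], em$hospital_kind[e])
        e_hosp[e] <<- h
        dur <- TT[em_loc[e], h]
        start_leg(v, t, h, dur)
        v_state[v] <<- ST_TO_HOSP
        v_ev_t[v] <<- t + dur; v_ev_type[v] <<- EV_ARRIVE_HOSP
      } else {
        v_state[v] <<- ST_AT_HOSP   # cleaning on site, no transport
        v_ev_t[v] <<- t + d_clean[e]; v_ev_type[v] <<- EV_SERVICE_END
      }
    } else if (type == EV_ARRIVE_HOSP) {
      e <- v_em[v]
      v_loc[v] <<- e_hosp[e]; v_state[v] <<- ST_AT_HOSP
      e_hosp_t[e] <<- t
      v_ev_t[v] <<- t + d_drop[e] + d_clean[e]; v_ev_type[v] <<- EV_SERVICE_END
    } else if (type == EV_SERVICE_END) {
      e <- v_em[v]
      e_closed[e] <<- t; e_status[e] <<- 3L
      v_em[v] <<- NA_integer_
      dur <- time_to(v, t, v_station[v])
      start_leg(v, t, v_station[v], dur)
      v_state[v] <<- ST_RETURN
      v_ev_t[v] <<- t + dur; v_ev_type[v] <<- EV_ARRIVE_STATION
      # under preemption a returning vehicle is available: queued calls may
      # grab it right away through the regular dispatch path
      if (preemptive) requeue_queued(t)
    } else if (type == EV_ARRIVE_STATION) {
      v_loc[v] <<- v_station[v]; v_state[v] <<- ST_IDLE
      v_leg[v, ] <<- rep(NA_real_, 6)
      if (in_shift_at(v_shift[v], t)) serve_queue(v, t)
    }
  }

  # re-attempt dispatch of queued emergencies (used when returning vehicles
  # become available under preemption)
  requeue_queued <- function(t) {
    if (length(queue) == 0) return()
    cand <- queue[order(-prio[queue], em$t_call[queue], queue)]
    for (e in cand) {
      pref <- if (prio[e] >= 3) c("ALS", "BLS") else c("BLS", "ALS")
      v <- pick_vehicle(e, t, pref)
      if (!is.na(v)) {
        queue <<- setdiff(queue, e)
        assign_vehicle(v, e, t)
        if (em$code[e] == "red") pair_mc(e, t)
      }
    }
  }

  # ---- main loop --------------------------------------------------------
  next_arrival <- 1L
  pending <- integer(0)     # emergencies in triage, dispatch at e_ready
  last_call <- if (n > 0) em$t_call[n] else 0
  shift_limit <- last_call + 7 * 1440   # stop issuing shift wake-ups eventually
  now <- 0

  repeat {
    t_veh <- if (nv > 0) min(v_ev_t) else Inf
    t_arr <- if (next_arrival <= n) em$t_call[next_arrival] else Inf
    t_rdy <- if (length(pending) > 0) min(e_ready[pending]) else Inf
    # next day/night shift boundary strictly after `now`, only relevant
    # while calls are waiting in the queue
    t_shift <- if (length(queue) > 0) {
      b <- (floor((now - 480) / 720) + 1) * 720 + 480
      if (b <= shift_limit) b else Inf
    } else Inf
    t <- min(t_veh, t_arr, t_rdy, t_shift)
    if (!is.finite(t) || t > horizon) break
    now <- t

    if (t_veh <= t) {                     # completions first
      v <- which(v_ev_t == t)[1]
      handle_vehicle_event(v, t)
    } else if (t_shift <= t) {            # shift opening: wake idle vehicles
      for (v in seq_len(nv)) {
        if (length(queue) == 0) break
        if (avail_for_queue(v, t)) serve_queue(v, t)
      }
    } else if (t_arr <= t) {              # new call: start triage
      e <- next_arrival; next_arrival <- next_arrival + 1L
      e_ready[e] <- t + d_triage[e]
      pending <- c(pending, e)
    } else {                              # triage done: dispatch scan
      e <- pending[which(e_ready[pending] == t)][1]
      pending <- setdiff(pending, e)
      try_dispatch(e, t)
    }
  }

  while (next_arrival <= n) {  # arrivals beyond a finite horizon stay queued
    e_status[next_arrival] <- 1L
    queue <- c(queue, next_arrival)
    next_arrival <- next_arrival + 1L
  }
  if (length(pending) > 0) {
    e_status[pending] <- 1L
    queue <- c(queue, pending)
  }

  log <- tibble::tibble(
    id = em$id, t_call = em$t_call, code = em$code,
    hospital_kind = em$hospital_kind, needs_transport = em$needs_transport,
    zone = em_loc,
    vehicle = ifelse(is.na(e_veh), NA_character_, fleet$id[e_veh]),
    vehicle_type = ifelse(is.na(e_veh), NA_character_, v_type[e_veh]),
    medical_car = ifelse(is.na(e_mc), NA_character_, fleet$id[e_mc]),
    hospital = e_hosp,
    t_dispatch = e_disp, t_scene_arrival = e_scene, t_scene_departure = e_dep,
    t_hospital_arrival = e_hosp_t, t_closed = e_closed,
    preemptions = e_pre,
    queue_wait = ifelse(is.na(e_disp), NA_real_, e_disp - (em$t_call + d_triage)),
    response_time = e_scene - em$t_call,
    status = c("queued", "queued", "in_service", "closed")[e_status + 1L]
  )
  structure(
    list(
      log = log, seed = seed, policy = dispatch$policy,
      durations = durations, dispatch = dispatch, horizon = horizon,
      n_emergencies = n, n_closed = sum(e_status == 3L),
      n_open = sum(e_status != 3L)
    ),
    class = "ems_simulation"
  )
}

snap_to_zones <- function(region, lon, lat) {
  zl <- cbind(region$zones$lon, region$zones$lat)
  vapply(seq_along(lon), function(i) {
    d <- geosphere::distHaversine(c(lon[i], lat[i]), zl, r = 6371000)
    region$zones$id[which.min(d)]
  }, character(1))
}

#' @export
print.ems_simulation <- function(x, ...) {
  cat("<ems_simulation> ", x$n_emergencies, " emergencies (", x$n_closed,
      " closed), policy = ", x$policy, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
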