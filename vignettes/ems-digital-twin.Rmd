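---
title: "Methods: a digital twin and multi-objective optimizer for regional EMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a digital twin and multi-objective optimizer for regional EMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emstwin)
```

## The problem

Emergency Medical Services (EMS) planners must decide where to station a
fixed fleet of ambulances across a region that mixes dense cities, a wide
rural belt, a sparsely populated mountain area and seaside tourist towns.
Two families of objectives pull in opposite directions: *efficiency*
(serve as many people as fast as possible, which argues for concentrating
vehicles where the population is) and *fairness* (give every municipality
comparable access to the service, which argues for spreading vehicles out).
`emstwin` provides the three tools this trade-off analysis needs:

1. a **KPI suite** quantifying fairness and coverage of a deployment,
2. a **discrete-event simulator** that replays an emergency stream against a
   deployment and produces per-call response times, and
3. a **multi-objective optimizer** that searches deployments and returns a
   Pareto front instead of a single "best" answer, so the planner retains
   the final choice among trade-offs.

A fourth component, the **synthetic scenario generator**, produces regions,
fleets and emergency streams with the statistical structure described below,
so the whole pipeline is testable without access to confidential dispatch
records.

## Region model and travel abstraction

A region is a set of municipalities, each split into census zones carrying
population and surface, plus hospitals (three tiers: *hubs* with full
specialist services, *spokes* with basic hospital care, and points of
primary care) and one candidate station per municipality. All travel is
read from two matrices (minutes and road km) over every location. This
matrix abstraction replaces real road-network isochrone computation: any
GIS pipeline that can produce travel-time matrices can feed the package,
and the synthetic generator produces internally consistent matrices on its
own. A zone counts as *reached* from a station when the travel time to its
centroid is below the threshold; this centroid rule is one of several
defensible discretizations of intersecting an isochrone polygon with a
census zone, and it is applied uniformly to every indicator so comparisons
between deployments are unaffected.

Coordinates are WGS84 lon/lat; great-circle distances use the haversine
formula on a 6371 km sphere; times are minutes, distances km.

## The indicators

All KPI parameters live in `kpi_config()`. Defaults: response threshold
18 minutes (the regulatory timeliness limit for urgent calls), BLS weight
0.70.

* **Fair coverage** — for every zone, the fraction of the shift's transport
  fleet that can reach it in time, weighting Advanced Life Support (ALS)
  ambulances 1 and Basic Life Support (BLS) ambulances 0.70 (they provide
  basic care only); medical cars are excluded since they never act alone.
  Municipality shares are population-weighted means over their zones, day
  and night shares are averaged, and the Gini index of the municipality
  shares is the indicator (0 = perfectly equal access). Two readings of the
  normalizing denominator are defensible from the prose definition of this
  indicator (total fleet weight, or each ambulance's own reachable
  population); both are implemented behind `fair_denominator`, with the
  fleet-size share as the default because it keeps shares in [0, 1] with an
  immediate interpretation.
* **Population / surface coverage** — the fraction of residents (surface)
  in zones reached within the threshold, crediting 1 when an ALS reaches
  the zone, 0.70 when only BLS do. The surface variant protects large,
  sparsely populated areas that the population variant would ignore.
* **Second-ambulance distance** — the maximum over zones of the road
  distance to the *second*-nearest transport ambulance: the worst case when
  the nearest vehicle is already busy. Counted with multiplicity, so two
  ambulances at one station cover first and second from the same distance.
  A config switch reports minutes instead of km.
* **Response-time statistics** — per urgency code: mean, 90th percentile,
  fraction within threshold and the cumulative frequency curve, computed
  from simulator logs. Unserved calls are reported separately, never
  dropped.

The optimizer's cost vector has seven components, all minimized: the fair
coverage Gini (computed across both shifts), and — separately for day and
night, because night resources are much scarcer — uncovered population
fraction, uncovered surface fraction, and second-ambulance distance.
Coverage enters as fractions rather than absolute counts so the components
are commensurately scaled for reporting and radar-style plots.

Degenerate cases are fixed by convention: the Gini of an all-zero vector is
0 (perfect, if degenerate, equality); coverage with an empty roster errors
for the reach shares (undefined denominator) and is 0 for coverage credit.

## The simulator

`simulate_ems()` is a discrete-event model of the full service cycle:
call → triage → dispatch → travel → on-scene treatment (the Italian
"stay and play" doctrine) → optional transport to the nearest suitable
hospital (a hub satisfies a spoke-level need, not vice versa) → drop-off →
cleaning → return to station. Phase durations are exponential
(`duration_model()`); the defaults (triage 1.5, scene 18, drop-off 10,
cleaning 5 minutes) are plausible order-of-magnitude choices documented as
such — real dispatch-record estimates vary by region and are typically
confidential.
A mean of zero makes a phase instantaneous, which is how the stylized
queueing scenarios used in validation are expressed.

Dispatching is hierarchical. Urgency determines the vehicle type order
(red/yellow: ALS first, BLS only when no ALS is available anywhere;
green/white: BLS first, then ALS). Candidates are pre-filtered to a 20 km
haversine radius; red and yellow calls escalate region-wide when the filter
comes back empty, non-urgent calls do not. Among candidates the nearest by
road time wins, ties broken by vehicle id. Red calls additionally try to
pair the nearest available medical car. Calls that cannot be served join a
queue ordered by urgency, then waiting time, then road time from the
vehicle that just became free.

Two availability policies are implemented:

* `no_preemption` — only vehicles idle at a station are available;
* `preemption` — additionally, a vehicle en route to a green/white call may
  be diverted to a red/yellow call within the proximity radius (default:
  the same 20 km; the concept of "close proximity" is not quantified in the
  source system, so it is a config value), and a vehicle returning to its
  station after completing a service is available for any call.

Mid-leg vehicle positions are linearly interpolated along the current leg;
travel from an interpolated point uses the haversine distance at a
configurable off-road speed (default 50 km/h), since a matrix lookup is
only defined between named locations. A preempted call re-enters the queue
keeping its original call time (so its waiting priority keeps growing) and
its preemption counter increments; red/yellow services are never
interrupted. A vehicle whose shift ends mid-service completes the service
and then returns off-shift — abandoning a patient at shift end is not a
modelling option. Green and white calls may wait indefinitely (no reneging
rule is modelled).

Determinism: all phase durations are pre-sampled per emergency from a
single stream at the start of the run, in a fixed order independent of the
dispatching policy. Two runs with the same stream and seed are identical,
and policy comparisons see identical random material. Simultaneous events
are ordered completions → call arrivals → dispatch scans, then by entity
id. Emergencies are snapped to the nearest zone centroid for road-time
lookups; the synthetic generator emits calls at zone centroids, making the
snap exact.

Known limitations (deliberate): no medical helicopters (their deployment is
a case-by-case medical decision), no hospital emergency-department
congestion, no follow-up calls or multi-casualty events, no crew fatigue.

## The optimizer

The search space assigns each relocatable vehicle (ALS and BLS; medical
cars stay fixed at healthcare facilities because they require a doctor) a
candidate station, one ordered vector per (type, shift) group. Ordering
breaks the symmetry between interchangeable vehicles; stations have
unlimited capacity, so repeats are allowed. Shifts are never modified. The
single move, *ChangeAmbulance*, relocates one vehicle to a different
candidate and re-sorts its group.

`plahc()` implements Pareto Late-Acceptance Hill Climbing: a circular
history of `L_h` solutions (default 20) is initialized with random
solutions (warm starts are inserted verbatim); each iteration perturbs the
solution under the cursor and accepts the candidate unless the reference
*dominates* it (strict Pareto dominance: better somewhere, no worse
anywhere). A rejected candidate is compared once more against the next
history slot — the "late acceptance" second chance — and on success the
cursor skips that slot to preserve diversity. This weak acceptance rule
(accept unless dominated, rather than accept only if dominating) is what
lets the search drift across incomparable solutions and grow a front; the
scheme above is this package's normative semantics.

Because the history holds only `L_h` solutions, an archive of all accepted
solutions is kept alongside (toggleable), and the returned front is the
non-dominated subset of history plus archive — without it the front could
never exceed `L_h` points. Cost evaluations are memoized by solution key;
this is purely an optimization and changes no semantics. Stopping: an
iteration budget (default 10^6), an optional wall-clock timeout, and an
idle test (stop once at least `min_iterations` have run and the fraction
of non-accepting iterations reaches 20%).

## The synthetic generator

`generate_region()` places municipalities in class-specific latitude bands
of a compact bounding box (mountains north, cities central, seaside south)
and splits class totals over municipalities and zones with moderately
dispersed random proportions (gamma weights), preserving totals exactly.
The defaults reproduce the reference class structure of the motivating
region: 5/125/83/2 municipalities, populations 413,647 / 613,074 /
155,930 / 14,644 and surfaces 242 / 3,233 / 4,322 / 135 km², whose class
densities (1,709.3 / 189.6 / 36.1 / 108.5, overall 150.9 per km²) follow
arithmetically. Travel time between two points is great-circle distance ×
a road-winding factor ÷ an average road speed, both averaged between the
endpoint classes (mountain: winding 1.6, 30 km/h; city 1.2, 40; rural
1.25, 60; seaside 1.2, 50), which reproduces the qualitative signature of
the real geography — mountain municipalities are much slower to reach than
city ones at similar crow-fly distance.

`generate_emergencies()` draws daily Poisson counts (default 108,000
calls/year for the full-size region, consistent with roughly 1.2 M
inhabitants), hours from a two-peak intensity profile (mid-morning and
early evening, night trough), locations proportional to zone population ×
a class-season multiplier (winter: mountain ×1.5; summer: mountain ×1.3,
seaside ×1.8 — tourist surges are modelled only through these multipliers,
not as population changes), urgency codes i.i.d. from a configurable mix
(defaults red 10%, yellow 35%, green 45%, white 10% — plausible values
rather than estimates from real records), and transport/hospital-need flags from Bernoulli
draws. `fvg_like_fleet()` builds the reference roster (ALS 17 day / 5
night / 26 all-day; BLS 6/1/3; MC 3/1/3; all-day vehicles count in both
rosters) with ambulances stationed in the most populous municipalities and
medical cars at hospitals.

What the generator does *not* emulate: real road topology (travel factors
are smooth, real isochrones are not), spatial correlation of demand beyond
population density, day-of-week structure, and multi-call incidents.
Passing tests on synthetic data therefore validate the *mechanics* of the
pipeline — dispatch logic, queueing behaviour, indicator arithmetic, search
dynamics — not the fidelity of any specific real region.

## Validation design and problem sizes

The test-suite checks were chosen so that each nontrivial component has an
independent oracle:

* **Gini** against the O(n²) pairwise formula; **Pareto filtering** against
  a naive double loop; **haversine** against the closed-form quarter
  circumference.
* **Queueing**: with zero travel, instantaneous triage and a single
  station, the simulator *is* an M/M/c queue; its mean wait is compared to
  the Erlang-C closed form for c ∈ {1, 2, 3} at load 0.7, over 20
  replications of 400 arrivals each (the first 100 discarded as warm-up),
  at a 3-standard-error tolerance.
* **Optimizer**: a 2-ambulance × 8-candidate problem has only 36 ordered
  configurations, so the true front is enumerable; `plahc()` at 10,000
  iterations must recover it in at least 19 of 20 seeds.
* **Policy ordering**: on a small heterogeneous region (10 municipalities,
  62,000 inhabitants, ~25 calls/day, a deliberately lean fleet of 4
  transport vehicles so the system experiences contention), the fraction of
  red codes served within 18 minutes under preemption must be at least
  that without preemption, pooled over 10 seeds of a common 30-day stream.
  This turns the expected operational benefit of preemption for urgent
  codes into a reproducible property.

These problem sizes are the package's validation choices; they keep the
full suite within a few minutes while leaving each statistical check
adequately powered.

## A worked example

```{r example, eval = FALSE}
region <- generate_region(seed = 1)
fleet <- fvg_like_fleet(region)
cost_vector(region, fleet)

stream <- generate_emergencies(region, demand_params(), horizon_days = 7, seed = 2)
sim <- simulate_ems(region, fleet, stream, seed = 3,
                    dispatch = dispatch_config("preemption"))
glance(sim)
autoplot(response_time_stats(tidy(sim)))

problem <- ems_location_problem(region, fleet)
front <- plahc(problem, max_iterations = 20000, seed = 4,
               warm_start = list(problem$current))
autoplot(front)
```
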