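#' Strict Pareto dominance between cost vectors
#'
#' `f1` dominates `f2` when it is strictly better (lower) in at least one
#' component and no worse in all others. All components are oriented for
#' minimization. The relation is irreflexive, antisymmetric and transitive.
#'
#' @param f1,f2 Numeric vectors of equal length (or one-row data frames).
#' @return `TRUE` or `FALSE`.
#' @export
dominates <- function(f1, f2) {
  f1 <- as.numeric(unlist(f1))
  f2 <- as.numeric(unlist(f2))
  if (length(f1) != length(f2)) stop("cost vectors must have equal length", call. = FALSE)
  all(f1 <= f2) && any(f1 < f2)
}

#' Non-dominated subset of a set of cost vectors
#'
#' Keeps exactly the rows not strictly dominated by any other row. Ties
#' (identical vectors) do not dominate each other and are all retained.
#' The result is independent of row order.
#'
#' @param x Numeric matrix or data frame, one cost vector per row.
#' @return The non-dominated rows of `x`, original order preserved.
#' @export
pareto_filter <- function(x) {
  was_df <- is.data.frame(x)
  m <- as.matrix(x)
  if (nrow(m) == 0) stop("pareto_filter needs a non-empty set", call. = FALSE)
  keep <- nondominated(m)
  if (was_df) x[keep, , drop = FALSE] else m[keep, , drop = FALSE]
}

# logical vector: row i not dominated by any other row
nondominated <- function(m) {
  n <- nrow(m)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    le <- sweep(m, 2, m[i, ], `<=`)
    lt <- sweep(m, 2, m[i, ], `<`)
    dom_i <- rowSums(le) == ncol(m) & rowSums(lt) > 0
    if (any(dom_i)) keep[i] <- FALSE
  }
  keep
}

#' Ambulance location problem for the optimizer
#'
#' Builds the search problem PLAHC explores: relocatable vehicles (by
#' default every ALS and BLS ambulance; medical cars stay fixed because they
#' require a doctor and are stationed at healthcare facilities) may be
#' assigned to any candidate station. A solution is one ordered vector of
#' candidate-location indices per (vehicle type, shift) group; ordering
#' breaks symmetry between interchangeable vehicles, and repeats are allowed
#' (stations have unlimited capacity). Shifts are never modified.
#'
#' @param region An [ems_region()].
#' @param fleet An [ems_fleet()]; its current stations give the warm-start
#'   solution available via `problem$current`.
#' @param config A [kpi_config()] used by the cost function.
#' @param relocatable Logical vector (recycled) flagging which fleet rows the
#'   optimizer may move; default moves ALS and BLS, keeps MC fixed.
#' @param candidates Character vector of candidate station ids; defaults to
#'   the region's candidate locations.
#' @return A list of class `plahc_problem` with elements `eval` (solution ->
#'   numeric cost vector), `random_solution`, `random_move`, `decode`
#'   (solution -> [ems_fleet()]), `current`, and `objectives`.
#' @export
ems_location_problem <- function(region, fleet, config = kpi_config(),
                                 relocatable = fleet$type != "MC",
                                 candidates = region$candidates$id) {
  if (length(candidates) == 0) stop("no candidate locations", call. = FALSE)
  relocatable <- rep_len(relocatable, nrow(fleet))
  idx <- which(relocatable)
  if (length(idx) == 0) stop("no relocatable vehicles", call. = FALSE)
  groups <- split(idx, paste(fleet$type[idx], fleet$shift[idx], sep = "."))

  decode <- function(sol) {
    f <- fleet
    for (g in names(groups)) f$station[groups[[g]]] <- candidates[sol[[g]]]
    f
  }
  cache <- new.env(parent = emptyenv())
  eval_sol <- function(sol) {
    key <- paste(unlist(sol), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    v <- as.numeric(cost_vector(region, decode(sol), config))
    cache[[key]] <- v
    v
  }
  random_solution <- function() {
    lapply(groups, function(g) sort(sample.int(length(candidates), length(g), replace = TRUE)))
  }
  random_move <- function(sol) {
    g <- names(groups)[[sample.int(length(groups), 1)]]
    i <- sample.int(length(sol[[g]]), 1)
    cur <- sol[[g]][i]
    l <- sample.int(length(candidates) - 1, 1)
    if (l >= cur) l <- l + 1   # uniform over candidates excluding the current one
    apply_move(sol, list(group = g, index = i, location = l))
  }
  current <- lapply(groups, function(g) sort(match(fleet$station[g], candidates)))
  if (anyNA(unlist(current))) current <- NULL  # current stations outside candidate set

  structure(
    list(
      eval = eval_sol, random_solution = random_solution, random_move = random_move,
      decode = decode, current = current, groups = groups,
      n_candidates = length(candidates), objectives = COST_COMPONENTS
    ),
    class = "plahc_problem"
  )
}

#' Apply a ChangeAmbulance move to a solution
#'
#' Reassigns one vehicle of one (type, shift) group to a new candidate
#' location and re-sorts that group's vector; every other vector is
#' untouched. The new location must differ from the current one.
#'
#' @param solution A solution as produced by the problem's generators: a
#'   named list of sorted integer vectors of candidate-location indices.
#' @param move A list with `group` (name), `index` (position in the group
#'   vector) and `location` (new candidate index).
#' @return The modified solution.
#' @export
apply_move <- function(solution, move) {
  v <- solution[[move$group]]
  if (v[move$index] == move$location) {
    stop("move precondition violated: new location equals the current one", call. = FALSE)
  }
  v[move$index] <- move$location
  solution[[move$group]] <- sort(v)
  solution
}

#' Pareto Late-Acceptance Hill Climbing
#'
#' Multi-objective local search over a circular history of `history_length`
#' solutions. Each iteration draws the reference solution under the cursor,
#' perturbs it with one random move, and accepts the candidate unless the
#' reference dominates it; a rejected candidate gets a second chance against
#' the next history slot (on success the cursor skips that slot to preserve
#' diversity). Accepted solutions are also archived so the final front is
#' not limited to the history length. The search stops at `max_iterations`,
#' at `timeout` seconds, or -- once `min_iterations` have elapsed -- when the
#' proportion of idle (no-acceptance) iterations reaches `idle_fraction`.
#'
#' @param problem A `plahc_problem`, e.g. from [ems_location_problem()].
#' @param history_length Circular history size `L_h` (default 20).
#' @param max_iterations Iteration budget (default 1e6).
#' @param idle_fraction Idle-iteration tolerance as a fraction of the
#'   iteration count (default 0.20).
#' @param min_iterations Iterations before the idle test activates.
#' @param seed Integer seed; fixed seeds give identical fronts.
#' @param timeout Optional wall-clock limit in seconds.
#' @param warm_start Optional list of solutions inserted verbatim into the
#'   initial history (the remainder is filled with random solutions).
#' @param archive Keep an archive of all accepted solutions (default TRUE);
#'   when FALSE the front is drawn from the final history only.
#' @return An `ems_front` object: tibble with a `solution` list-column, one
#'   column per cost component, and attributes `iterations`, `idle`, `seed`.
#' @export
plahc <- function(problem, history_length = 20, max_iterations = 1e6,
                  idle_fraction = 0.20, min_iterations = 10000, seed = 1,
                  timeout = Inf, warm_start = NULL, archive = TRUE) {
  stopifnot(history_length >= 1, idle_fraction > 0, idle_fraction < 1)
  set.seed(seed)
  t0 <- Sys.time()

  hist_sol <- vector("list", history_length)
  hist_cost <- vector("list", history_length)
  n_warm <- 0
  if (!is.null(warm_start)) {
    n_warm <- min(length(warm_start), history_length)
    for (k in seq_len(n_warm)) hist_sol[[k]] <- warm_start[[k]]
  }
  for (k in seq_len(history_length)) {
    if (is.null(hist_sol[[k]])) hist_sol[[k]] <- problem$random_solution()
    hist_cost[[k]] <- problem$eval(hist_sol[[k]])
  }

  sol_key <- function(s) paste(unlist(s), collapse = ",")
  arch <- new.env(parent = emptyenv())   # accepted solutions, unique by key
  if (archive) {
    for (k in seq_len(history_length)) {
      arch[[sol_key(hist_sol[[k]])]] <- list(hist_sol[[k]], hist_cost[[k]])
    }
  }
  cursor <- 1L
  iter <- 0L
  idle <- 0L

  dominates_num <- function(a, b) all(a <= b) && any(a < b)

  while (iter < max_iterations) {
    iter <- iter + 1L
    s <- hist_sol[[cursor]]
    cand <- problem$random_move(s)
    fc <- problem$eval(cand)
    accepted <- FALSE
    if (!dominates_num(hist_cost[[cursor]], fc)) {
      hist_sol[[cursor]] <- cand
      hist_cost[[cursor]] <- fc
      accepted <- TRUE
    } else {
      nxt <- cursor %% history_length + 1L
      if (!dominates_num(hist_cost[[nxt]], fc)) {
        hist_sol[[nxt]] <- cand
        hist_cost[[nxt]] <- fc
        accepted <- TRUE
        cursor <- nxt   # extra step: bypass the immediate re-check of the slot
      }
    }
    if (accepted) {
      if (archive) arch[[sol_key(cand)]] <- list(cand, fc)
    } else {
      idle <- idle + 1L
    }
    cursor <- cursor %% history_length + 1L
    if (iter >= min_iterations && idle / iter >= idle_fraction) break
    if (is.finite(timeout) && iter %% 256L == 0L &&
        as.numeric(difftime(Sys.time(), t0, units = "secs")) > timeout) break
  }

  if (archive) {
    entries <- mget(ls(arch, sorted = TRUE), envir = arch)
    pool_sol <- lapply(entries, `[[`, 1)
    pool_cost <- lapply(entries, `[[`, 2)
  } else {
    keys <- vapply(hist_sol, sol_key, character(1))
    pool_sol <- hist_sol[!duplicated(keys)]
    pool_cost <- hist_cost[!duplicated(keys)]
  }
  cost_m <- do.call(rbind, pool_cost)
  colnames(cost_m) <- problem$objectives
  rownames(cost_m) <- NULL
  keep <- nondominated(cost_m)

  out <- tibble::as_tibble(cost_m[keep, , drop = FALSE])
  out$solution <- unname(pool_sol[keep])
  out <- out[order(out[[1]]), c("solution", problem$objectives)]
  attr(out, "iterations") <- iter
  attr(out, "idle") <- idle
  attr(out, "seed") <- seed
  class(out) <- c("ems_front", class(out))
  out
}

#' Draw a uniform random solution for a problem
#'
#' Uniform independent draws per vehicle over the candidate locations,
#' sorted within each (type, shift) group.
#'
#' @param problem A `plahc_problem`.
#' @return A solution (named list of sorted integer vectors).
#' @export
random_solution <- function(problem) problem$random_solution()

#' @export
print.ems_front <- function(x, ...) {
  cat("<ems_front> ", nrow(x), " non-dominated solution(s), ",
      attr(x, "iterations"), " iterations (", attr(x, "idle"), " idle), seed ",
      attr(x, "seed"), "\n", sep = "")
  NextMethod()
}
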