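#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-emergency event log of a simulation
#'
#' @param x An `ems_simulation`.
#' @param ... Unused.
#' @return The event-log tibble (one row per emergency).
#' @export
tidy.ems_simulation <- function(x, ...) x$log

#' One-row summary of a simulation run
#'
#' @param x An `ems_simulation`.
#' @param threshold Response-time threshold in minutes for the timeliness
#'   fractions (default 18).
#' @param ... Unused.
#' @export
glance.ems_simulation <- function(x, threshold = 18, ...) {
  log <- x$log
  resp <- log$response_time
  urgent <- log$code %in% c("red", "yellow")
  tibble::tibble(
    n_emergencies = x$n_emergencies,
    n_closed = x$n_closed,
    n_open = x$n_open,
    mean_response = mean(resp, na.rm = TRUE),
    frac_within_threshold = mean(resp[!is.na(resp)] <= threshold),
    frac_urgent_within_threshold =
      mean(resp[urgent & !is.na(resp)] <= threshold),
    mean_queue_wait = mean(log$queue_wait, na.rm = TRUE),
    policy = x$policy,
    seed = x$seed
  )
}

#' Tidy an optimizer front
#'
#' @param x An `ems_front`.
#' @param ... Unused.
#' @return A tibble with a solution id and the cost components.
#' @export
tidy.ems_front <- function(x, ...) {
  out <- tibble::as_tibble(x[, setdiff(names(x), "solution")])
  dplyr::mutate(out, solution_id = dplyr::row_number(), .before = 1)
}

#' One-row summary of an optimizer run
#'
#' @param x An `ems_front`.
#' @param ... Unused.
#' @export
glance.ems_front <- function(x, ...) {
  tibble::tibble(
    n_front = nrow(x),
    iterations = attr(x, "iterations"),
    idle = attr(x, "idle"),
    seed = attr(x, "seed")
  )
}

#' Cumulative response-time frequency curves
#'
#' One panel per urgency code; the y-axis is the fraction of served
#' emergencies with a response time within the x-axis minutes. The
#' timeliness threshold is drawn as a vertical line.
#'
#' @param object An `ems_response_stats` from [response_time_stats()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ems_response_stats <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 18
  df <- object |>
    dplyr::filter(lengths(.data$curve) > 0) |>
    dplyr::mutate(curve_df = purrr::map(.data$curve, function(cv) {
      tibble::tibble(minutes = cv, cum_freq = seq_along(cv) / length(cv))
    })) |>
    dplyr::select("code", "curve_df") |>
    tidyr::unnest("curve_df")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$minutes, y = .data$cum_freq)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::facet_wrap(~code) +
    ggplot2::labs(x = "response time (minutes)", y = "cumulative frequency") +
    ggplot2::theme_minimal()
}

#' Normalized cost-component profile of a Pareto front
#'
#' Each solution is drawn as a line across the seven cost components, each
#' scaled to the [0, 1] range of the front (the flat analogue of the radar
#' chart used to compare deployments).
#'
#' @param object An `ems_front`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ems_front <- function(object, ...) {
  comp <- setdiff(names(object), "solution")
  df <- tidy.ems_front(object) |>
    tidyr::pivot_longer(dplyr::all_of(comp), names_to = "component", values_to = "value") |>
    dplyr::group_by(.data$component) |>
    dplyr::mutate(
      scaled = if (diff(range(.data$value)) > 0) {
        (.data$value - min(.data$value)) / diff(range(.data$value))
      } else {
        0
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(component = factor(.data$component, levels = comp))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$component, y = .data$scaled,
    group = .data$solution_id, colour = factor(.data$solution_id)
  )) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "normalized cost", colour = "solution") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
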