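#' Snapshot plot of a trajectory
#'
#' Agent positions at a set of sample times, with arrows along headings.
#'
#' @param object A `flock_trajectory`.
#' @param times Sample times to show (default: first and last).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flock_trajectory <- function(object, times = NULL, ...) {
  st <- object$states
  if (is.null(times)) times <- range(st$time)
  avail <- unique(st$time)
  times <- purrr::map_dbl(times, function(t) avail[which.min(abs(avail - t))])
  st <- dplyr::filter(st, .data$time %in% times)
  len <- object$params$epsilon / 2
  ggplot2::ggplot(st, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x + len * cos(.data$heading),
                   yend = .data$y + len * sin(.data$heading)),
      linewidth = 0.3, colour = "grey50"
    ) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~time, scales = "free", labeller = "label_both") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y")
}

#' Cohesion time series
#'
#' @param object A `flock_cohesion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flock_cohesion <- function(object, ...) {
  object$per_time |>
    tidyr::pivot_longer(c("largest_fraction", "n_clusters"),
                        names_to = "metric") |>
    ggplot2::ggplot(ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time", y = NULL)
}

#' Cohesion and network parameter versus neighbourhood size
#'
#' Replicate-averaged C and Np as functions of K, with standard-error
#' bars, one panel per group size; the data behind the saturation
#' analysis.
#'
#' @param object A `flock_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flock_sweep <- function(object, ...) {
  summarise_sweep(object) |>
    tidyr::pivot_longer(c("C", "Np"), names_to = "metric") |>
    dplyr::mutate(se = ifelse(.data$metric == "C", .data$C_se, .data$Np_se)) |>
    ggplot2::ggplot(ggplot2::aes(.data$K, .data$value,
                                 colour = .data$metric)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$value - .data$se,
                                          ymax = .data$value + .data$se)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(k_mode ~ N, labeller = "label_both") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "neighbourhood size K", y = NULL, colour = NULL)
}

#' Order-parameter trace
#'
#' @param object An `sde_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sde_trace <- function(object, ...) {
  ggplot2::ggplot(tidy.sde_trace(object),
                  ggplot2::aes(.data$time, .data$m)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "time", y = "polarization m",
                  subtitle = paste(object$model, "model"))
}
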