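#' Trajectory and event-log CSV round trip
#'
#' Trajectory CSV: columns `time`, `id`, `x`, `y`, `speed`, `heading`
#' (radians), one row per agent per sample time. Event-log CSV: columns
#' `time`, `focal`, `etype`, `partners` with partner ids semicolon-joined
#' (empty string for no partners). Both carry a header line and round-trip
#' losslessly to at least 12 significant digits.
#'
#' @param traj A `flock_trajectory` (or a states/events tibble for the
#'   `*_csv` writers).
#' @param path Output file path.
#' @return `path` invisibly for writers; a tibble for readers.
#' @name flock_io
NULL

#' @rdname flock_io
#' @export
write_trajectory_csv <- function(traj, path) {
  states <- if (inherits(traj, "flock_trajectory")) traj$states else traj
  readr::write_csv(states, path)
  invisible(path)
}

#' @rdname flock_io
#' @export
read_trajectory_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    time = "d", id = "i", x = "d", y = "d", speed = "d", heading = "d"
  ))
}

#' @rdname flock_io
#' @export
write_events_csv <- function(traj, path) {
  events <- if (inherits(traj, "flock_trajectory")) traj$events else traj
  flat <- dplyr::mutate(
    events,
    partners = purrr::map_chr(.data$partners,
                              function(p) paste(p, collapse = ";"))
  )
  readr::write_csv(flat, path)
  invisible(path)
}

#' @rdname flock_io
#' @export
read_events_csv <- function(path) {
  flat <- readr::read_csv(path, col_types = readr::cols(
    time = "d", focal = "i", etype = "c", partners = "c"
  ))
  flat$partners <- purrr::map(flat$partners, function(s) {
    if (is.na(s) || s == "") integer(0) else as.integer(strsplit(s, ";")[[1]])
  })
  flat
}

#' @rdname flock_io
#' @param network A `flock_network` from [network_parameter()].
#' @export
write_windows_csv <- function(network, path) {
  readr::write_csv(network$per_window, path)
  invisible(path)
}

#' @rdname flock_io
#' @param trace An `sde_trace` from [simulate_sde()].
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(tidy.sde_trace(trace), path)
  invisible(path)
}
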