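#' Segment a trial into gait cycles
#'
#' A gait cycle runs from one foot strike to the next foot strike of the same
#' (anchor) side. Cycles without exactly one interior ipsilateral foot off
#' are excluded with a warning (they cannot define stance and swing).
#'
#' @param trial A [gait_trial()] object.
#' @param side Anchor side, `"left"` or `"right"`.
#' @return List of `gait_cycle` objects in temporal order. Consecutive
#'   cycles tile the interval from the first to the last strike.
#' @export
segment_cycles <- function(trial, side) {
  assert_side(side)
  strikes <- strike_times(trial$events, side)
  if (length(strikes) < 2)
    stop("need at least 2 foot strikes on the ", side, " side", call. = FALSE)
  offs <- off_times(trial$events, side)
  cycles <- list()
  for (i in seq_len(length(strikes) - 1)) {
    t0 <- strikes[i]; t1 <- strikes[i + 1]
    inside <- offs[offs > t0 & offs < t1]
    if (length(inside) != 1) {
      warning(sprintf(
        "cycle %.3f-%.3f s on the %s side has %d interior foot offs; excluded",
        t0, t1, side, length(inside)), call. = FALSE)
      next
    }
    cycles[[length(cycles) + 1]] <- new_gait_cycle(trial, side, t0, t1)
  }
  if (!length(cycles))
    stop("no valid gait cycle on the ", side, " side", call. = FALSE)
  cycles
}

new_gait_cycle <- function(trial, side, t0, t1) {
  dur <- t1 - t0
  ev <- trial$events |>
    dplyr::filter(.data$time_s >= t0 - 1e-9, .data$time_s <= t1 + 1e-9) |>
    dplyr::mutate(pct = (.data$time_s - t0) / dur * 100)
  structure(
    list(anchor_side = side, start_time = t0, end_time = t1,
         events_pct = ev, trial = trial),
    class = "gait_cycle")
}

#' @export
print.gait_cycle <- function(x, ...) {
  cat(sprintf("<gait_cycle> %s side, %.3f-%.3f s (%.0f ms)\n",
              x$anchor_side, x$start_time, x$end_time,
              1000 * (x$end_time - x$start_time)))
  invisible(x)
}

#' Select the representative gait cycle
#'
#' Picks the recorded cycle closest to the ensemble mean: every cycle is time
#' normalised, then for each angle trajectory the RMS deviation from the
#' point-wise ensemble-mean curve is divided by that angle's ensemble
#' standard deviation (scale-free across angles; angles with ensemble SD
#' below 1e-9 are skipped), and the per-angle values are averaged. The cycle
#' with the minimal average wins; ties go to the earliest cycle, so the
#' choice is deterministic and permutation-invariant.
#'
#' @param cycles List of `gait_cycle` objects from [segment_cycles()].
#' @return The selected `gait_cycle`, with the distance table attached as
#'   attribute `"distances"`.
#' @export
select_representative_cycle <- function(cycles) {
  if (!length(cycles)) stop("no cycles to select from", call. = FALSE)
  ord <- order(vapply(cycles, `[[`, numeric(1), "start_time"))
  cycles <- cycles[ord]
  if (length(cycles) == 1) return(cycles[[1]])

  norm <- lapply(cycles, time_normalize)
  vals <- purrr::imap_dfr(norm, function(nc, i)
    dplyr::mutate(nc$values, cycle = i))
  dist <- vals |>
    dplyr::mutate(mu = mean(.data$value_deg),
                  .by = c("angle", "side", "pct")) |>
    dplyr::mutate(sd_angle = sqrt(mean((.data$value_deg - .data$mu)^2)),
                  .by = c("angle", "side")) |>
    dplyr::summarise(
      rms = sqrt(mean((.data$value_deg - .data$mu)^2)),
      sd_angle = .data$sd_angle[1],
      .by = c("angle", "side", "cycle")) |>
    dplyr::filter(.data$sd_angle >= 1e-9) |>
    dplyr::summarise(distance = mean(.data$rms / .data$sd_angle),
                     .by = "cycle") |>
    dplyr::arrange(.data$cycle)
  if (!nrow(dist)) {
    best <- 1L  # all cycles identical: earliest wins
  } else {
    best <- dist$cycle[which.min(dist$distance)]  # which.min: earliest on ties
  }
  structure(cycles[[best]], distances = dist)
}

#' Time normalise a gait cycle to the 101-point grid
#'
#' Resamples every angle trajectory of the cycle onto gait-cycle progress
#' 0, 1, ..., 100 % using the degree-5 interpolating B-spline
#' ([fit_spline()]); grid point 0 is the ipsilateral foot strike. Events are
#' re-expressed in percent of cycle. The fitted splines are retained so that
#' normalised angular velocities derive from the same interpolant.
#'
#' @param cycle A `gait_cycle` from [segment_cycles()].
#' @return An object of class `normalized_cycle` with elements `values`
#'   (tibble `angle`, `side`, `pct`, `value_deg`), `splines` (per-trajectory
#'   [fit_spline()] objects keyed `"<angle>|<side>"`), `events_pct`,
#'   `anchor_side`, `meta` and the source interval.
#' @export
time_normalize <- function(cycle) {
  stopifnot(inherits(cycle, "gait_cycle"))
  t0 <- cycle$start_time; t1 <- cycle$end_time
  dur <- t1 - t0
  grid <- cycle_grid()
  ang <- cycle$trial$angles
  keys <- paste(ang$angle, ang$side, sep = "|")
  idx <- split(seq_len(nrow(ang)), keys)
  splines <- list()
  acc <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    rows <- idx[[k]]
    ts <- ang$time_s[rows]; vs <- ang$value_deg[rows]
    if (ts[1] > t0 + 1e-9 || ts[length(ts)] < t1 - 1e-9)
      stop("trajectory ", names(idx)[k],
           " does not cover the cycle span", call. = FALSE)
    # pad two samples beyond each boundary so the grid end points are interior
    i0 <- max(1L, max(which(ts <= t0 + 1e-9)) - 2L)
    i1 <- min(length(ts), min(which(ts >= t1 - 1e-9)) + 2L)
    sp <- fit_spline((ts[i0:i1] - t0) / dur * 100, vs[i0:i1])
    splines[[names(idx)[k]]] <- sp
    gmin <- max(0, sp$range[1]); gmax <- min(100, sp$range[2])
    g <- grid[grid >= gmin - 1e-9 & grid <= gmax + 1e-9]
    acc[[k]] <- list(key = names(idx)[k], pct = g, val = eval_spline(sp, g))
  }
  ns <- vapply(acc, function(a) length(a$pct), integer(1))
  key_split <- strsplit(vapply(acc, `[[`, character(1), "key"), "|",
                        fixed = TRUE)
  values <- tibble::tibble(
    angle = rep(vapply(key_split, `[[`, character(1), 1), ns),
    side = rep(vapply(key_split, `[[`, character(1), 2), ns),
    pct = unlist(lapply(acc, `[[`, "pct")),
    value_deg = unlist(lapply(acc, `[[`, "val")))
  structure(
    list(values = values, splines = splines,
         events_pct = cycle$events_pct, anchor_side = cycle$anchor_side,
         start_time = t0, end_time = t1, meta = cycle$trial$meta),
    class = "normalized_cycle")
}

#' @export
print.normalized_cycle <- function(x, ...) {
  cat(sprintf(
    "<normalized_cycle> %s side anchor, %d trajectories on 0-100%% grid\n",
    x$anchor_side, length(x$splines)))
  invisible(x)
}

# ipsilateral foot off of a normalized cycle, in % of cycle
toe_off_pct <- function(ncycle, side = ncycle$anchor_side) {
  ev <- ncycle$events_pct
  off <- ev$pct[ev$side == side & ev$event == "off" &
                  ev$pct > 1e-9 & ev$pct < 100 - 1e-9]
  if (!length(off)) return(NA_real_)
  off[1]
}
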