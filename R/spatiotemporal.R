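#' Standard spatiotemporal gait parameters
#'
#' Computes the 14 standard parameters for one side from gait events and
#' foot-contact positions: gait speed (km/h), cadence (steps/min), stride /
#' step / stance / swing / single-support / double-support times (s), single
#' and double support durations (% of cycle), step and stride length and step
#' width (m), and the limp index (dimensionless).
#'
#' All quantities are evaluated on one ipsilateral gait cycle (strike to next
#' strike of `side`), selected by `anchor_time`. Within that cycle, single
#' support is the interval between contralateral foot off and contralateral
#' foot strike, and double support is the initial (loading) double-support
#' period from the ipsilateral strike to the contralateral foot off — with
#' this convention both sides' single supports plus both double supports sum
#' exactly to the stride time. The limp index is the ratio of ipsilateral to
#' contralateral stance time (`limp = "stance"`, the default) or of swing
#' times (`limp = "swing"`). Gait speed uses the mean progression velocity of
#' the pelvis-origin trajectory when one is supplied, otherwise stride
#' length / stride time.
#'
#' @param events Events tibble as in [gait_trial()] (columns `side`, `event`,
#'   `time_s`, `pos_prog_m`, `pos_lat_m`).
#' @param side Side the parameters describe.
#' @param anchor_time Start the cycle at the first ipsilateral strike at or
#'   after this time (default: first strike).
#' @param pelvis_origin Optional tibble `time_s`, `pos_prog_m`.
#' @param limp `"stance"` or `"swing"` time ratio.
#' @return Tibble with columns `feature` (grammar tail `std.<name>`) and
#'   `value`; 14 rows. Quantities that cannot be derived from the available
#'   events are `NA` (flagged absent, never silently zero).
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   side = rep(c("left", "right"), each = 4),
#'   event = rep(c("strike", "off", "strike", "off"), 2),
#'   time_s = c(0, .66, 1.1, 1.76, .55, 1.21, 1.65, 2.31),
#'   pos_prog_m = c(0, NA, 1.24, NA, .62, NA, 1.86, NA),
#'   pos_lat_m = c(.05, NA, .05, NA, -.05, NA, -.05, NA))
#' standard_parameters(ev, "left")
standard_parameters <- function(events, side, anchor_time = -Inf,
                                pelvis_origin = NULL,
                                limp = c("stance", "swing")) {
  assert_side(side)
  limp <- match.arg(limp)
  events <- validate_events(events)
  contra <- other_side(side)

  ipsi_str <- strike_times(events, side)
  ipsi_str <- ipsi_str[ipsi_str >= anchor_time - 1e-9]
  if (length(ipsi_str) < 2)
    stop("need two ipsilateral strikes from the anchor on the ", side,
         " side", call. = FALSE)
  t0 <- ipsi_str[1]; t1 <- ipsi_str[2]
  stride_time <- t1 - t0

  in_cycle <- function(x) x[x > t0 + 1e-9 & x < t1 - 1e-9]
  ipsi_off <- in_cycle(off_times(events, side))
  c_off <- in_cycle(off_times(events, contra))
  c_str <- in_cycle(strike_times(events, contra))
  one_or_na <- function(x) if (length(x) == 1) x else NA_real_
  ipsi_off <- one_or_na(ipsi_off)
  c_off <- one_or_na(c_off)
  c_str <- one_or_na(c_str)

  stance_time <- ipsi_off - t0
  swing_time <- t1 - ipsi_off
  step_time <- if (!is.na(c_str)) t1 - c_str else NA_real_
  single_support <- if (!is.na(c_off) && !is.na(c_str)) c_str - c_off
    else NA_real_
  double_support <- if (!is.na(c_off)) c_off - t0 else NA_real_
  if (!is.na(double_support) && double_support < -1e-9)
    stop("negative double-support time: inconsistent events", call. = FALSE)

  # contact geometry
  pos <- events |>
    dplyr::filter(.data$event == "strike")
  ipos <- pos |>
    dplyr::filter(.data$side == !!side,
                  abs(.data$time_s - t0) < 1e-9 | abs(.data$time_s - t1) < 1e-9)
  cpos <- pos |>
    dplyr::filter(.data$side == contra,
                  !is.na(c_str), abs(.data$time_s - c_str) < 1e-9)
  stride_length <- if (nrow(ipos) == 2 && !anyNA(ipos$pos_prog_m))
    diff(ipos$pos_prog_m) else NA_real_
  step_length <- if (nrow(ipos) == 2 && nrow(cpos) == 1 &&
                     !is.na(ipos$pos_prog_m[2]) && !is.na(cpos$pos_prog_m))
    ipos$pos_prog_m[2] - cpos$pos_prog_m else NA_real_
  # mean absolute lateral offset between consecutive opposite-side contacts
  allpos <- pos |> dplyr::filter(!is.na(.data$pos_lat_m))
  step_width <- NA_real_
  if (nrow(allpos) >= 2) {
    sw <- abs(diff(allpos$pos_lat_m))
    alt <- allpos$side[-1] != allpos$side[-nrow(allpos)]
    if (any(alt)) step_width <- mean(sw[alt])
  }

  speed <- NA_real_
  if (!is.null(pelvis_origin) && nrow(pelvis_origin) >= 2) {
    po <- pelvis_origin[pelvis_origin$time_s >= t0 - 1e-9 &
                          pelvis_origin$time_s <= t1 + 1e-9, ]
    if (nrow(po) >= 2)
      speed <- (po$pos_prog_m[nrow(po)] - po$pos_prog_m[1]) /
        (po$time_s[nrow(po)] - po$time_s[1]) * 3.6
  }
  if (is.na(speed) && !is.na(stride_length))
    speed <- stride_length / stride_time * 3.6

  # contralateral stance/swing from its own cycle (anchored at the
  # contralateral strike inside this cycle) for the limp index
  c_stance <- c_swing <- NA_real_
  if (!is.na(c_str)) {
    c_off_next <- off_times(events, contra)
    c_off_next <- c_off_next[c_off_next > c_str + 1e-9]
    c_str_next <- strike_times(events, contra)
    c_str_next <- c_str_next[c_str_next > c_str + 1e-9]
    if (length(c_off_next)) {
      c_stance <- c_off_next[1] - c_str
      if (length(c_str_next)) c_swing <- c_str_next[1] - c_off_next[1]
    }
  }
  limp_index <- if (limp == "stance") stance_time / c_stance
    else swing_time / c_swing

  tibble::tibble(
    feature = paste0("std.", standard_parameter_names()),
    value = c(speed,
              if (!is.na(step_time)) 60 / step_time else NA_real_,
              stride_time, step_time, stance_time, swing_time,
              single_support, double_support,
              single_support / stride_time * 100,
              double_support / stride_time * 100,
              step_length, stride_length, step_width, limp_index))
}
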