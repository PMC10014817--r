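#' Functional phase intervals of the gait cycle
#'
#' Computes the nine functional phases — stance, swing and the seven Perry
#' phases (loading response, mid stance, terminal stance, pre-swing, initial,
#' mid and terminal swing) — as intervals in percent of cycle. Boundaries are
#' anchored on events where available: loading response ends at contralateral
#' foot off; terminal stance ends at contralateral foot strike; pre-swing
#' ends at ipsilateral foot off (toe-off); the mid-stance/terminal-stance
#' boundary is the midpoint between contralateral foot off and strike (no
#' heel-rise event exists in the data model); swing is split into equal
#' thirds. When contralateral events are missing and `fallback = TRUE`, the
#' textbook percentages in `normative_boundaries` are used for the stance
#' phases instead.
#'
#' Intervals are half-open `[start, end)`; the final interval closes at 100.
#' Stance phases tile stance, swing phases tile swing, and stance + swing
#' tile the full cycle exactly.
#'
#' @param toe_off_pct Ipsilateral foot off, in percent of cycle
#'   (strictly inside (0, 100)).
#' @param contra_off_pct,contra_strike_pct Contralateral foot off and strike
#'   in percent of cycle, or `NA` to trigger the fallback.
#' @param fallback Use normative stance boundaries when contralateral events
#'   are absent (default `TRUE`).
#' @param normative_boundaries The normative stance-phase boundaries in
#'   percent of cycle at the textbook 60 % toe-off (ends of loading response,
#'   mid stance and terminal stance); default `c(10, 30, 50)`, rescaled
#'   proportionally to the actual toe-off, with pre-swing always ending at
#'   toe-off.
#' @return Tibble of class `phase_intervals` with columns `phase`, `start`,
#'   `end` (percent of cycle), nine rows.
#' @export
#' @examples
#' compute_phase_intervals(60)                # normative fallback
#' compute_phase_intervals(62, 12, 50)        # event-anchored
compute_phase_intervals <- function(toe_off_pct,
                                    contra_off_pct = NA,
                                    contra_strike_pct = NA,
                                    fallback = TRUE,
                                    normative_boundaries = c(10, 30, 50)) {
  if (is.na(toe_off_pct) || toe_off_pct <= 0 || toe_off_pct >= 100)
    stop("ipsilateral foot off must lie strictly inside (0, 100)%",
         call. = FALSE)
  have_contra <- !is.na(contra_off_pct) && !is.na(contra_strike_pct) &&
    contra_off_pct > 0 && contra_strike_pct > contra_off_pct &&
    contra_strike_pct < toe_off_pct
  if (!have_contra && !fallback)
    stop("contralateral events missing or inconsistent and fallback disabled",
         call. = FALSE)
  if (have_contra) {
    b1 <- contra_off_pct                       # end of loading response
    b3 <- contra_strike_pct                    # end of terminal stance
    b2 <- (b1 + b3) / 2                        # mid/terminal stance split
  } else {
    # normative boundaries assume the textbook 60% toe-off; rescale the
    # stance phases proportionally so they tile any actual stance duration
    scale <- toe_off_pct / 60
    b1 <- normative_boundaries[1] * scale
    b2 <- normative_boundaries[2] * scale
    b3 <- normative_boundaries[3] * scale
  }
  to <- toe_off_pct
  sw <- (100 - to) / 3
  out <- tibble::tibble(
    phase = c("stance", "swing", "loading_response", "mid_stance",
              "terminal_stance", "pre_swing", "initial_swing", "mid_swing",
              "terminal_swing"),
    start = c(0, to, 0, b1, b2, b3, to, to + sw, to + 2 * sw),
    end = c(to, 100, b1, b2, b3, to, to + sw, to + 2 * sw, 100))
  if (any(out$end < out$start))
    stop("inconsistent phase boundaries (events out of order)", call. = FALSE)
  class(out) <- c("phase_intervals", class(out))
  out
}

#' Phase intervals of a normalised cycle
#'
#' Convenience wrapper reading the ipsilateral and contralateral events off a
#' [time_normalize()]d cycle and delegating to [compute_phase_intervals()].
#'
#' @param ncycle A `normalized_cycle`.
#' @param side Side whose phases are wanted (default the anchor side).
#' @inheritParams compute_phase_intervals
#' @return A `phase_intervals` tibble.
#' @export
cycle_phase_intervals <- function(ncycle, side = ncycle$anchor_side,
                                  fallback = TRUE) {
  ev <- ncycle$events_pct
  contra <- other_side(side)
  if (side == ncycle$anchor_side) {
    to <- toe_off_pct(ncycle, side)
    coff <- interior_event(ev, contra, "off")
    cstr <- interior_event(ev, contra, "strike")
  } else {
    # phases of the contralateral limb within the anchored cycle: its own
    # cycle runs strike-to-strike, which the anchored window does not cover;
    # derive toe-off from its stance seen in the window when possible
    stop("phase intervals are defined on a cycle anchored on the same side; ",
         "normalise a cycle anchored on '", side, "' instead", call. = FALSE)
  }
  compute_phase_intervals(to, coff, cstr, fallback = fallback)
}

interior_event <- function(events_pct, side, what) {
  p <- events_pct$pct[events_pct$side == side & events_pct$event == what &
                        events_pct$pct > 1e-9 & events_pct$pct < 100 - 1e-9]
  if (!length(p)) NA_real_ else p[1]
}

#' The 16 phase parameters
#'
#' Start (% of cycle) of swing and of the six Perry phases whose start is not
#' fixed at 0 (all but loading response), plus duration (% of cycle) of
#' stance, swing and all seven Perry phases.
#'
#' @param intervals A `phase_intervals` tibble from
#'   [compute_phase_intervals()].
#' @return Tibble with columns `feature` (grammar tail,
#'   `phase.<name>.<start|duration>`) and `value`, 16 rows.
#' @export
phase_parameter_features <- function(intervals) {
  stopifnot(inherits(intervals, "phase_intervals"))
  iv <- tibble::as_tibble(intervals)
  starts <- iv |>
    dplyr::filter(!.data$phase %in% c("stance", "loading_response")) |>
    dplyr::transmute(
      feature = paste0("phase.", .data$phase, ".start"),
      value = .data$start)
  durs <- iv |>
    dplyr::transmute(
      feature = paste0("phase.", .data$phase, ".duration"),
      value = .data$end - .data$start)
  dplyr::bind_rows(starts, durs)
}
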