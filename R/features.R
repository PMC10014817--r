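#' The 18 movement characteristics of one angle
#'
#' Minimum, median and maximum of the angle and of its normalised angular
#' velocity over the stance phase, the swing phase and the whole gait cycle:
#' 2 signals x 3 phases x 3 statistics = 18 values. Statistics are taken over
#' the grid samples falling in each (half-open) phase interval; medians are
#' sample medians.
#'
#' @param angle_values Angle values on the 101-point grid (degrees).
#' @param nav_values NAV values on the same grid (degrees/%).
#' @param phases Either a `phase_intervals` tibble
#'   ([compute_phase_intervals()]) or a list with logical `stance` and
#'   `swing` masks of length 101 (used for the contralateral limb, whose
#'   stance is split across the anchored window).
#' @return Tibble with columns `feature` (`<signal>.<phase>.<stat>`) and
#'   `value`, 18 rows.
#' @export
movement_characteristics <- function(angle_values, nav_values, phases) {
  grid <- cycle_grid()
  stopifnot(length(angle_values) == length(grid),
            length(nav_values) == length(grid))
  if (inherits(phases, "phase_intervals")) {
    to <- phases$end[phases$phase == "stance"]
    masks <- list(stance = grid < to, swing = grid >= to)
  } else {
    masks <- phases
  }
  masks$cycle <- rep(TRUE, length(grid))
  rows <- list()
  for (ph in c("stance", "swing", "cycle")) {
    m <- masks[[ph]]
    for (sig in c("angle", "nav")) {
      v <- if (sig == "angle") angle_values else nav_values
      if (is.null(m) || !any(m, na.rm = TRUE)) {
        if (ph == "cycle")
          stop("phase contains no grid sample", call. = FALSE)
        val <- c(NA_real_, NA_real_, NA_real_)
      } else if (sum(m) < 1) {
        stop("phase contains no grid sample", call. = FALSE)
      } else {
        x <- v[m]
        val <- c(min(x), stats::median(x), max(x))
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        feature = paste(sig, ph, c("min", "median", "max"), sep = "."),
        value = val)
    }
  }
  out <- dplyr::bind_rows(rows)
  # canonical order: signal, then phase, then stat
  key <- feature_grammar()[1:18]
  key <- sub("^affected\\.mc\\.[^.]+\\.", "", key)
  out[match(key, out$feature), ]
}

#' Extract the full 744-feature description of a trial
#'
#' Runs the complete pipeline on one trial: segments the gait cycles on the
#' affected side, selects the representative cycle, time normalises it, and
#' extracts per side (affected / contralateral relabelling applied) the 14
#' standard spatiotemporal parameters, the 16 phase parameters and the
#' 19 x 18 movement characteristics — 372 features per side, 744 in total.
#' All values derive from the single affected-side-anchored representative
#' cycle; contralateral-limb trajectories are read from the same window and
#' contralateral event-based parameters anchor on the contralateral strike
#' inside it.
#'
#' Features whose source angle or event is missing are returned as `NA`
#' (explicitly absent, never silently zero); the result always has all 744
#' rows in canonical grammar order.
#'
#' @param trial A [gait_trial()] object.
#' @param cycle Optionally, a pre-selected `gait_cycle` (default: automatic
#'   representative-cycle selection).
#' @param fallback Use normative Perry boundaries when contralateral events
#'   are missing (see [compute_phase_intervals()]).
#' @return Tibble of class `feature_vector` with columns `feature`, `value`
#'   (744 rows) and attributes `subject_id`, `pain_subscore`, `score_target`.
#' @export
#' @examples
#' \donttest{
#' trial <- generate_trial(seed = 1)
#' fv <- extract_features(trial)
#' sum(!is.na(fv$value))
#' }
extract_features <- function(trial, cycle = NULL, fallback = TRUE) {
  stopifnot(inherits(trial, "gait_trial"))
  aff <- trial$meta$affected_side
  con <- other_side(aff)
  if (is.null(cycle)) {
    cycle <- select_representative_cycle(segment_cycles(trial, aff))
  }
  nc <- time_normalize(cycle)
  grid <- cycle_grid()

  # --- affected side: event-anchored Perry intervals ---------------------
  to_a <- toe_off_pct(nc, aff)
  coff <- interior_event(nc$events_pct, con, "off")
  cstr <- interior_event(nc$events_pct, con, "strike")
  iv_a <- compute_phase_intervals(to_a, coff, cstr, fallback = fallback)

  # --- contralateral side: its own cycle, anchored inside the window -----
  iv_c <- NULL
  c_anchor <- NA_real_
  if (!is.na(cstr)) {
    c_anchor <- nc$start_time + cstr / 100 * (nc$end_time - nc$start_time)
    c_next <- strike_times(trial$events, con)
    c_next <- c_next[c_next > c_anchor + 1e-9]
    if (length(c_next)) {
      cdur <- c_next[1] - c_anchor
      pct_of <- function(t) (t - c_anchor) / cdur * 100
      in01 <- function(p) p[p > 1e-9 & p < 100 - 1e-9][1] %|na|% NA_real_
      to_c <- in01(pct_of(off_times(trial$events, con)))
      aoff <- in01(pct_of(off_times(trial$events, aff)))
      astr <- in01(pct_of(strike_times(trial$events, aff)))
      if (!is.na(to_c))
        iv_c <- tryCatch(
          compute_phase_intervals(to_c, aoff, astr, fallback = fallback),
          error = function(e) NULL)
    }
  }

  # contralateral stance/swing membership on the anchored grid
  masks_c <- if (!is.na(coff) && !is.na(cstr)) {
    list(stance = grid < coff | grid >= cstr,
         swing = grid >= coff & grid < cstr)
  } else NULL

  mc_side <- function(physical, label, phases) {
    purrr::map_dfr(canonical_angles(), function(a) {
      key <- paste(a, physical, sep = "|")
      sp <- nc$splines[[key]]
      if (is.null(sp) || is.null(phases)) {
        val <- rep(NA_real_, 18)
        mc <- tibble::tibble(
          feature = sub("^affected\\.mc\\.[^.]+\\.", "",
                        feature_grammar()[1:18]),
          value = val)
      } else {
        av <- nc$values$value_deg[nc$values$angle == a &
                                    nc$values$side == physical]
        nv <- eval_spline(sp, grid, deriv = 1L)
        mc <- movement_characteristics(av, nv, phases)
      }
      dplyr::mutate(mc,
                    feature = paste(label, "mc", a, .data$feature, sep = "."))
    })
  }

  phase_side <- function(label, iv) {
    if (is.null(iv)) {
      tibble::tibble(
        feature = paste(label, "phase", phase_feature_names(), sep = "."),
        value = NA_real_)
    } else {
      phase_parameter_features(iv) |>
        dplyr::mutate(feature = paste(label, .data$feature, sep = "."))
    }
  }

  std_side <- function(physical, label, anchor) {
    std <- tryCatch(
      standard_parameters(trial$events, physical, anchor_time = anchor,
                          pelvis_origin = trial$pelvis_origin),
      error = function(e) tibble::tibble(
        feature = paste0("std.", standard_parameter_names()),
        value = NA_real_))
    dplyr::mutate(std, feature = paste(label, .data$feature, sep = "."))
  }

  feats <- dplyr::bind_rows(
    std_side(aff, "affected", nc$start_time),
    phase_side("affected", iv_a),
    mc_side(aff, "affected", iv_a),
    std_side(con, "contralateral",
             if (is.na(c_anchor)) nc$start_time else c_anchor),
    phase_side("contralateral", iv_c),
    mc_side(con, "contralateral", masks_c))

  out <- tibble::tibble(feature = feature_grammar()) |>
    dplyr::left_join(feats, by = "feature")
  attr(out, "subject_id") <- trial$meta$subject_id
  attr(out, "pain_subscore") <- trial$meta$pain_subscore
  attr(out, "score_target") <- trial$meta$score_target
  class(out) <- c("feature_vector", class(out))
  out
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
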