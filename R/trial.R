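#' Trial metadata
#'
#' Per-subject information carried alongside the recorded trajectories:
#' which limb was surgically treated, the patient-reported pain item of the
#' target clinical score, and walking-aid use.
#'
#' @param subject_id Character scalar.
#' @param affected_side `"left"` or `"right"`.
#' @param pain_subscore Points of the clinical score's pain item
#'   (Harris Hip Score: 0--44; Knee Society knee score: 0--50). Must be >= 0.
#' @param score_target `"HHS"` or `"KSS_ks"`.
#' @param walking_aid `"none"`, `"one_side"` or `"both_sides"`.
#' @return A list of class `trial_meta`.
#' @export
trial_meta <- function(subject_id, affected_side,
                       pain_subscore = 0,
                       score_target = c("HHS", "KSS_ks"),
                       walking_aid = c("none", "one_side", "both_sides")) {
  assert_side(affected_side)
  score_target <- match.arg(score_target)
  walking_aid <- match.arg(walking_aid)
  if (!is.numeric(pain_subscore) || length(pain_subscore) != 1 ||
      is.na(pain_subscore) || pain_subscore < 0)
    stop("`pain_subscore` must be a single non-negative number", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id), affected_side = affected_side,
         pain_subscore = as.numeric(pain_subscore),
         score_target = score_target, walking_aid = walking_aid),
    class = "trial_meta")
}

#' Assemble a gait trial
#'
#' Bundles joint-angle trajectories, gait events and metadata (plus optional
#' segment orientations and a pelvis-origin trajectory) into the unit that
#' the extraction pipeline consumes, and validates the pieces against each
#' other.
#'
#' @param meta A [trial_meta()] object.
#' @param angles Tibble with columns `angle`, `side`, `time_s`, `value_deg`;
#'   one row per sample. `angle` must use canonical names
#'   (see [angle_inventory()]); times strictly increasing within each
#'   trajectory.
#' @param events Tibble with columns `side`, `event` (`"strike"`/`"off"`),
#'   `time_s` and, for strikes, `pos_prog_m`, `pos_lat_m` (lab-frame contact
#'   position in metres; may be `NA` if positions are unavailable).
#' @param orientations Optional tibble with columns `segment`, `side`,
#'   `time_s`, `qw`, `qx`, `qy`, `qz` (scalar-first unit quaternions).
#'   Hemisphere alignment (consecutive dot products >= 0) is applied here.
#' @param pelvis_origin Optional tibble `time_s`, `pos_prog_m`, `pos_lat_m`.
#' @return A list of class `gait_trial`.
#' @export
gait_trial <- function(meta, angles, events,
                       orientations = NULL, pelvis_origin = NULL) {
  stopifnot(inherits(meta, "trial_meta"))
  angles <- validate_angles(angles)
  events <- validate_events(events)
  if (!is.null(orientations)) orientations <- validate_orientations(orientations)
  trial <- structure(
    list(meta = meta, angles = angles, events = events,
         orientations = orientations, pelvis_origin = pelvis_origin),
    class = "gait_trial")
  check_trial_span(trial)
  trial
}

validate_angles <- function(angles) {
  angles <- tibble::as_tibble(angles)
  need <- c("angle", "side", "time_s", "value_deg")
  if (!all(need %in% names(angles)))
    stop("`angles` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(angles$angle), canonical_angles())
  if (length(bad))
    stop("unknown angle name(s): ", paste(bad, collapse = ", "),
         "; see angle_inventory()", call. = FALSE)
  stopifnot(all(angles$side %in% c("left", "right")))
  ok <- angles |>
    dplyr::summarise(
      n = dplyr::n(),
      mono = all(diff(.data$time_s) > 0),
      fin = all(is.finite(.data$value_deg)),
      .by = c("angle", "side"))
  if (any(ok$n < 2))
    stop("every angle trajectory needs at least 2 samples", call. = FALSE)
  if (!all(ok$mono))
    stop("non-monotonic time in angle trajectory ",
         paste(ok$angle[!ok$mono], ok$side[!ok$mono], collapse = "; "),
         call. = FALSE)
  if (!all(ok$fin)) stop("non-finite angle values", call. = FALSE)
  angles
}

validate_events <- function(events) {
  events <- tibble::as_tibble(events)
  need <- c("side", "event", "time_s")
  if (!all(need %in% names(events)))
    stop("`events` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  stopifnot(all(events$side %in% c("left", "right")),
            all(events$event %in% c("strike", "off")))
  if (!"pos_prog_m" %in% names(events)) events$pos_prog_m <- NA_real_
  if (!"pos_lat_m" %in% names(events)) events$pos_lat_m <- NA_real_
  # two consecutive foot offs on one side cannot occur (a strike must lie
  # between them); a *missing* off, by contrast, is tolerated here and the
  # affected cycle is flagged and excluded during segmentation
  dbl_off <- events |>
    dplyr::arrange(.data$time_s) |>
    dplyr::summarise(
      bad = any(rle(.data$event)$lengths[rle(.data$event)$values == "off"] > 1),
      .by = "side")
  if (any(dbl_off$bad))
    stop("consecutive foot offs without an intervening strike", call. = FALSE)
  dplyr::arrange(events, .data$time_s)
}

validate_orientations <- function(orientations) {
  orientations <- tibble::as_tibble(orientations)
  need <- c("segment", "side", "time_s", "qw", "qx", "qy", "qz")
  if (!all(need %in% names(orientations)))
    stop("`orientations` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  q <- as.matrix(orientations[, c("qw", "qx", "qy", "qz")])
  nrm <- sqrt(rowSums(q^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("orientation quaternions must have unit norm (within 1e-6)",
         call. = FALSE)
  orientations |>
    dplyr::group_by(.data$segment, .data$side) |>
    dplyr::group_modify(~ hemisphere_align(.x)) |>
    dplyr::ungroup()
}

# flip signs so consecutive quaternions have non-negative dot product,
# removing the double-cover ambiguity before splining
hemisphere_align <- function(df) {
  q <- as.matrix(df[, c("qw", "qx", "qy", "qz")])
  if (nrow(q) > 1) {
    for (i in 2:nrow(q))
      if (sum(q[i, ] * q[i - 1, ]) < 0) q[i, ] <- -q[i, ]
  }
  df[, c("qw", "qx", "qy", "qz")] <- as.data.frame(q)
  df
}

check_trial_span <- function(trial) {
  spans <- trial$angles |>
    dplyr::summarise(t0 = min(.data$time_s), t1 = max(.data$time_s),
                     .by = c("angle", "side"))
  for (s in unique(trial$events$side)) {
    st <- strike_times(trial$events, s)
    if (length(st) >= 2) {
      if (any(spans$t0 > st[1] + 1e-9) || any(spans$t1 < st[2] - 1e-9))
        stop("trajectories must cover at least one full gait cycle per side",
             call. = FALSE)
    }
  }
  invisible(trial)
}

strike_times <- function(events, side) {
  sort(events$time_s[events$side == side & events$event == "strike"])
}

off_times <- function(events, side) {
  sort(events$time_s[events$side == side & events$event == "off"])
}

#' @export
print.gait_trial <- function(x, ...) {
  n_tr <- nrow(dplyr::distinct(x$angles, .data$angle, .data$side))
  cat("<gait_trial> subject", x$meta$subject_id,
      "| affected:", x$meta$affected_side,
      "| target:", x$meta$score_target, "\n")
  cat("  ", n_tr, " angle trajectories, ",
      nrow(x$events), " events, span ",
      sprintf("%.2f-%.2f s", min(x$angles$time_s), max(x$angles$time_s)),
      "\n", sep = "")
  invisible(x)
}
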