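#' Read a gait trial from disk
#'
#' Reads the package's plain-text trial dialect: a wide angle CSV
#' (`time_s` plus `<angle>_<side>` columns, degrees), a JSON events file
#' (per-side `foot_strikes` objects with `t`, `pos_prog_m`, `pos_lat_m`
#' and `foot_offs` with `t`) and a JSON metadata file mirroring
#' [trial_meta()]. An optional orientation CSV (`time_s`,
#' `<segment>_<side>_q{w,x,y,z}` columns) is read when present.
#'
#' @param trial_dir Directory containing `angles.csv`, `events.json`,
#'   `meta.json` and optionally `orientations.csv`, `pelvis_origin.csv`;
#'   alternatively pass the three file paths explicitly.
#' @param angle_file,events_file,meta_file Explicit file paths (override
#'   `trial_dir`).
#' @return A [gait_trial()] object.
#' @export
read_trial <- function(trial_dir = NULL, angle_file = NULL,
                       events_file = NULL, meta_file = NULL) {
  pick <- function(given, name) {
    if (!is.null(given)) return(given)
    if (is.null(trial_dir)) stop("supply `trial_dir` or explicit file paths",
                                 call. = FALSE)
    file.path(trial_dir, name)
  }
  angle_file <- pick(angle_file, "angles.csv")
  events_file <- pick(events_file, "events.json")
  meta_file <- pick(meta_file, "meta.json")

  m <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  meta <- trial_meta(m$subject_id, m$affected_side, m$pain_subscore,
                     m$score_target, m$walking_aid)

  wide <- readr::read_csv(angle_file, show_col_types = FALSE,
                          progress = FALSE)
  if (names(wide)[1] != "time_s")
    stop("angle file must declare its time column as `time_s` (seconds)",
         call. = FALSE)
  angles <- wide |>
    tidyr::pivot_longer(-"time_s", names_to = "key", values_to = "value_deg") |>
    tidyr::separate_wider_regex(
      "key", c(angle = ".*", "_", side = "left|right")) |>
    dplyr::filter(!is.na(.data$value_deg)) |>
    dplyr::select("angle", "side", "time_s", "value_deg") |>
    dplyr::arrange(.data$angle, .data$side, .data$time_s)

  ev <- jsonlite::read_json(events_file, simplifyVector = TRUE)
  events <- purrr::map_dfr(c("left", "right"), function(s) {
    es <- ev[[s]]
    if (is.null(es)) return(NULL)
    fs <- tibble::as_tibble(es$foot_strikes)
    dplyr::bind_rows(
      tibble::tibble(side = s, event = "strike", time_s = fs$t,
                     pos_prog_m = fs$pos_prog_m %||% NA_real_,
                     pos_lat_m = fs$pos_lat_m %||% NA_real_),
      tibble::tibble(side = s, event = "off",
                     time_s = as.numeric(unlist(es$foot_offs))))
  })

  orientations <- NULL
  ofile <- if (!is.null(trial_dir)) file.path(trial_dir, "orientations.csv")
  if (!is.null(ofile) && file.exists(ofile)) {
    ow <- readr::read_csv(ofile, show_col_types = FALSE, progress = FALSE)
    orientations <- ow |>
      tidyr::pivot_longer(-"time_s", names_to = "key", values_to = "q") |>
      tidyr::separate_wider_regex(
        "key", c(segment = ".*", "_", side = "left|right", "_",
                 comp = "q[wxyz]")) |>
      tidyr::pivot_wider(names_from = "comp", values_from = "q")
  }

  pelvis_origin <- NULL
  pfile <- if (!is.null(trial_dir)) file.path(trial_dir, "pelvis_origin.csv")
  if (!is.null(pfile) && file.exists(pfile))
    pelvis_origin <- readr::read_csv(pfile, show_col_types = FALSE,
                                     progress = FALSE)

  gait_trial(meta, angles, events, orientations, pelvis_origin)
}

#' Write a gait trial to disk
#'
#' Inverse of [read_trial()]; the round trip is lossless to the declared
#' precision (times and angles are written with full double precision and
#' re-read to within 1e-12; columns in canonical alphabetical order).
#'
#' @param trial A [gait_trial()] object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide <- trial$angles |>
    tidyr::unite("key", "angle", "side") |>
    tidyr::pivot_wider(names_from = "key", values_from = "value_deg") |>
    dplyr::arrange(.data$time_s)
  wide <- wide[, c("time_s", sort(setdiff(names(wide), "time_s")))]
  readr::write_csv(wide, file.path(dir, "angles.csv"))

  ev <- lapply(c(left = "left", right = "right"), function(s) {
    str <- trial$events |>
      dplyr::filter(.data$side == s, .data$event == "strike")
    list(
      foot_strikes = purrr::pmap(
        list(str$time_s, str$pos_prog_m, str$pos_lat_m),
        function(t, p, l) list(t = t, pos_prog_m = p, pos_lat_m = l)),
      foot_offs = off_times(trial$events, s))
  })
  jsonlite::write_json(ev, file.path(dir, "events.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  jsonlite::write_json(unclass(trial$meta), file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)

  if (!is.null(trial$orientations)) {
    ow <- trial$orientations |>
      tidyr::pivot_longer(c("qw", "qx", "qy", "qz"),
                          names_to = "comp", values_to = "q") |>
      tidyr::unite("key", "segment", "side", "comp") |>
      tidyr::pivot_wider(names_from = "key", values_from = "q")
    readr::write_csv(ow, file.path(dir, "orientations.csv"))
  }
  if (!is.null(trial$pelvis_origin))
    readr::write_csv(trial$pelvis_origin, file.path(dir, "pelvis_origin.csv"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
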