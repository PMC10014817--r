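#' Canonical physiological angles
#'
#' The 19 joint and segment angles of the full-body gait model, each recorded
#' for the left and the right side. Names follow the pattern
#' `<segment-or-joint>_<motion>`; they are the building blocks of the
#' movement-characteristic feature names (see [feature_grammar]).
#'
#' @return A tibble with columns `angle` (canonical name) and `segment`
#'   (parent segment or joint).
#' @export
#' @examples
#' angle_inventory()
angle_inventory <- function() {
  tibble::tribble(
    ~angle, ~segment,
    "pelvis_tilt", "pelvis",
    "pelvis_obliquity", "pelvis",
    "pelvis_rotation", "pelvis",
    "hip_flexion_extension", "hip",
    "hip_adduction_abduction", "hip",
    "knee_flexion_extension", "knee",
    "ankle_dorsiflexion_plantarflexion", "ankle",
    "ankle_rotation", "ankle",
    "foot_progression", "foot",
    "thorax_tilt", "thorax",
    "thorax_side_tilt", "thorax",
    "thorax_rotation", "thorax",
    "shoulder_flexion_extension", "shoulder",
    "shoulder_adduction_abduction", "shoulder",
    "shoulder_rotation", "shoulder",
    "elbow_flexion_extension", "elbow",
    "forearm_pronation_supination", "forearm",
    "wrist_dorsi_plantarflexion", "wrist",
    "wrist_deviation", "wrist"
  )
}

canonical_angles <- function() angle_inventory()$angle

#' Feature-name grammar
#'
#' Every extracted feature is named `"<side>.<block>.<rest>"` with
#' `side` one of `affected`/`contralateral` and three blocks:
#'
#' * `mc.<angle>.<signal>.<phase>.<stat>` — movement characteristics;
#'   `signal` is `angle` (degrees) or `nav` (normalised angular velocity,
#'   degrees per percent of gait cycle); `phase` is `stance`, `swing` or
#'   `cycle`; `stat` is `min`, `median` or `max`.
#' * `phase.<phase>.<start|duration>` — gait-phase parameters in % of cycle.
#' * `std.<parameter>` — the 14 standard spatiotemporal parameters.
#'
#' `feature_grammar()` enumerates the complete 744-name universe
#' (372 per side).
#'
#' @return Character vector of the 744 canonical feature names,
#'   affected side first.
#' @export
#' @examples
#' length(feature_grammar())  # 744
feature_grammar <- function() {
  unlist(lapply(c("affected", "contralateral"), side_feature_names),
         use.names = FALSE)
}

side_feature_names <- function(side) {
  mc <- as.vector(t(outer(
    canonical_angles(),
    as.vector(t(outer(
      c("angle", "nav"),
      as.vector(t(outer(c("stance", "swing", "cycle"),
                        c("min", "median", "max"), paste, sep = "."))),
      paste, sep = "."))),
    paste, sep = ".")))
  c(paste(side, "mc", mc, sep = "."),
    paste(side, "phase", phase_feature_names(), sep = "."),
    paste(side, "std", standard_parameter_names(), sep = "."))
}

# 7 starts (swing + 6 Perry phases; loading response and stance start at 0
# by definition and are omitted) + 9 durations = 16 parameters.
phase_feature_names <- function() {
  starts <- c("swing", "mid_stance", "terminal_stance", "pre_swing",
              "initial_swing", "mid_swing", "terminal_swing")
  durs <- c("stance", "swing", "loading_response", "mid_stance",
            "terminal_stance", "pre_swing", "initial_swing", "mid_swing",
            "terminal_swing")
  c(paste(starts, "start", sep = "."), paste(durs, "duration", sep = "."))
}

standard_parameter_names <- function() {
  c("gait_speed", "cadence", "stride_time", "step_time", "stance_time",
    "swing_time", "single_support_time", "double_support_time",
    "single_support_duration", "double_support_duration",
    "step_length", "stride_length", "step_width", "limp_index")
}

other_side <- function(side) {
  switch(side, left = "right", right = "left",
         affected = "contralateral", contralateral = "affected",
         stop("unknown side: ", side))
}

assert_side <- function(side) {
  if (!is.character(side) || length(side) != 1 || !side %in% c("left", "right"))
    stop("`side` must be \"left\" or \"right\"", call. = FALSE)
  side
}
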