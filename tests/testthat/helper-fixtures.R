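# A minimal hand-built trial: one angle per side, `n_cycles` one-second
# cycles, toe-off at `toe_pct`, contralateral strike at 50 %, foot contacts
# 0.62 m apart. The angle is a pure sinusoid of the cycle fraction.
make_simple_trial <- function(n_cycles = 2, toe_pct = 60, rate = 100,
                              amp = 30, affected = "left") {
  t <- seq(0, n_cycles, by = 1 / rate)
  angles <- dplyr::bind_rows(
    tibble::tibble(angle = "knee_flexion_extension", side = "left",
                   time_s = t, value_deg = amp * sin(2 * pi * t)),
    tibble::tibble(angle = "knee_flexion_extension", side = "right",
                   time_s = t, value_deg = amp * sin(2 * pi * (t - 0.5))))
  k <- 0:n_cycles
  kk <- 0:(n_cycles - 1)
  events <- dplyr::bind_rows(
    tibble::tibble(side = "left", event = "strike", time_s = k,
                   pos_prog_m = k * 1.24, pos_lat_m = 0.05),
    tibble::tibble(side = "left", event = "off",
                   time_s = k + toe_pct / 100,
                   pos_prog_m = NA_real_, pos_lat_m = NA_real_),
    tibble::tibble(side = "right", event = "strike", time_s = k + 0.5,
                   pos_prog_m = (k + 0.5) * 1.24, pos_lat_m = -0.05),
    tibble::tibble(side = "right", event = "off",
                   time_s = k + toe_pct / 100 - 0.5,
                   pos_prog_m = NA_real_, pos_lat_m = NA_real_))
  gait_trial(trial_meta("T1", affected), angles, events)
}

# Swap left and right everywhere (angles, events, lateral sign, metadata):
# the physical gait is unchanged, only the labelling is mirrored.
mirror_trial <- function(trial) {
  swap <- function(s) ifelse(s == "left", "right", "left")
  angles <- dplyr::mutate(trial$angles, side = swap(side))
  events <- dplyr::mutate(trial$events, side = swap(side),
                          pos_lat_m = -pos_lat_m)
  meta <- trial$meta
  meta <- trial_meta(meta$subject_id, swap(meta$affected_side),
                     meta$pain_subscore, meta$score_target, meta$walking_aid)
  gait_trial(meta, angles, events, trial$orientations, trial$pelvis_origin)
}
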