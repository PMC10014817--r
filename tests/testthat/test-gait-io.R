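test_that("trial validation rejects malformed inputs", {
  tr <- make_simple_trial()
  expect_s3_class(tr, "gait_trial")

  bad_angles <- dplyr::mutate(tr$angles, angle = "knee_bend")
  expect_error(gait_trial(tr$meta, bad_angles, tr$events), "unknown angle")

  rev_time <- dplyr::mutate(tr$angles,
                            time_s = ifelse(dplyr::row_number() == 5,
                                            time_s[4], time_s))
  expect_error(gait_trial(tr$meta, rev_time, tr$events), "non-monotonic")

  expect_error(trial_meta("s", "front"), "left")
  expect_error(trial_meta("s", "left", pain_subscore = -1), "non-negative")
})

test_that("quaternions are hemisphere-aligned on ingestion", {
  th <- seq(0, pi / 2, length.out = 11)
  q <- cbind(cos(th / 2), 0, 0, sin(th / 2))
  q[c(3, 7), ] <- -q[c(3, 7), ]   # double-cover sign flips
  ori <- tibble::tibble(segment = "thigh", side = "left",
                        time_s = seq(0, 1, length.out = 11),
                        qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4])
  tr <- make_simple_trial()
  tr2 <- gait_trial(tr$meta, tr$angles, tr$events, orientations = ori)
  qa <- as.matrix(tr2$orientations[, c("qw", "qx", "qy", "qz")])
  dots <- rowSums(qa[-1, ] * qa[-nrow(qa), ])
  expect_true(all(dots >= 0))
})

test_that("write/read round trip is lossless", {
  dir <- withr::local_tempdir()
  tr <- generate_trial(seed = 7, n_cycles = 2,
                       pathology = pathology_params(0.4, 0.5))
  write_trial(tr, dir)
  tr2 <- read_trial(dir)
  expect_equal(tr2$meta, tr$meta)
  expect_equal(
    dplyr::arrange(tr2$angles, angle, side, time_s),
    dplyr::arrange(tr$angles, angle, side, time_s),
    tolerance = 1e-12)
  ev1 <- dplyr::arrange(tr$events, side, event, time_s)
  ev2 <- dplyr::arrange(tr2$events, side, event, time_s)
  expect_equal(ev2, ev1, tolerance = 1e-12)
  # second round trip preserves the canonical column order and the values
  dir2 <- withr::local_tempdir()
  write_trial(tr2, dir2)
  h1 <- readLines(file.path(dir, "angles.csv"), n = 1)
  h2 <- readLines(file.path(dir2, "angles.csv"), n = 1)
  expect_identical(h1, h2)
  tr3 <- read_trial(dir2)
  expect_equal(tr3$angles, tr2$angles, tolerance = 1e-12)
})

test_that("read_trial names the missing angle for a score's predictors", {
  dir <- withr::local_tempdir()
  tr <- make_simple_trial()
  write_trial(tr, dir)
  fv <- extract_features(read_trial(dir))
  m <- packaged_models()$HHS
  res <- resolve_predictors(m, fv)
  expect_true(any(!res$found))
  expect_error(score(fv, m), "hip_flexion_extension")
})

test_that("segmentation yields n-1 cycles that tile the strike interval", {
  tr2 <- make_simple_trial(n_cycles = 2)
  expect_length(segment_cycles(tr2, "left"), 2)

  tr4 <- make_simple_trial(n_cycles = 4)
  cyc <- segment_cycles(tr4, "left")
  expect_length(cyc, 4)
  starts <- vapply(cyc, `[[`, numeric(1), "start_time")
  ends <- vapply(cyc, `[[`, numeric(1), "end_time")
  expect_equal(starts[-1], ends[-length(ends)])   # no gaps, no overlap
  expect_equal(c(starts[1], ends[length(ends)]),
               range(strikes <- tr4$events$time_s[
                 tr4$events$side == "left" & tr4$events$event == "strike"]))

  one_strike <- dplyr::filter(tr2$events,
                              side == "right" | time_s <= 0.9)
  tr_bad <- gait_trial(tr2$meta, tr2$angles, one_strike)
  expect_error(segment_cycles(tr_bad, "left"), "at least 2 foot strikes")
})

test_that("within-cycle foot offs land at the right percent of cycle", {
  t <- seq(0, 2.2, by = 0.01)
  angles <- tibble::tibble(angle = "knee_flexion_extension", side = "left",
                           time_s = t, value_deg = sin(t))
  events <- dplyr::bind_rows(
    tibble::tibble(side = "left", event = "strike",
                   time_s = c(0, 1.0, 2.1),
                   pos_prog_m = NA_real_, pos_lat_m = NA_real_),
    tibble::tibble(side = "left", event = "off", time_s = c(0.6, 1.62),
                   pos_prog_m = NA_real_, pos_lat_m = NA_real_))
  tr <- gait_trial(trial_meta("s", "left"), angles, events)
  cyc <- segment_cycles(tr, "left")
  expect_length(cyc, 2)
  expect_equal(cyc[[1]]$start_time, 0)
  expect_equal(cyc[[1]]$end_time, 1.0)
  off1 <- cyc[[1]]$events_pct
  expect_equal(off1$pct[off1$event == "off" & off1$pct > 0 & off1$pct < 100],
               60)
  off2 <- cyc[[2]]$events_pct
  expect_equal(off2$pct[off2$event == "off" & off2$pct > 0 & off2$pct < 100],
               (1.62 - 1.0) / 1.1 * 100)
})

test_that("cycles without an interior foot off are excluded with a warning", {
  tr <- make_simple_trial(n_cycles = 3)
  ev <- dplyr::filter(tr$events,
                      !(side == "left" & event == "off" &
                          abs(time_s - 1.6) < 1e-9))
  tr2 <- gait_trial(tr$meta, tr$angles, ev)
  expect_warning(cyc <- segment_cycles(tr2, "left"), "excluded")
  expect_length(cyc, 2)
})

test_that("representative-cycle selection picks the ensemble-mean cycle", {
  # three cycles: deviations -d, 0, +d around a base curve; cycle 2 is the
  # point-wise ensemble mean and must win (brute-force distance oracle)
  rate <- 100
  t <- seq(0, 3, by = 1 / rate)
  cycle_idx <- pmin(floor(t), 2)
  u <- t - floor(t)
  dev <- c(-1, 0, 1)[cycle_idx + 1]
  v <- 20 * sin(2 * pi * u) + dev * (3 + sin(4 * pi * u))
  angles <- tibble::tibble(angle = "knee_flexion_extension", side = "left",
                           time_s = t, value_deg = v)
  k <- 0:3
  events <- dplyr::bind_rows(
    tibble::tibble(side = "left", event = "strike", time_s = k,
                   pos_prog_m = NA_real_, pos_lat_m = NA_real_),
    tibble::tibble(side = "left", event = "off", time_s = k[-4] + 0.6,
                   pos_prog_m = NA_real_, pos_lat_m = NA_real_))
  tr <- gait_trial(trial_meta("s", "left"), angles, events)
  cyc <- segment_cycles(tr, "left")
  best <- select_representative_cycle(cyc)
  expect_equal(best$start_time, 1)

  # brute-force check of the documented distance
  norm <- lapply(cyc, time_normalize)
  mat <- sapply(norm, function(nc) nc$values$value_deg)
  mu <- rowMeans(mat)
  sd_angle <- sqrt(mean(rowMeans((mat - mu)^2)))
  d <- apply(mat, 2, function(col) sqrt(mean((col - mu)^2))) / sd_angle
  expect_equal(attr(best, "distances")$distance, d, tolerance = 1e-12)

  # single cycle -> itself; identical cycles -> earliest
  expect_identical(select_representative_cycle(cyc[2]), cyc[[2]])
  tr_id <- make_simple_trial(n_cycles = 3)
  cyc_id <- segment_cycles(tr_id, "left")
  expect_equal(select_representative_cycle(cyc_id)$start_time, 0)
  # permutation invariance
  expect_equal(select_representative_cycle(rev(cyc))$start_time, 1)
  expect_error(select_representative_cycle(list()), "no cycles")
})

test_that("time normalisation reproduces constants, lines and sines", {
  rate <- 100
  t <- seq(0, 1.3, by = 1 / rate)
  mk <- function(vals) {
    angles <- tibble::tibble(angle = "pelvis_tilt", side = "left",
                             time_s = t, value_deg = vals)
    events <- dplyr::bind_rows(
      tibble::tibble(side = "left", event = "strike", time_s = c(0.1, 1.2),
                     pos_prog_m = NA_real_, pos_lat_m = NA_real_),
      tibble::tibble(side = "left", event = "off", time_s = 0.76,
                     pos_prog_m = NA_real_, pos_lat_m = NA_real_))
    tr <- gait_trial(trial_meta("s", "left"), angles, events)
    time_normalize(segment_cycles(tr, "left")[[1]])
  }
  nc <- mk(rep(10, length(t)))
  expect_length(nc$values$value_deg, 101)
  expect_equal(nc$values$value_deg, rep(10, 101), tolerance = 1e-9)
  expect_equal(nc$values$pct, 0:100)

  nc_lin <- mk(5 + 2 * t)
  expect_equal(nc_lin$values$value_deg,
               5 + 2 * (0.1 + (0:100) / 100 * 1.1), tolerance = 1e-9)

  nc_sin <- mk(30 * sin(2 * pi * t / 1.1))
  expect_lt(max(abs(nc_sin$values$value_deg -
                      30 * sin(2 * pi * (0.1 + (0:100) / 100 * 1.1) / 1.1))),
            1e-3)
  # toe-off mapped to % of cycle
  expect_equal(toe_off_pct <- (0.76 - 0.1) / 1.1 * 100,
               nc$events_pct$pct[nc$events_pct$event == "off"])
})
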