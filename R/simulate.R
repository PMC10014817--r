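#' Synthetic gait template
#'
#' A smooth periodic reference gait: each of the 19 canonical angles is a
#' truncated Fourier series (mean + up to 4 harmonics) over the 0--100 %
#' cycle, plus an event template (toe-off at 60 %, contralateral strike at
#' 50 %, hence contralateral foot off at 10 %) and nominal stride parameters
#' (1.1 s, 1.24 m). The knee flexion/extension curve uses the classic
#' double-bump shape (stance flexion wave plus a ~60 degree swing peak),
#' obtained by projecting a two-bump reference curve onto the first four
#' harmonics; the remaining angles are low-amplitude sinusoids with
#' physiologically plausible means. Curves are C-infinity and periodic, so
#' the cycle ends match exactly.
#'
#' @param stride_time_s Nominal stride time (default 1.1 s).
#' @param stride_length_m Nominal stride length (default 1.24 m).
#' @param step_width_m Nominal step width (default 0.10 m).
#' @param toe_off_pct Ipsilateral toe-off (default 60 % of cycle).
#' @param contra_strike_pct Contralateral strike (default 50 %).
#' @return List of class `gait_template` with elements `fourier` (tibble
#'   `angle`, `a0`, `ac1..ac4`, `as1..as4`), and the event/stride scalars.
#' @export
gait_template <- function(stride_time_s = 1.1, stride_length_m = 1.24,
                          step_width_m = 0.10, toe_off_pct = 60,
                          contra_strike_pct = 50) {
  stopifnot(toe_off_pct > 40, toe_off_pct < 75)
  sinus <- function(angle, a0 = 0, ac1 = 0, as1 = 0, ac2 = 0, as2 = 0)
    tibble::tibble(angle = angle, a0 = a0, ac1 = ac1, ac2 = ac2, ac3 = 0,
                   ac4 = 0, as1 = as1, as2 = as2, as3 = 0, as4 = 0)
  # knee double bump: project a smooth two-bump reference onto 4 harmonics
  u <- seq(0, 1, length.out = 512)[-512]
  knee_ref <- 3 + 18 * exp(-((u - 0.15) / 0.09)^2) +
    60 * exp(-((u - 0.72) / 0.10)^2)
  proj <- function(f, k, fun) 2 * mean(f * fun(2 * pi * k * u))
  knee <- tibble::tibble(
    angle = "knee_flexion_extension", a0 = mean(knee_ref),
    ac1 = proj(knee_ref, 1, cos), ac2 = proj(knee_ref, 2, cos),
    ac3 = proj(knee_ref, 3, cos), ac4 = proj(knee_ref, 4, cos),
    as1 = proj(knee_ref, 1, sin), as2 = proj(knee_ref, 2, sin),
    as3 = proj(knee_ref, 3, sin), as4 = proj(knee_ref, 4, sin))
  fourier <- dplyr::bind_rows(
    sinus("pelvis_tilt", a0 = 10, ac2 = 1.5),
    sinus("pelvis_obliquity", as2 = 3, ac1 = 1),
    sinus("pelvis_rotation", as1 = 5),
    sinus("hip_flexion_extension", a0 = 10, ac1 = 18, as1 = 5),
    sinus("hip_adduction_abduction", ac1 = 3, as1 = 3, ac2 = 2),
    knee,
    sinus("ankle_dorsiflexion_plantarflexion", ac1 = -3, as1 = 5, ac2 = -4),
    sinus("ankle_rotation", as1 = 2, ac1 = 1),
    sinus("foot_progression", a0 = -7, as1 = 2, ac2 = 1),
    sinus("thorax_tilt", a0 = 5, ac2 = 1, as1 = 0.5),
    sinus("thorax_side_tilt", as1 = 2, ac2 = 0.5),
    sinus("thorax_rotation", as1 = 4, ac1 = 1),
    sinus("shoulder_flexion_extension", a0 = -5, as1 = 8, ac1 = 2),
    sinus("shoulder_adduction_abduction", a0 = 5, as1 = 2, ac2 = 0.5),
    sinus("shoulder_rotation", as1 = 3, ac1 = 1),
    sinus("elbow_flexion_extension", a0 = 25, as1 = 8, ac1 = 3),
    sinus("forearm_pronation_supination", a0 = 10, as1 = 3, ac2 = 1),
    sinus("wrist_dorsi_plantarflexion", a0 = -5, as1 = 4, ac1 = 1),
    sinus("wrist_deviation", a0 = 2, as1 = 3, ac2 = 0.5))
  stopifnot(setequal(fourier$angle, canonical_angles()))
  structure(
    list(fourier = fourier, stride_time_s = stride_time_s,
         stride_length_m = stride_length_m, step_width_m = step_width_m,
         toe_off_pct = toe_off_pct, contra_strike_pct = contra_strike_pct),
    class = "gait_template")
}

# evaluate a template angle at cycle fractions u (recycled mod 1)
template_curve <- function(template, angle, u) {
  co <- template$fourier[template$fourier$angle == angle, ]
  if (!nrow(co)) stop("template has no angle ", angle, call. = FALSE)
  u <- u %% 1
  val <- co$a0
  for (k in 1:4)
    val <- val + co[[paste0("ac", k)]] * cos(2 * pi * k * u) +
      co[[paste0("as", k)]] * sin(2 * pi * k * u)
  val
}

#' Pathology perturbation parameters
#'
#' Emulates post-arthroplasty gait impairment: reduced range of motion,
#' slower and shorter strides, and left/right asymmetry (shortened stance on
#' the affected limb). `severity = 0` reproduces the template exactly;
#' `asymmetry` in \[0, 1\] moves the impairment from symmetric (0) to fully
#' one-sided timing asymmetry (1).
#'
#' @param severity Overall impairment in \[0, 1\].
#' @param asymmetry Affected-vs-contralateral imbalance in \[0, 1\]
#'   (default 0.5).
#' @param rom_loss Fractional range-of-motion loss at severity 1
#'   (default 0.35).
#' @param stride_time_inflation Fractional stride-time increase at severity 1
#'   (default 0.3).
#' @param stride_length_loss Fractional stride-length decrease at severity 1
#'   (default 0.25).
#' @return List of class `pathology_params`.
#' @export
pathology_params <- function(severity = 0, asymmetry = 0.5, rom_loss = 0.35,
                             stride_time_inflation = 0.3,
                             stride_length_loss = 0.25) {
  stopifnot(severity >= 0, severity <= 1, asymmetry >= 0, asymmetry <= 1)
  structure(
    list(severity = severity, asymmetry = asymmetry, rom_loss = rom_loss,
         stride_time_inflation = stride_time_inflation,
         stride_length_loss = stride_length_loss),
    class = "pathology_params")
}

#' Generate a synthetic gait trial
#'
#' Samples all 19 angles x 2 sides at `sample_rate` over `n_cycles` gait
#' cycles, with events (including contact positions consistent with the
#' stride parameters) and smooth correlated noise (white noise convolved with
#' a 50 ms Gaussian kernel, so spline derivatives stay realistic). With
#' `severity = 0` and `noise_sd_deg = 0` the sampled curves reproduce the
#' template exactly.
#'
#' @param template A [gait_template()].
#' @param pathology A [pathology_params()].
#' @param noise_sd_deg Standard deviation of the smooth angle noise
#'   (degrees; default 0.3).
#' @param n_cycles Number of full cycles on the affected side (>= 2;
#'   default 5).
#' @param sample_rate Sampling rate in Hz (default 100, a typical optical
#'   motion-capture rate).
#' @param affected_side,subject_id,pain_subscore,score_target,walking_aid
#'   Metadata passed to [trial_meta()].
#' @param seed Optional integer seed (local to this call).
#' @return A [gait_trial()] object.
#' @export
generate_trial <- function(template = gait_template(),
                           pathology = pathology_params(),
                           noise_sd_deg = 0.3, n_cycles = 5,
                           sample_rate = 100,
                           affected_side = "left", subject_id = "synthetic",
                           pain_subscore = 0, score_target = "HHS",
                           walking_aid = "none", seed = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(seed, generate_trial(
      template, pathology, noise_sd_deg, n_cycles, sample_rate,
      affected_side, subject_id, pain_subscore, score_target, walking_aid)))
  stopifnot(n_cycles >= 2)
  sev <- pathology$severity; asym <- pathology$asymmetry
  T_s <- template$stride_time_s * (1 + pathology$stride_time_inflation * sev)
  L_m <- template$stride_length_m * (1 - pathology$stride_length_loss * sev)
  w_m <- template$step_width_m * (1 + 0.5 * sev)
  to_aff <- template$toe_off_pct - 4 * sev * asym     # antalgic: shorter stance
  to_con <- template$toe_off_pct + 3 * sev * asym
  phi <- template$contra_strike_pct / 100 + 0.03 * sev * asym
  c_off_frac <- to_con / 100 + phi - 1                # contralateral foot off
  stopifnot(c_off_frac > 0, c_off_frac < to_aff / 100)
  aff <- affected_side
  con <- other_side(aff)
  rom <- c(1 - pathology$rom_loss * sev,
           1 - pathology$rom_loss * sev * (1 - asym))
  names(rom) <- c(aff, con)

  # ---- events ------------------------------------------------------------
  # one extra contralateral cycle so the contralateral limb has a complete
  # own cycle after the last affected strike (event-only; no trajectory need)
  k <- 0:n_cycles
  lat <- function(s) if (s == "left") w_m / 2 else -w_m / 2
  events <- dplyr::bind_rows(
    tibble::tibble(side = aff, event = "strike", time_s = (0:n_cycles) * T_s,
                   pos_prog_m = (0:n_cycles) * L_m, pos_lat_m = lat(aff)),
    tibble::tibble(side = aff, event = "off",
                   time_s = (0:n_cycles + to_aff / 100) * T_s,
                   pos_prog_m = NA_real_, pos_lat_m = NA_real_),
    tibble::tibble(side = con, event = "strike", time_s = (k + phi) * T_s,
                   pos_prog_m = (k + 0.5 + 0.04 * sev * asym) * L_m,
                   pos_lat_m = lat(con)),
    tibble::tibble(side = con, event = "off",
                   time_s = (k + c_off_frac) * T_s,
                   pos_prog_m = NA_real_, pos_lat_m = NA_real_))

  # ---- angle trajectories -------------------------------------------------
  t <- (0:(ceiling(n_cycles * T_s * sample_rate) + 2)) / sample_rate
  phase0 <- c(0, phi); names(phase0) <- c(aff, con)
  angles <- purrr::map_dfr(canonical_angles(), function(a) {
    purrr::map_dfr(c(aff, con), function(s) {
      base <- template_curve(template, a, t / T_s - phase0[[s]])
      a0 <- template$fourier$a0[template$fourier$angle == a]
      v <- a0 + rom[[s]] * (base - a0)
      if (noise_sd_deg > 0)
        v <- v + smooth_noise(length(t), noise_sd_deg, sample_rate)
      tibble::tibble(angle = a, side = s, time_s = t, value_deg = v)
    })
  })

  meta <- trial_meta(subject_id, aff, pain_subscore, score_target,
                     walking_aid)
  gait_trial(meta, angles, events)
}

# white noise convolved with a Gaussian kernel (sd 50 ms), unit-variance
# preserving, then scaled to `sd`
smooth_noise <- function(n, sd, sample_rate, kernel_sd_s = 0.05) {
  ks <- max(1, kernel_sd_s * sample_rate)
  half <- ceiling(4 * ks)
  kern <- stats::dnorm(-half:half, sd = ks)
  kern <- kern / sqrt(sum(kern^2))
  x <- stats::rnorm(n + 2 * half)
  y <- stats::filter(x, kern, sides = 2)
  sd * as.numeric(y[(half + 1):(half + n)])
}

#' Cohort specification for planted-model simulations
#'
#' @param n Number of subjects (>= 1).
#' @param coefficients Named numeric vector: planted linear coefficients on
#'   canonical feature names.
#' @param intercept Planted intercept (score points, default 20).
#' @param noise_sd Score-noise standard deviation (points). Exactly one of
#'   `noise_sd` / `target_r2` must be given.
#' @param target_r2 Alternatively, the population R-squared of the planted
#'   gait signal; the noise SD is derived from the realised signal variance.
#' @param pain_max Pain subscores are drawn uniformly on 0..`pain_max`
#'   (default 40).
#' @param angle_noise_sd Per-trial smooth angle noise in degrees
#'   (default 0.3).
#' @param n_cycles,sample_rate Passed to [generate_trial()].
#' @param score_target `"HHS"` or `"KSS_ks"` (metadata only).
#' @param seed Integer seed governing all randomness of the cohort.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n, coefficients, intercept = 20, noise_sd = NULL,
                        target_r2 = NULL, pain_max = 40,
                        angle_noise_sd = 0.3, n_cycles = 4,
                        sample_rate = 100, score_target = "HHS", seed = 1L) {
  if (n < 1) stop("cohort needs at least one subject", call. = FALSE)
  if (is.null(names(coefficients)) || !all(nzchar(names(coefficients))))
    stop("`coefficients` must be a named numeric vector", call. = FALSE)
  bad <- setdiff(names(coefficients), feature_grammar())
  if (length(bad))
    stop("planted feature(s) outside the feature universe: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(noise_sd) == is.null(target_r2))
    stop("give exactly one of `noise_sd` or `target_r2`", call. = FALSE)
  structure(
    list(n = as.integer(n), coefficients = coefficients,
         intercept = intercept, noise_sd = noise_sd, target_r2 = target_r2,
         pain_max = pain_max, angle_noise_sd = angle_noise_sd,
         n_cycles = n_cycles, sample_rate = sample_rate,
         score_target = score_target, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Generate a cohort with a planted feature-to-score relationship
#'
#' Draws per-subject severities (uniform on 0.05--0.95), asymmetries
#' (0.2--0.8), sides and pain subscores; generates each subject's trial;
#' extracts features through the real pipeline
#' ([extract_features()]); and plants
#' `score = intercept + sum(beta * feature) + pain + Normal(0, sigma)`.
#' Everything is governed by `spec$seed`, so a fixed seed yields a
#' bit-identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `gait_cohort`: `features` (tibble, one row per
#'   subject, `subject_id` + 744 feature columns), `scores`, `pains`,
#'   `severities`, `noise_sd` (the realised sigma), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n
    sev <- stats::runif(n, 0.05, 0.95)
    asym <- stats::runif(n, 0.2, 0.8)
    side <- sample(c("left", "right"), n, replace = TRUE)
    pains <- round(stats::runif(n, 0, spec$pain_max))
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      trial <- generate_trial(
        pathology = pathology_params(sev[i], asym[i]),
        noise_sd_deg = spec$angle_noise_sd, n_cycles = spec$n_cycles,
        sample_rate = spec$sample_rate, affected_side = side[i],
        subject_id = sprintf("S%03d", i), pain_subscore = pains[i],
        score_target = spec$score_target)
      fv <- extract_features(trial)
      rows[[i]] <- stats::setNames(fv$value, fv$feature)
    }
    X <- tibble::as_tibble(do.call(rbind, rows))
    planted <- names(spec$coefficients)
    miss <- planted[vapply(planted, function(f) anyNA(X[[f]]), logical(1))]
    if (length(miss))
      stop("planted feature(s) absent from extraction: ",
           paste(miss, collapse = ", "), call. = FALSE)
    signal <- as.matrix(X[, planted]) %*% spec$coefficients
    sigma <- spec$noise_sd %||%
      sqrt(stats::var(drop(signal)) * (1 - spec$target_r2) / spec$target_r2)
    scores <- spec$intercept + drop(signal) + pains +
      stats::rnorm(n, 0, sigma)
    structure(
      list(features = dplyr::bind_cols(
             tibble::tibble(subject_id = sprintf("S%03d", seq_len(n))), X),
           scores = scores, pains = pains, severities = sev,
           noise_sd = sigma, spec = spec),
      class = "gait_cohort")
  })
}

#' Replant scores on an existing cohort's features
#'
#' Reuses a generated cohort's feature matrix and redraws only the score
#' noise (and optionally new coefficients), which makes repeated-seed
#' selection experiments cheap: the expensive kinematic simulation and
#' feature extraction are done once.
#'
#' @param cohort A `gait_cohort`.
#' @param coefficients,intercept,noise_sd,target_r2 As in [cohort_spec()];
#'   default to the cohort's own planted model.
#' @param seed Seed for the new noise draw.
#' @return The cohort with `scores` (and `noise_sd`) replaced.
#' @export
plant_scores <- function(cohort, coefficients = NULL, intercept = NULL,
                         noise_sd = NULL, target_r2 = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "gait_cohort"))
  coefficients <- coefficients %||% cohort$spec$coefficients
  intercept <- intercept %||% cohort$spec$intercept
  X <- cohort$features[, names(coefficients), drop = FALSE]
  signal <- as.matrix(X) %*% coefficients
  if (is.null(noise_sd) && is.null(target_r2)) {
    noise_sd <- cohort$spec$noise_sd
    target_r2 <- cohort$spec$target_r2
  }
  sigma <- if (!is.null(noise_sd)) noise_sd else if (target_r2 == 0) {
    stop("target_r2 must be > 0; use noise_sd for pure-noise scores",
         call. = FALSE)
  } else {
    sqrt(stats::var(drop(signal)) * (1 - target_r2) / target_r2)
  }
  cohort$scores <- drop(signal) + intercept + cohort$pains +
    withr::with_seed(seed, stats::rnorm(nrow(X), 0, sigma))
  cohort$noise_sd <- sigma
  cohort
}
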