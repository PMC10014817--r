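zero_vector <- function(model) {
  tibble::tibble(feature = model$predictors$feature, value = 0)
}

test_that("packaged models carry the published structure", {
  m <- packaged_models()
  expect_named(m, c("HHS", "KSS_ks"))
  expect_equal(nrow(m$HHS$predictors), 6)
  expect_equal(nrow(m$KSS_ks$predictors), 4)
  expect_equal(m$HHS$pain_coefficient, 1.0)
  expect_equal(m$KSS_ks$pain_coefficient, 1.0)
  expect_true(all(m$HHS$predictors$feature %in% feature_grammar()))
  expect_true(all(m$KSS_ks$predictors$feature %in% feature_grammar()))
  # scoring the zero vector returns the intercept
  expect_equal(score(zero_vector(m$HHS), m$HHS, 0)$raw, 25.786)
  expect_equal(score(zero_vector(m$KSS_ks), m$KSS_ks, 0)$raw, 39.680)
})

test_that("scores are linear with unit pain offset and additive breakdown", {
  m <- packaged_models()$HHS
  ones <- tibble::tibble(feature = m$predictors$feature, value = 1)
  s <- score(ones, m, pain_subscore = 10)
  expect_equal(s$raw, 25.786 + sum(m$predictors$coefficient) + 10)
  expect_equal(s$raw, 35.581, tolerance = 1e-9)   # hand summation
  expect_equal(sum(s$breakdown$contribution), s$raw, tolerance = 1e-9)

  # finite-difference slope equals the packaged coefficient, to 1e-12
  base <- withr::with_seed(5, tibble::tibble(
    feature = m$predictors$feature, value = rnorm(6)))
  s0 <- score(base, m, 3)$raw
  for (j in seq_len(6)) {
    pert <- base
    pert$value[j] <- pert$value[j] + 1
    expect_equal(score(pert, m, 3)$raw - s0, m$predictors$coefficient[j],
                 tolerance = 1e-12)
  }
  # pain linearity: score(v, pain + d) - score(v, pain) = d
  expect_equal(score(base, m, 7.5)$raw - s0, 4.5, tolerance = 1e-12)
})

test_that("score ignores non-predictor features and clamps with a warning", {
  m <- packaged_models()$KSS_ks
  full <- tibble::tibble(feature = feature_grammar(), value = 0)
  s0 <- score(full, m, 0)$raw
  jitter <- dplyr::mutate(full, value = ifelse(
    feature %in% m$predictors$feature, 0, 99))
  expect_equal(score(jitter, m, 0)$raw, s0)

  high <- dplyr::mutate(zero_vector(m), value = c(0, 0, 200, 0))  # +112 pts
  expect_warning(s <- score(high, m, 0), "clamped")
  expect_lte(s$score, 100)
  expect_gt(s$raw, 100)
  low <- dplyr::mutate(high, value = c(200, 0, 0, 0))  # big negative term
  expect_warning(sl <- score(low, m, 0), "clamped")
  expect_equal(sl$score, 0)
  expect_lt(sl$raw, 0)
})

test_that("missing predictors are reported by name; pain is validated", {
  m <- packaged_models()$HHS
  partial <- zero_vector(m)[-3, ]
  expect_error(score(partial, m, 0), "pelvis_tilt")
  expect_error(score(zero_vector(m), m, -2), "non-negative")
  expect_warning(score(zero_vector(m), m, 45), "pain item maximum")
  nonfin <- dplyr::mutate(zero_vector(m),
                          value = ifelse(dplyr::row_number() == 1, Inf, 0))
  expect_error(score(nonfin, m, 0), "non-finite")
})

test_that("packaged predictors need no head, trunk or upper-arm angles", {
  # a reduced body model (pelvis, hip, knee, foot, wrist) resolves both models
  reduced_angles <- c("pelvis_tilt", "pelvis_obliquity", "pelvis_rotation",
                      "hip_flexion_extension", "hip_adduction_abduction",
                      "knee_flexion_extension", "foot_progression",
                      "wrist_dorsi_plantarflexion", "wrist_deviation")
  keep <- feature_grammar()[
    !grepl("\\.mc\\.", feature_grammar()) |
      grepl(paste0("\\.mc\\.(", paste(reduced_angles, collapse = "|"),
                   ")\\."), feature_grammar())]
  fv <- tibble::tibble(feature = keep, value = 0)
  for (m in packaged_models()) {
    res <- resolve_predictors(m, fv)
    expect_true(all(res$found))
  }
  # dropping the wrist leaves exactly the wrist predictors unresolved
  m <- packaged_models()$HHS
  no_wrist <- tibble::tibble(
    feature = setdiff(keep, keep[grepl("wrist", keep)]), value = 0)
  res <- resolve_predictors(m, no_wrist)
  expect_identical(res$feature[!res$found],
                   res$feature[grepl("wrist", res$feature)])
})

test_that("scoring models round-trip through JSON", {
  m <- packaged_models()$KSS_ks
  path <- withr::local_tempfile(fileext = ".json")
  write_scoring_model(m, path)
  m2 <- read_scoring_model(path)
  expect_equal(m2$predictors$feature, m$predictors$feature)
  expect_equal(m2$predictors$coefficient, m$predictors$coefficient)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$pain_item_max, m$pain_item_max)
})
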