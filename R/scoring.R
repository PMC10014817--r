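#' The published instrumental scoring models
#'
#' Loads the two regression models shipped with the package: the instrumental
#' Harris Hip Score (6 gait-feature predictors) and the instrumental Knee
#' Society knee score (4 predictors). Each model is a linear combination of
#' named gait features plus an intercept, with the patient-reported pain item
#' added as a fixed offset (coefficient 1). Coefficient provenance (table row
#' and significance) is embedded in the packaged JSON files for auditability.
#'
#' @return Named list with elements `HHS` and `KSS_ks`, each a
#'   `scoring_model`.
#' @export
#' @examples
#' packaged_models()$HHS
packaged_models <- function() {
  dir <- system.file("extdata", "models", package = "gaitscore")
  list(HHS = read_scoring_model(file.path(dir, "hhs.json")),
       KSS_ks = read_scoring_model(file.path(dir, "kss_ks.json")))
}

#' Read a scoring model from JSON
#'
#' @param path JSON model file with fields `name`, `intercept`,
#'   `pain_coefficient`, `predictors` (objects with `feature`,
#'   `coefficient`), and optionally `pain_item_max`, `score_bounds`.
#' @return A `scoring_model` object.
#' @export
read_scoring_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_scoring_model(
    name = m$name,
    predictors = tibble::as_tibble(m$predictors),
    intercept = m$intercept,
    pain_coefficient = m$pain_coefficient %||% 1.0,
    pain_item_max = m$pain_item_max %||% Inf,
    score_bounds = m$score_bounds %||% c(0, 100))
}

#' Construct a scoring model
#'
#' @param name Model name (e.g. `"HHS"`).
#' @param predictors Tibble with columns `feature` (canonical grammar names)
#'   and `coefficient`.
#' @param intercept Intercept in score points.
#' @param pain_coefficient Weight of the pain offset (1 for the packaged
#'   models).
#' @param pain_item_max Upper end of the pain item's scale (for validation).
#' @param score_bounds Clamping bounds, default `c(0, 100)`.
#' @return A `scoring_model` object.
#' @export
new_scoring_model <- function(name, predictors, intercept,
                              pain_coefficient = 1.0, pain_item_max = Inf,
                              score_bounds = c(0, 100)) {
  predictors <- tibble::as_tibble(predictors)
  stopifnot(all(c("feature", "coefficient") %in% names(predictors)))
  unknown <- setdiff(predictors$feature, feature_grammar())
  if (length(unknown))
    stop("predictor name(s) outside the feature grammar: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(
    list(name = name, predictors = predictors,
         intercept = as.numeric(intercept),
         pain_coefficient = as.numeric(pain_coefficient),
         pain_item_max = pain_item_max,
         score_bounds = as.numeric(score_bounds)),
    class = "scoring_model")
}

#' Write a scoring model to JSON
#'
#' @param model A `scoring_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scoring_model <- function(model, path) {
  jsonlite::write_json(
    list(name = model$name, intercept = model$intercept,
         pain_coefficient = model$pain_coefficient,
         pain_item_max = model$pain_item_max,
         score_bounds = model$score_bounds,
         predictors = model$predictors),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.scoring_model <- function(x, ...) {
  cat("<scoring_model> ", x$name, ": ", nrow(x$predictors),
      " gait-feature predictors + pain offset (x",
      format(x$pain_coefficient), "), intercept ",
      format(x$intercept), "\n", sep = "")
  print(x$predictors[, c("feature", "coefficient")], n = Inf)
  invisible(x)
}

#' Evaluate an instrumental score
#'
#' Computes `intercept + sum(coefficient * feature) + pain_coefficient *
#' pain_subscore` and clamps the result to the model's score bounds
#' (with a warning — never silently).
#'
#' @param features A `feature_vector` from [extract_features()], or any
#'   tibble/data frame with columns `feature`, `value`, or a named numeric
#'   vector.
#' @param model A `scoring_model` (see [packaged_models()]).
#' @param pain_subscore Points on the clinical score's pain item; defaults to
#'   the value carried by the feature vector, else 0. Must be >= 0; values
#'   above the model's pain-item maximum produce a warning.
#' @return A list of class `instrumental_score`: `score` (clamped), `raw`,
#'   `breakdown` (per-term contributions summing to `raw`), `clamped`
#'   (logical), `model`, `subject_id`.
#' @export
#' @examples
#' m <- packaged_models()$HHS
#' fv <- tibble::tibble(feature = m$predictors$feature, value = 0)
#' score(fv, m, pain_subscore = 0)$raw   # the model intercept
score <- function(features, model, pain_subscore = NULL) {
  stopifnot(inherits(model, "scoring_model"))
  if (is.numeric(features) && !is.null(names(features)))
    features <- tibble::tibble(feature = names(features), value = features)
  if (is.null(pain_subscore))
    pain_subscore <- attr(features, "pain_subscore") %||% 0
  if (!is.numeric(pain_subscore) || length(pain_subscore) != 1 ||
      is.na(pain_subscore) || pain_subscore < 0)
    stop("`pain_subscore` must be a single non-negative number",
         call. = FALSE)
  if (pain_subscore > model$pain_item_max)
    warning("pain subscore ", pain_subscore, " exceeds the ", model$name,
            " pain item maximum (", model$pain_item_max, ")", call. = FALSE)

  res <- resolve_predictors(model, features)
  if (any(!res$found))
    stop("missing predictor feature(s) for ", model$name, ": ",
         paste(res$feature[!res$found], collapse = ", "), call. = FALSE)
  if (any(!is.finite(res$value)))
    stop("non-finite value for predictor(s): ",
         paste(res$feature[!is.finite(res$value)], collapse = ", "),
         call. = FALSE)

  breakdown <- tibble::tibble(
    term = c("(intercept)", res$feature, "pain"),
    value = c(NA, res$value, pain_subscore),
    coefficient = c(NA, res$coefficient, model$pain_coefficient),
    contribution = c(model$intercept, res$coefficient * res$value,
                     model$pain_coefficient * pain_subscore))
  raw <- sum(breakdown$contribution)
  lo <- model$score_bounds[1]; hi <- model$score_bounds[2]
  clamped <- raw < lo || raw > hi
  if (clamped)
    warning(sprintf("raw %s of %.2f outside [%g, %g]; clamped",
                    model$name, raw, lo, hi), call. = FALSE)
  structure(
    list(score = min(max(raw, lo), hi), raw = raw, breakdown = breakdown,
         clamped = clamped, model = model$name,
         subject_id = attr(features, "subject_id")),
    class = "instrumental_score")
}

#' @export
print.instrumental_score <- function(x, ...) {
  cat(sprintf("<instrumental_score> %s = %.2f points (raw %.2f%s)\n",
              x$model, x$score, x$raw,
              if (x$clamped) ", clamped" else ""))
  invisible(x)
}

#' Resolve a model's predictors against a feature vector
#'
#' Reports, per predictor, whether the feature is present and finite, its
#' value and its source angle and side — useful to check whether a reduced
#' body model (e.g. pelvis, hip, knee, foot and wrist sensors only) still
#' supports a model.
#'
#' @param model A `scoring_model`.
#' @param features As in [score()].
#' @return Tibble with columns `feature`, `coefficient`, `found`, `value`,
#'   `side`, `block`.
#' @export
resolve_predictors <- function(model, features) {
  if (is.numeric(features) && !is.null(names(features)))
    features <- tibble::tibble(feature = names(features), value = features)
  features <- tibble::as_tibble(features)[, c("feature", "value")]
  out <- model$predictors |>
    dplyr::left_join(features, by = "feature") |>
    dplyr::mutate(
      found = !is.na(.data$value),
      side = stringr::str_extract(.data$feature, "^[^.]+"),
      block = stringr::str_extract(.data$feature, "(?<=\\.)[^.]+"))
  out[, c("feature", "coefficient", "found", "value", "side", "block")]
}

#' @rdname score
#' @param x An `instrumental_score`.
#' @param ... Unused.
#' @method tidy instrumental_score
#' @export
tidy.instrumental_score <- function(x, ...) x$breakdown
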