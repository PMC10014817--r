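#' Seeded train/test split
#'
#' @param subjects Vector of subject identifiers (or any vector; rows of a
#'   cohort).
#' @param fraction Training fraction (default 0.7). Training size is
#'   `round(fraction * n)`.
#' @param seed Integer seed; the same seed always yields the same partition.
#' @return List with elements `train` and `test` (disjoint subsets of
#'   `subjects`, both non-empty).
#' @export
#' @examples
#' split_train_test(1:44, seed = 1)  # 31 train / 13 test
split_train_test <- function(subjects, fraction = 0.7, seed = 1L) {
  n <- length(subjects)
  if (n < 2) stop("need at least 2 subjects to split", call. = FALSE)
  stopifnot(fraction > 0, fraction < 1)
  n_train <- round(fraction * n)
  if (n_train < 1 || n_train >= n)
    stop("split leaves an empty train or test set (n = ", n, ", fraction = ",
         fraction, ")", call. = FALSE)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(train = subjects[sort(idx)], test = subjects[sort(setdiff(seq_len(n), idx))])
}

#' Maximum number of predictors for a sample size
#'
#' Two rules are shipped: `"cases_per_predictor"` (default), which allows one
#' predictor per `ratio` training cases (`floor(n_train / ratio)`, default
#' ratio 5), and the textbook rule `"tabachnick_50_8m"` requiring
#' `n >= 50 + 8m`, i.e. `floor((n_train - 50) / 8)` predictors. The
#' cases-per-predictor rule is the default because it is the one compatible
#' with small orthopaedic cohorts (the 50 + 8m rule allows no predictors at
#' all below 58 cases).
#'
#' @param n_train Number of training cases.
#' @param rule `"cases_per_predictor"` or `"tabachnick_50_8m"`.
#' @param ratio Cases per predictor for the default rule.
#' @return Integer >= 1.
#' @export
#' @examples
#' max_predictors(31)  # 6
max_predictors <- function(n_train,
                           rule = c("cases_per_predictor", "tabachnick_50_8m"),
                           ratio = 5) {
  rule <- match.arg(rule)
  m <- switch(rule,
              cases_per_predictor = floor(n_train / ratio),
              tabachnick_50_8m = floor((n_train - 50) / 8))
  if (m <= 0)
    stop("rule '", rule, "' allows no predictors at n_train = ", n_train,
         call. = FALSE)
  as.integer(m)
}

#' Default hierarchical stage grouping
#'
#' Orders the feature universe into the five stages of descending clinical
#' relevance used for instrumental-score building: (1) movement
#' characteristics of the score's own joint (hip for HHS, knee for KSS-ks),
#' (2) the other major joint, (3) pelvis and foot progression, (4) ankle,
#' thorax and arm features, (5) the gait parameters (standard + phase).
#'
#' @param score `"HHS"` or `"KSS_ks"`.
#' @param features Feature universe to partition (default the full grammar).
#' @return Named list of character vectors (the stages, in order); disjoint,
#'   union equal to `features`.
#' @export
stage_grouping <- function(score = c("HHS", "KSS_ks"),
                           features = feature_grammar()) {
  score <- match.arg(score)
  ang <- function(a) paste0("\\.mc\\.(", paste(a, collapse = "|"), ")\\.")
  hip <- c("hip_flexion_extension", "hip_adduction_abduction")
  knee <- "knee_flexion_extension"
  pelvis_foot <- c("pelvis_tilt", "pelvis_obliquity", "pelvis_rotation",
                   "foot_progression")
  distal <- c("ankle_dorsiflexion_plantarflexion", "ankle_rotation",
              "thorax_tilt", "thorax_side_tilt", "thorax_rotation",
              "shoulder_flexion_extension", "shoulder_adduction_abduction",
              "shoulder_rotation", "elbow_flexion_extension",
              "forearm_pronation_supination", "wrist_dorsi_plantarflexion",
              "wrist_deviation")
  first <- if (score == "HHS") hip else knee
  second <- if (score == "HHS") knee else hip
  grp <- list(
    score_joint = features[grepl(ang(first), features)],
    other_major_joint = features[grepl(ang(second), features)],
    pelvis_foot = features[grepl(ang(pelvis_foot), features)],
    ankle_thorax_arm = features[grepl(ang(distal), features)],
    gait_parameters = features[grepl("\\.(std|phase)\\.", features)])
  stopifnot(sum(lengths(grp)) == length(features))
  grp
}

#' Hierarchical stepwise regression
#'
#' Staged stepwise predictor selection: stages are opened in order; within
#' the pool of opened stages the procedure repeatedly enters the candidate
#' with the smallest partial-test p-value (the t test on its coefficient in
#' the augmented model) while `p < p_enter`, then removes — one at a time —
#' the retained predictor with the largest `p >= p_remove` (predictors from
#' earlier stages may be removed at later stages). Entry stops when
#' `max_predictors` is reached or the fit is numerically perfect. The final
#' model is the history entry with the best adjusted R-squared among those
#' with at most `max_predictors` predictors (ties: fewer predictors, then
#' earlier). Ties on entry p-values break by larger absolute t, then
#' lexicographic name, so the whole procedure is deterministic.
#'
#' Zero-variance columns are excluded up front; candidates whose residual
#' (after projection on the current model) has variance below `1e-9` of
#' their centred variance are skipped as collinear, with a warning.
#'
#' @param x Data frame / tibble or numeric matrix of candidate features
#'   (columns named).
#' @param y Numeric response. If pain offsets apply, pass `y - pain`: the
#'   pain item is excluded from selection and appended afterwards as a fixed
#'   offset (see [as_scoring_model()]).
#' @param grouping Named list of character vectors: the ordered stages
#'   (e.g. [stage_grouping()]). A single unnamed stage gives classical
#'   stepwise selection. Features of `x` not listed are never candidates.
#' @param p_enter,p_remove Entry / removal thresholds (defaults 0.05 / 0.10).
#' @param max_predictors Cap on the number of predictors (default
#'   [max_predictors()] of `nrow(x)`).
#' @return Object of class `stepwise_fit`: `selected`, `coefficients`
#'   (tibble with estimates, SE, t, p), `intercept`, `r_squared`,
#'   `adj_r_squared`, `history` (tibble: one row per accepted entry/removal),
#'   `fit` (the final `lm`), `n`.
#' @export
hierarchical_stepwise <- function(x, y, grouping,
                                  p_enter = 0.05, p_remove = 0.10,
                                  max_predictors = NULL) {
  stopifnot(p_enter > 0, p_enter <= p_remove, p_remove < 1)
  X <- as.matrix(as.data.frame(x))
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) stop("feature columns must be named", call. = FALSE)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (anyNA(X) || anyNA(y))
    stop("complete cases required: remove or impute missing values upstream",
         call. = FALSE)
  if (is.null(max_predictors)) max_predictors <- max_predictors(n)
  if (is.character(grouping)) grouping <- list(stage1 = grouping)
  if (is.null(names(grouping)) || any(names(grouping) == ""))
    names(grouping) <- paste0("stage", seq_along(grouping))

  # exclude zero-variance features up front
  v <- apply(X, 2, stats::var)
  usable <- colnames(X)[is.finite(v) & v > 1e-12]

  tss <- sum((y - mean(y))^2)
  selected <- character(0)
  history <- list()
  log_state <- function(action, feature, rss) {
    k <- length(selected)
    history[[length(history) + 1]] <<- tibble::tibble(
      step = length(history) + 1L, action = action, feature = feature,
      n_predictors = k,
      r_squared = 1 - rss / tss,
      adj_r_squared = 1 - (rss / (n - k - 1)) / (tss / (n - 1)),
      predictors = list(selected))
  }

  fit_current <- function() {
    M <- cbind(`(Intercept)` = 1, X[, selected, drop = FALSE])
    qr.default(M)
  }
  rss_of <- function(qrM) sum(qr.resid(qrM, y)^2)

  qrM <- fit_current()
  rss <- rss_of(qrM)
  log_state("start", NA_character_, rss)

  n_collinear <- 0L
  opened <- character(0)
  for (stage in names(grouping)) {
    opened <- union(opened, intersect(grouping[[stage]], usable))
    repeat {
      changed <- FALSE
      # ---- entry -------------------------------------------------------
      cand <- setdiff(opened, selected)
      df_res <- n - length(selected) - 2
      if (length(cand) && length(selected) < max_predictors &&
          rss / tss > 1e-12 && df_res >= 1) {
        Z <- X[, cand, drop = FALSE]
        U <- Z - qr.fitted(qrM, Z)
        s2 <- colSums(U^2)
        cz <- colSums(U * qr.resid(qrM, y))
        varz <- colSums(scale(Z, scale = FALSE)^2)
        ok <- s2 > 1e-9 * pmax(varz, 1e-300)
        n_collinear <- n_collinear + sum(!ok)
        if (any(ok)) {
          rss_new <- rss - cz^2 / s2
          rss_new <- pmax(rss_new, 0)
          tstat <- ifelse(ok & rss_new > 0,
                          (cz / sqrt(s2)) / sqrt(rss_new / df_res),
                          ifelse(ok, Inf * sign(cz), NA))
          p <- 2 * stats::pt(-abs(tstat), df_res)
          ord <- order(p, -abs(tstat), cand)
          bestj <- ord[1]
          if (is.finite(p[bestj]) && p[bestj] < p_enter && ok[bestj]) {
            selected <- c(selected, cand[bestj])
            qrM <- fit_current()
            rss <- rss_of(qrM)
            log_state("enter", cand[bestj], rss)
            changed <- TRUE
          }
        }
      }
      # ---- removal -----------------------------------------------------
      repeat {
        if (!length(selected)) break
        ct <- coef_table(qrM, X, selected, y)
        worst <- which.max(ct$p_value)
        if (ct$p_value[worst] >= p_remove) {
          gone <- ct$term[worst]
          selected <- setdiff(selected, gone)
          qrM <- fit_current()
          rss <- rss_of(qrM)
          log_state("remove", gone, rss)
          changed <- TRUE
        } else break
      }
      if (!changed) break
    }
  }

  if (n_collinear > 0)
    warning("skipped ", n_collinear,
            " (near-)collinear candidate evaluation(s) during entry steps",
            call. = FALSE)

  hist <- dplyr::bind_rows(history)
  eligible <- hist[hist$n_predictors <= max_predictors, ]
  best <- eligible[order(-eligible$adj_r_squared, eligible$n_predictors,
                         eligible$step), ][1, ]
  selected <- best$predictors[[1]]

  dat <- data.frame(.y = y, X[, selected, drop = FALSE], check.names = FALSE)
  fml <- stats::as.formula(paste(
    ".y ~", if (length(selected))
      paste0("`", selected, "`", collapse = " + ") else "1"))
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  coefs <- tibble::as_tibble(sm$coefficients, rownames = "term") |>
    stats::setNames(c("term", "estimate", "std_error", "statistic",
                      "p_value")) |>
    dplyr::mutate(term = gsub("`", "", .data$term))

  structure(
    list(selected = selected,
         coefficients = coefs[coefs$term != "(Intercept)", ],
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
         history = hist[, setdiff(names(hist), "predictors")],
         max_predictors = max_predictors,
         p_enter = p_enter, p_remove = p_remove,
         fit = fit, n = n),
    class = "stepwise_fit")
}

coef_table <- function(qrM, X, selected, y) {
  M <- cbind(`(Intercept)` = 1, X[, selected, drop = FALSE])
  fit <- stats::lm.fit(M, y)
  rss <- sum(fit$residuals^2)
  df <- length(y) - fit$rank
  R <- qr.R(qr.default(M))
  XtXinv <- chol2inv(R)  # (M'M)^-1, sign of R's diagonal is immaterial
  se <- sqrt(pmax(diag(XtXinv), 0) * rss / max(df, 1))
  tstat <- fit$coefficients / se
  p <- 2 * stats::pt(-abs(tstat), max(df, 1))
  tibble::tibble(term = colnames(M), estimate = fit$coefficients,
                 se = se, t = tstat, p_value = p)[-1, ]
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("<stepwise_fit> ", length(x$selected), " predictors selected from ",
      nrow(x$history) - 1, " steps; R2 = ", round(x$r_squared, 4),
      ", adj R2 = ", round(x$adj_r_squared, 4), "\n", sep = "")
  if (length(x$selected)) print(x$coefficients, n = Inf)
  invisible(x)
}

#' @rdname hierarchical_stepwise
#' @param x A `stepwise_fit`.
#' @param ... Unused.
#' @method tidy stepwise_fit
#' @export
tidy.stepwise_fit <- function(x, ...) x$coefficients

#' @rdname hierarchical_stepwise
#' @method glance stepwise_fit
#' @export
glance.stepwise_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
                 n = x$n, n_predictors = length(x$selected),
                 max_predictors = x$max_predictors)
}

#' Convert a stepwise fit into a scoring model
#'
#' Packages the selected predictors, coefficients and intercept as a
#' [new_scoring_model()], appending the patient-reported pain item as a fixed
#' offset with coefficient 1 (selection must have been run on
#' `score - pain`).
#'
#' @param fit A `stepwise_fit`.
#' @param name Model name.
#' @param pain_item_max Pain-item scale maximum for validation.
#' @return A `scoring_model`.
#' @export
as_scoring_model <- function(fit, name, pain_item_max = Inf) {
  new_scoring_model(
    name = name,
    predictors = tibble::tibble(feature = fit$coefficients$term,
                                coefficient = fit$coefficients$estimate),
    intercept = fit$intercept,
    pain_coefficient = 1.0, pain_item_max = pain_item_max)
}

#' k-fold cross-validation of a fixed predictor set
#'
#' Refits the linear model on each training fold and reports the held-out
#' R-squared per fold (`1 - SSE/SST`, SST about the held-out mean) and their
#' mean. Fold assignment is seeded and balanced (sizes differ by at most 1).
#' Held-out R-squared can be negative when the predictors carry no signal.
#'
#' @param x Feature data (as in [hierarchical_stepwise()]).
#' @param y Numeric response.
#' @param predictors Character vector of column names (a fixed set; typically
#'   `fit$selected`).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return Object of class `cv_report`: `folds` (tibble `fold`, `n_test`,
#'   `r_squared`), `mean_r_squared`, `assignment`.
#' @export
kfold_cv <- function(x, y, predictors, k = 10, seed = 1L) {
  X <- as.matrix(as.data.frame(x))[, predictors, drop = FALSE]
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(k >= 2, k <= n)
  fold <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  if (min(table(fold)) < 1 || (n - max(table(fold))) < length(predictors) + 2)
    stop("a fold leaves fewer than p + 2 training cases; use a smaller k",
         call. = FALSE)
  res <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- fold != f
    M <- cbind(1, X[tr, , drop = FALSE])
    beta <- stats::lm.fit(M, y[tr])$coefficients
    beta[is.na(beta)] <- 0
    pred <- cbind(1, X[!tr, , drop = FALSE]) %*% beta
    yt <- y[!tr]
    sst <- sum((yt - mean(yt))^2)
    tibble::tibble(fold = f, n_test = sum(!tr),
                   r_squared = 1 - sum((yt - pred)^2) / sst)
  })
  structure(list(folds = res, mean_r_squared = mean(res$r_squared),
                 assignment = fold, k = k, seed = seed,
                 predictors = predictors),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$k, "-fold CV, mean held-out R2 = ",
      round(x$mean_r_squared, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname kfold_cv
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$folds

#' @rdname kfold_cv
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(mean_r_squared = x$mean_r_squared, k = x$k, seed = x$seed)
}

#' Regression diagnostics
#'
#' Reports — without acting on them — the standard diagnostics for a fitted
#' model: variance-inflation factors per predictor (flagged above 10;
#' infinite under perfect collinearity), standardised residuals (|z| > 3
#' flagged as outliers), the Shapiro--Wilk test of residual normality and the
#' Breusch--Pagan test of homoscedasticity.
#'
#' @param fit A `stepwise_fit` or `lm` object.
#' @return List of class `regression_diagnostics`: `vif` (tibble `term`,
#'   `vif`, `flag`), `outliers` (tibble `case`, `std_residual`, `flag`),
#'   `shapiro` and `breusch_pagan` (tibbles `statistic`, `p_value`, `flag`
#'   at alpha = 0.05).
#' @export
diagnostics <- function(fit) {
  lmfit <- if (inherits(fit, "stepwise_fit")) fit$fit else fit
  stopifnot(inherits(lmfit, "lm"))
  X <- stats::model.matrix(lmfit)[, -1, drop = FALSE]

  vif <- purrr::map_dbl(seq_len(ncol(X)), function(j) {
    if (ncol(X) == 1) return(1)
    r <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])$residuals
    r2 <- 1 - sum(r^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  })
  vif_tbl <- tibble::tibble(term = colnames(X), vif = vif,
                            flag = !is.finite(vif) | vif > 10)

  z <- stats::rstandard(lmfit)
  out_tbl <- tibble::tibble(case = seq_along(z), std_residual = z,
                            flag = abs(z) > 3)

  res <- stats::residuals(lmfit)
  sh <- stats::shapiro.test(res)
  bp <- if (ncol(X) >= 1) lmtest::bptest(lmfit) else NULL

  structure(list(
    vif = vif_tbl,
    outliers = out_tbl,
    shapiro = tibble::tibble(statistic = unname(sh$statistic),
                             p_value = sh$p.value, flag = sh$p.value < 0.05),
    breusch_pagan = if (is.null(bp)) NULL else
      tibble::tibble(statistic = unname(bp$statistic), p_value = bp$p.value,
                     flag = bp$p.value < 0.05)),
    class = "regression_diagnostics")
}

#' @export
print.regression_diagnostics <- function(x, ...) {
  cat("<regression_diagnostics>\n  VIF: max",
      round(max(x$vif$vif), 2), if (any(x$vif$flag)) "[FLAG]" else "[ok]",
      "\n  outliers (|z|>3):", sum(x$outliers$flag),
      "\n  Shapiro-Wilk p:", signif(x$shapiro$p_value, 3),
      if (x$shapiro$flag) "[FLAG]" else "[ok]", "\n")
  if (!is.null(x$breusch_pagan))
    cat("  Breusch-Pagan p:", signif(x$breusch_pagan$p_value, 3),
        if (x$breusch_pagan$flag) "[FLAG]" else "[ok]", "\n")
  invisible(x)
}
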