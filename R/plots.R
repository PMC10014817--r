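#' Plot a normalised gait cycle
#'
#' Angle curves against gait-cycle progress, one facet per angle, coloured by
#' side, with the ipsilateral toe-off marked.
#'
#' @param object A `normalized_cycle` from [time_normalize()].
#' @param angles Angles to show (default: hip, knee, ankle and pelvis tilt).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot normalized_cycle
#' @export
autoplot.normalized_cycle <- function(object,
                                      angles = c("hip_flexion_extension",
                                                 "knee_flexion_extension",
                                                 "ankle_dorsiflexion_plantarflexion",
                                                 "pelvis_tilt"),
                                      ...) {
  to <- toe_off_pct(object)
  object$values |>
    dplyr::filter(.data$angle %in% angles) |>
    ggplot2::ggplot(ggplot2::aes(.data$pct, .data$value_deg,
                                 colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = to, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$angle), scales = "free_y") +
    ggplot2::labs(x = "gait cycle progress (%)", y = "angle (deg)",
                  colour = "side") +
    ggplot2::theme_minimal()
}

#' Plot an angle and its normalised angular velocity
#'
#' The two rows show the angle (degrees) and its NAV (degrees per percent of
#' cycle) over gait-cycle progress; the NAV is the analytic derivative of the
#' quintic interpolating spline.
#'
#' @param ncycle A `normalized_cycle`.
#' @param angle Canonical angle name.
#' @param side Physical side (default the anchor side).
#' @return A ggplot.
#' @export
plot_nav <- function(ncycle, angle = "knee_flexion_extension",
                     side = ncycle$anchor_side) {
  sp <- ncycle$splines[[paste(angle, side, sep = "|")]]
  if (is.null(sp)) stop("no trajectory for ", angle, "/", side, call. = FALSE)
  grid <- cycle_grid()
  df <- dplyr::bind_rows(
    tibble::tibble(pct = grid, value = eval_spline(sp, grid),
                   signal = "angle (deg)"),
    tibble::tibble(pct = grid, value = eval_spline(sp, grid, deriv = 1),
                   signal = "NAV (deg/%)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$pct, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = toe_off_pct(ncycle, side),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$signal), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "gait cycle progress (%)", y = NULL,
                  title = paste(angle, "-", side)) +
    ggplot2::theme_minimal()
}

#' Plot fold-wise cross-validation results
#'
#' @param object A `cv_report` from [kfold_cv()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(factor(.data$fold), .data$r_squared)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_r_squared,
                        linetype = "dashed") +
    ggplot2::labs(x = "fold", y = "held-out R squared") +
    ggplot2::theme_minimal()
}

#' Plot the selection history of a stepwise fit
#'
#' Adjusted R-squared after every accepted entry or removal.
#'
#' @param object A `stepwise_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stepwise_fit
#' @export
autoplot.stepwise_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(.data$step, .data$adj_r_squared)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$action)) +
    ggplot2::labs(x = "selection step", y = "adjusted R squared",
                  colour = "action") +
    ggplot2::theme_minimal()
}
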