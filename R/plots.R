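#' Plot the marginal-effect curve
#'
#' Marginal birthweight change per 10-ppb increment as a function of the
#' stratum-mean concentration, with its pointwise delta-method 95% band.
#'
#' @param object A `marginal_effect_curve`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.marginal_effect_curve <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = grid_ppb, y = estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = conf.low, ymax = conf.high),
                         fill = "red", alpha = 0.12) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::labs(x = "stratum-mean concentration (ppb)",
                  y = "marginal effect (g per 10 ppb)") +
    ggplot2::theme_minimal()
}

#' Plot the integrated exposure-response function
#'
#' Birthweight change relative to the TMREL with the Monte Carlo 95% band
#' (when draws are present).
#'
#' @param object An `o3_erf`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.o3_erf <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = grid_ppb, y = estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_vline(xintercept = object$tmrel_ppb, linetype = 2,
                        colour = "grey40")
  if (!all(is.na(d$conf.low))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = conf.low, ymax = conf.high),
      fill = "grey60", alpha = 0.35)
  }
  p + ggplot2::geom_line(colour = "black") +
    ggplot2::labs(x = "peak-season concentration (ppb)",
                  y = "birthweight change vs TMREL (g)") +
    ggplot2::theme_minimal()
}

#' Bar chart of country-level attributable reductions
#'
#' @param burden Output of [attributable_reduction()] /
#'   [relative_reduction()].
#' @param year Year to display; default the latest.
#' @param top_n Show the `top_n` highest-burden countries.
#' @return A ggplot object.
#' @export
plot_burden <- function(burden, year = max(burden$year), top_n = 15) {
  yr <- year
  d <- burden |>
    filter(year == yr) |>
    arrange(dplyr::desc(abs_g)) |>
    head(top_n)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(country_id, abs_g),
                                  y = abs_g)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = abs_lo, ymax = abs_hi),
                           width = 0.3, na.rm = TRUE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = sprintf("attributable reduction in %d (g)", yr)) +
    ggplot2::theme_minimal()
}
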