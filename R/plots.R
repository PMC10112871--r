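#' Plot a spectral sensitivity curve
#'
#' Points with s.e.m. error bars against wavelength, the standard display
#' for species-level ERG sensitivity curves.
#'
#' @param object A `sensitivity_curve` tibble (see [average_sensitivity()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensitivity_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$wavelength_nm,
                                            y = .data$s)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Relative sensitivity") +
    ggplot2::theme_classic()
  if ("sem" %in% names(object) && any(is.finite(object$sem))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$s - .data$sem, ymax = .data$s + .data$sem),
      width = 5)
  }
  p
}

#' Plot a pigment-mixture fit
#'
#' Overlays the target sensitivities, the fitted weighted sum, and each
#' pigment's contribution-scaled template, mirroring the usual
#' decomposition figure.
#'
#' @param object A `mixture_fit`.
#' @param dense_by Wavelength step (nm) of the curves (default 2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mixture_fit <- function(object, dense_by = 2, ...) {
  wl <- seq(min(object$target$wavelength_nm),
            max(object$target$wavelength_nm), by = dense_by)
  m <- object$model
  comp <- purrr::imap_dfr(as.list(m$lambda_max), function(lm, pig) {
    tibble(pigment = pig, wavelength_nm = wl,
           s = m$f[[pig]] * pigment_absorbance(wl, pigment_template(lm)))
  })
  total <- predict_sensitivity(m, wl) |>
    dplyr::mutate(pigment = "sum")
  ggplot2::ggplot() +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(x = .data$wavelength_nm, y = .data$s,
                                    colour = .data$pigment),
                       linetype = "dashed") +
    ggplot2::geom_line(data = total,
                       ggplot2::aes(x = .data$wavelength_nm, y = .data$s),
                       colour = "black") +
    ggplot2::geom_point(data = object$target,
                        ggplot2::aes(x = .data$wavelength_nm, y = .data$s)) +
    ggplot2::scale_colour_manual(values = c(UV = "violet", SW = "blue",
                                            LW = "darkgreen")) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Relative sensitivity",
                  colour = "Pigment") +
    ggplot2::theme_classic()
}

#' Plot per-pair parallel-substitution test results
#'
#' Observed counts versus neutral expectations for every diurnal lineage
#' pair, marking pairs significant at p < 0.05.
#'
#' @param data Output tibble of [parallel_test()].
#' @return A ggplot.
#' @export
plot_parallel_test <- function(data) {
  stopifnot(all(c("pair", "observed", "expected", "p_value") %in% names(data)))
  d <- data |>
    dplyr::mutate(significant = .data$p_value < 0.05) |>
    tidyr::pivot_longer(c("observed", "expected"), names_to = "quantity",
                        values_to = "count")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pair, y = .data$count,
                                  fill = .data$quantity,
                                  alpha = .data$significant)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.4)) +
    ggplot2::labs(x = NULL, y = "Parallel substitutions") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
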