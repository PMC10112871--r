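#' Fit the Naka-Rushton intensity-response function
#'
#' Fits \eqn{V = V_{max} I^n / (I^n + K^n)} to a V-log I series by
#' least squares. `K` is the intensity eliciting half of `v_max` and `n`
#' the exponential slope. The fit is run from a small multi-start set
#' (`n` in 0.5/1/2, `K` at the intensity nearest the half-maximal
#' response, `v_max` at 1.05 times the largest response) because the
#' objective has shallow valleys in (K, n); the best start wins.
#'
#' @param data A data frame with columns `log10_intensity`
#'   (log10 photons cm^-2 s^-1, strictly increasing) and `response_mv`
#'   (response amplitude, mV, >= 0). At least 4 points.
#' @return An object of class `"naka_rushton_fit"` with elements `v_max`
#'   (mV), `k` (photons cm^-2 s^-1), `n`, `rss`, `converged`, `n_starts`
#'   and the input `data`. Supports [predict()], [tidy()] and [glance()].
#' @examples
#' x <- seq(8, 12, by = 0.5)
#' d <- tibble::tibble(log10_intensity = x,
#'                     response_mv = 10 / (1 + 10^(10 - x)))
#' fit_naka_rushton(d)
#' @export
fit_naka_rushton <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("log10_intensity", "response_mv") %in% names(data)))
  x <- data$log10_intensity
  v <- data$response_mv
  if (length(x) < 4) abort("Need at least 4 V-log I points.")
  if (any(diff(x) <= 0)) abort("`log10_intensity` must be strictly increasing.")
  if (any(v < 0)) abort("Responses must be >= 0.")
  if (diff(range(v)) == 0) abort("Responses are all equal; fit is undefined.")

  vmax0 <- 1.05 * max(v)
  logk0 <- x[which.min(abs(v - max(v) / 2))]
  # parameters: log(v_max), log10(K), log(n); unconstrained
  resid_fn <- function(par) {
    vm <- exp(par[1]); lk <- par[2]; n <- exp(par[3])
    v - vm / (1 + 10^(n * (lk - x)))
  }
  best <- NULL
  for (n0 in c(0.5, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(log(vmax0), logk0, log(n0)), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = fit$par, rss = rss, info = fit$info)
    }
  }
  if (is.null(best)) {
    abort("Naka-Rushton fit failed to converge from all starts.")
  }
  out <- structure(
    list(v_max = exp(best$par[1]),
         k = 10^best$par[2],
         n = exp(best$par[3]),
         rss = best$rss,
         converged = best$info %in% 1:4,
         n_starts = 3L,
         data = as_tibble(data)),
    class = "naka_rushton_fit")
  out
}

#' @export
print.naka_rushton_fit <- function(x, ...) {
  cat("Naka-Rushton fit: v_max =", signif(x$v_max, 4), "mV, K =",
      signif(x$k, 4), "photons cm^-2 s^-1, n =", signif(x$n, 4),
      "\nrss =", signif(x$rss, 4), "\n")
  invisible(x)
}

#' Predict responses from a Naka-Rushton fit
#'
#' @param object A `"naka_rushton_fit"`.
#' @param log10_intensity Intensities (log10 scale) at which to predict.
#' @param ... Unused.
#' @return Numeric vector of predicted response amplitudes (mV).
#' @export
predict.naka_rushton_fit <- function(object,
                                     log10_intensity = object$data$log10_intensity,
                                     ...) {
  object$v_max /
    (1 + 10^(object$n * (log10(object$k) - log10_intensity)))
}

#' @export
tidy.naka_rushton_fit <- function(x, ...) {
  tibble(term = c("v_max", "k", "n"),
         estimate = c(x$v_max, x$k, x$n),
         unit = c("mV", "photons cm^-2 s^-1", ""))
}

#' @export
glance.naka_rushton_fit <- function(x, ...) {
  tibble(rss = x$rss, converged = x$converged, n_starts = x$n_starts,
         nobs = nrow(x$data))
}

#' Convert a spectral response series into a spectral sensitivity
#'
#' Sensitivity at each wavelength is the reciprocal of the stimulus
#' intensity needed for a criterion response. Assuming the V-log I curve
#' keeps its shape across wavelengths and only shifts horizontally, the
#' effective intensity that produced response `V` under an equal-quanta
#' stimulus is recovered by inverting the fitted Naka-Rushton curve,
#' \eqn{I_{eff} = K (V / (V_{max} - V))^{1/n}}. The intensity required for
#' a fixed criterion response scales as \eqn{1 / I_{eff}}, so the
#' sensitivity — its reciprocal — satisfies
#' \eqn{S(\lambda) \propto I_{eff}(\lambda)}, normalised to unit maximum.
#'
#' Responses at or above `v_max` are clipped to `(1 - clip_eps) * v_max`
#' with a warning; non-positive responses map to sensitivity 0.
#'
#' @param data Data frame with columns `wavelength_nm` and `response_mv`.
#'   Extra columns (species, individual, series, direction) pass through.
#' @param fit A [fit_naka_rushton()] result for the same eye.
#' @param clip_eps Clipping constant as a fraction of `v_max`
#'   (default 1e-3).
#' @param normalize Rescale the curve to unit maximum (default TRUE).
#' @return The input tibble with an added column `s` (and `response_mv`
#'   retained), normalised so `max(s) == 1` when `normalize` is TRUE.
#' @export
response_to_sensitivity <- function(data, fit, clip_eps = 1e-3,
                                    normalize = TRUE) {
  stopifnot(is.data.frame(data),
            all(c("wavelength_nm", "response_mv") %in% names(data)),
            inherits(fit, "naka_rushton_fit"))
  v <- data$response_mv
  if (any(v >= fit$v_max)) {
    warn(sprintf("%d response(s) at or above v_max; clipped to (1 - %g) * v_max.",
                 sum(v >= fit$v_max), clip_eps))
    v[v >= fit$v_max] <- (1 - clip_eps) * fit$v_max
  }
  s <- numeric(length(v))
  pos <- v > 0
  s[pos] <- fit$k * (v[pos] / (fit$v_max - v[pos]))^(1 / fit$n)
  out <- as_tibble(data)
  out$s <- if (normalize && any(pos)) s / max(s) else s
  out
}

#' Average sensitivity curves into a species curve
#'
#' Two-level averaging: repeated spectral series within an individual are
#' averaged first, then individual means are averaged across individuals,
#' yielding the species mean with its standard error (s.e.m.). The final
#' curve is re-normalised to unit maximum (the s.e.m. is rescaled by the
#' same factor).
#'
#' @param data Long data frame of per-series sensitivities with columns
#'   `individual`, `wavelength_nm`, `s` and optionally `series`.
#' @param renormalize Re-normalise the species mean to unit maximum
#'   (default TRUE).
#' @return A `sensitivity_curve` tibble with columns `wavelength_nm`, `s`,
#'   `sem` (NA when only one individual) and `n_individuals`.
#' @export
average_sensitivity <- function(data, renormalize = TRUE) {
  stopifnot(is.data.frame(data),
            all(c("individual", "wavelength_nm", "s") %in% names(data)))
  grids <- data |>
    dplyr::group_by(.data$individual) |>
    dplyr::summarise(g = paste(sort(unique(.data$wavelength_nm)),
                               collapse = ","), .groups = "drop")
  if (length(unique(grids$g)) != 1) {
    abort("All individuals must share one wavelength grid.")
  }
  indiv <- data |>
    dplyr::group_by(.data$individual, .data$wavelength_nm) |>
    dplyr::summarise(s = mean(.data$s), .groups = "drop")
  n_ind <- length(unique(indiv$individual))
  out <- indiv |>
    dplyr::group_by(.data$wavelength_nm) |>
    dplyr::summarise(
      sem = if (n_ind > 1) sd(.data$s) / sqrt(n_ind) else NA_real_,
      s = mean(.data$s),
      .groups = "drop") |>
    dplyr::select("wavelength_nm", "s", "sem") |>
    dplyr::mutate(n_individuals = n_ind)
  if (renormalize) {
    peak <- max(out$s)
    out$s <- out$s / peak
    out$sem <- out$sem / peak
  }
  new_sensitivity_curve(out)
}

new_sensitivity_curve <- function(x) {
  tibble::new_tibble(x, class = "sensitivity_curve")
}

#' Assemble a sensitivity curve tibble
#'
#' Light constructor/validator for a species-level spectral sensitivity
#' curve used as the fit target of the mixture model.
#'
#' @param wavelength_nm Wavelengths, nm.
#' @param s Normalised sensitivities in [0, 1] with `max(s) == 1`.
#' @param sem Optional per-wavelength standard errors.
#' @param n_individuals Number of individuals behind the curve.
#' @return A `sensitivity_curve` tibble.
#' @export
sensitivity_curve <- function(wavelength_nm, s, sem = NA_real_,
                              n_individuals = 1L) {
  stopifnot(length(wavelength_nm) == length(s))
  if (any(s < 0)) abort("Sensitivities must be >= 0.")
  if (abs(max(s) - 1) > 1e-8) abort("`s` must be normalised to unit maximum.")
  new_sensitivity_curve(tibble(
    wavelength_nm = as.numeric(wavelength_nm), s = as.numeric(s),
    sem = as.numeric(sem), n_individuals = as.integer(n_individuals)))
}
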