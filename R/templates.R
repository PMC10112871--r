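#' Visual-pigment absorbance band template
#'
#' Evaluates the exponential band template of Stavenga, Smits and Hoenders
#' (1993, Vision Research 33, 1011-1017) for one absorbance band of an
#' A1 visual pigment:
#' \deqn{\alpha(\lambda) = \exp\{-a x^2 (1 + b x + \tfrac{3}{8} b^2 x^2)\},
#'       \quad x = \log_{10}(\lambda / \lambda_{max}).}
#' The template equals 1 exactly at \eqn{\lambda = \lambda_{max}} and decays
#' on both flanks; `a` controls the band width and `b` its skew.
#'
#' @param wavelength Wavelength(s) in nm; must be positive.
#' @param lambda_max Peak wavelength of the band in nm; must be positive.
#' @param a Band-width parameter (dimensionless, > 0). Default 380, the
#'   alpha-band value for A1 pigments.
#' @param b Band-skew parameter (dimensionless, > 0). Default 6.09, the
#'   alpha-band value. Use `a = 247`, `b = 3.59` for the beta band.
#' @return Numeric vector of absorbances in (0, 1], same length as
#'   `wavelength`.
#' @examples
#' band_absorbance(520, 520)            # exactly 1 at the peak
#' band_absorbance(560, 520)            # green flank of a 520-nm pigment
#' @export
band_absorbance <- function(wavelength, lambda_max, a = 380, b = 6.09) {
  if (any(!is.finite(wavelength)) || any(wavelength <= 0)) {
    abort("`wavelength` must be positive and finite.")
  }
  if (!is.finite(lambda_max) || lambda_max <= 0) {
    abort("`lambda_max` must be positive and finite.")
  }
  if (a <= 0 || b <= 0) abort("Band shape parameters `a` and `b` must be > 0.")
  x <- log10(wavelength / lambda_max)
  exp(-a * x^2 * (1 + b * x + (3 / 8) * b^2 * x^2))
}

#' Visual-pigment template configuration
#'
#' Bundles the parameters of a whole-pigment absorbance template: the
#' alpha band at `lambda_max` plus a beta band fixed near the UV, with a
#' fixed beta-to-alpha amplitude ratio. Defaults are the A1-pigment values
#' used for insect photoreceptors: beta-band peak at 360 nm and amplitude
#' ratio 0.29.
#'
#' @param lambda_max Alpha-band peak wavelength, nm; must lie in [300, 700].
#' @param lambda_max_beta Beta-band peak wavelength, nm (fixed, not fitted).
#' @param beta_ratio Beta-band amplitude relative to the alpha band (>= 0).
#' @param alpha_a,alpha_b Alpha-band shape parameters.
#' @param beta_a,beta_b Beta-band shape parameters.
#' @return A list of class `"pigment_template"`.
#' @export
pigment_template <- function(lambda_max,
                             lambda_max_beta = 360,
                             beta_ratio = 0.29,
                             alpha_a = 380, alpha_b = 6.09,
                             beta_a = 247, beta_b = 3.59) {
  if (!is.finite(lambda_max) || lambda_max < 300 || lambda_max > 700) {
    abort("`lambda_max` must lie in [300, 700] nm.")
  }
  if (beta_ratio < 0) abort("`beta_ratio` must be >= 0.")
  structure(
    list(lambda_max = lambda_max, lambda_max_beta = lambda_max_beta,
         beta_ratio = beta_ratio,
         alpha_a = alpha_a, alpha_b = alpha_b,
         beta_a = beta_a, beta_b = beta_b),
    class = "pigment_template"
  )
}

#' Whole-pigment absorbance spectrum (alpha + beta bands)
#'
#' Absorbance of one visual pigment as the sum of its alpha and beta bands,
#' \eqn{R(\lambda) = \alpha(\lambda;\lambda_{max}) + 0.29\,
#' \beta(\lambda; 360)}, rescaled so that the maximum over a dense internal
#' grid equals 1. The rescaling makes mixture contributions comparable
#' across pigments; it can be switched off.
#'
#' @param wavelength Wavelengths in nm at which to evaluate.
#' @param template A [pigment_template()], or a bare `lambda_max` in nm.
#' @param normalize Rescale to unit peak over `norm_grid` (default TRUE).
#' @param norm_grid Grid used to locate the peak for normalisation;
#'   defaults to 300-740 nm at 1 nm. The 20-nm measurement grid is too
#'   coarse to pin the template peak, hence the dense internal grid.
#' @return Numeric vector of absorbances (>= 0; <= 1 when normalised).
#' @examples
#' pigment_absorbance(seq(300, 740, 20), pigment_template(520))
#' @export
pigment_absorbance <- function(wavelength, template,
                               normalize = TRUE,
                               norm_grid = seq(300, 740, by = 1)) {
  if (is.numeric(template)) template <- pigment_template(template)
  stopifnot(inherits(template, "pigment_template"))
  raw <- function(l) {
    band_absorbance(l, template$lambda_max, template$alpha_a, template$alpha_b) +
      template$beta_ratio *
        band_absorbance(l, template$lambda_max_beta, template$beta_a, template$beta_b)
  }
  r <- raw(wavelength)
  if (normalize) {
    if (length(norm_grid) == 0) abort("Empty normalisation grid.")
    r <- r / max(raw(norm_grid))
  }
  r
}

#' Screening-pigment parameters
#'
#' Parameters of the screening-pigment absorbance model: a sum of two
#' Gaussians with peaks `mu`, standard deviations `sigma` and relative
#' contributions `p`.
#'
#' @param mu Length-2 numeric, peak wavelengths in nm.
#' @param sigma Length-2 numeric, standard deviations in nm (> 0).
#' @param p Length-2 numeric, relative contributions (>= 0).
#' @return A list of class `"screening_params"`.
#' @export
screening_params <- function(mu = c(440, 560), sigma = c(30, 50),
                             p = c(0, 0)) {
  stopifnot(length(mu) == 2, length(sigma) == 2, length(p) == 2)
  if (any(sigma <= 0)) abort("`sigma` must be > 0.")
  if (any(p < 0)) abort("`p` must be >= 0.")
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma),
                 p = as.numeric(p)),
            class = "screening_params")
}

#' Screening-pigment absorbance spectrum
#'
#' Two-Gaussian absorbance model for the distal/proximal screening pigments
#' of the eye:
#' \deqn{A(\lambda) = p_1 e^{-(\lambda-\mu_1)^2 / 2\sigma_1^2}
#'                  + p_2 e^{-(\lambda-\mu_2)^2 / 2\sigma_2^2}.}
#'
#' @param wavelength Wavelengths in nm.
#' @param params A [screening_params()] object.
#' @return Numeric vector of absorbances (>= 0).
#' @export
screening_absorbance <- function(wavelength, params) {
  stopifnot(inherits(params, "screening_params"))
  params$p[1] * exp(-(wavelength - params$mu[1])^2 / (2 * params$sigma[1]^2)) +
    params$p[2] * exp(-(wavelength - params$mu[2])^2 / (2 * params$sigma[2]^2))
}
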