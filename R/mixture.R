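#' Construct a three-pigment mixture model
#'
#' Holds the peak wavelengths and relative contributions of the UV, SW and
#' LW visual pigments whose weighted template sum models a spectral
#' sensitivity curve.
#'
#' @param lambda_max Named numeric `c(UV = , SW = , LW = )`, nm, strictly
#'   increasing.
#' @param f Named numeric contributions `c(UV = , SW = , LW = )`, >= 0,
#'   not all zero.
#' @param screening Optional [screening_params()]; when present the model
#'   is the screened variant.
#' @param beta_ratio,lambda_max_beta Passed to [pigment_template()].
#' @return A list of class `"pigment_mixture"`.
#' @export
pigment_mixture <- function(lambda_max, f, screening = NULL,
                            beta_ratio = 0.29, lambda_max_beta = 360) {
  lambda_max <- unlist(lambda_max)[c("UV", "SW", "LW")]
  f <- unlist(f)[c("UV", "SW", "LW")]
  if (any(is.na(lambda_max)) || any(is.na(f))) {
    abort("`lambda_max` and `f` must be named numerics with UV, SW, LW.")
  }
  if (!(lambda_max[["UV"]] < lambda_max[["SW"]] &&
        lambda_max[["SW"]] < lambda_max[["LW"]])) {
    abort("Peak ordering violated: need lambda_max UV < SW < LW.")
  }
  if (any(f < 0)) abort("Contributions `f` must be >= 0.")
  if (sum(f) == 0) abort("At least one contribution must be > 0.")
  if (!is.null(screening)) stopifnot(inherits(screening, "screening_params"))
  structure(list(lambda_max = lambda_max, f = f, screening = screening,
                 beta_ratio = beta_ratio, lambda_max_beta = lambda_max_beta),
            class = "pigment_mixture")
}

template_matrix <- function(lambda_max, wavelength, beta_ratio = 0.29,
                            lambda_max_beta = 360) {
  vapply(lambda_max, function(lm) {
    pigment_absorbance(wavelength,
                       pigment_template(lm, lambda_max_beta = lambda_max_beta,
                                        beta_ratio = beta_ratio))
  }, numeric(length(wavelength)))
}

#' Predicted spectral sensitivity of a pigment mixture
#'
#' Weighted sum of the three pigment absorbance templates,
#' \eqn{S(\lambda) = \sum_i f_i R_i(\lambda)}, normalised to unit maximum
#' over the supplied wavelengths. If the model carries screening-pigment
#' parameters, the sum is first multiplied by the screening transmittance
#' \eqn{10^{-A(\lambda)}} and then renormalised.
#'
#' @param model A [pigment_mixture()].
#' @param wavelength Wavelengths (nm) at which to predict.
#' @return Tibble with columns `wavelength_nm` and `s` (max exactly 1).
#' @export
predict_sensitivity <- function(model, wavelength) {
  stopifnot(inherits(model, "pigment_mixture"))
  r <- template_matrix(model$lambda_max, wavelength,
                       beta_ratio = model$beta_ratio,
                       lambda_max_beta = model$lambda_max_beta)
  s <- as.numeric(r %*% model$f)
  if (!is.null(model$screening)) {
    s <- s * 10^(-screening_absorbance(wavelength, model$screening))
  }
  tibble(wavelength_nm = wavelength, s = s / max(s))
}

#' @rdname predict_sensitivity
#' @export
predict_sensitivity_screened <- predict_sensitivity

#' Separation between two pigment peak wavelengths
#'
#' @param model A [pigment_mixture()] or a `mixture_fit`.
#' @param pair Character vector of two distinct pigments among
#'   "UV", "SW", "LW".
#' @return Absolute difference of the two `lambda_max` values, nm.
#' @examples
#' m <- pigment_mixture(c(UV = 357, SW = 440, LW = 520),
#'                      c(UV = 0.3, SW = 0.15, LW = 1))
#' lambda_max_separation(m, c("SW", "LW"))
#' @export
lambda_max_separation <- function(model, pair = c("SW", "LW")) {
  if (inherits(model, "mixture_fit")) model <- model$model
  stopifnot(inherits(model, "pigment_mixture"))
  pair <- match.arg(pair, c("UV", "SW", "LW"), several.ok = TRUE)
  if (length(pair) != 2 || pair[1] == pair[2]) {
    abort("`pair` must name two distinct pigments.")
  }
  abs(model$lambda_max[[pair[1]]] - model$lambda_max[[pair[2]]])
}

default_bounds <- function(screened = FALSE) {
  b <- list(
    lower = c(lambda_UV = 300, lambda_SW = 400, lambda_LW = 480,
              f_UV = 0, f_SW = 0, f_LW = 0),
    upper = c(lambda_UV = 420, lambda_SW = 500, lambda_LW = 600,
              f_UV = 10, f_SW = 10, f_LW = 10))
  if (screened) {
    b$lower <- c(b$lower, mu1 = 300, mu2 = 300, sigma1 = 5, sigma2 = 5,
                 p1 = 0, p2 = 0)
    b$upper <- c(b$upper, mu1 = 740, mu2 = 740, sigma1 = 150, sigma2 = 150,
                 p1 = 3, p2 = 3)
  }
  b
}

mixture_from_par <- function(par, screened = FALSE) {
  screening <- NULL
  if (screened) {
    screening <- screening_params(mu = par[c("mu1", "mu2")],
                                  sigma = par[c("sigma1", "sigma2")],
                                  p = pmax(par[c("p1", "p2")], 0))
  }
  pigment_mixture(
    lambda_max = c(UV = par[["lambda_UV"]], SW = par[["lambda_SW"]],
                   LW = par[["lambda_LW"]]),
    f = c(UV = max(par[["f_UV"]], 0), SW = max(par[["f_SW"]], 0),
          LW = max(par[["f_LW"]], 0)),
    screening = screening)
}

# non-negative least squares for f at fixed peak positions
start_contributions <- function(lambda, target, weights) {
  r <- template_matrix(c(UV = lambda[1], SW = lambda[2], LW = lambda[3]),
                       target$wavelength_nm)
  f <- tryCatch(pracma::lsqnonneg(sqrt(weights) * r,
                                  sqrt(weights) * target$s)$x,
                error = function(e) c(0.3, 0.3, 1))
  f <- pmin(pmax(f, 1e-3), 10)
  f
}

fit_mixture_engine <- function(target, starts, lower, upper, weights,
                               screened) {
  wl <- target$wavelength_nm
  sqw <- sqrt(weights)
  # the beta band is fixed (peak 360 nm), so precompute it once; only the
  # alpha bands move with the lambda_max parameters
  dense <- seq(300, 740, by = 1)
  beta_wl <- 0.29 * band_absorbance(wl, 360, a = 247, b = 3.59)
  beta_dense <- 0.29 * band_absorbance(dense, 360, a = 247, b = 3.59)
  predict_fast <- function(par) {
    lam <- par[c("lambda_UV", "lambda_SW", "lambda_LW")]
    f <- pmax(par[c("f_UV", "f_SW", "f_LW")], 0)
    s <- numeric(length(wl))
    for (i in 1:3) {
      norm_i <- max(band_absorbance(dense, lam[i]) + beta_dense)
      s <- s + f[i] * (band_absorbance(wl, lam[i]) + beta_wl) / norm_i
    }
    if (screened) {
      sp <- screening_params(mu = par[c("mu1", "mu2")],
                             sigma = par[c("sigma1", "sigma2")],
                             p = pmax(par[c("p1", "p2")], 0))
      s <- s * 10^(-screening_absorbance(wl, sp))
    }
    s / max(s)
  }
  resid_fn <- function(par) {
    par <- setNames(pmin(pmax(par, lower), upper), names(lower))
    if (sum(par[c("f_UV", "f_SW", "f_LW")]) <= 0) return(rep(1e3, length(wl)))
    sqw * (target$s - predict_fast(par))
  }
  results <- purrr::map(starts, function(p0) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 150, ftol = 1e-12, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    par <- setNames(fit$par, names(lower))
    ok <- par[["lambda_UV"]] < par[["lambda_SW"]] &&
      par[["lambda_SW"]] < par[["lambda_LW"]] &&
      sum(par[c("f_UV", "f_SW", "f_LW")]) > 0
    list(par = par, rss = sum(fit$fvec^2), info = fit$info, valid = ok)
  }) |> purrr::compact()
  if (length(results) == 0) abort("All mixture-fit starts failed.")
  valid <- purrr::keep(results, "valid")
  if (length(valid) == 0) {
    abort("No start satisfied the peak-ordering constraint lambda UV < SW < LW.")
  }
  losses <- purrr::map_dbl(valid, "rss")
  best <- valid[[which.min(losses)]]
  list(best = best, losses = purrr::map_dbl(results, "rss"),
       n_starts = length(starts))
}

finalize_fit <- function(best, target, n_starts, losses, screened) {
  par <- best$par
  model <- mixture_from_par(par, screened)
  # canonical scale: raw weighted template sum has unit max on a dense grid
  dense <- seq(300, 740, by = 1)
  raw <- as.numeric(template_matrix(model$lambda_max, dense) %*% model$f)
  model$f <- model$f / max(raw)
  pred <- predict_sensitivity(model, target$wavelength_nm)$s
  structure(
    list(model = model,
         rss = best$rss,
         converged = best$info %in% 1:4,
         n_starts = n_starts,
         start_losses = losses,
         residuals = tibble(wavelength_nm = target$wavelength_nm,
                            observed = target$s, fitted = pred,
                            residual = target$s - pred),
         target = as_tibble(target),
         screened = screened),
    class = "mixture_fit")
}

#' Fit the three-pigment mixture model to a sensitivity curve
#'
#' Estimates the three peak wavelengths and contributions by bounded
#' Levenberg-Marquardt least squares from a multi-start lattice (3 x 3 x 3
#' peak-wavelength triplets, contributions seeded by a non-negative linear
#' solve at each triplet). The objective is multimodal, hence the lattice.
#' The peak-ordering constraint lambda_max UV < SW < LW is enforced; the
#' default bounds (UV 300-420, SW 400-500, LW 480-600 nm) reflect the
#' UV/SW/LW pigment classes and prevent label switching.
#'
#' Contributions are reported on a canonical scale on which the raw
#' weighted template sum has unit maximum, making `f` comparable across
#' fits (the normalisation inside the model makes the overall scale of `f`
#' unidentifiable).
#'
#' @param target A data frame with columns `wavelength_nm` and `s`
#'   (normalised, >= 6 wavelengths), e.g. from [average_sensitivity()].
#' @param bounds Optional list with `lower`/`upper` named vectors
#'   overriding the defaults.
#' @param starts Optional list of named start vectors; default is the
#'   lattice described above.
#' @param weights Per-wavelength weights; `NULL` (unweighted, default) or
#'   `"sem"` for 1/sem^2 weighting, or a numeric vector.
#' @return A `mixture_fit` object; see [tidy.mixture_fit()],
#'   [glance.mixture_fit()] and [autoplot.mixture_fit()].
#' @export
fit_mixture <- function(target, bounds = NULL, starts = NULL,
                        weights = NULL) {
  target <- validate_target(target)
  w <- resolve_weights(weights, target)
  b <- default_bounds(screened = FALSE)
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  if (is.null(starts)) {
    lat <- expand.grid(UV = c(330, 360, 390), SW = c(415, 450, 485),
                       LW = c(495, 530, 565))
    starts <- purrr::pmap(lat, function(UV, SW, LW) {
      f0 <- start_contributions(c(UV, SW, LW), target, w)
      c(lambda_UV = UV, lambda_SW = SW, lambda_LW = LW,
        f_UV = f0[1], f_SW = f0[2], f_LW = f0[3])
    })
  }
  eng <- fit_mixture_engine(target, starts, b$lower, b$upper, w,
                            screened = FALSE)
  finalize_fit(eng$best, target, eng$n_starts, eng$losses, screened = FALSE)
}

#' Fit the screened three-pigment mixture model
#'
#' Extends [fit_mixture()] with the two-Gaussian screening-pigment
#' absorbance (peaks, widths and amplitudes), an 11-parameter problem.
#' Starts are seeded from the unscreened fit with screening amplitudes at
#' and near zero plus a few bump hypotheses. Because a 23-point curve
#' weakly constrains 11 parameters, the result carries an
#' `identifiable` flag from a coarse profile of the residual sum of
#' squares over the screening amplitudes: when the profile is flat the
#' screening parameters are reported as non-identifiable.
#'
#' @inheritParams fit_mixture
#' @param profile_points Number of amplitude values per screening Gaussian
#'   used for the identifiability profile (default 4).
#' @return A `mixture_fit` with `screened = TRUE` and elements
#'   `identifiable` and `profile`.
#' @export
fit_mixture_screened <- function(target, bounds = NULL, starts = NULL,
                                 weights = NULL, profile_points = 4) {
  target <- validate_target(target)
  w <- resolve_weights(weights, target)
  b <- default_bounds(screened = TRUE)
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  base <- fit_mixture(target, weights = weights)
  bp <- c(lambda_UV = unname(base$model$lambda_max[["UV"]]),
          lambda_SW = unname(base$model$lambda_max[["SW"]]),
          lambda_LW = unname(base$model$lambda_max[["LW"]]),
          f_UV = unname(base$model$f[["UV"]]),
          f_SW = unname(base$model$f[["SW"]]),
          f_LW = unname(base$model$f[["LW"]]))
  if (is.null(starts)) {
    screen_starts <- list(
      c(mu1 = 440, mu2 = 560, sigma1 = 30, sigma2 = 50, p1 = 0, p2 = 0),
      c(mu1 = 440, mu2 = 560, sigma1 = 30, sigma2 = 50, p1 = 0.2, p2 = 0.2),
      c(mu1 = 380, mu2 = 500, sigma1 = 40, sigma2 = 60, p1 = 0.5, p2 = 0.1),
      c(mu1 = 480, mu2 = 620, sigma1 = 25, sigma2 = 40, p1 = 0.1, p2 = 0.5))
    starts <- purrr::map(screen_starts, ~ c(bp, .x))
  }
  eng <- fit_mixture_engine(target, starts, b$lower, b$upper, w,
                            screened = TRUE)
  out <- finalize_fit(eng$best, target, eng$n_starts, eng$losses,
                      screened = TRUE)
  # guard: unscreened model is nested; never return a worse optimum
  if (out$rss > base$rss + 1e-12) {
    refit <- fit_mixture_engine(
      target, list(c(bp, mu1 = 440, mu2 = 560, sigma1 = 30, sigma2 = 50,
                     p1 = 1e-6, p2 = 1e-6)),
      b$lower, b$upper, w, screened = TRUE)
    if (refit$best$rss < out$rss) {
      out <- finalize_fit(refit$best, target, out$n_starts + 1L,
                          c(out$start_losses, refit$best$rss), TRUE)
    }
  }
  prof <- screening_profile(out, target, w, b, n = profile_points)
  out$profile <- prof
  rng <- diff(range(prof$rss, na.rm = TRUE))
  out$identifiable <- is.finite(rng) && rng > max(1e-8, 0.01 * out$rss)
  if (!out$identifiable) {
    warn("Screening amplitudes are not practically identifiable on this grid (flat rss profile).")
  }
  out
}

# coarse profile of rss over fixed screening amplitudes
screening_profile <- function(fit, target, w, b, n = 4) {
  par <- fit_par_vector(fit)
  p_grid <- seq(0, max(0.5, 2 * max(par[c("p1", "p2")])), length.out = n)
  purrr::map_dfr(p_grid, function(p) {
    lower <- b$lower; upper <- b$upper
    lower[c("p1", "p2")] <- max(p - 1e-9, 0); upper[c("p1", "p2")] <- p + 1e-9
    p0 <- par; p0[c("p1", "p2")] <- p
    eng <- tryCatch(
      fit_mixture_engine(target, list(p0), lower, upper, w, screened = TRUE),
      error = function(e) NULL)
    tibble(p = p, rss = if (is.null(eng)) NA_real_ else eng$best$rss)
  })
}

fit_par_vector <- function(fit) {
  m <- fit$model
  par <- c(lambda_UV = unname(m$lambda_max[["UV"]]),
           lambda_SW = unname(m$lambda_max[["SW"]]),
           lambda_LW = unname(m$lambda_max[["LW"]]),
           f_UV = unname(m$f[["UV"]]), f_SW = unname(m$f[["SW"]]),
           f_LW = unname(m$f[["LW"]]))
  if (!is.null(m$screening)) {
    par <- c(par, mu1 = m$screening$mu[1], mu2 = m$screening$mu[2],
             sigma1 = m$screening$sigma[1], sigma2 = m$screening$sigma[2],
             p1 = m$screening$p[1], p2 = m$screening$p[2])
  }
  par
}

validate_target <- function(target) {
  stopifnot(is.data.frame(target),
            all(c("wavelength_nm", "s") %in% names(target)))
  if (nrow(target) < 6) abort("Need at least 6 wavelengths to fit.")
  if (abs(max(target$s) - 1) > 1e-6) {
    abort("Target curve must be normalised to unit maximum.")
  }
  target
}

resolve_weights <- function(weights, target) {
  if (is.null(weights)) return(rep(1, nrow(target)))
  if (identical(weights, "sem")) {
    if (!"sem" %in% names(target) || any(!is.finite(target$sem)) ||
        any(target$sem <= 0)) {
      abort("`weights = \"sem\"` needs finite positive `sem` in the target.")
    }
    return(1 / target$sem^2)
  }
  stopifnot(is.numeric(weights), length(weights) == nrow(target))
  weights
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(if (x$screened) "Screened" else "Unscreened",
      "pigment-mixture fit\n")
  cat("  lambda_max (nm): UV", round(x$model$lambda_max[["UV"]], 1),
      " SW", round(x$model$lambda_max[["SW"]], 1),
      " LW", round(x$model$lambda_max[["LW"]], 1), "\n")
  cat("  contributions f: UV", signif(x$model$f[["UV"]], 3),
      " SW", signif(x$model$f[["SW"]], 3),
      " LW", signif(x$model$f[["LW"]], 3), "\n")
  cat("  rss =", signif(x$rss, 4), "from", x$n_starts, "starts;",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Tidy a mixture fit
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return One row per parameter with columns `term`, `estimate`, `unit`.
#' @export
tidy.mixture_fit <- function(x, ...) {
  par <- fit_par_vector(x)
  units <- ifelse(grepl("^lambda|^mu|^sigma", names(par)), "nm", "")
  tibble(term = names(par), estimate = unname(par), unit = units)
}

#' Glance at a mixture fit
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return One-row tibble of fit diagnostics.
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(rss = x$rss, converged = x$converged, n_starts = x$n_starts,
         screened = x$screened, nobs = nrow(x$target),
         identifiable = if (x$screened) x$identifiable else NA)
}
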