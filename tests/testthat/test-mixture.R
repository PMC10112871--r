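grid20 <- seq(300, 740, 20)

target_from <- function(model, wl = grid20) {
  p <- predict_sensitivity(model, wl)
  names(p)[names(p) == "s"] <- "s"
  p
}

test_that("mixture prediction reduces to single templates and is scale-free", {
  m_lw <- pigment_mixture(c(UV = 350, SW = 440, LW = 520),
                          c(UV = 0, SW = 0, LW = 1))
  p <- predict_sensitivity(m_lw, grid20)
  r_lw <- pigment_absorbance(grid20, pigment_template(520))
  expect_equal(p$s, r_lw / max(r_lw), tolerance = 1e-12)
  # doubling all contributions changes nothing
  m1 <- pigment_mixture(c(UV = 357, SW = 440, LW = 520),
                        c(UV = 0.3, SW = 0.15, LW = 1))
  m2 <- pigment_mixture(c(UV = 357, SW = 440, LW = 520),
                        c(UV = 0.6, SW = 0.3, LW = 2))
  expect_equal(predict_sensitivity(m1, grid20)$s,
               predict_sensitivity(m2, grid20)$s, tolerance = 1e-12)
  # every predicted curve has max exactly 1
  expect_equal(max(predict_sensitivity(m1, grid20)$s), 1)
  # bimodal shape: a UV peak and a green peak, dip in between
  s <- predict_sensitivity(m1, grid20)$s
  uv_peak <- max(s[grid20 <= 400]); green_peak <- max(s[grid20 >= 480])
  trough <- min(s[grid20 > 400 & grid20 < 480])
  expect_gt(uv_peak, trough); expect_gt(green_peak, trough)
  expect_error(pigment_mixture(c(UV = 357, SW = 440, LW = 520),
                               c(UV = 0, SW = 0, LW = 0)), "contribution")
  expect_error(pigment_mixture(c(UV = 450, SW = 440, LW = 520),
                               c(UV = 1, SW = 1, LW = 1)), "ordering")
})

test_that("screened prediction applies 10^(-A) and reduces to unscreened at zero", {
  m <- pigment_mixture(c(UV = 357, SW = 440, LW = 520),
                       c(UV = 0.3, SW = 0.15, LW = 1))
  zero <- pigment_mixture(m$lambda_max, m$f,
                          screening = screening_params(p = c(0, 0)))
  expect_equal(predict_sensitivity_screened(zero, grid20)$s,
               predict_sensitivity(m, grid20)$s, tolerance = 1e-12)
  # tenfold attenuation where A = 1, before renormalisation
  scr <- screening_params(mu = c(500, 500), sigma = c(30, 30), p = c(0.5, 0.5))
  ms <- pigment_mixture(m$lambda_max, m$f, screening = scr)
  raw_un <- predict_sensitivity(m, grid20)$s
  raw_sc <- raw_un * 10^(-screening_absorbance(grid20, scr))
  expect_equal(predict_sensitivity_screened(ms, grid20)$s,
               raw_sc / max(raw_sc), tolerance = 1e-12)
  expect_equal(screening_absorbance(500, scr), 1)
  # the attenuation is strongest where A is largest
  ratio <- raw_sc / raw_un
  expect_equal(grid20[which.min(ratio)], 500)
})

test_that("noise-free mixture fit recovers generating parameters", {
  truth_l <- c(UV = 357, SW = 440, LW = 520)
  truth_f <- c(UV = 0.3, SW = 0.15, LW = 1)
  target <- target_from(pigment_mixture(truth_l, truth_f))
  fit <- fit_mixture(target)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$model$lambda_max - truth_l)), 0.5)
  f_canon <- canonical_f(truth_l, truth_f)
  expect_lt(max(abs(fit$model$f - f_canon) / f_canon), 0.01)
  # determinism: permuting the start order does not change the optimum
  lat <- expand.grid(UV = c(330, 360, 390), SW = c(415, 450, 485),
                     LW = c(495, 530, 565))
  starts <- purrr::pmap(lat, function(UV, SW, LW)
    c(lambda_UV = UV, lambda_SW = SW, lambda_LW = LW,
      f_UV = 0.3, f_SW = 0.3, f_LW = 1))
  f1 <- fit_mixture(target, starts = starts)
  f2 <- fit_mixture(target, starts = rev(starts))
  expect_equal(f1$model$lambda_max, f2$model$lambda_max, tolerance = 1e-8)
  expect_error(fit_mixture(target[1:4, ]), "6")
})

test_that("tidy, glance and autoplot work on mixture fits", {
  target <- target_from(pigment_mixture(c(UV = 357, SW = 440, LW = 520),
                                        c(UV = 0.3, SW = 0.15, LW = 1)))
  fit <- fit_mixture(target)
  td <- tidy(fit)
  expect_setequal(td$term, c("lambda_UV", "lambda_SW", "lambda_LW",
                             "f_UV", "f_SW", "f_LW"))
  gl <- glance(fit)
  expect_false(gl$screened)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("screened fit nests the unscreened model", {
  m <- pigment_mixture(c(UV = 357, SW = 440, LW = 520),
                       c(UV = 0.3, SW = 0.15, LW = 1))
  target <- target_from(m)
  fu <- fit_mixture(target)
  fs <- suppressWarnings(fit_mixture_screened(target))
  # zero-screening target: amplitudes near zero, lambda_max within 1 nm
  expect_lt(max(fs$model$screening$p), 0.05)
  expect_lt(max(abs(fs$model$lambda_max - fu$model$lambda_max)), 1)
  expect_lte(fs$rss, fu$rss + 1e-12)
  # known screening bump: screened fit strictly better, near-exact round trip
  scr <- screening_params(mu = c(460, 620), sigma = c(25, 40), p = c(0.6, 0.3))
  t2 <- target_from(pigment_mixture(m$lambda_max, m$f, screening = scr))
  fs2 <- suppressWarnings(fit_mixture_screened(t2))
  fu2 <- fit_mixture(t2)
  expect_lt(fs2$rss, fu2$rss)
  expect_lt(fs2$rss, 1e-10)
  expect_lt(max(abs(fs2$model$lambda_max - m$lambda_max)), 0.5)
})

test_that("lambda_max separation is the absolute peak difference", {
  m <- pigment_mixture(c(UV = 350, SW = 500, LW = 547),
                       c(UV = 0.3, SW = 0.5, LW = 1))
  expect_equal(lambda_max_separation(m, c("SW", "LW")), 47)
  expect_equal(lambda_max_separation(m, c("LW", "SW")), 47)
  expect_equal(lambda_max_separation(
    pigment_mixture(c(UV = 350, SW = 450, LW = 450.0001),
                    c(UV = 1, SW = 1, LW = 1)), c("SW", "LW")),
    0.0001, tolerance = 1e-6)
  expect_error(lambda_max_separation(m, c("LW", "LW")), "distinct")
  # consistency with a fitted model
  target <- target_from(m)
  fit <- fit_mixture(target)
  expect_equal(lambda_max_separation(fit, c("SW", "LW")),
               abs(fit$model$lambda_max[["LW"]] - fit$model$lambda_max[["SW"]]))
})
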