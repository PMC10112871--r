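# Amino-acid alphabet used throughout (fixed order; also the tie-break order
# for maximum-posterior states).
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Jones, Taylor & Thornton (1992, CABIOS 8, 275-282) accepted point mutation
# exchangeabilities (lower triangle, column-major over the alphabet above)
# and equilibrium frequencies, as distributed with standard phylogenetics
# software.
JTT_EXCHANGE <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64,
  126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232,
  8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46,
  31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26,
  597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18,
  5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47,
  16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40,
  245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47,
  103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62,
  285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112, 71, 25, 16)

JTT_FREQS <- c(
  A = 0.07674792, R = 0.05169095, N = 0.04264496, D = 0.05154395,
  C = 0.01980298, Q = 0.04075196, E = 0.06182994, G = 0.07315193,
  H = 0.02294398, I = 0.05376095, L = 0.09190391, K = 0.05867594,
  M = 0.02382598, F = 0.04012596, P = 0.05090095, S = 0.06876493,
  T = 0.05856494, W = 0.01426099, Y = 0.03210197, V = 0.06600493)

jtt_exchange_matrix <- function() {
  s <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  s[lower.tri(s)] <- JTT_EXCHANGE
  s + t(s)
}

#' Discrete-gamma rate categories
#'
#' Equal-probability discretisation of the gamma(shape, rate = shape)
#' distribution of among-site rate variation, each category represented by
#' its mean (Yang 1994). The category means average to 1.
#'
#' @param shape Gamma shape parameter alpha (> 0).
#' @param n_categories Number of categories (default 4).
#' @return Numeric vector of category mean rates.
#' @export
discrete_gamma_rates <- function(shape, n_categories = 4) {
  stopifnot(shape > 0, n_categories >= 1)
  if (n_categories == 1) return(1)
  k <- n_categories
  q <- qgamma((0:k) / k, shape = shape, rate = shape)
  r <- k * (pgamma(q[-1] * shape, shape + 1, rate = 1) -
              pgamma(q[-(k + 1)] * shape, shape + 1, rate = 1))
  r / mean(r)
}

#' Build an amino-acid substitution model
#'
#' Assembles a reversible 20-state rate matrix from the JTT
#' exchangeabilities with either the model's own equilibrium frequencies
#' or empirical frequencies pooled over an alignment ("f_gene", the "-f"
#' convention). The rate matrix is scaled to one expected substitution per
#' site per unit branch length; among-site rate variation uses the
#' discrete-gamma approximation.
#'
#' @param frequencies `"model"` (JTT's own) or `"f_gene"` (pooled empirical
#'   frequencies from `alignment`).
#' @param alignment A `protein_alignment`; required for `"f_gene"`.
#' @param gamma_shape Gamma shape alpha for among-site rate variation, or
#'   `NULL` for uniform rates.
#' @param n_categories Number of discrete gamma categories (default 4;
#'   ignored when `gamma_shape` is NULL).
#' @param pseudocount Added to each amino-acid count for `"f_gene"` so no
#'   frequency is exactly zero (default 1).
#' @return An object of class `"aa_subst_model"` with the scaled rate
#'   matrix `q`, frequencies `freqs`, rate categories `rates`, and a
#'   spectral decomposition used by [transition_prob()].
#' @export
substitution_model <- function(frequencies = c("model", "f_gene"),
                               alignment = NULL, gamma_shape = NULL,
                               n_categories = 4, pseudocount = 1) {
  frequencies <- match.arg(frequencies)
  if (frequencies == "f_gene") {
    if (is.null(alignment)) abort("`f_gene` frequencies need an alignment.")
    stopifnot(inherits(alignment, "protein_alignment"))
    if (pseudocount <= 0) {
      abort("`pseudocount` must be > 0: a zero equilibrium frequency makes the rate matrix degenerate.")
    }
    counts <- table(factor(unclass(alignment), levels = AA_ALPHABET))
    pi <- (as.numeric(counts) + pseudocount)
    names(pi) <- AA_ALPHABET
  } else {
    pi <- JTT_FREQS
  }
  pi <- pi / sum(pi)
  s <- jtt_exchange_matrix()
  q <- s * rep(pi, each = 20)           # q_ij = s_ij * pi_j
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  scale <- -sum(pi * diag(q))
  q <- q / scale
  # reversible: symmetrise with D^(1/2) for a stable eigendecomposition
  d <- sqrt(pi)
  b <- q * (d %o% (1 / d))
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  rates <- if (is.null(gamma_shape)) 1 else
    discrete_gamma_rates(gamma_shape, n_categories)
  structure(
    list(q = q, freqs = pi, frequencies = frequencies,
         gamma_shape = gamma_shape, rates = rates,
         eig = list(values = e$values,
                    left = t(e$vectors * d),        # rows: D^{1/2} U  (transposed)
                    right = e$vectors / d)),        # D^{-1/2} U
    class = "aa_subst_model")
}

#' @export
print.aa_subst_model <- function(x, ...) {
  cat("JTT amino-acid substitution model;",
      if (x$frequencies == "f_gene") "empirical (f_gene)" else "model",
      "frequencies;",
      if (is.null(x$gamma_shape)) "uniform rates"
      else sprintf("gamma(%.3g) x %d categories", x$gamma_shape,
                   length(x$rates)), "\n")
  invisible(x)
}

#' Transition-probability matrix
#'
#' \eqn{P(t) = \exp(Q t)} for branch length `t` (expected substitutions per
#' site). With a rate mixture, `rate` selects one category's rate
#' multiplier, or `rate = "average"` returns the mixture-averaged matrix.
#'
#' @param model An [substitution_model()] object.
#' @param t Branch length (>= 0).
#' @param rate Numeric rate multiplier (default 1) or `"average"`.
#' @return 20 x 20 row-stochastic matrix, rows = ancestral state.
#' @export
transition_prob <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "aa_subst_model"), t >= 0)
  if (identical(rate, "average")) {
    w <- 1 / length(model$rates)
    p <- Reduce(`+`, lapply(model$rates,
                            function(r) transition_prob(model, t, r) * w))
    return(p)
  }
  e <- model$eig
  p <- e$right %*% (exp(e$values * t * rate) * e$left)
  p[p < 0] <- 0
  p <- p / rowSums(p)
  dimnames(p) <- dimnames(model$q)
  p
}
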