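# Independent oracles used across the suite. These deliberately re-derive
# quantities through different code paths than the package implementation.

# Second, independent transcription of the visual-pigment band template:
# written out step by step from the published formula rather than sharing
# code with band_absorbance().
oracle_band <- function(lambda, lambda_max, a, b) {
  x <- log(lambda / lambda_max, base = 10)
  poly <- 1 + b * x + (3 / 8) * (b * x)^2
  exp(-(a * x * x) * poly)
}

# Brute-force tree likelihood: enumerate every assignment of states to the
# internal nodes and sum the joint probability. Only feasible on tiny trees.
brute_force_site_lik <- function(tip_states, tree, model, rate = 1) {
  n_tip <- length(tree$tip.label)
  internal <- (n_tip + 1):(n_tip + tree$Nnode)
  probs <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_prob(model, tree$edge.length[e], rate))
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  states <- matrix(NA_integer_, nrow(grid), n_tip + tree$Nnode)
  states[, internal] <- grid
  alphabet <- rownames(model$q)
  for (i in seq_len(n_tip)) {
    states[, i] <- match(tip_states[tree$tip.label[i]], alphabet)
  }
  joint <- model$freqs[states[, n_tip + 1]]
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    joint <- joint * probs[[e]][cbind(states[, u], states[, v])]
  }
  joint
}

brute_force_loglik <- function(alignment, tree, model) {
  aln <- unclass(alignment)
  site_ll <- vapply(seq_len(ncol(aln)), function(s) {
    per_cat <- vapply(model$rates, function(r) {
      sum(brute_force_site_lik(aln[, s], tree, model, r))
    }, numeric(1))
    log(mean(per_cat))
  }, numeric(1))
  sum(site_ll)
}

# Exhaustive marginal posterior for one internal node at one site.
brute_force_posterior <- function(alignment, tree, model, node, site) {
  aln <- unclass(alignment)
  n_tip <- length(tree$tip.label)
  internal <- (n_tip + 1):(n_tip + tree$Nnode)
  col <- which(internal == node)
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  acc <- numeric(20)
  for (r in model$rates) {
    joint <- brute_force_site_lik(aln[, site], tree, model, r)
    acc <- acc + vapply(1:20, function(a) sum(joint[grid[, col] == a]),
                        numeric(1)) / length(model$rates)
  }
  acc / sum(acc)
}

# Pairwise ML distance by a plain 1-D scan of the two-sequence likelihood.
pairwise_ml_distance <- function(seq1, seq2, model) {
  f <- function(t) {
    p <- transition_prob(model, t)
    i <- match(seq1, rownames(p)); j <- match(seq2, rownames(p))
    -sum(log(model$freqs[i] * p[cbind(i, j)]))
  }
  optimize(f, c(1e-8, 5), tol = 1e-8)$minimum
}

# Small random rooted tree with branch lengths, for property loops.
random_tree <- function(n_tip, min_len = 0.02, max_len = 0.3) {
  tr <- ape::rtree(n_tip, rooted = TRUE)
  tr$edge.length <- runif(nrow(tr$edge), min_len, max_len)
  tr
}

# Random gap-free alignment over the tips of a tree (iid sites; no tree
# signal needed when only likelihood identities are being checked).
random_alignment <- function(tree, n_sites) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  m <- matrix(sample(aa, length(tree$tip.label) * n_sites, replace = TRUE),
              nrow = length(tree$tip.label),
              dimnames = list(tree$tip.label, NULL))
  protein_alignment(m)
}

# Fabricated reconstruction object with chosen internal states, for testing
# the substitution-counting rules against hand-enumerated cases.
fake_reconstruction <- function(tree, alignment, map_states) {
  structure(list(map = map_states,
                 posterior = matrix(1, nrow(map_states), ncol(map_states),
                                    dimnames = dimnames(map_states)),
                 tree = ape::reorder.phylo(tree, "postorder"),
                 alignment = alignment, model = NULL),
            class = "ancestral_reconstruction")
}

# Full ERG-to-mixture pipeline on one simulated dataset; returns the fit.
run_erg_pipeline <- function(sim, screened = FALSE) {
  curves <- sim$spectral |>
    dplyr::group_by(individual, series) |>
    dplyr::group_modify(function(d, key) {
      nr <- fit_naka_rushton(
        dplyr::filter(sim$vlogi, individual == key$individual))
      response_to_sensitivity(d, nr)
    }) |>
    dplyr::ungroup()
  curve <- average_sensitivity(curves)
  if (screened) fit_mixture_screened(curve) else fit_mixture(curve)
}

# Canonical contribution scale (raw weighted template sum peaks at 1).
canonical_f <- function(lambda_max, f) {
  dense <- seq(300, 740, by = 1)
  r <- vapply(lambda_max, function(lm)
    pigment_absorbance(dense, pigment_template(lm)), numeric(length(dense)))
  f / max(as.numeric(r %*% f))
}
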