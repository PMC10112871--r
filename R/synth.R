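#' Simulate an ERG dataset from a known pigment mixture
#'
#' Forward model of the ERG pipeline: a true three-pigment mixture
#' (optionally screened) sets the spectral sensitivity
#' \eqn{S_{true}(\lambda)}; an equal-quanta stimulus of `flux` photons
#' cm^-2 s^-1 produces an effective intensity
#' \eqn{I_{eff}(\lambda) = flux \cdot S_{true}(\lambda)}, which drives the
#' Naka-Rushton transduction to a response amplitude; additive Gaussian
#' measurement noise (truncated at zero) is applied per series. A V-log I
#' series over a 4-log-unit range around K is simulated for each
#' individual with the same noise.
#'
#' Defaults mirror the standard recording design: a 300-740 nm grid in
#' 20-nm steps, equal-quanta flux 5e11 photons cm^-2 s^-1, and two paired
#' series (short-to-long then long-to-short sweeps) per individual,
#' simulated as independent noise draws of the same truth.
#'
#' @param mixture A [pigment_mixture()]; the truth to recover.
#' @param n_individuals Number of individuals (default 8).
#' @param n_series Spectral series per individual (default 2).
#' @param wavelengths Stimulus grid, nm (default `seq(300, 740, 20)`).
#' @param flux Equal-quanta photon flux (default 5e11).
#' @param v_max,k,n Naka-Rushton parameters shared by all individuals
#'   (defaults 20 mV, 5e10, 1).
#' @param noise_sd Gaussian response noise, mV (default 0.2; use 0 for
#'   noise-free round trips).
#' @param n_vlogi Points in each V-log I series (default 9 over 4 log
#'   units centred on K).
#' @param seed Random seed (required for reproducibility; default 20220912).
#' @return A list: `spectral` (tibble `individual, series, direction,
#'   wavelength_nm, response_mv`), `vlogi` (tibble `individual,
#'   log10_intensity, response_mv`), and `truth` (the inputs, including
#'   the true sensitivity curve).
#' @export
simulate_erg_dataset <- function(mixture, n_individuals = 8, n_series = 2,
                                 wavelengths = seq(300, 740, by = 20),
                                 flux = 5e11, v_max = 20, k = 5e10, n = 1,
                                 noise_sd = 0.2, n_vlogi = 9,
                                 seed = 20220912) {
  stopifnot(inherits(mixture, "pigment_mixture"), noise_sd >= 0,
            all(wavelengths >= 300 & wavelengths <= 740))
  set.seed(seed)
  s_true <- predict_sensitivity(mixture, wavelengths)$s
  nr <- function(i) v_max * i^n / (i^n + k^n)
  directions <- rep(c("short_to_long", "long_to_short"),
                    length.out = n_series)
  spectral <- tidyr::expand_grid(
    individual = sprintf("ind%02d", seq_len(n_individuals)),
    series = seq_len(n_series),
    wavelength_nm = wavelengths) |>
    dplyr::mutate(
      direction = directions[.data$series],
      response_mv = pmax(0, nr(flux * s_true[match(.data$wavelength_nm,
                                                   wavelengths)]) +
                           rnorm(dplyr::n(), 0, noise_sd)))
  grid_x <- seq(log10(k) - 2, log10(k) + 2, length.out = n_vlogi)
  vlogi <- tidyr::expand_grid(
    individual = sprintf("ind%02d", seq_len(n_individuals)),
    log10_intensity = grid_x) |>
    dplyr::mutate(response_mv = pmax(0, nr(10^.data$log10_intensity) +
                                       rnorm(dplyr::n(), 0, noise_sd)))
  list(spectral = spectral, vlogi = vlogi,
       truth = list(mixture = mixture, v_max = v_max, k = k, n = n,
                    flux = flux, noise_sd = noise_sd,
                    s_true = tibble(wavelength_nm = wavelengths,
                                    s = s_true)))
}

#' Simulate protein evolution along a labelled phylogeny
#'
#' Draws a root sequence from the model's equilibrium frequencies and
#' evolves it along each branch with the model's transition probabilities
#' (one gamma rate category drawn per site when the model has rate
#' variation). Optional injections force parallel substitutions: at each
#' injected site, every node strictly below the stem of the named diurnal
#' lineages (down to the tip) is overwritten with the injected derived
#' residue, guaranteeing a parallel substitution on those lineages.
#'
#' @param tree A [labeled_phylogeny()] with branch lengths.
#' @param model An [substitution_model()].
#' @param n_sites Number of sites to simulate.
#' @param injections Optional tibble with columns `site`, `residue` and
#'   `tips` (list column of diurnal tip labels, >= 2, in different
#'   clades for a guaranteed parallel pair). `residue = NA` picks the
#'   first amino acid (alphabet order) that differs from every target
#'   lineage's simulated stem state; a supplied residue equal to a stem
#'   state is an error, as are injections onto nocturnal tips.
#' @param seed Random seed (default 20221212).
#' @return A list: `alignment` (a [protein_alignment()] of the tips),
#'   `node_states` (all-nodes x sites character matrix, rows named by ape
#'   node number), `rates` (per-site rate multipliers) and `tree`.
#' @export
simulate_protein_evolution <- function(tree, model, n_sites = 300,
                                       injections = NULL, seed = 20221212) {
  stopifnot(inherits(tree, "labeled_phylogeny"),
            inherits(model, "aa_subst_model"))
  phy <- ape::reorder.phylo(tree$tree, "postorder")
  if (is.null(phy$edge.length)) abort("Tree needs branch lengths.")
  set.seed(seed)
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  root <- n_tip + 1L
  rates <- if (length(model$rates) == 1) rep(1, n_sites) else
    sample(model$rates, n_sites, replace = TRUE)
  states <- matrix(NA_integer_, n_node, n_sites)
  states[root, ] <- sample.int(20, n_sites, replace = TRUE,
                               prob = model$freqs)
  edge_order <- rev(seq_len(nrow(phy$edge)))  # preorder
  rate_vals <- sort(unique(rates))
  for (e in edge_order) {
    u <- phy$edge[e, 1]; v <- phy$edge[e, 2]
    for (r in rate_vals) {
      sel <- which(rates == r)
      if (length(sel) == 0) next
      p <- transition_prob(model, phy$edge.length[e], r)
      parent_states <- states[u, sel]
      for (a in unique(parent_states)) {
        ss <- sel[parent_states == a]
        states[v, ss] <- sample.int(20, length(ss), replace = TRUE,
                                    prob = p[a, ])
      }
    }
  }
  if (!is.null(injections) && nrow(injections) > 0) {
    paths <- diurnal_lineage_paths(tree)
    for (row in seq_len(nrow(injections))) {
      site <- injections$site[row]
      if (site > n_sites) abort("Injected site exceeds n_sites.")
      tips <- injections$tips[[row]]
      hits <- match(tips, paths$tip)
      if (anyNA(hits)) {
        abort(paste0("Injection target(s) not diurnal lineage tips: ",
                     paste(tips[is.na(hits)], collapse = ", ")))
      }
      stem_states <- vapply(hits, function(h) states[paths$nodes[[h]][1], site],
                            integer(1))
      res <- if (is.na(injections$residue[row])) {
        # smallest residue (alphabet order) unequal to every stem state
        setdiff(seq_len(20L), stem_states)[1]
      } else {
        match(injections$residue[row], AA_ALPHABET)
      }
      if (is.na(res)) abort("Injected residue must be a standard amino acid.")
      if (any(stem_states == res)) {
        abort("Injected derived residue equals an ancestral state at that site.")
      }
      for (h in hits) {
        nodes <- paths$nodes[[h]]
        states[nodes[-1], site] <- res
      }
    }
  }
  chars <- matrix(AA_ALPHABET[states], n_node, n_sites)
  rownames(chars) <- as.character(seq_len(n_node))
  aln <- chars[seq_len(n_tip), , drop = FALSE]
  rownames(aln) <- phy$tip.label
  list(alignment = protein_alignment(aln),
       node_states = chars, rates = rates, tree = tree)
}
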