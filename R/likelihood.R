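# --- internal: tree bookkeeping ---------------------------------------------

# postorder edge matrix plus children lists, tips first (ape convention)
tree_index <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  list(tree = tree,
       n_tip = length(tree$tip.label),
       n_node = length(tree$tip.label) + tree$Nnode,
       root = length(tree$tip.label) + 1L)
}

# 20 x S indicator partials for one tip; gaps and X are missing data
tip_partial <- function(residues) {
  s <- length(residues)
  m <- matrix(0, 20, s)
  known <- residues %in% AA_ALPHABET
  m[, !known] <- 1
  if (any(known)) {
    m[cbind(match(residues[known], AA_ALPHABET), which(known))] <- 1
  }
  m
}

# One upward (pruning) pass for a single rate category.
# Returns per-node partials `up`, per-node log scale vectors, per-edge
# child->parent messages `msg`, and per-site log-likelihood.
pruning_pass <- function(alignment, tree, model, rate) {
  ti <- tree_index(tree)
  tr <- ti$tree
  n_sites <- ncol(alignment)
  up <- vector("list", ti$n_node)
  uplog <- vector("list", ti$n_node)
  msg <- vector("list", nrow(tr$edge))
  for (i in seq_len(ti$n_tip)) {
    seq_i <- unclass(alignment)[tr$tip.label[i], ]
    up[[i]] <- tip_partial(seq_i)
    uplog[[i]] <- numeric(n_sites)
  }
  parents <- tr$edge[, 1]
  children <- tr$edge[, 2]
  for (e in seq_along(parents)) {
    u <- parents[e]; v <- children[e]
    p <- transition_prob(model, tr$edge.length[e], rate)
    m <- p %*% up[[v]]
    msg[[e]] <- list(m = m, log = uplog[[v]])
    if (is.null(up[[u]])) {
      up[[u]] <- m
      uplog[[u]] <- uplog[[v]]
    } else {
      up[[u]] <- up[[u]] * m
      uplog[[u]] <- uplog[[u]] + uplog[[v]]
    }
    # rescale to dodge underflow
    sc <- apply(up[[u]], 2, max)
    sc[sc == 0] <- 1
    up[[u]] <- up[[u]] / rep(sc, each = 20)
    uplog[[u]] <- uplog[[u]] + log(sc)
  }
  site_l <- colSums(model$freqs * up[[ti$root]])
  list(ti = ti, up = up, uplog = uplog, msg = msg,
       site_loglik = log(site_l) + uplog[[ti$root]])
}

# Downward pass complementing `pruning_pass` (for marginal reconstruction).
downward_pass <- function(pass, model, rate) {
  ti <- pass$ti
  tr <- ti$tree
  n_sites <- length(pass$site_loglik)
  down <- vector("list", ti$n_node)
  dnlog <- vector("list", ti$n_node)
  down[[ti$root]] <- matrix(model$freqs, 20, n_sites)
  dnlog[[ti$root]] <- numeric(n_sites)
  parents <- tr$edge[, 1]
  # preorder = reverse postorder
  for (e in rev(seq_along(parents))) {
    u <- parents[e]; v <- tr$edge[e, 2]
    sib_edges <- setdiff(which(parents == u), e)
    h <- down[[u]]
    hlog <- dnlog[[u]]
    for (se in sib_edges) {
      h <- h * pass$msg[[se]]$m
      hlog <- hlog + pass$msg[[se]]$log
    }
    p <- transition_prob(model, tr$edge.length[e], rate)
    d <- crossprod(p, h)           # t(P) %*% h
    sc <- apply(d, 2, max)
    sc[sc == 0] <- 1
    down[[v]] <- d / rep(sc, each = 20)
    dnlog[[v]] <- hlog + log(sc)
  }
  list(down = down, dnlog = dnlog)
}

#' Pruning-algorithm log-likelihood of an alignment on a tree
#'
#' Felsenstein's pruning algorithm under an [substitution_model()],
#' averaging over the model's discrete-gamma rate categories. Gap and `X`
#' columns are treated as missing data at the affected tips.
#'
#' @param alignment A [protein_alignment()] whose row names include every
#'   tip label.
#' @param tree A rooted `phylo` (or [labeled_phylogeny()]) with branch
#'   lengths in expected substitutions per site.
#' @param model An [substitution_model()].
#' @return The total log-likelihood (numeric scalar) with per-site values
#'   in attribute `"site_loglik"`.
#' @export
loglik_pruning <- function(alignment, tree, model) {
  tree <- as_phylo(tree)
  check_tree_alignment(alignment, tree)
  k <- length(model$rates)
  site_ll <- vapply(model$rates,
                    function(r) pruning_pass(alignment, tree, model, r)$site_loglik,
                    numeric(ncol(alignment)))
  site_ll <- matrix(site_ll, ncol = k)
  mx <- apply(site_ll, 1, max)
  site <- mx + log(rowMeans(exp(site_ll - mx)))
  structure(sum(site), site_loglik = site)
}

as_phylo <- function(tree) {
  if (inherits(tree, "labeled_phylogeny")) tree$tree else tree
}

check_tree_alignment <- function(alignment, tree) {
  stopifnot(inherits(alignment, "protein_alignment"), inherits(tree, "phylo"))
  missing <- setdiff(tree$tip.label, rownames(alignment))
  if (length(missing) > 0) {
    abort(paste0("Alignment lacks tree tips: ", paste(missing, collapse = ", ")))
  }
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Cyclic one-dimensional optimisation: each branch length in turn is
#' optimised by golden-section/parabolic search holding the others fixed,
#' sweeping until the log-likelihood improves by less than `tol`.
#'
#' @param alignment A [protein_alignment()].
#' @param tree A rooted `phylo` or [labeled_phylogeny()]; existing branch
#'   lengths are used as starting values, otherwise 0.1.
#' @param model An [substitution_model()].
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_sweeps Maximum passes over all branches (default 25).
#' @param upper Upper bound per branch, substitutions/site (default 5).
#' @return The input tree (same class) with optimised `edge.length` and the
#'   final log-likelihood in attribute `"loglik"`.
#' @export
estimate_branch_lengths <- function(alignment, tree, model, tol = 1e-6,
                                    max_sweeps = 25, upper = 5) {
  lab <- if (inherits(tree, "labeled_phylogeny")) tree else NULL
  phy <- as_phylo(tree)
  if (is.null(phy$edge.length)) {
    phy$edge.length <- rep(0.1, nrow(phy$edge))
  }
  check_tree_alignment(alignment, phy)
  seqs <- apply(unclass(alignment)[phy$tip.label, , drop = FALSE], 1,
                paste, collapse = "")
  if (length(unique(seqs)) == 1) {
    warn("All sequences identical; returning zero branch lengths.")
    phy$edge.length[] <- 0
    return(rewrap(phy, lab, loglik = c(loglik_pruning(alignment, phy, model))))
  }
  ll <- c(loglik_pruning(alignment, phy, model))
  for (sweep in seq_len(max_sweeps)) {
    for (e in seq_len(nrow(phy$edge))) {
      f <- function(t) {
        phy$edge.length[e] <- t
        -c(loglik_pruning(alignment, phy, model))
      }
      opt <- optimize(f, lower = 0, upper = upper, tol = 1e-6)
      phy$edge.length[e] <- opt$minimum
    }
    ll_new <- c(loglik_pruning(alignment, phy, model))
    if (ll_new - ll < tol) {
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  rewrap(phy, lab, loglik = ll)
}

rewrap <- function(phy, lab, loglik) {
  out <- if (is.null(lab)) phy else {
    lab$tree <- phy
    lab
  }
  attr(out, "loglik") <- loglik
  out
}

#' Estimate the gamma shape parameter by a likelihood grid
#'
#' One-dimensional grid search for the discrete-gamma shape alpha in
#' [0.1, 5] (log-spaced), holding branch lengths fixed.
#'
#' @inheritParams loglik_pruning
#' @param frequencies,n_categories Passed to [substitution_model()].
#' @param grid Candidate shape values.
#' @return The shape value with the highest likelihood.
#' @export
estimate_gamma_shape <- function(alignment, tree,
                                 frequencies = "f_gene",
                                 n_categories = 4,
                                 grid = exp(seq(log(0.1), log(5),
                                                length.out = 9))) {
  ll <- vapply(grid, function(a) {
    m <- substitution_model(frequencies, alignment, gamma_shape = a,
                            n_categories = n_categories)
    c(loglik_pruning(alignment, tree, m))
  }, numeric(1))
  grid[which.max(ll)]
}

#' Marginal maximum-likelihood ancestral reconstruction
#'
#' Per internal node and site, the marginal posterior over the 20 amino
#' acids is proportional to the product of the upward partial likelihood,
#' the downward partial from the rest of the tree, and the equilibrium
#' frequencies, summed over rate categories weighted by their site
#' likelihoods. The reported state is the posterior mode; exact ties are
#' broken by the fixed alphabet order (A, R, N, ...) with a warning.
#'
#' @inheritParams loglik_pruning
#' @return An object of class `"ancestral_reconstruction"`: `map`
#'   (internal nodes x sites character matrix of posterior-mode states,
#'   rows named by ape node number), `posterior` (matching matrix of mode
#'   posterior probabilities), `node_map` (ape node numbering of the
#'   reordered tree), `tree` and `alignment`.
#' @export
reconstruct_ancestral <- function(alignment, tree, model) {
  phy <- as_phylo(tree)
  check_tree_alignment(alignment, phy)
  k <- length(model$rates)
  n_sites <- ncol(alignment)
  passes <- lapply(model$rates,
                   function(r) pruning_pass(alignment, phy, model, r))
  downs <- lapply(seq_len(k), function(i)
    downward_pass(passes[[i]], model, model$rates[i]))
  ti <- passes[[1]]$ti
  site_ll <- vapply(passes, function(p) p$site_loglik, numeric(n_sites))
  site_ll <- matrix(site_ll, ncol = k)
  if (any(!is.finite(site_ll[cbind(seq_len(n_sites),
                                   max.col(site_ll))]))) {
    bad <- which(!is.finite(apply(site_ll, 1, max)))
    abort(paste0("Zero likelihood at site(s): ", paste(bad, collapse = ", ")))
  }
  internal <- (ti$n_tip + 1L):ti$n_node
  map <- matrix(NA_character_, length(internal), n_sites,
                dimnames = list(internal, NULL))
  post <- matrix(NA_real_, length(internal), n_sites,
                 dimnames = list(internal, NULL))
  tied <- 0L
  for (v in internal) {
    # log joint P(state, data, category) up to a per-site constant
    num <- matrix(0, 20, n_sites)
    mx <- apply(matrix(vapply(seq_len(k), function(i)
      passes[[i]]$uplog[[v]] + downs[[i]]$dnlog[[v]], numeric(n_sites)),
      ncol = k), 1, max)
    for (i in seq_len(k)) {
      w <- exp(passes[[i]]$uplog[[v]] + downs[[i]]$dnlog[[v]] - mx) / k
      num <- num + passes[[i]]$up[[v]] * downs[[i]]$down[[v]] *
        rep(w, each = 20)
    }
    tot <- colSums(num)
    pr <- num / rep(tot, each = 20)
    idx <- apply(pr, 2, which.max)
    tied <- tied + sum(apply(pr, 2, function(p) sum(p == max(p)) > 1))
    map[as.character(v), ] <- AA_ALPHABET[idx]
    post[as.character(v), ] <- pr[cbind(idx, seq_len(n_sites))]
  }
  if (tied > 0) {
    warn(sprintf("%d node-site posterior tie(s) broken by alphabet order.",
                 tied))
  }
  structure(list(map = map, posterior = post, tree = ti$tree,
                 alignment = alignment, model = model),
            class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat("Marginal ancestral reconstruction:", nrow(x$map), "internal nodes x",
      ncol(x$map), "sites; mean MAP posterior",
      round(mean(x$posterior), 3), "\n")
  invisible(x)
}

# state of any node (tip from the alignment, internal from the MAP states)
node_state <- function(reconstruction, node, sites = NULL) {
  tr <- reconstruction$tree
  n_tip <- length(tr$tip.label)
  s <- if (node <= n_tip) {
    unclass(reconstruction$alignment)[tr$tip.label[node], ]
  } else {
    reconstruction$map[as.character(node), ]
  }
  if (is.null(sites)) s else s[sites]
}
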