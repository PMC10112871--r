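#' Diurnal lineage paths
#'
#' One path per (diurnal clade, member tip): from the clade's stem node —
#' the interior node where the common ancestor of the diurnal clade
#' diverged from its nocturnal relatives — down to that tip. Substitutions
#' on a lineage are read between the stem node's reconstructed state and
#' the tip's observed state.
#'
#' @param tree A [labeled_phylogeny()].
#' @return A tibble with one row per path: `clade`, `tip`, `stem_node`
#'   (ape node number), `nodes` (list column, stem to tip), `edges` (list
#'   column of edge indices) and `path_length` (sum of branch lengths, NA
#'   if the tree has none).
#' @examples
#' diurnal_lineage_paths(hawkmoth_tree())
#' @export
diurnal_lineage_paths <- function(tree) {
  stopifnot(inherits(tree, "labeled_phylogeny"))
  phy <- tree$tree
  n_tip <- length(phy$tip.label)
  parent_of <- function(node) phy$edge[phy$edge[, 2] == node, 1]
  purrr::imap_dfr(tree$clades, function(members, tag) {
    crown <- if (length(members) > 1) {
      ape::getMRCA(phy, members)
    } else {
      match(members, phy$tip.label)
    }
    stem <- parent_of(crown)
    if (length(stem) != 1) {
      abort(paste0("Clade ", tag, " has no stem node (clade spans the root)."))
    }
    purrr::map_dfr(members, function(tip_label) {
      tip <- match(tip_label, phy$tip.label)
      nodes <- tip
      while (nodes[1] != stem) {
        nodes <- c(parent_of(nodes[1]), nodes)
      }
      edges <- vapply(seq_len(length(nodes) - 1), function(i) {
        which(phy$edge[, 1] == nodes[i] & phy$edge[, 2] == nodes[i + 1])
      }, integer(1))
      plen <- if (is.null(phy$edge.length)) NA_real_
              else sum(phy$edge.length[edges])
      tibble(clade = tag, tip = tip_label, stem_node = stem,
             nodes = list(nodes), edges = list(edges), path_length = plen)
    })
  })
}

#' Enumerate between-clade lineage pairs
#'
#' All unordered pairs of diurnal lineage paths whose clade tags differ;
#' the unit of the parallel-substitution test.
#'
#' @param paths Output of [diurnal_lineage_paths()].
#' @return Tibble with columns `pair` (label), `i`, `j` (row indices into
#'   `paths`), `clade_1`, `tip_1`, `clade_2`, `tip_2`.
#' @examples
#' nrow(enumerate_lineage_pairs(diurnal_lineage_paths(hawkmoth_tree())))
#' @export
enumerate_lineage_pairs <- function(paths) {
  stopifnot(is.data.frame(paths), nrow(paths) >= 2)
  if (length(unique(paths$clade)) < 2) {
    abort("Need lineages from at least two clades.")
  }
  idx <- utils::combn(nrow(paths), 2)
  keep <- paths$clade[idx[1, ]] != paths$clade[idx[2, ]]
  idx <- idx[, keep, drop = FALSE]
  tibble(
    pair = paste0(paths$tip[idx[1, ]], " / ", paths$tip[idx[2, ]]),
    i = idx[1, ], j = idx[2, ],
    clade_1 = paths$clade[idx[1, ]], tip_1 = paths$tip[idx[1, ]],
    clade_2 = paths$clade[idx[2, ]], tip_2 = paths$tip[idx[2, ]])
}

# per-lineage site table: ancestral (stem) and derived (tip) states
lineage_states <- function(path_row, reconstruction) {
  anc <- node_state(reconstruction, path_row$stem_node)
  der <- node_state(reconstruction, path_row$nodes[[1]][length(path_row$nodes[[1]])])
  list(anc = anc, der = der)
}

#' Identify parallel substitutions for one lineage pair
#'
#' A site is a parallel substitution for a pair of lineages when both
#' lineages substituted there, from the same ancestral amino acid (equal
#' reconstructed stem states) to the same derived amino acid (equal tip
#' states), following Zhang and Kumar (1997). Sites where the ancestors
#' differ but the derived states agree are convergent, not parallel, and
#' are tabulated separately, as are parallel indels (both tips gapped at a
#' site that most other taxa retain).
#'
#' Columns with a gap or ambiguity at either lineage's tip, or `X` in
#' either stem reconstruction, are excluded from the substitution scan and
#' routed to the indel report. Multiple hits along one path count once:
#' the comparison is stem state versus tip state.
#'
#' @param path_1,path_2 Single rows of [diurnal_lineage_paths()] output
#'   (from different clades).
#' @param reconstruction An [reconstruct_ancestral()] result.
#' @return A list with `n_parallel` (count), `sites` (tibble of all sites
#'   where both lineages substituted: `site`, `anc_1`, `anc_2`, `der_1`,
#'   `der_2`, `parallel`, `convergent`) and `indels` (tibble `site`,
#'   `type`).
#' @export
find_parallel_substitutions <- function(path_1, path_2, reconstruction) {
  stopifnot(inherits(reconstruction, "ancestral_reconstruction"))
  s1 <- lineage_states(path_1, reconstruction)
  s2 <- lineage_states(path_2, reconstruction)
  aln <- unclass(reconstruction$alignment)
  gap1 <- s1$der == "-" | s1$der == "X"
  gap2 <- s2$der == "-" | s2$der == "X"
  usable <- !gap1 & !gap2 & s1$anc != "X" & s2$anc != "X"
  sub1 <- usable & s1$anc != s1$der
  sub2 <- usable & s2$anc != s2$der
  both <- which(sub1 & sub2)
  sites <- tibble(
    site = both,
    anc_1 = s1$anc[both], der_1 = s1$der[both],
    anc_2 = s2$anc[both], der_2 = s2$der[both]) |>
    dplyr::mutate(
      parallel = .data$anc_1 == .data$anc_2 & .data$der_1 == .data$der_2,
      convergent = .data$anc_1 != .data$anc_2 & .data$der_1 == .data$der_2)
  # parallel indels: both tips gapped where the site is otherwise present
  other <- setdiff(rownames(aln), c(path_1$tip, path_2$tip))
  present_frac <- colMeans(aln[other, , drop = FALSE] != "-")
  del <- which(gap1 & gap2 & present_frac >= 0.5)
  indels <- tibble(site = del,
                   type = rep("parallel_deletion", length(del)))
  list(n_parallel = sum(sites$parallel), sites = sites, indels = indels,
       usable = usable)
}

#' Expected number of parallel substitutions under the model
#'
#' Neutral expectation for a lineage pair: summing over usable sites with
#' equal reconstructed ancestral states `a` at the two stem nodes,
#' \deqn{E = \sum_s \sum_{y \neq a} P_1(a \to y)\, P_2(a \to y),}
#' where \eqn{P_\ell} is the substitution-probability matrix over lineage
#' \eqn{\ell}'s total path length (mixture-averaged over rate categories
#' when the model carries gamma rates). The alternative `"conditional"`
#' mode instead conditions each lineage on its inferred per-site
#' substitution rate: \eqn{E = \sum_s q_1 q_2 \sum_{y \neq a}
#' \tilde P_1(y) \tilde P_2(y)} with \eqn{\tilde P_\ell(y) =
#' P_\ell(a\to y) / (1 - P_\ell(a \to a))} and \eqn{q_\ell} the observed
#' fraction of usable sites substituted on lineage \eqn{\ell}.
#'
#' @inheritParams find_parallel_substitutions
#' @param model The [substitution_model()] used for the expectation
#'   (JTT-f_gene in the standard analysis).
#' @param mode `"path_length"` (default) or `"conditional"`.
#' @return Expected count E (>= 0). Zero-length paths give E = 0.
#' @export
expected_parallel_count <- function(path_1, path_2, reconstruction, model,
                                    mode = c("path_length", "conditional")) {
  mode <- match.arg(mode)
  t1 <- path_1$path_length
  t2 <- path_2$path_length
  if (is.na(t1) || is.na(t2)) abort("Paths need branch lengths.")
  if (t1 == 0 || t2 == 0) return(0)
  s1 <- lineage_states(path_1, reconstruction)
  s2 <- lineage_states(path_2, reconstruction)
  gap1 <- s1$der == "-" | s1$der == "X"
  gap2 <- s2$der == "-" | s2$der == "X"
  usable <- !gap1 & !gap2 & s1$anc != "X" & s2$anc != "X"
  shared <- usable & s1$anc == s2$anc
  if (!any(shared)) return(0)
  p1 <- transition_prob(model, t1, rate = "average")
  p2 <- transition_prob(model, t2, rate = "average")
  a_idx <- match(s1$anc[shared], AA_ALPHABET)
  if (mode == "path_length") {
    # per ancestral state a: sum_y!=a p1[a,y] p2[a,y]
    cross <- rowSums(p1 * p2) - diag(p1) * diag(p2)
    return(sum(cross[a_idx]))
  }
  q1 <- sum(usable & s1$anc != s1$der) / sum(usable)
  q2 <- sum(usable & s2$anc != s2$der) / sum(usable)
  c1 <- p1 / (1 - diag(p1))
  c2 <- p2 / (1 - diag(p2))
  cross <- rowSums(c1 * c2) - diag(c1) * diag(c2)
  sum(q1 * q2 * cross[a_idx])
}

#' Poisson excess test for parallel substitutions
#'
#' Upper-tail Poisson test of whether an observed parallel-substitution
#' count exceeds its neutral expectation: p = P(X >= observed) for
#' X ~ Poisson(E). The null is rejected at p < 0.05 in the standard
#' analysis.
#'
#' @param observed Non-negative integer count of parallel substitutions.
#' @param expected Neutral expectation E (>= 0).
#' @return The p-value in (0, 1]. The degenerate case E = 0 with
#'   observed > 0 returns the smallest positive double with a warning.
#' @examples
#' poisson_parallel_test(5, 1)   # ~0.00366
#' @export
poisson_parallel_test <- function(observed, expected) {
  if (length(observed) != 1 || observed < 0 || observed != round(observed)) {
    abort("`observed` must be a single non-negative integer.")
  }
  if (expected < 0) abort("`expected` must be >= 0.")
  if (observed == 0) return(1)
  if (expected == 0) {
    warn("expected = 0 with observed > 0: p-value below machine precision.")
    return(.Machine$double.xmin)
  }
  ppois(observed - 1, lambda = expected, lower.tail = FALSE)
}

#' Parallel-evolution test across all diurnal lineage pairs
#'
#' End-to-end driver: (optionally) estimates branch lengths, reconstructs
#' ancestral states, enumerates between-clade diurnal lineage pairs, and
#' for each pair reports the observed parallel-substitution count, the
#' model expectation and the Poisson upper-tail p-value.
#'
#' @param alignment A [protein_alignment()] covering all tree tips.
#' @param tree A [labeled_phylogeny()]; branch lengths are estimated if
#'   absent (or when `optimize_lengths = TRUE`).
#' @param model An [substitution_model()], or NULL to build a JTT-f_gene
#'   model from the alignment.
#' @param gamma_shape `NULL` for uniform rates, a number, or
#'   `"estimate"` for a 1-D grid estimate.
#' @param optimize_lengths Re-estimate branch lengths even if present.
#' @param mode Expectation mode, see [expected_parallel_count()].
#' @return A tibble with one row per lineage pair: `pair`, `clade_1`,
#'   `tip_1`, `clade_2`, `tip_2`, `observed`, `expected`, `p_value`,
#'   plus list columns `sites` and `indels`.
#' @export
parallel_test <- function(alignment, tree, model = NULL, gamma_shape = NULL,
                          optimize_lengths = is.null(tree$tree$edge.length),
                          mode = "path_length") {
  stopifnot(inherits(tree, "labeled_phylogeny"))
  if (is.null(model)) {
    if (identical(gamma_shape, "estimate")) {
      stopifnot(!is.null(tree$tree$edge.length))
      gamma_shape <- estimate_gamma_shape(alignment, tree$tree)
    }
    model <- substitution_model("f_gene", alignment, gamma_shape = gamma_shape)
  }
  if (optimize_lengths || is.null(tree$tree$edge.length)) {
    tree <- estimate_branch_lengths(alignment, tree, model)
  }
  rec <- reconstruct_ancestral(alignment, tree$tree, model)
  paths <- diurnal_lineage_paths(tree)
  pairs <- enumerate_lineage_pairs(paths)
  res <- purrr::pmap_dfr(pairs, function(pair, i, j, ...) {
    p1 <- paths[i, ]; p2 <- paths[j, ]
    found <- find_parallel_substitutions(p1, p2, rec)
    e <- expected_parallel_count(p1, p2, rec, model, mode = mode)
    tibble(observed = found$n_parallel, expected = e,
           p_value = poisson_parallel_test(found$n_parallel, e),
           sites = list(found$sites), indels = list(found$indels))
  })
  dplyr::bind_cols(pairs[, c("pair", "clade_1", "tip_1", "clade_2", "tip_2")],
                   res)
}

#' Project alignment columns onto a reference sequence's numbering
#'
#' Reports use residue numbers in the coordinate system of a named
#' reference row (gaps in the reference are skipped), the convention used
#' for opsin site labels such as I38V.
#'
#' @param alignment A [protein_alignment()].
#' @param reference Row name of the reference sequence.
#' @return Integer vector, one entry per alignment column: the reference
#'   residue number, or NA where the reference is gapped.
#' @export
reference_numbering <- function(alignment, reference) {
  stopifnot(inherits(alignment, "protein_alignment"))
  if (!reference %in% rownames(alignment)) {
    abort(paste0("Reference sequence '", reference, "' not in alignment."))
  }
  ref <- unclass(alignment)[reference, ]
  out <- cumsum(ref != "-")
  out[ref == "-"] <- NA_integer_
  as.integer(out)
}
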