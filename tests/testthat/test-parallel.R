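test_that("diurnal lineage paths start at the stem node and share stems within a clade", {
  tr <- hawkmoth_tree()
  paths <- diurnal_lineage_paths(tr)
  expect_equal(nrow(paths), 6)
  counts <- table(paths$clade)
  expect_equal(as.integer(counts[c("D1", "D2", "D3")]), c(2L, 1L, 3L))
  # the two D1 paths share their stem (and hence the stem branch)
  d1 <- dplyr::filter(paths, clade == "D1")
  expect_equal(d1$stem_node[1], d1$stem_node[2])
  expect_equal(intersect(d1$edges[[1]], d1$edges[[2]]), d1$edges[[1]][1])
  # single-species clade still has >= 1 branch ending at its tip
  d2 <- dplyr::filter(paths, clade == "D2")
  expect_gte(length(d2$edges[[1]]), 1)
  tip_id <- match("N_himachala", tr$tree$tip.label)
  expect_equal(tail(d2$nodes[[1]], 1), tip_id)
  # every path is connected parent-to-child
  for (i in seq_len(nrow(paths))) {
    nodes <- paths$nodes[[i]]
    for (j in seq_len(length(nodes) - 1)) {
      expect_true(any(tr$tree$edge[, 1] == nodes[j] &
                        tr$tree$edge[, 2] == nodes[j + 1]))
    }
  }
})

test_that("between-clade pair enumeration matches brute force", {
  paths <- diurnal_lineage_paths(hawkmoth_tree())
  pairs <- enumerate_lineage_pairs(paths)
  expect_equal(nrow(pairs), 11)   # sizes (2, 1, 3): 2*1 + 2*3 + 1*3
  expect_true(all(pairs$clade_1 != pairs$clade_2))
  # brute force over all path pairs
  brute <- 0
  for (i in 1:(nrow(paths) - 1)) for (j in (i + 1):nrow(paths)) {
    if (paths$clade[i] != paths$clade[j]) brute <- brute + 1
  }
  expect_equal(nrow(pairs), brute)
  # (2, 2) design gives 4 pairs
  p22 <- tibble::tibble(clade = c("X", "X", "Y", "Y"),
                        tip = letters[1:4], stem_node = 1:4,
                        nodes = list(1, 2, 3, 4), edges = list(1, 2, 3, 4),
                        path_length = 0.1)
  expect_equal(nrow(enumerate_lineage_pairs(p22)), 4)
  expect_error(enumerate_lineage_pairs(p22[1:2, ]), "two clades")
})

test_that("parallel, divergent and convergent substitutions are classified per definition", {
  tr <- hawkmoth_tree()
  paths <- diurnal_lineage_paths(tr)
  p1 <- dplyr::filter(paths, tip == "C_hylas")
  p2 <- dplyr::filter(paths, tip == "M_pyrrhosticta")
  phy <- tr$tree
  n_tip <- length(phy$tip.label)
  # 6 sites: parallel A->V | divergent A->V/A->L | convergent S->V/A->V |
  #          one-sided A->V | identical | gap at a focal tip
  base <- c("A", "A", "A", "A", "G", "R")
  aln_mat <- matrix(rep(base, each = n_tip), nrow = n_tip,
                    dimnames = list(phy$tip.label, NULL))
  aln_mat["C_hylas", ] <- c("V", "V", "V", "V", "G", "-")
  aln_mat["M_pyrrhosticta", ] <- c("V", "L", "V", "A", "G", "V")
  aln <- protein_alignment(aln_mat)
  map <- matrix(rep(base, each = phy$Nnode), nrow = phy$Nnode,
                dimnames = list((n_tip + 1):(n_tip + phy$Nnode), NULL))
  map[as.character(p2$stem_node), 3] <- "S"   # convergent case: stem2 = S
  rec <- fake_reconstruction(phy, aln, map)
  # note: p2 stem state S at site 3 makes anc_1 = A != anc_2 = S
  res <- find_parallel_substitutions(p1, p2, rec)
  expect_equal(res$n_parallel, 1)
  expect_equal(res$sites$site[res$sites$parallel], 1)
  expect_equal(res$sites$site[res$sites$convergent], 3)
  # divergent double substitution is neither parallel nor convergent
  site2 <- dplyr::filter(res$sites, site == 2)
  expect_false(site2$parallel); expect_false(site2$convergent)
  # one-sided and invariant sites never appear in the both-substituted table
  expect_false(any(res$sites$site %in% c(4, 5)))
  # gap column excluded from substitutions
  expect_false(any(res$sites$site == 6))
  # symmetry in the pair order
  res_swap <- find_parallel_substitutions(p2, p1, rec)
  expect_equal(res_swap$n_parallel, res$n_parallel)
  expect_equal(sort(res_swap$sites$site), sort(res$sites$site))
})

test_that("parallel deletions are reported separately", {
  tr <- hawkmoth_tree()
  paths <- diurnal_lineage_paths(tr)
  p1 <- dplyr::filter(paths, tip == "N_himachala")
  p2 <- dplyr::filter(paths, tip == "M_pyrrhosticta")
  phy <- tr$tree
  n_tip <- length(phy$tip.label)
  aln_mat <- matrix("P", nrow = n_tip, ncol = 3,
                    dimnames = list(phy$tip.label, NULL))
  aln_mat[c("N_himachala", "M_pyrrhosticta"), 2] <- "-"   # shared deletion
  aln_mat[, 3] <- "-"                                     # alignment-wide gap
  rec <- fake_reconstruction(
    phy, protein_alignment(aln_mat),
    matrix("P", phy$Nnode, 3,
           dimnames = list((n_tip + 1):(n_tip + phy$Nnode), NULL)))
  res <- find_parallel_substitutions(p1, p2, rec)
  expect_equal(res$indels$site, 2)
  expect_equal(res$indels$type, "parallel_deletion")
  expect_equal(res$n_parallel, 0)
})

test_that("expected parallel count matches a Monte-Carlo oracle and its edge cases", {
  tr <- hawkmoth_tree()
  paths <- diurnal_lineage_paths(tr)
  p1 <- dplyr::filter(paths, tip == "C_hylas")
  p2 <- dplyr::filter(paths, tip == "M_pyrrhosticta")
  phy <- tr$tree
  n_tip <- length(phy$tip.label)
  mod <- substitution_model("model")
  # all-Alanine toy: every usable site shares ancestral state A
  n_sites <- 5
  aln <- protein_alignment(
    matrix("A", n_tip, n_sites, dimnames = list(phy$tip.label, NULL)))
  rec <- fake_reconstruction(
    phy, aln, matrix("A", phy$Nnode, n_sites,
                     dimnames = list((n_tip + 1):(n_tip + phy$Nnode), NULL)))
  e <- expected_parallel_count(p1, p2, rec, mod)
  # Monte-Carlo oracle: draw derived states independently down each path
  set.seed(41)
  n_mc <- 4e5
  prob1 <- transition_prob(mod, p1$path_length)["A", ]
  prob2 <- transition_prob(mod, p2$path_length)["A", ]
  y1 <- sample.int(20, n_mc, replace = TRUE, prob = prob1)
  y2 <- sample.int(20, n_mc, replace = TRUE, prob = prob2)
  p_par <- mean(y1 == y2 & y1 != 1)
  mc_se <- sqrt(p_par * (1 - p_par) / n_mc)
  expect_equal(e / n_sites, p_par, tolerance = 5 * mc_se / p_par)
  # zero-length path gives E = 0
  p0 <- p1; p0$path_length <- 0
  expect_equal(expected_parallel_count(p0, p2, rec, mod), 0)
  # conditional mode is finite and non-negative
  ec <- expected_parallel_count(p1, p2, rec, mod, mode = "conditional")
  expect_gte(ec, 0)
})

test_that("observed parallel counts match the expectation under neutral evolution", {
  # calibration of the expectation formula against the generator, counting
  # substitutions on the true (simulated) node states so that only the
  # formula - not reconstruction error - is under test
  tr <- hawkmoth_tree()
  phy <- ape::reorder.phylo(tr$tree, "postorder")
  n_tip <- length(phy$tip.label)
  paths <- diurnal_lineage_paths(tr)
  pairs <- enumerate_lineage_pairs(paths)
  gen <- substitution_model("model")
  set.seed(47)
  tot_o <- 0; tot_e <- 0
  for (r in 1:3) {
    sim <- simulate_protein_evolution(tr, gen, n_sites = 2e4,
                                      seed = sample.int(2^31 - 1, 1))
    rec <- fake_reconstruction(
      phy, sim$alignment,
      sim$node_states[(n_tip + 1):nrow(sim$node_states), , drop = FALSE])
    for (k in seq_len(nrow(pairs))) {
      p1 <- paths[pairs$i[k], ]; p2 <- paths[pairs$j[k], ]
      tot_o <- tot_o + find_parallel_substitutions(p1, p2, rec)$n_parallel
      tot_e <- tot_e + expected_parallel_count(p1, p2, rec, gen)
    }
  }
  # Poisson-scale Monte-Carlo error band on the total
  expect_lt(abs(tot_o - tot_e), 3 * sqrt(tot_e))
})

test_that("the Poisson excess test has the right tail and degenerate behaviour", {
  expect_equal(poisson_parallel_test(0, 2.3), 1)
  # direct tail sum at E = 1, observed = 5
  expect_equal(poisson_parallel_test(5, 1), 1 - sum(exp(-1) / factorial(0:4)),
               tolerance = 1e-12)
  expect_equal(poisson_parallel_test(5, 1), 0.003659847, tolerance = 1e-6)
  expect_equal(poisson_parallel_test(0, 0), 1)
  expect_warning(p <- poisson_parallel_test(3, 0), "machine")
  expect_gt(p, 0); expect_lt(p, 1e-200)
  expect_error(poisson_parallel_test(-1, 1), "non-negative")
  expect_error(poisson_parallel_test(1.5, 1), "integer")
})

test_that("the end-to-end parallel test flags injected parallel substitutions", {
  tr <- hawkmoth_tree()
  mod <- substitution_model("model")
  inj <- tibble::tibble(
    site = 1:10, residue = NA_character_,
    tips = rep(list(c("C_hylas", "M_pyrrhosticta")), 10))
  sim <- simulate_protein_evolution(tr, mod, n_sites = 300,
                                    injections = inj, seed = 91)
  res <- parallel_test(sim$alignment, tr,
                       model = substitution_model("f_gene", sim$alignment),
                       optimize_lengths = FALSE)
  expect_equal(nrow(res), 11)
  focal <- dplyr::filter(res, tip_1 == "C_hylas", tip_2 == "M_pyrrhosticta")
  # reconstruction is inferred, not read from the truth, so a site or two of
  # the ten injections may be lost to ancestral-state uncertainty
  expect_gte(focal$observed, 7)
  expect_lt(focal$p_value, 1e-6)
  expect_true(all(res$expected >= 0))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
})

test_that("reference numbering skips reference gaps", {
  aln <- protein_alignment(c(ref = "A-RN-D", other = "AQRNCD"))
  num <- reference_numbering(aln, "ref")
  expect_equal(num, c(1L, NA, 2L, 3L, NA, 4L))
  expect_error(reference_numbering(aln, "nope"), "not in alignment")
})
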