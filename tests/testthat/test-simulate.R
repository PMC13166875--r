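test_that("species trees are ultrametric with unit depth and seeded", {
  st <- simulate_species_tree(5, seed = 1)
  h <- node_heights(st)
  expect_true(all(abs(h[leaf_ids(st) + 1L] - 1) < 1e-9))
  expect_identical(write_newick(simulate_species_tree(5, seed = 1)),
                   write_newick(st))
  st64 <- simulate_species_tree(64, seed = 2)
  expect_equal(st64$n, 127)                       # 64 tips + 63 internals
  expect_setequal(seq_len(st64$n) - 1L, 0:(st64$n - 1))
  expect_error(simulate_species_tree(2), ">= 3")
})

test_that("zero rates give a congruent gene tree with identity assignment", {
  st <- simulate_species_tree(6, seed = 3)
  gt <- simulate_gene_family(st, 0, 0, seed = 4)
  expect_equal(gt$n, st$n)
  # same topology over species labels; branch lengths preserved
  gt_relab <- gt
  gt_relab$label <- sub("\\|.*$", "", gt_relab$label)
  expect_equal(canonical_form(gt_relab), canonical_form(st))
  ta <- attr(gt, "true_assignment")
  expect_equal(ta[gt$root_id + 1L], "root")
  # every non-root branch labelled with its own species branch
  rec <- lca_reconcile(gt, st)
  ab <- assign_branches(rec)
  expect_identical(ab$species_branch_id, ta)
})

test_that("gene family simulation is seed-deterministic", {
  st <- simulate_species_tree(8, seed = 5)
  g1 <- simulate_gene_family(st, 0.2, 0.1, seed = 6)
  g2 <- simulate_gene_family(st, 0.2, 0.1, seed = 6)
  expect_identical(write_newick(g1), write_newick(g2))
  expect_identical(attr(g1, "true_assignment"), attr(g2, "true_assignment"))
  expect_error(simulate_gene_family(st, 10, 0), "runaway")
})

test_that("mean copy number per species follows the branching process", {
  # with no loss, E[copies per species] = exp(lambda_d * depth) = exp(0.3)
  st <- simulate_species_tree(4, seed = 7)
  set.seed(8)
  lam <- 0.3
  tot <- 0L
  n_rep <- 2000
  for (r in seq_len(n_rep)) {
    gt <- simulate_gene_family(st, lam, 0)
    tot <- tot + sum(gt$is_leaf)
  }
  mean_copies <- tot / (n_rep * 4)
  se <- 0.05  # conservative MC bound for 8000 species draws
  expect_lt(abs(mean_copies - exp(lam)), 3 * se)
})

test_that("reconciliation recovers true branch assignments at low rates", {
  set.seed(9)
  st <- simulate_species_tree(8)
  hits <- 0L; total <- 0L
  for (r in 1:300) {
    gt <- simulate_gene_family(st, 0.1, 0.05)
    ta <- attr(gt, "true_assignment")
    rec <- lca_reconcile(gt, st)
    ab <- assign_branches(rec)$species_branch_id
    nonroot <- setdiff(seq_len(gt$n) - 1L, gt$root_id)
    hits <- hits + sum(ab[nonroot + 1L] == ta[nonroot + 1L])
    total <- total + length(nonroot)
  }
  expect_gte(hits / total, 0.95)
})

test_that("planted selection follows the stated probability model", {
  set.seed(10)
  n <- 4000
  asg <- sample(c("t", "o"), n, replace = TRUE)
  rec <- plant_selection(asg, "d1", "g1", seq_len(n), p0 = 0.05, f = 2,
                         transition_branches = "t")
  # on transition: selected fraction ~ 2 * p0; off: ~ p0
  on <- rec$true_selected[asg == "t"]; off <- rec$true_selected[asg == "o"]
  expect_lt(abs(mean(on) - 0.1), 3 * sqrt(0.1 * 0.9 / length(on)))
  expect_lt(abs(mean(off) - 0.05), 3 * sqrt(0.05 * 0.95 / length(off)))
  # significance at alpha = 0.05 is exactly the planted indicator
  expect_identical(rec$p_value < 0.05, rec$true_selected)
  # f = 0: no selected branches on transitions
  rec0 <- plant_selection(asg, "d1", "g1", seq_len(n), p0 = 0.05, f = 0,
                          transition_branches = "t")
  expect_false(any(rec0$true_selected[asg == "t"]))
  # seeded determinism
  a <- plant_selection(asg, "d", "g", seq_len(n), 0.05, 1, "t", seed = 11)
  b <- plant_selection(asg, "d", "g", seq_len(n), 0.05, 1, "t", seed = 11)
  expect_identical(a, b)
})

test_that("trait simulation respects shifts and seeds", {
  st <- simulate_species_tree(8, seed = 12)
  # BM with sigma2 = 0: all leaves equal the root value
  bm0 <- simulate_traits(st, "BM", list(sigma2 = 0, root = 1.5))
  expect_true(all(bm0$tip_values == 1.5))
  # Mk with rate -> 0 and one forced shift: two states split by the clade
  internal <- setdiff(which(!st$is_leaf) - 1L, st$root_id)
  shift <- internal[1]
  mk0 <- simulate_traits(st, "Mk",
                         list(Q = mk_Q(1e-9, 2, "ER"), states = c("A", "B")),
                         shift_branches = shift)
  below <- function(v) {   # leaves under v
    if (st$is_leaf[v + 1L]) return(st$label[v + 1L])
    unlist(lapply(st$children[[v + 1L]], below))
  }
  clade <- below(shift)
  expect_true(all(mk0$tip_values[clade] == "B"))
  expect_true(all(mk0$tip_values[setdiff(names(mk0$tip_values), clade)]
                  == "A"))
  s1 <- simulate_traits(st, "BM", list(), seed = 13)
  s2 <- simulate_traits(st, "BM", list(), seed = 13)
  expect_identical(s1, s2)
})

test_that("whole-dataset simulation is deterministic given a seed", {
  d1 <- simulate_or_dataset(n_gene_trees = 20, seed = 14)
  d2 <- simulate_or_dataset(n_gene_trees = 20, seed = 14)
  expect_identical(d1$records, d2$records)
  expect_identical(write_newick(d1$species_tree),
                   write_newick(d2$species_tree))
  expect_identical(d1$truth$transition_branches,
                   d2$truth$transition_branches)
})
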