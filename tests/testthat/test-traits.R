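test_that("two-state single-branch likelihood matches the closed form", {
  # cherry with one zero-length tip isolates a single branch of length t:
  # P(same state at both ends) = (1 + exp(-2 q t)) / 2 under ER
  for (q in c(0.3, 1.5)) {
    for (t in c(0.4, 2)) {
      st <- parse_newick(sprintf("(A:%g,B:0.0);", t), "species")
      Q <- mk_Q(q, 2, "ER")
      ll_same <- mk_loglik(st, c(A = "x", B = "x"), c("x", "y"), Q)
      expect_equal(exp(ll_same), (1 + exp(-2 * q * t)) / 2 / 2,
                   tolerance = 1e-10)   # extra 1/2 = uniform root prior
      ll_diff <- mk_loglik(st, c(A = "x", B = "y"), c("x", "y"), Q)
      expect_equal(exp(ll_diff), (1 - exp(-2 * q * t)) / 2 / 2,
                   tolerance = 1e-10)
    }
  }
})

test_that("pruning equals brute-force summation over ancestral states", {
  set.seed(23)
  for (rep in 1:6) {
    n <- sample(4:6, 1)
    m <- sample(2:3, 1)
    st <- parse_newick(random_newick(n), "species")
    ss <- letters[seq_len(m)]
    states <- setNames(sample(ss, n, replace = TRUE),
                       st$label[st$is_leaf])
    rates <- runif(m * (m - 1), 0.1, 1.2)
    Q <- mk_Q(rates, m, "ARD")
    expect_equal(mk_loglik(st, states, ss, Q),
                 mk_brute_loglik(st, states, ss, Q), tolerance = 1e-8)
  }
})

test_that("mk_fit maximizes the likelihood and computes AIC", {
  set.seed(24)
  st <- simulate_species_tree(16)
  sim <- simulate_traits(st, "Mk",
                         list(Q = mk_Q(0.8, 2, "ER"), states = c("A", "B")))
  fit <- mk_fit(st, sim$tip_values, "ER")
  expect_equal(fit$AIC, 2 * 1 - 2 * fit$logLik)
  # matches an independent ML fit of the same model
  pf <- phytools::fitMk(as_phylo(st), sim$tip_values, model = "ER",
                        pi = "equal")
  expect_equal(fit$logLik, as.numeric(stats::logLik(pf)), tolerance = 1e-4)
  # ER is nested in ARD
  fit_ard <- mk_fit(st, sim$tip_values, "ARD")
  expect_gte(fit_ard$logLik, fit$logLik - 1e-6)
  sel <- mk_select(st, sim$tip_values)
  expect_equal(sel$selected$AIC, min(sel$ER$AIC, sel$ARD$AIC))
})

test_that("a stationary root prior reweights the root distribution", {
  set.seed(32)
  st <- simulate_species_tree(12)
  sim <- simulate_traits(st, "Mk",
                         list(Q = mk_Q(c(2, 0.4), 2, "ARD"),
                              states = c("A", "B")))
  fu <- mk_fit(st, sim$tip_values, "ARD")
  fs <- mk_fit(st, sim$tip_values, "ARD", root_prior = "stationary")
  expect_equal(sum(fs$root_prior), 1)
  expect_equal(fu$root_prior, c(0.5, 0.5))
  # under ARD the stationary prior is not uniform, so the fits differ
  expect_false(isTRUE(all.equal(fs$root_prior, c(0.5, 0.5))))
  m <- marginal_states(fs)
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))
})

test_that("symmetric two-leaf conflict gives 50/50 root marginals", {
  st <- parse_newick("(A:1,B:1);", "species")
  fit <- mk_fit(st, c(A = "x", B = "y"), "ER")
  marg <- marginal_states(fit)
  expect_equal(unname(marg[st$root_id + 1L, ]), c(0.5, 0.5),
               tolerance = 1e-9)
  expect_true(all(abs(rowSums(marg) - 1) < 1e-9))
})

test_that("marginals match brute-force state-assignment summation", {
  set.seed(25)
  st <- parse_newick("((A:0.7,B:0.4):0.5,(C:0.9,D:0.3):0.6);", "species")
  ss <- c("x", "y")
  states <- c(A = "x", B = "x", C = "y", D = "x")
  Q <- mk_Q(c(0.6, 1.1), 2, "ARD")
  fit <- structure(list(states = ss, model = "ARD", Q = Q, tree = st,
                        tip_states = states), class = "mk_fit")
  marg <- marginal_states(fit)
  for (v in which(!st$is_leaf) - 1L) {
    expect_equal(unname(marg[v + 1L, ]),
                 mk_brute_marginal(st, states, ss, Q, v), tolerance = 1e-8)
  }
})

test_that("near-zero rates pin ancestors to the shared tip state", {
  st <- fixture_species_tree()
  states <- setNames(rep("w", 6), paste0("S", 1:6))
  expect_warning(fit <- mk_fit(st, states, "ER",
                               state_set = c("w", "z")), "degenerate")
  # with two declared states but one observed, reconstruct with tiny rate
  fit2 <- structure(list(states = c("w", "z"), model = "ER",
                         Q = mk_Q(1e-8, 2, "ER"), tree = st,
                         tip_states = states), class = "mk_fit")
  marg <- marginal_states(fit2)
  expect_true(all(marg[, "w"] > 0.999))
})

test_that("Brownian ancestral estimates are precision-weighted averages", {
  st <- parse_newick("(A:1,B:1);", "species")
  est <- brownian_ancestral(st, c(A = 0, B = 4))
  expect_equal(est[st$root_id + 1L], 2)
  st2 <- parse_newick("(A:1,B:3);", "species")
  est2 <- brownian_ancestral(st2, c(A = 0, B = 4))
  expect_equal(est2[st2$root_id + 1L], 1)      # (0/1 + 4/3) / (1 + 1/3)
  # constant input reconstructs constant everywhere
  st3 <- fixture_species_tree()
  est3 <- brownian_ancestral(st3, setNames(rep(2.5, 6), paste0("S", 1:6)))
  expect_true(all(abs(est3 - 2.5) < 1e-12))
})

test_that("Brownian estimates match rerooted-GLS and ignore leaf order", {
  set.seed(26)
  st <- simulate_species_tree(10)
  labs <- st$label[st$is_leaf]
  vals <- setNames(rnorm(10), labs)
  est <- brownian_ancestral(st, vals)
  phy <- as_phylo(st)
  fa <- phytools::fastAnc(phy, vals[phy$tip.label])
  # phytools numbers the root Ntip + 1
  expect_equal(est[st$root_id + 1L], unname(fa[as.character(11)]),
               tolerance = 1e-8)
  est_shuffled <- brownian_ancestral(st, vals[sample(labs)])
  expect_equal(est, est_shuffled)
})

test_that("transition branches are called by the stated rules", {
  st <- parse_newick("((A:1,B:1):1,C:1);", "species")
  n <- st$n
  marg <- matrix(0.5, n, 2, dimnames = list(NULL, c("s1", "s2")))
  ab <- st$parent[match("A", st$label)]
  marg[st$root_id + 1L, ] <- c(0.9, 0.1)
  marg[ab + 1L, ] <- c(0.1, 0.9)
  marg[match("A", st$label), ] <- c(0.05, 0.95)
  marg[match("B", st$label), ] <- c(0.05, 0.95)
  marg[match("C", st$label), ] <- c(0.9, 0.1)
  tr <- detect_transitions(st, marg, "discrete", floor = 0.7)
  expect_equal(nrow(tr), 1)     # only the root->AB branch changes state
  expect_equal(tr$label, "s1->s2")
  expect_equal(tr$species_branch_id, as.character(ab))
  # parent below the confidence floor suppresses the call
  marg[st$root_id + 1L, ] <- c(0.6, 0.4)
  expect_equal(nrow(detect_transitions(st, marg, "discrete", floor = 0.7)), 0)
  # continuous rule with delta
  est <- numeric(n)
  est[st$root_id + 1L] <- 3.0
  est[ab + 1L] <- 4.0
  est[match(c("A", "B", "C"), st$label)] <- c(4.0, 4.0, 3.0)
  trc <- detect_transitions(st, est, "continuous", delta = 0.5,
                            trait = "colony_size")
  expect_equal(trc$label, "colony_size:increase")
  expect_equal(trc$species_branch_id, as.character(ab))
  expect_error(detect_transitions(st, est, "discrete"), "configuration")
})

test_that("AIC prefers the generating model class for separated rates", {
  set.seed(27)
  st <- simulate_species_tree(48)
  # strongly asymmetric rates: ARD should win often; count over replicates
  Q <- mk_Q(c(2.5, 0.1), 2, "ARD")
  wins <- 0
  for (r in 1:12) {
    sim <- simulate_traits(st, "Mk", list(Q = Q, states = c("A", "B")))
    if (length(unique(sim$tip_values)) < 2) next
    sel <- mk_select(st, sim$tip_values)
    if (sel$selected$model == "ARD") wins <- wins + 1
  }
  expect_gt(wins, 6)
})
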