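test_that("weights are branch length over dataset mean and sum to n", {
  r <- make_records(c(2, 2, 2), c(0.5, 0.5, 0.5))
  expect_equal(normalize_weights(r), c(1, 1, 1))
  r2 <- make_records(c(1, 3), c(0.5, 0.5))
  expect_equal(normalize_weights(r2), c(0.5, 1.5))
  set.seed(8)
  r3 <- make_records(rexp(1000), runif(1000))
  expect_equal(sum(normalize_weights(r3)), 1000, tolerance = 1e-9)
  # two datasets normalized independently
  r4 <- rbind(make_records(c(1, 3), c(0.5, 0.5), dataset = "d1"),
              make_records(c(10, 30), c(0.5, 0.5), dataset = "d2"))
  expect_equal(normalize_weights(r4), c(0.5, 1.5, 0.5, 1.5))
  expect_warning(w <- normalize_weights(make_records(c(0, 0), c(0.5, 0.5))),
                 "degenerate")
  expect_equal(w, c(1, 1))
})

test_that("tally counts significant branches with rounded weighted sizes", {
  tr <- data.frame(label = "t", dataset_id = "d1", species_branch_id = "7")
  r <- make_records(c(1, 1, 1, 1), c(0.01, 0.2, 0.04, 0.5),
                    branch = c("7", "7", "3", "3"))
  tl <- tally(r, tr)
  expect_equal(unclass(tl)[c("N_w", "K", "n_w", "k")],
               list(N_w = 4L, K = 2L, n_w = 2L, k = 1L))
  # no records on the transition branch
  tl0 <- tally(r, data.frame(label = "t", dataset_id = "d1",
                             species_branch_id = "9"))
  expect_equal(tl0$n_w, 0L)
  expect_equal(tl0$k, 0L)
  # weighted: lengths [1,1,2], record 3 on the transition, n_w = round(1.5)
  r2 <- make_records(c(1, 1, 2), c(0.01, 0.5, 0.01),
                     branch = c("3", "3", "7"))
  tl2 <- tally(r2, tr)
  expect_equal(unclass(tl2)[c("N_w", "K", "n_w", "k")],
               list(N_w = 3L, K = 2L, n_w = 2L, k = 1L))
  # weighted-successes reading: K and k are rounded weighted sums too
  tlw <- tally(r2, tr, weighted_successes = TRUE)
  expect_equal(unclass(tlw)[c("N_w", "K", "n_w", "k")],
               list(N_w = 3L, K = 2L, n_w = 2L, k = 2L))
  # root-mapped branches count in the population, never in the draw
  r3 <- make_records(c(1, 1), c(0.01, 0.01), branch = c("root", "root"))
  tlr <- tally(r3, data.frame(label = "t", dataset_id = "d1",
                              species_branch_id = "root"))
  expect_equal(tlr$N_w, 2L)
  expect_equal(tlr$n_w, 0L)
  expect_error(tally(r, tr, valid_branches = "d1:3"), "unknown transition")
})

test_that("hypergeometric p-values match log-factorial enumeration", {
  tl <- structure(list(N_w = 20L, K = 5L, n_w = 8L, k = 2L), class = "tally")
  res <- hypergeom_test(tl)
  expect_equal(res$expected, 2)
  expect_equal(res$fold, 1)
  expect_equal(res$direction, "enrichment")
  expect_equal(res$p_enrich, hyper_tail_oracle(2, 20, 5, 8), tolerance = 1e-12)
  tl4 <- structure(list(N_w = 20L, K = 5L, n_w = 8L, k = 4L), class = "tally")
  res4 <- hypergeom_test(tl4)
  expect_equal(res4$fold, 2)
  expect_equal(res4$p_enrich, hyper_tail_oracle(4, 20, 5, 8), tolerance = 1e-12)
  expect_equal(res4$p_deplete, hyper_tail_oracle(4, 20, 5, 8, upper = FALSE),
               tolerance = 1e-12)
  # saturated case
  sat <- hypergeom_test(structure(list(N_w = 6L, K = 6L, n_w = 6L, k = 6L),
                                  class = "tally"))
  expect_equal(sat$fold, 1)
  expect_equal(sat$p_enrich, 1)
  expect_error(hypergeom_test(structure(list(N_w = 0L, K = 0L, n_w = 0L,
                                             k = 0L), class = "tally")),
               "empty population")
})

test_that("the two one-sided p-values share the observed point mass", {
  set.seed(13)
  for (i in 1:40) {
    N <- sample1(5:50); K <- sample1(0:N); n <- sample1(0:N)
    k <- sample1(max(0, n - (N - K)):min(n, K))
    res <- hypergeom_test(structure(list(N_w = N, K = K, n_w = n, k = k),
                                    class = "tally"))
    expect_gte(res$p_enrich + res$p_deplete, 1)
    expect_equal(res$p_reported,
                 if (res$direction == "enrichment") res$p_enrich
                 else res$p_deplete)
  }
})

test_that("pooling sums components exactly and is order-invariant", {
  t1 <- structure(list(N_w = 10L, K = 1L, n_w = 2L, k = 1L), class = "tally")
  t2 <- structure(list(N_w = 10L, K = 1L, n_w = 2L, k = 0L), class = "tally")
  expect_equal(unclass(pool(list(t1))), unclass(t1))
  p12 <- pool(list(t1, t2))
  expect_equal(unclass(p12)[c("N_w", "K", "n_w", "k")],
               list(N_w = 20L, K = 2L, n_w = 4L, k = 1L))
  set.seed(2)
  ts <- lapply(1:6, function(i) structure(
    list(N_w = sample(10:30, 1), K = sample(0:5, 1), n_w = sample(0:8, 1),
         k = sample(0:3, 1)), class = "tally"))
  shuffled <- ts[sample(6)]
  expect_equal(unclass(pool(ts)), unclass(pool(shuffled)))
})

test_that("Benjamini-Hochberg step-up matches the hand formula", {
  expect_equal(bh_correct(0.05), 0.05)
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(4)
  p <- runif(25)
  q <- bh_correct(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # q non-decreasing in p
  # hand step-up: q_(i) = min_{j >= i} m p_(j) / j
  o <- order(p); m <- length(p)
  qs <- rev(cummin(rev(m * p[o] / seq_len(m))))
  expect_equal(q[o], pmin(qs, 1))
})

test_that("one-sided enrichment tests are separately near size on nulls", {
  # unit-length records: the draw size is the exact branch count, so the
  # conditional null is exactly hypergeometric and each tail controls its
  # level (up to Monte-Carlo error and lattice conservatism)
  set.seed(42)
  n_rep <- 400
  pe <- pd <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    branch <- sample(c("a", "b", "c", "d"), 400, replace = TRUE)
    rec <- data.frame(dataset_id = "d1", gene_tree_id = "g",
                      gene_branch_id = seq_along(branch),
                      species_branch_id = branch,
                      branch_length = 1, p_value = runif(400))
    res <- enrichment_test(rec, data.frame(label = "t", dataset_id = "d1",
                                           species_branch_id = "a"))
    pe[r] <- res$p_enrich; pd[r] <- res$p_deplete
  }
  # 3 MC standard errors above the nominal level
  slack <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lte(mean(pe < 0.05), 0.05 + slack)
  expect_lte(mean(pd < 0.05), 0.05 + slack)
})

test_that("enrichment_test pools by label and corrects across labels", {
  r <- rbind(
    make_records(rep(1, 10), c(rep(0.01, 4), rep(0.9, 6)),
                 branch = c(rep("5", 4), rep("3", 6)), dataset = "d1"),
    make_records(rep(1, 10), c(0.01, rep(0.9, 9)),
                 branch = c(rep("5", 2), rep("3", 8)), dataset = "d2"))
  tr <- data.frame(label = c("up", "up", "flat"),
                   dataset_id = c("d1", "d2", "d1"),
                   species_branch_id = c("5", "5", "3"))
  res <- enrichment_test(r, tr)
  expect_equal(nrow(res), 2)
  up <- res[res$label == "up", ]
  expect_equal(up$N_w, 20)
  expect_equal(up$n_w, 6)
  expect_equal(up$k, 5)
  expect_equal(up$K, 5)
  expect_gt(up$fold, 1)
  expect_equal(res$q_value, bh_correct(res$p_reported))
  # per-branch mode splits members into separate tests
  resb <- enrichment_test(r, tr, per_branch = TRUE)
  expect_equal(nrow(resb), 3)
})
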