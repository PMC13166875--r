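# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration and log-factorial arithmetic only.

# ---- tree utilities ----------------------------------------------------

# canonical string form of a rooted tree: sorts children, rounds lengths;
# two trees are isomorphic (with equal lengths to `digits`) iff their
# canonical forms match
canonical_form <- function(tree, digits = 9) {
  canon <- function(v) {
    l <- format(round(tree$length[v + 1L], digits), nsmall = digits)
    if (tree$is_leaf[v + 1L]) return(paste0(tree$label[v + 1L], ":", l))
    kids <- sort(vapply(tree$children[[v + 1L]], canon, character(1)))
    paste0("(", paste(kids, collapse = ","), "):", l)
  }
  canon(tree$root_id)
}

# random rooted binary tree with exponential branch lengths, as Newick
random_newick <- function(n_leaves) {
  labs <- paste0("L", seq_len(n_leaves))
  nodes <- as.list(labs)
  while (length(nodes) > 1) {
    i <- sample.int(length(nodes), 2)
    merged <- sprintf("(%s:%.6f,%s:%.6f)", nodes[[i[1]]], rexp(1),
                      nodes[[i[2]]], rexp(1))
    nodes <- c(nodes[-i], merged)
  }
  paste0(nodes[[1]], ";")
}

# ---- duplication-loss oracle ------------------------------------------

# exhaustive minimum duplication+loss cost over all valid reconciliation
# maps (every internal gene node assigned any species node that is an
# ancestor-or-equal of both children's images); leaves fixed by leaf_map
dl_oracle <- function(gene_tree, species_tree, leaf_map) {
  sp <- species_tree$parent
  is_anc <- function(a, d) {        # is a an ancestor-or-equal of d
    while (TRUE) {
      if (a == d) return(TRUE)
      if (d == species_tree$root_id) return(FALSE)
      d <- sp[d + 1L]
    }
  }
  internal <- which(!gene_tree$is_leaf) - 1L
  n <- gene_tree$n
  M <- integer(n)
  for (v in which(gene_tree$is_leaf) - 1L)
    M[v + 1L] <- leaf_map[[as.character(v)]]
  # the child of species node s whose subtree contains d (s a strict
  # ancestor of d)
  child_towards <- function(s, d) {
    while (sp[d + 1L] != s) d <- sp[d + 1L]
    d
  }
  cost_of <- function() {
    dup <- logical(n)
    for (v in internal) {
      kids <- M[gene_tree$children[[v + 1L]] + 1L]
      dup[v + 1L] <- if (any(kids == M[v + 1L])) TRUE else {
        # a true speciation needs the children in distinct child subtrees
        sides <- vapply(kids, child_towards, integer(1), s = M[v + 1L])
        anyDuplicated(sides) > 0
      }
    }
    losses <- 0L
    for (v in seq_len(n) - 1L) {
      if (v == gene_tree$root_id) next
      u <- gene_tree$parent[v + 1L]
      if (M[u + 1L] == M[v + 1L]) next
      # walk from M(v) up to M(u), counting strictly-passed species nodes
      w <- sp[M[v + 1L] + 1L]; between <- 0L
      while (w != M[u + 1L]) { between <- between + 1L; w <- sp[w + 1L] }
      losses <- losses + between + as.integer(dup[u + 1L])
    }
    sum(dup) + losses
  }
  best <- Inf
  recurse <- function(i) {
    if (i > length(internal)) {
      best <<- min(best, cost_of())
      return(invisible())
    }
    v <- internal[i]               # post-order: children already assigned
    for (s in seq_len(species_tree$n) - 1L) {
      ok <- all(vapply(gene_tree$children[[v + 1L]],
                       function(c) is_anc(s, M[c + 1L]), logical(1)))
      if (ok) {
        M[v + 1L] <<- s
        recurse(i + 1L)
      }
    }
  }
  recurse(1L)
  best
}

# ---- hypergeometric oracle --------------------------------------------

# pmf from log-factorials, summed term by term
hyper_pmf_oracle <- function(x, N, K, n) {
  lf <- function(m) lgamma(m + 1)
  lchoose2 <- function(a, b) {
    if (b < 0 || b > a) return(-Inf)
    lf(a) - lf(b) - lf(a - b)
  }
  exp(lchoose2(K, x) + lchoose2(N - K, n - x) - lchoose2(N, n))
}
hyper_tail_oracle <- function(k, N, K, n, upper = TRUE) {
  xs <- if (upper) k:min(K, n) else max(0, n - (N - K)):k
  sum(vapply(xs, hyper_pmf_oracle, numeric(1), N = N, K = K, n = n))
}

# ---- Sankoff oracle ----------------------------------------------------

# exhaustive minimum over all ancestral count assignments
sankoff_oracle <- function(tree, leaf_counts, max_count) {
  internal <- which(!tree$is_leaf) - 1L
  leaves <- which(tree$is_leaf) - 1L
  x <- integer(tree$n)
  for (v in leaves) x[v + 1L] <- leaf_counts[[tree$label[v + 1L]]]
  best <- Inf
  recurse <- function(i) {
    if (i > length(internal)) {
      cost <- 0L
      for (v in seq_len(tree$n) - 1L) {
        if (v == tree$root_id) next
        cost <- cost + abs(x[v + 1L] - x[tree$parent[v + 1L] + 1L])
      }
      best <<- min(best, cost)
      return(invisible())
    }
    for (s in 0:max_count) {
      x[internal[i] + 1L] <<- s
      recurse(i + 1L)
    }
  }
  recurse(1L)
  best
}

# Wagner (Farris-interval) root state set under linear cost
wagner_root_interval <- function(tree, leaf_counts) {
  lo <- numeric(tree$n); hi <- numeric(tree$n)
  for (v in seq_len(tree$n) - 1L) {
    if (tree$is_leaf[v + 1L]) {
      lo[v + 1L] <- hi[v + 1L] <- leaf_counts[[tree$label[v + 1L]]]
    } else {
      ints <- lapply(tree$children[[v + 1L]], function(c)
        c(lo[c + 1L], hi[c + 1L]))
      # Farris down-pass (binary nodes): intersection when the child
      # intervals overlap, else the gap between them
      l <- max(vapply(ints, `[`, numeric(1), 1))
      h <- min(vapply(ints, `[`, numeric(1), 2))
      if (l <= h) { lo[v + 1L] <- l; hi[v + 1L] <- h }
      else { lo[v + 1L] <- h; hi[v + 1L] <- l }
    }
  }
  c(lo[tree$root_id + 1L], hi[tree$root_id + 1L])
}

# ---- Mk oracle ---------------------------------------------------------

# brute-force likelihood: sum over all internal state assignments of
# pi(root) * prod over branches P[s_parent, s_child](t); P via series
mk_brute_loglik <- function(tree, states, state_set, Q) {
  m <- length(state_set)
  Pm <- lapply(seq_len(tree$n) - 1L, function(v)
    series_expm(Q * tree$length[v + 1L]))
  internal <- which(!tree$is_leaf) - 1L
  s <- integer(tree$n)
  for (v in which(tree$is_leaf) - 1L)
    s[v + 1L] <- match(states[[tree$label[v + 1L]]], state_set)
  total <- 0
  recurse <- function(i) {
    if (i > length(internal)) {
      pr <- 1 / m
      for (v in seq_len(tree$n) - 1L) {
        if (v == tree$root_id) next
        u <- tree$parent[v + 1L]
        pr <- pr * Pm[[v + 1L]][s[u + 1L], s[v + 1L]]
      }
      total <<- total + pr
      return(invisible())
    }
    for (st in seq_len(m)) {
      s[internal[i] + 1L] <<- st
      recurse(i + 1L)
    }
  }
  recurse(1L)
  log(total)
}

# matrix exponential by scaling-and-squaring of the Taylor series
# (independent of ape::matexpo)
series_expm <- function(A, terms = 30) {
  sc <- max(1, 2^ceiling(log2(max(1, max(abs(A))))))
  As <- A / sc
  P <- diag(nrow(A)); term <- diag(nrow(A))
  for (i in seq_len(terms)) {
    term <- term %*% As / i
    P <- P + term
  }
  for (i in seq_len(log2(sc))) P <- P %*% P
  P
}

# brute-force marginal at one node: restrict the sum to assignments with
# node fixed at each state
mk_brute_marginal <- function(tree, states, state_set, Q, node) {
  m <- length(state_set)
  Pm <- lapply(seq_len(tree$n) - 1L, function(v)
    series_expm(Q * tree$length[v + 1L]))
  internal <- which(!tree$is_leaf) - 1L
  s <- integer(tree$n)
  for (v in which(tree$is_leaf) - 1L)
    s[v + 1L] <- match(states[[tree$label[v + 1L]]], state_set)
  acc <- numeric(m)
  recurse <- function(i) {
    if (i > length(internal)) {
      pr <- 1 / m
      for (v in seq_len(tree$n) - 1L) {
        if (v == tree$root_id) next
        u <- tree$parent[v + 1L]
        pr <- pr * Pm[[v + 1L]][s[u + 1L], s[v + 1L]]
      }
      acc[s[node + 1L]] <<- acc[s[node + 1L]] + pr
      return(invisible())
    }
    for (st in seq_len(m)) {
      s[internal[i] + 1L] <<- st
      recurse(i + 1L)
    }
  }
  recurse(1L)
  acc / sum(acc)
}

# draw one element of a vector (unlike sample(), safe for length 1)
sample1 <- function(v) v[sample.int(length(v), 1L)]

# ---- OLS oracle --------------------------------------------------------

ols_oracle <- function(x, y) {
  n <- length(x)
  b <- cov(x, y) * (n - 1) / (var(x) * (n - 1))
  a <- mean(y) - b * mean(x)
  r <- y - a - b * x
  s2 <- sum(r^2) / (n - 2)
  se_b <- sqrt(s2 / sum((x - mean(x))^2))
  list(intercept = a, slope = b, se_slope = se_b,
       t = b / se_b, p = 2 * pt(abs(b / se_b), n - 2, lower.tail = FALSE))
}
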