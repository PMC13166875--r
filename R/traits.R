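#' Continuous-time Markov (Mk) model fit for a discrete trait
#'
#' Maximum-likelihood fit of the Mk model on a rooted tree with branch
#' lengths, by Felsenstein pruning (post-order conditional likelihoods
#' with transition matrices `exp(Q t)`), a uniform root state prior, and
#' bounded numerical rate maximization. Two rate structures are
#' supported: ER (one rate for every transition) and ARD (one rate per
#' ordered state pair). `AIC = 2 k - 2 logL` with `k` the number of free
#' rates.
#'
#' @param tree species `ortree` with positive branch lengths on internal
#'   paths.
#' @param states named character vector, species label -> observed state;
#'   species with `NA` are pruned from the reconstruction.
#' @param model `"ER"` or `"ARD"`.
#' @param state_set optional explicit state space (default: sorted
#'   observed states).
#' @param root_prior `"uniform"` (flat over states, the default) or
#'   `"stationary"` (the stationary distribution of the fitted `Q`).
#' @return an `mk_fit`: list with `states` (state set), `model`, `rates`,
#'   `Q`, `logLik`, `AIC`, `tree` (possibly pruned), `tip_states`,
#'   `root_prior` (resolved numeric vector).
#' @export
mk_fit <- function(tree, states, model = c("ER", "ARD"), state_set = NULL,
                   root_prior = c("uniform", "stationary")) {
  model <- match.arg(model)
  root_prior <- match.arg(root_prior)
  pr <- prune_to_observed(tree, states)
  tree <- pr$tree; states <- pr$values
  ss <- if (is.null(state_set)) sort(unique(states)) else state_set
  m <- length(ss)
  if (!all(states %in% ss)) stop("observed state outside declared state set")
  if (length(unique(states)) < 2) {
    warning("degenerate trait: single observed state; rate at lower bound")
    np <- if (model == "ER") 1L else max(1L, m * (m - 1L))
    rates <- rep(1e-9, np)
    Q <- mk_Q(rates, m, model)
    dimnames(Q) <- list(ss, ss)
    ll <- if (m < 2) 0 else mk_loglik(tree, states, ss, Q)
    return(structure(list(states = ss, model = model, rates = rates,
                          Q = Q, logLik = ll, AIC = 2 * np - 2 * ll,
                          tree = tree, tip_states = states,
                          root_prior = rep(1 / m, m)),
                     class = "mk_fit"))
  }
  prior_of <- function(Q) {
    if (root_prior == "uniform") rep(1 / m, m) else mk_stationary(Q)
  }
  nll <- function(rates) {
    Q <- mk_Q(rates, m, model)
    ll <- mk_loglik(tree, states, ss, Q, prior_of(Q))
    if (!is.finite(ll)) 1e10 else -ll
  }
  if (model == "ER") {
    opt <- stats::optimize(function(lq) nll(exp(lq)), c(-18, 8))
    rates <- exp(opt$minimum); nllv <- opt$objective
    np <- 1L
  } else {
    np <- m * (m - 1L)
    er <- stats::optimize(function(lq) {
      Q <- mk_Q(exp(lq), m, "ER")
      -mk_loglik(tree, states, ss, Q, prior_of(Q))
    }, c(-18, 8))
    start <- rep(er$minimum, np)
    opt <- stats::optim(start, function(lq) nll(exp(lq)), method = "L-BFGS-B",
                        lower = -18, upper = 8)
    rates <- exp(opt$par); nllv <- opt$value
  }
  if (!is.finite(nllv) || nllv >= 1e10)
    stop("optimization error: non-finite Mk likelihood (rates = ",
         paste(signif(rates, 3), collapse = ","), ")")
  Q <- mk_Q(rates, m, model)
  dimnames(Q) <- list(ss, ss)
  structure(list(states = ss, model = model, rates = rates, Q = Q,
                 logLik = -nllv, AIC = 2 * np + 2 * nllv, tree = tree,
                 tip_states = states, root_prior = prior_of(Q)),
            class = "mk_fit")
}

# stationary distribution of a rate matrix: pi Q = 0, sum(pi) = 1
mk_stationary <- function(Q) {
  m <- nrow(Q)
  A <- rbind(t(Q), rep(1, m))
  pi <- qr.solve(A, c(rep(0, m), 1))
  pmax(pi, 0) / sum(pmax(pi, 0))
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("<mk_fit %s> %d states, logL = %.4f, AIC = %.4f\n",
              x$model, length(x$states), x$logLik, x$AIC))
  invisible(x)
}

# Rate matrix from a rate vector: ER uses rates[1] everywhere, ARD fills
# off-diagonals row-wise in state order.
mk_Q <- function(rates, m, model) {
  Q <- matrix(0, m, m)
  if (model == "ER") {
    Q[] <- rates[1]
  } else {
    Q[row(Q) != col(Q)] <- 0
    idx <- which(row(Q) != col(Q), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    Q[idx] <- rates
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Mk log-likelihood at a fixed rate matrix
#'
#' Felsenstein pruning with per-node rescaling. Exposed so that
#' likelihoods can be evaluated on a fixed `Q` without refitting.
#'
#' @param tree an `ortree`.
#' @param states named tip states; @param state_set state space in matrix
#'   order; @param Q rate matrix (rows sum to 0).
#' @param root_prior numeric state prior at the root (default uniform).
#' @return the log-likelihood.
#' @export
mk_loglik <- function(tree, states, state_set, Q, root_prior = NULL) {
  m <- length(state_set)
  if (is.null(root_prior)) root_prior <- rep(1 / m, m)
  cl <- mk_conditionals(tree, states, state_set, Q)
  root <- tree$root_id
  log(sum(cl$L[root + 1L, ] * root_prior)) + cl$scale[root + 1L]
}

# Post-order conditional likelihoods L[v, s] = P(tips below v | state s),
# rescaled per node; scale[v] accumulates the log correction for the
# whole subtree under v.
mk_conditionals <- function(tree, states, state_set, Q) {
  m <- length(state_set)
  L <- matrix(1, tree$n, m)
  scale <- numeric(tree$n)
  P <- lapply(seq_len(tree$n) - 1L, function(v)
    ape::matexpo(Q * tree$length[v + 1L]))
  for (v in seq_len(tree$n) - 1L) {
    if (tree$is_leaf[v + 1L]) {
      s <- states[[tree$label[v + 1L]]]
      L[v + 1L, ] <- as.numeric(state_set == s)
    } else {
      acc <- rep(1, m); sc <- 0
      for (c in tree$children[[v + 1L]]) {
        acc <- acc * as.numeric(P[[c + 1L]] %*% L[c + 1L, ])
        sc <- sc + scale[c + 1L]
      }
      mx <- max(acc)
      if (mx <= 0) return(list(L = L * 0, scale = rep(-Inf, tree$n)))
      L[v + 1L, ] <- acc / mx
      scale[v + 1L] <- sc + log(mx)
    }
  }
  list(L = L, scale = scale, P = P)
}

#' Marginal ancestral state probabilities
#'
#' Standard marginal reconstruction combining the downward conditional
#' likelihoods with the upward partial likelihoods (the likelihood of the
#' rest of the tree given the state at the node). Every returned row sums
#' to 1.
#'
#' @param fit an `mk_fit`.
#' @return matrix `n_nodes x n_states` of marginal probabilities, rows
#'   indexed by `node id + 1`, columns named by state.
#' @export
marginal_states <- function(fit) {
  tree <- fit$tree; ss <- fit$states; m <- length(ss)
  cl <- mk_conditionals(tree, fit$tip_states, ss, fit$Q)
  L <- cl$L; P <- cl$P
  G <- matrix(0, tree$n, m)            # upward partials (unnormalized)
  G[tree$root_id + 1L, ] <- fit$root_prior %||% rep(1 / m, m)
  for (u in rev(seq_len(tree$n) - 1L)) {      # pre-order
    if (tree$is_leaf[u + 1L]) next
    kids <- tree$children[[u + 1L]]
    down <- lapply(kids, function(c) as.numeric(P[[c + 1L]] %*% L[c + 1L, ]))
    for (i in seq_along(kids)) {
      c <- kids[i]
      sib <- rep(1, m)
      for (j in seq_along(kids)) if (j != i) sib <- sib * down[[j]]
      gu <- G[u + 1L, ] * sib          # at parent, excluding subtree of c
      G[c + 1L, ] <- as.numeric(t(P[[c + 1L]]) %*% gu)
      G[c + 1L, ] <- G[c + 1L, ] / max(G[c + 1L, ])
    }
  }
  marg <- G * L
  marg <- marg / rowSums(marg)
  colnames(marg) <- ss
  marg
}

#' Fit ER and ARD and select by AIC
#'
#' @inheritParams mk_fit
#' @return list with `ER`, `ARD` (both `mk_fit`s) and `selected` (the fit
#'   with the lower AIC; ties favour the simpler ER).
#' @export
mk_select <- function(tree, states, state_set = NULL) {
  er <- mk_fit(tree, states, "ER", state_set)
  ard <- mk_fit(tree, states, "ARD", state_set)
  list(ER = er, ARD = ard,
       selected = if (ard$AIC < er$AIC) ard else er)
}

#' Ancestral means of a continuous trait under Brownian motion
#'
#' Maximum-likelihood (equivalently GLS) ancestral estimates by the
#' two-pass algorithm: a post-order pass of precision-weighted averages
#' giving each subtree's estimate and variance, then a pre-order pass
#' combining each node's subtree with the complement of the tree, which
#' is equivalent to rerooting at every node. The root estimate equals the
#' GLS estimate of the root state.
#'
#' @param tree species `ortree`; leaves without a value are pruned.
#' @param values named numeric vector of tip values.
#' @return numeric vector of estimates indexed by `node id + 1` on the
#'   (possibly pruned) tree, returned with the tree as attribute `tree`.
#' @export
brownian_ancestral <- function(tree, values) {
  pr <- prune_to_observed(tree, values)
  tree <- pr$tree; values <- pr$values
  n <- tree$n
  xd <- numeric(n); vd <- numeric(n)
  eps_used <- FALSE
  safe <- function(l) {
    if (l <= 0) { eps_used <<- TRUE; 1e-8 } else l
  }
  for (v in seq_len(n) - 1L) {
    if (tree$is_leaf[v + 1L]) {
      xd[v + 1L] <- values[[tree$label[v + 1L]]]
      vd[v + 1L] <- 0
    } else {
      kids <- tree$children[[v + 1L]]
      p <- vapply(kids, function(c) 1 / safe(tree$length[c + 1L] + vd[c + 1L]),
                  numeric(1))
      xd[v + 1L] <- sum(p * xd[kids + 1L]) / sum(p)
      vd[v + 1L] <- 1 / sum(p)
    }
  }
  xu <- numeric(n); vu <- rep(NA_real_, n)
  est <- numeric(n)
  root <- tree$root_id
  est[root + 1L] <- xd[root + 1L]
  for (u in rev(seq_len(n) - 1L)) {   # pre-order
    if (tree$is_leaf[u + 1L]) { est[u + 1L] <- xd[u + 1L]; next }
    kids <- tree$children[[u + 1L]]
    for (c in kids) {
      xs <- xd[kids + 1L]; vs <- tree$length[kids + 1L] + vd[kids + 1L]
      keep <- kids != c
      px <- xs[keep]; pv <- vs[keep]
      if (!is.na(vu[u + 1L])) { px <- c(px, xu[u + 1L]); pv <- c(pv, vu[u + 1L]) }
      w <- 1 / vapply(pv, safe, numeric(1))
      xc <- sum(w * px) / sum(w); vc <- 1 / sum(w)
      xu[c + 1L] <- xc
      vu[c + 1L] <- vc + tree$length[c + 1L]
      if (!tree$is_leaf[c + 1L]) {
        wtot <- c(1 / safe(vd[c + 1L]), 1 / safe(vu[c + 1L]))
        # vd can be 0 for a cherry of zero-length tips; safe() regularizes
        est[c + 1L] <- (wtot[1] * xd[c + 1L] + wtot[2] * xu[c + 1L]) / sum(wtot)
      }
    }
  }
  if (eps_used)
    warning("zero-length branch regularized with epsilon = 1e-8")
  attr(est, "tree") <- tree
  est
}

#' Call transition branches from an ancestral reconstruction
#'
#' A species-tree branch is a transition branch when the ancestral
#' reconstruction infers a trait change along it. Discrete rule: the
#' parent's and child's most probable states differ and both maxima reach
#' the confidence floor. Continuous rule: the child-minus-parent estimate
#' exceeds `delta` in absolute value, labelled "increase"/"decrease".
#'
#' @param tree the `ortree` the reconstruction was computed on.
#' @param reconstruction for `kind = "discrete"` a node x state
#'   probability matrix ([marginal_states()]); for `"continuous"` a
#'   per-node estimate vector ([brownian_ancestral()]).
#' @param kind `"discrete"` or `"continuous"`.
#' @param floor minimum parent and child max-probability for a discrete
#'   call (default 0.7).
#' @param delta minimum absolute change for a continuous call, in trait
#'   units (default 0.5).
#' @param trait optional trait name prefixed to the labels.
#' @return data.frame: `label`, `species_branch_id` (one row per
#'   transition branch; empty when none).
#' @export
detect_transitions <- function(tree, reconstruction,
                               kind = c("discrete", "continuous"),
                               floor = 0.7, delta = 0.5, trait = NULL) {
  kind <- match.arg(kind)
  ids <- setdiff(seq_len(tree$n) - 1L, tree$root_id)
  out <- list()
  if (kind == "discrete") {
    if (!is.matrix(reconstruction) || nrow(reconstruction) != tree$n)
      stop("configuration error: discrete rule needs a node x state matrix")
    ss <- colnames(reconstruction)
    for (v in ids) {
      u <- tree$parent[v + 1L]
      pu <- reconstruction[u + 1L, ]; pv <- reconstruction[v + 1L, ]
      if (max(pu) < floor || max(pv) < floor) next
      s <- ss[which.max(pu)]; s2 <- ss[which.max(pv)]
      if (s != s2)
        out[[length(out) + 1L]] <- data.frame(
          label = paste0(s, "->", s2), species_branch_id = as.character(v),
          stringsAsFactors = FALSE)
    }
  } else {
    if (!is.numeric(reconstruction) || length(reconstruction) != tree$n)
      stop("configuration error: continuous rule needs a per-node vector")
    for (v in ids) {
      u <- tree$parent[v + 1L]
      d <- reconstruction[v + 1L] - reconstruction[u + 1L]
      if (abs(d) > delta)
        out[[length(out) + 1L]] <- data.frame(
          label = if (d > 0) "increase" else "decrease",
          species_branch_id = as.character(v), stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) == 0)
    data.frame(label = character(0), species_branch_id = character(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, out)
  if (!is.null(trait) && nrow(res) > 0)
    res$label <- paste0(trait, ":", res$label)
  res
}

# Prune a tree to the leaves observed (non-NA) in a named value vector.
prune_to_observed <- function(tree, values) {
  labs <- tree$label[tree$is_leaf]
  keep <- labs[labs %in% names(values)[!is.na(values)]]
  if (length(keep) < sum(tree$is_leaf)) {
    phy <- as_phylo(tree)
    phy <- ape::drop.tip(phy, setdiff(phy$tip.label, keep))
    if (is.null(phy)) stop("no observed leaves left after pruning")
    tree <- as_ortree(phy, kind = tree$kind)
  }
  list(tree = tree, values = values[keep])
}
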