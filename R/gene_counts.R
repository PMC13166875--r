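#' Ancestral gene-copy numbers by Sankoff parsimony
#'
#' Bottom-up dynamic program over integer copy-number states
#' `0..max_count` followed by a deterministic top-down backtrack. Under
#' the default linear cost (`|s - t|` per branch, one unit per gain or
#' loss) the result coincides with Wagner (Farris-interval) parsimony.
#'
#' Tie-breaking is deterministic: at the root the admissible minimum-cost
#' set (an interval under linear cost) is resolved to its midpoint rounded
#' down; below the root, the admissible state closest to the parent's
#' chosen state wins (then the smaller state).
#'
#' @param tree a species `ortree`.
#' @param leaf_counts named integer vector, species label -> observed copy
#'   number; every leaf must be present.
#' @param cost `"linear"` or a `(max_count+1) x (max_count+1)` matrix of
#'   transition costs `cost[s+1, t+1]` (parent state s, child state t).
#' @param max_count state-space cap; defaults to `max(leaf_counts)`.
#' @return an `ancestral_counts` object: list with `count` (integer per
#'   node, indexed `id + 1`), `cost` (minimal total cost), and the tree.
#' @export
sankoff_counts <- function(tree, leaf_counts, cost = "linear",
                           max_count = NULL) {
  leaves <- leaf_ids(tree)
  labs <- tree$label[leaves + 1L]
  miss <- setdiff(labs, names(leaf_counts))
  if (length(miss) > 0)
    stop("missing leaf counts for: ", paste(miss, collapse = ", "))
  x <- leaf_counts[labs]
  if (any(x < 0) || any(x != round(x))) stop("counts must be integers >= 0")
  if (is.null(max_count)) max_count <- max(x)
  if (max_count < max(x))
    stop("configuration error: max_count (", max_count,
         ") below maximum leaf count (", max(x), ")")
  S <- max_count + 1L
  states <- 0:max_count
  cmat <- if (identical(cost, "linear")) {
    abs(outer(states, states, "-"))
  } else {
    stopifnot(is.matrix(cost), all(dim(cost) == S))
    cost
  }
  C <- matrix(Inf, nrow = tree$n, ncol = S)
  for (v in seq_len(tree$n) - 1L) {
    if (tree$is_leaf[v + 1L]) {
      C[v + 1L, ] <- Inf
      C[v + 1L, x[[match(v, leaves)]] + 1L] <- 0
    } else {
      acc <- numeric(S)
      for (c in tree$children[[v + 1L]]) {
        # for each parent state s: min_t cmat[s,t] + C[c,t]
        acc <- acc + apply(sweep(cmat, 2L, C[c + 1L, ], "+"), 1L, min)
      }
      C[v + 1L, ] <- acc
    }
  }
  count <- integer(tree$n)
  root <- tree$root_id
  best <- which(C[root + 1L, ] == min(C[root + 1L, ])) - 1L
  count[root + 1L] <- floor((min(best) + max(best)) / 2)
  for (v in rev(seq_len(tree$n) - 1L)) {  # pre-order
    if (v == root) next
    p <- count[tree$parent[v + 1L] + 1L]
    tot <- cmat[p + 1L, ] + C[v + 1L, ]
    adm <- which(tot == min(tot)) - 1L
    count[v + 1L] <- adm[order(abs(adm - p), adm)][1]
  }
  structure(list(count = count, cost = min(C[root + 1L, ]), tree = tree),
            class = "ancestral_counts")
}

#' Per-branch copy-number changes
#'
#' The expansion/contraction readout: `delta(b) = count(child) -
#' count(parent)` for every non-root branch. Under linear cost the
#' absolute deltas sum to the parsimony cost.
#'
#' @param anc an `ancestral_counts` object from [sankoff_counts()].
#' @return data.frame: `branch_id`, `parent_count`, `child_count`,
#'   `delta`.
#' @export
branch_deltas <- function(anc) {
  tree <- anc$tree
  ids <- setdiff(seq_len(tree$n) - 1L, tree$root_id)
  pc <- anc$count[tree$parent[ids + 1L] + 1L]
  cc <- anc$count[ids + 1L]
  data.frame(branch_id = ids, parent_count = pc, child_count = cc,
             delta = cc - pc)
}

#' Drop mostly-single-copy gene families
#'
#' Families in which almost every species has at most one copy carry no
#' copy-number signal and inflate spurious correlations in the PGLS
#' screen; they are removed before the regression stage.
#'
#' @param counts species x family matrix (or data.frame) of nonnegative
#'   integer counts, species in rows.
#' @param single_copy_frac drop a family when the fraction of species
#'   with count <= 1 strictly exceeds this (default 0.8).
#' @return the filtered count matrix (possibly zero columns).
#' @export
filter_families <- function(counts, single_copy_frac = 0.8) {
  m <- as.matrix(counts)
  if (any(m < 0)) stop("counts must be >= 0")
  frac <- colMeans(m <= 1)
  m[, frac <= single_copy_frac, drop = FALSE]
}
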