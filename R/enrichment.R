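#' Length-normalized branch weights
#'
#' Because a long gene-tree branch is more likely to harbour a detectable
#' selection event than a short one, branch counts entering the
#' hypergeometric test are normalized by branch length: each branch gets
#' weight `length / mean(length)` computed within its dataset (one clade x
#' subfamily combination), so weights sum to the raw branch count per
#' dataset.
#'
#' @param records data.frame of branch test records with columns
#'   `dataset_id`, `gene_tree_id`, `gene_branch_id`, `branch_length`,
#'   `p_value`.
#' @return numeric weight vector aligned with `records` rows.
#' @export
normalize_weights <- function(records) {
  stopifnot(all(c("dataset_id", "branch_length", "p_value") %in% names(records)))
  if (any(records$branch_length < 0)) stop("negative branch lengths")
  if (any(records$p_value < 0 | records$p_value > 1))
    stop("p-values outside [0, 1]")
  means <- tapply(records$branch_length, records$dataset_id, mean)
  if (any(means == 0)) {
    warning("degenerate lengths: all-zero branch lengths in dataset(s) ",
            paste(names(means)[means == 0], collapse = ", "),
            "; falling back to unit weights there")
  }
  m <- as.numeric(means[as.character(records$dataset_id)])
  ifelse(m == 0, 1, records$branch_length / m)
}

#' Contingency tally for one transition set
#'
#' Builds the length-normalized 2x2 tally feeding the hypergeometric
#' test: `N_w` = rounded total weight (population size), `K` = number of
#' significant branches (p < alpha), `n_w` = rounded weight on the
#' transition branches (draw size), `k` = significant branches among
#' them. Significance counts stay unweighted; only the population and
#' draw sizes are normalized. Rounding is round-half-to-even; clamps keep
#' the hypergeometric support valid after rounding.
#'
#' @param records branch test records (see [normalize_weights()]) with an
#'   additional `species_branch_id` column (from [assign_branches()]).
#' @param transition data.frame with columns `dataset_id`,
#'   `species_branch_id`: the species branches sharing one trait change.
#' @param alpha significance threshold on the upstream branch-site test
#'   p-values (default 0.05).
#' @param weights optional precomputed weights; defaults to
#'   [normalize_weights()].
#' @param valid_branches optional character vector of known
#'   `dataset_id:species_branch_id` pairs (e.g. from the species trees); a
#'   transition member outside it raises an unknown-branch error. A member
#'   that is valid but that no record maps to simply contributes zero.
#' @param weighted_successes if `TRUE`, the significant-branch counts `K`
#'   and `k` are also length-normalized (rounded weighted sums) instead
#'   of plain event counts. The default keeps successes as events, the
#'   conservative reading of normalizing only "the number of branches"
#'   that defines the population.
#' @return a `tally` object: list(N_w, K, n_w, k).
#' @export
tally <- function(records, transition, alpha = 0.05, weights = NULL,
                  valid_branches = NULL, weighted_successes = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  if (!"species_branch_id" %in% names(records))
    stop("records lack species_branch_id; join assign_branches() output first")
  if (is.null(weights)) weights <- normalize_weights(records)
  key <- paste(records$dataset_id, records$species_branch_id, sep = ":")
  tkey <- paste(transition$dataset_id, transition$species_branch_id, sep = ":")
  if (!is.null(valid_branches)) {
    bad <- setdiff(tkey, valid_branches)
    if (length(bad) > 0)
      stop("unknown transition branch(es): ", paste(bad, collapse = ", "))
  }
  on_tr <- key %in% tkey & records$species_branch_id != "root"
  sig <- records$p_value < alpha
  N_w <- round(sum(weights))
  n_w <- round(sum(weights[on_tr]))
  if (weighted_successes) {
    K <- round(sum(weights[sig]))
    k <- round(sum(weights[sig & on_tr]))
  } else {
    K <- sum(sig)
    k <- sum(sig & on_tr)
  }
  # clamps: rounding can break the hypergeometric support
  N_w <- max(N_w, K, n_w, 1L)
  n_w <- min(n_w, N_w)
  k <- min(k, K, n_w)
  structure(list(N_w = as.integer(N_w), K = as.integer(K),
                 n_w = as.integer(n_w), k = as.integer(k)), class = "tally")
}

#' Pool tallies across datasets and convergent transitions
#'
#' Component-wise sums, used to combine all species-tree branches showing
#' the same trait change (and all clade x subfamily datasets) into a
#' single enrichment test.
#'
#' @param tallies list of `tally` objects over disjoint record sets.
#' @return a single `tally`.
#' @export
pool <- function(tallies) {
  stopifnot(length(tallies) >= 1)
  out <- list(N_w = 0L, K = 0L, n_w = 0L, k = 0L)
  for (t in tallies) {
    stopifnot(inherits(t, "tally"))
    out$N_w <- out$N_w + t$N_w; out$K <- out$K + t$K
    out$n_w <- out$n_w + t$n_w; out$k <- out$k + t$k
  }
  structure(out, class = "tally")
}

#' Hypergeometric enrichment/depletion test
#'
#' Tests whether significant branches are over- or under-represented on
#' the transition branches relative to drawing `n_w` branches at random
#' from the population: `p_enrich = P(X >= k)`, `p_deplete = P(X <= k)`
#' for `X ~ Hypergeometric(N_w, K, n_w)`. The expected count is
#' `n_w * K / N_w` and the fold enrichment is `k / expected`; the p-value
#' matching the observed direction (fold >= 1: enrichment) is reported.
#'
#' @param tl a `tally`.
#' @return an `enrichment_result`: list with the tally, `expected`,
#'   `fold`, `p_enrich`, `p_deplete`, `direction`, `p_reported`.
#' @export
hypergeom_test <- function(tl) {
  stopifnot(inherits(tl, "tally"))
  if (tl$N_w == 0) stop("empty population (N_w = 0)")
  expected <- tl$n_w * tl$K / tl$N_w
  fold <- if (expected == 0) {
    if (tl$k == 0) NaN else Inf
  } else tl$k / expected
  p_enrich <- stats::phyper(tl$k - 1L, tl$K, tl$N_w - tl$K, tl$n_w,
                            lower.tail = FALSE)
  p_deplete <- stats::phyper(tl$k, tl$K, tl$N_w - tl$K, tl$n_w)
  direction <- if (is.nan(fold) || fold >= 1) "enrichment" else "depletion"
  structure(list(tally = tl, expected = expected, fold = fold,
                 p_enrich = p_enrich, p_deplete = p_deplete,
                 direction = direction,
                 p_reported = if (direction == "enrichment") p_enrich
                              else p_deplete,
                 degenerate_expected = expected == 0),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  t <- x$tally
  cat(sprintf(
    "<enrichment> N=%d K=%d n=%d k=%d | expected %.3f, fold %.3f, %s p=%.4g\n",
    t$N_w, t$K, t$n_w, t$k, x$expected, x$fold, x$direction, x$p_reported))
  invisible(x)
}

#' Benjamini-Hochberg correction
#'
#' Step-up FDR control across the family of pooled trait-change tests (or
#' across individual transition branches when run per-branch).
#'
#' @param p numeric p-values in [0, 1].
#' @return q-values in input order.
#' @export
bh_correct <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Pooled enrichment tests over labelled transition sets
#'
#' The main entry point of the association method: for each transition
#' label (one type of trait change, e.g. "colony size increase"), tallies
#' all member branches across all datasets, pools, tests, and corrects
#' across labels with Benjamini-Hochberg.
#'
#' @param records branch test records joined with `species_branch_id`.
#' @param transitions data.frame with columns `label`, `dataset_id`,
#'   `species_branch_id`.
#' @param alpha per-branch significance threshold (default 0.05).
#' @param per_branch if `TRUE`, each member branch is tested individually
#'   (the BH family is then the branches, mirroring per-branch readouts);
#'   otherwise members sharing a label are pooled (default).
#' @return data.frame: label, N_w, K, n_w, k, expected, fold, p_enrich,
#'   p_deplete, direction, p_reported, q_value; sorted by label.
#' @export
enrichment_test <- function(records, transitions, alpha = 0.05,
                            per_branch = FALSE) {
  stopifnot(all(c("label", "dataset_id", "species_branch_id") %in%
                  names(transitions)))
  if (nrow(records) == 0) stop("empty population: no branch test records")
  weights <- normalize_weights(records)
  units <- if (per_branch) {
    split(transitions, paste0(transitions$label, "@",
                              transitions$dataset_id, ":",
                              transitions$species_branch_id))
  } else split(transitions, transitions$label)
  rows <- lapply(names(units), function(lb) {
    res <- hypergeom_test(tally(records, units[[lb]], alpha = alpha,
                                weights = weights))
    t <- res$tally
    data.frame(label = lb, N_w = t$N_w, K = t$K, n_w = t$n_w, k = t$k,
               expected = res$expected, fold = res$fold,
               p_enrich = res$p_enrich, p_deplete = res$p_deplete,
               direction = res$direction, p_reported = res$p_reported,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$label), , drop = FALSE]
  rownames(out) <- NULL
  out$q_value <- bh_correct(out$p_reported)
  out
}
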