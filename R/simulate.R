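#' Simulate an ultrametric species tree
#'
#' Pure-birth (Yule) tree with total depth normalized to 1, emulating a
#' clade of closely related species selected around a trait transition.
#'
#' @param n number of species (>= 3).
#' @param seed optional integer seed; when `NULL` the ambient RNG stream
#'   is used (so callers can seed a whole study once).
#' @return a species `ortree` with leaves `S1..Sn`.
#' @export
simulate_species_tree <- function(n, seed = NULL) {
  if (n < 3) stop("n must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rphylo(n, birth = 1, death = 0)
  phy$tip.label <- paste0("S", seq_len(n))
  tree <- as_ortree(phy, kind = "species")
  h <- node_heights(tree)
  depth <- max(h[tree$is_leaf])
  tree$length <- tree$length / depth
  tree$length[tree$root_id + 1L] <- 0
  tree
}

#' Simulate one gene family along a species tree
#'
#' Gene lineages descend the species tree from the root, duplicating at
#' rate `lambda_d` and dying at rate `lambda_l` per unit branch length;
#' at each species-tree node a surviving lineage splits into all species
#' children. The surviving-lineage gene tree is returned with every gene
#' branch labelled by its true species branch (child-side convention, the
#' same one the reconciliation uses). Families extinct in all species are
#' redrawn; the number of redraws is recorded.
#'
#' @param species_tree a species `ortree`.
#' @param lambda_d,lambda_l duplication and loss rates (events per unit
#'   branch length).
#' @param seed optional integer seed.
#' @param node_cap guard against runaway rates: simulation aborts when a
#'   family exceeds this many gene nodes.
#' @param min_genes redraw until at least this many gene copies survive
#'   (default 1 = any non-extinct family; dataset-level simulation uses 2
#'   so every family yields a well-formed tree with testable branches).
#' @return a gene `ortree` (leaf labels `species|g<i>`); attributes:
#'   `true_assignment` (character per node: species branch id, `"root"`
#'   for nodes on the species root), `redraws`.
#' @export
simulate_gene_family <- function(species_tree, lambda_d, lambda_l,
                                 seed = NULL, node_cap = 10000L,
                                 min_genes = 1L) {
  if (!is.finite(lambda_d) || !is.finite(lambda_l) ||
      lambda_d < 0 || lambda_l < 0)
    stop("rates must be finite and >= 0")
  sh <- node_heights(species_tree)
  if (lambda_d > 0 && (lambda_d - lambda_l) * max(sh) > 6)
    stop("runaway rates: expected family size exceeds cap")
  if (!is.null(seed)) set.seed(seed)
  st <- species_tree
  total <- lambda_d + lambda_l
  pdup <- if (total > 0) lambda_d / total else 0
  redraws <- 0L
  repeat {
    env <- new.env(parent = emptyenv())
    env$height <- numeric(64); env$loc <- integer(64)
    env$kid1 <- integer(64); env$kid2 <- integer(64)  # -1 = none (leaf)
    env$species <- integer(64)                        # species leaf id or -1
    env$count <- 0L
    add <- function(height, loc, k1, k2, species) {
      i <- env$count + 1L
      if (i > length(env$height)) {
        for (f in c("height", "loc", "kid1", "kid2", "species"))
          env[[f]] <- c(env[[f]], env[[f]])
      }
      if (i > node_cap) stop("runaway rates: family exceeded node cap")
      env$height[i] <- height; env$loc[i] <- loc
      env$kid1[i] <- k1; env$kid2[i] <- k2; env$species[i] <- species
      env$count <- i
      i - 1L  # 0-based id in creation (= post-) order
    }
    # one lineage entering the branch into species node s at offset pos
    sim_lineage <- function(s, pos) {
      L <- st$length[s + 1L]
      t <- if (total > 0) stats::rexp(1L, total) else Inf
      if (pos + t < L) {
        if (stats::runif(1L) < pdup) {
          c1 <- sim_lineage(s, pos + t)
          c2 <- sim_lineage(s, pos + t)
          if (is.na(c1)) return(c2)
          if (is.na(c2)) return(c1)
          add(sh[s + 1L] - L + pos + t, s, c1, c2, -1L)
        } else NA_integer_  # loss
      } else if (st$is_leaf[s + 1L]) {
        add(sh[s + 1L], s, -1L, -1L, s)
      } else {
        kids <- st$children[[s + 1L]]
        got <- integer(0)
        for (c in kids) {
          r <- sim_lineage(c, 0)
          if (!is.na(r)) got <- c(got, r)
        }
        if (length(got) == 0L) NA_integer_
        else if (length(got) == 1L) got[1]
        else {
          id <- got[1]
          for (j in 2:length(got))  # binary speciation nodes
            id <- add(sh[s + 1L], s, id, got[j], -1L)
          id
        }
      }
    }
    root <- {
      kids <- st$children[[st$root_id + 1L]]
      got <- integer(0)
      for (c in kids) {
        r <- sim_lineage(c, 0)
        if (!is.na(r)) got <- c(got, r)
      }
      if (length(got) == 0L) NA_integer_
      else if (length(got) == 1L) got[1]
      else {
        id <- got[1]
        for (j in 2:length(got))
          id <- add(sh[st$root_id + 1L], st$root_id, id, got[j], -1L)
        id
      }
    }
    if (!is.na(root) &&
        sum(env$species[seq_len(env$count)] >= 0L) >= min_genes) break
    redraws <- redraws + 1L
    if (redraws > 10000L) stop("family extinct in all species 10000 times; ",
                               "check rates")
  }
  n <- env$count
  # creation order is post-order (children are created before parents);
  # compact to the ids reachable from the surviving root
  ids <- reachable_order(env, root)
  remap <- integer(n); remap[ids + 1L] <- seq_along(ids) - 1L
  m <- length(ids)
  parent <- rep(NA_integer_, m)
  for (old in ids) {
    for (k in c(env$kid1[old + 1L], env$kid2[old + 1L])) {
      if (k >= 0L) parent[remap[k + 1L] + 1L] <- remap[old + 1L]
    }
  }
  height <- env$height[ids + 1L]
  len <- numeric(m)
  for (v in seq_len(m) - 1L) {
    p <- parent[v + 1L]
    len[v + 1L] <- if (is.na(p)) height[v + 1L] else
      height[v + 1L] - height[p + 1L]
  }
  len[len < 0] <- 0
  species <- env$species[ids + 1L]
  lab <- rep(NA_character_, m)
  tips <- which(species >= 0L)
  lab[tips] <- paste0(st$label[species[tips] + 1L], "|g", seq_along(tips))
  gt <- new_ortree(parent, len, lab, kind = "gene")
  loc <- env$loc[ids + 1L]
  ta <- as.character(loc)
  ta[loc == st$root_id] <- "root"
  attr(gt, "true_assignment") <- ta
  attr(gt, "redraws") <- redraws
  gt
}

# ids reachable from root, in increasing creation id (= post-order since
# children are always created before their parent)
reachable_order <- function(env, root) {
  n <- env$count
  seen <- logical(n)
  stack <- root
  while (length(stack) > 0) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[v + 1L]) next
    seen[v + 1L] <- TRUE
    for (k in c(env$kid1[v + 1L], env$kid2[v + 1L]))
      if (k >= 0L) stack <- c(stack, k)
  }
  which(seen) - 1L
}

#' Plant positive-selection signal on gene-tree branches
#'
#' Builds the branch test record table an external branch-site test would
#' produce, with a known enrichment signal: a branch assigned to a
#' transition species branch is "selected" with probability
#' `min(1, f * p0)`, any other branch with probability `p0`. Selected
#' branches draw p ~ Uniform(0, `sel_band`) and unselected branches
#' p ~ Uniform(`sel_band`, 1), so with `sel_band` equal to the call
#' threshold alpha, a branch is called significant exactly when it was
#' planted: the baseline significant fraction equals `p0` and the planted
#' fold `f` is directly comparable to the estimated fold (the upstream
#' test's false positives are absorbed into `p0` rather than layered on
#' top of it). Branch lengths (substitutions/site scale) are Exponential
#' with mean 0.1, independent of selection unless `length_sel_corr > 0`.
#'
#' @param assignment character vector of species branch ids, one per gene
#'   branch (pooled over gene trees).
#' @param dataset_id,gene_tree_id,gene_branch_id identifier vectors
#'   aligned with `assignment`.
#' @param p0 baseline selection probability; @param f planted fold on
#'   transition branches; @param transition_branches character ids.
#' @param p_model `"uniform"` (selected p ~ U(0, sel_band)) or
#'   `list(type = "beta", a = <shape>)` for p ~ Beta(a, 1) on selected
#'   branches (power studies; the selected-implies-called identity is
#'   then deliberately broken).
#' @param sel_band p-value band of selected branches (default 0.05,
#'   matching the downstream call threshold).
#' @param length_sel_corr selected-branch lengths are multiplied by
#'   `1 + length_sel_corr` (stress knob for the normalization).
#' @param seed optional integer seed.
#' @return data.frame of branch test records (`dataset_id`,
#'   `gene_tree_id`, `gene_branch_id`, `species_branch_id`,
#'   `branch_length`, `p_value`) plus logical column `true_selected`.
#' @export
plant_selection <- function(assignment, dataset_id, gene_tree_id,
                            gene_branch_id, p0, f, transition_branches,
                            p_model = "uniform", length_sel_corr = 0,
                            sel_band = 0.05, seed = NULL) {
  stopifnot(p0 >= 0, p0 < 1, f >= 0, sel_band > 0, sel_band < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(assignment)
  on_tr <- assignment %in% transition_branches
  prob <- ifelse(on_tr, pmin(1, f * p0), p0)
  sel <- stats::runif(n) < prob
  p <- stats::runif(n, sel_band, 1)
  if (identical(p_model, "uniform")) {
    p[sel] <- stats::runif(sum(sel), 0, sel_band)
  } else if (is.list(p_model) && identical(p_model$type, "beta")) {
    p[sel] <- stats::rbeta(sum(sel), p_model$a, 1)
  } else stop("unknown p_model")
  len <- stats::rexp(n, rate = 10)   # mean 0.1 substitutions/site
  if (length_sel_corr != 0) len[sel] <- len[sel] * (1 + length_sel_corr)
  data.frame(dataset_id = dataset_id, gene_tree_id = gene_tree_id,
             gene_branch_id = gene_branch_id,
             species_branch_id = assignment,
             branch_length = len, p_value = p, true_selected = sel,
             stringsAsFactors = FALSE)
}

#' Simulate species trait data
#'
#' Continuous traits evolve by Brownian motion with optional mean jumps
#' on designated shift branches; discrete traits evolve under an Mk rate
#' matrix with a forced state change on shift branches. Ground-truth node
#' states are returned for recovery tests.
#'
#' @param species_tree a species `ortree`.
#' @param model `"BM"` or `"Mk"`.
#' @param params for BM: `list(sigma2 =, root =, jump =)`; for Mk:
#'   `list(Q =, states =, root_state =)`.
#' @param shift_branches integer species branch ids receiving a forced
#'   jump/state change.
#' @param seed optional integer seed.
#' @return list: `tip_values` (named vector), `node_values` (per node,
#'   indexed `id + 1`).
#' @export
simulate_traits <- function(species_tree, model = c("BM", "Mk"),
                            params = list(), shift_branches = integer(0),
                            seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  st <- species_tree
  if (model == "BM") {
    sigma2 <- params$sigma2 %||% 1
    root <- params$root %||% 0
    jump <- params$jump %||% 1
    x <- numeric(st$n)
    x[st$root_id + 1L] <- root
    for (v in rev(seq_len(st$n) - 1L)) {
      if (v == st$root_id) next
      p <- st$parent[v + 1L]
      x[v + 1L] <- x[p + 1L] +
        (if (v %in% shift_branches) jump else 0) +
        stats::rnorm(1L, 0, sqrt(sigma2 * st$length[v + 1L]))
    }
  } else {
    states <- params$states %||% c("A", "B")
    m <- length(states)
    Q <- params$Q %||% mk_Q(0.5, m, "ER")
    root_state <- params$root_state %||% states[1]
    x <- character(st$n)
    x[st$root_id + 1L] <- root_state
    for (v in rev(seq_len(st$n) - 1L)) {
      if (v == st$root_id) next
      p <- st$parent[v + 1L]
      from <- match(x[p + 1L], states)
      if (v %in% shift_branches) {
        x[v + 1L] <- states[if (from == m) 1L else from + 1L]
      } else {
        P <- ape::matexpo(Q * st$length[v + 1L])
        x[v + 1L] <- sample(states, 1L, prob = P[from, ])
      }
    }
  }
  tips <- leaf_ids(st)
  list(tip_values = stats::setNames(x[tips + 1L], st$label[tips + 1L]),
       node_values = x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete clade dataset with planted enrichment
#'
#' One "dataset" in the study's sense (one clade of species x one gene
#' subfamily): a species tree, `n_gene_trees` gene families with
#' duplication-loss histories, LCA reconciliation of every family, and a
#' branch test table with a planted enrichment of factor `f` on the
#' designated transition branches.
#'
#' @param n_species clade size (default 8, matching clades of four to
#'   nine species).
#' @param n_gene_trees number of gene families (default 200).
#' @param lambda_d,lambda_l duplication/loss rates (defaults 0.1 / 0.05).
#' @param p0 baseline selection probability (default 0.05).
#' @param f planted fold (1 = null).
#' @param transition_branches ids on the simulated species tree; default
#'   `NULL` picks one internal non-root branch at random.
#' @param dataset_id label for the records.
#' @param use_true_assignment if `TRUE` skip reconciliation and use the
#'   simulator's ground-truth branch labels (for isolating the test from
#'   reconciliation error).
#' @param seed optional integer seed.
#' @param ... passed to [plant_selection()].
#' @return list: `species_tree`, `records` (branch test table with
#'   species_branch_id), `transitions` (label "planted"), `gene_trees`,
#'   `truth` (transition ids, per-branch true selection flags).
#' @export
simulate_or_dataset <- function(n_species = 8, n_gene_trees = 200,
                                lambda_d = 0.1, lambda_l = 0.05,
                                p0 = 0.05, f = 1,
                                transition_branches = NULL,
                                dataset_id = "d1",
                                use_true_assignment = FALSE,
                                seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  st <- simulate_species_tree(n_species)
  if (is.null(transition_branches)) {
    internal <- setdiff(which(!st$is_leaf) - 1L, st$root_id)
    transition_branches <- as.character(
      internal[sample.int(length(internal), 1L)])
  }
  gts <- vector("list", n_gene_trees)
  asg <- ds <- tid <- vector("list", n_gene_trees)
  gbid <- vector("list", n_gene_trees)
  for (i in seq_len(n_gene_trees)) {
    gt <- simulate_gene_family(st, lambda_d, lambda_l, min_genes = 2L)
    gts[[i]] <- gt
    a <- if (use_true_assignment) {
      attr(gt, "true_assignment")
    } else {
      rec <- lca_reconcile(gt, st)
      sb <- as.character(rec$node_map)
      sb[rec$node_map == st$root_id] <- "root"
      sb
    }
    nonroot <- setdiff(seq_len(gt$n) - 1L, gt$root_id)
    asg[[i]] <- a[nonroot + 1L]
    gbid[[i]] <- nonroot
    ds[[i]] <- rep(dataset_id, length(nonroot))
    tid[[i]] <- rep(paste0("g", i), length(nonroot))
  }
  records <- plant_selection(unlist(asg), unlist(ds), unlist(tid),
                             unlist(gbid), p0 = p0, f = f,
                             transition_branches = transition_branches, ...)
  transitions <- data.frame(label = "planted", dataset_id = dataset_id,
                            species_branch_id = transition_branches,
                            stringsAsFactors = FALSE)
  list(species_tree = st, records = records, transitions = transitions,
       gene_trees = gts,
       truth = list(transition_branches = transition_branches,
                    true_selected = records$true_selected))
}

#' Replicated enrichment study on synthetic data
#'
#' Repeatedly simulates a clade dataset with a planted fold and runs the
#' pooled enrichment test, returning one row per replicate. `f = 1` gives
#' the null calibration surface, `f > 1` the fold-recovery surface.
#'
#' @param n_rep number of replicates.
#' @param f planted fold.
#' @param seed integer seed fixing the whole study.
#' @param alpha per-branch significance threshold.
#' @param ... passed to [simulate_or_dataset()].
#' @return data.frame with columns `rep`, `fold`, `p_reported`,
#'   `direction`, `N_w`, `K`, `n_w`, `k`.
#' @export
simulate_enrichment_study <- function(n_rep, f = 1, seed = 1, alpha = 0.05,
                                      ...) {
  set.seed(seed)
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    d <- simulate_or_dataset(f = f, ...)
    res <- enrichment_test(d$records, d$transitions, alpha = alpha)
    rows[[r]] <- data.frame(rep = r, fold = res$fold,
                            p_reported = res$p_reported,
                            direction = res$direction, N_w = res$N_w,
                            K = res$K, n_w = res$n_w, k = res$k,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
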