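#' Rooted trees with stable post-order branch identifiers
#'
#' `ortree` is the tree container used throughout the package. Every node
#' carries an integer id in `0..n_nodes-1` assigned by post-order traversal
#' (children before parents, so the root always has id `n_nodes - 1`).
#' A branch is identified with the node it leads into, giving a single id
#' namespace for nodes and branches that all downstream tables
#' (reconciliation maps, branch test records, transition sets) share.
#'
#' @param parent integer vector, 0-based parent id per node (`NA` for the
#'   root). Must satisfy `parent[v] > v` for every non-root node, i.e. ids
#'   are already in post-order.
#' @param length numeric vector of branch lengths (length of the branch
#'   leading into each node; the root entry is the stem/root edge, 0 if
#'   absent).
#' @param label character vector of node labels; leaves must be labelled,
#'   internal labels are optional (`NA`).
#' @param kind `"species"` or `"gene"`.
#'
#' @return An object of class `ortree`: a list with fields `n`, `parent`,
#'   `length`, `label`, `is_leaf`, `children`, `root_id`, `kind`.
#' @export
new_ortree <- function(parent, length, label, kind = c("species", "gene")) {
  kind <- match.arg(kind)
  n <- base::length(parent)
  stopifnot(n >= 1, base::length(length) == n, base::length(label) == n)
  parent <- as.integer(parent)
  root <- which(is.na(parent)) - 1L
  if (base::length(root) != 1L)
    stop("ortree: exactly one root (NA parent) required, found ",
         base::length(root))
  nonroot <- setdiff(seq_len(n) - 1L, root)
  if (any(parent[nonroot + 1L] <= nonroot))
    stop("ortree: node ids must be in post-order (parent id > child id)")
  if (any(length < 0, na.rm = TRUE))
    stop("ortree: negative branch lengths are not allowed")
  children <- vector("list", n)
  for (v in nonroot) {
    p <- parent[v + 1L]
    children[[p + 1L]] <- c(children[[p + 1L]], v)
  }
  is_leaf <- vapply(children, function(x) base::length(x) == 0L, logical(1))
  if (anyNA(label[is_leaf]))
    stop("ortree: every leaf must be labelled")
  lab <- label[is_leaf]
  if (anyDuplicated(lab))
    stop("ortree: duplicate leaf labels: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  structure(list(n = n, parent = parent, length = as.numeric(length),
                 label = as.character(label), is_leaf = is_leaf,
                 children = children, root_id = root, kind = kind),
            class = "ortree")
}

#' @export
print.ortree <- function(x, ...) {
  cat(sprintf("<ortree kind=%s> %d nodes, %d leaves, root id %d\n",
              x$kind, x$n, sum(x$is_leaf), x$root_id))
  invisible(x)
}

#' Node ids of the leaves of an ortree
#' @param tree an `ortree`.
#' @return integer vector of 0-based leaf ids, in id order.
#' @export
leaf_ids <- function(tree) which(tree$is_leaf) - 1L

#' Parse a rooted Newick string
#'
#' Reads a single rooted Newick tree and assigns stable post-order branch
#' ids. Missing branch lengths are read as 0 and flagged in the
#' `missing_lengths` attribute. Unrooted trees (basal polytomies) and
#' duplicate leaf labels are rejected.
#'
#' @param text a single Newick string (terminating `;` optional).
#' @param kind `"species"` or `"gene"`.
#' @return an [new_ortree()] object; attribute `missing_lengths` is `TRUE`
#'   if any branch length was absent from the input.
#' @export
parse_newick <- function(text, kind = c("species", "gene")) {
  kind <- match.arg(kind)
  if (!is.character(text) || base::length(text) != 1L || !nzchar(trimws(text)))
    stop("parse error: empty Newick string")
  no <- sum(strsplit(text, "", fixed = TRUE)[[1]] == "(")
  nc <- sum(strsplit(text, "", fixed = TRUE)[[1]] == ")")
  if (no != nc)
    stop("parse error: unbalanced parentheses ('(' x ", no, ", ')' x ", nc, ")")
  txt <- trimws(text)
  if (!grepl(";\\s*$", txt)) txt <- paste0(txt, ";")
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) stop("parse error: ", conditionMessage(e)),
                  warning = function(w) stop("parse error: ", conditionMessage(w)))
  if (is.null(phy)) stop("parse error: unreadable Newick near '",
                         substr(txt, 1, 30), "'")
  if (anyDuplicated(phy$tip.label))
    stop("parse error: duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (phy$Nnode < 2L && ape::Ntip(phy) > 2L)
    stop("parse error: tree is a star/unrooted")
  if (ape::Ntip(phy) > 2L && !ape::is.rooted(phy))
    stop("parse error: unrooted tree (basal trifurcation); reroot before use")
  as_ortree(phy, kind = kind)
}

#' Convert an ape `phylo` tree to an `ortree`
#'
#' @param phy rooted `phylo` object.
#' @inheritParams parse_newick
#' @return an `ortree`; attribute `missing_lengths` flags absent lengths.
#' @export
as_ortree <- function(phy, kind = c("species", "gene")) {
  kind <- match.arg(kind)
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  po <- ape::reorder.phylo(phy, "cladewise")
  ape_root <- ntip + 1L
  # left-to-right depth-first post-order (children in cladewise order):
  # this makes branch ids reproducible from the Newick text alone, and a
  # write_newick()/parse_newick() round trip id-stable
  kids <- vector("list", nn)
  for (r in seq_len(nrow(po$edge)))
    kids[[po$edge[r, 1L]]] <- c(kids[[po$edge[r, 1L]]], po$edge[r, 2L])
  s1 <- ape_root; s2 <- integer(0)
  while (length(s1) > 0) {
    v <- s1[length(s1)]; s1 <- s1[-length(s1)]
    s2 <- c(s2, v)
    s1 <- c(s1, kids[[v]])
  }
  ord <- rev(s2)                         # post-order sequence of ape numbers
  id_of <- integer(nn)
  id_of[ord] <- seq_len(nn) - 1L
  parent <- rep(NA_integer_, nn)
  len <- numeric(nn)
  missing <- is.null(phy$edge.length)
  el <- if (missing) rep(NA_real_, nrow(po$edge)) else po$edge.length
  if (anyNA(el)) missing <- TRUE
  el[is.na(el)] <- 0
  parent[id_of[po$edge[, 2L]] + 1L] <- id_of[po$edge[, 1L]]
  len[id_of[po$edge[, 2L]] + 1L] <- el
  if (!is.null(phy$root.edge)) len[id_of[ape_root] + 1L] <- phy$root.edge
  lab <- rep(NA_character_, nn)
  lab[id_of[seq_len(ntip)] + 1L] <- phy$tip.label
  if (!is.null(phy$node.label)) {
    nl <- phy$node.label
    nl[!nzchar(nl)] <- NA_character_
    lab[id_of[ntip + seq_len(phy$Nnode)] + 1L] <- nl
  }
  out <- new_ortree(parent, len, lab, kind)
  attr(out, "missing_lengths") <- missing
  out
}

#' Convert an `ortree` back to an ape `phylo`
#'
#' Tips are numbered in increasing id order; internal ape numbers are
#' assigned in pre-order so the root is `Ntip + 1`, matching ape
#' conventions.
#' @param tree an `ortree`.
#' @return a `phylo` object (with `root.edge` when the stem length is > 0).
#' @export
as_phylo <- function(tree) {
  ntip <- sum(tree$is_leaf)
  apenum <- integer(tree$n)
  apenum[tree$is_leaf] <- seq_len(ntip)
  nexti <- ntip
  # pre-order = decreasing id among internal nodes (post-order reversed)
  for (v in rev(seq_len(tree$n) - 1L)) {
    if (!tree$is_leaf[v + 1L]) {
      nexti <- nexti + 1L
      apenum[v + 1L] <- nexti
    }
  }
  nonroot <- setdiff(seq_len(tree$n) - 1L, tree$root_id)
  # ape cladewise-ish ordering: parent rows before children is not required,
  # read.tree consumers reorder anyway; emit in pre-order for tidiness.
  pre <- rev(seq_len(tree$n) - 1L)
  pre <- pre[pre != tree$root_id]
  edge <- cbind(apenum[tree$parent[pre + 1L] + 1L], apenum[pre + 1L])
  phy <- list(edge = edge, tip.label = tree$label[tree$is_leaf],
              edge.length = tree$length[pre + 1L],
              Nnode = tree$n - ntip)
  if (tree$length[tree$root_id + 1L] > 0)
    phy$root.edge <- tree$length[tree$root_id + 1L]
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Serialize an `ortree` to Newick
#'
#' Round-trips with [parse_newick()]: the re-parsed tree is isomorphic with
#' branch lengths equal to 1e-9. Zero-length branches are written
#' explicitly (`:0.0`).
#'
#' @param tree an `ortree`.
#' @param digits significant digits for branch lengths.
#' @return a single Newick string terminated by `;`.
#' @export
write_newick <- function(tree, digits = 10) {
  fmt <- function(x) {
    s <- sprintf("%.*g", digits, x)
    if (!grepl("[.eE]", s)) s <- paste0(s, ".0")
    s
  }
  build <- function(v) {
    if (tree$is_leaf[v + 1L]) {
      paste0(tree$label[v + 1L], ":", fmt(tree$length[v + 1L]))
    } else {
      kids <- vapply(tree$children[[v + 1L]], build, character(1))
      lab <- tree$label[v + 1L]
      paste0("(", paste(kids, collapse = ","),
             ")", if (!is.na(lab)) lab else "",
             ":", fmt(tree$length[v + 1L]))
    }
  }
  paste0(build(tree$root_id), ";")
}

#' Depth (root distance in edges) of every node
#' @param tree an `ortree`.
#' @return integer vector indexed by `id + 1`; root depth is 0.
#' @export
node_depths <- function(tree) {
  d <- integer(tree$n)
  for (v in rev(seq_len(tree$n) - 1L)) {    # pre-order
    if (v == tree$root_id) next
    d[v + 1L] <- d[tree$parent[v + 1L] + 1L] + 1L
  }
  d
}

#' Root-to-node path length (sum of branch lengths, excluding the stem)
#' @param tree an `ortree`.
#' @return numeric vector indexed by `id + 1`.
#' @export
node_heights <- function(tree) {
  h <- numeric(tree$n)
  for (v in rev(seq_len(tree$n) - 1L)) {
    if (v == tree$root_id) next
    h[v + 1L] <- h[tree$parent[v + 1L] + 1L] + tree$length[v + 1L]
  }
  h
}

#' Resolve gene-tree leaves to species-tree leaves
#'
#' Gene leaf labels encode the species of origin as
#' `species_id<delimiter>gene_id`; the split is at the *first* occurrence
#' of the delimiter, so gene ids may themselves contain it.
#'
#' @param gene_tree an `ortree` of kind `"gene"`.
#' @param species_tree an `ortree` of kind `"species"`.
#' @param delimiter separator between species id and gene id (default
#'   `"|"`, taken literally).
#' @return integer vector mapping each gene leaf id to a species leaf id;
#'   names are the gene leaf ids.
#' @export
map_gene_leaves <- function(gene_tree, species_tree, delimiter = "|") {
  gl <- leaf_ids(gene_tree)
  labs <- gene_tree$label[gl + 1L]
  pos <- regexpr(delimiter, labs, fixed = TRUE)
  if (any(pos < 0))
    stop("unresolved leaves: no delimiter '", delimiter, "' in: ",
         paste(labs[pos < 0], collapse = ", "))
  sp <- substr(labs, 1L, pos - 1L)
  sl <- leaf_ids(species_tree)
  sp_ids <- structure(sl, names = species_tree$label[sl + 1L])
  bad <- !(sp %in% names(sp_ids))
  if (any(bad))
    stop("unresolved leaves: species not in species tree: ",
         paste(unique(sp[bad]), collapse = ", "))
  structure(unname(sp_ids[sp]), names = as.character(gl))
}
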