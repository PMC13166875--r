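#' Duplication-loss reconciliation by LCA mapping
#'
#' Maps every gene-tree node onto the species tree by the last-common-
#' ancestor (LCA) rule: a leaf maps to its species of origin and an
#' internal node to the LCA of its children's images. An internal node is
#' a duplication when it maps to the same species node as one of its
#' children, otherwise a speciation. Losses are counted per gene branch
#' (u, v) as `d(M(u), M(v)) - 1 + [event(u) == duplication]` where `d` is
#' the depth difference on the species tree, and 0 when `M(u) == M(v)`.
#' This is the parsimony solution minimizing duplications + losses.
#'
#' @param gene_tree an `ortree` of kind `"gene"`.
#' @param species_tree an `ortree` of kind `"species"`.
#' @param leaf_map integer vector from [map_gene_leaves()] (gene leaf id ->
#'   species leaf id, names = gene leaf ids). Computed if `NULL`.
#' @param delimiter passed to [map_gene_leaves()] when `leaf_map` is NULL.
#' @return a `reconciliation` object: list with `node_map` (gene id ->
#'   species id, indexed `id + 1`), `event` (character per gene node:
#'   "leaf", "speciation", "duplication"), `dup_count`, `loss_count`,
#'   plus the input trees.
#' @export
lca_reconcile <- function(gene_tree, species_tree, leaf_map = NULL,
                          delimiter = "|") {
  if (is.null(leaf_map))
    leaf_map <- map_gene_leaves(gene_tree, species_tree, delimiter)
  sdepth <- node_depths(species_tree)
  sparent <- species_tree$parent
  lca <- function(a, b) {
    while (a != b) {
      if (sdepth[a + 1L] >= sdepth[b + 1L]) a <- sparent[a + 1L]
      else b <- sparent[b + 1L]
    }
    a
  }
  n <- gene_tree$n
  M <- integer(n)
  event <- character(n)
  for (v in seq_len(n) - 1L) {           # post-order: children first
    if (gene_tree$is_leaf[v + 1L]) {
      M[v + 1L] <- leaf_map[[as.character(v)]]
      event[v + 1L] <- "leaf"
    } else {
      kids <- gene_tree$children[[v + 1L]]
      m <- M[kids[1] + 1L]
      for (c in kids[-1]) m <- lca(m, M[c + 1L])
      M[v + 1L] <- m
      event[v + 1L] <-
        if (any(M[kids + 1L] == m)) "duplication" else "speciation"
    }
  }
  losses <- 0L
  for (v in seq_len(n) - 1L) {
    if (v == gene_tree$root_id) next
    u <- gene_tree$parent[v + 1L]
    if (M[u + 1L] == M[v + 1L]) next
    d <- sdepth[M[v + 1L] + 1L] - sdepth[M[u + 1L] + 1L]
    losses <- losses + d - 1L + (event[u + 1L] == "duplication")
  }
  structure(list(node_map = M, event = event,
                 dup_count = sum(event == "duplication"),
                 loss_count = losses,
                 gene_tree = gene_tree, species_tree = species_tree),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("<reconciliation> %d gene nodes; %d duplications, %d losses\n",
              x$gene_tree$n, x$dup_count, x$loss_count))
  invisible(x)
}

#' Attribute every gene branch to one species branch
#'
#' The branch leading into gene node v is assigned to the species branch
#' leading into M(v) (child-side convention for branches spanning several
#' species branches through implied losses). Branches whose child maps to
#' the species root receive the synthetic id `"root"`: they are part of
#' the tested population but can never lie on a transition branch.
#'
#' @param rec a `reconciliation` from [lca_reconcile()] or
#'   [read_external_reconciliation()].
#' @return data.frame with columns `gene_branch_id` (integer),
#'   `species_branch_id` (character: species node id or `"root"`),
#'   `event`, `branch_length`.
#' @export
assign_branches <- function(rec) {
  gt <- rec$gene_tree
  ids <- seq_len(gt$n) - 1L
  sb <- as.character(rec$node_map)
  sb[rec$node_map == rec$species_tree$root_id] <- "root"
  data.frame(gene_branch_id = ids,
             species_branch_id = sb,
             event = rec$event,
             branch_length = gt$length,
             stringsAsFactors = FALSE)
}

# ---- NHX import --------------------------------------------------------

# Minimal recursive-descent Newick reader that keeps [&&NHX:...] comments
# attached to the node they follow. Only used for importing reconciled
# trees from external tools; plain Newick goes through parse_newick().
parse_newick_nhx <- function(text) {
  txt <- trimws(text)
  txt <- sub(";\\s*$", "", txt)
  i <- 1L
  nchar_t <- nchar(txt)
  peek <- function() if (i <= nchar_t) substr(txt, i, i) else ""
  # growing node store
  parent <- integer(0); len <- numeric(0); lab <- character(0)
  nhx <- character(0); order <- integer(0)
  add_node <- function(children) {
    id <- length(parent)                 # provisional 0-based creation id
    parent[id + 1L] <<- NA_integer_
    len[id + 1L] <<- 0; lab[id + 1L] <<- NA_character_
    nhx[id + 1L] <<- NA_character_
    for (c in children) parent[c + 1L] <<- id
    id
  }
  read_label <- function() {
    j <- i
    while (j <= nchar_t && !substr(txt, j, j) %in% c(",", ")", "(", ":", "[", ";"))
      j <- j + 1L
    s <- substr(txt, i, j - 1L)
    i <<- j
    s
  }
  read_suffix <- function(id) {          # label, :length, [comment] in any arrangement
    repeat {
      ch <- peek()
      if (ch == ":") {
        i <<- i + 1L
        len[id + 1L] <<- as.numeric(read_label())
      } else if (ch == "[") {
        j <- regexpr("]", substr(txt, i, nchar_t), fixed = TRUE)
        if (j < 0) stop("format error: unterminated comment")
        nhx[id + 1L] <<- substr(txt, i + 1L, i + j - 2L)
        i <<- i + j
      } else if (!ch %in% c("", ",", ")", ";")) {
        lab[id + 1L] <<- read_label()
      } else break
    }
  }
  read_clade <- function() {
    if (peek() == "(") {
      i <<- i + 1L
      kids <- integer(0)
      repeat {
        kids <- c(kids, read_clade())
        ch <- peek()
        if (ch == ",") { i <<- i + 1L; next }
        if (ch == ")") { i <<- i + 1L; break }
        stop("format error: expected ',' or ')' at position ", i)
      }
      id <- add_node(kids)
      read_suffix(id)
      id
    } else {
      id <- add_node(integer(0))
      lab[id + 1L] <<- read_label()
      read_suffix(id)
      id
    }
  }
  root <- read_clade()
  if (i <= nchar_t) stop("format error: trailing characters after tree")
  list(parent = parent, length = len, label = lab, nhx = nhx, root = root)
}

nhx_field <- function(comment, key) {
  if (is.na(comment)) return(NA_character_)
  body <- sub("^&&NHX:?", "", comment)
  for (kv in strsplit(body, ":", fixed = TRUE)[[1]]) {
    p <- strsplit(kv, "=", fixed = TRUE)[[1]]
    if (length(p) == 2 && p[1] == key) return(p[2])
  }
  NA_character_
}

#' Import a precomputed reconciliation from an NHX-annotated gene tree
#'
#' Reads a reconciled gene tree (e.g. exported by GeneRax-style tools) in
#' which internal nodes carry NHX tags: `S=<species node label>` for the
#' species assignment and `D=Y`/`D=N` for duplication vs speciation.
#' The imported map is re-validated against the LCA invariants; external
#' models may legitimately differ, so violations are reported as warnings,
#' not errors.
#'
#' @param path file containing one NHX Newick tree.
#' @param species_tree an `ortree`; internal species node labels (or leaf
#'   labels) must match the NHX `S` tags.
#' @param delimiter gene-leaf delimiter for species resolution.
#' @return a `reconciliation` object (same shape as [lca_reconcile()]).
#' @export
read_external_reconciliation <- function(path, species_tree, delimiter = "|") {
  raw <- parse_newick_nhx(paste(readLines(path, warn = FALSE), collapse = ""))
  if (all(is.na(raw$nhx)))
    stop("format error: no NHX comments found in ", path)
  # creation order is already post-order (children created before parents)
  gt <- new_ortree(raw$parent, raw$length, raw$label, kind = "gene")
  nhx <- raw$nhx
  leaf_map <- map_gene_leaves(gt, species_tree, delimiter)
  slab <- species_tree$label
  sp_by_label <- structure(seq_len(species_tree$n) - 1L, names = slab)
  n <- gt$n
  M <- integer(n); event <- character(n)
  for (v in seq_len(n) - 1L) {
    if (gt$is_leaf[v + 1L]) {
      M[v + 1L] <- leaf_map[[as.character(v)]]
      event[v + 1L] <- "leaf"
    } else {
      stag <- nhx_field(nhx[v + 1L], "S")
      if (is.na(stag))
        stop("format error: internal node without NHX S= species tag")
      if (!stag %in% names(sp_by_label) || is.na(sp_by_label[stag]))
        stop("format error: NHX species tag '", stag,
             "' not a labelled species-tree node")
      M[v + 1L] <- sp_by_label[[stag]]
      dtag <- nhx_field(nhx[v + 1L], "D")
      event[v + 1L] <- if (identical(dtag, "Y")) "duplication" else "speciation"
    }
  }
  ref <- lca_reconcile(gt, species_tree, leaf_map)
  sdepth <- node_depths(species_tree)
  for (v in seq_len(n) - 1L) {
    if (v == gt$root_id) next
    u <- gt$parent[v + 1L]
    anc <- M[v + 1L]; ok <- FALSE
    while (TRUE) {
      if (anc == M[u + 1L]) { ok <- TRUE; break }
      if (anc == species_tree$root_id) break
      anc <- species_tree$parent[anc + 1L]
    }
    if (!ok)
      warning("external reconciliation: node ", u,
              " does not map to an ancestor of its child ", v)
  }
  if (any(M != ref$node_map))
    warning("external reconciliation differs from LCA mapping at ",
            sum(M != ref$node_map), " node(s); keeping external assignment")
  losses <- 0L
  for (v in seq_len(n) - 1L) {
    if (v == gt$root_id) next
    u <- gt$parent[v + 1L]
    if (M[u + 1L] == M[v + 1L]) next
    d <- sdepth[M[v + 1L] + 1L] - sdepth[M[u + 1L] + 1L]
    if (d > 0)
      losses <- losses + d - 1L + (event[u + 1L] == "duplication")
  }
  structure(list(node_map = M, event = event,
                 dup_count = sum(event == "duplication"),
                 loss_count = losses,
                 gene_tree = gt, species_tree = species_tree),
            class = "reconciliation")
}

#' Export a reconciliation as a branch-mapping table
#'
#' Convenience wrapper producing the TSV contract shared with the
#' enrichment stage.
#'
#' @param rec a `reconciliation`.
#' @param dataset_id,gene_tree_id identifiers prepended to every row.
#' @return data.frame: dataset_id, gene_tree_id, gene_branch_id,
#'   species_branch_id, event, branch_length.
#' @export
reconciliation_table <- function(rec, dataset_id = "d1", gene_tree_id = "g1") {
  ab <- assign_branches(rec)
  cbind(data.frame(dataset_id = dataset_id, gene_tree_id = gene_tree_id,
                   stringsAsFactors = FALSE), ab)
}
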