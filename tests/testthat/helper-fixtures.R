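# Fixture builders shared across tests.

# random gene-tree Newick over the leaves of a species ortree: k gene
# leaves, each assigned a (possibly repeated) random species of origin
random_gene_newick <- function(species_tree, k) {
  sp <- sample(species_tree$label[species_tree$is_leaf], k, replace = TRUE)
  labs <- paste0(sp, "|g", seq_len(k))
  nodes <- as.list(labs)
  while (length(nodes) > 1) {
    i <- sample.int(length(nodes), 2)
    merged <- sprintf("(%s:%.4f,%s:%.4f)", nodes[[i[1]]], rexp(1),
                      nodes[[i[2]]], rexp(1))
    nodes <- c(nodes[-i], merged)
  }
  paste0(nodes[[1]], ";")
}

# all rooted binary species-tree shapes on 2..4 leaves, as Newick
small_species_trees <- function() {
  c("(A:1,B:1);",
    "((A:1,B:1):1,C:1);",
    "((A:1,B:1):1,(C:1,D:1):1);",
    "(((A:1,B:1):1,C:1):1,D:1);")
}

# branch test record table built by hand
make_records <- function(lengths, p, branch = NULL, dataset = "d1") {
  n <- length(lengths)
  data.frame(dataset_id = dataset, gene_tree_id = "g1",
             gene_branch_id = seq_len(n) - 1L,
             species_branch_id = branch %||% rep("1", n),
             branch_length = lengths, p_value = p,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small fixed species tree used across trait/count tests
fixture_species_tree <- function() {
  parse_newick(
    "(((S1:0.3,S2:0.3):0.4,(S3:0.5,S4:0.5):0.2):0.3,(S5:0.6,S6:0.6):0.4);",
    "species")
}
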