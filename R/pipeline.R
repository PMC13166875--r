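#' Read a branch test table
#'
#' TSV with columns `dataset_id`, `gene_tree_id`, `gene_branch_id`,
#' `branch_length`, `p_value` — one row per gene-tree branch tested for
#' positive selection by the upstream branch-site test.
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
read_branch_tests <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("dataset_id", "gene_tree_id", "gene_branch_id",
            "branch_length", "p_value")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("tests table missing column(s): ", paste(miss, collapse = ", "))
  if (any(x$p_value < 0 | x$p_value > 1)) stop("p_value outside [0, 1]")
  if (any(x$branch_length < 0)) stop("negative branch_length")
  key <- paste(x$dataset_id, x$gene_tree_id, x$gene_branch_id)
  if (anyDuplicated(key))
    stop("duplicate (dataset, tree, branch) records")
  x
}

#' Read a transitions table
#'
#' TSV with columns `label`, `dataset_id`, `species_branch_id`: the
#' species-tree branches sharing one inferred trait change, the pooling
#' unit of the enrichment test.
#' @param path TSV file.
#' @return data.frame.
#' @export
read_transitions <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("label", "dataset_id", "species_branch_id")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("transitions table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0) stop("empty transitions table")
  x
}

#' Read a species x trait table
#' @param path TSV with a `species` column; remaining columns are traits
#'   (numeric columns are treated as continuous, others as discrete).
#' @return data.frame with rownames = species.
#' @export
read_traits <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(x)) stop("traits table needs a 'species' column")
  rownames(x) <- x$species
  x[names(x) != "species"]
}

#' Read a species x family gene-count matrix
#' @param path TSV with a `species` column; remaining columns are family
#'   counts (nonnegative integers).
#' @return integer matrix, rownames = species.
#' @export
read_counts <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(x)) stop("counts table needs a 'species' column")
  m <- as.matrix(x[names(x) != "species"])
  rownames(m) <- x$species
  if (any(m < 0) || any(m != round(m))) stop("counts must be integers >= 0")
  storage.mode(m) <- "integer"
  m
}

#' Run the full association pipeline
#'
#' Orchestrates the stages end to end: trait reconstruction and
#' transition calling (or a user-supplied transitions file, the faithful
#' route when transition branches are known), gene-tree/species-tree
#' reconciliation, length-normalized tallying, pooling by trait-change
#' label, hypergeometric testing and Benjamini-Hochberg correction;
#' optionally ancestral gene counts and a PGLS screen. With a `simulate`
#' block the inputs are generated by the synthetic-data module instead of
#' read from disk. Identical config and inputs reproduce byte-identical
#' report bodies.
#'
#' @param config a named list or the path to a YAML file. Recognized
#'   fields: `seed`, `alpha`, `out_dir`, and either `simulate` (arguments
#'   of [simulate_or_dataset()]) or `inputs` (paths: `species_tree`,
#'   `gene_trees` [one Newick per line], `tests`, `transitions` or
#'   `traits`, optionally `counts`), plus optional `trait_rules` (per
#'   trait: `kind`, `delta`, `floor`), `pgls_trait`,
#'   `single_copy_frac`.
#' @return the report, invisibly also written to
#'   `<out_dir>/report.json` together with stage TSVs when `out_dir` is
#'   set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  alpha <- config$alpha %||% 0.05
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  seed <- config$seed %||% 1L
  set.seed(seed)
  stage <- function(s, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", s, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  report <- list(tool = "orsel",
                 version = as.character(utils::packageVersion("orsel")),
                 seed = seed, alpha = alpha)

  if (!is.null(config$simulate)) {
    sim <- stage("simulate",
                 do.call(simulate_or_dataset, config$simulate))
    st <- sim$species_tree
    records <- sim$records
    transitions <- sim$transitions
    counts <- NULL; traits <- NULL
    report$inputs <- list(mode = "simulate",
                          config_digest = digest_obj(config$simulate))
  } else {
    inp <- config$inputs
    if (is.null(inp)) stop("config needs a 'simulate' or 'inputs' block")
    for (f in unlist(inp))
      if (is.character(f) && !file.exists(f)) stop("missing input file: ", f)
    st <- stage("treeio",
                parse_newick(paste(readLines(inp$species_tree, warn = FALSE),
                                   collapse = ""), "species"))
    records <- stage("tests", read_branch_tests(inp$tests))
    if (!is.null(inp$gene_trees)) {
      lines <- readLines(inp$gene_trees, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      asg <- stage("reconcile", {
        maps <- lapply(seq_along(lines), function(i) {
          gt <- parse_newick(lines[i], "gene")
          rec <- lca_reconcile(gt, st)
          ab <- assign_branches(rec)
          ab$gene_tree_id <- paste0("g", i)
          ab
        })
        do.call(rbind, maps)
      })
      key_r <- paste(records$gene_tree_id, records$gene_branch_id)
      key_a <- paste(asg$gene_tree_id, asg$gene_branch_id)
      hit <- match(key_r, key_a)
      if (anyNA(hit))
        stop("stage 'reconcile' failed: test records without a reconciled ",
             "branch: ", paste(utils::head(key_r[is.na(hit)], 5),
                               collapse = "; "))
      records$species_branch_id <- asg$species_branch_id[hit]
    }
    if (!"species_branch_id" %in% names(records))
      stop("records carry no species branch assignment and no gene trees ",
           "were given")
    traits <- if (!is.null(inp$traits)) read_traits(inp$traits)
    counts <- if (!is.null(inp$counts)) read_counts(inp$counts)
    transitions <- if (!is.null(inp$transitions)) {
      read_transitions(inp$transitions)
    } else if (!is.null(traits)) {
      stage("traits",
            transitions_from_traits(st, traits, config$trait_rules,
                                    unique(records$dataset_id)))
    } else stop("no transitions file and no traits to derive them from")
    report$inputs <- list(mode = "files",
                          digests = lapply(inp, digest_file))
  }

  enr <- stage("enrich", enrichment_test(records, transitions, alpha = alpha))
  report$enrichment <- enr

  if (!is.null(config$simulate)) {
    report$truth <- list(
      transition_branches = sim$truth$transition_branches,
      n_records = nrow(records),
      n_true_selected = sum(records$true_selected))
  }

  if (!is.null(counts)) {
    anc <- stage("counts", lapply(colnames(counts), function(f) {
      a <- sankoff_counts(st, stats::setNames(counts[, f], rownames(counts)))
      list(family = f, cost = a$cost, counts = a$count)
    }))
    report$ancestral_counts <- data.frame(
      family = vapply(anc, `[[`, character(1), "family"),
      parsimony_cost = vapply(anc, `[[`, numeric(1), "cost"),
      root_count = vapply(anc, function(a)
        a$counts[st$root_id + 1L], numeric(1)))
    if (!is.null(traits)) {
      tr <- config$pgls_trait %||%
        names(traits)[vapply(traits, is.numeric, logical(1))][1]
      if (!is.null(tr) && !is.na(tr)) {
        kept <- filter_families(counts,
                                config$single_copy_frac %||% 0.8)
        if (ncol(kept) > 0) {
          report$pgls <- stage("pgls",
            pgls_screen(st, stats::setNames(traits[[tr]], rownames(traits)),
                        kept))
          report$pgls_trait <- tr
        }
      }
    }
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wtsv <- function(df, name)
      utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wtsv(records, "records.tsv")
    wtsv(transitions, "transitions.tsv")
    wtsv(enr, "enrichment.tsv")
    if (!is.null(report$ancestral_counts))
      wtsv(report$ancestral_counts, "ancestral_counts.tsv")
    if (!is.null(report$pgls)) wtsv(report$pgls, "pgls.tsv")
    writeLines(write_newick(st), file.path(config$out_dir, "species_tree.nwk"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

# Reconstruct every trait and call transition branches, expanded over the
# datasets sharing the species tree.
transitions_from_traits <- function(st, traits, rules, dataset_ids) {
  out <- list()
  for (tr in names(traits)) {
    rule <- rules[[tr]] %||% list()
    vals <- stats::setNames(traits[[tr]], rownames(traits))
    kind <- rule$kind %||%
      if (is.numeric(vals)) "continuous" else "discrete"
    det <- if (kind == "continuous") {
      est <- brownian_ancestral(st, vals)
      detect_transitions(attr(est, "tree"), est, "continuous",
                         delta = rule$delta %||% 0.5, trait = tr)
    } else {
      fit <- mk_select(st, as.character(vals))$selected
      detect_transitions(fit$tree, marginal_states(fit), "discrete",
                         floor = rule$floor %||% 0.7, trait = tr)
    }
    out[[tr]] <- det
  }
  det <- do.call(rbind, out)
  if (is.null(det) || nrow(det) == 0)
    stop("no transition branches inferred from the traits")
  # a transition on the shared species tree applies to every dataset
  do.call(rbind, lapply(dataset_ids, function(d)
    cbind(det[, "label", drop = FALSE], dataset_id = d,
          species_branch_id = det$species_branch_id)))
}

digest_file <- function(path) {
  if (!is.character(path) || !file.exists(path)) return(NA_character_)
  digest_obj(readLines(path, warn = FALSE))
}

# small stable content digest (sum of char codes by position mixed with a
# polynomial hash); enough to fingerprint inputs in the report without
# extra dependencies
digest_obj <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  v <- utf8ToInt(s)
  h <- 0
  for (i in seq_along(v)) h <- (h * 31 + v[i]) %% 2147483647
  sprintf("%08x-%d", h, nchar(s))
}
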