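#' Read a codon alignment from FASTA
#'
#' @param path FASTA file of aligned coding sequences; all sequences must
#'   share a length divisible by 3.
#' @return character matrix of codons, `n_sequences x n_codons`, rownames
#'   = sequence names.
#' @export
read_codon_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  as_codon_matrix(stats::setNames(as.character(seqs), names(seqs)))
}

#' @rdname read_codon_alignment
#' @param sequences named character vector of aligned sequences.
#' @export
as_codon_matrix <- function(sequences) {
  w <- unique(nchar(sequences))
  if (length(w) != 1) stop("dimension error: unequal alignment lengths")
  if (w %% 3 != 0) stop("dimension error: length not a multiple of 3")
  nc <- w / 3
  m <- t(vapply(sequences, function(s)
    substring(s, 3 * seq_len(nc) - 2, 3 * seq_len(nc)), character(nc)))
  rownames(m) <- names(sequences)
  m
}

#' Write a codon matrix back to FASTA
#' @param codons codon matrix; @param path output file.
#' @export
write_codon_alignment <- function(codons, path) {
  seqs <- apply(codons, 1L, paste, collapse = "")
  writeLines(paste0(">", rownames(codons), "\n", seqs), path)
  invisible(path)
}

#' Adaptive confidence-threshold masking of a codon alignment
#'
#' Masks unreliably aligned codons while bounding information loss:
#' starting from the highest threshold on the grid, codons with
#' confidence score strictly below the threshold are masked; if more than
#' `max_fraction` of codons would be masked, the threshold is lowered by
#' `step` and the fraction re-tested, until the masked fraction is within
#' the bound (defaults: start 0.8, step 0.1, at most 20% masked). If even
#' the floor threshold masks too much, the floor is used and the overflow
#' flagged.
#'
#' @param codons codon matrix from [read_codon_alignment()].
#' @param scores numeric matrix of per-residue confidence scores in
#'   [0, 1] with the same shape, or a vector of per-column scores.
#' @param start,step,max_fraction,floor the threshold grid and masked-
#'   fraction bound.
#' @param mask_char replacement for a masked codon (`"NNN"`, or `"---"`).
#' @return a `masked_alignment`: list with `codons` (masked matrix),
#'   `threshold`, `masked_fraction`, `overflow` (TRUE when the bound
#'   could not be met at the floor).
#' @export
adaptive_mask <- function(codons, scores, start = 0.8, step = 0.1,
                          max_fraction = 0.2, floor = 0,
                          mask_char = "NNN") {
  if (is.vector(scores) && !is.matrix(scores)) {
    if (length(scores) != ncol(codons))
      stop("dimension error: ", length(scores), " column scores for ",
           ncol(codons), " codon columns")
    scores <- matrix(scores, nrow = nrow(codons), ncol = ncol(codons),
                     byrow = TRUE)
  }
  if (!all(dim(scores) == dim(codons)))
    stop("dimension error: score matrix ", paste(dim(scores), collapse = "x"),
         " vs alignment ", paste(dim(codons), collapse = "x"))
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  grid <- round(seq(start, floor, by = -step), 10)  # guard fp drift on the grid
  if (length(grid) == 0 || grid[length(grid)] > floor + 1e-9)
    grid <- c(grid, floor)
  chosen <- NULL; frac <- NA_real_; overflow <- FALSE
  for (t in grid) {
    frac <- mean(scores < t)
    if (frac <= max_fraction) { chosen <- t; break }
  }
  if (is.null(chosen)) {
    chosen <- floor
    frac <- mean(scores < chosen)
    overflow <- frac > max_fraction
  }
  masked <- codons
  masked[scores < chosen] <- mask_char
  structure(list(codons = masked, threshold = chosen,
                 masked_fraction = frac, overflow = overflow),
            class = "masked_alignment")
}

#' @export
print.masked_alignment <- function(x, ...) {
  cat(sprintf("<masked_alignment> threshold %.2f, %.1f%% masked%s\n",
              x$threshold, 100 * x$masked_fraction,
              if (x$overflow) " [overflow: bound not met at floor]" else ""))
  invisible(x)
}

#' Summarize a batch of masked alignments
#'
#' @param batch list of `masked_alignment` objects (possibly named).
#' @return list with `table` (one row per alignment: threshold, fraction,
#'   overflow) and `histogram` (threshold -> alignment count).
#' @export
mask_report <- function(batch) {
  if (length(batch) == 0)
    return(list(table = data.frame(alignment = character(0),
                                   threshold = numeric(0),
                                   masked_fraction = numeric(0),
                                   overflow = logical(0)),
                histogram = table(numeric(0))))
  nm <- names(batch)
  if (is.null(nm)) nm <- paste0("aln", seq_along(batch))
  tab <- data.frame(alignment = nm,
                    threshold = vapply(batch, `[[`, numeric(1), "threshold"),
                    masked_fraction = vapply(batch, `[[`, numeric(1),
                                             "masked_fraction"),
                    overflow = vapply(batch, `[[`, logical(1), "overflow"),
                    stringsAsFactors = FALSE)
  list(table = tab, histogram = table(tab$threshold))
}
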