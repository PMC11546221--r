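# The matched genes + expression container shared by all analyses.

.new_gene_dataset <- function(gene_id, sequence, expression) {
  structure(list(gene_id = as.character(gene_id),
                 sequence = unname(as.character(sequence)),
                 expression = as.numeric(expression)),
            class = "gene_dataset")
}

#' Matched coding sequences and expression values
#'
#' Constructs the dataset container used by every index and predictor: an
#' ordered collection of in-frame coding sequences matched one-to-one to
#' protein abundance values e_k (copies per cell). Sequences are validated
#' against the CDS contract (length a positive multiple of 3 after stripping a
#' terminal stop, no internal in-frame stop).
#'
#' @param sequences Character vector of CDS strings. Names are used as gene
#'   ids unless `gene_ids` is given.
#' @param expressions Numeric vector of non-negative abundances, same length.
#' @param gene_ids Optional character vector of unique gene identifiers.
#' @param validate Validate each sequence against the CDS contract
#'   (default TRUE).
#' @return An object of class `"gene_dataset"` with fields `gene_id`,
#'   `sequence` and `expression`.
#' @examples
#' d <- gene_dataset(c(g1 = "ATGAAATAA", g2 = "ATGCCCGGG"), c(10, 2.5))
#' length(d)
#' @export
gene_dataset <- function(sequences, expressions, gene_ids = names(sequences),
                         validate = TRUE) {
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%d", seq_along(sequences))
  if (length(sequences) != length(expressions))
    stop("'sequences' and 'expressions' must have the same length")
  if (length(gene_ids) != length(sequences))
    stop("'gene_ids' must match 'sequences' in length")
  if (anyDuplicated(gene_ids))
    stop("gene ids must be unique; duplicated: ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 5L),
               collapse = ", "))
  expressions <- as.numeric(expressions)
  if (any(!is.finite(expressions)) || any(expressions < 0))
    stop("expression values must be finite and non-negative")
  if (validate)
    for (i in seq_along(sequences)) .cds_codons(sequences[[i]], gene_ids[[i]])
  .new_gene_dataset(gene_ids, sequences, expressions)
}

#' @export
length.gene_dataset <- function(x) length(x$gene_id)

#' @export
`[.gene_dataset` <- function(x, i) {
  .new_gene_dataset(x$gene_id[i], x$sequence[i], x$expression[i])
}

#' @export
print.gene_dataset <- function(x, ...) {
  K <- length(x)
  cat("gene_dataset:", K, "genes\n")
  if (K) {
    lens <- nchar(x$sequence) %/% 3L
    cat("  codons per gene: ", min(lens), "-", max(lens),
        " (median ", stats::median(lens), ")\n", sep = "")
    cat("  expression (copies/cell): ",
        format(min(x$expression), digits = 4), " - ",
        format(max(x$expression), digits = 4),
        " (", sum(x$expression == 0), " zero)\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.gene_dataset <- function(object, ...) {
  print(object)
  cat("  log(e+1) quantiles:\n")
  print(round(stats::quantile(log1p(object$expression)), 3))
  invisible(object)
}
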