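# Codon Adaptation Index comparator: relative-adaptiveness weights from a
# highly expressed reference set, geometric-mean gene scores, and evaluation
# under the same cross-validation harness as the codon indices.

#' Relative-adaptiveness weights from a reference gene set
#'
#' Pools the codon counts of a reference set (conventionally highly expressed
#' genes) and, within every synonym group, sets each codon's weight to its
#' count relative to the most frequent synonymous codon: max w = 1 per group.
#' Codons never observed in the reference receive a pseudo-weight of
#' `pseudocount / max-count` so that downstream geometric means never hit
#' zero. An amino acid entirely absent from the reference is an error.
#'
#' @param counts Codon count matrix rows of the reference genes (or a single
#'   pooled named count vector over the 61 sense codons).
#' @param pseudocount Count-scale pseudocount for unobserved codons
#'   (default 0.5).
#' @return An object of class `"cai_weights"`: a named numeric vector of 61
#'   weights in (0, 1\], with attribute `"reference_size"`.
#' @export
cai_weights <- function(counts, pseudocount = 0.5) {
  pooled <- if (is.matrix(counts)) colSums(counts) else counts
  if (is.null(names(pooled)) || !all(.SENSE %in% names(pooled)))
    stop("'counts' must cover the 61 sense codons")
  pooled <- pooled[.SENSE]
  w <- stats::setNames(numeric(length(.SENSE)), .SENSE)
  missing_aa <- character(0)
  for (aa in names(.GROUPS)) {
    g <- .GROUPS[[aa]]
    mx <- max(pooled[g])
    if (mx == 0) {
      missing_aa <- c(missing_aa, aa)
      next
    }
    wg <- pooled[g] / mx
    wg[pooled[g] == 0] <- pseudocount / mx
    w[g] <- wg
  }
  if (length(missing_aa))
    stop("amino acid(s) entirely absent from the reference set: ",
         paste(missing_aa, collapse = ", "))
  structure(w, class = "cai_weights",
            reference_size = if (is.matrix(counts)) nrow(counts) else NA_integer_)
}

#' @export
print.cai_weights <- function(x, ...) {
  cat("cai_weights: 61 codons")
  if (!is.na(attr(x, "reference_size")))
    cat(", reference of", attr(x, "reference_size"), "genes")
  cat("\n  weight range:", format(range(unclass(x)), digits = 4), "\n")
  invisible(x)
}

#' @export
as.data.frame.cai_weights <- function(x, ...) {
  data.frame(codon = names(unclass(x)), aa = unname(.CODON_AA[names(unclass(x))]),
             w = as.numeric(x), stringsAsFactors = FALSE)
}

#' Codon Adaptation Index of a gene
#'
#' The geometric mean of the relative-adaptiveness weights over a gene's
#' codon occurrences, computed in log space: exp(sum n_c log w_c / l).
#' Always in (0, 1\]; equal to 1 iff every codon used has weight 1.
#'
#' @param x A CDS string, a codon count vector, or a codon count matrix
#'   (genes in rows).
#' @param weights A [cai_weights()] object (or named weight vector over the
#'   61 sense codons).
#' @return CAI value(s) in (0, 1\].
#' @examples
#' w <- cai_weights(stats::setNames(rep(1, 61), sense_codons()))
#' cai_score("ATGAAATAA", w)  # all weights 1 -> CAI 1
#' @export
cai_score <- function(x, weights) {
  w <- unclass(weights)[.SENSE]
  if (any(is.na(w)) || any(w <= 0)) stop("invalid CAI weights")
  if (is.character(x)) x <- count_codons(x)
  if (is.null(dim(x))) x <- matrix(x[.SENSE], nrow = 1L,
                                   dimnames = list(NULL, .SENSE))
  l <- rowSums(x)
  if (any(l == 0)) stop("gene with no sense codons")
  as.vector(exp((x[, .SENSE, drop = FALSE] %*% log(w)) / l))
}

#' Evaluate CAI as an expression predictor under cross-validation
#'
#' Runs the Codon Adaptation Index through the same interleaved
#' cross-validation harness as the codon indices: within each training fold
#' the reference set is the top quarter of training genes by expression, CAI
#' is scored on the test genes, and (for comparability) the same affine
#' regression step maps scores to the log-expression scale. Equivalent to
#' `cross_validate(dataset, method = "cai", ...)`.
#'
#' @param dataset A [gene_dataset].
#' @param ... Passed to [cross_validate()].
#' @return A `"cv_report"`.
#' @export
evaluate_cai <- function(dataset, ...) {
  cross_validate(dataset, method = "cai", ...)
}
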