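# Expression-class partitioning and class-level codon distributions:
# genes are sorted by decreasing expression and split into contiguous
# equal-size classes (class 1 = highest expression), and each class gets a
# pooled, normalized 61-codon frequency distribution.

#' Split genes into expression classes with pooled codon distributions
#'
#' Sorts genes by decreasing expression (ties broken by stable input order)
#' and partitions them into `n_classes` contiguous blocks of equal size, the
#' remainder going to the earliest (highest-expression) classes. Class 1 holds
#' the highest-expressed genes. For each class the pooled codon counts are
#' normalized into a 61-codon frequency distribution summing to 1.
#'
#' @param dataset A [gene_dataset].
#' @param n_classes Number of classes (default 4).
#' @return An object of class `"expression_classes"`: a list of classes, each
#'   with `label`, `gene_ids`, `index` (positions in the dataset),
#'   `expression_range` and `distribution` (61 frequencies); attribute
#'   `"distributions"` holds the 61 x n_classes matrix.
#' @examples
#' cfg <- synthetic_config(n_genes = 40, gene_length_range = c(30, 60), seed = 1)
#' cls <- split_into_classes(generate_dataset(cfg)$dataset)
#' vapply(cls, function(x) length(x$gene_ids), 1L)  # 10 10 10 10
#' @export
split_into_classes <- function(dataset, n_classes = 4L) {
  stopifnot(inherits(dataset, "gene_dataset"))
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("'n_classes' must be at least 2")
  K <- length(dataset)
  if (K < n_classes) stop("need at least ", n_classes, " genes, got ", K)
  ord <- order(-dataset$expression)
  sizes <- rep(K %/% n_classes, n_classes) +
    (seq_len(n_classes) <= K %% n_classes)
  bounds <- c(0L, cumsum(sizes))
  counts <- codon_counts(dataset)
  classes <- lapply(seq_len(n_classes), function(j) {
    idx <- ord[(bounds[j] + 1L):bounds[j + 1L]]
    list(label = j,
         gene_ids = dataset$gene_id[idx],
         index = idx,
         expression_range = range(dataset$expression[idx]),
         distribution = class_distribution(counts[idx, , drop = FALSE]))
  })
  dist <- vapply(classes, `[[`, numeric(ncol(counts)), "distribution")
  colnames(dist) <- paste0("class_", seq_len(n_classes))
  structure(classes, class = "expression_classes", distributions = dist, K = K)
}

#' Pooled codon distribution of a set of genes
#'
#' Pools the codon counts of a group of genes (summing counts, not averaging
#' per-gene frequencies, so longer genes carry proportionally more weight) and
#' normalizes them to a frequency distribution summing to 1.
#'
#' @param counts One or more rows of a codon count matrix.
#' @return A named numeric vector of frequencies summing to 1.
#' @export
class_distribution <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL, names(counts)))
  if (nrow(counts) == 0L) stop("empty class: no genes to pool")
  total <- sum(counts)
  if (total == 0) stop("empty class: pooled codon count is zero")
  colSums(counts) / total
}

#' Pearson correlation between two codon distributions
#'
#' Product-moment correlation between two frequency vectors over the same
#' units, as used to compare expression-class codon distributions (and a
#' distribution from another species) pairwise.
#'
#' @param d1,d2 Numeric vectors of equal length with nonzero variance.
#' @return The Pearson correlation coefficient.
#' @export
distribution_correlation <- function(d1, d2) {
  if (length(d1) != length(d2)) stop("distributions differ in length")
  if (stats::sd(d1) == 0 || stats::sd(d2) == 0)
    stop("zero-variance distribution")
  stats::cor(d1, d2)
}

#' Correlation matrix between class codon distributions
#'
#' Pairwise Pearson correlations between the pooled codon distributions of
#' expression classes, optionally augmented with externally supplied
#' distributions (e.g. a class of genes from another species) given as extra
#' named 61-vectors.
#'
#' @param classes An `"expression_classes"` object.
#' @param extra Optional named list of additional distributions (numeric
#'   vectors over the same codons).
#' @return A symmetric correlation matrix.
#' @export
class_correlations <- function(classes, extra = NULL) {
  stopifnot(inherits(classes, "expression_classes"))
  dist <- attr(classes, "distributions")
  if (!is.null(extra)) {
    extra <- as.data.frame(extra)
    if (nrow(extra) != nrow(dist))
      stop("extra distributions must have ", nrow(dist), " entries")
    dist <- cbind(dist, as.matrix(extra))
  }
  stats::cor(dist)
}

#' @export
print.expression_classes <- function(x, ...) {
  cat("expression_classes:", length(x), "classes over", attr(x, "K"), "genes\n")
  for (cl in x) {
    cat(sprintf("  class %d: %4d genes, expression %s - %s copies/cell\n",
                cl$label, length(cl$gene_ids),
                format(cl$expression_range[2], digits = 4),
                format(cl$expression_range[1], digits = 4)))
  }
  invisible(x)
}
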