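# Gene-level scoring and the regression / cross-validation building blocks
# shared by CEIS, CPS, CPEIS and the CAI comparator.

#' Log-transformed expression
#'
#' The natural-log transform used on the prediction scale: log(e + 1), so
#' that genes with less than one protein copy per cell map to small
#' non-negative values and e = 0 maps to exactly 0.
#'
#' @param e Non-negative expression values (protein copies per cell).
#' @return log(e + 1), natural base.
#' @export
log_expression <- function(e) {
  if (!is.numeric(e)) stop("'e' must be numeric")
  if (any(e < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  log1p(e)
}

#' Count-weighted mean index value per gene
#'
#' Scores each gene by the mean index value of its codon (or pair)
#' occurrences: C_k = sum_c n_kc v_c / sum_c n_kc, identical to averaging the
#' index over the gene's unit sequence. Units with undefined index values
#' (NA: unobserved in training, or CP with N_c = 0) are skipped and the
#' denominator renormalized over the remaining occurrences.
#'
#' @param counts Count matrix from [codon_counts()] (genes in rows).
#' @param values Named numeric vector of index values aligned to the columns;
#'   NA marks undefined units.
#' @return Numeric vector of gene scores; attribute `"skipped_frac"` gives
#'   the per-gene fraction of counted units that were skipped as undefined.
#' @export
gene_scores <- function(counts, values) {
  if (is.null(names(values)) || !identical(names(values), colnames(counts)))
    values <- values[colnames(counts)]
  if (any(is.na(names(values))))
    stop("'values' must be named by the count matrix columns")
  defined <- !is.na(values)
  cd <- counts[, defined, drop = FALSE]
  den <- rowSums(cd)
  total <- rowSums(counts)
  if (any(den == 0))
    stop("gene(s) with no defined index units: ",
         paste(utils::head(rownames(counts)[den == 0], 5L), collapse = ", "))
  s <- as.vector(cd %*% values[defined]) / den
  attr(s, "skipped_frac") <- 1 - den / total
  s
}

#' Ordinary least-squares fit of log expression on gene scores
#'
#' Fits log(e_k + 1) = a C_k + b by ordinary least squares, the affine map
#' used to put index-based gene scores on the log-expression scale.
#'
#' @param scores Gene scores C_k (at least 2 distinct values).
#' @param log_expressions Matched log(e + 1) values.
#' @return Named vector `c(a = slope, b = intercept)`.
#' @examples
#' fit_regression(c(0, 1), c(1, 3))  # a = 2, b = 1
#' @export
fit_regression <- function(scores, log_expressions) {
  if (length(scores) != length(log_expressions))
    stop("'scores' and 'log_expressions' must have the same length")
  if (length(scores) < 2L) stop("need at least 2 genes to fit")
  if (stats::sd(scores) == 0) stop("zero variance in gene scores")
  co <- stats::coef(stats::lm(log_expressions ~ scores))
  c(a = unname(co[2L]), b = unname(co[1L]))
}

#' Interleaved cross-validation plan
#'
#' Assigns each gene to one of `n_folds` test folds by sorting genes in
#' decreasing expression order (ties broken by stable input order) and
#' dealing them out cyclically: the gene at sorted position i goes to fold
#' ((i - 1) mod n_folds) + 1. Every fold's test set therefore spans the full
#' expression range (one gene from each consecutive block of n_folds), and
#' every gene appears in exactly one test fold.
#'
#' @param x A [gene_dataset] or a numeric expression vector.
#' @param n_folds Number of folds (default 11).
#' @return Integer vector of fold assignments (1..n_folds) in dataset order,
#'   with attribute `"n_folds"`.
#' @export
make_cv_plan <- function(x, n_folds = 11L) {
  e <- if (inherits(x, "gene_dataset")) x$expression else as.numeric(x)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("'n_folds' must be at least 2")
  K <- length(e)
  if (K < n_folds) stop("need at least ", n_folds, " genes, got ", K)
  fold <- integer(K)
  fold[order(-e)] <- (seq_len(K) - 1L) %% n_folds + 1L
  attr(fold, "n_folds") <- n_folds
  fold
}

#' Pearson product-moment correlation with input validation
#'
#' Standard Pearson correlation, used as the prediction-accuracy measure;
#' errors on degenerate (constant) input rather than returning NA.
#'
#' @param x,y Numeric vectors of equal length >= 2, both nonconstant.
#' @return The correlation coefficient, in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  stats::cor(x, y)
}

#' Prediction accuracy stratified by expression level
#'
#' Recomputes the pooled Pearson correlation over the genes whose actual
#' log(e + 1) value is at least each threshold, reproducing the standard
#' accuracy-by-expression-stratum table (threshold 0 gives the unstratified
#' accuracy over all genes). Strata with fewer than 3 genes, or with
#' degenerate (constant) predictions or actuals, are flagged and get NA.
#'
#' @param report A `"cv_report"` from [cross_validate()], or a data.frame
#'   with columns `pred_log` and `actual_log`.
#' @param log_thresholds Numeric thresholds on the natural-log scale
#'   (default 0:4).
#' @return A data.frame with columns `threshold`, `range`, `n`, `r` and
#'   `flagged`.
#' @export
stratified_accuracy <- function(report, log_thresholds = 0:4) {
  df <- if (inherits(report, "cv_report")) report$predictions else report
  stopifnot(all(c("pred_log", "actual_log") %in% names(df)))
  top <- ceiling(max(df$actual_log))
  rows <- lapply(log_thresholds, function(t) {
    sel <- df$actual_log >= t
    n <- sum(sel)
    r <- NA_real_
    flagged <- TRUE
    if (n >= 3L && stats::sd(df$pred_log[sel]) > 0 &&
        stats::sd(df$actual_log[sel]) > 0) {
      r <- pearson_r(df$pred_log[sel], df$actual_log[sel])
      flagged <- FALSE
    }
    data.frame(threshold = t, range = sprintf("%g-%g", t, top), n = n,
               r = r, flagged = flagged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
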