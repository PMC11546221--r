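# Interleaved k-fold cross-validation of the expression predictors. Index
# values (and the CAI reference set) are re-estimated inside every training
# fold; test genes are scored and mapped to the log-expression scale.

#' Cross-validated evaluation of a codon-based expression predictor
#'
#' Evaluates CEIS, CPS, CPEIS or CAI by interleaved k-fold cross-validation:
#' genes are sorted by decreasing expression and dealt cyclically into
#' `n_folds` test folds ([make_cv_plan()]), so each gene is predicted exactly
#' once by a model whose index values, CAI reference set and regression
#' coefficients were estimated from the other folds only. The pooled
#' predictions are compared with actual log(e + 1) values by Pearson
#' correlation, overall and stratified by expression level.
#'
#' The `rescale` argument controls the affine step that puts pooled scores on
#' the log-expression scale: `"fold"` applies each training fold's own
#' least-squares coefficients to its test genes; `"average"` applies a single
#' affine map (the fold coefficients averaged) to all pooled scores, which
#' leaves the pooled Pearson r exactly equal to that of the raw scores;
#' `"none"` reports raw scores. The choice affects the convenience of the
#' predicted values, not the accuracy (identically for `"average"`/`"none"`,
#' and to well below rounding for `"fold"`).
#'
#' @param dataset A [gene_dataset].
#' @param method `"ceis"`, `"cps"`, `"cpeis"` or `"cai"`.
#' @param n_folds Number of interleaved folds (default 11).
#' @param rescale `"fold"`, `"average"` or `"none"` (see Details).
#' @param strata Log-scale thresholds for [stratified_accuracy()] (default
#'   0:4); NULL to skip.
#' @param reference_fraction CAI reference-set fraction (default 0.25).
#' @return An object of class `"cv_report"`: list with `predictions` (one row
#'   per gene: `gene_id`, `fold`, `score`, `pred_log`, `pred_copies`,
#'   `actual_log`, `skipped_frac`), `r` (pooled Pearson correlation),
#'   `coefficients` (per-fold a, b), `strata`, `method`, `n_folds`,
#'   `rescale` and `K`.
#' @examples
#' d <- generate_dataset(synthetic_config(n_genes = 70,
#'   gene_length_range = c(40, 80), noise_sd = 0.5, seed = 4))$dataset
#' rep <- cross_validate(d, "ceis")
#' rep$r
#' @export
cross_validate <- function(dataset, method = c("ceis", "cps", "cpeis", "cai"),
                           n_folds = 11L, rescale = c("fold", "average", "none"),
                           strata = 0:4, reference_fraction = 0.25) {
  method <- match.arg(method)
  rescale <- match.arg(rescale)
  stopifnot(inherits(dataset, "gene_dataset"))
  counts <- codon_counts(dataset, .METHOD_UNIT[[method]])
  e <- dataset$expression
  loge <- log_expression(e)
  K <- length(dataset)
  fold <- make_cv_plan(dataset, n_folds)
  score <- numeric(K)
  pred <- numeric(K)
  skipped <- numeric(K)
  ab <- matrix(NA_real_, n_folds, 2L, dimnames = list(NULL, c("a", "b")))
  for (f in seq_len(n_folds)) {
    train <- fold != f
    test <- !train
    iv <- .index_values(method, counts[train, , drop = FALSE], e[train],
                        reference_fraction)
    s_all <- .score_genes(counts, iv)
    co <- tryCatch(fit_regression(s_all[train], loge[train]),
                   error = function(err)
                     stop("fold ", f, ": ", conditionMessage(err),
                          call. = FALSE))
    ab[f, ] <- co
    score[test] <- s_all[test]
    skipped[test] <- attr(s_all, "skipped_frac")[test]
    pred[test] <- co[["a"]] * s_all[test] + co[["b"]]
  }
  if (rescale == "average") {
    pred <- mean(ab[, "a"]) * score + mean(ab[, "b"])
  } else if (rescale == "none") {
    pred <- score
  }
  predictions <- data.frame(gene_id = dataset$gene_id, fold = fold,
                            score = score, pred_log = pred,
                            pred_copies = pmax(expm1(pred), 0),
                            actual_log = loge, skipped_frac = skipped,
                            stringsAsFactors = FALSE)
  out <- structure(list(predictions = predictions,
                        r = pearson_r(pred, loge),
                        coefficients = data.frame(fold = seq_len(n_folds),
                                                  a = ab[, "a"], b = ab[, "b"]),
                        method = method, n_folds = n_folds, rescale = rescale,
                        K = K, strata = NULL),
                   class = "cv_report")
  if (!is.null(strata)) out$strata <- stratified_accuracy(out, strata)
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report: ", toupper(x$method), ", ", x$n_folds,
      "-fold interleaved CV over K = ", x$K, " genes\n", sep = "")
  cat(sprintf("  pooled Pearson r (predicted vs actual log expression): %.3f\n",
              x$r))
  if (!is.null(x$strata)) {
    cat("  accuracy by expression stratum (actual log(e+1) >= threshold):\n")
    s <- x$strata
    for (i in seq_len(nrow(s)))
      cat(sprintf("    log %-6s n = %4d   r = %s\n", s$range[i], s$n[i],
                  if (s$flagged[i]) "--" else sprintf("%.3f", s$r[i])))
  }
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  print(object)
  cat("  per-fold regression coefficients:\n")
  co <- object$coefficients
  cat(sprintf("    a: %.4g - %.4g   b: %.4g - %.4g\n",
              min(co$a), max(co$a), min(co$b), max(co$b)))
  if (any(object$predictions$skipped_frac > 0))
    cat(sprintf("  mean fraction of units skipped as undefined: %.4f\n",
                mean(object$predictions$skipped_frac)))
  invisible(object)
}

#' @export
plot.cv_report <- function(x, ...) {
  p <- x$predictions
  graphics::plot(p$pred_log, p$actual_log,
                 xlab = "predicted log(e + 1)", ylab = "actual log(e + 1)",
                 pch = 16, col = grDevices::adjustcolor("steelblue", 0.5), ...)
  graphics::abline(0, 1, col = "grey40", lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("%s, r = %.3f", toupper(x$method), x$r))
  invisible(x)
}

#' Write the per-gene predictions and stratified accuracy of a CV report
#'
#' @param report A `"cv_report"`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default the method name).
#' @return Invisibly, the paths written.
#' @export
write_cv_report <- function(report, dir, prefix = report$method) {
  stopifnot(inherits(report, "cv_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(predictions = file.path(dir, paste0(prefix, "_predictions.tsv")))
  .write_tsv(report$predictions, paths[["predictions"]])
  if (!is.null(report$strata)) {
    paths[["strata"]] <- file.path(dir, paste0(prefix, "_strata.tsv"))
    .write_tsv(report$strata, paths[["strata"]])
  }
  paths[["coefficients"]] <- file.path(dir, paste0(prefix, "_coefficients.tsv"))
  .write_tsv(report$coefficients, paths[["coefficients"]])
  invisible(paths)
}
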