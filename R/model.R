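# The fitted expression model: index values estimated from a dataset, gene
# scores, and the least-squares map from score to log(e + 1).

.METHOD_UNIT <- c(ceis = "codon", cps = "codon", cpeis = "pair", cai = "codon")

# Index values (NA = undefined unit) and the score transform for one method,
# estimated from the given (training) rows only.
.index_values <- function(method, counts, e, reference_fraction = 0.25) {
  if (method == "ceis" || method == "cpeis") {
    tab <- cei_zscores(codon_frequencies(counts), e)
    list(values = stats::setNames(ifelse(tab$observed, tab$z, NA_real_),
                                  tab$unit),
         transform = identity, table = tab)
  } else if (method == "cps") {
    tab <- codon_productivity(counts, e)
    list(values = stats::setNames(tab$cp, tab$unit),
         transform = identity, table = tab)
  } else {
    n_ref <- max(2L, floor(length(e) * reference_fraction))
    ref <- order(-e)[seq_len(n_ref)]
    w <- cai_weights(counts[ref, , drop = FALSE])
    list(values = stats::setNames(log(unclass(w)), names(unclass(w))),
         transform = exp, weights = w)
  }
}

.score_genes <- function(counts, iv) {
  s <- gene_scores(counts, iv$values)
  out <- iv$transform(s)
  attr(out, "skipped_frac") <- attr(s, "skipped_frac")
  out
}

#' Fit a codon-based expression model
#'
#' Fits one of the four gene-sequence expression predictors on a full
#' dataset: CEIS (gene-average Codon Expression Index), CPS (gene-average
#' Codon Productivity), CPEIS (gene-average codon-pair CEI) or CAI (geometric
#' mean of relative-adaptiveness weights, top-quartile reference). The index
#' is estimated from the dataset, each gene is scored by the count-weighted
#' mean of the index over its codons (geometric mean for CAI), and ordinary
#' least squares maps scores to log(e + 1):
#' \deqn{P_k = a C_k + b.}
#'
#' For honest accuracy estimates use [cross_validate()], which re-estimates
#' the index inside every training fold; the fitted model here is the
#' full-data estimator used for prediction on new sequences.
#'
#' @param dataset A [gene_dataset].
#' @param method `"ceis"`, `"cps"`, `"cpeis"` or `"cai"`.
#' @param reference_fraction Fraction of genes in the CAI reference set
#'   (default 0.25, the top quarter by expression).
#' @return An object of class `"expr_model"` with print, summary, coef,
#'   predict, fitted, residuals, plot and simulate methods.
#' @examples
#' d <- generate_dataset(synthetic_config(n_genes = 80,
#'   gene_length_range = c(40, 80), seed = 3))$dataset
#' fit <- fit_expression_model(d, "ceis")
#' fit
#' predict(fit, d[1:2], type = "copies")
#' @export
fit_expression_model <- function(dataset,
                                 method = c("ceis", "cps", "cpeis", "cai"),
                                 reference_fraction = 0.25) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "gene_dataset"))
  counts <- codon_counts(dataset, .METHOD_UNIT[[method]])
  e <- dataset$expression
  loge <- log_expression(e)
  iv <- .index_values(method, counts, e, reference_fraction)
  scores <- as.vector(.score_genes(counts, iv))
  ab <- fit_regression(scores, loge)
  fitted_log <- ab[["a"]] * scores + ab[["b"]]
  structure(list(call = match.call(), method = method,
                 unit = .METHOD_UNIT[[method]],
                 index = iv, coefficients = ab,
                 gene_id = dataset$gene_id, scores = as.vector(scores),
                 fitted_log = fitted_log, actual_log = loge,
                 r = pearson_r(fitted_log, loge),
                 sigma = stats::sd(loge - fitted_log),
                 K = length(dataset)),
            class = "expr_model")
}

#' @export
print.expr_model <- function(x, ...) {
  cat("Codon-based expression model (", toupper(x$method), "), K = ",
      x$K, " genes\n", sep = "")
  cat(sprintf("  log(e+1) = %.4g * score + %.4g\n",
              x$coefficients[["a"]], x$coefficients[["b"]]))
  cat(sprintf("  in-sample Pearson r = %.3f\n", x$r))
  invisible(x)
}

#' @export
summary.expr_model <- function(object, ...) {
  print(object)
  cat("  residual (log scale) sd:", format(object$sigma, digits = 4), "\n")
  if (object$method %in% c("ceis", "cpeis")) {
    tab <- object$index$table
    cat("  significant units (|Z| > 3):", sum(tab$significant), "of",
        nrow(tab), "\n")
  } else if (object$method == "cai") {
    cat("  CAI reference genes:",
        attr(object$index$weights, "reference_size"), "\n")
  }
  invisible(object)
}

#' @export
coef.expr_model <- function(object, ...) object$coefficients

#' @export
fitted.expr_model <- function(object, ...) {
  stats::setNames(object$fitted_log, object$gene_id)
}

#' @export
residuals.expr_model <- function(object, ...) {
  stats::setNames(object$actual_log - object$fitted_log, object$gene_id)
}

#' Predict expression for new coding sequences
#'
#' Scores new genes with the model's fitted index values (units unobserved in
#' the fitting data are skipped with the mean renormalized) and applies the
#' fitted affine map. Predictions are returned on the log(e + 1) scale or
#' back-transformed to protein copies per cell, clamped at 0.
#'
#' @param object An `"expr_model"`.
#' @param newdata A [gene_dataset], a character vector of CDS strings, or
#'   NULL for the fitted values.
#' @param type `"log"` (log(e + 1)) or `"copies"` (exp(P) - 1, clamped at 0).
#' @param ... Unused.
#' @export
predict.expr_model <- function(object, newdata = NULL,
                               type = c("log", "copies"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    p <- object$fitted_log
    names(p) <- object$gene_id
  } else {
    counts <- codon_counts(newdata, object$unit)
    s <- .score_genes(counts, object$index)
    p <- object$coefficients[["a"]] * as.vector(s) + object$coefficients[["b"]]
    names(p) <- rownames(counts)
  }
  if (type == "copies") pmax(expm1(p), 0) else p
}

#' @export
plot.expr_model <- function(x, ...) {
  graphics::plot(x$fitted_log, x$actual_log,
                 xlab = "predicted log(e + 1)", ylab = "actual log(e + 1)",
                 pch = 16, col = grDevices::adjustcolor("steelblue", 0.5), ...)
  graphics::abline(0, 1, col = "grey40", lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("%s, r = %.3f", toupper(x$method), x$r))
  invisible(x)
}

#' @export
simulate.expr_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(replicate(nsim, {
    p <- object$fitted_log + stats::rnorm(object$K, 0, object$sigma)
    pmax(expm1(p), 0)
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$gene_id
  out
}
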