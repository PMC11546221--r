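# Synthetic CDS + abundance datasets with planted per-codon (or per-pair)
# expression effects. The generator isolates the codon-usage signal the
# indices are built to detect: amino-acid composition is independent of
# expression, and only the synonymous choice within each group carries the
# planted effect.

# Expected per-position planted weight at full propensity (u = 1), used to
# map the planted score onto the target log-expression span.
.expected_max_score <- function(weights, tilt) {
  contrib <- vapply(.GROUPS, function(g) {
    w <- weights[g]
    eff <- w != 0
    if (sum(eff) < 2L) return(0)
    sm <- exp(tilt * w[eff])
    sm <- sm / sum(sm)
    (sum(eff) / length(g)) * sum(sm * w[eff])
  }, numeric(1L))
  mean(contrib)
}

.default_full_weights <- function() {
  w <- stats::setNames(numeric(length(.SENSE)), .SENSE)
  for (g in .GROUPS) {
    g <- sort(g)
    if (length(g) >= 2L) {
      w[g[1L]] <- 1
      w[g[length(g)]] <- -1
    }
  }
  w
}

# Deterministic default pair effects: pairs of the alphabetically first
# codons of the two-codon synonym groups are favoured (+1), pairs of the
# last codons disfavoured (-1).
.default_pair_weights <- function() {
  two <- Filter(function(g) length(g) == 2L, .GROUPS)
  first <- vapply(two, function(g) sort(g)[1L], "")
  last <- vapply(two, function(g) sort(g)[2L], "")
  w <- stats::setNames(numeric(length(.PAIRS)), .PAIRS)
  w[as.vector(outer(first, first, paste0))] <- 1
  w[as.vector(outer(last, last, paste0))] <- -1
  w
}

#' Configuration for the synthetic-data generator
#'
#' Defines a reproducible synthetic study: K genes whose synonymous-codon
#' choice is tilted by a latent per-gene propensity u ~ Uniform(0, 1) acting
#' on planted per-codon weights, and whose expression is an affine function
#' of the realized mean planted weight plus Gaussian noise on the log(e + 1)
#' scale.
#'
#' The `"full"` preset plants, in every synonym group of size >= 2, one
#' positive-effect codon (+1), one negative-effect codon (-1), and leaves the
#' rest at 0 (so groups of size >= 3 also contain null codons). The `"pairs"`
#' preset plants weights on adjacent codon pairs instead, to exercise the
#' codon-pair index.
#'
#' @param n_genes Number of genes K (default 1688, a typical filtered
#'   single-copy proteome dataset).
#' @param gene_length_range Codons per gene, drawn uniformly (default
#'   c(100, 500), typical bacterial CDS lengths).
#' @param preset `"full"` (per-codon effects) or `"pairs"` (per-pair effects).
#' @param planted_weights Optional named per-codon weight vector overriding
#'   the preset.
#' @param pair_weights Optional named per-pair weight vector (pairs preset).
#' @param tilt Strength of the synonymous-choice tilt: effect codons of a
#'   group share their combined probability mass proportionally to
#'   exp(tilt * u * w_c) (default 1.5, a strong effect).
#' @param effect_scale Multiplier from mean planted weight to log(e + 1);
#'   NULL (default) derives it so expression spans `expression_range`.
#' @param noise_sd Gaussian noise sd on the log(e + 1) scale (default 1).
#' @param expression_range Target range of protein copies per cell (default
#'   c(0, 38022)).
#' @param seed RNG seed; identical config + seed gives a byte-identical
#'   dataset.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_genes = 1688L, gene_length_range = c(100L, 500L),
                             preset = c("full", "pairs"),
                             planted_weights = NULL, pair_weights = NULL,
                             tilt = 1.5, effect_scale = NULL, noise_sd = 1,
                             expression_range = c(0, 38022), seed = 1L) {
  preset <- match.arg(preset)
  n_genes <- as.integer(n_genes)
  gene_length_range <- as.integer(gene_length_range)
  if (n_genes < 2L) stop("'n_genes' must be at least 2")
  if (length(gene_length_range) != 2L ||
      gene_length_range[1L] < 1L ||
      gene_length_range[2L] < gene_length_range[1L])
    stop("'gene_length_range' must be an increasing pair of positive lengths")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (length(expression_range) != 2L || any(expression_range < 0) ||
      expression_range[2L] <= expression_range[1L])
    stop("'expression_range' must be an increasing non-negative pair")
  if (tilt < 0) stop("'tilt' must be non-negative")
  if (is.null(planted_weights)) {
    planted_weights <- if (preset == "full") .default_full_weights()
                       else stats::setNames(numeric(length(.SENSE)), .SENSE)
  } else {
    if (is.null(names(planted_weights)) ||
        !all(names(planted_weights) %in% .SENSE))
      stop("'planted_weights' must be named by sense codons")
    w <- stats::setNames(numeric(length(.SENSE)), .SENSE)
    w[names(planted_weights)] <- planted_weights
    planted_weights <- w
  }
  if (preset == "pairs" && is.null(pair_weights))
    pair_weights <- .default_pair_weights()
  if (!is.null(pair_weights)) {
    if (is.null(names(pair_weights)) || !all(names(pair_weights) %in% .PAIRS))
      stop("'pair_weights' must be named by sense codon pairs")
    w <- stats::setNames(numeric(length(.PAIRS)), .PAIRS)
    w[names(pair_weights)] <- pair_weights
    pair_weights <- w
  }
  if (is.null(effect_scale) && preset == "full") {
    smax <- .expected_max_score(planted_weights, tilt)
    span <- log1p(expression_range[2L]) - log1p(expression_range[1L])
    effect_scale <- if (smax > 0) span / smax else 0
  }
  structure(list(n_genes = n_genes, gene_length_range = gene_length_range,
                 preset = preset, planted_weights = planted_weights,
                 pair_weights = pair_weights, tilt = tilt,
                 effect_scale = effect_scale, noise_sd = noise_sd,
                 expression_range = expression_range, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config:", x$n_genes, "genes,",
      x$gene_length_range[1], "-", x$gene_length_range[2], "codons,",
      "preset", shQuote(x$preset), "\n")
  cat("  tilt:", x$tilt, " effect_scale:",
      if (is.null(x$effect_scale)) "(empirical)" else format(x$effect_scale,
                                                             digits = 4),
      " noise_sd:", x$noise_sd, " seed:", x$seed, "\n")
  invisible(x)
}

# Per-gene codon choice for the "full" preset: every position's amino acid is
# uniform over the 20; within a synonym group the nonzero-weight codons share
# their combined probability mass by a softmax in u * w, while zero-weight
# codons keep their uniform 1/m share (so they are true nulls).
.group_probs <- function(u, weights, tilt) {
  lapply(.GROUPS, function(g) {
    m <- length(g)
    p <- rep(1 / m, m)
    names(p) <- g
    eff <- which(weights[g] != 0)
    if (length(eff) >= 2L) {
      sm <- exp(tilt * u * weights[g][eff])
      p[eff] <- (length(eff) / m) * sm / sum(sm)
    }
    p
  })
}

#' Generate a synthetic dataset with planted codon effects
#'
#' Draws, for each gene, a latent expression propensity u ~ Uniform(0, 1), an
#' amino-acid backbone uniform over the 20 amino acids, and synonymous codons
#' tilted by u and the planted weights (see [synthetic_config()]). Expression
#' is set on the log scale as
#' `log(e + 1) = intercept + effect_scale * s_k + N(0, noise_sd)`, where s_k
#' is the gene's realized mean planted weight, then back-transformed and
#' clamped at 0. A terminal TAA stop codon is appended to every gene.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `"synthetic_dataset"`: a list with `dataset`
#'   (a [gene_dataset]) and `truth` (per-gene `u` and realized `score`, the
#'   planted `weights`/`pair_weights`, and the config).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  K <- config$n_genes
  lens <- sample(config$gene_length_range[1L]:config$gene_length_range[2L],
                 K, replace = TRUE)
  u <- stats::runif(K)
  seqs <- character(K)
  s <- numeric(K)
  if (config$preset == "full") {
    w <- config$planted_weights
    aa_names <- names(.GROUPS)
    for (k in seq_len(K)) {
      probs <- .group_probs(u[k], w, config$tilt)
      aa_idx <- sample.int(length(aa_names), lens[k], replace = TRUE)
      codons <- character(lens[k])
      for (a in unique(aa_idx)) {
        pos <- which(aa_idx == a)
        g <- .GROUPS[[a]]
        codons[pos] <- g[sample.int(length(g), length(pos), replace = TRUE,
                                    prob = probs[[a]])]
      }
      seqs[k] <- paste0(paste(codons, collapse = ""), "TAA")
      s[k] <- sum(w[codons]) / lens[k]
    }
    lo <- log1p(config$expression_range[1L])
    loge <- lo + config$effect_scale * s +
      stats::rnorm(K, 0, config$noise_sd)
  } else {
    wp <- matrix(config$pair_weights, length(.SENSE), length(.SENSE),
                 byrow = TRUE, dimnames = list(.SENSE, .SENSE))
    aa_names <- names(.GROUPS)
    for (k in seq_len(K)) {
      aa_idx <- sample.int(length(aa_names), lens[k], replace = TRUE)
      codons <- character(lens[k])
      g1 <- .GROUPS[[aa_idx[1L]]]
      codons[1L] <- g1[sample.int(length(g1), 1L)]
      for (i in seq_len(lens[k] - 1L) + 1L) {
        g <- .GROUPS[[aa_idx[i]]]
        p <- exp(config$tilt * u[k] * wp[codons[i - 1L], g])
        codons[i] <- g[sample.int(length(g), 1L, prob = p / sum(p))]
      }
      seqs[k] <- paste0(paste(codons, collapse = ""), "TAA")
      s[k] <- mean(wp[cbind(codons[-lens[k]], codons[-1L])])
    }
    lo <- log1p(config$expression_range[1L])
    hi <- log1p(config$expression_range[2L])
    spread <- diff(range(s))
    base <- if (spread > 0) lo + (s - min(s)) / spread * (hi - lo)
            else rep((lo + hi) / 2, K)
    loge <- base + stats::rnorm(K, 0, config$noise_sd)
  }
  e <- pmax(expm1(loge), 0)
  ds <- gene_dataset(seqs, e, gene_ids = sprintf("gene_%05d", seq_len(K)),
                     validate = FALSE)
  structure(list(dataset = ds,
                 truth = list(u = u, score = s,
                              weights = config$planted_weights,
                              pair_weights = config$pair_weights,
                              config = config)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset (preset", shQuote(x$truth$config$preset), "):\n")
  print(x$dataset)
  invisible(x)
}

#' Permute the expression labels of a dataset
#'
#' Returns the dataset with its expression vector permuted uniformly at
#' random (gene order kept; the multiset of expressions preserved), the
#' pipeline-level null for every downstream index and predictor.
#'
#' @param dataset A [gene_dataset].
#' @param seed Seed for the permutation.
#' @return A [gene_dataset] with permuted expressions.
#' @export
shuffle_labels <- function(dataset, seed = NULL) {
  stopifnot(inherits(dataset, "gene_dataset"))
  if (!is.null(seed)) set.seed(seed)
  .new_gene_dataset(dataset$gene_id, dataset$sequence,
                    sample(dataset$expression))
}
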