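# Independent oracles and small fixture builders. The oracles deliberately
# avoid the package's computation paths: brute-force pair enumeration for
# Kendall's tau-a, sliding-window tallies for codon counting, and the
# closed-form normal equations for least squares.

# Genetic-code table built independently of the package's internals.
ORACLE_STOPS <- c("TAA", "TAG", "TGA")
ORACLE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sort(setdiff(all64, ORACLE_STOPS))
}

# Brute-force tau-a: direct double loop over all pairs of Eq.-style sign
# products; tied pairs contribute zero.
bf_kendall_tau_a <- function(x, y) {
  n <- length(x)
  s <- 0
  for (j in seq_len(n - 1L))
    for (k in (j + 1L):n)
      s <- s + sign(x[j] - x[k]) * sign(y[j] - y[k])
  2 * s / (n * (n - 1))
}

# Sliding-window codon tally (no stop handling: caller strips).
bf_codon_tally <- function(seq) {
  n <- nchar(seq)
  codons <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  table(factor(codons, levels = ORACLE_CODONS))
}

# Same enumeration, vectorized over the full pair grid (each unordered pair
# appears twice; the diagonal is zero).
bf_kendall_tau_outer <- function(x, y) {
  n <- length(x)
  s <- sum(sign(outer(x, x, "-")) * sign(outer(y, y, "-"))) / 2
  2 * s / (n * (n - 1))
}

# Closed-form simple least squares.
bf_least_squares <- function(x, y) {
  a <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(a = a, b = mean(y) - a * mean(x))
}

# Random in-frame CDS of l sense codons (+ terminal stop), no internal stop.
random_cds <- function(l, stop_codon = "TAA") {
  paste0(paste(sample(ORACLE_CODONS, l, replace = TRUE), collapse = ""),
         stop_codon)
}

# A small handmade dataset with easily checked counts.
tiny_dataset <- function() {
  gene_dataset(
    c(g1 = "ATGAAAAAATAA",          # ATG + 2x AAA
      g2 = "ATGCCCCCCGGGTAG",       # ATG + 2x CCC + GGG
      g3 = "ATGTTTAAATTTTGA",       # ATG + 2x TTT + AAA
      g4 = "ATGGGGGGGGGGTAA"),      # ATG + 3x GGG
    c(100, 10, 1, 0.5))
}

# Small/fast synthetic configs for unit tests (scaled-down study conditions).
small_config <- function(n_genes = 120, seed = 1, ...) {
  synthetic_config(n_genes = n_genes, gene_length_range = c(60, 120),
                   seed = seed, ...)
}
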