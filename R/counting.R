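# Codon and codon-pair counting. Sequences are plain in-frame CDS strings;
# the terminal stop codon, if present, is stripped before counting and stop
# codons never enter counts. An internal in-frame stop is a hard error.

# Split a CDS into its in-frame codons, strip a terminal stop, and check for
# internal stops. Returns the codon vector (possibly containing non-ACGT
# codons, which callers may skip).
.cds_codons <- function(seq, gene_id = NULL) {
  seq <- toupper(seq)
  n <- nchar(seq)
  id <- if (is.null(gene_id)) "<unnamed>" else gene_id
  if (n == 0L || n %% 3L != 0L)
    stop("gene '", id, "': sequence length ", n, " is not a positive multiple of 3")
  codons <- substring(seq, seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L))
  l <- length(codons)
  if (codons[l] %in% .STOPS) codons <- codons[-l]
  if (length(codons) == 0L)
    stop("gene '", id, "': no sense codons after stripping the terminal stop")
  internal <- which(codons %in% .STOPS)
  if (length(internal))
    stop("gene '", id, "': internal in-frame stop codon ", codons[internal[1L]],
         " at codon ", internal[1L])
  codons
}

.warn_skipped <- function(n_skipped, gene_id, what = "codons") {
  if (n_skipped > 0L) {
    id <- if (is.null(gene_id)) "<unnamed>" else gene_id
    warning("gene '", id, "': skipped ", n_skipped, " ", what,
            " containing non-ACGT characters", call. = FALSE)
  }
}

#' Count sense codons in a coding sequence
#'
#' Splits an in-frame CDS into codons, strips the terminal stop codon if
#' present, and tallies occurrences of the 61 sense codons. An internal
#' in-frame stop codon is an error (it violates the CDS contract); codons
#' containing non-ACGT characters (e.g. IUPAC ambiguity codes in draft
#' assemblies) are skipped with a warning rather than failing the gene.
#'
#' @param seq A single CDS string over A/C/G/T (case-insensitive), of length a
#'   positive multiple of 3.
#' @param gene_id Optional identifier used in error and warning messages.
#' @return A named integer vector of length 61 (one entry per sense codon, in
#'   the order of [sense_codons()]); its sum is the number of counted in-frame
#'   sense codons.
#' @examples
#' count_codons("ATGAAAAAATAA")[c("ATG", "AAA")]  # terminal TAA stripped
#' @seealso [count_codon_pairs()], [codon_counts()]
#' @export
count_codons <- function(seq, gene_id = NULL) {
  codons <- .cds_codons(seq, gene_id)
  idx <- match(codons, .SENSE)
  .warn_skipped(sum(is.na(idx)), gene_id)
  counts <- tabulate(idx[!is.na(idx)], nbins = length(.SENSE))
  names(counts) <- .SENSE
  counts
}

#' Count adjacent sense codon pairs in a coding sequence
#'
#' Tallies the overlapping adjacent in-frame codon pairs of a CDS — positions
#' (1,2), (2,3), ... — over the 3721 stop-free pairs, so a gene of l sense
#' codons contributes l - 1 pairs. The terminal stop is stripped first and an
#' internal stop is an error, as in [count_codons()]. A codon containing
#' non-ACGT characters is skipped with a warning and both pairs it would
#' participate in are dropped.
#'
#' @inheritParams count_codons
#' @return A named integer vector of length 3721, in the order of
#'   [sense_codon_pairs()].
#' @examples
#' p <- count_codon_pairs("ATGAAACCC")
#' p[p > 0]  # ATGAAA and AAACCC, once each
#' @export
count_codon_pairs <- function(seq, gene_id = NULL) {
  codons <- .cds_codons(seq, gene_id)
  idx <- match(codons, .SENSE)
  .warn_skipped(sum(is.na(idx)), gene_id)
  counts <- integer(length(.PAIRS))
  names(counts) <- .PAIRS
  l <- length(codons)
  if (l >= 2L) {
    a <- idx[-l]
    b <- idx[-1L]
    keep <- !is.na(a) & !is.na(b)
    if (any(keep)) {
      pair_idx <- (a[keep] - 1L) * length(.SENSE) + b[keep]
      counts <- tabulate(pair_idx, nbins = length(.PAIRS))
      names(counts) <- .PAIRS
    }
  }
  counts
}

#' Codon or codon-pair count matrix for a set of genes
#'
#' Builds the K x M matrix of per-gene unit counts n_kc used by every index in
#' the package: M = 61 sense codons (`unit = "codon"`) or M = 3721 stop-free
#' adjacent pairs (`unit = "pair"`). For a gene of l sense codons the row sum
#' is l for codon units and l - 1 for pair units (fewer if codons containing
#' non-ACGT characters were skipped).
#'
#' @param x A [gene_dataset] or a (optionally named) character vector of CDS
#'   strings.
#' @param unit `"codon"` or `"pair"`.
#' @return An integer matrix with one row per gene (rownames = gene ids) and
#'   fixed column order ([sense_codons()] / [sense_codon_pairs()]), with
#'   attribute `"unit"`.
#' @export
codon_counts <- function(x, unit = c("codon", "pair")) {
  unit <- match.arg(unit)
  if (inherits(x, "gene_dataset")) {
    seqs <- x$sequence
    ids <- x$gene_id
  } else if (is.character(x)) {
    seqs <- x
    ids <- if (is.null(names(x))) sprintf("seq_%d", seq_along(x)) else names(x)
  } else {
    stop("'x' must be a gene_dataset or a character vector of CDS strings")
  }
  if (length(seqs) == 0L) stop("no sequences to count")
  counter <- if (unit == "codon") count_codons else count_codon_pairs
  m <- t(vapply(seq_along(seqs), function(i) counter(seqs[[i]], ids[[i]]),
                integer(if (unit == "codon") length(.SENSE) else length(.PAIRS))))
  rownames(m) <- ids
  attr(m, "unit") <- unit
  m
}

#' Convert unit counts to per-gene frequencies
#'
#' Divides each row of a count matrix by its row sum, giving the per-gene
#' frequency p_kc of each sense codon (or codon pair): the fraction of the
#' gene's counted units that are unit c. Every row of the result sums to 1.
#'
#' @param counts A count matrix as returned by [codon_counts()].
#' @return A numeric matrix of the same shape with rows summing to 1.
#' @export
codon_frequencies <- function(counts) {
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    bad <- rownames(counts)[rs == 0]
    stop("gene(s) with zero counted units: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  f <- counts / rs
  attr(f, "unit") <- attr(counts, "unit")
  f
}
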