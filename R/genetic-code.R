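# Standard genetic code (translation table 1) derived from
# Biostrings::GENETIC_CODE at install time. Alternative codes are
# deliberately unsupported.

.CODE <- local({
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  list(
    sense = sense,
    stops = names(gc)[gc == "*"],
    codon_aa = gc[sense],
    groups = split(sense, gc[sense])
  )
})

.SENSE <- .CODE$sense
.STOPS <- .CODE$stops
.CODON_AA <- .CODE$codon_aa
.GROUPS <- .CODE$groups
.PAIRS <- paste0(rep(.SENSE, each = length(.SENSE)), .SENSE)

#' The standard genetic code used throughout the package
#'
#' Returns the fixed genetic-code tables (translation table 1): the 61 sense
#' codons, the 3 stop codons (TAA, TAG, TGA), the codon-to-amino-acid map and
#' the synonym groups. All counting, index and scoring functions in the
#' package use these tables; alternative genetic codes are out of scope.
#'
#' @return An object of class `"genetic_code"`: a list with elements
#'   `sense` (character vector of 61 codons), `stops` (3 codons),
#'   `codon_aa` (named character vector mapping sense codon to amino-acid
#'   letter) and `groups` (list mapping amino-acid letter to its synonymous
#'   codons).
#' @examples
#' code <- genetic_code()
#' length(code$sense)      # 61
#' code$groups[["K"]]      # the two lysine codons
#' @export
genetic_code <- function() {
  structure(.CODE, class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Standard genetic code (translation table 1)\n")
  cat(" ", length(x$sense), "sense codons,", length(x$stops),
      "stop codons (", paste(x$stops, collapse = ", "), ")\n")
  sizes <- table(lengths(x$groups))
  cat("  synonym group sizes:",
      paste(sprintf("%s codons x %s", names(sizes), sizes), collapse = ", "),
      "\n")
  invisible(x)
}

#' Sense codons and sense codon pairs
#'
#' `sense_codons()` returns the 61 amino-acid-coding codons in the fixed
#' column order used by all count/frequency matrices. `sense_codon_pairs()`
#' returns the 3721 ordered codon pairs that contain no stop codon, as
#' 6-character strings (first codon followed by second), in the fixed order
#' used by pair-unit matrices.
#'
#' @return A character vector of length 61 or 3721.
#' @export
sense_codons <- function() .SENSE

#' @rdname sense_codons
#' @export
sense_codon_pairs <- function() .PAIRS
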