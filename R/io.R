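# Reading CDS FASTA and abundance tables, gene/protein matching with the
# standard dataset filters, and the delimited-text writers.

#' Read coding sequences from a FASTA file
#'
#' Reads a CDS FASTA (one in-frame coding sequence per record) and validates
#' every record against the CDS contract: length a positive multiple of 3,
#' no internal in-frame stop codon after stripping a terminal stop. Invalid
#' records are dropped with a warning giving the count; records whose
#' identifiers are duplicated are kept, so that downstream single-copy
#' filtering ([match_and_filter()]) can see them.
#'
#' @param path Path to a readable FASTA file.
#' @return A named character vector of CDS strings; names are the first
#'   whitespace-delimited token of each record header. Attribute `"dropped"`
#'   holds the number of invalid records removed.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) stop("FASTA file is empty: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in: ", path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "[ \t]+"), `[[`, "", 1L)
  ok <- vapply(seq_along(seqs), function(i) {
    !inherits(tryCatch(.cds_codons(seqs[[i]], names(seqs)[[i]]),
                       error = identity), "error")
  }, logical(1L))
  if (any(!ok))
    warning(sum(!ok), " of ", length(seqs),
            " records dropped (not valid in-frame CDS)", call. = FALSE)
  seqs <- seqs[ok]
  if (length(seqs) == 0L) stop("no valid CDS records in: ", path)
  attr(seqs, "dropped") <- sum(!ok)
  seqs
}

#' Read a protein-abundance table
#'
#' Reads a delimited text table with a header, extracts a gene/protein
#' identifier column and one or more replicate abundance columns, and averages
#' the replicates into a single expression value per row (the arithmetic mean,
#' as used for repeated quantitative proteome measurements). Rows with
#' unparseable or missing replicate values are dropped with a warning.
#'
#' @param path Path to the table.
#' @param id_column Name or index of the identifier column (default 1).
#' @param value_columns Names or indices of the replicate columns; by default
#'   every column except the id column.
#' @param sep Field separator (default tab).
#' @return A data.frame with columns `gene_id`, the replicate columns, and
#'   `expression` (mean of replicates).
#' @export
read_expression_table <- function(path, id_column = 1L, value_columns = NULL,
                                  sep = "\t") {
  if (!file.exists(path)) stop("abundance table not found: ", path)
  tab <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (is.character(id_column) && !id_column %in% names(tab))
    stop("id column '", id_column, "' not found in ", path)
  if (is.numeric(id_column) && id_column > ncol(tab))
    stop("id column index ", id_column, " out of range in ", path)
  ids <- as.character(tab[[id_column]])
  if (is.null(value_columns)) {
    value_columns <- setdiff(seq_len(ncol(tab)),
                             if (is.numeric(id_column)) id_column
                             else match(id_column, names(tab)))
  }
  if (length(value_columns) == 0L) stop("no abundance value columns in ", path)
  vals <- as.matrix(as.data.frame(
    lapply(tab[value_columns], function(v) suppressWarnings(as.numeric(v)))))
  ok <- rowSums(is.na(vals)) == 0L & rowSums(vals < 0, na.rm = TRUE) == 0L
  if (any(!ok))
    warning(sum(!ok), " row(s) dropped (missing, unparseable or negative ",
            "abundance values)", call. = FALSE)
  out <- data.frame(gene_id = ids[ok], vals[ok, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  out$expression <- rowMeans(vals[ok, , drop = FALSE])
  out
}

#' Match genes to expression records and apply the standard dataset filters
#'
#' Builds a [gene_dataset] from a CDS collection and an abundance table by
#' shared identifier, applying the standard filters: keep genes whose
#' identifier (or, with `by_sequence = TRUE`, whose exact nucleotide sequence)
#' occurs exactly once among the CDS records ("single copy"), that have a
#' matched expression record, and whose expression is strictly positive.
#' Counts removed by each filter are reported via `message()` and stored in
#' the `"filter_counts"` attribute.
#'
#' @param sequences Named character vector of CDS strings (duplicated names
#'   allowed and used by the single-copy filter), as from [read_cds_fasta()].
#' @param records A data.frame with columns `gene_id` and `expression`, as
#'   from [read_expression_table()].
#' @param id_map Optional two-column data.frame (or path to a two-column TSV)
#'   mapping CDS identifiers (column 1) to record identifiers (column 2), for
#'   datasets keyed on different accession schemes.
#' @param require_unique Drop genes duplicated in the CDS collection
#'   (default TRUE).
#' @param require_nonzero Drop genes with expression exactly 0 (default TRUE).
#' @param by_sequence Use the exact nucleotide sequence instead of the
#'   identifier for the single-copy filter.
#' @return A [gene_dataset]; attribute `"filter_counts"` gives the number of
#'   genes removed by each filter.
#' @export
match_and_filter <- function(sequences, records, id_map = NULL,
                             require_unique = TRUE, require_nonzero = TRUE,
                             by_sequence = FALSE) {
  if (is.null(names(sequences)))
    stop("'sequences' must be named with gene identifiers")
  ids <- names(sequences)
  n_unmapped <- 0L
  if (!is.null(id_map)) {
    if (is.character(id_map) && length(id_map) == 1L)
      id_map <- utils::read.delim(id_map, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
    mapped <- as.character(id_map[[2L]])[match(ids, as.character(id_map[[1L]]))]
    n_unmapped <- sum(is.na(mapped))
    keep <- !is.na(mapped)
    sequences <- sequences[keep]
    ids <- mapped[keep]
  }
  n_dup <- 0L
  if (require_unique) {
    key <- if (by_sequence) as.character(sequences) else ids
    dup_key <- unique(key[duplicated(key)])
    drop <- key %in% dup_key
    n_dup <- sum(drop)
    sequences <- sequences[!drop]
    ids <- ids[!drop]
  }
  m <- match(ids, as.character(records$gene_id))
  n_unmatched <- sum(is.na(m))
  keep <- !is.na(m)
  sequences <- sequences[keep]
  ids <- ids[keep]
  e <- as.numeric(records$expression)[m[keep]]
  n_zero <- 0L
  if (require_nonzero) {
    nz <- e > 0
    n_zero <- sum(!nz)
    sequences <- sequences[nz]
    ids <- ids[nz]
    e <- e[nz]
  }
  if (length(sequences) == 0L)
    stop("no genes left after matching and filtering")
  counts <- c(unmapped = n_unmapped, duplicated = n_dup,
              unmatched = n_unmatched, zero_expression = n_zero,
              kept = length(sequences))
  message("match_and_filter: kept ", counts[["kept"]], " genes (removed ",
          n_dup, " duplicated, ", n_unmatched, " unmatched, ", n_zero,
          " zero-expression", if (n_unmapped) paste0(", ", n_unmapped,
          " unmapped") else "", ")")
  out <- gene_dataset(sequences, e, gene_ids = ids, validate = FALSE)
  attr(out, "filter_counts") <- counts
  out
}

# Tab-separated writer used for all result tables: header line, no quoting,
# floating values at 6 significant digits.
.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], signif, digits = 6L)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a dataset (and ground truth, if any) to standard files
#'
#' Writes a FASTA of coding sequences, a tab-separated abundance table
#' (`gene_id`, `expression`), and — for a synthetic dataset — the ground-truth
#' table (per-gene latent propensity and planted score) plus a flat key-value
#' configuration file.
#'
#' @param x A [gene_dataset] or the result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default "dataset").
#' @return Invisibly, the named character vector of paths written.
#' @export
write_dataset <- function(x, dir, prefix = "dataset") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth <- NULL
  if (inherits(x, "synthetic_dataset")) {
    truth <- x$truth
    x <- x$dataset
  }
  stopifnot(inherits(x, "gene_dataset"))
  paths <- c(fasta = file.path(dir, paste0(prefix, "_cds.fasta")),
             abundance = file.path(dir, paste0(prefix, "_abundance.tsv")))
  set <- Biostrings::DNAStringSet(x$sequence)
  names(set) <- x$gene_id
  Biostrings::writeXStringSet(set, paths[["fasta"]])
  .write_tsv(data.frame(gene_id = x$gene_id, expression = x$expression),
             paths[["abundance"]])
  if (!is.null(truth)) {
    paths[["truth"]] <- file.path(dir, paste0(prefix, "_truth.tsv"))
    .write_tsv(data.frame(gene_id = x$gene_id, u = truth$u, score = truth$score),
               paths[["truth"]])
    paths[["weights"]] <- file.path(dir, paste0(prefix, "_weights.tsv"))
    w <- if (truth$config$preset == "pairs") truth$pair_weights else truth$weights
    .write_tsv(data.frame(unit = names(w), weight = as.numeric(w)),
               paths[["weights"]])
    paths[["config"]] <- file.path(dir, paste0(prefix, "_config.txt"))
    cfg <- truth$config
    writeLines(sprintf("%s=%s", names(cfg),
                       vapply(cfg, function(v) paste(format(v), collapse = ","),
                              "")),
               paths[["config"]])
  }
  invisible(paths)
}
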