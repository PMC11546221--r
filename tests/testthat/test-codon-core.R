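test_that("genetic code tables partition the 64 trinucleotides", {
  code <- genetic_code()
  expect_length(code$sense, 61)
  expect_setequal(code$stops, c("TAA", "TAG", "TGA"))
  expect_length(unique(c(code$sense, code$stops)), 64)
  expect_setequal(code$sense, ORACLE_CODONS)
  # every sense codon appears in exactly one synonym group
  all_group_codons <- unlist(code$groups, use.names = FALSE)
  expect_length(all_group_codons, 61)
  expect_false(anyDuplicated(all_group_codons) > 0)
  # codon -> aa map consistent with the groups
  for (aa in names(code$groups))
    expect_true(all(code$codon_aa[code$groups[[aa]]] == aa))
  expect_length(sense_codon_pairs(), 3721)
})

test_that("codon counting strips the terminal stop and rejects internal stops", {
  counts <- count_codons("ATGAAAAAATAA")
  expect_equal(sum(counts), 3)
  expect_equal(unname(counts[c("ATG", "AAA")]), c(1L, 2L))
  expect_error(count_codons("ATGTAAAAA", gene_id = "g"),
               "internal in-frame stop codon TAA at codon 2")
  expect_error(count_codons("ATGAA"), "multiple of 3")
  # lower-case input and a stop-less CDS are fine
  expect_equal(sum(count_codons("atgaaa")), 2)
})

test_that("codon counts match an independent sliding-window tally", {
  set.seed(71)
  for (i in 1:5) {
    l <- sample(20:150, 1)
    seq <- random_cds(l, stop_codon = sample(ORACLE_STOPS, 1))
    stripped <- substr(seq, 1, nchar(seq) - 3)
    expect_equal(as.vector(count_codons(seq)[ORACLE_CODONS]),
                 as.vector(bf_codon_tally(stripped)))
    expect_equal(sum(count_codons(seq)), l)
  }
})

test_that("codons with non-ACGT characters are skipped with a warning", {
  expect_warning(counts <- count_codons("ATGANNAAA", gene_id = "gx"),
                 "skipped 1 codons")
  expect_equal(sum(counts), 2)
  expect_equal(unname(counts[c("ATG", "AAA")]), c(1L, 1L))
})

test_that("pair counting uses overlapping adjacent in-frame pairs", {
  p <- count_codon_pairs("ATGAAACCC")
  expect_equal(sum(p), 2)
  expect_equal(unname(p[c("ATGAAA", "AAACCC")]), c(1L, 1L))
  expect_equal(sum(count_codon_pairs("ATG")), 0)          # l - 1 = 0
  seq <- random_cds(100)
  expect_equal(sum(count_codon_pairs(seq)), 99)           # l - 1
  # pairs bridging a skipped (non-ACGT) codon are dropped
  expect_warning(p2 <- count_codon_pairs("ATGNNNAAACCC"))
  expect_equal(sum(p2), 1)
  expect_equal(unname(p2["AAACCC"]), 1L)
})

test_that("codon total equals pair total + 1 for any valid CDS", {
  set.seed(72)
  for (i in 1:8) {
    seq <- random_cds(sample(2:80, 1))
    expect_equal(sum(count_codons(seq)), sum(count_codon_pairs(seq)) + 1)
  }
})

test_that("frequency conversion divides rows by their sums", {
  d <- tiny_dataset()
  counts <- codon_counts(d)
  f <- codon_frequencies(counts)
  expect_equal(unname(rowSums(f)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(f["g1", c("ATG", "AAA")]), c(1 / 3, 2 / 3))
  # all-identical-codon gene
  f4 <- f["g4", ]
  expect_equal(unname(f4["GGG"]), 3 / 4)  # ATG + 3x GGG
  # random row matches elementwise division
  r <- counts[2, ]
  expect_equal(unname(f[2, ]), unname(r / sum(r)))
  # zero-length gene errors
  m <- matrix(0L, 1, 61, dimnames = list("z", sense_codons()))
  expect_error(codon_frequencies(m), "zero counted units")
})

test_that("class splitting is an ordered partition with the remainder rule", {
  d <- generate_dataset(small_config(n_genes = 37, seed = 3))$dataset
  cls <- split_into_classes(d, 4)
  sizes <- vapply(cls, function(x) length(x$gene_ids), 1L)
  expect_equal(sizes, c(10L, 9L, 9L, 9L))
  # partition: disjoint, union = dataset
  all_ids <- unlist(lapply(cls, `[[`, "gene_ids"))
  expect_setequal(all_ids, d$gene_id)
  expect_length(all_ids, length(d))
  # ordering: min of class j >= max of class j+1
  e_by_class <- lapply(cls, function(x) d$expression[x$index])
  for (j in 1:3)
    expect_gte(min(e_by_class[[j]]), max(e_by_class[[j + 1]]))
  expect_error(split_into_classes(d, 1), "at least 2")
})

test_that("class distributions pool counts rather than averaging genes", {
  counts <- codon_counts(c(a = "ATGATGATGTAA", b = "AAATAG"))
  # pooled: ATG 3, AAA 1 -> 3/4, 1/4 (a plain average of per-gene
  # frequencies would give 1/2, 1/2)
  dist <- class_distribution(counts)
  expect_equal(unname(dist[c("ATG", "AAA")]), c(3 / 4, 1 / 4))
  expect_equal(sum(dist), 1, tolerance = 1e-12)
  expect_error(class_distribution(counts[0, , drop = FALSE]), "empty class")
})

test_that("union of class distributions equals the pooled dataset distribution", {
  d <- generate_dataset(small_config(n_genes = 48, seed = 4))$dataset
  cls <- split_into_classes(d, 4)
  counts <- codon_counts(d)
  pooled <- class_distribution(counts)
  # recombine classes weighted by their pooled codon totals
  dist <- attr(cls, "distributions")
  totals <- vapply(cls, function(x) sum(counts[x$index, ]), 1)
  recombined <- as.vector(dist %*% (totals / sum(totals)))
  expect_equal(recombined, unname(pooled), tolerance = 1e-12)
})

test_that("distribution correlation is Pearson's r with validation", {
  d1 <- runif(61); d1 <- d1 / sum(d1)
  expect_equal(distribution_correlation(d1, d1), 1)
  expect_equal(distribution_correlation(d1, 2 * d1 + 0.1), 1)
  d2 <- runif(61)
  r <- distribution_correlation(d1, d2)
  expect_equal(r, sum((d1 - mean(d1)) * (d2 - mean(d2))) /
                 sqrt(sum((d1 - mean(d1))^2) * sum((d2 - mean(d2))^2)))
  expect_equal(distribution_correlation(d2, d1), r)
  expect_lte(abs(r), 1)
  expect_error(distribution_correlation(rep(1, 61), d1), "zero-variance")
  expect_error(distribution_correlation(d1[1:10], d2), "length")
})

test_that("class correlation matrix is symmetric with unit diagonal and accepts external distributions", {
  d <- generate_dataset(small_config(n_genes = 40, seed = 5))$dataset
  cls <- split_into_classes(d, 4)
  cc <- class_correlations(cls)
  expect_equal(dim(cc), c(4L, 4L))
  expect_equal(unname(diag(cc)), rep(1, 4))
  expect_equal(cc, t(cc))
  alien <- runif(61); alien <- alien / sum(alien)
  cc2 <- class_correlations(cls, extra = list(alien = alien))
  expect_equal(dim(cc2), c(5L, 5L))
  expect_true(all(abs(cc2) <= 1))
})
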