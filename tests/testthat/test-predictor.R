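test_that("log transform is natural log of e + 1", {
  expect_equal(log_expression(0), 0)
  expect_equal(log_expression(6), log(7))
  expect_equal(log_expression(6), 1.9459, tolerance = 1e-4)
  expect_equal(log_expression(38022), 10.546, tolerance = 1e-3)
  expect_error(log_expression(-1), "non-negative")
})

test_that("gene scores are count-weighted index means with undefined units skipped", {
  counts <- codon_counts(c(g1 = "AAAAAAAAATAA",    # AAA x3
                           g2 = "AAAGGGTAA"))      # AAA, GGG
  v <- setNames(rep(NA_real_, 61), sense_codons())
  v["AAA"] <- 2.5
  v["GGG"] <- 1.5
  s <- gene_scores(counts, v)
  expect_equal(as.vector(s), c(2.5, 2))
  # undefined units excluded from numerator and denominator
  counts2 <- codon_counts(c(g = "AAAGGGCCCTAA"))
  s2 <- gene_scores(counts2, v)  # CCC undefined
  expect_equal(as.vector(s2), (2.5 + 1.5) / 2)
  expect_equal(unname(attr(s2, "skipped_frac")), 1 / 3)
  v2 <- v; v2[] <- NA_real_
  expect_error(gene_scores(counts, v2), "no defined index units")
})

test_that("gene scores match a per-position oracle on random genes", {
  set.seed(31)
  v <- setNames(rnorm(61), sense_codons())
  for (i in 1:5) {
    l <- sample(20:120, 1)
    codons <- sample(sense_codons(), l, replace = TRUE)
    seq <- paste0(paste(codons, collapse = ""), "TAA")
    s <- gene_scores(codon_counts(seq), v)
    expect_equal(as.vector(s), sum(v[codons]) / l)
  }
})

test_that("least-squares fit matches hand and closed-form solutions", {
  expect_equal(fit_regression(c(0, 1), c(1, 3)), c(a = 2, b = 1))
  # constant response: slope 0, intercept at the constant
  expect_equal(fit_regression(c(0, 1, 2), c(4, 4, 4)), c(a = 0, b = 4))
  set.seed(32)
  x <- rnorm(100); y <- 2.5 * x + 1 + rnorm(100)
  expect_equal(fit_regression(x, y), bf_least_squares(x, y))
  expect_error(fit_regression(rep(1, 5), 1:5), "zero variance")
})

test_that("the interleaved CV plan deals sorted genes out cyclically", {
  e <- runif(22, 1, 100)
  fold <- make_cv_plan(e, 11)
  expect_equal(as.vector(table(fold)), rep(2L, 11))
  # every gene in exactly one test fold
  expect_length(fold, 22)
  expect_true(all(fold %in% 1:11))
  # consecutive blocks of 11 in sorted order hit all 11 folds
  ord <- order(-e)
  expect_setequal(fold[ord[1:11]], 1:11)
  expect_setequal(fold[ord[12:22]], 1:11)
  expect_error(make_cv_plan(runif(5), 11), "at least 11")
})

test_that("pearson_r validates and reproduces the covariance formula", {
  x <- rnorm(20)
  expect_equal(pearson_r(x, 2 * x + 5), 1)
  expect_equal(pearson_r(x, -x), -1)
  y <- rnorm(20)
  expect_equal(pearson_r(x, y),
               mean((x - mean(x)) * (y - mean(y))) /
                 (sd(x) * sd(y) * (19 / 20)))
  expect_error(pearson_r(x, rep(1, 20)), "constant")
  expect_error(pearson_r(x, y[1:5]), "same length")
})

test_that("cross-validation pools each gene exactly once and folds stay disjoint", {
  sim <- generate_dataset(small_config(n_genes = 77, seed = 33))
  rep <- cross_validate(sim$dataset, "ceis", n_folds = 11)
  p <- rep$predictions
  expect_equal(nrow(p), 77)
  expect_setequal(p$gene_id, sim$dataset$gene_id)
  expect_equal(as.vector(table(p$fold)), rep(7L, 11))
  expect_equal(nrow(rep$coefficients), 11)
  expect_equal(p$actual_log, log1p(sim$dataset$expression))
  expect_equal(p$pred_copies, pmax(expm1(p$pred_log), 0))
})

test_that("a single affine rescaling leaves the pooled correlation unchanged; per-fold rescaling agrees closely", {
  sim <- generate_dataset(small_config(n_genes = 120, seed = 34))
  r_avg <- cross_validate(sim$dataset, "ceis", rescale = "average")$r
  r_none <- cross_validate(sim$dataset, "ceis", rescale = "none")$r
  r_fold <- cross_validate(sim$dataset, "ceis", rescale = "fold")$r
  expect_equal(r_avg, r_none, tolerance = 1e-14)
  expect_equal(r_fold, r_none, tolerance = 0.02)
})

test_that("within each fold the regression step cannot change the correlation", {
  sim <- generate_dataset(small_config(n_genes = 66, seed = 35))
  rep <- cross_validate(sim$dataset, "cps", rescale = "fold")
  p <- rep$predictions
  for (f in unique(p$fold)) {
    sel <- p$fold == f
    expect_equal(pearson_r(p$pred_log[sel], p$actual_log[sel]),
                 pearson_r(p$score[sel], p$actual_log[sel]),
                 tolerance = 1e-12)
  }
})

test_that("CEIS and CPS achieve closely similar accuracy on monotone data", {
  sim <- generate_dataset(small_config(n_genes = 220, seed = 36,
                                       noise_sd = 0.8))
  r_ceis <- cross_validate(sim$dataset, "ceis")$r
  r_cps <- cross_validate(sim$dataset, "cps")$r
  expect_gt(r_ceis, 0.7)
  expect_gt(r_cps, 0.7)
  expect_lt(abs(r_ceis - r_cps), 0.05)
})

test_that("the pair-unit predictor runs end to end and logs skipped units", {
  sim <- generate_dataset(synthetic_config(n_genes = 90,
                                           gene_length_range = c(50, 90),
                                           preset = "pairs", noise_sd = 0.5,
                                           seed = 37))
  rep <- cross_validate(sim$dataset, "cpeis", n_folds = 5)
  expect_equal(nrow(rep$predictions), 90)
  # rare pairs unseen in a training fold are skipped, not imputed
  expect_true(all(rep$predictions$skipped_frac >= 0))
  expect_true(all(rep$predictions$skipped_frac < 0.5))
})

test_that("stratified accuracy reproduces the unstratified r at threshold 0", {
  sim <- generate_dataset(small_config(n_genes = 110, seed = 38))
  rep <- cross_validate(sim$dataset, "ceis", strata = NULL)
  st <- stratified_accuracy(rep, c(0, 2, 100))
  expect_equal(st$r[1], rep$r)
  expect_equal(st$n[1], 110)
  # counts match direct filtering
  expect_equal(st$n[2], sum(rep$predictions$actual_log >= 2))
  # threshold above all values: flagged, r unset
  expect_true(st$flagged[3])
  expect_true(is.na(st$r[3]))
})

test_that("the fitted model object supports the standard S3 generics", {
  sim <- generate_dataset(small_config(n_genes = 90, seed = 39))
  fit <- fit_expression_model(sim$dataset, "ceis")
  expect_s3_class(fit, "expr_model")
  expect_named(coef(fit), c("a", "b"))
  expect_length(fitted(fit), 90)
  expect_equal(unname(fitted(fit) + residuals(fit)),
               log1p(sim$dataset$expression))
  # predict on the training genes reproduces fitted values
  expect_equal(unname(predict(fit, sim$dataset)), unname(fitted(fit)),
               tolerance = 1e-12)
  pc <- predict(fit, sim$dataset$sequence[1:3], type = "copies")
  expect_length(pc, 3)
  expect_true(all(pc >= 0))
  set.seed(1)
  sims <- simulate(fit, nsim = 2, seed = 7)
  expect_equal(dim(sims), c(90L, 2L))
  expect_true(all(sims >= 0))
  # in-sample r equals the correlation of score with actual log expression
  expect_equal(fit$r, pearson_r(fit$scores, fit$actual_log), tolerance = 1e-12)
})
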