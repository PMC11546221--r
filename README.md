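# codonexpr

Codon-level indices and cross-validated predictors of protein expression.

Synonymous codons are used unevenly, and that usage tracks how much protein a
gene produces. Given a set of in-frame coding sequences matched to
quantitative proteome measurements (protein copies per cell, e.g. from
LC-MS/MS), `codonexpr` quantifies the contribution of every individual codon
— and every adjacent codon pair — to the expression level, and turns those
per-codon contributions into a predictor of per-gene protein abundance from
sequence alone. It is aimed at people studying codon usage bias and at anyone
designing or re-coding genes toward a target expression level in a host for
which proteome data exist.

## The indices

For each of the 61 sense codons *c*, with per-gene frequencies
*p<sub>kc</sub>* and per-gene abundances *e<sub>k</sub>* over *K* genes:

* **CEI (Codon Expression Index)** — the Kendall tau-a rank correlation
  between frequency and abundance,

  τ<sub>c</sub> = 2/(K(K−1)) Σ<sub>j&lt;k</sub>
  sgn(p<sub>jc</sub> − p<sub>kc</sub>) · sgn(e<sub>j</sub> − e<sub>k</sub>),

  expressed as a Z-value, Z<sub>c</sub> = 3 τ<sub>c</sub> √(K(K−1)) /
  √(2(2K+5)). Under independence Z is approximately standard normal; |Z| > 3
  marks a codon as significantly associated with expression, a boundary
  confirmed by recomputing Z against randomly shuffled abundances
  (`shuffle_null()`).

* **CP (Codon Productivity)** — the abundance-weighted mean expression per
  codon: A<sub>c</sub> = Σ<sub>k</sub> e<sub>k</sub> n<sub>kc</sub>,
  N<sub>c</sub> = Σ<sub>k</sub> n<sub>kc</sub>, CP<sub>c</sub> =
  A<sub>c</sub>/N<sub>c</sub> — the average number of amino acids a cell
  incorporates per use of codon *c*.

* **CPEI** — CEI computed over the 3721 stop-free adjacent codon pairs.

Each index yields a gene-level predictor (**CEIS / CPS / CPEIS**): a gene is
scored by the mean index value of its codons, C<sub>k</sub>, and ordinary
least squares maps scores to log abundance, P<sub>k</sub> = a C<sub>k</sub> +
b with log E = ln(e<sub>k</sub> + 1). Accuracy is measured by Pearson
correlation under interleaved 11-fold cross-validation, in which index
values, the regression — and, for the bundled **CAI** comparator, the
top-quartile reference set — are re-estimated inside every training fold.

## Worked example

Real data enter through `read_cds_fasta()` + `read_expression_table()` +
`match_and_filter()` (single-copy and non-zero filters, replicate averaging).
The bundled generator builds a matched synthetic dataset with planted
per-codon effects, so the whole pipeline can be exercised without downloads:

```r
library(codonexpr)

cfg <- synthetic_config(n_genes = 400, gene_length_range = c(100, 300), seed = 42)
sim <- generate_dataset(cfg)
sim$dataset
#> gene_dataset: 400 genes
#>   codons per gene: 101-301 (median 203.5)
#>   expression (copies/cell): 0 - 591450 (13 zero)

codon_index(sim$dataset, "cei")
#> codon_index: CEI over 61 codons, K = 400 genes
#>   significant (|Z| > 3): 36  unobserved: 0
#>   strongest: AAG (Z=-15.0), TGT (Z=-14.6), TTT (Z=-14.0), TAT (Z=-13.9), AAT (Z=-13.5)

cross_validate(sim$dataset, "ceis")
#> cv_report: CEIS, 11-fold interleaved CV over K = 400 genes
#>   pooled Pearson r (predicted vs actual log expression): 0.956
#>   accuracy by expression stratum (actual log(e+1) >= threshold):
#>     log 0-14   n =  400   r = 0.956
#>     log 1-14   n =  367   r = 0.941
#>     log 2-14   n =  350   r = 0.933
#>     log 3-14   n =  322   r = 0.913
#>     log 4-14   n =  301   r = 0.896

fit <- fit_expression_model(sim$dataset, "ceis")
fit
#> Codon-based expression model (CEIS), K = 400 genes
#>   log(e+1) = 1.666 * score + 2.849
#>   in-sample Pearson r = 0.958

round(predict(fit, sim$dataset[1:3], type = "copies"), 1)
#> gene_00001 gene_00002 gene_00003
#>        5.0     7217.4     2323.5
```

36 of 61 codons carry a planted synonymous-usage effect strong enough to
cross the |Z| > 3 boundary at this sample size; the cross-validated r of
0.956 says how well the gene-average CEI score recovers the (noisy) planted
log-abundance relationship; the final lines show the fitted affine map and
per-gene abundance predictions on the copies-per-cell scale.

A command-line wrapper over the same functions is installed at
`exec/codonexpr.R` (subcommands `simulate`, `indices`, `predict`, `classes`),
writing TSV tables plus a manifest for exact reruns.

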