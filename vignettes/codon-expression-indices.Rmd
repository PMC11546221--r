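---
title: "Codon-level expression indices: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-level expression indices: models, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonexpr)
```

This vignette is the package's own account of what it computes, the
assumptions behind each quantity, the numerical choices made where the design
was genuinely open, and what the synthetic benchmarks do and do not
demonstrate.

## The data model

The unit of analysis is a **matched dataset**: $K$ in-frame coding sequences
and, for each, a protein abundance $e_k \ge 0$ in copies per cell
(`gene_dataset()`). Abundances of this kind come from quantitative
proteomics; replicate measurements are averaged on load
(`read_expression_table()`). The standard filters applied by
`match_and_filter()` keep genes that occur exactly once in the CDS
collection (the CDS file standing proxy for the genome), have a matched
abundance record, and have strictly positive expression. Genes with a
protein match but missing replicate values are dropped with a logged count.

Counting is over the 61 sense codons of the standard genetic code
(translation table 1 only). A terminal stop codon is stripped; an internal
in-frame stop is a hard error, because it means the sequence is not the CDS
it claims to be. Codons containing non-ACGT characters are skipped with a
warning rather than failing the gene — draft assemblies contain ambiguity
codes, and skipping a codon does not bias the relative frequencies of the
others. Codon *pairs* are the overlapping adjacent in-frame pairs
(positions (1,2), (2,3), ...), giving $l - 1$ pairs for a gene of $l$ sense
codons; non-overlapping counting would halve the data and could not cover
the 3721 stop-free pairs on short genes. The initiator ATG is counted as an
ordinary methionine codon.

## The indices

**Codon Expression Index (CEI).** For codon $c$ with per-gene frequencies
$p_{kc}$ and abundances $e_k$:

$$\tau_c = \frac{2}{K(K-1)} \sum_{j<k}
  \operatorname{sgn}(p_{jc}-p_{kc})\,\operatorname{sgn}(e_j-e_k),
\qquad
Z_c = \frac{3\,\tau_c\,\sqrt{K(K-1)}}{\sqrt{2(2K+5)}}.$$

This is deliberately **tau-a**: tied pairs contribute zero and no tie
correction is applied to the denominator. Rank correlation is used because
only the *direction* of frequency change across the expression range is
claimed to be meaningful, not its magnitude. $Z_c$ is the usual normal
approximation; $|Z| > 3$ is the significance boundary, and it is *reported*,
never used to censor index values. `shuffle_null()` re-derives the boundary
empirically by permuting the expression vector (default `n_shuffles = 1`,
matching a single shuffled comparison array; configurable upward for
calibration checks).

**Codon Productivity (CP).** $A_c = \sum_k e_k n_{kc}$,
$N_c = \sum_k n_{kc}$, $CP_c = A_c / N_c$: a count-weighted mean of the
expressions of the genes using the codon, hence always inside
$[\min_k e_k, \max_k e_k]$ for observed codons. Codons never observed are
flagged undefined and left unset — never imputed. CP is defined purely from
counts and abundances; no tRNA-pool term enters the formulas.

**CPEI** is CEI over the 3721 pair units. Pairs unobserved in a training set
get $Z = 0$ in the table, are flagged, and are *skipped* (denominator
renormalized) when scoring genes, with the skipped fraction logged per gene.

## From index to predictor

A gene's score is the count-weighted mean of the index over its codon
occurrences, $C_k = \sum_c n_{kc} v_c / \sum_c n_{kc}$ — identical to the
per-position mean over the codon sequence. Expression is modelled on the
$\log(e+1)$ scale (natural log; the +1 keeps genes below one copy per cell
non-negative and maps $e=0$ to 0), and ordinary least squares gives
$P_k = a\,C_k + b$. `fit_expression_model()` returns this as a classed model
object with the standard `print`/`summary`/`coef`/`predict`/`residuals`/
`plot`/`simulate` methods; back-transformed predictions
$\max(e^{P_k}-1,\,0)$ are available via `predict(..., type = "copies")`.

**Cross-validation.** Honest accuracy comes from `cross_validate()`:
interleaved $k$-fold (default 11) on the expression-sorted gene list, fold
$((i-1) \bmod k)+1$ for sorted position $i$, so every test fold spans the
full expression range and every gene is tested exactly once. Index values,
regression coefficients and the CAI reference set are estimated from the
training folds only. Accuracy is the Pearson correlation between pooled
predictions and actual $\log(e+1)$, optionally stratified by expression
level (`stratified_accuracy()`).

**The rescaling step and its invariance.** Pearson correlation is invariant
under a positive affine map, so rescaling scores to the log-abundance scale
is a presentation step, not a modelling step. With per-fold coefficients
(`rescale = "fold"`, the default) the pooled correlation can differ from the
raw-score correlation by a vanishing amount — the folds' coefficients differ
only by estimation noise on 10/11-overlapping training sets — while a single
affine map (`rescale = "average"`, the per-fold coefficients averaged)
leaves the pooled correlation *exactly* unchanged relative to
`rescale = "none"`. The test suite asserts the exact identity for the
single-map variant and close agreement (within 0.02) for the per-fold
variant. Both are reported so users can choose fidelity to the per-fold
protocol or the exact invariance.

**CAI comparator.** The Codon Adaptation Index is included under the same
harness for head-to-head comparison: within each training fold the reference
set is the top quarter of training genes by expression
(`floor(K_train/4)`, minimum 2); relative adaptiveness is
$w_c = \text{count}_c / \max(\text{synonymous count})$ with a pseudo-weight
$0.5/\max$ for codons absent from the reference (standard practice for
sparse references, keeping the geometric mean away from zero); an amino acid
entirely absent from the reference is an error. A gene's CAI is the
geometric mean of $w$ over its codons, computed in log space. Single-codon
amino acids (ATG, TGG) contribute $w = 1$; stop codons are never scored.
Because the affine regression cannot change a Pearson correlation, applying
it to CAI scores (done here for comparability of outputs) cannot flatter or
harm CAI's measured accuracy.

## The synthetic generator

`generate_dataset()` builds datasets in which the ground truth is known, so
every pipeline stage can be tested end to end:

* a latent propensity $u_k \sim \mathrm{Uniform}(0,1)$ per gene;
* an amino-acid backbone drawn uniformly over the 20 amino acids, so
  amino-acid composition is independent of expression and only synonymous
  choice carries signal;
* within each synonym group, planted weights $w_c \in \{-1, 0, +1\}$ tilt
  the synonymous choice: the *nonzero-weight* codons share their combined
  probability mass proportionally to $\exp(\text{tilt} \cdot u_k w_c)$,
  while zero-weight codons keep their uniform $1/m$ share. Restricting the
  softmax to the effect codons is deliberate: a softmax over the whole group
  would shrink the zero-weight codons' share as the tilt grows, making them
  spuriously anti-correlated with expression, whereas here they are true
  nulls and calibrate the $|Z| > 3$ boundary;
* expression on the log scale:
  $\log(e_k+1) = b_0 + s\,\bar{w}_k + \varepsilon_k$, where $\bar{w}_k$ is
  the gene's *realized* mean planted weight,
  $\varepsilon_k \sim N(0, \text{noise\_sd})$, and $e_k = \max(\exp(\cdot)-1, 0)$.

Defaults are fixed study conditions: 1688 genes (a typical filtered
single-copy proteome dataset), 100–500 codons per gene (typical bacterial
CDS lengths), tilt 1.5 (a strong synonymous-usage effect), noise 1.0 on the
log scale, and an expression span of 0–38,022 copies per cell; the slope $s$
is derived analytically from the tilt so the planted score spans that range.
The `"full"` preset plants one positive and one negative codon per synonym
group (plus nulls in groups of three or more); the `"pairs"` preset plants
effects on adjacent codon pairs instead (first-codon chains favoured,
last-codon chains disfavoured, among the two-codon groups), generated by a
sequential Markov-style codon choice.

What the generator does **not** emulate: real codon-frequency profiles of
any particular organism, amino-acid composition effects, mRNA structure,
tRNA pools, or measurement error structure of proteomics. Passing the
synthetic benchmarks therefore shows that the estimators recover the kind of
monotone codon-frequency/expression relationship they model — not that any
particular organism's expression is predictable to the same accuracy.

## Numerical choices

* **Tau-a via the C-level Kendall scan.** `stats::cor(method = "kendall")`
  computes the tie-corrected tau-b; the exact sign sum is recovered by
  multiplying the tie correction back
  ($S = \tau_b \sqrt{(n_0-T_x)(n_0-T_y)}$) and renormalizing by $n_0$. An
  independent brute-force pair enumeration in the test suite guards against
  silently inheriting tau-b. Mostly-zero columns (pair frequencies) instead
  use a direct sparse identity — zero–zero pairs are ties, nonzero–zero
  pairs contribute $\operatorname{sgn}(e_i - e_k)$ — which makes the
  3721-column case tractable.
* **Log base.** Natural throughout; the $\log(e+1)$ bin edges used in
  stratified reporting (2 ↔ 6 copies, 3 ↔ 19, 4 ↔ 53, 10 ↔ 38,022) are
  consistent with $\ln$ and no other common base.
* **Ties and ordering.** Expression ties are broken by stable input order
  both in class splitting and in the CV plan. Class sizes differ by at most
  one, with the remainder assigned to the highest-expression classes.
* **Degenerate inputs.** Constant expression gives all $\tau = Z = 0$ (every
  sign term vanishes); constant gene scores are a fitting error (reported
  with the offending fold); strata with fewer than 3 genes are flagged
  rather than reported; zero-variance distributions are rejected by the
  correlation helpers.
* **Test problem sizes.** Unit tests run on scaled-down datasets (tens to a
  few hundred genes, 40–120 codons per gene); the study-scale checks —
  null calibration within $[-3, 3]$ and near-normality (Kolmogorov–Smirnov
  distance below 0.1 over 10 pooled shuffles; ties at zero frequency deflate
  the null variance slightly, which the loose bound accommodates), sign
  recovery of all planted effects with $|Z| > 3$, at most 5% of null codons
  beyond the boundary, noiseless cross-validated $r \ge 0.99$, shuffled-label
  $|r| \le 0.1$, and the CEI–CP rank agreement above 0.8 — run at
  $K = 1000$ (1688 for the partition arithmetic), the sizes at which the
  normal approximation and the planted-effect asymptotics are meant to hold.

## Known limitations

* Only the standard genetic code; no strand logic, no GFF/GenBank parsing —
  inputs are in-frame CDS FASTA plus a delimited abundance table.
* Tau-a only; no tie-corrected or weighted tau variants, and no FDR
  machinery beyond the $\pm 3$ boundary.
* The predictors require proteome data for the organism and condition of
  interest; accuracy on sequences foreign to the training organism is
  expected to degrade.
* CPEIS costs roughly 60× CEIS (3721 vs 61 units) for a modest accuracy
  difference; it is provided for completeness and for studying pair effects
  rather than recommended as the default predictor.
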