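---
title: "Methods: scoring and comparing gene-deletion phenotypes across genetic backgrounds"
author: "chemgenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and comparing gene-deletion phenotypes across genetic backgrounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemgenomics)
```

## The problem

Chemical-genomic screens pin a library of gene-deletion mutants onto agar
plates in high-density colony arrays (1,536 colonies, 32 x 48) and grow
them under chemical or environmental stresses. Colony size is the fitness
readout. When the same deletion library is constructed in several genetic
backgrounds — say a laboratory reference and a few wild isolates — the
interesting question is no longer only *which deletions have a phenotype
in which condition* but *which of those phenotypes depend on the genetic
background*. This package implements the full analysis chain for that
question, plus a ground-truth simulator so every stage can be validated
without access to a real screen.

## The fitness model and plate normalization

The analysis assumes multiplicative fitness: the expected colony size of
mutant $g$ in condition $c$ is the product of the gene's marginal effect,
the condition's marginal effect, and a chemical-genetic interaction term
that equals 1 in the absence of an interaction. On top of that sit two
plate-level artifacts that must be removed before any statistics:

* **Surface artifacts** — smooth spatial gradients from pinning pressure,
  agar thickness or incubation position. `surface_correct()` fits
  ordinary least squares of colony size on the degree-2 polynomial in the
  row and column indices, $\{1, r, c, r^2, c^2, rc\}$, via the QR
  factorization of the expanded design, and replaces each size by
  `raw - fitted + mean(raw)`. The basis is centered before expansion for
  conditioning only; the fit is basis-invariant. A rank-deficient design
  (possible only on pathological missingness patterns) degrades to the
  constant fit with a warning rather than failing the plate.
* **Border effects** — colonies in the two outermost rows and columns
  face less competition and grow larger. `border_correct()` rescales the
  outer ring multiplicatively so its median matches the inner median.
  Medians are taken over non-missing colonies; a zero or undefined outer
  median skips the correction with a warning.

Missing colonies stay missing through both steps — imputing them would
distort the medians everything downstream relies on. Quality control
(`qc_flag()`) runs before normalization: a plate is flagged when more than
5% of its non-empty layout positions have no measurable colony, or when
more than 90% of a whole row or column is missing (a signature of grid
misalignment). Known-empty spots never count as missing.

Relative wild-type fitness $\varphi$ is the ratio of a strain's median
normalized colony size to the reference strain's, per condition, and is
only computed for plates screened in the same batch — comparing across
batches would fold experimental drift into a biological quantity.

## S-scores

`compute_sscores()` turns replicate plates into one moderated t-like score
per gene and condition:

$$ S = \frac{m_E - m_C}{\sqrt{v'_E/n_E + v'_C/n_C}} $$

where the experimental side ($m_E, v_E, n_E$) summarizes the gene's
colonies in that condition and the control side uses the gene's behaviour
across the whole screen: $m_C$ is the median of its per-condition means,
$v_C$ their variance, $n_C$ the number of conditions. Both variances are
moderated by flooring at the median variance among genes in the same
decile of mean colony size, which prevents tiny-variance flukes from
producing huge scores. Sizes below 5 pixels are floored rather than
dropped, keeping strongly sick colonies informative, and plates are
rescaled to a common median first. Conditions with fewer than three
replicates are excluded. Genes pinned twice are pooled as extra
replicates by default; `split_duplicates = TRUE` scores the two positions
separately for reproducibility analysis.

S-scores are then quantile-normalized across conditions
(`quantile_normalize()`, delegating to limma's implementation) so every
condition shares one score distribution.

### Phenotype calling and the robust location/scale choice

`call_phenotypes()` standardizes each condition's scores to z-scores,
takes the one-tailed upper survival probability of $|z|$ under the
standard normal (the sign carries the direction: sensitive vs resistant),
and applies Benjamini–Hochberg across all gene x condition pairs of the
strain, calling at FDR 5% by default.

The location and scale are fitted as **median and MAD** by default rather
than mean and standard deviation. This was a genuinely open design point,
and the choice matters: the normality assumption concerns the *null bulk*
of each condition, but the plain standard deviation is computed over all
scores, including the real phenotypes in the tails. In simulations at
this package's study conditions (4 replicates, 20% of pairs carrying
interactions), the contaminated sd inflates roughly three-fold and
phenotype sensitivity collapses from essentially 1.0 to about 0.45. The
MAD estimates the bulk scale consistently regardless of how many true
phenotypes the screen contains. `robust = FALSE` restores the plain
mean/sd fit.

## Differences between genetic backgrounds

Calling a deletion phenotype *different* between two strains needs a null
for "how much do S-scores wobble between two screens of the same
biology". That null is built from two replicate batches of the reference
strain (`build_null()`): for every gene x condition pair,

$$ N_{sum} = -|S_1 + S_2|, \qquad N_{sub} = |S_1 - S_2|. $$

Because S-score variance grows with score magnitude, the pairs are sorted
by $N_{sum}$ and cut into 100 equal-count slices (each at least 20
observations; the count shrinks with a warning on small inputs), storing
each slice's mean $N_{sum}$, mean $N_{sub}$ and sd of $N_{sub}$. A
degenerate slice sd is floored at $10^{-6}$ so identical batches do not
produce zero-scale normals. `diff_pvalues()` then interpolates mean and
sd linearly at each observed strain-pair $N_{sum}$ (clamped beyond the
terminal slices), takes the upper-tail normal survival probability at the
observed $N_{sub}$, and BH-corrects across the comparison.

`classify_comparisons()` combines difference q-values with the two
strains' phenotype calls: significant differences where both strains
agree (same direction, or both without a phenotype) are *incoherent* and
masked by forcing the corrected P to 1 — they can never count as
strain-specific; both-significant pairs without a significant difference
are *shared*; a significant difference with exactly one significant
phenotype is *exclusive* to that strain; both significant in opposite
directions with a significant difference is a *sign reversal*; everything
else is not considered. The classes partition every compared pair.

Downstream summaries: `shared_fractions()` (fraction of a focal strain's
phenotypes conserved pairwise or in k-way strain subsets, mean ± sd
across subsets; k-way conservation requires the phenotype to be shared
with every other strain of the subset), `exclusiveness()` (per gene,
$E = P_{exclusive}/(P_{exclusive}+P_{shared})$, undefined at 0/0, genes
with $E > 0$ flagged high-exclusiveness; sign reversals count as
exclusive since the phenotype does vary significantly), and
`condition_summary()` (exclusive-phenotype counts per condition joined
with $\varphi$, their Pearson correlation, and the variable-gene list at
corrected P < 1e-4 in at least one comparison).

## Loss-of-function burden

For the association side, per-variant damage predictions are converted to
probabilities of being neutral: logistic transforms of SIFT
($z = 1.312\,\ln(\mathrm{SIFT} + 1.598\times10^{-5}) + 4.104$) and FoldX
($z = -0.218\,\Delta\Delta G + 0.074$), a positional rule for nonsense
variants (0.99 in the last 5% of the protein, 0.01 otherwise, boundary
strict), SIFT priority when both predictors exist, and the dataset-wide
maximum observed $P_{neutral}$ as the fallback for unscorable missense
variants. The printed forms of both logistic exponents are typographically
ambiguous in sign; the defaults are fixed by biological monotonicity
(neutral SIFT high, destabilizing FoldX low) and `literal_sign = TRUE`
reproduces the alternative reading. The gene disruption score is
$P(AF) = 1 - \prod_i P_{neutral,i}$; an absent gene is assigned 0.99
outright; digitization thresholds strictly at 0.9. Common variants pass a
minor-allele-frequency filter at $\geq 5\%$ (a `strict` flag switches to
$> 5\%$), and `encode_features()` stacks SNPs, CNVs, presence/absence and
digitized burden into one typed feature matrix for an external
association engine — the mixed-model scan itself is out of scope; the
pipeline consumes its result table.

`window_overlap()` intersects association hits (P < 1e-6) with genes
whose deletion has a phenotype in the same condition, using a 3-kbp
window centred on the gene midpoint; the gene body is included as well by
default so long genes are never excluded (flag-controlled). Enrichment is
Fisher's exact test on the gene universe cross-classified by hit-linkage
and KO phenotype; empty margins yield a "not computed" result rather than
an error.

## The synthetic-data generator

`simulate_screen()` and its building blocks (`gen_layout()`,
`ground_truth()`, `gen_plates()`, `gen_variant_panel()`) generate data
under exactly the model the analysis assumes: multiplicative
gene x condition x strain effects, a per-plate smooth quadratic surface
factor, a border factor of 1.2 on the outer two rows/columns, known-empty
spots, duplicate gene positions, and lognormal replicate noise
(sd 0.2 on the log scale). The noise law is an artifact choice — real
colony-size noise is not specified by any first principle — and is
configurable; everything is deterministic given the seed, with
independent streams per strain, batch, replicate and plate.

Planted interactions come in three layers, and the layering is a
deliberate design decision: 5% of gene x condition pairs carry a
strain-specific multiplier of 0.25 (|log2| = 2, conditional essentiality
in the focal strain), 5% carry the same multiplier conserved in all
strains, and 15% carry weak conserved effects (lognormal multipliers,
sd 0.4). The weak layer is what gives the synthetic S-score distribution
a realistic continuum of effect sizes: without it the scores are bimodal
(a clean null bulk plus a far island of strong hits), the sliding-window
null has nothing to estimate in the mid-range, and its variance-vs-
magnitude trend — the very structure the method exists to model — is
degenerate. With the layer, batch-replicate correlations sit around
0.85 and the null slices show smoothly increasing spread, matching the
qualitative behaviour of real screens.

What the generator does **not** emulate: pinning-order artifacts and
neighbour competition beyond the border ring, condition-specific noise
scales, batch effects beyond independent noise draws, linkage between
variants, population structure in the strain panel (the association table
comes from a per-variant Welch test, explicitly not a mixed model).
Passing tests therefore demonstrate correctness of the machinery under
the stated model, not performance on any real dataset.

## Numerical and testing choices

* Tie handling in quantile normalization averages tied ranks; missing
  values are excluded from ranks and stay missing.
* The surface fit requires ≥ 12 non-missing colonies (twice the
  parameter count); border correction requires at least a 5 x 5 grid.
* Degenerate guards: zero score spread skips a condition in phenotype
  calling; a zero reference median makes $\varphi$ an error; empty
  variant lists give $P(AF) = 0$; an all-empty plate cannot be QC'd.
* Test problem sizes: the shared unit-test screen is 600 genes x 10
  conditions with 40 duplicated genes; the type-I acceptance screen is
  2,000 genes x 20 conditions across three strains and two reference
  batches; the recovery screen uses the generator defaults (1,000 x 12).
  The closed-form null check uses 10,000 standard-normal pairs, where the
  pooled mean of $N_{sub}$ must sit within three standard errors of
  $2/\sqrt{\pi}$.
* Oracles: the surface fit is checked against an explicit
  normal-equations solution to 1e-8 relative; Fisher enrichment against
  exhaustive hypergeometric enumeration over all 2 x 2 tables with
  margins up to 12.

## Known limitations

* The S-score control variance is estimated across conditions, so a gene
  with strong phenotypes in many conditions has a conservatively inflated
  denominator; scores for such genes are compressed relative to a
  replicate-based control. The scorer is isolated behind
  `compute_sscores()` so an alternative can be swapped in.
* Quantile normalization assumes conditions are exchangeable in
  distribution; a condition with a genuinely heavier phenotype tail is
  pulled toward the rest.
* The k-way conservation fraction conditions on the focal phenotype
  being classifiable (shared or exclusive) against every strain of the
  subset; pairs lost to incoherence masking or missing scores drop out of
  the denominator.
* With only two strains the subset spread (sd) of `shared_fractions()`
  is undefined; it needs three or more strains to be informative.

## A compact end-to-end run

```{r example, eval = FALSE}
st <- simulate_screen(n_genes = 600, n_conditions = 10, seed = 101)
sm_ref1 <- score_simulated_strain(st, "ref", batch = 1)
sm_ref2 <- score_simulated_strain(st, "ref", batch = 2, seed_offset = 5000)
sm_a <- score_simulated_strain(st, "strainA")
sm_b <- score_simulated_strain(st, "strainB")

nullm <- build_null(sm_ref1, sm_ref2)
diffs <- classify_comparisons(
  diff_pvalues(sm_a, sm_b, nullm),
  call_phenotypes(sm_a), call_phenotypes(sm_b))
table(diffs$class)
head(exclusiveness(list(diffs)))
```
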