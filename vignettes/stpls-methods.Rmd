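---
title: "Mining genotype-phenotype relations with soft-thresholding PLS"
author: "stpls package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining genotype-phenotype relations with soft-thresholding PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stpls)
```

## The problem

Given a panel of resequenced strains (for instance a few dozen yeast
genomes), a reference gene set, and a table of quantitative phenotypes
(growth rates and efficiencies under environmental stresses), we want to
find the small subsets of genes whose sequence divergence from the
reference best explains the variation of each phenotype across strains.
The setting is extreme "large p, small n": thousands of genes, a few
dozen strains. Ordinary least squares is unusable, univariate screens
ignore the joint structure, and stepwise selection cannot retain groups
of correlated genes. The package implements a sparse partial least
squares (PLS) approach in which variable selection happens inside the
PLS recursion itself.

## From alignment scores to genotype features

Each strain genome is compared to every reference gene by pairwise
alignment (e.g. translated BLAST); the package consumes the tabular
output and keeps, for strain $g_i$ and reference gene $r_j$, the maximum
bit-score $S(g_i; r_j)$ over all HSPs (`parseBlastTabular()`). Each
reference gene is also "aligned against itself" with unit match scoring,
so its self score $S(r_j; r_j)$ equals its length in residues
(`selfScores()`). The normalized score is

$$s_{ij} = \frac{S(g_i; r_j)}{S(r_j; r_j)},$$

clamped to $[1/20, 1]$ (`normalizeScores()`). Three conventions matter
here and are deliberate:

* **Missing hits score zero.** A (strain, gene) pair with no alignment
  row normalizes to the floor $1/20$: absence of detectable homology is
  treated as maximal divergence under this feature scheme.
* **Upper clamp at 1.** Bit-scores and unit-match self scores live on
  different scales, so the raw ratio can exceed 1; values above 1 are
  undefined under the substitution model and are capped.
* **The floor is exactly $1/20$** because that is the saturation point
  of the 20-state substitution model used next.

Genes whose normalized score stays below 0.5 in *every* strain carry
noise rather than signal and are discarded (`filterReferences()`; the
threshold is configurable, default 0.5).

Surviving scores become approximate evolutionary distances through the
20-state (amino-acid) Jukes-Cantor transform (`jcDistance()`):

$$d = -\tfrac{19}{20}\,\ln\!\Big(\tfrac{20\,s - 1}{19}\Big).$$

The transform is strictly decreasing in $s$, equals 0 exactly at
$s = 1$ (gene found at 100% identity) and diverges at $s = 1/20$; the
logarithm's argument is therefore floored at $\varepsilon = 10^{-8}$
(configurable), giving a finite saturation distance
$d_{\max} = -\tfrac{19}{20}\ln\varepsilon \approx 17.5$. Downstream
modelling standardizes each gene column, so the choice of
$\varepsilon$ only affects how saturated genes spread, not whether they
dominate. `buildGenotypeMatrix()` composes the three steps into the
$n \times p$ genotype matrix $X$.

## Phenotype preparation

Missing phenotype values are imputed with a K-nearest-neighbour scheme
in overall phenotype pattern (`knnImpute()`): the distance between two
strains is the root mean square difference over the phenotype columns
observed in both, computed on per-column standardized values; the
missing cell is the unweighted mean of its column among the K nearest
strains that have the column observed. K defaults to 5, a common choice
at the n = 36 scale; the standardized-distance convention avoids letting
large-variance phenotypes dominate the neighbourhood. Imputed values are
always inside the observed range of their column, and imputed cells
never feed back into distances.

All model fitting standardizes X and y columns by subtracting the mean
and dividing by the sample (n − 1) standard deviation. In
cross-validation the held-out rows are standardized with the training
fold's parameters only, so no information leaks from the left-out
samples into the fit.

## The ST-PLS model

For one phenotype the model is the linear regression
$E(\mathbf{y}) = X\boldsymbol\beta$, fitted by an orthogonal-scores
NIPALS PLS1 recursion with a soft-thresholding step inside it. For
component $a$ on the deflated data $(E_a, f_a)$ (starting from the
standardized $X$, $y$):

1. raw weight $w = E_a^\top f_a$;
2. **scaling**: $w \leftarrow w / \max_j |w_j|$;
3. **soft-thresholding**: $w_j \leftarrow \mathrm{sign}(w_j)\,(|w_j| - \delta)_+$;
4. **orthogonalization**: Gram-Schmidt against previously accepted
   weight vectors (a no-op for the first component);
5. **normalization**: $w \leftarrow w / \lVert w \rVert$;
6. scores and loadings $t_a = E_a w_a$,
   $p_a = E_a^\top t_a / t_a^\top t_a$,
   $q_a = f_a^\top t_a / t_a^\top t_a$, then deflation
   $E_{a+1} = E_a - t_a p_a^\top$, $f_{a+1} = f_a - t_a q_a$.

After $k$ components the coefficients are
$\boldsymbol\beta = W (P^\top W)^{-1} q$ on the standardized scale; the
selected gene set is the support of $\boldsymbol\beta$, which is
contained in the union of the per-component weight supports. The
shrinkage $\delta \in [0, 1)$ controls sparsity: larger $\delta$ keeps
fewer genes per component. At $\delta = 0$ the procedure reduces
exactly to standard PLS1 (the test suite checks coefficient equality
against an independently implemented textbook NIPALS PLS1 to $10^{-8}$).

Numerical corner cases are handled explicitly:

* Because scaling puts the largest weight at 1, thresholding alone can
  never empty the weight vector; over-shrinkage happens when the
  thresholded vector lies (numerically) in the span of earlier weight
  vectors and orthogonalization annihilates it. This raises a classed
  condition: at the first component it is an error, at later components
  the fit is returned truncated and flagged, and cross-validation marks
  the affected grid cells invalid rather than failing.
* Ties in the scaled maximum need no tie-break (scaling only divides);
  in the single-survivor regime a tie yields several survivors, which is
  accepted as-is.
* Zero-variance X columns (possible inside a cross-validation fold) are
  centred but not scaled; the centred column is identically zero, so its
  weight and coefficient are exactly zero and the fit proceeds. The
  standalone `standardizeColumns()` keeps the strict error, since a
  zero-variance *phenotype* is a data problem the user should see.
* Coefficients are kept on the standardized scale (selection and biplots
  operate there); `predict()` alone back-transforms to original units.

## Choosing the number of components and the shrinkage level

`crossValidate()` runs random leave-3-out cross-validation: a seeded
disjoint partition into $\lfloor n/3 \rfloor$ segments (the last absorbs
any remainder, so segments have 3-5 samples for any n). For every
combination of component count (default 1-10) and shrinkage level
(default 0.70, 0.73, ..., 0.97) the held-out samples are predicted and
pooled into the cross-validated root mean square error (CVRMSE). The
standard error of a cell's CVRMSE is estimated as the standard deviation
of per-segment RMSEs divided by $\sqrt{\#\text{segments}}$ — the
standard estimator behind one/two-standard-error rules.

`selectModel()` applies the two-standard-error slack rule: among valid
cells whose CVRMSE is at most the grid minimum plus twice the SE of the
minimum cell, and whose mean selected-gene count is at least 25, it
picks the largest shrinkage level (ties broken by the smallest component
count). The preference order — sparser before simpler — reflects the
goal of gene selection; the opposite order is a configuration away. The
25-gene constraint keeps the per-phenotype gene lists comparable for
enrichment analysis; when no cell within slack reaches it the constraint
is dropped with a warning. The chosen cell is refit on all samples, and
the model's explanatory power is summarized by Willmott's index of
agreement

$$d = 1 - \frac{\sum_i (p_i - o_i)^2}{\sum_i (|p_i - \bar o| + |o_i - \bar o|)^2} \in [0, 1],$$

computed from the pooled cross-validated predictions at the chosen cell
(1 = perfect agreement; a constant prediction at the observed mean gives
exactly 0).

`permutationNull()` calibrates what "good" means: the rows of X are
reshuffled (breaking the genotype-phenotype link while preserving the
gene correlation structure), the entire CV + selection + refit pipeline
is rerun, and the null d-index and selected-set size are recorded. All
randomness flows from one user seed through derived substreams, so every
run is exactly reproducible.

## Post-processing of selected gene sets

* **Pleiotropy** (`pleiotropySet()`): genes selected for at least
  $\lceil 0.25 \times \#\text{phenotypes} \rceil$ phenotypes ("at least
  25%", hence the ceiling).
* **Enrichment** (`enrichGeneSet()`, `enrichCategories()`): one-sided
  Fisher exact test in the enrichment direction (the hypergeometric
  tail $P(X \ge x)$), with the complementary depletion-direction
  p-value also reported; the fold ratio is
  $(x/n_{sel})/(K/N)$, observed over expected. P-values are BH-adjusted
  across categories, and significance marks are attached at the 10%,
  5% and 1% levels for raw (`*`) and adjusted (`•`) p-values.
* **Paralogs** (`classifyParalogs()`): a gene has a paralog when a
  non-self within-reference protein alignment hit has E < 1e-10 over at
  least 50% of the query length.
* **Evolutionary rates** (`compareRates()`): Welch unequal-variance
  t-test, one-sided in the direction "selected genes evolve faster";
  the unequal-variance form makes no homogeneity assumption between a
  small selected group and a large background.
* **Biplots** (`biplotCoords()`): sample scores are PLS score columns;
  gene coordinates are *correlation loadings* (Pearson correlation of
  each standardized gene column with each score), bounded in [−1, 1],
  matching the correlation-biplot convention. Chromosome positions of
  selected genes are exported sorted for external plotting
  (`chromosomePositions()`).

## The synthetic-data generator

`simulateGenotypeMatrix()` draws latent block-equicorrelated Gaussians
(default block size 20, within-block correlation ρ = 0.3) and maps them
monotonically into normalized scores in [0.5, 1], then through the
Jukes-Cantor transform — so simulated features are valid distances with
a controlled gene-gene correlation structure.
`simulatePhenotypes()` realizes $y = Z_S\beta + \varepsilon$ on the
standardized genotype columns with a random support $S$ (default 10 of
1000 genes), random effect signs, $|\beta| = 1$ and
$\sigma = 0.5$. `simulateScoreTable()` inverts the feature pipeline:
it plants normalized scores (including all-below-0.5 columns that the
filter must drop and exact-floor cells emitted as absent rows) and
emits raw scores `normalized * selfScore`, so the expected genotype
matrix is known exactly. `simulateAnnotations()` plants category
enrichment (odds-boosted membership inside the support) and an
evolutionary-rate shift for support genes.

What the generator emulates: the n ≪ p shape, correlated gene blocks,
sparse linear influence, planted enrichment. What it does not emulate:
phylogenetic strain structure (population relatedness that correlates
rows of X), sequence-level mutation processes, and non-linear
genotype-phenotype maps. Passing tests on this generator therefore
demonstrate correctness of the machinery and qualitative behaviour
(signal/null separation, enrichment detection), not performance claims
about any real organism.

## Known limitations

Exact recovery of a planted support at this design scale has hard
statistical limits. With 10 equal-effect support genes among 1000, each
support gene's population correlation with the phenotype is about
$1/\sqrt{10} \approx 0.32$, while the expected maximum absolute sample
correlation of 990 unrelated genes at n = 36 is about 0.6: individually,
true genes rank below the extremes of the noise. In this regime no
selector — marginal screening, lasso, or sparse PLS — recovers most of
the support; our own measurements on the generator show best-achievable
recall around 0.3-0.6 for all three, with ST-PLS at the top of that
range. What the method does deliver, and what the test suite asserts, is
the contrast that matters for inference: under row-permuted genotypes
the selected sets share essentially no genes with the planted support
(median overlap ≤ 1 of 10), the cross-validated d-index of real signal
exceeds its permutation null, and planted enrichments are detected.
Recovery becomes reliable when effects are concentrated (fewer, stronger
genes): with 3 well-separated signal genes among 50 the selector
recovers the full support, as the unit tests show.

Other limitations: the normalization's upper clamp discards information
about unusually high-scoring alignments; the 20-state transform treats
all residue substitutions as exchangeable; the leave-3-out SE estimator
ignores the correlation between folds (standard practice, slightly
anti-conservative); and per-phenotype models are fitted independently —
no multi-response PLS2 mode in this version.

## Problem sizes used by the test suite

The packaged tests run the full pipeline at n = 36, p = 1000 (20 seeds)
for the recovery/null contrast, desk-scale problems (n = 18-36,
p = 40-100) for the oracle equivalences and permutation tests, and an
exhaustive sweep of all 2×2 tables with universe size up to 200 for the
enrichment p-values. These sizes were chosen so that the whole suite
runs in a few minutes on one CPU while still exercising every code path
at the study's n ≪ p shape.
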