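---
title: "Methods: bootstrap-consistent adiposity-associated gene discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bootstrap-consistent adiposity-associated gene discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placentaNAAG)
```

## The question and the design

Neonatal adiposity — percentage body fat at birth — varies widely even
after conditioning on maternal BMI, and the placental transcriptome is a
natural place to look for correlates of fetal fat accrual. The design
this package implements compares placental expression between
low-adiposity (LA) and high-adiposity (HA) neonates *within* each
maternal BMI stratum (lean, LE, pregravid BMI 18–24.9; obese, OB, BMI
30–40), so that any shared signal is by construction independent of
maternal BMI category. LA and HA are the first and third tertiles of
percentage body fat within the stratum; the middle tertile is excluded
to sharpen the contrast.

Adiposity is computed from bedside anthropometrics through a validated
linear equation,

$$\mathrm{FM\,(kg)} = 0.39055\,\mathrm{BW(kg)} + 0.0453\,\mathrm{SF(mm)}
  - 0.03237\,\mathrm{L(cm)} + 0.54657,$$

with lean mass $\mathrm{BW}-\mathrm{FM}$ and percentage body fat
$\mathrm{FM}/\mathrm{BW}\times 100$; `body_composition()` keeps both
identities exact. Tertiles are assigned by rank: the lowest
$\lceil n/3\rceil$ values are T1 and the highest $\lfloor n/3\rfloor$
are T3, with ties broken by stable sample-id order. This convention was
chosen (over quantile-interpolation conventions) because it makes the
intended group sizes achievable at any $n$ — with cohorts of 59 lean and
60 obese mothers it produces exactly the 20/19/20/20 sequenced groups.
A fully degenerate input (all body-fat values equal) is assigned all-T2
with a warning rather than an arbitrary split, since no adiposity
ordering exists. BMI bins are closed at their printed endpoints; values
in (24.9, 30) or outside [18, 40] are excluded.

## The differential-expression engine

Counts are modeled per gene as negative binomial with log link and the
variance function $\mathrm{Var} = \mu + \alpha\mu^2$:

$$\log \mu_{gj} = \log s_j + \beta_{0g} + \beta_{Ag}\,\mathrm{HA}_j
  + \beta_{Sg}\,\mathrm{male}_j .$$

* **Size factors** $s_j$ are median-of-ratios: the median over genes
  positive in every sample of the ratio of the sample's count to the
  gene's geometric mean. They are invariant to gene order, and scaling
  one sample's counts by $c$ scales its factor by $c$ relative to the
  others (the geometric-mean reference rescales all factors by
  $c^{1/n}$, which is irrelevant downstream since only offsets differ by
  a constant).
* **Dispersion** $\alpha_g$ is method-of-moments on depth-normalized
  counts, $\hat\alpha_g = \max(10^{-8}, (s^2_g - \bar m_g)/\bar m_g^2)$.
  When a grouping factor is available — as it always is inside
  `nb_wald_de()` — moments are computed within the LA and HA groups and
  combined with $n_k - 1$ weights, so a genuine expression difference
  between the classes is not absorbed into the dispersion. Without this,
  a planted 2-fold effect roughly doubles the apparent $\alpha$ and
  costs real power. An optional shrinkage pulls log-dispersions halfway
  toward a fitted $a_0 + a_1/\mu$ trend; it is off by default because
  the bootstrap layer, not per-gene dispersion refinement, carries the
  robustness in this pipeline.
* **Fitting** is iteratively reweighted least squares, vectorized across
  genes (all genes share the design matrix; the per-gene weighted normal
  equations are solved in closed form for up to three coefficients).
  Convergence is declared at a relative deviance change below $10^{-8}$,
  capped at 100 iterations; linear predictors are clamped to
  $|\eta| \le 30$ to contain separation. Genes that do not converge are
  flagged and carry no fabricated p-value; downstream they count as
  non-significant.
* **Testing** is a Wald z on $\beta_{Ag}$ with two-sided normal tail;
  `log2fc` is $\beta_{Ag}/\ln 2$. Sex uses female-reference treatment
  coding; a stratum (or bootstrap resample) with a single sex level
  drops the column with a warning. No multiple-testing correction is
  applied at this stage by design — the consistency rule below is the
  error-control mechanism.

The engine is intentionally an approximation of DESeq2, not a port: no
empirical-Bayes dispersion shrinkage across genes, no independent
filtering, no Cook's-distance outlier replacement. Gene-level numbers
will therefore differ from a DESeq2 run, but on simulated data the two
agree closely (the test suite checks log2FC correlation > 0.95 against
DESeq2 and exact agreement of size factors).

Before fitting, samples can be screened by `pca_outliers()`: principal
components of $\log_2(\text{normalized count}+1)$ over the 500 most
variable genes, flagging samples more than $k = 5$ MAD-scaled units from
the coordinate-wise median on PC1 or PC2. The rule is deterministic; the
specific criterion (top-500 genes, two PCs, 5×MAD) is a package choice,
since PCA screening conventions vary. Note that a sample whose counts
are scaled uniformly is *not* an outlier under this rule — depth scaling
is exactly what size-factor normalization removes — so the screen
targets composition outliers (many genes shifted relative to the rest).

## The bootstrap-consistency rule

Within a stratum, `bootstrap_de()` draws $B$ resamples with replacement
and reruns the *entire* DE fit (size factors, dispersions, GLM) on each.
Resampling is stratified within the LA and HA classes by default,
preserving class sizes; this guarantees the adiposity factor is
estimable in every iteration and is exposed as a flag because joint
resampling is also defensible. Per iteration a gene is
significant-up if $p < .05$, $|\mathrm{log2FC}| > \log_2 1.5 \approx
0.585$, and the effect is positive (significant-down analogously). A
gene is retained as a NAAG when
$\max(n_{up}, n_{down})/B \ge 0.5$ — "significant with consistent
direction in 50% or more of the iterations" — with exact directional
ties rejected. The fold-change threshold is interpreted on the linear
scale; retained genes with |median log2FC| well below $\log_2 1.5$ in
published tables of this design are consistent with that reading, and
the threshold is configurable.

Two conventions the rule leaves open are fixed with flags: the
consistency denominator is all $B$ iterations (not the significant-only
count), and the reported `median_log2fc` / `median_p` are medians over
all converged iterations (not significant-only). Retention is monotone:
tightening $p$, FC, or consistency thresholds never adds a gene — a
property the test suite asserts.

CNAAGs are the gene-wise intersection of the LE and OB NAAG sets,
classified concordant or discordant by direction agreement; together
with the two stratum-unique sets they partition the NAAG union.

## Downstream characterization

* **Over-representation** (`go_enrichment()`) is the one-sided
  hypergeometric tail $P(X \ge k)$ per gene set with Benjamini–Hochberg
  adjustment across terms (the FDR procedure is fixed as BH; the default
  significance threshold is FDR < 0.1). The universe defaults to all
  protein-coding genes surviving filters in the analysis, and is
  configurable. Gene sets are flat GMT collections; no term-hierarchy
  propagation is attempted.
* **Networks** (`confirm_edges()`, `hub_genes()`, `ppi_enrichment()`):
  database edges (3-column STRING-style TSV, default combined-score
  cutoff 400 = medium confidence) are confirmed when the endpoint genes'
  $\log_2(\text{normalized}+1)$ expression correlates with $|r| > 0.3$
  and $p < .05$ (t-distribution, df $n-2$) within the specified sample
  group; unconfirmed edges are retained for context. Correlations are
  computed within LE, within OB, and pooled, since which grouping
  underlies a published figure is often unstated. Hubs strictly exceed
  the 90th empirical degree quantile (type-7 interpolation). Interaction
  enrichment replaces a database's internal degree-corrected null with a
  seeded equal-size permutation null,
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(M+1)$; this is
  self-contained and testable, but its p-values are not comparable to a
  database's own enrichment p beyond order of magnitude.
* **Reference profiling** (`reference_profile()`) slices a cell-type ×
  gene matrix, z-scores each gene across cell types and reports the
  arg-max type; genes absent from the reference are listed, not fatal.
* **qPCR statistics**: relative expression is $2^{\Delta Ct}$ with
  assumed efficiency 2 (an explicit linearized-ratio flag exists);
  HA-vs-LA comparisons use a two-sided rank-sum test, exact by full
  enumeration of mid-rank assignments for combined $n \le 20$ and
  normal-approximated with continuity and tie corrections above; the
  RNA-seq/qPCR association uses Spearman correlation, exact by
  permutation enumeration for $n \le 8$, t-approximated otherwise. The
  independent-groups rank-sum test is the default for group comparisons
  (a paired signed-rank companion is provided), matching the unpaired
  structure of an LA/HA contrast.

## What the synthetic generator emulates — and what it does not

`simulation_config()` defaults encode the study conditions: groups of
20/19/20/20 sequenced samples (plus excluded middle tertiles of 20 per
stratum), NB counts with dispersion $\alpha = 0.1$, log-normal baseline
expression (median 100 counts, $\sigma_{\log} = 1$), depth factors
log-uniform on [0.5, 2], planted adiposity effects of magnitude 1 log2FC
in four classes (shared-concordant, shared-discordant, LE-unique,
OB-unique; 20 genes each by default), and a small sex effect (log2FC 0.2
on 5% of genes) keeping the sex covariate non-degenerate. Percentage
body fat is drawn from the tertile bands of a population distribution
(mean 12.2%, SD 3.9%, central span roughly 6–18%), so intended classes
are the true population tertiles and rank-based tertile assignment
recovers them by construction; birth weight and length are correlated
positive draws, and the flank skinfold is then *solved* from the
body-composition equation so computed body fat equals its target
exactly. Gene sets plant one enriched set containing 80% of the shared
planted genes; the edge list plants an 8-clique among shared genes over
1% background density; the reference elevates shared genes 16-fold in
one designated cell type (marker-like specificity, so the construction
check that ≥ 90% of planted genes arg-max there holds with margin); Ct
values follow $a - b\log_2(\text{normalized}+1)$ plus 0.25 cycles of
noise with an expression-independent housekeeping gene.

The generator does **not** emulate: library-size extremes or batch
effects, gene–gene correlation beyond the planted network clique,
zero-inflation, transcript-length bias, cell-type deconvolution of bulk
signal, or alignment/quantification artifacts. Passing recovery tests
therefore demonstrates that the statistical machinery identifies planted
effects under a faithful NB model of the study design — not that it is
robust to every failure mode of real RNA-seq. Library depth is a
convention (no depth is stated for the motivating design), which is why
it is a visible config parameter.

## Numerical choices and degenerate inputs

* IRLS tolerance $10^{-8}$ on relative deviance change, 100-iteration
  cap, $|\eta| \le 30$ clamp; non-convergence is a flag, never a number.
* Dispersion floor $10^{-8}$; zero-mean and constant genes floor with a
  flag.
* Even-count medians are midpoints of the central pair.
* Tertile ties break by stable sample-id order; the all-equal input is
  all-T2 with a warning.
* The two-way cohort ANOVA uses partial (Type-III) sums of squares under
  sum-to-zero contrasts — required for the unbalanced 20/19/20/20
  design — with Tukey compact-letter groupings across the four cells and
  Fisher exact tests for categorical variables; a variable with zero
  within-cell variance everywhere is flagged rather than tested.
* Exact-test cutoffs: rank-sum enumeration up to combined $n = 20$
  ($\binom{20}{10} = 184{,}756$ assignments), Spearman enumeration up to
  $n = 8$ ($8! = 40{,}320$ permutations); beyond these the standard
  approximations apply and the suite checks agreement across the
  boundary.
* Permutation enrichment uses $M \ge 100$ (default 999) with the add-one
  estimator, so $p \ge 1/(M+1)$ honestly reflects resolution.

## Problem sizes used by the test suite

The suite favors many small, targeted simulations: smoke-level
configurations use 10 samples per group and ~120 genes; the planted-truth
recovery battery uses the full study geometry (20 per class per stratum,
$\alpha = 0.1$, |log2FC| = 1, $B = 100$) at 600 genes across five seeds,
which the package's vectorized fitter completes in a few minutes. These
sizes were chosen as the smallest at which the checked properties are
statistically meaningful; all thresholds and generator defaults are the
study conditions stated above, independent of test size.

## Known limitations

* The NB engine's per-gene results are approximations of a DESeq2 fit;
  analyses seeking exact parity with published per-gene tables should
  not expect it (and the bootstrap layer, which dominates the
  gene-selection behavior, is the point of the package).
* Consistency fractions are Binomial($B$) estimates; at $B = 100$ a gene
  whose true per-iteration significance probability is near 0.5 can
  cross the retention boundary between seeds. Increasing `B` stabilizes
  the fraction at linear cost.
* The permutation interaction-enrichment null ignores node degree; very
  high-degree genes in a background network will inflate enrichment
  relative to a degree-corrected null.
* The qPCR module assumes amplification efficiency 2 and a
  housekeeping gene uncorrelated with the phenotype; neither is checked
  from data.
* `cohort_table()` requires all four design cells to be non-empty and
  does not impute missing anthropometrics.
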