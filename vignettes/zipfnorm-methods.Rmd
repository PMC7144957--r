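---
title: "Zipf-plot based normalization: model, estimators and design choices"
author: "zipfnorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zipf-plot based normalization: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zipfnorm)
```

## The problem

Bulk RNA-seq count profiles are often dominated by zeros and very small
counts: in deeply zero-inflated data sets well over 80% of genes can have a
zero measure in any given sample, and most positive counts are tiny.  Linear
normalizers that rely on a central quantile (median, upper quartile) or on
fold changes of typical genes then break down — medians are zero, quantiles
tie exactly across samples, and log ratios are driven by measurement error
in weakly expressed genes.

`zipfnorm` normalizes such profiles using only the *upper tail* of each
sample's expression distribution, where measurement is reliable, under the
assumption that all profiles share a similar upper-tail shape.  It makes no
assumption that the majority of genes are not differentially expressed, and
it never alters gene-level ordering within a sample.

## The Zipf plot and the power-law tail

For a profile $X = (X_1, \dots, X_n)$ with distinct positive values
$z_1 > z_2 > \dots > z_m$ and frequencies $f_1, \dots, f_m$, the rank of
$z_i$ is

$$ r_i \;=\; \sum_{j=1}^n I(X_j \ge z_i) \;=\; \sum_{j \le i} f_j . $$

The Zipf plot is the scatter of $\log r_i$ against $\log z_i$ (natural
logarithms throughout).  If the upper tail of the distribution follows a
power law with density $f(x) \propto x^{-\kappa}$ above some threshold, then
for large $n$, $r_i \approx n\,[1 - F(z_i)]$ and

$$ \log r_i \;\approx\; \text{const} + (1 - \kappa) \log z_i , $$

so the tail of the Zipf plot is a straight line with slope
$1 - \kappa < 0$.  `fit_tail()` selects the *distinct-value* points with
$\log r_i < 6$ — i.e. the values of rank $\lfloor e^6 \rfloor = 403$ or
lower, the highly expressed genes — and fits ordinary least squares of
$\log r_i$ on $\log z_i$.

Three design points deserve emphasis:

* **Tail membership is by rank cutoff**, not by a lower value threshold
  $x_{\min}$.  Joint estimation of $(\kappa, x_{\min})$ by Hill-type or
  maximum-likelihood estimators is deliberately out of scope; the rank
  cutoff ties the fitted object directly to the plotted one and behaves
  identically across samples regardless of their scale.
* **One point per distinct value, unweighted.**  The line is fitted to the
  Zipf-plot points themselves; tied counts collapse into a single point
  with the appropriate cumulative rank, with no jitter and no frequency
  weighting.  An alternative would repeat tied values once per gene; for
  the large counts that populate the tail, ties are rare and the two
  conventions nearly coincide.
* **At least `min_tail_points = 10` qualifying points** are required, with
  a clear error otherwise.  Ten points is the smallest tail we consider
  honest to summarise by a fitted slope.

On integer count data the discreteness of the values interacts with the
distinct-value construction: rounding merges neighbouring tail values into
single points, which steepens the fitted distinct-value slope somewhat
relative to the continuous ideal $1-\kappa$.  Both profiles in a pair are
affected alike, so the *ratio* of slopes (below) is far less sensitive than
each slope individually.

## The two normalizing parameters

A target profile $Y$ is normalized against a reference profile $X$ (chosen
by default as the sample with the fewest zeros) by

$$ Y' \;=\; (Y / \sigma)^{\gamma} . $$

**Rescaling ($\sigma$).**  Dividing by $\sigma$ shifts the Zipf plot of $Y$
horizontally by $\log\sigma$.  To estimate the shift, the qualifying tail
points of both profiles are pooled: $Z$ the log values, $R$ the log ranks,
and $G$ a 0/1 group indicator (0 = reference, 1 = target).  The shared-slope
regression

$$ Z = \alpha + \beta R + c\,G + \varepsilon $$

is fitted by least squares; the coefficient $c$ of $G$ is the horizontal
displacement of the target's tail at matched log rank, i.e. an estimate of
$\log\sigma$.  Two conventions are fixed here: the coefficient lives on the
*log* scale (the Zipf-plot shift is additive in $\log z$, and the rescaling
scheme acts as $\log Y' = \log Y - \log\sigma$), and $G = 1$ marks the
target, so a tail to the right of the reference yields $\sigma > 1$ and
division moves it back.  The shared slope $\beta$ across the two groups is
adopted as written; it is exactly right when the tails are parallel, which
is also the regime in which pure rescaling is the appropriate scheme.

**Power transform ($\gamma$).**  When the two tail slopes differ, raising
$Y$ to a power rotates its Zipf line: $Y^{a}$ has tail slope
$s_Y / a$.  Choosing

$$ \hat\gamma \;=\; s_Y / s_X $$

(the *target* slope over the *reference* slope) makes the transformed
target's slope equal the reference's.  The ratio is sometimes written the
other way around; for near-parallel tails ($\gamma \approx 1$) the two
differ negligibly, but only the target/reference orientation makes
$(Y/\sigma)^\gamma$ exactly undo a distortion of the form
$Y = \sigma X^{1/\gamma}$, which is the property the recovery tests assert.

**Order of operations.**  In the full scheme $\gamma$ is estimated first
from the two slopes; $\sigma$ is then estimated from the pooled regression
with the target's log values already multiplied by $\hat\gamma$ (and the
$G$ coefficient divided by $\hat\gamma$), so that the reported pair is
jointly consistent with $(Y/\sigma)^\gamma$.  Estimating $\sigma$ from the
raw tails instead is available via `sigma_on_raw_tails = TRUE`; on
noise-free distortions the consistent ordering is exact while the raw-tail
ordering is not, which is why it is the default.

## Kolmogorov–Smirnov refinement

The regression estimates can be refined jointly by minimizing

$$ D(\sigma, \gamma) \;=\; \sup_t \,\bigl| \hat F_x(t) - \hat F_{y'}(t) \bigr| , $$

the two-sample Kolmogorov–Smirnov distance between the reference
distribution and the transformed target distribution, over a deterministic
grid centred at the regression estimates: $\sigma$ log-spaced over
$[\sigma_0 e^{-0.5}, \sigma_0 e^{0.5}]$ (101 points) and $\gamma$ linear
over $[\gamma_0 - 0.05, \gamma_0 + 0.05]$ (51 points).  Choices made here:

* **ECDFs are computed over positive values only.**  Zeros are invariant
  under $(y/\sigma)^\gamma$, so including them would floor $D$ at the gap
  between the two zero proportions and blunt the objective's sensitivity to
  the parameters.  This is a judgment call; with equal zero proportions the
  two versions order candidates identically.
* $D$ is evaluated *exactly* at every pooled jump point of the two step
  functions — no interpolation, no asymptotic approximation — and the scan
  is a full deterministic grid (no stochastic optimizer), so a refinement
  is exactly reproducible and can never be worse than its own grid centre.
* Ties on the grid are broken by smaller $D$, then by proximity to the
  centre in $(\log\sigma, \gamma)$, then by smaller $\sigma$.
* Grid half-widths and resolutions are package defaults chosen to bracket
  regression estimates comfortably while keeping a scan around five
  thousand KS evaluations; `grid_spec()` exposes all of them.

Empirically (and visibly in the exported $D$-surfaces) $D$ responds far
more strongly to $\sigma$ than to $\gamma$ in the zero-inflated count
regime, which is why the linear scheme alone is often sufficient and why
`zipf_normalize(refine = TRUE)` pins $\gamma = 1$ when
`scheme = "linear"`.

## The simplified baseline normalizers

For benchmarking, five classical linear normalizers are implemented in
their plain *pairwise* form against the same reference: total count (TC),
median ratio (MED), upper-quartile ratio (UQ), trimmed mean of M-values
(TMM; $M_g = \log(y_g/x_g)$, lowest and highest 30% of M-values dropped,
$\sigma = e^{\bar M}$), and relative log expression (RLE;
$\sigma = e^{\operatorname{median} M}$).  These deliberately omit the
refinements of the canonical library implementations (no A-trimming or
precision weights in TMM, no geometric-mean pseudo-reference in RLE), so
they should not be expected to match `edgeR::calcNormFactors` or
`DESeq2::estimateSizeFactors` output.

Zero handling follows a two-step cascade: genes zero in *both* profiles are
dropped first; if the resulting statistic is invalid (zero median or
quartile, non-finite trimmed mean or median of M), genes zero in *either*
profile are dropped and the statistic recomputed; if it is still invalid,
the method is declared inapplicable for that sample with an informative
error — UQ, for instance, cannot work when more than 75% of the retained
measures are zero.  The path taken is recorded per sample.  Quantiles use
linear interpolation between order statistics (R's default type 7); the
summary table's "Scal Up" column counts samples with $\sigma < 1$ (dividing
by $\sigma < 1$ scales expressions up) and "No Chng" counts exact
$\sigma = 1$, which arises from exactly tied quantiles in integer data.

## Benchmarking by invariant genes

Given a normalized matrix, the per-gene coefficient of variation
$\mathrm{CV} = s/\bar x$ (sample standard deviation, $n-1$ denominator)
is computed across all samples.  Genes with 50% or more zeros are excluded
from invariant consideration — most are weakly expressed and dominated by
measurement error — but for eligible genes the zeros they do have are kept
in the CV computation, since a normalization that leaves a gene
intermittently at zero should pay for it.  The $n$ eligible genes with the
smallest CV (default $n = 1000$) are the method's *invariants*, with
boundary ties resolved by gene order; the cutoff CV is the largest selected
CV.  Methods are compared in a single square matrix: invariant-set overlaps
below the diagonal, cutoff CVs on it, and Spearman correlations (average
ranks for ties) of the CV vectors over jointly eligible genes above it.
MA-plots ($M = \log X - \log Y$ against $A = (\log X + \log Y)/2$, over
genes positive in both profiles) with a loess trend (`ma_smooth()`, spans
0.2 and 0.1 are typical) serve as the per-pair diagnostic; the loess step
delegates to `stats::loess` and is a visualization aid, not part of the
estimators.

## The synthetic generator

`simulate_zipf_counts()` emulates the data regime the method is designed
for: each gene draws one latent base measure — zero with probability 0.85;
otherwise a small count (truncated Poisson, mean 3) with probability 0.3,
mimicking the heavy spike of counts of ten or less; otherwise a
Pareto($\kappa = 2.7$, $x_{\min} = 10$) tail draw, so the Zipf tail slope
is near $-1.7$.  Sample $j$ observes $\sigma_j \cdot \text{base}^{1/\gamma_j}$,
rounded by `floor(x + 0.5)` in counts mode or left continuous so that
recovery experiments are not confounded by rounding of small values.

Because all samples share one latent base profile, columns are exact
monotone transforms of one another: the generator isolates exactly the
distortion that the $(Y/\sigma)^\gamma$ normalization is supposed to undo.  It does *not*
emulate biological between-sample variation, differentially expressed
genes, per-sample sampling noise, gene-length effects, or sample-specific
zero patterns.  Recovery results on this generator therefore demonstrate
the correctness and numerical behaviour of the estimators under their own
model — not performance on real data, where tail-shape similarity is an
assumption to be checked (the Zipf plots themselves are the check).

## Problem sizes and numerical conventions

The test-suite and acceptance runs use matrices of 50,000 genes (matching
the scale at which rank approximations and tail fits are comfortably
stable) with 4–10 samples, 10–20 generator replicates for recovery-rate
estimates, and KS grids of $101 \times 51$; these sizes are the package's
own choices balancing statistical resolution against runtime.  All
logarithms are natural; normalized outputs are real-valued and never
re-rounded; zeros are preserved exactly by `normalize_profile()`
($(0/\sigma)^\gamma = 0$ for the admissible $\sigma, \gamma > 0$);
reference selection breaks ties by column order; and every stochastic
procedure accepts an explicit seed.

## Known limitations

* A single reference profile anchors all pairwise estimates; no
  multi-reference or consensus normalization is provided.
* The OLS tail-slope estimator is simple and transparent but not efficient
  for power-law indices; Hill-type or likelihood estimators would reduce
  variance at the cost of an $x_{\min}$ selection problem.
* On heavily discretized data the KS surface is jagged and the refinement
  can legitimately return its own centre.
* Downstream differential-expression testing, gene-length correction
  (RPKM/FPKM/TPM) and quantile normalization are out of scope; profiles
  already quantile-normalized share a distribution by construction and
  cannot benefit from this method.
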