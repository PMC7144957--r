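# zipfnorm

Normalization of RNA-seq count profiles with excessive zeros, based on the
upper-tail behaviour of each sample's Zipf plot.

## The problem

Bulk RNA-seq profiles from deeply zero-inflated experiments — where 80% or
more of genes have zero counts and most positive counts are tiny — defeat
the usual linear normalizers.  Medians are zero, upper quartiles tie
exactly across samples, and fold-change based factors (TMM, RLE) are
driven by measurement error in weakly expressed genes.  `zipfnorm` is for
analysts who need reliable between-sample scaling factors for such data:
it estimates them from the highly expressed genes only, assuming the
profiles share similar upper-tail shapes, and requires no assumption that
most genes are non-differentially expressed.

## The method

For a profile with distinct positive values `z_1 > ... > z_m`, the rank of
`z_i` is `r_i = #{ j : X_j >= z_i }`.  The *Zipf plot* is `log r_i` versus
`log z_i`; a power-law upper tail with index `kappa` makes it linear with
slope `1 - kappa < 0`.  A target profile `Y` is normalized against a
reference `X` by

    Y' = (Y / sigma)^gamma

* `sigma` (linear rescaling) is the horizontal Zipf-plot shift: pooling
  the tail points of both profiles (log rank < 6, i.e. the top 403 ranked
  values), the regression `Z = a + b R + c G` of log values on log ranks
  and a group indicator gives `log sigma` as the coefficient of `G`.
* `gamma` (optional power transform) is the ratio of the two fitted tail
  slopes, `s_Y / s_X`, which makes the transformed target's tail parallel
  to the reference's.
* Optionally the pair is refined by scanning a deterministic grid around
  the estimates and minimizing the two-sample Kolmogorov–Smirnov distance
  `D(sigma, gamma) = sup_t |F_x(t) - F_y'(t)|` between positive values.

Five simplified pairwise baselines (TC, MED, UQ, TMM, RLE) with a
zero-handling cascade, an invariant-gene benchmarking protocol based on
per-gene coefficients of variation, MA-plot diagnostics, and a
zero-inflated power-law count simulator round out the package.  See the
methods vignette (`vignettes/zipfnorm-methods.Rmd`) for the full account.

## Worked example

```r
library(zipfnorm)

# 50,000 genes, 85% zeros, power-law tails (kappa = 2.7), 5 samples with
# known rescaling distortions; counts rounded to integers
sim <- simulate_zipf_counts(n_genes = 50000, n_samples = 5,
                            sigma = c(1, 0.5, 2.2, 0.8, 1.6),
                            seed = 42)
counts <- filter_all_zero_genes(sim$counts)$counts
fit <- zipf_normalize(counts, reference = "S1", scheme = "full")
round(coef(fit), 4)
#>     sigma  gamma
#> S1 1.0000 1.0000
#> S2 0.4934 0.9963
#> S3 2.3169 1.0111
#> S4 0.7946 0.9984
#> S5 1.6539 1.0069
```

The estimated `sigma` column recovers the simulated distortions (0.5, 2.2,
0.8, 1.6) to within a few percent despite 85% zeros — the residual error
comes from integer rounding of the distorted counts — and `gamma` stays
near 1 because all simulated tails share one shape.  `summary(fit)` prints
the factor distribution in the conventional layout:

```r
summary(fit)
#> Zipf-plot normalization (full scheme), 7602 genes x 5 samples, reference 'S1'
#>
#> Normalizing parameters (sigma):
#>           Min. 1st Qu. Median  Mean 3rd Qu.  Max.     SD Scal Up No Chng
#> ZN-full 0.4934  0.7193  1.224 1.315    1.82 2.317 0.8296     0.5       0
#>
#> Zipf tail slopes:
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  -1.593  -1.586  -1.575  -1.579  -1.573  -1.569
```

`normalized_counts(fit)` returns the normalized matrix,
`baseline_normalize(counts, "tmm")` fits a baseline method into the same
object shape, and `gene_cv()` / `select_invariants()` / `agreement()`
implement the invariant-gene benchmark across methods.

A command-line front-end wrapping the same functions ships at
`inst/exec/zipfnorm`:

```sh
Rscript inst/exec/zipfnorm simulate --n-genes 50000 --n-samples 5 --seed 1 --out demo
Rscript inst/exec/zipfnorm normalize --input demo/counts.tsv --scheme linear --out demo
Rscript inst/exec/zipfnorm evaluate --input demo/counts.tsv --n-invariants 500 --out demo
```

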