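# mixrsm

Mixture-design response surface analysis for formulation optimization in R.

`mixrsm` is aimed at formulation scientists and biostatisticians who run
mixture experiments — blends of q components whose fractions are
non-negative and sum to one — and need the full analysis chain on the
composition simplex:

* **Design**: candidate-set construction (lattice + centroid + axial check
  blends), the I-optimality criterion (average scaled prediction variance
  `mean f(x)' (X'X)^-1 f(x)` over a simplex grid), point-exchange search,
  and replicate augmentation for pure-error degrees of freedom.
* **Modeling**: Scheffé mixture polynomials
  `y = Σ βᵢxᵢ + Σ βᵢⱼxᵢxⱼ + Σ δᵢⱼxᵢxⱼ(xᵢ−xⱼ)` (no intercept), fit by least
  squares on an optionally transformed response (`sqrt`, `ln`, `inverse`,
  `inverse_sqrt`, `power`), with SD, R², adjusted R², predicted R² (PRESS),
  and CV%.
* **Inference**: the mixture ANOVA — Type I sums of squares for the linear
  mixture, partial (drop-one) SS per non-linear term, lack-of-fit tested
  against pure error from replicate groups — and backward model reduction.
* **Optimization**: Derringer–Suich desirabilities per response and
  maximization of their weighted geometric mean over the simplex (dense
  barycentric grid + Nelder–Mead polish).
* **Formulation metrics**: Sauter mean diameter (d₃.₂), DPPH inhibition %,
  IC50 by log-linear interpolation, droplet growth ratio, and the FICI
  checkerboard synergy index.
* **Synthetic data**: simulation of mixture studies from known Scheffé
  surfaces with transformed-scale Gaussian noise, plus a bundled 17-run
  three-essential-oil nanoemulsion dataset used throughout the examples
  and tests.

## Worked example

Fit the eight-term reduced-cubic model to the bundled droplet-size data on
the square-root scale and inspect its ANOVA:

```r
library(mixrsm)
fx <- nanoemulsion_runs()
fit <- scheffe_fit(fx$design, fx$responses$d32_um,
                   c("A","B","C","AB","AC","BC","AB(A-B)","BC(B-C)"),
                   transform = "sqrt")
fit
#> Scheffe mixture fit (17 runs, 8 terms, transform: sqrt)
#> Coefficients (transformed scale):
#>        A        B        C       AB       AC       BC  AB(A-B)  BC(B-C)
#>  1.43775  1.29895  2.18600 -1.31117 -0.95065 -1.99599  3.59846 -3.91701
#> SD = 0.06811  R2 = 97.98%  R2adj = 96.41%  R2pred = 71.73%  CV = 5.19%

mixture_anova(fit)
#> Mixture ANOVA (transformed scale: sqrt)
#>          source       ss df        ms        F         p
#>           Model 2.023000  7 0.2890000  62.3030 6.604e-07
#>  Linear Mixture 1.268100  2 0.6340400 136.6900 1.842e-07
#>              AB 0.141430  1 0.1414300  30.4890 3.697e-04
#>              AC 0.076509  1 0.0765090  16.4940 2.837e-03
#>              BC 0.317830  1 0.3178300  68.5180 1.684e-05
#>         AB(A-B) 0.140400  1 0.1404000  30.2680 3.794e-04
#>         BC(B-C) 0.075229  1 0.0752290  16.2180 2.986e-03
#>        Residual 0.041748  9 0.0046387       NA        NA
#>     Lack of Fit 0.030611  4 0.0076528   3.4358 1.041e-01
#>      Pure Error 0.011137  5 0.0022274       NA        NA
#>       Cor Total 2.064800 16                NA        NA
```

The model explains 98% of the variation in √d₃.₂ (F = 62.3 on 7 and 9 df);
the non-significant lack of fit (p = 0.10) says the reduced cubic is
adequate relative to the replicate repeatability (5 pure-error df from the
quadruplicated centroid and two duplicated binary blends).

Find the blend that simultaneously minimizes droplet size, IC50 and both
colony counts:

```r
fits <- nanoemulsion_fits()   # the four default models
goals <- lapply(stats::setNames(names(fits), names(fits)),
                function(n) desirability_goal("minimize"))
optimize_desirability(fits, goals, grid_step = 0.005)
#> Desirability optimum on the simplex
#> Blend: EO_CU = 0.2120 (21.20%), EO_CA = 0.6182 (61.82%), EO_CO = 0.1699 (16.99%)
#> Overall desirability D = 0.9758
#>   d32_um: predicted 0.505 (d = 1.0000)
#>   ic50_mgml: predicted 6.87877 (d = 1.0000)
#>   bsubtilis_cfu: predicted 201041 (d = 0.9301)
#>   ecoli_cfu: predicted 1.91237e+06 (d = 0.9747)
```

A carvi-rich blend (~60% carvi oil, ~20% each cumin and coriander) achieves
overall desirability 0.98: the predicted droplet size and IC50 sit at their
observed minima (d = 1) and both bacterial counts near theirs. See the
`mixture-analysis` vignette for the model details and the reasoning behind
the defaults.

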