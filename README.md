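# dfareg

Scale-dependent bivariate regression via detrended fluctuation analysis
(DFA), for nonstationary time series — built for questions like *how
strongly does the PM2.5 concentration in one city depend on its two
neighbours, and over which time horizons?* A single OLS coefficient answers
that question once for the whole record; `dfareg` answers it at every time
scale.

## The model

For equal-length series, the bivariate regression

```
Y_t = β0 + β1·X1_t + β2·X2_t + ε_t
```

has the OLS solution expressible purely in (co)variances. DFA provides
scale-dependent replacements: the profile Z_t = Σ_{i≤t}(z_i − z̄) is split
into 2⌊N/n⌋ windows of length n (from both ends, so nothing is discarded),
an order-2 polynomial trend is removed per window, and averaged squared
residuals give the DFA variance F²_z(n); cross products of detrended
profiles give the DCCA covariance. Substituting into the OLS closed form,

```
β̂1(n) = [F²_{X1Y}(n)·F²_{X2}(n) − F²_{X2Y}(n)·F²_{X1X2}(n)] / [F²_{X1}(n)·F²_{X2}(n) − F²_{X1X2}(n)²]
```

(symmetrically for β̂2(n)), with per-scale coefficient variances, the
determination coefficient R²_DFA(n) = 1 − F²_ε(n)/F²_Y(n), standardized
coefficients β*_j(n) and elasticities η_j(n). Because the null spread of
the per-scale t-statistic varies with n, significance uses per-scale
Monte-Carlo critical curves t^c(n) and ρ^c_PDCCA(n) from shuffled
surrogates. Scale-dependent (partial) cross-correlations ρ_DCCA(n) and
ρ_PDCCA(n) are included, as are the simulators used for validation:
ARFIMA(0, d, 0) fractional noise, binomial multifractal cascades, and a
synthetic three-city PM2.5-like fixture.

## Worked example

```r
library(dfareg)

fx  <- gen_pm25_fixture(8000, seed = 42)          # three synthetic "cities"
fit <- dfa_fit(fx$beijing, fx$tianjin, fx$baoding,
               grid = scale_grid(10, 1000, 10))
fit
#> DFA-based bivariate regression (N = 8000, order-2 detrending, 10 scales)
#>  scale  beta1  beta2      var1      var2     r2
#>     10 0.4945 0.3001 0.0001723 7.579e-05 0.4992
#>     17 0.4813 0.3097 0.0001822 8.514e-05 0.4756
#>     28 0.5984 0.2625 0.0002117 9.344e-05 0.4745
#>     46 0.5053 0.3281 0.0002037 8.656e-05 0.4774
#>     77 0.5202 0.3437 0.0001946 7.349e-05 0.5279
#>    129 0.5906 0.3199 0.0002012 7.040e-05 0.5708
#>    215 0.4765 0.4208 0.0002530 8.608e-05 0.5784
#>    359 0.4609 0.4183 0.0002118 9.177e-05 0.5604
#>    599 0.4754 0.3451 0.0001858 7.436e-05 0.4799
#>   1000 0.6403 0.2032 0.0002188 8.318e-05 0.5301
```

Each row is the fitted regression *at that scale*: at n = 10 hours a unit
fluctuation of the first neighbour moves the response by ≈ 0.49 units, and
the two regressors jointly explain ≈ 50% of the response fluctuations
(`r2`). Significance against the per-scale shuffle null:

```r
cc <- critical_curve_t(fx$beijing, fx$tianjin, fx$baoding,
                       grid = scale_grid(10, 1000, 10),
                       n_shuffles = 200, seed = 1)
st <- scale_t_statistics(fit)
head(data.frame(scale = st$table$scale, t1 = round(st$table$t1, 1),
                critical = round(cc$table$critical, 2)), 3)
#>   scale   t1 critical
#> 1    10 37.7     3.49
#> 2    17 35.7     3.39
#> 3    28 41.1     4.91
```

t1 far exceeds t^c(n) at every scale — the dependence is significant
throughout (the critical value itself grows with n, which is why a single
t-table cutoff would be misleading). The partial cross-correlation at
n = 100, removing the third city, drops from the raw value as the shared
component is conditioned away:

```r
rho_dcca(fx$beijing, fx$tianjin, 100)                            #> 0.6466
rho_pdcca(list(fx$beijing, fx$tianjin, fx$baoding), 1, 2, 100)   #> 0.3075
```

A command-line interface over the same functions (subcommands `simulate`,
`fit`, `pdcca`, `test-t`, `test-pdcca`, `split-seasons`, `config`) ships at
`system.file("cli", "dfareg.R", package = "dfareg")`.

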