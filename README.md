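# leksim

Lek counts — tallies of birds on communal display grounds — are the
standard monitoring instrument for lekking grouse such as the lesser
prairie-chicken (*Tympanuchus pallidicinctus*). They observe only the
birds that attend a lek **and** get detected, so when attendance or
detection is below one, growth rates estimated from lek counts can tell a
very different story from the demographic trajectory of the whole
population. `leksim` is a virtual-ecologist toolkit for quantifying that
gap: it simulates the full population from female vital rates, simulates
the lek survey on top of it, analyses the simulated counts exactly as
field data would be analysed, and measures the bias of the results
against the simulated truth.

The package provides:

* an **individual-based demographic simulator** (age- and sex-structured;
  reproduction, mortality, aging) parameterised with literature-derived
  vital rates for lesser prairie-chickens, under which the expected
  per-female production is
  `F_j = [P·C1·S1j + (1−S1j)·R·C2·S2j] · φc · φjuv · 0.5 · H`
  and the population declines at roughly 0.72/yr;
* an **observation layer**: annual lek attendance by age/sex class
  (0.60/0.80 for SY/ASY males, 0.30 for females) or density-dependent
  male attendance `γ = min(1, K/N_male)` with lek carrying capacity
  `K = 25`, plus two within-year survey occasions with
  `Binomial(n_lek, p)` detection under six detection regimes;
* a **scenario engine** covering the 13 attendance-by-detection study
  designs (plus "N" variants analysed with the N-mixture model);
* two **Bayesian growth estimators** sharing the latent process
  `N[i,t] = N[i,t−1]·λ[i,t]`, `λ ~ Gamma(r, β)` with
  `r = λ̄²/σ²`, `β = λ̄/σ²`: a state-space model on per-site-year max
  counts (`y ~ Poisson(N)`) and an N-mixture model on the repeated
  counts (`y ~ Binomial(X, p)`, `X ~ Poisson(N)`), both fitted by a fast
  slice-within-Gibbs sampler written in C++;
* an **evaluation harness**: true growth rates from trajectories, bias
  `θ = λ̄_sim − λ̄_true`, abundance-overlap diagnostics, scenario-grid
  bias tables and parameter sweeps, with `tidy()`/`glance()` summaries
  and `autoplot()` figures throughout.

## Worked example

Simulate scenario 7 (age/sex lek attendance, fixed detection p = 0.5) at
a reduced scale, fit the uncorrected state-space model, and compare the
estimated long-term growth rate with the simulated truth:

```r
library(leksim)

cfg  <- scenario_config(7, n_sims = 1, n_sites = 100, n_years = 25, seed = 1)
sims <- run_scenario(cfg)
fit  <- fit_state_space(sims$counts, control = mcmc_control(), seed = 1)
tidy(fit)
#> # A tibble: 2 × 6
#>   term         estimate std.error conf.low conf.high  rhat
#>   <chr>           <dbl>     <dbl>    <dbl>     <dbl> <dbl>
#> 1 lambda_bar      0.711   0.00603    0.699     0.723  1.03
#> 2 sigma_lambda    0.205   0.0108     0.185     0.226  1.06

truth <- dplyr::filter(sims$truth, simulation == 1)
lambda_true(truth)
#> [1] 0.6733938
bias(lambda_bar_sim(fit), lambda_true(truth))
#> [1] 0.03780564
```

The fitted `λ̄ ≈ 0.71` says the counts *do* reveal a steep decline (the
95% credible interval is far below 1), but the estimate still sits about
0.04 above the per-site geometric-mean truth of 0.67: halving the counts
with `p = 0.5` hides none of the trend, yet small-count noise and
imperfect observation leave a positive bias. Scenario-wide comparisons
(`scenario_bias_study()`) and detection/carrying-capacity sweeps
(`sensitivity_sweep()`) extend this to the full design grid, and
`autoplot()` on any result draws the corresponding figure.

A thin command-line front end is installed with the package
(`exec/leksim`) with `simulate`, `fit`, `evaluate` and `reproduce`
subcommands over the same functions.

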