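# radhab

Radiolytic dose modelling and microbial survival analysis for deep
subsurface brines, together with the genome-annotation summaries used
alongside such analyses.

## Who it is for

Geomicrobiologists asking whether a long-isolated, radionuclide-enriched
fluid system is habitable face two coupled questions. Radiolysis of pore
water by U/Th/K decay continuously produces H2, H2O2, OH radicals and,
secondarily, O2 — substrates that can fuel a microbial community with no
surface input. The same radiation accumulates as damage in any cell that is
not actively repairing, so a dormant population is inactivated once its
accumulated dose crosses a lethal threshold. `radhab` quantifies both
sides, and additionally implements the annotation/QC bookkeeping used to
characterise the genomes recovered from such fluids (module completeness,
presence calls, genus aggregation, composition, retention filters).

## The model at the core

For a scenario with absorbed dose rate *Ḋ* (Gy/yr) and particle-mix
fractions *f_p*, the biologically weighted rate is

    Ḋ_eff = Ḋ (f_α w_α + f_β w_β + f_γ w_γ)   [Gy-eq/yr]

with configurable weights (default w_α = 20, w_β = w_γ = 1). Survival under
dose follows single-hit log-linear inactivation with decimal-reduction dose
D10: `log10 S = −D / D10`. The accumulated dose leaving a surviving
fraction *f* is `D10 · log10(1/f)` — six decades (`6 × D10`) for the 10⁻⁶
convention — and the time to inactivation of a dormant population is

    t_inact = D_threshold / Ḋ_eff .

Radiolytic species production uses G-values (molecules per 100 eV):
`P = (G/100) · Ḋ · ρ · (6.2415×10¹⁸ eV/J) / N_A` in mol L⁻¹ yr⁻¹.

## Worked example

The packaged reference analysis: three organisms spanning the
radiotolerance range (10⁻⁶-survival thresholds 1000 Gy for *E. coli*,
8400 Gy for *B. subtilis*, 15 000 Gy for *D. radiodurans*) under two site
dose rates (0.02 and 0.3 Gy/yr) and three particle mixes.

```r
library(radhab)
library(dplyr)

st <- survival_table(reference_thresholds(), reference_scenarios())
format_survival_table(st) |>
  select(organism, scenario, effective_rate_gy_eq_yr, time_yr_2sf)
#> # A tibble: 18 × 4
#>    organism       scenario             effective_rate_gy_eq_yr time_yr_2sf
#>  1 E. coli        west_rand_low_gamma                     0.02 50 000
#>  2 B. subtilis    west_rand_low_gamma                     0.02 420 000
#>  3 D. radiodurans west_rand_low_gamma                     0.02 750 000
#>  4 E. coli        west_rand_low_alpha                     0.4  2 500
#>  ...
#> 13 E. coli        vaal_reef_high_alpha                    6    170
#> 15 D. radiodurans vaal_reef_high_alpha                    6    2 500
#> 18 D. radiodurans vaal_reef_high_mixed                    3.15 4 800
```

Reading it: under the low-dose pure-gamma scenario the most radioresistant
organism survives up to 750 000 years before its accumulated dose reaches
15 000 Gy, while alpha-dominated delivery at the high-dose site inactivates
everything within a few thousand years. Times assume dormant,
non-repairing cells — actively repairing populations survive longer.

Fitting your own survival curve and extrapolating:

```r
curve <- tibble::tibble(dose_gy = c(0, 1000, 2000, 3000),
                        surviving_fraction = c(1, 0.19, 0.041, 0.0078))
fit <- fit_loglinear(curve)
fit
#> Log-linear inactivation fit
#>   D10: 1425.75 Gy  (slope -0.0007014 per Gy, intercept fixed at 0)
#>   R-squared: 0.9999 over 4 points
dose_to_fraction(fit$d10_gy, 1e-6)
#> [1] 8554.499
```

Radiolytic species production at the high-dose site:

```r
radiolytic_production(0.3) |> head(3)
#> # A tibble: 3 × 3
#>   species g_value production_mol_per_l_yr
#> 1 H2         0.45            0.0000000140
#> 2 H2O2       0.68            0.0000000211
#> 3 OH         2.7             0.0000000840
```

The annotation side (completeness scoring, presence calls, genus
aggregation, composition, QC filters) and the seeded synthetic-data
generators are covered in the vignette
(`vignettes/radiolytic-habitability.Rmd`).

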