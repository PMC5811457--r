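# stoichdemo

Demographic and stoichiometric analysis of phosphorus-supplementation
feeding trials on planktonic grazers.

## The problem

Phosphorus-limited algae are poor zooplankton food for two separable
reasons: a **direct, stoichiometric** one (too little P per unit C in the
diet) and **indirect, non-stoichiometric** ones (the biochemical and
morphological consequences of a P-limited growth history, which persist
even after the elemental deficit is repaired). A three-arm
P-supplementation design separates them:

| Arm | Food | Molar C:P |
|-----|------|-----------|
| HP  | algae grown P-replete | ≈ 112 |
| LP  | algae grown P-limited | ≈ 631 |
| LP+P | P-limited algae spiked with phosphate just before feeding | ≈ 113 |

LP+P food has HP's elemental composition but LP's growth history, so for
any trait with treatment means \(\bar y\):

    indirect (%) = 100 · (ȳ_LP+P − ȳ_HP) / ȳ_HP      (non-stoichiometric)
    direct   (%) = 100 · (ȳ_LP − ȳ_LP+P) / ȳ_LP+P    (stoichiometric)

which compound exactly to the total LP/HP response. Mortality-type traits
are decomposed on survival = 1 − mortality so a zero-mortality baseline
stays well-defined.

The package covers the whole pipeline for a rotifer
(*Brachionus calyciflorus*) trial: an individual-based synthetic-data
generator matching the design (3 treatments × 5 chemostat replicates × 15
individuals checked every 2 h; 45 serial-transfer census units; 75
morphometric units; pooled elemental samples), validated CSV readers and
writers, age-classed survivorship/fecundity schedules from
interval-censored event logs, the intrinsic rate of increase from the
Euler–Lotka equation `1 = Σ lx·mx·e^(−r·x)` (bracketed bisection),
exponential growth rates `R = (ln Nt − ln N0)/t` from daily census
ratios, ellipsoid body/egg volumes and somatic growth, molar C:N:P
ratios, and the direct/indirect decomposition with replicate-level
bootstrap intervals. See `vignettes/stoichdemo-methods.Rmd` for the full
methods account.

## Worked example

```r
library(stoichdemo)

log <- simulate_individuals(seed = 42)   # 225 individuals, full design
mortality_summary(log)
#>   treatment n_individuals n_deaths eggs_resolved eggs_died
#> 1 HP                   75        0           277         0
#> 2 LP                   75        6           125        36
#> 3 LP+P                 75        3           264         0
#> # plus individual_mortality_pct (0, 8.0, 4.0) and egg_mortality_pct (0, 28.8, 0)
```

Six deaths among 75 LP individuals is the 8.0% individual mortality the
design builds in; LP eggs die at the configured ~23% rate (28.8% in this
draw), and no HP or LP+P eggs die.

```r
fit <- euler_lotka_r(build_schedule(dplyr::filter(log, treatment == "HP")))
fit
#> Euler-Lotka intrinsic rate of increase
#>   r  = 1.153176 per day
#>   R0 = 6.3114;  mean generation time = 1.657 days
#>   residual 3.20e-11 after 35 bisection steps
```

A pooled HP schedule implies a population multiplying e^1.15 ≈ 3.2-fold
per day with ~6.3 daughters per female. Per-replicate rates
(`intrinsic_rates(log)`) recover the designed ordering — HP 1.11 d⁻¹,
LP+P 0.84 d⁻¹, LP 0.10 d⁻¹ (the LP value is depressed by its 62-h
monitoring horizon and flagged `truncated`).

```r
res <- decompose_effects(0, 0, 0.231, trait = "egg mortality", mortality = TRUE)
tidy(res)
#>   trait         component contrast   relative_difference_pct scenario
#> 1 egg mortality indirect  (LP+P)-HP                      0        I
#> 2 egg mortality direct    LP-(LP+P)                    -23.1      I
```

Egg mortality of 0%, 0%, 23.1% across HP, LP+P, LP decomposes (on the
survival scale) into no indirect effect and a −23.1% direct effect:
scenario I, a purely stoichiometric response. `run_pipeline()` chains all
stages for a full trial and `autoplot()` methods draw schedules and
decompositions; `inst/cli/stoichdemo.R` exposes the same steps as shell
subcommands.

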