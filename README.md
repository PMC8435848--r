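# bicompete

Simulation and inference for semi-continuous bi-algal competition
experiments between a marine diatom (*Phaeodactylum tricornutum*) and a
dinoflagellate (*Prorocentrum minimum*).

Experiments of this kind grow monocultures and bicultures across a
factorial design — three temperatures (12, 18, 24 °C), three nutrient
concentration levels and three N:P molar supply ratios (10:1, 24:1, 63:1),
in triplicate — first as batch cultures, then semi-continuously: every day
a fraction `D = 1 − exp(−μt)` of the 200-mL culture is replaced with fresh
medium, with the gross growth rate pinned at `μ = 0.2 μ_max` and renewal
interval `t = 1` d. The question is who outcompetes whom, where, and how
the community's chemical composition tracks the shift.

`bicompete` provides the full analysis path:

* **Dynamics.** Competitive Lotka–Volterra model
  `dN1/dt (1/N1) = r1 (K1 − N1 − α N2)/K1` (and symmetrically with β),
  integrated with a compiled fixed-step RK4 scheme and instantaneous daily
  dilution events (`simulate_batch`, `simulate_semicontinuous`).
* **Inference.** Monoculture `μ_max` from the most log-linear window,
  logistic `(r, K)` by nonlinear least squares, daily per-capita rates
  `g = Δlog N − log(1 − D)` corrected for dilution losses, and a
  closed-form least-squares estimate of the interaction coefficients α and
  β with iteratively refined within-day density averages and
  error-propagated standard errors (`fit_logistic_mono`,
  `per_capita_rates`, `estimate_interaction`). α > 0 means dinoflagellate
  competitive superiority, α < 0 diatom.
* **Composition.** Molar POC/PON and PON/POP, fatty-acid ratios
  16:1n-7/16:0 and EPA/DHA, the sterol index B/(B+D) =
  brassicasterol/(brassicasterol + dinosterol), carbon-normalized lipid
  contents, and >5%-of-total fatty-acid screening (`composition_indices`).
* **Statistics.** Fixed-effects GLMs with AICc model selection (10-unit
  rule with a significant-interaction exception), univariate
  smoothing-spline partial effects with GCV and response amplitudes, and
  OLS regressions of composition indices against community structure
  (`select_glm`, `fit_gam_1d`, `response_amplitude`, `ols_regression`).
* **Synthetic data.** A generator that emulates the complete factorial
  experiment — batch-then-semi-continuous protocol, Poisson hemocytometer
  counting noise, lognormal process/chemistry noise, species-specific
  elemental and lipid signatures — with a documented ground truth, so every
  stage is testable end to end (`generate_experiment`, `write_fixture`).

## Worked example

```r
library(bicompete)

report <- run_pipeline(pipeline_config(seed = 1, days_semi = 20))
print(report)
#> Competition-pipeline report
#>   interaction estimates: 81 bicultures (0 excluded records)
#>   superiority:  diatom 52, dinoflagellate 29
#>   pon_pop ~ log10_diatom_dino_ratio: slope -0.908 (p = 2.54e-05, n = 81)
#>   r_16_1_16_0 ~ log10_diatom_dino_ratio: slope 0.2682 (p = 2.68e-13, n = 81)
#>   epa_dha ~ log10_diatom_dino_ratio: slope 0.7094 (p = 3.55e-13, n = 81)
#>   b_over_bd ~ diatom_fraction: slope 3.116 (p = 4.29e-66, n = 81)
```

This generates one synthetic 27-treatment × 3-replicate experiment at the
default noise levels, fits monoculture growth curves, estimates α and β for
all 81 bicultures, and runs the statistical layer. The printout shows the
competitive-superiority tally across the design (diatoms win mostly at high
nutrient concentrations, dinoflagellates at low) and the four
composition-community regressions: nitrogen-to-phosphorus stoichiometry
falls, while the diatom-marker lipid ratios and the sterol index rise, as
the community shifts toward the diatom — each with its slope, p-value and
sample size.

Single pieces work standalone:

```r
p <- community_params(r_diatom = 0.9, r_dino = 0.45,
                      K_diatom = 100, K_dino = 30,
                      alpha = 0.5, beta = 0.3)
traj <- simulate_semicontinuous(p, n0_diatom = 50, n0_dino = 5,
                                D = renewal_rate(0.2 * 0.9), days = 25)
series <- per_capita_rates(traj)
head(series, 2)
#>   day species per_capita_rate n_diatom   n_dino n_diatom_start n_dino_start
#> 1   0  diatom       0.3338081 59.35673 5.256765       50.00000     5.000000
#> 2   1  diatom       0.2681500 66.88002 4.784158       58.31335     4.612507
```

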