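# bppfit

Analysis of solid-state ¹H NMR relaxometry for small-molecule drugs:
extraction of spin–lattice relaxation times T₁ from saturation-recovery
curves, and fitting of multi-motion Bloembergen–Purcell–Pound (BPP)
relaxation models with Arrhenius correlation times to T₁(T) series to
recover the activation parameters of internal molecular motions. The
package was built around the radiation-sterilization stability assessment
of crystalline magnolol (MAG) and honokiol (HON) and also ships the small
stability metrics used in such studies (encapsulation efficiency, EPR
amplitude decay, relative content with propagated uncertainty,
degradation peak-area fractions).

It is aimed at people who run low-field solid-state relaxometry (here
25 MHz, 80–300 K) and want a reproducible, tested pipeline from tabulated
magnetization recoveries to activation parameters with honest
uncertainties.

## The model

Each thermally activated motion *k* is described by a pre-exponential
correlation time τ₀ₖ (s), an activation energy E_aₖ (kJ/mol), and the
second-moment reduction ΔM₂ₖ (G²) it averages out. Contributions add:

    1/T₁ = (2/3) γ² Σₖ ΔM₂ₖ [ τ_ck / (1 + ω₀²τ_ck²) + 4τ_ck / (1 + 4ω₀²τ_ck²) ]
    τ_ck = τ₀ₖ · exp(E_aₖ / RT)

Fitting minimizes squared residuals in ln T₁ (T₁ spans orders of
magnitude over 80–300 K) over (log₁₀τ₀, E_a, log₁₀ΔM₂) per motion, by
seeded Latin-hypercube multi-start Levenberg–Marquardt plus a
basin-hopping polish. Uncertainty comes from a parametric residual
bootstrap. A synthetic-data generator (forward model + 10% lognormal
measurement noise) supports end-to-end parameter-recovery validation.

## Worked example

```r
library(bppfit)

# Reference activation parameters for unirradiated magnolol
mag0 <- reference_model("mag_0kGy")
mag0
#> <relaxation_model>  3 motion(s) at 25 MHz
#>   [1] tau0 = 4.45e-12 s   Ea = 12.77 kJ/mol   dM2 = 0.036 G^2
#>   [2] tau0 = 2.12e-14 s   Ea = 19.55 kJ/mol   dM2 = 0.11 G^2
#>   [3] tau0 = 5.83e-14 s   Ea = 9.66 kJ/mol   dM2 = 0.003 G^2

# Where does the dominant motion put its T1 minimum at 25 MHz?
m <- t1_minimum(motion(2.12e-14, 19.55, 0.110))
round(m$temperature, 1); round(m$t1_min, 3)
#> [1] 193.9
#> [1] 2.1

# Fit a noisy saturation-recovery curve (2% additive noise)
cv <- simulate_recovery_curve(1, 1.74, noise_sd = 0.02, seed = 7,
                              temperature = 194)
f <- fit_saturation_recovery(cv)
round(c(m0 = f$m0, t1 = f$t1), 4)
#>     m0     t1
#> 1.0256 1.7136

# Simulate a 30-point T1(T) series at 10% measurement uncertainty
# and fit the three-motion model back
s   <- simulate_t1_series(mag0, noise_cv = 0.10, seed = 42)
fit <- fit_bpp(s, k = 3, n_starts = 64, seed = 42)
fit
#> <bpp_fit>  k = 3, sse(log T1) = 0.289, 64/64 starts converged
#>      tau0_s ea_kJ_per_mol   dm2_G2
#> 1 1.416e-12        14.018 0.081830
#> 2 7.803e-16        23.697 0.060092
#> 3 6.714e-14         9.528 0.002754
```

One replicate at 10% noise scatters; `run_recover()` repeats the
simulate→fit→match cycle over seeded replicates and reports per-motion
median recovered parameters, which is how the package validates itself
(medians land within 10% of the generators for identifiable motions).

A thin command-line front end with the same functionality ships at
`inst/cli/bppfit` (subcommands `simulate-series`, `simulate-recovery`,
`fit-recovery`, `fit-bpp`, `recover`, `stability`).

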