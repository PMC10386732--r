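# hydrolysim

Semi-mechanistic kinetic modelling of batch enzymatic hydrolysis of
pretreated sugarcane bagasse.

Producing fermentable sugars from lignocellulose requires pretreating
the biomass and then saccharifying it enzymatically; designing and
scaling those reactors requires a kinetic model that captures how the
enzymes, the substrate and the released sugars interact over a 72-hour
batch. `hydrolysim` implements such a model for hydrothermally
pretreated ("HB", lignin-rich) and organosolv-pretreated ("OB",
delignified) bagasse at 4–12% w/v solids loadings, together with the
machinery to estimate its parameters, screen their influence, and
generate synthetic assay data. It is aimed at bioprocess modellers and
at anyone who needs a tested reference implementation of this model
family.

## The model

Five states (mg/mL): cellulose C, cellobiose G₂, glucose G, xylan Xₙ,
xylose X. Mass balances:

    dC/dt  = −r₁ − r₃          dXₙ/dt = −r₄
    dG₂/dt = 1.056 r₁ − r₂     dX/dt  = 1.136 r₄
    dG/dt  = 1.053 r₂ + 1.111 r₃

with Michaelis–Menten rate laws under competitive product inhibition:

    r₁ = k₁ᵣ E₁bC C e^(−λt) / (1 + G₂/K₁iG₂ + G/K₁iG + X/K₁iX)
    r₂ = k₂ᵣ E₂f G₂ / (K₂m (1 + G/K₂iG + X/K₂iX) + G₂)
    r₃ = k₃ᵣ E₁bC C e^(−λt) / (1 + G₂/K₃iG₂ + G/K₃iG + X/K₃iX)
    r₄ = K₄ Xₙ/(1 + X/K₄iX) · Xₙ/(k_S + Xₙ),   K₄ = k₄ E₃/(K_eq + E₃)

The cellulose-bound cellulase E₁bC comes from a Langmuir isotherm whose
capacity and affinity evolve with cellulose conversion
(`exp(a + bX% + cX%²)`), with optional non-productive adsorption on
lignin; the surface-decay rate λ is constant for delignified bagasse
and follows a Hill law in lignin concentration,
λ(L) = λ_max Lⁿ/(kⁿ + Lⁿ), for lignin-rich bagasse. Parameters are
estimated from concentration profiles by a Pikaia-style real-coded
genetic algorithm minimising maximum-normalised squared residuals, and
a 20-run Plackett–Burman design screens the time-resolved influence of
all 17 kinetic parameters. The methods vignette
(`vignettes/hydrolysis-kinetics.Rmd`) documents the model, the
numerical choices and the design decisions in detail.

## Worked example

Simulate the 10% w/v hydrothermal assay with the shipped fitted
parameter set:

```r
library(hydrolysim)
assay <- load_assay("HB", 10)   # Tables of batch conditions ship as YAML fixtures
params <- load_params("HB")
traj <- simulate_assay(assay, params)
traj
#> Hydrolysis trajectory: HB 10% w/v, 15 report times to 72 h
#>   final (mg/mL): C=24.338 G2=0.000 G=40.812 Xn=0.0161 X=2.3674
#>   cellulose conversion 60.1%, xylan conversion 99.2%
```

The final state says: 60% of the cellulose was hydrolysed (product
inhibition and surface decay stop it there), the cellobiose
intermediate has fully drained into glucose, and the small xylan pool
is almost exhaustively converted (99.2% of its theoretical xylose).

Recover the lignin law of the surface-decay rate from (lignin, λ)
pairs:

```r
L <- seq(5, 40, by = 5)
fit_hill(L, lambda_of_lignin(L, lambda_hill(0.1817, 9.45, 18.354)))
#> Hill surface-decay fit: lambda_max=0.1817 1/h, n=9.45, k=18.354 mg/mL (R^2=1.0000)
```

Screen parameter influence at the reference conditions:

```r
des <- pb_design(params, rel_width = 0.10, lignin = assay$L0)
des
#> Plackett-Burman design: 20 runs, 17 factors, 2 dummy column(s), level width 10%
eff <- classify_effects(pb_effects(des, assay))
head(influence_table(eff)[order(-influence_table(eff)$peak_effect), ], 4)
#>    species factor peak_effect class
#> 38       G lambda    2.092834 great
#> 33       G    k3r    1.987696   low
#> 19       C lambda    1.883630   low
#> 30       G   K3iG    1.866871   low
```

λ, k₃ᵣ and K₃iG dominate the cellulose and glucose responses — the
glucose route through r₃ and the surface-decay term carry the
sensitivity, while the cellobiose-route constants only matter for the
transient G₂ pool.

Fit free parameters to (synthetic or measured) profiles:

```r
prof <- generate_profiles(assay, params, noise_model(rel = 0.05, seed = 7))
spec <- objective_spec(list(list(assay = assay, profile = prof)),
                       params, free = c("k3r", "K3iG", "lambda"))
fit <- fit_ga(spec, ga_config(pop_size = 50, generations = 60, seed = 1))
coef(fit); summary(fit)   # per-profile RSDs in percent
```

A command-line front end over the same functions ships in
`inst/cli/hydrolysim.R` (subcommands `simulate`, `generate`, `rsd`,
`pb`, `fit`; each run writes a JSON manifest for reproducibility).

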