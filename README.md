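# lacferm

Kinetic modelling of pH-regulated lactic acid production by
*Lactobacillus delbrueckii* subsp. *bulgaricus*.

Post-acidification — the continued production of lactic acid by
*L. bulgaricus* during cold storage — spoils yogurt, and the usual fixes
either fail or kill the culture. A synthetic-biology alternative keeps the
metabolism intact and instead drives a *lacR* repressor gene from a
pH-induced promoter (such as rcfB): when fermentation has acidified the
milk to the promoter threshold, LacR accumulates, binds upstream of the
*lacSZ* operon, and shuts down further synthesis of lactose permease and
beta-galactosidase. `lacferm` is for modellers and strain designers who
want to size that switch before building it.

## The model

Eleven ODEs couple lactose metabolism, gene regulation and growth:
Michaelis–Menten reversible lactose transport, hydrolysis, lumped
glycolysis (2 pyruvate per glucose) and lactate dehydrogenase, with 80 %
of the LDH flux appearing as lactic acid; Monod growth with linear product
inhibition,

    mu = mu_max * LAC_out/(LAC_out + Ks) * (1 - LA/K_LA);

transcription of *lacR* at `(V0 + V1 * F(pH)) * GR` with the smoothed
promoter switch

    F(pH) = 1 - tanh(n * (pH - 5.5)),

equal to 1 at the threshold and saturating at 2 in acid; *lacSZ*
transcription `V2*G` repressed by `T_max * S*LR/(1+S*LR) * G`; LacR–lactose
binding `Kb * LR * LAC_in`; and medium pH slaved to lactic acid through the
milk buffering quadratic `pH = c0 - c1*LA + c2*LA^2`. A wild-type variant
(constitutive *lacSZ*, no *lacR*) drops the repressor circuit. All rate
constants default to published values; `V2` is the one fitted parameter.

The package provides batch simulation (stiff deSolve integration with a
compiled right-hand side), calibration (`fit_V2`, `fit_pH_curve`), local
and Sobol sensitivity analysis of the lactic-acid output (hand-rolled
Saltelli scheme, validated against the Ishigami function), the two-level
promoter/RBS scenario study, synthetic-data generators with known ground
truth, and an `Rscript` command-line front-end
(`inst/scripts/lacferm_cli.R`).

## Worked example

Calibrate `V2` on a synthetic wild-type fermentation (batch at 43 °C
emulated conditions: 0.117 M lactose, sampled every 2 h over 8 h, 2 %
measurement noise), then compare promoter strengths:

```r
library(lacferm)

d <- generate_fermentation_data(seed = 42)   # ground truth V2 = 3.5 1/h
fit <- fit_V2(d$data)
fit
#> Wild-type calibration of the basal lacSZ transcription rate
#>   V2 = 3.517 1/h  (bounds 0.1-50)
#>   R^2 lactose = 0.9977, R^2 lactic acid = 0.9964

run_two_level("V1")
#> Two-level scenario: V1 at 10.5 vs 21 1/h (+ wild-type)
#>      level value   final_LA final_pH pH_cross_time_h lactose_consumed t_end
#>        low  10.5 0.08230751 4.927856        4.251038       0.04140229     8
#>       high  21.0 0.06403453 5.286184        5.338156       0.03226682     8
#>  wild_type    NA 0.11033622 4.417153        3.604429       0.05541517     8
```

The fit recovers the generating transcription rate to half a percent with
R² above 0.996 on both observables. In the scenario study the wild type
reaches 0.110 M lactic acid (pH 4.42) in 8 h; the engineered strain with a
moderate promoter (`V1 = 10.5` 1/h) stops at 0.082 M, and doubling the
promoter strength cuts the titre to 0.064 M and holds the final pH at
5.29 — the repressor switch trips where the pH series crosses 5.5
(`pH_cross_time_h`). Final pH values are conditional on the package's
milk-buffering constants (see the methods vignette); fit your own
titration with `fit_pH_curve()` to replace them.

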