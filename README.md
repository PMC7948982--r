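# halokin

Transient-kinetics simulation and analysis of flavin-dependent halogenase
(FDH) catalysis, built around tryptophan 6-halogenase (Thal) as the model
system. The package is for enzymologists who study two-component flavin
monooxygenases with stopped-flow and rapid-quench instruments and want a
tested, seeded, end-to-end harness for the standard analyses: phase
fitting, halide saturation, branching budgets, inactivation kinetics and
transition-state-theory ordering.

## The model

The catalytic cycle is a branched mass-action scheme. Reduced flavin binds
the enzyme (`k_bind`), and the active complex either isomerizes to a
dead-end form (`k_inact`) or reacts with O2 (`k_ox·[O2]`) to form
C4a-hydroperoxyflavin (C4aOOH-FAD). That intermediate partitions between
uncoupling to FAD + H2O2 (`k_unc`) and reaction with halide to give
C4a-hydroxyflavin (C4aOH-FAD) plus hypohalous acid (HOX), with
rapid-equilibrium halide binding lumped as

    kobs = k_hox · [X] / (Kd + [X])

C4aOH-FAD dehydrates to FAD (`k_dehyd`); nascent HOX is either captured by
bound tryptophan (`k_capture`) or leaks to bulk (`k_leak`). The flux
partition at the C4aOOH node,

    f_unc = k_unc / (k_unc + kobs),   coupling_ratio = f_hox · f_capture,

connects the phase amplitudes, the single-turnover product yield, and the
HOX-leakage budget. O2 and halide are non-depleting baths; fluoride is a
valid input with identically zero HOX flux. A Gillespie sampler over the
same reaction network provides the stochastic oracle, and a closed-form
two-step chain solution the analytic one.

Because no raw instrument data are deposited for this system, a seeded
generator emulates the experiments with the published rate constants as
ground truth; every analysis is a generate-and-recover loop with stated
tolerances. See `vignettes/halogenase-kinetics.Rmd` for the full model
description and the reasoning behind each numerical choice.

## Worked example

Simulate the halide-free oxygen reaction, read out the 380-nm channel, and
ask how many kinetic phases it carries and how fast they are:

```r
library(halokin)
truths <- thal_truths()

a380 <- generate_trace(truths$halide_free_trace, "A380",
                       noise = noise_model(0))
n <- select_phase_count(a380, 3)
fit <- fit_exponentials(a380, n)
fit$phases$kobs
#> [1] 16.52  0.41
```

Two phases: C4aOOH-FAD formation at 16.52 s^-1 and its H2O2-eliminating
decay at 0.41 s^-1. The same loop over the halide-saturation experiment
(`analysis/03_halide_saturation.R`) refits the two-step (Kd, k) model for
each halide:

```
I   Kd = 0.064 mM, k = 4.51 s^-1
Br  Kd = 0.40  mM, k = 2.54 s^-1
Cl  Kd = 0.78  mM, k = 1.83 s^-1
```

so iodide binds tightest and reacts fastest, and the measured rate order
HOI > HOBr > HOCl is perfectly anti-correlated with the computed barriers
(1.3, 5.7, 12.6 kcal/mol; `analysis/06_energetics.R` prints the rank
correlation of -1). The partition analysis
(`analysis/04_partition_budgets.R`) shows the single-turnover plateau at
400 s equal to the analytic coupling product (0.30 with 80% HOX formation
and 37.5% capture - i.e. ~63% of the HOX formed escapes as free HOX), and
the double-mixing analysis (`analysis/05_inactivation.R`) recovers the
0.41 s^-1 isomerization rate of the inactive-complex pathway.

The numbered scripts under `analysis/` run these analyses end to end and
write their tables to `results/`.

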