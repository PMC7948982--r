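---
title: "Transient kinetics of flavin-dependent halogenase catalysis with halokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient kinetics of flavin-dependent halogenase catalysis with halokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halokin)
```

## The kinetic problem

Flavin-dependent halogenases (FDHs) such as tryptophan 6-halogenase (Thal)
halogenate aromatic substrates through a two-site relay: reduced FAD
(FADH^-^) delivered by a partner reductase binds the halogenase, reacts
with O~2~ to form C4a-hydroperoxyflavin (C4aOOH-FAD), and that intermediate
either reacts with a halide ion X^-^ to release hypohalous acid (HOX) and
leave fluorescent C4a-hydroxyflavin (C4aOH-FAD), or decays nonproductively
to FAD and H~2~O~2~ (uncoupling). Nascent HOX is then either guided to the
tryptophan site (capture, yielding halo-tryptophan) or escapes to bulk
solution (leakage). Two further branches limit the enzyme: anaerobic aging
of the enzyme:FADH^-^ complex isomerizes it to a dead-end form that cannot
make C4aOOH-FAD, and fluoride binds the cycle nowhere productively — its
HOX-formation rate is identically zero.

`halokin` implements this branched scheme as a mass-action ODE system,
maps species to stopped-flow observables, and provides the fitting
machinery that turns synthetic (or real) traces back into rate constants.
Because no raw instrument data are deposited for this chemistry, the
package ships a seeded generator whose default truths are the published
kinetic constants; every analysis is a closed generate-and-recover loop.

## The reaction scheme and its assumptions

States (µM): free enzyme and FADH^-^, the active complex E:FADH^-^, the
inactive isomer E:FADH^-^*, C4aOOH-FAD (plus its halide complex in
explicit-binding mode), C4aOH-FAD, FAD species, nascent/free HOX, H~2~O~2~,
Trp and halo-Trp, and a leaked-HOX trap counter. Reactions:

| step | rate | meaning |
|---|---|---|
| E + FADH^-^ → E:FADH^-^ | `k_bind_flavin` (µM^-1^ s^-1^) | flavin binding |
| E:FADH^-^ → E:FADH^-^* | `k_inact` (s^-1^) | dead-end isomerization |
| E:FADH^-^ + O~2~ → C4aOOH | `k_ox`·[O~2~] | oxygenation (O~2~ a fixed bath) |
| C4aOOH → FAD + H~2~O~2~ | `k_unc` | uncoupling |
| C4aOOH + X^-^ → C4aOH + HOX | `k_hox`·[X]/(K~d~+[X]) | rapid-equilibrium lumping |
| C4aOH → FAD | `k_dehyd` | dehydration |
| HOX → TrpX | `k_capture` | enzyme-guided halogenation |
| HOX → bulk | `k_leak` | leakage |

Assumptions, each a deliberate design choice:

* **Non-depleting baths.** O~2~ (128 µM air-saturated) and halide (mM
  range) vastly exceed flavin (≤ 15 µM), so both are held constant and all
  their steps are pseudo-first-order.
* **All flavin starts bound.** Enzyme (30 µM) exceeds FADH^-^ (15 µM) in
  the emulated experiments, so free-flavin autoxidation is omitted and
  single-mixing simulations start from the E:FADH^-^ complex.
* **Rapid-equilibrium halide binding** is the default, matching the
  hyperbolic k~obs~ analysis. An explicit two-step mode (finite on/off
  rates consistent with the same K~d~, default `kon = 1000/Kd` mM^-1^
  s^-1^) exists for sensitivity checks; in it, uncoupling acts on the
  halide-bound pool as well, so the two modes agree in the
  rapid-equilibrium limit at any halide concentration.
* **Memoryless HOX partition.** Only end-point capture/leak budgets are
  measurable, so HOX transfer is modelled as first-order competition
  `k_capture` vs `k_leak` with no transfer kinetics or tunnel geometry.
  The defaults (37.5 / 62.5 s^-1^) fix the capture fraction at 0.375 —
  the value implied by an 80% HOX yield and a 30% coupling ratio — on a
  fast (100 s^-1^) timescale that does not distort the turnover kinetics.
* **Fluoride** is accepted everywhere and routed to zero HOX flux.

Integration uses `deSolve::lsoda` (stiff-capable) at rtol 1e-8, atol
1e-10 µM; round-off negatives are clipped to zero on output only. Total
flavin is conserved to a relative 1e-6 on every simulation, and the linear
sub-chain E:FADH^-^ → C4aOOH → FAD is checked against the closed-form
two-step solution ([closed_form_chain()]) at the same tolerance. A
Gillespie direct-method sampler over the identical reaction table provides
the stochastic oracle for all branching fractions.

## Population-partition mode

With the tabulated chloride constants, flux competition predicts an
uncoupled fraction of `0.41/(0.41+1.70) ≈ 0.19` at 10 mM Cl^-^, yet the
measured phase-2 share of the 450-nm rise is ~55% for Cl^-^ (and ~20% for
Br^-^). The mechanistic origin of that discrepancy is unresolved, and the
package does not guess: alongside plain flux competition it offers a
*population-partition* mode (`f_unc_pop`) in which a fixed fraction of
complexes commits to the uncoupling branch at the oxidation step. The
generator uses that mode (with `f_unc_pop = 0.55`) when emulating the
chloride amplitude experiment, and `amplitude_partition()` recovers the
committed fraction from the synthetic A450 trace.

## Optical readout

`species_to_trace()` applies a linear Beer–Lambert readout at 380/450 nm
and a linear fluorescence brightness for the long-pass emission channels.
No extinction coefficients for enzyme-bound C4a adducts have been
published, so the defaults are literature-typical placeholders (FAD
ε~450~ = 11.3, ε~380~ = 6.0; C4aOOH ε~380~ = 8.0; C4aOH ε~380~ = 7.5
mM^-1^ cm^-1^; C4aOH fluorescence brightness 1.0 with all other flavins at
0.02). Two choices matter and are deliberate:

* both C4a adducts carry the same small ε~450~ (0.8): their 450-nm
  chromophores are nearly identical, and equal coefficients keep the
  450-nm channel a clean reporter of FAD regeneration, so phase-amplitude
  fractions track population fractions rather than spectral bleed-through;
* non-C4aOH fluorescence brightness is kept at 2% of C4aOH so the
  fluorescence-rise k~obs~ is not biased by the co-decaying
  C4aOOH pools.

Every recovered quantity in the package depends on rate constants and
*relative* amplitudes, never on the absolute coefficient scale;
fluorescence is reported in arbitrary units and never compared across
detector settings.

## Fitting machinery

**Multi-exponential fits** (`fit_exponentials()`) use variable projection:
at fixed rates the model is linear in offset and amplitudes, so only the
log-rates are optimized (Nelder–Mead plus a BFGS polish), from 20
deterministic starts log-spaced across `[1/t_end, 1/t_min]` — exponential
sums are notoriously multi-modal and a single start is not trustworthy.
Standard errors come from the Jacobian-based covariance at the optimum.
Two rates within 5% of each other set an `ill_conditioned` flag. On
noise-free single-exponential input the recovered k~obs~ is within 0.1% of
truth (tested).

**Phase counts** (`select_phase_count()`) minimize small-sample-corrected
AIC over 1..`max_n` phases. The residual variance entering the AIC is
floored at (1e-6 × dynamic range)² so that on effectively noise-free
synthetic traces additional phases are not rewarded for chasing integrator
round-off; ties break toward fewer phases.

**Saturation fits** (`fit_saturation()`) exploit the same separability:
the hyperbola `k·[X]/(Kd+[X])` is linear in k at fixed K~d~, so the
weighted RSS is profiled over log K~d~ with a one-dimensional
golden-section search — deterministic, start-free, and verified in the
tests against an exhaustive 200×200 grid-search oracle. The intercept is
fixed at zero (the curve passes through the origin); a dataset whose
optimum runs to either end of the K~d~ bracket, or whose implied
half-saturation point lies far outside the sampled concentrations, raises
an unidentifiability error rather than returning a meaningless K~d~. Fits
are unweighted unless per-point errors are supplied; when the generator
supplies its known noise SD the covariance is used as-is (not rescaled by
residuals), which makes the reported 2-SE intervals z-calibrated.

**Inactivation fits** (`fit_inactivation()`) reuse the exponential core
for `floor + A0·exp(-k_inact·age)` and reject non-decaying series.

## What the generator emulates — and what it does not

`generate_trace()`, `generate_saturation_dataset()`,
`generate_inactivation_series()` and `generate_quench_series()` emulate,
respectively: single-mixing stopped-flow absorbance/fluorescence traces,
the k~obs~-vs-halide saturation experiment, the double-mixing aging
experiment, and the rapid-quench single-turnover product time course.
Noise is additive, homoscedastic Gaussian with SD expressed as a fraction
of the dynamic range (default 2%) — photomultiplier noise at these signal
levels is approximately Gaussian; a heteroscedastic or shot-noise model is
deliberately out of scope, as are instrument dead time, mixing artifacts
and photobleaching. Each output carries a sidecar truth record
(full-precision JSON) and every random draw is seeded with RNG-state
isolation, so (truth, seed) pairs reproduce outputs exactly.

The generator truths (`thal_truths()`) *are* the study conditions:

* single-mixing truths set `k_inact = 0`, because the printed formation
  k~obs~ (16.52 s^-1^) already is the total decay rate of the freshly
  formed active complex — isomerization is only engaged by anaerobic aging
  in the double-mixing protocol;
* the chloride cascade truth takes the printed fluorescence phase rates
  (rise 1.5 s^-1^, decay 0.073 s^-1^) as effective truth, with the halide
  step back-calculated so `k_hox·[X]/(Kd+[X])` equals 1.5 s^-1^ at 10 mM;
* the single-turnover truth tunes the bromide step so 80% of the flavin
  flux forms HOBr and capture is 37.5%, giving the 30% coupling plateau;
  `k_inact = 0` there too, so the ODE plateau equals the analytic
  branching product exactly (the general `predicted_coupling()` includes
  the oxidation/isomerization competition for arbitrary parameter sets).

Passing the recovery suite therefore demonstrates that the estimators are
unbiased and calibrated *under these idealized conditions*; it does not
validate the scheme against real instrument data, which carry dead-time
truncation, heteroscedastic noise, and model error the generator does not
emulate.

## Energetics

`eyring_rate()` converts an activation barrier E (kcal/mol) to
`(k_B T / h)·exp(-E/RT)`. Computed potential-energy barriers for HOX
formation (I^-^ 1.3, Br^-^ 5.7, Cl^-^ 12.6 kcal/mol) are used *only* for
ordering: `rank_reactivity()` checks that barriers and measured limiting
rates are perfectly anti-correlated (Spearman ρ = −1, HOI > HOBr > HOCl).
The absolute Eyring rate for the chloride barrier (~3.6×10³ s^-1^) exceeds
the measured 1.83 s^-1^ by three orders of magnitude — expected for
potential energies standing in for free energies — and is documented, not
reconciled. Tied barriers or rates are flagged rather than ranked.

## Problem sizes and runtime choices

The default trace grid is 500 log-spaced points over 0.002–100 s,
mirroring stopped-flow sampling. Replicate studies use 200 seeded
replicates per fitter; the stochastic oracle uses 10,000 molecules, at
which the binomial 3-SD band on a branch fraction is about ±0.012. These
sizes keep every analysis in the seconds-to-a-few-minutes range on one
CPU while leaving Monte-Carlo error well below the tolerances being
tested.

One statistical note on the replicate studies: the nominal coverage of a
±2 SE interval is 95.45%, so at a few hundred replicates the observed
coverage of a perfectly calibrated fitter fluctuates by about ±1.5%. The
package's calibration property test therefore compares pooled coverage
against the nominal rate minus its binomial sampling allowance, rather
than against a hard threshold that a correct fitter would fail by chance.

## Known limitations

* No global multi-trace fitting or SVD spectral analysis — phases are
  analyzed trace by trace, as in the experimental convention emulated.
* Optical coefficients are placeholders; absolute amplitudes in physical
  units are not meaningful.
* No pH or temperature dependence (beyond the Eyring ordering check), no
  HOX transfer geometry, no substrate-limited single-turnover regime
  (FADH^-^ must be limiting; violating this only triggers a warning).
* Whether the measured 30% bromide coupling reflects steady leakage or
  partial inactivation during turnover cannot be distinguished from
  end-point data; the model attributes it wholly to the capture/leak
  partition.
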