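---
title: "Membrane permeability from unbiased crossing kinetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane permeability from unbiased crossing kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bilayerperm` turns unbiased particle trajectories that spontaneously cross
a lipid-bilayer-like barrier into thermodynamic profiles, crossing
kinetics, and a permeability prediction at a target (typically
physiological) temperature. This vignette is the package's account of the
science: the models, their assumptions, the tunable parameters, the
numerical choices, and what the bundled synthetic generator does and does
not emulate.

## The problem

Passive trans-bilayer diffusion is the dominant route by which small
molecules enter tissue behind barriers such as the brain microvascular
endothelium. At physiological temperature, crossing events for all but the
fastest solutes are so rare that unbiased simulation cannot sample them.
Heating accelerates the kinetics by orders of magnitude, but the naive
Arrhenius extrapolation of high-temperature rates back to 310 K fails,
because the attempt frequency is itself temperature dependent. The package
implements a corrected extrapolation in which the whole temperature
dependence of the prefactor is carried by two measurable bilayer
properties: the lateral lipid diffusion coefficient and the barrier width.

## Free-energy profiles

The trans-bilayer free-energy profile is obtained by Boltzmann inversion
of the solute position density along the membrane normal,

    G(z) = -kB * T * ln(rho(z)),

with `rho(z)` histogrammed in 0.1 nm bins (configurable) over the full box
and normalized so that the bulk-water plateau (the outermost 0.5 nm at
each edge by default) averages to one; bulk water therefore defines
`G = 0`. Zero-count bins are censored, never interpolated: if the barrier
apex is censored the data do not determine the barrier, and
`barrier_summary()` raises an error advising longer sampling or a higher
temperature rather than guessing.

Statistical errors come from block averaging with 100 ns temporal blocks
(the pipeline scales the block length down to a fifth of the run for short
high-temperature runs): the profile is recomputed per block and the
per-bin standard error is the between-block standard deviation over
`sqrt(n_blocks)`. A bin censored in any block carries no error estimate.

The barrier height is

    dG = G_B - (G_A + G_C)/2,

where `G_B` is the apex (the maximum inside the membrane region, by
default `|z|` up to the crossing plane; ties break towards `z = 0` for
determinism) and `G_A`, `G_C` are the lowest minima on either side. The
effective (Aniansson) barrier width is the Boltzmann-weighted width

    lb = integral over [-h, h] of exp((G(z) - G_B)/kB*T) dz,

evaluated by the midpoint rule over the profile bins (exact for a flat
profile; second order otherwise). The weight is referenced to the apex
value `G_B`, which coincides with `exp((G - dG)/kBT)` whenever the
flanking minima sit at the zero reference and, unlike the latter, is
invariant under shifting the profile's zero — relevant for interfacially
binding solutes whose minima lie below bulk. `h` is half the box height,
a choice that is insensitive to bilayer-thickness fluctuations because
`G` vanishes in bulk water.

Two empirical temperature laws summarize the profiles across a
temperature scan, fitted by (optionally weighted) least squares:

* barrier height falls linearly, `dG(T) = G0 - g*T`;
* barrier width grows quadratically, `ln lb = ln a + ml * ln T` with
  `ml` close to 2 (the fit can be constrained to exactly 2).

The profiles are not symmetrized about `z = 0` by default — leaflet
asymmetry is data, not noise — but `density_profile(symmetrize = TRUE)`
pools `z` with `-z` for symmetric bilayers.

## Crossing kinetics and permeability

A crossing event is a completed ordered traversal of the membrane region:
the detector classifies every frame into upper water (`z > z_plane`),
membrane (`|z| <= z_plane`) and lower water, and counts
upper -> membrane -> lower traversals and their mirror images. Direct
upper <-> lower transitions — molecules circling through the periodic
water phase — are structurally excluded, membrane visits that return to
the entry side are not events, and traversals in progress at either end
of the trajectory are discarded (unbiased counting). The plane defaults
to half the phosphate-phosphate distance in file mode and to the
generator's channel half-width in simulate mode; the detector is
insensitive to moderate shifts of the plane because the interfacial peaks
act as committor bottlenecks. Single-frame jumps that remain large after
minimum-image correction are flagged as wrap artefacts.

The transport rate is `r = N_events / t` with Poisson standard error
`sqrt(N)/t`; both flux directions are pooled. Zero events is a valid
estimate and is flagged as undersampled with the `1/t` scale as an error
bound. The per-molecule rate constant `k = r / n_solutes` is reported as
a diagnostic; the permeability itself is computed normatively as

    P = r / (2 * S * C),

with `S` the membrane area (mean lateral box cross-section, or area per
lipid times lipids per leaflet), `C` the aqueous concentration converted
to molecules/nm^3, the factor 2 accounting for the bidirectional flux of
equilibrium simulations, and the result reported in cm/s. The shorthand
"P = k/2" sometimes used for per-molecule rate constants is dimensionally
incomplete (it implies an unspecified water-column height) and is not
used for reported permeabilities. `C` is the nominal loading
concentration by default; for strongly membrane-partitioning solutes
`aqueous_concentration()` estimates the equilibrium aqueous-phase
concentration from water-phase occupancy instead, and either can be
passed to `permeability_direct()`.

For bench comparison, `transwell_permeability()` implements the standard
sink-condition transwell formula `P = V_A * C_A / (t * S * C_L)` with a
warning when the receiver concentration exceeds the donor (sink violated).

## Diffusion estimators

The lateral lipid diffusion coefficient `DL(T)` is estimated from the
pooled mean-squared displacement of all phosphate markers (all lipid
species together — the bilayer-average mobility is what enters the
kinetics), after removing the per-frame centre-of-mass drift. Removing
the mean of `N` walks shrinks increment variance by `(N-1)/N`, which the
estimator undoes. `D = slope / (2 * dim)` over a fit window defaulting to
10-50% of the maximum lag; a window with `r^2 < 0.9` triggers a
non-diffusive-regime warning.

The solute's normal diffusion coefficient at the barrier apex, `DZ(T)`,
is estimated from short-lag (default up to 20 ps) one-dimensional MSD of
trajectory segments confined to a slab around the apex — at short lags
the confining curvature has not yet bent the MSD, so the estimate
approaches the local free diffusion coefficient. Solutes that never visit
the apex at the simulated temperature make this estimator fail loudly;
directly supplied `DZ` values are accepted wherever the estimate would be
used. Across temperatures the two coefficients are proportional:
`ln DZ = ln b + mD * ln DL` with `mD = 1` for small solutes
(`fit_dz_vs_dl()`, optionally constrained).

## The corrected Arrhenius law

Kramers' theory for diffusive barrier crossing gives an attempt frequency
proportional to `DZ / lb^2`. Substituting the two empirical laws
`DZ = b * DL(T)` and `lb = a * T^2` and absorbing the linear part of the
barrier law (whose `g*T` term contributes a temperature-independent
factor `exp(g/kB)`) into the prefactor yields

    k(T) = c'' * DL(T) / T^4 * exp(-G0 / (kB * T)).

The fit is linear: `y = ln(P * T^4 / DL)` against `x = 1/T`, slope
`-G0/kB`, weighted by `1/var(ln P)` when counting errors are available.
Fitting permeability rather than the per-molecule rate constant changes
nothing in `G0` (area and concentration are temperature-constant in a
fixed system) and keeps the units unambiguous. At least three distinct
temperatures spanning at least 20 K are required; the default protocol
uses the four highest available at or above 440 K, the regime where
single-exponential kinetics hold. Predictions at a target temperature
take `DL` at that temperature directly — lipid diffusion is samplable at
310 K without rare events — falling back to log-log interpolation of the
DL table, flagged in the report. Prediction intervals use first-order
propagation of the fit covariance and widen monotonically as the target
moves below the fitted range.

The uncorrected fit (`fit_naive_arrhenius()`, `ln P` against `1/T`) is
retained as the deviation diagnostic: when `DL(T)` is super-Arrhenius —
as lipid lateral diffusion is — the naive fit shows curved residuals and
systematically misses the low-temperature rate, which is the package's
motivating failure mode. The same `G0` appears in the thermodynamic
barrier law and the kinetic prefactor law; `cross_check_G0()` reports
their difference with combined uncertainty as an internal consistency
check.

## The synthetic generator

All tests run against an overdamped Langevin generator
(Euler-Maruyama, `z <- z - (D/kBT) G'(z) dt + sqrt(2 D dt) xi`, periodic
box, R's RNG for bit-reproducibility) in a double-Gaussian-peak
trans-bilayer potential with an optional central well. Positions are
recorded at 1 ps cadence after a burn-in; the integrator refuses to run
when the drift-to-noise step ratio exceeds 0.2 and suggests a smaller
step (default 0.08 ps for the bundled potentials).

The generator's defining feature is that the ground truth of every law
the analysis layer fits is known exactly. Per temperature, three
parameters — peak height `H(T)`, peak width `sigma(T)` and box height
`Lz(T)` — are calibrated by nested root-finds on exact quadratures so
that:

1. `dG(T) = G0 - g*T` exactly (default `G0 = 5.5` kcal/mol,
   `g = 0.004` kcal/mol/K, i.e. barriers of 4.26 kcal/mol at 310 K
   falling to 3.5 at 500 K);
2. `lb(T) = a * T^2` exactly (default `a = 7.284e-6` nm/K^2, i.e.
   0.7 nm at 310 K);
3. the product of the Boltzmann partition length
   `Z = integral exp(-G/kBT)` and the channel resistance
   `R_chan = integral exp(+G/kBT)` grows as `T^4 * exp(G0/kBT)`.

The third condition deserves a comment. For one-dimensional diffusion the
exact per-particle crossing rate is the equilibrium transition-path flux
`k1 = D / (Z * R_chan)`; the Kramers prefactor carries one power of the
barrier width and one of the reservoir width. A fixed-size box therefore
yields `k ~ DL/T^2`, not the `DL/T^4` of the corrected law, because its
aqueous reservoir does not grow. Calibrating `Lz(T)` so that `Z` scales
as `T^2` — the box's aqueous partition entropy grows quadratically, from
7 nm at 310 K to about 18 nm at 500 K — makes the corrected Arrhenius law
hold exactly, with `ln c'' = ln(b) - ln(anchor const)`. On the calibrated
family, a noiseless fit recovers `G0` to three decimal places and the
310 K rate to 0.1%, so any discrepancy a stochastic test sees is
sampling noise, not model error.

Solute diffusion follows the lipid table, `D = b * DL(T)` with `b = 10`
by default, and the bundled lipid law is Vogel-Fulcher,
`DL(T) = 0.5 * exp(361/110 - 361/(T - 200))` nm^2/ns — the
super-Arrhenius form typical of lipid lateral diffusion, and the reason
naive extrapolation fails on this system by a factor of about three at
310 K. The absolute scale (0.5 nm^2/ns at 310 K, roughly two orders of
magnitude faster than a real bilayer) is a deliberate desk-scale
compression: it buys countable crossing events in hundreds of
nanoseconds at barriers of realistic shape, while leaving every fitted
exponent and ratio — the quantities under test — untouched.

Two analytic oracles accompany the generator. `mfpt_oracle()` computes
the mean first passage time by the standard double quadrature (reflecting
at `a`, absorbing at `b`), matching closed forms for flat potentials and
the Kramers formula at high barriers. `crossing_rate_oracle()` computes
the exact flux `k1 = D/(Z * R_chan)` at any barrier height; the expected
detector count over time `t` with `n` particles is `2*n*k1*t`, the
comparison used by the event-count tests.

What the generator does **not** emulate: explicit lipids and water (the
membrane is a potential of mean force, so there is no bilayer
fluctuation, undulation or solute-induced perturbation), solute-solute
interaction, orientational degrees of freedom, inertial dynamics below
the 1 ps cadence, and any coupling between crossing events. Passing tests
therefore demonstrate that the estimators and the extrapolation machinery
are correct on data that obey the model laws exactly — not that a real
membrane obeys those laws; that evidence must come from the molecular
dynamics data the package analyses in file mode.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `bin_width` | 0.1 | nm | profile resolution |
| `block_ns` | 100 (auto-scaled) | ns | error blocks |
| `bulk_width` | 0.5 | nm | bulk reference zone |
| `z_plane` | half P-P distance / channel half-width | nm | detector planes |
| `z_mem` | `z_plane` | nm | apex search window |
| `h` | half box height | nm | width-integral window |
| `fit_temps` | four highest >= 440 K | K | extrapolation fit set |
| `target_temp` | 310 | K | prediction temperature |
| `dt_ps` | 0.08 | ps | integrator step |
| `cadence_ps` | 1 | ps | recording interval |
| MSD window | 10-50% of max lag | — | diffusive-regime fit |
| slab `max_lag_ps` | 20 | ps | DZ short-lag window |

## Numerical choices and degenerate inputs

Wrapping maps coordinates into `(-Lz/2, Lz/2]` (a value just past the
upper edge reappears just past the lower). The bilayer midplane is the
mean of all phosphate z after unwrapping each lipid in time by nearest
image — phosphates, not the lipid centre of mass, because they are the
standard reference markers; recentring is invariant under global
translation and under box-period shifts. Monotone profiles, censored
apexes, empty bulk regions, fewer than two error blocks, empty slabs,
non-positive inputs and ill-conditioned fits (under 20 K of temperature
span) all raise errors rather than returning numbers. The realized bin
width (the window divided into an integer number of bins) is stored and
used by all downstream quadrature.

Test problem sizes are chosen for desk-scale runtimes: million-frame
(1 microsecond equivalent) runs for profile recovery, a few hundred
events per temperature for kinetics, ten seeded replicates of the
four-temperature protocol (about 800 events per run) against one direct
150-event run at 310 K for the extrapolation benchmark. The benchmark
passes when the corrected prediction agrees with the direct run within
twice the combined stochastic error and beats the naive extrapolation in
at least nine of ten replicates.

## Known limitations

* The analysis is one-dimensional in `z`; orientation-dependent barriers
  and lateral heterogeneity are averaged over.
* The corrected law assumes the two scaling laws hold over the fitted
  range; compounds whose barrier topology changes qualitatively with
  temperature (for example interfacial peaks fusing into a single central
  barrier) can shift `lb`'s effective exponent away from 2, which the
  unconstrained width fit will reveal.
* Permeability from nominal concentration overestimates the driving force
  for strongly partitioning solutes; use the equilibrium aqueous
  concentration channel for those.
* Poisson errors treat events as independent; at very high temperatures
  with near-ballistic recrossings this slightly understates the variance.
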