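---
title: "Hydration numbers from water reorientation dynamics and dielectric relaxation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydration numbers from water reorientation dynamics and dielectric relaxation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(solvshell)
```

## The problem

How many water molecules does a dissolved salt actually "remove" from bulk
water? The *coordination number* — waters within a distance cutoff of an ion,
obtained by integrating an ion–water radial distribution function (RDF) — is a
purely structural count and says nothing about how strongly those waters are
bound. The *hydration number* h used here is dynamical: the number of water
molecules per dissolved salt unit whose dipole reorientation is retarded beyond
bulk-like behaviour. This definition connects directly to GHz–THz dielectric
relaxation spectroscopy (DRS), where slow ("irrotationally bound") waters stop
contributing to the bulk relaxation modes and h can be measured from the loss
of dielectric strength.

`solvshell` implements both routes at full strength on molecular dynamics
trajectories and measured dielectric spectra, plus seeded synthetic generators
that emulate the statistical structure of both inputs, so the entire chain is
testable without an ab initio MD engine or a vector network analyzer.

## The simulation-side model

### Subpopulations

Every water in an electrolyte solution is labelled `W_abc` by its position
relative to the ions:

* `a` — shell state of the **oxygen** with respect to the **nearest cation**:
  `1` (first shell), `2` (second shell), or `B` (beyond), using the first and
  second minima of the cation–oxygen RDF as boundaries;
* `b`, `c` — shell states of the two **hydrogens** with respect to the
  **nearest anion**, using the anion–hydrogen RDF minima.

The two hydrogens are exchangeable, so `bc` is an unordered pair (canonical
order `1 < 2 < B`), giving 3 × 6 = 18 labels. Three of them (`W_11B`,
`W_21B`, `W_B1B`) would require one hydrogen in the first anion shell while
the other is beyond both shells — a dissociated O–H bond — and are flagged
inadmissible; `enumerate_subpopulations()` returns all 18 with the flags.
Shell intervals are half-open, `[0, r_min1)`, `[r_min1, r_min2)`,
`[r_min2, ∞)`, so boundary ties resolve deterministically.

This split-attribution scheme (oxygen to cations, hydrogens to anions)
reflects how the two ion types lock water: cations orient the dipole, anions
orient an O–H bond. It is what lets the model see *cooperative* retardation —
waters simultaneously in the second cation shell and first anion shell.

### Per-subpopulation reorientation times

For each subpopulation the first-order Legendre dipole autocorrelation

$$C_1(t) = \langle \hat\mu(0)\cdot\hat\mu(t) \rangle$$

is computed over many overlapping time origins (default target 1024, 16 ps
windows). Membership is evaluated **at the origin**: a water contributes to
the subpopulation it belonged to at t = 0 and its dipole is followed across
the window even if it migrates. (The translationally frozen synthetic boxes
have no migration, which is exactly why they test this estimator cleanly;
real trajectories do exchange, and origin membership is the convention
implemented throughout.)

The long-time decay is fitted with
$a\,e^{-t/\tau_1} + b\,e^{-t/\tau_2}$ and summarized by the amplitude-weighted
mean $\tau_{reor} = (a\tau_1 + b\tau_2)/(a+b)$; the fit starts at 0.2 ps to
exclude the fast librational transient. Uncertainties come from refitting on
four consecutive, non-overlapping origin blocks (standard error of the block
estimates).

Numerical safeguards in `fit_biexponential()` deserve a note, because the
amplitude-weighted mean is brutally sensitive to spurious slow components.
A TCF estimated from finitely many molecules carries noise that is smooth and
correlated across lags, and a vanishing-amplitude component with a huge time
constant can absorb such a tail deviation for a modest residual gain while
multiplying $\tau_{reor}$ several-fold. Two defences are used: both time
constants are bounded above (25× the fitted span), and the second component
is kept only when it reduces the residual sum of squares by at least 90%
relative to a single exponential — a genuine second relaxation improves the
RSS by orders of magnitude, while noise-absorption yields only a few-fold
gain. Otherwise the single-exponential fit is reported (`b = 0`).

### Retardation and classification

The retardation factor of subpopulation i is $f_i = \tau_i / \tau_{bulk}$.
The bulk reference $\tau_{bulk}$ is the population-weighted mean time of the
*seed bulk set*: populated subpopulations with the oxygen outside the first
cation shell and no hydrogen in the first anion shell. A set is used rather
than the fully-bulk label `W_BBB` alone because at high concentration
`W_BBB` can be empty while several labels still behave bulk-like.

Classification follows the Empirical (68–95–99.7) Rule: a subpopulation is
bulk-like when its f lies within 3σ of the bulk mean, where about 99.7% of
genuinely bulk draws fall. Starting from the seed set, the population-weighted
mean and σ are computed, every fitted label is reassigned by the window test,
and the procedure iterates to a fixed point. σ combines, in quadrature, the
spread of f across the current bulk set and the population-weighted mean
block error (`sigma_mode = "combined"`; `"spread"` and `"block"` isolate
either part — whether the reference spread or the per-label error is the
right yardstick is genuinely ambiguous, so both are exposed).

The hydration number is then

$$h = \frac{\sum_{i \in slow} \langle N_i \rangle}{N_{salt}}$$

split into the first-cation-shell contribution (`a = 1`) and the contribution
from beyond. h is intensive: doubling the box and the salt content leaves it
unchanged.

## The measurement-side model

Dielectric spectra over ~0.01–110 GHz are described by the double-Debye model

$$\varepsilon(\nu) = \frac{S_1}{1 + i\omega\tau_1} + \frac{S_2}{1 + i\omega\tau_2} + \varepsilon_\infty$$

with the slow mode near 20 GHz, the fast mode near 1 THz, and
$\varepsilon_\infty$ fixed at 3.52 (overridable). Before fitting, the Ohmic
loss $\sigma/(\omega\varepsilon_0)$ from ionic conduction is subtracted using
the independently measured conductivity. The fit is a bounded
Levenberg–Marquardt least squares on the stacked real and imaginary parts
with equal weights, multi-started, with a post-fit swap enforcing
$\tau_1 > \tau_2$ so mode labels cannot switch.

The strength change of a solution relative to pure water is split into
depolarization mechanisms. All strength changes are signed losses here
(negative when strength is lost) — that convention is what makes the algebra
of the chain close:

* total: $\Delta S_{total} = S(c) - S(0)$, with $S = S_1 + S_2$;
* kinetic (perfect-slip ion drift):
  $\Delta S_{kinetic} = -\tfrac{2}{3}\,\sigma(c)\,\tau_1(0)\,
  \frac{\varepsilon_s(0) - \varepsilon_\infty(c)}{\varepsilon_s(0)\,\varepsilon_0}$,
  evaluated fully in SI units;
* static: $\Delta S_{static} = \Delta S_{total} - \Delta S_{kinetic}$.

The DRS hydration number combines the static part with the dilution effect:

$$N_{hyd} = \frac{c_{H_2O}(c)}{c} - \frac{S(0) + \Delta S_{static}}{S(0)}\cdot\frac{c_{H_2O}(0)}{c}.$$

With the loss convention above, $S(0) + \Delta S_{static}$ is the strength
the bulk-like waters alone would produce, and the synthetic round trip
(`gen_concentration_series()` → `run_drs_pipeline()`) recovers a designed
$N_{hyd}$ to the fit tolerance. Whether $S(0)$ should be the total strength
or the slow-mode strength alone is not uniquely determined by the physics;
the total is the default and `S0` is an explicit argument. Negative fitted
values are reported with a warning, never clipped — they are diagnostic.

An open-ended coaxial probe maps reflection coefficients to permittivities
through the bilinear model $\varepsilon = (A\rho + C)/(1 + B\rho)$;
`calibrate_probe()` solves for the complex coefficients exactly from three
standards.

## What the synthetic generators emulate — and what they do not

`gen_rotational_trajectory()` builds a periodic box with placed ions and
rigid ideal waters whose orientations evolve by isotropic rotational Brownian
motion, class by class. The propagator rotates each molecule per step about a
uniformly random axis by an angle drawn from Normal(0, √(6 D dt)). For a
uniformly random axis the expected single-step alignment is
$E[\hat u\cdot R\hat u] = (1 + 2E[\cos\phi])/3 = 1 - 2D\,dt$, which makes
$C_1(t) = e^{-2Dt}$ exact in the small-step limit; the variance constant 6
(not 4) is specific to the uniform-axis convention — with a rotation axis
constrained perpendicular to the dipole the constant would be 4. The
propagator enforces D·dt < 0.01.

Designed subpopulations are placed by rejection sampling inside the geometric
region of their label with margins covering the whole hydrogen sphere
(O–H arm + 0.25 Å), so hydrogen shell states cannot flip as molecules rotate,
and the frame-1 labels are verified against the design before the trajectory
is returned. Two consequences are worth understanding:

* only labels with equal hydrogen states (`b = c`) can be pinned — a mixed
  label like `W_212` would need an orientation constraint incompatible with
  isotropic rotation, and the spec constructor rejects it;
* the default label geometry (cation shells 3/7.5 Å, anion shells 6/10 Å,
  ion-pair separation with first shells touching) is wider than physical
  RDF minima would be. That is intentional: the H-sphere margin must fit
  inside one shell band. Analyses of real trajectories take their boundaries
  from the RDF minima (or explicit configuration), not from these defaults.

What the generator deliberately does **not** emulate: liquid structure and
packing correlations, translational diffusion and subpopulation exchange,
hydrogen-bond networks coupled to rotation, polarization, and forces of any
kind. Passing the recovery tests therefore demonstrates that the *estimator
chain* — labelling, origin-membership TCFs, fitting, classification, and the
population bookkeeping — is correct on data whose ground truth is known; it
does not validate the physics of any particular simulation.

`gen_hb_event_series()` produces Poisson bond-breaking series (bonded at
t = 0, per-step breaking probability 1 − e^{−k dt}, no reformation), whose
continuous survival is exactly $e^{-kt}$ — the analytic oracle for the
`correlate()` survival kernel and the lifetime integration.
`gen_dielectric_spectrum()` evaluates the double-Debye model, adds the Ohmic
term and multiplicative Gaussian noise.

## Other observables

* **RDF and coordination number** — `compute_rdf()` histograms minimum-image
  pair distances and normalizes by the exact ideal-gas shell count;
  `coordination_number()` integrates $4\pi\rho\,g(r)r^2$ by the trapezoid
  rule from 0 to the cut, interpolating g at the cut so no partial shell is
  dropped. `find_shell_minima()` locates the first two minima on a smoothed
  profile (centered moving average, default 5 bins — short-trajectory RDFs
  are noisy); a decayed tail counts as a final minimum, and configured
  fallback boundaries are used when detection fails.
* **Hydrogen bonds** — geometric criteria (O–O < 3.5 Å, covalent O–H <
  1.2 Å, H-acceptor < 2.5 Å, angle ≤ 30°). The angle vertex sits at the
  donor oxygen between the O→O and O→H vectors by default; the convention is
  configurable because the two readings of the angle differ for bent bonds
  and sensitivity checks should be cheap. The continuous survival
  $S_{HB}(t)$ (11 ps windows) counts a donor–acceptor–hydrogen triple only
  while bonded at *every* intermediate frame; its trapezoid integral is the
  lifetime, optionally with a single-exponential tail correction fitted on
  the last 20% of the window (both reported by choosing `tail`).
* **Ion pairing** — per cation, the nearest anion within a configurable 8 Å
  horizon is a contact (CIP), solvent-shared (SSHIP) or solvent-separated
  (SSIP) pair by distance shell; fractions sum to 100%.
* **Water exchange** — the direct counting method: a crossing counts only if
  the water stays on the new side at least t* (default 0.5 ps, the standard
  choice for this estimator; shorter excursions are flickers).
* **VDOS** — per-species velocity autocorrelations over multiple origins,
  Hann window, magnitude of the one-sided FFT, wavenumber grid in cm⁻¹.
  Mass weighting is off: plain velocity autocorrelations are summed, which
  is the convention the in-shell restriction analysis uses.

## Validation scales and statistical honesty

The package validates itself on synthetic data at desk scale (seconds to a
few minutes per check): rotational-diffusion recovery uses boxes of 500
dipoles over 20 ps at a 4 fs step; hydration-number recovery uses 500-water
boxes with designed slow counts of 6–21 per salt unit; HB kinetics uses 2000
bonded pairs; the dielectric round trip uses 20 random parameter sets on a
200-point 0.01–110 GHz grid.

One realization of a 500-dipole / 20 ps box determines $\tau_{reor}$ with a
standard error near 6% — correlated TCF noise, not estimator bias (the mean
error across replicates is below 1%), and the error distribution is
heavy-tailed (an occasional box realizes a fat correlated tail). Recovery
checks therefore take the median of the fitted time over 8 independently
seeded replicate boxes, bringing the effective standard error near 2–3% so a
5% tolerance tests the estimator rather than one realization's luck. The
survival and dielectric checks are far better conditioned and use single
realizations.

## A short worked example

```{r example, eval = FALSE}
# a small designed solution: 1 salt unit, 4 + 6 slow waters, 50 bulk waters
spec <- synthetic_solution_spec(
  n_salt_units = 1, class_counts = c(W_122 = 4, W_211 = 6),
  n_bulk_waters = 50, n_frames = 1001, seed = 7
)
sol <- gen_rotational_trajectory(spec)
cfg <- run_config(cation_shells = spec$cation_shells,
                  anion_shells = spec$anion_shells, window = 3)
res <- run_hydration_pipeline(sol$traj, cfg)
res$result$h          # ~10: 4 first-shell + 6 beyond
autoplot(res$table)   # retardation factors with the 3-sigma bulk window
```

## Known limitations

* Orthorhombic cells only; triclinic lattices are rejected at read time.
* The water topology is built once from a reference frame and held fixed —
  appropriate for non-reactive trajectories, wrong for dissociating ones.
* Origin-membership is the only fully supported subpopulation tracking mode;
  continuous-membership sensitivity analysis would require exchange-aware
  generators to test against.
* The collective (auto + cross) dipole correlation needed to predict a DRS
  spectrum directly from simulation is out of scope; single-molecule
  $\tau_{reor}$ values are not directly comparable to DRS relaxation times.
* The DRS chain assumes the conductivity, density and concentrations are
  measured independently and supplied as metadata.
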