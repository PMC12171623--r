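---
title: "Cavitation thresholds from coupled bubble-cluster dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cavitation thresholds from coupled bubble-cluster dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavithresh)
```

## The model

Therapeutic ultrasound (HIFU, histotripsy) relies on acoustic cavitation:
gas nuclei in tissue grow explosively and collapse when the rarefaction of
the sound field is strong enough. The *cavitation threshold* is the minimum
drive amplitude at which this happens, and it depends on frequency, on the
population of nuclei present, and on the viscoelasticity of the medium.
This package computes that threshold from the radial dynamics of a bubble
cluster rather than from a single-bubble model.

The cluster holds `q` discrete size classes with rest radii $R_{0i}$ and
counts $N_i$ inside a cloud of volume $V$. Each class obeys a Keller--Miksis
equation — radial dynamics with first-order liquid compressibility —

$$\left(1-\frac{\dot R_i}{c_l}\right) R_i \ddot R_i
  + \frac{3}{2}\dot R_i^2\left(1-\frac{\dot R_i}{3c_l}\right)
  = \left(1+\frac{\dot R_i}{c_l}\right)\frac{p_i}{\rho}
  + \frac{R_i}{\rho c_l}\frac{dp_i}{dt}
  - \sum_{j=1}^{q} S_j\!\left(2R_j\dot R_j^2 + R_j^2\ddot R_j\right),$$

with a Kelvin--Voigt (viscous + elastic) stress at the wall:

$$p_i = \left(p_0 - p_v + \frac{2\sigma}{R_{0i}}\right)
        \left(\frac{R_{0i}}{R_i}\right)^{3\kappa}
      - p_0 + p_v - \frac{2\sigma}{R_i}
      - \frac{4\mu\dot R_i}{R_i}
      - \frac{4G}{3R_i^3}\left(R_i^3 - R_{0i}^3\right) - p_s(t),$$

driven by $p_s(t) = -p_a\sin(2\pi f t)$ (rarefaction first). Water is the
Newtonian limit $G = 0$. The last sum is the mean-field radiation coupling
between bubbles: assuming the bubbles of class $j$ are uniformly
distributed and vibrate synchronously, the sum of inverse distances to all
of them collapses to a single strength
$S_j = 2\pi n_j^{1/3}$, where $n_j = N_j/V$ is the class number density and
$\delta r_j = n_j^{-1/3}$ its mean bubble spacing. The gas core is an ideal
gas compressed adiabatically, so its temperature follows
$T = T_0 (R_0/R)^{3(\kappa-1)}$.

Assumptions worth keeping in mind: bubbles stay spherical; there is no
thermal diffusion, phase change or rectified gas diffusion ($p_v$ is
constant); the coupling is mean-field, so bubbles have no positions and no
near-neighbour interactions; and each size class moves as one synchronized
degree of freedom. The model is valid while the void fraction stays below
5 % (no acoustic shielding) and each class's spacing stays below one eighth
of the wavelength (synchronous vibration); `validity_check()` reports both,
as warnings rather than errors, because marginal configurations are still
informative.

## Parameters and defaults

| parameter | symbol | water | viscoelastic (liver) |
|---|---|---|---|
| surface tension (N/m) | $\sigma$ | 0.0725 | 0.056 |
| sound speed (m/s) | $c_l$ | 1500 | 1549 |
| density (kg/m³) | $\rho$ | 998 | 1060 |
| viscosity (mPa·s) | $\mu$ | 1 | 9 |
| shear modulus (kPa) | $G$ | 0 | 40 |
| static / vapor pressure (kPa) | $p_0$, $p_v$ | 101.3, 2.33 | same |
| adiabatic exponent, core temperature | $\kappa$, $T_0$ | 1.4, 290 K | same |
| gas sound speed (m/s) | $c_g$ | 340 | same |

The default cluster has classes $\{0.5, 1, 3, 6, 8, 10\}\,\mu$m with a
total of $4\times 10^5$ bubbles split equally (rounded to the nearest
integer per class; the residual of at most three bubbles out of
$\sim 10^5$ is irrelevant because coupling scales as $n^{1/3}$) in a
$2.7\times10^{-8}\,$m³ cloud (a 3 mm cube). Its void fraction is about
1.8 %, safely inside the 5 % limit. A single decoupled bubble
(`single_bubble()`) and a one-class cluster with full coupling
(`same_radius_cluster()`) are the two standard comparison models.

$\kappa$ plays a double role — polytropic index in the wall pressure and
adiabatic exponent in the core temperature — with the single value 1.4.

## Cavitation criteria and the threshold

Five onset criteria are evaluated per class on the maxima inside the
analysis window: $R_\max \ge 2R_0$, $U_\max \ge c_l$, $U_\max \ge c_g$,
$T_\max \ge 1550$ K, $T_\max \ge 5000$ K. The cluster cavitates as soon as
*any* class fires; each class is judged against its own $R_0$. The
expansion-ratio criterion is consistently the cheapest to satisfy, which is
why the parameter studies default to it (conservative from a safety
standpoint). The quasi-static Blake threshold — the static-pressure /
surface-tension balance, frequency-independent — is provided as a
reference; for a cluster it is the Blake threshold of the largest populated
class, since larger nuclei activate at lower pressure.

"Classical Blake threshold theory" is not a single formula: conventional
variants differ in whether the vapor pressure enters. The default here is

$$P_B = p_0 - p_v + \frac{8\sigma}{9}
 \sqrt{\frac{3\sigma}{2\,(p_0 - p_v + 2\sigma/R_0)\,R_0^3}},$$

giving 101.0 kPa for a 10 µm nucleus in water; the `no_vapor` variant gives
103.3 kPa. The ~2 % spread between variants is documented rather than
resolved.

## Integration protocol and numerical choices

Each simulation integrates the $2q$ first-order equations from the
equilibrium state $(R_{0i}, 0)$ — the only parameter-free initial condition
— over 60 drive cycles with an adaptive Dormand–Prince 5(4) scheme
implemented in C++. Maxima are taken over cycles 35–55 so that start-up
transients have died out. Numerical choices that matter:

* **Exact equilibrium.** The wall pressure is grouped as
  $p_g^0[(R_0/R)^{3\kappa}-1] + 2\sigma(1/R_0 - 1/R) - \dots$ so the rest
  state is a floating-point fixed point; an undriven 60-cycle run drifts by
  strictly zero rather than accumulating tolerance-level error.
* **Implicit accelerations.** $dp_i/dt$ is analytic; its
  $-4\mu\ddot R/R$ part moves to the left-hand side, giving the diagonal
  $d_i = (1-\dot R_i/c_l)R_i + 4\mu/(\rho c_l)$. The coupling adds the
  rank-one term $\mathbf{1}s^T$ with $s_j = S_jR_j^2$, and the $q\times q$
  system is solved by the Sherman–Morrison identity; a dense solve is kept
  as a cross-check and the two agree to machine precision.
* **Tolerances.** `rtol = 1e-8`, absolute tolerances $10^{-12}$ m on radius
  and $10^{-6}$ m/s on velocity. Halving the tolerances moves sub-threshold
  window maxima by well under 1 %.
* **Maxima from internal steps.** Collapse spikes are far narrower than
  any fixed output grid, so the per-class maxima of $R/R_0$, $|\dot R|$ and
  the minimum radius (hence $T_\max$) are accumulated at every accepted
  solver step plus interpolated sub-samples; the 200-samples-per-cycle
  output grid is for plotting and export only.
* **Failure classification.** A violent inertial collapse can drive the
  step size to underflow. Such a run is not an error: if a criterion
  already fired inside the window it counts as cavitated; otherwise it is
  retried once at 10× tighter tolerance, and if it still fails silently it
  is classified inconclusive and treated as cavitated for bracketing
  (step collapse accompanies exactly the violent collapse the criteria
  detect).
* **Coupling-term parse.** The coupling is taken as
  $S_j\,d(R_j^2\dot R_j)/dt$, the standard radiation-coupling form, with
  the sum including $j = i$ (a bubble couples to the other members of its
  own class; the continuum approximation absorbs the self-term). The
  prefactor is a single internal constant so the alternative halved
  reading is a one-line switch for sensitivity analysis.

## Threshold search

`find_threshold()` scans amplitude upward from 10 kPa in 10 kPa steps until
the criterion first fires, then bisects the bracket to 1 kPa. The upward
scan is not an optimization detail: the response is *not* guaranteed
monotone in amplitude, so a pure bisection from the ceiling could latch
onto a higher firing branch and miss the true minimum. Near such
non-monotone stretches the first-firing amplitude can depend mildly on the
coarse step; the bracketing tests quantify this. The search ceiling
defaults to 6 MPa. For expensive sweeps the coarse step can be widened
(e.g. 25 kPa) with the final bisection tolerance unchanged.

`threshold_vs_frequency()` sweeps a grid (40 log-spaced points over
20–2500 kHz by default) and `fit_power_law()` fits $P = A f^\alpha + B$
(P in Pa, f in Hz) by Levenberg–Marquardt on the linear scale,
multi-started over $\alpha \in \{0.5, 0.75, 1.0\}$ with $A, B$ seeded by
ordinary least squares at fixed $\alpha$, and $\alpha$ constrained to
$(0, 2)$. $A$ and $B$ trade off strongly against $\alpha$, so only the
exponent is a stable summary of a sweep; noiseless synthetic curves are
recovered to $10^{-6}$, and 2 % multiplicative noise perturbs $\alpha$ by
less than 0.05 at 30 points.

The composition study (`composition_study()`) fixes the total count and
gives one class a share $Q$, the remainder split equally over the other
five. The viscoelasticity map (`viscoelastic_map()`) varies only
$(G, \mu)$ with everything else held at the tissue values, and the number
study (`number_study()`) sweeps the total count.

## What the tests exercise, and at what size

The suite checks the closed-form layer (geometry, wall pressure, Blake,
temperature) against hand-evaluated values; the acceleration assembly
against an independently coded scalar Keller–Miksis law and a dense-matrix
solve; the compiled integrator against `deSolve` on an R-level
right-hand side; the weak-drive limit against the linear oscillator and
the surface-tension-corrected Minnaert resonance (within 5 %); and the
scan-plus-bisection search against an exhaustive fine scan. End-to-end
checks reproduce reference threshold values for the default cluster in
water and tissue; to keep runtimes at desk scale those use 10- and
20-point frequency sweeps and a 1–2 kPa search tolerance, which moves
simulation-derived thresholds by far less than their 10 % comparison
bands. Unit tests integrate 10–40 cycles with correspondingly earlier
windows; the protocol quantities (60 cycles, window 35–55) are used
wherever a printed reference value is reproduced.

What passing these tests does *not* show: real nuclei populations are
continuous and unknown, tissue is lossier and less homogeneous than a
Kelvin–Voigt half-space, and the mean-field coupling has no spatial
structure — so agreement with the reference computation is a statement
about the model, not a validated prediction for any particular tissue.

## Known limitations

* No thermal conduction, phase change or gas diffusion; collapse
  temperatures from the adiabatic law are upper estimates.
* The wall-speed criteria compare against fixed sound speeds; the
  Keller–Miksis equation itself degrades near and beyond $\dot R = c_l$.
* Discrete size classes only; a continuous distribution must be binned.
* Threshold curves fluctuate with frequency (the underlying response is
  resonant and nonlinear); printed single-frequency thresholds should be
  read with that granularity in mind.
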