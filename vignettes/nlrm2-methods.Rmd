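---
title: "Quantifying nanoparticle-labeled cells from the second harmonic of magnetization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nanoparticle-labeled cells from the second harmonic of magnetization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nlrm2)
```

## The measurement and the model

Superparamagnetic iron-oxide nanoparticles (SPIONs) internalized by
mesenchymal stem cells cluster into aggregates that behave as single
magnetically active centers: the SPIONs within an aggregate are strongly
exchange-coupled, while different aggregates are magnetically independent.
An organ specimen containing `N_P` such centers per gram therefore produces
a nonlinear magnetic response proportional to `N_P`, and counting centers
counts labeled cells once the mean aggregate load per cell is known.

The measurement registers the second harmonic `M2` of the magnetization
under a dc field `H` (swept over ±300 Oe) and a parallel weak ac field
`h sin(2*pi*f*t)` with `h = 13.8` Oe and `f = 15.7` MHz. Both quadratures,
`Re M2(H)` and `Im M2(H)`, are recorded. For a linear response the second
harmonic vanishes identically; for a superparamagnetic ensemble it is an
odd function of `H` whose shape encodes the moment distribution and whose
phase lag encodes the relaxation dynamics.

The forward model solves the axially symmetric Brown rotational
Fokker–Planck equation for the orientation distribution `W(x, t)`,
`x = cos(theta)`, of a single-domain moment `m` with reduced energy

```
beta*E = -xi(t) * x - sigma_A * x^2,
xi(t)  = m*mu_B*(H + h*sin(2*pi*f*t)) / (k_B*T),
sigma_A = E_A / T,
```

with the diffusion timescale set by the longitudinal free-relaxation time
`tau_N = (1 + alpha^2) * m*mu_B / (2*gamma*alpha*k_B*T)`. Expanding `W` in
Legendre polynomials turns the equation into a coupled mode hierarchy for
`f_l = <P_l>`; seeking the periodic steady state as a Fourier series in the
drive (harmonic balance) yields a sparse block-tridiagonal linear system
whose solution gives the complex amplitude of `<x>` at twice the drive
frequency. The per-particle response is `m*mu_B` times that amplitude, and
the specimen response is the lognormal-moment-distribution average scaled
by `N_P = M_tilde / (M_C*mu_B)` — the linearity in `N_P` on which the whole
quantification rests.

All quantities are CGS-Gaussian (Oe, emu, erg, K; moments in Bohr
magnetons), matching how such measurements are reported. The constants live
in `m2_constants()`.

### Parameters and their meaning

| parameter | units | meaning | typical scale |
|---|---|---|---|
| `M_tilde` | emu/g | saturation magnetization per gram | 1e-7 – 1e-5 |
| `M_C` | mu_B | mean aggregate moment (lognormal mean) | 2e4 – 4e4 |
| `sigma` | – | log-width of the moment distribution | 0.2 – 0.9 |
| `alpha` | – | magnetization-dynamics damping factor | 0.2 – 1.1 |
| `tau_N` | ns | longitudinal free-relaxation time | 0.3 – 1.3 |
| `E_A` | K | uniaxial anisotropy energy | 0 – 20 |

`tau_N` is derived from `(M_C, alpha, T)` rather than fitted independently:
the derived values reproduce the reported relaxation times of all fully
processed specimens to better than 4% (the injection solution to 0.2%),
which is also what fixes the otherwise unstated measurement temperature at
`T = 300 K` in this package. A configuration flag (`free_tau`) restores an
independently fitted `tau_N` for comparison.

The distribution of aggregate moments is lognormal *in the mean*: the
parametrization is chosen so that `N_P = M_tilde/(M_C*mu_B)` reproduces
every reported center count from its `(M_tilde, M_C)` pair, which implies
`M_C` is the ensemble mean moment, not the median or mode.

### Anisotropy and geometry

The easy axis is taken parallel to the field and the solver is axially
symmetric; powder averaging over easy-axis orientations is omitted. The
reported anisotropy energies (`E_A <= 17.4 K`, i.e. `sigma_A <= 0.06` at
300 K) put orientation effects below the fit noise. The damping factor
enters only through the `tau_N` relation; there is no independent
precessional term in the axially symmetric geometry. Sign convention: under
a drive `h*sin(wt)`, `Re M2` is the `cos(2wt)` coefficient and `Im M2` the
`sin(2wt)` coefficient; a global sign flip is exposed as the `sign_flip`
configuration switch since the phase origin of real instruments varies.

## Numerical scheme

**Truncation control.** The Legendre order `l_max` and Fourier order
`n_max` start at (10, 4) and are doubled until the second-harmonic
amplitude changes by less than 1e-4 relative, with a hard cap at (80, 16);
`single_particle_m2()` raises an error naming the offending `(H, m)` node
if the cap is hit without convergence. The ensemble quadrature additionally
uses a validated heuristic (`l` grows linearly with the total reduced field
`|xi_0| + xi_1`, `n` with the reduced ac amplitude) to pick per-node orders
in one shot, certifying the largest-amplitude node against an
enlarged-order solve and falling back to the doubling ladder on
disagreement; the test suite checks the heuristic against the ladder across
the working parameter range. Per-node convergence tolerances are scaled by
each node's share of the ensemble weight, so saturated tail nodes (which
contribute ~1e-4 of the ensemble amplitude) are not solved to needless
precision.

**Quadrature.** The lognormal average uses a fixed log-grid (Simpson rule
on `ln m` over the mean ± 4 sigma, weights renormalized; >= 21 nodes).
Gauss–Hermite nodes were rejected because at `sigma ~ 0.9` their outermost
abscissae land at reduced fields of several hundred where no practical
Legendre truncation converges, while carrying ~1e-13 of the weight. The ±4
sigma truncation discards ~6e-5 of the distribution mass.

**Oracles.** Three mutually independent solution routes guard the solver:
an analytic quasi-static perturbative limit (`-(h^2/4) d^2M_eq/dH^2`), a
non-perturbative quasi-static Fourier oracle (equilibrium Boltzmann average
sampled along the drive period), and direct time-stepping of the Legendre
mode hierarchy to its periodic steady state (`deSolve::lsoda`, projecting
the final period onto the second harmonic). The harmonic-balance solution
agrees with the time-stepped one to better than 1e-3 relative and collapses
onto the quasi-static oracle when the drive frequency is scaled down a
thousandfold.

**Interpolation in fitting.** During inversion the model curve is evaluated
on a 33-point field grid and interpolated to the data grid by cubic spline;
the curve is smooth enough that this changes fitted parameters by far less
than their uncertainties (the noiseless round trip recovers `M_C` and
`M_tilde` to 0.03%), and it keeps a full fit within tens of seconds.

## Preprocessing and the applicability screen

Raw sweeps come as direct and reverse branches at two scan frequencies of
the dc field (8 and 0.25 Hz). Branches of a pair are linearly interpolated
onto their common grid and averaged, which cancels a branch-antisymmetric
hysteresis to first order; the two scan frequencies record the same
underlying response, so their branch-averaged curves are averaged again,
halving the noise. Finally the curve is antisymmetrized,
`(s(H) - s(-H))/2`, as the model response is odd in `H`; fitting then uses
only the nonnegative half-axis. Averaging precedes antisymmetrization,
mirroring the acquisition protocol's processing order.

Field hysteresis is quantified by `hysteresis_index()`: the mean modulus of
the complex branch difference over the peak-to-peak amplitude (complex-plane
diameter) of the branch mean. The superparamagnetic applicability screen
passes a specimen whose fast-scan index is below 0.05, or whose index both
decreases by at least 30% from the fast to the slow scan and ends below
0.05; it fails a specimen whose indices are above threshold and within 10%
of each other — scan-rate-independent hysteresis is the signature of a
multi-domain (ferromagnetic) fraction for which the formalism is invalid.
The thresholds are configurable; the defaults were chosen once so that
noiseless superparamagnetic data pass and a constructed scan-rate-independent
offset fails, the two regimes the screen exists to separate.

## Inversion

`fit_m2()` minimizes the joint sum of squares over the concatenated real
and imaginary samples with equal weights (amplitude-proportional weighting
is available behind a switch), free parameters
`(M_tilde, M_C, sigma, alpha, E_A)` within bounds
`M_C in [1e3, 1e6] mu_B`, `sigma in [0, 2]`, `alpha in [0.01, 5]`,
`E_A in [0, 30] K`. The anisotropy ceiling covers every reported value plus
its uncertainty (the largest being 0 ± 29 K); a wider ceiling only lengthens
the unidentifiable valley described below. The initial guess places `M_C`
via the field of the `|Re M2|` extremum (at reduced field 1.3723, where the
second derivative of the Langevin function peaks, corrected by `exp(sigma^2)`
for the response-weighted moment of a lognormal ensemble) and scales
`M_tilde` from the peak amplitude.

**The anisotropy valley.** `E_A` is weakly identifiable from a
single-temperature sweep: the likelihood is nearly flat along a curved
valley trading `E_A` against `M_C` and `sigma` (parameter sets 9% apart in
`M_C` produce curves differing by 0.3% of peak). Three measures keep the
inversion honest. First, multistart screening (5 perturbed starts, fixed
seed) runs with `E_A` frozen, and the two best-screened basins are polished
with all parameters free — this reliably finds the global optimum rather
than a point partway along the valley. Second, reported 1-sigma
uncertainties are the Jacobian-based covariance at the optimum (directions
of negligible curvature removed by an eigenvalue cut) plus the parameter
displacement to the far ends of the `E_A` envelope, obtained by two
warm-started profile fits; the two parts add linearly rather than in
quadrature because the marginal spread along a curved valley is not
Gaussian, and without this floor the intervals undercover badly whenever
the optimum sits on an `E_A` bound.
Third, the screening ranking is never trusted blindly (close basins
misrank under truncated iterations), hence the two-basin polish.

Specimens whose applicability screen returns FAIL are refused (error, or
nonzero exit status in the command-line interface) unless explicitly
forced, mirroring how a multi-domain specimen must be excluded from
quantification rather than silently fitted.

## From magnetics to cell counts

`count_centers()` computes `N_P = M_tilde/(M_C*mu_B)`; `count_mscs()`
divides by the calibration of the injection solution, 8.27e4 aggregates per
labeled cell (with 160 nanoparticles per aggregate and 1.5e5 cells in the
injected dose recorded alongside). Specimens that could not be fitted are
estimated by amplitude scaling against a fitted reference organ, assuming
close aggregate moments: per-gram-normalized peak amplitudes make organ
masses cancel (the amplitude statistic is peak `|Re M2|` by default,
configurable to RMS). Such rows are flagged approximate and rendered with a
"~" prefix and dashes for the absent magnetic parameters in
`summary_table()`, which reproduces the standard report layout; cell counts
are rounded to two significant figures there. `rank_organs()` sorts one
subject's records by ascending cell density with alphabetical, flagged tie
breaks.

## The synthetic generator

No raw sweeps of this kind are public, so `simulate_sweep()` and
`make_phantom_study()` stand in for the instrument: the forward model is
evaluated on the signed field grid (default 301 points over ±300 Oe, both
scan frequencies), a branch-antisymmetric offset emulates field hysteresis
(a fraction of the peak modulus, settable per scan frequency — the simplest
mechanism reproducing the pass/fail phenomenology without modelling
multi-domain physics), and homoscedastic Gaussian noise is added (default
1% of the peak; the instrument noise law is not published). The default
phantom preset is the rat 1 organ column of the reference table; organs
without directly fitted magnetics use the moment implied by their printed
center count, so the manifest always satisfies the counting identities
exactly. Everything is deterministic given the seed, which is recorded in
the file metadata.

What the generator does *not* emulate: baseline drift, field-dependent or
multiplicative noise, temperature gradients across a specimen, the biogenic
magnetite background of control animals, and genuine multi-domain dynamics
(only their hysteresis signature). Passing recovery tests therefore shows
the inversion is correct and stable under the stated noise model, not that
real tissue data are free of systematics.

## Problem sizes and known limitations

The test suite and the acceptance script run the recovery study at 10
replicates of 301-point sweeps with 2% noise, the oracle comparison on a
3-point field grid at three parameter combinations spanning the reference
table, and the quasi-static check on a 31-point grid; these sizes give
stable statistics while keeping a full run within minutes on one core.

Limitations: single measurement temperature (the formalism supports
temperature sweeps, which would break the anisotropy valley, but the
package fits one temperature at a time); no powder averaging; no
inter-aggregate dipolar coupling (the counting identity assumes magnetic
independence); `E_A` estimates should be read as envelope-constrained, not
as resolved material constants.
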