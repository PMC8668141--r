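---
title: "Dynamic maximum entropy: model reduction for 1D stochastic dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic maximum entropy: model reduction for 1D stochastic dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmaxent)
```

## The reduction

This package works with one-dimensional diffusions whose drift derives from
a potential that is linear in a set of time-dependent *forces*
$\alpha(t) = (\alpha_1, \dots, \alpha_d)$ acting on *observables*
$A(x) = (A_1, \dots, A_d)$:

$$dx = \frac{g^2(x)}{2}\,\partial_x\big[\alpha(t)\cdot A(x)\big]\,dt
       + g(x)\,d\xi(t).$$

The density $u(t,x)$ obeys the Fokker–Planck equation (FPE) with no-flux
boundaries. For constant forces the stationary solution is the
exponential-family (maximum-entropy) density
$\bar u_\alpha(x) \propto g^{-2}(x)\,e^{s\,\alpha\cdot A(x)}$, where $s$ is
a constant scale fixed by the model's parameterization and $g^{-2}$ is the
no-force baseline. The observable expectations evolve as

$$\frac{d\langle A\rangle}{dt} = B\,\alpha(t) + V,
\qquad B_{ji} = \frac{s}{2}\big\langle g^2 A_j' A_i'\big\rangle,
\qquad V_j = \frac{1}{2}\big\langle g^2 A_j''\big\rangle,$$

a system that is not closed whenever the $A_j$ are nonlinear. The dynamic
maximum entropy (DME) closure assumes the solution stays inside the
stationary family with time-dependent *effective forces* $\alpha^*(t)$,
chosen so that the ansatz matches the true observable expectations at each
time. Quasi-stationarity ($B_{\alpha^*}\alpha^* + V_{\alpha^*} = 0$, an
identity of the stationary family that `test-core.R` verifies numerically
at random force points) turns the unclosed system into

$$\frac{d\alpha^*}{dt} = C_{\alpha^*}^{-1} B_{\alpha^*}
  \big(\alpha(t) - \alpha^*\big),
\qquad C = \frac{\partial\langle A\rangle}{\partial\alpha^*} = s\,\mathrm{Cov}(A),$$

a $d$-dimensional deterministic ODE. Constant applied forces are exact
fixed points; everything interesting happens when $\alpha(t)$ moves, and
the package's purpose is to quantify how well the moving equilibrium family
tracks the true non-equilibrium density.

Two remarks about what the closure does *not* claim. First, the residual
between the true density and the ansatz is neglected without any a priori
bound; the package therefore measures it a posteriori as the
Kullback–Leibler divergence $\mathrm{KL}(u_{\mathrm{FPE}}\,\|\,\bar
u_{\alpha^*})$ at every output time of every comparison experiment. Second,
matching holds for the $d$ constrained expectations only — microscopic
features of the distribution may differ even when the observables agree.

## The two models

**Ornstein–Uhlenbeck** (`ou_model(sigma0)`). $dx = \beta(\mu - x)dt +
\sigma_0 d\xi$ on $(-\infty,\infty)$; $A = (x, x^2)$, canonical exponent
coordinates $\alpha_c = (2\mu\beta, -\beta)$, scale $s = 1/\sigma_0^2$.
Because the first two moment equations close, the DME system — which
decouples into $d\mu^*/dt = \beta(\mu - \mu^*)$ and $d\beta^*/dt =
2\beta^*(\beta - \beta^*)$, independent of $\sigma_0$ — reproduces the
exact Gaussian dynamics $m(t), v(t)$ for *any* drive. The test suite
exploits this as an end-to-end oracle: step and sinusoidal protocols must
agree with the closed-form/ODE Gaussian solution to $10^{-6}$.

**Stochastic logistic island model with immigration** (`island_model()`).
$dn = [n(r - \lambda n) + m]dt + \sqrt{n}\,d\xi$ on $(0,\infty)$:
logistic growth at intrinsic rate $r$ [1/time], density regulation
$\lambda = r/K$ [1/(time·individuals)], immigration $m$
[individuals/time], demographic noise of per-capita variance 1 (a
Poisson(1)-offspring scale; the general noise coefficient is fixed at 1
throughout and is a documented non-goal). Observables $(n, -n^2/2, \log
n)$, $s = 2$. The stationary density $\propto n^{2m-1}
e^{-\lambda n^2 + 2rn}$ gives moment integrals

$$G(k) = \int_0^\infty n^{k+2m-1} e^{-\lambda n^2 + 2rn}\,dn
  \quad (k + 2m > 0),$$

with $(\log n)^j$-weighted companions $H(k,j) = 2^{-j}\partial^j
G/\partial m^j$. The reduction is no longer exact, and it *fails* for
$m \le 1/2$: the ansatz concentrates as $n^{2m-1}$ at the extinction
boundary and $\langle 1/n\rangle$, which enters $B$, diverges. The package
refuses such force vectors with an error that names the diverging quantity
(the boundary-layer construction that would repair weak migration is out
of scope), and `island_validity_frontier()` localizes the threshold
numerically — by probing the decay of shrinking-cutoff increments of the
$\langle 1/n\rangle$ integral, not by reading off the known constant.

## Numerical choices

* **Quadrature.** All island moments are computed by adaptive quadrature of
  the log-shifted integrand (absolute tolerance $10^{-12}$, relative
  $10^{-10}$), split at the integrand mode; the maximum of the log-weight
  is subtracted before exponentiation so large exponents (big $r^2/\lambda$)
  never overflow. The printed Kummer-function form of $G(k)$ is implemented
  (`island_G(..., method = "kummer")`, an all-positive-term ${}_1F_1$
  series, so double precision carries ~13 digits at the argument sizes the
  models produce) but serves as a cross-check only: quadrature is the
  production route, and the two must agree to $10^{-8}$ relative. $H(k,j)$
  uses direct log-weight quadrature; the $\partial/\partial m$
  finite-difference route (step $5\times10^{-5}\max(1,m)$, balancing
  truncation $\propto (2h\langle\log n\rangle)^2$ against quadrature noise)
  is the cross-check, because symbolic differentiation of the
  hypergeometric form is ill-conditioned.
* **Effective-force integration.** `deSolve::lsoda` (stiff-capable,
  adaptive) at rtol $10^{-8}$/atol $10^{-10}$, stopped and restarted at
  every declared protocol switch time so step-size control never straddles
  a jump. Validity ($m^* > 1/2$) is asserted at every right-hand-side
  evaluation and a violation aborts with the time of violation.
* **Linear algebra.** The systems $C y = B(\alpha - \alpha^*)$ are solved
  by Cholesky with a symmetric-eigendecomposition fallback; an indefinite
  $C$ raises an error reporting the smallest eigenvalue. $C$ is never
  inverted explicitly (a dense-inverse route exists only inside a test, as
  an oracle).
* **Moment matching** (`project_to_forces`). Recovering $\alpha^*$ from
  target expectations is solved as the convex dual problem
  $\min_\theta\,[\log Z(\theta) - \theta\cdot\mathrm{target}]$ in the
  exponent coordinates $\theta = s\alpha_c$ (gradient $\langle
  A\rangle_\theta - \mathrm{target}$), by box-constrained L-BFGS plus a
  damped Newton polish with the covariance Hessian. Plain Newton on the
  force coordinates is genuinely fragile here — the observables span many
  scales, $C$ has condition numbers up to $10^{13}$ at realistic carrying
  capacities, and an undamped iteration walks into the $m = 1/2$ boundary —
  which is why the implementation leans on convexity instead.
* **FPE solver.** Finite-volume Chang–Cooper (exponential-fitting) fluxes
  on a uniform cell-centered grid, zero flux through both walls, stiff
  banded `lsoda` in time. The scheme's discrete stationary state satisfies
  detailed balance identically (zero face fluxes to round-off) and
  converges to the analytic density at second order in the cell width —
  both are asserted in `test-fpe.R`. Mass is monitored at every output
  time (abort beyond $10^{-6}$ drift); negative excursions beyond $10^{-8}$
  of the peak abort, smaller ones are clipped as time-stepping round-off.
  The island grid's left wall sits at a small $n_{lo} > 0$ chosen so the
  analytic mass below it is $< 10^{-10}$: the density vanishes at 0 for
  $m > 1/2$, so a positive cutoff with zero flux is consistent and avoids
  the $g^2 = n$ coordinate singularity.
* **Grids for densities.** OU: linear, mean $\pm 10$ sd. Island: log-spaced
  over the $n^{2m-1}$ shoulder then linear through the bulk, up to the mode
  plus 12 Gaussian widths $\sqrt{1/(2\lambda)}$.
* **Birth–death reference.** The continuous-time chain uses rates
  $b_n = m + n(1+r)/2$, $d_n = n(1-r)/2 + \lambda n^2$ — one of many
  nonnegative splits (requiring $|r|\le 1$) whose difference reproduces the
  SDE drift exactly; the sum $m + n + \lambda n^2$ only approximates the
  SDE's variance $n$, so the chain is held to a looser standard (total
  variation $< 0.05$ against the FPE, stationary mean within 3%) than the
  continuum methods.

## The trajectory ensembles

`simulate_ou`/`simulate_island` generate the Monte-Carlo ground truth:
Euler–Maruyama at dt = 0.01 by default (chosen so drift·dt and the
per-step noise are small against the state scale for both worked parameter
sets; halving dt moves ensemble means by less than one Monte-Carlo
standard error, which is a test), 3000 trajectories for headline
comparisons, initial states drawn from the stationary density by seeded
inverse-CDF sampling. Euler steps can overshoot the island state below
zero even though the true $m > 1/2$ process cannot; the step is followed
by reflection $n \leftarrow |n|$, which — unlike clamping to zero — leaves
no artificial atom at the boundary (the stationary histogram check in
`test-simulate.R` is what that choice is answerable to). A single
`set.seed` per run governs initial draw and increments; ensembles are
bit-reproducible given (seed, dt, n_traj, protocol), at the cost that
changing n_traj reshuffles all draws.

What the ensembles emulate is exactly the SDE the FPE describes — they are
a discretization check, not an independent biological model. None of the
synthetic machinery introduces demographic structure, environmental
stochasticity, or multi-island coupling; conclusions drawn from passing
tests are claims about the reduction's fidelity to this one-dimensional
diffusion, not about real census data.

## Experiment design

`run_step_experiment` starts at the stationary state of $\alpha_0$ and
applies constant $\alpha_1$ from $t = 0$; `run_reversibility_experiment`
runs both directions and reports the symmetric Hausdorff distance between
the two paths projected on the first two force coordinates (the paths of a
nonlinear relaxation are not time-reverses of each other; any path-set
metric would do, Hausdorff is simply symmetric and parameter-free);
`run_periodic_experiment` alternates two force levels either abruptly
(square wave) or smoothly. The smooth drive is a cosine ramp between
levels with a configurable ramp fraction — the package's own choice of a
continuous, periodic, level-matching interpolation; alternatives are a
one-line config change. The periodic island experiments alternate the
carrying capacity between 20 and 50 by switching $\lambda$ between 0.005
and 0.002 at fixed $r = 0.1$, $m = 3$; a variant config with
$\lambda \in \{5, 2\}\times10^{-4}$ (K of 200 and 500) ships alongside.

`analyze_error_decay` fits $\log\mathrm{KL}$ against time on each
post-switch window. Because KL is continuous through a switch (both
densities are), the decay is fitted from the post-switch *peak* of the
transient, not from the switch instant, until the first ten-fold drop;
later increases above a $10^{-12}$ noise floor raise the non-monotonicity
flag. The step scenario's KL relaxes monotonically after its peak, while
under periodic re-switching every steady-state window shows the
drop-then-rebound pattern the flag is designed to catch.

## Problem sizes

Default sizes balance resolution against runtime and are stated here as
the package's reference configuration: 400 FPE cells (2500 when
fourth-order-in-h moment accuracy is needed, as in the OU
variance-tracking test), 81–601 output times per experiment, 3000
trajectories for Monte-Carlo comparisons, horizons of 10 (OU), 40–60
(island step/periodic), and 1600 time units for the adiabatic-limit check
(the slowest drive must beat the slowest relaxation mode, which for the
island target forces has rate $\approx 0.17$/time).

## Known limitations

* One state dimension only. The formalism generalizes; this implementation
  does not (the matrices would need multi-dimensional quadrature).
* Island validity requires $m > 1/2$ strictly; near the boundary the
  moment integrals become slow and ill-conditioned before they diverge.
* The island fixed point is approached at the physical relaxation rate
  ($\approx 0.17$/time for the K = 50 target), so force-space convergence
  to $10^{-6}$ takes $t \approx 110$, not a short horizon — the relevant
  test integrates that far.
* Time-dependent $\sigma(t)$ for the OU model is excluded; a smooth
  invertible $\sigma(t)$ can be absorbed into a time change, and only the
  constant-$\sigma_0$ form is implemented.
* The birth–death reference deliberately mismatches the SDE variance (see
  above); it bounds, rather than matches, the continuum solutions.
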