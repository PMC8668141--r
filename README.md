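# dmaxent

Dynamic maximum entropy (DME) reduction of one-dimensional stochastic
dynamics: replace a Fokker–Planck equation by a low-dimensional
deterministic ODE for *effective forces*, and check how much accuracy that
costs.

## The problem

Stochastic models in population biology — and many other fields — are
written as diffusions

    dx = (g²(x)/2) ∂ₓ[α(t)·A(x)] dt + g(x) dξ(t),

whose probability density u(t, x) obeys a Fokker–Planck equation (FPE) with
no-flux boundaries. When the forces α are constant the stationary density
is an exponential family,

    ū_α(x) = (1/Z) g⁻²(x) exp[s α·A(x)],

the maximum-entropy density constrained by the expectations of the
observables A(x). The DME approximation extends this to time-dependent
drives: the solution is represented at every instant by a stationary-form
ansatz ū_{α*(t)} whose *effective forces* α*(t) follow the closed
deterministic system

    dα*/dt = C⁻¹_{α*} B_{α*} (α(t) − α*),     C = ∂⟨A⟩/∂α* = s·Cov(A),

with B the Gram matrix of observable gradients under the stationary weight.
Instead of a PDE in x you integrate d ordinary differential equations, and
a point α*(t) summarizes the entire population-size distribution.

Two models are built in:

* **Ornstein–Uhlenbeck** (`ou_model`): dx = β(μ−x)dt + σ₀dξ, observables
  (x, x²), forces (μ, β). The reduction is *exact* — the effective-force
  system decouples into dμ*/dt = β(μ−μ*), dβ*/dt = 2β*(β−β*) — which makes
  the OU process the testbed where every numerical layer can be checked
  against closed forms.
* **Stochastic logistic island model with immigration**
  (`island_model`): dn = [n(r−λn) + m]dt + √n dξ, observables
  (n, −n²/2, log n), ecological forces (r, λ, m) (growth, density
  regulation λ = r/K, migration). The reduction is approximate; its moment
  calculus reduces to the integrals G(k) = ∫ n^(k+2m−1) e^(−λn²+2rn) dn,
  evaluated by adaptive quadrature and cross-validated against their
  confluent-hypergeometric (Kummer ₁F₁) closed form. The ansatz behaves as
  n^(2m−1) near n = 0, so the method requires m > 1/2 — weaker migration
  makes ⟨1/n⟩ diverge and the package refuses it with an explanatory error.

The validation stack — seeded Euler–Maruyama ensembles (`simulate_*`), a
conservative Chang–Cooper FPE solver (`solve_fpe`), a birth–death
transition-matrix reference (`build_birth_death`, `solve_master`), and
relative-entropy (KL) error tracking — lets every claim about the
approximation be measured rather than assumed.

## Worked example

An abrupt environmental step for the island model: the population sits in
the stationary state of weak growth and migration (r, λ, m) =
(0.05, 0.005, 1) (carrying capacity K = 10), and at t = 0 the environment
jumps to (0.1, 0.002, 3) (K = 50):

```r
library(dmaxent)
isl <- island_model()
f0 <- c(r = 0.05, lambda = 0.005, m = 1)
f1 <- c(r = 0.1,  lambda = 0.002, m = 3)
rep <- run_step_experiment(isl, f0, f1, horizon = 40, n_times = 81)
rep
#> <dme_comparison 'island'> t in [0, 40], methods: dme, fpe; max KL = 2.053e-04

idx <- match(c(1, 5, 10, 40), rep$times)
round(data.frame(t = rep$times[idx],
                 n_dme    = rep$observables$dme$n[idx],
                 n_fpe    = rep$observables$fpe$n[idx],
                 logn_dme = rep$observables$dme$logn[idx],
                 logn_fpe = rep$observables$fpe$logn[idx],
                 kl       = rep$kl[idx]), 5)
#>    t    n_dme    n_fpe logn_dme logn_fpe      kl
#> 1  1 21.81396 21.80907  2.98227  2.98097 0.00017
#> 2  5 37.44359 37.42656  3.55726  3.55615 0.00014
#> 3 10 52.35154 52.32673  3.91510  3.91437 0.00009
#> 4 40 68.82785 68.82704  4.21010  4.21009 0.00000
```

The mean population size ⟨n⟩ relaxes from ~10 to ~69; the three-dimensional
DME system tracks the full Fokker–Planck solution to within 0.05% at every
time, and the KL divergence between the FPE density and the DME ansatz
peaks at 2×10⁻⁴ nats before decaying to zero. The effective forces
themselves are *not* monotone — `rep$forces` shows r* dipping negative
before converging to 0.1 — even though the observables change smoothly:
that is the expected signature of representing a relaxing density by a
moving equilibrium family.

The same experiment with Monte-Carlo ground truth (`n_traj = 3000`), with
density snapshots, or under periodic drives
(`run_periodic_experiment`), is one call away; `inst/cli/dme.R` exposes the
same runs as shell subcommands driven by YAML configs (see
`inst/cli/configs/`).

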