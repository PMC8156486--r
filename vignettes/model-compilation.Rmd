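---
title: "Compiling categorical generative models into chemical kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling categorical generative models into chemical kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catflow)
```

## The idea

`catflow` treats a *prescribed steady-state distribution* over binary
chemical species as a generative model, and compiles it into dynamics that
attain that steady state. The same prescription can be realized at several
levels of description, and the package implements all of them behind one
set of model objects:

1. an **exact master equation** over the joint categorical distribution,
   `dp/dt = L p`;
2. **mean-field marginal dynamics**, one nonlinear ODE per species,
   coupled only through each species' Markov blanket;
3. **mass-action kinetics** in concentration units, whose rate constants
   are closed-form functions of the model parameters;
4. a **Michaelis--Menten reduction** that eliminates explicitly
   represented enzymes under a separation of timescales.

The payoff of the probabilistic reading is that every trajectory carries a
variational free energy
`F(p) = p . (log p - log p_inf) + z_inf`
— with `z_inf = 0` the Kullback--Leibler divergence to the steady state —
which the dynamics descend. Reaction networks then admit an inferential
interpretation: reaction rates are messages, a lesioned enzyme is a
changed prior, and the distributed consequences of a local lesion
(diaschisis) are the network re-attaining a different steady state.

## Master equations and the flow decomposition

A `rate_matrix` has columns summing to zero (probability conservation) and
non-negative transition rates off the diagonal. Its stationary
distribution is the right singular vector with singular value zero
(`steady_state()`); a singular value is treated as zero below `1e-10`
times the largest one, a scale-invariant threshold that is robust for
well-conditioned chains. The singular vector's sign is flipped to make it
non-negative and it is divided by its sum — the natural normalization for
a probability. Zero singular values beyond the first signal a reducible
chain and are reported as an error rather than silently resolved.

`decompose()` writes the generator as `L = (Q - Gamma) Lambda` with
`Lambda = diag(p_inf)^{-1}`, `A = L Lambda^{-1}`, skew `Q = (A - A^T)/2`
and symmetric `Gamma = -(A + A^T)/2`. The skew part is the solenoidal
(free-energy-conserving) component and the symmetric part the dissipative
one; detailed balance is exactly `Q = 0`. `simulate_mode()` integrates
either component alone. Solenoidal trajectories conserve the *linearized*
functional `p . Lambda p / 2` (exactly, by skew symmetry) and are
deliberately not clamped to the simplex — they can and do develop negative
coordinates, which is the honest behaviour of that flow. The exact free
energy is only reported on the simplex; off it, the trajectory is flagged
as unnormalized. The linearization comes from expanding
`grad F = 1 + log(Lambda p)` around `Lambda p = 1`; the package does not
claim a validity domain for it and uses it only as the solenoidal-mode
diagnostic.

All integration goes through one contract: `deSolve::lsoda` with relative
tolerance `1e-8` and absolute tolerance `1e-10`. A single stiff-capable
integrator keeps behaviour uniform between the benign master equations and
the stiff enzymatic systems later in the pipeline.

## Generative models and mean-field operators

A `generative_model` is a list of binary species (state order: present,
then absent) and conditional factors whose product is the joint steady
state. Kronecker ordering is fixed once: species in declared order, the
leftmost varying slowest, and every indicator row vector uses the same
order. Where a basis over variable subsets is needed, subsets are
enumerated by size and then by species order; this is the package's own
convention, documented rather than inherited.

Marginal dynamics for species `i` take the form
`dq1_i/dt = lambda_i (beta_1 + sum_k beta_k prod_{j in S_k} q1_j)`,
a weighted sum of products of presence probabilities over subsets `S_k`
confined to the species' Markov blanket (plus the species itself). The
`lambda_i` default to 1: they only set the time scale.

Two coefficient conventions coexist, and keeping them distinct matters:

* **Uncorrected** (`build_operator(..., corrected = FALSE)`, the default):
  coefficients balance against the *joint* steady state, so the operator
  row vector is exactly orthogonal to `p_inf`. This is the construction
  that makes the exact joint dynamics stationary, but — because a product
  of marginals is not the joint — the mean-field system it induces settles
  on marginals that differ from the model's.
* **Corrected** (`corrected = TRUE`, and all kinetic compilation):
  coefficients are solved so the *product of the target marginals* is the
  fixed point. For the two-block reaction structure this is the closed
  form `corrected_beta(alpha, n_substrates, n_products) =
  alpha^n_s / (1-alpha)^n_p`: the equilibrium constant with its numerator
  raised to the number of substrate species and denominator to the number
  of products.

For multi-reaction models each reversible conversion contributes a
forward/reverse constant pair. One side's constant is pinned to the
reaction's base rate (the `z` split: `lambda z` for one reaction of a
coupled pair, `lambda (1-z)` for the other) and the opposite side is
solved from the stationarity condition — against joint probabilities for
the uncorrected operators, against products of marginals for the corrected
ones. Non-equilibrium models declare constant sources and sinks; the
per-reaction steady throughput is then obtained by a minimum-norm
least-squares solve of `Omega phi = -sources`, and enters the balance as
an offset. Minimum norm is the tie-break because several coefficient
combinations can satisfy the constraints; it is reproducible and
unbiased.

One subtlety: with deterministic factors the information-theoretic Markov
blanket can be *smaller* than the set of species a reaction couples (a
fully determined co-substrate d-separates everything else). Operators are
therefore validated against the union of the blanket and the reaction
partners.

The initial condition matters: closed mean-field systems conserve linear
combinations of presence probabilities (left null vectors of the reaction
stoichiometry), so the prescribed marginals are reachable only from
initial states with the right conserved mass. `meanfield_simulate()`
checks this and warns instead of failing, since the off-manifold dynamics
are still well defined.

## From probabilities to concentrations

Concentrations are `u = N q1 / V` (`to_concentration()`): the presence
probability read as an occupied fraction of `N` molecules in volume `V`.
All bundled examples use `N = V = 1`, i.e. concentrations are
dimensionless multiples of `N/V`; there is no unit registry, because every
relation in the framework is scale-covariant and carrying units would add
nothing but bookkeeping. Under this mapping each extra molecule of
reaction order multiplies a rate constant by `V/N`.

For the five-species coupled pair `S1 + S2 <-> S3 <-> S4 + S5`,
`table1_constants()` gives the compiled constants

```
kappa1 = lambda V/N z (alpha2 - alpha1) / (alpha1^2 alpha2)
kappa2 = lambda z
kappa3 = lambda (1 - z)
kappa4 = lambda V/N (1 - z) alpha2 (alpha2 - alpha1) / (alpha1^2 (1 - alpha2)^2)
```

and for the open enzymatic system `S + E <-> C <-> P + E` with throughput
`c`, `table2_constants()` gives

```
kappa1 = lambda V/N (z - alpha1 z + c) / (alpha1^2 alpha2)
kappa2 = lambda z
kappa3 = lambda (1 - z)
kappa4 = lambda V/N ((1 - z)(1 - alpha1) - c) / (alpha1^2 (1 - alpha2))
```

Both sets are verified in two independent ways in the test suite: once as
frozen closed forms, and once by re-deriving them from the generative
model through the operator machinery. In the enzymatic model the
convention is that `alpha1` is the *free-enzyme* marginal (complex
`1 - alpha1`), and conditioned on the free enzyme the substrate is present
with probability `alpha2`; these are the only assignments under which the
constants above make the prescribed marginals stationary, which is how the
package fixes them. `kappa4 >= 0` is exactly the throughput bound
`c <= (1 - z)(1 - alpha1)`.

The source/sink is implemented as a constant influx `+c` on the substrate
and efflux `-c` on the product. A zeroth-order efflux would drive an empty
pool negative, so the efflux ramps linearly below a threshold of `1e-9`
concentration units. Two consequences are worth knowing. First, if
production never exceeds `c`, an empty product pool can legitimately pin
at zero — the sink swallows all production; this is real behaviour of a
constant-rate sink, not an artifact. Second, starting from an empty pool
the system sheds a small amount of the conserved substrate+complex+product
mass (of order `c` times the time production needs to reach `c`) before
the sink saturates, so its attained steady state sits on a very slightly
shifted conservation manifold. Analyses that need the exactly prescribed
marginals should start with the complex pre-formed, as the bundled tests
do where it matters.

## Michaelis--Menten reduction

With binding and unbinding much faster than catalysis (`z` close to 1) and
the reverse catalytic flux negligible (`c` close to its bound), the
complex equilibrates at `u_C = e_T u_S / (kappa_m + u_S)` with
`kappa_m = kappa2 / kappa1`, and the product formation rate is
`v_max u_S / (kappa_m + u_S)` with `v_max = kappa3 e_T`
(`e_T = u_E + u_C`, conserved). Some treatments scale `v_max` by the
binding constant `kappa1` as well; that convention is not consistent with
the quasi-equilibrium complex above — the reduced rate it produces does
not reproduce the full system's catalytic flux `kappa3 u_C` — so the
package uses `kappa3 e_T` and validates it by simulating the full
four-species system. `mm_reduce()` warns (rather than fails) when
`kappa3 >= kappa2`, since the approximation degrades continuously.

The reduction-quality study fixes `alpha1 = 0.95`, `alpha2 = 0.5`,
`c = 0.9 (1 - 0.99)(1 - alpha1)` and sweeps `z` over
`{0.5, 0.7, 0.9, 0.99}`, starting from `u_S = 0.9` with the complex
quasi-equilibrated. The parameters are chosen to sit squarely in the
regime the reduction assumes: a large free-enzyme fraction keeps the
complex pool small relative to the substrate pool (the reduced model has
no complex reservoir, so a large complex pool is unrepresentable), and a
throughput near its bound makes the neglected reverse catalytic flux
small at the largest `z`. Runs use a horizon of 6000 time units — a few
relaxation times of the slow substrate mode — which keeps the whole sweep
within seconds. The relative error of the reduced product trajectory
decreases monotonically along the sweep and is a few percent at
`z = 0.99`; exact figures are computed by the test suite and the
acceptance script, not quoted here.

## The inferential reading

In the enzymatic system, substrate and product are conditionally
independent given the enzyme/complex state, and their presence
probabilities sum to a constant at steady state (equal to `alpha1` in the
convention above). Each side's concentration therefore encodes an implicit
belief about the other: `implicit_beliefs()` computes
`q~_S = offset - q_P` and `q~_P = offset - q_S`, clipping transient
excursions outside `[0, 1]` with a warning.

`belief_free_energy()` scores each belief against the model's conditional
distribution of that species given the free enzyme, after renormalizing
the belief by the free-enzyme probability; the complex state — in which
both species are absent with certainty — is excluded by that
renormalization (it would otherwise contribute an infinite divergence for
any belief with mass on presence, which is a statement about support, not
about inference quality). This averaging convention is one of several
defensible readings of "averaged under the enzyme and complex
probabilities", and the package treats only its qualitative behaviour as
meaningful: both series decrease overall and vanish at steady state, and
the product-held belief shows a transient *increase* while the free-enzyme
probability (its data) collapses faster than the product concentration
(its belief) can adjust — a prediction error that is subsequently
suppressed. The mirrored-parameter symmetry (`alpha2 -> 1 - alpha2`,
`z -> 1 - z`, substrate and product initial conditions swapped, `c = 0`)
is exact and tested to `1e-8`.

## Reaction networks, lesions and diaschisis

`reaction_network()` assembles mass-action and Michaelis--Menten reactions
into a stoichiometry matrix with one column per *directed* reaction
(reversible pairs contribute two), plus constant sources. Conserved
moieties — left null vectors of the stoichiometry supported on source-free
species — are computed at assembly and checked along simulations.

`find_steady_state()` integrates in growing windows until the derivative
stays below `1e-8` across a full time unit (a sustained criterion: a
point-wise one can fire on slow crossings), then polishes with damped
Newton iterations to solver precision. Polishing is applied only to a
settled state; polishing an oscillator would jump to an unstable fixed
point and misreport convergence, which is why the horizon (default `1e4`
time units) exists and non-convergence is a reported state rather than an
error.

The bundled `metabolic` example encodes the qualitative architecture of a
sensed-and-secreting pathway: an external source feeds `S3` (the sensory
species), mass flows `S3 -> S2 -> S1` and branches to `S4 -> S5` and
`S6 -> S7`, with saturating efflux from the active species `S5` and `S7`.
All conversions are Michaelis--Menten (`v_max = 1`, `kappa_m = 1`) with
weaker reverse reactions (`v_max = 0.5`) so that back-pressure can
propagate upstream; the influx is `0.1`, far from saturating any step, so
the pre-lesion steady state keeps every species positive. The topology and
parameters live in a YAML spec, not in code, so users can substitute their
own network. `lesion()` silences one reaction's `v_max` — a parameter
change, never a structural one — and `diaschisis()` classifies each
species' steady-state change as lost / decreased / unchanged / increased
under a `1e-6` threshold. On the bundled example, lesioning `S1 -> S4`
extinguishes `S4` and `S5` and raises `S2` and `S6` (among others): the
loss of one efflux route is compensated by the other branch, at a
different steady state — the signature pattern of diaschisis.

## What the examples do and do not show

The bundled models are exact realizations of their generative models: they
demonstrate that the compilation chain (model, operators, constants,
reductions) is self-consistent, that steady states are attained with the
prescribed marginals, and that free energy behaves as a Lyapunov function.
They are not fits to measured kinetics: real enzymes have substrate pools
far exceeding `N = 1`, rate constants spanning orders of magnitude,
temperature dependence, and regulatory interactions none of which are
modelled here. Passing tests show the mathematics is implemented
correctly, not that any particular biochemical system follows it.

## Numerical choices, in one place

* lsoda everywhere, `rtol = 1e-8`, `atol = 1e-10`.
* Null-space threshold: singular value `< 1e-10 x` largest.
* Steady-state declaration: `||du/dt||_inf < 1e-8` sustained over one time
  unit; horizon `1e4`; Newton polish only after settling.
* `0 log 0 = 0` throughout free-energy evaluation; support violations are
  reported as infinite divergence, not as overflow.
* Sink ramp below `1e-9` concentration units; right-hand sides tolerate
  integrator undershoot to `-1e-6` and clamp it, but reject genuinely
  negative inputs.
* Minimum-norm least squares (SVD pseudoinverse, cutoff `1e-12` relative)
  for under-determined coefficient and throughput solves.
* CSV output at 17 significant digits; repeated runs are byte-identical.

## Known limitations

* Species are strictly binary; general categorical species would need a
  different operator basis.
* `build_operator()` requires a reaction annotation or a recognizable
  two-block reaction structure; arbitrary factor graphs without one are
  rejected rather than guessed at.
* The belief free-energy averaging convention is a documented choice;
  alternative conventions shift the curves quantitatively (the qualitative
  shapes are what the package asserts).
* SBML export is one-way; no import.
* No stochastic (jump-process) sampling: the package works with the
  distribution, not with realizations, and continuous-state
  Fokker--Planck dynamics are out of scope.
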