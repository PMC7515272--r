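---
title: "Steady-state diagram thermodynamics and MTEP optimization: models, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state diagram thermodynamics and MTEP optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtepkin)
```

# The model

An enzyme (or pump) is a Markov jump process on a finite set of functional
states connected by reversible first-order transitions. A transition
$i \to j$ carries forward and backward rate constants $k_{ij}, k_{ji} > 0$
(1/s) and the equilibrium constant $K_{ij} = k_{ij}/k_{ji}$. Binding and
release steps are pseudo-first-order: their effective constants are
second-order constants times the activity of the bound species, applied as
a pre-processing step (`with_concentrations()`). One mole of enzyme is
assumed throughout, and every transition is reversible — an enzyme that
catalyzes a forward step can catalyze its reverse, so zero backward rates
are disallowed and activities are floored at a configurable positive value
(default $10^{-30}$ M; the transition affinity diverges logarithmically at
a zero backward rate, so the floor caps, but does not distort, the
dissipation assigned to an effectively irreversible step).

At the stationary distribution $p$ the package reports, per transition,

$$X_{ij} = RT\,\ln\frac{k_{ij} p_i}{k_{ji} p_j}, \qquad
  J_{ij} = k_{ij} p_i - k_{ji} p_j, \qquad
  \sigma_{ij} = \frac{X_{ij} J_{ij}}{T} \ge 0,$$

in molar units (kJ/mol; kJ mol$^{-1}$K$^{-1}$s$^{-1}$) and in the
dimensionless per-molecule forms $X/RT$ and $\sigma/k_B$ (1/s), because
the theory is most natural per molecule while tabulated enzyme observables
are molar. Around any cycle the $p$-dependence of the affinities
telescopes away, leaving the cycle affinity $RT\ln K$ with $K$ the product
of the equilibrium constants (the Wegscheider closure; $K = 1$ is detailed
balance). The total entropy production satisfies the cycle decomposition
$T\sigma_{\mathrm{tot}} = \sum_c J_c X_c$ over any fundamental cycle basis,
which the package uses as an identity check (`cycle_decomposition()`).

## The diagram solution

`stationary_probabilities()` implements Hill's diagram (King–Altman)
method: $p_i$ is proportional to the sum over all spanning trees of the
underlying multigraph of the product of rate constants with the tree's
edges directed toward $i$. Enumeration is exact and exhaustive; parallel
edges (the light and thermal paths of a photocycle) are distinct. This is
deliberate: every scheme of interest here has at most eight states, where
exhaustive enumeration costs microseconds and the combinatorial route gives
probabilities as ratios of sums of positive products — no linear-algebra
cancellation. The spanning-tree count is cross-checked against the
matrix-tree determinant.

For a chosen transition $e = (i, j)$ the trees split into those containing
$e$ and those not. This yields the decomposition (`diagram_sums()`)

$$p_i \propto b_{ij} + \tfrac{k}{K}a, \quad p_j \propto b_{ji} + k a, \quad
  \Sigma = k\,\Sigma_a + \Sigma_b,$$

whose coefficients are independent of $k = k_{ij}$, so the steady state is
a closed-form function of one rate constant — the engine of the MTEP
optimizer. A bridge (cut) edge has $b_{ij} = b_{ji} = 0$, zero flux for
every $k$, and is flagged degenerate.

## MTEP: maximizing one transition's dissipation

With $K_{ij}$ fixed, $J_{ij}(k)$ is monotonically increasing and
$X_{ij}(k)$ monotonically decreasing, so
$\sigma_{ij}(k) = J\,X/T$ vanishes at both ends of the $k$ axis and has a
unique interior maximum. `maximize_transition_ep()`:

1. maximizes $\log \sigma$ over $\log k$ with golden-section search
   (`stats::optimize`) on a bracket $[k/10^8,\,k\,10^8]$ around the current
   value, expanded geometrically (factor $10^4$ per side) until the profile
   decreases at both ends;
2. polishes the optimum by root-finding the analytic stationarity
   condition
   $\Sigma_b L (K b_{ij} + k a)(b_{ji} + k a) =
    k a (K b_{ij} - b_{ji})(k \Sigma_a + \Sigma_b)$
   with $L = X/RT$, to relative tolerance $10^{-14}$ in $k$;
3. verifies the result four ways: the stationarity residual
   $|d\sigma/dk|\,k/\sigma$ from the analytic derivative; agreement of the
   maximized value with the closed form
   $$\sigma(k^0)/k_B = \frac{a\,(k^0)^2 (K b_{ij}-b_{ji})^2}
     {K\,\Sigma_b (k^0 a + K b_{ij})(k^0 a + b_{ji})}$$
   to $10^{-8}$ relative (disagreement is a hard failure); a grid scan
   confirming unimodality; and re-evaluation of the maximum by full
   steady-state recomputation.

The closed form above was re-derived from the product rule on
$\sigma(k) = J(k)X(k)/T$ in its diagram-sum form; the derivation
reproduces the stationarity condition exactly, and the maximal value
carries $1/K$ where a $K$ might be expected from a casual reading —
the package trusts the derivation, which matches the numerical maximum to
machine precision on every tested scheme.

Maximizing one transition's entropy production does **not** in general
increase the total entropy production: the test suite pins a seeded
counterexample (found by random search over generated schemes) where a
chord optimization lowers $\sigma_{\mathrm{tot}}$, mirroring the known
behaviour of upstream steps of multi-step isomerase cycles. Joint
optimization of two transitions (`joint_iterative_optimization()`) is
cyclic coordinate ascent — alternately optimizing each transition and
substituting — with convergence declared when both constants move by less
than $10^{-6}$ relative between sweeps (at most 100 sweeps). Whether
"simultaneous" maximization means coordinate-wise iteration or a true 2-D
search is genuinely open; coordinate-wise is the default here because each
1-D subproblem is unimodal with a closed-form objective, and the
order-invariance of the fixed point is itself tested.

## Catalytic constants

For a single-binding-site cycle with the product activity at the floor,
the diagram solution makes the cycle flux an exact rectangular hyperbola
in the substrate activity, $J(S) = k_{cat} S/(K_M + S)$.
`catalytic_parameters()` identifies $k_{cat}$ and $K_M$ exactly from two
substrate activities via the double-reciprocal line — equivalent to the
symbolic solution for these schemes — and cross-checks $k_{cat}$ by a
numeric saturation limit at $S = 10^6 K_M$.

# The light-driven extension

A photocycle adds, between the ground state (1) and excited state (2), a
light edge L with absorption rate $\alpha_{01}$ and a non-radiative decay
edge D with decay rate $k_d$, as genuine parallel edges. Their
relaxation-direction equilibrium constants are
$K_L = e^{h\nu/k_B T_R}$ and $K_D = e^{h\nu/k_B T}$, with $T_R > T$ an
effective radiation temperature, so declared $1 \to 2$ the edges carry
$K_{\mathrm{eq}} = 1/K_L$ and $1/K_D$. This orientation is the only one
for which the L–D cycle affinity is the Carnot-like photon driving force
$RT \ln(K_D/K_L) = N_A h\nu\,(1 - T/T_R) > 0$ and the pump cycles forward;
the package exposes the alternative closure orientation behind a flag but
does not default to it, because at a negative (opposing) secondary force it
cannot pump.

The productive cycle closes thermodynamically on the secondary force: the
all-thermal pathway D + T1..T7 has no photon input, so its
equilibrium-constant product must equal $e^{X_{sec}/RT}$, which fixes
$K_1$ (`close_cycle_equilibrium_constant()`). The transduction efficiency
uses input power $X_{\mathrm{photon}} J_L$ with
$X_{\mathrm{photon}} = RT\ln(K_D/K_L)$ and output power $-X_{sec} J$; with
these conventions the steady-state energy balance
$T\sigma_{\mathrm{tot}} = X_{\mathrm{photon}} J_L + X_{sec} J$ is exact
(it is the fundamental-cycle decomposition with chords L and T7), so
$0 \le \eta < 1$ always — this balance is asserted in the tests rather
than stated on faith.

Parameters of the packaged photocycle: $\alpha_{01} = 100$ /s,
$k_d = 10^8$ /s, $k_1 = 2.5\times10^{11}$ /s ($= 1/4$ ps), $k_7 = 700$ /s,
$K_7 = 2\times10^7$, $\lambda = 570$ nm, $T = 298.16$ K. The intermediate
T2..T6 rate constants of the reference photocycle model were never
published, so they are required inputs; `synthetic_br_photocycle()`
supplies a clearly-labelled synthetic set ($k = 4600, 1550, 920, 710, 575$
/s; $K = 6, 3.3, 2.6, 2.3, 1$) chosen so the intermediates hold a few
percent occupancy each and the pump still runs at a secondary force of
$-123$ kJ/mol; they are stand-ins for exercising the machinery, not a
reconstruction of any published rate set. The effective radiation
temperature is likewise a model input; the synthetic default
$T_R = 1570$ K is the package's own reconstruction from the published
light-step dissipation and excited-state occupancy at $\alpha_{01} = 100$
/s, fixed before any testing and not revisited. Fixture tables also store
published state probabilities alongside published Shannon entropies even
though the two are mutually inconsistent (the entropy of the printed
occupancies is about 1.57 nats where 1.28 is printed); both are retained
and flagged rather than reconciled.

# Numerical choices

**Scaling.** Directional-diagram weights are products of up to $n-1$ rate
constants spanning, in the photocycle, fourteen orders of magnitude; all
weights are accumulated on rates scaled by their geometric mean and
rescaled once at the end.

**Stable fluxes and affinities.** The naive $k_{ij}p_i - k_{ji}p_j$
cancels catastrophically on bridge edges (true flux exactly zero) and near
equilibrium. For each spanning tree not containing the edge, the two
oppositely-rooted diagrams differ only along the tree path between the
edge's endpoints, giving
$k_{ij}w_i - k_{ji}w_j = k_{ji}w_j\,\mathrm{expm1}(\ln K_{\mathrm{cycle}})$
— subtraction-free, exactly zero at detailed balance. When a single cycle
term is exponentially larger than the net flux this form is in turn the
worse-conditioned one, so the implementation accumulates a rounding bound
alongside the sum and falls back to the plain difference per edge whenever
that bound exceeds the plain form's. Affinities use
$\mathrm{log1p}$ of the stable numerator near equilibrium and the plain
log-ratio otherwise. These choices are why the Kirchhoff current law and
the cycle-decomposition identity hold to $\sim10^{-14}$ relative in the
test suite rather than $\sim10^{-7}$.

**The independent oracle.** `steady_state_oracle()` solves the linear
stationarity conditions by GTH (Grassmann–Taksar–Heyman) state reduction,
a subtraction-free elimination that attains small *componentwise* relative
error even when stationary probabilities span tens of orders of magnitude
— a plain LU null-space solve cannot certify the $10^{-10}$ relative
agreement demanded of it. The oracle shares no code with the spanning-tree
solver.

**Grid oracle for the optimizer.** The brute-force check of the MTEP
maximizer is a $10^4$-point log-spaced scan of the optimizer's bracket,
each point re-solved from scratch through the GTH path, refined by a
second scan of $2\times10^4$ points across one coarse-grid cell around the
argmax; the refined grid resolves $\sim 4\times10^{-7}$ relative, against
which the optimizer is required to agree to $10^{-6}$.

**Degenerate inputs.** Two-state (single-edge) schemes are supported and
report zero flux and dissipation everywhere; MTEP on a bridge or on a
zero-force transition raises a "flat profile" error; absorbing
(non-ergodic) schemes are rejected, not regularized. Validation never
raises — it returns the complete list of violations.

# The random-scheme generator

Property tests and the acceptance script draw schemes from
`generate_random_scheme()`: a uniform random attachment tree (3–8 states)
with log-uniform rates in $[10^{-3}, 10^6]$ /s, plus up to three chord
edges whose backward rates are closed so each chord's fundamental cycle
realizes a prescribed affinity drawn uniformly from $X/RT \in [-20, 20]$.
The construction is thermodynamically consistent by design and exactly
deterministic given a seed (the session's RNG state is restored). It
emulates the *structure* of enzyme schemes — small, sparse, reversible,
with few cycles and widely spread rates — but not their biochemical
correlations: real schemes have rates tuned by evolution, concentrate
force on binding/release steps, and couple cycles through shared edges.
Passing the property suite therefore certifies the solver and optimizer
mathematics across the relevant regime of graph shapes and conditioning,
not the realism of any particular enzyme parameterization; the fixture
models carry that role.

Test problem sizes — 200 schemes for oracle equivalence, 50 for MTEP
verification, 60 for conservation laws, $3\times10^4$ grid points per
optimizer check — were chosen as the smallest sets that exercise every
state count and cycle multiplicity combination several times over;
enlarging them has shown no new behaviour.

# Known limitations

- Exhaustive tree enumeration is exponential in principle; the package is
  not intended for graphs beyond ~10 states (no iterative or sparse
  solvers).
- No time-dependent kinetics: steady states only, no relaxation or
  periodic driving.
- Optimization is one rate constant at a time under fixed equilibrium
  constants (plus the two-transition coordinate ascent); no global search
  over all constants, no other constraint sets.
- The photocycle model is the unbranched eight-state cycle; branched
  recovery pathways are out of scope.
- The affinity-transfer efficiency reported in some published photocycle
  tables is defined in work not reproduced here; it is stored as fixture
  data only.
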