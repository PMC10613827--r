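---
title: "Biokinetic compartment models, the matrix exponential, and stiff-solver diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biokinetic compartment models, the matrix exponential, and stiff-solver diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biokinet)
```

## The model

A biokinetic model partitions the body (and its excretion routes) into
first-order compartments. For decay-chain member $i$ in compartment $j$,

$$\frac{\mathrm{d}A_{i,j}}{\mathrm{d}t}
  = \sum_{k \ne j} A_{i,k}\,\lambda_{i,j,k}
  - A_{i,j}\Big(\sum_{k \ne j}\lambda_{i,k,j} + \lambda^D_i\Big)
  + \sum_{p} A_{p,j}\,\beta_{p,i}\,\lambda^D,$$

with transfer rates $\lambda$ in d$^{-1}$, decay constants $\lambda^D$, and
branching fractions $\beta_{p,i}$. Stacking the states chain-member-major
gives $Y' = AY$, $Y(0) = Y^0$ with a constant matrix $A$ that is Metzler
(non-negative off-diagonals) within each member's block and block lower
triangular across members, since only parents feed progeny.

**Units convention for the ingrowth term.** Which decay constant multiplies
$\beta_{p,i}$ depends on what the state *is*. If $Y$ counts atoms (or any
amount-like quantity), mass balance requires the **parent's** constant:
each parent decay removes one parent atom and creates $\beta$ child atoms,
and column sums of a single-member model are exactly $-\lambda^D$. If $Y$
is expressed in activity units ($A = \lambda N$), the same physics
re-expressed carries the **progeny's** constant on the ingrowth term. Both
are internally consistent; `assemble_matrix(ingrowth = )` implements both,
with `"parent"` as the default because the amount-balance convention makes
conservation directly checkable (total of a closed single-nuclide model
decays as $e^{-\lambda^D t}$ to rounding, which the tests assert). The
Bateman oracle (`bateman_chain()`) uses the same default convention, so the
two routes are comparable term by term. Mixing conventions between model
definition and interpretation is the one error to avoid.

Other structural decisions:

* **State ordering** is chain-member-major with compartments in declaration
  order. This makes the cross-member coupling strictly below-diagonal,
  which is also what makes assembly permutation-equivariant per block (a
  tested property).
* **Excreta are explicit sink compartments** (`in_body = FALSE`), never
  implicit losses, so whole-body + excreta conservation is testable
  exactly.
* **Duplicate transfer entries** (same donor, receiver, nuclide) are summed
  with a warning — published pathways are sometimes printed split.
* **Validation returns violations** rather than raising, so a user can
  collect every defect of a hand-written model file in one pass.

## The matrix exponential

The linear system has the exact solution $Y(t) = e^{At}Y^0$, and the
package's reference solver is an own implementation of the Padé
rational approximation with scaling and squaring:

$$R_{pq}(B) = D_{pq}(B)^{-1} N_{pq}(B), \qquad
N_{pq}(B) = \sum_{j=0}^{p} \frac{(p+q-j)!\,p!}{(p+q)!\,j!\,(p-j)!}B^j,$$

with $D_{pq}$ the analogous polynomial in $-B$. Numerical choices:

* **Diagonal orders only** in the ladder $\{3, 5, 7, 9, 13\}$, selected by
  the standard 1-norm thresholds; when even order 13 is not admissible the
  matrix is scaled by $2^{-s}$ and the result squared $s$ times. This
  avoids *over*-scaling (squaring amplifies rounding error) while keeping
  the approximant in its accurate regime.
* **Coefficients by ratio recurrence**
  $c_j/c_{j-1} = (p-j+1)/((p+q-j+1)\,j)$ — no explicit factorials, exact in
  double precision for every order used.
* **The denominator is solved, never inverted** (`solve(D, N)`), for
  conditioning; a singular $D$ is reported as an insufficient-scaling
  error rather than silently producing garbage.
* **Eigen-decomposition is deliberately not offered.** Compartmental
  matrices with similar consecutive rates are nearly defective; eigenvector
  bases degenerate precisely on the models of interest. Padé
  scaling-and-squaring has no such failure mode.
* **Propagation** advances the state by $y_{n+1} = e^{A\,\Delta t_n}y_n$,
  caching $e^{A\Delta t}$ per distinct step so a log-spaced grid costs one
  exponential per distinct spacing. Tiny negative entries (roundoff) are
  clipped at $10^{-12}$ with a logged count; values at $10^{-45}$ are
  physically indistinguishable from zero in this problem class, and the
  clip threshold sits comfortably above rounding and below anything
  meaningful.

An independent check in the test suite compares this route against
`Matrix::expm` and against a 40-term truncation of the defining power
series on small-norm matrices; the propagator is additionally checked
against the closed-form Bateman chain (implemented via confluent divided
differences, so the equal-rate degenerate case is exact rather than a
perturbation hack) and against a tightly-toleranced adaptive implicit
integration.

## Solver profiles

Six adaptive methods are exposed through one adapter over deSolve: the
explicit pairs RK45 (Dormand–Prince 5(4)), RK23 (Bogacki–Shampine 3(2)) and
DOP853 (order 8(7) Dormand–Prince — the nearest available order-8 explicit
pair), the implicit Radau IIA order 5 and variable-order BDF, and LSODA
with automatic Adams/BDF switching. Three protocols matter in practice:

| profile | rtol | atol | max step |
|---|---|---|---|
| `default` | 1e−3 | 1e−6 | free |
| `customized` | 1e−12 | 1e−15 | free |
| `customized2` | 1e−12 | 1e−15 | 0.2 d |

The `customized` protocol is what makes implicit methods track the exact
solution on stiff systems; `customized2` adds the step bound that the very
stiffest fast-clearing scenarios need. On one point the available
descriptions of this protocol family disagree about which of the two
tolerances is $10^{-12}$ and which $10^{-15}$; this package fixes
rtol = 1e−12, atol = 1e−15 (the strict-relative reading) and exposes both
fields, so either ordering is one constructor call away.

Two adapter decisions:

* **Analytic Jacobian by default.** The system is linear with constant
  $A$, so the exact Jacobian is free; `jacobian = "fd"` restores the
  finite-difference behaviour of stock front ends for faithful
  reproduction of that setup (the two agree to ~1e−9 on the toy fixture,
  which the tests check).
* **A step-count cap** (`maxsteps`) bounds the runtime of explicit methods
  on stiff systems, which otherwise grind through hundreds of thousands of
  stability-limited steps. A capped run reports `success = FALSE` with the
  integrator's message and a partial solution — failure is data here, not
  an exception, because diagnosing divergence is half the package's point.

## Diagnostics

**Stiffness ratio.** $\mathrm{SR} = |\lambda_L|/|\lambda_S|$ over the
retained spectrum, discarding eigenvalues with $|\lambda| <
10^{-12}\max|\lambda|$ or non-negative real part (closed systems and sinks
contribute zeros that would make the ratio undefined; the $10^{-12}$
relative floor is double-precision scale). The diagonal bound
$\max_i |A_{ii}|/\min_i |A_{ii}|$ over non-zero loss terms is reported
alongside; it is often quoted as a lower bound on SR but that inequality is
not a theorem for arbitrary compartmental matrices, so the package reports
both and enforces nothing.

**Amplification factor.** $G_n = |q_{n+1}/q_n|$ per consecutive grid pair;
$G \le 1$ over time is the stability criterion. Steps with $|q_n| <
10^{-30}$ are masked — ratios between numerically-zero values (integrators
alternating between exactly 0 and ~1e−45) carry no information. Note $G$ is
grid-dependent: every report records its grid, and the default grid is
$t = 0$ plus 600 log-spaced points from $10^{-2}$ d to 18 262.5 d
(50 y × 365.25 d/y), resolving fast early clearance and slow late retention
simultaneously.

**Divergence grading.** Published solver comparisons grade runs
None/Moderate/High without printing criteria; this package operationalizes
the qualitative language (oscillating derivatives, negative solutions,
divergent solutions) as:

* *negative*: any value below $-\max(\mathrm{atol},\,100\,\varepsilon\,s_0)$,
  where $s_0$ is the run's initial total and $\varepsilon$ machine epsilon.
  The second term matters only for atol below ~1e−14: a strictly-toleranced
  implicit run on a unit-scale problem emits rounding residues of a few
  $10^{-15}$, which are unrepresentable as genuine negativity — flagging
  them would grade the best runs as badly as sloppy ones.
* *oscillatory*: ≥ 3 sign changes of the discrete derivative at amplitude
  beyond $10^3\,$atol.
* *divergent*: $G > 10$ on ≥ 2 consecutive unmasked steps, any non-finite
  value, or growth beyond $10^3 \times$ the initial total (a retention
  fraction cannot legitimately dwarf the intake).

Grade **None** = no flags; **Moderate** = negativity only, within
$10^3\,$atol; **High** = anything worse. Transient $G$ slightly above 1 in
individual organs (inter-compartmental exchange) does *not* trigger a flag
by itself — stability is judged over time, which is why the divergent flag
requires sustained or unbounded growth.

**Relative differences.** $\mathrm{RD}\% = (\text{test} -
\text{ref})/\text{ref} \times 100$, masked where $|\text{ref}| < 10^{-30}$.
Relative differences against values near the resolution floor are noise by
construction; the comparison report shows exactly this blow-up when asked
to compare into the deep tail, and that is a feature of honest reporting,
not a defect to hide.

## The synthetic generator

`generate_stiff_model(n, target_log10_SR, seed)` builds fixtures whose
total outflow rates are log-equispaced over exactly `target_log10_SR`
decades (then shuffled over compartments), with each donor splitting its
outflow between a random receiver and a guaranteed route to a sink.
Construction guarantees: Metzler structure, column sums $\le 0$
(dissipative, so all eigenvalues have non-positive real parts by Gershgorin
column discs), validity, and bit-reproducibility per seed (the generator
saves and restores the caller's RNG state). The fixed
`toy_respiratory_model()` adds the *topology* that makes inhalation hard:
competing mechanical (ET → oesophagus → stomach → faeces) and dissolution
(fast/slow → blood → systemic → urine) clearance from shared deposition
compartments, with rates spanning seven decades. Its default decay constant
is 0 so conservation is exact and the diagonal spread reflects transfer
structure alone; decay variants take the constant as an argument.

What the generator does *not* emulate: real ICRP compartment inventories or
transfer-coefficient values (all fixture rates are invented and labelled as
such), age- or time-dependent rates, nonlinear kinetics, and the particular
eigenvalue clustering of real published models. Passing tests on these
fixtures therefore demonstrates correctness of assembly, propagation and
diagnosis across the stiffness range — not agreement with any published
dosimetric quantity, which requires user-supplied coefficient files.

## Problem sizes and test design

The suite exercises fixtures of 6–14 compartments over stiffness spreads up
to $10^{12}$, grids of 40–600 points, and 50-fixture random batches for the
series-oracle checks; the full suite runs in well under a minute. Two test
bands deserve explanation:

* The propagate-vs-implicit-oracle comparison applies its $10^{-6}$
  relative bound where retention exceeds $10^{-10}$: below that, the
  *oracle's* own absolute-tolerance floor (atol $10^{-18}$ is the tightest
  the integrator sustains) dominates the comparison. The matrix
  exponential, not the adaptive integrator, is the accurate route at tiny
  magnitudes.
* The all-methods agreement check on non-stiff fixtures uses the mixed band
  $|e| \le 10(\mathrm{rtol}\,|y| + 10^3\,\mathrm{atol})$: any adaptive
  method at default tolerances accumulates an absolute noise floor of
  roughly $10^3 \times$ atol over a run, so a purely relative bound is
  unattainable — by every solver — once the true solution decays beneath
  it. This is the same small-value effect discussed under relative
  differences above.

## Known limitations

* Linear, constant-coefficient kinetics only; no sources after $t = 0$.
* The Padé propagator is dense ($O(N^3)$ per distinct step); systems with
  thousands of states would want Krylov/action-of-exponential methods,
  which are out of scope.
* Divergence grading is heuristic by necessity; the flags and thresholds
  are documented above and configurable where they are parameters.
* Wall-clock timings in reports are informational only — they are
  hardware- and load-dependent and are never part of any assertion.
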