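# biokinet

Compartmental biokinetic modelling of radionuclide intake and retention,
with a semi-analytical matrix-exponential solver, configurable adaptive
stiff/non-stiff integrators, and stiffness/stability diagnostics.

## The problem

Internal dosimetry describes the uptake, retention and clearance of an
incorporated radionuclide as a network of first-order compartments (organs,
tissues, tract segments, excreta). For chain member *i* in compartment *j*
the activity A obeys

    dA[i,j]/dt =  Σ_{k≠j} A[i,k] λ[i,j,k]
                − A[i,j] ( Σ_{k≠j} λ[i,k,j] + λD_i )
                + Σ_{parents p} A[p,j] β[p,i] λD

with fractional transfer rates λ in d⁻¹, physical decay constants λD, and
branching fractions β. Stacking all (member, compartment) states gives the
linear system **Y′ = A Y**, Y(0) = Y⁰ with a constant Metzler-structured
coefficient matrix.

Inhalation models are the hard case: fast mechanical transit (tens per day)
and slow particle dissolution (down to 1e−5 per day) coexist in one matrix,
so the system is severely *stiff* — the eigenvalue spread (stiffness ratio
SR = |λ_L|/|λ_S| after discarding zero eigenvalues) reaches 1e17–1e22 for
realistic coupled respiratory-tract + systemic models. Explicit integrators
oscillate, go negative, or diverge; even implicit ones need deliberate
tolerance and step-size configuration. This package is for dosimetrists and
modellers who need to (a) solve such systems reliably, and (b) *quantify*
how any given solver configuration behaves on them.

What it provides:

* **model_core** — declarative model definition (compartments, transfers,
  decay chains, initial deposition), validation, sub-model coupling with
  namespacing, and assembly of the coefficient matrix
  (`biokinetic_model()`, `couple_models()`, `assemble_matrix()`);
* **matrix exponential** — an own implementation of the Padé
  scaling-and-squaring exponential (orders 3/5/7/9/13, 1-norm ladder) and
  the step propagator `y_{n+1} = e^{AΔt} y_n` with per-Δt caching
  (`pade_rational()`, `expm_matrix()`, `propagate()`), plus a Bateman
  closed-form chain oracle (`bateman_chain()`);
* **ode_solvers** — a uniform adapter over deSolve's adaptive integrators
  (RK45, RK23, DOP853, Radau IIA-5, BDF, LSODA) with the three standard
  protocols: `default` (rtol 1e−3, atol 1e−6), `customized` (rtol 1e−12,
  atol 1e−15), `customized2` (customized + max step 0.2 d)
  (`integrate_model()`, `standard_profiles()`);
* **diagnostics** — stiffness ratio with the zero-eigenvalue discard rule,
  per-step amplification factors G = |q_{n+1}/q_n|, divergence grading
  (None / Moderate / High), percent relative differences, group/whole-body
  aggregation (`stiffness_ratio()`, `amplification_factor()`,
  `stability_summary()`, `relative_difference()`, `aggregate_retention()`);
* **synthetic models** — seeded generators of Metzler fixtures with
  controllable stiffness spread and a fixed stiff respiratory-tract-like
  toy model (`generate_stiff_model()`, `toy_respiratory_model()`), so the
  whole pipeline is testable without any external data;
* **io / cli** — JSON model files, CSV retention tables with provenance
  headers, external-reference comparison, and a command-line front end
  (`inst/cli/biokinet.R`: `solve`, `diagnose`, `compare`, `fixture`).

ICRP transfer-coefficient values are *not* bundled: they are user-supplied
input (JSON model files), as are any reference retention exports.

## Worked example

```r
library(biokinet)

toy <- toy_respiratory_model()     # fixed stiff 10-compartment fixture
toy
#> <biokinetic_model> 'toy_respiratory'
#>   compartments: 10 (8 in-body)
#>   transfers:    13
#>   chain:        toy_nuclide

stiffness_ratio(assemble_matrix(toy))
#> <stiffness_report> SR = 1.238e+07 (|lambda| in [8.889e-06, 110],
#>                    2 discarded); diag bound = 1.1e+07

grid <- default_grid(n = 300)                 # 0 + log-spaced to 50 y
sol  <- propagate(toy, grid = grid)           # exact (expm) solution
wb   <- aggregate_retention(sol, groups = list(excreta = c("FAECES", "URINE")))
round(wb$values[c(1, 151, 301), ], 4)
#>      excreta whole_body
#> [1,]  0.0000     1.0000
#> [2,]  0.4960     0.5040
#> [3,]  0.9136     0.0864

run_comparison(toy, list("Radau-customized", "BDF-customized"), grid = grid)
#>              label success grade max_G_whole_body   rd_min    rd_max
#> 1 Radau-customized    TRUE  None            0.999 -8.8e-09 1.255e-08
#> 2   BDF-customized    TRUE  None            0.999 -8.8e-09 1.488e-09
#> 3             expm    TRUE  None            0.999  0.0e+00 0.000e+00
```

Reading this: the fixture's eigenvalues span seven decades (stiff); the
exact propagation moves ~50% of the unit intake to excreta by the middle
grid row (~14 d on the log grid) and ~91% by 50 years; both strictly-toleranced
implicit integrators track the matrix-exponential whole-body retention to
within ~1e−8 %, their whole-body amplification factors stay below 1, and no
run is flagged negative, oscillatory or divergent (`grade None`).

The same operations are scriptable from a shell:

```sh
Rscript inst/cli/biokinet.R fixture --seed 42 --n 12 --log10-sr 10 --out fix.json
Rscript inst/cli/biokinet.R diagnose --model fix.json
Rscript inst/cli/biokinet.R solve --model fix.json --method Radau \
    --profile customized --grid-spec log:1e-2:18262.5:600 --out retention.csv
Rscript inst/cli/biokinet.R compare --model fix.json \
    --profiles Radau-customized,BDF-customized --report report.csv
```

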