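# rhinocomp

Comparing two airway geometries under constant flow, constant pressure, or
constant power forcing.

## The problem

When computational fluid dynamics is used to judge a nasal surgery — or to
compare any two upper-airway anatomies — a global constraint must be chosen
to drive the flow, and the choice changes the answer. Three options exist,
borrowed from the study of forced duct flows:

* **CFR** (constant flow rate): enforce the same volumetric flow rate
  `Q = Q0` in both anatomies — physiologically, the same oxygen-consumption
  rate;
* **CPG** (constant pressure gradient): enforce the same ambient-to-throat
  pressure drop `Δp = Δp0`;
* **CPI** (constant power input): enforce the same mechanical pumping power

  ```
  P = Q Δp = −Q p_th ,
  ```

  with `p_th` the throat pressure relative to the ambient reference
  (`p = 0` outside the nose, `p_th < 0` during inspiration) —
  physiologically, the same ventilation effort from the lungs. In a
  time-stepping solver CPI is realized with the one-step-lagged controller
  `p_th(t) = −P0 / Q(t − dt)`.

For a single anatomy the three are equivalent: a CFR run at `Q0` yields some
mean `Δp0` and `P0 = Q0 Δp0`, and re-running the same anatomy under CPG at
`Δp0` or CPI at `P0` returns the same state. As soon as two *different*
anatomies are compared (pre-surgery versus post-surgery), the outcomes
diverge: the apparent change in the clinical summary quantity, the nasal
resistance

```
R = Δp / Q     [Pa·s/m³],
```

depends strongly on the forcing. For a resistance-lowering surgery the
reduction in `R` is largest under CFR, smallest under CPG, with CPI in
between (for a purely quadratic pressure–flow law the post/pre resistance
ratios are `f`, `f^(2/3)` and `f^(1/2)` respectively, where `f` is the
coefficient-reduction factor).

`rhinocomp` packages this comparison problem for desk-scale study:

* `forcing_core` — the sign conventions, power identity, CPI controller,
  resistance and time-averaging utilities shared by every flow model;
* `lumped_airway` — a quasi-steady lumped network (two nasal passages in
  parallel, a pharyngeal segment in series, each with
  `Δp = aQ + bQ²`), with closed-form oracles and root-found steady states
  under each forcing;
* `duct_solver` — a 2D unsteady incompressible Navier–Stokes solver
  (projection method, staggered grid, CFL-limited adaptive stepping) on a
  channel with a one-wall constriction, realizing all three forcings as
  boundary conditions;
* `comparison_engine` — the six-run pre/post protocol and a report-only
  mode that reproduces published table arithmetic from `(Q, Δp)` pairs;
* `synthetic_case` — seeded generation of matched pre/post model pairs
  emulating a unilateral resistance-lowering surgery;
* `cli` — `simulate`, `compare`, `make-fixtures` and `sweep` commands
  driven by JSON configuration files.

## Worked example

Calibrate a pre-operative lumped airway to a mild steady inspiration
(16 l/min against 24.45 Pa), apply a virtual surgery that scales the right
passage's coefficients by 0.6, and compare under all three forcings:

```r
library(rhinocomp)
pre  <- calibrate_airway(Q0 = 2.67e-4, dp0 = 24.45, blend = 0.5)
post <- apply_virtual_surgery(pre, side = "right", factor = 0.6)
report <- run_comparison(pre, post, backend = "lumped")
print(report)
```

```
Global quantities under the three flow forcings
(backend: lumped)

                                              CPG                        CFR                        CPI
                            pre     post     %chg      pre     post     %chg      pre     post     %chg
p_th [Pa]                 -24.4    -24.4        -    -24.4    -19.8    -19.1    -24.4    -22.5     -8.1
Q [1e-4 m^3/s]             2.67     3.07     15.0     2.67     2.67        -     2.67     2.91      8.8
P [1e-3 W]                -6.53    -7.51     15.0    -6.53    -5.28    -19.1    -6.53    -6.53        -
R [1e4 Pa s/m^3]           9.16     7.96    -13.1     9.16     7.40    -19.1     9.16     7.73    -15.6
```

Reading the table: the same operation looks like a 19.1% resistance
reduction if both anatomies are forced at the same flow rate, but only
13.1% at the same pressure drop — here a relative overestimation of

```r
resistance_reduction_overestimate(report)
#> 46.7  (percent)
```

— and 15.6% at the same power. The enforced quantity in each column is
unchanged by construction (`-`); flow rate and power rise under CPG while
pressure drop and power fall under CFR, so even the *sign* of the power
change depends on the forcing choice.

The same protocol runs on the dynamical duct stand-in
(`backend = "duct"` with `duct_geometry()` pre/post pairs), and
`report_from_globals()` applies the table arithmetic to externally supplied
`(Q, Δp)` pairs without running any solver.

## Command line

```sh
Rscript inst/cli/rhinocomp-cli.R simulate --config config.json --out outdir --seed 1
```

with, e.g.,

```json
{
  "model":   {"type": "lumped",
              "calibration": {"Q0": {"value": 2.67e-4, "units": "m3/s"},
                              "dp0": {"value": 24.45, "units": "Pa"}}},
  "forcing": {"mode": "CFR", "target": {"value": 2.67e-4, "units": "m3/s"}},
  "output":  {"dir": "outdir"}
}
```

Commands: `simulate`, `compare`, `make-fixtures`, `sweep`. Every output
directory receives a `manifest.json` (config hash, package version, seed).

## Vignette

`vignettes/flow-forcing-comparison.Rmd` documents the models, the numerical
choices and the limits of the desk-scale stand-ins.
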