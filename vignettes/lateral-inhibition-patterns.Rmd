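---
title: "Methods: lateral inhibition with Notch heterogeneity and tension-dependent binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lateral inhibition with Notch heterogeneity and tension-dependent binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(tipstalk)
```

This vignette records the model, the numerical methods and the design
decisions behind `tipstalk`, in enough detail to reimplement the package
from this document alone. It also states explicitly what the test suite
does and does not establish, and the known limitations of the implemented
distance law.

## 1. Model

We consider `n` cells on a one-dimensional periodic array (indices modulo
`n`). Each cell `j` carries a dimensionless Delta level `D_j` and two
membrane-resolved activated-Notch pools, `N_l,j` on the side facing cell
`j−1` and `N_r,j` on the side facing cell `j+1`. All three variables live
in `[0, 1]` scaled units (Delta in units of its production/degradation
balance `b0`-scale, activated Notch as a fraction of total receptor).

The dynamics are

```
dD_j/dτ   = −D_j + b0 / (1 + ((N_l,j + N_r,j) / (2K))^hill)
dN_l,j/dτ = −kd · N_l,j + kf_{j−1} · D_{j−1} · (1 − N_l,j) + W (N_r,j − N_l,j)
dN_r,j/dτ = −kd · N_r,j + kf_{j}   · D_{j+1} · (1 − N_r,j) + W (N_l,j − N_r,j)
```

where `kf_j` is the binding rate on the interface between cells `j` and
`j+1`. Delta is produced at maximal rate `b0` and repressed by the
*cell-mean* activated Notch through a Hill function with threshold `K`
(default Hill exponent 2); activated Notch decays at rate `kd`, is produced
by trans-binding of the neighbour's Delta to free receptor `(1 − N)`, and
the two membrane pools exchange by intracellular diffusion at rate `W`.

Two switches select four model regimes:

* **Intracellular diffusion `W`.** Finite `W` is the *heterogeneous* model.
  `W = ∞` (the default of `li_params()`) is the classical *well-mixed*
  (pooled) limit: the two sides equilibrate instantly and the model reduces
  to one Notch pool per cell,

  ```
  dN_j/dτ = −kd · N_j + kf0 · (D_{j−1} + D_{j+1}) · (1 − N_j)
  ```

  (`rhs_classical()`; available only when the binding rate is constant,
  i.e. `h = 0`). The convention throughout the package is that the
  well-mixed equation uses the *sum* of neighbour Delta, while averaging
  the two side equations gives the same form with `kf0/2`; tests pin this
  factor-of-two convention down exactly.

* **Tension sensitivity `h`.** For `h > 0`, the binding rate on interface
  `j|j+1` follows a catch-bond-type constitutive law

  ```
  kf_j = kf0 · exp(−h · (x_j − λ)²)
  ```

  where `λ` is the rest length and `x_j` is the intercellular distance,
  modelled as inversely proportional to the number of adhesive bridges on
  the interface:

  ```
  x_j = 1 / ( max(1 − N_r,j, D_{j+1}) + max(1 − N_l,j+1, D_j) )
  ```

  Each `max()` term counts the species limiting bridge formation from one
  side. `interface_distance()` exposes this map and raises a
  `tipstalk_error_degenerate_interface` when the denominator falls below
  `1e-9`. For `h = 0` the exponential is identically 1 and `kf_j = kf0` on
  every interface.

### Parameters

`li_params()` collects the dimensionless parameters and validates them once
at construction:

| name | meaning | constraint | default |
|---|---|---|---|
| `b0` | maximal Delta production | `> 0` | — |
| `K` | Notch repression threshold | `> 0` | — |
| `kd` | activated-Notch decay rate | `> 0` | — |
| `kf0` | basal binding rate | `> 0` | — |
| `h` | tension sensitivity | `≥ 0` | `0` |
| `lambda` | interface rest length | `≥ 0` | `0` |
| `W` | intracellular Notch diffusion | `≥ 0` or `Inf` | `Inf` |
| `n_cells` | array size | even, `≥ 2` | `12` |
| `hill` | Hill exponent | `≥ 1` | `2` |

`dimensional_params()` + `nondimensionalize()` map laboratory-scale rate
constants onto this set, so the dimensionless defaults can be traced to
physical magnitudes.

## 2. Steady patterns and the ansatz solver

An *n-cell spacing* pattern has one Delta-high tip followed by `n`
Delta-low stalk cells, repeated around the ring; its period `n + 1` must
divide `n_cells` (violations raise `tipstalk_error_incompatible_lattice`).
`solve_pattern(params, spacing)` exploits the translational symmetry: it
solves the steady-state equations on a single period and tiles the result,
so the nonlinear system has `3·(spacing+1)` unknowns instead of
`3·n_cells`.

The root finder (`newton_solve()`) is a damped Gauss–Newton iteration:

* forward-difference Jacobian with step `1e-8 · max(1, |x_i|)` per
  coordinate;
* least-squares step via QR (`qr.coef`), which handles square and
  overdetermined systems uniformly;
* step halving (up to 20 halvings) until the residual norm decreases;
* convergence at max-norm residual `1e-10`; divergence guard at `1e8`;
* degenerate interfaces during iteration abort that attempt (returns
  `NULL`) rather than erroring.

Because Newton iterations from a single ansatz can land on collapsed
(shorter-period) or unstable roots, `solve_pattern()` tries the structured
ansatz plus 8 randomized restarts (Delta uniform on `(0, b0)`, Notch on
`(0, 1)`, drawn under `withr::with_seed` with the package-wide restart seed
`20180622` unless overridden), deduplicates converged roots by an 8
significant-digit key, and keeps the best by the ranking *stable
non-collapsed* > *non-collapsed* > *collapsed*, stopping early once a
stable non-collapsed root is found. `found = FALSE` is returned as data,
not as an error.

Two special cases:

* **Spacing 0** (uniform) is solved by `uniform_state()`, a nested
  one-dimensional root find: for each trial Delta level the inner problem
  yields the self-consistent Notch level (for `h > 0` in the well-mixed
  limit, via an inner fixed point on the distance), and `uniroot` closes
  the outer equation.
* **Well-mixed tension model** (`W = ∞`, `h > 0`): the side-resolved
  steady equations are kept (distances need side-resolved Notch) but the
  diffusion term drops out and the constraint `N_l` and `N_r` equilibrate
  is imposed, giving an overdetermined system (`2·period` unknowns,
  `3·period` residuals) solved by the same Gauss–Newton core.

### Stability

`lattice_jacobian()` differentiates the full-lattice right-hand side
(forward differences, step `1e-6`); `assess_stability()` calls the root
*stable* if all eigenvalues have real part below `−1e-8`, *unstable* if
any exceeds `+1e-8`, otherwise *marginal*. For the well-mixed tension
model, which has no explicit dynamics, the Jacobian is evaluated on the
heterogeneous right-hand side with a large-`W` surrogate (`W = 1e4`): a
root of the pooled system is also a root of the fast-diffusion system, and
for large `W` the extra eigenvalues are strongly negative mixing modes
that do not affect the verdict.

`check_interface_balance()` verifies the steady-state flux identity — at a
fixed point the bound flux `kf_j · D_{j+1}`-type terms must balance around
each cell — and is used as an independent certificate on converged roots.

## 3. Dynamics, classification, sweeps

`integrate_lattice()` wraps `deSolve::lsoda` over the heterogeneous
right-hand side (the classical limit is integrated with `W = ∞` reduced
equations); the well-mixed tension model has no dynamics and is rejected
with `tipstalk_error_unsupported_variant`. `relax_to_steady()` integrates
in doubling time chunks until the right-hand-side max-norm falls below
tolerance. `perturb()` applies multiplicative noise under a fixed seed and
clips to valid ranges.

`classify_spacing()` detects the pattern of a state: cells within relative
tolerance `1e-3` of each other (with an absolute floor of `1e-12` so the
all-zero state is classed uniform) are merged; tips are the Delta-maximal
class; equal cyclic gaps between tips give the spacing, unequal gaps give
`irregular` (`NA` spacing). `label_cells()` assigns `tip` / `stalk` /
`hybrid` by Delta relative to the state's maximum (fractions 0.9 and 0.1
by default). `notch_asymmetry()` reports `|N_l − N_r|` per cell — the
signature of the heterogeneous mechanism.

`sweep_grid()` + `sweep_existence()` map a `(K, kf0)` grid × spacing list
to verdicts `stable` / `unstable-only` / `not-found` (collapsed roots
count as not-found for the requested spacing). `regime_summary()` runs a
fixed reference grid in each of the four regimes and reports the set of
stable spacings. Grid sizes and ranges in the reference summaries are the
package's own choices, made to keep a full regime comparison within a few
minutes on one core.

## 4. Analytic structure of the fast-diffusion tension model

For `W = ∞`, `h > 0`, steady states satisfy, per interface, a flux balance
that reduces the pattern equations to a scalar *matching* condition: all
stalk Notch levels of a pattern must produce the same value of

```
M(x) = (1 − x) / x · (1 + (x / K)²)
```

(`m_function()`). Clearing the stationarity condition `M′(x) = 0` of
denominators gives the cubic

```
x² − 2x³ = K².
```

The left side attains its maximum `1/27` at `x = 1/3`, so two distinct
stationary points — and hence unequal matched stalk pairs, the gateway to
spacings beyond salt-and-pepper in this regime — exist exactly when

```
K < K* = 1 / (3√3) ≈ 0.1924500897...
```

(`critical_K()`; `m_prime_roots()` brackets the two roots on
`(0, 1/3)` and `(1/3, 1/2)`; `m_function_analysis()` bundles the pieces;
`equality_residual()` and `three_cell_symmetry_check()` measure how well a
candidate state satisfies the matching and mirror-symmetry conditions).
Note that the conventional 4-decimal quotation of this threshold, 0.1924,
is a truncation of the closed form, not a rounding.

## 5. Known limitations

* **The distance law caps what the tension terms can do.** With the
  `max()` form of `interface_distance()` implemented here, tension-only
  modulation (`W = ∞`, `h > 0`) admits genuine stable patterns only up to
  one-cell spacing across wide `(K, kf0)` scans at the documented base
  parameters, and the combined model (finite `W`, `h > 0`) stabilizes
  spacings up to two but not three. Exploratory work during development
  showed that replacing both `max(·,·)` terms with `min(·,·)` — i.e.
  letting the *scarcer* of free receptor and ligand limit bridge count —
  produces genuine stable two- and three-cell tension patterns near the
  documented parameter sets. The `max()` form is kept because it is the
  contracted definition of `interface_distance()` (e.g.
  `interface_distance(0.5, 0.8, 0.2, 0.1) = 0.625`); the acceptance suite
  reports the resulting discrepancies honestly rather than altering the
  primitive.
* The well-mixed tension stability verdicts rest on the large-`W`
  surrogate Jacobian; eigenvalues of the surrogate mixing modes are not
  separated out, only thresholded.
* `classify_spacing()` assumes a single tip level; multi-amplitude
  patterns are reported as irregular by design.

## 6. What the tests establish

The unit suites verify: parameter validation and error classes; the
right-hand sides against independent finite-difference and
rotation/reflection-equivariance oracles; the factor-of-two well-mixed
convention; Newton convergence certificates (residuals re-checked on the
full lattice after tiling); stability verdicts against long-time
relaxation from perturbed roots across seeds; classification invariances;
analytic roots against a dense scan-and-bisect oracle written before the
closed forms; round-tripping of all I/O formats; and determinism of every
seeded path. The acceptance suite additionally runs the documented
reference parameter sets end-to-end; as noted in §5, the tension-regime
expectations beyond one-cell spacing fail under the implemented distance
law, and those failures are reported rather than masked. The tests do
*not* establish global uniqueness of the roots found, nor basin-of-
attraction sizes — coexistence of stable spacings at a given parameter
point is expected and demonstrated, not excluded.
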