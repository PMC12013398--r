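---
title: "Steady-state chemostat modeling of antibody production: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state chemostat modeling of antibody production: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`chemoflux` couples a constraint-based (stoichiometric) model of cell
metabolism to the macroscopic mass balances of a continuously operated
bioreactor, and analyzes the coupled system as a linear program (LP).

Inside the cell, the usual flux-balance assumptions hold: the metabolic
network is at steady state, so the stoichiometric matrix $S$ and the flux
vector $v$ (mmol gDW$^{-1}$ h$^{-1}$) satisfy $S v = 0$ within the flux
bounds $l \le v \le u$. The flux of the biomass reaction equals the
specific growth rate $\mu$ (h$^{-1}$).

Around the cell, a chemostat with dilution rate $D$ (h$^{-1}$) and biomass
concentration $X$ (gDW L$^{-1}$) obeys, for every medium nutrient $s$ with
feed concentration $s_m$ and tank concentration $s_t$ (mM):

$$\frac{ds_t}{dt} = (s_m - s_t)\,D - u_s X, \qquad
  \frac{dX}{dt} = (\mu - D)\,X, \qquad
  \frac{da_t}{dt} = u_a X - D\,a_t,$$

where $u_s$ is the cell's uptake rate of $s$, $u_a$ the antibody
secretion rate and $a_t$ the antibody tank concentration. At steady state
all three derivatives vanish. `build_problem()` therefore emits, per
nutrient, the equality row $\lambda_{in}[s] - D\,s_t - u_s X = 0$ with the
inflow $\lambda_{in}[s] = D\,s_m$; the biomass balance is imposed as
$\mu = D$ whenever $X > 0$ (the algebraic consequence of
$(\mu - D)X = 0$); and the product balance links secretion to the tank
concentration. Non-negativity of the tank concentrations is what couples
the scales: consumption by the culture, $u_s X$, can never exceed the
feed, $D\,s_m$.

The products $u_s X$ and $D s_m$ make the balances bilinear in general.
Every analysis in this package fixes $D$ and $X$ per solve (validation
fixes them outright; the production scan samples them on a grid), so each
solve is a true LP. The IgG production reported in volumetric units is
$u_a X \times 1000$ ($\mu$M h$^{-1}$).

### The antibody pathway

Host models do not contain antibody chemistry, so `augment_with_igg()`
appends three reactions: subunit synthesis (amino acids + GTP + H$_2$O
$\to$ subunit + protons and GTP-hydrolysis products), assembly (two
identical half-antibody subunits $\to$ one IgG) and secretion (IgG
$\to \varnothing$, irreversible). The five published coefficients
(Ala 39, Arg 14, GTP 1324, H$_2$O 1326, H 1326) are carried verbatim in
the packaged table; the remaining amino-acid coefficients in
`igg_stoichiometry_synthetic.csv` are synthetic IgG-like residue counts,
constructed to be internally consistent (662 residues per subunit
$= \mathrm{GTP}/2$; $\mathrm{H_2O} = \mathrm{GTP} + 2$). Analyses that
depend on exact full-length coefficients should supply a measured table
through `read_igg_stoichiometry(path)`.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `D` | h$^{-1}$ | per analysis | feed/washout rate; equals $\mu$ at steady state |
| `X` | gDW L$^{-1}$ | per analysis | scales all exchange fluxes to volumetric rates |
| `gdw_per_1e6cells` | gDW per $10^6$ cells | `3e-4` | cell-density conversion ($\approx$ 300 pg dry weight per cell, typical of CHO); a documented placeholder — measure it for quantitative axis placement |
| uptake bounds | mmol gDW$^{-1}$ h$^{-1}$ | dataset | kinetic caps on uptake magnitude only; secretion inherits model bounds |
| `uncertainty` $u$ | fraction in $[0,1)$ | 0 | medium concentrations range over $[c(1-u),\,c(1+u)]$ with the summed concentration fixed |
| `eps` (limiting) | flux | $10^{-6}\max(1,|f|)$ | an exact zero FVA width is numerically unattainable |
| `tol_change` | relative | $10^{-6}$ | redundant vs modulatory threshold in `classify_nutrients()` |
| feasibility tol | relative | $10^{-9}$ | steady-state row residuals, checked on every optimal solve |

Interpretation choices that were genuinely open:

* **Measured growth rates are enforced as equalities** during validation
  (`growth_fix`), not as upper bounds. An upper bound would let the
  optimizer trade growth for product and reproduce the unconstrained
  dichotomy instead of the measured phenotype.
* **Uptake datasets cap only the uptake direction.** A measured maximum
  uptake says nothing about secretion, which keeps the host model's bound.
* **Exchanges of metabolites absent from the medium are closed for
  uptake** (lower bound clamped at zero), because the medium defines what
  the culture can consume; freely available species (water, protons,
  secreted byproducts) are exempted via `free_exchanges`.
* **Fixing the product flux for variability and medium analyses** is an
  equality at the stage-1 optimum, not a fraction-of-optimum relaxation,
  following the analysis's literal definition.
* **All limiting nutrients are reported per grid cell**; the criterion is
  a set, and ties are not broken arbitrarily.

## The LP backend and its oracle

The coupled problems solved here are small (tens of variables), so the
package ships a dense two-phase primal simplex (`solve_lp()`) with Bland's
anti-cycling rule. Bounded variables are shifted/mirrored into standard
form, free variables split, and finite ranges handled with one slack row
each. Statuses are restricted to `optimal`, `infeasible` (phase-1 optimum
above tolerance) and `unbounded` (no ratio limit in phase 2). Feasibility
uses a $10^{-9}$ row-scale-relative tolerance throughout; solutions
additionally report their maximum steady-state residual.

The test suite never trusts the simplex on its own word: toy optima are
compared against brute-force vertex enumeration (an independent oracle
implemented in the test helpers, sharing no code with the solver) to
$10^{-8}$, across production, growth, minimization and uncertain-medium
objectives. This backend is intended for the package's desk-scale
problems; genome-scale models (thousands of reactions) call for a sparse
industrial solver behind the same `solve_problem()` contract.

Degenerate inputs are defined, not errors: at $X = 0$ the biomass balance
degenerates to $0 = 0$ and any growth within the reaction bounds is
feasible; at $D = 0$ the feed vanishes and a producing steady state is
infeasible unless production is zero; reversed bounds make the problem
infeasible rather than raising.

## What the synthetic generator emulates

`make_toy_network()` emits a complete study environment — BiGG-dialect
model, medium, cost and uptake tables — whose biology is known by
construction (see `?toy_network_spec`): designed indispensable, modulatory
and redundant nutrient sets, a designed maximum growth rate, a designed
uniquely-limiting amino acid, and a growth/production trade-off through
shared amino-acid pools. Defaults: $\mu_{max} = 0.03$ h$^{-1}$ and amino
acid uptake caps of $0.03$ mmol gDW$^{-1}$ h$^{-1}$ (typical magnitudes
for CHO cultures), reference operating point $D = 0.01$ h$^{-1}$,
$X = 2$ gDW L$^{-1}$, and nutrient counts 3/2/2+glucose, sized so that
brute-force vertex enumeration stays tractable as an oracle
($\le 25$ metabolites, $\le 40$ reactions). The `medium_margin` parameter
selects the regime: margins $> 1$ make the medium non-binding (washout and
classification analyses), margins $< 1$ make the nominal medium binding,
the regime in which uncertainty intervals buy production until the kinetic
caps saturate the curve. Randomness is confined to jitter on medium
concentrations and costs; topology and ground truth are deterministic per
seed, and generation asserts the designed optima by direct solves before
returning.

What the toy deliberately does **not** emulate: genome-scale redundancy
(thousands of alternative routes), compartmentalization, maintenance ATP
demands, byproduct inhibition, or measured kinetic detail. Passing the
structure-recovery tests therefore shows the analyses are implemented
correctly, not that any particular real medium is optimal; conclusions
about a real process require a curated genome-scale model and measured
uptake datasets in the same file formats.

## Problem sizes used by the tests

The suite runs entirely on the micro fixtures (3–4 metabolites) and the
toy generator (16 metabolites, 28 reactions, 8 nutrients): 20 seeded
fixtures for structure recovery, an 11-point uncertainty grid and a
7-point washout grid, all solved by the dense simplex in a few seconds
total.

## Known limitations

* The dense simplex does not scale to genome-scale models; it is the
  desk-scale backend, by design.
* The cells-to-biomass conversion default is a placeholder; heatmap axes
  in cell-density units are only as good as that constant.
* The packaged full-length IgG stoichiometry beyond the five published
  coefficients is synthetic (labelled so in the file name).
* Steady state only: batch/fed-batch transients, and time-resolved
  uptake profiles, are out of scope.
* Nutrient classification depends on the operating point $(D, X)$; the
  packaged ground truth holds at the dataset's reference point.
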