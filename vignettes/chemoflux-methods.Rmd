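---
title: "Methods: chemostat physiology and measurement-constrained pFBA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemostat physiology and measurement-constrained pFBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoflux)
```

## What this package computes

`chemoflux` analyses the physiology of a continuous (chemostat) cultivation
growing on two carbon sources — monosodium glutamate (MSG) and glucose — and
the metabolic flux state consistent with those measurements. It covers four
stages, each usable on its own:

1. **Mass-balance physiology.** Specific growth, uptake and production rates
   from paired reactor samples; Cmol conversion; yields and the carbon
   balance.
2. **Constraint-based flux analysis.** FBA and parsimonious FBA (pFBA) over a
   stoichiometric model, with measured exchange rates as constraints and a
   fixed maintenance (NGAM) demand.
3. **Uncertainty propagation.** Uniform resampling of the measured exchange
   rates within ±2 SD, pFBA per draw, ensemble averaging of growth and
   fluxes; pathway-normalized flux reporting and flux-map overlay export.
4. **Expression screening.** Benjamini–Hochberg FDR adjustment and
   differential-expression calls on per-gene statistics tables, tallied by
   arCOG class.

A synthetic-data generator produces every input with known ground truth, so
the full pipeline is testable without any external download.

## The reactor balances

For a window between sampling times $t_{n-1}$ and $t_n$ with working volume
$V_R$ (held constant by a fixed-height bleed), mean dry cell weight
$\bar{x}$, bleed volume $\Delta V_{bleed}$, supplied volume $V_{in}$ and
discharged volume $V_{out}$:

$$\mu = \frac{(x_{t_n}-x_{t_{n-1}})\,V_R + \bar{x}\,\Delta V_{bleed}}
             {\bar{x}\,V_R\,\Delta t}, \qquad
  q_S = \frac{s_{in}V_{in} - \bar{s}\,V_{out} - (s_{t_n}-s_{t_{n-1}})V_R}
             {\bar{x}\,V_R\,\Delta t},$$

$$q_P = \frac{(p_{t_n}-p_{t_{n-1}})V_R + \bar{p}\,V_{out} - p_{in}V_{in}}
             {\bar{x}\,V_R\,\Delta t}, \qquad
  r_S = q_S\,\bar{x}\,V_R,$$

with the accumulation rate $(s_{t_n}-s_{t_{n-1}})/\Delta t$. Averages
($\bar{x}, \bar{s}, \bar{p}$) are arithmetic means of the window endpoints.
Uptake is positive when the substrate is consumed; production is positive
when the product is formed. At steady state $\mu$ reduces exactly to the
bleed-based dilution rate — the package's most load-bearing identity, tested
to machine precision.

Two published variants of the substrate balance circulate: one in which the
broth accumulation term is *added* to the supply term, and the
mass-balance-consistent one above in which it is subtracted. The two agree
whenever the broth concentration is unchanged over the window and differ
precisely when substrate accumulates — the situation of interest under
overfeeding. The default is the mass-balance form; `verbatim = TRUE` on
`specific_uptake_rate()` / `volumetric_uptake_rate()` reproduces the
accumulation-added algebra for auditability. Product feed and discharge
terms enter as masses ($p_{in}V_{in}$, $\bar{p}V_{out}$) for dimensional
consistency.

### Cmol accounting

Yields are formed on a carbon-mole basis: a rate in g/g/h is multiplied by
`carbon_atoms / molar_mass` from the species registry
(`default_species_registry()`: glucose 180.16 g/mol, 6 C; MSG 169.11, 5 C;
trehalose 342.30, 12 C; valine/glycine/alanine; CO~2~). Biomass uses a
configurable Cmol mass, default 24.6 g/Cmol — the generic
CH~1.8~O~0.5~N~0.2~ composition — which must be stated alongside any
reported yield, since it scales $Y_{x/s}$ directly. The carbon balance is

$$C\text{-balance} = Y_{x/s} + Y_{CO_2/s} + Y_{Tre/s} + Y_{AA/s},$$

and a value below 1 quantifies carbon leaving through unmeasured routes.

The CO~2~ evolution rate is reconstructed from the exhaust CO~2~ mole
fraction and the aeration rate via a configured molar gas volume (default
24.0 L/mol) after subtracting an inlet baseline (default 0.04 %). Both are
configuration, not constants of nature: the off-gas analyzer's
pressure/temperature normalization is rarely reported, so the package makes
the choice explicit rather than hiding it. Missing off-gas data yields `NA`
and a *partial* carbon balance, never a silent zero.

## The synthetic chemostat

`chemostat_scenario()` fixes the biology as constant true rates ($\mu$,
per-substrate $q_S$, per-product $q_P$) plus an *unmeasured carbon sink*
taking a fraction $f$ of consumed carbon; the CO~2~ rate is then defined by
exact closure, so the generator's ledger always satisfies
consumed = biomass + products + CO~2~ + sink. Because the rates are
constants, the reactor balances are linear ODEs with closed-form solutions
(exponentials in $\mu - D_{out}$ and $D_{out}$), which the generator
evaluates directly on the sampling grid — there is no numerical integration
error to tune, and window estimators are exact at steady state and
second-order accurate ($O(\Delta t^2)$) on transients. Measurement noise is
multiplicative Gaussian per channel (defaults: DCW 1 %, concentrations 2 %,
off-gas 1 %).

The dual-feed plumbing mirrors the studied process: a concentrated substrate
feed (76 g/L MSG, 36 g/L glucose) diluted in-line by a water feed, total
mass flow split as 22.5/67.5 g/h (low), 40/80 (high) and 60/60 (overfeed)
at 2 L working volume, with feed density taken as 1 g/mL. An explicit
evaporation-rate parameter (g/h) accounts for the gap between inflow and
bleed at high cultivation temperature; the presets set it so that the
steady-state dilution rate equals the per-condition growth rate (28 g/h low,
46 g/h high/overfeed).

### What the presets do and do not emulate

The shipped `low` / `high` / `overfeed` presets reproduce the *structure* of
the study conditions: growth rates 0.031, 0.037 and 0.054 h⁻¹; cell
densities 5.0 and 16.2 g/L (overfeed starts from the high state and grows
toward ≈18.5 g/L); declining MSG/glucose uptake ratios (2.30, 1.90, 1.83);
trehalose secretion tripling from low to high (0.003 → 0.009 g/g/h) and
amino-acid secretion (valine > glycine > alanine) appearing under overfeed;
substrate accumulating only in the overfeed transient, MSG far faster than
glucose; and carbon balances of 0.90, 0.80 and 0.79 via sink fractions
0.10/0.20/0.21.

These published quantities over-determine a closed mass balance: with the
stated feed concentrations and flows, an overfeed growth rate of 0.054 h⁻¹
forces a biomass yield near 0.39 Cmol/Cmol, and the uptake rates that
reproduce the printed accumulation rates fix the uptake ratio at 1.83 rather
than the reported 1.7. The presets resolve such conflicts in favour of
internal consistency (exact carbon closure, positive concentrations),
keeping the flow settings and growth rates exact; consequences are a ~4.6
g/L MSG residual in the high preset and the 1.83 overfeed ratio. Passing
tests on these presets therefore demonstrates that the estimators recover a
*self-consistent* chemostat exactly — not that the generator reproduces
every published number, nor that real broth (with its evaporation,
density and sampling vagaries) behaves this cleanly.

## Flux analysis

`fba()` maximizes the objective flux subject to $S\,v = 0$ and bounds;
`pfba()` then fixes the objective at its optimum (within a relative slack
$\varepsilon$, default $10^{-6}$) and minimizes total absolute flux
$\sum_j |v_j|$ via the standard split $v = v^+ - v^-$. The reported pFBA
objective is the realized objective flux, which may sit up to
$\varepsilon\cdot$opt below the true optimum by construction. Residual
degeneracy of the minimal-$L_1$ vector (for example two transaminase twins
carrying an arbitrary share of a fixed sum) is not broken further; the
uncertainty ensemble averages over it.

The linear programs are solved by a small dense two-phase primal simplex
written for this package (`R/lp.R`). FBA systems are maximally degenerate —
all steady-state right-hand sides are zero — so the implementation uses
Bland's smallest-index rule throughout, which guarantees termination without
cycling at the cost of a few extra pivots; the problems here have tens of
variables, where that cost is negligible. Fluxes are pre-transformed so the
solver only ever sees non-negative variables: pinned fluxes
($lb = ub$, e.g. measured exchanges and zero-fixed secretions) are
eliminated into the constants, non-negative fluxes are shifted, non-positive
fluxes reflected, and only sign-indefinite fluxes split. Correctness is
cross-checked two independent ways in the test suite: exhaustive vertex
enumeration (`fba_enumerate()`, exact for ≤ ~10 reactions) and an external
constraint-based implementation (cobrapy/GLPK) fed the identical model via
`write_cobra_json()`.

Measured exchange constraints follow the convention uptake = negative flux
(configurable on entry); secretion products shown absent from the broth are
clamped to exactly zero; the maintenance reaction's lower bound is raised to
1.9 mmol/(g·h). Fixing $lb = ub$ at the measured rate (rather than
one-sided bounding) is the stricter reading of "constrained to the
measurement" and is what the uncertainty stage assumes; interval
constraining is available via `sampling_spec(independent_bounds = TRUE)`.

### Uncertainty propagation

Each non-fixed measured exchange is drawn independently and **uniformly**
from $[\text{rate} - 2\,SD,\ \text{rate} + 2\,SD]$ — the minimal assumption
for an interval-specified uncertainty; the distribution is recorded in the
result metadata rather than left implicit. Default 1000 draws, pFBA per
draw, means over the feasible draws only. Infeasible draws are dropped and
counted (`feasible_fraction`), never imputed: with hard-fixed exchanges a
draw can violate stoichiometric consistency, and the feasible fraction
itself is diagnostic (in the bundled analysis the overfeed condition sits at
the edge of its feasible envelope). An all-infeasible ensemble raises an
error carrying the first sampled constraint set as a diagnostic. With a
fixed seed the ensemble is bit-reproducible.

### Flux reporting

Normalization schemes are configuration, not code, because reaction ids
differ between model reconstructions. Four reference rules are supported:
a single reference reaction (glucose uptake for the glycolytic block; the
G3P-forming step for the storage block), the maximal member flux (TCA-cycle
convention, so the largest member reads exactly 1.0), and a summed reference
(total glutamate incorporated via deamination plus transamination).
Magnitudes are normalized; direction is reported in a separate column, and
`flag_direction_conflicts()` marks reactions whose sign differs across
conditions — those cannot carry a single normalized value on a shared map
arrow. Overlays are written as flat reaction→flux JSON consumable by
pathway-map viewers such as Escher; layout mismatches warn and list the
unmapped reactions instead of failing.

## Toy networks

Three hand-solvable networks (`make_toy_model()`) stand in for a
genome-scale model at desk scale, each committed together with its known
optimum, verified against $S v = 0$ and the bounds at construction and
against vertex enumeration in the tests:

* `chain` — uptake bound 10, biomass yield 0.5; optimum 5.
* `dual_substrate` (8 reactions) — glutamate is oxidized completely
  (deamination or transamination, 2 ATP) or incompletely with acetate
  secretion (3 ATP); biomass needs both carbons plus ATP. Unconstrained FBA
  secretes acetate (optimum 11.24); clamping the acetate exchange to zero —
  the measured absence of fermentation products — forces complete oxidation
  (optimum 9.05 with maintenance 1.9). The zero-secretion constraint is
  thereby *binding*, not decorative.
* `branched_tca` (7 reactions) — one substrate, a direct (no-ATP) route and
  a two-step ATP-yielding route to precursor, a TCA-like ATP regenerator,
  biomass consuming precursor + ATP, and the maintenance drain; optimum
  $10 - 1.9/3 = 9.3\overline{6}$ with all flux on the ATP-yielding branch.
  This is also the SBML fixture (`inst/extdata/toy_branched_tca.xml`).

## Expression screening

`bh_adjust()` validates and delegates to the standard step-up FDR
adjustment; the test suite compares it against a direct evaluation of the
step-up definition on a thousand random vectors. DEG calls use a strict
adjusted-p threshold (< 0.05) with inclusive fold-change cuts
(log~2~FC ≥ 1 or ≤ −1, i.e. at least doubled or halved expression); the
boundary gene with log~2~FC exactly 1 is a call. The planted-truth generator
gives true positives a test statistic shifted by $3\times$`effect`, making
recovery essentially complete at the default settings while null tables
yield ≈0 discoveries — exercising both directions of FDR control. Whether
fold-change thresholds should apply to shrunken or raw estimates is left to
the upstream model-fitting stage, which this package deliberately does not
reimplement: it ingests per-gene statistics tables.

## Numerical and design choices

* LP tolerances: pivot/feasibility 10⁻⁹; mass-balance residual asserted at
  10⁻⁶; pFBA optimum slack $\varepsilon = 10^{-6}$ relative.
* Vertex enumeration rounds coordinates to 9 decimals for uniqueness and is
  $O\!\binom{n}{n-\mathrm{rank}\,S} 2^{n-\mathrm{rank}\,S}$ — an oracle for
  toy networks, not a solver.
* Windows with non-increasing time are rejected with an error, never
  silently skipped; zero mean biomass, zero substrate uptake and zero
  normalization references are explicit error conditions.
* Scenario construction fails fast when the stated rates over-commit carbon
  (negative implied CO~2~) or would drive a concentration negative on the
  sampling horizon.
* Problem sizes in the tests and acceptance script — toy networks of ≤ 8
  reactions, ensembles of ≤ 1000 draws, gene tables of 2000 rows, five
  replicate series per condition — were chosen as the smallest sizes at
  which every statistical assertion has comfortable power.

## Known limitations

* The simplex is dense and unfactorized: right for toy-scale LPs, wrong for
  genome-scale models (thousands of reactions). The model I/O layer reads
  full SBML-fbc models, but solving them needs a sparse LP backend.
* The generator's constant-rate biology has no substrate kinetics: imposed
  uptake continues even as a substrate nears depletion (the scenario errors
  rather than saturating). Monod-style closures are out of scope.
* The SBML reader covers the FBA-relevant L3+fbc subset only — no kinetic
  laws, no groups/annotations semantics, no gene–protein–reaction logic.
* Inferential statistics beyond mean ± SD (ANOVA, post-hoc tests) are out
  of scope, as is everything upstream of per-gene statistics tables.
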