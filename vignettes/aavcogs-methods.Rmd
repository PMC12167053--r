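---
title: "Models and methods behind aavcogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aavcogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aavcogs)
```

This vignette is the package's own account of the models it implements:
the cost-of-goods and scheduling engine for AAV production platforms, the
upstream/downstream mass-balance arithmetic, the face-centred central
composite design (CCD) machinery for lysis optimization, and the
perfusion lactate balance used to estimate viable cell number. It also
records the numerical and design choices that were genuinely open, and
what the synthetic-data generators do and do not emulate.

## The cost-of-goods model

The engine is a deterministic activity-based cost model. A *scenario*
bundles four things: platform specifications, day-indexed production
schedules, a facility configuration, and a cost catalog.

**Unit sizing.** For a post-downstream target of $T$ vector genomes, a
platform yielding $y$ vg of crude product per unit and an end-to-end
downstream recovery $r$, the required unit count is the smallest integer
$n$ with $n\,y\,r \ge T$. The recovery is deliberately a single
compounded scalar (default $r = 0.30$ from harvested lysate through to
drug-product formulation) rather than a per-operation ledger: the batch
sizing decision only needs the end-to-end number, and the per-operation
decomposition lives in the mass-balance module instead.

**Capacity packing.** Units are packed into *productions* — sequential
runs of the full schedule inside the same facility. A production of $n$
units must satisfy simultaneously:

* **area**: $n \cdot \text{footprint} + \text{MSCs} \cdot a_{\mathrm{MSC}}
  + \text{incubators} \cdot a_{\mathrm{inc}} + \text{operators} \cdot
  2.0\,\mathrm{m^2} \le 60\,\mathrm{m^2}$ (defaults; all configurable),
* **MSC throughput**: $\lceil n / u_{\mathrm{MSC}} \rceil \le 3$ cabinets,
  with $u_{\mathrm{MSC}} = 6$ flask units or $10$ bioreactor systems per
  cabinet, and
* **staffing**: two GMP operators per occupied MSC, overridden by a
  platform crew rule where one applies (two operators run up to ten
  hollow-fiber systems; the flask platforms carry a fixed five-operator
  production crew).

The packing is greedy — each production takes the maximum feasible unit
count. Because the feasible-size set here is always a contiguous range
$1..c$, greedy is provably minimal in production count; the test suite
nevertheless cross-checks it against an independent exhaustive
shortest-path oracle over all unit counts up to 30 and a grid of small
capacity bounds, since later platform rules could break contiguity
silently. Productions run sequentially, so calendar time is
(productions) × (schedule days); no parallel-suite modelling is
attempted.

**Costing.** Four components, all in unitless "cost units":

* materials: catalog lines with an explicit basis flag — `per_unit` lines
  scale with the total unit count, `per_batch` lines are provisioned once
  per production (and at least once even for a degenerate zero-unit plan,
  so fixed provisioning is never silently dropped);
* labor: step hours × operators × hourly rate, repeated per production;
* facility: total calendar days × day rate;
* QC: samples accumulate across productions and are billed in whole
  analytical plates at the catalog's sharing capacity (ceiling division —
  a partly-filled plate still costs a full plate, the conservative
  reading of plate sharing).

Open manipulations follow the same per-unit/per-batch accounting and are
reported as the process-risk metric. What counts as "open" is entirely a
property of the scenario file; closed-system welds and sterile
connections are simply recorded as zero.

**Fold-change reporting.** `compare_platforms()` divides each metric by
the reference platform's value at the same target. This is the only
honest way to present results from a fixture price catalog: fold changes
are invariant under global price rescaling (a tested property), while
absolute costs are not meaningful. Production time is reported as
calendar days (the headline metric) with operator-hours alongside, and
facility usage as peak concurrent area, since amortized-area reporting
would depend on how one attributes idle days between productions.

### The fixture catalog

No real price list ships with the package. The reference catalog contains
round numbers chosen once to be *relatively* plausible — a single-use
hollow-fiber kit is the dominant per-unit consumable on the closed
platform, while the flask platforms are cheap per vessel but labor- and
schedule-heavy. Conclusions drawn from the shipped scenario are therefore
ordering-level (which platform is cheaper, riskier, slower), never
magnitude-level.

## Mass-balance arithmetic

The operations are deliberately small and total: titer × volume totals,
full-particle ratio $100\,\mathrm{vg}/\mathrm{vp}$ (with the subset
invariant $\mathrm{vg} \le \mathrm{vp}$ enforced), step recovery
$100\,\mathrm{out}/\mathrm{in}$, impurity clearance
$100\,(\mathrm{in}-\mathrm{out})/\mathrm{in}$, compounded chain recovery,
equivalence ratios, and VRF volume reduction. Two reporting conventions
are baked in and mirrored from field practice: ratios and clearances
round to the nearest whole percent, equivalence folds to one decimal
place (surface equivalence against the 36-layer flask uses two decimals,
where one decimal would round a 1.17-fold difference invisible). The raw
unrounded value always travels alongside the rounded one, as an
attribute.

Recovery above 100 % is flagged, not rejected — assay noise around
complete recovery genuinely produces such values — and clearance below
0 % likewise. Vendor-nominal surface areas (21,000 cm² hollow-fiber,
6,360 cm² CS10, 18,000 cm² HYPERStack-36) ship as named constants; the
flask areas are vendor catalog values, not measurements.

## CCD and response surfaces

`ccd_face_centered()` emits the textbook face-centred design: $2^k$
factorial vertices, $2k$ axial points at the face centres (coded
magnitude 1, which is what distinguishes the face-centred variant from
rotatable CCDs), and replicated centre points. The default of 3 centre
replicates is a package choice — standard practice for a three-factor
CCD when the true replication of a historical study is unknown — and is
exposed as a parameter.

Fitting is ordinary least squares on the full second-order model in
*coded* units (better conditioning than natural units, and the standard
CCD convention); coefficients are reported in a canonical order
(intercept, linear, pure quadratic, interactions). Responses are
multiplied by per-row dilution factors before fitting, matching the
practice of correcting diluted titer measurements back to scale; per-row
factors are supported because dilution typically varies with cell
density. Model significance is the overall F-test against the
intercept-only model. A constant response vector is treated as the null
surface ($R^2 = 0$, $p = 1$) rather than propagating the 0/0 F
statistic. Designs with fewer rows than the $1 + 2k + k(k-1)/2$
coefficients are rejected naming the inestimable terms.

**Bounded optimization.** The optimum of a quadratic over the coded cube
$[-1,1]^k$ lies at an interior stationary point or on a face. The
optimizer enumerates all $3^k$ face patterns (each coordinate fixed at
$\pm 1$ or free), solves each restricted stationary system exactly, and
keeps the best feasible candidate — an exact, derivative-free-iteration-
free global optimizer for $k \le 6$. Singular restricted systems are
skipped; their optima are recovered on lower-dimensional faces. The test
suite pins this against a dense grid oracle at 0.001 resolution on random
two-factor quadratics.

## The perfusion lactate balance

The estimator treats the culture as a single well-mixed volume $V$ with
feed rate $Q(t)$ and feed lactate concentration $C_f$ (default 0,
fresh media). The interval lactate production rate is

$$P = V\,\frac{\Delta C}{\Delta t} + Q\,(C - C_f),$$

and viable cells are $P / q_{\mathrm{lac}}$, floored at zero. The default
$q_{\mathrm{lac}} = 5$ pmol/cell/day is a literature-typical constant for
cultured HEK-lineage cells, shipped as an overridable named default — it
is *not* a value measured in any study this package models, and absolute
cell numbers inherit its uncertainty linearly (the estimator output
scales exactly as $1/q_{\mathrm{lac}}$, a tested property).

This is an explicit reconstruction from first principles of the kind of
lactate-and-perfusion growth prediction used for hollow-fiber systems
whose vendor tooling is proprietary; it makes no claim to reproduce any
vendor algorithm.

**Differencing.** The default is forward (left-endpoint) differences, at
which the estimator is the exact discrete inverse of the package's
explicit forward simulator — the noiseless simulate-then-estimate round
trip is exact to machine precision, so the round-trip test measures
implementation correctness rather than a discretization artifact. A
centred-difference option exists for real, noisy data, where its
averaging behaviour is preferable; on simulator output it recovers
interval averages instead of endpoint values. Intervals touching a
missing lactate measurement (a real failure mode — analyzers miss days)
yield `NA` estimates rather than interpolated guesses.

**Simulator.** `simulate_metabolites()` integrates the same balance
forward for all four analytes (glucose and glutamine consumed, lactate
and ammonium produced) with perfusion dilution toward the feed,
non-negativity clamping, and measurement noise added last (then clamped
again — a measured concentration cannot be negative). The explicit daily
update is stable provided $Q\,\Delta t / V < 1$; the shipped defaults
(volume 2 L, feed ramping 200→1600 mL/day over 8 days) respect this with
margin. Single-compartment mixing is an acknowledged simplification: a
hollow-fiber system has intra- and extracapillary compartments with
diffusion between them, which this package does not model.

## Synthetic data: what it does and does not show

The generators exist so that every pipeline stage is testable without
external data:

* `gen_reference_scenario()` is fully deterministic and carries the
  operational assumptions described above plus the fixture catalog.
* `gen_doe_dataset()` draws responses from a known quadratic truth plus
  i.i.d. Gaussian noise. The shipped recovery test uses a truth surface
  peaked at (60 min, 10⁶ cells/mL, 0.2 % Triton) with curvature strong
  enough that the interior time optimum is statistically identifiable at
  2 % relative noise — a flat ridge would defeat any estimator, which is
  a statement about experimental design, not about the fitting code.
* `gen_growth_run()` uses a logistic curve (plateau 5 × 10⁹ cells,
  rate 1.2/day, inflection at mid-run) so that metabolic rates visibly
  accelerate in the second half of an 8-day process. The logistic form
  is a package choice; no growth equation is claimed for any real run.

Passing tests on these generators demonstrates internal consistency —
the estimator inverts the simulator, the fitter recovers known surfaces,
the packer matches an exhaustive oracle. They do not demonstrate that
real harvests, real lysis responses or real perfusion cultures follow
these functional forms, and the i.i.d. Gaussian noise model is kinder
than real assay error (qPCR and ELISA errors are multiplicative and
correlated within plates).

## Numerical choices

* `required_units()` and `doses_from_batch()` apply a $10^{-12}$
  relative tolerance so exact integer multiples resolve exactly despite
  floating-point association.
* Same-day schedule steps keep insertion order (stable sort), so reports
  are reproducible.
* All randomness sits behind explicit seeds; generators refuse to add
  noise without one.
* Scenario YAML serialization is field-ordered and written at fixed
  precision, so load/write round trips are byte-stable.

Problem sizes in the test suite are chosen for exhaustiveness at small
scale: packing is verified for all unit counts to 30 over a grid of
capacity bounds, surface recovery over 50 seeds per noise level and a
six-level noise ladder, the optimizer against 4-million-point grids on
20 random quadratics, and growth round trips at daily sampling over 8
days.

## Known limitations

* No currency, inflation, depreciation or NPV modelling; equipment
  amortization is representable only as catalog line items.
* No stochastic contamination or batch-failure modelling; open-step
  counts are a risk *proxy*.
* No TFF/depth-filtration hydraulics (flux, pressure); the mass-balance
  module covers quantities, not transport.
* No lack-of-fit decomposition or term pruning in the RSM fit.
* Absolute cost magnitudes are fixture-dependent by construction.
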