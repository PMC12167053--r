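# aavcogs

Techno-economic and process modelling for adeno-associated virus (AAV)
vector manufacturing, written for process-development and translational
manufacturing groups who need to compare production platforms before
committing cleanroom space to one of them.

The package models a closed hollow-fiber bioreactor (Quantum-class, 2.1 m²
of growth surface per system) against the two multilayer adherent flask
systems commonly used at R&D and early translational scale, the 10-layer
CellSTACK (CS10) and the 36-layer HYPERStack. Around that comparison it
provides the supporting arithmetic a vector process team uses every day:
harvest titer and yield mass balance, downstream recovery and impurity
clearance, designed-experiment machinery for lysis optimization, and a
perfusion lactate balance for estimating viable cell number in a bioreactor
that has no direct biomass sensor.

## What it computes

**Cost of goods and scheduling.** For a post-purification target output
*T* (vector genomes), a platform with per-unit crude yield *y* and an
end-to-end downstream recovery *r* (default 0.30) needs

    n = ceil( T / (y · r) )

vessels or systems. Units are packed into sequential *productions* by a
greedy fill against three facility constraints — floor area (equipment plus
microbial-safety-cabinet (MSC), incubator and 2.0 m²-per-operator space
within a 60 m² suite), MSC throughput (at most 3 cabinets, 6 flask units or
10 bioreactor systems per cabinet), and staffing (2 GMP operators per MSC,
or a fixed platform crew). A batch split into *p* productions of an
*d*-day schedule occupies the facility for *p·d* days. Cost per batch is
the sum of materials (per-unit and per-batch lines from a cost catalog),
labor (step hours × operators × rate), facility occupancy (days × day
rate) and QC (whole shared analytical plates). Open manipulations — the
contamination-risk metric — are counted the same way. `compare_platforms()`
reports everything as fold changes relative to a reference platform, which
makes the comparison invariant to the absolute price level.

**Mass balance.** Titer × volume yields, the full-particle ratio
100·vg/vp, per-step recovery and impurity clearance percentages,
compounded chain recovery, volumetric reduction (VRF), and platform
equivalence ratios (surface or yield multiples).

**Lysis DoE.** Face-centred central composite designs over the three lysis
factors (detergent contact time 30–240 min, cell density 1–10 × 10⁶
cells/mL, Triton X-100 0.2–1.0 %), full-quadratic response-surface fits
with an overall model F-test, an exact box-constrained optimizer, and
contour-grid export.

**Growth from lactate.** In a perfused, well-mixed volume the lactate
production rate is `P = V·dC/dt + Q·(C − C_feed)`; dividing by a specific
lactate production rate q_lac (pmol/cell/day) gives viable cells. A
forward difference-equation simulator generates matching synthetic
metabolite time courses for testing.

All monetary quantities are unitless "cost units" from a clearly labelled
fixture catalog: the comparison structure, not a price list, is the point.

## Worked example

```r
library(aavcogs)

s <- gen_reference_scenario()        # shipped three-platform scenario
run_cog(s, "Quantum", 1e14)          # one batch sized for 1e14 vg post-DSP
#> CoG report: Quantum (5 units, 1 production(s))
#>   materials     3205.0
#>   labor         2400.0
#>   facility      4500.0
#>   QC             960.0
#>   total        11065.0 cost units
#>   open steps 12, production days 9, operator hours 48
```

Five bioreactor systems (each 6.81 × 10¹³ vg crude, 30 % downstream
recovery) cover the 10¹⁴ vg target in one 9-day production. Sweeping the
translational output range:

```r
compare_platforms(s, "Quantum", c(1e14, 5.5e14, 1e15))
#> Platform comparison (reference: Quantum)
#>  target_vg     platform units productions fold_cost fold_open_steps fold_days
#>      1e+14      Quantum     5           1      1.00            1.00      1.00
#>      1e+14 HYPERStack36     3           1      1.83            3.33      1.78
#>      1e+14         CS10    14           1      2.25           15.50      2.00
#>    5.5e+14      Quantum    27           1      1.00            1.00      1.00
#>    5.5e+14 HYPERStack36    15           1      1.22            3.29      1.78
#>    5.5e+14         CS10    75           5      4.90           17.77     10.00
#>      1e+15      Quantum    49           2      1.00            1.00      1.00
#>      1e+15 HYPERStack36    27           2      1.25            3.25      1.78
#>      1e+15         CS10   137           8      4.40           17.77      8.00
```

At every sweep point both flask platforms cost more, expose more open
steps and occupy the facility longer than the bioreactor, with CS10 the
most expensive — the flask platforms' labor-heavy schedules and capacity
splitting (CS10 needs 8 sequential productions at 10¹⁵ vg) dominate. The
fold magnitudes depend on the fixture prices; the orderings do not.

Mass-balance one-liners:

```r
full_particle_ratio(6.81e13, 4.92e14)   # 14  (% genome-containing capsids)
clearance(1.8e7, 2.0e6)                 # 89  (% total-DNA clearance)
equivalence_ratio(21000, 6360, 1)       # 3.3 (bioreactor surface in CS10 units)
```

A shell entry point wrapping the same functions is installed at
`inst/cli/aavcogs` (subcommands `cogs`, `massbalance`, `doe`, `growth`,
`synth`).

## Documentation

The methods vignette (`vignettes/aavcogs-methods.Rmd`) describes the
models, their assumptions, the synthetic-data generators and the numerical
choices in detail.
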