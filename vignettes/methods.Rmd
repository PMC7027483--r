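---
title: "Methods: dairy intensification, GHG accounting and forest carbon change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dairy intensification, GHG accounting and forest carbon change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dairyshed)
```

# The problem

Smallholder dairy systems around East African montane forests interact
with the forest carbon balance in two directions: cattle graze inside
forests when on-farm feed is short (suppressing regrowth, a carbon loss),
and feed intensification that would keep cattle out of the forest claims
agricultural land and fertilizer, adding greenhouse-gas emissions of its
own. `dairyshed` implements the accounting needed to evaluate that
trade-off at sector scale: attribute forest carbon loss to dairy grazing,
compute Tier-2 livestock emissions and milk output under feeding
scenarios, track the land those scenarios demand, and feed land
shortages back into the forest term.

This vignette documents the models, the parameters that matter, the
numerical decisions, and what the synthetic test landscape does and does
not establish.

# Forest attribution

Net forest carbon loss on a 1-km² grid is reduced to its
grazing-attributable component in four steps, in this order:

1. restrict to **natural forest** (forest mask minus plantation mask);
2. **exclude burnt pixels** — fire-driven loss can neither be attributed
   to cattle nor mitigated by feeding. Burnt pixels become nodata, not
   zero, so they drop out of both numerators and area denominators;
3. subtract **nonrenewable fuelwood biomass** (NRB), clamped at zero per
   pixel: where fuelwood extraction exceeds net loss, a negative
   grazing-attributed loss would be physically meaningless;
4. scale by the county-level **dairy proportion** of the cattle herd.

Uncertainty propagates analytically for the subtraction:
`var(loss_cattle) = var(net loss) + var(NRB) − 2·cov`, floored at zero
against round-off, with a Cauchy–Schwarz guard on the covariance. How the
covariance between the two input products should be estimated is not
published, so `cor_inputs` is an explicit parameter defaulting to 0
(independent inputs); sensitivity to it is linear and easy to probe.

Layers stay in kg C ha⁻¹ yr⁻¹ internally; conversion to CO₂-equivalents
(× 44/12) happens only in reporting helpers. Inputs that are cumulative
over an observation window rather than annual rates are annualised by a
`period_years` argument (default 1; use 12 for a 2003–2014 stack).

# Herd model and Tier-2 emissions

Per-cow annual emissions follow the IPCC Tier-2 forms:

- **enteric CH₄** = `GE · Ym / 55.65`, with gross energy `GE` summed from
  the diet (18.45 MJ per kg DM for all feeds) and `Ym` the methane
  conversion factor (default 0.065, range 0.060–0.070);
- **manure CH₄** = `VS · B0 · 0.67 · Σ_s split_s · MCF_s`, with volatile
  solids from undigested plus urinary energy net of ash;
- **N₂O**: excreted N (intake CP/6.25 minus milk N and a 2 % body
  retention) is routed by the manure-system split — pasture-deposited N
  to the managed-soil category (EF 0.02), heap-stored N to manure
  management (EF 0.005) — with indirect volatilisation
  (`Frac_gas = 0.2`, EF₄ = 0.01) and leaching
  (`Frac_leach = 0.3`, EF₅ = 0.0075) pathways, and synthetic fertilizer N
  in its own category (EF₁ = 0.01). 44/28 converts N₂O-N to N₂O.

GWP100 defaults are CH₄ = 25 and N₂O = 298 (the national-inventory
convention of the study period); both are configuration entries because
the source study does not state its values. The manure split defaults to
70 % pasture / 30 % heap in the baseline and FeCo; the reduced-grazing
scenarios (FoCo, FoFeCo) shift 0.3 from pasture to heaps for later use as
organic fertilizer.

**Milk.** The milk model is an annualised energy/protein balance, a
deliberate surrogate for a daily stochastic herd simulator (whose
internals are not published): metabolisable energy is
`GE × digestibility × 0.81`; the digestible-energy-dependent efficiency
`REM = 1.123 − 4.092e−3·DE% + 1.126e−5·DE%² − 25.4/DE%` converts it to
net energy; maintenance is `0.322 · W^0.75` MJ/day (a lifetime-average
coefficient spanning lactating and dry periods) with a 5 % pregnancy
overhead at a 350-kg mature weight; the residual divided by the energy
content of milk (`1.47 + 0.40·fat%` MJ/kg) gives energy-limited milk,
capped by a protein balance (64 % marginal conversion of digestible CP
net of 1 g per kg metabolic weight per day). Yields are averaged over a
13-year lifetime with 3 rearing years. The surrogate has the right
monotonicities (more energy, higher digestibility → never less milk) and
the right order of magnitude, but the packaged per-system diet table
carries reference milk yields that act as a **calibration fixture**: when
supplied, they override the surrogate, so every downstream aggregate
(intensities, deltas, scenario milk gains of 44/45/51 %) is exact with
respect to the reference table. FPCM correction, where raw milk needs
normalising, is `raw × (0.337 + 0.116·fat% + 0.06·protein%)` at 4.0 %
fat, 3.3 % protein.

**Uncertainty.** Every ranged factor is perturbed one at a time — the
baseline samples each range with a one-dimensional Latin hypercube while
all other factors sit at their means; scenarios evaluate at each range's
minimum and maximum (half the spread taken as that factor's SD).
Per-factor SDs combine in quadrature; the combination rule is not
published, and quadrature is exact if the model is locally linear in
independent factors. Degenerate ranges contribute zero variance rather
than an error.

# Land budget and scenarios

Cropland demand per pixel is
`heads × intake_of_cultivated_feed / yield`, summed over cultivated
feeds (Napier at 12 t DM ha⁻¹; maize silage at the yield-gap level).
Only existing grazing land is convertible — no cropland is taken from
forest inside the study area — so a pixel is in **deficit** where demand
exceeds the grazing land available. Deficit pixels form 8-connected
components (fewer, larger polygons: conservative, more forest flagged as
at risk), each a multipart polygon of pixel squares. Buffering by the
5-km farm-neighbourhood radius is an exact Euclidean Minkowski sum over
those squares: a point is inside the buffer iff its distance to the
nearest deficit square is at most the radius; on the grid this is a
binary dilation with the exact point-to-square metric, so
pixel-centre-in-polygon intersection has no approximation error. Forest
loss pixels whose centres fall inside the buffered deficits are
**retained** losses (land shortage keeps cattle grazing in the forest);
the remainder of the baseline attributed loss is the scenario's forest
mitigation. Because demand falls pointwise as maize yields rise, deficit
sets are nested across Ya → Yw50 → Yw80, buffers of nested sets are
nested, and the whole chain (demand → deficit → retained loss) is
provably monotone; the acceptance sweep asserts it on every seed.

**Yield-gap closure.** Maize silage yields step from the actual yield
(Ya, default 1.766 t DM ha⁻¹) to 50 % and 80 % of the water-limited
potential (Yw, default 6.4 t DM ha⁻¹), modulated per livestock production
system by agro-ecological multipliers (arid 0.8, humid 1.1, highland
1.0). The nitrogen to move from Ya to a target yield converts crop
uptake (22 kg N per t additional DM) to applied N through source
nitrogen-use efficiencies — 33 % for fertilizer, 20 % for manure — with
half the uptake assigned to each source by default. At Yw80 this yields
fertilizer applications of ~90–130 kg N ha⁻¹ depending on zone, inside
the range reported for closing maize yield gaps in the region.

**LUC.** Converting grazing land to feed cropland releases a one-time
stock change (default 80 Mg CO₂eq ha⁻¹, range 60–100) spread over a
20-year amortisation horizon — the inventory convention for land-use
change. With this horizon the scenario proportions are coherent: closing
the maize yield gap cuts LUC emissions several-fold more than it adds
fertilizer N₂O (a ratio of ~4 on the default landscape), which is the
mechanism that makes yield-gap closure worthwhile. Setting
`luc_amortisation_years: 1` charges the full stock change to the
scenario year instead.

**Concentrates.** Concentrate production is accounted separately from
the spatial budget, since ingredients are purchased and partly imported:
demand is productive cows × 450 kg (3 kg/day × 150 days of early
lactation; medium intensification) or × 900 kg (high), split into
ingredients (27 % rice bran, 4 % lime, 27 % wheat, 27 % maize, 5 %
sunflower cake, 10 % cotton-seed cake), converted to hectares with
national yields, minus the area already serving baseline demand. The
worst case — meeting that footprint by clearing secondary forest — uses
112.7 ± 3.9 Mg CO₂eq ha⁻¹ and is reported as a leakage risk, never added
to the combined scenario total. The per-head concentrate production
emission factor has no published value; it ships as a documented
placeholder (0.3 kg CO₂eq per kg, range 0.2–0.4) and is excluded from
exact benchmark checks. Emissions from fertilizer manufacture and
transport are excluded throughout.

**Combined total.** A scenario's combined AFOLU position is agricultural
emissions plus retained forest loss minus the forest-gain credit;
intensity (kg CO₂eq per kg FPCM) is reported both with and without the
forest term, since the forest contribution is small per kilogram of milk
but decisive for the sector's net sign. Percentage deltas always use the
baseline as denominator. Internal arithmetic is double precision;
rounding to integer tonnes/hectares (half away from zero, as the
reference tables round) happens only at report time.

# The synthetic landscape

`generate_landscape()` emulates the *structure* of the study region's
data stack, not its geography: clustered forest patches (thresholded
low-pass-filtered Gaussian noise, correlation length 3 pixels),
plantation and burn subsets, lognormal-like positive carbon fields
scaled to configured means (net loss 2,000, gain 500, NRB 600 kg C ha⁻¹
yr⁻¹ — magnitudes and the negative net change under grazing match the
farm-neighbourhood statistics reported for the region), cattle density
(5–120 head km⁻²) boosted 1.8× within 5 km of forest edges, grazing
land (20–80 ha per 100-ha pixel) *reduced* near forest edges
(`grazing_edge_scarcity = 0.5`) so land deficits cluster at forest
margins — the spatial pattern the deficit-buffer analysis assumes. Where
real deficits sit relative to forests is not published, so that
clustering is a parameter, not a fact. County zones are a raster Voronoi
partition (only a zonal overlay is needed); one master seed drives all
substreams via named child seeds, so runs are bit-reproducible and
stage-insertions do not shift other streams.

The farm survey induces target Spearman correlations between practice
indicators and neighbourhood forest loss through a single-factor
Gaussian copula with monotone marginal transforms — only rank structure
is asserted downstream, and strictly monotone margins preserve Spearman
correlations exactly in population. Count-valued indicators (herd sizes)
are rounded to integers, which introduces ties and attenuates their
recovered correlations somewhat toward zero (a −0.37 target typically
recovers near −0.30 at n = 216) — exactly as a real count-valued survey
would; the recovery contract is ±0.1 of the target. Farm types are
assigned from the joint milk/fodder rank (top tercile "intensified"), so
intensified farms have higher milk yields and fodder fractions by
construction.

What passing tests on this landscape do **not** show: agreement with the
real remote-sensing stack (absolute totals differ — on the synthetic
shed the forest term is proportionally larger than in the real sector),
realistic fire behaviour, within-county heterogeneity of dairy
proportions, or survey measurement error. The exactly reproducible
surface is the aspatial arithmetic chain (concentrate demand, land
footprint, worst-case deforestation, milk gains) plus the algebraic and
monotonicity properties of the spatial chain.

# Numerical decisions

- Difference clamping at 0 in the fuelwood subtraction and in N
  excretion; variance floored at 0; Cauchy–Schwarz enforced with a 1e−12
  relative slack.
- Burnt pixels are nodata (excluded), never zero.
- Pixel–polygon intersection by pixel centre, consistent between the
  deficit buffers and the farm-neighbourhood buffers.
- Buffered-polygon *areas* use deterministic fine-grid quadrature
  (resolution radius/100); containment tests are exact.
- Wilcoxon tests use mid-ranks with the normal approximation and tie
  correction for larger groups and the exact distribution otherwise;
  Holm correction (uniformly more powerful than Bonferroni; the source
  figure says "corrected" without naming a method); compact letters via
  insert-and-absorb.
- Rank-correlation targets are converted copula-side via
  `ρ_P = 2 sin(π ρ_S / 6)`; the implied correlation matrix is checked
  positive semidefinite and rejected otherwise.
- The sector cow-population table's baseline concentrate column is a
  reported fixture (it is not derivable from baseline per-head intakes);
  its printed entries round-sum 1 t below their printed total, so
  recomputed footprint totals can differ from printed ones by ±1 unit.

# Problem sizes

The test suite runs a 40 × 40-km landscape for pipeline properties, a
100-seed sweep of 30 × 30-km landscapes for the monotonicity chain, 20
replicates of the 216-farm survey for correlation recovery, 200
replicates for the null-correlation check, and 100–500 random draws for
kernel/algebra equivalence — sizes chosen so the full suite completes in
well under a minute of compute per module while keeping Monte-Carlo
standard errors a few times smaller than the tolerances they guard.

# Limitations

No animal disease, reproduction failure or market dynamics; no daily
weather-driven feed availability; all emissions are allocated to milk
(no milk/meat co-product allocation is mentioned in the source tables);
no economic feasibility of fertilizer-led intensification; no trade or
rebound modelling of concentrate demand. The concentrate-production
emission factor is a placeholder pending a published value.
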