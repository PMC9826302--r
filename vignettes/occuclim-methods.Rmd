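---
title: "Methods: occurrence cleaning and semiquantitative climatic characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occurrence cleaning and semiquantitative climatic characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occuclim)
```

## The problem

Large aggregated occurrence databases (GBIF, BIEN, national portals,
digitized herbaria) are the raw material for characterizing where — and
under which climates — taxa occur. They are also notoriously noisy: the
same specimen is served by several databases, coordinates are truncated
or land in the sea, botanical-garden plants masquerade as wild records,
and digitization errors place records far outside a taxon's native
range. `occuclim` implements a rule-based cleaning pipeline for such
tables, builds categorical bioclimatic regionalizations of a study
grid, and derives per-taxon *climatic preference profiles* — the
percentage of a taxon's occurrences in each category of a
classification — together with sampling-effort and range-size
diagnostics.

The approach is *semiquantitative*: instead of fitting a continuous
niche model, each taxon is described by its share of occurrences per
climatic category, and is called **unequivocally assigned** to a
category only when that share strictly exceeds 75%. The strictness
matters: a genus with exactly 3 of 4 unique localities in one zone
(75.00%) remains *equivocal*.

## Cleaning model

Stages run in a fixed order; every stage conserves records
(`input = kept + removed`), and the report exposes raw per-stage and
per-genus counts so users can audit totals rather than trust a single
summary number.

1. **Administrative harmonization.** TDWG level-3 and ISO country codes
   are overwritten from point-in-polygon lookups, which simultaneously
   fills gaps and repairs typographic errors. Points on a shared
   polygon boundary are assigned to the lexicographically smallest
   code — the data give no better rule, and reproducibility requires
   one.
2. **Replicate removal.** Records are replicates when they agree on the
   normalized nine-field voucher key (species, year, country code,
   locality, longitude and latitude *as text*, elevation, catalog
   number, basis of record). Text fields are trimmed and case-folded and
   missing values compare equal as empty strings, because sources differ
   systematically in voucher completeness. The first record in stable
   input order is kept; the source label is deliberately not in the key.
3. **Coordinate precision.** A record survives only if *both* textual
   coordinates carry at least two decimals. The rule is defined on the
   original text: numerically, 12.3 and 12.30 are the same number, but
   only the second asserts deca-meter-scale precision. This is why the
   data model stores `longitude_text`/`latitude_text` alongside the
   parsed values.
4. **Land / coastal filter.** A land-template grid (any raster whose
   data cells define the land surface) separates records on land,
   misplaced coastal records — off land but within 10 km (great-circle)
   of the nearest data cell's center, which are kept and snapped to
   that center so seaboard environments are not lost — and erroneous
   records beyond 10 km, which are removed. Distance is measured to
   cell centers because the template raster, not a vector coastline, is
   the operational definition of land here. Snapped records get new
   coordinates, so the pipeline re-harmonizes their country codes after
   this stage; without that, a snapped record would still carry its
   offshore (missing) code and be lost later at the native-range filter.
5. **Cultivated flagging.** Twelve multilingual keywords (garden,
   jardín, parque, golf, zoo, …) are matched as case- and
   diacritic-insensitive substrings of the locality. Flagging and
   removal are separate: the keyword list intentionally over-triggers
   (national *park* records are usually wild), so flagged records are
   returned for review and automatic removal is a config switch.
6. **Native-range filter.** A record is kept only when its TDWG code is
   in the declared native range of its genus. Records with no code
   (points in no polygon) cannot match and are removed, counted
   separately.

## Regionalizations

Five classification systems are supported at their broadest
hierarchical level, so analytical and synthetic systems are comparable:

* **Latitudinal zonation** (built): tropical < 23.5°, subtropical
  [23.5, 40), temperate [40, 66.5), polar ≥ 66.5° absolute latitude,
  symmetric across hemispheres. 40° is the conventional subtropical
  limit among physical geographers.
* **Holdridge life zones** (built): biotemperature (BioT) is the
  12-month mean of monthly temperatures with values outside [0, 30] °C
  set to 0 — the range in which plants grow efficiently. Zones:
  tropical [24, 30], subtropical [17, 24), warm temperate [12, 17),
  cool temperate [6, 12), boreal [3, 6), subpolar [1.5, 3), polar
  [0, 1.5). Published interval tables for this scheme circulate with an
  overlapping boreal/subpolar boundary (6–3 vs 3.5–1.5); a partition
  needs contiguous bounds, so 3 °C is used, with intervals closed on
  the warmer side (BioT 24 is tropical).
* **Köppen–Geiger main classes** (aggregated): A→tropical, B→dry,
  C→temperate, D→continental; the polar group E keeps its two subtypes
  as distinct broad classes, ET→tundra and EF→polar frost.
* **GEnS broad biomes** (pass-through): consumed as a supplied
  categorical layer with its own legend; no attempt is made to re-derive
  the stratification from its 42 input variables.
* **Simplified ecoregions** (aggregated): of the 14 terrestrial biomes,
  the four tropical/subtropical forest-and-grassland biomes merge into
  one category and the three temperate ones into another; the remaining
  seven pass through, giving 9 categories.

Grids are lightweight lon/lat matrices with half-open cells
`[x, x+Δ) × [y, y+Δ)` — every point belongs to exactly one cell — and
ship as plain-text ESRI ASCII grids with a JSON legend sidecar, a
format every GIS reads. Zone assignment uses cell centers.

## Profiles

`genus_profile()` first collapses records to unique coordinate pairs
(the exact (longitude, latitude) pair after snapping — a literal "one
record per coordinate", not a grid-cell thinning), then samples the
layer. Points in NoData cells are excluded from the percentage
denominator but always reported, so an ocean-heavy layer cannot
silently shrink a profile.

`clade_profile()` pools genera, damping taxonomic sampling bias: any
genus with strictly more than 1500 records is reduced to 1000
spatially regular records. The subsampler lays a systematic node grid
over the genus's bounding box, assigns each node its nearest unused
record, densifies until the yield reaches the target, and drops the
picks farthest from their nodes to land on the target exactly. This is
a deterministic, seeded stand-in for classic "regular" spatial sampling
routines whose exact point placement is not reproducible bit-for-bit;
what matters — and what the tests assert — is that the selection is
exactly sized and spatially more even than a random pick. Pooling does
*not* deduplicate coordinates across genera: two genera legitimately
co-occurring at one locality both contribute.

## Sampling effort, hotspots, range metrics

Sampling-effort grids count records in 1° half-open cells anchored at
integer degrees. Occupied-cell counts are classed with exact
Fisher–Jenks natural breaks (dynamic programming over the sorted
values, `O(kn²)`; ties resolve to the partition whose last class starts
lowest). Zero-count cells are not classed — only sampled cells carry
information about effort. The default class count is `k = 7`,
mirroring the usual heat-map legend depth; it is configurable. A class
is a **sampling hotspot** when its class maximum reaches 25% of the
regional per-cell maximum; the threshold is reported raw and as its
ceiling in records (a maximum of 8093 gives the integer threshold
2024). Among plausible readings of "classes including 25% of sampling
effort within their ranges", the class-max rule is implemented because
it reproduces the documented flagged classes; the fraction is config.

**AOO** projects points to a world cylindrical equal-area grid
(authalic sphere, fixed origin at the projection origin) with a 2-km
mesh and counts occupied cells × 4 km². The occupied-cell count depends
on where the mesh sits for point pairs straddling a grid line; fixing
(and exposing) the origin makes results reproducible. **EOO** is the
geodesic area of the convex hull on the WGS84 ellipsoid; fewer than
three non-collinear points give 0, and point sets whose longitudes span
more than 180° are unwrapped first so trans-Pacific disjunctions get
the compact hull. Size classes use the 2000 km² minimum AOO of IUCN
criterion B2 (Vulnerable) as an objective *size* cutoff — explicitly
not a risk assessment — and 10,000 km² (strict) for widespread.

Temporal series accumulate records per region and label from 1900
(earlier records are too sparse to interpret and are excluded but
counted), reporting the first year at which 25/50/75% of each series is
reached.

## Synthetic data and what the tests show

The generator builds a 6°×6° landmass of four rectangular botanical
countries in a sea margin, a 0.05° land-mask template, monthly
temperature grids with a linear latitudinal gradient (defaults 28 °C at
the equator, −0.35 °C per degree, ±5 °C seasonality, 0.1 °C noise) so
Holdridge boundaries sit at closed-form latitudes, and a 100-record,
5-genus occurrence table with planted defects: 10 replicates, 5
low-precision, 4 coastal (< 10 km), 3 offshore (> 10 km), 2
cultivated-keyword, 4 out-of-native-range. Defect classes are disjoint
by construction — a record carries at most one defect — because
overlapping defects would make per-stage removal counts unidentifiable.
Coordinates are generated as text first and parsed from it, so the
precision filter sees realistic textual forms.

Passing the planted-error recovery suite (stage counts equal planted
counts on 20+ seeds) shows the *rules* are implemented exactly as
specified. It does not show the rules are sufficient for real data:
real duplicates differ subtly instead of byte-identically, real
coastlines are not rectangles, cultivated records rarely announce
themselves, and native-range checklists are incomplete. The synthetic
world also has no elevation structure and no collector-behavior bias.

## Numerical choices and limitations

* Problem sizes default to desk scale (coarse grids ≤ 1°, hundreds of
  records); all operations accept larger inputs but the exact Jenks DP
  is quadratic in the number of occupied cells.
* The coastal search examines candidate cells in a window padded beyond
  the 10-km threshold, then measures geodesic distance; results equal a
  brute-force scan over all cells (tested).
* Share comparisons at the 75% threshold are exact in binary floating
  point (0.75 is representable), so "strictly greater" behaves exactly.
* `jenks_breaks()` requires `k` ≤ number of distinct values; degenerate
  single-valued inputs take `k = 1`.
* Profiles need at least one classifiable record per genus; the
  pipeline logs and skips genera that fail rather than aborting a run.
* The equal-area projection for AOO uses the authalic radius; EOO uses
  ellipsoidal geodesic areas. Mixing a spherical grid with ellipsoidal
  hull areas is deliberate: AOO only needs equal-area *cells*, EOO
  needs the best available area.

## Reproducibility

Every stochastic step (generator, subsampler, pipeline) takes an
explicit seed; `run_pipeline()` writes a manifest with the config, seed
and MD5 checksum of every artifact, and reruns with the same config and
seed are byte-identical (tested). The command-line wrapper
(`inst/scripts/occuclim.R`) is a thin veneer over the exported
functions.
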