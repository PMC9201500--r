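---
title: "Methods: water productivity, root-trait decomposition and the RDPI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water productivity, root-trait decomposition and the RDPI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootplast)
```

`rootplast` implements a complete analysis pipeline for pot-based root
phenotyping trials that contrast a well-watered (WW) and a water-deficit (WD)
irrigation regime across a set of genotypes in a randomized complete block
design (RCBD). This vignette documents the models, conventions and numerical
choices; the README shows a worked run.

## Gravimetric water accounting

Pots are weighed repeatedly over the run (default: three times per week,
evenly spaced within each week, i.e. days 0, 2 and 4 of each 7-day week,
with day 0 and the final day always included). WW pots are refilled to the
field-capacity weight at every weighing; WD pots receive no water. Unplanted
control pots, open to drainage but carrying no plant, estimate the
non-transpiration losses.

Water use of one plant over the run is the telescoped sum over successive
weighings

$$\mathrm{WU} = \sum_i \left[(PW_{i-1} - PW_i) - (CPW_{i-1} - CPW_i)
  - \mathrm{PBG}\,\Delta t_i\right],$$

with $PW$ the planted pot weight (kg), $CPW$ the control pot weight, and
PBG the plant biomass gain, the daily fresh-weight gain
$(\text{final} - \text{initial})/n_\text{days}$ in g/day (converted to kg
inside the sum). Units: 1 kg of water = 1 L.

Two conventions deserve notice:

* **Irrigation refills.** Applying the difference formula across a refill
  would count the added water as negative consumption. The series therefore
  records pre- and post-irrigation weights as separate rows and the sum
  skips the zero-length refill jump, so each interval contributes the water
  actually lost between weighings. With no refills, constant control and
  zero PBG the sum telescopes to (first weight − last weight) exactly, which
  the tests assert to 1e-12.
* **PBG inside the sum.** The per-interval subtraction is daily PBG times
  the interval length, so the total subtraction equals the whole
  fresh-biomass gain regardless of the weighing schedule.

Water productivity is $\mathrm{WP} = (\mathrm{RDW} + \mathrm{SDW}) /
\mathrm{WU}$ in kg·m⁻³ (numerically g dry matter per litre), with RDW and
SDW the root and shoot (leaves + stems) dry weights; WP is undefined
(NA, with a warning) when WU ≤ 0. The root:shoot ratio is RDW/SDW.

## Root-trait decomposition

Scanned root systems arrive as segment tables (depth, length, diameter).
Each segment is treated as a cylinder: $SA = \pi d L$,
$RV = \pi (d/2)^2 L$. Aggregation yields total root length (RL, cm),
surface area (SA, cm²), volume (RV, cm³) and mean root diameter (MRD, mm)
per plant, per 10-cm depth layer (0–10, 10–20, 20–30, 30–40 cm) and per
0.5-mm diameter class (0.0–0.5 … 4.0–4.5 mm).

Conventions:

* Bins are half-open $[a, b)$ with the last bin closed, so the partition is
  exact and RL/SA/RV sums over layers or classes equal the whole-plant
  totals to machine precision (asserted at ≤1e-9 relative error).
* Diameters above 4.5 mm are not an error: they are flagged and assigned to
  an overflow class so conservation still holds.
* Segments are assigned to layers by their midpoint depth and are not split
  across layers; the generator emits segments shorter than the 10-cm layer
  thickness, so the approximation is mild.
* MRD is the **length-weighted** mean segment diameter. The scanner
  software's exact definition is proprietary; weighting by length is the
  natural definition for a root system whose segments differ in length, and
  an unweighted variant is available via `mrd_weighted = FALSE`.

## The relative distance plasticity index

For a genotype and trait $x$, every individual $j$ grown under WW is paired
with every individual $j'$ grown under WD, and

$$\mathrm{RDPI} = \frac{1}{n} \sum_{j,j'}
  \frac{|x_{j'} - x_{j}|}{x_{j'} + x_{j}},$$

with $n$ the number of cross-condition pairs (9 under the default 3-block
design). Within-condition pairs are never used. RDPI lies in $[0, 1]$: 0
means no response to the regime, 1 a maximal response. The absolute value
follows the index's verbal definition as an absolute distance (and is what
makes published RDPI tables nonnegative). Pairs with $x_j = x_{j'} = 0$ are
undefined (0/0) and are excluded with $n$ decremented, rather than being
scored 0.

A useful identity: if the WD values are exactly $k$ times the WW values,
every pair has $rd = (1-k)/(1+k)$, so RDPI $= (1-k)/(1+k)$ — e.g. $k = 0.5
\Rightarrow 1/3$. The tests use this closed form, and the synthetic
generator configures one genotype at exactly $k = 0.5$ so the end-to-end run
recovers it.

**Replication unit for the RDPI ANOVA.** The one-way ANOVA comparing RDPI
across genotypes needs observations. Two modes are provided: `"pairs"`
passes each of the 9 cross-condition relative distances as an observation —
this matches an $n = 9$ bookkeeping but is pseudo-replicated, since the 9
pairs reuse 6 plants; `"block"` pairs only the WW and WD plant of the same
block, giving 3 independent distances. Neither mode is asserted to be what
any particular study did; `"pairs"` is the default and the caveat stands.

## Inferential layer

* **Assumption checks.** Shapiro–Wilk on the residuals, Bartlett across
  groups, run before the ANOVAs and reported with the results.
* **Two-way RCBD ANOVA.** `value ~ block + genotype + regime +
  genotype:regime`, all factors fixed. Sums of squares are Type II, which
  equal the classical sequential decomposition on balanced data and degrade
  gracefully under mild imbalance (a warning is emitted). A saturated
  (zero-residual) fit falls back to the sequential table, which is identical
  on balanced data. Block is fixed: with 3 blocks there is little to gain
  from a variance component, and the classical analysis is the reference
  here.
* **Fisher's LSD letters.** Two groups differ when their mean difference
  exceeds $t_{1-\alpha/2,\,df_e}\sqrt{MSE(1/n_a + 1/n_b)}$ with the pooled
  ANOVA error. The compact letter display uses insert-and-absorb: start
  with one letter covering all groups, split it on each significant pair,
  drop letters whose group set is contained in another's, and order letters
  by the highest mean they contain so "a" marks the top group. This
  guarantees exactly that two groups share a letter iff they are not
  significantly different, which the tests verify against an all-pairs t
  oracle. No multiplicity adjustment is applied beyond the LSD itself — a
  known limitation of the procedure, kept deliberately.
* **Regime contrasts.** Per genotype, estimate $=\bar{x}_{WW} -
  \bar{x}_{WD}$ with SE from the pooled two-way MSE. The WW − WD
  orientation makes estimates positive for traits that drought reduces and
  negative for traits (root:shoot) that it raises, matching the sign pattern
  of published contrast tables whose captions label the comparison the other
  way around.
* **Correlations.** Pairwise Pearson $r$ with two-sided p from
  $t = r\sqrt{(n-2)/(1-r^2)}$; computed on genotype means within each
  regime (8 observations by default). Which observational unit enters such
  panels is rarely stated in print; genotype means are the default here and
  plant-level input is a one-line change.
* **PCA.** Eigendecomposition of the correlation matrix of {WP, RL, SA,
  MRD, RV} over the genotype means of one regime. Eigenvalues sum to the
  number of variables; loadings reconstruct the correlation matrix;
  observation scores come from the standardized data. Sign convention: each
  component is flipped so its largest-magnitude loading is positive, making
  biplots reproducible. Biplot coordinates scale the loadings by
  $\sqrt{\lambda}$.

## The synthetic-data generator

No raw data of this kind are publicly deposited, so the generator is a
first-class module: it produces complete, seeded datasets with the
statistical structure the analysis assumes, and the whole pipeline is tested
against it.

What it emulates (defaults in parentheses):

* the RCBD layout — 8 genotypes × 2 regimes × 3 blocks, one plant per cell
  (48 plants), 35 days, 3 weighings/week, 20 L pots at 30 kg field
  capacity;
* WW pots refilled to field capacity at each weighing with ~0.65 kg/day
  evapotranspiration (scaled per genotype), WD pots declining
  monotonically with a daily loss that decays exponentially (0.5 kg/day
  initial, rate 0.08/day), flattening as plants die toward the end of the
  run; control pots losing only 0.02 kg/day;
* biomass: genotype-specific WW dry weights with WD reduction factors of
  ~0.63 (roots) and ~0.20 (shoots), so the root:shoot ratio rises under
  drought; fresh weights are dry weights times a fixed fresh:dry ratio of
  10 (a value such studies do not print; 10 is typical for cucurbit
  seedlings);
* root systems: per-layer length targets (allocation 0.30/0.35/0.20/0.15
  over the four layers), log-normal segment lengths, and a two-component
  log-normal diameter mixture (fine roots: median 0.75 mm, log-SD 0.45,
  88% of segments; thick roots: median 2.8 mm, log-SD 0.30) scaled per
  genotype — under these defaults the modal root-length diameter class is
  0.5–1.0 mm, the canonical fine-root pattern;
* under WD, the extensive root traits are reduced to 40–50% of WW per
  genotype (the study pattern being a reduction of *at least* 50% in every
  layer), with Osorno at exactly $k = 0.5$ as the closed-form RDPI
  reference; diameter medians shrink by 15%, consistent with printed
  whole-plant MRD means — note that an intensive trait cannot also halve
  per layer while the diameter distribution barely moves, so the ≥50%
  signature is asserted for RL/SA/RV only.

Noise enters multiplicatively (log-normal) per block (log-SD 0.05) and per
plant (log-SD 0.08), and on the daily water losses (SD 4%, truncated at
zero so WD weights stay monotone by construction). With all noise set to
zero the generator is exactly proportional: WD totals equal the reduction
factor times WW totals, which the tests assert to 1e-12.

What it does **not** emulate: soil physics, weather-driven
evapotranspiration, root images, within-plant correlation between biomass
and architecture beyond the shared plant/block multipliers, measurement
error of the scanner, or mortality other than the smooth WD die-back. A
green test suite therefore shows that the *analysis* is correct under the
assumed structure, not that real data satisfy that structure.

An optional quality-control check flags plants whose total dry biomass per
pot volume exceeds 2 g/L, a published guidance bound above which pot size
itself restricts growth.

## Problem sizes and numerical tolerances

The default simulated experiment has 48 plants and ~6,000 root segments;
property tests use 50–1,000 random replicates per invariant and the ANOVA
null calibration uses 2,000 simulated experiments — sizes chosen to make
Monte-Carlo error small relative to the asserted bounds. Exact identities
(telescoping, partition conservation, RDPI brute-force equivalence, SS
partitions, PCA reconstruction) are asserted at 1e-9–1e-12; stochastic
checks (type-I error 0.05 ± 0.02; RDPI 1/3 ± 0.05 under plant noise) at
bounds derived from their sampling variance. Ties in the letter display
cannot occur for continuous data; equal means share letters by
construction. Degenerate inputs (empty groups, zero variance, WU ≤ 0,
SDW = 0, both-zero RDPI pairs) return NA with a warning rather than
silently propagating, and hard precondition violations (nonpositive
segment dimensions, schedule mismatches) are errors.

## Interfaces

The package's functions are the interface; `run_pipeline()` is the
end-to-end entry point, configurable from a YAML file (`read_config()`),
and writes every result table as CSV when given an output directory.
Datasets exchange as three documented CSVs (`plants.csv`,
`pot_weights.csv`, `root_segments.csv`), comma-separated, UTF-8, `.`
decimal, header mandatory, empty cells meaning missing.
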