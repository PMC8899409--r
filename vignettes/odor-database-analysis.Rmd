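---
title: "Curating and mining an insect odorant-response database"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and mining an insect odorant-response database}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorDB)
```

## The problem

Behavioral and electrophysiological responses of mosquitoes (and of
*Drosophila*) to odorants are scattered across hundreds of papers that
differ in units, normalization, background treatment, odorant naming and
assay design. Pooling them into one table enables analyses no single
study can support — but only if every measurement is first mapped onto a
common schema. `odorDB` implements that standardization and the
pattern-discovery analyses such a table enables, and ships a synthetic
database generator so that every analysis can be validated closed-loop
against planted effects.

The standardized record schema has one row per measurement with four data
types: **OR** (receptor responses from heterologous expression —
empty-neuron recordings in spikes/s or *Xenopus* oocyte currents in nA),
**SSR** (native single-sensillum recordings), **EAG** (electroantennogram
amplitudes, normalized), and **BEHAVIOR** (two-choice preference indices).

## Standardization rules

* **Preference index.** All behavioral metrics are mapped to
  $PI = (n_{test} - n_{control}) / (n_{test} + n_{control}) \in [-1, 1]$.
  The literature's percent attraction $a$ and percent repellency $r$ name
  the metrics without giving conversion formulas; we adopt the
  two-alternative linear maps $PI = 2a/100 - 1$ and $PI = 1 - 2r/100$,
  which agree with the counting definition when every animal chooses one
  of two arms (75% attraction $\leftrightarrow$ 75:25 $\leftrightarrow$
  $PI = 0.5$). The original metric name travels with the record so an
  alternative map can be swapped in; protective-efficacy values are
  imported through the repellency map and flagged.
* **Concentration.** Reported concentrations become V/V fractions, W/V
  g/mL, or flagged dry amounts: molarity $m \to m \cdot MW / 1000$ g/mL,
  ppm $p \to p$ mg/L $= p \times 10^{-6}$ g/mL, and a surface density $d$
  g/cm² applied over $A$ cm² in $V$ mL $\to dA/V$ g/mL. Converted values
  are stored at 3 significant digits, the reporting precision of curated
  databases (so $1.11 \times 10^{-5}$ M of lactic acid, MW 90.08, is
  stored as $10^{-6}$ g/mL). Dry amounts never compare equal to solution
  concentrations in any matching operation.
* **Decades.** Cross-study matching always happens on concentrations
  rounded to the nearest power of ten, $10^{\mathrm{round}(\log_{10} c)}$.
  Exact half-cases ($c = 10^{k+1/2}$) round toward the lower exponent — a
  documented tie-break, not a numerical accident.
* **EAG.** Studies that report raw amplitudes are divided by the study's
  mean response to a reference odorant, 1-octen-3-ol when present; the
  reference used is recorded per data point. Already-normalized records
  pass through unchanged (the operation is idempotent).
* **Background.** OR responses reported without background subtraction
  have the solvent response subtracted; negative results are retained as
  inhibition.
* **Odorant names.** A two-column synonym table maps reported names
  (case- and whitespace-insensitively) to one canonical name per
  compound; unknown names are rejected with an explicit error, because a
  silent pass-through would corrupt every downstream join. No fuzzy
  matching is attempted.

Numeric storage uses fixed reporting precisions (concentrations 3
significant digits; spikes/s and nA 4 decimals; indices and normalized
EAG 6 decimals), and the rounding is performed through decimal text
(`sprintf`/`strtod`, both correctly rounded). This guarantees the
round-trip contracts: a database written to CSV and re-read is
field-identical, and the messy-variant emitter followed by
`standardizeRecords()` reproduces its input exactly.

## Gaussian tuning with a permutation null

For each physicochemical property with at least ten distinct values, the
OR empty-neuron responses at the $10^{-2}$ decade (the most common
concentration) are fitted with
$r = a \exp(-(x - b)^2 / (2\sigma^2))$, reported directly in $\sigma$,
the standard deviation of the Gaussian (some toolboxes use a width $c =
\sigma\sqrt{2}$; parameterizing in $\sigma$ removes the ambiguity).
Reliability is assessed by shuffling the property-to-response mapping
(1000 shuffles by default) and reporting
$p = \#\{\sigma_{shuffle} \le \sigma_{actual}\} / n_{shuffles}$.

Numerical choices:

* The fit is a Levenberg–Marquardt least-squares solve (compiled) with a
  deterministic, scale-aware initialization: $a_0 = \max r$, $b_0 = x$ at
  the maximum response, $\sigma_0 = \mathrm{IQR}(x)/2$ bounded positive.
  Inhibitory (negative) responses stay in the fit.
* An iteration-capped iterate counts as a valid fit; only a non-finite
  breakdown is a failure. This matters: the permutation test is exact
  only if the data-to-$\sigma$ map is the same deterministic function for
  observed and shuffled data. The calibration suite (1000 null datasets,
  200 shuffles each) verifies a rejection rate at $\alpha = 0.05$ inside
  $[0.03, 0.07]$. Genuine breakdowns contribute
  $\sigma_{shuffle} = +\infty$ and are counted in the result.
* One global seed drives all shuffles; per-property streams are derived
  by hashing the property name, so properties can be analyzed in any
  order with identical p-values. An exhaustive mode enumerates all $n!$
  permutations for small $n$; the suite checks it against an independent
  solver (`minpack.lm`) enumeration.

Raw (unbinned) responses are fitted — scatter-level fitting is assumed
since binning rules are not part of the record schema — and species are
analyzed independently via the `species` filter.

## Descriptor-based response prediction

Molecular descriptors pass a three-stage cascade: drop descriptors with
any missing value; drop raw variance $< 0.005$ (the threshold is
scale-dependent by design, so variance is computed before any
standardization); then a greedy keep-first scan drops any descriptor
correlated $> 0.95$ in absolute value with an already-retained one. The
greedy direction is a documented choice — with the descriptor file fixed,
the survivor set is reproducible. The cascade is idempotent and never
increases the count.

Each OR gets its own feedforward network (three hidden layers of 50 tanh
units, linear output) trained on 70% of the odorants with 15% for early
stopping and 15% held out for testing; split sizes round to the nearest
integer with the remainder to training (112 odorants give 78/17/17).
Inputs and targets are standardized on the training set only. The
optimizer is full-batch Adam (rate 0.01, up to 400 epochs, patience 30,
best-validation weights restored) — hyperparameters beyond the
architecture are package defaults, all seeded, and training is
deterministic given the seed. The control model reads its "predictions"
from a global random permutation of the OR × odorant response matrix (a
per-row variant is available via `control_per_row`); model and control
are compared across ORs with a two-sided paired sign-rank test on per-OR
test correlations and on mean absolute errors.

## Comparative analyses

* **Techniques** (`crosstabTechniques`): empty-neuron and oocyte records
  are joined on (receptor, odorant, decade) and cross-tabulated by
  zero/non-zero response. "Zero" means exactly 0 after standardization —
  oocyte non-responses are recorded as literal zeros — with no epsilon
  band. Among negative empty-neuron responses, means ± SD are reported
  separately for zero and non-zero oocyte responses, to test whether
  oocyte zeros merely reflect inhibition.
* **Assay categories** (`pairByAssayCategory`): for each (odorant,
  decade, species) present in both category sets, points within each set
  are averaged, one pair is emitted, and pairs are pooled across species
  after the per-species pairing. Presets: mosquito landing vs
  {dual-port, Y-tube}; fly T-maze vs {dual-port, Y-maze}.
* **Preference vs oviposition** (`correlatePiOviposition`): matched per
  (odorant, decade) within species; species with fewer than 5 matched
  items are skipped with an explicit signal.
* **Cross-species** (`crossSpeciesCorrelation`): equal decades preferred,
  otherwise the nearest decade within ±10-fold; with one candidate above
  and one below, the lower decade wins (logged tie-break). Pairs with
  fewer than 10 common odorants are skipped.
* **Concentration dependence** (`concentrationPairDeltas`): cells need at
  least two data points (averaged); adjacent-decade deltas
  $PI_{high} - PI_{low}$ are sign-rank tested against zero, optionally
  filtered by the sign of the lower-decade PI.
* **Activation count** (`orActivationVsPi`): ORs with response
  $\ge$ 10 spikes/s count as activated ("at least" — exactly 10 counts);
  counts are Pearson-correlated with the averaged PI at the matched
  decade. Pearson is used throughout the correlation analyses.

The sign-rank test uses the exact null distribution for up to 25 non-zero
differences (dynamic programming over doubled ranks, which stays exact
under ties), and a normal approximation with continuity correction and
tie-adjusted variance above; zero differences are dropped. The suite
checks it against full $2^n$ enumeration.

No meta-analytic weighting by study size is applied (points are averaged
unweighted) and no multiple-testing correction is applied across the
analysis suite; both choices mirror standard practice for this kind of
descriptive cross-study screen.

## The synthetic database generator

`generateDatabase()` plants every effect the analyses are meant to
detect, under one seed (identical configurations are byte-identical):

* OR empty-neuron responses
  $a^* e^{-(x - b^*)^2 / (2\sigma^{*2})} + \varepsilon$ with defaults
  $a^* = 100$ spikes/s, $b^* = 100$, $\sigma^* = 30$ property units on a
  molecular-volume-like property $\sim N(100, 40)$, and noise SD 10
  (i.e. $0.1\,a^*$); 20% of OR–odorant pairs receive a negative uniform
  offset (up to 20 spikes/s) so inhibitory subgroups have mass.
* Oocyte records $= gain \cdot \max(0, en - \theta)$ with $\theta = 15$
  spikes/s — a less sensitive second technique producing literal zeros.
* Preference indices
  $base(odor) - \beta (d - d_{ref}) + \delta(assay) - \gamma n_{act} +
  \varepsilon$, clipped to $[-1, 1]$ last, with $base \sim U(-0.5, 0.5)$,
  $\beta = 0.2$ per decade, landing/T-maze offset $\delta = -0.3$,
  $\gamma = 0.01$ per activated OR, noise SD 0.05, decades
  $10^{-4}..10^{-1}$, two replicate studies per cell (the
  concentration-delta analysis requires $\ge 2$ points per cell).
  Oviposition indices are drawn independently by default (`coupled`
  optionally).
* Sizes default to 200 odorants, 30 ORs, 3 species — large enough for
  stable recovery, small enough that the whole validation suite runs in
  about a minute of fitting time. The descriptor-model checks use 112
  odorants and 30 ORs.

The descriptor panel contains the tuning property, a near-duplicate
(correlation > 0.95, exercising the filter), a moderately correlated
nuisance, other properties, pure-noise columns, a constant column and a
column with missing entries — plus a squared-deviation transform of the
tuning property. The transform matters: a symmetric tuning curve has
essentially zero *linear* correlation with every raw descriptor, so at
~100 training odorants a gradient-trained network cannot discover it from
the raw property alone; real descriptor collections (PubChem, Mordred)
likewise contain many nonlinear transforms of shared structural factors,
which is what makes such data learnable in practice.

`generateRawVariants()` re-expresses a standardized database with
randomized messy conventions (synonym spellings, molar / ppm /
mass-per-area concentrations, percent attraction/repellency,
de-normalized EAG studies, un-subtracted backgrounds with the solvent
response in its own column) such that `standardizeRecords()` recovers the
original table field-identically — the round-trip is the standardization
module's closed-loop test.

### What passing tests do and do not show

The generator emulates the *statistical structure* the analyses rely on,
not the marginal distributions of any real database: species
proportions, odorant chemistry, study-size imbalance, reporting biases
and correlated measurement error are all absent. Parameter-recovery and
calibration results therefore validate the estimators and their
implementation, not the biological conclusions one would draw from real
data; headline real-data values (e.g. a mean model correlation of
0.37, or 71.7% empty-neuron-nonzero/oocyte-zero pairs) require the real
curated database, which users can supply as a flat file through
`readResponseRecords()`.

## Known limitations

* The shared tuning center across ORs is a simplification; real
  receptors differ in both center and width, so the synthetic crosstab
  and activation-count distributions are more bimodal than real data.
* Clipping of planted preference indices at $[-1, 1]$ slightly attenuates
  the recovered concentration slope (the recovery band in the validation
  suite accounts for this).
* The percent-attraction/repellency maps assume a two-alternative assay;
  metrics from assays with a no-choice fraction would need their own map
  (the raw metric name is preserved to allow this).
* Exhaustive permutation enumeration is limited to $n \le 8$ pairs.
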