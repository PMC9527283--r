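---
title: "Methods: exposure-driven TTC prioritization of chemicals in food"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure-driven TTC prioritization of chemicals in food}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Food-monitoring programmes accumulate analytical data on far more
chemicals — pesticide residues, environmental contaminants, mycotoxins,
metals — than can ever receive a full toxicological evaluation. An
exposure-led prioritization puts the screening effort where it matters:
estimate how much of each substance the population actually ingests,
compare that exposure against a structure-based hazard threshold (the
Threshold of Toxicological Concern, TTC), and carry only the substances
whose exposure exceeds their threshold into high-throughput screening.
`ttcprior` implements that workflow end to end, together with a seeded
synthetic-data generator, so every stage is testable without access to
restricted monitoring and consumption databases.

Priority here means "evaluate sooner", not "more dangerous": a high
hazard quotient flags a substance for follow-up, it does not constitute
a risk assessment.

# Chronic dietary exposure: the OIM model

Exposure is chronic and dietary. For subject $i$ on survey day $d$, the
intake of substance $s$ is

$$
y_{i,d,s} \;=\; \frac{1}{bw_i} \sum_{c} a_{i,d,c} \cdot x_{s,c},
$$

where $a_{i,d,c}$ is the amount of raw commodity $c$ consumed (g/day,
obtained by expanding each diary food through the food-translation
table's percentages), $x_{s,c}$ the concentration of $s$ in $c$
(mg/kg), and $bw_i$ the body weight (kg); with these units
$1\,\mathrm{g} \times 1\,\mathrm{mg/kg} = 1\,\mu\mathrm{g}$, so intakes
are in µg/kg bw/day throughout. The observed individual mean (OIM) is
the average of $y_{i,d,s}$ over the subject's recorded days (two in the
emulated survey design). Subjects who never consume a contributing food
stay in the distribution with OIM = 0 — the chronic population
distribution includes non-consumers.

**Censored concentrations.** Monitoring results below the limit of
detection (LOD) or quantification (LOQ) are handled by two bounding
scenarios: the *lower bound* sets non-detects to zero; the *upper
bound* substitutes the LOD (for results below detection) or the LOQ
(below quantification). Every downstream exposure is therefore a pair
of bounds; the upper bound is the default driver of prioritization.

**Pooling.** Within a substance × commodity pair, the engine uses the
arithmetic mean of the scenario-resolved sample concentrations — a
standard chronic-exposure convention where long-run average intake is
the quantity of interest. Sample-level resampling would matter for
acute assessment, which is out of scope.

**Survey weighting.** Population summaries (mean, median, 95th
percentile) are weighted by the survey weights that correct the sample
for sociodemographic composition. The weighted mean is
$\sum w_i y_i / \sum w_i$. For quantiles we use the inverse of the
weighted empirical distribution, averaging the two adjacent values when
the target probability falls exactly on a cumulative-weight boundary;
with equal weights this is the classical type 2 sample quantile (so the
equal-weight p95 of $1..100$ is $95.5$).

That quantile definition is a deliberate choice. Interpolating
quantiles on a cumulative-weight grid (the type-7-style generalization)
looks natural, but its grid depends on *which subject's weight sits at
which rank*. When two value vectors sort differently — exactly what
happens between the lower- and upper-bound intake vectors — such
interpolation is not monotone under pointwise dominance, and we
observed lower-bound 95th percentiles exceeding their upper-bound
counterparts by several percent on unequal survey weights. The step
inverse is monotone by construction, which makes the scenario ordering
(lower ≤ upper for every substance and every statistic) an exact
invariant rather than an approximate one.

**Which statistic meets the TTC?** The workflow compares the
upper-bound weighted *mean* against the TTC by default; median or p95
are available through the run configuration. A single statistic is used
for both priority lists (TTC-applicable and TTC-excluded) — simpler and
more defensible than mixing statistics between lists.

# The TTC decision tree

Each substance with a representative structure passes through four
short-circuiting steps; the first step that fires determines the
outcome.

1. **Exclusion rules.** Inorganic, metal-containing, mixture,
   bioaccumulating, or aflatoxin-like substances are excluded: no safe
   exposure threshold can be derived for these categories, and any
   exposure above the reporting cutoff is a follow-up trigger.
2. **Genotoxicity consensus.** Six alert booleans — three models
   (DEREK, ISS, OASIS) × two endpoints (Ames mutagenicity, chromosome
   damage) — are inputs, not computed here; re-implementing the
   underlying profilers is explicitly out of scope. An endpoint is
   positive when at least two of the three models flag it; a substance
   is genotoxic when either endpoint is positive, and receives the
   lowest TTC, 0.0025 µg/kg bw/day.
3. **Organophosphate/carbamate filter.** Structures are matched against
   the phosphate pattern (a P with a doubly-bonded O and three O-linked
   non-hydrogen substituents) and the carbamate pattern
   (R–O–C(=O)–N(R)R, all R non-hydrogen). A hit receives 0.3 µg/kg
   bw/day.
4. **Cramer classes.** Remaining substances are mapped by their
   (input) Cramer class: III → 1.5, II → 9, I → 30 µg/kg bw/day. The
   class II tier is implemented even though realistic pesticide sets
   rarely populate it.

Substances without a parseable structure get the `no_structure`
verdict and are reported as *unevaluated — awaiting further
prioritization*; structure-less does not mean safe.

**Literal vs relaxed matching.** The patterns in step 3 are encoded as
SMARTS and matched with OpenBabel (via ChemmineOB). The default
*literal* mode applies them exactly as written above — which means
thiophosphates (P=S, e.g. dimethoate) and N–H carbamates (e.g.
chlorpropham) do **not** hit, although both kinds are common
organophosphate/carbamate pesticides. The *relaxed* mode widens the
phosphate pattern to P(=O or =S) with three O/S-linked heavy
substituents and the carbamate pattern to a single N–H; that is the
behaviour a practitioner would probably expect from an
"organophosphate or carbamate" filter. Both modes are first-class
options rather than a silent fix; the relaxed phosphate deliberately
admits S-linked substituents so that full thio analogues like
dimethoate match. The literal hits are provably a subset of the
relaxed hits.

Precedence is strictly 1 → 2 → 3 → 4: a genotoxic organophosphate gets
0.0025, not 0.3. The test suite checks the whole tree against an
independently coded brute-force oracle over the exhaustive enumeration
of $2^6$ alert profiles × 3 substructure states × 3 Cramer classes in
both matching modes (1,152 cases), and the substructure engine against
a hand-written molecular-graph matcher that shares no code with the
SMARTS engine.

# Hazard quotients and the priority lists

For a substance with an assigned TTC, the hazard quotient is
$HQ = \text{exposure} / \text{TTC}$. Four mutually exclusive lists
partition every substance:

* `ttc_priority`: TTC assigned and $HQ > 1$ (strict, so a substance
  exactly at its threshold is *not* priority);
* `ttc_excluded_priority`: TTC-excluded and exposure ≥ 0.5 µg/kg
  bw/day (the cutoff comparison is inclusive, unlike the strict HQ rule);
* `unevaluated`: no representative structure, regardless of exposure;
* `not_priority`: everything else.

The screening subset takes, within each TTC class, the top-HQ
substances: 10 from the 0.0025 class and 2 each from 0.3 and 1.5; the
configuration extends the same count of 2 to classes 9 and 30 for
symmetry, since nothing principled distinguishes them once populated.
Ties (which essentially never occur at data precision, but must be
deterministic) break by descending exposure, then ascending substance
code. Output order is TTC ascending, then HQ descending.

# HTS potency normalization

The screened substances meet heterogeneous prediction-model outputs:
composite multiparameter scores, percent-of-maximum activity, AC50s,
potency ranks, lowest effect levels. To compare across models, each
readout is first mapped to a scale monotone in potency — identity for
scores and percentages, $-\log_{10}$ for concentration readouts (AC50
and LEL alike, both being concentrations), and rank reversal
($N - r + 1$) for ranked lists — then min–max scaled within the model
to $[0, 100]$ with the most potent substance anchored at exactly 100.
The max anchor is the one documented property of the published
normalization; the min anchor at 0 and the rank/LEL transforms are this
package's documented choices. The implementation computes the ratio
before scaling by 100 so the anchor holds exactly in floating point.

Two kinds of empty cell are kept distinct and never conflated:
`not_active` (an observed negative) and `not_tested` (absence of
data). A substance untested in *every* model is flagged in the final
matrix — missing coverage is itself a reportable finding.

# The synthetic-data generator

The generator emulates the statistical structure of the real inputs the
workflow was designed around, with known ground truth:

* **Survey**: 3,819 subjects × 2 recall days by default (the emulated
  consumption-survey design); body weights normal around 70 kg
  (clipped to 25–120 kg); survey weights uniform in $[0.5, 2]$,
  normalized — the real weighting scheme is not published, only its
  existence.
* **Diet**: each subject-day samples foods with probability 0.5 (one
  staple always consumed), amounts gamma with shape 2 and mean 120
  g/day — the standard right-skewed model for intake amounts.
* **Concentrations**: log-normal per substance (log-sd 0.4, a
  realistic spread for residue monitoring within a commodity), eight
  samples per substance × commodity, censored with probability 0.3 by
  default, split between below-LOD and below-LOQ reports. LOD and LOQ
  sit at 0.8× and 1.2× the substance's mean concentration, so
  upper-bound substitution is scale-preserving in expectation while
  the lower bound loses the censored mass.
* **Planted truth**: substances cycle through the decision-tree
  branches (excluded, genotoxic, organophosphate, carbamate, Cramer
  I/II/III, no structure) with alternating high/low exposure tiers.
  Annotations are constructed to *realize* their branch — e.g. a
  planted genotoxic substance gets ≥ 2 positive alerts on one
  endpoint, a planted Cramer substance gets a structure that misses
  both substructure patterns even in relaxed mode — and realizability
  is asserted at generation time, so a downstream test failure always
  indicates a pipeline bug, not generator noise.
* **Calibration**: the survey-weighted exposure per unit concentration
  is computed for each substance's commodities from the generated
  consumption, and the concentration scale is set so the expected
  upper-bound mean exposure equals 10× the substance's threshold
  (high tier) or 0.1× (low tier); the threshold is the TTC for
  TTC-branch substances and the 0.5 µg/kg bw/day reporting cutoff for
  excluded and structure-less ones.
* **HTS tables**: one per readout type, raw values strictly
  monotone-consistent with a planted potency order, with a
  configurable `not_tested` fraction per model.

Everything is deterministic given the parameter object and its seed,
down to the bytes of the written CSV files.

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: correlation structure between foods
(market baskets, seasonality), realistic food-translation hierarchies,
heaped amount reporting, substance co-occurrence, model-specific HTS
noise, or the real databases' code systems beyond their flat shape.
Plant recovery demonstrates that the pipeline's arithmetic and
decision logic are correct under controlled separation; it says
nothing about the epidemiological quality of any real exposure
estimate.

# Numerical and design choices

* Identifiers are case-sensitive exact strings; no fuzzy matching of
  food or substance codes.
* Readers are strict: structurally malformed rows abort with row
  numbers. The single defined demotion is an unparseable SMILES, which
  keeps the record as structure-less with a warning — mirroring the
  workflow's retention of structure-less entries.
* Processing factors are not applied anywhere; commodity-level
  concentrations are used as consumed.
* Run outputs carry no timestamps; rerunning a configuration with the
  same seed reproduces the run directory byte-for-byte, and the
  resolved configuration plus a content hash are written with every
  run for audit.
* Problem sizes in the test suite are chosen for tight feedback loops:
  oracle-equivalence tests run on hand-sized data (≤ 5 subjects),
  property suites on hundreds to a thousand randomized cases, and
  end-to-end plant recovery on 200 subjects across 20 seeds — large
  enough that sampling noise cannot blur the planted 10×/0.1×
  separation, small enough to run in seconds per seed.

# Known limitations

* Cramer classes and genotoxicity alerts are consumed as annotations;
  the package neither implements the Cramer tree nor any alert model.
* Only chronic exposure is modelled; no acute assessment, no
  parametric usual-intake models, no unit-variability corrections.
* The exposure statistic compared against the TTC is configurable but
  single; mixing statistics between the two priority lists is not
  supported.
* TTC tiers for categories absent from typical food-chemical sets
  (proteins, steroids, nanomaterials) are not represented.
* The normalization places all concentration readouts on µM; unit
  conversion must happen upstream of the HTS tables.
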