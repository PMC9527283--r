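# ttcprior

Exposure-driven prioritization of chemicals in food, built around the
Threshold of Toxicological Concern (TTC).

Regulatory food-safety programmes hold analytical data on thousands of
substances — pesticide residues, environmental contaminants,
mycotoxins, metals — far more than can receive a full toxicological
dossier. `ttcprior` is for risk assessors and computational
toxicologists who need a transparent, reproducible way to decide which
of those substances to evaluate first. It is organised as an analysis
workflow (`analysis/01_simulate.R` … `05_hts.R`) over a package whose
functions carry all computation, with a seeded synthetic-data generator
standing in for the restricted monitoring and consumption databases
such workflows normally require.

## The method

1. **Chronic dietary exposure (OIM).** Consumption diaries (two recall
   days per subject) are expanded through a food-translation table to
   raw-commodity amounts; the intake of substance *s* for subject *i*
   on day *d* is

   *y₍ᵢ,d,s₎ = Σ_c a₍ᵢ,d,c₎ · x₍s,c₎ / bwᵢ*  (µg/kg bw/day),

   and the observed individual mean (OIM) averages each subject's
   days. Censored results are bounded: non-detects are 0 in the
   *lower-bound* scenario and substituted by their LOD/LOQ in the
   *upper-bound* scenario. Population summaries (mean, median, p95)
   use survey weights.

2. **TTC decision tree.** Four short-circuiting steps: exclusion
   categories (inorganic, metal-containing, mixture, bioaccumulating,
   aflatoxin-like) → two-of-three cross-model genotoxicity consensus
   (DEREK/ISS/OASIS × Ames/chromosome damage) → organophosphate or
   carbamate substructure → Cramer class. Thresholds: 0.0025
   (genotoxic), 0.3 (OP/carbamate), 1.5 / 9 / 30 (Cramer III/II/I),
   all µg/kg bw/day. Substructures are matched as SMARTS in a
   *literal* mode (the patterns exactly as defined above, which miss P=S
   phosphates and N–H carbamates) or a documented *relaxed* mode that
   admits them.

3. **Hazard quotients and lists.** HQ = exposure / TTC. Substances
   with HQ > 1 form the TTC-applicable priority list; TTC-excluded
   substances with exposure ≥ 0.5 µg/kg bw/day form the second list;
   structure-less substances are reported as unevaluated. The
   screening subset takes the highest-HQ 10/2/2 substances from the
   TTC classes 0.0025/0.3/1.5.

4. **HTS normalization.** Heterogeneous screening readouts (composite
   scores, percent activity, AC50, rank, LEL) are mapped to a common
   0–100 potency scale per model — log-transforming concentrations —
   with the most potent substance anchored at exactly 100, and
   assembled into a substance × model matrix grouped by toxicological
   domain.

See `vignettes/methods.Rmd` for the full model description, parameter
defaults, and design rationale.

## Worked example

```r
library(ttcprior)

ann <- tibble::tibble(
  code = c("DIM-PPP", "CAR-PPP", "NIT-CHE"),
  name = c("dimethoate-like", "carbamate-like", "nitrate-like"),
  smiles = c("COP(=S)(OC)SCC(=O)NC", "CN(C)C(=O)Oc1ccccc1", NA),
  exclusion_flags = c(NA, NA, "inorganic"),
  alert_ames_derek = c(TRUE, FALSE, NA),  alert_ames_iss = c(TRUE, FALSE, NA),
  alert_ames_oasis = c(FALSE, FALSE, NA), alert_ca_derek = c(FALSE, FALSE, NA),
  alert_ca_iss = c(FALSE, FALSE, NA),     alert_ca_oasis = c(FALSE, FALSE, NA),
  cramer_class = c("III", "III", NA)
)
assign_ttc(ann, mode = "literal")
#> # A tibble: 3 × 5
#>   substance_code outcome      ttc_value decision_path                                                exclusion_reason
#>   <chr>          <chr>            <dbl> <chr>                                                        <chr>
#> 1 DIM-PPP        ttc_assigned    0.0025 exclusion:clear>genotoxicity:positive                        NA
#> 2 CAR-PPP        ttc_assigned    0.3    exclusion:clear>genotoxicity:negative>op_carbamate:carbamate NA
#> 3 NIT-CHE        excluded       NA      exclusion:inorganic                                          inorganic
```

The first substance carries two positive Ames alerts, so the
two-of-three consensus fires and it receives the genotoxicity TTC of
0.0025 µg/kg bw/day — its thiophosphate structure is never reached.
The second is a disubstituted carbamate (0.3), and the third is
excluded from the TTC approach as inorganic: no threshold exists, and
any appreciable exposure flags it for follow-up.

A complete run over a synthetic study, with its funnel of counts:

```r
cfg <- run_config(inputs = scenario_params(n_subjects = 200, seed = 7), seed = 7)
res <- run_pipeline(cfg, "runs/demo")
res$funnel
#> # A tibble: 9 × 2
#>   stage                  count
#>   <chr>                  <int>
#> 1 substances_in             15
#> 2 with_structure            14
#> 3 ttc_excluded               2
#> 4 ttc_assigned              12
#> 5 hq_above_1                 6
#> 6 excluded_priority          2
#> 7 unevaluated                1
#> 8 not_priority               6
#> 9 selected_for_screening     6
```

Of 15 substances, 14 have structures; 2 are TTC-excluded and 12 get a
threshold; 6 exceed it (HQ > 1) and, with the 2 excluded substances
over the 0.5 µg/kg bw/day cutoff, drive the screening selection. The
run directory contains every intermediate table, the three-part
priority report, the normalized HTS matrix, and a byte-reproducible
log.

## The analysis workflow

The numbered drivers under `analysis/` run the same computation at the
emulated survey scale (3,819 subjects × 2 days) and narrate what they
find; each writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # synthetic inputs + planted truth
Rscript analysis/02_exposure.R    # OIM exposure, both censoring bounds
Rscript analysis/03_ttc.R         # decision tree, literal vs relaxed
Rscript analysis/04_prioritize.R  # HQ, priority lists, screening subset
Rscript analysis/05_hts.R         # normalized potency matrix
```

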