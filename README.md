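# spectsuv

Quantitative SPECT-CT bone-lesion analysis in R: lean-body-mass standardized
uptake values (SUVlbm) from reconstructed activity volumes, iterative
global-maximum lesion extraction, and the cohort statistics that ask whether
a per-lesion SUVmax threshold separates metastatic from degenerative bone
lesions in breast-cancer patients.

Benign degenerative changes take up bone-seeking Tc-99m tracers just as
metastases do, which limits visual reading of bone scans. Quantitative
SPECT-CT expresses each lesion's peak uptake as an absolute SUVmax (g/mL),
so the two lesion classes can be compared statistically and an operating
threshold chosen. The package is aimed at nuclear-medicine physicists and
imaging statisticians who want that chain — quantification, segmentation,
cohort statistics — as tested, scriptable functions rather than a vendor
workstation, plus calibrated simulators to exercise it without patient data.

## The model

For a voxel with activity concentration C (Bq/mL):

    SUVlbm = C · LBM · 1000 / A_actual        [g/mL]

with the James lean body mass (female: `1.07 W − 148 (W/H)²` kg) and the net
injected activity decay-corrected to scan time from the syringe assays and
the injection chronology:

    λ          = 0.693 / T½                     (T½ = 6.0067 h for Tc-99m)
    decay1     = exp(λ (t_measured − t_administered))
    decay2     = exp(λ (t_post − t_measured))
    decay_scan = exp(λ (t_administered − t_scan))
    A_actual   = decay_scan · decay1 · (A_pre − decay2 · A_post)

Lesions are enumerated from the SUV volume by repeatedly taking the hottest
unclaimed voxel and growing a 40%-of-maximum, 26-connected VOI (radius-capped),
up to five per patient per category. Cohort analysis: Mann–Whitney (exact for
n₁+n₂ ≤ 12, tie/continuity-corrected normal approximation otherwise),
empirical ROC whose trapezoidal AUC equals U/(n₁n₂), DeLong 95% CI,
Youden-optimal cut-off under the strict rule "positive if SUVmax > t", bin
breakdowns at 20/27 g/mL and the inter-class overlap range. A
truncated-lognormal generator calibrated by moment matching (mean, sd, min,
max per category) and inverse-SUV digital sphere phantoms make every stage
testable end to end.

## Worked example

```r
library(spectsuv)

p <- patient_record("P01", "female", weight_kg = 70, height_cm = 170,
  pre_injection_activity_mbq = 700, post_injection_activity_mbq = 20,
  measured_time = "2021-03-01T09:00", administered_time = "2021-03-01T09:05",
  post_injection_time = "2021-03-01T09:10", scan_time = "2021-03-01T12:05")

decay_correction(p)$actual_activity_mbq
#> [1] 476.179
suv_from_concentration(30000, lean_body_mass(70, 170, "female"), 476.179)
#> [1] 3.137891
```

700 MBq assayed at 09:00 minus a 20 MBq residual, decayed to a 12:05 scan,
leaves 476.2 MBq effectively injected; a voxel at 30 kBq/mL in that patient
(LBM 49.8 kg) is an SUVlbm of 3.14 g/mL.

Simulated cohort at the study conditions (70 patients, 236 metastatic + 179
degenerative lesions):

```r
co  <- sample_cohort(cohort_config(seed = 1))
run_analyze(co$lesions, seed = 1)
#> Cohort analysis: 236 metastatic, 179 degenerative lesions
#>   SUVmax metastatic   32.97 +/- 18.70 [11.00, 129.55]
#>   SUVmax degenerative 9.72 +/- 4.64 [3.54, 25.89]
#>   Mann-Whitney U = 40616.0, p = 2.23e-58
#>   AUC = 0.961 (95% CI 0.946-0.976)
#>   Cut-off SUVmax > 13.03 g/mL: sens 95.8%, spec 80.4%
#>   Overlap range [11.00, 25.89]: 39.3% of lesions inside
```

The metastatic class sits far above the degenerative one (AUC ≈ 0.96); the
per-seed Youden cut-off is noisy (here 13.0 g/mL), which is why cohort-level
estimates are reported seed-averaged (see `analysis/04_seed_stability.R`).

## Analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data and
write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_cohort.R` | simulate the cohort; write `patients.csv`, `lesions.csv`, provenance |
| `02_phantom_quantification.R` | sphere phantoms → NIfTI → SUV volumes → lesion recovery table |
| `03_cohort_analysis.R` | full statistics on the simulated table; `report.json`, ROC points |
| `04_seed_stability.R` | 50-seed spread of means, AUC, cut-off, sensitivity/specificity |

Each takes an optional integer seed argument (default 1).

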