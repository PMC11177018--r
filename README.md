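# headctrisk

Radiation burden of routine non-contrast **adult head CT on the thyroid
gland**, end to end: scan parameters → dose indices → organ dose and
effective dose → lifetime cancer risk → male-versus-female comparison. The
package is aimed at medical physicists and radiation epidemiologists who
want a transparent, fully seeded, testable implementation of this chain —
including a synthetic cohort generator, so every stage runs without any
patient data.

## The models at the core

**Scan dose.** CTDIvol = CTDIw_ref · (mAs/100) · (kVp/kVp_ref)^n / pitch
(n ≈ 2), DLP = CTDIvol · L, and the dose-report inversion L = DLP/CTDIvol.
Helical scans over-range by 0.5 · pitch · beam width per side.

**Organ dose.** The thyroid lies outside the scanned volume and is dosed by
scatter. A one-dimensional longitudinal profile — D(z) = CTDIvol in-field,
CTDIvol · A · e^(−μd) at distance d beyond the field edge — is averaged in
closed form over the sex-specific thyroid extent (male neck 9 cm, female
8 cm, on 170 cm/70 kg and 160 cm/60 kg adult phantoms). Effective dose is
the ICRP-103 weighted sum Σ w_T H_T (thyroid w_T = 0.04), with a DLP·k
backend as cross-check. The model's free constants are recovered by a
deterministic least-squares calibration against printed reference-cohort
means (`calibrate_dose_model()`); the shipped configuration reproduces the
six targeted per-sex means to well under 1 %.

**Risk.** Lifetime attributable risk (LAR) of thyroid-cancer incidence per
BEIR VII, linear in dose with no threshold. Default backend: sex-specific
coefficients per 0.1 Gy by age at exposure (Table 12D-1 fixture),
piecewise-linearly interpolated — LAR = coef(sex, e) · D(mGy)/100, in cases
per 100 000 persons. A generic lifetable backend implements
LAR(D,e) = Σ_a ERR(D,e) λ(a) S(a)/S(e) with the committee's thyroid ERR
parameters (β = 0.53/1.05 per Gy for males/females).

**Statistics.** Lilliefors normality screening; pooled t-test or
Mann-Whitney U per its outcome; OLS of dose quantities on DLP; noncentral-t
power (0.799 at d = 0.66, n = 38+36, α = 0.05).

## Worked example

```r
library(headctrisk)

cohort <- generate_cohort(seed = 1)        # 74 records, 3 scanners
cohort <- fill_dose_indices(cohort)        # CTDIvol, DLP
cohort <- add_organ_doses(cohort)          # thyroid dose, effective dose
cohort <- add_lar(cohort, backend = "table")
report <- run_full_analysis(cohort)
print(report)
```

Excerpts of what this prints (dose/risk block, truncated):

```
== Dose and risk by sex ==
           variable    sex  n                              summary
        ctdivol_mGy female 36 44.27 +/- 15.69 (41.01, 13.48-64.59)
        ctdivol_mGy   male 38 42.71 +/- 13.96 (41.01, 17.00-62.64)
   thyroid_dose_mGy female 36      2.62 +/- 0.96 (2.52, 0.76-3.84)
   thyroid_dose_mGy   male 38      2.53 +/- 0.86 (2.52, 0.96-3.72)
 effective_dose_mSv female 36      1.57 +/- 0.56 (1.46, 0.48-2.29)
 effective_dose_mSv   male 38      1.51 +/- 0.50 (1.46, 0.60-2.22)
       lar_per_100k female 36      0.33 +/- 0.50 (0.14, 0.00-2.47)
       lar_per_100k   male 38      0.09 +/- 0.16 (0.03, 0.00-0.81)

== Tests (dose and risk) ==
           variable           test     p_value
       lar_per_100k Mann-Whitney U 0.002595705

Power: d = 0.66, n = 38 + 36, alpha = 0.05 -> 0.799
```

Read: each summary cell is "mean ± SD (median, min–max)". On this seeded
cohort the sexes receive statistically indistinguishable doses
(CTDIvol ~44 vs ~43 mGy, thyroid dose ~2.6 vs ~2.5 mGy, effective dose
~1.6 vs ~1.5 mSv), yet the female lifetime risk is roughly 3–4 times the
male one and the Mann-Whitney comparison of LAR is significant
(p ≈ 0.003) — the female thyroid sits closer to the field edge *and* its
risk coefficients are several-fold higher at every age.

The same pipeline runs on disk, stage by stage or at once:

```r
run_pipeline("results_run", seed = 1)      # cohort.csv ... report/*.csv
```

or from a shell via the thin wrapper
`Rscript inst/cli/headctrisk.R run-all --out results_run --seed 1`
(subcommands: `simulate`, `dose`, `risk`, `report`, `calibrate`, `run-all`).

## Package layout

- `R/cohort.R` — cohort specification and seeded synthetic generator
- `R/scan_dose.R` — CTDIvol/DLP laws, irradiated interval
- `R/organ_dose.R`, `R/calibrate.R` — scatter-profile organ dose, ICRP-103
  effective dose, model calibration
- `R/lar.R` — BEIR VII risk backends and fixtures
- `R/stats.R`, `R/report.R` — statistical battery and comparison report
- `R/pipeline.R`, `inst/cli/headctrisk.R` — file-level pipeline and CLI
- `inst/extdata/` — risk coefficients, ERR model, reference means,
  calibrated dose model (all plain text, with provenance headers)
- `vignettes/head-ct-thyroid-risk.Rmd` — the methods vignette: model
  assumptions, calibration objective, design decisions, limitations
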