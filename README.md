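# mtxresponse

Dose-normalized treatment-response analysis for methotrexate (MTX) in
rheumatoid arthritis (RA) cohorts.

MTX is the anchor drug in RA, but both response and the dose a clinician
settles on vary widely between patients, so a raw change in disease
activity conflates improvement with drug exposure. This package implements
a response measure that separates the two, and everything needed to use it
on a longitudinal cohort:

* **DAS28-CRP** scoring from components:
  `DAS28 = 0.56·√T28 + 0.28·√S28 + 0.36·ln(CRP+1) + 0.014·VAS + 0.96`
* **Improved DAS28 area** over a window `(t0, t1)`: the reference area of a
  score pinned at 10 (30 score-months over 0–3 months, 60 over 0–6) minus
  the patient's trapezoidal DAS28 AUC
* **Index R** = improved area / cumulative MTX dose over the same window
  (1/mg): improvement bought per milligram, homogeneous of degree −1 in
  dose
* **Disease-control classification** over months 6–12: good control =
  fixed weekly dose and DAS28 > 2 recorded less than once per month at
  visits (strict zero-exceedance variant available)
* **Folate-pathway genotype grouping** (RFC1 80G>A, FPGS 1994G>A,
  GGH −401C>T, MTHFR 1298A>C, TYMS 3′-UTR −6/+6) into the binary
  carrier/non-carrier contrasts actually analysed
* **Mann-Whitney U tests**, exact under ties via the full permutation
  distribution of mid-ranks, with median (25th–75th percentile) summaries
* a **synthetic cohort generator** emulating a 21-patient (7 good / 14
  poor) design, so the entire chain is testable without patient data, and a
  **pipeline** that writes the full report bundle with a reproducibility
  manifest

## Worked example

Simulate the default cohort, score it, classify disease control, and build
both comparison reports:

```r
library(mtxresponse)
res <- run_pipeline(run_config(seed = 42))
```

Control-status comparisons (`res$table2`, median (25–75th percentile)):

```
  window                    variable                   good                   poor p_value
1    0-3 Cumulative dose of MTX (mg)   96.00 (96.00-114.00)   96.00 (72.00-120.00) 0.79551
2    0-3         Improved DAS28 area    20.38 (19.36-22.71)    18.81 (14.59-19.59) 0.02416
3    0-3              Index R (1/mg)       0.21 (0.19-0.23)       0.18 (0.16-0.21) 0.13212
4    0-6 Cumulative dose of MTX (mg) 192.00 (192.00-228.00) 192.00 (144.00-240.00) 0.79551
5    0-6         Improved DAS28 area    45.22 (42.62-47.40)    39.16 (31.31-40.38) 0.00152
6    0-6              Index R (1/mg)       0.22 (0.20-0.25)       0.18 (0.17-0.22) 0.04296
```

The shape mirrors what such a study design produces: cumulative dose does
not separate the groups, the improved DAS28 area separates them in both
windows, and index R reaches significance over 0–6 months — early
improvement, not dose, distinguishes good control.

Genotype comparisons of 0–6-month index R (`res$table3`):

```
         snp                   g1                   g2 p_value
1    rfc1_80       G/G (n=8) 0.22 A allele (n=13) 0.19  0.1042
2  fpgs_1994 G allele (n=15) 0.20       A/A (n=6) 0.22  0.5187
3    ggh_401      C/C (n=11) 0.18 T allele (n=10) 0.22  0.0159
4 mthfr_1298 A allele (n=19) 0.21       C/C (n=2) 0.24  0.6857
5   tyms_utr    -6/-6 (n=13) 0.22 +6 allele (n=8) 0.18  0.0890
```

(Under the default generator genotypes have no effect on response, so any
small p here is a type-I event of the 21-patient design.)

Classification against the simulator's ground truth for this seed
(`table(res$labels$control_status, res$true_labels)`): all 7 good
responders recovered; 3 of 14 poor responders misclassified as good —
realistic for noisy monthly scores near the threshold.

Individual pieces are plain functions:

```r
das28_crp(4, 4, 50, 1.26)                      # 3.634
v <- data.frame(month = 0:6, das28 = c(6, 5, 4, 3, 2.5, 2.2, 2))
das28_auc(v, c(0, 6))                          # 20.7 score-months
d <- data.frame(start_month = 0, end_month = 12, weekly_dose_mg = 8)
index_r(v, d, c(0, 6))                         # improved area 39.3, R = 0.205
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/mtx-response.R simulate --out-dir cohort --seed 7
Rscript inst/cli/mtx-response.R analyze --csv-dir cohort --out-dir results
Rscript inst/cli/mtx-response.R report --out-dir results
```

See `vignettes/dose-normalized-response.Rmd` for the model, every analysis
convention (window-edge interpolation, 4-weeks-per-month dose arithmetic,
quartile rule, the two readings of the control criterion), the simulator's
assumptions, and measured operating characteristics.

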