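# honeyaudit

Regulatory quality auditing and botanical classification of honey, built
for food-chemistry and authenticity labs that screen physicochemical
panels (sugars, 5-HMF, moisture, free acidity, diastase activity,
insoluble matter, electrical conductivity) against international limits.

The package re-implements the analysis workflow of a 609-sample Serbian
honey survey as reusable, tested code:

* **Reclassification.** Electrical conductivity separates honeydew from
  nectar honey: a flower-type sample with EC > 0.8 mS/cm is reassigned to
  honeydew, a declared honeydew with EC < 0.8 to polyfloral.
* **Threshold rule engine.** Type-aware limits — glucose + fructose
  ≥ 60 g/100 g for blossom honey (≥ 45 for honeydew), sucrose ≤ 5 g/100 g
  (≤ 10 for acacia), 5-HMF ≤ 40 mg/kg, acidity ≤ 50 meq/kg, diastase
  ≥ 8 DN, moisture ≤ 20 %, insolubles ≤ 0.1 %, low-EC flag below
  0.1 mS/cm — with strict comparisons and a two-tier verdict: violations
  of sucrose/5-HMF/acidity/diastase grade a sample ADULTERATED, the rest
  SUSPECT, with adulteration dominating. Samples with a mid-range sugar
  sum and EC in [0.70, 0.8) are flagged as possible nectar/honeydew
  blends.
* **Statistics.** Descriptive tables (n, mean ± SD, 95 % t-interval
  mean ± t·s/√n, variance, extremes, quartiles), one-way ANOVA
  F = MSB/MSW on (k−1, N−k) df, tie-corrected Kruskal–Wallis H, Tukey HSD
  (Tukey–Kramer) with compact letter displays, and the 9 × 9 Pearson
  matrix with raw significance stars.
* **Synthetic data.** A Gaussian-copula generator over per-type
  truncated-normal marginals calibrated to the survey's published summary
  tables, plus a deterministic 609-record fixture that embodies its
  deviation inventory exactly.
* **Classifier.** A from-scratch 8-12-6 multilayer perceptron (logistic
  hidden layer, softmax output, categorical cross-entropy, analytic
  backprop gradient) trained by BFGS with random restarts selected on
  held-out loss.

## Worked example

```r
library(honeyaudit)

fx <- build_fixture(7)               # deterministic 609-sample table
rc <- reclassify_table(fx$table)
rc$report[c("moved", "moved_in", "moved_out", "final_honeydew")]
#> $moved          [1] 25
#> $moved_in       [1] 9
#> $moved_out      [1] 16
#> $final_honeydew [1] 29

summarize_compliance(rc$table)
#> Compliance audit of 609 samples
#>   adulterated: 22  suspect: 64  compliant: 523 (14.1% non-conforming)
#>   violations: HIGH_SUCROSE=5 HIGH_HMF=12 HIGH_ACIDITY=1 LOW_DIASTASE=4
#>               LOW_SUGAR_SUM=57 HIGH_MOISTURE=2 LOW_ECOND=9 HIGH_INSOLUBLE=0
```

Twenty-five samples change botanical class on conductivity grounds,
leaving 29 honeydew. The rule engine then finds 86 of 609 samples
(14.1 %) non-conforming: 22 carry adulteration-grade violations (5
sucrose, 12 HMF, 1 acidity, 4 diastase — 4 of the sucrose violators also
have a low sugar sum and are counted once, in the adulterated tier) and
64 carry suspect-grade deviations only (53 low sugar sum, 2 high
moisture, 9 low conductivity).

The numbered scripts under `analysis/` run the full workflow — table
construction, reclassification, audit, descriptive statistics with
compact letters and correlation stars, classifier training — and write
their tables under `results/`.

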