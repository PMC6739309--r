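# riskscan

Cut-point discovery and risk stratification for prognostic plasma
biomarkers in clinical cohorts.

The motivating setting is sepsis: extracellular NAPRT (eNAPRT), a
NAD-biosynthetic enzyme released by stressed cells, behaves as a
damage-associated molecular pattern, and its plasma concentration
stratifies mortality risk. `riskscan` is for biostatisticians and
translational researchers who need to turn such a continuous biomarker
into a dichotomous prognostic rule and to quantify everything that rule
implies — without hand-rolled spreadsheets and with every step testable on
synthetic data.

## What it computes

For a cohort (one row per subject: biomarker concentrations, binary
outcome, optional survival time/censoring):

* **Exhaustive threshold scan.** Every admissible cut-off τ (the sorted
  unique observed values whose "≥ τ" split respects a group-size floor)
  gets a 2×2 confusion matrix (a, b, c, d) = (high∧died, high∧alive,
  low∧died, low∧alive) with
  - Fisher's exact two-sided p (minimum-likelihood rule over the
    conditional hypergeometric support),
  - Pearson's χ² = Σ(O−E)²/E (Yates optional, off by default),
  - risk ratio RR = [a/(a+b)] / [c/(c+d)] with the Katz CI
    exp(ln RR ± z·√(1/a − 1/(a+b) + 1/c − 1/(c+d))), plus the Woolf-CI
    odds ratio, Haldane–Anscombe-corrected (flagged) on zero cells.

  The best cut-off minimizes raw Fisher p (ties: larger |ln RR|, then
  smaller τ); Bonferroni/Holm-adjusted p-values are reported alongside.
* **Survival.** Kaplan–Meier curves per group and the two-group log-rank
  test (aggregated ties, hypergeometric variance), via the `survival`
  package behind a small stable surface.
* **Interactor search.** Binomial GLMs over candidate effects (main
  effects + pairwise interactions under the marginality constraint),
  ranked by BIC = −2ℓ + k·ln n, searched by a seeded genetic algorithm
  with an exhaustive-enumeration oracle for validation; analysis of
  deviance for nested pairs; Pearson correlation with regression line.
* **Gene-signature overlap.** Exact Venn arithmetic on identifier lists.
* **Synthetic cohorts.** A seeded generator with log-normal marginals, a
  step (or logistic) mortality model, uniform-in-follow-up death times,
  and a Gaussian copula linking CRP to the primary biomarker — calibrated
  to published cohort summaries (median 27.1 ng/ml, 71%/29% split at
  15 ng/ml, 44%/10% group mortality, raw-scale r = 0.31 with CRP).

## Worked example

```r
library(riskscan)

cohort <- generate_cohort(sepsis_generator_config(n = 100, seed = 1))
ledger <- adjust_ledger_pvalues(scan_thresholds(cohort, "eNAPRT"),
                                "bonferroni")
best <- select_best_threshold(ledger)
best[, c("tau", "a", "b", "c", "d", "fisher_p", "rr", "adjusted_p")]
#>       tau  a  b c  d     fisher_p       rr adjusted_p
#>  18.86504 27 35 3 35 0.0001119625 5.516129 0.01018859

grp <- ifelse(cohort$eNAPRT >= best$tau, "high", "low")
logrank_test(cohort$time, cohort$event, grp)
#> <logrank_result> chisq=12.89 on 1 df, p=0.00033
#>      observed expected
#> high       27 17.30633
#> low         3 12.69367

ga_search(cohort,
          c("eNAPRT", "CRP", "PCT", "WBC", "eNAMPT",
            "eNAPRT:CRP", "eNAPRT:PCT", "eNAPRT:WBC"),
          ga_config(pop_size = 30, generations = 30, seed = 1))
#> <model_search_result> ga search over 8 candidate effect(s); 10 model(s)
#>   1. BIC 121.406  {eNAPRT}
#>   2. BIC 121.580  {eNAPRT, eNAMPT}
#>   3. BIC 124.499  {eNAPRT, WBC}
#>   ...
```

Reading: on this simulated cohort of 100 septic patients the scan selects
a cut-off of ≈18.9 ng/ml (the planted change-point is 15; at n = 100 the
selected cut-off is an interval-quality estimate with a long right tail —
see the methods vignette). Mortality is 44% above the cut-off vs 8% below
(risk ratio 5.5), the dichotomized groups separate in survival (log-rank
p = 3.3×10⁻⁴), and BIC ranks the primary biomarker alone as the best
mortality model — interactions do not pay their complexity penalty at this
sample size. `run_pipeline()` chains the same stages and writes a JSON
report, the full ledger as TSV, and the cohort echo.

The methods vignette (`vignettes/risk-stratification-methods.Rmd`)
documents the model choices, generator calibration, numerical conventions
and limitations.

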