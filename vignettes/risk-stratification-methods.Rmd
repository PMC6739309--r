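---
title: "Biomarker cut-point discovery and risk stratification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomarker cut-point discovery and risk stratification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskscan)
```

## The problem

A continuous plasma biomarker — here extracellular NAPRT (eNAPRT), a
NAD-biosynthetic enzyme released by stressed cells and acting as a
damage-associated molecular pattern in sepsis — is to be turned into a
prognostic rule: patients at or above a concentration cut-off form a
high-risk group, those below a low-risk group. `riskscan` implements the
full discovery pipeline around that idea:

1. **exhaustive cut-point scan** — every admissible threshold is tested,
   each with a 2×2 confusion matrix, Fisher's exact test, Pearson's
   chi-square and a risk ratio with a 95% CI;
2. **survival comparison** — Kaplan–Meier curves and the log-rank test for
   the two groups defined by the selected cut-off;
3. **interactor search** — binomial GLMs over candidate biomarker effects
   (main effects and pairwise interactions), ranked by BIC, searched with a
   genetic algorithm and validated against exhaustive enumeration;
4. **synthetic cohorts** — a seeded generator with the statistical
   structure the analysis assumes, so every stage runs and is testable
   without patient data.

## The cut-point scan

For a threshold $\tau$, subjects with biomarker value $x \ge \tau$ are
"exposed" (ties go to the high group, matching the "$\ge$ cut-off" group
definition); missing values are excluded and counted, never imputed. With
$a,b,c,d$ the exposed/dead, exposed/alive, unexposed/dead, unexposed/alive
counts:

* **Fisher's exact test** conditions on both margins; the two-sided p is
  the minimum-likelihood rule, $\sum_k \Pr(k)\,[\Pr(k) \le \Pr(a)(1 +
  10^{-7})]$ over the hypergeometric support. The relative tolerance
  absorbs floating error; the test suite checks the implementation against
  an exact integer-arithmetic enumeration on *every* 2×2 table with $n \le
  40$ (135,750 tables).
* **Pearson chi-square** $\sum (O-E)^2/E$, by default *without* the Yates
  correction: on the reference table (31, 40, 3, 26) the uncorrected
  statistic is 10.19 ($p = 0.0014$), the corrected one 8.75 ($p =
  0.0031$).
* **Risk ratio** $\widehat{RR} = \frac{a/(a+b)}{c/(c+d)}$ with the Katz
  log-scale CI; the odds ratio uses the Woolf CI. Zero event cells get the
  Haldane–Anscombe +0.5 on all four cells, flagged as `corrected` — a
  threshold scan routinely hits zero cells at extreme candidates, and the
  flag keeps those records identifiable rather than fatal.

**Candidate grid.** Candidates are the sorted unique *observed* values
whose split leaves both groups at or above `min_group_size` (default 5;
set 1 for toy data). Observed values, not midpoints: with a "$\ge$" rule
they are the natural exhaustive grid, and comparisons on exact stored
values keep the scan deterministic.

**Selection.** The best cut-off minimizes the *raw* Fisher p among
non-degenerate records; ties go to the larger $|\ln RR|$, then the smaller
$\tau$. Bonferroni/Holm-adjusted p-values are reported alongside
(`adjust_ledger_pvalues()`) but do not drive selection — the scan is an
uncorrected exhaustive procedure, and the adjusted column makes its
optimism explicit. Under permuted-outcome nulls the Bonferroni-adjusted
minimum p exceeds 0.05 in ≈99% of replicates, i.e. family-wise error is
controlled when the adjusted column *is* consulted.

**What recovery looks like.** On synthetic cohorts with a planted step
change-point at 15 ng/ml (risk 0.44 above, 0.10 below, 71/29 split, $n =
100$) the median selected cut-off sits at ≈15.9 ng/ml, but the sampling
distribution has a long right tail: any cut above the change-point keeps
most of the risk contrast (everyone above 15 carries high risk), so the
Fisher-p surface is shallow on that side and roughly one replicate in
seven selects a cut-off above 22 ng/ml. The spread shrinks as $n$ grows
(checked at $n$ = 100/1000/4000). Users should read a selected cut-off at
this sample size as an interval estimate, not a point value.

## Survival comparison

Kaplan–Meier estimation and the log-rank test are delegated to the
`survival` package behind a thin surface (`km_estimate()`,
`logrank_test()`), with the conventional choices pinned: tied events are
aggregated with the hypergeometric variance
$d_j(n_j-d_j)n_{1j}n_{2j}/(n_j^2(n_j-1))$, subjects censored at an event
time count as at risk at that time, and p comes from the upper
$\chi^2_1$ tail. The tests verify hand-computed ledgers (e.g. the
6-deaths-vs-6-survivors design: $E_A = 6/12 + \dots + 1/7 \approx 2.081$,
$V \approx 1.270$, $\chi^2 \approx 12.09$, $p \approx 5.1\times10^{-4}$)
rather than trusting the backend.

## GLM interactor search

Mortality is modelled with a logistic (binomial, canonical logit) GLM
fitted by IRLS (`stats::glm`; relative deviance tolerance $10^{-8}$, 100
iterations). Concentration covariates enter on the log scale. Models are
scored by $\mathrm{BIC} = -2\ell + k\ln n$ with $k$ counting the
intercept, so the intercept-only fit on 34 deaths / 66 survivors has
$\beta_0 = \ln(34/66)$ and BIC $= 132.81$ — a frozen closed-form anchor in
the tests.

The candidate space defaults to seven main effects (eNAPRT, CRP, PCT,
WBC, Plts, INR, eNAMPT) plus the six pairwise interactions involving
eNAPRT. The **marginality (hierarchy) constraint** — an interaction only
alongside both its main effects — is enforced everywhere: enumeration
filters invalid subsets, and the genetic algorithm applies a repair
operator that drops orphan interactions after crossover and mutation.

GA hyperparameters (population 50, 100 generations, tournament $k=3$,
uniform crossover 0.9, per-bit mutation $1/L$, elitism 2, mandatory seed)
are conventional defaults; none is published for the original analysis,
so all are configurable. The initial population always contains the
intercept-only and the repaired full chromosome, and fitness evaluations
are cached by inclusion vector, which makes small candidate spaces cost
one fit per distinct model. On spaces of ≤ 8 effects the GA's best BIC
equals the exhaustive oracle's on every seeded test cohort (20/20).

Nested models are compared by analysis of deviance
(`anova_deviance()`): the deviance difference against $\chi^2_{\Delta k}$.

## The synthetic cohort generator

The generator emulates the *summary structure* of a sepsis admission
cohort; it is calibrated once and is not a tuning dial.

* **Marginals.** All concentrations are log-normal — strictly positive,
  right-skewed plasma analytes. The primary biomarker has median 27.1
  ng/ml, and its log-sd is *derived*, not chosen:
  $\sigma = (\ln 27.1 - \ln 15)/\Phi^{-1}(0.71) = 1.069$ makes exactly 71%
  of the population sit at or above the 15 ng/ml cut-off
  (`calibrate_sigma_from_split()`).
* **Mortality.** The default is a step model: death probability 0.44 at or
  above 15 ng/ml, 0.10 below — reproducing the dichotomized rates exactly
  (overall rate $0.71 \times 0.44 + 0.29 \times 0.10 = 0.341$). A smooth
  logistic mode exists for power studies.
* **Survival times.** Deaths draw a time uniformly in (0, 28] days;
  survivors are censored at 28 days (a common sepsis-trial follow-up).
  Only a consistent convention is needed for the KM stage; no per-patient
  follow-up distribution is published.
* **CRP and the copula.** CRP is linked to the primary biomarker through a
  Gaussian copula with group-conditional medians (209 mg/l at or above the
  cut-off, 130 below). Because the mean of the primary latent within each
  group is nonzero, the copula contribution is median-centered per group
  using the truncated-normal group medians; this keeps the realized group
  medians within ~2% of their configured values. The latent correlation
  (default 0.3739) is tuned by bisection with fixed latents
  (`tune_copula_rho()`) so the *raw-scale* Pearson correlation between CRP
  and the primary biomarker is 0.31.
* **Other covariates.** Creatinine and LDH are group-conditional
  (medians 1.8/1.1 mg/dl and 488/392 U/l, log-sd 0.6). eNAMPT (median
  5.05 ng/ml), PCT (5 ng/ml), WBC (14 ×10⁹/l), platelets (180 ×10⁹/l) and
  INR (1.3) are independent log-normals with typical sepsis-admission
  medians; no dispersions are published for any covariate, so log-sd 0.6
  (0.25 for INR, 0.4 for WBC, 1.0 for PCT) is generator policy.
* **Determinism.** One integer seed; every sampling stage draws from a
  sub-stream derived deterministically from it, so
  `generate_cohort(config)` is a pure function of its configuration.

**What passing tests do and do not show.** The generator reproduces
printed cohort *summaries* (medians, a tail split, dichotomized death
rates, one correlation). Real sepsis cohorts additionally have heavy-tailed
measurement error, correlated covariate blocks beyond one pair,
informative censoring, and mortality that is not a clean step in a single
biomarker. Green tests therefore certify the pipeline's arithmetic and its
behaviour under the assumed structure — not clinical performance on real
data.

## Numerical choices and degenerate inputs

* Fisher point-probability comparisons use a $1+10^{-7}$ relative
  tolerance; the exact-rational enumeration lives in the test oracle.
* Zero-margin tables: Fisher returns p = 1 with a `degenerate` flag;
  chi-square refuses (zero expected counts); ratio estimates apply the
  flagged +0.5 correction or refuse when an exposure row is empty.
* Thresholds are compared on exact stored values; no binning.
* Constant biomarkers, all-missing columns, all-same outcomes, non-nested
  model pairs and rank-deficient designs all raise named errors rather
  than returning silent results.
* Problem sizes used by the checks — $2\times10^5$ draws for generator
  calibration, $10^5$ for copula tuning, 200 replicates of $n = 100$ for
  recovery/null simulations, 20 seeds for GA-vs-oracle — keep every
  quantity's Monte Carlo error well inside its stated band.

## Known limitations

* Observed-value candidate grids make the selected cut-off a sample
  statistic with optimism; the adjusted-p column quantifies but does not
  remove it. No maximally-selected-statistics correction, ROC machinery or
  cross-validated tuning is provided.
* Survival: no Cox regression, Greenwood CIs, or weighted log-rank
  variants.
* 2×2 only — no stratified (Mantel–Haenszel) or r×c generalizations.
* One row per subject; no repeated measures, treatment effects, or
  competing risks in the generator.

## A worked example

```{r example, eval = FALSE}
cohort <- generate_cohort(sepsis_generator_config(n = 100, seed = 1))
ledger <- scan_thresholds(cohort, "eNAPRT")
ledger <- adjust_ledger_pvalues(ledger, "bonferroni")
best <- select_best_threshold(ledger)
best[, c("tau", "a", "b", "c", "d", "fisher_p", "rr")]

grp <- ifelse(cohort$eNAPRT >= best$tau, "high", "low")
logrank_test(cohort$time, cohort$event, grp)

models <- ga_search(cohort, default_candidate_effects(),
                    ga_config(seed = 1))
models
```

The same stages run end-to-end, with a JSON report, through
`run_pipeline()`.
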