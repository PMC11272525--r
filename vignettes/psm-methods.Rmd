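---
title: "Methods: a partitioned survival model for first-line squamous NSCLC immunochemotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a partitioned survival model for first-line squamous NSCLC immunochemotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

Two immunochemotherapy regimens are approved in mainland China for
first-line treatment of locally advanced or metastatic squamous
non-small-cell lung cancer: camrelizumab with paclitaxel and carboplatin
(CTC) and sintilimab with gemcitabine and platinum (SGP). They have never
been compared head-to-head. This package implements the full
economic-evaluation chain used to compare them from the payer perspective:
an indirect comparison of their trial evidence, parametric extrapolation of
the reference arm's survival, a three-state partitioned survival model
(PSM), and deterministic plus probabilistic sensitivity analysis.

## Model structure

The cohort is partitioned at each cycle among three mutually exclusive
states — progression-free (PFS), progressed disease (PD), and death —
directly from two survival curves rather than from transition
probabilities:

* progression-free occupancy at time $t$ is $\min\{S_{PFS}(t),
  S_{OS}(t)\}$ (the minimum guards against extrapolated curve crossing),
* death is $1 - S_{OS}(t)$,
* PD is the remainder, clamped at zero.

The cycle length is 21 days (one administration interval) and the horizon
is 173 cycles, about ten years, by which time survival in both arms is
negligible. Occupancy is evaluated at cycle midpoints by default
(equivalent to a half-cycle correction); a start-of-cycle convention is
available via `cycle_eval = "start"`. Outcomes and costs are discounted
continuously at the evaluation point, $w(t) = (1 + r)^{-t/12}$ with $t$ in
months and $r = 0.05$ per year.

## Survival curves

Both endpoints follow a Weibull law in the rate parameterisation
$S(t) = \exp(-\lambda t^{\gamma})$, with $t$ in months. The reference
(CTC) parameters are $\lambda = 0.04, \gamma = 1.28$ for PFS and
$\lambda = 0.01, \gamma = 1.53$ for OS. Months are the working time unit
because the restricted mean of the PFS curve under month units
(about 11.5 months) is consistent with the reference arm's reported
progression-free life-years, whereas cycle units would not be.

The comparator's curves are derived under proportional hazards: the shape
is kept and the scale is multiplied by a factor $k$, so
$S_{SGP}(t) = S_{CTC}(t)^k$. The pooled hazard ratios are reported in the
reference-versus-comparator direction (PFS 0.75, OS 0.95, both favouring
CTC), so the comparator's hazard is the reference hazard *divided* by the
HR — the default `hr_direction = "divide"`. The literal scale product
(`"multiply"`) is retained as an option because the source description of
the adjustment is ambiguous on direction, but it would make the comparator
*better* on PFS, contradicting the reported life-year ordering; both
conventions are exercised in the test suite via the proportional-hazards
identity.

Two fitters recover Weibull parameters from data:

* `fit_weibull_mle()` maximises the right-censored log-likelihood
  $\sum_{events}\log(\lambda\gamma t^{\gamma-1}) - \sum_{all}\lambda
  t^{\gamma}$ over $(\log\lambda, \log\gamma)$ with BFGS from the fixed
  starting point $\gamma = 1$, $\lambda = \#events/\sum t$ (the
  exponential MLE) and a relative tolerance of $10^{-12}$, so fits are
  deterministic. AIC and BIC are reported for family comparison; only the
  Weibull family is implemented because it is the family the analysis
  selected — the report structure leaves room for others.
* `fit_weibull_to_km_points()` regresses $\log(-\log S)$ on $\log t$ by
  ordinary least squares — exact on noiseless digitized coordinates, and
  the deterministic fallback when only curve coordinates (not patient
  data) are available. Points with survival exactly 0 or 1 carry no
  information on this scale and are excluded.

## Indirect comparison

With no head-to-head trial, the treatment network (CTC — chemotherapy —
SGP) is pooled by fixed-effect, inverse-variance weighted least squares on
the edge-incidence matrix, the graph-theoretical formulation of frequentist
network meta-analysis. On a path-shaped network this reduces exactly to
the Bucher chain — log effects add, variances add — which serves as the
closed-form oracle in the tests. Fixed effect only: with one trial per
edge, heterogeneity is inestimable per comparison. Pooling is on the
log-HR scale. `pool_network()` reports each treatment's pooled log hazard
ratio in the reference-versus-treatment direction, the direction in which
the economic model consumes a reference-vs-comparator HR. The default
pipeline does not re-run the pooling — the pooled HRs are carried in the
configuration as validated inputs, per-trial estimates not being published
— but the engine accepts any user-supplied trial table.

## Costs and quality adjustment

Per-cycle drug acquisition prices (USD, converted from CNY at 6.73, for a
typical 1.73 m^2 patient) enter directly. Each arm gives all induction
components every cycle for six cycles, then PD-1 monotherapy maintenance
on progression-free occupancy; all treatment stops on progression, and the
progressed state carries no treatment cost (best supportive care). The
24-month PD-1 cap is anchored at treatment start: a cycle accrues
maintenance cost when its start time lies before 24 months. The SGP
platinum defaults to cisplatin (listed first in the regimen); the
configuration can swap or reweight it.

Grade $\ge 3$ adverse events (plus grade-2 reactive cutaneous capillary
endothelial proliferation, a camrelizumab-specific toxicity) contribute in
two ways:

* **Management costs** accrue as the incidence-weighted sum
  $\sum_j p_j c_j$ per cycle over progression-free occupancy
  (`ae_cost_timing = "per_cycle"`). This convention was frozen after
  checking both candidates against the published cost breakdown with an
  independent single-loop implementation: a one-off charge at entry
  (`"one_off"`, retained as an option) produces totals two orders of
  magnitude below the reported adverse-event costs of either arm, while
  per-cycle accrual reproduces both arms' magnitudes.
* **Disutilities** decrement the PFS utility by the incidence-weighted sum
  during induction cycles only (`ae_disutility_timing = "induction"`),
  the window in which the cytotoxic components are given. A lifetime
  per-cycle decrement (`"per_cycle"`) is available but is not the default:
  under the comparator's adverse-event burden it pushes the effective
  progression-free utility (0.75 − 0.246 = 0.504) *below* the
  progressed-state utility (0.59), so shortening progression-free
  survival would add QALYs — an incoherent preference ordering that also
  contradicts the reported PFS/PD QALY split.

State utilities are 0.75 (PFS) and 0.59 (PD); QALYs accrue as occupancy ×
utility × cycle length × discount weight, so `QALY <= LY` whenever
utilities are below one — a tested invariant, as is per-cycle conservation
of the three memberships to $10^{-12}$.

## Sensitivity analysis

**One-way (tornado).** Every enumerated parameter — hazard ratios,
discount rate (0.03–0.08), drug prices, adverse-event costs, incidences,
disutilities, and utilities — is set to its low and high bound in turn
with everything else at baseline, the full base case is rerun, and bars
are sorted by the absolute ICER swing. ICERs are reported as raw
incremental ratios even when a bound crosses into dominance, the usual
caveat when reading sign-crossing tornado bars.

**Probabilistic.** Each non-fixed parameter is drawn independently —
beta for probabilities and utilities, gamma for costs and disutilities,
normal for hazard ratios — parameterised by method of moments from the
baseline and an SE of $(high - low)/3.92$, the printed range treated as a
95% interval (applied uniformly, including where the range is visibly
±20% of baseline). HRs are sampled on the log scale by default
(`hr_sampling = "lognormal"`) because the published intervals are
asymmetric around the point estimates; a natural-scale normal truncated at
zero matches the literal distribution label and is available by
configuration. The comparator's zero-incidence RCCEP row is excluded from
sampling entirely (a degenerate beta). One published disutility row prints
a baseline below its own range; it is kept verbatim, the loader warns, and
the method-of-moments rule is applied to it unchanged. No correlation
structure is imposed — none is reported.

The probabilistic ICER is the ratio of mean incremental cost to mean
incremental QALY; the mean of per-draw ratios is unstable when the QALY
difference changes sign and is returned only as a diagnostic. The
acceptability curve applies the net-monetary-benefit rule
$w\,\Delta QALY - \Delta cost > 0$ strictly, ties counting for the
comparator, so the two curves are complementary at every threshold; the
default grid (0–50,000 by 500) is augmented in the pipeline with the two
GDP-based thresholds (12,734 and 38,202 USD/QALY) so both appear exactly.

## Synthetic data

Because the underlying patient-level data are not deposited, the
`simulate_ipd()` / `generate_km_points()` / `generate_trial_table()`
generators emulate the three inputs the pipeline can consume, with known
ground truth: Weibull event times with independent exponential censoring
plus an administrative cutoff (the minimal standard follow-up mechanism —
the source reports no censoring detail, and none is guessed); noiseless
digitization coordinates on a monthly 0–36-month grid (a typical published
axis); and trial-level log-HR tables with normal noise at stated standard
errors over a connected network. All generators are pure functions of
their parameters and seed.

What passing tests on these data show — and do not show: parameter
recovery, estimator convergence and pooling consistency are demonstrated
under correctly specified models with independent censoring. Real digitized
curves carry reading error, interval-censored steps and dependent
censoring that these generators deliberately do not emulate, so the tests
validate the machinery, not the published curves themselves.

## Numerical choices

* Optimisation: BFGS on log-parameters, fixed start, `reltol = 1e-12`;
  non-convergence raises an error rather than returning a fit.
* Restricted means: adaptive quadrature at `rel.tol = 1e-10`, with the
  upper limit capped where $S(t)$ underflows past $10^{-16}$ (the
  truncated tail is below $10^{-16} t$), which keeps very long horizons
  from defeating the subdivision heuristic.
* Trace conservation is exact by construction (PD is the residual); the
  suite still asserts it to $10^{-12}$.
* Degenerate inputs: zero events is a non-identifiability error; fewer
  than three usable digitized points is an insufficient-data error; a zero
  QALY difference flags the ICER undefined instead of dividing.

Problem sizes used in the test suite are chosen to keep the full run
within a few minutes on a single core while leaving Monte-Carlo margins
wide: parameter recovery at $n = 2{,}000$, KM convergence at
$n = 50{,}000$, pooling coverage over 60 seeds, PSA stability at 400 draws
over 6 seeds, and the published-value comparisons at the analysis's own
5,000 replications.

## Known limitations and divergences

* Reproduction of the published table is limited by its own precision:
  the OS scale parameter is printed to two decimals, and at
  $\lambda = 0.01$ versus, say, 0.012 the OS life-years change by more
  than 10%. The package's totals therefore land close on costs but
  systematically differ on overall life-years.
* The published QALY/LY ratios (≈0.37) lie below every stated utility
  (0.59–0.75); no accrual convention constructible from the printed inputs
  reproduces them, so QALY-scale results differ by construction. The
  acceptance workflow computes and reports the deviations rather than
  calibrating them away.
* The published probabilistic means (incremental cost far above the
  deterministic base case) are not reachable by mean-preserving
  method-of-moments sampling around the printed baselines; the recomputed
  PSA centres near the deterministic base case, as it must under this
  sampling scheme.
* Second-line sequencing, grade 1–2 adverse events (except grade-2
  RCCEP), PD-state costs, heterogeneity/inconsistency diagnostics for the
  network, and non-Weibull families are out of scope.
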