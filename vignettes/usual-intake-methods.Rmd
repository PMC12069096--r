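---
title: "Estimating usual hormone intake from beef: models and design choices"
author: "hgpintake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating usual hormone intake from beef: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgpintake)
library(dplyr)
```

## The problem

Hormonal growth promotants (HGP) — endogenous hormones such as progesterone
and testosterone, and synthetic agents such as melengestrol acetate (MGA) —
are widely used in beef production and can leave residues in retail beef.
Estimating how much of each hormone people actually ingest requires chaining
four very different pieces of evidence:

1. **residue concentrations** measured in retail beef, with most
   measurements below the assay's limit of detection (LOD);
2. **dietary recalls** (two non-consecutive 24-hour recalls per person)
   reporting consumed foods, many of which contain beef only as one
   ingredient of a recipe;
3. a **usual-intake model** that removes the large day-to-day variation of
   episodic beef consumption to recover the long-run intake distribution;
4. **toxicological reference values** (acceptable daily intakes, ADIs)
   against which intake percentiles are screened via hazard quotients.

`hgpintake` implements this chain end to end, driven by a synthetic-data
generator with known ground truth so that every stage is testable without
restricted survey microdata or unreleased assay data.

## Concentrations: censoring, inclusion, scenarios

Non-detects are left-censored observations; they are imputed at
LOD/&radic;2, the conventional substitution when censoring is moderate.
Intake is only estimated for analytes detected in at least ten samples
(`select_analytes()`); more sparsely detected analytes carry essentially no
distributional information.

Per analyte and tissue class (visible subcutaneous fat versus everything
else), `summarize_by_tissue()` computes the mean, 95th percentile, and
maximum over detected plus imputed values, and `build_scenario_tables()`
maps these to three exposure scenarios: *typical* (mean), *high* (95th
percentile) and *max* (largest observed value).

One subtlety is worth stating plainly: *typical &le; high* is **not** a
theorem. When fewer than about 5% of samples are detected, the 95th
percentile sits on the imputed LOD/&radic;2 value while the mean is pulled
above it by the detected tail — real residue surveys show this pattern for
sparsely detected hormones (e.g. testosterone in fat). The package preserves
the mean/p95/max mapping verbatim rather than re-ordering scenarios, and its
monotonicity tests assert intake ordering exactly where the concentration
cells are ordered.

Paired fat/non-fat comparisons use a Wilcoxon matched-pairs signed-rank test
implemented in the package: exact by full sign enumeration for up to 12
non-zero differences (valid under ties), normal approximation with
continuity and tie corrections otherwise.

## From recalls to single-day intake

Each consumed food is disaggregated into ingredients; beef ingredients are
identified by a case-insensitive substring match on the token "beef", with
no exclusion list — adding one would silently editorialise the stated rule.
Consumed grams are multiplied by the recipe's beef weight fraction and
divided by a moisture adjustment factor of 0.75 (25% of cooked weight
assumed lost as water) to express intake in raw-beef grams, the basis on
which concentrations were measured. Raw beef is split into fat and non-fat
portions using the ingredient's nutrient-label fat proportion, each portion
is multiplied by the matching scenario concentration, summed over
ingredients, and divided by 1000 x bodyweight:
g x pg/mg / 1000 = &micro;g, so intakes are in &micro;g/kg/day.

## The usual-intake model

Single days are noisy: a person who eats beef twice a week records zero
intake on most recall days. The two-part mixed model separates

* the **probability part**: a logistic mixed model for whether any beef is
  consumed on a recall day,
  `logit P(R_ij > 0) = beta_10 + x_ij' beta_1 + u_1i`, and
* the **amount part**: a linear mixed model for the Box-Cox transformed
  positive amount,
  `g(R_ij; lambda) = beta_20 + x_ij' beta_2 + u_2i + eps_ij`,

with person-level random intercepts `(u_1i, u_2i)` drawn from a correlated
bivariate normal — people who eat beef more often also tend to eat more of
it, so the correlation `rho` is a first-class parameter. Covariates follow
the survey-analysis convention for this model class: gender, continuous
age, a linear age spline (knot at 11 for children 1-19; knots at 29, 39,
49, 59, 69 for adults 20+), age x gender cross-products, an end-of-week
indicator (Friday-Sunday), and a recall-sequence indicator. Children and
adults are always fitted separately. Survey weights enter the likelihood as
person-level weights, normalised to mean 1 within each fit (weighted
maximum likelihood is scale invariant; normalisation just stabilises the
optimiser).

### Estimation

`fit_two_part()` maximises the weighted marginal likelihood directly. The
random effects are integrated out with a Gauss-Hermite product rule (15
nodes per dimension by default, 225-node grid) scaled by the current
`(sigma_u1, sigma_u2, rho)`. With at most two observations per person the
integrand is dominated by the random-effect distribution itself, so
prior-scaled quadrature is accurate without per-person mode adaptation; the
test suite verifies that doubling the node count moves every parameter by
less than 0.1%.

The Box-Cox parameter is estimated **jointly** with everything else by
including the transformation Jacobian `(lambda - 1) sum(log R)` in the
likelihood, with `lambda` kept in `[0.01, 1]` through a scaled-logit
reparameterisation (variances via log, correlation via arctanh). This is
the standard consistent estimator and avoids a profile grid of ~100 full
refits. The optimiser is BFGS with analytic gradients (posterior-weighted
quadrature moments); a single deterministic GLM/LM-derived start is used,
with jittered restarts available via `n_starts` — at the sample sizes this
model is intended for, the likelihood surface is well behaved and the
deterministic start converges reliably. Standard errors come from the
numerically differentiated analytic gradient (observed information), with a
delta-method transform back to the natural scale.

Degenerate inputs are refused rather than coerced: all-zero or all-positive
consumption patterns raise errors, and fits with fewer than 50 persons
consuming on both days warn, matching the usual stability recommendation
for this model class.

### Simulation of usual intake

`simulate_usual_intake()` draws `(u_1, u_2)` pairs per person (100 by
default, a population of "pseudo-persons") and computes each draw's usual
intake as `P(consumption | u_1) x E[amount | u_2]`. The residual noise term
is integrated with 9-point Gauss-Hermite quadrature on the transformed
scale; nodes falling outside the Box-Cox support (`lambda y + 1 <= 0`) are
truncated at the support boundary (back-transformed value 0) and counted.
Day-level covariates use the usual-day convention: a 4/7 weekday, 3/7
end-of-week mixture at the first-recall mode. Group summaries are
survey-weighted mean, median, 95th and 99th percentiles over pooled draws.

A single percentile convention is used everywhere in the package: weighted
empirical quantiles with linear interpolation between order statistics at
midpoint plotting positions on the cumulative-weight scale (the median of
1..100 with equal weights is 50.5).

## Hazard screening

`hazard_quotient()` divides an intake statistic by the analyte's ADI (MGA
0.03, progesterone 30, testosterone 2 &micro;g/kg/day; testosterone is
screened as the sum of testosterone and epitestosterone intakes against the
testosterone ADI). Reported tables render quotients to two decimals with
"<0.01" below 0.005, while unrounded values are always retained. A hazard
index (sum of related quotients) is available; when every quotient but one
is negligible it adds nothing over the dominant quotient. Two-day-average
("short-term") intakes are also screened, flagged as not strictly
comparable to chronic ADIs.

## Sociodemographic intake ratios and survey variance

`intake_ratios()` compares each subgroup's weighted median usual intake to
the overall cohort median (the overall population *includes* the subgroup,
matching the "versus overall" convention). Sampling variability uses
balanced repeated replication with Fay's factor F = 0.3 and 32 replicates
by default: each pseudo-stratum has two half-sample units; a Hadamard
design selects, per replicate, one unit to up-weight by 2 − F and the
complement down to F, and each replicate is rescaled to the full-sample
weight total. The replicate variance is
`sum_r (theta_r - theta_hat)^2 / (R (1 - F)^2)`. Confidence intervals and
two-sided tests are formed on the log-ratio scale with a delta-method
standard error and normal reference — the log scale guarantees positive
bounds for a ratio. Replicates whose estimator fails are dropped and
counted; more than 25% failures aborts. Full replicate refits of the
two-part model are the default (holding `lambda` at its full-sample
estimate keeps 32 refits affordable); a fast draws-reweighting mode is
available for exploration.

## The synthetic-data generator

`simulate_study()` generates everything the pipeline reads: a population
with gender, age, bodyweight, sociodemographics, lognormal survey weights
and paired BRR pseudo-strata; a recipe catalog (1-5 ingredients per food,
beef fractions and fat proportions uniform in configured ranges, the token
"beef" deterministically present or absent in descriptions); two recall
days per person generated from the two-part model itself, with generated
raw-beef grams allocated to foods such that recipe disaggregation recovers
them exactly; and censored-lognormal assay tables whose detection
frequencies reproduce a realistic retail regime (fat detection 36%/25%/21%/4%
for epitestosterone/MGA/progesterone/testosterone at LODs of 0.1-0.5 pg/mg,
with a sparsely detected trenbolone-like analyte that the ten-detection rule
excludes).

Choices the generator makes where no external value was available, made
once and documented here:

* **Age mix**: children are oversampled (10/8/15% for ages 1-5/6-9/10-19)
  as dietary surveillance surveys do, keeping every gender x age-group cell
  populated at moderate sizes; populations with any cell under 10 persons
  are refused.
* **Two-part truth defaults**: consumption probability ~0.5 per recall day,
  `sigma2_u1 = 1.5`, median positive amount ~40 g raw beef
  (`beta_20 = 7.5`, `lambda = 0.35`), `sigma2_u2 = 1`, `sigma2 = 1`,
  `rho = 0.65`. These describe a commonly consumed episodic food and make
  every parameter well identified at the package's reference recovery scale
  (1500 persons x 2 days, ~570 two-day consumers): the frequency-amount
  correlation, in particular, is only weakly identified when two-day
  consumers are scarce, and a generative truth that cannot be recovered by
  any correct estimator would make parameter-recovery testing meaningless.
  National surveys show beef on a smaller share of recall days (~15% of
  persons consume on both days); users emulating that regime can lower
  `beta1_0` and should expect proportionally wider uncertainty in the
  variance parameters.
* **Within-person error**: positive amounts follow the amount model
  exactly. This is the model's own assumption, not a validated recall-error
  model; passing recovery tests therefore demonstrate correct estimation
  under the model, not robustness to recall biases (which no within-survey
  method can correct).

What the generator deliberately does **not** emulate: survey XPT file
formats, a real food-code vocabulary, masked-variance PSU designs, and
systematic self-report bias.

## Numerical choices, in one place

* Quadrature: 15 Gauss-Hermite nodes/dimension for fitting (Golub-Welsch
  nodes computed in-package), 9 for the back-transformation expectation,
  61 for reference oracles in tests.
* Optimiser: BFGS, relative tolerance 1e-12, analytic gradients;
  convergence is additionally checked by the gradient norm with one
  automatic restart from the incumbent.
* Box-Cox support violations: refused in `inv_boxcox()` unless callers
  truncate explicitly; the generator redraws noise up to 100 times before
  flooring at 0.1 g; the simulator truncates at the support boundary and
  counts.
* Ties in the signed-rank test: average ranks; the exact enumeration null
  conditions on the realised ranks, so ties are handled exactly.
* Percentiles: the single weighted-interpolation convention described
  above, used identically for concentration tables, intake summaries, and
  medians in ratios.

## Problem sizes used by the test-suite and reproduction script

Unit tests run at 120-800 persons; the parameter-recovery harness uses 20
replicates of 1500 persons x 2 days; the draw-distribution oracle uses
2000 persons with a 10^6-draw reference; BRR coverage uses 200 populations
of 240 persons with 32 replicates; the end-to-end determinism check runs
the full pipeline twice at 450 persons. These sizes were chosen so the
whole suite completes on a single CPU at desk scale while leaving every
statistical check comfortably powered.

## Known limitations

* The NCI-style model corrects random within-person error only; systematic
  recall bias passes straight through (documented, not computed).
* Single recipe per food code; recipe-variant mixtures are not modelled.
* One moisture factor (0.75) for all beef ingredients; per-ingredient
  raw/cooked flags are not modelled.
* Fat/non-fat assay pairing is used for the signed-rank comparison only;
  summaries treat subsamples as independent rows, mirroring how retail
  surveys report them.
* Replicate-weight BRR assumes exactly two half-sample units per
  pseudo-stratum; more complex designs need a different variance estimator.

## A worked example

```{r example, eval = FALSE}
cfg <- validate_and_load(list(n_persons = 600, seed = 3,
                              analytes = "MGA",
                              brr = list(n_replicates = 16, fay = 0.3,
                                         refit = "draws")))
bundle <- run_pipeline(cfg)
bundle$usual_summaries |>
  dplyr::filter(scenario == "max") |>
  dplyr::select(gender, age_group, median, p99)
hq_report(bundle$usual_summaries) |>
  dplyr::filter(statistic == "p99") |>
  dplyr::arrange(dplyr::desc(hq)) |>
  head()
```

The README shows this example with the numbers it prints.
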