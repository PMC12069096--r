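# hgpintake

Estimation of human dietary intake of hormonal growth promotants (HGP)
from beef consumption, for exposure scientists and nutritional
epidemiologists working with 24-hour dietary recall surveys and retail
residue measurements.

## What it computes

Hormones used in beef production — melengestrol acetate (MGA),
progesterone (P), testosterone (T), epitestosterone (EpiT) and others —
can leave residues in retail beef. `hgpintake` chains the full exposure
assessment:

1. **Censored assay summaries.** Residue concentrations below the limit of
   detection are imputed at LOD/√2; analytes with fewer than ten detections
   are excluded; mean / 95th percentile / maximum concentrations per
   analyte × tissue class (fat vs non-fat) define *typical*, *high* and
   *max* exposure scenarios. Paired fat/meat differences are tested with an
   in-package exact Wilcoxon matched-pairs signed-rank test.

2. **Recipe disaggregation.** Consumed foods are decomposed into
   ingredients; beef ingredients (case-insensitive substring "beef") give

   `raw beef (g) = food (g) × beef fraction ÷ 0.75`,

   and single-day intake for analyte *a* under scenario *s* is

   `HGP (µg/kg/day) = Σ_j [raw_j · fat_j · C_fat,s + raw_j · (1 − fat_j) · C_nonfat,s] / (1000 · bodyweight)`.

3. **Usual intake (two-part mixed model).** Beef is episodic, so the
   long-run intake distribution is estimated with a correlated two-part
   model: a logistic mixed model for daily consumption probability,
   `logit P(R_ij > 0) = β₁₀ + x'β₁ + u₁ᵢ`, and a linear mixed model for
   Box-Cox transformed positive amounts,
   `g(R_ij; λ) = β₂₀ + x'β₂ + u₂ᵢ + ε_ij`, with `(u₁ᵢ, u₂ᵢ)` bivariate
   normal with correlation ρ. The survey-weighted marginal likelihood is
   maximised with 2-D Gauss–Hermite quadrature and analytic gradients; λ is
   estimated jointly (Jacobian included). Fitted models simulate 100
   usual-intake draws per person ("pseudo-persons") with the residual term
   integrated out by quadrature.

4. **Hazard screening.** Intake statistics are divided by acceptable daily
   intakes (MGA 0.03, P 30, T 2 µg/kg/day; T is screened as T + EpiT) to
   give hazard quotients; two-day-average short-term intakes are screened
   the same way.

5. **Disparities.** Subgroup-to-overall ratios of median usual intake with
   balanced-repeated-replication confidence intervals (Fay's method,
   F = 0.3, 32 replicates, full model refits per replicate).

A synthetic-data generator (`simulate_study()`) produces populations,
recipes, recalls and censored assay tables from a known ground truth, so
the whole pipeline is testable end to end without restricted survey
microdata.

## Worked example

```r
library(hgpintake)
library(dplyr)

cfg <- validate_and_load(list(n_persons = 600, seed = 3, analytes = "MGA",
                              brr = list(n_replicates = 16, fay = 0.3,
                                         refit = "draws")))
bundle <- run_pipeline(cfg)

bundle$usual_summaries |>
  filter(scenario == "max") |>
  select(gender, age_group, n_total, median, p99)
#>    gender age_group n_total   median     p99
#>  1 female 1-5            29 0.00364  0.00953
#>  2 female 6-9            25 0.00208  0.00589
#>  3 female 10-19          53 0.00106  0.00344
#>  4 male   1-5            32 0.00488  0.0130
#>  ...
```

Usual daily MGA intake is highest for young boys and declines with age —
the youngest children eat the most beef per kilogram of bodyweight. The
hazard screen divides these intakes by the MGA ADI (0.03 µg/kg/day):

```r
hq_report(bundle$usual_summaries) |>
  filter(statistic == "p99", scenario == "max") |>
  arrange(desc(hq)) |>
  select(gender, age_group, intake, hq, hq_label) |> head(4)
#>   gender age_group  intake    hq hq_label
#> 1 male   1-5       0.0130  0.434 0.43
#> 2 female 1-5       0.00953 0.318 0.32
#> 3 male   6-9       0.00791 0.264 0.26
#> 4 female 6-9       0.00589 0.196 0.20
```

Even at the 99th percentile under the worst-case concentration scenario,
this synthetic population stays below the ADI (all HQ < 1). Subgroup
median-intake ratios with BRR confidence intervals come out of
`bundle$intake_ratios` (plot with `autoplot()`); quotients below 0.005
render as `"<0.01"`, matching reporting conventions for negligible
hazards.

All numbers above are what the code printed for this seed; they describe
the synthetic study, not any real population.

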