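# bronchoscore

Composite bronchoscopy scoring and chance-corrected inter-rater agreement
for pediatric cystic fibrosis (CF) airway assessment.

Flexible bronchoscopy lets clinicians see CF airway disease directly —
mucus plugging, viscous secretions, mucosal bleeding, abnormal vascular
drawing — but unaided visual impression is subjective. `bronchoscore`
implements a standardized scoring tool and the statistics needed to study
how reliably different raters apply it:

* **Scoring model.** Ten visual features, each rated per bronchial lobe
  (RUL/RML/RLL/LUL/LLL) on an ordinal scale: secretion color on the 9-point
  Murray sputum chart (0 watery … 8 purulent), secretion amount 0–3, mucus
  plugging binary, seven further features 0–2. Per-lobe scores reduce to a
  per-recording composite by a threshold rule: with lobe counts
  `n≥v = #{lobes scoring ≥ v}` over `m` lobes,

  `C = max over levels v with n≥v ≥ 1 of ( v + 1 if n≥v > m/2 else v )`,

  and `C = 0` when every lobe is 0. Secretion color instead takes the
  maximum across lobes. On the usual 0–2 scale this reads: 1 = some lobe
  mild but fewer than three; 2 = three or more lobes involved or any lobe
  moderate-severe; 3 = three or more lobes moderate-severe.
* **Agreement engine.** Weighted Gwet's AC2 (AC1 with identity weights),
  the chance-corrected multi-rater coefficient that stays well-behaved when
  one score dominates the marginals — precisely where Cohen's kappa shows
  the "kappa paradox". Linearized standard errors, untruncated t-based 95%
  CIs, Cohen's weighted kappa for comparison, pairwise rater tables,
  Landis–Koch interpretation bands.
* **Study pipeline.** `analyze_study()` runs composites → per-feature
  overall AC2 → CF / non-CF strata → all rater pairs → optional comparison
  against literature coefficients, and `render_report()` writes CSV, JSON
  and a text forest plot.
* **Synthetic studies.** A latent-severity generator
  (`simulate_ratings()`) with tunable rater noise, bias, prevalence and
  group structure, so the whole pipeline is testable without patient data.

## Worked example

```r
library(bronchoscore)

ratings    <- simulate_ratings(simulation_config(n_subjects = 80, seed = 2026))
composites <- compose_all(ratings)
head(composites, 3)
#>   subject_id group rater_id feature_id composite
#> 1       S001    CF  expert1   bleeding         3
#> 2       S001    CF  expert2   bleeding         3
#> 3       S001    CF  expert3   bleeding         3

report <- analyze_study(ratings,
                        config = study_config(reference_values = thomas_reference_values()))
report
#> <study_report> 10 features, 4 raters, 80 units (composite), weights = ordinal
#>          feature_id coefficient ci_low ci_high           band
#> 1   secretion_color       0.974  0.969   0.978 almost_perfect
#> 2  secretion_amount       0.894  0.871   0.917 almost_perfect
#> 3     mucosal_edema       0.800  0.757   0.842    substantial
#> ...
```

Each row is one feature's inter-rater reliability across the four simulated
raters: the ordinal-weighted AC2 coefficient, its 95% CI, and the
Landis–Koch verbal band (values ≤ 0.6 are at best moderate; > 0.8 almost
perfect). `report$by_stratum` holds the same estimates within the CF and
non-CF subgroups, `report$pairwise` one estimate per rater pair
(`choose(4, 2) = 6` per feature), and `report$comparison` places external
literature coefficients next to this study's.

The motivation for AC2 in one fixture — two raters, 100 subjects, 90%
both-negative:

```r
tab <- paradox_fixture()
percent_agreement(pair_table_to_counts(tab), "identity")$coefficient  # 0.91
cohen_weighted_kappa(tab, "identity")$coefficient                     # 0.135
gwet_agreement(pair_table_to_counts(tab), "identity")$coefficient     # 0.900
```

Same data: kappa calls 0.91 observed agreement "slight", AC1 calls it
"almost perfect". Rare findings (most scores 0) are the norm in this
instrument, hence AC2.

A command-line wrapper covers the same flow
(`inst/cli/bronchoscore.R simulate|score|agree|report`, logs to stderr,
results to files).

## Method details

See `vignettes/bronchoscore-methods.Rmd` for the composite algorithm's
edge-case semantics, the AC2 formulas, variance estimator and CI
conventions, the synthetic generator's model and defaults, and known
limitations.
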