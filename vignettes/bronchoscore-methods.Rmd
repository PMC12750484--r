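---
title: "Scoring model and agreement methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring model and agreement methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bronchoscore)
```

## The instrument

Flexible bronchoscopy in children with cystic fibrosis (CF) shows airway
changes — mucus plugging, viscous secretions, mucosal bleeding, abnormal
vascular drawing — that plain visual impression grades inconsistently.
`bronchoscore` implements a standardized scoring tool for such recordings:
ten visual features, each rated per bronchial lobe (right upper/middle/lower,
left upper/lower) on a small ordinal scale, then aggregated to one composite
score per recording and feature. Around the instrument it provides the
statistical machinery a reliability study needs: chance-corrected multi-rater
agreement with confidence intervals, stratified and pairwise analyses, and a
synthetic study generator for testing the pipeline end to end.

The registry (`default_feature_registry()`) fixes the scales: secretion color
uses the 9-point Murray sputum chart (0 watery … 8 purulent) and is the only
feature aggregated by the *maximum* across lobes; secretion amount is 0–3;
mucus plugging is binary per lobe; the remaining seven features are 0–2
(normal / mild / moderate-severe).

## The composite algorithm

For threshold features the per-lobe scores $s_1,\dots,s_m$ (five lobes by
default) reduce to a composite that reflects both severity and extent. Let
$n_{\ge v}$ be the number of lobes with score at least $v$. The composite is

$$C = \max_{v \,:\, n_{\ge v} \ge 1} \left\{ v + \mathbf{1}\!\left[n_{\ge v} >
\tfrac{1}{2} m\right] \right\},$$

and $C = 0$ when all lobes are 0. With five lobes the strict majority means
three or more lobes. On a 0–2 scale this enumerates to the familiar clinical
rules: 1 = some lobe mild but fewer than three; 2 = three or more lobes
involved, or any lobe moderate-severe; 3 = three or more lobes
moderate-severe.

Two reading choices were genuinely open and are resolved as follows:

* **"Rated v" is read as "rated at least v".** The enumerated rules only
  cover pure vectors; on mixed vectors (e.g. `(2,1,1,1,1)`) counting *exact*
  levels would be non-monotone (upgrading a lobe from 1 to 2 could lower the
  composite). The $\ge$ reading reproduces every enumerated case, is monotone
  in each lobe score, and generalizes to any scale maximum. The test suite
  proves equivalence with a literal transcription of the rules over all
  $3^5$ and $4^5$ lobe vectors.
* **Mucus plugging.** Scored binary per lobe; the general rule at scale
  maximum 1 yields a graded composite 0/1/2 (absent / minority of lobes /
  three or more lobes), which is the package default because it preserves the
  extent information the algorithm is designed to carry. A strictly binary
  composite (any-lobe OR) is available via
  `default_feature_registry(mucus_plugging_binary = TRUE)`; at scale 1 the OR
  is exactly the maximum rule, so no third aggregation type exists.

Missing lobes are an error under the default strict policy (the instrument
requires all five); the lenient policy rescales the majority cutoff to the
observed lobe count, which is the natural reading of "more than 50% of
lobes" when a lobe could not be inspected.

## Agreement methodology

Reliability is summarized by Gwet's AC, the chance-corrected coefficient
designed for imbalanced category prevalences. Ordinal clinical scores are
exactly the setting of the *kappa paradox*: when one category (usually
"normal") dominates, Cohen's kappa can be near zero despite raters agreeing
on almost every recording, because its chance term is built from the raters'
own marginals. `paradox_fixture()` packages the canonical 2×2 demonstration
(percent agreement 0.91, kappa 0.13, AC1 0.90). Cohen's weighted kappa
(`cohen_weighted_kappa()`, Fleiss–Cohen–Everitt standard error) is included
for comparison output only.

For $n$ subjects, $r_{ik}$ raters placing subject $i$ in category $k$,
$r_i = \sum_k r_{ik}$, and weights $w_{kl}$:

$$p_{a|i} = \sum_k \frac{r_{ik}(r^*_{ik} - 1)}{r_i(r_i - 1)}, \quad
r^*_{ik} = \sum_l w_{kl} r_{il},$$

averaged over the subjects with $r_i \ge 2$;
$\pi_k = n^{-1}\sum_i r_{ik}/r_i$;
$p_e = \frac{T_w}{q(q-1)} \sum_k \pi_k (1 - \pi_k)$ with $T_w = \sum_{kl}
w_{kl}$; and $AC = (p_a - p_e)/(1 - p_e)$. Identity weights give AC1;
any non-trivial weight family gives the weighted AC2.

Key numerical and design choices:

* **Weight family.** Default `ordinal`
  ($w = 1 - d(d+1)/(q(q-1))$, $d$ the rank distance), the family built for
  ordinal categories; `identity`, `linear` and `quadratic` are available and
  every report records the family used.
* **Category space.** $q$ is the feature's full composite range
  (`composite_range()`), e.g. 0–3 for a 0–2 threshold feature and 0–8 for
  secretion color, whether or not every value occurs in the sample. The
  weighted $p_e$ depends on $q$, and the instrument — not the sample —
  defines the scale.
* **Variance and CI.** The standard error is the linearized per-subject
  estimator (each subject's influence on the coefficient through both $p_a$
  and $p_e$); the CI is $AC \pm t_{0.975,\,n-1}\,se$ and is deliberately not
  truncated at 1, so near-ceiling features can report bounds like 1.01. The
  finite-population correction is off by default (recordings are a sample
  from an unbounded population). The test suite validates the linearized SE
  against a leave-one-subject-out jackknife (within 15% at study size) and
  checks empirical 95% CI coverage of the large-sample limiting coefficient
  over 1000 simulated studies.
* **Interpretation bands.** The conventional verbal scale leaves gaps
  (0.20/0.21, …); `interpret_band()` uses contiguous half-open intervals
  with 0.60 as the moderate/substantial boundary, matching the convention of
  drawing the reference line at 0.6. Bands are always recomputed from
  coefficients, never stored.
* **Unit of analysis.** Default is the composite score, one value per
  recording, so $n$ is the number of recordings; `per_lobe` treats every
  (recording, lobe) pair as a unit on the raw per-lobe scale, for users who
  want agreement before aggregation.
* **Missing ratings.** Subjects rated by fewer than two raters still inform
  the prevalences $\pi_k$ but cannot contribute observed agreement; a rater
  pair with no co-rated subjects is flagged absent rather than zero.

`analyze_study()` assembles the full report: per-feature overall AC2,
CF / non-CF strata, all $\binom{R}{2}$ rater pairs per feature, and an
optional comparison against external literature coefficients (the packaged
`thomas_reference_values()` table for the six features shared with the
earlier pediatric score — literature values, not recomputed).

## The synthetic study generator

No rater-level data ship with the package, so `simulate_ratings()` generates
studies with the structure the analysis assumes: subject $i$'s latent
severity for feature $f$ is $\theta_{if} \sim N(\mu_{gf}, \sigma^2_s)$; lobe
$l$ adds $N(0, \sigma^2_l)$; rater $j$ observes the lobe value plus
$b_j + N(0, \sigma^2_j)$ and scores it by counting cutpoints below the
observation. This latent-threshold model is the simplest generator with
independently tunable agreement (rater noise/bias), prevalence (cutpoint
placement) and group structure (latent shift for CF subjects), which is all
the pipeline's properties need.

Defaults mirror the reliability study the package is built around: 80
recordings with a 50/30 CF/non-CF split, four raters (one trained student,
three experienced pulmonologists — modelled exchangeably with bias 0 and
noise sd 0.6 latent units, absent any published rater-level parameters),
between-subject sd 1, between-lobe sd 0.4, and first cutpoints above the
latent mean so that score 0 dominates — the imbalanced-marginals regime that
motivates AC2. CF subjects receive a positive latent shift on
secretion-related features. Seeds are mandatory and the generator never
touches the caller's RNG stream.

What the generator does *not* emulate: rater-specific scale use (halo or
end-aversion effects), feature-to-feature correlation within a recording,
video-quality artefacts, and rater learning over time. Green simulation
tests therefore certify the statistical machinery, not the clinical
instrument itself.

## Problem sizes used by the test suite

Exhaustive composite checks cover all 1299 lobe vectors at scale maxima 1, 2
and 3. Agreement oracle equivalence uses 200 random instances with up to 10
subjects, 4 raters and 5 categories at tolerance 1e-12. Variance validation
uses 80-subject, 4-rater simulated studies (jackknife comparison) and 1000
replicates for CI coverage against a truth estimated once at 50,000
subjects. The noise-monotonicity grid uses 4 noise levels × 20 replicates at
200 subjects with common random numbers across levels.

## Known limitations

* The per-feature composite ranges are derived from the generalized rule;
  any instrument revision that caps individual composites differently needs
  registry edits.
* The AC variance estimator is asymptotic in subjects; with very small
  strata (a handful of recordings) the t-interval is only indicative, and
  strata below two subjects are reported absent.
* Weighted kappa is provided for two raters only (comparison use); no
  Fleiss kappa, Krippendorff alpha or ICC — they answer different questions
  and were deliberately left out of scope.
* The CLI is a thin wrapper over the exported functions; programmatic use
  should call the functions directly.
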