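---
title: "Methods: from monitoring records to periphyton growth risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from monitoring records to periphyton growth risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perigrow)
```

## The problem

Excessive growth of periphyton — the attached algal and microbial biofilm on
stream beds — is the visible face of river eutrophication. Whether a
catchment is at risk depends on two things: which nutrient limits growth,
and whether the limiting nutrient's concentration exceeds the level at which
growth becomes undesirable. `perigrow` implements a complete, testable
pipeline from raw site-level monitoring records to a four-way catchment
classification and its continental roll-up.

The chain is: harmonise heterogeneous records → keep only baseflow,
growing-season samples from adequately monitored sites → summarise each
catchment by a median concentration → model medians on catchment predictors
in log space → predict medians for unmonitored catchments → classify every
catchment → aggregate areas, populations and land use.

## The statistical model

Catchment median concentrations are strongly right-skewed; their natural
logarithms are close to normal (the pipeline reports a Shapiro–Wilk check on
both scales). The model for each analyte is ordinary least squares on the
log scale,

$$\ln y_i = \beta_0 + x_i^\top \beta + \varepsilon_i,
  \qquad \varepsilon_i \sim \mathrm{iid}\; (0, \sigma^2),$$

with the predictor subset chosen by the Mallows statistic

$$C_p = \frac{\mathrm{SSE}_p}{\hat\sigma^2_{\mathrm{full}}} - n + 2p .$$

All $2^k$ subsets of the candidate terms are scored when $k \le 20$
(categorical predictors such as biome enter and leave as whole indicator
blocks; the reference level is the most frequent category); larger pools are
first capped by forward selection. The default rule takes the minimum $C_p$;
ties break toward fewer parameters, then lexicographic term names, so the
choice is deterministic. The alternative rule — the smallest subset with
$C_p \le p$ — is available through `pipeline_config(cp_rule = "cp_le_p")`.
Per-coefficient t-tests are reported for reference but play no role in
selection.

Back-transforming $\exp(\hat y)$ under-estimates the conditional mean, so
predictions are multiplied by the Duan smearing factor

$$S = \frac{1}{n} \sum_{i=1}^{n} e^{\hat\varepsilon_i} \ge 1 ,$$

applied uniformly over the prediction range on the assumption of
homoscedastic residuals. `validate_holdout()` scores a disjoint hold-out set
by the squared correlation of log observed with log predicted, the
observed-on-predicted slope, and the percentage bias of mean predictions.

## Classification

With TN and TP medians in hand (observed or predicted), the Redfield mass
ratio decides limitation and the limiting nutrient's threshold decides
growth:

* TN:TP < 7 — N-limited; undesirable growth if TN > 0.800 mg L⁻¹
  (type 2), otherwise type 1;
* TN:TP ≥ 7 — P-limited; undesirable growth if TP > 0.046 mg L⁻¹
  (type 4), otherwise type 3.

The thresholds are the means of a literature survey of periphyton-response
studies, which `summarize_thresholds()` and `anova_thresholds_by_biome()`
reproduce from a survey table (the across-biome ANOVA is what justifies a
single global mean per analyte). `classify_with_regional_thresholds()`
re-runs the classification with region-specific thresholds and reports
per-type area shifts against the global rule.

Two boundary conventions are deliberate. A median exactly equal to a
concentration threshold classifies as *acceptable*: the rule set defines
only the strict inequalities, and the conservative reading is
config-overridable (`classification_rule(equality_undesirable = TRUE)`).
And the ratio comparison carries a $10^{-9}$ relative tolerance so a
catchment sitting exactly on the 7:1 boundary (e.g. 0.70/0.10) is not
misrouted by floating-point rounding. One documentation note: some report
renderings of the TP threshold print 48 µg L⁻¹; the canonical value used
throughout is 0.046 mg L⁻¹ (46 µg L⁻¹).

## Filters and their tunables

| Tunable | Default | Why |
|---|---|---|
| Unit-anomaly factor | 100 × site-analyte median | flags values recorded in the wrong unit (µg vs mg is a factor 1000); flagged rows are excluded, never rescaled — an automated pipeline must not invent corrections |
| Censored substitution | 0.5 × detection limit | the standard substitution for left-censored water-quality values |
| Censored tolerance | 10% per site-analyte series (strictly greater excludes; exactly 10% retained) | a median built mostly from substituted values reflects the detection limit, not the river |
| Filter parameter α | 0.925, 3 passes, 30-day reflected warm-up | standard values for the Lyne–Hollick single-parameter filter family |
| Baseflow minimum | 75% of day-of-sampling flow, inclusive | samples taken in stormflow are not comparable: scour and turbidity suppress periphyton |
| Site–gauge link | ≤ 50 km downstream, inclusive; nearest wins | beyond that the gauge no longer represents the site's flow state |
| Date window | most recent 7 years per site-analyte, inside 1990–2016 | recent enough to avoid long-term trends while keeping enough sites |
| Season | May–Oct (N), Nov–Apr (S), all months within \|lat\| ≤ 23.43695° | growing-season medians; tropical growth is not seasonal in the same way |
| Eligibility | ≥ 37 samples and median inter-sample gap ≤ 61 days | fewer or sparser samples make the median unstable; "at least bimonthly" is operationalised as the median gap because no formula is standard |

Three interpretation choices were genuinely open and are recorded here as
the package's own: the censored-fraction rule is evaluated *after* the
baseflow/window/season filters, because it is a property of the series that
actually enters the analysis; the 75% baseflow criterion applies to the
sampling day itself rather than an antecedent window; and where several
eligible sites fall in one catchment their medians are pooled by a further
median. All three sit in `pipeline_config()` rather than in code.

## The baseflow filter

Per pass, quickflow follows the recursion
$qf_t = \alpha\, qf_{t-1} + \tfrac{1+\alpha}{2}(Q_t - Q_{t-1})$, clamped to
$[0, Q_t]$; baseflow is the remainder, and passes alternate
forward–backward–forward. Each gap-free segment is warmed up by reflecting
up to 30 days of record at both ends, so the start-up state is absorbed
outside the real series. Gaps (missing days) split the record; segments
shorter than 10 days are left unfiltered rather than filtered badly. A
zero-flow day has baseflow fraction 1 by convention — no quickflow is
possible. The filter is deterministic and scale-equivariant, and the test
suite holds it equal to an independently hand-iterated recursion on every
series it checks.

## What the synthetic generator emulates — and what it does not

`gen_world()` builds a complete toy world: catchment predictors (standard
normal continuous columns plus an inert five-level biome), a sparse linear
truth in log space per analyte, site records spread across both hemispheres
and the tropics, censored log-normal samples, one gauge per site with a
storm-pulsed hydrograph, and a threshold survey.

Defaults, chosen once as realistic study conditions:

* intercepts at the logs of the classification thresholds, so catchments
  straddle the decision boundaries instead of clustering safely away from
  them;
* two active predictors of effect ±1 among ten candidates, residual
  σ = 0.3 (log space) — clearly detectable but far from noiseless;
* within-site scatter σ = 0.4 and a detection limit at each series' 5th
  percentile, so censoring is present but rarely trips the 10% rule;
* storms on 4% of days with mean pulses 6 × baseflow and a 2-day half-life,
  giving a baseflow index near 0.6 (an ordinary temperate river) while
  still failing the 75% rule on roughly a quarter of days;
* fortnightly sampling for five years: after the growing-season filter an
  extratropical site keeps ~65 samples and still clears the 37-sample
  eligibility floor after baseflow losses. (Monthly sampling, common in
  practice, cannot satisfy a 37-sample floor within a seven-year window
  outside the tropics — half the months are out of season — so a
  monthly-sampled toy world would test only tropical sites.)

What passing on this world shows: that every filter, the selection, the
smearing correction and the classification do what they claim when the data
really are log-normal, homoscedastic, spatially independent, and sampled on
a regular schedule. What it does not show: robustness to spatially
correlated predictors, heteroscedastic or autocorrelated residuals,
rating-curve errors in discharge, laboratory method drift, or the
irregular, clustered sampling of real networks. The generator is a
correctness instrument, not a realism claim.

Test problem sizes are the package's own choices: parameter recovery uses
100 seeded designs of 500 catchments; the end-to-end type-match check runs
the full pipeline on three seeded 500-catchment worlds and asks that at
least 95% of catchments classify identically to the types derived from the
generator's systematic medians. "Recovered" means every truly active
predictor is in the selected set with its estimate within three standard
errors: a minimum-$C_p$ rule admits an occasional noise predictor by
construction (each enters with probability ≈ 0.16), so exact set equality
is not the right yardstick for a correct implementation.

## Numerical and degenerate-input choices

* Subset search uses cross-product matrices, so each subset costs a small
  solve independent of $n$; a rank-deficient full design is an error that
  names the collinear columns.
* If the full model fits exactly ($\hat\sigma^2_{\mathrm{full}} = 0$, where
  $C_p$ is undefined), the smallest subset that also fits exactly is chosen.
* A degenerate (all-equal) response makes the normality check undefined; it
  warns and proceeds.
* Aggregation sums unrounded values and computes percentages from them;
  rounding (e.g. to 0.1 million km²) happens only at rendering, because
  rounded continental rows generally do not sum to their world row. For the
  same reason published tables can carry world totals a few parts in 10⁵
  away from their printed continental sums; the aggregate here sums exactly
  and documents the difference instead of reproducing it.
* CSV round-trips write doubles with `%.17g`, so written tables reproduce
  their source bit-for-bit.

## Worked example

```{r example, eval = FALSE}
library(perigrow)
world <- gen_world(n_catchments = 60, seed = 42)
run <- run_pipeline(world)
print(run)
run$headline
summary(run$models$TN)
```

## Known limitations

The pipeline models catchments as independent observations: no spatial
autocorrelation, no nested site-within-catchment variance components. The
substitution treatment of censored values is the conventional one, not a
maximum-likelihood estimator, and is only defensible under the 10% cap the
pipeline enforces. The Redfield boundary is a stoichiometric indicator, not
a site-specific limitation assay — N-fixing cyanobacteria can overcome
apparent N-limitation, which would move type-1 catchments toward risk. And
the classifier's thresholds are global literature means; where tailored
regional thresholds exist, `classify_with_regional_thresholds()` should be
preferred and the global rule treated as the fallback.
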