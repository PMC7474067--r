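---
title: "Normative age modelling of regional cortical morphometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative age modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(normdev)
```

This vignette is the package's own account of its statistical machinery:
the model and its assumptions, the tunable parameters and their defaults,
what the synthetic-data generator emulates, the numerical choices made at
points where the design was genuinely open, and known limitations. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The normative model

### Estimator

For one region, let $(a_i, y_i)$ be the ages and morphometric values
(e.g. mean cortical thickness in mm) of the reference (control) group,
restricted to a single sex stratum. The age trajectory is estimated by
LOESS: at a query age $a_0$, a degree-$p$ polynomial is fit by weighted
least squares over the $k$ nearest neighbours in age,
$k = \max(\lceil s\,n \rceil,\, p + 2)$, with tricube weights
$(1 - (d/d_{\max})^3)^3$ on the scaled distances. The package implements
this definition directly (a few dozen lines of vectorized linear algebra)
rather than delegating to `stats::loess`, because the test suite holds
the estimator to exact (1e-8) agreement with a brute-force
weighted-least-squares oracle, and `loess`'s interpolation surface and
internal normalizations are close to but not identical with the textbook
definition.

Fitted means are evaluated at every reference subject's age and tabulated
into one-year half-open bins $[k, k+1)$ starting at the floor of the
youngest reference age. Each bin contributes

* $\mu$ — the **median** of the fitted means in the bin (robust to the
  handful of extreme ages a bin can contain), and
* $\sigma$ — the SD of the raw residuals (observed − fitted) in the bin.

A subject of age $a$ with value $y$ in region $r$ then receives the
deviation score $w = (y - \mu_{r,b(a)})/\sigma_{r,b(a)}$.

**Why residual-based $\sigma$:** the within-bin residual SD is the
simplest estimator consistent with the binned framing of the norms; a
second smoother on squared residuals would add a bandwidth choice without
changing what the tests can verify. $\sigma$ therefore pools residual
noise, site offsets, and stable inter-individual differences — the score
asks "how unusual is this value among same-aged reference subjects as
observed across the study", not "net of site".

### Bin retention

Bins with fewer than `min_bin_count = 5` reference subjects are dropped:
an SD from 4 points is too unstable to standardize against. Bins whose
$\sigma$ falls below `sigma_floor = 1e-6` mm are likewise treated as
unusable (a near-zero SD makes $w$ arbitrarily large); this arises only
for degenerate (noise-free) inputs. Subjects whose age bin is dropped get
**missing** w-scores — never zero — and every downstream operation
(flagging, ratios, models) excludes missing cells and reports counts.

### Span selection

The span $s \in [0.05, 1]$ is chosen per region by Brent scalar
minimization seeded by a 12-point grid scan (the cross-validation
objective need not be unimodal; the grid guards the bracketing). Two
objectives are offered:

* `sse_mode = "cv"` (default): 5-fold cross-validated SSE, folds assigned
  deterministically by age rank so the procedure is seed-free. This is
  the statistically defensible choice — in-sample SSE decreases
  monotonically as the span shrinks, so minimizing it does not select a
  smoothing level.
* `sse_mode = "literal"`: in-sample SSE bounded below by the span floor
  0.05. Provided for comparability with pipelines that optimize training
  error; it typically returns the floor.

Near-ties (within $10^{-10}\times$ the response's total sum of squares)
break toward the **smaller** span, so flat objectives — e.g. exactly
linear data — resolve deterministically to the lower bound.

### Centile cross-check

`centile_scores()` places each scored value in the empirical distribution
of same-bin reference values under the Hazen mid-rank convention:
$c = 100\,\mathrm{clamp}\big((\#\text{less} + 0.5\,\#\text{equal})/n,\;
0.5/n,\; (n-0.5)/n\big)$. The clamp assigns values beyond the reference
range the plotting position of the extreme reference point instead of
0/100. Note the resolution limit: a bin with $n$ reference subjects
cannot produce a centile below $100/(2n)$, so centile-based outlier
calls (beyond the two-sided normal 2-SD tails, $c < 2.275$) require
$n \ge 22$ per bin. The test suite checks that centile-derived and
w-derived global ratios correlate at $r > 0.8$ on a synthetic cohort.

### Bootstrap reliability

`bootstrap_reliability()` resamples the reference group with replacement
$B$ times, refits the LOESS mean and the bin table per resample, and
recomputes each scored subject's w. Spans are **held fixed** at the
full-sample optimum: re-selecting the span inside every resample
multiplies cost roughly fifty-fold while the quantity of interest — the
sampling variability of the bin norms — is unchanged. The two-sided
empirical p-value is the position of the real w in its bootstrap
distribution with add-one smoothing,
$p = \min\!\big(1,\; 2\min(1 + \#\{w^* \le w\},\, 1 + \#\{w^* \ge w\})/(B+1)\big)$,
so $p$ is never zero and a w at the bootstrap median gets $p \approx 1$.
(A plausible alternative — counting $|w^*| \ge |w|$ — is *not* a
positional reliability measure: it gives $p \approx 0.5$ to a perfectly
central score whose bootstrap distribution is centred away from zero.)
Resamples in which a subject's bin falls below the retention rule
contribute missing and shrink that cell's effective $B$. BH-FDR is
applied across regions within each subject.

## 2. Atypicality summaries

Outlier flags use strict $|w| > 2$: the global ratio's numerator counts
$|w| > 2$ and its denominator $|w| \le 2$, so the boundary convention
follows the denominator and every scored region lands in exactly one of
the two counts. The global ratio $gW$ is a count ratio (outlier regions
over non-outlier regions); $gW^+$ and $gW^-$ restrict the numerator to
positive/negative deviations, so their numerators partition $gW$'s. A
subject with *every* scored region an outlier has an undefined ratio and
is returned as `Inf` with a `degenerate` flag. The global-thin flag is
$gW^- > 0.5$ — note a *count* ratio of 0.5 corresponds to one third of
regions deviant, not one half; the implementation follows the ratio
definition literally and documents the distinction here.

The prevalence test is the one-sample proportion $\chi^2$,
$X^2 = n\,(|\hat p - p_0| - c)^2 / (p_0(1-p_0))$ with Yates correction
$c = 1/(2n)$ (capped at zero) or $c = 0$, on 1 df. The count $n$ is an
explicit argument because published analyses differ — silently — in
whether the region count or the subject count is used, and the two give
different statistics.

## 3. Inference

Case-control contrasts fit `value ~ group + covariates + (1 | site)` with
`lme4`, group coded control→case so the coefficient is case − control.
Available covariates are age, sex, mean framewise displacement and the
Euler index; subjects missing a *used* covariate are dropped from that
model only (and counted), so a missing QC measure never silently shrinks
unrelated analyses. With a single site the model reduces to OLS, where
the covariate-free contrast is exactly the pooled-variance two-sample
t-test (verified to 1e-6 in the suite).

* **Cohen's d** is the group coefficient divided by the model's residual
  SD. With no covariates and one site this is classical pooled-SD d
  (tested); with a site random intercept it is a *within-site* effect
  size — site variance is deliberately excluded from the denominator.
* **p-values** use the residual-df t approximation
  ($\mathrm{df} = n - p_{\text{fixed}}$). At hundreds of subjects per
  group the difference from Satterthwaite/Kenward-Roger df is far below
  the FDR resolution; the approximation is deterministic and
  implementation-independent. This is a known deviation surface for
  small-sample use.
* **Region-wise outlier removal** drops case subjects with $|w| > 2$ in
  that region only (never controls, never listwise), refits, and reports
  significant-region counts before/after and their fold change. Regions
  left with fewer than 10 cases are flagged unstable.
* **BH-FDR** is a 12-line step-up implementation (q-values
  $\min_{j \ge i} p_{(j)} m / j$, monotonized); the suite proves it
  against a brute-force transcription of the definition and against
  `p.adjust`.
* **Brain–behaviour maps** are Spearman correlations, pairwise-complete
  per phenotype × region, corrected in a single joint FDR family (all
  phenotypes × all regions together — the conservative reading when
  phenotypes are analysed jointly). p-values use the
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation for $n > 30$ and a
  seeded 20,000-draw permutation below (full enumeration is infeasible
  past $n \approx 10$).
* **Power**: minimum detectable d solves the two-sided two-sample
  noncentral-t power equation ($\mathrm{df} = 2n-2$,
  $\lambda = d\sqrt{n/2}$); minimum detectable r solves the analogous
  correlation-test equation ($\mathrm{df} = n-2$,
  $\lambda = r\sqrt{n-2}/\sqrt{1-r^2}$), with a Fisher-z alternative
  (`method = "fisher"`). The two r methods differ by ~2e-4 at n = 421.

## 4. The synthetic world

`generate_cohort()` draws from an explicit generative model:

| Component | Default | Rationale |
|---|---|---|
| Trajectory | asymptote U(2.2, 3.0) mm + offset U(0.3, 0.7) mm · exp(−(age−5)/τ), τ ~ U(8, 15) yr | monotone cortical thinning toward an adult asymptote, the qualitative shape regional CT follows from childhood |
| Ages | 5–40 yr, Beta(1.5, 3.5) | right-skewed: more children than adults, as in pooled developmental cohorts |
| Sites | 20 sites, offsets N(0, 0.05 mm) | multi-site consortium structure; site share of variance ≈ 15–17 %, matching what variance-partition analyses attribute to site |
| Subject offsets | N(0, 0.05 mm) | stable inter-individual global thickness differences |
| Residual noise | N(0, 0.10 mm), optional linear age trend | typical within-region measurement + biological noise for ~500 mm² parcels |
| Group sizes | 624 controls / 699 cases | the post-QC male sample scale the analysis targets |
| Planted outliers | prevalence 0.05 per region, shift ±3 × total local SD, sign bias configurable | detectable-by-construction atypicality; the shift is in units of the *total* SD because that is what the w denominator estimates |
| Global-thin subjects | 5 cases, −2.5 SD in 60 % of regions | a small QC-artifact-like subgroup |
| Phenotypes | baseline + slope × mean planted deviation + noise, MCAR mask | couples symptom scores to deviations without imposing a spatial pattern |

One master seed expands into fixed substreams (trajectories, demographics,
offsets, noise, planting, phenotypes), so adding a stream never perturbs
earlier ones; `world_seed` separates the population-level draws from the
subject-level draws so that two cohorts can be sampled from the *same*
population — which is what out-of-sample calibration requires.

**What the generator does not emulate:** spatial correlation between
regions (beyond the shared subject/site offsets), site × age sampling
interactions, scanner-specific heteroscedasticity, non-Gaussian residuals,
or any attempt to fit real consortium data. A green test therefore
establishes that the machinery behaves as specified under a realistic
variance budget — not that the pipeline's numbers transfer to any
particular real dataset.

### Calibration of w-scores

Because subject and site offsets are each ~41 % of the total SD
(0.05/0.122 mm) and are shared across *all* of a subject's regions, they
do not average out when a one-year bin is pooled across regions. The mean
w of a bin with $n_b$ scoring subjects therefore fluctuates with
sampling SD $\approx \sqrt{2}\,(0.05/0.122)/\sqrt{n_b} \approx
0.58/\sqrt{n_b}$: roughly ±0.1 at 100 subjects per bin. Holding per-bin
means inside ±0.05 at high confidence would need over a thousand subjects
*per bin* — no cohort of 1000 subjects spread over ~30 bins can exhibit
it, whatever the seed. The corresponding acceptance check is accordingly
expected to fail on its per-bin mean/SD clauses and is left failing with
an explanatory label; the *aggregate* calibration — overall tail mass
$P(|w|>2) \approx 0.046$, per-region SDs near 1 — holds and is asserted.
The in-sample per-bin centering property is tested in an iid-noise
configuration (site and subject SDs zero) with many regions, which
isolates the scoring machinery from this irreducible cohort-level
variance.

Recovery of planted 3-SD outliers by $|w| > 2$ has a theoretical ceiling
of $P(|N(3,1)| > 2) \approx 0.84$; the suite requires ≥ 0.80, leaving
room for norm-estimation noise at ~30 reference subjects per bin.

## 5. Data handling choices

Tables are UTF-8 delimited text (comma default, tab accepted) with
period-only decimals; a value like `"14,2"` is a validation rejection
with the row cited, not a silent locale guess. Numeric columns round-trip
at full double precision (17 significant digits). Age matching is greedy
1:1 nearest-neighbour without replacement in *descending* case-age order
— the sparse adult tail gets first pick of the few old controls — with
ties broken toward the younger control; the procedure is invariant to a
constant age shift. Euler-index QC removes the worst
$\lfloor n f \rfloor$ subjects via an order-statistic threshold, with
ties at the threshold conservatively retained. Matching is nearest-
neighbour only; genetic matching (which optimizes covariate balance
globally) is a documented non-goal.

## 6. Known limitations

* Norms are static per one-year bin; no subject-level trajectory claims.
* One sex stratum per model; the API takes a sex filter rather than
  modelling sex jointly.
* Residual-df p-values and the count-ratio gW are faithful to the
  analysis this package operationalizes, not necessarily the choices a
  fresh design would make (GAMLSS/Gaussian-process normative backends are
  out of scope by design).
* The bootstrap holds spans fixed; span-selection variability is not
  propagated.
* `fit_loess` is O(n · q) per evaluation; cohorts of tens of thousands
  would want a compiled kernel.
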