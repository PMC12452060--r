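---
title: "Models and methods in immunokin"
author: "immunokin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in immunokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

immunokin implements the quantitative machinery needed to compare two
transplantable syngeneic tumor models functionally: Bayesian fitting of an
exponential (log-linear) tumor growth model across immunocompetent and
immunodeficient hosts, a posterior log-ratio summarising immune selective
pressure, two-parameter IC50 dose-response regression, and a control-based
null-envelope procedure for duplicate-spot antibody arrays. This vignette
explains each model, its assumptions, the tunable parameters, and the
design choices made where more than one reasonable implementation exists.

## The growth model

Subcutaneous tumor volume is modelled as pure exponential growth,

$$V_i(t) = C_{T0,i}\, e^{k t},$$

where $C_{T0,i}$ (mm^3) is the initial bolus of tumor-initiating cells of
mouse $i$ and $k$ (day^-1) is a net growth rate shared by every mouse in a
cohort. In a severely immunodeficient host (NSG) the net rate equals the
intrinsic proliferation rate $k_P$; in an immunocompetent host (C57BL/6)
it is $k_P - k_D$, where the single parameter $k_D$ absorbs every
immune-mediated killing mechanism present in the competent host and absent
in the deficient one. No carrying-capacity (Gompertz/logistic) term is
included: over the observable range (palpability to the humane endpoint)
growth is empirically log-linear, and richer models would not be
identifiable from 3-12 points per mouse.

Measurement error is multiplicative: observed $\ln V$ is Gaussian around
$\ln C_{T0} + k t$ with a cohort-shared standard deviation $\sigma$.
Caliper measurement error scales with tumor size, so constant variance on
the log scale is the natural error model, and it is what makes the
log-linear regression well-posed. A per-mouse $\sigma$ would not be
identifiable from three-point curves, so $\sigma$ is shared.

Two data-hygiene rules apply before fitting. Volumes at or below the
detection floor (default 1 mm^3) are excluded, because $\ln V$ is unstable
near zero and sub-palpable "measurements" are mostly noise; exclusion
counts are reported in the fit object. Right-truncation at euthanasia is
treated as missing-at-random: the likelihood simply ends where the series
ends, with no informative-censoring correction, matching how such curves
are analysed in practice.

Caliper pairs convert to volume via the standard ellipsoid formula
$\pi/6 \times \mathrm{length} \times \mathrm{width}^2$, with the longer
diameter as length (swapped with a warning if supplied reversed).

### Priors

The literature rarely states priors for this kind of fit, so immunokin
uses flat priors wide enough to be effectively non-informative at the
scales that matter:

* $k \sim U(-1, 3)$ day^-1 — allows shrinking tumors in immunocompetent
  hosts while bounding the sampler away from absurd rates;
* $\ln C_{T0} \sim U(\ln 10^{-3}, \ln 10^{2})$ mm^3 — spans sub-cell-pellet
  to ~100 mm^3 boluses;
* $\sigma \sim U(0.01, 2)$ — from near-noiseless to over-dispersed by any
  realistic standard.

All posterior summaries of interest sit well inside these bounds, so the
prior's only practical role is to keep the random walk in a sane region.

### The sampler

The posterior over $(k, \ln C_{T0,1..m}, \sigma)$ — at most ~15
parameters for realistic cohorts — is sampled by coordinatewise Gaussian
random-walk Metropolis, the simplest kernel adequate at this
dimensionality. Three features matter for correctness:

* **Adaptation only during burn-in.** Each coordinate's proposal scale is
  multiplied by $\exp(\hat a - 0.25)$ every 100 sweeps, where $\hat a$ is
  that window's acceptance rate; after burn-in (default 50% of steps) the
  scales freeze, so retained draws come from a fixed, valid kernel. The
  recorded scale trajectory lets tests assert the freeze.
* **Multiple overdispersed chains.** Three chains (minimum two) start from
  jittered, spread-out OLS estimates, enabling the Gelman-Rubin potential
  scale reduction factor. The convergence gate is PSRF $\le$ 1.1 on every
  parameter; failing fits are returned with `converged = FALSE` rather
  than an error so pipelines can retry with longer chains.
* **Effective sample size** uses the initial-positive-sequence truncation
  of the autocorrelation sum (stop at the first non-positive paired
  autocorrelation), capped at the retained length.

Default run length is 20,000 sweeps per chain, thinned by 5 after a 50%
burn-in. On the small posteriors in this package that yields thousands of
retained draws with PSRF typically below 1.01; examples and tests use
shorter runs (2,500-10,000 sweeps) because these posteriors are nearly
Gaussian and mix quickly.

### Immune pressure

Immune selective pressure is summarised as the posterior distribution of
$\ln(k_{NSG}/k_{C57})$. Because the two cohorts are fitted independently,
draws are paired by randomly permuting equal-length thinned samples from
each posterior (seeded, hence reproducible). Pairs with a non-positive
immunocompetent rate are rejected — the log is undefined there — and the
rejection fraction is reported; if every draw is non-positive the
statistic errors out. The companion quantity $k_D = k_P - k_{net}$ uses
the same pairing but is *not* clipped: negative $k_D$ (faster growth under
immune surveillance) is biologically meaningful and should be visible.

The natural logarithm is used throughout. Zero means no detectable
pressure; 0.195 — the value for the fast-growing model in the
comparison this package is built around — means the tumor grows about 22%
faster per day without adaptive immunity.

## The synthetic-data generators

The generators exist so that every downstream stage is testable without
animal data; they encode the statistical structure the fitters assume,
which is exactly what makes parameter-recovery tests meaningful — and
also their limitation (see *What passing tests do not show*).

**Growth cohorts.** Defaults were chosen once, to mirror the study design
the package targets: measurement every 2 days from day 4 (palpability) to
day 30; humane-endpoint ceiling 1500 mm^3 (euthanasia in such studies
occurs at 1000-1500 mm^3), implemented as right-truncation with no volume
above the ceiling emitted; detection floor 1 mm^3; per-mouse $C_{T0}$
lognormal with log-sd 0.5 around the cohort median, producing the fanned
but parallel log-scale curves seen in practice; and measurement noise
`noise_log_sd = 0.15`, i.e. ~15% caliper coefficient of variation,
mid-range for small subcutaneous tumors. Inoculum converts to volume at
$10^6$ cells/mm^3 — a convention, so a $3\times10^5$-cell inoculum is 0.3
mm^3 — used for forward predictions and documented wherever it appears.
A curve left with fewer than 3 points by truncation is an error by
default (`on_short_curve = "resimulate"` redraws the noise instead).

**Viability plates.** The generating curve is the same two-parameter
hyperbola the fitter uses; noise is additive Gaussian in percentage
points (default sd 5), clipped at zero, with 4 biological replicates per
dose. The assay's true error model is unstated in most reports; additive
percentage noise is the simplest adequate choice.

**Antibody arrays.** Each probe has a latent abundance (lognormal,
median 500 arbitrary units, log-sd 1.2). Per condition the probe's level
is observed once with heteroscedastic noise SD $= c\,\mathrm{level}^\gamma$
(defaults $c = 0.1$, $\gamma = 0.8$ — any monotone widening law the
envelope can track would do), then spotted twice with relative duplicate
jitter (default sd 5%). Differential probes multiply their condition-B
level by a fold change. Controls sit on fixed log-spaced ladders —
negatives 10-150, positives 300-10,000 — spanning the analyte abundance
range, because the whole point of the controls is to let the null
envelope be estimated wherever analytes live; 9 negative + 9 positive
controls give the binned envelope fit (4-8 bins of at least 3) a stable
basis.

## Dose-response fitting

The viability model is exactly the two-parameter form
$100(1 - x/(x + IC_{50}))$: no Hill slope, no floor/ceiling. Zero-dose
wells are included (the model predicts exactly 100 there). The fit
minimises the residual sum of squares over $\theta = \log IC_{50}$
(enforcing positivity) by golden-section search on a factor-of-1000
window around an initial guess — the dose whose mean viability is nearest
50%, falling back to the geometric mean of positive doses — and
cross-checks the optimum against a 400-point grid on the same window; the
`converged` flag requires agreement and an interior optimum. Plates in
which no dose brings mean viability below 90% are refused with the
diagnosis *insufficient inhibition* rather than returning an
extrapolated, meaningless IC50. Because the objective depends on
concentration only through $x/IC_{50}$, rescaling units rescales the
fitted IC50 exactly; a unit column is carried through I/O and never
implied.

## The array null envelope and z-scores

The comparison plot for two conditioned-media arrays puts mean abundance
(the average of the two conditions' duplicate-collapsed intensities) on
the x-axis and the A-minus-B difference on the y-axis, both on the raw
intensity scale — heteroscedasticity is handled by the envelope rather
than by transforming the data. The null envelope answers "how large a
difference does chance alone produce at this abundance?":

1. Control probes (positive and negative; analytes never contribute, so
   real differential signal cannot inflate the null) are sorted by mean
   abundance and cut into equal-count bins — between 4 and 8 bins with at
   least 3 members, adapting to the control count.
2. Each bin contributes its mean abundance and twice the standard
   deviation of its differences. Sample SDs of tiny bins are biased low
   on the log scale ($E[\log s] - \log\sigma =
   (\psi((m-1)/2) - \log((m-1)/2))/2 \approx -0.29$ for $m = 3$), which
   would systematically narrow the envelope and inflate every z-score by
   ~30%, so each bin SD is multiplied by the corresponding correction
   factor before fitting.
3. The half-width $h(x) = a x^b$ is fitted to (bin mean, 2 SD) by least
   squares on the log-log scale, with $b$ clamped at 0 so the envelope
   never narrows with abundance; if the unconstrained slope is negative
   the envelope falls back to the flat geometric-mean width.

Since $h(x)$ is twice the local null SD, the z-score is
$z = 2d/h(x)$ — the difference in SD units — and the dotted ~95% band
sits at $|z| = 2$. Significance is called at $|z| \ge 3$, the customary
threshold for this assay. Two optional normalization steps (rescaling B
so positive-control means match, and subtracting per-condition
negative-control means) are provided but off by default, since whether
membranes were normalized to each other before comparison varies between
laboratories; the procedure itself only needs the two arrays to be
comparable.

Two exact invariances follow from this construction and are tested:
multiplying every intensity on both arrays by a constant leaves every z
unchanged (both the differences and the fitted power law scale), and
swapping the conditions negates every difference and every z.

**Calibration and its limits.** With many controls the null z-scores are
close to standard Gaussian (empirically: sd within a few percent of 1,
$P(|z|>1.96) \approx 5$-6%). But the envelope is *estimated*, so z is a
ratio with a noisy denominator — a t-like statistic — and its extreme
tail is heavier than Gaussian: with 48 controls the null $|z|>3$ rate is
~0.6% rather than the idealised 0.27%, and with 18 controls ~1.4%. This
is intrinsic to any control-based envelope with realistic control counts,
not a defect of the fit; calibration tests therefore use 48 controls,
where envelope-estimation error is secondary to the tail being checked,
and treat the $|z|>3$ rate as bounded by 1% rather than equal to the
Gaussian value. Users should read $|z| \ge 3$ calls on arrays with few
controls as "merits follow-up", not as a calibrated p-value.

## Problem sizes in examples and tests

The test suite and the acceptance script run cohorts of 5 mice with
10,000-sweep chains (3 chains) for the headline recovery checks, 50
scaled-down cohorts (3 mice, 2,500 sweeps, 2 chains) for
credible-interval coverage, and 50 simulated array pairs for envelope
calibration. These sizes were chosen as the smallest at which the checks
are statistically meaningful: the headline posteriors have Monte-Carlo
error well below the tolerances being asserted, and the coverage and
calibration rates have binomial standard errors a few times smaller than
the margins they are compared against.

## What passing tests do and do not show

The generators produce data from exactly the models the fitters assume.
Parameter-recovery and calibration results therefore demonstrate that the
machinery is *correct* — the sampler targets the stated posterior, the
envelope tracks the injected noise law, seeds reproduce byte-identical
tables — but not that the models are *adequate* for any particular real
dataset. Real tumor growth decelerates near the humane endpoint,
euthanasia decisions are not blind to tumor size (informative
truncation), caliper error has an additive component at small volumes,
dose-response curves can have non-unit Hill slopes, and array spot
intensities saturate. Each of these would appear as model misfit (large
$\sigma$, structured residuals, unconverged IC50 fits) rather than being
silently absorbed.

## Known limitations

* A single rate per cohort: mouse-to-mouse rate heterogeneity is absorbed
  into $\sigma$ rather than modelled hierarchically.
* The log-ratio pairs *independent* posteriors; it does not model any
  shared batch structure between the two cohorts.
* The IC50 model cannot represent partial maximal inhibition; plates
  whose viability plateaus above 0% at high dose will show inflated
  residual sd.
* The envelope is a two-parameter power law; noise laws with a sharp
  regime change within the control range would be tracked only on
  average.
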