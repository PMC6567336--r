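---
title: "Non-invasive assessment of sea pen populations: models, generator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-invasive assessment of sea pen populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seapenbio)
```

## The problem

Sea pens (Pennatulacea) are soft-bottom octocorals that form dense fields
on Mediterranean muddy shelves. These fields are Vulnerable Marine
Ecosystems, yet the standard way to measure the size structure and biomass
of a population — bottom trawling followed by laboratory measurement — is
destructive. The red sea pen *Pennatula rubra* lives with its peduncle
(basal stalk) buried in the sediment; only the rachis, the polyp-bearing
upper part, is visible to a camera, so neither total length nor weight can
be observed directly on ROV video.

What *can* be counted on video is the number of pinnately arranged polyp
leaves, $n$. This package implements the biometric chain that turns leaf
counts into population-level quantities:

* linear size models $\hat l_r(n) = a\,n + b$ (rachis) and
  $\hat l_t(n) = a'\,n + b'$ (total length), fitted on the **max-side**
  leaf count;
* a cubic fresh-weight model
  $\hat w_f(n) = c_3 n^3 + c_2 n^2 + c_1 n + c_0$, fitted on the
  **mean-side** count (weight scales with tissue on both sides, length with
  the intact side), with a validity bound: the model is *not applicable*
  for $n \le 15$;
* a bivariate surface $\hat w_{2f}(n, l_r)$ adding rachis length to the
  cubic basis;
* a cubic dry-from-fresh weight model $\hat w_d(w_f)$;
* the goodness-of-fit metric used throughout, the RMS *relative* error
  $e = \sqrt{\tfrac1M \sum_i \big((\hat y_i - y_i)/y_i\big)^2}$;
* bias-corrected moment statistics (standard deviation, skewness $G_1$,
  non-excess kurtosis) for comparing leaf-count distributions between
  survey methods;
* the estimation pipeline: per-colony weights from ROV counts (zero for
  $n \le 15$), their mean $\hat w_{\text{mean}}$, and the total biomass
  $\hat w_{\text{tot}} = \hat w_{\text{mean}}\,\delta\,S$ for a density
  $\delta$ (colonies·m⁻²) over an area $S$ (m²).

Fitting is ordinary (absolute) least squares via `lm`; the relative error
is a reporting metric, not the fitting criterion. Both conventions are
computed so the distinction is always visible in the output.

## Moment conventions

Two standard deviations are reported: the bias-corrected form
($M-1$ denominator, `sd_corrected`) and the population form
($M$ denominator, `sd_uncorrected`); their ratio is exactly
$\sqrt{M/(M-1)}$. Skewness is the bias-corrected sample skewness
$G_1 = \frac{\sqrt{M(M-1)}}{M-2}\, m_3/\sigma'^3$ with
$m_3 = \tfrac1M\sum (n_i - \mu)^3$. Kurtosis is reported in the
**non-excess** convention — the bias-corrected excess kurtosis plus 3, so
a large normal sample tends to 3 — which is algebraically identical to

$$k = \frac{M-1}{(M-2)(M-3)}\Big[(M+1)\,\tfrac1M\textstyle\sum
\big(\tfrac{n_i-\mu}{\sigma'}\big)^4 - 3(M-1)\Big] + 3.$$

Constant samples report skewness and kurtosis as `NA`, never as
infinities. These estimators are deliberately re-derived rather than taken
from a contributed package so that the exact small-sample corrections are
pinned down; the test suite checks them against literal loop
implementations and the anchor value $k(\{1,2,3,4\}) = 1.8$ (the
Excel-style `KURT` plus 3).

## Default coefficients and a known misprint

The default model coefficients describe a trawl-sampled Mediterranean
*P. rubra* population: rachis $2.6\,n - 1.1$ mm, total $5.8\,n + 8.1$ mm,
dry weight $0.062 w_f^3 - 0.412 w_f^2 + 1.134 w_f - 0.416$ g. For the
fresh-weight cubic the leading coefficient is widely printed as $-0.013$
g/leaf³, which yields $\approx -122$ g at the typical count $n = 22$ —
irreconcilable with a measured mean colony weight around 2.4 g and with
the bivariate surface, which gives $\approx 2.47$ g at
$(n, l_r) = (22, 56.1)$. With $-0.0013$ the cubic gives 2.54 g at
$n = 22$, consistent with everything else, so the package defaults to the
sign/scale-corrected value $(-0.0013, 0.076, -1.170, 5.342)$. Because the
true coefficient cannot be recovered from summary statistics alone, all
coefficients are configuration, not constants.

Two further consequences of these defaults are worth knowing. The cubic
has an interior maximum near $n \approx 28.4$: predictions increase
strictly only up to $n = 28$ and decline slightly beyond, a reminder that
cubics extrapolate poorly. And the cubic is *negative* for mean-side
counts roughly between 10 and 12.5 — harmless in practice because the
model is not applicable at $n \le 15$ anyway, but it is why the synthetic
generator floors juvenile weights (below).

## What the synthetic generator emulates

No raw colony measurements are publicly deposited for this kind of
survey, so the package ships a first-class generator
(`generator_config()`, `generate_colonies()`) that emulates the study
conditions: a trawl sample of about 168 colonies over a 41,000 m² swept
area and an ROV observation set of 207 colonies.

**Leaf-count law.** Only four moments of the count distribution are
available (mean 22.0, sd 3.7, skewness −1.3, non-excess kurtosis 5.6 for
the trawl survey), not a distributional family. The generator therefore
uses a moment-matching cubic (Fleishman) transform of a standard normal,
rounded to integers and clamped at a minimum of 4 leaves (the published
samples' minima are unknown; the clamp is a documented guess and a config
field). Rounding and clamping attenuate the higher moments — by about 5%
in skewness and 10% in kurtosis at the default targets — so the continuous
moment targets are pre-calibrated by a deterministic fixed-point loop:
population moments of the discretised transform are computed by quadrature
over a normal grid and the continuous targets inflated until the
discretised moments match the requested ones (relative tolerance 10⁻³,
with a warning if 2% cannot be reached). With this calibration a sample of
20,000 counts reproduces all four targets within 1%.

**Sizes and weights.** Noise is multiplicative because the survey's
stated model errors are *relative*: Gaussian for lengths, mean-one
lognormal for weights (positivity). The lognormal $\sigma$ is chosen so
that the RMS relative deviation *in the package's error-metric convention*
(denominator = observed value) equals the configured fraction, i.e.
$e^{3\sigma^2} - 2e^{\sigma^2} + 1 = \text{noise}^2$; the naive
$\sigma^2 = \log(1+\text{noise}^2)$ would make a 46% noise level measure
as ≈60% under the metric, because the metric divides by the noisy
observation. Defaults are the published model errors: 11.8% (rachis),
10.6% (total), 46% (fresh), 19.2% (dry).

Because total length is generated as the sum of two independently noisy
parts (rachis plus peduncle), its relative error would come out *smaller*
than either part's if the peduncle simply carried the total-length noise.
The peduncle noise is therefore derived by variance decomposition — using
the length shares at the mean count — so that the *total* length carries
the configured 10.6% (peduncle relative noise ≈ 0.16 at the defaults).

Fresh weight is the cubic at the mean-side count times its lognormal
multiplier, floored at 0.01 g (one balance resolution unit); the generator
warns when the cubic itself is non-positive at a sampled count. Dry weight
is the dry cubic evaluated at the (noisy) fresh weight times its own
multiplier, kept strictly below fresh weight, and recorded as *not
measured* where the dry law is non-positive (fresh below ≈0.45 g).

**Survey views.** The trawl view applies logistic size selectivity: each
colony is retained with probability
$\text{logit}^{-1}\big((n - L_{50})\,k\big)$, defaults $L_{50} = 15$
leaves and $k = 0.8$ per leaf (invented but fisheries-typical), so small
colonies slip through the net. A population of 180 colonies yields about
168 retained, the study's sample size. The ROV view subtracts an
independent Bernoulli miss for each of the two terminal polyp leaves,
which are small and hard to resolve on video; the default miss probability
0.78 was calibrated once, deterministically, so that the simulated ROV
mean count sits near 90% of the trawl-sample mean — the gap the two
surveys actually showed (means 22.0 vs 19.9).

**What the generator does not emulate.** Fresh weight is drawn
conditionally independent of rachis length given the count, so the
bivariate surface model cannot beat the cubic on synthetic data the way it
did on the real survey (46% → 38.7%); the surface's machinery is fully
tested, but its error reduction is not a reproducible quantity here.
Likewise the ROV skewness shift (−1.3 vs −1.1) emerges only qualitatively:
left-truncating selectivity moves the trawl sample's skewness the other
way. Spatial structure, colony contraction dynamics, and video
segmentation are out of scope — ROV counts are inputs, not outputs of an
imaging model. Passing tests on synthetic data therefore demonstrate
correctness of the estimation machinery under the stated statistical
structure, not field validity of the biometric laws.

## The drying-protocol emulation

The dry-weight model is fitted on a subset of up to 54 colonies (the
study's drying protocol size), chosen deterministically to span the
fresh-weight range — colonies are ordered by fresh weight and sampled at
evenly spaced ranks between `dry_min_fresh` (0.8 g) and `dry_max_fresh`
(4.5 g). The window reflects measurement physics at both ends. Below
≈0.8 g fresh the dry law predicts under ≈0.2 g, within ~20 counts of a
0.01 g balance's resolution: relative residuals there are dominated by
quantisation and model misfit near the law's zero crossing (≈0.45 g
fresh), not by biological variability, and they inflate an RMS *relative*
error metric without bound. Above ≈4.5 g the cubic dry law approaches and
then (near 6.5 g) exceeds the fresh weight, so generated dry weights are
clamped and no longer follow the law. Within the window the refitted dry
model recovers the configured 19.2% noise level to within a few percent.

## Pipeline conventions

* The small-colony rule is applied at the pipeline level: predicted weight
  is exactly 0 for $n \le 15$ (the boundary is the model's
  `validity_min_n` and is configurable); `predict_fresh_weight()` itself
  returns `NA` (not applicable) there, so a model-level "don't know" is
  distinguishable from a pipeline-level zero. The report carries the count
  and fraction of zeroed colonies.
* ROV counts are single-side counts and are fed to the weight model as
  provided, mirroring how the method is applied in the field.
* Density $\delta$ may be supplied directly or derived as retained
  colonies / swept area; the report states which.
* Validation compares means only — the predicted mean weight against the
  trawl-measured mean — with signed relative error
  $(\hat w_{\text{mean}} - w_{\text{mean}})/w_{\text{mean}}$. With
  selectivity on, the prediction underestimates (the trawl mean is
  inflated by under-sampling of small colonies), reproducing the sign and
  mechanism of the roughly −22% validation error the survey comparison
  showed. On the synthetic defaults the pipeline's mean predicted weight
  comes out near 2.1 g against a measured mean near 2.6 g, i.e. an error
  around −20%.
* With a fixed seed the whole pipeline is deterministic; reports
  serialised twice are byte-identical. All randomness flows through one
  seeded stream; stochastic operations also accept an explicit `seed`.

## Numerical choices

* The Fleishman system is solved with `pracma::fsolve` from a published
  polynomial starting approximation; solutions are validated to residual
  10⁻⁶ and infeasible moment combinations (kurtosis ≤ skewness² + 1) are
  rejected before any sampling.
* Calibrated count transforms are cached per target-moment tuple.
* Length noise is resampled (up to 100 rounds) on the rare draws where a
  multiplicative Gaussian would make a length non-positive.
* Cubic and surface fits use the raw power basis via `lm.fit`; rank is
  checked via QR and deficiency reported as an explicit error (e.g. a
  rachis length exactly collinear with the count makes the surface basis
  singular — which is precisely what noise-free synthetic data produce).
* CSV writers serialise doubles at 17 significant digits and the JSON
  report writer at full precision, so both round-trip bit-exactly.

## Problem sizes

The shipped defaults and tests use the study's scales: populations of 180
(trawl view) and 207 (ROV view), 168-colony fit samples, a drying subset
of up to 54, and 20,000-draw samples for moment-calibration checks.
Replicate-based properties (confidence-interval coverage, selectivity
direction) use 100 seeded replicates.

## Limitations

* All coefficients describe one population in one season; nothing here
  validates their transfer to other *P. rubra* fields or other sea pen
  species with polyp leaves.
* The biomass estimate is a point estimate; no uncertainty interval is
  attached (a bootstrap over ROV observations would be a natural
  extension).
* The validity bound $n \le 15$ zeroes small colonies rather than
  modelling them; in juvenile-dominated populations the pipeline would
  understate biomass and the zeroed fraction in the report should be
  inspected.
* Moment comparisons between surveys are descriptive, as in the original
  analysis; no two-sample test is performed.
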