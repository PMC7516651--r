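---
title: "Entropy of thresholded extrema profiles: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy of thresholded extrema profiles: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmiqa)
```

## The model

Magnitude MR images degraded by shortened acquisition or channel noise are
characterized by isolated impulse-like intensity irregularities: single
pixels that stand above or below their surroundings by amounts a clean scan
rarely produces. The measure quantifies this directly. For each threshold
$t$ in $T = [1, 2, \dots, S]$, non-maximum suppression marks pixel $(a,b)$
as a local extremum when

$$\forall (i,j):\; I(a,b) > I(a+i,\, b+j) + t
  \quad\text{or}\quad
  \forall (i,j):\; I(a,b) < I(a+i,\, b+j) - t,$$

both branches strict, $(i,j)$ ranging over the pixel's 3×3 neighborhood.
Summing over the image gives the count $I(t)$; the sequence
$I(T) = [I(1), \dots, I(S)]$, divided by the image size, is the extrema
profile. The quality score is the Shannon entropy of the profile treated as
a counting measure over the threshold partition,

$$h = -\sum_{i: k_i > 0} k_i \log k_i, \qquad k_i = \frac{I(i)}{\sum_t I(t)},$$

so $h \in [0, \log S]$. The profile is non-increasing in $t$ by
construction. In a clean image almost all extrema sit at small thresholds:
mass concentrates, entropy is low. Impulse noise keeps generating extrema
at large $t$, flattening the distribution and raising the entropy, which is
why the score increases with distortion severity.

The assumptions worth keeping in mind: intensities are non-negative
integers in the native units of the source (thresholds are defined in those
units, so silently rescaling an image changes the measure); the disorder of
interest is local and impulse-like (smooth shading is invisible to the
test); and quality differences manifest as differences in how extrema
persist across thresholds, not merely in their number at $t = 1$.

## Parameters

* **S** (threshold count, default 30): the largest local intensity
  difference still examined, in intensity units. Performance is flat for S
  roughly between 20 and 60 on 8-bit-range data; 30 is the reference
  setting. For 16-bit-range intensities the meaningful S depends on the
  actual signal range, and no automatic adaptation is attempted — choose S
  in the units of your data, or use `rescale_to_8bit` at read time for
  cross-depth comparability.
* **Neighborhood** (4 or 8, default 8): with 4 axial neighbors, diagonal
  impulses escape suppression (a 0/255 checkerboard makes the difference
  stark: every interior pixel is an extremum under the 4-neighborhood,
  none under the 8-neighborhood). The full neighborhood discriminates
  quality better and is the method's setting; the 4-variant is exposed for
  sensitivity analyses.
* **Logarithm base** (natural, default): entropy is reported in nats with
  upper bound $\log S$; a base-2 option exists. All correlation-based
  evaluation is invariant to the base.

## Numerical and boundary choices

* **Borders.** The test is undefined where a neighbor falls outside the
  image, so the 1-pixel border is skipped rather than padded: padding
  would invent intensities and manufacture or suppress extrema at the rim.
  Counts therefore run over the $(M-2)(N-2)$ interior. Implementations
  that pad instead will differ by at most the border ring.
* **Plateaus.** Both branches are strict, so equal-valued neighbors never
  yield an extremum; a constant image has an all-zero profile.
* **Probability construction.** The entropy formula needs
  $\sum k_i = 1$, so the profile is renormalized by its own total; the
  image-size normalization then cancels exactly (tested to 1e-12). An
  all-zero profile would leave $k$ undefined; the score is defined as 0
  there — a flat image exhibits no intensity disorder.
* **Determinism.** Scoring consumes no randomness; repeated calls on the
  same bytes are bit-identical.

## The evaluation stack

Objective scores are compared with mean opinion scores through the usual
four criteria. PLCC and RMSE are computed after the five-parameter logistic
mapping $Q_p = \beta_1(\tfrac12 - \tfrac{1}{1+\exp(\beta_2(Q-\beta_3))})
+ \beta_4 Q + \beta_5$; SRCC and KRCC are rank-based and invariant to any
monotone mapping, so they are computed on raw scores.

* **Fit.** Levenberg–Marquardt least squares, initialized at
  $\beta_1 = \max(\mathrm{MOS}) - \min(\mathrm{MOS})$,
  $\beta_2 = 1/\mathrm{sd}(Q)$, $\beta_3 = \bar Q$, $\beta_4 = 0$,
  $\beta_5 = \overline{\mathrm{MOS}}$, tolerance 1e-8. The linear family
  is nested in the model ($\beta_1 = 0$), and the returned fit is never
  worse than the ordinary linear regression: if the nonlinear iteration
  ends above that baseline the baseline is returned. On weakly correlated
  data the sigmoid can wander on a flat residual plateau until the
  iteration cap; such a fit is returned (flagged `converged = FALSE`, with
  a warning) rather than raised as an error, because the parameters are
  still the best found and a hard failure would make whole-dataset
  benchmarking brittle.
* **Ties.** The classical Spearman closed form assumes none; with ties the
  implementation switches to Pearson on average ranks. Kendall is tau-a
  exactly as the concordant/discordant definition states: tied pairs count
  toward neither, the denominator is not corrected.
* **Jarque–Bera.** $JB = \tfrac{n}{6}(s^2 + \tfrac{(k-3)^2}{4})$ with
  method-of-moments skewness and kurtosis. The asymptotic $\chi^2_2$
  critical value overstates significance badly at bench sizes, so below
  n = 2000 the 5% critical value is simulated under the null (10,000
  replicates, cached per sample size, internally seeded).
* **Variance-ratio F test.** A normal distribution is fitted to each
  measure's residual vector, 1000 samples are drawn from each (explicitly
  seeded; the seed is part of the report), and the ratio of the resampled
  variances is referred to $F(999, 999)$. Both the two-sided decision
  (different variances) and the one-sided decision (first measure's
  variance smaller) are reported, since the substantive claim is usually
  one-sided. The test runs only after both residual vectors pass the
  Jarque–Bera screen, which is the condition for the F statistic to be
  meaningful.

  A caveat discovered while calibrating the test's size: the $F(999,999)$
  reference accounts only for the resampling stage. Sampling error in the
  fitted variances themselves is not propagated, so with short residual
  vectors (dozens of images) the procedure is markedly anti-conservative
  under the null — the analytic size at m = 70 is near 0.6, not 0.05.
  The calibration test therefore draws long residual vectors (1e5 per
  replicate), isolating the redraw-stage test, whose size does sit at the
  nominal 5%. Conclusions drawn from this test on small image sets should
  be treated as suggestive, not confirmatory.

## The phantom generator

The generator emulates what matters to this measure in a T2-weighted
slice: bright elliptical anatomy (a body ellipse, a brighter fluid-like
core with a mild intensity gradient, a small hypointense lesion) over a
near-black background, 8- or 16-bit, with noise added to the magnitude
image. Rician noise — $\sqrt{(A+n_1)^2 + n_2^2}$ with independent
zero-mean Gaussians — is the physically appropriate model for magnitude MR
data and reduces to Rayleigh in the background, which the tests verify
against the closed-form Rayleigh mean and variance. Rendering is
deterministic; all randomness is seeded per noise level.

What it does **not** emulate: parallel-imaging (GRAPPA-style) subsampling
artifacts, which are structured aliasing in k-space rather than i.i.d.
intensity noise; anatomy beyond ellipse composites; partial-volume and
bias-field effects; 3-D context. Passing the distortion-sensitivity tests
therefore shows the measure responds monotonically to Rician noise
severity on MR-like compositions — it does not by itself certify behavior
on clinical acquisition artifacts, which is what evaluation against real
scored datasets (the `evaluate` CLI pathway) is for.

Default study conditions used by the tests and the acceptance script:
128×128 phantoms, noise levels $\sigma \in \{5, 10, 20, 40\}$ on the 8-bit
scale spanning barely-visible to severe degradation, 20 replicates per
level; oracle-equivalence checks run on exhaustive 3–16 pixel images where
a literal triple-loop implementation is affordable.

## Known limitations

* Scores across different bit depths are not comparable without
  rescaling, since thresholds live in intensity units.
* The measure is blind to smooth, non-impulsive degradations (shading,
  low-frequency bias) by design.
* The polarity of the score (higher entropy = lower quality) is absorbed
  by the logistic mapping during evaluation; raw scores are reported
  without sign convention.
* DICOM files are not decoded; frames must be converted to PNG/TIFF with
  the rescale transform applied (`apply_rescale()` implements the
  arithmetic).
* The variance-ratio test's anti-conservativeness on small image sets,
  discussed above.
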