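# enmiqa

Blind (no-reference) image-quality assessment for 2-D magnetic resonance
images, with the full benchmarking stack used to validate quality measures
against radiologist opinion scores, and a synthetic MR phantom generator so
everything can be exercised without clinical data.

## The measure

Distorted MR scans are full of isolated impulse-like intensity
irregularities. The measure detects them by **thresholded non-maximum
suppression**: for each threshold *t* in the sequence *T* = [1, 2, …, S], a
pixel at (a, b) counts as a local extremum when it strictly exceeds every
neighbor by more than *t*, or lies strictly below every neighbor by more
than *t*,

    T(a,b,t) = 1  if ∀(i,j): I(a,b) > I(a+i, b+j) + t
               1  if ∀(i,j): I(a,b) < I(a+i, b+j) − t
               0  otherwise,

with (i, j) ranging over the 3×3 neighborhood (8 neighbors by default; a
4-neighbor variant is available). Summing the test over the image gives the
extrema count I(t), and the sequence I(T) = [I(1), …, I(S)], normalized by
the image size M·N, is the image's **extrema profile**. The quality score is
the Shannon entropy of the profile,

    h = − Σᵢ kᵢ log kᵢ ,   kᵢ = I(i) / Σₜ I(t) ,

in nats, bounded by [0, log S]. Clean images concentrate their extrema at
small thresholds (low entropy); noisy or artifact-laden images keep
producing extrema across many thresholds (high entropy). The reference
setting is S = 30 with the full 8-pixel neighborhood.

The evaluation stack implements the standard IQA benchmarking protocol:
a five-parameter logistic mapping
`Qp = β₁(1/2 − 1/(1+exp(β₂(Q−β₃)))) + β₄Q + β₅` fitted by nonlinear least
squares, PLCC and RMSE on the mapped scores, SRCC and KRCC (tau-a) on the
raw scores, a Jarque–Bera normality screen on the mapping residuals, and a
residual-resampling variance-ratio F test for comparing measures.

## Worked example

```r
library(enmiqa)

spec <- phantom_spec()                                   # 128x128 T2w-like composite
good <- add_noise(render_phantom(spec), "rician", sigma = 5,  seed = 11)
bad  <- add_noise(render_phantom(spec), "rician", sigma = 40, seed = 12)
enmiqa(good)
#> ENMIQA score 1.734452 nats (S = 30, nbhd 8, phantom_128x128_clean+rician(sigma=5,seed=11))
enmiqa(bad)
#> ENMIQA score 3.270202 nats (S = 30, nbhd 8, phantom_128x128_clean+rician(sigma=40,seed=12))
```

The lightly distorted image scores 1.73 nats, the heavily distorted one
3.27: its extrema profile stays populated far up the threshold sequence
(counts 3073, 2919, 2745, … at t = 1, 2, 3, …), spreading the distribution
and raising the entropy. Across a graded severity series the score rises
monotonically with the Rician noise level:

```r
series <- graded_series(phantom_spec(), sigmas = c(5, 10, 20, 40))
vapply(series, function(s) enmiqa(s$image)$value, numeric(1))
#> 1.7669 2.4087 3.0130 3.2716
```

Scores for real images: `read_image("slice.png")` (PNG/TIFF, 8- or 16-bit,
native intensity units; convert DICOM frames first, applying
`apply_rescale()` for the header's slope/intercept) then `enmiqa()`, or use
the CLI:

```sh
Rscript inst/cli/enmiqa.R batch --dir images/ --out scores.csv
Rscript inst/cli/enmiqa.R evaluate --scores scores.csv --mos mos.csv --out report.json
Rscript inst/cli/enmiqa.R sweep --dir images/ --mos mos.csv --S 5:100:5
```

`evaluate` joins the two CSVs strictly on `image_id` and emits the
four-criterion report (PLCC/SRCC/KRCC/RMSE, fitted β, residuals,
Jarque–Bera screen) as JSON — given a scored image set with mean opinion
scores this reproduces the full benchmarking protocol end to end.

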