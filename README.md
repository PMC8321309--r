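# pixelcov

Detecting invasive *Heracleum sosnowskyi* (Sosnowsky's hogweed) — or any
spectrally distinct land cover — in multiband satellite imagery, and
verifying the reliability of the resulting class map through the spatial
covariance structure of its pixel intensities.

`pixelcov` is aimed at remote-sensing and invasion-ecology analysts
working with visible-band scenes (e.g. Sentinel-2 B2/B3/B4 at 10 m) who
need both a classification and an internal check of it that does not
require field data.

## The method

**Classification.** Each land-cover class is summarised by its spectral
signature: the per-band mean intensity over a region of interest. Pixels
are assigned by *minimum distance* — the class whose signature mean μ_c is
nearest in band space:

    class(x) = argmin_c ‖x − μ_c‖₂

with an optional rejection threshold. Agreement with reference labels is
measured by overall accuracy and Cohen's kappa, κ = (p_o − p_e)/(1 − p_e).
An unsupervised alternative thresholds the *mean spectral signature*
(B3 + B4)/2 inside a window (spring hogweed sits near 950 DN; 800–1000 is
a practical window), removes 8-connected components below a minimum
mapping unit (5 px), and applies majority smoothing.

**Covariance verification.** The rectangular clip of each class is
column-stacked into a pixel vector φ, the mean trend φ̄ is removed
(δφ = φ − φ̄), and the covariance function is estimated over quantisation
intervals (lags) k = 0 … n/2:

    K(k) = 1/(n−k) · Σ_{i=1}^{n−k} δφ₁(uᵢ) · δφ₂(u_{i+k})

auto-covariance when φ₁ and φ₂ are the same vector, cross-covariance for
two classes. Normalizing by the vectors' standard deviations gives
correlation coefficients r(k) with r(0) = 1 for auto-series, and each
coefficient carries the standard error σ_r = (1 − r²)/√m from its m = n − k
pairs. Dense, spatially coherent cover (high chlorophyll, bright visible
response) keeps r(k) elevated over long lags, while spectrally mixed
classes decay toward zero — a qualitative fingerprint that distinguishes a
real target class from noise.

## Worked example

A synthetic three-class agricultural scene (stripes of hogweed / other
plants / agricultural land, class band means at realistic spring DN
values, 30 DN Gaussian noise with a 2-pixel correlation length):

```r
library(pixelcov)

spec <- scene_spec(120, 120, classes = list(
  list(class_label = "H. sosnowskyi",     mean = c(B2 = 473, B3 = 1090, B4 = 822),
       noise_std = 30, corr_length = 2),
  list(class_label = "other plants",      mean = c(B2 = 356, B3 = 870,  B4 = 816),
       noise_std = 30, corr_length = 2),
  list(class_label = "agricultural land", mean = c(B2 = 694, B3 = 1130, B4 = 1264),
       noise_std = 30, corr_length = 2)),
  layout = "stripes", seed = 42)
g <- generate_scene(spec)

sigs <- signatures_from_rois(g$scene, g$rois)
sigs[["H. sosnowskyi"]]
#> <spectral_signature> 'H. sosnowskyi' (200 px)
#>          B2      B3     B4
#> mean 476.60 1089.89 816.66
#> std   31.91   28.93  30.44
mean_signature_b3b4(sigs[["H. sosnowskyi"]])
#> [1] 953.345

pred <- min_distance_classify(g$scene, sigs)
cm <- confusion(pred, g$truth)
overall_accuracy(cm); kappa_coefficient(cm)
#> [1] 1
#> [1] 1

v <- detrend(extract_class_vector(g$scene, g$truth, "H. sosnowskyi", "B3"))
s <- normalize_series(covariance_series(v, kmax = 500), v)
s
#> <cov_series> auto-covariance of H. sosnowskyi, n = 4800, lags 0..500
#>   r: 1.00000 0.89967 0.68654 0.43508 0.21805 0.07545 ...
```

The recovered signature means sit within sampling error of the generating
values (e.g. 1089.89 vs 1090 in the green band), the classification is
perfect at this class separation (κ = 1), and the hogweed auto-correlation
starts at exactly 1 and decays smoothly — with a secondary peak at the
clip's column period (k = 40 here), the signature of column-stacking a
2-D field.

`run_pipeline()` drives the same stages from one YAML/JSON config and
writes the six series files `kfr1..kfr3` (auto) and `kfr12/kfr13/kfr23`
(cross) plus a hashed run report; `inst/cli/pixelcov` exposes each stage
as a shell subcommand.

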