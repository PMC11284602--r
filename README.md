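# strawpheno

Image-based strawberry phenotyping in physical units, built around
fiducial-marker spatial calibration.

Strawberry growers and researchers track a handful of phenotypic traits —
crown diameter (CD), plant height (PH), petiole length (PL), leaf area /
length / width (LA, LL, LW), flower area (Fl.A) and fruit area (Fr.A) —
because they predict vigor, dormancy and yield. Measuring them by hand is
slow, subjective and sometimes destructive. `strawpheno` implements the
measurement side of a camera-based alternative: a photograph contains the
plant part **and a square fiducial marker of known side length (4.7 cm)
held coplanar with it**; the marker's four corners determine a plane
homography that converts pixels to centimeters, and detections /
segmentation masks of the plant parts are turned into trait values in
their conventional units (mm for CD, cm for lengths, cm² for areas).

## The model

Let the marker corners be detected at image points $x_i$ and let
$X_i \in \{(0,0),(s,0),(s,s),(0,s)\}$ be the physical corners of the
$s = 4.7$ cm square. Four correspondences determine a projective map
$H \in \mathbb{R}^{3\times3}$ (direct linear transform, exact for 4
points) with

$$\lambda_i \, (X_i, 1)^\top = H \,(x_i, 1)^\top .$$

Any image point on the marker plane maps to metric plane coordinates
through $H$; distances and areas measured there are physical. Box traits
(CD, PH, PL) map box landmarks through $H$; mask traits (LA, LL, LW,
Fl.A, Fr.A) are counted on a rectified metric grid. A fruit-area → fresh
weight calibration $w = \beta_1 A + \beta_0$ (OLS; log–log variant
available) turns fruit area into a yield proxy, and the validation /
field statistics of such a tool are included: Pearson correlation with
RMSE and paired *t*-tests, detection frequency, 1-D k-means size
clustering (cluster 1 = largest), one-way ANOVA with Tukey HSD and
compact letter displays.

Detection and segmentation are **pluggable backends** behind two
generics (`detect()`, `segment()`): an *oracle* backend replays synthetic
ground truth and a *classical* backend finds color-coded parts by
thresholding + connected components. A trained-network backend can be
added behind the same contract. The package ships a synthetic scene
generator (`render_scene()`, `trait_scene()`) that renders marker +
plant-proxy scenes under arbitrary projective poses with pixel-exact
ground truth, so the whole pipeline is testable without photographs.

## Worked example

```r
library(strawpheno)

# a synthetic validation scene: marker + two fruit disks of 6.52 cm^2,
# viewed at a random tilt (<= 30 degrees)
sc <- render_scene(trait_scene("fruit", pose = random_pose(7), n_fruits = 2))
ms <- measure_image(sc$image, "FrA", classical_backend(), image_id = "demo")
measurements_to_df(ms)
#>   image_id trait    value units confidence   backend scale_cm_per_px
#> 1     demo   FrA 6.433180   cm2  0.9941660 classical      0.03438298
#> 2     demo   FrA 6.431112   cm2  0.9939197 classical      0.03438298
```

Both fruits are recovered within 1.4% of the true 6.52 cm² despite the
perspective distortion — the homography, not the raw pixel count, carries
the units. Fitting the weight model on a synthetic harvest of 310 fruits
(true slope 3 g/cm², intercept −1 g, noise SD 2 g):

```r
d <- generate_weight_dataset(310, slope = 3, intercept = -1, noise_sd = 2, seed = 42)
m <- fit_weight_model(d$area_cm2, d$weight_g)
m
#> weight = -0.9681 + 2.996 area  (R^2 = 0.976, n = 310)
predict_weight(m, 6.5)   # 18.51 g

p <- generate_validation_pairs(70, error_sd = 0.8, dropout_rate = 0.1, seed = 42)
validate_trait(p$measured, p$predicted, p$attempts, trait = "PH")
#> validation [PH]: n=66  r=0.988 (p=2.16e-53)  RMSE=0.695  t=1.673 (p=0.0991)  freq=94.3%
```

`validate_trait()` reports the Pearson *r* between conventional and
image-based values, the paired *t*-test for bias, and the detection
frequency (here 66 of 70 attempts = 94.3%).

## Command line

```sh
inst/cli/strawpheno generate  --trait fruit --seed 7 --out-prefix scene
inst/cli/strawpheno calibrate --image scene.ppm --out cal.json
inst/cli/strawpheno measure   --image scene.ppm --trait FrA --backend classical --out results.csv
inst/cli/strawpheno fit-weight --input pairs.csv --out model.json
inst/cli/strawpheno validate  --input val.csv --attempts 70 --out report.csv
inst/cli/strawpheno cluster   --input sizes.csv --k 3 --seed 1 --out clusters.csv
```

PNG input/output needs the optional `png` package; portable anymaps
(`.ppm`) work with no extra dependency.

## Scope and limitations

Measurements are valid only for content coplanar with the marker (the
capture protocol holds the part parallel to it); radial lens distortion
is not modelled (four points identify a projective map only); real QR
symbol decoding, network training and ripe/unripe fruit classification
are out of scope. See `vignettes/strawpheno-methods.Rmd` for the full
methods discussion.
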