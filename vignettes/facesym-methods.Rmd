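---
title: "Methods: variance-weighted facial symmetry scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance-weighted facial symmetry scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facesym)
```

## The measurement model

`facesym` quantifies *dynamic* facial asymmetry in peripheral facial
palsy: every expression image is compared against the same patient's
neutral face, so the score reflects how symmetrically the face *moved*,
not how symmetric it is at rest. The processing chain is deliberately
simple — landmark-based registration, masked absolute difference, heavy
smoothing, and a two-factor score — because each stage has an
interpretable role and the whole chain is cheap enough for real-time
feedback during rehabilitation exercises.

The core assumptions are:

* photographs are near-frontal and consistently lit, so a similarity
  transform (translation, rotation, isotropic scale) is sufficient to
  register expression to reference; out-of-plane head rotation is not
  modeled and will inflate apparent differences;
* a 478-point face-mesh landmark provider works reliably on palsy faces
  (the package treats the provider as a pluggable contract and validates
  only the point count);
* the facial midline estimated from landmarks (mean x of nose bridge,
  nose tip, lip centers, chin) is a valid mirror axis after registration.

## Scoring

With \(L_i\) and \(R_i\) the processed difference intensities of the
\(N\) valid left/mirrored-right pixel pairs inside the mask,

\[ S_\mathrm{mean} = 1 - \frac{1}{N}\sum_{i=1}^{N}
   \frac{|L_i - R_i|}{255}, \qquad
   S = S_\mathrm{mean}\left(1 - \min\!\big(\sigma^2/\sigma^2_\mathrm{max},\,
   1\big)\right). \]

Two numerical choices deserve a note. First, the mean absolute
difference is normalized by the 8-bit full scale (255): without this the
mean-difference term could go negative, while the score is defined on
\([0, 1]\). The variance \(\sigma^2\), by contrast, stays on the raw
0–255 scale, because the default ceiling
\(\sigma^2_\mathrm{max} = 5000\) is calibrated there (a left/right
difference pattern alternating ±70.7 gray levels is enough to zero the
score). Both constants are `score_config()` fields. Second,
\(\sigma^2\) is the *population* variance of the signed differences
(divide by \(N\)); at the pixel counts involved (tens of thousands) the
sample variance is indistinguishable. The score is computed on the
amplified, clipped difference map — the same raster the heatmap renders,
so a heatmap and its score always refer to the same data.

Pixel pairing uses the pixel-center convention (pixel \(j\) has center
\(j + 0.5\); coordinates are 0-based, origin top-left, y down). A pixel
column strictly containing the midline coordinate is excluded from both
halves to avoid self-pairing; when the midline falls exactly on a pixel
boundary (as with the bilaterally symmetric test template) every pixel
participates. Scoring errors out, rather than silently returning, when
no valid pair exists — e.g. a mask entirely on one side.

## Registration pipeline

* **Interocular scaling** multiplies image and landmarks by
  \(200/d_{33,263}\), the outer eye-corner distance. The landmark
  distance is exactly 200 px afterwards; the raster is resampled
  bilinearly. The operation is exactly idempotent.
* **Canvas centering** uses the offset \(\lfloor(\mathrm{ref} -
  \mathrm{src})/2\rfloor\) per axis (ties toward top-left); content
  beyond the canvas is cropped and landmarks shifted by the same offset.
* **Alignment** is a 4-degree-of-freedom least-squares similarity fit
  over all 478 correspondences, solved in closed form via the complex
  regression coefficient of centered destination on centered source
  points. Shear/anisotropy are excluded by design: the transform
  normalizes pose, and a full affine could partially "explain away" the
  asymmetric motion the score must measure. The estimator is exact on
  noiseless similarity-transformed sets (machine precision; the test
  suite verifies ≤ 1e-6 over 100 random transforms with scales 0.5–2 and
  rotations ±30°). Centering happens before alignment, matching the
  listed order of the processing steps; with the subsequent
  landmark-based alignment the choice is immaterial to the score.
* **Warping** samples the output grid through the inverse transform with
  bilinear interpolation and zero fill. Integer translations reproduce
  exact pixel shifts. Interpolation choice is immaterial downstream of a
  111×111 blur; bilinear is the cheapest smooth option.

## Blurs and the difference map

Gaussian kernels are specified by their side length \(k\), with
\(\sigma = 0.3\,((k-1)/2 - 1) + 0.8\) — the convention of the dominant
image-processing libraries, so stated kernel sizes fully determine the
blur. Borders are handled by reflect-101 padding: zero padding would
inject dark halos at the image edge directly into the score. Blurs are
separable two-pass convolutions, tested against a direct 2-D convolution
oracle; constants map to constants exactly.

The 5×5 pre-blur suppresses high-frequency texture (stubble, skin) that
would otherwise dominate the pixel difference; the 111×111 post-blur
absorbs residual misalignment while keeping the spatial pattern of
movement; the ×5 amplification with saturation at 255 restores dynamic
range (the smallest saturating smoothed difference is 51, since
51 × 5 = 255). Grayscale conversion uses Rec.601 luma weights
(0.299/0.587/0.114). The heatmap palette runs blue → cyan → green →
yellow → red with a monotone red (rising) and blue (falling) channel, so
hotter always means larger difference; 0 is pure blue, 255 pure red.

The **movement intensity** — the mean processed difference inside the
mask — guards the score's main failure mode: a hesitantly performed
expression moves little, differs little from rest, and therefore scores
*high*. Expressions below the `movement_intensity_min` threshold
(default 5 of 255; on the synthetic faces, genuine expressions measure
roughly 20–40 while a repeated neutral measures 0) are flagged but never
dropped — the heatmap remains the interpretive context.

## Mask

The mask is built from 9 landmarks (eye corners 33/133/362/263, nose
bridge/tip 1/0, lip centers 13/14, chin 152): a rectangle spanning the
padded eye-corner extent down to the midpoint between eye line and
padded chin, and a half-ellipse reaching the padded chin. Padding
defaults to 10% per side. The rectangle top rises 25% of the eye-to-chin
height above the eye line — far enough to cover the brow region on any
plausible face — because the *binding* upper boundary is the eyebrow
cut: everything above the lowest of the ten brow landmarks
(70/63/105/66/107/336/296/334/293/300) is removed, excluding hair and
forehead. The cut is a single horizontal line; rasterization is by
pixel-center inclusion, which makes mask construction exactly
translation-equivariant and mirror-symmetric for symmetric templates.

## Longitudinal analysis

Per-visit scores (mean over available expressions by default; median or
a single expression are config options — the choice of aggregate is
genuinely open, and the mean is the least committal) are filtered with a
centered rolling median, window 3. Series shorter than the window pass
through unchanged. At the series ends the window shrinks
*symmetrically* (size 1 at the outermost points): a shrunken
even-sized window would replace endpoints with two-point midpoints and
bias the ends of exactly linear series, which the symmetric rule leaves
invariant.

The trend is the Theil–Sen estimator — the median of all pairwise
slopes — over the examination index (0, 1, 2, …) by default; per-day
slopes are an option, but the ±0.001 classification threshold is
calibrated per examination step. Threshold comparisons are strict, so
boundary slopes conservatively count as no significant change.

Spearman's rank correlation (average ranks for ties) relates scores to
ordinal clinical grades (0–6). The default two-sided p value uses the
t-approximation \(t = r\sqrt{(n-2)/(1-r^2)}\), standard at the cohort
sizes this analysis targets; an exact permutation null is available for
\(n \le 8\), where full enumeration (≤ 40 320 permutations) is instant —
beyond that the approximation is the appropriate tool anyway.

## The synthetic face generator

Real patient photographs cannot ship with the package, so the generator
draws schematic faces — flat-shaded ellipses, bars and arcs for face,
eyes, brows, nose and mouth, plus mild mirrored texture noise — with an
analytic 478-point landmark template whose named mesh indices sit on
their features and whose remaining points lie on an interior face ring,
so whole-set alignment is genuinely exercised. Expression indices move
the protocol's feature groups: 2/3 close the eyes (gently/tightly), 4
frowns (brows pulled *down*, into the mask — a raised brow would leave
the masked region and with it most of the measurable signal), 5 wrinkles
the nose, 6–9 move the mouth. The unilateral-palsy dial \(a \in [0,1]\)
attenuates the image-right displacement by \(1-a\): \(a = 0\) yields an
exactly mirror-symmetric pair (noise included, since the noise field is
mirrored), \(a = 1\) freezes the right side up to noise.

Defaults — 320×400 px canvas, interocular 160 px (scaled ×1.25 by the
pipeline), displacement 14 px, noise sd 1.5 gray levels — were chosen
once as a plausible schematic of a clinical frontal photograph and a
clearly visible expression. What the generator does *not* emulate:
photographic texture and lighting variation, out-of-plane pose, facial
hair, landmark-detector noise (the replay provider returns the analytic
template verbatim), and synkinesis. Passing tests therefore validate the
*computational* contract of every stage, and the end-to-end property
that the score decreases monotonically with injected asymmetry for every
expression — not detector robustness on real faces.

## Problem sizes and determinism

The test suite runs everything at desk scale: score-oracle equivalence
on 1000 random ≤16×16 instances against a brute-force per-pixel
implementation (≤ 1e-12), alignment recovery over 100 random transforms
(noiseless ≤ 1e-6; with 0.5 px landmark jitter, scale/rotation and the
mapped centroid are recovered within \(3\sigma/\sqrt{478}\) in ≥ 95% of
runs — translation components are compared at the centroid because
their raw error is amplified by the centroid lever arm), the full
asymmetry grid \(a \in \{0, 0.25, 0.5, 0.75, 1\}\) across all eight
expressions, and Theil–Sen slope recovery (true slope 0.02, noise sd
0.005, n = 8) over 1000 seeds at a ≥ 95% within-0.01 rate. All
randomness is seeded; image generation is a pure function of its spec,
and dataset runs produce byte-identical tables on re-run.

## Known limitations

* The score conflates residual registration error with true asymmetry;
  large head movements between shots degrade it (mitigated, not removed,
  by the 111×111 blur).
* Low-movement expressions can score deceptively high; the flag and the
  heatmap are the guards, but no automatic rejection is attempted.
* The mask is a single region; per-feature sub-scores (eye vs mouth) are
  out of scope.
* Laterality (which side is palsied) is visible in the heatmap but not
  computed.
* Clinical-scale mapping (House–Brackmann, Sunnybrook, Stennert) is not
  attempted; grades are consumed as given integers for correlation only.
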