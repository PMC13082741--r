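---
title: "PolStokes: methods and design notes"
author: "PolStokes authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PolStokes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PolStokes)
```

## The instrument model

PolStokes models a transmission microscope performing full-Stokes
polarimetric imaging of stained blood smears, in two modalities: polarized
hyperspectral imaging (many narrow bands, here 470–750 nm) and polarized
light imaging (three broadband RGB channels treated as three crude bands).

The optical chain is: unpolarized source → polarizer 1 (transmissive axis
45°, the polarization state generator) → sample → LCVR 1 (fast axis 0°) →
LCVR 2 (fast axis 45°) → polarizer 2 (axis 0°, the polarization state
analyzer) → camera. Everything is expressed in Mueller calculus: light is a
Stokes vector $S = (S_0, S_1, S_2, S_3)^\top$ with $S_0$ the total
intensity, and each element is a $4 \times 4$ Mueller matrix
(`rotationMueller()`, `linearPolarizer()`, `variableRetarder()`).

Four retardance settings of the LCVR pair turn the fixed analyzer into four
different analyzers:

| label | LCVR 1 | LCVR 2 | acts as                    | measures            |
|-------|--------|--------|----------------------------|---------------------|
| Ih    | 0      | 0      | horizontal linear analyzer | $(S_0 + S_1)/2$     |
| Iv    | 0      | $\pi$  | vertical linear analyzer   | $(S_0 - S_1)/2$     |
| I45   | $\pi/2$| $\pi/2$| 45° linear analyzer        | $(S_0 + S_2)/2$     |
| Irc   | 0      | $\pi/2$| right-circular analyzer    | $(S_0 + S_3)/2$     |

from which the reconstruction (`computeStokes()`) is

$$S_0 = I_h + I_v,\qquad S_1 = I_h - I_v,\qquad
  S_2 = 2 I_{45} - (I_h + I_v),\qquad S_3 = 2 I_{rc} - (I_h + I_v).$$

The derived maps (`computeDerived()`) are the standard degrees of
polarization,

$$\mathrm{DOP} = \frac{\sqrt{S_1^2 + S_2^2 + S_3^2}}{S_0},\qquad
  \mathrm{DOLP} = \frac{\sqrt{S_1^2 + S_2^2}}{S_0},\qquad
  \mathrm{DOCP} = \frac{|S_3|}{S_0},$$

the only forms that are bounded by 1 and satisfy
$\mathrm{DOP} = \sqrt{\mathrm{DOLP}^2 + \mathrm{DOCP}^2}$ identically —
an identity the test suite asserts pixelwise.

### Sign conventions

Handedness conventions differ across the polarimetry literature, so the
package fixes them operationally: the retarder Mueller block acting on
$(S_2, S_3)$ is $\begin{pmatrix} \cos\delta & -\sin\delta \\ \sin\delta &
\cos\delta\end{pmatrix}$, chosen so that the (0, $\pi/2$) LCVR setting is a
*right*-circular analyzer, i.e. $2 I_{rc} - (I_h + I_v) = +S_3$ for
right-circular light with $S_3 > 0$. The frame rotation uses
$+\sin 2\theta$ in the $S_1$ row. Both conventions are cross-checked in the
test suite against an independent Jones-calculus oracle (coherency-matrix
transform with retarder $\mathrm{diag}(1, e^{i\delta})$).

## The synthetic phantom

No deposited image data exist for this kind of instrument, so the package
ships a first-class generator (`generatePhantom()`) emulating a
Wright's-stained blood-smear field. Each pixel carries a compact parametric
sample model

$$M_{\text{sample}}(x, y, \lambda) = t(x,y,\lambda)\;
  R\big(\theta(x,y), \delta(x,y)\big)\;
  \mathrm{diag}\big(1, d, d, d\big)(x,y,\lambda),$$

a transmittance times a weak linear retarder times an isotropic partial
depolarizer — the minimal model that produces contrast in all of DOP, DOLP
and DOCP. Because the illumination leaving the generator polarizer is fully
polarized, the exit DOP of a pixel equals its depolarization factor $d$
exactly; this is what makes the depolarization-monotonicity acceptance
check a sharp test.

Cell classes differ in morphology and in their depolarization
distributions:

* **granulocyte-like** (default mean $d = 0.5$): high-spatial-frequency
  granule speckle added to $d$ (zero-mean, amplitude
  `granuleDepolContrast` = 0.3, granule fraction 0.3), granules absorb
  slightly more;
* **lymphocyte-like** (mean $d = 0.3$): smooth low-amplitude surface
  texture (amplitude 0.05) in both $d$ and retardance, dense nuclear core;
* **monocyte-like** (mean $d = 0.4$): the large cell class, with a lobed
  nucleus (two offset ellipses, offset set by `nucleusLobedness`) of higher
  chromatin density. The monocyte mean sits between the other two classes;
  no sharper prior was available, and none of the quantitative checks
  depends on it.

The between-cell SD of $d$ is 0.05 for every class, so the
granulocyte–lymphocyte separation is four between-cell SDs — the regime the
15-vs-15 spectral discrimination experiment probes.

Transmittance follows Beer–Lambert, $t = \exp(-\rho(x,y) A(\lambda))$,
where $A(\lambda)$ comes from a Gaussian stain absorption band (baseline
transmission 0.92, depth 0.45, centered at 535 nm, width 30 nm) giving
every stained pixel the characteristic transmission minimum in the
520–550 nm region, and $\rho$ is the local chromatin density (cytoplasm 1,
granules 1.3, lymphocyte core 1.5, monocyte nucleus 1.8, background 0.05).
Each cell's density is additionally scaled by a random stain-uptake factor
(SD 0.1): real staining varies between cells, and without this the
between-cell variance of $S_0$ spectra would be implausibly small, making
$S_0$ an unrealistically strong class discriminator. The depolarization
factor falls linearly with wavelength by `depolDispersion` = 0.15 across
the grid (scattering weakens toward the red).

Measurement noise defaults to Gaussian with $\sigma$ equal to 1% of full
scale (the maximum noiseless intensity), applied independently per analyzer
image; a Poisson shot-noise model is available. At this noise level,
physicality violations ($\sqrt{S_1^2+S_2^2+S_3^2} > S_0$) appear only
where DOP is already close to 1 — the bright, weakly polarized background
sits tens of noise standard deviations below its $S_0$, so violations
there are essentially impossible. The physicality tests therefore exercise
the near-unity-DOP regime.

What the phantom does **not** emulate: optical blur and defocus, camera
fixed-pattern noise, chromatic registration errors between bands, LCVR
retardance dispersion (ideal, wavelength-independent retardances are
assumed), anisotropic or Mie-type angular scattering, and real chromatin
texture. Passing tests show the *pipeline* is correct and well calibrated
on data obeying the stated optical model; they do not certify performance
on real smears.

## Numerical choices

* **$S_0$ floor**: ratios are meaningless at dark pixels. The default
  floor is $10^{-3}$ times the 99th percentile of $S_0$, a relative
  threshold that avoids hard-coding a detector unit. Pixels at or below it
  are flagged invalid and set to 0.
* **Clipping**: noisy reconstructions can push the derived parameters just
  above 1. The default policy clips to 1 and counts the clipped values
  (`clippedCount()`); `flag` and `allow` keep the raw values.
* **Extrema ties**: a flat-topped plateau reports its shortest-wavelength
  band; endpoints are never extrema.
* **Degenerate t-tests**: if both groups are constant at a band, the test
  returns $p = 1$ for equal means and $p = 0$ otherwise, instead of
  erroring.
* **Cube files**: the primary on-disk format is ENVI-style float64
  (band-sequential, little-endian), which round-trips bit-exactly; the
  multi-page TIFF writer stores float32 scaled into [0, 1] with the affine
  scale in the JSON sidecar, so TIFF round trips are exact to float32
  precision only.
* **Seeds**: every stochastic operation is a pure function of its inputs
  and a seed; the pipeline derives its phantom and noise seeds from one
  master seed, and all derived seeds stay below $2^{31}$.

## RGB synthesis

The hyperspectral-to-RGB transform (`hsiToRGB()`) weights each band by
three response curves and sums. The default curves
(`buildDefaultResponse()`) are analytic piecewise-Gaussian approximations
of the CIE 1931 color matching functions — the red curve keeps its
short-wavelength lobe — clipped to nonnegative and normalized to unit sum,
so a spectrally flat cube renders gray. "Similar to the human eye's
spectral response" is the only constraint the instrument's description
imposes, and these curves are the standard analytic realization of it.
Signed planes ($S_1$–$S_3$) are affinely shifted to [0, 1] per plane
before weighting, with the shift recorded in the image provenance. Display
normalization defaults to per-channel percentile-99 scaling, robust to hot
pixels; plane-joint normalization (to make the four Stokes renderings of
one cell comparable) is available as `norm = "global"`.

## Spectral statistics

ROI spectra are arithmetic means over binary cell masks, one value per cell
per band, excluding all background pixels. Group comparison uses a
two-sided two-sample *t*-test per band on those per-cell means — never on
pooled pixels, which would pseudo-replicate. Welch's unequal-variance form
is the default (per-class variances are unknown; the pooled-variance form
is available via `varEqual = TRUE`). Raw p-values are the primary output,
matching how per-band significance is conventionally read against
$\alpha = 0.05$; Benjamini–Hochberg adjusted values are reported alongside,
never replacing the raw series. Spectrum normalization (max or area) is
available for display but is *not* applied before testing by default.

## Problem sizes used in the checks

The packaged experiments are desk-scale by design: the discrimination
experiment uses one 280×280-pixel field with 15 granulocyte-like and 15
lymphocyte-like cells over 29 bands; the type-I calibration runs 500
replicates of a 110×110 field with 30 same-class cells over 5 bands,
splitting them 15/15 at random; monotonicity uses six depolarization
levels on a single-cell scene. These sizes give stable Monte-Carlo
estimates (binomial SE of the rejection rate ≈ 0.01 at 500 replicates)
while keeping the whole suite fast.

```{r example, eval = FALSE}
cfg <- runConfig(phantom = phantomSpec(seed = 1), seed = 1,
                 outDir = "run1")
res <- runPipeline(cfg)
res$tests$DOP_granulocyte_lymphocyte   # per-band Welch p-values
```

## Known limitations

* The instrument is simulated as ideal: perfect polarizers, exact LCVR
  retardances (an optional per-band retardance table is future work), no
  objective-induced polarization aberrations.
* Only Stokes imaging is modeled — the sample's full 16-element Mueller
  image is never estimated, and no Lu–Chipman decomposition is provided.
* ROI masks come from ground truth; there is no automatic segmentation.
* The RGB-mode (PLI) path treats the three color channels as three
  broadband bands through the same arithmetic; channel cross-talk of a
  real Bayer sensor is not modeled.
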