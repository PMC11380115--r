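---
title: "Models and methods behind lsmtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lsmtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lsmtools)
```

`lsmtools` is a computation stack for home-built light-sheet microscopes
(LSM/SPIM): design calculators for the illumination optics, a synthetic
acquisition simulator, the calibration procedures a builder runs before
collecting data, the static 3D reconstruction chain, and an fcsSOFI engine
that turns per-pixel intensity fluctuations into diffusion maps fused with
super-resolved structure. This vignette explains the models implemented,
the conventions and tunable parameters, what the simulator does and does
not emulate, and the numerical choices made where the procedures were
genuinely open.

## Optical design calculators

All beam-level lengths are in micrometres; objective- and camera-level
wavelengths are accepted in nanometres and converted at the API boundary.
Angles are radians internally, degrees at user-facing boundaries.

**Gaussian beams.** The intensity profile is

$$I(r,z) = \frac{I_0}{2\pi\omega_{0g}^2\left(1+(z/z_{Rg})^2\right)}
  \exp\!\left(\frac{-2r^2}{\omega_{0g}^2\left(1+(z/z_{Rg})^2\right)}\right),
  \qquad z_{Rg} = \frac{\pi \omega_{0g}^2 n}{\lambda},$$

with the confocal parameter $b_g = 2 z_{Rg}$ setting the usable sheet
length, and $\omega(z)=\omega_{0g}\sqrt{1+(z/z_{Rg})^2}$ the spreading
function. The prefactor above is implemented exactly as written even though
it is inconsistent with reading $I_0$ as the beam's maximum intensity (the
on-axis value at the waist is $I_0/2\pi\omega_{0g}^2$); a peak-normalized
accessor (`normalize = "peak"`) is provided. Every quantity the package
reports from this profile is an intensity *ratio*, which both conventions
agree on. The waist-divergence relation $\omega_{0g}=\lambda/\pi\theta$
uses the far-field approximation without correction terms.

**Bessel beams from an axicon.** The printed axicon-parameter expression is
typographically garbled in common renderings; we interpret it as the
deflection through the base angle of a cone of apex angle $\tau$ and index
$n$: $\alpha_0 = (n-1)(\pi-\tau)/2$. The profile carries
$J_0^2(k r \sin\alpha_0)$ radially and the propagation envelope
$\propto (z/b_b) e^{-2z^2/b_b^2}$ with $b_b = \omega_{0g}\cos\alpha_0 /
\sin\alpha_0$. The `AxiconSpec` constructor accepts $\alpha_0$ directly for
users who know their deflection angle.

**Airy beams.** The exponentially apertured Airy profile needs the Airy
function at complex argument $x/x_0 - z^2/(4k^2x_0^4) + i a z/(k x_0^2)$.
No installed numerical library exposes complex $\mathrm{Ai}$, so `airyAi`
evaluates the entire-function Maclaurin series
$\mathrm{Ai}(z) = c_1 f(z) - c_2 g(z)$; cancellation limits accuracy to
roughly $|z| \lesssim 9$, which comfortably covers the main-lobe region
where beam-profile evaluation happens. The propagation-length grouping
$b_{Ai} = \tfrac12\sqrt{2\ln 2}\,2\pi n \omega_{0g}^2/(\gamma\lambda)$ is
one defensible reading of an ambiguously printed expression, so it is
isolated behind the `grouping` argument of `airyPropagation` and can be
swapped without touching callers.

**Lens trains.** `propagateTrain` applies the focused-diameter relation
$2\omega_z = 4 f \lambda M^2 / (\pi\,\omega(z))$ element by element, with
$\omega(z)$ the beam radius arriving from the upstream focus. Cylindrical
elements update a single transverse axis, which is how an anisotropic sheet
(width × thickness) emerges from a round input beam.

**Objectives, sampling, depth of field.** $f_{obj}=f_{tl}/M$;
$R_{x,y}=\lambda/2NA$; $R_z = 2\lambda/NA^2$; $P_I = P_P/M$; and
$DOF = \lambda n/NA^2 + n P_I/(M\,NA)$. Two editorial notes a user should
be aware of: published prose sometimes swaps the lateral/axial labels on
the resolution formulas — we follow the formulas; and for the modeled
40×/NA 0.8 system the DOF is quoted in different places as 1.20 and
1.44 µm — the calculator reproduces 1.20 µm from the formula above, and we
treat the other figure as an upstream inconsistency. Similarly, the
expected bead extents in the pixel-size calibration table are consistent
with the image pixel 0.163 µm (the rounded 6.5/40) rather than the
"ideal 160 nm" a footnote mentions; the package default is the exact
$6.5/40 = 0.1625$ µm.

## The synthetic acquisition simulator

The simulator exists so that every downstream stage is testable against
known ground truth. It emulates two experiments: a fluorescent-bead
calibration standard (0.25–2 µm beads in an index-matched gel) imaged
through a tilted sheet, and movies of point emitters diffusing at
1–30 µm²/s, emulating a 155 kDa dextran tracer in 2 wt.% agarose.

The forward model, per stage position $k\,\Delta z$:

1. each emitter is weighted by the sheet's Gaussian axial profile
   $\exp(-2 d^2/\omega^2)$ with $\omega$ = thickness/2 (thickness is the
   full 1/e² width, matching the Gaussian-waist convention);
2. it is shifted laterally by $(k \Delta z\, s_x,\; k \Delta z\, s_y)$ —
   the ground-truth skew of the tilted-sheet geometry, with
   $s_x = \tan(90^\circ - \phi)$ for sheet angle $\phi$;
3. a bead of diameter $b$ is rendered as a Gaussian blob of FWHM $b$
   (approximating a filled sphere's projection, consistent with treating
   bead images as PSF-broadened spots), combined in quadrature with the
   detection PSF;
4. the spot is rasterized at the image pixel size by 4× supersampling and
   area binning (not centre sampling), which keeps sub-pixel centroids
   stable for the calibration tests;
5. camera noise is applied: Poisson shot noise, Gamma-distributed EM gain
   for EMCCD (which realises the ≈√2 excess noise factor), Gaussian read
   noise, and offset. `kind = "none"` is a deterministic pass-through.

Diffusion movies use per-frame Gaussian steps of per-axis sd
$\sqrt{2 D\,\Delta t}$. Walkers live in a domain 2 µm wider than the field
of view on every side, at the same areal density, and reflect at the domain
boundary; without the margin, the reflecting wall sits inside the
observation region and measurably distorts edge-pixel correlation times.
An optional porosity mask confines walkers by step rejection — the
simplest rule that produces the confinement effect a gel imposes.
All randomness flows from one explicit seed per call; no global RNG state
is consumed or leaked.

Default parameter choices for the emulated study: frame interval 2 ms (the
modeled camera exposure), 5000-frame movies, ~40 walkers per FOV at
300 detected photons per frame per emitter, sCMOS read noise 1.6 e⁻ rms
with offset 100. The rendered PSF sd defaults to 0.25 µm: the nominal
NA 0.8 / 575 nm PSF would be sharper (≈0.15 µm), but the modeled
instrument's under-filled back pupil reduces its effective NA, and 0.25 µm
represents that effective, slightly degraded PSF. These were fixed as the
study conditions before the recovery experiments were run.

What the simulator does *not* emulate: rolling-shutter timing, striping and
shadowing in scattering samples, refractive-index-mismatch aberrations,
photobleaching, and 3D (out-of-sheet) walker motion. Passing tests
therefore demonstrate correctness of the computational chain under the
stated forward model, not robustness to every artifact of real data.

## Calibration procedures

**Bead localization.** The upstream workflow delegates localization to
external software, so the package implements a standard, testable chain:
threshold → local maxima with non-maximum suppression over the fit window
→ least-squares symmetric 2D Gaussian fit (amplitude, centre, sd,
constant background) via Levenberg–Marquardt. FWHM $= 2\sqrt{2\ln 2}\,
\sigma$. Fits that diverge, leave the window, or return non-positive widths
are dropped and counted.

**Pixel size.** Each localization of a bead of known diameter gives one
sample $P_{I,i} = \text{diameter}/\text{FWHM}_i$; the estimate is the mean
± sd with $n$ reported. Note this estimator inherits the PSF broadening of
the bead image: with a 2 µm bead and a ≈0.36 µm-FWHM PSF the bias is below
1%, which is why large beads are the right standard for this measurement.

**Axial skew.** Bead centroids are tracked across a z-series by
nearest-neighbour linking and each track's displacement (µm, via the pixel
size) is regressed against stage travel; the slopes are $(s_x, s_y)$.
The linking gate defaults to $\Delta z/P_I + 3$ px — the worst-case
45°-sheet shift per slice plus localization slack. (A fixed few-pixel gate
fails here: with a 5 µm step and 0.1625 µm pixels the *expected* skew shift
is already ~13 px.) The sheet angle follows from
$\phi = 90^\circ - \arctan(\Delta x_{img}/\Delta z)$: the measured 2.2 µm
shift per 5 µm step gives 66°, not the intended 45°. The y-skew is
estimated empirically by the same slope fit rather than predicted
trigonometrically, since the geometric construction behind the predicted
y-shift depends on instrument details not exposed here.

**Sheet dimensions.** A beam-profiler image is reduced to its intensity
second-moment principal axes; 1D profiles through the centroid along each
axis give the two FWHMs, converted to the sample plane by the profiler
pitch and the objective demagnification. Principal axes (rather than array
axes) are used because the profiler need not be aligned with the beam.

## Static reconstruction

The pipeline order is fixed as import/ROI → de-skew → deconvolve →
threshold → assemble, the order the acquisition corrections are described
in. Conventions: (row, col) = (y, x); z increases with stage travel; ROI
bounds are user-facing inclusive; de-skew translates slice $k$ by
$(-k\Delta z\, s_x/P_I, -k\Delta z\, s_y/P_I)$ px with bilinear
interpolation, and the vacated margins are filled with NA — a sentinel that
every downstream statistic (tile backgrounds, line sections) excludes, so
margins cannot bias thresholds.

**Deconvolution.** Among the iterative deconvolution family we implement
Richardson–Lucy: multiplicative, nonnegativity-preserving updates computed
in the frequency domain with reflective boundary padding; default 20
iterations with early stop when the mean relative update falls below 1e-4.
The 3D PSF is a separable Gaussian built from the measured lateral FWHM
and an axial FWHM in slices, unit-sum by construction.

**Background thresholding.** Per-tile (default 16 px) mean + 3·sd maps,
bilinearly interpolated between tile centres and subtracted with clamping
at zero. Tile statistics are computed on raw counts including any emitter
pixels — whether the upstream procedure excludes emitters from its
background statistics is unstated, so the simplest (raw) choice is used
and documented; for sparse emitters the contamination of a 256-pixel tile
by one spot is small and quantified in the tests.

**Volume assembly and line sections.** Assembly is pure bookkeeping: the
(rows × cols × slices) voxel grid is scaled by $(P_I, P_I, \Delta z)$ and
never resampled. Line sections sample bilinearly (trilinearly through
volumes) and report the FWHM of the largest peak in physical units, with
an explicit undefined flag when no peak rises above half of
(max − baseline).

## fcsSOFI dynamics

**Autocorrelation.** $G(\tau) = \langle\delta F(t)\,\delta F(t+\tau)\rangle
/\langle F\rangle^2$. Lags are placed on the standard multi-tau
(pseudo-logarithmic) grid, but the value at each lag is computed with the
exact FFT estimator rather than by octave binning: the full series is in
memory, so the hardware-correlator approximation would only add bias. The
estimator consequently agrees with a direct $O(N^2)$ correlator to
machine precision, which the tests assert.

**Model fits.** Weighted (√samples-per-lag) Levenberg–Marquardt fits of
the 2D diffusion models $G_0/(1+\tau/\tau_D)$,
$G_0[f/(1+\tau/\tau_{D1}) + (1-f)/(1+\tau/\tau_{D2})]$, and
$G_0/(1+(\tau/\tau_D)^\alpha)$. Initialization comes from curve heuristics
($G_0$ from the first lag, $\tau_D$ from the half-amplitude lag);
$\tau_D$ is bounded by the frame interval and ten times the largest lag;
non-convergence is reported honestly, never silently patched.

An optional additive baseline $G_\infty$ (`baseline = TRUE`, used by the
per-pixel pipeline) absorbs a known finite-series artifact: subtracting the
*sample* mean depresses the measured correlation by roughly
$2 G_0 \tau_c / N$ at all lags. At 5000-frame movies with correlation
times of tens of frames this offset is a few percent of $G_0$, enough to
shorten the fitted $\tau_D$ — and hence inflate $D$ — by tens of percent
if unmodelled. The baseline is a nuisance parameter reported as an
attribute, not part of the diffusion model itself.

**Diffusion maps.** $D = \omega^2/(4\tau_D)$ per valid pixel. The
convention for $\omega$ matters: it is documented here as the **1/e²
radius of the Gaussian PSF intensity profile** ($\omega = 2\sigma =
\mathrm{FWHM}/1.177$). With the imaging-FCS derivation, a PSF of sd
$\sigma$ gives $\tau_D = \sigma^2/D$, so this convention is the one under
which $\omega^2/4\tau_D$ returns the true $D$; reading $\omega$ as the
plain sd would systematically under-recover $D$ fourfold. Users fitting
their PSF should pass `omega = 2 * sigma_fit`.

**Per-pixel validity.** In `fcsSofiSlice` a pixel's fit is masked when the
pixel is dimmer than 5% of the brightest mean intensity; when its
short-lag correlation does not rise at least three tail standard
deviations above the tail (no resolvable decay at all); when the fit
fails, pins to the frame-interval bound, or returns a $\tau_D$ longer than
the largest measured lag (a decay that was never observed); or when the
fitted amplitude does not exceed five times the residual noise floor of
its own curve. Together these reject immobile or empty pixels, whose
correlation is flat noise. Masked pixels are excluded, never
interpolated.

**XC-SOFI.** Second-order cross-correlation at one-frame lag on an
interleaved (2×) grid: native pixels carry their autocorrelation, virtual
pixels at horizontal/vertical midpoints carry the symmetrized neighbour
cross-correlation, and diagonal midpoints average the two diagonal pairs.
The exact pixel-pair combination scheme (and any distance-factor
correction) used by upstream implementations lives in prior literature,
so this neighbour scheme is documented as this package's choice. Negative
correlation values are clamped to zero with the clamped fraction logged.

**Fusion.** Hue encodes $\log_{10} D$ clipped to a configurable range
(default 0.1–100 µm²/s, blue → red); saturation marks fit validity; value
is the SOFI image normalized to its 99.5th percentile. One fused image per
slice movie is produced, consumable by `assembleVolume`.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which each statistical property is stable:
bead stacks of 4–6 slices at 96–160 px, diffusion movies of 16×16–24×24 px
× 5000 frames with ~40 in-view walkers, deconvolution fixtures of ≤ 33³
voxels, and 100-seed Monte-Carlo loops for fit-noise properties. Key
tolerances: kernel normalization to 1e-9; correlator-vs-oracle agreement
to 1e-10; quadrature power conservation to 1e-6 relative; RL interior flux
drift ≤ 1%; deskew inversion < 0.1 px RMS. Degenerate inputs have defined
behaviour: all-zero volumes return unchanged with a warning, zero-mean
series are rejected, flat line sections flag their FWHM undefined, and
invalid FCS fits are masked pixels rather than errors.

## Known limitations

- The Airy-profile series loses accuracy for $|z| \gtrsim 9$ characteristic
  lengths; far-sidelobe work would need a rotated-contour evaluation.
- The RL stopping rule is a mean-relative-change heuristic; no automatic
  regularization or iteration-count selection is attempted.
- Pixel-wise FCS fits at realistic photon budgets are noisy; the median
  over a region is the robust summary the package reports in its own
  validation, and single-pixel values should be read with their mask.
- The simulator's diffusion is in-plane only; out-of-sheet excursions
  shorten real residence times slightly relative to the 2D model.
- `estimatePixelSize` inherits PSF broadening of the bead image (small for
  large beads, material below ~0.5 µm bead diameter).
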