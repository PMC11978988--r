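---
title: "flowSIM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flowSIM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowSIM)
```

flowSIM is a desk-scale digital twin of an integrated optofluidic imaging
flow cytometer that combines light-sheet illumination, structured
illumination microscopy (SIM) and flow-scan volumetric acquisition. Two
coherent beams emerge from on-chip waveguides at a semi-angle and interfere
inside the microfluidic channel, writing a sinusoidal intensity pattern onto
a thin light sheet. A resistive thermal shifter on one interferometer arm
steps the pattern phase; cells flow through the patterned sheet at constant
speed, and every three consecutive camera frames (phases 0, 2π/3, 4π/3)
encode one object plane at super-resolution along the modulation axis. This
vignette records the models, the tunable parameters, and the numerical and
design decisions behind the implementation.

## Optical forward model

**Fringe period.** Two plane waves crossing at semi-angle θ in a medium of
index *n* interfere with period *p* = λ / (2 *n* sin θ). The geometry is
defined inside the fused-silica chip, so the default uses *n*~chip~ = 1.458
with λ = 561 nm and θ = 15°, giving 743.3 nm. No standard index choice
reproduces the 754 nm sometimes quoted as the theoretical value for this
geometry (water immersion gives 813.0 nm), so the package records the
closed form via `pattern_period()` but standardizes all simulation and
reconstruction defaults on the *measured* period of the physical device,
791 nm, stored as `period_nm` in `optical_config()` and returned by
`carrier_period()`. Setting `period_nm = NULL` falls back to the closed
form.

**Illumination.** `pattern_intensity()` is the normalized sinusoid
1 + *m* cos(2π x / p + φ). The modulation depth *m* is not published for
the device (the raw fringe images show imperfect contrast); the default is
*m* = 0.8 and every piece of reconstruction math works for any
*m* ∈ (0, 1].

**Phase shifter.** The optical phase is proportional to the dissipated
electrical power, hence quadratic in the drive voltage for constant
resistance: φ(V) = φ~ref~ (V/V~ref~)², anchored at 4π/3 for 5.86 V and
zero at 0 V. Inverting the law puts the 2π/3 step at 5.86/√2 ≈ 4.14 V,
which rounds to the instrument's printed 4.15 V. The documented 0.18 %
peak-to-peak electrical stability is carried as metadata
(`drift_ppk`) and not simulated: at that level its effect on a 3-phase
cycle is ~2 mrad, far below every other error source modelled here.

**Light sheet.** The actual cylindrical-lens profile is unpublished; the
sheet is modelled as a Gaussian beam anchored at the 1.1 µm focal FWHM,
with Rayleigh range z~R~ = π w₀² n~medium~ / λ. This predicts 3.55 µm at
±20 µm from focus, against 3.4/3.2 µm for the physical-optics design —
agreement within 10 % of the prediction, which is all the anchor is used
for. The model is symmetric where the real lens is slightly asymmetric.

**Detection.** Widefield imaging through a 1.15 NA objective at 60×
total magnification (108.3 nm object pixels). The incoherent OTF is the
analytic circular-pupil autocorrelation with cutoff k~c~ = 2 NA / λ~em~ =
3.833 µm⁻¹ at the 600 nm emission proxy for the Alexa 594 channel
(the emission wavelength is not printed; 600 nm is a round configurable
default). The carrier at 791 nm extends the support along the modulation
axis to k~c~ + 1/p = 5.098 µm⁻¹, a theoretical 1D gain of 1.330.

**Geometry.** Frames are (row = y, col = x) images of the sheet plane;
x is the modulation axis and the sheet propagation direction (thickness
grows with |x| via the Gaussian-beam law), and z is the flow/sectioning
axis along which the sheet is thin. Pixel centres sit at integer
coordinates with the origin on the FFT centre pixel. Note that the
object-side pixel (108.3 nm) slightly undersamples the *extended* SIM
cutoff (Nyquist would need 98.1 nm); `validate_sampling()` reports this,
and the reconstruction sidesteps it by synthesizing the output on a 2×
upsampled grid.

## Synthetic data

Phantoms are explicit emitter lists (x, y, z, brightness in expected
photons/frame at the focal sheet), pure functions of their parameters and
seed:

* `make_dye_phantom()` — homogeneous Poisson emitters, the proxy for the
  rhodamine solution used in fringe calibration. Because the real dye is
  continuous, the discrete proxy must be dense enough that its spatial
  granularity stays well below the fringe modulation; the calibration
  scenario uses 100 emitters/µm³, at which the residual texture on a
  rep-averaged line profile is a few percent of the 80 % modulation.
* `make_cell_phantom()` — a uniform spherical shell (membrane label, as in
  WGA-conjugate-stained cells) plus Gaussian vesicle clusters
  (SD 0.25 µm, sub-diffraction, to exercise the resolution gain). Cell
  size is not printed in the characterization; the default radius of
  7.5 µm makes one cell span ≈15 µm of flow, consistent with 15 planes
  per cell at the native plane spacing and 40 cells/min at 10 µm/s.
* `make_bead_phantom()` — minimum-separation point emitters (dart
  throwing) for resolution metrology. The resolution scenario uses very
  bright beads (10⁶ photons/frame) so that spectral cutoffs are
  optics-limited rather than noise-limited; this is the regime the
  support-ratio gain measurement assumes.

The renderer weights each emitter by the Gaussian sheet profile in its
flow-axis distance (thickness evaluated at the emitter's x), multiplies by
the pattern at its exact x, bins to the nearest pixel and convolves with
the detection PSF on a padded grid; camera noise is Poisson on
qe·photons plus Gaussian read noise (1.6 e⁻ RMS, sCMOS-like), then
gain/offset to ADU. Not modelled: intra-exposure motion blur,
photobleaching, scattering, cell deformation, wall-roughness illumination
stripes, coherent speckle.

## Fringe calibration

The calibration chain mirrors the device characterization: a 2–7.5 V
sweep in 0.5 V increments (note this enumerates 12 values although the
characterization describes it as 11 steps; the package simulates the full
12-value grid and leaves the discrepancy visible), each voltage repeated
8 times and rep-averaged; a line profile over a uniform row band;
a raised-cosine spectral high-pass (cutoff 0.3× the expected carrier)
that removes the sheet envelope while preserving the carrier within 2 %;
peak detection with sub-pixel refinement; nearest-neighbour peak matching
between consecutive voltages averaged over >20 peaks; and a zero-offset
quadratic fit of phase against V².

Numerical choices worth recording:

* **Sub-pixel interpolation.** The generic 3-point parabola has a ~0.01 px
  bias on sinusoidal peaks sampled at 7.3 px/period. `detect_peaks()`
  therefore refines with the sinusoid-exact 3-point formula
  δ = atan((c−a)/(2b sin k))/k, taking k from the parabola-refined median
  spacing in a first pass; residual error on clean carriers is <10⁻³ px.
* **Pooled period.** The mean inter-peak spacing is trimmed to
  (0.5, 1.5)× the median spacing so an occasionally missed peak (a
  double-width gap) cannot inflate the estimate.
* **Tracking limit.** Nearest-neighbour matching caps displacements at
  half a period, so a median displacement above 0.45 period is reported
  as an untrackable phase step rather than silently wrapped.
* **Fit reference.** Measured cumulative phases are relative to the first
  sweep voltage (2 V), so the zero-offset power law is fitted as
  φ = a (V² − V₁²); the drive voltages for 0, 2π/3 and 4π/3 come from
  `a` alone, reported to 0.01 V.

Under the default noise model this chain recovers the generating period
within 1 % and the shifter coefficient within 1 % across seeds, and the
solved 2π/3 voltage within 0.05 V. The 791 nm value itself is a property
of the physical chip; simulations recover whatever period they were
generated with.

## Three-phase SIM reconstruction

Band separation inverts, per frequency, the 3×3 mixing system with rows
\[1, (m/2)e^{iφₙ}, (m/2)e^{−iφₙ}\]; with the three phases equally spaced
the matrix is optimally conditioned and the inversion is exact (the
package verifies equality with brute-force-constructed bands to 10⁻⁶ on
noise-free data). The carrier is estimated by cross-correlating the
first-order and zeroth-order bands — the correlation over trial shifts is
the Fourier transform of the pixel-wise band product, searched within
±15 % of the configured carrier (calibration provides a strong prior) and
refined to sub-pixel by zoomed explicit-DFT evaluations plus a quadratic
fit; accuracy is ~0.1 % of k₀ on bead fields. Recombination embeds the
bands in a 2× grid, shifts the first orders by ∓k₀ with real-space phase
ramps (sub-pixel exact), applies generalized Wiener weights
OTF\*(k±k₀)/(Σ|OTF|² + w²) with w = 0.05 (relative to the unit OTF;
configurable — the device characterization names no value) and a triangle
apodization to the extended cutoff. Negative values are retained
internally and clipped only on export; the policy is recorded in the
result object.

**Per-frame phase estimation.** With three frames, every
correlation-based estimator reduces to the model
z_n = K + R e^{iφₙ} + B e^{−iφₙ}, where K and B are object-dependent
cross terms. K is eliminated exactly by differencing, giving the closed
ratio (e^{iφ₃}−1)/(e^{iφ₂}−1) = (z₃−z₁)/(z₂−z₁) solved on the unit
circle near the commanded increments. The neglected conjugate term B
biases the estimate by roughly (2/m)/√N, with N the effective number of
emitters: negligible for spectrally dense scenes (dye slabs, labelled
cells; <0.05 rad noise-free) but 0.1–0.25 rad for ~25-bead fields. This
is a property of the estimation problem, not of the implementation — the
object's own spectral self-similarity at the carrier lag is
indistinguishable from a phase shift. Consequently the reconstruction
uses the *commanded* phases by default (the device drives them
open-loop) and the estimated carrier; estimated phases are reported as
the quality metric and can be opted into with `use_estimated_phases`.
For the same reason, the absence of a carrier is detected through the
estimated modulation depth (below 0.05 → error) rather than a
correlation-contrast threshold, which cannot separate carrier from
no-carrier on sparse scenes. The reported `m_est` is biased low by the
OTF overlap between the displaced and centred passbands (≈0.8× for these
optics) and is diagnostic; separation uses the configured depth.

**Resolution gain.** `measure_gain()` offers two estimators. The
Fourier-cutoff method takes the ratio of the largest |k~x~| at which the
near-axis spectral magnitude exceeds a noise floor (3× the median over
the outermost 12 % of frequencies, with a 10⁻³ relative floor for
noise-free spectra); the reconstruction side is measured on the
unapodized Wiener spectrum. On optics-limited (bright) bead data this
yields 1.33, matching both the theoretical 1.330 and the measured
improvement of the physical device. The bead-FWHM method returns
~1.40–1.42 because the Wiener recombination also deconvolves the zeroth
band, which narrows bead profiles beyond the pure support extension; it
is reported for completeness. A known limitation: on flat-spectrum
(bead) fixtures the measured support gain *rises* with noise, because the
widefield cutoff is noise-limited while the SIM extension zone has
k-independent signal-to-noise (signal and noise share the same transfer
there). A "gain degrades with noise" intuition holds for objects with
decaying spectra, not for bead fields; the package therefore quotes the
gain only in the low-noise regime.

## Flow-scan volumes and throughput

Frames are grouped into consecutive complete (0, 1, 2) phase triplets
(incomplete ends dropped and counted; a corrupted cycle is an
acquisition fault and raises an error naming the frame). Each triplet is
one plane at the mean flow position of its three frames — at 10 µm/s and
50 Hz the intra-triplet motion of 0.4 µm is an accepted, modelled
artifact. Planes stack at the native spacing 3·speed/rate = 0.6 µm with
*no registration*, mirroring the stability of the pressure-driven flow;
an integer-pixel cross-correlation drift check between neighbouring
planes is computed and reported but never applied. The x-z view
resamples the central row of every plane onto isotropic display pixels.
The native 0.6 µm spacing and any display sub-sampling are both exposed,
since published galleries typically show a selected subset of planes
(e.g. every ~1.1 µm) rather than the native stack. Throughput follows
from the protocol alone: 60·speed/(cell extent + gap) cells/min and
⌊extent/spacing⌋ planes per cell — 40 cells/min and 15 planes at the
default 15 µm cell pitch, 9 µm optical cell extent, 10 µm/s and 50 Hz.

## Reproducibility, I/O and problem sizes

Every scenario (`run_scenario()`) is a pure function of (configuration,
seed): one global seed feeds deterministic per-stage substreams, so
stages can be re-run independently and identical runs are bit-identical.
Stacks travel as multi-page 32-bit TIFF plus a CSV metadata table; the
R `tiff` package stores samples in [0, 1], so frames are affinely scaled
(scale/offset recorded in the CSV) and quantized to float32 — round
trips are lossless at float32 precision (~10⁻⁷ relative), and external
8/16-bit integer TIFFs are promoted to float ADU with a logged flag.
Configurations serialize to YAML with units embedded in key names;
unknown keys are rejected, and the defaults-resolved configuration is
written next to every output.

The shipped tests run the full pipelines at reduced problem sizes chosen
to keep the suite fast while preserving the physics: 48–256 px grids
(the fringe axis keeps its full 700 px in calibration tests, since the
>20-peak averaging rule needs it), 25-bead resolution fields on 256²
grids, and a 5 µm shell for the volume geometry check. The acceptance
script uses the full 512×700 field for the resolution measurement.

## Known limitations

* The light-sheet model is symmetric and Gaussian; the real lens profile
  is asymmetric (3.4 vs 3.2 µm at ±20 µm) and not public.
* Per-frame phase estimation on sparse scenes carries the
  (2/m)/√N bias discussed above; three frames cannot disambiguate it.
* The support-ratio gain is meaningful only when both images are
  optics-limited; on noise-limited data it reflects SNR, not optics.
* No multi-orientation machinery: the device provides one pattern
  orientation, so super-resolution is one-dimensional by design.
* Electrical drift, fabrication tolerances and real-cell image quality
  are outside the simulation scope.
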