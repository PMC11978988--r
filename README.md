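# flowSIM

A desk-scale digital twin of an integrated optofluidic 3D imaging flow
cytometer. The instrument it models combines three ideas on one chip: two
waveguide-fed light sheets cross inside a microfluidic channel and
interfere, writing a sinusoidal structured-illumination pattern onto the
sheet; a thermal phase shifter steps the pattern phase (optical phase ∝
dissipated power ∝ V²); and cells flowing at constant speed are sectioned
plane by plane, three phase-stepped frames per plane, yielding volumetric
structured-illumination microscopy (SIM) at flow-cytometry style
throughput.

flowSIM is for microscopists and instrument builders who want to simulate,
calibrate and reconstruct such data without the hardware: it provides the
closed-form optical model, emitter-based phantom generators (uniform dye,
bead fields, membrane-labelled cells with vesicles), a camera acquisition
simulator with Poisson + read noise, the fringe-calibration analysis
(sub-pixel peak tracking → period and voltage-to-phase law), a three-phase
single-orientation SIM reconstructor (band separation, carrier estimation
by Fourier cross-correlation, sub-pixel Wiener recombination), and
flow-scan volume assembly with throughput accounting.

## The model in brief

* Fringe period *p* = λ / (2 n sin θ): λ = 561 nm, θ = 15°, n = 1.458
  (fused silica) → 743 nm theoretical; all defaults use the device's
  *measured* 791 nm.
* Phase shifter φ(V) = (4π/3)(V/5.86)²: the SIM triple {0, 2π/3, 4π/3}
  maps to drive voltages {0, 4.14, 5.86} V.
* Detection: widefield, NA 1.15, 40×·1.5 magnification, OTF cutoff
  k_c = 2 NA/λ_em = 3.83 µm⁻¹. The carrier 1/p extends the support along
  the modulation axis to k_c + 1/p, a one-dimensional resolution gain of
  (k_c + 1/p)/k_c = 1.33.
* Flow scan: at 10 µm/s and 50 Hz, planes (3-frame triplets) are spaced
  3·v/f = 0.6 µm; a 15 µm cell pitch gives 40 cells/min, 15 planes per
  9 µm cell.

## Worked example

```r
library(flowSIM)

cfg <- optical_config()
cfg
#> <optical_config>
#>   excitation 561 nm | emission 600 nm | semi-angle 15 deg
#>   detection NA 1.15, magnification 60x, camera pixel 6.5 um (object 0.1083 um)
#>   pattern period: theoretical 743.3 nm, in use 791.0 nm

# drive voltages for the three-phase protocol
voltage_for_phase(phase_shifter(), c(0, 2, 4) * pi / 3)
#> 0.00  4.14  5.86   (V, rounded)

# simulate a dye-filled channel, sweep the shifter, calibrate the fringes
cal <- run_scenario("calibration",
                    experiment_config(camera = list(roi_px = c(64, 700))),
                    seed = 1)
cal$result
#> <calibration_result>
#>   fringe period: 7.300 px = 790.8 nm
#>   phase law: a = 0.12206 rad/V^2 (R^2 = 0.99991)
#>   solved drive voltages (0, 2pi/3, 4pi/3): 0.00, 4.14, 5.86 V

# render a bright bead field under the pattern and reconstruct
beads <- run_scenario("bead_resolution", experiment_config(), seed = 1)
beads$reconstruction
#> <sim_reconstruction>
#>   carrier: (1.2643, 0.0003) 1/um -> period 790.9 nm
#>   phases (rad): 0.000, 2.269, 4.178 | m = 0.644
#>   measured 1D resolution gain: 1.331

# protocol throughput at the default flow settings
throughput(10, 50, cell_extent_um = 9, gap_um = 6)
#> $cells_per_min   40
#> $planes_per_cell 15
#> $z_spacing_um    0.6
```

Reading the numbers: the calibration recovers the fringe period it was
generated with (791 nm ↔ 7.30 px at the 108.3 nm object pixel) and the
quadratic voltage-to-phase coefficient (true value 4π/3 / 5.86² =
0.1220 rad/V²), from which the three drive voltages are solved. The bead
reconstruction finds the carrier within ~0.1 %, and the Fourier-support
ratio of the reconstruction over the widefield image is 1.33 — the
one-dimensional super-resolution gain this pattern period and detection
NA allow. `run_scenario("flow_cell", ...)` runs the full cell pipeline:
flow scan → triplet grouping → per-plane SIM → volume at 0.6 µm plane
spacing, with an x–z view assembled without any inter-plane registration.

A methods write-up — the optical model and its assumptions, the
calibration and reconstruction algorithms, estimator biases, and known
limitations — is in `vignettes/flowSIM-methods.Rmd`.

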