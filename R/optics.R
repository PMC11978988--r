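# Closed-form optical forward model: interference pattern, voltage->phase
# law, Gaussian-limit light-sheet thickness, and the widefield detection
# PSF/OTF used by both the simulator and the reconstruction.

#' Fringe period of the two-beam interference pattern
#'
#' Two coherent beams crossing at semi-angle theta in a medium of index n
#' interfere with period `p = lambda / (2 n sin(theta))`. The semi-angle is
#' defined inside the fused-silica chip, so `n = n_chip`; the transverse
#' spatial frequency of the pattern is invariant across the flat
#' silica/water interface.
#'
#' @param cfg an [optical_config()].
#' @return period in nanometres. The carrier spatial frequency is `1/p`.
#' @seealso [carrier_period()] for the period actually used downstream,
#'   which defaults to the measured 791 nm.
#' @export
pattern_period <- function(cfg) {
  theta <- cfg$semi_angle_deg * pi / 180
  if (sin(theta) <= 0) stop("degenerate interference geometry", call. = FALSE)
  cfg$lambda_exc_nm / (2 * cfg$n_chip * sin(theta))
}

#' Fringe period used by the simulator and reconstruction
#'
#' Returns the measured-period override stored in the configuration when
#' present (default 791 nm), otherwise the theoretical [pattern_period()].
#'
#' @param cfg an [optical_config()].
#' @return period in nanometres.
#' @export
carrier_period <- function(cfg) cfg$period_nm %||% pattern_period(cfg)

#' Sinusoidal illumination intensity profile
#'
#' `I(x) = 1 + m cos(2 pi x / p + phi)`, normalized so the spatial mean
#' tends to 1 as the window grows. `x` is the lateral coordinate across the
#' fringes (micrometres); the period defaults to [carrier_period()].
#'
#' @param cfg an [optical_config()].
#' @param x lateral coordinates, micrometres (vector).
#' @param phi pattern phase, radians.
#' @param modulation_depth fringe contrast m in \[0, 1\].
#' @param period_nm fringe period, nm; defaults to [carrier_period()].
#' @return intensity values, same length as `x`, mean 1 over whole periods.
#' @export
pattern_intensity <- function(cfg, x, phi = 0, modulation_depth = 1,
                              period_nm = carrier_period(cfg)) {
  if (modulation_depth < 0 || modulation_depth > 1)
    stop("modulation_depth must lie in [0, 1]", call. = FALSE)
  p_um <- period_nm / 1000
  1 + modulation_depth * cos(2 * pi * x / p_um + phi)
}

#' Phase of the thermal shifter at a given drive voltage
#'
#' Phase is proportional to the dissipated electrical power, hence quadratic
#' in voltage: `phi(V) = phi_offset + phi_ref * (V / v_ref)^2`.
#'
#' @param psm a [phase_shifter()].
#' @param v drive voltage, volts (>= 0); vectorized.
#' @return phase in radians.
#' @export
phase_from_voltage <- function(psm, v) {
  if (psm$v_ref <= 0) stop("phase shifter misconfigured: v_ref <= 0", call. = FALSE)
  if (any(v < 0)) stop("drive voltage must be non-negative", call. = FALSE)
  psm$phi_offset + psm$phi_ref * (v / psm$v_ref)^2
}

#' Drive voltage producing a requested phase
#'
#' Exact inverse of [phase_from_voltage()].
#'
#' @param psm a [phase_shifter()].
#' @param phi requested phase, radians (>= `phi_offset`); vectorized.
#' @return voltage in volts.
#' @export
voltage_for_phase <- function(psm, phi) {
  if (any(phi < psm$phi_offset - 1e-12))
    stop("unreachable phase: below the shifter's zero-voltage phase", call. = FALSE)
  psm$v_ref * sqrt(pmax(phi - psm$phi_offset, 0) / psm$phi_ref)
}

#' Light-sheet thickness away from focus
#'
#' Gaussian-beam law: the 1/e^2 waist is `w0 = fwhm_focus / sqrt(2 ln 2)`,
#' the Rayleigh range `zR = pi w0^2 n_medium / lambda_exc`, and
#' `fwhm(z) = fwhm_focus * sqrt(1 + ((z - z_center)/zR)^2)`.
#'
#' @param ls a [light_sheet_profile()].
#' @param cfg an [optical_config()] supplying wavelength and medium index.
#' @param z position along the sheet propagation axis, micrometres; vectorized.
#' @return sheet thickness FWHM in micrometres.
#' @export
sheet_fwhm_at <- function(ls, cfg, z) {
  w0 <- ls$fwhm_focus_um / sqrt(2 * log(2))
  zr <- pi * w0^2 * cfg$n_medium / (cfg$lambda_exc_nm / 1000)
  ls$fwhm_focus_um * sqrt(1 + ((z - ls$z_center_um) / zr)^2)
}

#' Rayleigh range of the light sheet, micrometres
#' @inheritParams sheet_fwhm_at
#' @export
sheet_rayleigh_um <- function(ls, cfg) {
  w0 <- ls$fwhm_focus_um / sqrt(2 * log(2))
  pi * w0^2 * cfg$n_medium / (cfg$lambda_exc_nm / 1000)
}

#' Incoherent detection OTF value at radial frequency k
#'
#' Aberration-free circular-pupil autocorrelation ("chat" function):
#' `OTF(k) = (2/pi) (acos(rho) - rho sqrt(1 - rho^2))` with `rho = k / kc`
#' and cutoff `kc = 2 NA / lambda_em`; zero beyond the cutoff.
#'
#' @param cfg an [optical_config()].
#' @param k radial spatial frequency, 1/micrometres; vectorized.
#' @return OTF values in \[0, 1\], `OTF(0) = 1`.
#' @export
otf_value <- function(cfg, k) {
  kc <- otf_cutoff(cfg)
  rho <- pmin(abs(k) / kc, 1)
  (2 / pi) * (acos(rho) - rho * sqrt(pmax(1 - rho^2, 0)))
}

#' Detection OTF cutoff frequency `kc = 2 NA / lambda_em`, 1/micrometres
#' @param cfg an [optical_config()].
#' @export
otf_cutoff <- function(cfg) 2 * cfg$na_det / (cfg$lambda_em_nm / 1000)

#' Widefield detection PSF and OTF on a sampling grid
#'
#' Evaluates the radially symmetric incoherent OTF on the FFT frequency grid
#' of an `nr x nc` image with the given pixel size, and derives the PSF as
#' its inverse transform, normalized to unit sum. Both are returned in
#' unshifted FFT layout (DC at element \[1, 1\]).
#'
#' @param cfg an [optical_config()].
#' @param nr,nc grid size in pixels (rows = y, cols = x).
#' @param pixel_um pixel size, micrometres; defaults to [object_pixel_um()].
#' @param warn warn when the grid undersamples the recommended
#'   `lambda_em / (4 NA)` pitch.
#' @return list with `psf` (real matrix, unit sum), `otf` (real matrix,
#'   `otf[1,1] = 1`), `kx`, `ky` (frequency vectors, 1/um), `pixel_um`, `kc`.
#' @export
detection_psf_otf <- function(cfg, nr, nc, pixel_um = object_pixel_um(cfg),
                              warn = TRUE) {
  rec <- (cfg$lambda_em_nm / 1000) / (4 * cfg$na_det)
  if (warn && pixel_um > rec * (1 + 1e-9))
    warning(sprintf("grid pixel %.1f nm exceeds the recommended %.1f nm (lambda_em/4NA)",
                    pixel_um * 1000, rec * 1000), call. = FALSE)
  kx <- fft_freq(nc, pixel_um)
  ky <- fft_freq(nr, pixel_um)
  kr <- sqrt(outer(ky^2, kx^2, `+`))
  otf <- otf_value(cfg, kr)
  psf <- Re(ifft2(otf))
  psf <- psf / sum(psf)
  otf <- Re(stats::fft(psf))   # renormalized so OTF(0) is exactly 1
  list(psf = psf, otf = otf, kx = kx, ky = ky, pixel_um = pixel_um,
       kc = otf_cutoff(cfg))
}

#' Theoretical 1D resolution gain of the structured-illumination system
#'
#' The sinusoidal pattern at period `p` shifts object frequencies by the
#' carrier `1/p`, extending the support along the modulation axis from `kc`
#' to `kc + 1/p`: the gain is `(kc + 1/p)/kc`, capped at 2 (carrier at the
#' detection cutoff).
#'
#' @param cfg an [optical_config()].
#' @param period_nm pattern period, nm; defaults to [carrier_period()].
#' @return dimensionless gain factor in \[1, 2\].
#' @export
theoretical_sim_gain <- function(cfg, period_nm = carrier_period(cfg)) {
  if (period_nm <= 0) stop("pattern period must be positive", call. = FALSE)
  kc <- otf_cutoff(cfg)
  k0 <- 1 / (period_nm / 1000)
  min((kc + k0) / kc, 2)
}

#' Sampling diagnostics for the configured detection path
#'
#' Reports the object-side pixel size, the fringe sampling rate in pixels
#' per period, and Nyquist checks against the plain detection cutoff `kc`
#' and the extended structured-illumination cutoff `kc + 1/p`. A warning is
#' raised when the pixel grid cannot represent the detection passband at
#' all, or when the fringe itself sits at the sampling limit; the extended
#' cutoff check is reported as a flag only.
#'
#' @param cfg an [optical_config()].
#' @param period_nm fringe period, nm; defaults to [carrier_period()].
#' @return list with `pixel_um`, `px_per_period`, `kc`, `k_ext`,
#'   `nyquist_ok_detection`, `nyquist_ok_extended`, `warnings` (character).
#' @export
validate_sampling <- function(cfg, period_nm = carrier_period(cfg)) {
  px <- object_pixel_um(cfg)
  kc <- otf_cutoff(cfg)
  k0 <- 1 / (period_nm / 1000)
  k_ext <- kc + k0
  ppp <- (period_nm / 1000) / px
  msgs <- character(0)
  det_ok <- px <= 1 / (2 * kc)
  ext_ok <- px <= 1 / (2 * k_ext)
  if (!det_ok)
    msgs <- c(msgs, sprintf(
      "detection Nyquist violation: pixel %.1f nm > %.1f nm (1/(2 kc))",
      px * 1000, 1000 / (2 * kc)))
  if (ppp <= 2 + 1e-9)
    msgs <- c(msgs, sprintf("fringe at sampling limit: %.2f px/period", ppp))
  for (m in msgs) warning(m, call. = FALSE)
  list(pixel_um = px, px_per_period = ppp, kc = kc, k_ext = k_ext,
       nyquist_ok_detection = det_ok, nyquist_ok_extended = ext_ok,
       warnings = msgs)
}
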