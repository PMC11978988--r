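#' Optical configuration of the chip and detection path
#'
#' Single source of truth for the optics: excitation/emission wavelengths,
#' refractive indices, the semi-angle between the two interfering beams that
#' sets the fringe period, and the detection path (NA, magnification, camera
#' pixel pitch). Defaults describe a 561 nm excitation chip read out through
#' a 40x/1.15 NA water-immersion objective with a 1.5x tube lens.
#'
#' `period_nm` optionally pins the fringe period used by the simulator and
#' reconstruction to a measured value (default 791 nm, the calibrated period
#' of the physical device); set it to `NULL` to fall back to the theoretical
#' [pattern_period()].
#'
#' @param lambda_exc_nm excitation vacuum wavelength, nm.
#' @param lambda_em_nm emission vacuum wavelength, nm (600 nm is a round
#'   proxy for the Alexa Fluor 594 channel).
#' @param n_medium refractive index of the channel fluid.
#' @param n_chip refractive index of the fused-silica lens substrate at the
#'   excitation wavelength.
#' @param semi_angle_deg semi-angle between the two interfering beams,
#'   degrees; must lie strictly in (0, 90).
#' @param na_det detection numerical aperture.
#' @param mag_total total detection magnification (objective x tube lens).
#' @param cam_pixel_um camera pixel pitch, micrometres.
#' @param period_nm measured fringe period override, nm, or `NULL`.
#' @return an object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' pattern_period(cfg)   # theoretical period from the interference geometry
#' carrier_period(cfg)   # period actually used downstream (measured default)
#' @export
optical_config <- function(lambda_exc_nm = 561, lambda_em_nm = 600,
                           n_medium = 1.333, n_chip = 1.458,
                           semi_angle_deg = 15, na_det = 1.15,
                           mag_total = 60, cam_pixel_um = 6.5,
                           period_nm = 791) {
  stopifnot(lambda_exc_nm > 0, lambda_em_nm > 0,
            n_medium >= 1, n_chip >= 1,
            na_det > 0, na_det < 1.52, mag_total > 0, cam_pixel_um > 0)
  if (!(semi_angle_deg > 0 && semi_angle_deg < 90))
    stop("semi_angle_deg must lie strictly between 0 and 90 degrees", call. = FALSE)
  if (!is.null(period_nm)) stopifnot(period_nm > 0)
  structure(list(lambda_exc_nm = lambda_exc_nm, lambda_em_nm = lambda_em_nm,
                 n_medium = n_medium, n_chip = n_chip,
                 semi_angle_deg = semi_angle_deg, na_det = na_det,
                 mag_total = mag_total, cam_pixel_um = cam_pixel_um,
                 period_nm = period_nm),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  excitation %g nm | emission %g nm | semi-angle %g deg\n",
              x$lambda_exc_nm, x$lambda_em_nm, x$semi_angle_deg))
  cat(sprintf("  detection NA %g, magnification %gx, camera pixel %g um (object %0.4f um)\n",
              x$na_det, x$mag_total, x$cam_pixel_um, object_pixel_um(x)))
  cat(sprintf("  pattern period: theoretical %.1f nm, in use %.1f nm\n",
              pattern_period(x), carrier_period(x)))
  invisible(x)
}

#' Object-side pixel size
#'
#' Camera pixel pitch demagnified to the object plane, in micrometres.
#'
#' @param cfg an [optical_config()].
#' @export
object_pixel_um <- function(cfg) cfg$cam_pixel_um / cfg$mag_total

#' Thermal phase-shifter model
#'
#' Resistive microheater over one interferometer arm: the optical phase shift
#' is proportional to the dissipated electrical power, hence to the square of
#' the drive voltage for a constant resistance. The model is anchored by one
#' calibration point: `phi_ref` radians at `v_ref` volts (defaults 4*pi/3 at
#' 5.86 V, the top of the three-phase drive triple).
#'
#' @param v_ref reference drive voltage, volts (> 0).
#' @param phi_ref phase at `v_ref`, radians.
#' @param phi_offset phase at 0 V, radians (0 by convention).
#' @param drift_ppk documented peak-to-peak power stability fraction over
#'   12 h of operation; informational only, never simulated by default.
#' @return an object of class `phase_shifter`.
#' @examples
#' psm <- phase_shifter()
#' phase_from_voltage(psm, 5.86)    # 4*pi/3
#' voltage_for_phase(psm, 2*pi/3)   # ~4.14 V
#' @export
phase_shifter <- function(v_ref = 5.86, phi_ref = 4 * pi / 3,
                          phi_offset = 0, drift_ppk = 0.0018) {
  if (v_ref <= 0) stop("v_ref must be positive", call. = FALSE)
  stopifnot(phi_ref >= 0, drift_ppk >= 0)
  structure(list(v_ref = v_ref, phi_ref = phi_ref,
                 phi_offset = phi_offset, drift_ppk = drift_ppk),
            class = "phase_shifter")
}

#' Light-sheet axial thickness profile
#'
#' Gaussian-beam model of the sheet thickness along its propagation axis,
#' anchored at the focal FWHM. The thickness grows as
#' `fwhm(z) = fwhm_focus * sqrt(1 + ((z - z_center)/zR)^2)` with the Rayleigh
#' range `zR` set by the focal waist, the medium index and the excitation
#' wavelength (see [sheet_fwhm_at()]).
#'
#' @param fwhm_focus_um sheet thickness FWHM at focus, micrometres.
#' @param z_center_um focus position along the propagation axis, micrometres.
#' @return an object of class `light_sheet_profile` (model tag `"gaussian"`).
#' @export
light_sheet_profile <- function(fwhm_focus_um = 1.1, z_center_um = 0) {
  stopifnot(fwhm_focus_um > 0)
  structure(list(fwhm_focus_um = fwhm_focus_um, z_center_um = z_center_um,
                 model = "gaussian"),
            class = "light_sheet_profile")
}

# ---- serialization -------------------------------------------------------

config_block <- function(x) {
  cls <- class(x)[1]
  lst <- unclass(x)
  lst[vapply(lst, is.null, logical(1))] <- NULL
  c(list(class = cls), lst)
}

#' Write / read optics configuration files
#'
#' Serializes the optics triple (optical configuration, phase-shifter model,
#' light-sheet profile) to a single YAML file with units embedded in the key
#' names, and reads it back.
#'
#' @param cfg an [optical_config()].
#' @param psm a [phase_shifter()].
#' @param ls a [light_sheet_profile()].
#' @param path file path of the YAML configuration.
#' @return `write_optics_config` returns `path` invisibly;
#'   `read_optics_config` returns `list(cfg, psm, ls)`.
#' @export
write_optics_config <- function(cfg, psm, ls, path) {
  out <- list(optical_config = config_block(cfg),
              phase_shifter = c(config_block(psm)[1],
                                list(v_ref_volt = psm$v_ref,
                                     phi_ref_rad = psm$phi_ref,
                                     phi_offset_rad = psm$phi_offset,
                                     drift_ppk = psm$drift_ppk)),
              light_sheet = config_block(ls))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_optics_config
#' @export
read_optics_config <- function(path) {
  raw <- yaml::read_yaml(path)
  stopifnot(all(c("optical_config", "phase_shifter", "light_sheet") %in% names(raw)))
  oc <- raw$optical_config; oc$class <- NULL
  ps <- raw$phase_shifter
  lsb <- raw$light_sheet; lsb$class <- NULL; lsb$model <- NULL
  list(cfg = do.call(optical_config, oc),
       psm = phase_shifter(v_ref = ps$v_ref_volt, phi_ref = ps$phi_ref_rad,
                           phi_offset = ps$phi_offset_rad,
                           drift_ppk = ps$drift_ppk),
       ls = do.call(light_sheet_profile, lsb))
}
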