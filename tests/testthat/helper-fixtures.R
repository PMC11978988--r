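# Shared fixtures: small grids keep renders fast; physics parameters stay at
# the device defaults (561 nm excitation, 15 deg semi-angle, NA 1.15, 40x1.5
# magnification, 791 nm measured carrier period).

fix_cfg <- function(...) optical_config(...)
fix_ls <- function(...) light_sheet_profile(...)
fix_psm <- function(...) phase_shifter(...)

fix_cam <- function(n = 128L, ...) camera_model(roi_px = c(n, n), ...)

fix_px <- object_pixel_um(optical_config())

# square extent slightly inside an n-pixel field of view, thin in z
fix_extent <- function(n = 128L, z_half = 0.25, frac = 0.8) {
  half <- n * fix_px / 2 * frac
  list(x = c(-half, half), y = c(-half, half), z = c(-z_half, z_half))
}

fix_beads <- function(n_px = 256L, n_beads = 25, brightness = 5000,
                      seed = 7, min_sep_um = if (n_px >= 256) 2 else 1)
  make_bead_phantom(n_beads, fix_extent(n_px), min_sep_um = min_sep_um,
                    brightness = brightness, seed = seed)

# dense emitter slab: a spectrally dense scene for estimator tests
fix_dense <- function(n_px = 256L, seed = 11)
  make_dye_phantom(fix_extent(n_px, z_half = 0.3), density_per_um3 = 20,
                   brightness = 300, seed = seed)

fix_triplet <- function(phantom, n_px = 256L, phases = c(0, 2, 4) * pi / 3,
                        m = 0.8, noise = FALSE, seed = 1, cam = NULL) {
  cam <- cam %||% fix_cam(n_px)
  fr <- render_phase_triplet(phantom, fix_cfg(), fix_ls(), cam,
                             phases = phases, modulation_depth = m,
                             noise = noise, seed = seed)
  lapply(fr, function(f) f - cam$offset_adu)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent forward construction of a 3-phase triplet and its
# ground-truth bands from an arbitrary object image (oracle for band
# separation): frames built by real-space multiplication then blurring,
# bands by modulating the object with complex carriers before blurring.
oracle_sim_data <- function(s_img, period_nm, phases, m, cfg = fix_cfg(),
                            pixel_um = fix_px) {
  n <- nrow(s_img)
  po <- detection_psf_otf(cfg, n, ncol(s_img), pixel_um, warn = FALSE)
  x <- (seq_len(ncol(s_img)) - (ncol(s_img) %/% 2 + 1)) * pixel_um
  k0 <- 1 / (period_nm / 1000)
  blur <- function(img) stats::fft(stats::fft(img) * po$otf, inverse = TRUE) /
    length(img)
  xs <- matrix(x, n, ncol(s_img), byrow = TRUE)
  frames <- lapply(phases, function(ph)
    Re(blur(s_img * (1 + m * cos(2 * pi * k0 * xs + ph)))))
  carrier <- exp(2i * pi * k0 * xs)
  bands_truth <- list(
    band0 = stats::fft(s_img) * po$otf,
    band_plus = stats::fft(s_img * carrier) * po$otf,
    band_minus = stats::fft(s_img * Conj(carrier)) * po$otf)
  list(frames = frames, bands = bands_truth, k0 = c(k0, 0), otf = po$otf)
}

# smooth random test object (band-limited positive image)
random_object <- function(n, seed = 1, cut_frac = 0.2) {
  flowSIM:::with_seed(seed, {
    z <- matrix(stats::rnorm(n * n), n)
    k <- flowSIM:::fft_freq(n)
    keep <- outer(abs(k), abs(k), function(a, b) pmax(a, b)) < cut_frac / 2
    img <- Re(stats::fft(stats::fft(z) * keep, inverse = TRUE)) / n^2
    img - min(img) + 0.1 * diff(range(img))
  })
}
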