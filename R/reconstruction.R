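# Three-phase, single-orientation structured-illumination reconstruction:
# band separation by inverting the 3x3 phase-mixing system, carrier and
# phase estimation by Fourier cross-correlation of the separated bands,
# sub-pixel band shifting by real-space phase ramps on a 2x upsampled grid,
# generalized Wiener recombination with triangle apodization, and the
# resolution-gain metrics.
#
# FFT conventions: forward unnormalized, inverse 1/N, spectra kept in
# unshifted layout (DC at [1,1]); real-space pixel centres sit at
# pixel_coords() so the origin coincides with the FFT centre pixel.

#' Widefield image from a 3-phase triplet
#'
#' Pixel-wise mean of the three phase-stepped frames. For equally spaced
#' phases (0, 2pi/3, 4pi/3) the sinusoidal modulation cancels exactly, so
#' the mean equals the unpatterned widefield image in expectation.
#'
#' @param frames3 list of 3 matrices of identical shape.
#' @return numeric matrix.
#' @export
widefield_from_triplet <- function(frames3) {
  stopifnot(length(frames3) == 3)
  d <- dim(frames3[[1]])
  if (!all(vapply(frames3, function(f) identical(dim(f), d), logical(1))))
    stop("triplet frames differ in shape", call. = FALSE)
  (frames3[[1]] + frames3[[2]] + frames3[[3]]) / 3
}

phase_mixing_matrix <- function(phases, m) {
  cbind(1, (m / 2) * exp(1i * phases), (m / 2) * exp(-1i * phases))
}

#' Separate the three frequency bands of a 3-phase triplet
#'
#' Per-frequency inversion of the mixing system
#' `I_n(k) = C0(k) + (m/2) e^{i phi_n} C+(k) + (m/2) e^{-i phi_n} C-(k)`
#' where `C0 = S(k) OTF(k)` and `C+/- = S(k -/+ k0) OTF(k)` are the object
#' spectrum and its carrier-displaced copies seen through the detection
#' OTF. The inversion is exact whenever the phase matrix is non-singular.
#'
#' @param frames3 list of 3 matrices (background-subtracted raw frames).
#' @param phases the 3 pattern phases, radians (pairwise distinct mod 2pi).
#' @param m modulation depth used in the mixing matrix.
#' @return list of 3 complex spectra (`band0`, `band_plus`, `band_minus`)
#'   in unshifted FFT layout.
#' @export
separate_bands <- function(frames3, phases, m = 1) {
  stopifnot(length(frames3) == 3, length(phases) == 3, m > 0)
  M <- phase_mixing_matrix(phases, m)
  sv <- svd(M)$d
  if (max(sv) / min(sv) > 1e6)
    stop("degenerate phase set: mixing matrix is singular", call. = FALSE)
  Minv <- solve(M)
  Fs <- lapply(frames3, stats::fft)
  bands <- lapply(1:3, function(j)
    Minv[j, 1] * Fs[[1]] + Minv[j, 2] * Fs[[2]] + Minv[j, 3] * Fs[[3]])
  names(bands) <- c("band0", "band_plus", "band_minus")
  bands
}

# Explicit DFT of matrix r at physical frequency (kx, ky), centred coords.
dft_at <- function(r, kx, ky, x, y) {
  wy <- exp(-2i * pi * ky * y)
  wx <- exp(-2i * pi * kx * x)
  as.complex(crossprod(wy, r %*% wx))
}

#' Estimate the carrier frequency, pattern phases and modulation depth
#'
#' Separates the bands with the nominal phase triple, then locates the
#' carrier k0 by maximizing the magnitude of the cross-correlation between
#' the first-order and zeroth-order bands: the correlation as a function of
#' the trial shift is the Fourier transform of the pixel-wise product
#' `B+(x) conj(B0(x))`, whose peak sits at k0. The peak is searched inside
#' a window around the nominal carrier and refined to sub-pixel precision
#' by a two-stage local zoom with explicit DFT evaluations plus a final
#' quadratic fit. Per-frame pattern phases are then read off as the
#' argument of the k0 Fourier component of each widefield-subtracted frame
#' correlated against the widefield, and the modulation depth from the
#' correlation magnitude.
#'
#' @param frames3 list of 3 matrices (background-subtracted raw frames).
#' @param cfg an [optical_config()].
#' @param pixel_um object pixel size, micrometres.
#' @param phases_nominal commanded phases (default 0, 2pi/3, 4pi/3).
#' @param k0_nominal nominal carrier `c(kx, ky)` in 1/um (default: along x
#'   at `1/carrier_period`).
#' @param search_frac half-width of the search window as a fraction of
#'   |k0_nominal| (default 0.15: calibration gives a strong prior).
#' @param contrast_min minimum ratio between the in-window correlation
#'   peak and the off-peak annulus maximum. Reported as a diagnostic and
#'   disabled by default (0): for sparse scenes the off-peak correlation
#'   field fluctuates at `1/sqrt(n_emitters)` of the peak and its maxima
#'   can exceed the coherent peak, so this ratio separates carrier from
#'   no-carrier only on spectrally dense scenes.
#' @param m_min minimum estimated modulation depth; the robust no-carrier
#'   gate. An unmodulated triplet yields an m estimate at the noise level,
#'   far below 0.05, for any scene density.
#' @return list with `k0` (c(kx, ky), 1/um), `k0_mag`, `phases` (3,
#'   radians, relative scale matching the commanded triple), `m_est`,
#'   `contrast`.
#' @export
estimate_carrier_crosscorr <- function(frames3, cfg, pixel_um,
                                       phases_nominal = c(0, 2, 4) * pi / 3,
                                       k0_nominal = NULL,
                                       search_frac = 0.15,
                                       contrast_min = 0, m_min = 0.05) {
  nr <- nrow(frames3[[1]]); nc <- ncol(frames3[[1]])
  if (is.null(k0_nominal))
    k0_nominal <- c(1 / (carrier_period(cfg) / 1000), 0)
  k0n_mag <- sqrt(sum(k0_nominal^2))
  bands <- separate_bands(frames3, phases_nominal, m = 1)
  g0 <- ifft2(bands$band0)
  gp <- ifft2(bands$band_plus)
  r <- gp * Conj(g0)
  corr <- stats::fft(r)
  kx <- fft_freq(nc, pixel_um)
  ky <- fft_freq(nr, pixel_um)
  dist <- sqrt(outer((ky - k0_nominal[2])^2, (kx - k0_nominal[1])^2, `+`))
  win <- dist <= search_frac * k0n_mag
  if (!any(win)) stop("carrier search window is empty", call. = FALSE)
  mag <- Mod(corr)
  peak_val <- max(mag[win])
  # a genuine carrier peak dominates the off-peak region; without
  # modulation the correlation field is structureless there. The zero-lag
  # neighbourhood is excluded: the band DC overlap c(0) is large whether
  # or not a carrier exists.
  dist0 <- sqrt(outer(ky^2, kx^2, `+`))
  ref <- dist > 2 * search_frac * k0n_mag & dist <= k0n_mag &
    dist0 > 0.5 * k0n_mag
  contrast <- peak_val / max(mag[ref])
  if (!is.finite(contrast) || contrast < contrast_min)
    stop("no carrier found: correlation peak contrast below threshold",
         call. = FALSE)
  mag[!win] <- -Inf
  pk <- which(mag == peak_val, arr.ind = TRUE)[1, ]
  k0 <- c(kx[pk[2]], ky[pk[1]])
  # sub-pixel refinement: zoomed explicit-DFT grids, then a parabola
  x <- pixel_coords(nc, pixel_um)
  y <- pixel_coords(nr, pixel_um)
  dk <- 1 / (max(nr, nc) * pixel_um)
  for (step in c(0.2, 0.04) * dk) {
    grid <- expand.grid(dx = -2:2 * step, dy = -2:2 * step)
    vals <- mapply(function(dx, dy)
      Mod(dft_at(r, k0[1] + dx, k0[2] + dy, x, y)), grid$dx, grid$dy)
    b <- which.max(vals)
    k0 <- k0 + c(grid$dx[b], grid$dy[b])
  }
  h <- 0.04 * dk
  fx <- vapply(c(-h, 0, h), function(d) Mod(dft_at(r, k0[1] + d, k0[2], x, y)),
               numeric(1))
  fy <- vapply(c(-h, 0, h), function(d) Mod(dft_at(r, k0[1], k0[2] + d, x, y)),
               numeric(1))
  par_off <- function(v) {
    den <- v[1] - 2 * v[2] + v[3]
    if (abs(den) > 0) 0.5 * (v[1] - v[3]) / den else 0
  }
  k0 <- k0 + h * c(par_off(fx), par_off(fy))
  # Per-frame phases from the k0 component of each raw frame correlated
  # against the widefield reference. The model is
  # z_n = K + R e^{i phi_n}: K collects all phase-independent object terms
  # and R carries the +1 band. Taking differences eliminates K and the
  # ratio w = (z3 - z1)/(z2 - z1) = (e^{i phi3} - 1)/(e^{i phi2} - 1)
  # (gauge phi1 = 0) pins phi2 on the unit circle; the root nearest the
  # commanded increment is taken. The neglected conjugate-band term biases
  # the estimate by about (2/m)/sqrt(N_eff) radians, where N_eff is the
  # number of effective emitters: negligible for dense scenes (dye, cells),
  # noticeable for sparse bead fields.
  wf <- widefield_from_triplet(frames3)
  z <- vapply(frames3, function(f)
    dft_at(f * wf, k0[1], k0[2], x, y), complex(1))
  phases <- phases_nominal
  w_ratio <- (z[3] - z[1]) / (z[2] - z[1])
  d2_nom <- phases_nominal[2] - phases_nominal[1]
  g <- function(p2) Mod(1 + w_ratio * (exp(1i * p2) - 1))^2 - 1
  root <- tryCatch(
    stats::uniroot(g, c(d2_nom - 1, d2_nom + 1), tol = 1e-12)$root,
    error = function(e) NA_real_)
  if (is.finite(root)) {
    p3 <- Arg(1 + w_ratio * (exp(1i * root) - 1)) %% (2 * pi)
    phases <- (phases_nominal[1] + c(0, root, p3)) %% (2 * pi)
  }
  # modulation depth from the +1-band correlation amplitude; biased low by
  # the OTF overlap between the carrier-displaced and centred passbands
  # (diagnostic only -- reconstruction uses the configured depth)
  R_amp <- (z[2] - z[1]) / (exp(1i * phases[2]) - exp(1i * phases[1]))
  m_est <- 2 * Mod(R_amp) / sum(wf^2)
  if (!is.finite(m_est) || m_est < m_min)
    stop("no carrier found: estimated modulation depth below threshold",
         call. = FALSE)
  list(k0 = k0, k0_mag = sqrt(sum(k0^2)), phases = phases,
       m_est = m_est, contrast = contrast)
}

# Embed an unshifted N-grid spectrum centrally into an upsampled grid,
# scaled so the image mean (DC / n_pixels) is preserved.
embed_spectrum <- function(band, factor = 2L) {
  nr <- nrow(band); nc <- ncol(band)
  big <- matrix(0 + 0i, factor * nr, factor * nc)
  sh <- fft_shift(band)
  r0 <- (factor * nr) %/% 2 - nr %/% 2
  c0 <- (factor * nc) %/% 2 - nc %/% 2
  big[r0 + seq_len(nr), c0 + seq_len(nc)] <- sh
  ifft_shift(big) * factor^2
}

#' Recombine separated bands into the super-resolved image
#'
#' The +/- first-order bands are translated back by -/+ k0 with sub-pixel
#' accuracy (real-space phase ramps on a 2x upsampled grid), then all three
#' bands are merged with generalized Wiener weights
#' `conj(OTF_b) / (sum_b |OTF_b|^2 + w^2)` and a triangle apodization that
#' tapers linearly to zero at the extended cutoff `kc + |k0|`. Negative
#' values are retained in the returned image; clipping at zero is applied
#' only on export (the policy is recorded in the result).
#'
#' @param bands output of [separate_bands()].
#' @param k0 carrier `c(kx, ky)`, 1/um.
#' @param cfg an [optical_config()].
#' @param pixel_um pixel size of the input frames, micrometres.
#' @param wiener_w Wiener regularization (relative to the unit-normalized
#'   OTF; default 0.05).
#' @param apodize apply the triangle apodization (default TRUE).
#' @param upsample integer upsampling factor for the output grid
#'   (default 2, needed to represent the extended support).
#' @return list with `image` (real matrix, `upsample` times the input
#'   grid), `pixel_um` (output pixel size), `k_ext` (extended cutoff,
#'   1/um), `wiener_w`, `clip_policy`.
#' @export
recombine_wiener <- function(bands, k0, cfg, pixel_um, wiener_w = 0.05,
                             apodize = TRUE, upsample = 2L) {
  if (wiener_w <= 0) stop("wiener_w must be positive", call. = FALSE)
  nr <- nrow(bands$band0); nc <- ncol(bands$band0)
  nru <- upsample * nr; ncu <- upsample * nc
  pxu <- pixel_um / upsample
  B0 <- embed_spectrum(bands$band0, upsample)
  Bp <- embed_spectrum(bands$band_plus, upsample)
  Bm <- embed_spectrum(bands$band_minus, upsample)
  xu <- pixel_coords(ncu, pxu)
  yu <- pixel_coords(nru, pxu)
  ramp <- function(sign) {
    outer(exp(sign * 2i * pi * k0[2] * yu), exp(sign * 2i * pi * k0[1] * xu))
  }
  Bp <- stats::fft(ifft2(Bp) * ramp(-1))   # S(k) OTF(k + k0)
  Bm <- stats::fft(ifft2(Bm) * ramp(+1))   # S(k) OTF(k - k0)
  kxu <- fft_freq(ncu, pxu)
  kyu <- fft_freq(nru, pxu)
  kr0 <- sqrt(outer(kyu^2, kxu^2, `+`))
  krp <- sqrt(outer((kyu + k0[2])^2, (kxu + k0[1])^2, `+`))
  krm <- sqrt(outer((kyu - k0[2])^2, (kxu - k0[1])^2, `+`))
  H0 <- otf_value(cfg, kr0)
  Hp <- otf_value(cfg, krp)
  Hm <- otf_value(cfg, krm)
  num <- H0 * B0 + Hp * Bp + Hm * Bm      # OTFs are real
  den <- H0^2 + Hp^2 + Hm^2 + wiener_w^2
  spec <- num / den
  k_ext <- otf_cutoff(cfg) + sqrt(sum(k0^2))
  if (apodize) spec <- spec * pmax(0, 1 - kr0 / k_ext)
  list(image = Re(ifft2(spec)), pixel_um = pxu, k_ext = k_ext,
       wiener_w = wiener_w, clip_policy = "negatives retained; clip at export")
}

#' Measure the 1D resolution gain of a reconstruction over widefield
#'
#' `fourier_cutoff`: ratio of the spectral support cutoffs along the
#' modulation (x) axis, where the cutoff is the largest |kx| at which the
#' near-axis magnitude profile exceeds a spectral noise floor (default:
#' 3x the median magnitude over the outer 20% of the profile, with a
#' relative floor of `floor_min_frac` of the profile maximum for noise-free
#' data). `bead_fwhm`: ratio of mean bead FWHMs along x, beads detected as
#' bright local maxima of the widefield image.
#'
#' @param recon reconstructed image (matrix; pass the unapodized
#'   reconstruction for the `fourier_cutoff` method).
#' @param widefield widefield image (matrix).
#' @param pixel_recon_um,pixel_wf_um pixel sizes of the two images.
#' @param method `"fourier_cutoff"` or `"bead_fwhm"`.
#' @param floor_mult noise-floor multiplier (default 3).
#' @param floor_min_frac minimum floor as a fraction of the profile peak
#'   (guards noise-free data whose outer spectrum is exactly zero).
#' @return gain factor (>= 1 on noise-free data by construction).
#' @export
measure_gain <- function(recon, widefield, pixel_recon_um, pixel_wf_um,
                         method = c("fourier_cutoff", "bead_fwhm"),
                         floor_mult = 3, floor_min_frac = 1e-3) {
  method <- match.arg(method)
  if (method == "fourier_cutoff") {
    one_cut <- function(img, px) {
      p <- spectral_profile_x(img, px)
      floor_val <- max(floor_mult * stats::median(p$prof[p$outer]),
                       floor_min_frac * max(p$prof))
      last_above(p, floor_val)
    }
    return(one_cut(recon, pixel_recon_um) / one_cut(widefield, pixel_wf_um))
  }
  pk_w <- find_beads(widefield)
  if (nrow(pk_w) == 0) stop("no beads found in the widefield image", call. = FALSE)
  scale <- pixel_wf_um / pixel_recon_um
  cw <- c(nrow(widefield) %/% 2 + 1, ncol(widefield) %/% 2 + 1)
  cr <- c(nrow(recon) %/% 2 + 1, ncol(recon) %/% 2 + 1)
  f_w <- f_r <- numeric(0)
  for (i in seq_len(nrow(pk_w))) {
    fw <- profile_fwhm_x(widefield, pk_w[i, 1], pk_w[i, 2]) * pixel_wf_um
    rr <- round(cr + scale * (pk_w[i, ] - cw))
    loc <- refine_peak_local(recon, rr[1], rr[2], halfwin = 6L)
    fr <- profile_fwhm_x(recon, loc[1], loc[2]) * pixel_recon_um
    if (is.finite(fw) && is.finite(fr)) {
      f_w <- c(f_w, fw); f_r <- c(f_r, fr)
    }
  }
  if (!length(f_w)) stop("no measurable beads", call. = FALSE)
  mean(f_w) / mean(f_r)
}

# Near-axis spectral magnitude profile along |kx|: mean |F| over ky = 0 and
# two neighbouring rows each side, folded in +/- kx and lightly smoothed.
# `outer` marks the outermost frequencies, beyond any optical support on an
# adequately sampled grid, used for noise-floor estimates.
spectral_profile_x <- function(img, pixel_um) {
  Fm <- Mod(stats::fft(img - mean(img)))
  nr <- nrow(img); nc <- ncol(img)
  rows <- c(1L, 2L, 3L, nr - 1L, nr)
  prof_pos <- colMeans(Fm[rows, , drop = FALSE])
  kx <- fft_freq(nc, pixel_um)
  ord <- order(abs(kx))
  prof_raw <- prof_pos[ord]
  prof <- stats::filter(prof_raw, rep(1 / 3, 3), sides = 2)
  prof[is.na(prof)] <- prof_raw[is.na(prof)]
  k_abs <- abs(kx)[ord]
  list(k_abs = k_abs, prof = as.numeric(prof),
       outer = k_abs >= 0.88 * max(k_abs))
}

last_above <- function(p, floor_val) {
  above <- which(p$prof > floor_val)
  if (!length(above)) return(0)
  p$k_abs[max(above)]
}

# Local maxima above half the image maximum, separated by >= min_sep px.
find_beads <- function(img, frac = 0.3, min_sep = 8L) {
  nr <- nrow(img); nc <- ncol(img)
  thr <- frac * max(img)
  cand <- which(img >= thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 2 & cand[, 1] < nr - 1 &
                 cand[, 2] > 2 & cand[, 2] < nc - 1, , drop = FALSE]
  is_max <- apply(cand, 1, function(rc) {
    patch <- img[(rc[1] - 1):(rc[1] + 1), (rc[2] - 1):(rc[2] + 1)]
    img[rc[1], rc[2]] >= max(patch)
  })
  pk <- cand[is_max, , drop = FALSE]
  if (nrow(pk) <= 1) return(pk)
  keep <- rep(TRUE, nrow(pk))
  o <- order(img[pk], decreasing = TRUE)
  pk <- pk[o, , drop = FALSE]
  for (i in seq_len(nrow(pk))) {
    if (!keep[i]) next
    d <- sqrt((pk[, 1] - pk[i, 1])^2 + (pk[, 2] - pk[i, 2])^2)
    keep[d < min_sep & d > 0] <- FALSE
  }
  pk[keep, , drop = FALSE]
}

refine_peak_local <- function(img, r, c, halfwin = 6L) {
  r0 <- max(2, r - halfwin); r1 <- min(nrow(img) - 1, r + halfwin)
  c0 <- max(2, c - halfwin); c1 <- min(ncol(img) - 1, c + halfwin)
  sub <- img[r0:r1, c0:c1, drop = FALSE]
  w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  c(r0 + w[1] - 1L, c0 + w[2] - 1L)
}

# FWHM along x (columns) of the profile through (r, c), linear-interpolated
# half-maximum crossings, in pixels of img.
profile_fwhm_x <- function(img, r, c, halfwin = 20L) {
  c0 <- max(1, c - halfwin); c1 <- min(ncol(img), c + halfwin)
  p <- img[r, c0:c1]
  p <- p - min(p)
  pk <- which.max(p)
  half <- p[pk] / 2
  left <- right <- NA_real_
  for (i in seq(pk, 2)) if (p[i - 1] < half) {
    left <- (i - 1) + (half - p[i - 1]) / (p[i] - p[i - 1]); break
  }
  for (i in seq(pk, length(p) - 1)) if (p[i + 1] < half) {
    right <- i + (p[i] - half) / (p[i] - p[i + 1]); break
  }
  right - left
}

#' Full three-phase SIM reconstruction of one plane
#'
#' Chains carrier/phase estimation, band separation and Wiener
#' recombination for one 3-frame triplet, and computes the widefield
#' reference and (optionally) the Fourier-analysis resolution gain.
#'
#' @param frames3 list of 3 raw frames (matrices, ADU).
#' @param cfg an [optical_config()].
#' @param pixel_um object pixel size; defaults to [object_pixel_um()].
#' @param offset_adu camera offset subtracted before analysis.
#' @param phases_nominal commanded phase triple.
#' @param use_estimated_k0 use the cross-correlation carrier estimate in
#'   the recombination (`FALSE`: use the configuration's nominal carrier).
#' @param use_estimated_phases use the estimated phases in the band
#'   separation instead of the commanded triple. Off by default: the
#'   device drives the phases, and the estimate carries an
#'   object-sparsity-dependent bias (see
#'   [estimate_carrier_crosscorr()]).
#' @param modulation_depth modulation depth used in the separation
#'   (default 0.8, the simulator's default contrast); `NULL` falls back to
#'   the (OTF-overlap-biased) estimate.
#' @param wiener_w,apodize,upsample see [recombine_wiener()].
#' @param compute_gain also measure the Fourier-cutoff gain.
#' @return an object of class `sim_reconstruction`: fields `k0_est`,
#'   `phases_est`, `m_est`, `bands`, `recon` (matrix, upsampled grid),
#'   `widefield`, `pixel_um`, `pixel_um_recon`, `gain_measured` (or NA),
#'   `wiener_w`, `k_ext`, `clip_policy`.
#' @export
reconstruct_sim <- function(frames3, cfg, pixel_um = object_pixel_um(cfg),
                            offset_adu = 0,
                            phases_nominal = c(0, 2, 4) * pi / 3,
                            use_estimated_k0 = TRUE,
                            use_estimated_phases = FALSE,
                            modulation_depth = 0.8,
                            wiener_w = 0.05, apodize = TRUE, upsample = 2L,
                            compute_gain = FALSE) {
  frames3 <- lapply(frames3, function(f) f - offset_adu)
  est <- if (use_estimated_k0 || use_estimated_phases) {
    estimate_carrier_crosscorr(frames3, cfg, pixel_um,
                               phases_nominal = phases_nominal)
  } else {
    # estimation is diagnostic only here; a plane without enough signal to
    # locate the carrier still reconstructs with the commanded parameters
    tryCatch(estimate_carrier_crosscorr(frames3, cfg, pixel_um,
                                        phases_nominal = phases_nominal),
             error = function(e) list(k0 = c(NA_real_, NA_real_),
                                      phases = rep(NA_real_, 3),
                                      m_est = NA_real_))
  }
  phases <- if (use_estimated_phases) est$phases else phases_nominal
  k0 <- if (use_estimated_k0) est$k0
        else c(1 / (carrier_period(cfg) / 1000), 0)
  m <- modulation_depth %||% min(max(est$m_est, 0.05), 1)
  bands <- separate_bands(frames3, phases, m)
  rec <- recombine_wiener(bands, k0, cfg, pixel_um, wiener_w = wiener_w,
                          apodize = apodize, upsample = upsample)
  wf <- widefield_from_triplet(frames3)
  gain <- NA_real_
  if (compute_gain) {
    # the support metric uses the unapodized Wiener spectrum so both images
    # retain comparable noise plateaus beyond their optical supports
    rec_raw <- if (apodize)
      recombine_wiener(bands, k0, cfg, pixel_um, wiener_w = wiener_w,
                       apodize = FALSE, upsample = upsample)
    else rec
    gain <- measure_gain(rec_raw$image, wf, rec$pixel_um, pixel_um,
                         method = "fourier_cutoff")
  }
  structure(list(k0_est = est$k0, phases_est = est$phases,
                 m_est = est$m_est, bands = bands, recon = rec$image,
                 widefield = wf, pixel_um = pixel_um,
                 pixel_um_recon = rec$pixel_um, gain_measured = gain,
                 wiener_w = wiener_w, k_ext = rec$k_ext,
                 clip_policy = rec$clip_policy),
            class = "sim_reconstruction")
}

#' @export
print.sim_reconstruction <- function(x, ...) {
  cat("<sim_reconstruction>\n")
  cat(sprintf("  carrier: (%.4f, %.4f) 1/um -> period %.1f nm\n",
              x$k0_est[1], x$k0_est[2], 1000 / sqrt(sum(x$k0_est^2))))
  cat(sprintf("  phases (rad): %s | m = %.3f\n",
              paste(sprintf("%.3f", x$phases_est), collapse = ", "), x$m_est))
  if (is.finite(x$gain_measured))
    cat(sprintf("  measured 1D resolution gain: %.3f\n", x$gain_measured))
  invisible(x)
}

#' Export a reconstruction: TIFFs plus a JSON report
#'
#' Writes the reconstructed and widefield images as 32-bit float TIFFs
#' (negative reconstruction values clipped to zero at this point, per the
#' recorded policy) and a JSON report of carrier, phases, modulation depth,
#' gain and Wiener parameter.
#'
#' @param x a `sim_reconstruction`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the report path, invisibly.
#' @export
write_sim_reconstruction <- function(x, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rp <- file.path(dir, paste0(prefix, "_recon.tif"))
  wp <- file.path(dir, paste0(prefix, "_widefield.tif"))
  scale_unit <- function(img) {
    img <- pmax(img, 0)
    img / max(img, .Machine$double.eps)
  }
  tiff::writeTIFF(as_float32(scale_unit(x$recon)), rp, bits.per.sample = 32L)
  tiff::writeTIFF(as_float32(scale_unit(x$widefield)), wp, bits.per.sample = 32L)
  report <- file.path(dir, paste0(prefix, "_report.json"))
  jsonlite::write_json(list(k0_per_um = x$k0_est, phases_rad = x$phases_est,
                            m_est = x$m_est, gain_measured = x$gain_measured,
                            wiener_w = x$wiener_w, k_ext_per_um = x$k_ext,
                            pixel_um = x$pixel_um,
                            pixel_um_recon = x$pixel_um_recon,
                            clip_policy = x$clip_policy),
                       report, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
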