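cfg <- fix_cfg()

test_that("widefield is the triplet mean and cancels balanced modulation", {
  f <- matrix(runif(64), 8)
  expect_equal(widefield_from_triplet(list(f, f, f)), f)
  expect_error(widefield_from_triplet(list(f, f, matrix(0, 4, 4))),
               "shape")
  # balanced phases cancel for any m; unbalanced phases leave a residual
  s <- random_object(64, seed = 2)
  for (m in c(0.3, 0.8, 1)) {
    od <- oracle_sim_data(s, 791, c(0, 2, 4) * pi / 3, m)
    wf <- widefield_from_triplet(od$frames)
    plain <- oracle_sim_data(s, 791, 0, 0)$frames[[1]]
    expect_lt(max(abs(wf - plain)) / max(plain), 1e-6)
  }
  od_bad <- oracle_sim_data(s, 791, c(0, pi / 2, pi), 0.8)
  wf_bad <- widefield_from_triplet(od_bad$frames)
  plain <- oracle_sim_data(s, 791, 0, 0)$frames[[1]]
  expect_gt(max(abs(wf_bad - plain)) / max(plain), 0.01)
})

test_that("band separation equals brute-force constructed bands (oracle)", {
  s <- random_object(64, seed = 5)
  phases <- c(0, 2, 4) * pi / 3
  for (m in c(0.4, 0.8)) {
    od <- oracle_sim_data(s, 791, phases, m)
    bands <- separate_bands(od$frames, phases, m)
    for (b in names(bands)) {
      rel <- max(Mod(bands[[b]] - od$bands[[b]])) / max(Mod(od$bands[[b]]))
      expect_lt(rel, 1e-6)
    }
  }
  # non-equally-spaced (but distinct) phases still invert exactly
  ph2 <- c(0.2, 1.9, 4.4)
  od2 <- oracle_sim_data(s, 791, ph2, 0.7)
  b2 <- separate_bands(od2$frames, ph2, 0.7)
  expect_lt(max(Mod(b2$band_plus - od2$bands$band_plus)) /
              max(Mod(od2$bands$band_plus)), 1e-6)
  expect_error(separate_bands(od2$frames, c(0, 1, 1), 0.8), "degenerate")
})

test_that("carrier estimation recovers k0 to 0.5% and errors without modulation", {
  fr <- fix_triplet(fix_beads(256), 256)
  est <- estimate_carrier_crosscorr(fr, cfg, fix_px)
  k0_true <- 1000 / 791
  expect_lt(abs(est$k0_mag - k0_true) / k0_true, 0.005)
  expect_lt(abs(est$k0[2]), 0.02 * k0_true)
  expect_gt(est$m_est, 0.3)
  # no pattern, no carrier
  fr0 <- fix_triplet(fix_beads(128, n_beads = 10, seed = 2), 128, m = 0)
  expect_error(estimate_carrier_crosscorr(fr0, cfg, fix_px), "no carrier")
})

test_that("phase estimation tracks commanded and deviating phases on dense scenes", {
  dense <- fix_dense(256)
  # commanded triple, noise-free: RMS < 0.05 rad
  fr <- fix_triplet(dense, 256)
  est <- estimate_carrier_crosscorr(fr, cfg, fix_px)
  err <- (est$phases - est$phases[1]) - c(0, 2, 4) * pi / 3
  expect_lt(sqrt(mean(err^2)), 0.05)
  # deviating actual phases are detected, not parroted back
  true_ph <- c(0, 2.25, 4.05)
  frd <- fix_triplet(dense, 256, phases = true_ph)
  estd <- estimate_carrier_crosscorr(frd, cfg, fix_px)
  errd <- (estd$phases - estd$phases[1]) - (true_ph - true_ph[1])
  expect_lt(max(abs(errd)), 0.08)
  expect_gt(abs(estd$phases[2] - 2 * pi / 3), 0.08)  # deviation seen
  # default noise, 20 seeds: RMS < 0.15 rad
  errs <- vapply(1:20, function(s) {
    frn <- fix_triplet(fix_dense(256, seed = s), 256, noise = TRUE, seed = s)
    e <- estimate_carrier_crosscorr(frn, cfg, fix_px)
    sqrt(mean(((e$phases - e$phases[1]) - c(0, 2, 4) * pi / 3)^2))
  }, numeric(1))
  expect_lt(max(errs), 0.15)
})

test_that("Wiener recombination extends the support and conserves energy", {
  fr <- fix_triplet(fix_beads(256), 256)
  est <- estimate_carrier_crosscorr(fr, cfg, fix_px)
  bands <- separate_bands(fr, c(0, 2, 4) * pi / 3, 0.8)
  rec <- recombine_wiener(bands, est$k0, cfg, fix_px)
  wf <- widefield_from_triplet(fr)
  expect_equal(dim(rec$image), c(512, 512))
  expect_equal(rec$pixel_um, fix_px / 2)
  # mean intensity preserved within 5%
  expect_lt(abs(mean(rec$image) - mean(wf)) / mean(wf), 0.05)
  # Fourier support along x extends to kc + |k0| within one frequency bin
  spec <- Mod(stats::fft(rec$image))
  kx <- flowSIM:::fft_freq(512, rec$pixel_um)
  row0 <- spec[1, ]
  k_ext <- otf_cutoff(cfg) + est$k0_mag
  bin <- 1 / (512 * rec$pixel_um)
  support_max <- max(abs(kx[row0 > 1e-9 * max(row0)]))
  expect_lt(abs(support_max - k_ext), 1.5 * bin)
  expect_error(recombine_wiener(bands, est$k0, cfg, fix_px, wiener_w = 0),
               "positive")
})

test_that("two 300-nm beads are resolved by SIM but not widefield", {
  em <- data.frame(x_um = c(-0.15, 0.15), y_um = 0, z_um = 0,
                   brightness = 1e5)
  pair <- flowSIM:::new_phantom(em, "beads", fix_extent(128, z_half = 1), 1L)
  fr <- fix_triplet(pair, 128)
  rec <- reconstruct_sim(fr, cfg, use_estimated_k0 = FALSE)
  count_maxima <- function(img, frac = 0.3) {
    r <- which(img == max(img), arr.ind = TRUE)[1, 1]
    p <- img[r, ]
    sum(diff(sign(diff(p))) == -2 & p[2:(length(p) - 1)] > frac * max(p))
  }
  expect_equal(count_maxima(rec$widefield), 1)
  ri <- pmax(rec$recon, 0)
  expect_equal(count_maxima(ri), 2)
  # dip between the two reconstructed maxima is at least 20%
  r <- which(ri == max(ri), arr.ind = TRUE)[1, 1]
  p <- ri[r, ]
  ctr <- length(p) %/% 2 + 1
  win <- (ctr - 8):(ctr + 8)                    # +/- 0.43 um at 54 nm pixels
  pk <- win[which(diff(sign(diff(p[win]))) == -2) + 1]
  expect_equal(length(pk), 2)
  dip <- min(p[pk[1]:pk[2]])
  expect_gt(1 - dip / min(p[pk]), 0.2)
})

test_that("measured gain matches theory on low-noise beads and stays bounded", {
  fr <- fix_triplet(fix_beads(256, brightness = 1e6), 256, noise = TRUE,
                    seed = 3)
  camless <- reconstruct_sim(fr, cfg, compute_gain = TRUE)
  expect_equal(camless$gain_measured, 1.33, tolerance = 0.04)
  expect_lte(camless$gain_measured, theoretical_sim_gain(cfg) + 0.02)
  # identical images give unit gain
  wf <- camless$widefield
  expect_equal(measure_gain(wf, wf, fix_px, fix_px, "fourier_cutoff"), 1)
  # bead-FWHM method agrees within its deconvolution-inflated band
  g_bead <- measure_gain(camless$recon, wf, camless$pixel_um_recon, fix_px,
                         method = "bead_fwhm")
  expect_gt(g_bead, 1)
  expect_lt(g_bead, 1.6)
})

test_that("reconstruction is reported with carrier, phases and policies", {
  fr <- fix_triplet(fix_beads(128, n_beads = 10, seed = 4), 128)
  rec <- reconstruct_sim(fr, cfg)
  expect_s3_class(rec, "sim_reconstruction")
  expect_equal(1000 / rec$k0_est[1], 791, tolerance = 8)
  expect_match(rec$clip_policy, "clip at export")
  expect_output(print(rec), "carrier")
  dir <- withr::local_tempdir()
  write_sim_reconstruction(rec, dir, "t")
  expect_true(file.exists(file.path(dir, "t_recon.tif")))
  rep <- jsonlite::read_json(file.path(dir, "t_report.json"),
                             simplifyVector = TRUE)
  expect_equal(rep$wiener_w, 0.05)
  # exported TIFF is non-negative (clip applied at export only)
  expect_gte(min(tiff::readTIFF(file.path(dir, "t_recon.tif"))), 0)
})
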