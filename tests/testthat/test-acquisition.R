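cfg <- fix_cfg(); lsq <- fix_ls(); psm <- fix_psm()

test_that("empty phantom renders offset plus read noise only", {
  cam <- fix_cam(64)
  empty <- flowSIM:::new_phantom(
    data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
               brightness = numeric(0)), "beads",
    fix_extent(64), 1L)
  f0 <- render_frame(empty, cfg, lsq, cam, noise = FALSE)
  expect_equal(f0, matrix(cam$offset_adu, 64, 64))
  fn <- render_frame(empty, cfg, lsq, cam, noise = TRUE, seed = 2)
  expect_equal(mean(fn), cam$offset_adu, tolerance = 0.05)
  expect_equal(sd(fn), cam$read_noise_e / cam$gain_e_per_adu, tolerance = 0.1)
  # reproducible under seed
  expect_identical(fn, render_frame(empty, cfg, lsq, cam, noise = TRUE,
                                    seed = 2))
})

test_that("a dye slab renders the sinusoidal fringe at the carrier period", {
  cam <- fix_cam(64)
  dye <- make_dye_phantom(fix_extent(64, z_half = 0.3, frac = 1.2),
                          density_per_um3 = 120, brightness = 50, seed = 8)
  f <- render_frame(dye, cfg, lsq, cam, phase = 0, modulation_depth = 1,
                    noise = FALSE) - cam$offset_adu
  prof <- colMeans(f)
  # spectral peak of the profile sits at the fringe frequency
  amp <- Mod(fft(prof - mean(prof)))[2:32]
  k_measured <- flowSIM:::fft_freq(64, fix_px)[which.max(amp) + 1]
  expect_equal(k_measured, 1 / 0.791, tolerance = 0.1)
  # fringe phase matches the commanded phase: peak of the cosine at x = 0
  x <- flowSIM:::pixel_coords(64, fix_px)
  expect_gt(cor(prof, cos(2 * pi * x / 0.791)), 0.85)
})

test_that("out-of-sheet emitters are suppressed by the Gaussian sheet profile", {
  cam <- fix_cam(64)
  mk <- function(z) flowSIM:::new_phantom(
    data.frame(x_um = 0, y_um = 0, z_um = z, brightness = 1000), "beads",
    fix_extent(64, z_half = 5), 1L)
  in_focus <- sum(render_frame(mk(0), cfg, lsq, cam, noise = FALSE) -
                    cam$offset_adu)
  defocus <- sum(render_frame(mk(3 * 1.1), cfg, lsq, cam, noise = FALSE) -
                   cam$offset_adu)
  expect_lt(defocus / in_focus, 0.01)
})

test_that("rendering is linear in the phantom (expectation)", {
  cam <- fix_cam(64)
  a <- fix_beads(64, n_beads = 4, seed = 1)
  b <- fix_beads(64, n_beads = 4, seed = 2)
  merged <- flowSIM:::new_phantom(rbind(a$emitters, b$emitters), "beads",
                                  a$extent_um, 1L)
  fa <- render_frame(a, cfg, lsq, cam, noise = FALSE)
  fb <- render_frame(b, cfg, lsq, cam, noise = FALSE)
  fm <- render_frame(merged, cfg, lsq, cam, noise = FALSE)
  expect_equal(fm - cam$offset_adu,
               (fa - cam$offset_adu) + (fb - cam$offset_adu),
               tolerance = 1e-9)
})

test_that("mean of the three expected phase frames equals unmodulated illumination", {
  fr <- fix_triplet(fix_beads(128, n_beads = 8, seed = 3), 128)
  wf <- widefield_from_triplet(fr)
  cam <- fix_cam(128)
  unmod <- render_frame(fix_beads(128, n_beads = 8, seed = 3), cfg, lsq, cam,
                        modulation_depth = 0, noise = FALSE) - cam$offset_adu
  expect_lt(max(abs(wf - unmod)) / max(unmod), 1e-6)
})

test_that("total expected dye signal is independent of the commanded phase", {
  cam <- fix_cam(64)
  dye <- make_dye_phantom(fix_extent(64, z_half = 0.3, frac = 1.4),
                          density_per_um3 = 60, brightness = 50, seed = 5)
  totals <- vapply(c(0, 2, 4) * pi / 3, function(ph)
    sum(render_frame(dye, cfg, lsq, cam, phase = ph, modulation_depth = 0.8,
                     noise = FALSE)), numeric(1))
  expect_lt(diff(range(totals)) / mean(totals), 0.005)
})

test_that("calibration sweep has the documented layout and monotone fringe motion", {
  cam <- camera_model(roi_px = c(32, 256), frame_rate_hz = 100)
  dye <- make_dye_phantom(list(x = c(-15, 15), y = c(-2.5, 2.5),
                               z = c(-1, 1)),
                          density_per_um3 = 100, brightness = 60, seed = 2)
  protocol <- acquisition_protocol("calibration_sweep")
  stack <- run_calibration_sweep(dye, cfg, lsq, psm, cam, protocol,
                                 noise = FALSE, seed = 1)
  # 12 voltages (2 to 7.5 V in 0.5 V increments) x 8 repetitions
  expect_equal(length(stack$frames), 96)
  expect_equal(unique(stack$meta$voltage_V), seq(2, 7.5, 0.5))
  # repetition-major ordering
  expect_equal(stack$meta$voltage_V[1:12], seq(2, 7.5, 0.5))
  expect_equal(stack$meta$rep[1:13], c(rep(1L, 12), 2L))
  # fringe moves monotonically with voltage (quadratic phase law): track
  # the carrier phase of each profile and check all steps share one sign
  x <- flowSIM:::pixel_coords(256, fix_px)
  carrier_phase <- vapply(stack$frames[1:12], function(f)
    Arg(sum(colMeans(f) * exp(-2i * pi * x / 0.791))), numeric(1))
  steps <- diff(carrier_phase)
  steps <- (steps + pi) %% (2 * pi) - pi    # principal value per step
  expect_true(all(steps > 0) || all(steps < 0))
  # single voltage, single repetition
  p1 <- acquisition_protocol("calibration_sweep", sweep_voltages = 3,
                             sweep_reps = 1)
  expect_equal(length(run_calibration_sweep(dye, cfg, lsq, psm, cam, p1,
                                            noise = FALSE)$frames), 1)
})

test_that("flow scan advances 0.2 um per frame and cycles three phases", {
  cam <- fix_cam(32, frame_rate_hz = 50)
  cell <- make_cell_phantom(radius_um = 1.2, shell_thickness_um = 0.2,
                            n_shell = 100, n_vesicles = 0, seed = 1)
  stack <- run_flow_scan(cell, flow_trajectory(10, -7.5, 7.5), cfg, lsq, psm,
                         cam, acquisition_protocol("flow_scan"),
                         noise = FALSE, seed = 1)
  expect_equal(diff(stack$meta$flow_um)[1], 0.2)
  expect_equal(stack$meta$phase_idx[1:7], c(0L, 1L, 2L, 0L, 1L, 2L, 0L))
  expect_equal(stack$meta$phase_rad[1:3], c(0, 2, 4) * pi / 3,
               tolerance = 0.01)
  # a 15-um span at 10 um/s and 50 Hz yields 25 complete triplets
  expect_equal(length(group_triplets(stack)), 25)
  expect_error(run_flow_scan(cell, flow_trajectory(10, 0, 0.3), cfg, lsq,
                             psm, cam, acquisition_protocol("flow_scan")),
               "shorter than one")
})

test_that("protocol and camera validation rejects bad configurations", {
  expect_error(acquisition_protocol(sweep_voltages = c(3, 2)), "increasing")
  expect_error(acquisition_protocol(phase_voltages = c(0, 1)), "3 voltages")
  expect_error(camera_model(frame_rate_hz = 500), "400 Hz")
  expect_error(frame_stack(list(matrix(0, 2, 2)),
                           data.frame(frame = 0:1), 0.1),
               "match the frame count")
  expect_error(frame_stack(list(matrix(0, 2, 2), matrix(0, 3, 3)),
                           data.frame(frame = 0:1), 0.1), "one shape")
})
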