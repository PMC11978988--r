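# Synthetic 1D fringe profiles (no rendering) exercise each analysis step;
# one small noise-free rendered sweep closes the loop end to end.

fringe_profile <- function(n = 700, period = 7.3, phase = 0, amp = 1,
                           envelope = NULL) {
  x <- seq_len(n)
  p <- amp * cos(2 * pi * x / period + phase)
  if (!is.null(envelope)) p <- p + envelope(x)
  p
}

test_that("repetition averaging groups by voltage and reduces noise by sqrt(reps)", {
  f <- matrix(rnorm(32 * 32), 32)
  frames <- c(replicate(3, f + 1, simplify = FALSE),
              replicate(3, f + 2, simplify = FALSE))
  meta <- data.frame(frame = 0:5, time_s = 0, voltage_V = rep(c(2, 2.5), 3),
                     phase_idx = NA, phase_rad = 0, flow_um = NA,
                     rep = rep(1:3, each = 2))
  stack <- frame_stack(frames[c(1, 4, 2, 5, 3, 6)], meta, 0.1)
  avg <- average_repetitions(stack)
  expect_equal(length(avg$frames), 2)
  expect_equal(avg$meta$voltage_V, c(2, 2.5))
  expect_equal(avg$frames[[1]], f + 1)
  # white-noise SD shrinks by sqrt(8)
  noise_frames <- lapply(1:8, function(i) matrix(rnorm(64 * 64, sd = 4), 64))
  ns <- frame_stack(noise_frames,
                    data.frame(frame = 0:7, time_s = 0, voltage_V = 3,
                               phase_idx = NA, phase_rad = 0, flow_um = NA,
                               rep = 1:8), 0.1)
  ratio <- 4 / sd(average_repetitions(ns)$frames[[1]])
  expect_gt(ratio, 2.3); expect_lt(ratio, 3.4)
  bad <- frame_stack(frames[1:5], meta[1:5, ], 0.1)
  expect_error(average_repetitions(bad), "unequal repetition")
})

test_that("profile extraction averages the requested row band", {
  f <- matrix(rep(1:10, each = 6), nrow = 6)
  expect_equal(extract_profile(f), as.numeric(1:10))
  expect_equal(extract_profile(f, row_band = 2), f[2, ])
  f2 <- matrix(0, 6, 10); f2[2, ] <- 1:10
  expect_equal(extract_profile(f2, row_band = 2), as.numeric(1:10))
  expect_error(extract_profile(f, row_band = integer(0)), "empty")
  expect_error(extract_profile(f, row_band = 99), "outside")
})

test_that("spectral high-pass removes the envelope but preserves the carrier", {
  # an integer number of periods has no spectral leakage: exact preservation
  carrier7 <- fringe_profile(700, 7, 0.4)
  hp7 <- highpass_profile(carrier7, 7)
  expect_lt(max(abs(hp7 - (carrier7 - mean(carrier7)))), 1e-9)
  # a non-commensurate period leaks at the window edges only; the interior
  # is preserved within 2%
  carrier <- fringe_profile(700, 7.3, 0.4)
  hp <- highpass_profile(carrier, 7.3)
  interior <- 30:670
  expect_lt(max(abs((hp - (carrier - mean(carrier)))[interior])) /
              max(carrier), 0.02)
  # slow Gaussian envelope is rejected to <= 5% residual
  env <- function(x) 10 * exp(-(x - 350)^2 / (2 * 120^2))
  hp_env <- highpass_profile(env(seq_len(700)), 7.3)
  expect_lt(max(abs(hp_env)) / 10, 0.05)
  expect_equal(highpass_profile(rep(3, 700), 7.3), rep(0, 700),
               tolerance = 1e-12)
  expect_lt(abs(mean(highpass_profile(carrier + env(seq_len(700)), 7.3))),
            1e-9)
  expect_error(highpass_profile(rep(1, 10), 7.3), "shorter")
})

test_that("peak detection is sub-pixel accurate on smooth carriers", {
  pk <- detect_peaks(highpass_profile(fringe_profile(700, 7.3), 7.3))
  expect_true(length(pk) %in% c(95, 96))
  expect_true(all(abs(diff(pk) - 7.3) < 0.05))
  # pure triangle peaks are recovered exactly (symmetric parabola)
  tri <- rep(c(rep(0, 10), 1, 2, 3, 2, 1, rep(0, 10)), 3)
  tri_pk <- detect_peaks(tri - mean(tri), prominence_frac = 0.5)
  expect_equal(tri_pk, c(13, 38, 63))
  # a quarter-pixel translation moves every peak by 0.25 +/- 0.02 px
  # (a pure cosine is already zero-mean, so no high-pass is needed)
  a <- detect_peaks(fringe_profile(700, 7.3, 0))
  b <- detect_peaks(fringe_profile(700, 7.3, -2 * pi * 0.25 / 7.3))
  shifts <- b[seq_along(a)] - a
  shifts <- shifts[abs(shifts) < 1]
  expect_true(all(abs(shifts - 0.25) < 0.02))
  expect_error(detect_peaks(c(0, 1, 0)), "too short")
})

test_that("shift tracking recovers translations and the pooled period", {
  pk0 <- detect_peaks(highpass_profile(fringe_profile(2000, 7.3), 7.3))
  same <- estimate_shift_and_period(list(pk0, pk0), c(2, 2.5))
  expect_equal(same$shifts_px, 0)
  expect_equal(same$phases_rad, c(0, 0))
  expect_equal(same$period_px, 7.3, tolerance = 0.01)
  expect_false(same$low_confidence)
  # translation by period/3 reads as a 2 pi / 3 phase step
  pk1 <- detect_peaks(highpass_profile(
    fringe_profile(2000, 7.3, -2 * pi / 3), 7.3))
  shifted <- estimate_shift_and_period(list(pk0, pk1), c(2, 2.5))
  expect_equal(abs(shifted$phases_rad[2]), 2 * pi / 3, tolerance = 0.02)
  # a near-half-period jump is ambiguous and cannot be tracked
  expect_error(estimate_shift_and_period(list(pk0, pk0 + 7.3 * 0.49),
                                         c(2, 3)),
               "too large")
  expect_error(estimate_shift_and_period(list(pk0), 2), "two voltage")
})

test_that("round trip: peaks generated by the quadratic law refit it", {
  volts <- seq(2, 7.5, 0.5)
  a_true <- (4 * pi / 3) / 5.86^2
  peaks <- lapply(volts, function(v)
    detect_peaks(highpass_profile(
      fringe_profile(2000, 7.3, -a_true * v^2), 7.3)))
  core <- estimate_shift_and_period(peaks, volts)
  fit <- fit_phase_vs_voltage(core$phases_rad, core$voltages)
  expect_gt(fit$r_squared, 0.999)
  expect_lt(abs(fit$a - a_true) / a_true, 0.01)
  expect_equal(unname(fit$solved_voltages), c(0, 4.14, 5.86),
               tolerance = 0.011)
  expect_true(fit$monotone)
})

test_that("phase-vs-voltage fit solves the drive triple and scales correctly", {
  volts <- seq(2, 7.5, 0.5)
  a <- (4 * pi / 3) / 5.86^2
  phases <- a * (volts^2 - volts[1]^2)
  fit <- fit_phase_vs_voltage(phases, volts)
  expect_equal(unname(fit$solved_voltages), c(0, 4.14, 5.86))
  expect_equal(fit$residuals, rep(0, length(volts)), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # doubling the coefficient scales the solved voltages by 1/sqrt(2)
  fit2 <- fit_phase_vs_voltage(2 * phases, volts)
  expect_equal(unname(fit2$solved_voltages),
               round(unname(fit$solved_voltages) / sqrt(2), 2),
               tolerance = 0.011)
})

test_that("phase estimates are invariant to a smooth illumination envelope", {
  volts <- c(2, 3, 4)
  a_true <- (4 * pi / 3) / 5.86^2
  env <- function(x) 3 * exp(-(x - 1000)^2 / (2 * (3 * 7.3 * 10)^2))
  get_phases <- function(with_env) {
    peaks <- lapply(volts, function(v) {
      pr <- fringe_profile(2000, 7.3, -a_true * v^2,
                           envelope = if (with_env) env else NULL)
      detect_peaks(highpass_profile(pr, 7.3))
    })
    estimate_shift_and_period(peaks, volts)$phases_rad
  }
  expect_lt(max(abs(get_phases(TRUE) - get_phases(FALSE))), 0.05)
})

test_that("noise-free rendered sweep recovers period and coefficient to <1%", {
  cfg <- fix_cfg()
  cam <- camera_model(roi_px = c(32, 700), frame_rate_hz = 100)
  dye <- make_dye_phantom(list(x = c(-39, 39), y = c(-2.5, 2.5),
                               z = c(-1, 1)),
                          density_per_um3 = 100, brightness = 60, seed = 7)
  protocol <- acquisition_protocol("calibration_sweep", sweep_reps = 1)
  stack <- run_calibration_sweep(dye, cfg, fix_ls(), fix_psm(), cam,
                                 protocol, noise = FALSE, seed = 1)
  res <- calibrate_sweep(stack, cfg)
  expect_lt(abs(res$period_nm - 791) / 791, 0.005)
  a_true <- (4 * pi / 3) / 5.86^2
  expect_lt(abs(res$fit$a - a_true) / a_true, 0.01)
  expect_true(all(res$peaks_used >= 21))
  expect_false(res$low_confidence)
  expect_equal(unname(res$solved_voltages[2]), 4.14, tolerance = 0.02)
  # result serialization
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_calibration_result(res, jp, cp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$period_nm, res$period_nm, tolerance = 1e-9)
  tab <- read.csv(cp)
  expect_equal(nrow(tab), 12)
  expect_equal(tab$phase_rad, res$phases_rad, tolerance = 1e-9)
})
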