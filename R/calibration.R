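# Fringe-calibration analysis of a voltage-sweep stack: repetition
# averaging, line-profile extraction, spectral high-pass, sub-pixel peak
# tracking, pairwise shift averaging (>20 peaks per step), fringe-period
# estimation, and the quadratic phase-vs-voltage fit that yields the drive
# voltages of the three-phase protocol.

#' Average sweep repetitions pixel-wise
#'
#' Groups frames by drive voltage and averages across repetitions, giving
#' one low-noise frame per voltage (white-noise SD shrinks by sqrt(reps)).
#'
#' @param stack a [frame_stack()] from [run_calibration_sweep()].
#' @return a [frame_stack()] with one frame per voltage, ordered by voltage.
#' @export
average_repetitions <- function(stack) {
  v <- stack$meta$voltage_V
  if (anyNA(v)) stop("stack metadata lacks voltages", call. = FALSE)
  groups <- split(seq_along(v), v)
  counts <- lengths(groups)
  if (length(unique(counts)) != 1)
    stop("unequal repetition counts per voltage", call. = FALSE)
  volts <- as.numeric(names(groups))
  ord <- order(volts)
  frames <- lapply(groups[ord], function(idx)
    Reduce(`+`, stack$frames[idx]) / length(idx))
  meta <- data.frame(frame = seq_along(ord) - 1L,
                     time_s = NA_real_,
                     voltage_V = volts[ord],
                     phase_idx = NA_integer_,
                     phase_rad = vapply(groups[ord], function(idx)
                       stack$meta$phase_rad[idx[1]], numeric(1)),
                     flow_um = NA_real_, rep = NA_integer_)
  frame_stack(frames, meta, stack$pixel_um)
}

#' Extract a fringe line profile from a frame
#'
#' Column-wise mean over a band of rows chosen in a region of uniform light
#' sheet; the profile length equals the frame width.
#'
#' @param frame numeric matrix (rows = y, cols = x).
#' @param row_band integer vector of row indices to average (default: the
#'   central half of the frame).
#' @return numeric vector of length `ncol(frame)`.
#' @export
extract_profile <- function(frame, row_band = NULL) {
  nr <- nrow(frame)
  if (is.null(row_band)) row_band <- seq.int(nr %/% 4 + 1L, nr - nr %/% 4)
  if (length(row_band) == 0 || any(row_band < 1) || any(row_band > nr))
    stop("row band empty or outside the frame", call. = FALSE)
  colMeans(frame[row_band, , drop = FALSE])
}

#' High-pass a fringe profile
#'
#' Removes the slow light-sheet envelope without touching the fringe
#' carrier, using a smooth raised-cosine spectral mask: frequencies below
#' `cutoff_frac` of the expected carrier are rejected, the carrier itself is
#' preserved within 2%, and the output is zero-mean.
#'
#' @param profile numeric vector.
#' @param period_px expected fringe period in pixels.
#' @param cutoff_frac mask cutoff as a fraction of the carrier frequency
#'   (default 0.3).
#' @return filtered profile, same length.
#' @export
highpass_profile <- function(profile, period_px, cutoff_frac = 0.3) {
  n <- length(profile)
  if (n < 4 * period_px)
    stop("profile shorter than four fringe periods", call. = FALSE)
  f <- abs(fft_freq(n))               # cycles/px
  kcar <- 1 / period_px
  lo <- cutoff_frac * kcar * 0.7      # fully rejected below
  hi <- cutoff_frac * kcar * 1.3      # fully passed above
  mask <- ifelse(f <= lo, 0,
                 ifelse(f >= hi, 1, 0.5 - 0.5 * cos(pi * (f - lo) / (hi - lo))))
  mask[1] <- 0                        # exact DC removal
  Re(stats::fft(stats::fft(profile) * mask, inverse = TRUE)) / n
}

#' Detect fringe peaks with sub-pixel refinement
#'
#' Local maxima of a high-passed profile above a prominence floor, each
#' refined to sub-pixel position by 3-point interpolation. For periodic
#' profiles the refinement uses the sinusoid-exact estimator
#' `delta = atan((c - a) / (2 b sin k)) / k` with the local wavenumber `k`
#' taken from the median integer peak spacing; isolated (non-periodic)
#' peaks fall back to the symmetric parabola, which is exact for them.
#'
#' @param profile high-passed (zero-mean) fringe profile.
#' @param prominence_frac floor as a fraction of the profile maximum
#'   (default 0.1).
#' @return strictly increasing sub-pixel peak positions (1-based pixels).
#' @export
detect_peaks <- function(profile, prominence_frac = 0.1) {
  n <- length(profile)
  floor_val <- prominence_frac * max(profile)
  i <- which(profile[-c(1, n)] > profile[-c(n - 1, n)] &
               profile[-c(1, n)] >= profile[-c(1, 2)]) + 1L
  i <- i[profile[i] >= floor_val]
  if (length(i) < 3)
    stop("profile too short for calibration: fewer than 3 peaks", call. = FALSE)
  a <- profile[i - 1L]; b <- profile[i]; cc <- profile[i + 1L]
  denom <- a - 2 * b + cc
  delta <- ifelse(abs(denom) > 0, 0.5 * (a - cc) / denom, 0)
  # two-pass: the parabola refines positions enough to estimate the true
  # (sub-pixel) period, which the sinusoid-exact formula then needs as k
  per_est <- stats::median(diff(sort(i + delta)))
  if (is.finite(per_est) && per_est >= 4) {
    k <- 2 * pi / per_est
    ok <- b > 0
    delta[ok] <- atan((cc[ok] - a[ok]) / (2 * b[ok] * sin(k))) / k
  }
  sort(i + delta)
}

#' Track fringe shifts across voltage steps and estimate the period
#'
#' Pools inter-peak spacings over all voltage steps into one mean fringe
#' period, matches peaks between consecutive steps by nearest neighbour
#' within half a period, averages the matched displacements into a per-step
#' shift, and converts the cumulative shift into phase via
#' `phase = 2 pi * shift / period`. The sign of the cumulative phase is
#' chosen so that it increases with voltage (the geometric shift direction
#' depends only on fringe orientation). Any step whose matched-peak count
#' falls below 21 flags the result as low-confidence.
#'
#' @param peaks_by_voltage list of sub-pixel peak-position vectors, one per
#'   voltage step, ordered by voltage.
#' @param voltages the corresponding drive voltages.
#' @return list with `period_px`, `shifts_px` (length `n_steps - 1`),
#'   `phases_rad` (cumulative, length `n_steps`, starting at 0),
#'   `peaks_used`, `low_confidence`, `voltages`.
#' @export
estimate_shift_and_period <- function(peaks_by_voltage, voltages) {
  ns <- length(peaks_by_voltage)
  if (ns < 2) stop("need at least two voltage steps", call. = FALSE)
  stopifnot(length(voltages) == ns)
  spacings <- unlist(lapply(peaks_by_voltage, diff))
  # trimmed mean: an occasionally missed peak leaves a double-width gap
  # that would otherwise inflate the pooled mean spacing
  med <- stats::median(spacings)
  period <- mean(spacings[spacings > 0.5 * med & spacings < 1.5 * med])
  shifts <- numeric(ns - 1)
  used <- integer(ns - 1)
  for (j in seq_len(ns - 1)) {
    a <- peaks_by_voltage[[j]]
    b <- peaks_by_voltage[[j + 1]]
    near <- vapply(b, function(p) {
      k <- which.min(abs(a - p)); p - a[k]
    }, numeric(1))
    # nearest-neighbour matching caps |displacement| at half a period, so a
    # median close to that cap means the step is ambiguous, not trackable
    if (stats::median(abs(near)) > 0.45 * period)
      stop("phase step too large to track between voltages ",
           voltages[j], " and ", voltages[j + 1], call. = FALSE)
    keep <- abs(near) <= period / 2
    shifts[j] <- mean(near[keep])
    used[j] <- sum(keep)
  }
  cum <- cumsum(c(0, shifts))
  if (sum(shifts) < 0) cum <- -cum   # orient phase to increase with voltage
  list(period_px = period,
       shifts_px = shifts,
       phases_rad = 2 * pi * cum / period,
       peaks_used = used,
       low_confidence = any(used < 21),
       voltages = voltages)
}

#' Fit the quadratic phase-vs-voltage law and solve the SIM drive triple
#'
#' Least-squares fit of the zero-offset power law `phase = a * V^2`,
#' expressed relative to the first sweep voltage (the measured cumulative
#' phase is zero there): `phase_i = a * (V_i^2 - V_1^2)`. The drive
#' voltages for phases 0, 2pi/3 and 4pi/3 are `sqrt(phase / a)`, reported
#' to 0.01 V.
#'
#' @param phases cumulative phases, radians (first element 0).
#' @param voltages drive voltages, volts.
#' @return list with `a` (rad/V^2), `residuals`, `r_squared`, `monotone`,
#'   `solved_voltages` (named, volts).
#' @export
fit_phase_vs_voltage <- function(phases, voltages) {
  stopifnot(length(phases) == length(voltages), length(phases) >= 3)
  monotone <- all(diff(phases) >= -1e-9)
  u <- voltages^2 - voltages[1]^2
  a <- sum(phases * u) / sum(u^2)
  fitted <- a * u
  res <- phases - fitted
  ss_tot <- sum((phases - mean(phases))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  targets <- c(0, 2 * pi / 3, 4 * pi / 3)
  solved <- round(sqrt(targets / a), 2)
  names(solved) <- c("phi_0", "phi_2pi3", "phi_4pi3")
  list(a = a, residuals = res, r_squared = r2, monotone = monotone,
       solved_voltages = solved)
}

#' Full fringe calibration of a voltage-sweep stack
#'
#' Runs the complete analysis chain: repetition averaging, line-profile
#' extraction over a uniform row band, spectral high-pass, sub-pixel peak
#' detection, shift/period estimation and the quadratic phase-vs-voltage
#' fit.
#'
#' @param stack a [frame_stack()] from [run_calibration_sweep()].
#' @param cfg the [optical_config()] used for acquisition (supplies the
#'   expected period prior and the pixel size for the nm conversion).
#' @param row_band rows to average for the profile (default: central half).
#' @param cutoff_frac high-pass cutoff as a fraction of the carrier.
#' @param prominence_frac peak prominence floor.
#' @return an object of class `calibration_result` with fields
#'   `period_px`, `period_nm`, `shifts_px`, `phases_rad`, `peaks_used`,
#'   `fit`, `solved_voltages`, `low_confidence`, `voltages`.
#' @export
calibrate_sweep <- function(stack, cfg, row_band = NULL, cutoff_frac = 0.3,
                            prominence_frac = 0.1) {
  avg <- average_repetitions(stack)
  period_prior_px <- (carrier_period(cfg) / 1000) / stack$pixel_um
  peaks <- lapply(avg$frames, function(f) {
    pr <- extract_profile(f, row_band)
    hp <- highpass_profile(pr, period_prior_px, cutoff_frac)
    detect_peaks(hp, prominence_frac)
  })
  core <- estimate_shift_and_period(peaks, avg$meta$voltage_V)
  fit <- fit_phase_vs_voltage(core$phases_rad, core$voltages)
  structure(c(core,
              list(period_nm = core$period_px * stack$pixel_um * 1000,
                   fit = fit, solved_voltages = fit$solved_voltages)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat(sprintf("  fringe period: %.3f px = %.1f nm%s\n", x$period_px,
              x$period_nm, if (x$low_confidence) "  [LOW CONFIDENCE]" else ""))
  cat(sprintf("  phase law: a = %.5f rad/V^2 (R^2 = %.5f)\n",
              x$fit$a, x$fit$r_squared))
  cat(sprintf("  solved drive voltages (0, 2pi/3, 4pi/3): %s V\n",
              paste(sprintf("%.2f", x$solved_voltages), collapse = ", ")))
  invisible(x)
}

#' Write a calibration result as JSON + CSV (+ optional plot)
#'
#' @param result a `calibration_result`.
#' @param json_path output JSON path (full result).
#' @param csv_path output CSV path of `(voltage_V, shift_px, phase_rad)`.
#' @param plot_path optional PNG path of the phase-vs-voltage fit.
#' @return `json_path`, invisibly.
#' @export
write_calibration_result <- function(result, json_path, csv_path,
                                     plot_path = NULL) {
  out <- unclass(result)
  out$fit$residuals <- as.numeric(out$fit$residuals)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(voltage_V = result$voltages,
                              shift_px = c(0, result$shifts_px),
                              phase_rad = result$phases_rad),
                   csv_path, row.names = FALSE)
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 640, height = 480)
    on.exit(grDevices::dev.off())
    graphics::plot(result$voltages^2, result$phases_rad,
                   xlab = expression(V^2 ~ "(V"^2 * ")"),
                   ylab = "cumulative phase (rad)",
                   main = "Thermal shifter: phase vs dissipated power")
    graphics::abline(-result$fit$a * result$voltages[1]^2, result$fit$a,
                     col = "red")
  }
  invisible(json_path)
}
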