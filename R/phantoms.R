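# Emitter-based phantom generators. A phantom is a table of point emitters
# (x, y, z in micrometres, brightness in expected photons/frame at the focal
# sheet) plus a kind tag, a bounding box and the seed that produced it.
# Scaling by sheet intensity and defocus happens in the acquisition
# simulator, not here.

new_phantom <- function(emitters, kind, extent_um, seed, params = list()) {
  stopifnot(is.data.frame(emitters),
            all(c("x_um", "y_um", "z_um", "brightness") %in% names(emitters)))
  if (nrow(emitters) > 0 && any(emitters$brightness <= 0))
    stop("emitter brightness must be positive", call. = FALSE)
  structure(list(emitters = emitters, kind = kind, extent_um = extent_um,
                 seed = seed, params = params),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom: %s> %d emitters, seed %d\n", x$kind,
              nrow(x$emitters), x$seed))
  ext <- x$extent_um
  cat(sprintf("  extent x[%g, %g] y[%g, %g] z[%g, %g] um\n",
              ext$x[1], ext$x[2], ext$y[1], ext$y[2], ext$z[1], ext$z[2]))
  invisible(x)
}

as_extent <- function(extent_um) {
  stopifnot(is.list(extent_um), all(c("x", "y", "z") %in% names(extent_um)))
  lapply(extent_um[c("x", "y", "z")], function(r) {
    stopifnot(length(r) == 2, r[2] >= r[1])
    as.numeric(r)
  })
}

#' Uniform-dye phantom (rhodamine-filled channel proxy)
#'
#' Homogeneous Poisson point process of equal-brightness emitters inside a
#' box, emulating a fluorescent dye solution filling the microchannel for
#' fringe-calibration imaging. Expected emitter count is
#' `density * volume`.
#'
#' @param extent_um bounding box, `list(x = c(lo, hi), y = ..., z = ...)`
#'   in micrometres.
#' @param density_per_um3 expected emitters per cubic micrometre.
#' @param brightness expected photons/frame per emitter at the focal sheet.
#' @param seed integer RNG seed; identical seed and parameters give a
#'   bit-identical phantom.
#' @return a `phantom` of kind `"dye"`.
#' @export
make_dye_phantom <- function(extent_um, density_per_um3, brightness = 200,
                             seed = 1L) {
  ext <- as_extent(extent_um)
  vol <- prod(vapply(ext, diff, numeric(1)))
  if (vol <= 0) stop("phantom extent has zero volume", call. = FALSE)
  if (density_per_um3 <= 0) stop("density must be positive", call. = FALSE)
  with_seed(seed, {
    n <- stats::rpois(1, density_per_um3 * vol)
    em <- data.frame(
      x_um = stats::runif(n, ext$x[1], ext$x[2]),
      y_um = stats::runif(n, ext$y[1], ext$y[2]),
      z_um = stats::runif(n, ext$z[1], ext$z[2]),
      brightness = rep(brightness, n))
    new_phantom(em, "dye", ext, seed,
                list(density_per_um3 = density_per_um3, brightness = brightness))
  })
}

#' Membrane-labelled cell phantom
#'
#' Hollow fluorescent shell (plasma-membrane label proxy, e.g. WGA-Alexa
#' conjugates on fixed HeLa cells) with optional punctate intracellular
#' vesicles. Shell emitters are uniform on a spherical shell of the given
#' outer radius and thickness; each vesicle is an isotropic Gaussian blob of
#' emitters at a uniform-random interior position. The default 7.5 um radius
#' makes one cell span about 15 um of flow travel.
#'
#' @param radius_um outer cell radius, micrometres.
#' @param shell_thickness_um membrane shell thickness (< radius).
#' @param n_shell number of shell emitters.
#' @param n_vesicles number of vesicles.
#' @param vesicle_radius_um Gaussian SD of each vesicle blob (default
#'   0.25 um, sub-diffraction).
#' @param emitters_per_vesicle emitters per vesicle blob.
#' @param brightness expected photons/frame per emitter.
#' @param center_um cell centre `c(x, y, z)`, micrometres.
#' @param seed integer RNG seed.
#' @return a `phantom` of kind `"cell"`.
#' @export
make_cell_phantom <- function(radius_um = 7.5, shell_thickness_um = 0.3,
                              n_shell = 4000, n_vesicles = 15,
                              vesicle_radius_um = 0.25,
                              emitters_per_vesicle = 40,
                              brightness = 200, center_um = c(0, 0, 0),
                              seed = 1L) {
  if (!(radius_um > shell_thickness_um && shell_thickness_um > 0))
    stop("need radius_um > shell_thickness_um > 0", call. = FALSE)
  if (n_shell < 0 || n_vesicles < 0 || emitters_per_vesicle < 0)
    stop("emitter counts must be non-negative", call. = FALSE)
  with_seed(seed, {
    # uniform direction x uniform-in-volume radius within [r - t, r]
    u <- stats::rnorm(n_shell); v <- stats::rnorm(n_shell); w <- stats::rnorm(n_shell)
    nrm <- sqrt(u^2 + v^2 + w^2)
    r_in <- radius_um - shell_thickness_um
    rad <- (stats::runif(n_shell, r_in^3, radius_um^3))^(1 / 3)
    shell <- cbind(u, v, w) / nrm * rad
    ves <- NULL
    if (n_vesicles > 0 && emitters_per_vesicle > 0) {
      # vesicle centres uniform in the interior sphere (leaving shell margin)
      cu <- stats::rnorm(n_vesicles); cv <- stats::rnorm(n_vesicles); cw <- stats::rnorm(n_vesicles)
      cn <- sqrt(cu^2 + cv^2 + cw^2)
      crad <- (stats::runif(n_vesicles, 0, (r_in - 2 * vesicle_radius_um)^3))^(1 / 3)
      cen <- cbind(cu, cv, cw) / cn * crad
      ves <- do.call(rbind, lapply(seq_len(n_vesicles), function(i) {
        sweep(matrix(stats::rnorm(3 * emitters_per_vesicle, sd = vesicle_radius_um),
                     ncol = 3), 2, cen[i, ], `+`)
      }))
    }
    pts <- rbind(shell, ves)
    pts <- sweep(pts, 2, center_um, `+`)
    em <- data.frame(x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
                     brightness = rep(brightness, nrow(pts)))
    ext <- list(x = center_um[1] + c(-radius_um, radius_um),
                y = center_um[2] + c(-radius_um, radius_um),
                z = center_um[3] + c(-radius_um, radius_um))
    new_phantom(em, "cell", ext, seed,
                list(radius_um = radius_um, shell_thickness_um = shell_thickness_um,
                     n_shell = n_shell, n_vesicles = n_vesicles,
                     vesicle_radius_um = vesicle_radius_um,
                     emitters_per_vesicle = emitters_per_vesicle,
                     brightness = brightness, center_um = center_um))
  })
}

#' Sparse bead-field phantom
#'
#' Point emitters with a minimum pairwise separation (dart throwing),
#' used as the fixture for FWHM and resolution-gain measurements.
#'
#' @param n_beads number of beads.
#' @param extent_um bounding box as in [make_dye_phantom()].
#' @param min_sep_um minimum pairwise separation, micrometres.
#' @param brightness expected photons/frame per bead.
#' @param seed integer RNG seed.
#' @param max_tries dart-throwing attempts before giving up.
#' @return a `phantom` of kind `"beads"`.
#' @export
make_bead_phantom <- function(n_beads, extent_um, min_sep_um = 1,
                              brightness = 2000, seed = 1L,
                              max_tries = 10000L) {
  ext <- as_extent(extent_um)
  vol <- prod(vapply(ext, diff, numeric(1)))
  if (n_beads * min_sep_um^3 >= vol)
    stop("infeasible bead packing: n * min_sep^3 exceeds the extent volume",
         call. = FALSE)
  with_seed(seed, {
    pts <- matrix(numeric(0), ncol = 3)
    tries <- 0L
    while (nrow(pts) < n_beads) {
      if (tries >= max_tries)
        stop("infeasible bead packing: retry budget exhausted", call. = FALSE)
      cand <- c(stats::runif(1, ext$x[1], ext$x[2]),
                stats::runif(1, ext$y[1], ext$y[2]),
                stats::runif(1, ext$z[1], ext$z[2]))
      ok <- nrow(pts) == 0 ||
        min(sqrt(colSums((t(pts) - cand)^2))) >= min_sep_um
      if (ok) pts <- rbind(pts, cand)
      tries <- tries + 1L
    }
    em <- data.frame(x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
                     brightness = rep(brightness, n_beads))
    new_phantom(em, "beads", ext, seed,
                list(n_beads = n_beads, min_sep_um = min_sep_um,
                     brightness = brightness))
  })
}

#' Constant-speed flow trajectory
#'
#' Position along the flow axis as a function of time:
#' `z(t) = start + speed * t (+ jitter)`. Per-frame Gaussian positional
#' jitter is off by default (the device's flow is stable enough that planes
#' need no registration).
#'
#' @param speed_um_s constant flow speed, micrometres/second (default 10).
#' @param start_z_um,end_z_um flow-axis start and end positions of the
#'   phantom centre, micrometres.
#' @param jitter_sd_um per-frame positional jitter SD, micrometres.
#' @return an object of class `flow_trajectory`.
#' @export
flow_trajectory <- function(speed_um_s = 10, start_z_um = 0, end_z_um = 15,
                            jitter_sd_um = 0) {
  stopifnot(speed_um_s > 0, end_z_um > start_z_um, jitter_sd_um >= 0)
  structure(list(speed_um_s = speed_um_s, start_z_um = start_z_um,
                 end_z_um = end_z_um, jitter_sd_um = jitter_sd_um),
            class = "flow_trajectory")
}

#' Write / read a phantom as CSV plus JSON sidecar
#'
#' The CSV holds the emitter table (`x_um, y_um, z_um, brightness`); the
#' JSON sidecar records kind, extent, seed and generator parameters.
#'
#' @param phantom a `phantom`.
#' @param csv_path path of the emitter CSV; the sidecar is written next to
#'   it with extension `.json`.
#' @return `write_phantom` returns `csv_path` invisibly; `read_phantom`
#'   returns the reconstructed `phantom`.
#' @export
write_phantom <- function(phantom, csv_path) {
  utils::write.csv(phantom$emitters, csv_path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", csv_path)
  jsonlite::write_json(list(kind = phantom$kind, extent_um = phantom$extent_um,
                            seed = phantom$seed, params = phantom$params),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(csv_path) {
  em <- utils::read.csv(csv_path)
  side <- sub("\\.csv$", ".json", csv_path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  new_phantom(em, meta$kind, as_extent(meta$extent_um), meta$seed,
              as.list(meta$params))
}
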