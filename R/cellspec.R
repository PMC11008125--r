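#' Specification of a single synthetic red blood cell
#'
#' Encodes the per-cell heterogeneity of the sickling response: cells differ
#' in their sickling delay time (lag after deoxygenation onset before HbS
#' polymerization deforms the cell), their sickling and unsickling rates, and
#' whether they are irreversibly sickled cells (ISCs), which stay sickled at
#' all times. Unsickling is faster than sickling, so `k_u >= k_s` is
#' enforced.
#'
#' @param center length-2 numeric, cell center in 0-based pixel coordinates
#'   (x right, y down).
#' @param base_radius cell radius in pixels before deformation.
#' @param is_isc logical; irreversibly sickled cell.
#' @param delay sickling delay time tau in seconds (>= 0).
#' @param k_s sickling rate in 1/s.
#' @param k_u unsickling rate in 1/s; must be `>= k_s`.
#' @param orientation elongation axis in radians.
#' @param texture_seed integer seed controlling the cell's spicule harmonics
#'   and texture noise, fixed over its lifetime.
#' @return an object of class `cell_spec`.
#' @export
cell_spec <- function(center = c(0, 0), base_radius = 45, is_isc = FALSE,
                      delay = 30, k_s = 0.12, k_u = 0.5, orientation = 0,
                      texture_seed = 1L) {
  if (base_radius <= 0) stopf("base_radius must be positive")
  if (delay < 0) stopf("delay time must be >= 0")
  if (k_s <= 0 || k_u <= 0) stopf("rates must be positive")
  if (k_u < k_s) stopf("unsickling must not be slower than sickling (k_u >= k_s)")
  structure(list(center = as.numeric(center), base_radius = base_radius,
                 is_isc = isTRUE(is_isc), delay = delay, k_s = k_s, k_u = k_u,
                 orientation = orientation,
                 texture_seed = as.integer(texture_seed)),
            class = "cell_spec")
}

#' Specification of a synthetic multi-cell scene
#'
#' Defines the study conditions a synthetic time-lapse emulates: dispersed,
#' non-overlapping red blood cells (pairwise center distance greater than the
#' cell diameter) on a light background, with a pre-existing irreversibly
#' sickled subpopulation (default 20%, the fraction observed in the initial
#' oxygenated state) and lognormal sickling delay times whose default
#' (meanlog = log 30 s, sdlog = 0.5) makes both a fast sickler (< 36 s) and a
#' slow sickler (> 56 s) plausible draws.
#'
#' @param n_cells number of cells.
#' @param isc_fraction probability a cell is an ISC (default 0.20).
#' @param frame_size `c(width, height)` in pixels (default 720 x 480, the
#'   recording format).
#' @param cell_diameter mean cell diameter in pixels (default 90).
#' @param delay_distribution named distribution of delay times; one of
#'   `list(dist = "lognormal", meanlog =, sdlog =)`,
#'   `list(dist = "exponential", rate =)` or `list(dist = "fixed", value =)`.
#' @param background_level background intensity in normalized `[0, 1]` units.
#' @param noise_sd additive Gaussian frame-noise standard deviation.
#' @param seed integer seed; fixed seed gives bit-identical scenes.
#' @param jitter_sd per-frame sub-pixel center jitter (cells are otherwise
#'   static: the assay is hydrostatic).
#' @param margin minimum center distance from the frame edge, in pixels.
#' @param spacing_factor placement spacing as a multiple of `cell_diameter`;
#'   the non-overlap invariant only requires > 1, but the default 1.3 keeps
#'   fully deformed neighbors from touching.
#' @param rate_meanlog,rate_sdlog lognormal parameters of the sickling rate
#'   `k_s`; the unsickling rate is a uniform 3-6x multiple of `k_s`.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(n_cells = 15, isc_fraction = 0.20,
                       frame_size = c(720, 480), cell_diameter = 90,
                       delay_distribution = list(dist = "lognormal",
                                                 meanlog = log(30), sdlog = 0.5),
                       background_level = 0.85, noise_sd = 0.01, seed = 1L,
                       jitter_sd = 0.15, margin = NULL, spacing_factor = 1.3,
                       rate_meanlog = log(0.12), rate_sdlog = 0.25) {
  if (isc_fraction < 0 || isc_fraction > 1) stopf("isc_fraction must lie in [0, 1]")
  if (n_cells < 0) stopf("n_cells must be >= 0")
  if (cell_diameter <= 0) stopf("cell_diameter must be positive")
  if (is.null(margin)) margin <- 0.55 * cell_diameter
  structure(list(n_cells = as.integer(n_cells), isc_fraction = isc_fraction,
                 frame_size = as.integer(frame_size),
                 cell_diameter = cell_diameter,
                 delay_distribution = delay_distribution,
                 background_level = background_level, noise_sd = noise_sd,
                 seed = as.integer(seed), jitter_sd = jitter_sd,
                 margin = margin, spacing_factor = spacing_factor,
                 rate_meanlog = rate_meanlog,
                 rate_sdlog = rate_sdlog),
            class = "scene_spec")
}

sample_delay <- function(n, dd) {
  switch(dd$dist,
    lognormal = rlnorm(n, dd$meanlog, dd$sdlog),
    exponential = rexp(n, dd$rate),
    fixed = rep(dd$value, n),
    stopf("unknown delay distribution '%s'", dd$dist))
}

# Rejection-sample cell centers with pairwise distance > cell_diameter and
# the given edge margin. Bounded retries; failure names the density limit.
place_centers <- function(n, frame_size, cell_diameter, margin,
                          max_tries = 5000L) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  lo <- c(margin, margin)
  hi <- c(frame_size[1] - 1 - margin, frame_size[2] - 1 - margin)
  if (any(hi < lo)) stopf("frame too small for the requested margin")
  pts <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      p <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
      if (i == 1L ||
          all(sqrt(rowSums((pts[seq_len(i - 1), , drop = FALSE] -
                            matrix(p, i - 1, 2, byrow = TRUE))^2)) >
              cell_diameter)) {
        pts[i, ] <- p; ok <- TRUE; break
      }
    }
    if (!ok)
      stopf(paste0("could not place %d non-overlapping cells of diameter %g ",
                   "in a %dx%d frame (density exceeds the non-overlap ",
                   "placement limit after %d retries)"),
            n, cell_diameter, frame_size[1], frame_size[2], max_tries)
  }
  pts
}

#' Draw the cell population of a scene
#'
#' Samples centers (rejection sampling under the non-overlap constraint),
#' ISC status, delay times, rates, orientations and texture seeds, all from
#' the scene's seed.
#'
#' @param scene a [scene_spec()].
#' @return list of [cell_spec()] objects.
#' @export
sample_cell_specs <- function(scene) {
  with_seed(scene$seed, {
    centers <- place_centers(scene$n_cells, scene$frame_size,
                             scene$cell_diameter * scene$spacing_factor,
                             scene$margin)
    n <- scene$n_cells
    if (n == 0L) return(list())
    radii <- scene$cell_diameter / 2 * runif(n, 0.92, 1.08)
    isc <- runif(n) < scene$isc_fraction
    tau <- sample_delay(n, scene$delay_distribution)
    ks <- rlnorm(n, scene$rate_meanlog, scene$rate_sdlog)
    ku <- ks * runif(n, 3, 6)
    ori <- runif(n, 0, 2 * pi)
    seeds <- sample.int(.Machine$integer.max, n)
    lapply(seq_len(n), function(i)
      cell_spec(center = centers[i, ], base_radius = radii[i], is_isc = isc[i],
                delay = tau[i], k_s = ks[i], k_u = ku[i], orientation = ori[i],
                texture_seed = seeds[i]))
  })
}
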