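#' Parameters of the synthetic cell morphology model
#'
#' The cell contour is a radial perturbation of a disc,
#' `r(theta) = R * (1 + e(s) * cos 2(theta - orientation)
#'               + s * A * sum_k a_k cos(k theta + phi_k))`,
#' where `s` in `[0, 1]` is the sickling degree. The elongation term `e(s)`
#' grows linearly from `e0` to `e1` with `s`; the harmonic sum (orders 3-8,
#' amplitudes and phases drawn from the cell's texture seed) produces the
#' concave spicule lobes of a sickled cell at `s > 0`.
#'
#' @param e0,e1 elongation coefficient at `s = 0` and `s = 1`.
#' @param spicule_amplitude total spicule amplitude `A` at `s = 1`, as a
#'   fraction of the base radius.
#' @param harmonics integer orders of the spicule harmonics.
#' @param texture_contrast multiplicative texture amplitude at `s = 1`.
#' @param texture_sigma correlation length (pixels) of the texture noise.
#' @return list of class `shape_params`.
#' @export
shape_params <- function(e0 = 0.02, e1 = 0.22, spicule_amplitude = 0.25,
                         harmonics = 3:8, texture_contrast = 0.28,
                         texture_sigma = 1.5) {
  structure(list(e0 = e0, e1 = e1, spicule_amplitude = spicule_amplitude,
                 harmonics = as.integer(harmonics),
                 texture_contrast = texture_contrast,
                 texture_sigma = texture_sigma),
            class = "shape_params")
}

# maximum radial extent of a rendered cell, used for patch-size checks
max_cell_radius <- function(spec, shape) {
  spec$base_radius * (1 + max(shape$e0, shape$e1) + shape$spicule_amplitude)
}

#' Render a single synthetic red blood cell patch
#'
#' Draws one cell at a given sickling degree. A nonsickled cell (`s = 0`) is
#' a near-circular disc with a light, smooth interior and central pallor; as
#' `s` grows the contour elongates and develops concave spicule lobes while
#' the interior darkens and gains high-frequency multiplicative texture
#' ("dark coarse texture"). ISC specs are pinned at `s = 1`.
#'
#' @param spec a [cell_spec()].
#' @param sickling_degree fraction in `[0, 1]`.
#' @param patch_size side of the square patch in pixels; must accommodate
#'   the fully deformed contour.
#' @param shape a [shape_params()].
#' @param background background intensity.
#' @param center optional subpixel cell center within the patch (0-based);
#'   defaults to the patch center.
#' @return list with `patch` (numeric matrix `[x, y]`, values in `[0, 1]`),
#'   `mask` (logical ground-truth mask) and `s` (the degree rendered).
#' @export
render_cell <- function(spec, sickling_degree, patch_size,
                        shape = shape_params(), background = 0.85,
                        center = NULL) {
  if (!is.finite(sickling_degree) || sickling_degree < 0 || sickling_degree > 1)
    stopf("sickling_degree must lie in [0, 1]")
  s <- if (spec$is_isc) 1 else sickling_degree
  patch_size <- as.integer(patch_size)
  if (patch_size < 2 * max_cell_radius(spec, shape) + 2)
    stopf("patch_size %d too small to contain the cell contour (need >= %.0f)",
          patch_size, 2 * max_cell_radius(spec, shape) + 2)
  if (is.null(center)) center <- rep((patch_size - 1) / 2, 2)

  nh <- length(shape$harmonics)
  tex <- with_seed(spec$texture_seed, {
    a <- runif(nh, 0.2, 1); a <- a / sum(a)
    phi <- runif(nh, 0, 2 * pi)
    g <- smooth_noise(patch_size, patch_size, shape$texture_sigma)
    list(a = a, phi = phi, g = g)
  })

  xs <- (0:(patch_size - 1)) - center[1]
  ys <- (0:(patch_size - 1)) - center[2]
  dx <- matrix(xs, patch_size, patch_size)
  dy <- matrix(ys, patch_size, patch_size, byrow = TRUE)
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)

  e <- shape$e0 + (shape$e1 - shape$e0) * s
  pert <- e * cos(2 * (theta - spec$orientation))
  for (i in seq_len(nh))
    pert <- pert + s * shape$spicule_amplitude * tex$a[i] *
      cos(shape$harmonics[i] * theta + tex$phi[i])
  r <- pmax(spec$base_radius * (1 + pert), 0.12 * spec$base_radius)

  alpha <- clamp(r - rho + 0.5, 0, 1)   # 1-px feathered edge
  mask <- alpha >= 0.5
  u <- clamp(rho / r, 0, 1)
  i_ns <- 0.60 + 0.16 * exp(-(u / 0.45)^2)        # light, smooth, central pallor
  i_base <- (1 - s) * i_ns + s * 0.34             # darkens with s
  i_cell <- clamp(i_base * (1 + s * shape$texture_contrast * tex$g), 0.02, 0.98)
  patch <- background * (1 - alpha) + i_cell * alpha
  list(patch = patch, mask = mask, s = s)
}

#' Sickling degree of a cell at a protocol time
#'
#' Phenomenological single-cell kinetics: before the deoxygenation onset the
#' degree is 0; during low-oxygen phases it rises as
#' `s(t) = 1 - exp(-k_s * max(0, t - t_deoxy - tau))` after the cell's delay
#' time `tau`; during reoxygenation it relaxes towards 0 at the (faster)
#' unsickling rate `k_u`. ISCs return 1 at all times. The curve is continuous
#' in `t` and clamped to `[0, 1]`.
#'
#' @param spec a [cell_spec()].
#' @param t time(s) in seconds, within the protocol duration.
#' @param protocol an [oxygen_protocol()].
#' @return numeric vector of sickling degrees, one per element of `t`.
#' @export
sickling_degree_at <- function(spec, t, protocol) {
  dur <- protocol_duration(protocol)
  if (any(t < 0 | t > dur)) stopf("t must lie within the protocol duration")
  if (spec$is_isc) return(rep(1, length(t)))
  ph <- protocol$phases
  onset <- deoxy_onset(protocol)
  if (is.na(onset)) return(rep(0, length(t)))
  s_out <- numeric(length(t))
  s_state <- 0   # degree at the start of the current phase
  for (i in seq_len(nrow(ph))) {
    sel <- t >= ph$start[i] & (t < ph$end[i] | (i == nrow(ph) & t <= ph$end[i]))
    low <- ph$o2[i] < LOW_O2
    if (low) {
      rise <- function(tt) {
        el <- pmax(0, tt - pmax(ph$start[i], onset + spec$delay))
        1 - (1 - s_state) * exp(-spec$k_s * el)
      }
      if (any(sel)) s_out[sel] <- rise(t[sel])
      s_state <- rise(ph$end[i])
    } else {
      if (ph$start[i] < onset || s_state == 0) {      # pre-deoxygenation
        if (any(sel)) s_out[sel] <- s_state
      } else {                                        # reoxygenation decay
        if (any(sel)) s_out[sel] <- s_state * exp(-spec$k_u * (t[sel] - ph$start[i]))
        s_state <- s_state * exp(-spec$k_u * ph$duration[i])
      }
    }
  }
  clamp(s_out, 0, 1)
}
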