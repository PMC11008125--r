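#' Generate a synthetic sickling time-lapse with ground truth
#'
#' Renders every frame of the oxygenation protocol for a scene of seeded
#' cells, compositing each cell at its protocol-time sickling degree over a
#' noisy background, and records per-cell-per-frame ground truth. A fixed
#' scene seed yields bit-identical output. The ground-truth label is
#' "sickled" iff the true degree exceeds 0.5 or the cell is an ISC.
#'
#' @param scene a [scene_spec()].
#' @param protocol an [oxygen_protocol()].
#' @param shape a [shape_params()].
#' @return object of class `rbc_sequence`: list with `frames` (list of
#'   `labeled_frame`: `pixels`, integer `label_mask`, 0-based `frame_index`,
#'   time `t`), `truth` (data frame `cell_id, frame, t_seconds, s_true,
#'   label_true, x, y`), `specs`, `scene`, `protocol`.
#' @export
generate_sequence <- function(scene, protocol = oxygen_protocol(),
                              shape = shape_params()) {
  specs <- sample_cell_specs(scene)
  times <- frame_times(protocol)
  w <- scene$frame_size[1]; h <- scene$frame_size[2]
  n <- length(specs)
  # patch big enough for the fully deformed largest cell plus jitter
  pad <- 3
  frames <- vector("list", length(times))
  truth <- vector("list", length(times))
  with_seed(derive_seed(scene$seed, 1L), {
    for (fi in seq_along(times)) {
      t <- times[fi]
      jit <- if (n > 0) matrix(rnorm(2 * n, 0, scene$jitter_sd), n, 2) else
        matrix(0, 0, 2)
      px <- matrix(scene$background_level + rnorm(w * h, 0, scene$noise_sd), w, h)
      lab <- matrix(0L, w, h)
      rows <- vector("list", n)
      for (i in seq_len(n)) {
        sp <- specs[[i]]
        s <- sickling_degree_at(sp, t, protocol)
        ctr <- sp$center + jit[i, ]
        ps <- as.integer(2 * ceiling(max_cell_radius(sp, shape)) + 2 * pad)
        x0 <- round(ctr[1]) - ps %/% 2            # 0-based patch origin
        y0 <- round(ctr[2]) - ps %/% 2
        rc <- render_cell(sp, s, ps, shape = shape,
                          background = scene$background_level,
                          center = ctr - c(x0, y0))
        xs <- (x0 + 1):(x0 + ps); ys <- (y0 + 1):(y0 + ps)
        ok_x <- xs >= 1 & xs <= w; ok_y <- ys >= 1 & ys <= h
        # additive compositing of the cell's deviation from the flat
        # background preserves the sensor noise over the cell interior
        px[xs[ok_x], ys[ok_y]] <- px[xs[ok_x], ys[ok_y], drop = FALSE] +
          (rc$patch[ok_x, ok_y, drop = FALSE] - scene$background_level)
        sub_m <- rc$mask[ok_x, ok_y, drop = FALSE]
        lm <- lab[xs[ok_x], ys[ok_y], drop = FALSE]
        paint <- sub_m & lm == 0L                 # first-painted cell wins
        lm[paint] <- i
        lab[xs[ok_x], ys[ok_y]] <- lm
        rows[[i]] <- data.frame(cell_id = i, frame = fi - 1L, t_seconds = t,
                                s_true = s,
                                label_true = if (s > 0.5 || sp$is_isc)
                                  "sickled" else "nonsickled",
                                x = ctr[1], y = ctr[2])
      }
      frames[[fi]] <- structure(list(pixels = clamp(px, 0, 1), label_mask = lab,
                                     frame_index = fi - 1L, t = t),
                                class = "labeled_frame")
      truth[[fi]] <- if (n > 0) do.call(rbind, rows) else
        data.frame(cell_id = integer(), frame = integer(),
                   t_seconds = numeric(), s_true = numeric(),
                   label_true = character(), x = numeric(), y = numeric())
    }
  })
  structure(list(frames = frames, truth = do.call(rbind, truth),
                 specs = specs, scene = scene, protocol = protocol,
                 shape = shape),
            class = "rbc_sequence")
}

#' Write / read a synthetic sequence as plain files
#'
#' Frames are written as 16-bit grayscale PNG (`frame_%04d.png`), label masks
#' as 16-bit PNG (`mask_%04d.png`, label value scaled by 1/65535), the ground
#' truth as CSV and the scene + protocol configuration as YAML.
#'
#' @param seq an `rbc_sequence`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sequence <- function(seq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (fr in seq$frames) {
    write_png16(fr$pixels, file.path(dir, sprintf("frame_%04d.png", fr$frame_index)))
    write_png16(fr$label_mask / 65535, file.path(dir, sprintf("mask_%04d.png", fr$frame_index)))
  }
  utils::write.csv(seq$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  cfg <- list(scene = unclass(seq$scene), protocol = protocol_to_list(seq$protocol))
  yaml::write_yaml(cfg, file.path(dir, "scene.yaml"))
  invisible(dir)
}

#' @rdname write_sequence
#' @export
read_sequence_frames <- function(dir) {
  ff <- sort(list.files(dir, pattern = "^frame_\\d{4}\\.png$", full.names = TRUE))
  mf <- sort(list.files(dir, pattern = "^mask_\\d{4}\\.png$", full.names = TRUE))
  cfg <- file.path(dir, "scene.yaml")
  interval <- if (file.exists(cfg))
    yaml::read_yaml(cfg)$protocol$frame_interval else 1
  lapply(seq_along(ff), function(i) {
    lab <- if (length(mf) >= i) {
      m <- round(read_gray_png(mf[i]) * 65535)
      storage.mode(m) <- "integer"; m
    } else NULL
    structure(list(pixels = read_gray_png(ff[i]), label_mask = lab,
                   frame_index = i - 1L, t = (i - 1) * interval),
              class = "labeled_frame")
  })
}

#' Sample a labeled patch dataset for classifier training
#'
#' Draws cells from the scene population model (ISC status, lognormal delay
#' times, rates) at uniformly random protocol times and observes each one
#' exactly as the segmentation stage would: rendered at the assay scale
#' (90 px cell diameter), additive sensor noise, a square center crop of
#' `ceil(1.5 * cell_diameter)`, per-patch min-max rescaling, and bilinear
#' resize to `patch_size`. Labels follow the ground-truth rule (sickled iff
#' degree > 0.5 or ISC); sampling continues until both class quotas are
#' met, so the returned set is balanced.
#'
#' @param n_per_class patches per class.
#' @param patch_size model input side in pixels (default 64).
#' @param protocol an [oxygen_protocol()].
#' @param isc_fraction,delay_distribution,rate_meanlog,rate_sdlog population
#'   parameters, defaulting to the scene defaults.
#' @param shape a [shape_params()].
#' @param background background intensity.
#' @param cell_diameter rendered cell diameter in pixels before the resize.
#' @param noise_sd additive sensor-noise standard deviation.
#' @param seed integer seed.
#' @return list with `x` (array `patch_size x patch_size x n`), `y` (integer
#'   labels, 0 = nonsickled, 1 = sickled), `s` (true degrees), `meta`
#'   (per-patch data frame).
#' @export
sample_patch_dataset <- function(n_per_class, patch_size = 64,
                                 protocol = oxygen_protocol(),
                                 isc_fraction = 0.20,
                                 delay_distribution = list(dist = "lognormal",
                                                           meanlog = log(30),
                                                           sdlog = 0.5),
                                 rate_meanlog = log(0.12), rate_sdlog = 0.25,
                                 shape = shape_params(), background = 0.85,
                                 cell_diameter = 90, noise_sd = 0.01,
                                 seed = 1L) {
  n_tot <- 2L * n_per_class
  x <- array(0, c(patch_size, patch_size, n_tot))
  y <- integer(n_tot); sdeg <- numeric(n_tot)
  isc <- logical(n_tot)
  quota <- c(n_per_class, n_per_class)   # nonsickled, sickled
  got <- 0L
  dur <- protocol_duration(protocol)
  crop_side <- as.integer(ceiling(1.5 * cell_diameter))
  with_seed(seed, {
    while (got < n_tot) {
      sp <- cell_spec(base_radius = cell_diameter / 2 * runif(1, 0.92, 1.08),
                      is_isc = runif(1) < isc_fraction,
                      delay = sample_delay(1, delay_distribution),
                      k_s = rlnorm(1, rate_meanlog, rate_sdlog),
                      k_u = 1, orientation = runif(1, 0, 2 * pi),
                      texture_seed = sample.int(.Machine$integer.max, 1))
      sp$k_u <- sp$k_s * runif(1, 3, 6)
      t <- runif(1, 0, dur)
      s <- sickling_degree_at(sp, t, protocol)
      lab <- as.integer(s > 0.5 || sp$is_isc)
      if (quota[lab + 1L] == 0L) next
      got <- got + 1L
      quota[lab + 1L] <- quota[lab + 1L] - 1L
      x[, , got] <- observe_cell(sp, s, patch_size = patch_size,
                                 crop_side = crop_side, shape = shape,
                                 background = background, noise_sd = noise_sd)
      y[got] <- lab; sdeg[got] <- s; isc[got] <- sp$is_isc
    }
  })
  list(x = x, y = y, s = sdeg,
       meta = data.frame(label = y, s_true = sdeg, is_isc = isc))
}

#' Observe a single cell as the segmentation stage would
#'
#' Renders the cell at its native scale, adds sensor noise, center-crops to
#' the standard square crop, min-max rescales, and resizes to the model
#' input side — the same observation chain a cell goes through in a full
#' frame. Noise is drawn from the caller's RNG state.
#'
#' @param spec a [cell_spec()].
#' @param sickling_degree fraction in `[0, 1]`.
#' @param patch_size returned (model input) side in pixels.
#' @param crop_side square crop side before the resize; defaults to
#'   `ceil(1.5 * 2 * base_radius)`.
#' @param shape a [shape_params()].
#' @param background background intensity.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @return numeric `patch_size x patch_size` matrix in `[0, 1]`.
#' @export
observe_cell <- function(spec, sickling_degree, patch_size = 64,
                         crop_side = NULL, shape = shape_params(),
                         background = 0.85, noise_sd = 0.01) {
  if (is.null(crop_side))
    crop_side <- as.integer(ceiling(3 * spec$base_radius))
  render_size <- max(as.integer(2 * ceiling(max_cell_radius(spec, shape)) + 4),
                     crop_side)
  rc <- render_cell(spec, sickling_degree, render_size, shape = shape,
                    background = background)
  obs <- rc$patch
  if (noise_sd > 0)
    obs <- obs + matrix(rnorm(render_size^2, 0, noise_sd),
                        render_size, render_size)
  off <- (render_size - crop_side) %/% 2
  obs <- rescale01(obs[off + seq_len(crop_side), off + seq_len(crop_side)])
  if (crop_side == patch_size) obs else
    EBImage::imageData(EBImage::resize(EBImage::Image(obs),
                                       w = patch_size, h = patch_size))
}
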