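#' Segment a grayscale frame into labeled cell masks
#'
#' Built-in classical segmenter: estimate and subtract a smoothed background
#' (cells are darker than background), apply an automatic two-class (Otsu)
#' threshold, fill holes, remove components smaller than
#' `0.15 * pi * (expected_diameter / 2)^2`, and label connected components.
#' A constant or empty frame yields an all-zero mask. An external segmenter
#' (e.g. a Cellpose wrapper) can be substituted via
#' [segment_with_adapter()]; downstream stages are segmenter-agnostic.
#'
#' @param frame numeric matrix `[x, y]` with intensities in `[0, 1]`.
#' @param expected_diameter expected cell diameter in pixels (default 90).
#' @param bg_downscale background is estimated on a frame downscaled by this
#'   factor and smoothed, then upsampled.
#' @return integer label matrix, 0 = background, k = cell k (consecutive).
#' @export
segment_frame <- function(frame, expected_diameter = 90, bg_downscale = 8) {
  if (!is.matrix(frame)) stopf("frame must be a single-channel matrix")
  if (expected_diameter <= 0) stopf("expected_diameter must be positive")
  zero <- matrix(0L, nrow(frame), ncol(frame))
  if (diff(range(frame)) < 1e-8) return(zero)
  bg <- estimate_background(frame, expected_diameter, bg_downscale)
  d <- pmax(bg - frame, 0)                       # cells are darker
  rng <- range(d)
  if (rng[2] - rng[1] < 1e-8) return(zero)
  dn <- (d - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(dn), range = c(0, 1))
  bw <- EBImage::fillHull(EBImage::Image(dn > thr))
  lab <- EBImage::bwlabel(bw)
  lab <- EBImage::imageData(lab)
  storage.mode(lab) <- "integer"
  min_area <- 0.15 * pi * (expected_diameter / 2)^2
  areas <- tabulate(lab[lab > 0L])
  drop <- which(areas < min_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  relabel_mask(lab)
}

estimate_background <- function(frame, expected_diameter, down = 8) {
  w <- nrow(frame); h <- ncol(frame)
  small <- EBImage::resize(EBImage::Image(frame),
                           w = max(8, round(w / down)),
                           h = max(8, round(h / down)))
  # keep the Gaussian kernel inside the downscaled image
  sigma <- min(max(2, expected_diameter / down),
               (min(dim(small)) - 1) / 6.5)
  sm <- EBImage::gblur(small, sigma = sigma)
  EBImage::imageData(EBImage::resize(sm, w = w, h = h))
}

#' Relabel a mask to consecutive positive integers
#'
#' @param mask integer label matrix.
#' @return integer label matrix with labels `1..K` in order of first
#'   appearance of the original labels.
#' @export
relabel_mask <- function(mask) {
  labs <- sort(unique(mask[mask > 0L]))
  if (!length(labs)) return(mask)
  out <- match(mask, labs, nomatch = 0L)
  dim(out) <- dim(mask)
  storage.mode(out) <- "integer"
  out
}

#' Apply the cell exclusion rules to a label mask
#'
#' Implements the assay's discard rules with reason codes:
#' \describe{
#'   \item{border}{component touches a frame edge and its area is below
#'     `border_area_frac` of the median component area ("majorly located
#'     outside the frame").}
#'   \item{clump}{equivalent-circle diameter exceeds
#'     `clump_factor * expected_diameter` — the diameter-based surrogate for
#'     excluding the small fraction of overlapping cells. Two merged
#'     average-size cells have an equivalent diameter of about 1.37 times
#'     the single-cell diameter, so the default factor is 1.3.}
#'   \item{debris}{equivalent diameter below
#'     `debris_factor * expected_diameter`.}
#' }
#' Survivors are relabeled consecutively.
#'
#' @param mask integer label mask.
#' @param expected_diameter expected cell diameter in pixels.
#' @param border_area_frac,clump_factor,debris_factor rule thresholds.
#' @return list with `mask` (filtered, relabeled) and `log` (data frame
#'   `label, area, eq_diameter, reason` for discarded components).
#' @export
filter_cells <- function(mask, expected_diameter = 90, border_area_frac = 0.6,
                         clump_factor = 1.3, debris_factor = 0.4) {
  labs <- sort(unique(mask[mask > 0L]))
  if (!length(labs))
    return(list(mask = mask,
                log = data.frame(label = integer(), area = numeric(),
                                 eq_diameter = numeric(), reason = character())))
  areas <- tabulate(mask[mask > 0L], nbins = max(labs))[labs]
  eq_d <- 2 * sqrt(areas / pi)
  w <- nrow(mask); h <- ncol(mask)
  edge <- unique(c(mask[1, ], mask[w, ], mask[, 1], mask[, h]))
  med_area <- median(areas)
  reason <- rep(NA_character_, length(labs))
  reason[labs %in% edge & areas < border_area_frac * med_area] <- "border"
  reason[is.na(reason) & eq_d > clump_factor * expected_diameter] <- "clump"
  reason[is.na(reason) & eq_d < debris_factor * expected_diameter] <- "debris"
  keep <- labs[is.na(reason)]
  out <- mask
  out[!(mask %in% c(0L, keep))] <- 0L
  list(mask = relabel_mask(out),
       log = data.frame(label = labs, area = areas, eq_diameter = eq_d,
                        reason = reason)[!is.na(reason), ])
}

#' Crop standardized square patches for each labeled cell
#'
#' For every label, a square crop of side `ceil(1.5 * expected_diameter)`
#' centered on the component centroid, edge-padded with the background
#' median where the crop exceeds the frame, and min-max rescaled to
#' `[0, 1]` per patch (a constant patch maps to all zeros). Pixels belonging
#' to other labeled cells are replaced by the background median, so each
#' patch is a single-cell image.
#'
#' @param frame numeric image matrix `[x, y]`.
#' @param mask filtered integer label mask.
#' @param frame_index 0-based frame index recorded in each record.
#' @param t frame time in seconds.
#' @param expected_diameter expected cell diameter in pixels.
#' @param patch_side override of the square patch side.
#' @return list of `cell_record` objects: `cell_label`, `frame_index`, `t`,
#'   `mask` (cropped logical), `patch` (square, rescaled), `centroid`
#'   (0-based subpixel `(x, y)`), `bbox` (half-open 0-based
#'   `(x0, y0, x1, y1)`), `discarded`.
#' @export
crop_patches <- function(frame, mask, frame_index = 0L, t = 0,
                         expected_diameter = 90, patch_side = NULL) {
  if (is.null(patch_side)) patch_side <- ceiling(1.5 * expected_diameter)
  patch_side <- as.integer(patch_side)
  labs <- sort(unique(mask[mask > 0L]))
  if (!length(labs)) return(list())
  bg_med <- median(frame[mask == 0L])
  w <- nrow(frame); h <- ncol(frame)
  half <- patch_side %/% 2L
  lapply(labs, function(l) {
    idx <- which(mask == l, arr.ind = TRUE)
    cx <- mean(idx[, 1]) - 1; cy <- mean(idx[, 2]) - 1   # 0-based subpixel
    x0 <- as.integer(round(cx)) - half
    y0 <- as.integer(round(cy)) - half
    xs <- x0:(x0 + patch_side - 1L); ys <- y0:(y0 + patch_side - 1L)
    patch <- matrix(bg_med, patch_side, patch_side)
    cmask <- matrix(FALSE, patch_side, patch_side)
    ok_x <- xs >= 0 & xs < w; ok_y <- ys >= 0 & ys < h
    sub <- frame[xs[ok_x] + 1L, ys[ok_y] + 1L, drop = FALSE]
    msub <- mask[xs[ok_x] + 1L, ys[ok_y] + 1L, drop = FALSE]
    sub[msub != l & msub != 0L] <- bg_med    # suppress neighboring cells
    patch[ok_x, ok_y] <- sub
    cmask[ok_x, ok_y] <- msub == l
    structure(list(cell_label = l, frame_index = as.integer(frame_index),
                   t = t, mask = cmask, patch = rescale01(patch),
                   centroid = c(cx, cy),
                   bbox = c(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L,
                            max(idx[, 1]), max(idx[, 2])),
                   discarded = FALSE),
              class = "cell_record")
  })
}

#' Run an external segmenter through the adapter contract
#'
#' The adapter maps a grayscale matrix to an integer label mask of the same
#' shape (for instance a wrapper around a retrained Cellpose model). The
#' output is validated and relabeled consecutively, after which it is
#' indistinguishable from the built-in segmenter's output.
#'
#' @param frame numeric image matrix.
#' @param adapter function `frame -> label matrix`.
#' @return integer label mask with consecutive labels.
#' @export
segment_with_adapter <- function(frame, adapter) {
  out <- adapter(frame)
  if (!is.matrix(out) || !identical(dim(out), dim(frame)))
    stopf("segmenter adapter contract violation: expected a %d x %d label matrix",
          nrow(frame), ncol(frame))
  if (any(out < 0) || any(out != round(out)))
    stopf("segmenter adapter contract violation: labels must be non-negative integers")
  storage.mode(out) <- "integer"
  relabel_mask(out)
}

#' Segment, filter and crop a whole sequence
#'
#' Convenience wrapper running [segment_frame()] (or an adapter),
#' [filter_cells()] and [crop_patches()] over every frame.
#'
#' @param frames list of `labeled_frame` objects (only `pixels`,
#'   `frame_index`, `t` are used).
#' @param expected_diameter expected cell diameter in pixels.
#' @param adapter optional external segmenter for [segment_with_adapter()].
#' @param ... passed to [filter_cells()].
#' @return list with `records` (flat list of `cell_record`) and `discards`
#'   (per-frame discard log).
#' @export
segment_sequence <- function(frames, expected_diameter = 90, adapter = NULL,
                             ...) {
  recs <- list(); logs <- list()
  for (fr in frames) {
    lab <- if (is.null(adapter)) segment_frame(fr$pixels, expected_diameter)
           else segment_with_adapter(fr$pixels, adapter)
    fc <- filter_cells(lab, expected_diameter, ...)
    if (nrow(fc$log)) {
      fc$log$frame <- fr$frame_index
      logs[[length(logs) + 1L]] <- fc$log
    }
    recs <- c(recs, crop_patches(fr$pixels, fc$mask, fr$frame_index, fr$t,
                                 expected_diameter))
  }
  list(records = recs,
       discards = if (length(logs)) do.call(rbind, logs) else
         data.frame(label = integer(), area = numeric(),
                    eq_diameter = numeric(), reason = character(),
                    frame = integer()))
}
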