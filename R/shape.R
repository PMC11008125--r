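#' Contour shape factors
#'
#' The seven dimensionless shape factors of the sickling assay, applied
#' verbatim to a cell's contour geometry:
#' \describe{
#'   \item{CSF}{circular shape factor, `4 pi Area_r / Perm_r^2` (1 for a circle).}
#'   \item{ESF}{ellipticity, `Rb / Ra` (minor over major fitted-ellipse axis).}
#'   \item{SF1}{`Rb / max_FD`.}
#'   \item{SF2}{`min_FD / max_FD`.}
#'   \item{Elongation}{`max_FD / min_FD` (so `SF2 * Elongation = 1` exactly).}
#'   \item{Convexity}{`Area_r / Area_c` (1 for convex shapes).}
#'   \item{Compactness}{`4 pi Area_r / Perm_c^2` (equals CSF for convex
#'     shapes, otherwise larger since `Perm_c <= Perm_r`).}
#' }
#'
#' @param geometry list with positive fields `area_r`, `perm_r`, `area_c`,
#'   `perm_c`, `ra`, `rb`, `max_fd`, `min_fd`.
#' @return one-row data frame with columns `CSF, ESF, SF1, SF2, Elongation,
#'   Convexity, Compactness`.
#' @export
shape_factors <- function(geometry) {
  g <- geometry
  need <- c("area_r", "perm_r", "area_c", "perm_c", "ra", "rb", "max_fd", "min_fd")
  miss <- setdiff(need, names(g))
  if (length(miss)) stopf("geometry is missing: %s", paste(miss, collapse = ", "))
  vals <- unlist(g[need])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("all geometry fields must be positive and finite")
  data.frame(CSF = 4 * pi * g$area_r / g$perm_r^2,
             ESF = g$rb / g$ra,
             SF1 = g$rb / g$max_fd,
             SF2 = g$min_fd / g$max_fd,
             Elongation = g$max_fd / g$min_fd,
             Convexity = g$area_r / g$area_c,
             Compactness = 4 * pi * g$area_r / g$perm_c^2)
}

#' Intensity distribution moments of a cell
#'
#' Sample skewness `g1 = m3 / m2^1.5` and excess kurtosis
#' `g2 = m4 / m2^2 - 3` (Gaussian -> 0) of the intensities inside the mask,
#' from central moments `m_k`.
#'
#' @param patch numeric intensity matrix.
#' @param mask logical matrix selecting the cell interior (>= 4 pixels).
#' @return list with `skewness`, `kurtosis`, `degenerate` (TRUE when the
#'   intensity variance is zero, in which case both moments are `NA`).
#' @export
intensity_moments <- function(patch, mask) {
  v <- patch[mask > 0]
  if (length(v) < 4) stopf("need at least 4 foreground pixels")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 < 1e-24)
    return(list(skewness = NA_real_, kurtosis = NA_real_, degenerate = TRUE))
  list(skewness = mean((v - m)^3) / m2^1.5,
       kurtosis = mean((v - m)^4) / m2^2 - 3,
       degenerate = FALSE)
}

#' Full morphometric profile of one cell
#'
#' Runs the contour, hull, Feret and ellipse analyses on a mask and the
#' intensity moments on the patch, returning the seven contour factors plus
#' skewness and kurtosis.
#'
#' @param mask single-component logical mask.
#' @param patch optional intensity patch (same shape); without it the
#'   intensity moments are `NA`.
#' @param smooth_sigma passed to [extract_contour()].
#' @return one-row data frame `CSF, ESF, SF1, SF2, Elongation, Convexity,
#'   Compactness, Skewness, Kurtosis`.
#' @export
cell_shape_factors <- function(mask, patch = NULL, smooth_sigma = 0.8) {
  ct <- extract_contour(mask, smooth_sigma)
  hull <- convex_hull_metrics(ct$polygon)
  fd <- feret_diameters(ct$polygon)
  el <- fit_ellipse(mask)
  sf <- shape_factors(list(area_r = ct$area, perm_r = ct$perimeter,
                           area_c = hull$area, perm_c = hull$perimeter,
                           ra = el$ra, rb = el$rb,
                           max_fd = fd[["max_fd"]], min_fd = fd[["min_fd"]]))
  if (is.null(patch)) {
    sf$Skewness <- NA_real_; sf$Kurtosis <- NA_real_
  } else {
    im <- intensity_moments(patch, mask)
    sf$Skewness <- im$skewness; sf$Kurtosis <- im$kurtosis
  }
  sf
}

#' Shape-factor table for a list of cell records
#'
#' @param records list of `cell_record` objects (from [crop_patches()]).
#' @param ... passed to [cell_shape_factors()].
#' @return data frame with `cell_id, frame, t` and the nine factors; records
#'   whose contour analysis fails (e.g. fragmented masks) are skipped with a
#'   warning.
#' @export
shape_factor_table <- function(records, ...) {
  rows <- lapply(records, function(r) {
    if (isTRUE(r$discarded)) return(NULL)
    sf <- tryCatch(cell_shape_factors(r$mask, r$patch, ...),
                   error = function(e) NULL)
    if (is.null(sf)) return(NULL)
    cbind(data.frame(cell_id = r$cell_label, frame = r$frame_index, t = r$t), sf)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) < length(records))
    warning(sprintf("%d record(s) skipped in shape-factor extraction",
                    length(records) - length(rows)))
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Scatter-matrix report of shape factors by class
#'
#' Pairs plot of the seven contour factors, colored by class label —
#' nonsickled cells cluster tightly near the convex fixed point while
#' sickled cells scatter broadly.
#'
#' @param tbl data frame from [shape_factor_table()].
#' @param labels character/factor vector of class labels per row.
#' @param file output PNG path.
#' @return `file`, invisibly.
#' @export
plot_shape_matrix <- function(tbl, labels, file) {
  cols <- c("CSF", "ESF", "SF1", "SF2", "Elongation", "Convexity", "Compactness")
  grDevices::png(file, width = 1400, height = 1400)
  on.exit(dev.off())
  pairs(tbl[, cols], col = as.integer(factor(labels)) + 1L, pch = 20,
        cex = 0.5, main = "Cell shape factors by class")
  invisible(file)
}
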