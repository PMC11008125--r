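# Contour geometry: subpixel polygon extraction, convex hull, Feret
# diameters and moment-based ellipse fit. These feed the shape factors.

shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

polygon_perimeter <- function(xy) {
  d <- rbind(diff(xy), xy[1, ] - xy[nrow(xy), ])
  sum(sqrt(rowSums(d^2)))
}

#' Extract the subpixel contour of a single-component mask
#'
#' The binary mask is lightly smoothed and traced at the 0.5 iso-level with a
#' marching-squares-style contour (via [grDevices::contourLines()]), giving a
#' closed polygon with subpixel vertices. The smoothing removes the
#' staircase bias of pixel-edge perimeters (which would push the circular
#' shape factor of a disc far below 1).
#'
#' @param mask logical or 0/1 matrix with exactly one connected foreground
#'   component.
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels.
#' @return list with `polygon` (n x 2 matrix of 0-based `(x, y)` vertices,
#'   implicitly closed), `area` (`Area_r`, shoelace) and `perimeter`
#'   (`Perm_r`).
#' @export
extract_contour <- function(mask, smooth_sigma = 0.8) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) stopf("empty mask: no foreground component")
  ncomp <- max(EBImage::bwlabel(EBImage::Image(m)))
  if (ncomp > 1) stopf("mask has %d connected components; expected exactly one", ncomp)
  pad <- as.integer(ceiling(3 * smooth_sigma) + 2)
  mp <- matrix(0, nrow(m) + 2 * pad, ncol(m) + 2 * pad)
  mp[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  if (smooth_sigma > 0)
    mp <- EBImage::imageData(EBImage::gblur(EBImage::Image(mp), smooth_sigma))
  cl <- contourLines(x = seq_len(nrow(mp)) - 1 - pad,
                     y = seq_len(ncol(mp)) - 1 - pad, z = mp, levels = 0.5)
  if (!length(cl)) stopf("no iso-contour found (mask too small?)")
  areas <- vapply(cl, function(ct) shoelace_area(cbind(ct$x, ct$y)), numeric(1))
  ct <- cl[[which.max(areas)]]
  poly <- cbind(x = ct$x, y = ct$y)
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  list(polygon = poly, area = shoelace_area(poly),
       perimeter = polygon_perimeter(poly))
}

#' Convex hull area and perimeter of a polygon
#'
#' @param polygon n x 2 vertex matrix (implicitly closed).
#' @return list with `hull` (vertex matrix), `area` (`Area_c`) and
#'   `perimeter` (`Perm_c`).
#' @export
convex_hull_metrics <- function(polygon) {
  if (nrow(polygon) < 3) stopf("polygon needs at least 3 vertices")
  h <- chull(polygon)
  hull <- polygon[h, , drop = FALSE]
  if (nrow(hull) < 3 || shoelace_area(hull) < .Machine$double.eps)
    stopf("degenerate (collinear) polygon")
  list(hull = hull, area = shoelace_area(hull),
       perimeter = polygon_perimeter(hull))
}

#' Maximum and minimum Feret diameters of a polygon
#'
#' Computed on the convex hull: the maximum Feret diameter is the largest
#' pairwise vertex distance; the minimum is the smallest width over hull-edge
#' normal directions (exact for convex polygons).
#'
#' @param polygon n x 2 vertex matrix.
#' @return named numeric vector `c(max_fd, min_fd)`.
#' @export
feret_diameters <- function(polygon) {
  hull <- convex_hull_metrics(polygon)$hull
  n <- nrow(hull)
  dmat <- as.matrix(dist(hull))
  max_fd <- max(dmat)
  min_fd <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < .Machine$double.eps) next
    nrm <- c(-e[2], e[1]) / len
    proj <- hull %*% nrm
    min_fd <- min(min_fd, max(proj) - min(proj))
  }
  c(max_fd = max_fd, min_fd = min_fd)
}

#' Moment-based ellipse fit of a mask
#'
#' Axes from the eigenvalues of the second central moment matrix of the
#' foreground pixel coordinates, scaled so that a solid ellipse recovers its
#' own axes: full axis length = 4 * sqrt(eigenvalue).
#'
#' @param mask logical or 0/1 matrix, nonempty single component.
#' @return list with `ra` (major full axis), `rb` (minor full axis),
#'   `orientation` (radians).
#' @export
fit_ellipse <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) < 2) stopf("mask too small for an ellipse fit (single pixel)")
  xy <- idx - 1
  mu <- colMeans(xy)
  d <- sweep(xy, 2, mu)
  cv <- crossprod(d) / nrow(d)        # population second central moments
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[2] <= 0) stopf("degenerate mask: collinear pixels")
  list(ra = 4 * sqrt(ev$values[1]), rb = 4 * sqrt(ev$values[2]),
       orientation = atan2(ev$vectors[2, 1], ev$vectors[1, 1]))
}
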