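# Independent geometry and statistics oracles, kept free of the package's
# own computation paths.

# Feret diameters by dense angle sweep: project all polygon vertices onto
# 3600 directions and take the extreme extents.
feret_sweep <- function(poly, n_angles = 3600) {
  ang <- seq(0, pi, length.out = n_angles)
  ext <- vapply(ang, function(a) {
    u <- c(cos(a), sin(a))
    p <- poly %*% u
    max(p) - min(p)
  }, numeric(1))
  c(max_fd = max(ext), min_fd = min(ext))
}

# Central moments by explicit summation loops.
moments_direct <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  m2 <- 0; m3 <- 0; m4 <- 0
  for (x in v) {
    d <- x - m
    m2 <- m2 + d^2; m3 <- m3 + d^3; m4 <- m4 + d^4
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
  c(skew = m3 / m2^1.5, kurt = m4 / m2^2 - 3)
}

# Classification metrics by brute-force counting over label/prediction pairs.
metrics_direct <- function(pred, truth) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  c(accuracy = (tp + tn) / length(pred),
    precision = prec, recall = rec,
    f1 = if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_)
}

# Analytic test masks ------------------------------------------------------

disc_mask <- function(r, size = 2 * r + 20) {
  c0 <- (size - 1) / 2
  x <- matrix(0:(size - 1), size, size)
  y <- t(x)
  (x - c0)^2 + (y - c0)^2 <= r^2
}

ellipse_mask <- function(a, b, angle = 0, size = 2 * a + 20) {
  c0 <- (size - 1) / 2
  x <- matrix(0:(size - 1), size, size) - c0
  y <- t(matrix(0:(size - 1), size, size)) - c0
  xr <- x * cos(angle) + y * sin(angle)
  yr <- -x * sin(angle) + y * cos(angle)
  (xr / a)^2 + (yr / b)^2 <= 1
}

square_mask <- function(side, pad = 10) {
  size <- side + 2 * pad
  m <- matrix(FALSE, size, size)
  m[pad + seq_len(side), pad + seq_len(side)] <- TRUE
  m
}

# Random star-shaped polygon (radial function), guaranteed simple.
random_polygon <- function(n_vertices = 12) {
  th <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, 0.5, 2)
  cbind(r * cos(th), r * sin(th))
}
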