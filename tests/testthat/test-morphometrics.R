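test_that("contour extraction recovers analytic circle and square geometry", {
  ct <- extract_contour(disc_mask(45))
  expect_equal(ct$area, pi * 45^2, tolerance = 0.015)
  expect_equal(ct$perimeter, 2 * pi * 45, tolerance = 0.02)

  sq <- extract_contour(square_mask(100))
  expect_equal(sq$area, 1e4, tolerance = 0.01)
  expect_equal(sq$perimeter, 400, tolerance = 0.02)

  expect_error(extract_contour(matrix(FALSE, 10, 10)), "empty mask")
  two <- matrix(FALSE, 30, 30); two[3:8, 3:8] <- TRUE; two[20:25, 20:25] <- TRUE
  expect_error(extract_contour(two), "components")
})

test_that("convex hull metrics satisfy hull properties", {
  # hull of a convex polygon is itself
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  hexish <- cbind(cos(th), sin(th))
  h <- convex_hull_metrics(hexish)
  expect_equal(h$area, sicklekin:::shoelace_area(hexish), tolerance = 1e-12)
  expect_equal(h$perimeter, sicklekin:::polygon_perimeter(hexish),
               tolerance = 1e-12)

  # five-pointed star: hull larger in area, smaller in perimeter
  a <- seq(0, 2 * pi, length.out = 11)[-11]
  star <- cbind(ifelse(seq_along(a) %% 2 == 1, 1, 0.4) * cos(a),
                ifelse(seq_along(a) %% 2 == 1, 1, 0.4) * sin(a))
  hs <- convex_hull_metrics(star)
  expect_gt(hs$area, sicklekin:::shoelace_area(star))
  expect_lt(hs$perimeter, sicklekin:::polygon_perimeter(star))

  # unit square exact values
  usq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  hu <- convex_hull_metrics(usq)
  expect_equal(hu$area, 1)
  expect_equal(hu$perimeter, 4)

  expect_error(convex_hull_metrics(cbind(0:3, 0:3)), "degenerate")
})

test_that("Feret diameters match closed forms and the angle-sweep oracle", {
  usq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  fd <- feret_diameters(usq)
  expect_equal(fd[["max_fd"]], sqrt(2), tolerance = 1e-12)
  expect_equal(fd[["min_fd"]], 1, tolerance = 1e-12)

  dfd <- feret_diameters(extract_contour(disc_mask(45))$polygon)
  expect_equal(dfd[["max_fd"]], 90, tolerance = 0.02)
  expect_equal(dfd[["min_fd"]], 90, tolerance = 0.02)

  set.seed(91)
  for (i in 1:100) {
    poly <- random_polygon(12)
    fd <- feret_diameters(poly)
    or <- feret_sweep(poly)
    expect_lt(abs(fd[["max_fd"]] - or[["max_fd"]]), 1e-6)
    expect_lt(abs(fd[["min_fd"]] - or[["min_fd"]]) / or[["min_fd"]], 1e-3)
  }
})

test_that("moment ellipse fit recovers analytic axes and is rotation invariant", {
  d <- fit_ellipse(disc_mask(45))
  expect_equal(d$ra, 90, tolerance = 0.02)
  expect_equal(d$rb, 90, tolerance = 0.02)

  e <- fit_ellipse(ellipse_mask(60, 30))
  expect_equal(e$ra, 120, tolerance = 0.02)
  expect_equal(e$rb, 60, tolerance = 0.02)

  er <- fit_ellipse(ellipse_mask(60, 30, angle = 37 * pi / 180))
  expect_equal(er$ra, e$ra, tolerance = 0.01)
  expect_equal(er$rb, e$rb, tolerance = 0.01)

  one <- matrix(FALSE, 10, 10); one[5, 5] <- TRUE
  expect_error(fit_ellipse(one), "single pixel")
})

test_that("shape factors: circle fixed point, square closed forms, invariants", {
  # analytic circle geometry -> every factor exactly 1
  g <- list(area_r = pi, perm_r = 2 * pi, area_c = pi, perm_c = 2 * pi,
            ra = 2, rb = 2, max_fd = 2, min_fd = 2)
  expect_true(all(abs(unlist(shape_factors(g)) - 1) < 1e-12))

  # analytic unit square
  gs <- list(area_r = 1, perm_r = 4, area_c = 1, perm_c = 4,
             ra = sqrt(4 / 3), rb = sqrt(4 / 3),
             max_fd = sqrt(2), min_fd = 1)
  sf <- shape_factors(gs)
  expect_equal(sf$CSF, pi / 4, tolerance = 1e-12)
  expect_equal(sf$SF2, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(sf$Elongation, sqrt(2), tolerance = 1e-12)
  expect_equal(sf$Convexity, 1)

  expect_error(shape_factors(list(area_r = -1, perm_r = 4, area_c = 1,
                                  perm_c = 4, ra = 1, rb = 1, max_fd = 1,
                                  min_fd = 1)), "positive")

  # measured factors on rendered cells satisfy the typed invariants
  eps <- 0.03
  for (seed in c(5, 6)) {
    sp <- cell_spec(base_radius = 40, texture_seed = seed)
    for (s in c(0, 0.6, 1)) {
      r <- render_cell(sp, s, 140)
      f <- cell_shape_factors(r$mask, r$patch)
      expect_true(all(unlist(f[c("CSF", "ESF", "SF1", "SF2", "Convexity",
                                 "Compactness")]) <= 1 + eps))
      expect_gte(f$Elongation, 1 - eps)
      expect_equal(f$SF2 * f$Elongation, 1, tolerance = 1e-12)
      expect_gte(f$Compactness, f$CSF)
    }
  }
})

test_that("star-shaped sickled mask separates convexity from compactness", {
  sp <- cell_spec(base_radius = 40, texture_seed = 77)
  r <- render_cell(sp, 1, 140)
  f <- cell_shape_factors(r$mask)
  expect_lt(f$Convexity, 1)
  expect_gt(f$Compactness, f$CSF)
})

test_that("shape factors are scale and rotation invariant within tolerance", {
  sp1 <- cell_spec(base_radius = 30, texture_seed = 13)
  sp2 <- cell_spec(base_radius = 60, texture_seed = 13)
  cols <- c("CSF", "ESF", "SF1", "SF2", "Convexity", "Compactness")
  f1 <- cell_shape_factors(render_cell(sp1, 0.8, 110)$mask)
  f2 <- cell_shape_factors(render_cell(sp2, 0.8, 220)$mask)
  expect_true(all(abs(unlist(f1[cols]) - unlist(f2[cols])) < 0.03))

  sp3 <- cell_spec(base_radius = 40, texture_seed = 13,
                   orientation = 37 * pi / 180)
  # rotating the elongation axis is the deterministic rotation the
  # generator exposes; spicule phases stay fixed
  f3 <- cell_shape_factors(render_cell(
    cell_spec(base_radius = 40, texture_seed = 13), 0, 150)$mask)
  f4 <- cell_shape_factors(render_cell(sp3, 0, 150)$mask)
  expect_true(all(abs(unlist(f3[cols]) - unlist(f4[cols])) < 0.03))
})

test_that("intensity moments match direct summation and flag degeneracy", {
  v <- c(1, 1, 1, 2, 2, 10)
  patch <- matrix(c(v, rep(0, 3)), 3, 3)
  mask <- matrix(c(rep(TRUE, 6), rep(FALSE, 3)), 3, 3)
  im <- intensity_moments(patch, mask)
  # frozen values from the direct-summation oracle
  expect_equal(im$skewness, 1.713657476319, tolerance = 1e-10)
  expect_equal(im$kurtosis, 1.062007049934, tolerance = 1e-10)
  or <- moments_direct(v)
  expect_equal(im$skewness, or[["skew"]], tolerance = 1e-12)
  expect_equal(im$kurtosis, or[["kurt"]], tolerance = 1e-12)

  set.seed(17)
  for (i in 1:20) {
    v <- runif(50)
    p <- matrix(c(v, rep(0, 14)), 8, 8)
    m <- matrix(c(rep(TRUE, 50), rep(FALSE, 14)), 8, 8)
    im <- intensity_moments(p, m)
    or <- moments_direct(v)
    expect_equal(im$skewness, or[["skew"]], tolerance = 1e-12)
    expect_equal(im$kurtosis, or[["kurt"]], tolerance = 1e-12)
  }

  # symmetric two-level pattern -> zero skewness
  p2 <- matrix(rep(c(0.2, 0.8), 8), 4, 4)
  expect_equal(intensity_moments(p2, matrix(TRUE, 4, 4))$skewness, 0)

  # large Gaussian sample -> excess kurtosis near 0
  set.seed(8)
  g <- matrix(rnorm(200 * 200), 200, 200)
  expect_equal(intensity_moments(g, matrix(TRUE, 200, 200))$kurtosis, 0,
               tolerance = 0.1)

  # zero variance -> degenerate, moments missing
  const <- intensity_moments(matrix(0.5, 4, 4), matrix(TRUE, 4, 4))
  expect_true(const$degenerate)
  expect_true(is.na(const$skewness))
  expect_error(intensity_moments(matrix(1, 2, 2),
                                 matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)),
               "4 foreground")
})

test_that("shape factors of the two classes form distinct clusters", {
  # population surrogate of the scatter-matrix figure: >= 200 cells per class
  n <- 200
  sfs <- vector("list", 2 * n)
  set.seed(55)
  for (i in seq_len(n)) {
    sp <- cell_spec(base_radius = 40 * runif(1, 0.92, 1.08),
                    texture_seed = 1000 + i, orientation = runif(1, 0, pi))
    r0 <- render_cell(sp, 0, 150)
    r1 <- render_cell(sp, 1, 150)
    sfs[[i]] <- cbind(cell_shape_factors(r0$mask, r0$patch), class = "nonsickled")
    sfs[[n + i]] <- cbind(cell_shape_factors(r1$mask, r1$patch), class = "sickled")
  }
  d <- do.call(rbind, sfs)
  for (col in c("CSF", "Convexity")) {
    q_ns <- quantile(d[d$class == "nonsickled", col], c(0.25, 0.75))
    q_s <- quantile(d[d$class == "sickled", col], c(0.25, 0.75))
    expect_lt(q_s[2], q_ns[1])   # non-overlapping interquartile ranges
  }
  # sickled morphologies are more heterogeneous in every factor
  for (col in c("CSF", "ESF", "SF1", "SF2", "Elongation", "Convexity",
                "Compactness")) {
    expect_gt(var(d[d$class == "sickled", col]),
              var(d[d$class == "nonsickled", col]))
  }
})
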