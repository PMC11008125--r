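test_that("greedy nearest-centroid tracking recovers static identities", {
  p <- oxygen_protocol(frame_interval = 10)
  specs <- sample_population(20, seed = 71)
  det <- withr::with_seed(72, truth_detections(specs, p, jitter_sd = 0.3))
  tr <- link_tracks(det, max_displacement = 15)
  expect_equal(length(unique(tr$track_id)), 20)
  # each track maps to exactly one ground-truth cell, full length
  tab <- table(tr$track_id, tr$cell_label)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(tapply(tr$frame, tr$track_id, length) ==
                    length(frame_times(p))))

  # single cell -> one full-length track
  one <- truth_detections(specs[1], p)
  expect_equal(unique(link_tracks(one)$track_id), 1L)

  # a cell disappearing mid-sequence truncates its track without merging
  gap <- det[!(det$cell_label == 3 & det$frame > 8), ]
  trg <- link_tracks(gap, max_displacement = 15)
  l3 <- trg$track_id[trg$cell_label == 3][1]
  expect_equal(max(trg$frame[trg$track_id == l3]), 8)
  expect_true(all(trg$cell_label[trg$track_id == l3] == 3))
})

test_that("sickled-fraction curve counts per frame with smoothing", {
  p <- oxygen_protocol(frame_interval = 30)
  det <- data.frame(frame = rep(0:1, each = 10), t = rep(c(0, 30), each = 10),
                    cell_label = rep(1:10, 2),
                    x = rep(seq(0, 900, by = 100), 2), y = 100,
                    label = c(rep("sickled", 2), rep("nonsickled", 8),
                              rep("sickled", 5), rep("nonsickled", 5)))
  tr <- link_tracks(det)
  cv <- sickled_fraction_curve(tr, smoothing_window = 1, protocol = p)
  expect_equal(cv$fraction, c(0.2, 0.5))
  expect_equal(cv$n_total, c(10L, 10L))

  # an all-ISC scene stays at fraction 1 throughout
  isc <- sample_population(10, seed = 3, isc_fraction = 1)
  cv1 <- sickled_fraction_curve(link_tracks(truth_detections(isc, p)),
                                protocol = p)
  expect_true(all(cv1$fraction == 1))
})

test_that("delay extraction matches the generator's closed-form crossing", {
  p <- oxygen_protocol()   # 1 s frames
  onset <- deoxy_onset(p)

  # ISC: delay 0 with flag
  isc <- sample_population(1, seed = 5, isc_fraction = 1)
  d <- delay_times(link_tracks(truth_detections(isc, p)), p)
  expect_equal(d$delay_s, 0)
  expect_true(d$isc)

  # known delay, fast rate: recovered within 3 s of the true 0.5-crossing
  sp <- cell_spec(center = c(50, 50), delay = 20, k_s = 0.3, k_u = 1)
  d2 <- delay_times(link_tracks(truth_detections(list(sp), p)), p)
  t_cross <- 20 + log(2) / 0.3
  expect_false(d2$censored)
  expect_lt(abs(d2$delay_s - t_cross), 3)

  # delay beyond the deoxygenation window: censored
  late <- cell_spec(center = c(50, 50), delay = 500, k_s = 0.1, k_u = 1)
  d3 <- delay_times(link_tracks(truth_detections(list(late), p)), p)
  expect_true(d3$censored)

  # track starting after onset: censored with reason
  det <- truth_detections(list(sp), p)
  d4 <- delay_times(link_tracks(det[det$t > 40, ]), p)
  expect_true(d4$censored)
  expect_match(d4$reason, "onset")
})

test_that("delays recover the known lognormal population within 2 s", {
  p <- oxygen_protocol()   # 1 s frames
  specs <- sample_population(300, seed = 81)
  det <- truth_detections(specs, p)
  tr <- link_tracks(det)
  d <- delay_times(tr, p)
  onset <- deoxy_onset(p)
  true_cross <- vapply(specs, function(sp)
    sp$delay + log(2) / sp$k_s, numeric(1))
  isc <- vapply(specs, `[[`, logical(1), "is_isc")
  # compare uncensored, non-ISC recovered delays to the true crossing times
  cell_of_track <- vapply(split(tr$cell_label, tr$track_id), `[`, numeric(1), 1)
  d$cell <- cell_of_track[as.character(d$track_id)]
  ok <- !d$censored & !d$isc
  err <- abs(d$delay_s[ok] - true_cross[d$cell[ok]])
  expect_lte(median(err), 2)
  # ISC flags agree with the generator
  expect_true(all(isc[d$cell[d$isc]]))
})

test_that("unsickling: non-ISC sickled fraction falls during reoxygenation", {
  p <- oxygen_protocol()
  specs <- sample_population(150, seed = 91, isc_fraction = 0)
  cv <- sickled_fraction_curve(link_tracks(truth_detections(specs, p)),
                               protocol = p)
  reox <- cv[cv$t >= reoxy_start(p) + 2, ]
  expect_true(all(diff(reox$fraction) <= 0))
  expect_lt(tail(reox$fraction, 1), head(reox$fraction, 1))
})

test_that("condition comparison aligns summaries and checks protocols", {
  p <- oxygen_protocol(frame_interval = 10)
  specs <- sample_population(50, seed = 101)
  cv <- sickled_fraction_curve(link_tracks(truth_detections(specs, p)),
                               protocol = p)
  cmp <- compare_conditions(list(a = cv, b = cv))
  expect_equal(cmp$end_deoxy_fraction[1], cmp$end_deoxy_fraction[2])

  p2 <- oxygen_protocol(phases = list(c(0.2, 10), c(0.02, 60), c(0.2, 10)),
                        frame_interval = 10)
  cv2 <- sickled_fraction_curve(link_tracks(truth_detections(specs[1:5], p2)),
                                protocol = p2)
  expect_error(compare_conditions(list(a = cv, b = cv2)),
               "different protocols")
})

test_that("curve pooling sums counts across fields of view", {
  p <- oxygen_protocol(frame_interval = 30)
  s1 <- sample_population(10, seed = 1, isc_fraction = 1)
  s2 <- sample_population(10, seed = 2, isc_fraction = 0)
  c1 <- sickled_fraction_curve(link_tracks(truth_detections(s1, p)), protocol = p)
  c2 <- sickled_fraction_curve(link_tracks(truth_detections(s2, p)), protocol = p)
  pooled <- pool_curves(list(c1, c2))
  expect_equal(pooled$n_total, c1$n_total + c2$n_total)
  expect_equal(pooled$fraction[1], 0.5)
})
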