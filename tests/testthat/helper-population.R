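# Build detection tables straight from generator ground truth (an oracle
# classifier): every cell observed in every frame at its true position and
# true label.
truth_detections <- function(specs, protocol, jitter_sd = 0) {
  times <- frame_times(protocol)
  rows <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    s <- sickling_degree_at(sp, times, protocol)
    data.frame(frame = seq_along(times) - 1L, t = times,
               cell_label = i,
               x = sp$center[1] + rnorm(length(times), 0, jitter_sd),
               y = sp$center[2] + rnorm(length(times), 0, jitter_sd),
               label = ifelse(s > 0.5 | sp$is_isc, "sickled", "nonsickled"),
               s_true = s)
  })
  do.call(rbind, rows)
}

sample_population <- function(n, seed, delay_meanlog = log(30),
                              rate_factor = 1, isc_fraction = 0.2) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ks <- rlnorm(1, log(0.12), 0.25) * rate_factor
      cell_spec(center = c(100 * i, 100), base_radius = 20,
                is_isc = runif(1) < isc_fraction,
                delay = rlnorm(1, delay_meanlog, 0.5),
                k_s = ks, k_u = ks * runif(1, 3, 6),
                orientation = runif(1, 0, pi),
                texture_seed = sample.int(1e6, 1))
    })
  })
}
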