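#' Timed oxygenation protocol
#'
#' The gas schedule driving the sickling assay: an ordered list of
#' (oxygen level, duration) phases sampled at a fixed frame interval. The
#' default reproduces the assay schedule: 30 s at high oxygen (20% O2),
#' 120 s at low oxygen (2% O2), then 30 s of reoxygenation.
#'
#' @param phases list of length-2 numeric vectors `c(o2_fraction, seconds)`.
#'   Oxygen levels are fractions in `[0, 0.21]`; durations are positive.
#' @param frame_interval seconds between recorded frames (default 1 s; the
#'   number of frames is the total duration divided by the interval, rounded
#'   down).
#' @return an object of class `oxygen_protocol`.
#' @examples
#' p <- oxygen_protocol()
#' deoxy_onset(p)        # 30
#' length(frame_times(p))
#' @export
oxygen_protocol <- function(phases = list(c(0.20, 30), c(0.02, 120), c(0.20, 30)),
                            frame_interval = 1) {
  if (!length(phases)) stopf("protocol needs at least one phase")
  ph <- do.call(rbind, lapply(phases, function(p) {
    if (length(p) != 2L) stopf("each phase is c(o2_level, duration)")
    data.frame(o2 = p[1], duration = p[2])
  }))
  if (any(ph$duration <= 0)) stopf("phase durations must be positive")
  if (any(ph$o2 < 0 | ph$o2 > 0.21)) stopf("oxygen levels must lie in [0, 0.21]")
  if (frame_interval <= 0) stopf("frame_interval must be positive")
  ph$start <- cumsum(c(0, ph$duration[-nrow(ph)]))
  ph$end <- ph$start + ph$duration
  structure(list(phases = ph, frame_interval = frame_interval),
            class = "oxygen_protocol")
}

#' @export
print.oxygen_protocol <- function(x, ...) {
  cat("Oxygenation protocol (", protocol_duration(x), " s, ",
      x$frame_interval, " s/frame):\n", sep = "")
  for (i in seq_len(nrow(x$phases)))
    cat(sprintf("  phase %d: %4.0f s at %.0f%% O2\n", i,
                x$phases$duration[i], 100 * x$phases$o2[i]))
  invisible(x)
}

# oxygen level below which a phase counts as deoxygenating
LOW_O2 <- 0.1

#' @rdname oxygen_protocol
#' @param protocol an `oxygen_protocol`.
#' @export
protocol_duration <- function(protocol) sum(protocol$phases$duration)

#' Frame timestamps of a protocol
#'
#' @inheritParams protocol_duration
#' @return numeric vector of frame times in seconds, starting at 0.
#' @export
frame_times <- function(protocol) {
  n <- floor(protocol_duration(protocol) / protocol$frame_interval)
  (seq_len(n) - 1) * protocol$frame_interval
}

#' Deoxygenation onset and reoxygenation start times
#'
#' `deoxy_onset` is the start of the first low-oxygen phase; `reoxy_start`
#' the end of the last low-oxygen phase.
#'
#' @inheritParams protocol_duration
#' @return time in seconds, or `NA` if the protocol has no low-oxygen phase.
#' @export
deoxy_onset <- function(protocol) {
  low <- which(protocol$phases$o2 < LOW_O2)
  if (!length(low)) return(NA_real_)
  protocol$phases$start[low[1]]
}

#' @rdname deoxy_onset
#' @export
reoxy_start <- function(protocol) {
  low <- which(protocol$phases$o2 < LOW_O2)
  if (!length(low)) return(NA_real_)
  protocol$phases$end[low[length(low)]]
}

protocol_to_list <- function(protocol) {
  list(phases = lapply(seq_len(nrow(protocol$phases)), function(i)
    c(protocol$phases$o2[i], protocol$phases$duration[i])),
    frame_interval = protocol$frame_interval)
}

protocol_from_list <- function(x) {
  oxygen_protocol(phases = lapply(x$phases, as.numeric),
                  frame_interval = as.numeric(x$frame_interval))
}

protocols_equal <- function(a, b) {
  isTRUE(all.equal(a$phases[c("o2", "duration")], b$phases[c("o2", "duration")])) &&
    isTRUE(all.equal(a$frame_interval, b$frame_interval))
}
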