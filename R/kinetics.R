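#' Link per-frame cell detections into tracks
#'
#' Greedy nearest-centroid matching frame to frame with a distance gate
#' (default 15 px, about one sixth of a cell diameter — the assay is
#' hydrostatic so cells barely move). Unmatched detections start new tracks;
#' ties are broken by smallest distance, then lowest existing track id.
#'
#' @param detections data frame with columns `frame` (0-based), `t`,
#'   `cell_label`, `x`, `y` and any per-detection payload columns (e.g.
#'   `label`, `p_sickled`, shape factors); one row per detection, sorted or
#'   not.
#' @param max_displacement gate in pixels.
#' @return the same data frame with a `track_id` column, ordered by track
#'   then frame.
#' @export
link_tracks <- function(detections, max_displacement = 15) {
  need <- c("frame", "x", "y")
  if (!all(need %in% names(detections)))
    stopf("detections need columns: %s", paste(need, collapse = ", "))
  det <- detections[order(detections$frame), , drop = FALSE]
  det$track_id <- NA_integer_
  active <- data.frame(track_id = integer(), x = numeric(), y = numeric())
  next_id <- 1L
  for (f in sort(unique(det$frame))) {
    rows <- which(det$frame == f)
    if (!nrow(active)) {
      det$track_id[rows] <- seq.int(next_id, length.out = length(rows))
      next_id <- next_id + length(rows)
    } else {
      D <- outer(active$x, det$x[rows], "-")^2 + outer(active$y, det$y[rows], "-")^2
      D <- sqrt(D)
      D[D > max_displacement] <- Inf
      used_t <- rep(FALSE, nrow(active)); used_d <- rep(FALSE, length(rows))
      repeat {
        D2 <- D; D2[used_t, ] <- Inf; D2[, used_d] <- Inf
        if (!any(is.finite(D2))) break
        # smallest distance; among exact ties the lowest track id wins
        # (column-major which.min scans track ids first)
        k <- which.min(D2)
        ti <- (k - 1) %% nrow(D2) + 1; di <- (k - 1) %/% nrow(D2) + 1
        det$track_id[rows[di]] <- active$track_id[ti]
        used_t[ti] <- TRUE; used_d[di] <- TRUE
      }
      if (any(!used_d)) {
        det$track_id[rows[!used_d]] <- seq.int(next_id, length.out = sum(!used_d))
        next_id <- next_id + sum(!used_d)
      }
    }
    # active set: last known position of every track seen so far
    cur <- det[det$frame <= f & !is.na(det$track_id), c("track_id", "frame", "x", "y")]
    cur <- cur[order(cur$track_id, cur$frame), ]
    last <- cur[!duplicated(cur$track_id, fromLast = TRUE), ]
    active <- data.frame(track_id = last$track_id, x = last$x, y = last$y)
  }
  det[order(det$track_id, det$frame), , drop = FALSE]
}

#' Majority-vote smoothing of a binary label sequence
#'
#' Centered odd window; the window shrinks symmetrically at the ends.
#'
#' @param lab logical or 0/1 vector.
#' @param window odd window length (1 disables smoothing).
#' @return smoothed 0/1 integer vector.
#' @export
smooth_labels <- function(lab, window = 3L) {
  lab <- as.integer(lab > 0)
  if (window <= 1L) return(lab)
  if (window %% 2L == 0L) stopf("smoothing window must be odd")
  half <- window %/% 2L
  n <- length(lab)
  out <- integer(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    out[i] <- as.integer(mean(lab[(i - h):(i + h)]) > 0.5)
  }
  out
}

#' Population sickled-fraction curve
#'
#' Per frame, the fraction of tracked, non-discarded cells classified
#' sickled, after optional per-track majority-vote label smoothing. Frames
#' with no cells get `NA`.
#'
#' @param tracks data frame from [link_tracks()] with a `label` column
#'   (`"sickled"`/`"nonsickled"` or 0/1) and `track_id`.
#' @param smoothing_window odd window for [smooth_labels()] (default 3).
#' @param protocol optional [oxygen_protocol()] attached to the curve.
#' @return object of class `kinetics_curve`: data frame `frame, t, n_total,
#'   n_sickled, fraction` with the protocol as attribute.
#' @export
sickled_fraction_curve <- function(tracks, smoothing_window = 3L,
                                   protocol = NULL) {
  if (!"label" %in% names(tracks)) stopf("tracks need a 'label' column")
  tr <- tracks
  tr$sick <- if (is.character(tr$label) || is.factor(tr$label))
    as.integer(tr$label == "sickled") else as.integer(tr$label > 0)
  tr <- tr[order(tr$track_id, tr$frame), ]
  tr$sick_s <- unlist(lapply(split(tr$sick, tr$track_id), smooth_labels,
                             window = smoothing_window), use.names = FALSE)
  frames <- sort(unique(tr$frame))
  agg_n <- tapply(tr$sick_s, tr$frame, length)
  agg_s <- tapply(tr$sick_s, tr$frame, sum)
  tt <- tapply(tr$t, tr$frame, function(v) v[1])
  out <- data.frame(frame = frames, t = as.numeric(tt),
                    n_total = as.integer(agg_n), n_sickled = as.integer(agg_s))
  out$fraction <- ifelse(out$n_total > 0, out$n_sickled / out$n_total, NA_real_)
  structure(out, class = c("kinetics_curve", "data.frame"), protocol = protocol)
}

#' Pool sickled-fraction curves across fields of view
#'
#' Sums per-frame counts of several curves recorded under the same protocol
#' (the assay images multiple fields to accumulate its cell population).
#'
#' @param curves list of `kinetics_curve` objects with identical frames.
#' @return a pooled `kinetics_curve`.
#' @export
pool_curves <- function(curves) {
  if (!length(curves)) stopf("no curves to pool")
  f0 <- curves[[1]]$frame
  for (cv in curves)
    if (!identical(cv$frame, f0)) stopf("curves cover different frame sets")
  out <- curves[[1]]
  out$n_total <- Reduce(`+`, lapply(curves, `[[`, "n_total"))
  out$n_sickled <- Reduce(`+`, lapply(curves, `[[`, "n_sickled"))
  out$fraction <- ifelse(out$n_total > 0, out$n_sickled / out$n_total, NA_real_)
  out
}

#' Per-cell sickling delay time
#'
#' The delay is the time from deoxygenation onset to the first frame at
#' which the (smoothed) label is sickled and stays sickled for at least
#' `persistence` consecutive frames. Cells already sickled at onset are
#' ISCs: delay 0 with an ISC flag. Cells that never sickle are
#' right-censored at their last observed frame, as are tracks that do not
#' cover the onset.
#'
#' @param track data frame of one track (columns `frame, t, label`), frames
#'   increasing.
#' @param protocol an [oxygen_protocol()].
#' @param persistence minimum run length in frames (default 3).
#' @param smoothing_window odd majority-vote window applied first.
#' @return one-row data frame `delay_s, censored, reason, isc`.
#' @export
delay_time <- function(track, protocol, persistence = 3L,
                       smoothing_window = 3L) {
  onset <- deoxy_onset(protocol)
  tr <- track[order(track$frame), ]
  sick <- if (is.character(tr$label) || is.factor(tr$label))
    as.integer(tr$label == "sickled") else as.integer(tr$label > 0)
  sick <- smooth_labels(sick, smoothing_window)
  if (is.na(onset) || min(tr$t) > onset)
    return(data.frame(delay_s = NA_real_, censored = TRUE,
                      reason = "track does not cover deoxygenation onset",
                      isc = FALSE))
  post <- which(tr$t >= onset)
  hit <- NA_integer_
  for (i in post) {
    j <- i + persistence - 1L
    if (j > nrow(tr)) break
    if (all(sick[i:j] == 1L)) { hit <- i; break }
  }
  if (is.na(hit))
    return(data.frame(delay_s = NA_real_, censored = TRUE,
                      reason = "no persistent sickled call", isc = FALSE))
  pre <- which(tr$t <= onset)
  already <- length(pre) > 0 && sick[max(pre)] == 1L && tr$t[hit] - onset <=
    persistence * protocol$frame_interval
  if (already)
    return(data.frame(delay_s = 0, censored = FALSE, reason = NA_character_,
                      isc = TRUE))
  data.frame(delay_s = tr$t[hit] - onset, censored = FALSE,
             reason = NA_character_, isc = FALSE)
}

#' Delay times for all tracks
#'
#' @param tracks data frame from [link_tracks()] with `label`.
#' @inheritParams delay_time
#' @return data frame `track_id, delay_s, censored, reason, isc`.
#' @export
delay_times <- function(tracks, protocol, persistence = 3L,
                        smoothing_window = 3L) {
  parts <- lapply(split(tracks, tracks$track_id), function(tr) {
    d <- delay_time(tr, protocol, persistence, smoothing_window)
    d$track_id <- tr$track_id[1]
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[, c("track_id", "delay_s", "censored", "reason", "isc")]
}

#' Compare sickling kinetics across conditions
#'
#' Aligned per-condition summary: sickled fraction at the end of
#' deoxygenation, median delay among uncensored non-ISC cells (when delays
#' are supplied), and censoring rate. All curves must share the protocol.
#'
#' @param curves named list of `kinetics_curve` objects.
#' @param delays optional named list of [delay_times()] tables (same names).
#' @return data frame, one row per condition.
#' @export
compare_conditions <- function(curves, delays = NULL) {
  if (is.null(names(curves)) || any(names(curves) == ""))
    stopf("curves must be a named list")
  protos <- lapply(curves, attr, "protocol")
  if (any(vapply(protos, is.null, logical(1))))
    stopf("every curve needs its protocol attribute")
  for (p in protos[-1])
    if (!protocols_equal(protos[[1]], p))
      stopf("curves were recorded under different protocols")
  t_end <- reoxy_start(protos[[1]])
  rows <- lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    de <- cv[cv$t < t_end, ]
    end_frac <- de$fraction[which.max(de$t)]
    md <- NA_real_; cens <- NA_real_
    if (!is.null(delays) && nm %in% names(delays)) {
      dl <- delays[[nm]]
      ok <- !dl$censored & !dl$isc
      md <- if (any(ok)) median(dl$delay_s[ok]) else NA_real_
      cens <- mean(dl$censored)
    }
    data.frame(condition = nm, end_deoxy_fraction = end_frac,
               median_delay_s = md, censoring_rate = cens)
  })
  do.call(rbind, rows)
}
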