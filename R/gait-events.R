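#' Find peaks by topographic prominence
#'
#' Local maxima are ranked by topographic prominence: the height of the peak
#' above the higher of the two lowest points one must descend to before
#' reaching higher ground (or the signal edge) on either side. Peaks closer
#' together than `min_distance` are resolved greedily, keeping the more
#' prominent of any conflicting pair.
#'
#' @param x numeric vector
#' @param min_prominence minimum prominence to keep a peak (signal units)
#' @param min_distance minimum spacing between kept peaks (samples); 0 keeps all
#' @return data.frame with `index`, `value`, `prominence`, sorted by index
#' @export
find_peaks <- function(x, min_prominence = 0, min_distance = 0) {
  n <- length(x)
  out0 <- data.frame(index = integer(0), value = numeric(0), prominence = numeric(0))
  if (n < 3L || !any(is.finite(x)) || all(x == x[1], na.rm = TRUE)) return(out0)
  # candidate maxima; plateaus contribute their first sample
  idx <- integer(0)
  i <- 2L
  while (i < n) {
    if (!is.na(x[i]) && !is.na(x[i - 1L]) && x[i] > x[i - 1L]) {
      j <- i
      while (j < n && !is.na(x[j + 1L]) && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && !is.na(x[j + 1L]) && x[j + 1L] < x[i]) idx <- c(idx, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(idx)) return(out0)
  prom <- vapply(idx, function(p) {
    h <- x[p]
    # walk left to the first strictly higher sample, tracking the minimum
    lmin <- h
    k <- p - 1L
    while (k >= 1L) {
      if (!is.na(x[k])) {
        if (x[k] > h) break
        if (x[k] < lmin) lmin <- x[k]
      }
      k <- k - 1L
    }
    rmin <- h
    k <- p + 1L
    while (k <= n) {
      if (!is.na(x[k])) {
        if (x[k] > h) break
        if (x[k] < rmin) rmin <- x[k]
      }
      k <- k + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence & prom > 0
  idx <- idx[keep]; prom <- prom[keep]
  if (!length(idx)) return(out0)
  if (min_distance > 0 && length(idx) > 1L) {
    ord <- order(-prom, idx)
    taken <- logical(length(idx))
    for (k in ord) {
      if (any(taken & abs(idx - idx[k]) < min_distance)) next
      taken[k] <- TRUE
    }
    idx <- idx[taken]; prom <- prom[taken]
  }
  o <- order(idx)
  data.frame(index = idx[o], value = x[idx[o]], prominence = prom[o])
}

#' Detect heelstrikes from vertical heel-marker position
#'
#' Heelstrikes are negative peaks (minima) of the 10 Hz-filtered vertical
#' heel trajectory with topographic prominence above 20 mm and at least
#' 250 ms between events of the same foot. Event time is the sample of the
#' extremum (no sub-sample interpolation).
#'
#' @param heel_z vertical heel-marker position (mm), already low-pass filtered
#' @param fs sampling rate (Hz)
#' @param min_prominence_mm prominence threshold (mm)
#' @param min_distance_ms minimum inter-event spacing (ms)
#' @param t0 time of the first sample (s)
#' @return data.frame with `time` (s), `index`, `prominence`
#' @export
detect_heelstrikes <- function(heel_z, fs, min_prominence_mm = 20,
                               min_distance_ms = 250, t0 = 0) {
  pk <- find_peaks(-heel_z, min_prominence = min_prominence_mm,
                   min_distance = min_distance_ms * fs / 1000)
  data.frame(time = t0 + (pk$index - 1L) / fs, index = pk$index,
             prominence = pk$prominence)
}

#' Detect pushoffs from 2nd-metatarsal vertical velocity
#'
#' For each ipsilateral heelstrike, the pushoff is the first subsequent peak
#' of the forefoot vertical velocity with prominence above 350 mm/s. Steps
#' where no qualifying peak occurs before the next ipsilateral heelstrike are
#' flagged.
#'
#' @param mt2_z_vel vertical velocity of the 2nd-metatarsal marker (mm/s),
#'   derived from the filtered position
#' @param fs sampling rate (Hz)
#' @param heelstrike_times ipsilateral heelstrike times (s)
#' @param min_prominence minimum peak prominence (mm/s)
#' @param t0 time of the first sample (s)
#' @return data.frame with `heelstrike_time`, `time` (NA when flagged),
#'   `flagged`
#' @export
detect_pushoffs <- function(mt2_z_vel, fs, heelstrike_times,
                            min_prominence = 350, t0 = 0) {
  if (!length(heelstrike_times))
    return(data.frame(heelstrike_time = numeric(0), time = numeric(0),
                      flagged = logical(0)))
  pk <- find_peaks(mt2_z_vel, min_prominence = min_prominence)
  pk_t <- t0 + (pk$index - 1L) / fs
  hs <- sort(heelstrike_times)
  nxt <- c(hs[-1], Inf)
  res <- vapply(seq_along(hs), function(i) {
    cand <- pk_t[pk_t > hs[i] & pk_t < nxt[i]]
    if (length(cand)) cand[1] else NA_real_
  }, numeric(1))
  data.frame(heelstrike_time = hs, time = res, flagged = is.na(res))
}

#' Detect all gait events of a trial bundle
#'
#' Runs heelstrike and pushoff detection for both feet on the filtered
#' marker streams and returns a combined event table. Alternation of feet is
#' checked: between consecutive heelstrikes of one foot exactly one
#' contralateral heelstrike must occur; violations are flagged with a
#' warning, never silently repaired.
#'
#' @param markers_f filtered marker matrix (time x channel) containing
#'   `LHEE_z`, `RHEE_z`, `LMT2_z`, `RMT2_z`
#' @param fs marker sampling rate (Hz)
#' @param t0 time of the first sample (s)
#' @return data.frame of class `gait_events` with columns `time`, `foot`,
#'   `kind` ("heelstrike"/"pushoff"), `source` ("auto")
#' @export
detect_gait_events <- function(markers_f, fs, t0 = 0) {
  ev <- list()
  for (side in c("left", "right")) {
    pre <- if (side == "left") "L" else "R"
    hz <- markers_f[, paste0(pre, "HEE_z")]
    hs <- detect_heelstrikes(hz, fs, t0 = t0)
    mtv <- central_diff(markers_f[, paste0(pre, "MT2_z")], 1 / fs)
    po <- detect_pushoffs(mtv, fs, hs$time, t0 = t0)
    ev[[side]] <- rbind(
      data.frame(time = hs$time, foot = side, kind = "heelstrike",
                 stringsAsFactors = FALSE),
      data.frame(time = po$time[!po$flagged], foot = side, kind = "pushoff",
                 stringsAsFactors = FALSE)
    )
  }
  out <- do.call(rbind, ev)
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  out$source <- "auto"
  hs <- out[out$kind == "heelstrike", ]
  if (nrow(hs) > 1L && any(hs$foot[-1] == hs$foot[-nrow(hs)]))
    warning("heelstrike feet do not alternate; check marker quality")
  class(out) <- c("gait_events", "data.frame")
  out
}

#' Apply manual event corrections
#'
#' Deterministically applies reviewed edits (add / remove / move) to an
#' automatically detected event table, then re-validates: per-foot
#' heelstrikes must stay at least `min_spacing_ms` apart and every pushoff
#' must lie strictly between its heelstrike and the next ipsilateral
#' heelstrike. An override that breaks these rules is rejected with an error.
#'
#' @param events a `gait_events` table
#' @param overrides data.frame with columns `action` ("add"/"remove"/"move"),
#'   `foot`, `kind`, `time`, and `new_time` (used by "move"); an empty or
#'   NULL table is the identity
#' @param min_spacing_ms minimum per-foot heelstrike spacing (ms)
#' @param tol_s time tolerance for matching `time` to an existing event (s)
#' @return corrected `gait_events` table; edited rows have `source = "manual"`
#' @export
review_events <- function(events, overrides = NULL, min_spacing_ms = 250,
                          tol_s = 0.005) {
  if (is.null(overrides) || nrow(overrides) == 0L) return(events)
  ev <- as.data.frame(events)
  for (i in seq_len(nrow(overrides))) {
    o <- overrides[i, ]
    match_row <- function() {
      j <- which(ev$foot == o$foot & ev$kind == o$kind &
                   abs(ev$time - o$time) <= tol_s)
      if (!length(j))
        stop(sprintf("override %d: no %s %s event near t=%.3f s",
                     i, o$foot, o$kind, o$time), call. = FALSE)
      j[1]
    }
    if (o$action == "add") {
      ev <- rbind(ev, data.frame(time = o$time, foot = o$foot, kind = o$kind,
                                 source = "manual", stringsAsFactors = FALSE))
    } else if (o$action == "remove") {
      ev <- ev[-match_row(), , drop = FALSE]
    } else if (o$action == "move") {
      j <- match_row()
      ev$time[j] <- o$new_time
      ev$source[j] <- "manual"
    } else stop(sprintf("unknown override action '%s'", o$action), call. = FALSE)
  }
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  for (side in c("left", "right")) {
    hs <- sort(ev$time[ev$foot == side & ev$kind == "heelstrike"])
    if (length(hs) > 1L && any(diff(hs) < min_spacing_ms / 1000))
      stop(sprintf("overrides rejected: %s heelstrikes closer than %g ms",
                   side, min_spacing_ms), call. = FALSE)
    po <- sort(ev$time[ev$foot == side & ev$kind == "pushoff"])
    if (length(po)) {
      if (!length(hs) || any(po <= hs[1]))
        stop("overrides rejected: pushoff without a preceding ipsilateral heelstrike",
             call. = FALSE)
      # at most one pushoff per ipsilateral heelstrike interval
      slot <- findInterval(po, hs)
      if (anyDuplicated(slot))
        stop("overrides rejected: multiple pushoffs within one ipsilateral step",
             call. = FALSE)
    }
  }
  class(ev) <- c("gait_events", "data.frame")
  ev
}
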