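#' Pointwise 95% confidence band of a trajectory set
#'
#' At each time point the band is `mean +/- t(0.975, n-1) * SE`, treating
#' the values at that point as independent and normally distributed (the
#' visualization-grade band; model-based CIs are the inference module's
#' job). With a single trajectory the band is undefined.
#'
#' @param mat matrix, one row per repeat, one column per time point
#' @param conf confidence level
#' @return data.frame with `mean`, `lower`, `upper`, `n` per time point
#' @export
pointwise_ci <- function(mat, conf = 0.95) {
  mat <- as.matrix(mat)
  m <- colMeans(mat, na.rm = TRUE)
  n <- colSums(!is.na(mat))
  s <- apply(mat, 2L, stats::sd, na.rm = TRUE)
  half <- ifelse(n >= 2L, stats::qt(1 - (1 - conf) / 2, n - 1L) * s / sqrt(n), NA_real_)
  data.frame(mean = m, lower = m - half, upper = m + half, n = n)
}

#' Response onset by tangent extrapolation
#'
#' Estimates when a pooled stimulus response departs from baseline:
#' (1) compute the pointwise 95% CI of the mean response; (2) find the first
#' contiguous region (at least `min_region` samples) where the CI excludes
#' zero with consistent sign; (3) within it, locate the first local maximum
#' of the response's rate of change (central differences, signed along the
#' response direction); (4) fit the tangent line at that point; (5) the
#' tangent's zero crossing is the onset. When no CI-exclusion region exists
#' the onset is undefined (NA).
#'
#' @param mat response matrix, one row per repeat (pooled steps), one column
#'   per time point
#' @param times_ms time of each column (ms post-stimulus)
#' @param conf confidence level for the exclusion band
#' @param min_region minimum exclusion-region length (samples)
#' @param search_start_ms earliest time an exclusion region may start; when
#'   the responses were re-referenced to an early baseline window, that
#'   window is uninformative by construction and must be excluded from the
#'   region search
#' @return list of class `onset_estimate`: `onset_ms`, `t_star_ms` (tangent
#'   anchor), `slope` (units/ms), `value` (response at anchor), `region_ms`
#'   (range of the exclusion window), `n` (rows pooled)
#' @export
estimate_onset <- function(mat, times_ms, conf = 0.95, min_region = 5L,
                           search_start_ms = -Inf) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == length(times_ms))
  und <- structure(list(onset_ms = NA_real_, t_star_ms = NA_real_,
                        slope = NA_real_, value = NA_real_,
                        region_ms = c(NA_real_, NA_real_), n = nrow(mat)),
                   class = "onset_estimate")
  if (nrow(mat) < 2L) return(und)
  ci <- pointwise_ci(mat, conf)
  excl <- (ci$lower > 0 & ci$upper > 0) | (ci$lower < 0 & ci$upper < 0)
  excl[is.na(excl)] <- FALSE
  excl[times_ms < search_start_ms] <- FALSE   # trim, don't discard, regions
  r <- rle(excl)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= min_region)
  # consistent sign within the run
  cand <- cand[vapply(cand, function(j) {
    sg <- sign(ci$mean[starts[j]:ends[j]])
    all(sg == sg[1])
  }, logical(1))]
  if (!length(cand)) return(und)
  # with well-pooled data there is a single exclusion region; when noise at
  # small n produces several disjoint ones, analyze the region carrying the
  # dominant response
  peak <- vapply(cand, function(j) max(abs(ci$mean[starts[j]:ends[j]])), numeric(1))
  j <- cand[which.max(peak)]
  a <- starts[j]; b <- ends[j]
  dirn <- sign(ci$mean[a])

  # The rising flank that produces the exclusion region precedes it whenever
  # few repeats make the band wide, so the search window for the
  # rate-of-change maximum extends backward from the region start to the
  # last zero crossing of the mean response. With many pooled repeats the
  # region itself already contains the flank and the extension is empty.
  a0 <- a
  while (a0 > 1L && sign(ci$mean[a0 - 1L]) == dirn) a0 <- a0 - 1L

  dt <- mean(diff(times_ms))
  dm <- central_diff(ci$mean, dt) * dirn
  # first local maximum of the rate of change (plateaus count at their first
  # sample); maxima below half the window's peak rate are noise bumps on the
  # baseline, not the response flank, and are passed over
  lo <- max(a0, 2L); hi <- min(b, length(dm) - 1L)
  thr <- 0.5 * max(dm[lo:hi])
  t_star <- NA_integer_
  for (i in lo:hi) {
    if (dm[i] >= dm[i - 1L] && dm[i] >= dm[i + 1L] && dm[i] > 0 && dm[i] >= thr) {
      t_star <- i; break
    }
  }
  if (is.na(t_star)) {
    i <- which.max(dm[lo:hi]) + lo - 1L
    if (dm[i] <= 0) return(und)
    t_star <- i
  }
  slope <- dm[t_star] * dirn
  val <- ci$mean[t_star]
  onset <- times_ms[t_star] - val / slope
  if (!is.finite(onset) || onset < times_ms[1] || onset > times_ms[length(times_ms)])
    onset <- NA_real_
  structure(list(onset_ms = onset, t_star_ms = times_ms[t_star], slope = slope,
                 value = val, region_ms = c(times_ms[a], times_ms[b]),
                 n = nrow(mat)),
            class = "onset_estimate")
}

#' @export
print.onset_estimate <- function(x, ...) {
  if (is.na(x$onset_ms)) cat("<onset_estimate> undefined (no CI-exclusion region)\n")
  else cat(sprintf("<onset_estimate> %.1f ms (tangent at %.1f ms, slope %.3g/ms, n=%d)\n",
                   x$onset_ms, x$t_star_ms, x$slope, x$n))
  invisible(x)
}
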