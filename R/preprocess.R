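#' Zero-phase Butterworth low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase, so event
#' timing is preserved), with odd-reflection padding at the ends to suppress
#' edge transients. DC gain is 1. Standard cutoffs in this pipeline are
#' 10 Hz for kinematics, 50 Hz for force-plate data and 6 Hz for rectified
#' EMG.
#'
#' @param x numeric vector or matrix (filtered column-wise); must be gap-free
#'   (fill or exclude NA runs first, see [fill_gaps()])
#' @param fs sampling rate (Hz)
#' @param fc cutoff frequency (Hz), must be below Nyquist
#' @param order filter order (applied twice, so effective order doubles)
#' @return filtered signal, same shape as `x`
#' @export
lowpass <- function(x, fs, fc, order = 4) {
  assert_scalar_pos(fs, "fs")
  assert_scalar_pos(fc, "fc")
  if (fc >= fs / 2)
    stop(sprintf("cutoff %g Hz must be below the Nyquist frequency %g Hz", fc, fs / 2),
         call. = FALSE)
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  filt1 <- function(v) {
    if (anyNA(v)) stop("NA in signal: fill or exclude gaps before filtering", call. = FALSE)
    n <- length(v)
    if (n < 2L) return(v)
    # reflection padding must outlast the filter's settling time, since
    # filtfilt starts from zero initial conditions
    npad <- min(n - 1L, max(24L, 6L * ceiling(fs / fc)))
    # odd reflection about the end points
    pre <- 2 * v[1] - v[(npad + 1L):2L]
    post <- 2 * v[n] - v[(n - 1L):(n - npad)]
    y <- signal::filtfilt(bf, c(pre, v, post))
    y[(npad + 1L):(npad + n)]
  }
  if (is.matrix(x)) apply(x, 2L, filt1) else filt1(x)
}

#' Fill short marker occlusions with cubic splines
#'
#' NA runs up to `max_gap_ms` that are flanked by data on both sides are
#' replaced by a cubic spline fitted through neighbouring samples; longer
#' runs (and runs touching the signal edge) are left as NA and marked
#' excluded, so downstream steps overlapping them can be dropped.
#'
#' @param x numeric vector or matrix (per-column) possibly containing NA runs
#' @param fs sampling rate (Hz)
#' @param max_gap_ms longest occlusion that may be interpolated (ms)
#' @param support number of finite samples used on each side of a gap
#' @return list with `data` (gaps filled) and `excluded` (logical, same shape,
#'   TRUE where data remain unusable)
#' @export
fill_gaps <- function(x, fs, max_gap_ms = 100, support = 5L) {
  assert_scalar_pos(fs, "fs")
  fill1 <- function(v) {
    excl <- rep(FALSE, length(v))
    if (!anyNA(v)) return(list(data = v, excluded = excl))
    if (all(is.na(v))) {
      warning("all-NA channel: fully excluded")
      return(list(data = v, excluded = rep(TRUE, length(v))))
    }
    na <- is.na(v)
    r <- rle(na)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    max_len <- max_gap_ms * fs / 1000
    for (j in which(r$values)) {
      s <- starts[j]; e <- ends[j]
      interior <- s > 1L && e < length(v)
      if (interior && r$lengths[j] <= max_len) {
        li <- max(1L, s - support):(s - 1L)
        ri <- (e + 1L):min(length(v), e + support)
        sup <- c(li, ri)
        sup <- sup[!is.na(v[sup])]
        if (length(sup) >= 4L) {
          v[s:e] <- stats::spline(sup, v[sup], xout = s:e, method = "natural")$y
          next
        }
      }
      excl[s:e] <- TRUE
    }
    list(data = v, excluded = excl)
  }
  if (is.matrix(x)) {
    res <- lapply(seq_len(ncol(x)), function(j) fill1(x[, j]))
    data <- do.call(cbind, lapply(res, `[[`, "data"))
    excl <- do.call(cbind, lapply(res, `[[`, "excluded"))
    dimnames(data) <- dimnames(x); dimnames(excl) <- dimnames(x)
    list(data = data, excluded = excl)
  } else fill1(x)
}

#' Simplified segment mass-fraction table
#'
#' Whole-body CoM is computed as the mass-fraction-weighted mean of segment
#' CoM positions. This package uses a compact five-segment table (trunk,
#' pelvis, head, left/right leg) whose fractions sum to 1; the synthetic
#' walker emits segment CoM proxies for exactly these segments, so generator
#' and analysis are consistent.
#'
#' @return data.frame with columns `segment` and `fraction`
#' @export
default_segment_table <- function() {
  data.frame(
    segment = c("trunk", "pelvis", "head", "leg_left", "leg_right"),
    fraction = c(0.532, 0.142, 0.081, 0.1225, 0.1225),
    stringsAsFactors = FALSE
  )
}

#' Whole-body centre of mass from segment positions
#'
#' @param segments matrix (time x segment) of segment CoM positions along one
#'   axis (mm), with column names matching `table$segment`
#' @param table segment mass-fraction table, fractions summing to 1
#' @return CoM position trajectory (mm)
#' @export
compute_com <- function(segments, table = default_segment_table()) {
  if (abs(sum(table$fraction) - 1) > 1e-6)
    stop("segment mass fractions must sum to 1", call. = FALSE)
  missing <- setdiff(table$segment, colnames(segments))
  if (length(missing))
    stop(sprintf("missing segment(s): %s", paste(missing, collapse = ", ")), call. = FALSE)
  as.vector(segments[, table$segment, drop = FALSE] %*% table$fraction)
}

#' CoM state: position, velocity, acceleration
#'
#' Velocity and acceleration are successive central-difference derivatives of
#' the (already low-pass filtered) CoM position.
#'
#' @param com_pos CoM position trajectory (mm)
#' @param fs sampling rate (Hz)
#' @return data.frame with columns `position` (mm), `velocity` (mm/s),
#'   `acceleration` (mm/s^2)
#' @export
com_state <- function(com_pos, fs) {
  assert_scalar_pos(fs, "fs")
  dt <- 1 / fs
  vel <- central_diff(com_pos, dt)
  acc <- central_diff(vel, dt)
  data.frame(position = com_pos, velocity = vel, acceleration = acc)
}

#' Lateral centre of pressure from dual force plates
#'
#' Per-plate lateral CoP follows the moment-over-vertical-force rule
#' `cop_x = 1000 * Mx / Fz + origin_x` (mm, treadmill frame). The whole-body
#' CoP is the vertical-force-weighted combination of the plates, which
#' algebraically reduces to total moment over total vertical force
#' (`cop = (sum(Fz_i * origin_i) + 1000 * sum(Mx_i)) / sum(Fz_i)`); this
#' form never divides by a small per-plate force, so weight transfer
#' produces no numerical glitches. Samples where the total vertical force is
#' below `fz_threshold` (nobody on the plates) have an undefined CoP (NA)
#' and are flagged invalid; a single plate's CoP is reported NA while that
#' plate carries less than `fz_threshold`.
#'
#' @param forces matrix/data.frame with columns `fz_left`, `mx_left`,
#'   `fz_right`, `mx_right` (N, N m)
#' @param origins named numeric, lateral plate origins in the common frame
#'   (mm), e.g. `c(left = 0, right = 0)`
#' @param fz_threshold minimum vertical force for a valid CoP (N)
#' @return data.frame with `cop_x` (mm, whole-body), `valid` (logical),
#'   `cop_left`, `cop_right` (mm, per plate, NA when unloaded)
#' @export
compute_cop <- function(forces, origins = c(left = 0, right = 0), fz_threshold = 50) {
  forces <- as.data.frame(forces)
  need <- c("fz_left", "mx_left", "fz_right", "mx_right")
  miss <- setdiff(need, names(forces))
  if (length(miss))
    stop(sprintf("missing force channel(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  wl <- pmax(forces$fz_left, 0)
  wr <- pmax(forces$fz_right, 0)
  tot <- wl + wr
  valid <- is.finite(tot) & tot > fz_threshold
  cop <- ifelse(valid,
                (wl * origins[["left"]] + wr * origins[["right"]] +
                   1000 * (forces$mx_left + forces$mx_right)) / tot,
                NA_real_)
  copl <- ifelse(wl > fz_threshold,
                 1000 * forces$mx_left / wl + origins[["left"]], NA_real_)
  copr <- ifelse(wr > fz_threshold,
                 1000 * forces$mx_right / wr + origins[["right"]], NA_real_)
  data.frame(cop_x = cop, valid = valid, cop_left = copl, cop_right = copr)
}

#' EMG envelope: rectify and low-pass
#'
#' @param raw raw EMG vector or matrix (a.u.)
#' @param fs sampling rate (Hz)
#' @param fc envelope cutoff (Hz)
#' @return envelope, same shape
#' @export
emg_envelope <- function(raw, fs, fc = 6) {
  lowpass(abs(raw), fs, fc)
}

#' Normalize an EMG envelope to control strides
#'
#' The grand mean of the envelope over all control-stride samples (per
#' channel) is set to 100%.
#'
#' @param envelope envelope vector (a.u.)
#' @param control_idx integer or logical index of samples belonging to
#'   control strides
#' @return normalized envelope (% of control mean)
#' @export
emg_normalize <- function(envelope, control_idx) {
  if (length(control_idx) == 0L)
    stop("no control-stride samples supplied", call. = FALSE)
  m <- mean(envelope[control_idx], na.rm = TRUE)
  if (!is.finite(m) || m == 0)
    stop("control-stride mean is zero or undefined; cannot normalize", call. = FALSE)
  100 * envelope / m
}
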