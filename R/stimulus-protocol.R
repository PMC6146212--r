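#' Rotation stimulus parameters
#'
#' Parameters of the visual fall stimulus: the virtual scene rolls about the
#' anterior-posterior axis with constant angular acceleration, holds the
#' reached angle, then returns to neutral at constant angular velocity.
#' Defaults are the experimental values: 60 deg/s^2 for 600 ms (reaching
#' 1/2 * 60 * 0.6^2 = 10.8 deg), a 2000 ms hold, and a 1000 ms reset.
#'
#' @param accel angular acceleration of the ramp (deg/s^2)
#' @param accel_duration duration of the accelerating ramp (s)
#' @param hold_duration duration of the constant-angle hold (s)
#' @param reset_duration duration of the constant-velocity return to 0 (s)
#' @return object of class `rotation_params`
#' @seealso [rotation_profile()], [schedule_stimuli()]
#' @export
#' @examples
#' p <- rotation_params()
#' rotation_peak(p)  # 10.8 deg
rotation_params <- function(accel = 60, accel_duration = 0.6,
                            hold_duration = 2, reset_duration = 1) {
  assert_scalar_pos(accel, "accel")
  assert_scalar_pos(accel_duration, "accel_duration")
  assert_scalar_pos(hold_duration, "hold_duration")
  assert_scalar_pos(reset_duration, "reset_duration")
  structure(list(accel = accel, accel_duration = accel_duration,
                 hold_duration = hold_duration, reset_duration = reset_duration),
            class = "rotation_params")
}

#' @export
print.rotation_params <- function(x, ...) {
  cat(sprintf("Rotation stimulus: %g deg/s^2 for %g ms -> peak %g deg, hold %g ms, reset %g ms\n",
              x$accel, 1000 * x$accel_duration, rotation_peak(x),
              1000 * x$hold_duration, 1000 * x$reset_duration))
  invisible(x)
}

#' Peak angle of the rotation stimulus
#'
#' Closed form `1/2 * accel * accel_duration^2`.
#'
#' @param params a [rotation_params()] object
#' @return peak rotation angle (deg)
#' @export
rotation_peak <- function(params) {
  0.5 * params$accel * params$accel_duration^2
}

#' Total duration of one stimulus (ramp + hold + reset)
#'
#' @param params a [rotation_params()] object
#' @return duration (s)
#' @export
rotation_duration <- function(params) {
  params$accel_duration + params$hold_duration + params$reset_duration
}

#' Rotation stimulus waveform
#'
#' Scene roll angle at time `t` after stimulus onset: quadratic ramp under
#' constant angular acceleration, constant peak during the hold, linear
#' return to neutral ("uniform speed") during the reset, 0 afterwards.
#' The profile is continuous everywhere.
#'
#' @param t time since stimulus onset (s); vectorized, must be >= 0
#' @param params a [rotation_params()] object
#' @return roll angle (deg), same length as `t`
#' @export
#' @examples
#' rotation_profile(0.6, rotation_params())  # 10.8
rotation_profile <- function(t, params = rotation_params()) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and non-negative", call. = FALSE)
  a <- params$accel
  t1 <- params$accel_duration
  t2 <- t1 + params$hold_duration
  t3 <- t2 + params$reset_duration
  peak <- rotation_peak(params)
  angle <- numeric(length(t))
  ramp <- t <= t1
  angle[ramp] <- 0.5 * a * t[ramp]^2
  hold <- t > t1 & t <= t2
  angle[hold] <- peak
  reset <- t > t2 & t <= t3
  angle[reset] <- peak * (1 - (t[reset] - t2) / params$reset_duration)
  angle
}

#' Heelstrike trigger threshold from standing calibration
#'
#' The online trigger fires on a downward crossing of the vertical
#' heel-marker position through the quiet-standing height plus 3 mm.
#'
#' @param standing_heel_height vertical heel-marker position during quiet
#'   standing (mm); vectorized
#' @return trigger threshold (mm)
#' @export
standing_trigger_threshold <- function(standing_heel_height) {
  if (any(!is.finite(standing_heel_height)))
    stop("standing heel height must be finite", call. = FALSE)
  standing_heel_height + 3
}

#' Duration of one data-collection block
#'
#' A block alternates metronome phases (30 s, 90 bpm auditory metronome) and
#' stimulus phases (120 s, visual fall stimuli), starting with a metronome
#' phase. Five of each gives the 12.5 min standard block.
#'
#' @param n_metronome,n_stimulus number of phases of each kind
#' @param metronome_s,stimulus_s phase durations (s)
#' @return block duration in minutes
#' @export
#' @examples
#' block_duration_min()  # 12.5
block_duration_min <- function(n_metronome = 5, metronome_s = 30,
                               n_stimulus = 5, stimulus_s = 120) {
  (n_metronome * metronome_s + n_stimulus * stimulus_s) / 60
}

#' Heelstrike-triggered randomized stimulus schedule
#'
#' Places fall stimuli on heelstrikes. After each stimulus resets to neutral,
#' a gap of 10-13 heelstrikes (uniform) elapses; the gap-th heelstrike after
#' reset completion triggers the next stimulus. The first stimulus uses the
#' same rule counted from the start of the trial. Heelstrikes of both feet
#' count toward the gap. Roll direction is drawn uniformly.
#'
#' @param heelstrikes data.frame with columns `time` (s, strictly increasing)
#'   and `foot` ("left"/"right"); expected to alternate feet (violations are
#'   flagged with a warning, not repaired)
#' @param params a [rotation_params()] object (sets the reset-completion time)
#' @param min_gap,max_gap washout bounds in steps (inclusive)
#' @param seed integer seed; the schedule is fully reproducible from it
#' @return data.frame of class `stimulus_schedule` with columns `time_s`,
#'   `trigger_foot`, `direction` ("left"/"right" = perceived fall direction),
#'   `peak_angle_deg`
#' @export
schedule_stimuli <- function(heelstrikes, params = rotation_params(),
                             min_gap = 10, max_gap = 13, seed = NULL) {
  empty <- data.frame(time_s = numeric(0), trigger_foot = character(0),
                      direction = character(0), peak_angle_deg = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("stimulus_schedule", "data.frame")
  if (is.null(heelstrikes) || nrow(heelstrikes) == 0L) return(empty)
  stopifnot(all(c("time", "foot") %in% names(heelstrikes)),
            min_gap >= 1, max_gap >= min_gap)
  tt <- heelstrikes$time
  ft <- as.character(heelstrikes$foot)
  if (any(diff(tt) <= 0))
    stop("heelstrike times must be strictly increasing", call. = FALSE)
  n_swap <- sum(ft[-1] == ft[-length(ft)])
  if (n_swap > 0)
    warning(sprintf("%d consecutive same-foot heelstrikes (feet should alternate)", n_swap))

  stim_dur <- rotation_duration(params)
  peak <- rotation_peak(params)
  with_seed(seed, {
    times <- numeric(0); feet <- character(0); dirs <- character(0)
    cursor <- -Inf  # reset-completion time of the previous stimulus
    repeat {
      g <- sample(seq.int(min_gap, max_gap), 1L)
      cand <- which(tt > cursor)
      if (length(cand) < g) break
      i <- cand[g]
      times <- c(times, tt[i])
      feet <- c(feet, ft[i])
      dirs <- c(dirs, sample(c("left", "right"), 1L))
      cursor <- tt[i] + stim_dur
    }
    out <- data.frame(time_s = times, trigger_foot = feet, direction = dirs,
                      peak_angle_deg = rep(peak, length(times)),
                      stringsAsFactors = FALSE)
    class(out) <- c("stimulus_schedule", "data.frame")
    out
  })
}

#' Write / read a stimulus log
#'
#' Tidy delimited table with columns `time_s`, `trigger_foot`, `direction`,
#' `peak_angle_deg`.
#'
#' @param schedule a schedule from [schedule_stimuli()]
#' @param path file path (tab-separated)
#' @return `read_stimulus_log` returns the schedule data.frame
#' @export
write_stimulus_log <- function(schedule, path) {
  data.table::fwrite(as.data.frame(schedule), path, sep = "\t")
  invisible(path)
}

#' @rdname write_stimulus_log
#' @export
read_stimulus_log <- function(path) {
  out <- as.data.frame(data.table::fread(path, sep = "\t"))
  class(out) <- c("stimulus_schedule", "data.frame")
  out
}
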