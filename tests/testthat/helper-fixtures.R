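# shared fixtures: all synthetic, built in code at test time

# fully deterministic walker: no noise, no step-to-step variability, no gaps
frozen_config <- function(...) {
  walker_config(com_amp_sd = 0, com_b_sd = 0, fp_noise_sd = 0,
                marker_noise_sd = 0, force_noise_sd = 0, moment_noise_sd = 0,
                emg_noise_sd = 0, angle_noise_sd = 0, gap_rate = 0, ...)
}

# noiseless but with CoM-state variability, so the foot-placement model is
# identifiable; station-keeping off keeps the placement law exact
noiseless_config <- function(...) {
  walker_config(fp_noise_sd = 0, marker_noise_sd = 0, force_noise_sd = 0,
                moment_noise_sd = 0, emg_noise_sd = 0, angle_noise_sd = 0,
                gap_rate = 0, station_keeping = 0, ...)
}

# a schedule with exactly one stimulus placed mid-trial on a known heelstrike
one_stimulus_schedule <- function(truth_hs, k = 10, direction = "right") {
  data.frame(time_s = truth_hs$time[k + 1], trigger_foot = truth_hs$foot[k + 1],
             direction = direction, peak_angle_deg = 10.8,
             stringsAsFactors = FALSE)
}

# independent O(n^2) topographic-prominence oracle for peak finding
peaks_bruteforce <- function(x, min_prominence = 0) {
  n <- length(x)
  res <- data.frame(index = integer(0), prominence = numeric(0))
  if (n < 3L) return(res)
  for (i in 2:(n - 1L)) {
    if (!(x[i] > x[i - 1L] && x[i] > x[i + 1L])) next
    lmin <- x[i]
    for (k in (i - 1L):1L) {
      if (x[k] > x[i]) break
      lmin <- min(lmin, x[k])
    }
    rmin <- x[i]
    for (k in (i + 1L):n) {
      if (x[k] > x[i]) break
      rmin <- min(rmin, x[k])
    }
    p <- x[i] - max(lmin, rmin)
    if (p >= min_prominence && p > 0)
      res <- rbind(res, data.frame(index = i, prominence = p))
  }
  res
}

# synthetic heelstrike stream: strictly increasing, alternating feet
alternating_heelstrikes <- function(n, period = 0.667) {
  data.frame(time = seq_len(n) * period,
             foot = rep(c("right", "left"), length.out = n),
             stringsAsFactors = FALSE)
}
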