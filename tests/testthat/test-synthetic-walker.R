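test_that("generation is bit-identical under a fixed seed", {
  g1 <- suppressWarnings(generate_trial(walker_config(), n_steps = 12, seed = 10))
  g2 <- suppressWarnings(generate_trial(walker_config(), n_steps = 12, seed = 10))
  expect_identical(g1$bundle$markers$data, g2$bundle$markers$data)
  expect_identical(g1$bundle$forces$data, g2$bundle$forces$data)
  expect_identical(g1$bundle$emg$data, g2$bundle$emg$data)
  expect_identical(g1$truth$steps, g2$truth$steps)
  expect_identical(g1$bundle$stimulus_log, g2$bundle$stimulus_log)
})

test_that("walker configuration is validated", {
  expect_error(walker_config(step_period = 0), "positive")
  expect_error(walker_config(marker_noise_sd = -1), ">= 0")
  expect_error(walker_config(fp_shift_gain = Inf), "finite")
  expect_error(walker_config(response_onset_fp = 0.65), "before the step ends")
})

test_that("ground-truth events are ordered and onsets lie within two steps", {
  gen <- generate_trial(walker_config(), n_steps = 20, seed = 11)
  tr <- gen$truth
  expect_true(all(diff(tr$heelstrikes$time) > 0))
  expect_true(all(diff(tr$pushoffs$time) > 0))
  T <- walker_config()$step_period
  for (on in c(tr$onset_cop_ms, tr$onset_fp_ms, tr$onset_ankle_ms, tr$onset_emg_ms))
    expect_true(on >= 0 && on <= 2000 * T)
  # each pushoff lies strictly between consecutive ipsilateral heelstrikes
  for (side in c("left", "right")) {
    hs <- tr$heelstrikes$time[tr$heelstrikes$foot == side]
    po <- tr$pushoffs$time[tr$pushoffs$foot == side]
    po <- po[po > min(hs) & po < max(hs)]
    slot <- findInterval(po, hs)
    expect_true(all(slot >= 1 & slot < length(hs)))
    expect_false(anyDuplicated(slot) > 0)
  }
})

test_that("heel trajectories have their minima exactly at true heelstrikes", {
  gen <- generate_trial(frozen_config(), n_steps = 16, seed = 12)
  b <- gen$bundle
  tm <- b$markers$time
  for (side in c("left", "right")) {
    z <- b$markers$data[, paste0(if (side == "left") "L" else "R", "HEE_z")]
    want <- gen$truth$heelstrikes$time[gen$truth$heelstrikes$foot == side]
    for (t0 in want) {
      win <- which(abs(tm - t0) < 0.25)
      expect_lt(abs(tm[win[which.min(z[win])]] - t0), 1 / b$markers$rate + 1e-9)
    }
    # prominence comfortably above the 20 mm detection rule
    expect_gt(diff(range(z)), 20)
  }
})

test_that("with all gains and variability frozen, stimulus steps equal control steps", {
  # a 0.668 s step is exactly 167 marker samples, so every step has the same
  # sampling phase and the identity holds sample for sample; station keeping
  # is off to avoid its deterministic settling transient in the placements
  cfg <- frozen_config(cop_shift_gain = 0, fp_shift_gain = 0, pushoff_gain = 0,
                       ankle_eversion_gain = 0, hip_abduction_gain = 0,
                       emg_gain = 0, station_keeping = 0, step_period = 0.668)
  gen <- generate_trial(cfg, n_steps = 40, seed = 13)
  ss <- build_step_set(gen$bundle)
  info <- ss$info
  n_checked <- 0L
  for (foot in c("left", "right")) {
    st <- which(info$condition == "stimulus" & info$step_index == 1L &
                  !info$excluded & info$stance_foot == foot)
    ct <- which(info$condition == "control" & !info$excluded &
                  info$stance_foot == foot)
    if (!length(st)) next
    cm <- colMeans(ss$traj$cop_rel[ct, , drop = FALSE])
    for (i in st)
      expect_equal(ss$traj$cop_rel[i, ], cm, tolerance = 1e-6)
    expect_equal(info$foot_placement[st], rep(mean(info$foot_placement[ct]),
                                              length(st)), tolerance = 1e-6)
    n_checked <- n_checked + length(st)
  }
  expect_gt(n_checked, 0)
})

test_that("the injected placement offset appears in full at the first post-stimulus landing", {
  cfg <- noiseless_config(fp_shift_gain = 5)
  gen <- generate_trial(cfg, n_steps = 60, seed = 14)
  tr <- gen$truth
  stim_rows <- which(tr$steps$stim_off != 0)
  expect_gt(length(stim_rows), 0)
  # mirrored placement = law + mirrored offset; subtracting the law leaves
  # exactly the injected 5 mm toward the perceived fall
  dev_pos <- abs(tr$steps$com_pos_mid) - cfg$com_amp
  s <- ifelse(tr$steps$stance_foot == "left", -1, 1)
  law <- -cfg$step_width + cfg$fp_coeff_pos * dev_pos +
    cfg$fp_coeff_vel * (s * tr$steps$com_vel_mid)
  resid <- tr$steps$placement_mirrored - law
  expect_equal(abs(resid[stim_rows]), rep(5, length(stim_rows)), tolerance = 1e-9)
  expect_equal(resid[-stim_rows], rep(0, nrow(tr$steps) - length(stim_rows)),
               tolerance = 1e-9)
})

test_that("stimuli that cannot fit four post-steps are truncated with a warning", {
  hs <- alternating_heelstrikes(20, period = 0.667)
  hs$time <- hs$time  # triggers at late heelstrikes must be dropped
  stim <- data.frame(time_s = hs$time[c(10, 19)], trigger_foot = hs$foot[c(10, 19)],
                     direction = "right", peak_angle_deg = 10.8)
  expect_warning(
    gen <- generate_trial(walker_config(), n_steps = 19, stimuli = stim, seed = 15),
    "truncated")
  expect_identical(nrow(gen$bundle$stimulus_log), 1L)
})

test_that("marker dropouts occur as contiguous NA runs at the configured rate", {
  cfg <- walker_config(gap_rate = 0.05, marker_noise_sd = 0)
  gen <- generate_trial(cfg, n_steps = 40, seed = 16)
  mk <- gen$bundle$markers$data
  expect_gt(sum(is.na(mk)), 0)
  # no gaps at all when the rate is zero
  gen0 <- generate_trial(walker_config(gap_rate = 0), n_steps = 10, seed = 16)
  expect_false(anyNA(gen0$bundle$markers$data))
})
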