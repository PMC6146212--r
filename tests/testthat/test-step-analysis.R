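test_that("one stimulus on a clean trial yields six analysis steps", {
  gen <- generate_trial(frozen_config(), n_steps = 20, seed = 20)
  stim <- one_stimulus_schedule(gen$truth$heelstrikes, k = 10)
  gen2 <- generate_trial(frozen_config(), n_steps = 20, stimuli = stim, seed = 20)
  ss <- build_step_set(gen2$bundle)
  sel <- ss$info[!is.na(ss$info$step_index), ]
  expect_identical(nrow(sel), 6L)
  expect_setequal(sel$step_index, c(-2L, -1L, 1L, 2L, 3L, 4L))
  expect_identical(sum(sel$condition == "control"), 2L)
  expect_identical(sum(sel$condition == "stimulus"), 4L)
})

test_that("steps with unrecoverable marker gaps are excluded with a reason", {
  gen <- generate_trial(frozen_config(), n_steps = 20, seed = 21)
  stim <- one_stimulus_schedule(gen$truth$heelstrikes, k = 10)
  gen2 <- generate_trial(frozen_config(), n_steps = 20, stimuli = stim, seed = 21)
  b <- gen2$bundle
  # plant a 200 ms occlusion inside step +2
  t_mid <- stim$time_s + 1.5 * frozen_config()$step_period
  idx <- which(abs(b$markers$time - t_mid) < 0.1)
  b$markers$data[idx, "PELVIS_x"] <- NA_real_
  ss <- build_step_set(b)
  sel <- ss$info[!is.na(ss$info$step_index), ]
  expect_true(sel$excluded[sel$step_index == 2L])
  expect_match(sel$reason[sel$step_index == 2L], "missing")
  expect_false(any(sel$excluded[sel$step_index != 2L]))
})

test_that("with no stimuli every step is control-eligible", {
  gen <- generate_trial(frozen_config(), n_steps = 10,
                        stimuli = data.frame(), seed = 22)
  ss <- build_step_set(gen$bundle)
  expect_true(all(ss$info$condition == "control"))
  expect_true(all(is.na(ss$info$step_index)))
})

test_that("time normalization preserves endpoints and resamples evenly", {
  ramp <- seq(0, 1, length.out = 37)
  y <- normalize_time(ramp, 100)
  expect_identical(length(y), 100L)
  expect_equal(y[1], 0)
  expect_equal(y[100], 1)
  expect_equal(y, seq(0, 1, length.out = 100), tolerance = 1e-12)
  expect_equal(normalize_time(rep(2.5, 10)), rep(2.5, 100))
  tt <- seq(0, 1, length.out = 400)
  s <- sin(2 * pi * 2 * tt)
  got <- normalize_time(s, 100)
  want <- sin(2 * pi * 2 * seq(0, 1, length.out = 100))
  expect_equal(got, want, tolerance = 1e-3)
  expect_error(normalize_time(1), "2 samples")
})

test_that("toward/away classification and mirroring behave as an involution", {
  expect_identical(classify_direction("right", "right"), "toward")
  expect_identical(classify_direction("right", "left"), "away")
  expect_identical(classify_direction("left", "left"), "toward")
  x <- rnorm(50)
  expect_identical(mirror_lateral(mirror_lateral(x, TRUE), TRUE), x)
  expect_identical(mirror_lateral(x, FALSE), x)
})

test_that("baseline subtraction leaves a matched stimulus step at zero", {
  # sample-aligned step period and no station keeping: all steps identical
  cfg <- frozen_config(cop_shift_gain = 0, fp_shift_gain = 0, pushoff_gain = 0,
                       ankle_eversion_gain = 0, hip_abduction_gain = 0,
                       emg_gain = 0, station_keeping = 0, step_period = 0.668)
  gen <- generate_trial(cfg, n_steps = 40, seed = 23)
  ss <- build_step_set(gen$bundle)
  base <- baseline_subtract(ss)
  for (nm in c("com_pos", "cop_rel", "swing_heel_x"))
    expect_lt(max(abs(base$responses[[nm]])), 1e-6)
  # control steps against their own mean have zero-mean residuals
  info <- ss$info
  for (foot in c("left", "right")) {
    ct <- which(info$condition == "control" & !info$excluded &
                  info$stance_foot == foot)
    resid <- sweep(ss$traj$com_pos[ct, , drop = FALSE], 2,
                   colMeans(ss$traj$com_pos[ct, , drop = FALSE]))
    expect_lt(max(abs(colMeans(resid))), 1e-9)
  }
})

test_that("the injected CoP shift appears in the baseline-subtracted response", {
  # sensor-noise free, small CoM-state variability so the placement model is
  # identifiable while step-to-step scatter stays small
  cfg <- walker_config(fp_noise_sd = 0, marker_noise_sd = 0, force_noise_sd = 0,
                       moment_noise_sd = 0, emg_noise_sd = 0, angle_noise_sd = 0,
                       gap_rate = 0, com_amp_sd = 0.5, com_b_sd = 0.5,
                       fp_shift_gain = 0, cop_shift_gain = 5)
  gen <- suppressWarnings(generate_trial(cfg, n_steps = 120, seed = 24))
  an <- suppressWarnings(analyze_trial(gen$bundle))
  expect_equal(an$estimates$cop_gain_mm, 5, tolerance = 0.2)
})

test_that("the foot-placement model recovers exact linear data to machine precision", {
  set.seed(31)
  n <- 40
  info <- data.frame(
    stance_foot = rep(c("left", "right"), n / 2),
    com_pos_mid = rnorm(n, 0, 5), com_vel_mid = rnorm(n, 0, 25),
    condition = "control", excluded = FALSE, subject = "S"
  )
  s <- ifelse(info$stance_foot == "left", -1, 1)
  info$foot_placement <- s * (-100 + 0.37 * (s * info$com_pos_mid) +
                                0.21 * (s * info$com_vel_mid))
  ss <- list(info = info, subject = "S")
  m <- fit_foot_placement_model(structure(ss, class = "step_set"))
  expect_equal(unname(m$coef), c(-100, 0.37, 0.21), tolerance = 1e-12)
  # control steps through their own model leave zero-mean residuals
  r <- stimulus_induced_fp_change(info, m)
  expect_lt(abs(mean(r)), 1e-12)
})

test_that("the foot-placement model validates its preconditions", {
  info <- data.frame(stance_foot = "right", com_pos_mid = 1, com_vel_mid = 1,
                     foot_placement = 1, condition = "control", excluded = FALSE)
  ss <- structure(list(info = info[rep(1, 5), ], subject = "S"), class = "step_set")
  expect_error(fit_foot_placement_model(ss), "control steps")
  ss2 <- structure(list(info = info[rep(1, 12), ], subject = "S"), class = "step_set")
  expect_error(fit_foot_placement_model(ss2), "rank-deficient")
})

test_that("full-chain noiseless recovery of placement coefficients and offset", {
  cfg <- noiseless_config(fp_shift_gain = 5)
  gen <- generate_trial(cfg, n_steps = 120, seed = 25)
  an <- analyze_trial(gen$bundle)
  expect_equal(unname(an$fp_model$coef[2]), cfg$fp_coeff_pos, tolerance = 5e-3)
  expect_equal(unname(an$fp_model$coef[3]), cfg$fp_coeff_vel, tolerance = 5e-3)
  expect_equal(an$estimates$fp_gain_mm, 5, tolerance = 0.05)
})

test_that("outcome variables are near zero under the null generator", {
  cfg <- walker_config(cop_shift_gain = 0, fp_shift_gain = 0, pushoff_gain = 0,
                       ankle_eversion_gain = 0, hip_abduction_gain = 0,
                       emg_gain = 0, gap_rate = 0)
  gen <- generate_trial(cfg, n_steps = 160, seed = 26)
  an <- analyze_trial(gen$bundle)
  oc <- an$outcomes
  expect_gt(nrow(oc), 4)
  expect_lt(abs(mean(oc$stimulus_induced_fp_change)), 1.5)
  expect_lt(abs(mean(oc$integrated_relative_cop_change)), 1.0)
  expect_lt(abs(mean(oc$hip_abduction_change)), 0.5)
  expect_lt(abs(mean(oc$ankle_eversion_change)), 0.5)
})

test_that("the integrated CoP outcome matches the analytic integral of the shift", {
  # constant 5 mm shift active from the very start of the step: the integral
  # over the swing window equals shift * window length
  cfg <- walker_config(fp_noise_sd = 0, marker_noise_sd = 0, force_noise_sd = 0,
                       moment_noise_sd = 0, emg_noise_sd = 0, angle_noise_sd = 0,
                       gap_rate = 0, com_amp_sd = 0.5, com_b_sd = 0.5,
                       fp_shift_gain = 0, cop_shift_gain = 5,
                       response_onset_cop = 0.0, response_ramp = 0.002)
  gen <- suppressWarnings(generate_trial(cfg, n_steps = 120, seed = 27))
  an <- suppressWarnings(analyze_trial(gen$bundle))
  oc <- an$outcomes
  info <- an$step_set$info
  first <- info[!is.na(info$step_index) & info$step_index == 1L & !info$excluded, ]
  win <- (1 - first$pushoff_frac[match(oc$stim_id, first$stim_id)]) * first$duration[1]
  # per-step values scatter with the step-to-step CoM/placement variability;
  # the mean matches the analytic integral of the constructed shift
  expect_equal(mean(oc$integrated_relative_cop_change), mean(5 * win),
               tolerance = 0.1)
})

test_that("flipping the stimulus direction leaves sign-adjusted outcomes unchanged", {
  # five stimuli, all triggered by right heelstrikes; identical seeds mean the
  # two runs differ only in fall direction (toward vs away from the trigger)
  cfg <- walker_config(fp_noise_sd = 0, marker_noise_sd = 0, force_noise_sd = 0,
                       moment_noise_sd = 0, emg_noise_sd = 0, angle_noise_sd = 0,
                       gap_rate = 0, com_amp_sd = 0.5, com_b_sd = 0.5)
  base_gen <- suppressWarnings(generate_trial(cfg, n_steps = 80, seed = 28))
  hs <- base_gen$truth$heelstrikes
  kk <- c(10, 26, 42, 58, 74)          # even indices: right-foot triggers
  res <- list()
  for (dir in c("left", "right")) {
    stim <- data.frame(time_s = hs$time[kk + 1], trigger_foot = hs$foot[kk + 1],
                       direction = dir, peak_angle_deg = 10.8,
                       stringsAsFactors = FALSE)
    gen <- suppressWarnings(generate_trial(cfg, n_steps = 80, stimuli = stim,
                                           seed = 28))
    res[[dir]] <- suppressWarnings(analyze_trial(gen$bundle))$outcomes
  }
  expect_true(all(res$right$direction == "toward"))
  expect_true(all(res$left$direction == "away"))
  # body-relative and CoP outcomes are injected symmetrically: the adjusted
  # values match across directions
  for (v in c("hip_abduction_change", "ankle_eversion_change",
              "integrated_gluteus_medius_emg_change",
              "integrated_peroneus_longus_emg_change",
              "integrated_relative_cop_change"))
    expect_equal(mean(res$left[[v]]), mean(res$right[[v]]), tolerance = 0.15)
  # the placement outcomes carry the CoM-driven component with opposite
  # adjusted sign in the two runs (identical seeds), so their cross-run
  # average isolates the injected 5 mm shift
  for (v in c("foot_placement_change", "stimulus_induced_fp_change"))
    expect_equal((mean(res$left[[v]]) + mean(res$right[[v]])) / 2, 5,
                 tolerance = 0.1)
})
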