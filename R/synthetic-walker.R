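#' Synthetic walker configuration
#'
#' Parameters of the kinematic synthetic walker used to exercise the whole
#' analysis chain with known ground truth. The walker prescribes marker,
#' force-plate, EMG and joint-angle trajectories directly (no dynamics):
#' periodic heel vertical motion with minima exactly at heelstrikes at the
#' 90 steps/min cadence, medial-lateral CoM oscillation, CoP under the
#' stance foot, a linear dependence of lateral foot placement on the CoM
#' state at midstance, and stimulus-locked injected responses with
#' configurable onset times and gains.
#'
#' Foot placement follows the relative law
#' `placement = fp_coeff_pos * CoM_pos(midstance) + fp_coeff_vel *
#' CoM_vel(midstance) + stimulus offset + noise`, where the stimulus offset
#' (`fp_shift_gain`, signed by perceived fall direction) ramps in as a
#' smoothstep starting `response_onset_fp` seconds after the trigger. The
#' lateral CoP acquires a `cop_shift_gain` shift (toward the perceived fall)
#' ramping in at `response_onset_cop`. Smoothstep ramps (`response_ramp`,
#' default 60 ms) give the tangent-extrapolation onset estimator a
#' well-defined target.
#'
#' @param step_period step duration (s); 0.667 s is ~90 steps/min
#' @param step_width nominal lateral distance between heel centres (mm)
#' @param step_length nominal anterior heel-to-heel distance at heelstrike (mm)
#' @param com_amp nominal lateral CoM oscillation amplitude toward the stance
#'   side (mm)
#' @param com_amp_sd step-to-step SD of the CoM amplitude (mm); drives the
#'   CoM-position variability the foot-placement model explains
#' @param com_b_sd SD of the second-harmonic CoM component (mm); drives CoM
#'   velocity variability at midstance
#' @param fp_coeff_pos,fp_coeff_vel foot-placement model coefficients
#'   (mm per mm, mm per mm/s)
#' @param fp_noise_sd residual foot-placement noise SD (mm)
#' @param station_keeping gain of the absolute lateral position control that
#'   keeps the feet near their nominal lanes (0 disables it; the placement
#'   law then makes absolute foot positions a random walk)
#' @param marker_noise_sd additive marker noise SD (mm)
#' @param force_noise_sd,moment_noise_sd force-plate noise SDs (N, N m)
#' @param emg_noise_sd additive raw-EMG noise SD (a.u.)
#' @param angle_noise_sd additive joint-angle noise SD (deg)
#' @param response_onset_cop,response_onset_fp,response_onset_ankle,response_onset_emg
#'   injected response onsets (s post-trigger)
#' @param response_ramp smoothstep ramp duration of injected responses (s)
#' @param cop_shift_gain lateral CoP shift toward the perceived fall (mm)
#' @param fp_shift_gain foot-placement shift toward the perceived fall (mm)
#' @param pushoff_gain ankle plantarflexion modulation (deg)
#' @param ankle_eversion_gain stance-ankle eversion modulation (deg)
#' @param hip_abduction_gain swing-hip abduction modulation (deg)
#' @param emg_gain fractional EMG burst amplitude modulation
#' @param heel_lift,mt2_lift vertical excursion of heel / forefoot markers (mm)
#' @param stance_heel_height heel-marker height during stance and quiet
#'   standing (mm)
#' @param stance_frac stance duration of a foot as a multiple of the step
#'   period (swing occupies the rest of the 2-step stride)
#' @param double_support_frac weight-transfer duration as a fraction of the
#'   step period
#' @param body_weight_n body weight (N)
#' @param marker_rate,analog_rate sampling rates (Hz) for markers/angles and
#'   forces/EMG
#' @param gap_rate expected marker dropouts per channel per second
#' @param gap_mean_ms mean dropout length (ms, geometric); the tail produces
#'   occasional gaps longer than the 100 ms fill limit
#' @param subject subject identifier
#' @return object of class `walker_config`
#' @export
walker_config <- function(step_period = 0.667, step_width = 100, step_length = 700,
                          com_amp = 20, com_amp_sd = 4, com_b_sd = 3,
                          fp_coeff_pos = 0.4, fp_coeff_vel = 0.15, fp_noise_sd = 2,
                          station_keeping = 0.3,
                          marker_noise_sd = 0.5, force_noise_sd = 2,
                          moment_noise_sd = 0.3, emg_noise_sd = 0.05,
                          angle_noise_sd = 0.2,
                          response_onset_cop = 0.300, response_onset_fp = 0.420,
                          response_onset_ankle = 0.300, response_onset_emg = 0.150,
                          response_ramp = 0.060,
                          cop_shift_gain = 8, fp_shift_gain = 5, pushoff_gain = 2,
                          ankle_eversion_gain = 1, hip_abduction_gain = 1,
                          emg_gain = 0.3,
                          heel_lift = 80, mt2_lift = 100, stance_heel_height = 30,
                          stance_frac = 1.2, double_support_frac = 0.2,
                          body_weight_n = 700,
                          marker_rate = 250, analog_rate = 1000,
                          gap_rate = 0.01, gap_mean_ms = 60,
                          subject = "S01") {
  cfg <- as.list(environment())
  assert_scalar_pos(cfg$step_period, "step_period")
  for (nm in c("com_amp_sd", "com_b_sd", "fp_noise_sd", "marker_noise_sd",
               "force_noise_sd", "moment_noise_sd", "emg_noise_sd",
               "angle_noise_sd", "gap_rate")) {
    if (cfg[[nm]] < 0) stop(sprintf("'%s' must be >= 0", nm), call. = FALSE)
  }
  for (nm in c("cop_shift_gain", "fp_shift_gain", "pushoff_gain",
               "ankle_eversion_gain", "hip_abduction_gain", "emg_gain")) {
    if (!is.finite(cfg[[nm]])) stop(sprintf("'%s' must be finite", nm), call. = FALSE)
  }
  if (cfg$response_onset_fp + cfg$response_ramp >= cfg$step_period)
    stop("foot-placement response must complete before the step ends", call. = FALSE)
  structure(cfg, class = "walker_config")
}

#' @export
print.walker_config <- function(x, ...) {
  cat(sprintf("<walker_config> %g steps/min, fp law (%.2f, %.2f), gains fp=%g mm cop=%g mm, onsets fp=%g ms cop=%g ms\n",
              60 / x$step_period, x$fp_coeff_pos, x$fp_coeff_vel,
              x$fp_shift_gain, x$cop_shift_gain,
              1000 * x$response_onset_fp, 1000 * x$response_onset_cop))
  invisible(x)
}

#' Classify a stimulus as a perceived fall toward or away from the trigger foot
#'
#' Assuming body symmetry, a fall stimulus whose direction matches the side
#' of the triggering foot is "toward" it, otherwise "away".
#'
#' @param direction perceived fall direction ("left"/"right"); vectorized
#' @param trigger_foot foot whose heelstrike triggered the stimulus
#' @return character vector, "toward" or "away"
#' @export
classify_direction <- function(direction, trigger_foot) {
  ifelse(direction == trigger_foot, "toward", "away")
}

#' Generate a synthetic walking trial with ground truth
#'
#' Produces a [trial_bundle()] plus a ground-truth record (true event times,
#' injected onsets and gains, per-step CoM states and placements) so
#' downstream stages can be validated by parameter recovery. All randomness
#' derives from `seed`; regeneration is bit-identical.
#'
#' @param config a [walker_config()]
#' @param n_steps number of steps to simulate
#' @param stimuli optional stimulus schedule (from [schedule_stimuli()]);
#'   when NULL a schedule is generated internally from the seed. Stimuli too
#'   close to the trial end (needing step +4 past the last heelstrike) are
#'   dropped with a warning.
#' @param seed integer seed
#' @return list with `bundle` (a `trial_bundle`) and `truth` (list of
#'   `heelstrikes`, `pushoffs`, `steps`, `stimuli`, and the injected
#'   parameters)
#' @export
generate_trial <- function(config = walker_config(), n_steps = 120,
                           stimuli = NULL, seed = 1) {
  stopifnot(inherits(config, "walker_config"), n_steps >= 6)
  cfg <- config
  T <- cfg$step_period
  with_seed(seed, {
    # --- event timing -----------------------------------------------------
    hs_k <- 0:n_steps
    hs_t <- (hs_k + 1) * T
    hs_foot <- ifelse(hs_k %% 2 == 0, "right", "left")
    duration <- (n_steps + 2) * T
    hs_df <- data.frame(time = hs_t, foot = hs_foot, stringsAsFactors = FALSE)

    if (is.null(stimuli))
      stimuli <- schedule_stimuli(hs_df, seed = sample.int(2^30, 1))
    stimuli <- as.data.frame(stimuli)
    if (nrow(stimuli) == 0L)
      stimuli <- data.frame(time_s = numeric(0), trigger_foot = character(0),
                            direction = character(0), peak_angle_deg = numeric(0),
                            stringsAsFactors = FALSE)
    if (nrow(stimuli)) {
      k_trig <- match(round(stimuli$time_s / T), round(hs_t / T))
      ok <- !is.na(k_trig) & (hs_k[k_trig] + 4) <= n_steps
      if (any(!ok)) {
        warning(sprintf("%d stimulus(es) scheduled too close to trial end: truncated",
                        sum(!ok)))
        stimuli <- stimuli[ok, , drop = FALSE]
        k_trig <- k_trig[ok]
      }
      stimuli$k <- if (nrow(stimuli)) hs_k[k_trig] else integer(0)
      stimuli$dir_sign <- ifelse(stimuli$direction == "right", 1, -1)
      stimuli$relative <- classify_direction(stimuli$direction, stimuli$trigger_foot)
      # injected body-relative responses are signed so that the standard
      # sign adjustment (invert body-relative for "toward") yields +gain
      stimuli$rel_sign <- ifelse(stimuli$relative == "away", 1, -1)
    } else {
      stimuli$k <- integer(0); stimuli$dir_sign <- numeric(0)
      stimuli$relative <- character(0); stimuli$rel_sign <- numeric(0)
    }

    # --- per-step CoM parameters and placements ---------------------------
    s_sign <- ifelse(hs_foot == "right", 1, -1)   # stance side of step k
    A <- pmax(cfg$com_amp + stats::rnorm(n_steps, 0, cfg$com_amp_sd), 1)
    B <- stats::rnorm(n_steps, 0, cfg$com_b_sd)
    com_pos_mid <- s_sign[1:n_steps] * A
    com_vel_mid <- -2 * pi * B / T

    eps <- stats::rnorm(n_steps, 0, cfg$fp_noise_sd)
    stim_off <- numeric(n_steps)                 # offset of landing k+1 (absolute)
    if (nrow(stimuli))
      stim_off[stimuli$k + 1] <- cfg$fp_shift_gain * stimuli$dir_sign
    # mirrored placement law: p = -W + a*dev_pos + b*dev_vel
    #                             - gamma*(mirrored feet midpoint) + off + eps.
    # The station-keeping term (gamma) emulates the absolute position control
    # treadmill walkers exert via vision/belt edges; it bounds the lateral
    # drift of the feet and is independent of the current CoM state, so the
    # two-regressor model remains exactly recoverable.
    gam <- cfg$station_keeping
    x_land <- numeric(n_steps + 1)
    x_land[1] <- s_sign[1] * cfg$step_width / 2
    p_mirror <- numeric(n_steps)
    for (k in 1:n_steps) {
      xbar <- if (k == 1) x_land[1] else (x_land[k] + x_land[k - 1]) / 2
      dev_pos <- A[k] - cfg$com_amp                 # mirrored CoM pos deviation
      dev_vel <- s_sign[k] * com_vel_mid[k]         # mirrored CoM vel
      p_mirror[k] <- -cfg$step_width + cfg$fp_coeff_pos * dev_pos +
        cfg$fp_coeff_vel * dev_vel - gam * (s_sign[k] * xbar) +
        s_sign[k] * stim_off[k] + eps[k]
      x_land[k + 1] <- x_land[k] + s_sign[k] * p_mirror[k]
    }
    placement <- x_land[-1] - x_land[-(n_steps + 1)]

    # --- continuous signal builders ---------------------------------------
    po <- cfg$stance_frac * T                    # swing starts po after landing
    stride <- 2 * T
    sw <- stride - po
    ds <- cfg$double_support_frac * T

    # onset-gated smoothstep, sustained through step +1, decaying over step +2
    inj <- function(t, t_trig, onset)
      smoothstep((t - t_trig - onset) / cfg$response_ramp) *
        ifelse(t <= t_trig + T, 1, 1 - smoothstep((t - t_trig - T) / T))

    com_x_at <- function(t) {
      j <- pmin(pmax(floor(t / T) - 1, 0), n_steps - 1)
      u <- t - (j + 1) * T
      s_sign[j + 1] * A[j + 1] * sin(pi * u / T) + B[j + 1] * sin(2 * pi * u / T)
    }

    foot_land <- lapply(c(left = "left", right = "right"), function(f) {
      sel <- hs_foot == f
      list(t = hs_t[sel], x = x_land[sel], k = hs_k[sel])
    })
    # onset-gated landing offsets: landing k+1 of the swing foot
    gate <- lapply(foot_land, function(fl) {
      g <- list(off = numeric(length(fl$t)), t_on = numeric(length(fl$t)))
      g
    })
    if (nrow(stimuli)) {
      for (i in seq_len(nrow(stimuli))) {
        swing <- if (stimuli$trigger_foot[i] == "left") "right" else "left"
        li <- match(stimuli$k[i] + 1, foot_land[[swing]]$k)
        if (!is.na(li)) {
          gate[[swing]]$off[li] <- cfg$fp_shift_gain * stimuli$dir_sign[i]
          gate[[swing]]$t_on[li] <- stimuli$time_s[i] + cfg$response_onset_fp
        }
      }
    }

    heel_x_at <- function(t, f) {
      fl <- foot_land[[f]]
      m <- length(fl$t)
      i <- pmin(pmax(findInterval(t, fl$t), 1L), m - 1L)
      u <- t - fl$t[i]
      x0 <- fl$x[i]
      off <- gate[[f]]$off[i + 1L]
      x1 <- fl$x[i + 1L] - off
      x <- x0 + (x1 - x0) * smoothstep((u - po) / sw)
      g <- off != 0
      if (any(g))
        x[g] <- x[g] + off[g] * smoothstep((t[g] - gate[[f]]$t_on[i[g] + 1L]) / cfg$response_ramp)
      x
    }
    phase_at <- function(t, f) {
      fl <- foot_land[[f]]
      (t - fl$t[1]) %% stride
    }
    heel_z_at <- function(t, f) {
      u <- phase_at(t, f)
      cfg$stance_heel_height + cfg$heel_lift * 0.5 * (1 - cos(2 * pi * u / stride))
    }
    mt2_z_at <- function(t, f) {
      u <- phase_at(t, f)
      z <- rep(cfg$stance_heel_height, length(t))
      swp <- u > po
      z[swp] <- cfg$stance_heel_height +
        cfg$mt2_lift * sin(pi * (u[swp] - po) / sw)^2
      z
    }
    heel_y_at <- function(t, f) {
      u <- phase_at(t, f)
      L <- cfg$step_length
      v <- L / T
      y <- L / 2 - v * pmin(u, po)
      swp <- u > po
      y[swp] <- (L / 2 - v * po) + (L / 2 - (L / 2 - v * po)) * smoothstep((u[swp] - po) / sw)
      y
    }
    load_at <- function(t, f) {
      u <- phase_at(t, f)
      lam <- numeric(length(t))
      lam[u <= ds] <- u[u <= ds] / ds
      lam[u > ds & u <= T] <- 1
      idx <- u > T & u <= T + ds
      lam[idx] <- 1 - (u[idx] - T) / ds
      lam
    }

    # --- marker streams ----------------------------------------------------
    tm <- seq(0, duration, by = 1 / cfg$marker_rate)
    lhx <- heel_x_at(tm, "left"); rhx <- heel_x_at(tm, "right")
    lhy <- heel_y_at(tm, "left"); rhy <- heel_y_at(tm, "right")
    comx <- com_x_at(tm)
    seg <- default_segment_table()
    frac <- stats::setNames(seg$fraction, seg$segment)
    trunk_x <- (comx * (1 - frac[["pelvis"]] - frac[["head"]]) -
                  frac[["leg_left"]] * lhx - frac[["leg_right"]] * rhx) / frac[["trunk"]]
    markers <- cbind(
      LHEE_x = lhx, LHEE_y = lhy, LHEE_z = heel_z_at(tm, "left"),
      RHEE_x = rhx, RHEE_y = rhy, RHEE_z = heel_z_at(tm, "right"),
      LMT2_x = lhx - 10, LMT2_y = lhy + 150, LMT2_z = mt2_z_at(tm, "left"),
      RMT2_x = rhx + 10, RMT2_y = rhy + 150, RMT2_z = mt2_z_at(tm, "right"),
      PELVIS_x = comx, PELVIS_y = rep(0, length(tm)), PELVIS_z = rep(1000, length(tm)),
      TRUNK_x = trunk_x, TRUNK_y = rep(0, length(tm)), TRUNK_z = rep(1300, length(tm)),
      HEAD_x = comx, HEAD_y = rep(0, length(tm)), HEAD_z = rep(1700, length(tm)),
      LEG_L_x = lhx, LEG_L_y = lhy / 2, LEG_L_z = rep(500, length(tm)),
      LEG_R_x = rhx, LEG_R_y = rhy / 2, LEG_R_z = rep(500, length(tm))
    )
    if (cfg$marker_noise_sd > 0)
      markers <- markers + stats::rnorm(length(markers), 0, cfg$marker_noise_sd)

    # --- joint-angle streams ----------------------------------------------
    phl <- phase_at(tm, "left") / stride
    phr <- phase_at(tm, "right") / stride
    ang <- cbind(
      ankle_plantarflexion_left = 10 * sin(2 * pi * phl),
      ankle_plantarflexion_right = 10 * sin(2 * pi * phr),
      ankle_eversion_left = 2 * sin(2 * pi * phl + 0.5),
      ankle_eversion_right = 2 * sin(2 * pi * phr + 0.5),
      hip_abduction_left = 4 + 2 * sin(2 * pi * phl + 1),
      hip_abduction_right = 4 + 2 * sin(2 * pi * phr + 1)
    )
    if (nrow(stimuli)) {
      for (i in seq_len(nrow(stimuli))) {
        ts <- stimuli$time_s[i]
        rs <- stimuli$rel_sign[i]
        stance <- stimuli$trigger_foot[i]
        swing <- if (stance == "left") "right" else "left"
        w <- inj(tm, ts, cfg$response_onset_ankle)
        ang[, paste0("ankle_eversion_", stance)] <-
          ang[, paste0("ankle_eversion_", stance)] + cfg$ankle_eversion_gain * rs * w
        ang[, paste0("ankle_plantarflexion_", stance)] <-
          ang[, paste0("ankle_plantarflexion_", stance)] + cfg$pushoff_gain * rs * w
        ang[, paste0("hip_abduction_", swing)] <-
          ang[, paste0("hip_abduction_", swing)] + cfg$hip_abduction_gain * rs * w
      }
    }
    if (cfg$angle_noise_sd > 0)
      ang <- ang + stats::rnorm(length(ang), 0, cfg$angle_noise_sd)

    # --- analog streams: forces and EMG -----------------------------------
    ta <- seq(0, duration, by = 1 / cfg$analog_rate)
    lam_l <- load_at(ta, "left"); lam_r <- load_at(ta, "right")
    cop_l <- heel_x_at(ta, "left"); cop_r <- heel_x_at(ta, "right")
    if (nrow(stimuli)) {
      for (i in seq_len(nrow(stimuli))) {
        ts <- stimuli$time_s[i]
        shift <- cfg$cop_shift_gain * stimuli$dir_sign[i] * inj(ta, ts, cfg$response_onset_cop)
        if (stimuli$trigger_foot[i] == "left") cop_l <- cop_l + shift
        else cop_r <- cop_r + shift
      }
    }
    fz_l <- cfg$body_weight_n * lam_l
    fz_r <- cfg$body_weight_n * lam_r
    mx_l <- fz_l * cop_l / 1000
    mx_r <- fz_r * cop_r / 1000
    if (cfg$force_noise_sd > 0) {
      fz_l <- fz_l + stats::rnorm(length(ta), 0, cfg$force_noise_sd)
      fz_r <- fz_r + stats::rnorm(length(ta), 0, cfg$force_noise_sd)
    }
    if (cfg$moment_noise_sd > 0) {
      mx_l <- mx_l + stats::rnorm(length(ta), 0, cfg$moment_noise_sd)
      mx_r <- mx_r + stats::rnorm(length(ta), 0, cfg$moment_noise_sd)
    }
    forces <- cbind(fz_left = fz_l, mx_left = mx_l, fz_right = fz_r, mx_right = mx_r)

    burst <- function(ph, centre, width) {
      # wrapped Gaussian burst in stride-phase units
      exp(-0.5 * ((ph - centre) / width)^2) +
        exp(-0.5 * ((ph - centre - 1) / width)^2) +
        exp(-0.5 * ((ph - centre + 1) / width)^2)
    }
    centres <- c(glut_med = 0.12, peroneus = 0.65, tib_ant = 0.95,
                 gastroc = 0.62, soleus = 0.60)
    widths <- c(glut_med = 0.08, peroneus = 0.06, tib_ant = 0.05,
                gastroc = 0.06, soleus = 0.07)
    pha_l <- phase_at(ta, "left") / stride
    pha_r <- phase_at(ta, "right") / stride
    emg_env <- list()
    for (m in names(centres)) {
      emg_env[[paste0(m, "_left")]] <- 0.2 + burst(pha_l, centres[[m]], widths[[m]])
      emg_env[[paste0(m, "_right")]] <- 0.2 + burst(pha_r, centres[[m]], widths[[m]])
    }
    if (nrow(stimuli)) {
      for (i in seq_len(nrow(stimuli))) {
        ts <- stimuli$time_s[i]
        rs <- stimuli$rel_sign[i]
        stance <- stimuli$trigger_foot[i]
        swing <- if (stance == "left") "right" else "left"
        mod <- 1 + cfg$emg_gain * rs * inj(ta, ts, cfg$response_onset_emg)
        emg_env[[paste0("glut_med_", swing)]] <- emg_env[[paste0("glut_med_", swing)]] * mod
        emg_env[[paste0("peroneus_", stance)]] <- emg_env[[paste0("peroneus_", stance)]] * mod
      }
    }
    carrier <- sin(2 * pi * 137.3 * ta)
    emg <- do.call(cbind, lapply(emg_env, function(e) e * carrier))
    if (cfg$emg_noise_sd > 0)
      emg <- emg + stats::rnorm(length(emg), 0, cfg$emg_noise_sd)

    # --- marker dropouts ---------------------------------------------------
    if (cfg$gap_rate > 0) {
      for (j in seq_len(ncol(markers))) {
        n_gaps <- stats::rpois(1, cfg$gap_rate * duration)
        if (n_gaps == 0) next
        starts <- sample.int(length(tm), n_gaps)
        lens <- 1L + stats::rgeom(n_gaps, 1000 / (cfg$gap_mean_ms * cfg$marker_rate))
        for (g in seq_len(n_gaps)) {
          idx <- starts[g]:min(length(tm), starts[g] + lens[g] - 1L)
          markers[idx, j] <- NA_real_
        }
      }
    }

    # --- true pushoff times ------------------------------------------------
    po_list <- lapply(names(foot_land), function(f) {
      fl <- foot_land[[f]]
      tp <- fl$t + po + sw / 4
      data.frame(time = tp[tp < duration], foot = f, stringsAsFactors = FALSE)
    })
    pushoffs <- do.call(rbind, po_list)
    pushoffs <- pushoffs[order(pushoffs$time), ]
    rownames(pushoffs) <- NULL

    steps <- data.frame(
      step = 1:n_steps, start = hs_t[1:n_steps], end = hs_t[2:(n_steps + 1)],
      stance_foot = hs_foot[1:n_steps],
      com_pos_mid = com_pos_mid, com_vel_mid = com_vel_mid,
      placement = placement, placement_mirrored = p_mirror, stim_off = stim_off,
      stringsAsFactors = FALSE
    )

    bundle <- trial_bundle(
      markers = list(time = tm, data = markers, rate = cfg$marker_rate),
      forces = list(time = ta, data = forces, rate = cfg$analog_rate),
      emg = list(time = ta, data = emg, rate = cfg$analog_rate),
      angles = list(time = tm, data = ang, rate = cfg$marker_rate),
      stimulus_log = stimuli[, c("time_s", "trigger_foot", "direction",
                                 "peak_angle_deg"), drop = FALSE],
      meta = list(subject = cfg$subject,
                  standing_heel_height = list(left = cfg$stance_heel_height,
                                              right = cfg$stance_heel_height),
                  plate_origin_x = list(left = 0, right = 0),
                  markers = colnames(markers))
    )
    truth <- list(
      heelstrikes = hs_df,
      pushoffs = pushoffs,
      steps = steps,
      stimuli = stimuli,
      fp_coeff_pos = cfg$fp_coeff_pos, fp_coeff_vel = cfg$fp_coeff_vel,
      fp_shift_gain = cfg$fp_shift_gain, cop_shift_gain = cfg$cop_shift_gain,
      onset_cop_ms = 1000 * cfg$response_onset_cop,
      onset_fp_ms = 1000 * cfg$response_onset_fp,
      onset_ankle_ms = 1000 * cfg$response_onset_ankle,
      onset_emg_ms = 1000 * cfg$response_onset_emg
    )
    list(bundle = bundle, truth = truth)
  })
}
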