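#' Resample a within-step trajectory to 100 normalized time points
#'
#' Linear interpolation onto `n_out` evenly spaced points spanning the step
#' including both endpoints, so endpoint values are preserved exactly.
#'
#' @param x samples of one signal within a step (uniformly sampled)
#' @param n_out number of output points
#' @return numeric vector of length `n_out`
#' @export
normalize_time <- function(x, n_out = 100) {
  n <- length(x)
  if (n < 2L) stop("a step needs at least 2 samples to normalize", call. = FALSE)
  if (n == n_out) return(as.numeric(x))
  stats::approx(seq(0, 1, length.out = n), x,
                xout = seq(0, 1, length.out = n_out))$y
}

#' Segment a trial into steps and select analysis steps
#'
#' Steps run from one heelstrike to the contralateral heelstrike. For each
#' stimulus, the four steps following the triggering heelstrike (indices
#' +1..+4) and the two preceding it (-2, -1) are selected; the two preceding
#' steps are the unperturbed controls. With no stimuli all steps are
#' control-eligible and carry no stimulus index.
#'
#' @param events a `gait_events` table (see [detect_gait_events()])
#' @param stimuli stimulus schedule (`time_s`, `trigger_foot`, `direction`),
#'   may have zero rows
#' @param trigger_tol_s tolerance for matching a stimulus trigger to a
#'   heelstrike (s)
#' @return data.frame with one row per step: `step`, `start`, `end`,
#'   `duration`, `stance_foot`, `swing_foot`, `pushoff_time` (swing-foot
#'   pushoff within the step, NA if missing), `stim_id`, `step_index`,
#'   `condition` ("control"/"stimulus"/"unused"), `trigger_foot`, `direction`
#' @export
segment_steps <- function(events, stimuli, trigger_tol_s = 0.01) {
  hs <- events[events$kind == "heelstrike", , drop = FALSE]
  hs <- hs[order(hs$time), , drop = FALSE]
  n <- nrow(hs) - 1L
  if (n < 1L) stop("need at least two heelstrikes to form a step", call. = FALSE)
  po <- events[events$kind == "pushoff", , drop = FALSE]
  swing_foot <- as.character(hs$foot[-1])
  out <- data.frame(
    step = seq_len(n),
    start = hs$time[1:n], end = hs$time[2:(n + 1L)],
    stance_foot = as.character(hs$foot[1:n]), swing_foot = swing_foot,
    stringsAsFactors = FALSE
  )
  out$duration <- out$end - out$start
  # swing-foot pushoff inside the step (start of the swing phase)
  out$pushoff_time <- vapply(seq_len(n), function(i) {
    cand <- po$time[po$foot == out$swing_foot[i] &
                      po$time > out$start[i] & po$time < out$end[i]]
    if (length(cand)) cand[1] else NA_real_
  }, numeric(1))
  out$stim_id <- NA_integer_
  out$step_index <- NA_integer_
  out$condition <- "unused"
  out$trigger_foot <- NA_character_
  out$direction <- NA_character_
  if (is.null(stimuli) || nrow(stimuli) == 0L) {
    out$condition <- "control"
    return(out)
  }
  for (i in seq_len(nrow(stimuli))) {
    k <- which(abs(out$start - stimuli$time_s[i]) <= trigger_tol_s)
    if (!length(k)) {
      warning(sprintf("stimulus %d at t=%.3f s does not coincide with a heelstrike; skipped",
                      i, stimuli$time_s[i]))
      next
    }
    k <- k[1]
    idx <- c(-2L, -1L, 1L, 2L, 3L, 4L)
    rows <- k + c(-2L, -1L, 0L, 1L, 2L, 3L)
    ok <- rows >= 1L & rows <= n
    if (!all(ok))
      warning(sprintf("stimulus %d too close to trial edge: partial step set", i))
    for (j in which(ok)) {
      r <- rows[j]
      out$stim_id[r] <- i
      out$step_index[r] <- idx[j]
      out$condition[r] <- if (idx[j] < 0) "control" else "stimulus"
      out$trigger_foot[r] <- as.character(stimuli$trigger_foot[i])
      out$direction[r] <- as.character(stimuli$direction[i])
    }
  }
  out
}

#' Mirror lateral signals for left-side triggers
#'
#' Spatial (lateral) variables are negated when `flip` is TRUE so that
#' positive always means "toward the triggering foot". Applying the mirror
#' twice returns the original signal.
#'
#' @param x numeric vector/matrix of a lateral spatial signal
#' @param flip logical; TRUE negates
#' @return mirrored signal
#' @export
mirror_lateral <- function(x, flip) {
  if (isTRUE(flip)) -x else x
}

#' Assemble normalized step records from a trial bundle
#'
#' Runs the preprocessing chain (gap filling and 10/50/6 Hz zero-phase
#' filtering, CoM from the segment table, CoP from plate moments, EMG
#' envelopes normalized to control strides), detects gait events unless
#' supplied, segments steps, and extracts 100-point normalized trajectories
#' plus per-step scalars (midstance CoM state, foot placement, duration,
#' step length). Steps overlapping unrecoverable marker occlusions or
#' shorter than `min_step_ms` are excluded with a reason.
#'
#' @param bundle a [trial_bundle()]
#' @param events optional pre-computed `gait_events` table
#' @param n_norm normalized trajectory length
#' @param max_gap_ms marker gap-fill limit (ms)
#' @param midstance_frac fraction of step time defining midstance (0.5 =
#'   halfway between the step's heelstrikes)
#' @param min_step_ms minimum credible step duration (ms)
#' @return object of class `step_set`: list with `info` (per-step
#'   data.frame), `traj` (named list of n_steps x n_norm matrices for
#'   `com_pos`, `com_vel`, `cop`, `cop_rel`, `heel_x_left`, `heel_x_right`,
#'   `swing_heel_x`, angle and EMG channels), `events`, `subject`
#' @export
build_step_set <- function(bundle, events = NULL, n_norm = 100,
                           max_gap_ms = 100, midstance_frac = 0.5,
                           min_step_ms = 50) {
  fs <- bundle$markers$rate
  tm <- bundle$markers$time
  gf <- fill_gaps(bundle$markers$data, fs, max_gap_ms = max_gap_ms)
  excl_any <- rowSums(gf$excluded) > 0
  # bridge unrecoverable occlusions by linear interpolation so filtering and
  # event detection stay stable; steps touching them are dropped regardless
  mk <- apply(gf$data, 2L, function(v) {
    if (!anyNA(v)) return(v)
    ok <- which(!is.na(v))
    stats::approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
  })
  mk_f <- lowpass(mk, fs, 10)
  colnames(mk_f) <- colnames(bundle$markers$data)

  if (is.null(events)) events <- detect_gait_events(mk_f, fs, t0 = tm[1])

  seg <- default_segment_table()
  seg_x <- mk_f[, c("TRUNK_x", "PELVIS_x", "HEAD_x", "LEG_L_x", "LEG_R_x")]
  colnames(seg_x) <- c("trunk", "pelvis", "head", "leg_left", "leg_right")
  com <- com_state(compute_com(seg_x, seg), fs)

  fa <- bundle$forces$rate
  forces_f <- lowpass(bundle$forces$data, fa, 50)
  colnames(forces_f) <- colnames(bundle$forces$data)
  origins <- c(left = bundle$meta$plate_origin_x$left %||% 0,
               right = bundle$meta$plate_origin_x$right %||% 0)
  cop <- compute_cop(forces_f, origins)
  cop_m <- stats::approx(bundle$forces$time, cop$cop_x, xout = tm)$y
  cop_rel <- cop_m - com$position

  fe <- bundle$emg$rate
  env <- emg_envelope(bundle$emg$data, fe, 6)
  colnames(env) <- colnames(bundle$emg$data)
  env_m <- apply(env, 2L, function(v) stats::approx(bundle$emg$time, v, xout = tm)$y)

  steps <- segment_steps(events, bundle$stimulus_log)

  # nearest-sample window indices: immune to floating-point boundary ties
  win_idx <- function(a, b) {
    i0 <- round((a - tm[1]) * fs) + 1
    i1 <- round((b - tm[1]) * fs) + 1
    seq.int(max(1L, i0), min(length(tm), i1))
  }

  # EMG normalization: grand mean over control-step samples per channel = 100%
  ctrl <- steps[steps$condition == "control", , drop = FALSE]
  ctrl_idx <- unlist(lapply(seq_len(nrow(ctrl)), function(i)
    win_idx(ctrl$start[i], ctrl$end[i])))
  emg_n <- apply(env_m, 2L, emg_normalize, control_idx = ctrl_idx)
  colnames(emg_n) <- colnames(env_m)

  ang <- NULL
  if (!is.null(bundle$angles)) {
    ang <- lowpass(bundle$angles$data, bundle$angles$rate, 10)
    colnames(ang) <- colnames(bundle$angles$data)
  }

  signals <- list(com_pos = com$position, com_vel = com$velocity,
                  cop = cop_m, cop_rel = cop_rel,
                  heel_x_left = mk_f[, "LHEE_x"], heel_x_right = mk_f[, "RHEE_x"],
                  heel_y_left = mk_f[, "LHEE_y"], heel_y_right = mk_f[, "RHEE_y"])
  if (!is.null(ang)) for (j in colnames(ang)) signals[[j]] <- ang[, j]
  for (j in colnames(emg_n)) signals[[paste0("emg_", j)]] <- emg_n[, j]

  n <- nrow(steps)
  traj <- lapply(signals, function(s) matrix(NA_real_, n, n_norm))
  steps$excluded <- FALSE
  steps$reason <- NA_character_
  steps$com_pos_mid <- NA_real_
  steps$com_vel_mid <- NA_real_
  steps$foot_placement <- NA_real_
  steps$step_length <- NA_real_
  steps$pushoff_frac <- NA_real_

  for (i in seq_len(n)) {
    idx <- win_idx(steps$start[i], steps$end[i])
    if (steps$duration[i] * 1000 < min_step_ms) {
      steps$excluded[i] <- TRUE; steps$reason[i] <- "degenerate step"; next
    }
    if (length(idx) < 2L) {
      steps$excluded[i] <- TRUE; steps$reason[i] <- "too few samples"; next
    }
    if (any(excl_any[idx])) {
      steps$excluded[i] <- TRUE; steps$reason[i] <- "missing kinematic data"; next
    }
    for (nm in names(signals))
      traj[[nm]][i, ] <- normalize_time(signals[[nm]][idx], n_norm)
    t_mid <- steps$start[i] + midstance_frac * steps$duration[i]
    steps$com_pos_mid[i] <- stats::approx(tm, com$position, xout = t_mid)$y
    steps$com_vel_mid[i] <- stats::approx(tm, com$velocity, xout = t_mid)$y
    swx <- signals[[paste0("heel_x_", steps$swing_foot[i])]]
    stx <- signals[[paste0("heel_x_", steps$stance_foot[i])]]
    swy <- signals[[paste0("heel_y_", steps$swing_foot[i])]]
    sty <- signals[[paste0("heel_y_", steps$stance_foot[i])]]
    iend <- idx[length(idx)]
    steps$foot_placement[i] <- swx[iend] - stx[iend]
    steps$step_length[i] <- swy[iend] - sty[iend]
    if (!is.na(steps$pushoff_time[i]))
      steps$pushoff_frac[i] <- (steps$pushoff_time[i] - steps$start[i]) / steps$duration[i]
  }
  traj[["swing_heel_x"]] <- matrix(NA_real_, n, n_norm)
  for (i in seq_len(n)) {
    if (steps$excluded[i]) next
    traj[["swing_heel_x"]][i, ] <- traj[[paste0("heel_x_", steps$swing_foot[i])]][i, ]
  }
  structure(list(info = steps, traj = traj, events = events,
                 subject = bundle$meta$subject %||% "S"),
            class = "step_set")
}

#' @export
print.step_set <- function(x, ...) {
  cat(sprintf("<step_set> subject %s: %d steps (%d control, %d stimulus, %d excluded)\n",
              x$subject, nrow(x$info), sum(x$info$condition == "control" & !x$info$excluded),
              sum(x$info$condition == "stimulus" & !x$info$excluded),
              sum(x$info$excluded)))
  invisible(x)
}

# spatial (lateral) trajectory variables, mirrored for left-side analysis
spatial_traj_names <- function(traj)
  intersect(c("com_pos", "com_vel", "cop", "cop_rel", "heel_x_left",
              "heel_x_right", "swing_heel_x"), names(traj))

#' Subtract control-step baselines
#'
#' For each trajectory variable the mean over included control steps with
#' the same stance foot is subtracted pointwise in normalized time from the
#' stimulus steps, giving the response to the stimulus. For left-foot
#' triggers the spatial (lateral) responses are mirrored so that positive
#' means toward the triggering foot.
#'
#' @param step_set a [build_step_set()] result
#' @return list with `responses` (named list of matrices, rows = included
#'   stimulus steps), `rows` (their row indices in `step_set$info`), and
#'   `control_mean` (named list of per-stance-foot mean trajectories)
#' @export
baseline_subtract <- function(step_set) {
  info <- step_set$info
  ctrl <- which(info$condition == "control" & !info$excluded)
  stim <- which(info$condition == "stimulus" & !info$excluded)
  cmean <- list()
  for (foot in c("left", "right")) {
    ci <- ctrl[info$stance_foot[ctrl] == foot]
    if (!length(ci))
      stop(sprintf("no control steps with stance foot '%s'", foot), call. = FALSE)
    cmean[[foot]] <- lapply(step_set$traj, function(m)
      colMeans(m[ci, , drop = FALSE]))
  }
  spat <- spatial_traj_names(step_set$traj)
  responses <- lapply(names(step_set$traj), function(nm) {
    r <- matrix(NA_real_, length(stim), ncol(step_set$traj[[nm]]))
    for (j in seq_along(stim)) {
      i <- stim[j]
      r[j, ] <- step_set$traj[[nm]][i, ] - cmean[[info$stance_foot[i]]][[nm]]
      if (nm %in% spat)
        r[j, ] <- mirror_lateral(r[j, ], info$trigger_foot[i] == "left")
    }
    r
  })
  names(responses) <- names(step_set$traj)
  list(responses = responses, rows = stim, control_mean = cmean)
}

#' Fit the CoM-state foot-placement model on control steps
#'
#' Per-subject ordinary least squares of (mirrored) lateral foot placement
#' on lateral CoM position and velocity at midstance, fitted on control
#' steps only. Left-stance steps are mirrored so both feet pool into one
#' model.
#'
#' @param step_set a [build_step_set()] result
#' @param min_control minimum number of control steps required
#' @return object of class `fp_model`: list with `coef`
#'   (intercept/position/velocity), `fit` (the lm), `n`
#' @export
fit_foot_placement_model <- function(step_set, min_control = 10) {
  info <- step_set$info
  ctrl <- info[info$condition == "control" & !info$excluded, , drop = FALSE]
  if (nrow(ctrl) < min_control)
    stop(sprintf("need >= %d control steps, have %d", min_control, nrow(ctrl)),
         call. = FALSE)
  d <- fp_design(ctrl)
  fit <- stats::lm(placement ~ pos + vel, data = d)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient foot-placement design (no CoM-state variation?)",
         call. = FALSE)
  structure(list(coef = stats::setNames(stats::coef(fit),
                                        c("intercept", "position", "velocity")),
                 fit = fit, n = nrow(ctrl)),
            class = "fp_model")
}

# mirrored design for the foot-placement regression (mirror by stance foot)
fp_design <- function(info) {
  s <- ifelse(info$stance_foot == "left", -1, 1)
  data.frame(placement = s * info$foot_placement,
             pos = s * info$com_pos_mid,
             vel = s * info$com_vel_mid)
}

#' @export
print.fp_model <- function(x, ...) {
  cat(sprintf("<fp_model> placement = %.2f %+.3f*pos %+.3f*vel (mm; %d control steps)\n",
              x$coef[1], x$coef[2], x$coef[3], x$n))
  invisible(x)
}

#' Stimulus-induced foot-placement change
#'
#' Observed (mirrored) foot placement minus the placement predicted from the
#' CoM state at midstance by the control-fitted model: the component of the
#' placement change attributable to the stimulus rather than to the ongoing
#' CoM state.
#'
#' @param info rows of `step_set$info` (any condition)
#' @param model a [fit_foot_placement_model()] result
#' @return numeric vector (mm), in the mirrored (stance-side) frame
#' @export
stimulus_induced_fp_change <- function(info, model) {
  d <- fp_design(info)
  d$placement - stats::predict(model$fit, newdata = d)
}

#' Compute the seven outcome variables for first post-stimulus steps
#'
#' For every included step +1, computes: (i) foot placement change (mm),
#' (ii) stimulus-induced foot placement change (mm), (iii) hip abduction
#' change of the swing leg at heelstrike (deg), (iv) integrated gluteus
#' medius EMG change of the swing leg (% s), (v) integrated CoP-relative-
#' to-CoM change (mm s), (vi) ankle eversion change of the stance leg at
#' heelstrike (deg), (vii) integrated peroneus longus EMG change of the
#' stance leg (% s). Integrals run over the first post-stimulus swing phase
#' (swing-foot pushoff to step-ending heelstrike) in real time. Spatial
#' variables (i, ii, v) are sign-inverted for perceived falls *away* from
#' the triggering foot; body-relative variables (iii, iv, vi, vii) for falls
#' *toward* it.
#'
#' @param step_set a [build_step_set()] result
#' @param model a [fit_foot_placement_model()] result
#' @return data.frame with one row per stimulus: factors `subject`,
#'   `trigger_foot`, `direction` (relative: "toward"/"away"), and the seven
#'   outcomes
#' @export
compute_outcomes <- function(step_set, model) {
  info <- step_set$info
  base <- baseline_subtract(step_set)
  rows <- base$rows
  first <- rows[info$step_index[rows] == 1L]
  out <- lapply(first, function(i) {
    ri <- match(i, rows)
    stance <- info$stance_foot[i]
    swing <- info$swing_foot[i]
    rel <- classify_direction(info$direction[i], info$trigger_foot[i])
    s_spatial <- if (rel == "away") -1 else 1
    s_body <- if (rel == "toward") -1 else 1

    # mirrored placement change vs control mean placement (same stance foot)
    ctrl_rows <- which(info$condition == "control" & !info$excluded &
                         info$stance_foot == stance)
    d <- fp_design(info[i, , drop = FALSE])
    dctrl <- fp_design(info[ctrl_rows, , drop = FALSE])
    fp_change <- d$placement - mean(dctrl$placement)
    fp_stim <- stimulus_induced_fp_change(info[i, , drop = FALSE], model)

    # integration window: swing-foot pushoff to step end, in real time
    dur <- info$duration[i]
    pf <- info$pushoff_frac[i]
    n_norm <- ncol(base$responses[[1]])
    tgrid <- seq(0, dur, length.out = n_norm)
    win <- if (is.na(pf)) rep(TRUE, n_norm) else tgrid >= pf * dur
    integ <- function(resp_row) trapz(tgrid[win], resp_row[win])

    hip <- base$responses[[paste0("hip_abduction_", swing)]][ri, n_norm]
    ever <- base$responses[[paste0("ankle_eversion_", stance)]][ri, n_norm]
    glut <- integ(base$responses[[paste0("emg_glut_med_", swing)]][ri, ])
    perl <- integ(base$responses[[paste0("emg_peroneus_", stance)]][ri, ])
    cop_int <- integ(base$responses[["cop_rel"]][ri, ])

    data.frame(
      subject = step_set$subject,
      stim_id = info$stim_id[i],
      trigger_foot = info$trigger_foot[i],
      direction = rel,
      foot_placement_change = s_spatial * fp_change,
      stimulus_induced_fp_change = s_spatial * fp_stim,
      hip_abduction_change = s_body * hip,
      integrated_gluteus_medius_emg_change = s_body * glut,
      integrated_relative_cop_change = s_spatial * cop_int,
      ankle_eversion_change = s_body * ever,
      integrated_peroneus_longus_emg_change = s_body * perl,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
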