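test_that("zero-phase lowpass has unit DC gain and the expected passband/stopband", {
  fs <- 250
  expect_equal(lowpass(rep(3.7, 500), fs, 10), rep(3.7, 500), tolerance = 1e-5)
  tt <- seq(0, 8, by = 1 / fs)
  core <- seq(round(length(tt) * 0.2), round(length(tt) * 0.8))
  s1 <- sin(2 * pi * 1 * tt)
  y1 <- lowpass(s1, fs, 10)
  expect_equal(max(abs(y1[core])), 1, tolerance = 0.01)
  s50 <- sin(2 * pi * 50 * tt)
  y50 <- lowpass(s50, fs, 10)
  expect_lt(max(abs(y50[core])), 0.05)
  # filtering is idempotent in the passband
  expect_lt(max(abs(lowpass(y1, fs, 10)[core] - y1[core])), 0.02)
})

test_that("lowpass validates the cutoff and rejects NA input", {
  expect_error(lowpass(rnorm(100), 250, 125), "Nyquist")
  expect_error(lowpass(c(1, NA, 3), 250, 10), "gap")
})

test_that("gap filling reconstructs short occlusions and excludes long ones", {
  fs <- 250
  tt <- seq(0, 4, by = 1 / fs)
  truth <- 40 * sin(2 * pi * 1.5 * tt)
  x <- truth
  gap60 <- 300:314                      # 60 ms
  x[gap60] <- NA
  r <- fill_gaps(x, fs, max_gap_ms = 100)
  expect_false(anyNA(r$data))
  expect_false(any(r$excluded))
  expect_lt(max(abs(r$data[gap60] - truth[gap60])), 0.5)
  x2 <- truth
  gap200 <- 500:549                     # 200 ms
  x2[gap200] <- NA
  r2 <- fill_gaps(x2, fs, max_gap_ms = 100)
  expect_true(all(is.na(r2$data[gap200])))
  expect_true(all(r2$excluded[gap200]))
  expect_false(any(r2$excluded[-gap200]))
  # gapless input is untouched
  r3 <- fill_gaps(truth, fs)
  expect_identical(r3$data, truth)
  expect_warning(r4 <- fill_gaps(rep(NA_real_, 100), fs), "all-NA")
  expect_true(all(r4$excluded))
})

test_that("CoM is the mass-fraction-weighted mean of segment positions", {
  tab2 <- data.frame(segment = c("a", "b"), fraction = c(0.5, 0.5))
  seg <- cbind(a = rep(-10, 5), b = rep(10, 5))
  expect_equal(compute_com(seg, tab2), rep(0, 5))
  tab1 <- data.frame(segment = "a", fraction = 1)
  expect_equal(compute_com(cbind(a = 1:5), tab1), as.numeric(1:5))
  tab3 <- data.frame(segment = c("a", "b", "c"), fraction = c(0.5, 0.3, 0.2))
  seg3 <- cbind(a = 0, b = 10, c = 20)
  expect_equal(compute_com(seg3, tab3), 7)
  expect_error(compute_com(cbind(a = 1), tab3), "missing segment.*b")
  bad <- data.frame(segment = "a", fraction = 0.9)
  expect_error(compute_com(cbind(a = 1), bad), "sum to 1")
  expect_equal(sum(default_segment_table()$fraction), 1)
})

test_that("CoM derivatives agree with an independent finite-difference oracle", {
  fs <- 250
  tt <- seq(0, 3, by = 1 / fs)
  pos <- 20 * sin(2 * pi * 0.8 * tt)
  st <- com_state(pos, fs)
  vel_oracle <- diff(pos) * fs
  mid <- 2:(length(pos) - 1)
  expect_equal(st$velocity[mid], (vel_oracle[mid] + vel_oracle[mid - 1]) / 2,
               tolerance = 1e-10)
  acc_analytic <- -20 * (2 * pi * 0.8)^2 * sin(2 * pi * 0.8 * tt)
  expect_equal(st$acceleration[mid], acc_analytic[mid], tolerance = 0.05)
})

test_that("CoP equals the closed-form moment-over-force oracle", {
  f1 <- data.frame(fz_left = 700, mx_left = 35, fz_right = 0, mx_right = 0)
  r1 <- compute_cop(f1)
  expect_equal(r1$cop_x, 50)
  expect_equal(r1$cop_left, 50)
  expect_true(is.na(r1$cop_right))
  # equal load, symmetric CoPs at +/-50 mm -> whole-body CoP at 0
  f2 <- data.frame(fz_left = 350, mx_left = 350 * -0.05,
                   fz_right = 350, mx_right = 350 * 0.05)
  expect_equal(compute_cop(f2)$cop_x, 0)
  # one plate unloaded -> whole-body CoP equals the loaded plate's
  f3 <- data.frame(fz_left = 0, mx_left = 0, fz_right = 600, mx_right = 18)
  expect_equal(compute_cop(f3)$cop_x, 30)
  # nobody on the plates -> undefined and flagged
  f4 <- data.frame(fz_left = 5, mx_left = 0, fz_right = 5, mx_right = 0)
  r4 <- compute_cop(f4)
  expect_true(is.na(r4$cop_x) && !r4$valid)
  expect_error(compute_cop(data.frame(fz_left = 1)), "missing force")
})

test_that("whole-body CoP matches the weighted oracle on random loading", {
  set.seed(21)
  n <- 200
  fzl <- runif(n, 100, 700); fzr <- runif(n, 100, 700)
  cl <- runif(n, -80, 0); cr <- runif(n, 0, 80)
  f <- data.frame(fz_left = fzl, mx_left = fzl * cl / 1000,
                  fz_right = fzr, mx_right = fzr * cr / 1000)
  r <- compute_cop(f)
  expect_equal(r$cop_x, (fzl * cl + fzr * cr) / (fzl + fzr), tolerance = 1e-9)
  expect_true(all(r$valid))
})

test_that("EMG conditioning rectifies, smooths and normalizes to control strides", {
  fs <- 1000
  sq <- rep(c(2.5, -2.5), 2000)          # +/-c square wave -> DC level c
  env <- emg_envelope(sq, fs, fc = 6)
  core <- 500:3500
  expect_equal(mean(env[core]), 2.5, tolerance = 0.01)
  ctrl <- 1:2000
  nrm <- emg_normalize(env, ctrl)
  expect_equal(mean(nrm[ctrl]), 100, tolerance = 1e-9)
  # doubling the raw amplitude doubles the normalized signal when the
  # normalization constant is held at the original control mean
  nrm2 <- 100 * (2 * env) / mean(env[ctrl])
  expect_equal(nrm2, 2 * nrm, tolerance = 1e-12)
  expect_error(emg_normalize(rep(0, 100), 1:50), "zero")
  expect_error(emg_normalize(env, integer(0)), "control")
})
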