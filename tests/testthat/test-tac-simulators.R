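test_that("default frame schedule has 41 frames spanning 90 min", {
  fs <- frame_schedule_default()
  expect_length(fs, 41)
  expect_equal(sum(fs), 5400)
  ref <- simulate_reference_tac()
  expect_equal(nrow(ref), 41)
  expect_equal(max(ref$frame_start_s + ref$frame_duration_s), 5400)
})

test_that("reference TAC frame averages match fine-grid quadrature", {
  A <- 25; lf <- 2.5; ls <- 0.04
  ref <- simulate_reference_tac(A, lf, ls)
  f <- function(t) A * (exp(-ls * t) - exp(-lf * t))
  ends <- cumsum(ref$frame_duration_s) / 60
  starts <- c(0, ends[-41])
  quad <- vapply(seq_len(41), function(i)
    stats::integrate(f, starts[i], ends[i],
                     rel.tol = 1e-10)$value / (ends[i] - starts[i]),
    numeric(1))
  expect_true(max(abs(ref$concentration_kBq_per_mL - quad) / max(quad)) < 1e-3)
})

test_that("reference TAC edge cases are handled", {
  expect_equal(simulate_reference_tac(0)$concentration_kBq_per_mL,
               rep(0, 41))
  expect_error(simulate_reference_tac(30, lambda_fast = 0.02,
                                      lambda_slow = 0.05),
               "lambda_fast")
})

test_that("SRTM generative identity: BP = 0, R1 = 1 reproduces the reference", {
  ref <- simulate_reference_tac()
  tg <- simulate_target_tac(ref, R1 = 1, BP = 0, k2 = 0.3)
  expect_equal(tg$concentration_kBq_per_mL, ref$concentration_kBq_per_mL,
               tolerance = 1e-10)
})

test_that("generated SRTM curve matches independent ODE integration", {
  # dCt/dt = R1 dCref/dt + k2 Cref - k2a Ct, integrated by RK4
  A <- 30; lf <- 3; ls <- 0.03
  R1 <- 1; k2 <- 0.3; BP <- 1
  k2a <- k2 / (1 + BP)
  cref <- function(t) A * (exp(-ls * t) - exp(-lf * t))
  dcref <- function(t) A * (-ls * exp(-ls * t) + lf * exp(-lf * t))
  rhs <- function(t, ct) R1 * dcref(t) + k2 * cref(t) - k2a * ct
  dt <- 0.005
  tt <- seq(0, 90, by = dt)
  ct <- numeric(length(tt))
  for (i in seq_len(length(tt) - 1)) {
    t0 <- tt[i]; y0 <- ct[i]
    k1 <- rhs(t0, y0)
    k2_ <- rhs(t0 + dt / 2, y0 + dt / 2 * k1)
    k3 <- rhs(t0 + dt / 2, y0 + dt / 2 * k2_)
    k4 <- rhs(t0 + dt, y0 + dt * k3)
    ct[i + 1] <- y0 + dt / 6 * (k1 + 2 * k2_ + 2 * k3 + k4)
  }
  fs <- frame_schedule_default()
  gen <- simulate_target_tac(function(t) cref(t), R1 = R1, k2 = k2, BP = BP,
                             frame_durations_s = fs)
  ends <- cumsum(fs) / 60; starts <- c(0, ends[-41])
  ode_avg <- vapply(seq_len(41), function(i) {
    sel <- tt >= starts[i] - 1e-9 & tt <= ends[i] + 1e-9
    mean(ct[sel])
  }, numeric(1))
  expect_true(max(abs(gen$concentration_kBq_per_mL - ode_avg)) /
                max(ode_avg) < 2e-3)
  # DVR = integral ratio at late equilibrium is 2 by construction (BP = 1)
  lg <- logan_ref_bpnd(gen, simulate_reference_tac(A, lf, ls),
                       k2prime = k2 / R1, t_star = 30)
  expect_equal(lg$dvr, 2, tolerance = 0.02)
})

test_that("frame noise scales as 1/sqrt(frame duration)", {
  ref <- simulate_reference_tac()
  clean <- simulate_target_tac(ref, R1 = 1, k2 = 0.3, BP = 1)
  sd0 <- 0.8
  res <- sapply(1:200, function(i) {
    noisy <- simulate_target_tac(ref, R1 = 1, k2 = 0.3, BP = 1,
                                 noise_sd0 = sd0, seed = i)
    noisy$concentration_kBq_per_mL - clean$concentration_kBq_per_mL
  })
  emp_sd <- apply(res, 1, sd)
  expected <- sd0 / sqrt(clean$frame_duration_s / 60)
  # pooled over frame groups to keep Monte-Carlo error small
  grp <- rep(1:5, c(6, 6, 11, 15, 3))
  emp <- tapply(emp_sd, grp, mean)
  exp_ <- tapply(expected, grp, mean)
  expect_true(all(abs(emp / exp_ - 1) < 0.05))
})

test_that("noisy TAC simulation is seed-reproducible", {
  ref <- simulate_reference_tac()
  a <- simulate_target_tac(ref, 1, 0.3, 1, noise_sd0 = 1, seed = 7)
  b <- simulate_target_tac(ref, 1, 0.3, 1, noise_sd0 = 1, seed = 7)
  expect_identical(a, b)
  expect_error(simulate_target_tac(ref, -1, 0.3, 1), "positive")
  expect_error(simulate_target_tac(ref, 1, 0.3, -0.5), "nonnegative")
})

test_that("frame-averaged curves converge to the instantaneous curve", {
  f <- function(t) 30 * (exp(-0.03 * t) - exp(-3 * t))
  for (dur in c(60, 10, 1)) {
    fs <- rep(dur, 600 / dur)
    ref <- simulate_reference_tac(30, 3, 0.03, frame_durations_s = fs)
    mids <- tac_mid_min(ref)
    err <- max(abs(ref$concentration_kBq_per_mL - f(mids)))
    if (dur == 60) err60 <- err
    if (dur == 1) expect_lt(err, 2e-4 * 30)
  }
  expect_lt(err, err60)
})
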