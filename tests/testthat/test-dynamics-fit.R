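# Jerk smoothing, linear COM system, angular system, residual metrics.

test_that("jerk smoothing: quadratic invariance, noise shrink, LS oracle", {
  T_ <- 60; dt <- 0.01
  tt <- (seq_len(T_) - 1) * dt
  quad <- cbind(1 + 2 * tt - 3 * tt^2, 0.5 * tt^2)
  expect_equal(smooth_jerk(quad, dt), quad, tolerance = 1e-12,
               ignore_attr = TRUE)
  set.seed(4)
  noisy <- quad + matrix(rnorm(2 * T_, 0, 0.01), T_)
  sm <- smooth_jerk(noisy, dt)
  expect_lt(stats::var(as.numeric(sm - quad)),
            stats::var(as.numeric(noisy - quad)))
  # dense least-squares oracle: minimize via the stacked QR system
  w <- (2 * pi * 6 * dt)^-6
  D <- matrix(0, T_ - 3, T_)
  for (t in seq_len(T_ - 3)) D[t, t:(t + 3)] <- c(-1, 3, -3, 1)
  Astack <- rbind(diag(T_), sqrt(w) * D)
  oracle <- qr.solve(Astack, rbind(noisy, matrix(0, T_ - 3, 2)))
  expect_equal(sm, oracle, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(smooth_jerk(noisy[1:3, ], dt), "4 frames")
})

test_that("COM system matches a step-by-step integrator", {
  set.seed(6)
  T_ <- 50; dt <- 0.01; g <- c(0, -9.80665, 0)
  f <- matrix(rnorm(T_ * 3, 0, 300), T_)
  sys <- build_com_system(f, dt, g)
  zeta <- c(rnorm(3), rnorm(3), 1 / 70)
  Z <- matrix(sys$A %*% zeta + sys$b, ncol = 3, byrow = TRUE)
  expect_equal(Z, oracle_com_rollout(zeta, f, dt, g), tolerance = 1e-12)
  # first row block returns z1 exactly
  expect_equal(Z[1, ], zeta[1:3])
  expect_equal(unname(sys$A[1:3, ]), cbind(diag(3), matrix(0, 3, 4)))
  # free fall: zero force gives the gravity parabola
  sys0 <- build_com_system(f * 0, dt, g)
  zeta0 <- c(0, 2, 0, 0, 0, 0, 1 / 70)
  Z0 <- matrix(sys0$A %*% zeta0 + sys0$b, ncol = 3, byrow = TRUE)
  expect_equal(Z0, oracle_com_rollout(zeta0, f * 0, dt, g),
               tolerance = 1e-12)
  expect_lt(max(abs(sys0$A[, 7])), 1e-15)   # mu column vanishes
  expect_error(build_com_system(f[1, , drop = FALSE], dt), "2 frames")
})

test_that("fit_com: exact on integrator data, degenerate flight, noise", {
  set.seed(13)
  T_ <- 120; dt <- 0.01; g <- c(0, -9.80665, 0)
  m_true <- 72.5
  tt <- (seq_len(T_) - 1) * dt
  f <- cbind(30 * sin(2 * pi * tt), m_true * 9.80665 +
               200 * sin(2 * pi * 1.7 * tt), 20 * cos(2 * pi * tt))
  zeta <- c(0.1, 0.95, -0.05, 0.02, 0, 0.01, 1 / m_true)
  Zhat <- oracle_com_rollout(zeta, f, dt, g)
  fit <- fit_com(Zhat, f, dt, g)
  expect_lt(abs(fit$mass - m_true) / m_true, 1e-6)
  expect_equal(fit$z1, zeta[1:3], tolerance = 1e-8)
  expect_equal(fit$zdot1, zeta[4:6], tolerance = 1e-8)
  expect_lt(fit$rmse, 1e-10)
  # pure flight: mu structurally unidentifiable -> degenerate fallback
  expect_warning(fl <- fit_com(Zhat, f * 0, dt, g, fallback_mass = 60),
                 "falling back")
  expect_true(fl$degenerate)
  expect_equal(fl$mass, 60)
  # 5 mm observation noise: mass within 2%, unbiased over 20 seeds
  errs <- sapply(1:20, function(s) {
    set.seed(s)
    fit_com(Zhat + matrix(rnorm(3 * T_, 0, 0.005), T_), f, dt,
            g)$mass / m_true - 1
  })
  expect_lt(max(abs(errs)), 0.02)
  expect_lt(abs(mean(errs)), 0.005)
})

test_that("angular system equals its rollout and embeds the COM blocks", {
  syn <- generate_trial(21, duration = 1.5, marker_sigma = 0,
                        occlusion = 0)
  truth <- syn$truth
  dt <- 0.01
  sys <- build_angular_system(truth$skel, truth$q, syn$grf,
                              truth$assignment, dt)
  T_ <- nrow(truth$q)
  set.seed(2)
  xi <- c(truth$com[1, ] + rnorm(3, 0, 0.01), rnorm(3, 0, 0.1),
          truth$q[1, 4:6] + rnorm(3, 0, 0.02), rnorm(3, 0, 0.1))
  Xi <- drop(sys$Atil %*% xi + sys$btil)
  czdd <- sys$f_tot / sys$mass +
    matrix(truth$skel$gravity, T_, 3, byrow = TRUE)
  oracle <- oracle_angular_rollout(xi, sys$terms, czdd, dt)
  oracle_vec <- c(as.numeric(t(oracle[, 1:3])),
                  as.numeric(t(oracle[, 4:6])))
  expect_lt(max(abs(Xi - oracle_vec)), 1e-10)
  # upper-left quadrant: identical to the COM system's first two blocks
  com_sys <- build_com_system(sys$f_tot, dt, truth$skel$gravity)
  expect_equal(sys$Atil[seq_len(3 * T_), 1:6], com_sys$A[, 1:6],
               tolerance = 1e-12)
  # upper-right quadrant of the Z rows is zero
  expect_equal(max(abs(sys$Atil[seq_len(3 * T_), 7:12])), 0)
  # zero external force: the lower-left (GRF-coupling) quadrant vanishes
  grf0 <- syn$grf
  for (k in 1:2) {
    grf0$plates[[k]]$force[] <- 0
    grf0$plates[[k]]$torque[] <- 0
  }
  sys0 <- build_angular_system(truth$skel, truth$q, grf0,
                               truth$assignment, dt)
  expect_equal(max(abs(sys0$Atil[3 * T_ + seq_len(3 * T_), 1:6])), 0)
})

test_that("fit_angular: fixed point on consistent data, perturbed recovery", {
  syn <- generate_trial(22, duration = 1.5, marker_sigma = 0,
                        occlusion = 0)
  truth <- syn$truth
  dt <- 0.01
  Zhat <- truth$com
  Thetahat <- truth$q[, 4:6]
  fx <- fit_angular(truth$skel, truth$q, Zhat, Thetahat, syn$grf,
                    truth$assignment, dt, tol = 1e-6)
  expect_true(fx$converged)
  expect_lte(fx$iterations, 10)
  expect_lt(max(abs(fx$Theta - Thetahat)), 0.01)
  expect_lt(max(abs(fx$xi[7:9] - truth$q[1, 4:6])), 0.5 * pi / 180)
  expect_lt(max(abs(fx$Z - truth$com)), 0.005)
  # perturbed pelvis rotations (<= 3 deg) converge in <= 30 iterations
  q_pert <- truth$q
  set.seed(3)
  T_ <- nrow(q_pert)
  for (j in 4:6)
    q_pert[, j] <- q_pert[, j] +
      (3 * pi / 180) * sin(2 * pi * seq_len(T_) / T_ + runif(1))
  q_pert <- apply_com_trajectory(truth$skel, q_pert, truth$com)
  fx2 <- fit_angular(truth$skel, q_pert, Zhat, Thetahat, syn$grf,
                     truth$assignment, dt, tol = 1e-6)
  expect_true(fx2$converged)
  expect_lte(fx2$iterations, 30)
  expect_lt(sqrt(mean((fx2$Theta - Thetahat)^2)) * 180 / pi, 1)
})

test_that("residual metrics: zero at truth, monotone in mass error", {
  syn <- generate_trial(23, duration = 1.2, marker_sigma = 0,
                        occlusion = 0)
  truth <- syn$truth
  rm0 <- residual_metrics(truth$skel, truth$q, syn$grf,
                          truth$assignment, 0.01)
  expect_lt(rm0$force_pct, 0.05)
  expect_lt(rm0$torque_pct, 0.05)
  heavier <- set_masses(truth$skel, truth$skel$segment_masses * 2)
  rm2 <- residual_metrics(heavier, truth$q, syn$grf,
                          truth$assignment, 0.01)
  expect_gt(rm2$force_rms, rm0$force_rms + 10)
})
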