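# Synthetic trial generator: determinism, noise model, dynamic
# consistency, impulse-momentum balance.

test_that("subject draws: determinism, zero spread, prior support", {
  s1 <- generate_subject(123)
  s2 <- generate_subject(123)
  expect_identical(s1$scales, s2$scales)
  expect_identical(s1$segment_masses, s2$segment_masses)
  expect_identical(marker_offsets(s1), marker_offsets(s2))
  s0 <- generate_subject(5, scale_spread = 0, mass_spread = 0,
                         anatomical_perturb = 0, tracking_perturb = 0)
  nom <- default_skeleton()
  expect_equal(s0$scales, nom$scales)
  expect_equal(s0$segment_masses, nom$segment_masses)
  expect_equal(marker_offsets(s0), marker_offsets(nom))
  # draws stay within the +/- 10% support = 3 sigma of the scale prior
  devs <- sapply(1:200, function(s)
    max(abs(generate_subject(s)$scales - 1)))
  expect_lt(max(devs), 0.3)
  expect_gt(max(devs), 0.05)
  # placement perturbations respect the anatomical/tracking caps
  dp <- marker_offsets(generate_subject(9)) - marker_offsets(nom)
  lim <- ifelse(nom$cmp$marker_anat, 0.005, 0.020)
  expect_true(all(sqrt(colSums(dp^2)) <= lim + 1e-12))
})

test_that("equal seeds give identical trials; noise controls apply", {
  a <- generate_trial(7, duration = 1.2, check_consistency = FALSE)
  b <- generate_trial(7, duration = 1.2, check_consistency = FALSE)
  expect_identical(a$trial$positions, b$trial$positions)
  expect_identical(a$grf$plates[[1]]$force, b$grf$plates[[1]]$force)
  # zero noise reproduces forward kinematics exactly
  c0 <- generate_trial(8, duration = 1.2, marker_sigma = 0,
                       occlusion = 0, check_consistency = FALSE)
  t5 <- 5L
  expect_equal(t(c0$trial$positions[t5, , ]),
               unname(forward_kinematics(c0$truth$skel,
                                         c0$truth$q[t5, ])),
               tolerance = 1e-12)
  expect_true(all(c0$trial$visible))
})

test_that("occlusion rate is honored", {
  syn <- generate_trial(9, duration = 4, occlusion = 0.10,
                        check_consistency = FALSE)
  frac <- mean(syn$trial$visible)
  expect_lt(abs(frac - 0.90), 0.02)
})

test_that("generated trials are dynamically consistent at the truth", {
  for (s in c(41, 42)) {
    syn <- generate_trial(s, duration = 1.5)   # asserts internally too
    rm0 <- residual_metrics(syn$truth$skel, syn$truth$q, syn$grf,
                            syn$truth$assignment, 0.01)
    expect_lt(rm0$force_pct, 0.1)
    expect_lt(rm0$torque_pct, 0.1)
  }
})

test_that("vertical GRF impulse balances weight over whole strides", {
  # cadence 100 -> stride period 1.2 s; use an integer number of strides
  syn <- generate_trial(43, duration = 2.4, marker_sigma = 0,
                        occlusion = 0)
  dt <- 1 / syn$config$frame_rate
  fy <- rowSums(sapply(syn$grf$plates, function(p) p$force[, 2]))
  impulse <- sum(fy) * dt
  expect_lt(abs(impulse / (syn$truth$mass * 9.80665 * 2.4) - 1), 0.01)
})

test_that("cadence doubles the stride frequency of the hip pattern", {
  sk <- generate_subject(44)
  g1 <- generate_gait(sk, duration = 4, cadence = 60)
  g2 <- generate_gait(sk, duration = 4, cadence = 120)
  peak_freq <- function(x, rate) {
    sp <- Mod(stats::fft(x - mean(x)))[2:(length(x) %/% 2)]
    which.max(sp) / (length(x) / rate)
  }
  hip <- match("hip_r_rz", sk$cmp$dof_names)
  f1 <- peak_freq(g1$q[, hip], 100)
  f2 <- peak_freq(g2$q[, hip], 100)
  expect_equal(f2 / f1, 2, tolerance = 0.15)
  expect_equal(f1, 0.5, tolerance = 0.15)   # 60 steps/min = 0.5 strides/s
})

test_that("synthetic trials round-trip through the standard files", {
  syn <- generate_trial(45, duration = 1.2, check_consistency = FALSE)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_trial(syn, dir)
  tr <- read_trc(paths$markers)
  expect_equal(tr$positions[tr$visible], syn$trial$positions[syn$trial$visible],
               tolerance = 1e-6)
  grf <- read_grf_mot(paths$grf)
  expect_equal(grf$plates[[1]]$force, syn$grf$plates[[1]]$force,
               tolerance = 1e-6, ignore_attr = TRUE)
  skel <- read_skeleton_json(paths$truth_skeleton)
  expect_equal(skel$scales, syn$truth$skel$scales, tolerance = 1e-12)
  mot <- read_motion_mot(paths$truth_motion, skel)
  expect_equal(mot$q, syn$truth$q, tolerance = 1e-9, ignore_attr = TRUE)
  # the pipeline-facing skeleton is the generic, unscaled model
  generic <- read_skeleton_json(paths$skeleton)
  expect_equal(unname(generic$scales), matrix(1, 3, 13))
})
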