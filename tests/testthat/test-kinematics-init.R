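# Functional joint centers/axes, scale initialization, inverse kinematics.

# two clusters: a static parent and a child rotating about a known center
rotating_fixture <- function(center = c(0.1, 0.9, 0), T_ = 40,
                             noise = 0, seed = 1, axis_only = FALSE) {
  set.seed(seed)
  angles <- seq(0, 2.2, length.out = T_)
  radii <- c(0.12, 0.18, 0.15, 0.1, 0.2)
  offs <- c(-0.05, 0.02, 0.08, 0.12, -0.1)
  axisA <- c(0.2, 0.3, 1); axisA <- axisA / sqrt(sum(axisA^2))
  child <- hinge_cluster(center, axisA, radii = radii,
                         angles = angles, offsets_along = offs)
  if (!axis_only) {
    # add out-of-plane motion: rotate half the frames about another axis
    axisB <- c(1, -0.2, 0.1); axisB <- axisB / sqrt(sum(axisB^2))
    child2 <- hinge_cluster(center, axisB, radii = radii,
                            angles = angles * 0.8,
                            offsets_along = offs)
    sel <- seq(2, T_, by = 2)
    child[sel, , ] <- child2[sel, , ]
  }
  parent <- array(rep(c(0, 0.6, 0, 0.25, 0.65, 0.1, -0.1, 0.75, -0.15,
                        0.05, 0.9, 0.2), each = T_), c(T_, 4, 3))
  if (noise > 0) {
    child <- child + array(rnorm(length(child), 0, noise), dim(child))
    parent <- parent + array(rnorm(length(parent), 0, noise), dim(parent))
  }
  list(parent = parent, child = child, center = center,
       axis = axisA, T_ = T_)
}

test_that("closed-form joint center: exact, noisy, and degenerate", {
  fx <- rotating_fixture()
  gl <- closed_form_joint_center(fx$parent, fx$child)
  expect_false(gl$degenerate)
  expect_lt(max(abs(gl$centers - matrix(fx$center, fx$T_, 3, TRUE))),
            1e-8)
  # 1 mm noise: center within 5 mm (seeded)
  fxn <- rotating_fixture(noise = 1e-3, seed = 4)
  gln <- closed_form_joint_center(fxn$parent, fxn$child)
  expect_lt(max(sqrt(rowSums(
    (gln$centers - matrix(fx$center, fx$T_, 3, TRUE))^2))), 5e-3)
  # static markers: rank-deficient, flagged
  static <- fx
  static$child <- array(rep(static$child[1, , ], each = fx$T_),
                        dim(static$child))
  expect_true(closed_form_joint_center(static$parent,
                                       static$child)$degenerate)
})

test_that("sphere fit: exact on noise-free rotation, flags T = 1", {
  fx <- rotating_fixture()
  gl <- closed_form_joint_center(fx$parent, fx$child)
  sf <- sphere_fit(fx$child, gl)
  expect_lt(sf$objective, 1e-10)
  expect_lt(max(abs(sf$centers - matrix(fx$center, fx$T_, 3, TRUE))),
            1e-6)
  expect_lte(sf$objective,
             biomechfit:::sphere_objective(
               fx$child, matrix(TRUE, fx$T_, 3), gl$centers, gl$radii))
  one <- sphere_fit(fx$child[1, , , drop = FALSE],
                    list(centers = gl$centers[1, , drop = FALSE],
                         radii = gl$radii, degenerate = TRUE))
  expect_true(one$degenerate || is.na(one$objective))
})

test_that("sphere fit recovers the center under noise and artifact", {
  fx <- rotating_fixture(T_ = 60)
  set.seed(9)
  tt <- seq_len(fx$T_)
  child <- fx$child + array(rnorm(length(fx$child), 0, 1e-3),
                            dim(fx$child))
  child[, 1, 1] <- child[, 1, 1] + 0.005 * sin(2 * pi * tt / 20)
  gl <- closed_form_joint_center(fx$parent, child)
  sf <- sphere_fit(child, gl)
  expect_lte(sf$objective, biomechfit:::sphere_objective(
    child, matrix(TRUE, fx$T_, 5), gl$centers, gl$radii) + 1e-12)
  expect_lt(mean(sqrt(rowSums(
    (sf$centers - matrix(fx$center, fx$T_, 3, TRUE))^2))), 5e-3)
})

test_that("axis fit: recovers a pure hinge and rejects ball motion", {
  fx <- rotating_fixture(axis_only = TRUE)
  gl <- closed_form_joint_center(fx$parent, fx$child)
  sf <- sphere_fit(fx$child, gl)
  ax <- axis_fit(fx$child, sf, sphere_rms = sf$rms_residual)
  expect_true(ax$succeeded)
  expect_lt(ax$objective, 1e-10)
  ang <- acos(pmin(abs(ax$axes %*% fx$axis), 1)) * 180 / pi
  expect_lt(max(ang), 0.5)
  # ball-like motion with large out-of-plane excursion must fail
  fxb <- rotating_fixture(axis_only = FALSE)
  glb <- closed_form_joint_center(fxb$parent, fxb$child)
  sfb <- sphere_fit(fxb$child, glb)
  axb <- axis_fit(fxb$child, sfb, sphere_rms = sfb$rms_residual)
  expect_false(axb$succeeded)
  # selection rule: axis wins iff it succeeded
  expect_equal(select_joint_constraint(sf, ax)$type, "axis")
  expect_equal(select_joint_constraint(sfb, axb)$type, "point")
})

test_that("axis fit still succeeds for a hinge with 1 mm noise", {
  fx <- rotating_fixture(axis_only = TRUE, T_ = 50)
  set.seed(12)
  child <- fx$child + array(rnorm(length(fx$child), 0, 1e-3),
                            dim(fx$child))
  gl <- closed_form_joint_center(fx$parent, child)
  sf <- sphere_fit(child, gl)
  ax <- axis_fit(child, sf, sphere_rms = sf$rms_residual)
  expect_true(ax$succeeded)
  ang <- acos(pmin(abs(ax$axes %*% fx$axis), 1)) * 180 / pi
  expect_lt(mean(ang), 3)
})

test_that("scale initialization: fixed point at s = 1, recovery of 1.1", {
  sk <- chain_skeleton()
  T_ <- 30
  tt <- seq(0, 1, length.out = T_)
  q <- matrix(0, T_, n_dof(sk))
  q[, 2] <- 0.9
  q[, 7] <- 0.6 * sin(2 * pi * tt)
  q[, 8] <- 0.4 * cos(2 * pi * tt)
  q[, 9] <- 0.3 * sin(4 * pi * tt + 1)
  q[, 10] <- 0.8 * sin(2 * pi * tt + 0.5)
  gen_trial <- function(sk_true) {
    pos <- array(0, c(T_, sk_true$cmp$n_markers, 3))
    for (t in seq_len(T_))
      pos[t, , ] <- t(forward_kinematics(sk_true, q[t, ]))
    marker_trial(sk_true$cmp$marker_lab, pos, 100)
  }
  # truth = generic skeleton: s = 1 must be a fixed point
  tr1 <- gen_trial(sk)
  s1 <- initialize_scales(sk, q, list(), tr1)
  expect_lt(max(abs(s1$scales - 1)), 1e-3)
  expect_lte(s1$objective, s1$init_objective)
  # truth scaled uniformly by 1.1: recover within 1%, using the
  # functional joint constraints exactly as the pipeline does
  sk_true <- set_scales(sk, rep(1.1, 3))
  tr2 <- gen_trial(sk_true)
  cons <- functional_joint_constraints(sk, tr2, max_frames = T_)
  expect_gt(length(cons), 0)
  cur <- sk
  qq <- ik_solve(cur, tr2)$q
  for (pass in 1:12) {
    s2 <- initialize_scales(cur, qq, cons, tr2)
    cur <- set_scales(cur, s2$scales)
    qq <- ik_solve(cur, tr2, q_init = qq)$q
  }
  expect_lt(max(abs(s2$scales - 1.1)), 0.011)
})

test_that("inverse kinematics: exact recovery, constant pose, occlusion", {
  sk <- chain_skeleton()
  T_ <- 25
  tt <- seq(0, 1, length.out = T_)
  q <- matrix(0, T_, n_dof(sk))
  q[, 1] <- 0.2 * sin(2 * pi * tt); q[, 2] <- 1 + 0.05 * cos(2 * pi * tt)
  q[, 5] <- 0.3 * sin(2 * pi * tt)
  q[, 7] <- 0.5 * sin(2 * pi * tt + 0.3)
  q[, 10] <- 0.7 * sin(2 * pi * tt + 1)
  pos <- array(0, c(T_, sk$cmp$n_markers, 3))
  for (t in seq_len(T_)) pos[t, , ] <- t(forward_kinematics(sk, q[t, ]))
  tr <- marker_trial(sk$cmp$marker_lab, pos, 100)
  sol <- ik_solve(sk, tr)
  expect_lt(max(abs(sol$q - q)), 1e-3)
  expect_lt(max(sol$rmse), 1e-6)
  # constant pose -> constant solution
  pos_c <- pos
  for (t in seq_len(T_)) pos_c[t, , ] <- pos[1, , ]
  trc <- marker_trial(sk$cmp$marker_lab, pos_c, 100)
  sol_c <- ik_solve(sk, trc)
  expect_lt(max(abs(sweep(sol_c$q, 2, sol_c$q[1, ]))), 1e-6)
  # 20% occlusion: marker fit still well under 1 cm
  set.seed(31)
  vis <- matrix(runif(T_ * sk$cmp$n_markers) > 0.2, T_)
  pos_o <- pos
  for (a in 1:3) pos_o[, , a][!vis] <- NA
  tro <- marker_trial(sk$cmp$marker_lab, pos_o, 100, visible = vis)
  sol_o <- ik_solve(sk, tro)
  expect_lt(mean(sol_o$rmse, na.rm = TRUE), 0.01)
  expect_lt(sqrt(mean((sol_o$q - q)^2)), 0.05)
})

test_that("frames with < 3 visible markers are interpolated, with warning", {
  sk <- chain_skeleton()
  T_ <- 10
  q <- matrix(0, T_, n_dof(sk)); q[, 2] <- seq(0, 0.5, length.out = T_)
  pos <- array(0, c(T_, sk$cmp$n_markers, 3))
  for (t in seq_len(T_)) pos[t, , ] <- t(forward_kinematics(sk, q[t, ]))
  vis <- matrix(TRUE, T_, sk$cmp$n_markers)
  vis[5, -1] <- FALSE
  for (a in 1:3) pos[, , a][!vis] <- NA
  tr <- marker_trial(sk$cmp$marker_lab, pos, 100, visible = vis)
  expect_warning(sol <- ik_solve(sk, tr), "interpolated")
  expect_true(sol$interpolated[5])
  expect_lt(abs(sol$q[5, 2] - q[5, 2]), 1e-3)
})
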