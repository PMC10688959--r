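# Independent oracles and small fixtures used across the test files.
# Everything here is written from first principles (explicit homogeneous
# transforms, finite differences, step-by-step integrators) so that it
# never shares code paths with the package implementation it checks.

# --- small 3-segment chain: free root + ball + revolute -------------------
chain_skeleton <- function(total_mass = 30) {
  segs <- list(
    list(name = "base", nominal_length = c(0.2, 0.3, 0.2),
         nominal_mass_fraction = 0.5, inertia_model = "box",
         com_local = c(0, -0.1, 0)),
    list(name = "mid", nominal_length = c(0.1, 0.35, 0.1),
         nominal_mass_fraction = 0.3, inertia_model = "cylinder",
         com_local = c(0, -0.15, 0)),
    list(name = "tip", nominal_length = c(0.08, 0.3, 0.08),
         nominal_mass_fraction = 0.2, inertia_model = "box",
         com_local = c(0, -0.12, 0)))
  joints <- list(
    list(name = "root", type = "free6", parent_segment = "",
         child_segment = "base", parent_offset_local = c(0, 0, 0),
         child_offset_local = c(0, 0, 0), axis_local = NULL),
    list(name = "j1", type = "ball3", parent_segment = "base",
         child_segment = "mid", parent_offset_local = c(0, -0.3, 0.02),
         child_offset_local = c(0, 0.02, 0), axis_local = NULL),
    list(name = "j2", type = "revolute1", parent_segment = "mid",
         child_segment = "tip", parent_offset_local = c(0, -0.35, 0),
         child_offset_local = c(0, 0, 0), axis_local = c(0, 0, 1)))
  mk <- function(label, seg, off, anat = FALSE)
    list(label = label, segment = seg, offset_local = off,
         anatomical = anat)
  markers <- list(
    mk("B1", "base", c(0.1, 0, 0.1), TRUE),
    mk("B2", "base", c(-0.1, -0.05, 0.1), TRUE),
    mk("B3", "base", c(0, -0.2, -0.1)),
    mk("B4", "base", c(0.08, -0.25, 0)),
    mk("M1", "mid", c(0.05, -0.1, 0), TRUE),
    mk("M2", "mid", c(-0.05, -0.2, 0.04), TRUE),
    mk("M3", "mid", c(0, -0.3, -0.05)),
    mk("T1", "tip", c(0.04, -0.05, 0), TRUE),
    mk("T2", "tip", c(-0.04, -0.2, 0.03), TRUE),
    mk("T3", "tip", c(0, -0.28, -0.03)))
  skeleton(segs, joints, markers, total_mass = total_mass)
}

# --- FK oracle: explicit homogeneous-matrix composition -------------------
# Recomputes every marker position of the chain skeleton by sequentially
# multiplying 4x4 transforms, written independently of the package FK.
hmat <- function(R = diag(3), t = c(0, 0, 0)) {
  H <- diag(4)
  H[1:3, 1:3] <- R
  H[1:3, 4] <- t
  H
}
oracle_rx <- function(a) hmat(matrix(c(1, 0, 0, 0, cos(a), sin(a),
                                       0, -sin(a), cos(a)), 3, 3))
oracle_ry <- function(a) hmat(matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                                       sin(a), 0, cos(a)), 3, 3))
oracle_rz <- function(a) hmat(matrix(c(cos(a), sin(a), 0, -sin(a),
                                       cos(a), 0, 0, 0, 1), 3, 3))
oracle_axis_rot <- function(axis, a) {
  # Rodrigues, written out
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  hmat(diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K)
}

oracle_fk_markers <- function(skel, q) {
  # segment frames for the chain skeleton, by explicit composition
  sc <- skel$scales
  seg_i <- function(nm) match(nm, vapply(skel$segments, `[[`, "", "name"))
  H <- list()
  # root: translate then intrinsic XYZ rotation
  H[["base"]] <- hmat(t = q[1:3]) %*% oracle_rx(q[4]) %*%
    oracle_ry(q[5]) %*% oracle_rz(q[6])
  for (j in skel$joints) {
    if (j$parent_segment == "") next
    Hp <- H[[j$parent_segment]]
    sp <- sc[, seg_i(j$parent_segment)]
    scl <- sc[, seg_i(j$child_segment)]
    Hj <- Hp %*% hmat(t = j$parent_offset_local * sp)
    if (j$type == "ball3") {
      k <- if (j$name == "j1") 7:9 else stop("unexpected joint")
      Hj <- Hj %*% oracle_rx(q[k[1]]) %*% oracle_ry(q[k[2]]) %*%
        oracle_rz(q[k[3]])
    } else {
      Hj <- Hj %*% oracle_axis_rot(j$axis_local, q[10])
    }
    Hj <- Hj %*% hmat(t = -j$child_offset_local * scl)
    H[[j$child_segment]] <- Hj
  }
  out <- sapply(skel$markers, function(m) {
    si <- seg_i(m$segment)
    drop(H[[m$segment]] %*% c(m$offset_local * sc[, si], 1))[1:3]
  })
  colnames(out) <- vapply(skel$markers, `[[`, "", "label")
  out
}

# --- finite-difference marker Jacobians -----------------------------------
fd_marker_jacobians <- function(skel, q, h = 1e-6) {
  f_q <- function(qq) as.numeric(forward_kinematics(skel, qq))
  nq <- length(q)
  Jq <- sapply(seq_len(nq), function(k) {
    e <- numeric(nq); e[k] <- h
    (f_q(q + e) - f_q(q - e)) / (2 * h)
  })
  s0 <- as.numeric(skel$scales)
  Js <- sapply(seq_along(s0), function(k) {
    e <- numeric(length(s0)); e[k] <- h
    a <- as.numeric(forward_kinematics(
      set_scales(skel, matrix(s0 + e, 3)), q))
    b <- as.numeric(forward_kinematics(
      set_scales(skel, matrix(s0 - e, 3)), q))
    (a - b) / (2 * h)
  })
  p0 <- as.numeric(marker_offsets(skel))
  Jp <- sapply(seq_along(p0), function(k) {
    e <- numeric(length(p0)); e[k] <- h
    a <- as.numeric(forward_kinematics(
      set_marker_offsets(skel, matrix(p0 + e, 3)), q))
    b <- as.numeric(forward_kinematics(
      set_marker_offsets(skel, matrix(p0 - e, 3)), q))
    (a - b) / (2 * h)
  })
  list(Jq = Jq, Js = Js, Jp = Jp)
}

# --- mass-matrix oracle: J^T (spatial inertia) J per body -----------------
oracle_mass_matrix <- function(skel, q, h = 1e-6) {
  nq <- length(q)
  cmp <- skel$cmp
  com_of <- function(qq, s) {
    fk <- biomechfit:::forward_kinematics_full(skel, qq)
    drop(fk$xseg[, s] + fk$Rseg[, , s] %*%
           (skel$scales[, s] * cmp$com_local[, s]))
  }
  R_of <- function(qq, s)
    biomechfit:::forward_kinematics_full(skel, qq)$Rseg[, , s]
  M <- matrix(0, nq, nq)
  for (s in seq_len(cmp$S)) {
    Jv <- matrix(0, 3, nq); Jw <- matrix(0, 3, nq)
    R0 <- R_of(q, s)
    for (k in seq_len(nq)) {
      e <- numeric(nq); e[k] <- h
      Jv[, k] <- (com_of(q + e, s) - com_of(q - e, s)) / (2 * h)
      dR <- ((R_of(q + e, s) - R_of(q - e, s)) / (2 * h)) %*% t(R0)
      Jw[, k] <- c(dR[3, 2], dR[1, 3], dR[2, 1])
    }
    m <- skel$segment_masses[s]
    Iw <- R0 %*% biomechfit:::segment_inertia_local(skel, s) %*% t(R0)
    M <- M + t(Jv) %*% (m * Jv) + t(Jw) %*% Iw %*% Jw
  }
  M
}

# --- semi-implicit forward-dynamics integrator ----------------------------
integrate_free <- function(skel, q0, qd0, dt, n_steps, tau = NULL,
                           external = NULL) {
  nq <- length(q0)
  if (is.null(tau)) tau <- numeric(nq)
  q <- q0; qd <- qd0
  for (i in seq_len(n_steps)) {
    qdd <- forward_dynamics(skel, q, qd, tau, external)
    qd <- qd + qdd * dt
    q <- q + qd * dt
  }
  list(q = q, qd = qd)
}

# --- step-by-step COM integrator (oracle for the linear systems) ----------
oracle_com_rollout <- function(zeta, f, dt, g) {
  T_ <- nrow(f)
  z <- matrix(0, T_, 3)
  zt <- zeta[1:3]; vt <- zeta[4:6]; mu <- zeta[7]
  z[1, ] <- zt
  for (t in 2:T_) {
    vt <- vt + (mu * f[t - 1, ] + g) * dt
    zt <- zt + vt * dt
    z[t, ] <- zt
  }
  z
}

# rollout oracle for the linearized angular recursion, using the
# per-frame terms (B, th0, z0) exported by build_angular_system
oracle_angular_rollout <- function(xi, terms, czdd, dt) {
  T_ <- nrow(terms$th0)
  Z <- matrix(0, T_, 3); Th <- matrix(0, T_, 3)
  zt <- xi[1:3]; vz <- xi[4:6]; th <- xi[7:9]; vt <- xi[10:12]
  Z[1, ] <- zt; Th[1, ] <- th
  for (t in 2:T_) {
    thdd <- terms$th0[t - 1, ] +
      drop(terms$B[, , t - 1] %*% (Z[t - 1, ] - terms$z0[t - 1, ]))
    vz <- vz + czdd[t - 1, ] * dt
    zt <- zt + vz * dt
    vt <- vt + thdd * dt
    th <- th + vt * dt
    Z[t, ] <- zt; Th[t, ] <- th
  }
  cbind(Z, Th)
}

# markers rotating rigidly about a center/axis (functional joint fixtures)
hinge_cluster <- function(center, axis, radii, angles, offsets_along) {
  axis <- axis / sqrt(sum(axis^2))
  b1 <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- b1 - axis * sum(axis * b1); b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(axis[2] * b1[3] - axis[3] * b1[2],
          axis[3] * b1[1] - axis[1] * b1[3],
          axis[1] * b1[2] - axis[2] * b1[1])
  T_ <- length(angles); n <- length(radii)
  out <- array(0, c(T_, n, 3))
  for (t in seq_len(T_)) for (i in seq_len(n)) {
    ph <- angles[t] + 2 * pi * i / n
    out[t, i, ] <- center + offsets_along[i] * axis +
      radii[i] * (cos(ph) * b1 + sin(ph) * b2)
  }
  out
}

rand_pose <- function(skel, sd = 0.3) stats::rnorm(n_dof(skel), 0, sd)
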