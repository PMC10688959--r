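# Synthetic walking-trial generator with exact ground truth.
#
# The generator builds a smooth periodic joint trajectory (truncated
# Fourier patterns per coordinate), then *derives* the ground reaction
# forces that make the motion dynamically consistent: at every frame the
# root wrench required to balance the equations of motion (inverse
# dynamics with no external load) is converted to a ground wrench and
# split across the two feet by a smooth stance weight, with the center of
# pressure placed at the stance foot's ground projection and the
# remainder carried by the plate free moment.  Residual forces and
# moments at the true skeleton, masses and kinematics are therefore zero
# by construction (to floating point), emulating a simulated walking
# trial where the answer is known.

#' Draw a ground-truth subject
#'
#' Per-axis segment scales uniform in `1 +/- scale_spread`, total mass
#' uniform in `nominal * (1 +/- mass_spread)` distributed by (optionally
#' perturbed) nominal fractions, and true marker positions displaced from
#' nominal by up to 5 mm (anatomical) / 20 mm (tracking).
#'
#' @param seed integer seed; equal seeds give identical subjects
#' @param scale_spread half-width of the uniform scale draw (default 0.10)
#' @param mass_spread half-width of the relative total mass draw
#' @param base base skeleton (default [default_skeleton()])
#' @param anatomical_perturb,tracking_perturb max marker displacement, m
#' @param fraction_perturb optional named vector of multiplicative
#'   segment mass-fraction perturbations (renormalized to sum 1)
#' @return a `bm_skeleton` with true scales, masses and marker offsets
#' @export
generate_subject <- function(seed, scale_spread = 0.10,
                             mass_spread = 0.10,
                             base = default_skeleton(),
                             anatomical_perturb = 0.005,
                             tracking_perturb = 0.020,
                             fraction_perturb = NULL) {
  set.seed(seed)
  cmp <- base$cmp
  s <- matrix(stats::runif(3L * cmp$S, 1 - scale_spread, 1 + scale_spread),
              3L, cmp$S)
  sk <- set_scales(base, s)
  total <- sum(base$segment_masses) *
    stats::runif(1L, 1 - mass_spread, 1 + mass_spread)
  fr <- vapply(base$segments, `[[`, 0, "nominal_mass_fraction")
  names(fr) <- cmp$seg_names
  if (!is.null(fraction_perturb)) {
    fr[names(fraction_perturb)] <- fr[names(fraction_perturb)] *
      fraction_perturb
    fr <- fr / sum(fr)
  }
  sk <- set_masses(sk, fr * total)
  p <- cmp$marker_off
  lim <- ifelse(cmp$marker_anat, anatomical_perturb, tracking_perturb)
  for (i in seq_len(cmp$n_markers)) {
    dir <- stats::rnorm(3L); dir <- dir / sqrt(sum(dir^2))
    p[, i] <- p[, i] + dir * lim[i] * stats::runif(1L)^(1 / 3)
  }
  set_marker_offsets(sk, p)
}

gait_bump <- function(d, kappa = 3) exp(kappa * (cos(d) - 1))

#' Generate a dynamically consistent walking trial (kinematics + GRF)
#'
#' Walking in place: smooth periodic joint patterns at the given cadence,
#' a pelvis height trajectory that keeps the stance foot just above the
#' ground, and ground reaction forces derived from inverse dynamics so
#' that the trial's residual loads are zero at the truth.
#'
#' @param skel ground-truth skeleton (scales, masses applied)
#' @param duration trial length, seconds
#' @param cadence steps per minute (default 100)
#' @param frame_rate frames per second (default 100)
#' @return list with `q` (T x nq), `grf` (`bm_grf_trial`, 2 plates:
#'   right then left foot), `assignment` (ground-truth plate-foot
#'   assignment), `torques` (T x nq ground-truth generalized forces),
#'   `com` (T x 3), `frame_rate`
#' @export
generate_gait <- function(skel, duration = 5, cadence = 100,
                          frame_rate = 100) {
  cmp <- skel$cmp
  dn <- cmp$dof_names
  for (need in c("hip_r_rz", "knee_r_r", "ankle_r_r", "foot_r"))
    if (!(need %in% c(dn, cmp$seg_names)))
      stop("gait generation needs lower-body joints (missing ", need, ")")
  T_ <- round(duration * frame_rate)
  dt <- 1 / frame_rate
  tt <- (seq_len(T_) - 1L) * dt
  f_stride <- cadence / 120          # strides per second
  phi <- 2 * pi * f_stride * tt
  q <- matrix(0, T_, cmp$nq, dimnames = list(NULL, dn))
  sw_r <- 3 * pi / 2; sw_l <- pi / 2   # swing-phase centers
  set_ <- function(name, v) q[, name] <<- v
  set_("hip_r_rz", 0.05 + 0.28 * cos(phi - sw_r))
  set_("hip_l_rz", 0.05 + 0.28 * cos(phi - sw_l))
  set_("hip_r_rx", 0.04 * sin(phi))
  set_("hip_l_rx", -0.04 * sin(phi))
  set_("hip_r_ry", 0.03 * sin(phi + 0.5))
  set_("hip_l_ry", -0.03 * sin(phi + 0.5))
  set_("knee_r_r", -(0.06 + 0.90 * gait_bump(phi - sw_r)))
  set_("knee_l_r", -(0.06 + 0.90 * gait_bump(phi - sw_l)))
  set_("ankle_r_r", 0.05 + 0.10 * sin(phi - sw_r))
  set_("ankle_l_r", 0.05 + 0.10 * sin(phi - sw_l))
  set_("lumbar_rx", 0.03 * sin(2 * phi))
  set_("lumbar_ry", 0.06 * sin(phi))
  set_("lumbar_rz", 0.02 * sin(2 * phi + 0.4))
  set_("neck_rx", 0.02 * sin(phi + 1))
  set_("neck_ry", -0.03 * sin(phi))
  set_("shoulder_r_rz", -0.22 * cos(phi - sw_r))
  set_("shoulder_l_rz", -0.22 * cos(phi - sw_l))
  set_("shoulder_r_rx", 0.06 * sin(phi + 2))
  set_("shoulder_l_rx", -0.06 * sin(phi + 2))
  set_("shoulder_r_ry", 0.05 * sin(phi + 1))
  set_("shoulder_l_ry", -0.05 * sin(phi + 1))
  set_("elbow_r_r", 0.40 + 0.25 * cos(phi - sw_l))
  set_("elbow_l_r", 0.40 + 0.25 * cos(phi - sw_r))
  set_("root_rx", 0.03 * sin(phi + pi / 2))
  set_("root_ry", 0.05 * sin(phi))
  set_("root_rz", 0.02 * sin(2 * phi))
  set_("root_tx", 0.015 * sin(2 * phi + 0.8))
  set_("root_tz", 0.03 * sin(phi))

  # leg-length discrepancy compensation: a drawn subject can have
  # different effective leg lengths; without compensation the shorter
  # leg never reaches the ground and the gait degenerates to single-leg
  # loading.  Like a human walker, flex the longer leg's knee by the
  # constant angle that equalizes effective lengths (law of cosines).
  sc <- skel$scales
  seg_y <- function(nm) sc[2L, match(nm, cmp$seg_names)]
  a <- stats::setNames(c(0.41 * seg_y("thigh_r"),
                         0.41 * seg_y("thigh_l")), c("r", "l"))
  b <- stats::setNames(c(0.40 * seg_y("shank_r") + 0.08 * seg_y("foot_r"),
                         0.40 * seg_y("shank_l") + 0.08 * seg_y("foot_l")),
                       c("r", "l"))
  l_min <- min(a + b)
  for (side in c("r", "l")) {
    cth <- (l_min^2 - a[side]^2 - b[side]^2) / (2 * a[side] * b[side])
    flex <- acos(max(min(cth, 1), -1))   # 0 for the shortest leg
    # rotate the hip forward by the thigh-to-chord angle so the sole
    # stays vertically under the hip despite the bent knee
    hip_corr <- atan2(b[side] * sin(flex), a[side] + b[side] * cos(flex))
    q[, paste0("knee_", side, "_r")] <-
      q[, paste0("knee_", side, "_r")] - flex
    q[, paste0("hip_", side, "_rz")] <-
      q[, paste0("hip_", side, "_rz")] + hip_corr
  }

  # pelvis height: keep the lower foot at a small clearance via a smooth
  # soft-minimum of the two sole heights computed with the pelvis at 0
  feet <- match(c("foot_r", "foot_l"), cmp$seg_names)
  ylow <- numeric(T_)
  ys <- matrix(0, T_, 2L)
  k_soft <- 60
  for (t in seq_len(T_)) {
    fk <- forward_kinematics_full(skel, q[t, ])
    ys[t, ] <- fk$xseg[2L, feet]
    ylow[t] <- -log(sum(exp(-k_soft * ys[t, ]))) / k_soft
  }
  q[, "root_ty"] <- 0.012 - ylow

  # stance weight on the right foot (1 = right single support): load is
  # transferred smoothly to whichever foot is nearer its own stance
  # floor, so a loaded foot is always close to the ground
  rel <- sweep(ys, 2L, apply(ys, 2L, min))
  w_r <- smoothstep(rel[, 2L] - rel[, 1L], -0.01, 0.01)

  der <- traj_derivatives(q, dt)
  rot <- cmp$root_rot; trn <- cmp$root_trans
  force <- list(matrix(0, T_, 3L), matrix(0, T_, 3L))
  torque <- list(matrix(0, T_, 3L), matrix(0, T_, 3L))
  cop <- list(matrix(0, T_, 3L), matrix(0, T_, 3L))
  torques <- matrix(0, T_, cmp$nq, dimnames = list(NULL, dn))
  com <- matrix(0, T_, 3L)
  for (t in seq_len(T_)) {
    tau <- inverse_dynamics(skel, q[t, ], der$d1[t, ], der$d2[t, ])
    fk <- forward_kinematics_full(skel, q[t, ])
    com[t, ] <- drop(segment_coms(skel, fk) %*%
                       (skel$segment_masses / sum(skel$segment_masses)))
    Fw <- tau[trn]                                  # required world force
    E <- fk$w[, rot]
    m_pelvis <- drop(solve(t(E), tau[rot]))         # moment about pelvis
    xp <- q[t, 1:3]
    w2 <- c(w_r[t], 1 - w_r[t])
    for (k in 1:2) {
      pf <- fk$xseg[, feet[k]]
      cop[[k]][t, ] <- c(pf[1L], 0, pf[3L])
      force[[k]][t, ] <- w2[k] * Fw
      torque[[k]][t, ] <- w2[k] * m_pelvis -
        cross3(cop[[k]][t, ] - xp, force[[k]][t, ])
    }
    exts <- list(
      list(segment = "foot_r", force = force[[1L]][t, ],
           torque = torque[[1L]][t, ], point = cop[[1L]][t, ]),
      list(segment = "foot_l", force = force[[2L]][t, ],
           torque = torque[[2L]][t, ], point = cop[[2L]][t, ]))
    torques[t, ] <- inverse_dynamics(skel, q[t, ], der$d1[t, ],
                                     der$d2[t, ], exts)
  }
  geo <- lapply(1:2, function(k) {
    loaded <- sqrt(rowSums(force[[k]]^2)) > 1
    xs <- cop[[k]][loaded, 1L]; zs <- cop[[k]][loaded, 3L]
    list(xlim = range(xs) + c(-0.15, 0.15),
         zlim = range(zs) + c(-0.08, 0.08))
  })
  plates <- lapply(1:2, function(k)
    list(force = force[[k]], torque = torque[[k]], cop = cop[[k]],
         geometry = geo[[k]]))
  grf <- grf_trial(plates, frame_rate)
  assignment <- matrix(rep(c("foot_r", "foot_l"), each = T_), T_, 2L)
  zero <- vapply(1:2, function(k)
    sqrt(rowSums(force[[k]]^2)) == 0, logical(T_))
  assignment[zero] <- NA_character_
  attr(assignment, "plate_foot") <- c("foot_r", "foot_l")
  list(q = q, grf = grf, assignment = assignment, torques = torques,
       com = com, frame_rate = frame_rate)
}

#' Synthesize a noisy marker trial from ground-truth kinematics
#'
#' Forward-kinematics marker positions plus i.i.d. Gaussian observation
#' noise, optional sinusoidal soft-tissue artifact on thigh/shank
#' tracking markers, and Bernoulli occlusion.
#'
#' @param skel ground-truth skeleton
#' @param q T x nq ground-truth trajectory
#' @param frame_rate frames per second
#' @param marker_sigma Gaussian noise SD per axis, m (default 1.5 mm)
#' @param occlusion per-(frame, marker) occlusion probability
#' @param soft_tissue_amp,soft_tissue_freq artifact amplitude (m) and
#'   frequency (Hz); amplitude 0 disables it
#' @param seed integer seed
#' @return a `bm_marker_trial`
#' @export
synthesize_markers <- function(skel, q, frame_rate,
                               marker_sigma = 0.0015, occlusion = 0.02,
                               soft_tissue_amp = 0,
                               soft_tissue_freq = 6, seed = 1L) {
  set.seed(seed + 7L)
  cmp <- skel$cmp
  T_ <- nrow(q)
  M <- cmp$n_markers
  pos <- array(0, c(T_, M, 3L))
  for (t in seq_len(T_))
    pos[t, , ] <- t(forward_kinematics_full(skel, q[t, ])$markers)
  if (marker_sigma > 0)
    pos <- pos + array(stats::rnorm(length(pos), 0, marker_sigma),
                       dim(pos))
  if (soft_tissue_amp > 0) {
    soft <- which(!cmp$marker_anat &
                    grepl("^(thigh|shank)", cmp$seg_names[cmp$marker_seg]))
    tt <- (seq_len(T_) - 1L) / frame_rate
    for (i in soft) {
      ph <- stats::runif(3L, 0, 2 * pi)
      for (a in 1:3)
        pos[, i, a] <- pos[, i, a] +
          soft_tissue_amp * sin(2 * pi * soft_tissue_freq * tt + ph[a])
    }
  }
  visible <- matrix(stats::runif(T_ * M) >= occlusion, T_, M)
  for (a in 1:3) pos[, , a][!visible] <- NA_real_
  marker_trial(cmp$marker_lab, pos, frame_rate, visible = visible)
}

#' Generate a complete synthetic walking trial with ground truth
#'
#' @param seed integer seed controlling every random draw
#' @param duration seconds (default 5, ~500 frames at 100 Hz)
#' @param frame_rate Hz
#' @param cadence steps per minute
#' @param scale_spread,mass_spread subject draw spreads
#' @param marker_sigma,occlusion,soft_tissue_amp noise configuration
#' @param fraction_perturb optional mass-fraction perturbation (see
#'   [generate_subject()])
#' @param check_consistency assert that normalized residuals at the truth
#'   are below 0.1% (on by default)
#' @return list with `trial` (`bm_marker_trial`), `grf`, `truth` (list:
#'   `skel`, `q`, `torques`, `assignment`, `com`, `mass`), `config`
#' @export
generate_trial <- function(seed, duration = 5, frame_rate = 100,
                           cadence = 100, scale_spread = 0.10,
                           mass_spread = 0.10, marker_sigma = 0.0015,
                           occlusion = 0.02, soft_tissue_amp = 0,
                           fraction_perturb = NULL,
                           check_consistency = TRUE) {
  skel <- generate_subject(seed, scale_spread, mass_spread,
                           fraction_perturb = fraction_perturb)
  gait <- generate_gait(skel, duration = duration, cadence = cadence,
                        frame_rate = frame_rate)
  trial <- synthesize_markers(skel, gait$q, frame_rate,
                              marker_sigma = marker_sigma,
                              occlusion = occlusion,
                              soft_tissue_amp = soft_tissue_amp,
                              seed = seed)
  if (check_consistency) {
    rm_ <- residual_metrics(skel, gait$q, gait$grf, gait$assignment,
                            1 / frame_rate)
    if (rm_$force_pct > 0.1 || rm_$torque_pct > 0.1)
      stop(sprintf(
        "generated trial is not dynamically consistent (%.3g%% / %.3g%%)",
        rm_$force_pct, rm_$torque_pct))
  }
  list(trial = trial, grf = gait$grf,
       truth = list(skel = skel, q = gait$q, torques = gait$torques,
                    assignment = gait$assignment, com = gait$com,
                    mass = sum(skel$segment_masses)),
       config = list(seed = seed, duration = duration,
                     frame_rate = frame_rate, cadence = cadence,
                     scale_spread = scale_spread,
                     mass_spread = mass_spread,
                     marker_sigma = marker_sigma, occlusion = occlusion,
                     soft_tissue_amp = soft_tissue_amp))
}

#' Write a synthetic trial to standard files
#'
#' TRC markers, MOT ground reaction forces, skeleton JSON (the *generic*
#' unscaled model the pipeline should start from), and a ground-truth
#' sidecar JSON (scales, masses, joint angles file, plate geometry).
#'
#' @param syn result of [generate_trial()]
#' @param dir output directory (created if needed)
#' @return invisibly, the list of written paths
#' @export
write_synthetic_trial <- function(syn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    markers = file.path(dir, "markers.trc"),
    grf = file.path(dir, "grf.mot"),
    skeleton = file.path(dir, "skeleton.json"),
    truth_skeleton = file.path(dir, "truth_skeleton.json"),
    truth_motion = file.path(dir, "truth_motion.mot"),
    truth = file.path(dir, "truth.json"))
  write_trc(syn$trial, paths$markers)
  write_grf_mot(syn$grf, paths$grf)
  write_skeleton_json(default_skeleton(), paths$skeleton)
  write_skeleton_json(syn$truth$skel, paths$truth_skeleton)
  write_motion_mot(syn$truth$q, syn$truth$skel,
                   syn$config$frame_rate, paths$truth_motion)
  jsonlite::write_json(list(
    config = syn$config, mass = syn$truth$mass,
    scales = as.numeric(syn$truth$skel$scales),
    segment_masses = as.numeric(syn$truth$skel$segment_masses),
    plate_geometry = lapply(syn$grf$plates, `[[`, "geometry")),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
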