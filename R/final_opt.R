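# Final tuning stage: distribute segment masses (and re-consolidate the
# root trajectory) to minimize residual loads while keeping the marker
# fit.  The root residual wrench is exactly linear in the segment masses
# (inertia scales with mass under the box/cylinder models), so the mass
# update is a ridge least-squares problem with Gaussian priors pulling
# the fractions toward the segment nominals and the total toward the
# linear COM-fit mass; the root trajectory is then re-fit with the new
# mass distribution.

# per-frame residual basis: res_root(t) = Psi(t) %*% masses - Qext_root(t)
residual_mass_basis <- function(skel, q, qd, qdd, exts_by_frame, frames) {
  cmp <- skel$cmp
  rot <- cmp$root_rot; trn <- cmp$root_trans
  S <- cmp$S
  g <- skel$gravity
  Psi <- vector("list", length(frames))
  Qr <- matrix(0, length(frames), 6L)
  for (k in seq_along(frames)) {
    t <- frames[k]
    bk <- body_kinematics(skel, q[t, ], qd[t, ], qdd[t, ])
    P <- matrix(0, 6L, S)
    for (s in seq_len(S)) {
      f_unit <- bk$acom[, s] - g
      Iu <- bk$fk$Rseg[, , s] %*%
        (seg_inertia(skel, s) / skel$segment_masses[s]) %*%
        t(bk$fk$Rseg[, , s])
      n_unit <- drop(Iu %*% bk$al_s[, s]) +
        cross3(bk$om_s[, s], drop(Iu %*% bk$om_s[, s]))
      P[1:3, s] <- f_unit
      for (j in seq_along(rot)) {
        d <- rot[j]
        P[3L + j, s] <- sum(bk$fk$w[, d] *
                              (n_unit + cross3(bk$com[, s] - bk$fk$x[, d],
                                               f_unit)))
      }
    }
    Psi[[k]] <- P
    Qe <- generalized_ext_forces(skel, bk$fk, exts_by_frame[[t]])
    Qr[k, ] <- c(Qe[trn], Qe[rot])
  }
  list(Psi = Psi, Qr = Qr)
}

#' Final optimization: segment masses and root trajectory
#'
#' Minimizes the negative-log joint objective (marker fit, scale and
#' marker priors, Gaussian residual-wrench penalty, mass priors) over the
#' per-segment masses, exploiting that the residual wrench is linear in
#' the masses; then re-runs the iterative angular fit so the root
#' trajectory stays consistent with the new mass distribution.  Scales
#' and marker offsets are held at their marker-fit values (see the
#' package vignette for the rationale).
#'
#' @param skel skeleton after the COM fit (masses = nominal fractions
#'   times the fitted total mass)
#' @param q T x nq trajectory after the angular fit
#' @param q_smooth jerk-smoothed kinematic trajectory (source of the
#'   observed COM / root-rotation targets)
#' @param trial a `bm_marker_trial`
#' @param grf a `bm_grf_trial` at marker rate
#' @param assignment plate-to-foot assignment
#' @param fit_mass total mass from the linear COM fit, kg
#' @param priors a `bm_priors`
#' @param max_frames frame subsample for the mass system (default 150)
#' @param refit_angular re-run the angular fit after the mass update
#' @return list with `skel` (masses updated), `q`, `segment_masses`,
#'   `total_mass`, `objective`, `objective_init`, residual metrics before
#'   and after
#' @export
final_fit <- function(skel, q, q_smooth, trial, grf, assignment,
                      fit_mass, priors = default_priors(),
                      max_frames = 150L, refit_angular = TRUE) {
  cmp <- skel$cmp
  T_ <- nrow(q)
  dt <- trial$dt
  der <- traj_derivatives(q, dt)
  exts <- lapply(seq_len(T_), function(t)
    grf_external_wrenches(grf, assignment, t))
  interior <- 2:(T_ - 1L)
  frames <- interior[unique(round(seq(1L, length(interior),
                                      length.out = min(length(interior),
                                                       max_frames))))]
  basis <- residual_mass_basis(skel, q, der$d1, der$d2, exts, frames)

  S <- cmp$S
  wf <- 1 / priors$residual_force_sigma
  wt <- 1 / priors$residual_torque_sigma
  rw <- rep(c(wf, wf, wf, wt, wt, wt), length(frames))
  A <- do.call(rbind, basis$Psi) * rw
  y <- as.numeric(t(basis$Qr)) * rw
  fr <- vapply(skel$segments, `[[`, 0, "nominal_mass_fraction")
  A <- rbind(A, diag(1 / (priors$mass_fraction_sigma * fit_mass), S),
             matrix(1 / priors$total_mass_sigma, 1L, S))
  y <- c(y, fr * fit_mass / (priors$mass_fraction_sigma * fit_mass),
         fit_mass / priors$total_mass_sigma)
  m_new <- drop(solve(crossprod(A), crossprod(A, y)))
  low <- m_new < 0.5
  if (any(low)) {
    warning("clamping ", sum(low), " segment masses at 0.5 kg")
    m_new[low] <- 0.5
  }

  eval_obj <- function(sk, qq) {
    d2 <- traj_derivatives(qq, dt)
    res <- 0
    for (t in frames) {
      tau <- inverse_dynamics(sk, qq[t, ], d2$d1[t, ], d2$d2[t, ],
                              exts[[t]])
      res <- res + sum((tau[cmp$root_trans] * wf)^2) / 2 +
        sum((tau[cmp$root_rot] * wt)^2) / 2
    }
    mk <- marker_error_metrics(sk, qq[frames, , drop = FALSE],
                               subset_trial_frames(trial, frames))
    nvis <- sum(trial$visible[frames, ])
    res + nvis * mk$rmse^2 / (2 * priors$marker_obs_sigma^2) +
      sum((sk$segment_masses - fr * fit_mass)^2) /
        (2 * (priors$mass_fraction_sigma * fit_mass)^2) +
      (sum(sk$segment_masses) - fit_mass)^2 /
        (2 * priors$total_mass_sigma^2)
  }
  obj0 <- eval_obj(skel, q)
  res0 <- residual_metrics(skel, q, grf, assignment, dt)

  # mass step: the ridge solve minimizes the residual + mass-prior terms
  # exactly (marker terms do not depend on m), so the objective cannot
  # increase unless clamping interfered -- guard anyway
  skel2 <- set_masses(skel, m_new)
  obj_m <- eval_obj(skel2, q)
  if (obj_m > obj0) { skel2 <- skel; obj_m <- obj0 }
  # root-trajectory step: re-fit the angular dynamics under the new mass
  # distribution; accept only if the joint objective does not get worse
  q2 <- q
  ang <- NULL
  obj1 <- obj_m
  if (refit_angular) {
    Zhat <- com_position(skel2, q_smooth)
    Thetahat <- q_smooth[, cmp$root_rot, drop = FALSE]
    ang <- fit_angular(skel2, q2, Zhat, Thetahat, grf, assignment, dt,
                       max_iter = 25L)
    obj_q <- eval_obj(skel2, ang$q)
    if (obj_q <= obj_m) { q2 <- ang$q; obj1 <- obj_q }
  }
  res1 <- residual_metrics(skel2, q2, grf, assignment, dt)
  list(skel = skel2, q = q2,
       segment_masses = skel2$segment_masses,
       total_mass = sum(skel2$segment_masses),
       objective = obj1, objective_init = obj0,
       residual_before = res0, residual_after = res1,
       angular = ang)
}

# view of a trial restricted to the given frames (cheap, used for metrics)
subset_trial_frames <- function(trial, frames) {
  marker_trial(trial$labels,
               trial$positions[frames, , , drop = FALSE],
               trial$frame_rate,
               visible = trial$visible[frames, , drop = FALSE])
}

#' Joint torque trajectories
#'
#' Generalized forces from inverse dynamics along the trajectory: root
#' rows are the residual wrench, the remaining rows are net joint
#' torques.  Optionally normalized by body weight times height (percent).
#'
#' @param skel fitted skeleton
#' @param q T x nq trajectory
#' @param grf a `bm_grf_trial` at marker rate (NULL: no external loads)
#' @param assignment plate-to-foot assignment
#' @param dt frame interval
#' @param normalize if TRUE, divide by `m g h` and express as percent
#' @return T x nq matrix of generalized forces (N m, or % BW x height)
#' @export
joint_torques <- function(skel, q, grf = NULL, assignment = NULL, dt,
                          normalize = FALSE) {
  T_ <- nrow(q)
  der <- traj_derivatives(q, dt)
  out <- matrix(0, T_, skel$cmp$nq,
                dimnames = list(NULL, skel$cmp$dof_names))
  for (t in seq_len(T_)) {
    exts <- if (!is.null(grf)) grf_external_wrenches(grf, assignment, t)
    out[t, ] <- inverse_dynamics(skel, q[t, ], der$d1[t, ], der$d2[t, ],
                                 exts)
  }
  if (normalize) {
    bwh <- sum(skel$segment_masses) * 9.80665 * skeleton_height(skel)
    out <- 100 * out / bwh
  }
  out
}
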