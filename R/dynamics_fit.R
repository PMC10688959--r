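# Dynamics fitting: jerk smoothing of the kinematic solution, the linear
# center-of-mass/mass fit against the measured ground reaction forces,
# the iteratively re-linearized angular (root rotation) fit, and residual
# load metrics.
#
# Both linear systems are built around the semi-explicit Euler scheme
#   vdot_{t+1} = vdot_t + a_t * dt ;  x_{t+1} = x_t + vdot_{t+1} * dt
# so a trajectory reconstructed from fitted initial conditions satisfies
# the discrete dynamics exactly, by construction.

#' Jerk smoothing of a joint trajectory
#'
#' Per-coordinate minimizer of `||q - q_in||^2 + w ||D3 q||^2`, where `D3`
#' is the raw third-order finite-difference operator (null space:
#' quadratic trajectories, which pass through unchanged).  The default
#' weight places the half-power cutoff at `cutoff_hz`, independent of
#' frame rate.
#'
#' @param q T x n matrix (T >= 4)
#' @param dt frame interval, seconds
#' @param weight penalty weight on the raw third difference; overrides
#'   `cutoff_hz` when given
#' @param cutoff_hz target cutoff frequency of the implied low-pass
#'   (default 6 Hz, suited to gait)
#' @return smoothed T x n matrix
#' @export
smooth_jerk <- function(q, dt, weight = NULL, cutoff_hz = 6) {
  q <- as.matrix(q)
  T_ <- nrow(q)
  if (T_ < 4L) stop("jerk smoothing needs at least 4 frames")
  if (is.null(weight)) weight <- (2 * pi * cutoff_hz * dt)^-6
  D <- matrix(0, T_ - 3L, T_)
  for (t in seq_len(T_ - 3L))
    D[t, t:(t + 3L)] <- c(-1, 3, -3, 1)
  Hm <- diag(T_) + weight * crossprod(D)
  ch <- chol(Hm)
  backsolve(ch, forwardsolve(t(ch), q))
}

#' Build the linear center-of-mass system
#'
#' Maps the unknowns `zeta = (z1, zdot1, mu)` (initial COM position,
#' initial COM velocity, inverse mass) onto the stacked COM trajectory
#' `Z = A zeta + b` under semi-explicit Euler integration of
#' `zddot = mu f + g`.
#'
#' @param f T x 3 total ground reaction force, N, world frame
#' @param dt frame interval, seconds
#' @param g gravity 3-vector, m/s^2
#' @return list with `A` (3T x 7) and `b` (3T)
#' @export
build_com_system <- function(f, dt, g = c(0, -9.80665, 0)) {
  f <- as.matrix(f)
  T_ <- nrow(f)
  if (T_ < 2L) stop("need at least 2 frames")
  A <- matrix(0, 3L * T_, 7L)
  b <- numeric(3L * T_)
  # sum_{i<t} (t-i) f_i computed from cumulative sums
  S1 <- apply(f, 2L, cumsum)
  S2 <- apply(f * seq_len(T_), 2L, cumsum)
  for (t in seq_len(T_)) {
    r <- (3L * (t - 1L) + 1L):(3L * t)
    A[r, 1:3] <- diag(3L)
    A[r, 4:6] <- (t - 1L) * dt * diag(3L)
    if (t > 1L) {
      A[r, 7L] <- dt^2 * (t * S1[t - 1L, ] - S2[t - 1L, ])
      b[r] <- dt^2 * sum(seq_len(t - 1L)) * g
    }
  }
  list(A = A, b = b)
}

#' Least-squares fit of mass and initial COM state
#'
#' Minimum-norm pseudo-inverse solution `zeta = A^+ (Zhat - b)` of the
#' linear COM system, giving the total mass (1/mu) and a ground-force
#' consistent COM trajectory `Z = A zeta + b`.
#'
#' @param Zhat T x 3 observed COM trajectory from the kinematic fit, m
#' @param f T x 3 total ground reaction force, N
#' @param dt frame interval, seconds
#' @param g gravity vector
#' @param fallback_mass mass used if `mu` comes back non-positive
#'   (structurally unidentifiable, e.g. a flight-only trial)
#' @return list with `z1`, `zdot1`, `mu`, `mass`, `Z` (T x 3), `rmse`,
#'   `degenerate`
#' @export
fit_com <- function(Zhat, f, dt, g = c(0, -9.80665, 0),
                    fallback_mass = 72.5) {
  sys <- build_com_system(f, dt, g)
  zhat <- as.numeric(t(Zhat))
  zeta <- pinv_solve(sys$A, zhat - sys$b)
  mu <- zeta[7L]
  degenerate <- !(mu > 1e-8)
  if (degenerate) {
    warning("inverse mass not identifiable from this trial; ",
            "falling back to prior mass ", fallback_mass, " kg")
    mass <- fallback_mass
    zeta[7L] <- 1 / mass
  } else mass <- 1 / mu
  Z <- matrix(sys$A %*% zeta + sys$b, ncol = 3L, byrow = TRUE)
  list(z1 = zeta[1:3], zdot1 = zeta[4:6], mu = zeta[7L], mass = mass,
       Z = Z, rmse = sqrt(mean((Z - Zhat)^2) * 3),
       degenerate = degenerate)
}

#' Translate the pelvis so the model COM tracks a target trajectory
#'
#' The whole-body COM shifts one-for-one with root translation, so the
#' update is exact and leaves all other coordinates fixed.
#'
#' @param skel a `bm_skeleton`
#' @param q T x nq trajectory
#' @param Z T x 3 target COM positions
#' @return updated trajectory
#' @export
apply_com_trajectory <- function(skel, q, Z) {
  com <- com_position(skel, q)
  q[, 1:3] <- q[, 1:3] + (Z - com)
  q
}

# generalized external forces Q_ext (length nq) from a wrench list
generalized_ext_forces <- function(skel, fk, exts) {
  cmp <- skel$cmp
  Q <- numeric(cmp$nq)
  if (!length(exts)) return(Q)
  exts <- resolve_external(skel, exts)
  for (e in exts) {
    s <- e$segment
    for (d in which(cmp$anc[, s])) {
      w <- fk$w[, d]
      if (cmp$type[d] == "p") {
        Q[d] <- Q[d] + sum(w * e$force)
      } else {
        Q[d] <- Q[d] + sum(w * (cross3(e$point - fk$x[, d], e$force) +
                                  e$torque))
      }
    }
  }
  Q
}

# Per-frame quantities for the angular fit at the current trajectory:
# B_t (3x3 response of root-rotation acceleration to a COM shift),
# theta0dd_t (nominal root-rotation acceleration from the equations of
# motion with non-root accelerations held), z0_t (current COM).
angular_frame_terms <- function(skel, q, qd, qdd, exts_by_frame) {
  T_ <- nrow(q)
  cmp <- skel$cmp
  rot <- cmp$root_rot
  B <- array(0, c(3L, 3L, T_))
  th0 <- matrix(0, T_, 3L)
  z0 <- matrix(0, T_, 3L)
  m <- skel$segment_masses
  for (t in seq_len(T_)) {
    fk <- forward_kinematics_full(skel, q[t, ])
    M <- mass_matrix(skel, q[t, ], fk = fk)
    cg <- inverse_dynamics(skel, q[t, ], qd[t, ], numeric(cmp$nq),
                           fk = fk)
    Qe <- generalized_ext_forces(skel, fk, exts_by_frame[[t]])
    Mrr <- M[rot, rot]
    oth <- setdiff(seq_len(cmp$nq), rot)
    rhs <- Qe[rot] - cg[rot] - drop(M[rot, oth] %*% qdd[t, oth])
    Mrr_inv <- solve(Mrr)
    th0[t, ] <- drop(Mrr_inv %*% rhs)
    E <- fk$w[, rot]                 # 3x3, columns = world Euler axes
    ftot <- Reduce(`+`, lapply(exts_by_frame[[t]],
                               function(e) e$force), numeric(3L))
    B[, , t] <- Mrr_inv %*% t(E) %*% skew3(ftot)
    z0[t, ] <- drop(segment_coms(skel, fk) %*% (m / sum(m)))
  }
  list(B = B, th0 = th0, z0 = z0)
}

#' Build the linearized angular dynamics system
#'
#' Maps `xi = (z1, zdot1, theta1, thetadot1)` onto the stacked trajectory
#' `Xi = [Z; Theta] = Atil xi + btil`, where root-rotation accelerations
#' respond linearly to COM displacement (ground reaction forces act at
#' fixed centers of pressure) and the mass matrix, Coriolis and gravity
#' terms are frozen at the current trajectory.  The upper-left quadrant
#' reproduces the first two column blocks of the COM system; the upper
#' right quadrant is zero.
#'
#' @param skel skeleton with fitted masses applied
#' @param q T x nq current trajectory
#' @param grf a `bm_grf_trial` at marker rate
#' @param assignment plate-to-foot assignment
#' @param dt frame interval, seconds
#' @param mass total mass used for the COM rows (default: skeleton mass)
#' @return list with `Atil` (6T x 12), `btil` (6T), plus the per-frame
#'   linearization terms
#' @export
build_angular_system <- function(skel, q, grf, assignment, dt,
                                 mass = NULL) {
  T_ <- nrow(q)
  if (is.null(mass)) mass <- sum(skel$segment_masses)
  der <- traj_derivatives(q, dt)
  exts <- lapply(seq_len(T_), function(t)
    grf_external_wrenches(grf, assignment, t))
  f_tot <- t(vapply(seq_len(T_), function(t)
    Reduce(`+`, lapply(exts[[t]], function(e) e$force), numeric(3L)),
    numeric(3L)))
  terms <- angular_frame_terms(skel, q, der$d1, der$d2, exts)
  g <- skel$gravity

  Atil <- matrix(0, 6L * T_, 12L)
  btil <- numeric(6L * T_)
  zr <- function(t) (3L * (t - 1L) + 1L):(3L * t)
  tr <- function(t) 3L * T_ + zr(t)

  # COM rows: identical to the first two column blocks of the COM system;
  # the force/gravity integrals (with mass fixed) go into btil.
  czdd <- f_tot / mass + matrix(g, T_, 3L, byrow = TRUE)
  I3 <- diag(3L)
  # running sums for sum_{i<t} (t-i) x_i
  s1z <- matrix(0, 1L, 3L); s2z <- matrix(0, 1L, 3L)
  cum1 <- function(X) apply(X, 2L, cumsum)
  S1z <- cum1(czdd); S2z <- cum1(czdd * seq_len(T_))
  for (t in seq_len(T_)) {
    Atil[zr(t), 1:3] <- I3
    Atil[zr(t), 4:6] <- (t - 1L) * dt * I3
    if (t > 1L)
      btil[zr(t)] <- dt^2 * (t * S1z[t - 1L, ] - S2z[t - 1L, ])
  }
  bz <- matrix(btil[seq_len(3L * T_)], ncol = 3L, byrow = TRUE)

  # rotation rows: theta_t = theta1 + (t-1) dt thetadot1
  #   + dt^2 sum_{i<t} (t-i) [th0_i + B_i (z_i - z0_i)],  z_i from the rows
  # above.  Accumulate the (t-i)-weighted sums incrementally.
  SB <- matrix(0, 3L, 3L);  SBt <- matrix(0, 3L, 3L)   # sum B, sum t*B
  SBi <- matrix(0, 3L, 3L); SBti <- matrix(0, 3L, 3L)  # sum (i-1)B etc.
  sc <- numeric(3L); sct <- numeric(3L)                # constant parts
  for (t in seq_len(T_)) {
    Atil[tr(t), 7:9] <- I3
    Atil[tr(t), 10:12] <- (t - 1L) * dt * I3
    if (t > 1L) {
      Atil[tr(t), 1:3] <- dt^2 * (t * SB - SBt)
      Atil[tr(t), 4:6] <- dt^3 * (t * SBi - SBti)
      btil[tr(t)] <- dt^2 * (t * sc - sct)
    }
    Bt <- terms$B[, , t]
    cpart <- terms$th0[t, ] + drop(Bt %*% (bz[t, ] - terms$z0[t, ]))
    SB <- SB + Bt;            SBt <- SBt + t * Bt
    SBi <- SBi + (t - 1L) * Bt; SBti <- SBti + t * (t - 1L) * Bt
    sc <- sc + cpart;         sct <- sct + t * cpart
  }
  list(Atil = Atil, btil = btil, terms = terms, mass = mass,
       f_tot = f_tot, dt = dt)
}

#' Iteratively re-linearized angular dynamics fit
#'
#' Repeats: assemble the linearized system at the current trajectory,
#' solve `xi = Atil^+ (Xihat - btil)`, reconstruct `Xi = Atil xi + btil`,
#' and write the root rotations and COM-tracking root translations back
#' into the trajectory, until the reconstructed trajectory stops changing.
#'
#' @param skel skeleton with fitted masses
#' @param q T x nq trajectory (after jerk smoothing and the COM update)
#' @param Zhat,Thetahat T x 3 observed COM positions and root rotations
#'   (from the smoothed kinematic solution)
#' @param grf a `bm_grf_trial` at marker rate
#' @param assignment plate-to-foot assignment
#' @param dt frame interval
#' @param mass total mass (default: skeleton mass)
#' @param tol max-norm convergence tolerance on the reconstructed
#'   trajectory (m and rad)
#' @param max_iter outer re-linearization cap
#' @return list with updated `q`, `Z`, `Theta`, `xi`, `iterations`,
#'   `converged`
#' @export
fit_angular <- function(skel, q, Zhat, Thetahat, grf, assignment, dt,
                        mass = NULL, tol = 1e-6, max_iter = 50L) {
  T_ <- nrow(q)
  rot <- skel$cmp$root_rot
  xihat <- c(as.numeric(t(Zhat)), as.numeric(t(Thetahat)))
  Xi_prev <- c(as.numeric(t(com_position(skel, q))),
               as.numeric(t(q[, rot])))
  iterations <- 0L
  converged <- FALSE
  xi <- NULL
  for (it in seq_len(max_iter)) {
    iterations <- it
    sys <- build_angular_system(skel, q, grf, assignment, dt, mass)
    xi <- pinv_solve(sys$Atil, xihat - sys$btil)
    Xi <- drop(sys$Atil %*% xi + sys$btil)
    Z <- matrix(Xi[seq_len(3L * T_)], ncol = 3L, byrow = TRUE)
    Theta <- matrix(Xi[-seq_len(3L * T_)], ncol = 3L, byrow = TRUE)
    q[, rot] <- Theta
    q <- apply_com_trajectory(skel, q, Z)
    dXi <- max(abs(Xi - Xi_prev))
    Xi_prev <- Xi
    if (dXi < tol) { converged <- TRUE; break }
  }
  list(q = q, Z = matrix(Xi_prev[seq_len(3L * T_)], ncol = 3L,
                         byrow = TRUE),
       Theta = matrix(Xi_prev[-seq_len(3L * T_)], ncol = 3L,
                      byrow = TRUE),
       xi = xi, iterations = iterations, converged = converged)
}

#' Residual load metrics
#'
#' Root residual wrench trajectory from inverse dynamics with
#' finite-difference accelerations, its RMS magnitudes, and the
#' conventional normalizations: residual force as a percent of peak
#' ground reaction force; residual torque as a percent of peak ground
#' reaction force times average center of mass height.  The two endpoint
#' frames (one-sided differences) are excluded from the RMS.
#'
#' @param skel skeleton with masses applied
#' @param q T x nq trajectory
#' @param grf a `bm_grf_trial` at marker rate
#' @param assignment plate-to-foot assignment
#' @param dt frame interval
#' @return list with `force_rms` (N), `torque_rms` (N m), `force_pct`,
#'   `torque_pct`, and per-frame `force`, `torque` trajectories
#' @export
residual_metrics <- function(skel, q, grf, assignment, dt) {
  T_ <- nrow(q)
  der <- traj_derivatives(q, dt)
  rot <- skel$cmp$root_rot
  trn <- skel$cmp$root_trans
  force <- matrix(NA_real_, T_, 3L)
  torque <- matrix(NA_real_, T_, 3L)
  fmag <- numeric(T_)
  for (t in seq_len(T_)) {
    exts <- grf_external_wrenches(grf, assignment, t)
    tau <- inverse_dynamics(skel, q[t, ], der$d1[t, ], der$d2[t, ], exts)
    fk <- forward_kinematics_full(skel, q[t, ])
    E <- fk$w[, rot]
    force[t, ] <- tau[trn]
    torque[t, ] <- drop(solve(t(E), tau[rot]))   # world-frame moment
    fmag[t] <- sqrt(sum(Reduce(`+`, lapply(exts, function(e) e$force),
                               numeric(3L))^2))
  }
  keep <- if (T_ > 4L) 2:(T_ - 1L) else seq_len(T_)
  frms <- sqrt(mean(rowSums(force[keep, , drop = FALSE]^2)))
  trms <- sqrt(mean(rowSums(torque[keep, , drop = FALSE]^2)))
  peak <- max(fmag)
  comh <- mean(com_position(skel, q)[, 2L])
  list(force_rms = frms, torque_rms = trms,
       force_pct = 100 * frms / peak,
       torque_pct = 100 * trms / (peak * comh),
       peak_grf = peak, com_height = comh,
       force = force, torque = torque)
}
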