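# Rigid-body dynamics: velocity/acceleration propagation, Newton-Euler
# inverse dynamics, composite-rigid-body mass matrix, and a forward
# dynamics helper used mainly for verification.

# Propagate velocities/accelerations down the element chain.
# Returns per-element angular velocity/acceleration and linear
# velocity/acceleration of the element origin, plus per-segment COM
# position/velocity/acceleration and angular terms.
body_kinematics <- function(skel, q, qd, qdd, fk = NULL) {
  cmp <- skel$cmp
  if (is.null(fk)) fk <- forward_kinematics_full(skel, q)
  E <- cmp$E
  om <- matrix(0, 3L, E); al <- matrix(0, 3L, E)
  vv <- matrix(0, 3L, E); aa <- matrix(0, 3L, E)
  for (e in seq_len(E)) {
    p <- cmp$parent[e]
    if (p == 0L) {
      om_p <- c(0, 0, 0); al_p <- c(0, 0, 0)
      v_p <- c(0, 0, 0); a_p <- c(0, 0, 0); x_p <- c(0, 0, 0)
    } else {
      om_p <- om[, p]; al_p <- al[, p]
      v_p <- vv[, p]; a_p <- aa[, p]; x_p <- fk$x[, p]
    }
    r <- fk$x[, e] - x_p
    w <- fk$w[, e]
    v_b <- v_p + cross3(om_p, r)
    a_b <- a_p + cross3(al_p, r) + cross3(om_p, cross3(om_p, r))
    if (cmp$type[e] == "p") {
      om[, e] <- om_p
      al[, e] <- al_p
      vv[, e] <- v_b + w * qd[e]
      aa[, e] <- a_b + 2 * cross3(om_p, w * qd[e]) + w * qdd[e]
    } else {
      om[, e] <- om_p + w * qd[e]
      al[, e] <- al_p + w * qdd[e] + cross3(om_p, w * qd[e])
      vv[, e] <- v_b
      aa[, e] <- a_b
    }
  }
  S <- cmp$S
  com <- segment_coms(skel, fk)
  vcom <- matrix(0, 3L, S); acom <- matrix(0, 3L, S)
  om_s <- matrix(0, 3L, S); al_s <- matrix(0, 3L, S)
  for (s in seq_len(S)) {
    e <- cmp$seg_elem[s]
    d <- com[, s] - fk$x[, e]
    om_s[, s] <- om[, e]; al_s[, s] <- al[, e]
    vcom[, s] <- vv[, e] + cross3(om[, e], d)
    acom[, s] <- aa[, e] + cross3(al[, e], d) +
      cross3(om[, e], cross3(om[, e], d))
  }
  list(fk = fk, om = om, al = al, vv = vv, aa = aa,
       com = com, vcom = vcom, acom = acom, om_s = om_s, al_s = al_s)
}

# normalize the `external` argument: list of wrenches, each
# list(segment=<name|index>, force=3, torque=3, point=3 world)
resolve_external <- function(skel, external) {
  if (is.null(external)) return(list())
  lapply(external, function(e) {
    s <- e$segment
    if (is.character(s)) s <- match(s, skel$cmp$seg_names)
    if (is.na(s)) stop("unknown segment in external wrench")
    list(segment = as.integer(s),
         force = as.numeric(e$force %||% c(0, 0, 0)),
         torque = as.numeric(e$torque %||% c(0, 0, 0)),
         point = as.numeric(e$point %||% c(0, 0, 0)))
  })
}

#' Inverse dynamics
#'
#' Computes the generalized forces `tau` satisfying the equations of
#' motion `M(q) qdd + C(q, qd) = tau + J^T f_ext` via Newton-Euler
#' balance of every segment.  The six entries for the root free joint are
#' the residual wrench (force in the translational rows, generalized
#' torque in the rotational rows); remaining entries are net joint
#' torques.
#'
#' @param skel a `bm_skeleton`
#' @param q,qd,qdd generalized position, velocity, acceleration
#' @param external optional list of external wrenches, each a list with
#'   `segment` (name or index), `force` (3, N, world), `torque` (3, N m,
#'   world) and `point` (3, m, world application point of the force)
#' @param fk optional precomputed FK pass
#' @return numeric vector of generalized forces, length `n_dof(skel)`
#' @export
inverse_dynamics <- function(skel, q, qd, qdd, external = NULL,
                             fk = NULL) {
  if (is.null(qd) || is.null(qdd))
    stop("inverse dynamics requires qd and qdd")
  cmp <- skel$cmp
  bk <- body_kinematics(skel, q, qd, qdd, fk = fk)
  ext <- resolve_external(skel, external)
  S <- cmp$S
  g <- skel$gravity
  Fs <- matrix(0, 3L, S)  # net required force at segment COM
  Ns <- matrix(0, 3L, S)  # net required moment about segment COM
  for (s in seq_len(S)) {
    m <- skel$segment_masses[s]
    Iw <- bk$fk$Rseg[, , s] %*% seg_inertia(skel, s) %*%
      t(bk$fk$Rseg[, , s])
    Fs[, s] <- m * (bk$acom[, s] - g)
    Ns[, s] <- Iw %*% bk$al_s[, s] +
      cross3(bk$om_s[, s], Iw %*% bk$om_s[, s])
  }
  for (e in ext) {
    s <- e$segment
    Fs[, s] <- Fs[, s] - e$force
    Ns[, s] <- Ns[, s] - e$torque -
      cross3(e$point - bk$com[, s], e$force)
  }
  tau <- numeric(cmp$nq)
  for (d in seq_len(cmp$E)) {
    segs <- which(cmp$anc[d, ])
    w <- bk$fk$w[, d]
    if (cmp$type[d] == "p") {
      tau[d] <- sum(w * rowSums(Fs[, segs, drop = FALSE]))
    } else {
      o <- bk$fk$x[, d]
      acc <- c(0, 0, 0)
      for (s in segs)
        acc <- acc + Ns[, s] + cross3(bk$com[, s] - o, Fs[, s])
      tau[d] <- sum(w * acc)
    }
  }
  names(tau) <- cmp$dof_names
  tau
}

#' Generalized mass matrix (composite rigid body algorithm)
#'
#' @param skel a `bm_skeleton`
#' @param q generalized coordinates
#' @param fk optional precomputed FK pass
#' @return symmetric positive-definite nq x nq matrix
#' @export
mass_matrix <- function(skel, q, fk = NULL) {
  cmp <- skel$cmp
  if (is.null(fk)) fk <- forward_kinematics_full(skel, q)
  E <- cmp$E
  # spatial inertia of each segment about the world origin, (angular; linear)
  com <- segment_coms(skel, fk)
  Ic <- vector("list", E)
  for (e in seq_len(E)) Ic[[e]] <- matrix(0, 6L, 6L)
  for (s in seq_len(cmp$S)) {
    m <- skel$segment_masses[s]
    Iw <- fk$Rseg[, , s] %*% seg_inertia(skel, s) %*%
      t(fk$Rseg[, , s])
    Sc <- skew3(com[, s])
    IO <- rbind(cbind(Iw + m * Sc %*% t(Sc), m * Sc),
                cbind(m * t(Sc), m * diag(3L)))
    e <- cmp$seg_elem[s]
    Ic[[e]] <- Ic[[e]] + IO
  }
  for (e in rev(seq_len(E))) {
    p <- cmp$parent[e]
    if (p > 0L) Ic[[p]] <- Ic[[p]] + Ic[[e]]
  }
  phi <- matrix(0, 6L, E)
  for (e in seq_len(E)) {
    w <- fk$w[, e]
    phi[, e] <- if (cmp$type[e] == "p") c(0, 0, 0, w)
    else c(w, cross3(fk$x[, e], w))
  }
  M <- matrix(0, cmp$nq, cmp$nq)
  for (e in seq_len(E)) {
    F <- Ic[[e]] %*% phi[, e]
    a <- e
    while (a > 0L) {
      M[e, a] <- M[a, e] <- sum(phi[, a] * F)
      a <- cmp$parent[a]
    }
  }
  dimnames(M) <- list(cmp$dof_names, cmp$dof_names)
  M
}

#' Coriolis, centrifugal and gravity generalized forces
#'
#' `C(q, qd)` such that `M qdd + C = tau + J^T f_ext`; equal to
#' `inverse_dynamics(skel, q, qd, 0)`.
#' @param skel a `bm_skeleton`
#' @param q,qd position and velocity
#' @export
coriolis_gravity <- function(skel, q, qd) {
  inverse_dynamics(skel, q, qd, numeric(length(q)))
}

#' Forward dynamics
#'
#' Accelerations from applied generalized forces and external wrenches:
#' `qdd = M^-1 (tau - ID(q, qd, 0, external))`.
#'
#' @inheritParams inverse_dynamics
#' @param tau applied generalized forces
#' @export
forward_dynamics <- function(skel, q, qd, tau, external = NULL) {
  M <- mass_matrix(skel, q)
  bias <- inverse_dynamics(skel, q, qd, numeric(length(q)), external)
  drop(solve(M, tau - bias))
}

#' Total mechanical energy
#'
#' Kinetic plus gravitational potential energy of the skeleton.
#' @param skel a `bm_skeleton`
#' @param q,qd position and velocity
#' @export
mechanical_energy <- function(skel, q, qd) {
  bk <- body_kinematics(skel, q, qd, numeric(length(q)))
  ke <- 0; pe <- 0
  for (s in seq_len(skel$cmp$S)) {
    m <- skel$segment_masses[s]
    Iw <- bk$fk$Rseg[, , s] %*% seg_inertia(skel, s) %*%
      t(bk$fk$Rseg[, , s])
    ke <- ke + 0.5 * m * sum(bk$vcom[, s]^2) +
      0.5 * sum(bk$om_s[, s] * (Iw %*% bk$om_s[, s]))
    pe <- pe - m * sum(skel$gravity * bk$com[, s])
  }
  ke + pe
}
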