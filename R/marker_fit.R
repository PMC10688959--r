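# Maximum-a-posteriori refinement of scales, marker registrations and
# kinematics against the measured markers.  The bilevel problem (outer:
# scales s and marker offsets p; inner: per-frame inverse kinematics for
# q_t) is solved by exact alternation: the inner problem is re-solved to
# first-order stationarity between outer quasi-Newton steps on (s, p), so
# the stationarity condition of the single-level reformulation holds at
# every outer iterate.

#' Gaussian priors for the MAP stages
#'
#' @param scale_mean prior mean for every per-axis scale (scalar or 3S
#'   vector), dimensionless
#' @param scale_sigma prior standard deviation per scale axis
#' @param anatomical_sigma,tracking_sigma marker-offset prior SDs, meters
#' @param marker_obs_sigma marker observation noise SD, meters
#' @param residual_force_sigma,residual_torque_sigma residual wrench SDs
#'   (N, N m) used by the final dynamics stage
#' @param mass_fraction_sigma SD of segment mass fractions about nominal
#' @param total_mass_sigma SD (kg) of total mass about the linear-fit mass
#' @return a `bm_priors` list
#' @export
default_priors <- function(scale_mean = 1, scale_sigma = 0.1,
                           anatomical_sigma = 0.01, tracking_sigma = 0.05,
                           marker_obs_sigma = 0.01,
                           residual_force_sigma = 5,
                           residual_torque_sigma = 2,
                           mass_fraction_sigma = 0.03,
                           total_mass_sigma = 1) {
  structure(list(scale_mean = scale_mean, scale_sigma = scale_sigma,
                 anatomical_sigma = anatomical_sigma,
                 tracking_sigma = tracking_sigma,
                 marker_obs_sigma = marker_obs_sigma,
                 residual_force_sigma = residual_force_sigma,
                 residual_torque_sigma = residual_torque_sigma,
                 mass_fraction_sigma = mass_fraction_sigma,
                 total_mass_sigma = total_mass_sigma),
            class = "bm_priors")
}

#' Condition the scale prior on known subject height and/or mass
#'
#' A documented linear-Gaussian rule: the prior mean of every scale axis
#' is shifted to the ratio of stated height to the unscaled model height
#' (and, for mass, by the cube root of the mass ratio), and the scale SD
#' is tightened.
#'
#' @param priors a `bm_priors`
#' @param skel the unscaled skeleton
#' @param height subject height, m (optional)
#' @param mass subject mass, kg (optional)
#' @export
condition_priors <- function(priors, skel, height = NULL, mass = NULL) {
  ratio <- 1
  if (!is.null(height)) ratio <- height / skeleton_height(skel)
  else if (!is.null(mass)) ratio <- (mass / sum(skel$segment_masses))^(1 / 3)
  priors$scale_mean <- ratio
  priors$scale_sigma <- priors$scale_sigma / 2
  priors
}

marker_sigmas <- function(skel, priors) {
  ifelse(skel$cmp$marker_anat, priors$anatomical_sigma,
         priors$tracking_sigma)
}

#' Negative log MAP objective and analytic gradient
#'
#' `sum_t sum_visible ||f_FK - xbar||^2 / (2 sigma_x^2)
#'  + sum_axis (s - mu_s)^2 / (2 sigma_s^2)
#'  + sum_i ||p_i - pbar_i||^2 / (2 sigma_i^2)`
#' with `sigma_i` chosen by the marker's anatomical flag.
#'
#' @param skel skeleton carrying the current scales `s` and offsets `p`
#' @param q T x nq coordinates for the evaluated frames
#' @param trial a `bm_marker_trial`
#' @param frames frame indices corresponding to the rows of `q`
#' @param priors a `bm_priors`
#' @param p_bar 3 x M nominal marker offsets (default: current offsets,
#'   i.e. a freshly loaded skeleton)
#' @param wrt which gradients to compute: subset of `c("q","s","p")`
#' @return list with `value`, and `grad_q` (T x nq), `grad_s` (3S),
#'   `grad_p` (3M) as requested
#' @export
neg_log_map_objective <- function(skel, q, trial, frames, priors,
                                  p_bar = NULL, wrt = c("s", "p")) {
  cmp <- skel$cmp
  if (is.null(p_bar)) p_bar <- cmp$marker_off
  midx <- match(cmp$marker_lab, trial$labels)
  inv2sx <- 1 / (2 * priors$marker_obs_sigma^2)
  value <- 0
  grad_q <- if ("q" %in% wrt) matrix(0, nrow(q), cmp$nq)
  grad_s <- if ("s" %in% wrt) numeric(3L * cmp$S)
  grad_p <- if ("p" %in% wrt) numeric(3L * cmp$n_markers)
  for (k in seq_along(frames)) {
    t <- frames[k]
    vis <- which(trial$visible[t, midx])
    if (!length(vis)) next
    fk <- forward_kinematics_full(skel, q[k, ])
    rmat <- matrix(0, 3L, cmp$n_markers)
    rmat[, vis] <- fk$markers[, vis, drop = FALSE] -
      t(trial$positions[t, midx[vis], , drop = TRUE])
    value <- value + inv2sx * sum(rmat^2)
    if (length(wrt)) {
      pb <- marker_pullback(skel, fk, rmat, wrt = wrt)
      if (!is.null(grad_q)) grad_q[k, ] <- 2 * inv2sx * pb$q
      if (!is.null(grad_s)) grad_s <- grad_s + 2 * inv2sx * pb$s
      if (!is.null(grad_p)) grad_p <- grad_p + 2 * inv2sx * pb$p
    }
  }
  ds <- as.numeric(skel$scales) - priors$scale_mean
  value <- value + sum(ds^2) / (2 * priors$scale_sigma^2)
  if (!is.null(grad_s)) grad_s <- grad_s + ds / priors$scale_sigma^2
  sig_i <- marker_sigmas(skel, priors)
  dp <- cmp$marker_off - p_bar
  value <- value + sum(sweep(dp^2, 2L, 2 * sig_i^2, `/`))
  if (!is.null(grad_p))
    grad_p <- grad_p + as.numeric(sweep(dp, 2L, sig_i^2, `/`))
  out <- list(value = value)
  if (!is.null(grad_q)) out$grad_q <- grad_q
  if (!is.null(grad_s)) out$grad_s <- grad_s
  if (!is.null(grad_p)) out$grad_p <- grad_p
  out
}

#' Per-frame stationarity of the inner inverse-kinematics problem
#'
#' Gradient of the marker data term with respect to `q_t` alone; the
#' scale and marker-offset priors do not depend on `q_t`, so this is the
#' full objective gradient in `q_t`.  Zero (to tolerance) at any inner
#' optimum, which is the equality constraint of the single-level
#' reformulation of the bilevel problem.
#'
#' @inheritParams neg_log_map_objective
#' @param q_t coordinates for one frame
#' @param t frame index into the trial
#' @return gradient vector, length nq
#' @export
stationarity_constraint <- function(skel, q_t, trial, t, priors) {
  drop(neg_log_map_objective(skel, matrix(q_t, 1L), trial, t, priors,
                             wrt = "q")$grad_q)
}

#' Marker error metrics of a solution
#'
#' RMSE over all visible (frame, marker) pairs, the maximum single-marker
#' error, and a per-marker breakdown.
#'
#' @param skel fitted skeleton (scales and offsets applied)
#' @param q T x nq coordinates
#' @param trial a `bm_marker_trial`
#' @return list with `rmse` (m), `max` (m), `per_marker` named vector
#' @export
marker_error_metrics <- function(skel, q, trial) {
  cmp <- skel$cmp
  midx <- match(cmp$marker_lab, trial$labels)
  sq <- matrix(NA_real_, nrow(q), cmp$n_markers)
  for (t in seq_len(nrow(q))) {
    vis <- which(trial$visible[t, midx])
    if (!length(vis)) next
    X <- forward_kinematics_full(skel, q[t, ])$markers
    sq[t, vis] <- colSums((X[, vis, drop = FALSE] -
                             t(trial$positions[t, midx[vis], ,
                                               drop = TRUE]))^2)
  }
  if (all(is.na(sq))) stop("no visible markers in any frame")
  per <- sqrt(colMeans(sq, na.rm = TRUE))
  names(per) <- cmp$marker_lab
  list(rmse = sqrt(mean(sq, na.rm = TRUE)),
       max = sqrt(max(sq, na.rm = TRUE)),
       per_marker = per,
       per_frame = sqrt(rowMeans(sq, na.rm = TRUE)))
}

# Levenberg-Marquardt on the joint MAP problem over (s, p, q_1:F).
# All terms are sums of squares; the Gauss-Newton Hessian is block-sparse
# (each frame's q_t couples only to (s, p)), so the q blocks are
# eliminated by a Schur complement and the damped normal equations are
# solved in the (s, p) space only.  Scale bounds [0.5, 2] enforced by
# projection.
lm_bundle_fit <- function(skel, q, trial, frames, priors, p_bar,
                          max_iter = 60L, tol = 1e-9) {
  cmp <- skel$cmp
  nq <- cmp$nq
  nS3 <- 3L * cmp$S
  nP3 <- 3L * cmp$n_markers
  nsp <- nS3 + nP3
  midx <- match(cmp$marker_lab, trial$labels)
  inv_sx <- 1 / priors$marker_obs_sigma
  sig_i <- marker_sigmas(skel, priors)
  w_p <- rep(1 / sig_i, each = 3L)
  w_s <- rep(1 / priors$scale_sigma, nS3)
  F_ <- length(frames)

  eval_resid <- function(sk, qm, want_jac = FALSE) {
    val <- 0
    per <- vector("list", F_)
    for (k in seq_len(F_)) {
      t <- frames[k]
      vis <- which(trial$visible[t, midx])
      fk <- forward_kinematics_full(sk, qm[k, ])
      r <- as.numeric(fk$markers[, vis, drop = FALSE] -
                        t(trial$positions[t, midx[vis], ,
                                          drop = TRUE])) * inv_sx
      val <- val + 0.5 * sum(r^2)
      if (want_jac) {
        rows <- rep(3L * (vis - 1L), each = 3L) + 1:3
        J <- marker_jacobians(sk, qm[k, ], fk = fk)
        per[[k]] <- list(r = r,
                         A = J$Jq[rows, , drop = FALSE] * inv_sx,
                         B = cbind(J$Js[rows, , drop = FALSE],
                                   J$Jp[rows, , drop = FALSE]) * inv_sx)
      }
    }
    rs <- (as.numeric(sk$scales) - priors$scale_mean) * w_s
    rp <- as.numeric(marker_offsets(sk) - p_bar) * w_p
    val <- val + 0.5 * sum(rs^2) + 0.5 * sum(rp^2)
    list(value = val, per = per, rs = rs, rp = rp)
  }

  cur_sk <- skel
  cur_q <- q
  ev <- eval_resid(cur_sk, cur_q, want_jac = TRUE)
  obj <- ev$value
  lambda <- 1e-4
  for (it in seq_len(max_iter)) {
    H <- matrix(0, nsp, nsp)
    g <- numeric(nsp)
    Ablocks <- vector("list", F_)
    for (k in seq_len(F_)) {
      pk <- ev$per[[k]]
      AtA <- crossprod(pk$A) + lambda * diag(nq)
      AtB <- crossprod(pk$A, pk$B)
      Atr <- crossprod(pk$A, pk$r)
      sol <- solve(AtA, cbind(AtB, Atr))
      H <- H + crossprod(pk$B) - crossprod(AtB, sol[, seq_len(nsp)])
      g <- g + drop(crossprod(pk$B, pk$r)) -
        drop(crossprod(AtB, sol[, nsp + 1L]))
      Ablocks[[k]] <- list(AtA = AtA, AtB = AtB, Atr = Atr)
    }
    diag(H)[seq_len(nS3)] <- diag(H)[seq_len(nS3)] + w_s^2
    diag(H)[nS3 + seq_len(nP3)] <- diag(H)[nS3 + seq_len(nP3)] + w_p^2
    g[seq_len(nS3)] <- g[seq_len(nS3)] + ev$rs * w_s
    g[nS3 + seq_len(nP3)] <- g[nS3 + seq_len(nP3)] + ev$rp * w_p
    diag(H) <- diag(H) + lambda
    step_sp <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(step_sp)) { lambda <- lambda * 10; next }
    new_s <- pmin(pmax(as.numeric(cur_sk$scales) +
                         step_sp[seq_len(nS3)], 0.5), 2)
    new_p <- as.numeric(marker_offsets(cur_sk)) +
      step_sp[nS3 + seq_len(nP3)]
    new_sk <- set_marker_offsets(set_scales(cur_sk, matrix(new_s, 3L)),
                                 matrix(new_p, 3L))
    new_q <- cur_q
    for (k in seq_len(F_)) {
      bk <- Ablocks[[k]]
      dq <- -solve(bk$AtA, bk$Atr + bk$AtB %*% step_sp)
      new_q[k, ] <- cur_q[k, ] + drop(dq)
    }
    ev_new <- eval_resid(new_sk, new_q, want_jac = FALSE)
    if (ev_new$value < obj) {
      accepted <- obj - ev_new$value
      cur_sk <- new_sk; cur_q <- new_q
      lambda <- max(lambda / 3, 1e-8)
      ev <- eval_resid(cur_sk, cur_q, want_jac = TRUE)
      obj <- ev$value
      if (accepted < tol * (1 + obj)) break
    } else {
      lambda <- lambda * 10
      if (lambda > 1e8) break
    }
  }
  list(skel = cur_sk, q = cur_q, objective = obj)
}

#' Bilevel MAP fit of scales, marker offsets and kinematics
#'
#' Starting from the initialization solution, alternates (a) per-frame
#' inverse kinematics at the current (s, p), which enforces the
#' first-order stationarity constraint of the single-level reformulation,
#' with (b) bounded quasi-Newton (L-BFGS-B) steps on (s, p) under the
#' scale and marker-placement priors, on a uniform frame subsample.  The
#' full-rate trajectory is then recovered by per-frame inverse kinematics
#' with the optimized (s, p).
#'
#' @param skel skeleton with initialization scales applied
#' @param init list with at least `q` (T x nq initialization trajectory)
#' @param trial a `bm_marker_trial`
#' @param priors a `bm_priors`
#' @param max_frames subsample cap for the outer problem (default 80,
#'   hard-capped at 200)
#' @param max_outer outer alternations
#' @param tol relative objective decrease tolerance
#' @return a kinematic solution: list with `skel` (optimized), `q`
#'   (full-rate), `scales`, `marker_offsets`, `objective`,
#'   `objective_init`, `marker_rmse`, `marker_max`, `stationarity_inf`
#' @export
bilevel_fit <- function(skel, init, trial, priors = default_priors(),
                        max_frames = 80L, max_outer = 8L, tol = 1e-5) {
  cmp <- skel$cmp
  T_ <- dim(trial$positions)[1L]
  max_frames <- min(max_frames, 200L)
  ts <- unique(round(seq(1L, T_, length.out = min(T_, max_frames))))
  p_bar <- cmp$marker_off
  q_sub <- init$q[ts, , drop = FALSE]

  pack <- function(sk) c(as.numeric(sk$scales),
                         as.numeric(marker_offsets(sk)))
  unpack <- function(x) {
    sk <- set_scales(skel, matrix(x[seq_len(3L * cmp$S)], 3L))
    set_marker_offsets(sk, matrix(x[-seq_len(3L * cmp$S)], 3L))
  }
  nS <- 3L * cmp$S
  lower <- c(rep(0.5, nS), rep(-Inf, 3L * cmp$n_markers))
  upper <- c(rep(2.0, nS), rep(Inf, 3L * cmp$n_markers))

  cur <- skel
  obj0 <- NA_real_
  obj <- Inf
  # staged alternation warm-up: inner IK <-> outer steps, first over the
  # scales alone with the marker offsets pinned at their nominal
  # locations.  Releasing p too early lets the offsets absorb a tilted
  # root orientation (the pelvis-tilt ambiguity), stranding the joint
  # refinement in a poor basin.
  for (outer in seq_len(3L)) {
    iks <- ik_solve(cur, trial, frames = ts, q_init = q_sub)
    q_sub <- iks$q
    if (is.na(obj0))
      obj0 <- neg_log_map_objective(cur, q_sub, trial, ts, priors,
                                    p_bar = p_bar,
                                    wrt = character(0))$value
    s_only <- outer < 3L
    cfg <- cache_fn_gr(function(x) {
      sk <- if (s_only) set_scales(skel, matrix(x, 3L)) else unpack(x)
      o <- neg_log_map_objective(sk, q_sub, trial, ts, priors,
                                 p_bar = p_bar, wrt = c("s", "p"))
      list(value = o$value,
           grad = if (s_only) o$grad_s else c(o$grad_s, o$grad_p))
    })
    x0 <- if (s_only) as.numeric(cur$scales) else pack(cur)
    res <- stats::optim(x0, cfg$fn, cfg$gr, method = "L-BFGS-B",
                        lower = if (s_only) lower[seq_len(nS)] else lower,
                        upper = if (s_only) upper[seq_len(nS)] else upper,
                        control = list(maxit = 40L))
    cur <- if (s_only) set_scales(cur, matrix(res$par, 3L))
    else unpack(res$par)
    obj <- res$value
  }
  # joint refinement over (s, p, q_subsample) by Levenberg-Marquardt
  # with per-frame Schur elimination of the q blocks (the problem is a
  # separable nonlinear least squares); the inner stationarity is
  # restored by a final IK pass below
  lm <- lm_bundle_fit(cur, q_sub, trial, ts, priors, p_bar,
                      max_iter = 12L * max_outer)
  cur <- lm$skel
  q_sub <- lm$q
  obj <- min(obj, lm$objective)
  # final inner solve (restores stationarity after the last outer step)
  iks <- ik_solve(cur, trial, frames = ts, q_init = q_sub)
  q_sub <- iks$q
  obj <- neg_log_map_objective(cur, q_sub, trial, ts, priors,
                               p_bar = p_bar, wrt = character(0))$value
  # full-rate trajectory
  full <- ik_solve(cur, trial, q_init = {
    qi <- matrix(0, T_, cmp$nq)
    for (j in seq_len(cmp$nq))
      qi[, j] <- stats::approx(ts, q_sub[, j], xout = seq_len(T_),
                               rule = 2L)$y
    qi
  })
  met <- marker_error_metrics(cur, full$q, trial)
  stat_inf <- max(abs(stationarity_constraint(
    cur, q_sub[1L, ], trial, ts[1L], priors)))
  list(skel = cur, q = full$q, scales = cur$scales,
       marker_offsets = marker_offsets(cur),
       objective = obj, objective_init = obj0,
       marker_rmse = met$rmse, marker_max = met$max,
       per_frame_rmse = met$per_frame,
       stationarity_inf = stat_inf, frames_used = ts)
}
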