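# Initialization of the kinematic decision variables: functional joint
# centers (moving sphere fit), functional joint axes, an analytic
# center-of-rotation start (Gamage-Lasenby), scale initialization against
# the estimated joint centers/axes, and plain per-frame inverse
# kinematics.

# Rigid anchoring: express each frame's world points in the frame that
# makes the parent marker cluster static (Procrustes to the reference
# frame).  Returns per-frame transforms (R_t, t_t): world -> anchored.
anchor_transforms <- function(parent_pts, visible) {
  T_ <- dim(parent_pts)[1L]
  ref <- which(rowSums(visible) >= 3L)[1L]
  if (is.na(ref)) stop("parent cluster never has 3 visible markers")
  out <- vector("list", T_)
  A_ref <- t(parent_pts[ref, visible[ref, ], , drop = TRUE])
  for (t in seq_len(T_)) {
    vis <- visible[t, ] & visible[ref, ]
    if (sum(vis) < 3L) { out[[t]] <- NULL; next }
    A <- t(parent_pts[t, vis, , drop = TRUE])
    B <- t(parent_pts[ref, vis, , drop = TRUE])
    out[[t]] <- procrustes_fit(A, B)
  }
  out
}

#' Analytic center-of-rotation estimate (Gamage-Lasenby construction)
#'
#' Estimates the center about which the child marker cluster rotates
#' relative to the parent cluster.  The child markers are expressed in a
#' parent-anchored frame via per-frame rigid (orthogonal Procrustes)
#' alignment, the deterministic linear least-squares sphere-center system
#' is solved there, and the constant anchored-frame center is mapped back
#' to a world-frame trajectory.
#'
#' @param markersA T x nA x 3 array of parent-segment marker positions
#' @param markersB T x nB x 3 array of child-segment marker positions
#' @param visibleA,visibleB optional T x n logical masks
#' @return list with `centers` (T x 3, world), `radii` (per child marker),
#'   `degenerate` (TRUE when the linear system is rank deficient, e.g.
#'   pure translation), `anchored` (per-frame transforms, reused downstream)
#' @export
closed_form_joint_center <- function(markersA, markersB,
                                     visibleA = NULL, visibleB = NULL) {
  T_ <- dim(markersA)[1L]
  nB <- dim(markersB)[2L]
  if (is.null(visibleA)) visibleA <- matrix(TRUE, T_, dim(markersA)[2L])
  if (is.null(visibleB)) visibleB <- matrix(TRUE, T_, nB)
  if (dim(markersA)[2L] + nB < 3L)
    stop("need at least 3 markers across the two segments")
  tf <- anchor_transforms(markersA, visibleA)
  frames <- which(!vapply(tf, is.null, NA))
  if (length(frames) < 10L)
    stop("need at least 10 frames with a visible parent cluster")
  # child markers in the anchored frame
  anch <- array(NA_real_, c(T_, nB, 3L))
  for (t in frames) {
    for (i in seq_len(nB)) {
      if (!visibleB[t, i]) next
      anch[t, i, ] <- tf[[t]]$R %*% markersB[t, i, ] + tf[[t]]$t
    }
  }
  # shift to the child-cluster centroid so the minimum-norm solution of
  # a rank-deficient (hinge) system lands near the cluster
  m0 <- apply(anch, 3L, mean, na.rm = TRUE)
  A <- matrix(0, 3L, 3L); b <- numeric(3L)
  for (i in seq_len(nB)) {
    x <- anch[, i, , drop = TRUE]
    x <- x[stats::complete.cases(x), , drop = FALSE]
    if (nrow(x) < 10L) next
    x <- sweep(x, 2L, m0)
    mx <- colMeans(x)
    xx <- crossprod(x) / nrow(x)
    n2 <- rowSums(x^2)
    A <- A + 2 * (xx - tcrossprod(mx))
    b <- b + (colMeans(x * n2) - mx * mean(n2))
  }
  # For a pure hinge the system is rank 2 (the center is only determined
  # up to sliding along the axis); the minimum-norm solution still lies
  # on the axis and the axis fit resolves the ambiguity downstream.
  # Degenerate means not even a line is determined (static markers or
  # pure translation).
  eg <- eigen(A, symmetric = TRUE)
  ev <- eg$values
  degenerate <- ev[1L] <= 0 || ev[2L] / ev[1L] < 1e-8
  c_loc <- m0 + if (degenerate) c(0, 0, 0) else {
    keep <- ev > 1e-8 * ev[1L]
    drop(eg$vectors[, keep, drop = FALSE] %*%
           ((t(eg$vectors[, keep, drop = FALSE]) %*% b) / ev[keep]))
  }
  centers <- matrix(NA_real_, T_, 3L)
  for (t in frames)
    centers[t, ] <- t(tf[[t]]$R) %*% (c_loc - tf[[t]]$t)
  # fill frames without an anchor by nearest neighbour
  bad <- which(is.na(centers[, 1L]))
  for (t in bad) centers[t, ] <- centers[frames[which.min(abs(frames - t))], ]
  radii <- vapply(seq_len(nB), function(i) {
    d <- sqrt(rowSums((anch[, i, , drop = TRUE] -
                         matrix(c_loc, T_, 3L, byrow = TRUE))^2))
    mean(d, na.rm = TRUE)
  }, 0)
  list(centers = centers, radii = radii, degenerate = degenerate,
       anchored = tf)
}

sphere_objective <- function(pts, vis, centers, radii) {
  tot <- 0
  for (i in seq_len(ncol(vis))) {
    t_ok <- which(vis[, i])
    d <- sqrt(rowSums((pts[t_ok, i, , drop = TRUE] -
                         centers[t_ok, , drop = FALSE])^2))
    tot <- tot + sum((d - radii[i])^2)
  }
  tot
}

#' Moving-sphere functional joint center fit
#'
#' Refines a center-of-rotation trajectory by minimizing
#' `sum_t sum_i (||x_t^i - c_t|| - r_i)^2` over the per-frame centers and
#' per-marker radii, with block coordinate descent: exact radii update,
#' damped Gauss-Newton per-frame center update.
#'
#' @param markers T x n x 3 array of child-cluster world positions
#' @param init result of [closed_form_joint_center()]
#' @param visible optional T x n logical mask
#' @param max_iter outer iterations
#' @return list (`centers`, `radii`, `rms_residual`, `objective`,
#'   `degenerate`)
#' @export
sphere_fit <- function(markers, init, visible = NULL, max_iter = 20L) {
  T_ <- dim(markers)[1L]; n <- dim(markers)[2L]
  if (is.null(visible)) visible <- matrix(TRUE, T_, n)
  if (T_ < 2L)
    return(list(centers = init$centers, radii = init$radii,
                rms_residual = NA_real_, objective = NA_real_,
                degenerate = TRUE))
  centers <- init$centers
  radii <- init$radii
  obj <- sphere_objective(markers, visible, centers, radii)
  obj0 <- obj
  for (it in seq_len(max_iter)) {
    # exact radii given centers
    for (i in seq_len(n)) {
      t_ok <- which(visible[, i])
      if (length(t_ok) < 2L) next
      radii[i] <- mean(sqrt(rowSums(
        (markers[t_ok, i, , drop = TRUE] - centers[t_ok, , drop = FALSE])^2)))
    }
    # per-frame Gauss-Newton with backtracking
    for (t in seq_len(T_)) {
      ii <- which(visible[t, ])
      if (length(ii) < 3L) next
      X <- markers[t, ii, , drop = TRUE]
      c_t <- centers[t, ]
      f_old <- {
        d <- sqrt(rowSums((X - matrix(c_t, length(ii), 3L, TRUE))^2))
        sum((d - radii[ii])^2)
      }
      for (gn in 1:5) {
        D <- X - matrix(c_t, length(ii), 3L, byrow = TRUE)
        d <- sqrt(rowSums(D^2))
        r <- d - radii[ii]
        J <- -D / d
        g <- crossprod(J, r)
        H <- crossprod(J) + 1e-9 * diag(3L)
        step <- drop(solve(H, g))
        lam <- 1
        repeat {
          c_new <- c_t - lam * step
          d2 <- sqrt(rowSums((X - matrix(c_new, length(ii), 3L, TRUE))^2))
          f_new <- sum((d2 - radii[ii])^2)
          if (f_new <= f_old || lam < 1e-4) break
          lam <- lam / 2
        }
        if (f_new > f_old) break
        c_t <- c_new
        if (f_old - f_new < 1e-16 + 1e-10 * f_old) { f_old <- f_new; break }
        f_old <- f_new
      }
      centers[t, ] <- c_t
    }
    new_obj <- sphere_objective(markers, visible, centers, radii)
    if (obj - new_obj < 1e-12 * (1 + obj)) { obj <- new_obj; break }
    obj <- new_obj
  }
  if (obj > obj0 + 1e-12) {   # should not happen; keep the init contract
    warning("sphere fit failed to improve; returning initialization")
    centers <- init$centers; radii <- init$radii; obj <- obj0
  }
  list(centers = centers, radii = radii,
       rms_residual = sqrt(obj / sum(visible)),
       objective = obj, degenerate = isTRUE(init$degenerate))
}

axis_objective <- function(pts, vis, centers, axes, u, v) {
  tot <- 0
  for (t in seq_len(nrow(vis))) {
    ii <- which(vis[t, ])
    if (!length(ii)) next
    D <- pts[t, ii, , drop = TRUE]
    if (is.null(dim(D))) D <- matrix(D, 1L)
    D <- D - matrix(centers[t, ], length(ii), 3L, byrow = TRUE)
    par <- drop(D %*% axes[t, ])
    perp <- sqrt(pmax(rowSums(D^2) - par^2, 0))
    tot <- tot + sum((par - u[ii])^2) + sum((perp - v[ii])^2)
  }
  tot
}

#' Functional joint axis fit
#'
#' Fits, per frame, a joint center and a unit axis direction such that
#' each marker keeps a constant signed distance `u_i` along the axis and a
#' constant distance `v_i` perpendicular to it.  Succeeds when the axis
#' residual is comparable to the sphere residual (within a factor 1.5) and
#' the per-frame axes are mutually consistent (mean pairwise angle < 10
#' degrees); failure indicates out-of-plane (non-hinge) motion.
#'
#' @param markers T x n x 3 array of child-cluster world positions
#' @param init result of [sphere_fit()] (centers initialize the fit)
#' @param visible optional mask
#' @param sphere_rms sphere-fit RMS residual used in the success rule
#' @param max_iter outer iterations
#' @return list (`centers`, `axes`, `u`, `v`, `rms_residual`, `succeeded`)
#' @export
axis_fit <- function(markers, init, visible = NULL, sphere_rms = NULL,
                     max_iter = 25L) {
  T_ <- dim(markers)[1L]; n <- dim(markers)[2L]
  if (is.null(visible)) visible <- matrix(TRUE, T_, n)
  centers <- init$centers
  if (is.null(sphere_rms)) sphere_rms <- init$rms_residual
  # axis start: dominant relative-rotation axis from marker displacements
  ref <- which(rowSums(visible) >= 3L)[1L]
  axes <- matrix(0, T_, 3L)
  a0 <- c(0, 0, 1)
  best <- 0
  for (t in seq_len(T_)) {
    both <- visible[ref, ] & visible[t, ]
    if (sum(both) < 3L) next
    Dref <- markers[ref, both, , drop = TRUE] -
      matrix(centers[ref, ], sum(both), 3L, byrow = TRUE)
    D <- markers[t, both, , drop = TRUE] -
      matrix(centers[t, ], sum(both), 3L, byrow = TRUE)
    H <- t(Dref) %*% D
    sv <- svd(H)
    R <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
    ang <- acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1))
    if (ang > best && ang < pi - 0.1) {
      best <- ang
      ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
      if (sqrt(sum(ax^2)) > 1e-12) a0 <- ax / sqrt(sum(ax^2))
    }
  }
  axes[] <- matrix(a0, T_, 3L, byrow = TRUE)
  u <- numeric(n); v <- numeric(n)
  upd_uv <- function() {
    for (i in seq_len(n)) {
      t_ok <- which(visible[, i])
      D <- markers[t_ok, i, , drop = TRUE] - centers[t_ok, , drop = FALSE]
      par <- rowSums(D * axes[t_ok, , drop = FALSE])
      u[i] <<- mean(par)
      v[i] <<- mean(sqrt(pmax(rowSums(D^2) - par^2, 0)))
    }
  }
  upd_uv()
  obj <- axis_objective(markers, visible, centers, axes, u, v)
  for (it in seq_len(max_iter)) {
    for (t in seq_len(T_)) {
      ii <- which(visible[t, ])
      if (length(ii) < 3L) next
      X <- markers[t, ii, , drop = TRUE]
      c_t <- centers[t, ]; a_t <- axes[t, ]
      m <- length(ii)
      frame_obj <- function(c_, a_) {
        D <- X - matrix(c_, m, 3L, byrow = TRUE)
        par <- drop(D %*% a_)
        perp <- sqrt(pmax(rowSums(D^2) - par^2, 0))
        sum((par - u[ii])^2) + sum((perp - v[ii])^2)
      }
      f_old <- frame_obj(c_t, a_t)
      for (gn in 1:4) {
        # orthonormal basis of the plane perpendicular to a_t
        tmp <- if (abs(a_t[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        b1 <- cross3(a_t, tmp); b1 <- b1 / sqrt(sum(b1^2))
        b2 <- cross3(a_t, b1)
        B <- cbind(b1, b2)
        D <- X - matrix(c_t, m, 3L, byrow = TRUE)
        par <- drop(D %*% a_t)
        W <- D - outer(par, a_t)
        perp <- sqrt(pmax(rowSums(W^2), 1e-20))
        Nw <- W / perp
        r <- c(par - u[ii], perp - v[ii])
        J <- rbind(cbind(-matrix(a_t, m, 3L, byrow = TRUE), D %*% B),
                   cbind(-Nw, -par * (Nw %*% B)))
        g <- crossprod(J, r)
        H <- crossprod(J) + 1e-9 * diag(5L)
        step <- drop(solve(H, g))
        lam <- 1
        repeat {
          c_new <- c_t - lam * step[1:3]
          a_new <- a_t - drop(B %*% (lam * step[4:5]))
          a_new <- a_new / sqrt(sum(a_new^2))
          f_new <- frame_obj(c_new, a_new)
          if (f_new <= f_old || lam < 1e-4) break
          lam <- lam / 2
        }
        if (f_new > f_old) break
        c_t <- c_new; a_t <- a_new
        if (f_old - f_new < 1e-16 + 1e-10 * f_old) { f_old <- f_new; break }
        f_old <- f_new
      }
      centers[t, ] <- c_t; axes[t, ] <- a_t
    }
    upd_uv()
    new_obj <- axis_objective(markers, visible, centers, axes, u, v)
    if (obj - new_obj < 1e-12 * (1 + obj)) { obj <- new_obj; break }
    obj <- new_obj
  }
  rms <- sqrt(obj / (2 * sum(visible)))
  # pairwise axis consistency on a subsample
  ts <- unique(round(seq(1L, T_, length.out = min(T_, 25L))))
  angs <- c()
  for (i in seq_along(ts)) for (j in seq_len(i - 1L)) {
    d <- abs(sum(axes[ts[i], ] * axes[ts[j], ]))
    angs <- c(angs, acos(pmin(d, 1)))
  }
  consistent <- length(angs) == 0L || mean(angs) < 10 * pi / 180
  succeeded <- is.finite(sphere_rms) &&
    rms < 1.5 * max(sphere_rms, 1e-9) && consistent
  list(centers = centers, axes = axes, u = u, v = v, rms_residual = rms,
       objective = obj, succeeded = succeeded,
       mean_axis_angle = if (length(angs)) mean(angs) * 180 / pi else 0)
}

#' Choose the constraint passed downstream for one joint
#'
#' The axis fit solves a strictly harder problem than the sphere fit, so a
#' successful axis fit wins; otherwise the motion had out-of-plane content
#' and the unambiguous sphere-fit center is used.
#'
#' @param sphere result of [sphere_fit()]
#' @param axis result of [axis_fit()]
#' @return list with `type` (`"axis"` or `"point"`) and the fit
#' @export
select_joint_constraint <- function(sphere, axis) {
  if (!is.null(axis) && isTRUE(axis$succeeded))
    list(type = "axis", centers = axis$centers, axes = axis$axes)
  else
    list(type = "point", centers = sphere$centers)
}

# world positions of all joint centers, as virtual markers on the child
# segment (offset = +child_offset_local, which lands on the joint origin)
joint_virtual_skeleton <- function(skel) {
  NJ <- length(skel$joints)
  skel$cmp$marker_seg <- skel$cmp$joint_child
  skel$cmp$marker_off <- vapply(skel$joints, function(j)
    as.numeric(j$child_offset_local %||% c(0, 0, 0)), numeric(3L))
  skel$cmp$marker_anat <- rep(TRUE, NJ)
  skel$cmp$marker_lab <- vapply(skel$joints, `[[`, "", "name")
  skel$cmp$n_markers <- NJ
  skel$cmp$seg_marker_idx <- lapply(seq_len(skel$cmp$S), function(s)
    which(skel$cmp$marker_seg == s))
  skel
}

#' Initialize body segment scales from joint constraints and markers
#'
#' Minimizes a squared-error version of the scale-initialization
#' objective: marker fit plus the distance of every model joint center to
#' its estimated functional center (point constraint) or axis line (axis
#' constraint), over uniform per-segment scale multipliers, on a frame
#' subsample.  Scales are clipped to [0.5, 2].
#'
#' @param skel a `bm_skeleton`
#' @param q T x nq coordinate guess (from IK at current scales)
#' @param constraints named list (by joint name) of
#'   [select_joint_constraint()] results; may be empty (marker-only fit)
#' @param trial a `bm_marker_trial`
#' @param max_frames frame subsample cap (default 50)
#' @param joint_weight relative weight of the joint-constraint term
#' @return list with `scales` (uniform per segment), `objective`
#' @export
initialize_scales <- function(skel, q, constraints, trial,
                              max_frames = 50L, joint_weight = 2) {
  cmp <- skel$cmp
  T_ <- nrow(q)
  ts <- unique(round(seq(1L, T_, length.out = min(T_, max_frames))))
  midx <- match(cmp$marker_lab, trial$labels)
  jskel <- joint_virtual_skeleton(skel)
  jnames <- vapply(skel$joints, `[[`, "", "name")
  cidx <- match(names(constraints), jnames)
  per_seg <- function(gs3) colSums(matrix(gs3, 3L))   # tie axes together
  fn_gr <- function(u) {
    sk <- set_scales(skel, u)
    jk <- set_scales(jskel, u)
    f <- 0; g <- numeric(cmp$S)
    for (t in ts) {
      fk <- forward_kinematics_full(sk, q[t, ])
      vis <- which(trial$visible[t, midx])
      if (length(vis)) {
        rmat <- matrix(0, 3L, cmp$n_markers)
        rmat[, vis] <- fk$markers[, vis, drop = FALSE] -
          t(trial$positions[t, midx[vis], , drop = TRUE])
        f <- f + sum(rmat^2)
        g <- g + 2 * per_seg(marker_pullback(sk, fk, rmat, "s")$s)
      }
      if (length(cidx)) {
        fkj <- forward_kinematics_full(jk, q[t, ])
        rj <- matrix(0, 3L, length(jnames))
        for (k in seq_along(cidx)) {
          con <- constraints[[k]]
          d <- fkj$markers[, cidx[k]] - con$centers[t, ]
          if (con$type == "axis") {
            a <- con$axes[t, ]
            d <- d - a * sum(a * d)     # residual perpendicular to axis
          }
          rj[, cidx[k]] <- d
          f <- f + joint_weight * sum(d^2)
        }
        g <- g + joint_weight * 2 *
          per_seg(marker_pullback(jk, fkj, rj, "s")$s)
      }
    }
    list(value = f, grad = g)
  }
  u0 <- colMeans(skel$scales)
  cfg <- cache_fn_gr(fn_gr)
  res <- stats::optim(u0, fn = cfg$fn, gr = cfg$gr,
                      method = "L-BFGS-B", lower = 0.5, upper = 2,
                      control = list(maxit = 50L))
  list(scales = res$par, objective = res$value,
       init_objective = fn_gr(u0)$value)
}

# -- inverse kinematics ------------------------------------------------------

# Root pose initial guess: rigid Procrustes alignment of the root-segment
# markers (scaled local offsets -> measured world positions).
root_pose_guess <- function(skel, trial, t, midx) {
  cmp <- skel$cmp
  root_seg <- cmp$joint_child[which(vapply(
    skel$joints, `[[`, "", "parent_segment") == "")]
  on_root <- which(cmp$marker_seg == root_seg &
                     trial$visible[t, midx])
  q0 <- numeric(cmp$nq)
  if (length(on_root) >= 3L) {
    loc <- cmp$marker_off[, on_root, drop = FALSE] *
      skel$scales[, root_seg]
    wld <- t(trial$positions[t, midx[on_root], , drop = TRUE])
    pr <- procrustes_fit(loc, wld)
    q0[1:3] <- pr$t
    R <- pr$R
    q0[4L] <- atan2(-R[2L, 3L], R[3L, 3L])
    q0[5L] <- asin(max(min(R[1L, 3L], 1), -1))
    q0[6L] <- atan2(-R[1L, 2L], R[1L, 1L])
  } else {
    vis <- which(trial$visible[t, midx])
    if (length(vis))
      q0[1:3] <- colMeans(trial$positions[t, midx[vis], , drop = FALSE])
  }
  q0
}

ik_frame <- function(skel, target, vis, q0, max_iter = 40L,
                     grad_tol = 1e-10) {
  nq <- length(q0)
  q <- q0
  lambda <- 1e-6
  fk <- forward_kinematics_full(skel, q)
  resid <- function(fk) as.numeric(t(target[vis, , drop = FALSE]) -
                                     fk$markers[, vis, drop = FALSE])
  r <- resid(fk)
  f <- sum(r^2)
  for (it in seq_len(max_iter)) {
    J <- marker_jacobians(skel, q, fk = fk, wrt = "q")$Jq
    rows <- as.numeric(outer(1:3, 3L * (vis - 1L), `+`))
    J <- J[rows, , drop = FALSE]
    g <- crossprod(J, r)           # note r = target - fk, so step adds
    if (max(abs(g)) < grad_tol) break
    H <- crossprod(J)
    ok <- FALSE
    for (tries in 1:12) {
      step <- tryCatch(solve(H + lambda * diag(nq), g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        q_new <- q + drop(step)
        fk_new <- forward_kinematics_full(skel, q_new)
        r_new <- resid(fk_new)
        f_new <- sum(r_new^2)
        if (f_new <= f) {
          q <- q_new; fk <- fk_new; r <- r_new
          lambda <- max(lambda / 3, 1e-12)
          ok <- if (f - f_new < 1e-18 + 1e-14 * f) NA else TRUE
          f <- f_new
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!isTRUE(ok)) break
  }
  list(q = q, fk = fk, rmse = sqrt(f / length(vis)),
       grad_inf = max(abs(crossprod(
         marker_jacobians(skel, q, fk = fk, wrt = "q")$Jq[
           as.numeric(outer(1:3, 3L * (vis - 1L), `+`)), , drop = FALSE],
         resid(fk)))))
}

#' Per-frame inverse kinematics with fixed scales and marker offsets
#'
#' Damped Gauss-Newton least-squares marker fit per frame, each frame warm
#' started from the previous; the first frame's root pose comes from rigid
#' alignment of the root-segment markers.  Frames with fewer than three
#' visible markers are interpolated from their neighbours.
#'
#' @param skel a `bm_skeleton` (scales and marker offsets fixed)
#' @param trial a `bm_marker_trial`
#' @param frames integer vector of frames to solve (default all)
#' @param q_init optional T x nq warm start
#' @param max_iter Gauss-Newton cap per frame
#' @return list with `q` (length(frames) x nq), `rmse` per frame,
#'   `frames`, `interpolated` (logical)
#' @export
ik_solve <- function(skel, trial, frames = NULL, q_init = NULL,
                     max_iter = 40L) {
  cmp <- skel$cmp
  T_ <- dim(trial$positions)[1L]
  if (is.null(frames)) frames <- seq_len(T_)
  midx <- match(cmp$marker_lab, trial$labels)
  if (anyNA(midx))
    stop("trial lacks markers: ",
         paste(cmp$marker_lab[is.na(midx)], collapse = ", "))
  q <- matrix(0, length(frames), cmp$nq)
  rmse <- rep(NA_real_, length(frames))
  interp <- logical(length(frames))
  prev <- NULL
  for (k in seq_along(frames)) {
    t <- frames[k]
    vis <- which(trial$visible[t, midx])
    if (length(vis) < 3L) { interp[k] <- TRUE; next }
    target <- trial$positions[t, midx, , drop = TRUE]
    # chain from the previous solved frame (consecutive frames move
    # little); fall back to the supplied warm start, then to the rigid
    # root alignment
    q0 <- if (!is.null(prev)) prev
    else if (!is.null(q_init)) q_init[k, ]
    else root_pose_guess(skel, trial, t, midx)
    sol <- ik_frame(skel, target, vis, q0,
                    max_iter = if (is.null(prev)) max(max_iter, 60L)
                    else max_iter)
    # guard against a poisoned chain: retry from the warm start or the
    # root alignment if the fit is far off
    if (sol$rmse > 0.05) {
      alt <- if (!is.null(q_init)) q_init[k, ]
      else root_pose_guess(skel, trial, t, midx)
      sol2 <- ik_frame(skel, target, vis, alt, max_iter = 60L)
      if (sol2$rmse < sol$rmse) sol <- sol2
    }
    q[k, ] <- sol$q
    rmse[k] <- sol$rmse
    prev <- sol$q
  }
  if (any(interp)) {
    warning(sum(interp), " frames had < 3 visible markers; interpolated")
    good <- which(!interp)
    for (j in seq_len(cmp$nq))
      q[interp, j] <- stats::approx(frames[good], q[good, j],
                                    xout = frames[interp], rule = 2L)$y
  }
  list(q = q, rmse = rmse, frames = frames, interpolated = interp)
}
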