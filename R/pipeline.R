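# Pipeline orchestration: functional joint initialization -> scale
# initialization -> inverse kinematics -> bilevel marker fit ->
# [given GRF] jerk smoothing -> linear COM/mass fit -> iterative angular
# fit -> final mass optimization -> metrics and reports.

# marker clusters (trial-space index arrays) adjacent to one joint
joint_clusters <- function(skel, trial, joint) {
  cmp <- skel$cmp
  midx <- match(cmp$marker_lab, trial$labels)
  pick <- function(seg) {
    ii <- which(cmp$seg_names[cmp$marker_seg] == seg)
    list(pos = trial$positions[, midx[ii], , drop = FALSE],
         vis = trial$visible[, midx[ii], drop = FALSE],
         n = length(ii))
  }
  list(parent = pick(joint$parent_segment),
       child = pick(joint$child_segment))
}

#' Estimate functional joint constraints from marker data
#'
#' For every non-root joint with at least three markers across its two
#' adjacent segments: analytic center-of-rotation start, moving-sphere
#' refinement, axis fit, and the axis-versus-point selection rule.
#'
#' @param skel a `bm_skeleton` (topology/marker set only)
#' @param trial a `bm_marker_trial`
#' @param max_frames frame subsample for the functional fits
#' @return named list (by joint name) of constraints, each carrying
#'   `type`, `centers`, optional `axes`, and the underlying fits
#' @export
functional_joint_constraints <- function(skel, trial, max_frames = 60L) {
  T_ <- dim(trial$positions)[1L]
  ts <- unique(round(seq(1L, T_, length.out = min(T_, max_frames))))
  out <- list()
  for (j in skel$joints) {
    if (j$parent_segment == "") next
    cl <- joint_clusters(skel, trial, j)
    if (cl$parent$n + cl$child$n < 3L || cl$child$n < 2L) next
    pa <- cl$parent$pos[ts, , , drop = FALSE]
    ch <- cl$child$pos[ts, , , drop = FALSE]
    va <- cl$parent$vis[ts, , drop = FALSE]
    vc <- cl$child$vis[ts, , drop = FALSE]
    gl <- tryCatch(closed_form_joint_center(pa, ch, va, vc),
                   error = function(e) NULL)
    if (is.null(gl) || gl$degenerate) next
    sph <- sphere_fit(ch, gl, visible = vc)
    ax <- axis_fit(ch, sph, visible = vc, sphere_rms = sph$rms_residual)
    con <- select_joint_constraint(sph, ax)
    con$frames <- ts
    con$sphere <- sph
    con$axis <- ax
    out[[j$name]] <- con
  }
  out
}

# expand frame-subsampled constraint centers/axes to full-rate via
# interpolation (the scale initializer indexes them by absolute frame)
expand_constraints <- function(constraints, T_) {
  lapply(constraints, function(con) {
    ts <- con$frames
    ex <- function(mat) apply(mat, 2L, function(yy)
      stats::approx(ts, yy, xout = seq_len(T_), rule = 2L)$y)
    con$centers <- ex(con$centers)
    if (!is.null(con$axes)) {
      a <- ex(con$axes)
      con$axes <- a / sqrt(rowSums(a^2))
    }
    con
  })
}

#' Run the full processing pipeline on in-memory objects
#'
#' @param skel generic (unscaled) `bm_skeleton`
#' @param trial a `bm_marker_trial`
#' @param grf optional `bm_grf_trial` (any rate; resampled internally).
#'   When NULL the dynamics stages are skipped and a kinematics-only
#'   solution is returned.
#' @param priors a `bm_priors`
#' @param kinematics_only force skipping the dynamics stages
#' @param max_frames_bilevel frame subsample for the bilevel stage
#' @param verbose print per-stage progress
#' @return a solution list: optimized `skel`, full-rate `q`, `scales`,
#'   `marker_offsets`, marker error metrics, and (with GRF) `total_mass`,
#'   `segment_masses`, residual metrics, `torques`, `angular_iterations`,
#'   plus a per-stage `stage_log`
#' @export
fit_pipeline <- function(skel, trial, grf = NULL,
                         priors = default_priors(),
                         kinematics_only = is.null(grf),
                         max_frames_bilevel = 80L, verbose = FALSE) {
  t0 <- proc.time()[3L]
  log_ <- list()
  note <- function(stage, ...) {
    entry <- c(list(...), wall_s = round(proc.time()[3L] - t0, 2L))
    log_[[stage]] <<- entry
    if (verbose) message(sprintf("[%s] %s", stage,
                                 paste(names(entry), unlist(entry),
                                       sep = "=", collapse = " ")))
  }
  T_ <- dim(trial$positions)[1L]
  dt <- trial$dt

  # 1. functional joint centers and axes
  constraints <- functional_joint_constraints(skel, trial)
  note("functional_joints", n = length(constraints),
       axes = sum(vapply(constraints, function(x)
         x$type == "axis", NA)))
  constraints <- expand_constraints(constraints, T_)

  # 2. scale initialization (alternating with IK), uniform per segment
  sub <- unique(round(seq(1L, T_, length.out = min(T_, 40L))))
  ik0 <- ik_solve(skel, trial, frames = sub)
  q_sub <- ik0$q
  cur <- skel
  for (pass in 1:2) {
    si <- initialize_scales(cur, q_sub, constraints,
                            subset_trial_frames(trial, sub))
    cur <- set_scales(cur, si$scales)
    iks <- ik_solve(cur, trial, frames = sub, q_init = q_sub)
    q_sub <- iks$q
  }
  note("scale_init", objective = si$objective,
       mean_scale = mean(si$scales))

  # 3. bilevel MAP fit (its warm-up re-solves IK on its own subsample;
  # interpolating the scale-init IK between subsample frames is enough
  # of a start)
  q_init <- matrix(0, T_, n_dof(cur))
  for (j in seq_len(n_dof(cur)))
    q_init[, j] <- stats::approx(sub, q_sub[, j], xout = seq_len(T_),
                                 rule = 2L)$y
  note("ik_init", rmse = mean(iks$rmse, na.rm = TRUE))
  bl <- bilevel_fit(cur, list(q = q_init), trial, priors,
                    max_frames = max_frames_bilevel)
  note("bilevel", objective = bl$objective,
       objective_init = bl$objective_init, marker_rmse = bl$marker_rmse)

  sol <- list(skel = bl$skel, q = bl$q, scales = bl$skel$scales,
              marker_offsets = marker_offsets(bl$skel),
              marker_rmse = bl$marker_rmse, marker_max = bl$marker_max,
              objective = bl$objective,
              stationarity_inf = bl$stationarity_inf,
              kinematics_only = TRUE)

  if (kinematics_only || is.null(grf)) {
    sol$stage_log <- log_
    return(sol)
  }

  # 4. dynamics: smoothing, plate assignment, linear COM fit
  grf_m <- resample_grf(grf, trial$time, trial$frame_rate)
  q_smooth <- smooth_jerk(bl$q, dt)
  assignment <- assign_plates_to_feet(bl$skel, q_smooth, grf_m)
  f_tot <- Reduce(`+`, lapply(grf_m$plates, `[[`, "force"))
  Zhat <- com_position(bl$skel, q_smooth)
  cf <- fit_com(Zhat, f_tot, dt, g = bl$skel$gravity,
                fallback_mass = sum(skel$segment_masses))
  fr <- vapply(skel$segments, `[[`, 0, "nominal_mass_fraction")
  skel_d <- set_masses(bl$skel, fr * cf$mass)
  q_d <- apply_com_trajectory(skel_d, q_smooth, cf$Z)
  note("com_fit", mass = cf$mass, rmse = cf$rmse,
       degenerate = cf$degenerate)

  # 5. iterative angular fit
  Zhat_d <- com_position(skel_d, q_smooth)
  Thetahat <- q_smooth[, skel_d$cmp$root_rot, drop = FALSE]
  ang <- fit_angular(skel_d, q_d, Zhat_d, Thetahat, grf_m, assignment,
                     dt, mass = cf$mass)
  note("angular_fit", iterations = ang$iterations,
       converged = ang$converged)

  # 6. final mass optimization + consolidation
  fin <- final_fit(skel_d, ang$q, q_smooth, trial, grf_m, assignment,
                   fit_mass = cf$mass, priors = priors)
  note("final_fit", objective = fin$objective,
       objective_init = fin$objective_init,
       force_pct = fin$residual_after$force_pct,
       torque_pct = fin$residual_after$torque_pct)

  met <- marker_error_metrics(fin$skel, fin$q, trial)
  tq <- joint_torques(fin$skel, fin$q, grf_m, assignment, dt)
  sol$skel <- fin$skel
  sol$q <- fin$q
  sol$q_smooth <- q_smooth
  sol$kinematics_only <- FALSE
  sol$assignment <- assignment
  sol$grf <- grf_m
  sol$total_mass <- fin$total_mass
  sol$segment_masses <- fin$segment_masses
  sol$com_fit <- cf
  sol$marker_rmse <- met$rmse
  sol$marker_max <- met$max
  sol$residual <- fin$residual_after
  sol$residual_force_rms <- fin$residual_after$force_rms
  sol$residual_torque_rms <- fin$residual_after$torque_rms
  sol$residual_force_pct <- fin$residual_after$force_pct
  sol$residual_torque_pct <- fin$residual_after$torque_pct
  sol$angular_iterations <- ang$iterations
  sol$angular_converged <- ang$converged
  sol$torques <- tq
  sol$stage_log <- log_
  sol
}

#' Run the pipeline from files
#'
#' @param config list (or path to a JSON config file) with `skeleton`,
#'   `markers`, optional `grf`, `outdir`, `kinematics_only`, `seed`,
#'   `plate_geometry` (per-plate `list(xlim=, zlim=)`), and prior
#'   overrides (passed to [default_priors()])
#' @return the solution (invisibly writes skeleton JSON, motion MOT,
#'   torque MOT and a JSON report into `outdir`)
#' @export
run_pipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  skel <- read_skeleton_json(config$skeleton)
  trial <- read_trc(config$markers)
  pg <- config$plate_geometry
  geometry <- if (is.data.frame(pg)) {
    # jsonlite simplification turns a list of {xlim, zlim} objects into
    # a data frame with list (or matrix) columns
    pick <- function(col, i) {
      as.numeric(if (is.matrix(col)) col[i, ] else col[[i]])
    }
    lapply(seq_len(nrow(pg)), function(i)
      list(xlim = pick(pg$xlim, i), zlim = pick(pg$zlim, i)))
  } else if (!is.null(pg)) {
    lapply(pg, function(g)
      list(xlim = as.numeric(unlist(g$xlim)),
           zlim = as.numeric(unlist(g$zlim))))
  }
  grf <- if (!is.null(config$grf)) read_grf_mot(config$grf, geometry)
  pr_args <- config[intersect(names(config),
                              names(formals(default_priors)))]
  priors <- do.call(default_priors, pr_args)
  sol <- fit_pipeline(skel, trial, grf, priors = priors,
                      kinematics_only = isTRUE(config$kinematics_only) ||
                        is.null(grf),
                      verbose = isTRUE(config$verbose))
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_skeleton_json(sol$skel, file.path(outdir, "fitted_skeleton.json"))
  write_motion_mot(sol$q, sol$skel, trial$frame_rate,
                   file.path(outdir, "motion.mot"))
  if (!is.null(sol$torques))
    write_motion_mot(sol$torques, sol$skel, trial$frame_rate,
                     file.path(outdir, "torques.mot"))
  sol$seed <- config$seed
  write_report(sol, file.path(outdir, "report.json"))
  invisible(sol)
}

#' Compare two solutions (or a solution against ground truth)
#'
#' @param ours,reference solution lists with at least `q`; optionally
#'   `skel`, `marker_rmse`, residual metrics, `torques`
#' @param skel skeleton giving coordinate names/types (default: ours)
#' @return list of per-metric deltas and per-coordinate angle RMSE
#'   (degrees, rotational coordinates on the shared coordinate set)
#' @export
compare_solutions <- function(ours, reference, skel = ours$skel) {
  cmp <- skel$cmp
  qa <- ours$q; qb <- reference$q
  ca <- colnames(qa) %||% cmp$dof_names
  cb <- colnames(qb) %||% cmp$dof_names
  colnames(qa) <- ca; colnames(qb) <- cb
  shared <- intersect(ca, cb)
  if (length(shared) < length(union(ca, cb)))
    warning("coordinate sets differ; comparing the intersection (",
            length(shared), " coordinates)")
  rot <- shared[cmp$type[match(shared, cmp$dof_names)] == "r"]
  T_ <- min(nrow(qa), nrow(qb))
  d <- qa[seq_len(T_), rot, drop = FALSE] -
    qb[seq_len(T_), rot, drop = FALSE]
  per_coord <- sqrt(colMeans(d^2)) * 180 / pi
  out <- list(joint_angle_rmse_deg = sqrt(mean(d^2)) * 180 / pi,
              per_coordinate_deg = per_coord)
  for (m in c("marker_rmse", "residual_force_pct",
              "residual_torque_pct", "total_mass"))
    if (!is.null(ours[[m]]) && !is.null(reference[[m]]))
      out[[paste0("d_", m)]] <- ours[[m]] - reference[[m]]
  if (!is.null(ours$torques) && !is.null(reference$torques)) {
    ta <- ours$torques; tb <- reference$torques
    nonroot <- setdiff(seq_len(ncol(ta)),
                       c(cmp$root_rot, cmp$root_trans))
    out$joint_torque_rmse <- sqrt(mean(
      (ta[seq_len(T_), nonroot] - tb[seq_len(T_), nonroot])^2))
  }
  out
}
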