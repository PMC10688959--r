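# Readers and writers for the marker/force ecosystem: TRC marker files,
# tab-delimited MOT files (ground reaction forces in, joint angles and
# torques out), JSON reports, plus force-plate-to-foot assignment.

#' Construct a marker trial
#'
#' @param labels character vector of marker labels (unique)
#' @param positions T x M x 3 array of world positions, meters
#' @param frame_rate frames per second
#' @param visible optional T x M logical mask (default: finite positions)
#' @return a `bm_marker_trial`
#' @export
marker_trial <- function(labels, positions, frame_rate, visible = NULL) {
  stopifnot(length(dim(positions)) == 3L, dim(positions)[3L] == 3L,
            dim(positions)[2L] == length(labels))
  if (anyDuplicated(labels)) stop("marker labels must be unique")
  T_ <- dim(positions)[1L]
  if (T_ < 2L) stop("a marker trial needs at least 2 frames")
  if (is.null(visible))
    visible <- apply(is.finite(positions), c(1L, 2L), all)
  structure(list(labels = labels, positions = positions,
                 visible = visible, frame_rate = frame_rate,
                 dt = 1 / frame_rate,
                 time = (seq_len(T_) - 1L) / frame_rate),
            class = "bm_marker_trial")
}

#' @export
print.bm_marker_trial <- function(x, ...) {
  cat(sprintf("<bm_marker_trial> %d frames x %d markers @ %g Hz (%.1f%% visible)\n",
              dim(x$positions)[1L], length(x$labels), x$frame_rate,
              100 * mean(x$visible)))
  invisible(x)
}

#' Read a TRC marker file
#'
#' Positions in mm are converted to meters; blank cells become invisible
#' frames for that marker.
#'
#' @param path file path
#' @return a `bm_marker_trial`
#' @export
read_trc <- function(path) {
  ln <- readLines(path)
  perr <- function(i, msg) stop("TRC parse error at line ", i, " of ",
                                path, ": ", msg, call. = FALSE)
  if (length(ln) < 6L) perr(length(ln), "file too short")
  hdr_keys <- strsplit(ln[2L], "\t", fixed = TRUE)[[1L]]
  hdr_vals <- strsplit(ln[3L], "\t", fixed = TRUE)[[1L]]
  if (length(hdr_vals) < length(hdr_keys))
    hdr_vals <- c(hdr_vals, rep("", length(hdr_keys) - length(hdr_vals)))
  hdr <- stats::setNames(as.list(hdr_vals[seq_along(hdr_keys)]), hdr_keys)
  rate <- as.numeric(hdr$DataRate)
  nfr <- as.integer(hdr$NumFrames)
  nmk <- as.integer(hdr$NumMarkers)
  units <- hdr$Units
  if (!isTRUE(rate > 0)) perr(3L, "bad DataRate")
  if (is.na(nfr) || is.na(nmk)) perr(3L, "bad NumFrames/NumMarkers")
  labs <- strsplit(ln[4L], "\t", fixed = TRUE)[[1L]]
  labs <- labs[-(1:2)]
  labs <- labs[labs != ""]
  if (length(labs) != nmk) perr(4L, sprintf(
    "found %d labels, header says %d markers", length(labs), nmk))
  first_data <- 6L
  while (first_data <= length(ln) && !nzchar(trimws(ln[first_data])))
    first_data <- first_data + 1L
  rows <- ln[first_data:length(ln)]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != nfr) perr(first_data, sprintf(
    "found %d data rows, header says %d frames", length(rows), nfr))
  pos <- array(NA_real_, c(nfr, nmk, 3L))
  for (t in seq_len(nfr)) {
    f <- strsplit(rows[t], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L + 3L * nmk)
      f <- c(f, rep("", 2L + 3L * nmk - length(f)))
    if (length(f) > 2L + 3L * nmk)
      perr(first_data + t - 1L, "too many columns")
    v <- suppressWarnings(as.numeric(f[-(1:2)]))
    pos[t, , ] <- matrix(v, nmk, 3L, byrow = TRUE)
  }
  if (identical(tolower(units), "mm")) pos <- pos / 1000
  marker_trial(labs, pos, rate)
}

#' Write a TRC marker file
#' @param trial a `bm_marker_trial`
#' @param path file path
#' @param units `"m"` or `"mm"`
#' @export
write_trc <- function(trial, path, units = "mm") {
  T_ <- dim(trial$positions)[1L]
  M <- length(trial$labels)
  fac <- if (units == "mm") 1000 else 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)),
    paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
          "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t"),
    paste(trial$frame_rate, trial$frame_rate, T_, M, units,
          trial$frame_rate, 1, T_, sep = "\t"),
    paste(c("Frame#", "Time",
            as.vector(rbind(trial$labels, "", ""))), collapse = "\t"),
    paste(c("", "", paste0(rep(c("X", "Y", "Z"), M),
                           rep(seq_len(M), each = 3L))), collapse = "\t"),
    ""), con)
  for (t in seq_len(T_)) {
    cells <- character(3L * M)
    v <- t(trial$positions[t, , ]) * fac   # 3 x M
    cells[] <- sprintf("%.10f", as.numeric(v))
    hidden <- rep(!trial$visible[t, ], each = 3L)
    cells[hidden] <- ""
    writeLines(paste(c(t, sprintf("%.8f", trial$time[t]), cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

# -- MOT ---------------------------------------------------------------------

read_mot_table <- function(path) {
  ln <- readLines(path)
  end <- which(trimws(ln) == "endheader")
  if (!length(end)) stop("MOT parse error: no endheader in ", path)
  end <- end[1L]
  hdr <- ln[seq_len(end - 1L)]
  in_degrees <- any(grepl("^\\s*inDegrees\\s*=\\s*yes", hdr,
                          ignore.case = TRUE))
  cols <- strsplit(ln[end + 1L], "\t", fixed = TRUE)[[1L]]
  cols <- trimws(cols)
  cols <- cols[nzchar(cols)]
  rows <- ln[-(seq_len(end + 1L))]
  rows <- rows[nzchar(trimws(rows))]
  dat <- matrix(NA_real_, length(rows), length(cols))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(
      strsplit(rows[i], "\t", fixed = TRUE)[[1L]]))
    if (length(v) != length(cols))
      stop("MOT parse error at data row ", i, " of ", path,
           ": expected ", length(cols), " columns, got ", length(v))
    dat[i, ] <- v
  }
  colnames(dat) <- cols
  nrows_hdr <- suppressWarnings(as.integer(
    sub(".*=", "", grep("^\\s*nRows", hdr, value = TRUE)[1L])))
  if (!is.na(nrows_hdr) && nrows_hdr != nrow(dat))
    stop("MOT parse error: nRows=", nrows_hdr, " but ", nrow(dat),
         " data rows in ", path)
  list(data = dat, in_degrees = in_degrees)
}

write_mot_table <- function(dat, path, name = "motion",
                            in_degrees = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name,
               "version=1",
               sprintf("nRows=%d", nrow(dat)),
               sprintf("nColumns=%d", ncol(dat)),
               sprintf("inDegrees=%s", if (in_degrees) "yes" else "no"),
               "endheader",
               paste(colnames(dat), collapse = "\t")), con)
  for (i in seq_len(nrow(dat)))
    writeLines(paste(sprintf("%.10f", dat[i, ]), collapse = "\t"), con)
  invisible(path)
}

#' Construct a ground-reaction-force trial
#'
#' @param plates list of plates, each a list with `force`, `torque`, `cop`
#'   (T x 3 matrices: N, N m, m) and optional `geometry`
#'   (`list(xlim=, zlim=)`, the world-frame rectangle of the plate surface)
#' @param frame_rate frames per second
#' @return a `bm_grf_trial`
#' @export
grf_trial <- function(plates, frame_rate) {
  T_ <- nrow(plates[[1L]]$force)
  for (p in plates)
    stopifnot(nrow(p$force) == T_, nrow(p$torque) == T_,
              nrow(p$cop) == T_, all(is.finite(p$force)))
  structure(list(plates = plates, frame_rate = frame_rate,
                 dt = 1 / frame_rate,
                 time = (seq_len(T_) - 1L) / frame_rate),
            class = "bm_grf_trial")
}

#' @export
print.bm_grf_trial <- function(x, ...) {
  cat(sprintf("<bm_grf_trial> %d plates x %d frames @ %g Hz\n",
              length(x$plates), length(x$time), x$frame_rate))
  invisible(x)
}

#' Read ground reaction forces from a tab-delimited MOT file
#'
#' Expects OpenSim-style columns `ground_force<k>_v{x,y,z}` (force, N),
#' `ground_force<k>_p{x,y,z}` (center of pressure, m) and
#' `ground_torque<k>_{x,y,z}` (free moment, N m) per plate `k`, plus a
#' leading `time` column.
#'
#' @param path file path
#' @param geometry optional list of per-plate `list(xlim=, zlim=)`
#' @return a `bm_grf_trial`
#' @export
read_grf_mot <- function(path, geometry = NULL) {
  tab <- read_mot_table(path)
  dat <- tab$data
  cols <- colnames(dat)
  ks <- sort(unique(as.integer(
    sub("^ground_force([0-9]+)_vx$", "\\1",
        grep("^ground_force[0-9]+_vx$", cols, value = TRUE)))))
  if (!length(ks)) stop("no ground_force<k>_vx columns in ", path)
  time <- dat[, "time"]
  rate <- 1 / stats::median(diff(time))
  plates <- lapply(ks, function(k) {
    gc <- function(fmt) dat[, sprintf(fmt, k), drop = FALSE]
    list(force = cbind(gc("ground_force%d_vx"), gc("ground_force%d_vy"),
                       gc("ground_force%d_vz")),
         cop = cbind(gc("ground_force%d_px"), gc("ground_force%d_py"),
                     gc("ground_force%d_pz")),
         torque = cbind(gc("ground_torque%d_x"), gc("ground_torque%d_y"),
                        gc("ground_torque%d_z")),
         geometry = if (!is.null(geometry)) geometry[[which(ks == k)]])
  })
  grf_trial(plates, rate)
}

#' Write ground reaction forces to a tab-delimited MOT file
#' @param grf a `bm_grf_trial`
#' @param path file path
#' @export
write_grf_mot <- function(grf, path) {
  cols <- list(time = grf$time)
  for (k in seq_along(grf$plates)) {
    p <- grf$plates[[k]]
    for (i in 1:3) cols[[sprintf("ground_force%d_v%s", k, c("x","y","z")[i])]] <- p$force[, i]
    for (i in 1:3) cols[[sprintf("ground_force%d_p%s", k, c("x","y","z")[i])]] <- p$cop[, i]
    for (i in 1:3) cols[[sprintf("ground_torque%d_%s", k, c("x","y","z")[i])]] <- p$torque[, i]
  }
  dat <- do.call(cbind, cols)
  colnames(dat) <- names(cols)
  write_mot_table(dat, path, name = basename(path))
}

#' Write a joint-coordinate trajectory as a MOT motion file
#'
#' Rotational coordinates are written in degrees (`inDegrees=yes`),
#' translations in meters, matching the common motion-file convention.
#'
#' @param q T x nq matrix of generalized coordinates (radians / meters)
#' @param skel the skeleton the coordinates belong to
#' @param frame_rate frames per second
#' @param path file path
#' @export
write_motion_mot <- function(q, skel, frame_rate, path) {
  cmp <- skel$cmp
  rot <- cmp$type == "r"
  out <- q
  out[, rot] <- out[, rot] * 180 / pi
  dat <- cbind(time = (seq_len(nrow(q)) - 1L) / frame_rate, out)
  colnames(dat) <- c("time", cmp$dof_names)
  write_mot_table(dat, path, name = basename(path), in_degrees = TRUE)
}

#' Read a joint-coordinate MOT motion file
#' @param path file path
#' @param skel the skeleton giving coordinate order and types
#' @return list with `q` (T x nq, radians/meters) and `time`
#' @export
read_motion_mot <- function(path, skel) {
  tab <- read_mot_table(path)
  cmp <- skel$cmp
  missing <- setdiff(cmp$dof_names, colnames(tab$data))
  if (length(missing))
    stop("motion file lacks coordinates: ", paste(missing, collapse = ", "))
  q <- tab$data[, cmp$dof_names, drop = FALSE]
  if (tab$in_degrees) q[, cmp$type == "r"] <- q[, cmp$type == "r"] * pi / 180
  list(q = q, time = tab$data[, "time"])
}

#' Resample a GRF trial to marker timestamps
#'
#' Linear interpolation of force, torque and center of pressure at the
#' requested times.
#'
#' @param grf a `bm_grf_trial`
#' @param times numeric vector of target times, seconds
#' @param frame_rate frame rate associated with `times`
#' @return a `bm_grf_trial` at the new rate
#' @export
resample_grf <- function(grf, times, frame_rate) {
  interp <- function(mat) {
    apply(mat, 2L, function(y)
      stats::approx(grf$time, y, xout = times, rule = 2L)$y)
  }
  plates <- lapply(grf$plates, function(p)
    list(force = interp(p$force), torque = interp(p$torque),
         cop = interp(p$cop), geometry = p$geometry))
  grf_trial(plates, frame_rate)
}

#' Assign force plates to feet
#'
#' A plate is assigned, per frame, to the foot whose segment origin lies
#' horizontally inside the plate rectangle and below a height threshold
#' while the plate force magnitude exceeds a threshold; otherwise no
#' assignment.  If both feet qualify for one active plate the foot with
#' the smaller horizontal CoP distance wins (with a warning): a plate is
#' assumed never to be loaded by both feet at once.
#'
#' @param skel a `bm_skeleton`
#' @param q T x nq matrix of joint coordinates (from the kinematic fit)
#' @param grf a `bm_grf_trial` resampled to the same frames
#' @param feet character vector of foot segment names
#' @param force_threshold N, minimum force magnitude (default 10)
#' @param height_threshold m, maximum foot origin height (default 0.05)
#' @return T x n_plates character matrix of foot names (NA = none), with
#'   attribute `plate_foot` giving each plate's majority foot
#' @export
assign_plates_to_feet <- function(skel, q, grf,
                                  feet = c("foot_r", "foot_l"),
                                  force_threshold = 10,
                                  height_threshold = 0.05) {
  T_ <- nrow(q)
  P <- length(grf$plates)
  foot_idx <- match(feet, skel$cmp$seg_names)
  if (anyNA(foot_idx)) stop("unknown foot segments")
  fpos <- array(NA_real_, c(T_, length(feet), 3L))
  for (t in seq_len(T_)) {
    fk <- forward_kinematics_full(skel, q[t, ])
    fpos[t, , ] <- t(fk$xseg[, foot_idx, drop = FALSE])
  }
  out <- matrix(NA_character_, T_, P)
  tied <- 0L
  for (k in seq_len(P)) {
    p <- grf$plates[[k]]
    geo <- p$geometry
    fmag <- sqrt(rowSums(p$force^2))
    for (t in seq_len(T_)) {
      if (fmag[t] <= force_threshold) next
      ok <- logical(length(feet))
      for (j in seq_along(feet)) {
        pt <- fpos[t, j, ]
        inside <- is.null(geo) ||
          (pt[1L] >= geo$xlim[1L] && pt[1L] <= geo$xlim[2L] &&
             pt[3L] >= geo$zlim[1L] && pt[3L] <= geo$zlim[2L])
        ok[j] <- inside && pt[2L] <= height_threshold
      }
      if (sum(ok) == 1L) out[t, k] <- feet[ok]
      else if (sum(ok) > 1L) {
        d <- vapply(which(ok), function(j)
          sum((fpos[t, j, c(1L, 3L)] - p$cop[t, c(1L, 3L)])^2), 0)
        out[t, k] <- feet[which(ok)[which.min(d)]]
        tied <- tied + 1L
      }
    }
  }
  if (tied > 0L)
    warning(tied, " frame-plate pairs had both feet on one active plate; ",
            "assigned the foot nearer the center of pressure")
  plate_foot <- apply(out, 2L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) NA_character_
    else names(sort(table(col), decreasing = TRUE))[1L]
  })
  attr(out, "plate_foot") <- plate_foot
  out
}

# Per-frame external wrench list for the dynamics code.  Frames where a
# plate has no per-frame assignment but nonzero force fall back to the
# plate's majority foot so that small forces around contact transitions
# are not dropped from the balance.
grf_external_wrenches <- function(grf, assignment, t) {
  plate_foot <- attr(assignment, "plate_foot")
  out <- list()
  for (k in seq_along(grf$plates)) {
    p <- grf$plates[[k]]
    f <- p$force[t, ]
    if (all(f == 0) && all(p$torque[t, ] == 0)) next
    foot <- assignment[t, k]
    if (is.na(foot)) foot <- plate_foot[k]
    if (is.na(foot)) next
    out[[length(out) + 1L]] <- list(segment = foot, force = f,
                                    torque = p$torque[t, ],
                                    point = p$cop[t, ])
  }
  out
}

#' Write a JSON processing report
#'
#' @param solution a kinematic or dynamic solution (list-like); metric
#'   fields (`marker_rmse`, `marker_max`, residual metrics, `scales`,
#'   `segment_masses`, per-stage objectives) are serialized
#' @param path file path
#' @export
write_report <- function(solution, path) {
  keep <- intersect(names(solution), c(
    "marker_rmse", "marker_max", "objective", "stage_log", "scales",
    "segment_masses", "total_mass", "residual_force_rms",
    "residual_torque_rms", "residual_force_pct", "residual_torque_pct",
    "angular_iterations", "angular_converged", "seed"))
  jsonlite::write_json(solution[keep], path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
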