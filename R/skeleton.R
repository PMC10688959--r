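# Skeleton definition: a kinematic tree of scalable rigid segments with
# attached optical markers.  Segments are connected by free (6-DOF), ball
# (3-DOF, intrinsic XYZ Euler) or revolute (1-DOF) joints; the tree is
# rooted at exactly one free joint (the pelvis).  All quantities are SI
# (m, kg, s, N, radians) with a Y-up world and gravity along -Y.

SKELETON_FORMAT <- "biomechfit-skeleton-v1"

#' Construct a skeleton
#'
#' @param segments list of segment specs: `name`, `nominal_length` (3-vector,
#'   m, per-axis dimensions), `nominal_mass_fraction`, `inertia_model`
#'   (`"box"` or `"cylinder"`), `com_local` (3-vector, m, unscaled COM
#'   offset in the segment frame).
#' @param joints list of joint specs: `name`, `type` (`"free6"`, `"ball3"`,
#'   `"revolute1"`), `parent_segment` (`""` for the root joint),
#'   `child_segment`, `parent_offset_local`, `child_offset_local`
#'   (3-vectors, m, unscaled), `axis_local` (unit 3-vector, revolute only).
#' @param markers list of marker defs: `label`, `segment`, `offset_local`
#'   (3-vector, m, unscaled), `anatomical` (logical).
#' @param total_mass subject mass in kg, distributed by mass fraction
#' @param gravity world gravity vector, m/s^2
#' @return an object of class `bm_skeleton`
#' @export
skeleton <- function(segments, joints, markers, total_mass = 72.5,
                     gravity = c(0, -9.80665, 0)) {
  seg_names <- vapply(segments, `[[`, "", "name")
  if (anyDuplicated(seg_names)) stop("duplicate segment names")
  fr <- vapply(segments, `[[`, 0, "nominal_mass_fraction")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("segment mass fractions must sum to 1 (got ", sum(fr), ")")
  lab <- vapply(markers, `[[`, "", "label")
  if (anyDuplicated(lab)) stop("duplicate marker labels")
  jtypes <- vapply(joints, `[[`, "", "type")
  jparent <- vapply(joints, `[[`, "", "parent_segment")
  if (sum(jparent == "") != 1L || jtypes[jparent == ""] != "free6")
    stop("joint graph must be rooted at exactly one free6 joint")
  for (j in joints) {
    if (!(j$child_segment %in% seg_names))
      stop("unknown child segment: ", j$child_segment)
    if (j$parent_segment != "" && !(j$parent_segment %in% seg_names))
      stop("unknown parent segment: ", j$parent_segment)
    if (j$type == "revolute1") {
      a <- j$axis_local
      if (abs(sqrt(sum(a^2)) - 1) > 1e-8) stop("revolute axis must be unit")
    }
  }
  for (m in markers)
    if (!(m$segment %in% seg_names)) stop("unknown marker segment: ", m$segment)
  S <- length(segments)
  sk <- structure(list(
    format = SKELETON_FORMAT,
    segments = segments, joints = joints, markers = markers,
    scales = matrix(1, 3L, S, dimnames = list(NULL, seg_names)),
    segment_masses = stats::setNames(fr * total_mass, seg_names),
    gravity = gravity
  ), class = "bm_skeleton")
  sk$cmp <- compile_skeleton(sk)
  refresh_inertia_cache(sk)
}

# local inertia tensors depend only on scales and masses; cache them on
# the skeleton so per-frame dynamics code does not recompute them
refresh_inertia_cache <- function(skel) {
  skel$I_loc <- lapply(seq_len(skel$cmp$S), function(s)
    segment_inertia_local(skel, s))
  skel
}

#' @export
print.bm_skeleton <- function(x, ...) {
  cat(sprintf(
    "<bm_skeleton> %d segments, %d joints (%d DOF), %d markers, %.1f kg\n",
    length(x$segments), length(x$joints), x$cmp$nq, length(x$markers),
    sum(x$segment_masses)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Compilation: expand joints into elementary 1-DOF elements so that all
# kinematics/dynamics code runs a single uniform recursion.  Each element
# applies (1) a fixed pre-translation scaled by the parent segment, then
# (2) one prismatic or revolute DOF.  The last element of a joint also
# carries a post-translation (-child_offset, scaled by the child segment)
# and has the child segment frame attached.

compile_skeleton <- function(sk) {
  seg_names <- vapply(sk$segments, `[[`, "", "name")
  S <- length(seg_names)
  seg_idx <- stats::setNames(seq_len(S), seg_names)

  elems <- list()
  seg_elem <- integer(S)        # element carrying each segment's frame
  seg_parent <- integer(S)      # parent segment index (0 for root segment)
  joint_last_elem <- integer(length(sk$joints))
  joint_child <- integer(length(sk$joints))

  add_elem <- function(parent, type, axis, tpre, tpre_seg, post, post_seg,
                       seg_at, joint) {
    elems[[length(elems) + 1L]] <<- list(
      parent = parent, type = type, axis = axis, tpre = tpre,
      tpre_seg = tpre_seg, post = post, post_seg = post_seg,
      seg_at = seg_at, joint = joint)
    length(elems)
  }

  # breadth-first over joints so parents are compiled before children
  done_seg <- character(0)
  pending <- seq_along(sk$joints)
  order_j <- integer(0)
  root_j <- which(vapply(sk$joints, `[[`, "", "parent_segment") == "")
  queue <- root_j
  done_seg <- sk$joints[[root_j]]$child_segment
  order_j <- root_j
  while (length(order_j) < length(sk$joints)) {
    nxt <- setdiff(which(vapply(sk$joints, `[[`, "", "parent_segment")
                         %in% done_seg), order_j)
    if (!length(nxt)) stop("joint graph is not a connected tree")
    order_j <- c(order_j, nxt)
    done_seg <- c(done_seg, vapply(sk$joints[nxt], `[[`, "", "child_segment"))
  }

  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  for (ji in order_j) {
    j <- sk$joints[[ji]]
    cs <- seg_idx[[j$child_segment]]
    ps <- if (j$parent_segment == "") 0L else seg_idx[[j$parent_segment]]
    parent_elem <- if (ps == 0L) 0L else seg_elem[ps]
    child_off <- -as.numeric(j$child_offset_local %||% c(0, 0, 0))
    par_off <- as.numeric(j$parent_offset_local %||% c(0, 0, 0))
    zero3 <- c(0, 0, 0)
    dofs <- switch(j$type,
      free6 = list(list("p", ex), list("p", ey), list("p", ez),
                   list("r", ex), list("r", ey), list("r", ez)),
      ball3 = list(list("r", ex), list("r", ey), list("r", ez)),
      revolute1 = list(list("r", as.numeric(j$axis_local))),
      stop("unknown joint type: ", j$type))
    n <- length(dofs)
    e_prev <- parent_elem
    for (k in seq_len(n)) {
      last <- k == n
      e_prev <- add_elem(
        parent = e_prev, type = dofs[[k]][[1L]], axis = dofs[[k]][[2L]],
        tpre = if (k == 1L) par_off else zero3,
        tpre_seg = if (k == 1L) ps else 0L,
        post = if (last) child_off else zero3,
        post_seg = if (last) cs else 0L,
        seg_at = if (last) cs else 0L, joint = ji)
    }
    seg_elem[cs] <- e_prev
    seg_parent[cs] <- ps
    joint_last_elem[ji] <- e_prev
    joint_child[ji] <- cs
  }

  E <- length(elems)
  parent <- vapply(elems, `[[`, 0L, "parent")
  type <- vapply(elems, `[[`, "", "type")
  axis <- vapply(elems, `[[`, numeric(3L), "axis")
  tpre <- vapply(elems, `[[`, numeric(3L), "tpre")
  tpre_seg <- vapply(elems, `[[`, 0L, "tpre_seg")
  post <- vapply(elems, `[[`, numeric(3L), "post")
  post_seg <- vapply(elems, `[[`, 0L, "post_seg")
  seg_at <- vapply(elems, `[[`, 0L, "seg_at")
  joint_of <- vapply(elems, `[[`, 0L, "joint")

  # ancestry: anc[e, s] TRUE if element e lies on the path root -> segment s
  anc <- matrix(FALSE, E, S)
  for (s in seq_len(S)) {
    e <- seg_elem[s]
    while (e > 0L) { anc[e, s] <- TRUE; e <- parent[e] }
  }

  M <- length(sk$markers)
  marker_seg <- vapply(sk$markers, function(m) seg_idx[[m$segment]], 0L)
  marker_off <- if (M) vapply(sk$markers, function(m)
    as.numeric(m$offset_local), numeric(3L)) else matrix(0, 3L, 0L)
  marker_anat <- vapply(sk$markers, function(m) isTRUE(m$anatomical), NA)
  marker_lab <- vapply(sk$markers, `[[`, "", "label")

  com_local <- vapply(sk$segments, function(s)
    as.numeric(s$com_local %||% c(0, 0, 0)), numeric(3L))
  nom_len <- vapply(sk$segments, function(s)
    as.numeric(s$nominal_length), numeric(3L))
  inertia_model <- vapply(sk$segments, function(s)
    s$inertia_model %||% "box", "")

  dof_names <- character(E)
  for (e in seq_len(E)) {
    jn <- sk$joints[[joint_of[e]]]$name
    suffix <- if (type[e] == "p") c("tx", "ty", "tz") else c("rx", "ry", "rz")
    k <- sum(joint_of[seq_len(e)] == joint_of[e])
    dof_names[e] <- if (sk$joints[[joint_of[e]]]$type == "revolute1")
      paste0(jn, "_r") else paste0(jn, "_", suffix[(k - 1L) %% 3L + 1L])
  }

  root_rot <- which(type == "r" & joint_of == root_j)
  root_trans <- which(type == "p" & joint_of == root_j)

  children <- lapply(seq_len(E), function(e) which(parent == e))
  seg_marker_idx <- lapply(seq_len(S), function(s) which(marker_seg == s))

  list(nq = E, E = E, S = S, parent = parent, type = type, axis = axis,
       children = children, seg_marker_idx = seg_marker_idx,
       tpre = tpre, tpre_seg = tpre_seg, post = post, post_seg = post_seg,
       seg_at = seg_at, joint_of = joint_of, seg_elem = seg_elem,
       seg_parent = seg_parent, joint_last_elem = joint_last_elem,
       joint_child = joint_child, anc = anc, seg_names = seg_names,
       marker_seg = marker_seg, marker_off = marker_off,
       marker_anat = marker_anat, marker_lab = marker_lab,
       com_local = com_local, nominal_length = nom_len,
       inertia_model = inertia_model, dof_names = dof_names,
       root_rot = root_rot, root_trans = root_trans, n_markers = M)
}

#' Number of generalized coordinates of a skeleton
#' @param skel a `bm_skeleton`
#' @export
n_dof <- function(skel) skel$cmp$nq

#' Set per-segment scales
#'
#' @param skel a `bm_skeleton`
#' @param scales either a 3 x S matrix (per-axis scales, columns in segment
#'   order) or a length-S vector of uniform per-segment scales
#' @return the updated skeleton
#' @export
set_scales <- function(skel, scales) {
  S <- skel$cmp$S
  if (is.matrix(scales)) {
    stopifnot(nrow(scales) == 3L, ncol(scales) == S)
    skel$scales[, ] <- scales
  } else {
    stopifnot(length(scales) == S)
    skel$scales[, ] <- rep(scales, each = 3L)
  }
  if (any(skel$scales <= 0)) stop("scales must be positive")
  refresh_inertia_cache(skel)
}

#' Set segment masses
#' @param skel a `bm_skeleton`
#' @param masses length-S numeric, kg, in segment order (or named)
#' @export
set_masses <- function(skel, masses) {
  if (!is.null(names(masses))) masses <- masses[skel$cmp$seg_names]
  stopifnot(length(masses) == skel$cmp$S, all(masses > 0))
  skel$segment_masses[] <- masses
  refresh_inertia_cache(skel)
}

#' Replace marker local offsets
#' @param skel a `bm_skeleton`
#' @param p 3 x M matrix of local marker offsets (unscaled), meters
#' @export
set_marker_offsets <- function(skel, p) {
  stopifnot(nrow(p) == 3L, ncol(p) == skel$cmp$n_markers)
  for (i in seq_along(skel$markers)) skel$markers[[i]]$offset_local <- p[, i]
  skel$cmp$marker_off <- unname(p)
  skel
}

#' Marker local offsets as a 3 x M matrix
#' @param skel a `bm_skeleton`
#' @export
marker_offsets <- function(skel) skel$cmp$marker_off

#' Standing height of the skeleton
#'
#' Vertical extent (lowest foot frame origin to crown of the most distal
#' segment along +Y) in the zero pose, after scaling.  Used to normalize
#' joint torques by body weight times height.
#' @param skel a `bm_skeleton`
#' @return height in meters
#' @export
skeleton_height <- function(skel) {
  fk <- forward_kinematics_full(skel, numeric(n_dof(skel)))
  tops <- vapply(seq_len(skel$cmp$S), function(s) {
    l <- skel$scales[, s] * skel$cmp$nominal_length[, s]
    pts <- cbind(fk$xseg[, s],
                 fk$xseg[, s] + fk$Rseg[, , s] %*% c(0, l[2L], 0))
    max(pts[2L, ])
  }, 0)
  max(tops) - min(fk$xseg[2L, ])
}

seg_inertia <- function(skel, s) {
  if (!is.null(skel$I_loc)) skel$I_loc[[s]]
  else segment_inertia_local(skel, s)
}

# local inertia tensor (about segment COM, segment axes) for unit axes
segment_inertia_local <- function(skel, s) {
  m <- skel$segment_masses[s]
  l <- skel$scales[, s] * skel$cmp$nominal_length[, s]
  if (skel$cmp$inertia_model[s] == "cylinder") {
    r <- (l[1L] + l[3L]) / 4
    h <- l[2L]
    diag(c(m * (3 * r^2 + h^2) / 12, m * r^2 / 2, m * (3 * r^2 + h^2) / 12))
  } else {
    diag(m / 12 * c(l[2L]^2 + l[3L]^2, l[1L]^2 + l[3L]^2, l[1L]^2 + l[2L]^2))
  }
}

# ---------------------------------------------------------------------------
# JSON serialization

#' Read a skeleton from its JSON description
#'
#' The dialect is a versioned JSON object (`"format":
#' "biomechfit-skeleton-v1"`) with arrays `segments`, `joints`, `markers`
#' and optional `scales` (3 x S), `segment_masses`, `gravity`.
#'
#' @param path file path
#' @return a `bm_skeleton`
#' @export
read_skeleton_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$format, SKELETON_FORMAT))
    stop("not a ", SKELETON_FORMAT, " file: ", path)
  num <- function(v) as.numeric(unlist(v))
  segments <- lapply(x$segments, function(s) list(
    name = s$name, nominal_length = num(s$nominal_length),
    nominal_mass_fraction = as.numeric(s$nominal_mass_fraction),
    inertia_model = s$inertia_model %||% "box",
    com_local = num(s$com_local %||% c(0, 0, 0))))
  joints <- lapply(x$joints, function(j) list(
    name = j$name, type = j$type,
    parent_segment = j$parent_segment %||% "",
    child_segment = j$child_segment,
    parent_offset_local = num(j$parent_offset_local %||% c(0, 0, 0)),
    child_offset_local = num(j$child_offset_local %||% c(0, 0, 0)),
    axis_local = if (!is.null(j$axis_local)) num(j$axis_local)))
  markers <- lapply(x$markers, function(m) list(
    label = m$label, segment = m$segment,
    offset_local = num(m$offset_local),
    anatomical = isTRUE(m$anatomical)))
  sk <- skeleton(segments, joints, markers,
                 total_mass = as.numeric(x$total_mass %||% 72.5),
                 gravity = num(x$gravity %||% c(0, -9.80665, 0)))
  if (!is.null(x$scales))
    sk <- set_scales(sk, matrix(num(x$scales), nrow = 3L))
  if (!is.null(x$segment_masses))
    sk <- set_masses(sk, num(x$segment_masses))
  sk
}

#' Write a skeleton to JSON
#' @param skel a `bm_skeleton`
#' @param path file path
#' @export
write_skeleton_json <- function(skel, path) {
  x <- list(
    format = SKELETON_FORMAT,
    total_mass = sum(skel$segment_masses),
    gravity = skel$gravity,
    segments = skel$segments,
    joints = lapply(skel$joints, function(j) j[!vapply(j, is.null, NA)]),
    markers = skel$markers,
    scales = as.numeric(skel$scales),
    segment_masses = as.numeric(skel$segment_masses))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
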