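# Default full-body gait skeleton: 13 segments, 30 DOF, 43 markers.
# Dimensions and mass fractions follow common anthropometric conventions
# (pelvis-rooted, Y-up, X forward, Z to the subject's right).  Segment
# frames sit at the proximal joint; the foot frame sits at the sole so
# that ground contact reasoning can use the frame origin height.

seg_spec <- function(name, len, frac, model, com) {
  list(name = name, nominal_length = len, nominal_mass_fraction = frac,
       inertia_model = model, com_local = com)
}
joint_spec <- function(name, type, parent, child, par_off,
                       child_off = c(0, 0, 0), axis = NULL) {
  list(name = name, type = type, parent_segment = parent,
       child_segment = child, parent_offset_local = par_off,
       child_offset_local = child_off, axis_local = axis)
}
marker_def <- function(label, segment, off, anatomical = FALSE) {
  list(label = label, segment = segment, offset_local = off,
       anatomical = anatomical)
}

#' Default 13-segment full-body gait skeleton
#'
#' Pelvis, torso, head, and paired thigh/shank/foot/upper-arm/forearm
#' segments; ball joints at hips, lumbar, neck and shoulders, revolute
#' knees, ankles and elbows (flexion about the Z axis); 43 markers, at
#' least one anatomical marker per segment.  Mass fractions sum to one.
#'
#' @param total_mass subject mass in kg
#' @return a `bm_skeleton`
#' @export
default_skeleton <- function(total_mass = 72.5) {
  mirror <- function(x) x * c(1, 1, -1)
  segs <- list(
    seg_spec("pelvis", c(0.15, 0.15, 0.28), 0.142, "box", c(0, 0, 0)),
    seg_spec("torso", c(0.20, 0.45, 0.30), 0.355, "box", c(0, 0.20, 0)),
    seg_spec("head", c(0.15, 0.25, 0.15), 0.081, "cylinder", c(0, 0.10, 0)),
    seg_spec("thigh_r", c(0.12, 0.41, 0.12), 0.100, "cylinder",
             c(0, -0.18, 0)),
    seg_spec("thigh_l", c(0.12, 0.41, 0.12), 0.100, "cylinder",
             c(0, -0.18, 0)),
    seg_spec("shank_r", c(0.09, 0.40, 0.09), 0.0465, "cylinder",
             c(0, -0.17, 0)),
    seg_spec("shank_l", c(0.09, 0.40, 0.09), 0.0465, "cylinder",
             c(0, -0.17, 0)),
    seg_spec("foot_r", c(0.20, 0.08, 0.08), 0.0145, "box", c(0.05, 0.03, 0)),
    seg_spec("foot_l", c(0.20, 0.08, 0.08), 0.0145, "box", c(0.05, 0.03, 0)),
    seg_spec("uarm_r", c(0.08, 0.28, 0.08), 0.028, "cylinder",
             c(0, -0.12, 0)),
    seg_spec("uarm_l", c(0.08, 0.28, 0.08), 0.028, "cylinder",
             c(0, -0.12, 0)),
    seg_spec("forearm_r", c(0.06, 0.25, 0.06), 0.022, "cylinder",
             c(0, -0.11, 0)),
    seg_spec("forearm_l", c(0.06, 0.25, 0.06), 0.022, "cylinder",
             c(0, -0.11, 0)))
  ez <- c(0, 0, 1)
  joints <- list(
    joint_spec("root", "free6", "", "pelvis", c(0, 0, 0)),
    joint_spec("lumbar", "ball3", "pelvis", "torso", c(0, 0.10, 0)),
    joint_spec("neck", "ball3", "torso", "head", c(0, 0.45, 0)),
    joint_spec("hip_r", "ball3", "pelvis", "thigh_r", c(0, -0.07, 0.09)),
    joint_spec("hip_l", "ball3", "pelvis", "thigh_l", c(0, -0.07, -0.09)),
    joint_spec("knee_r", "revolute1", "thigh_r", "shank_r",
               c(0, -0.41, 0), axis = ez),
    joint_spec("knee_l", "revolute1", "thigh_l", "shank_l",
               c(0, -0.41, 0), axis = ez),
    joint_spec("ankle_r", "revolute1", "shank_r", "foot_r",
               c(0, -0.40, 0), child_off = c(0, 0.08, 0), axis = ez),
    joint_spec("ankle_l", "revolute1", "shank_l", "foot_l",
               c(0, -0.40, 0), child_off = c(0, 0.08, 0), axis = ez),
    joint_spec("shoulder_r", "ball3", "torso", "uarm_r", c(0, 0.42, 0.18)),
    joint_spec("shoulder_l", "ball3", "torso", "uarm_l", c(0, 0.42, -0.18)),
    joint_spec("elbow_r", "revolute1", "uarm_r", "forearm_r",
               c(0, -0.28, 0), axis = ez),
    joint_spec("elbow_l", "revolute1", "uarm_l", "forearm_l",
               c(0, -0.28, 0), axis = ez))

  right <- list(
    marker_def("RASI", "pelvis", c(0.09, 0.02, 0.12), TRUE),
    marker_def("RPSI", "pelvis", c(-0.11, 0.03, 0.05), TRUE),
    marker_def("RKNE", "thigh_r", c(0.0, -0.41, 0.06), TRUE),
    marker_def("RKNM", "thigh_r", c(0.0, -0.41, -0.05), TRUE),
    marker_def("RTHI", "thigh_r", c(0.02, -0.22, 0.055)),
    marker_def("RTH2", "thigh_r", c(-0.03, -0.30, 0.05)),
    marker_def("RANK", "shank_r", c(0.0, -0.40, 0.045), TRUE),
    marker_def("RANM", "shank_r", c(0.0, -0.40, -0.04), TRUE),
    marker_def("RTIB", "shank_r", c(0.01, -0.20, 0.05)),
    marker_def("RTB2", "shank_r", c(-0.02, -0.28, 0.045)),
    marker_def("RHEE", "foot_r", c(-0.05, 0.03, 0.0), TRUE),
    marker_def("RTOE", "foot_r", c(0.15, 0.02, 0.01), TRUE),
    marker_def("RMT5", "foot_r", c(0.10, 0.02, 0.04)),
    marker_def("RSHO", "uarm_r", c(0.0, 0.02, 0.05), TRUE),
    marker_def("RELB", "uarm_r", c(0.0, -0.28, 0.04), TRUE),
    marker_def("RUPA", "uarm_r", c(0.01, -0.15, 0.045)),
    marker_def("RWRA", "forearm_r", c(0.01, -0.25, 0.03), TRUE),
    marker_def("RWRB", "forearm_r", c(-0.02, -0.25, -0.03), TRUE),
    marker_def("RFRM", "forearm_r", c(0.0, -0.13, 0.04)))
  left <- lapply(right, function(m) {
    m$label <- sub("^R", "L", m$label)
    m$segment <- sub("_r$", "_l", m$segment)
    m$offset_local <- mirror(m$offset_local)
    m
  })
  axial <- list(
    marker_def("STRN", "torso", c(0.10, 0.25, 0), TRUE),
    marker_def("C7", "torso", c(-0.09, 0.42, 0), TRUE),
    marker_def("T10", "torso", c(-0.10, 0.18, 0)),
    marker_def("CLAV", "torso", c(0.09, 0.38, 0.02)),
    marker_def("RFHD", "head", c(0.07, 0.12, 0.04), TRUE),
    marker_def("LFHD", "head", c(0.07, 0.12, -0.04)),
    marker_def("RBHD", "head", c(-0.07, 0.11, 0.045)),
    marker_def("LBHD", "head", c(-0.07, 0.11, -0.045)))
  skeleton(segs, joints, c(right, left, axial), total_mass = total_mass)
}
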