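# Virtual 6-DOF serial arm: geometric forward kinematics, angle
# normalization, and the dual sensory/motor error used for learning.

.rot3 <- function(axis, theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
         y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
         z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3),
         stop("unknown rotation axis: ", axis))
}

#' Define a 6-DOF serial arm
#'
#' A serial chain of revolute joints with alternating yaw (z) and pitch (y)
#' axes; each link extends along the local x axis. The default link lengths
#' sum to 50 cm so that the default 25 x 30 x 40 cm cuboid workspace is
#' reachable. The workspace cuboid is centered on the dense region of the
#' reachable set under uniformly drawn in-range joint angles.
#'
#' @param link_lengths_cm positive link lengths (cm), one per joint.
#' @param joint_axes rotation axis (`"x"`, `"y"` or `"z"`) per joint.
#' @param angle_range admissible joint angle range in radians (default
#'   `c(0, 4.45)`).
#' @param workspace_dims cuboid extents (cm) along x, y, z.
#' @param workspace_center cuboid center (cm).
#' @return an object of class `arm_model`.
#' @export
arm_model <- function(link_lengths_cm = c(10, 10, 8, 8, 7, 7),
                      joint_axes = c("z", "y", "z", "y", "z", "y"),
                      angle_range = c(0, 4.45),
                      workspace_dims = c(25, 30, 40),
                      workspace_center = c(-2, 2, -2)) {
  if (length(link_lengths_cm) != length(joint_axes))
    stop("need one axis per link")
  if (any(link_lengths_cm <= 0)) stop("link lengths must be positive")
  structure(list(n_joints = length(link_lengths_cm),
                 link_lengths_cm = link_lengths_cm,
                 joint_axes = joint_axes, angle_range = angle_range,
                 workspace_dims = workspace_dims,
                 workspace_center = workspace_center),
            class = "arm_model")
}

#' Forward kinematics of the serial arm
#'
#' Chained-rotation position of the end effector: frame `i` rotates by
#' `theta_i` about its joint axis and translates by the link length along its
#' local x axis. With all angles zero the arm is fully extended along the
#' reference x axis.
#'
#' @param angles joint angles (radians), one per joint.
#' @param arm an [arm_model()].
#' @return end-effector position, numeric xyz (cm).
#' @export
#' @examples
#' arm <- arm_model()
#' forward_kinematics(rep(0, 6), arm)  # c(50, 0, 0)
forward_kinematics <- function(angles, arm) {
  if (length(angles) != arm$n_joints) stop("need one angle per joint")
  if (any(!is.finite(angles))) stop("angles must be finite")
  R <- diag(3)
  p <- c(0, 0, 0)
  for (i in seq_len(arm$n_joints)) {
    R <- R %*% .rot3(arm$joint_axes[i], angles[i])
    p <- p + R %*% c(arm$link_lengths_cm[i], 0, 0)
  }
  as.numeric(p)
}

#' Map raw decoder outputs onto the joint-angle range
#'
#' Affine map of values in (0, 1) onto the arm's angle range (default
#' `[0, 4.45]` radians); invertible on its range via
#' `(angle - lo) / (hi - lo)`.
#'
#' @param raw_outputs numeric vector in (0, 1).
#' @param arm an [arm_model()] (supplies the range).
#' @return joint angles in radians.
#' @export
normalize_angles <- function(raw_outputs, arm = arm_model()) {
  lo <- arm$angle_range[1]; hi <- arm$angle_range[2]
  lo + raw_outputs * (hi - lo)
}

#' Is a point inside the arm's workspace cuboid?
#'
#' @param xyz numeric position (cm).
#' @param arm an [arm_model()].
#' @return logical.
#' @export
in_workspace <- function(xyz, arm) {
  lo <- arm$workspace_center - arm$workspace_dims / 2
  hi <- arm$workspace_center + arm$workspace_dims / 2
  all(xyz >= lo & xyz <= hi)
}

#' Dual sensory and motor errors
#'
#' The motor error is the per-joint difference between desired and predicted
#' joint angles (radians, 6 components); the sensory error is the difference
#' between the target position and the realized end-effector position, i.e.
#' the forward kinematics of the predicted angles (cm, 3 components).
#'
#' @param desired_angles,predicted_angles joint-angle vectors (radians).
#' @param target_xyz target end-effector position (cm).
#' @param arm an [arm_model()].
#' @return a list with `e_m` (motor error, radians), `e_s` (sensory error,
#'   cm) and `realized_xyz`.
#' @export
dual_errors <- function(desired_angles, predicted_angles, target_xyz, arm) {
  realized <- forward_kinematics(predicted_angles, arm)
  list(e_m = desired_angles - predicted_angles,
       e_s = target_xyz - realized,
       realized_xyz = realized)
}
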