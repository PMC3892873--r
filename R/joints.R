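#' The twenty Kinect skeletal joints
#'
#' Fixed joint order used throughout the package: every per-frame feature
#' vector concatenates the (x, y, z) coordinates of the joints in exactly
#' this order, so the order is part of the data contract.
#'
#' @return Character vector of the 20 joint names.
#' @export
#' @examples
#' joint_names()
joint_names <- function() {
  c("HIP_CENTER", "SPINE", "SHOULDER_CENTER", "HEAD",
    "SHOULDER_LEFT", "ELBOW_LEFT", "WRIST_LEFT", "HAND_LEFT",
    "SHOULDER_RIGHT", "ELBOW_RIGHT", "WRIST_RIGHT", "HAND_RIGHT",
    "HIP_LEFT", "KNEE_LEFT", "ANKLE_LEFT", "FOOT_LEFT",
    "HIP_RIGHT", "KNEE_RIGHT", "ANKLE_RIGHT", "FOOT_RIGHT")
}

#' The skeleton bone tree
#'
#' The 19 bones connecting the 20 joints (the standard Kinect hierarchy:
#' a 3-segment trunk, two 4-segment arms hanging off SHOULDER_CENTER and
#' two 4-segment legs hanging off HIP_CENTER).
#'
#' @return A tibble with columns `from` and `to` (joint names), 19 rows.
#' @export
bone_edges <- function() {
  tibble::tibble(
    from = c("HIP_CENTER", "SPINE", "SHOULDER_CENTER",
             "SHOULDER_CENTER", "SHOULDER_LEFT", "ELBOW_LEFT", "WRIST_LEFT",
             "SHOULDER_CENTER", "SHOULDER_RIGHT", "ELBOW_RIGHT", "WRIST_RIGHT",
             "HIP_CENTER", "HIP_LEFT", "KNEE_LEFT", "ANKLE_LEFT",
             "HIP_CENTER", "HIP_RIGHT", "KNEE_RIGHT", "ANKLE_RIGHT"),
    to = c("SPINE", "SHOULDER_CENTER", "HEAD",
           "SHOULDER_LEFT", "ELBOW_LEFT", "WRIST_LEFT", "HAND_LEFT",
           "SHOULDER_RIGHT", "ELBOW_RIGHT", "WRIST_RIGHT", "HAND_RIGHT",
           "HIP_LEFT", "KNEE_LEFT", "ANKLE_LEFT", "FOOT_LEFT",
           "HIP_RIGHT", "KNEE_RIGHT", "ANKLE_RIGHT", "FOOT_RIGHT")
  )
}

# Joint chain used for body-height estimation: trunk segments plus the
# left/right leg chains (averaged across sides).
height_chain <- function() {
  list(
    trunk = list(c("HEAD", "SHOULDER_CENTER"),
                 c("SHOULDER_CENTER", "SPINE"),
                 c("SPINE", "HIP_CENTER")),
    leg_left = list(c("HIP_CENTER", "HIP_LEFT"),
                    c("HIP_LEFT", "KNEE_LEFT"),
                    c("KNEE_LEFT", "ANKLE_LEFT"),
                    c("ANKLE_LEFT", "FOOT_LEFT")),
    leg_right = list(c("HIP_CENTER", "HIP_RIGHT"),
                     c("HIP_RIGHT", "KNEE_RIGHT"),
                     c("KNEE_RIGHT", "ANKLE_RIGHT"),
                     c("ANKLE_RIGHT", "FOOT_RIGHT"))
  )
}

# Upper-body joints trusted in seated (10-joint) tracking mode.
upper_body_joints <- function() {
  c("HIP_CENTER", "SPINE", "SHOULDER_CENTER", "HEAD",
    "SHOULDER_LEFT", "ELBOW_LEFT", "WRIST_LEFT",
    "SHOULDER_RIGHT", "ELBOW_RIGHT", "WRIST_RIGHT")
}
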