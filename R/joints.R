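#' Canonical 20-joint skeleton convention
#'
#' The package fixes the de-facto Kinect-v1 joint order for all skeleton data:
#' 20 joints, indexed 0 to 19, each with (x, y, z) coordinates in meters in a
#' right-handed, y-up frame (documented convention, not enforced). All readers,
#' the preprocessing chain and the synthetic generator use this order.
#'
#' @return A tibble with columns `index` (0-based, as used in file formats),
#'   `position` (1-based row position in a frame matrix) and `name`.
#' @examples
#' kinect_joints()
#' @export
kinect_joints <- function() {
  tibble::tibble(
    index = 0:19,
    position = 1:20,
    name = joint_names()
  )
}

#' @rdname kinect_joints
#' @export
joint_names <- function() {
  c(
    "stomach", "spine", "neck", "head",
    "shoulder_left", "elbow_left", "wrist_left", "hand_left",
    "shoulder_right", "elbow_right", "wrist_right", "hand_right",
    "hip_left", "knee_left", "ankle_left", "foot_left",
    "hip_right", "knee_right", "ankle_right", "foot_right"
  )
}

# 1-based row positions of the anchor joints used throughout.
JOINT <- list(
  stomach = 1L, spine = 2L, neck = 3L, head = 4L,
  shoulder_left = 5L, elbow_left = 6L, wrist_left = 7L, hand_left = 8L,
  shoulder_right = 9L, elbow_right = 10L, wrist_right = 11L, hand_right = 12L,
  hip_left = 13L, knee_left = 14L, ankle_left = 15L, foot_left = 16L,
  hip_right = 17L, knee_right = 18L, ankle_right = 19L, foot_right = 20L
)

N_JOINTS <- 20L

#' Validate a posture frame
#'
#' A posture frame is a 20 x 3 numeric matrix of joint coordinates in the
#' canonical joint order, all entries finite.
#'
#' @param frame Candidate frame.
#' @return The frame, invisibly, with canonical dimnames.
#' @keywords internal
check_frame <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    stop("posture frame must be a numeric matrix", call. = FALSE)
  }
  if (nrow(frame) != N_JOINTS || ncol(frame) != 3L) {
    stop(sprintf(
      "posture frame must be %d x 3, got %d x %d",
      N_JOINTS, nrow(frame), ncol(frame)
    ), call. = FALSE)
  }
  if (!all(is.finite(frame))) {
    stop("posture frame contains non-finite coordinates", call. = FALSE)
  }
  dimnames(frame) <- list(joint_names(), c("x", "y", "z"))
  invisible(frame)
}
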