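#' Ego-centered coordinate basis
#'
#' Builds a body-anchored orthonormal frame from the stomach and the two hip
#' joints, removing global position and orientation so that the same action
#' looks the same from any viewing angle. The origin is the stomach; the
#' lateral axis points from the right hip to the left hip; the forward axis is
#' the unit normal of the stomach/hips plane; the vertical-ish axis completes
#' a right-handed triad.
#'
#' @param frame A 20 x 3 posture frame in canonical joint order.
#' @return An `ego_basis`: list with `origin` (3-vector) and `axes`
#'   (3 x 3 orthonormal matrix, rows = lateral, vertical, forward).
#' @examples
#' f <- matrix(0, 20, 3)
#' f[17, ] <- c(-0.1, -0.05, 0) # right hip
#' f[13, ] <- c(0.1, -0.05, 0)  # left hip
#' f[3, 2] <- 0.5               # neck
#' build_ego_basis(f)$axes
#' @export
build_ego_basis <- function(frame) {
  check_frame(frame)
  stomach <- frame[JOINT$stomach, ]
  rhip <- frame[JOINT$hip_right, ]
  lhip <- frame[JOINT$hip_left, ]

  lateral <- lhip - rhip
  n <- cross3(rhip - stomach, lhip - stomach)
  if (sqrt(sum(n^2)) < 1e-9 || sqrt(sum(lateral^2)) < 1e-9) {
    stop("degenerate pose: stomach and hip joints are collinear or coincident",
         call. = FALSE)
  }
  lateral <- lateral / sqrt(sum(lateral^2))
  forward <- n / sqrt(sum(n^2))
  vertical <- cross3(forward, lateral)

  axes <- rbind(lateral = lateral, vertical = vertical, forward = forward)
  structure(list(origin = stomach, axes = axes), class = "ego_basis")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Transform a frame into an ego-centered basis
#'
#' Maps every joint p to `axes %*% (p - origin)`; the stomach maps to the
#' zero vector.
#'
#' @param frame A 20 x 3 posture frame.
#' @param basis An [build_ego_basis()] result (defaults to the frame's own).
#' @return The transformed 20 x 3 frame.
#' @export
to_ego <- function(frame, basis = build_ego_basis(frame)) {
  check_frame(frame)
  stopifnot(inherits(basis, "ego_basis"))
  out <- sweep(frame, 2L, basis$origin) %*% t(basis$axes)
  dimnames(out) <- list(joint_names(), c("x", "y", "z"))
  out
}

#' Scale a frame to a standard body size
#'
#' Multiplies all coordinates by `target_len / ||neck - stomach||` so the
#' stomach-to-neck segment (approximately rigid across postures) has a fixed
#' length, removing actor size and camera distance.
#'
#' @param frame A 20 x 3 posture frame (typically ego-centered).
#' @param target_len Reference segment length after scaling (default 1).
#' @return The scaled frame.
#' @export
scale_frame <- function(frame, target_len = 1) {
  check_frame(frame)
  ref <- frame[JOINT$neck, ] - frame[JOINT$stomach, ]
  len <- sqrt(sum(ref^2))
  if (len < 1e-9) {
    stop("degenerate pose: stomach-to-neck reference segment has zero length",
         call. = FALSE)
  }
  out <- frame * (target_len / len)
  dimnames(out) <- list(joint_names(), c("x", "y", "z"))
  out
}

#' Full per-frame preprocessing: ego transform then size scaling
#'
#' @inheritParams scale_frame
#' @return The ego-centered, size-normalized frame.
#' @export
preprocess_frame <- function(frame, target_len = 1) {
  scale_frame(to_ego(frame), target_len = target_len)
}

#' Per-joint accumulated motion
#'
#' Sums per-frame displacement magnitudes for each joint over a window of
#' (ego-centered, scaled) frames. Frame rate is assumed constant, so the sum
#' of displacements stands in for velocity.
#'
#' @param frames List of at least two 20 x 3 frames.
#' @return Named numeric vector of 20 non-negative scores.
#' @export
motion_scores <- function(frames) {
  stopifnot(is.list(frames))
  if (length(frames) < 2L) {
    stop("motion scores need at least 2 frames", call. = FALSE)
  }
  scores <- numeric(N_JOINTS)
  for (t in 2:length(frames)) {
    d <- frames[[t]] - frames[[t - 1L]]
    scores <- scores + sqrt(rowSums(d^2))
  }
  names(scores) <- joint_names()
  scores
}

#' Select the most-moving joints (attention mechanism)
#'
#' Picks the `n` joints with the highest accumulated motion; ties go to the
#' lower joint position; the result is ordered by ascending position so the
#' feature layout is deterministic.
#'
#' @param scores Numeric vector of 20 per-joint scores.
#' @param n Number of joints to attend (default 4).
#' @return An `attention_set`: list with `joints` (1-based positions,
#'   ascending) and `scores` (their motion scores).
#' @export
select_attention <- function(scores, n = 4L) {
  stopifnot(length(scores) == N_JOINTS, n >= 1L, n <= N_JOINTS)
  # order() with a position tie-breaker: highest score first, lowest position
  # on ties
  ord <- order(-scores, seq_along(scores))
  picked <- sort(ord[seq_len(n)])
  structure(
    list(joints = as.integer(picked), scores = unname(scores[picked])),
    class = "attention_set"
  )
}

#' Flatten the attended joints of a frame into the SOM input vector
#'
#' Concatenates (x, y, z) of the attended joints in ascending joint order;
#' with the default 4-joint attention this is the 12-dimensional posture
#' vector fed to the first-layer SOM.
#'
#' @param frame A preprocessed 20 x 3 frame.
#' @param attention An [select_attention()] result.
#' @return Numeric vector of length `3 * length(attention$joints)`.
#' @export
frame_to_vector <- function(frame, attention) {
  stopifnot(inherits(attention, "attention_set"))
  as.numeric(t(frame[attention$joints, , drop = FALSE]))
}

#' Preprocess a whole action sequence
#'
#' Applies the per-frame ego transform and scaling, computes whole-sequence
#' motion scores, selects the attention set and returns the matrix of posture
#' vectors.
#'
#' @param x An [action_sequence()].
#' @param target_len Reference length for [scale_frame()].
#' @param n_attend Number of attended joints.
#' @param attention Optional fixed `attention_set` to use instead of the
#'   sequence's own (used by the online recognizer).
#' @return List with `vectors` (n_frames x 3*n_attend matrix), `attention`,
#'   and `frames` (the preprocessed 20 x 3 frames).
#' @export
preprocess_sequence <- function(x, target_len = 1, n_attend = 4L,
                                attention = NULL) {
  stopifnot(inherits(x, "action_sequence"))
  pf <- lapply(x$frames, preprocess_frame, target_len = target_len)
  if (is.null(attention)) {
    attention <- select_attention(motion_scores(pf), n = n_attend)
  }
  vectors <- do.call(rbind, lapply(pf, frame_to_vector, attention = attention))
  list(vectors = vectors, attention = attention, frames = pf)
}
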