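#' Action primitive library
#'
#' Ten one-arm action primitives modeled as parametric displacement curves of
#' the right hand, with the wrist, elbow and shoulder following the same
#' curve at decreasing amplitude (hand > wrist > elbow, shoulder nearly
#' static), mirroring the trajectory structure of real skeleton recordings
#' where distal joints sweep wide arcs and proximal joints barely move.
#'
#' @return Character vector of the primitive names.
#' @export
action_primitives <- function() {
  c("wave_vertical", "wave_horizontal", "punch", "draw_circle", "draw_x",
    "draw_tick", "hammer", "catch", "throw", "swing")
}

# Classes whose natural performance begins by lifting the arm, used by the
# shared-onset switch to reproduce confusable beginnings.
ONSET_CLASSES <- c("wave_vertical", "hammer", "catch", "throw", "draw_x",
                   "draw_circle")

# Unit displacement curve of the hand for one primitive, u in [0, 1].
# Units are meters at amplitude 1, relative to the resting hand position.
primitive_curve <- function(primitive, u) {
  switch(primitive,
    wave_vertical = {
      # raise overhead, then wave side to side at the top
      lift <- pmin(u / 0.3, 1)
      x <- 0.25 * sin(4 * pi * pmax(u - 0.3, 0) / 0.7)
      cbind(x, 1.15 * lift, 0.1 * lift)
    },
    wave_horizontal = {
      ramp <- pmin(u / 0.15, 1)
      cbind(0.45 * sin(4 * pi * u) * ramp, 0.55 * ramp, 0.25 * ramp)
    },
    punch = {
      # two forward thrusts at chest height
      thrust <- abs(sin(2 * pi * u))
      cbind(0, 0.45 * pmin(u / 0.15, 1), 0.85 * thrust)
    },
    draw_circle = {
      ramp <- pmin(u / 0.2, 1)
      ang <- 2 * pi * (u - 0.2) / 0.8
      cbind(0.3 * cos(ang) * ramp, 0.7 + 0.3 * sin(ang) * ramp - 0.3 * (1 - ramp),
            0.35 * ramp)
    },
    draw_x = {
      # stroke top-left -> bottom-right, reposition, top-right -> bottom-left
      p1 <- c(-0.3, 1.0, 0.35); p2 <- c(0.3, 0.45, 0.35)
      p3 <- c(0.3, 1.0, 0.35); p4 <- c(-0.3, 0.45, 0.35)
      piecewise_path(u, list(c(0, 0, 0), p1, p2, p3, p4),
                     breaks = c(0.12, 0.42, 0.58, 1.0))
    },
    draw_tick = {
      p1 <- c(-0.15, 0.85, 0.35); p2 <- c(0.0, 0.55, 0.35)
      p3 <- c(0.35, 1.05, 0.35)
      piecewise_path(u, list(c(0, 0, 0), p1, p2, p3),
                     breaks = c(0.15, 0.5, 1.0))
    },
    hammer = {
      # repeated overhead chop, forward of the body
      lift <- pmin(u / 0.2, 1)
      chop <- 0.3 - 0.45 * abs(sin(3 * pi * pmax(u - 0.2, 0) / 0.8))
      cbind(-0.1 * lift, (0.9 + chop) * lift, 0.3 * lift)
    },
    catch = {
      # reach far forward-up, close, pull back to the chest
      reach <- sin(pi * pmin(u / 0.55, 1))
      hold <- pmax(0, pmin((u - 0.55) / 0.45, 1))
      cbind(0.1 * reach, 0.5 * reach + 0.35 * hold, 0.8 * reach - 0.1 * hold)
    },
    throw = {
      # wind back then release forward-high
      wind <- sin(pi * pmin(u / 0.4, 1))
      rel <- pmax(0, pmin((u - 0.4) / 0.6, 1))
      cbind(-0.15 * wind + 0.1 * rel, 0.55 * wind + 0.65 * rel,
            -0.35 * wind + 1.05 * rel)
    },
    swing = {
      # lateral arc across the body, high to low
      s <- sin(pi * u / 2)
      cbind(0.9 * s - 0.1, 0.55 - 0.75 * s^2, 0.25 + 0.45 * sin(pi * u))
    },
    stop("unknown action primitive: ", primitive, call. = FALSE)
  )
}

# Linear interpolation along waypoints; breaks are the cumulative u at the
# end of each segment.
piecewise_path <- function(u, points, breaks) {
  stopifnot(length(points) == length(breaks) + 1L)
  out <- matrix(0, length(u), 3L)
  prev_b <- 0
  for (k in seq_along(breaks)) {
    b <- breaks[k]
    sel <- u >= prev_b & u <= b
    if (any(sel)) {
      v <- (u[sel] - prev_b) / (b - prev_b)
      a <- points[[k]]; z <- points[[k + 1L]]
      out[sel, ] <- cbind(a[1] + v * (z[1] - a[1]),
                          a[2] + v * (z[2] - a[2]),
                          a[3] + v * (z[3] - a[3]))
    }
    prev_b <- b
  }
  out
}

#' Rest-pose skeleton template
#'
#' An anatomically plausible 20-joint standing pose (meters, y-up, facing
#' +z); stomach-to-neck length 0.45 m; hips and stomach non-collinear.
#'
#' @return A 20 x 3 matrix in canonical joint order.
#' @export
skeleton_template <- function() {
  m <- rbind(
    stomach = c(0, 1.00, 0),
    spine = c(0, 1.15, 0),
    neck = c(0, 1.45, 0),
    head = c(0, 1.65, 0),
    shoulder_left = c(0.20, 1.40, 0),
    elbow_left = c(0.26, 1.12, 0),
    wrist_left = c(0.29, 0.88, 0),
    hand_left = c(0.30, 0.80, 0),
    shoulder_right = c(-0.20, 1.40, 0),
    elbow_right = c(-0.26, 1.12, 0),
    wrist_right = c(-0.29, 0.88, 0),
    hand_right = c(-0.30, 0.80, 0),
    hip_left = c(0.12, 0.88, 0),
    knee_left = c(0.12, 0.50, 0),
    ankle_left = c(0.13, 0.08, 0),
    foot_left = c(0.13, 0.00, 0.06),
    hip_right = c(-0.12, 0.88, 0),
    knee_right = c(-0.12, 0.50, 0),
    ankle_right = c(-0.13, 0.08, 0),
    foot_right = c(-0.13, 0.00, 0.06)
  )
  colnames(m) <- c("x", "y", "z")
  m
}

#' Synthetic skeleton-action generator configuration
#'
#' Defines the study conditions the generator emulates: distinct
#' spatiotemporal action classes performed by a 20-joint skeleton, with
#' per-sequence frame counts in the tens, speed variation that produces runs
#' of near-identical postures, actor variation (global scale, rotation,
#' translation), and additive coordinate noise.
#'
#' @param classes Character vector of class names drawn from
#'   [action_primitives()] (default: all ten).
#' @param amplitude Trajectory amplitude multiplier (1 = life-size reach).
#' @param frames_range Min/max base frames per sequence before speed jitter.
#' @param speed_jitter Range of per-sequence speed multipliers; speeds below
#'   1 stretch the sequence, repeating similar postures.
#' @param noise_sd Stationary SD (meters) of the additive, temporally
#'   correlated (AR(1)) tracker noise per coordinate.
#' @param yaw_range Max absolute random rotation about the vertical axis
#'   (radians) applied to the whole sequence.
#' @param translation_range Max absolute random global translation (meters)
#'   per axis.
#' @param scale_range Range of random global scale multipliers.
#' @param shared_onset If `TRUE`, classes that naturally start by lifting the
#'   arm share an identical arm-lift onset segment, making their beginnings
#'   deliberately confusable.
#' @param seed Generator master seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(classes = action_primitives(), amplitude = 1,
                             frames_range = c(40L, 60L),
                             speed_jitter = c(0.7, 1.3), noise_sd = 0.002,
                             yaw_range = pi, translation_range = 1,
                             scale_range = c(0.8, 1.2),
                             shared_onset = FALSE, seed = 1L) {
  stopifnot(length(classes) >= 1L, all(classes %in% action_primitives()),
            !anyDuplicated(classes),
            frames_range[1L] >= 10L, frames_range[2L] >= frames_range[1L],
            speed_jitter[1L] > 0, speed_jitter[2L] >= speed_jitter[1L],
            noise_sd >= 0, scale_range[1L] > 0,
            scale_range[2L] >= scale_range[1L])
  structure(
    list(classes = classes, amplitude = amplitude,
         frames_range = as.integer(frames_range),
         speed_jitter = speed_jitter, noise_sd = noise_sd,
         yaw_range = yaw_range, translation_range = translation_range,
         scale_range = scale_range, shared_onset = isTRUE(shared_onset),
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Deterministic child seed, kept under 2^31.
child_seed <- function(seed, k) {
  as.integer((as.double(seed %% 49999L) * 40009 + as.double(k) * 7919 +
                12347) %% 2147483629)
}

#' Generate one synthetic action sequence
#'
#' Moves the right-arm chain (hand, wrist, elbow, shoulder at amplitudes
#' 1, 0.8, 0.45, 0.2) along the class primitive's curve, resamples time with
#' a smooth speed profile, adds coordinate noise, and applies a random global
#' rigid motion and scale. Deterministic for a given (config, class, seed).
#'
#' @param config A [generator_config()].
#' @param class_id Class name (in `config$classes`) or index.
#' @param seed Sequence seed.
#' @return A labeled [action_sequence()].
#' @export
generate_sequence <- function(config, class_id, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (is.numeric(class_id)) class_id <- config$classes[class_id]
  if (!class_id %in% config$classes) {
    stop("unknown class: ", class_id, call. = FALSE)
  }
  withr::with_seed(seed, {
    base_frames <- config$frames_range[1L] +
      sample.int(config$frames_range[2L] - config$frames_range[1L] + 1L,
                 1L) - 1L
    speed <- stats::runif(1L, config$speed_jitter[1L], config$speed_jitter[2L])
    n <- max(10L, as.integer(round(base_frames / speed)))

    # smooth within-sequence speed profile, then normalized cumulative time
    phase <- stats::runif(1L, 0, 2 * pi)
    incr <- 1 + 0.35 * sin(2 * pi * seq_len(n) / n + phase)
    u <- cumsum(incr)
    u <- (u - u[1L]) / (u[n] - u[1L])

    hand_disp <- config$amplitude * class_path(class_id, u, config$shared_onset)

    template <- skeleton_template()
    arm <- c(hand = JOINT$hand_right, wrist = JOINT$wrist_right,
             elbow = JOINT$elbow_right, shoulder = JOINT$shoulder_right)
    arm_scale <- c(1, 0.8, 0.45, 0.2)

    # temporally correlated tracker noise (AR(1), stationary sd = noise_sd):
    # skeleton trackers drift smoothly rather than jumping independently
    # frame to frame
    noise <- array(0, dim = c(n, N_JOINTS, 3L))
    if (config$noise_sd > 0) {
      rho <- 0.95
      noise[1L, , ] <- stats::rnorm(N_JOINTS * 3L, sd = config$noise_sd)
      if (n > 1L) {
        for (t in 2:n) {
          noise[t, , ] <- rho * noise[t - 1L, , ] +
            sqrt(1 - rho^2) * stats::rnorm(N_JOINTS * 3L,
                                           sd = config$noise_sd)
        }
      }
    }

    yaw <- stats::runif(1L, -config$yaw_range, config$yaw_range)
    rot <- rbind(c(cos(yaw), 0, sin(yaw)), c(0, 1, 0),
                 c(-sin(yaw), 0, cos(yaw)))
    trans <- stats::runif(3L, -config$translation_range,
                          config$translation_range)
    gscale <- stats::runif(1L, config$scale_range[1L], config$scale_range[2L])

    frames <- lapply(seq_len(n), function(t) {
      f <- template
      for (k in seq_along(arm)) {
        f[arm[k], ] <- f[arm[k], ] + arm_scale[k] * hand_disp[t, ]
      }
      if (config$noise_sd > 0) {
        f <- f + noise[t, , ]
      }
      gscale * (f %*% t(rot)) + matrix(trans, N_JOINTS, 3L, byrow = TRUE)
    })
    action_sequence(frames, label = class_id)
  })
}

# Hand displacement path with onset handling.
class_path <- function(class_id, u, shared_onset) {
  if (shared_onset && class_id %in% ONSET_CLASSES) {
    lift <- c(0, 1.0, 0.15)
    out <- matrix(0, length(u), 3L)
    pre <- u < 0.3
    if (any(pre)) {
      v <- u[pre] / 0.3
      out[pre, ] <- cbind(v * lift[1], v * lift[2], v * lift[3])
    }
    if (any(!pre)) {
      v <- (u[!pre] - 0.3) / 0.7
      g <- primitive_curve(class_id, v)
      blend <- pmin(v / 0.2, 1)
      out[!pre, ] <- (1 - blend) * matrix(lift, sum(!pre), 3L, byrow = TRUE) +
        blend * g
    }
    out
  } else {
    ramp <- pmin(u / 0.12, 1)
    g <- primitive_curve(class_id, pmax(u - 0.12, 0) / 0.88)
    ramp * g
  }
}

#' Generate a balanced labeled dataset
#'
#' @param config A [generator_config()].
#' @param n_per_class Sequences per class.
#' @param seed Master seed; child seeds are derived deterministically.
#' @return List of labeled [action_sequence()] objects, `n_per_class` for
#'   each class in `config$classes`.
#' @export
generate_dataset <- function(config, n_per_class, seed = config$seed) {
  stopifnot(n_per_class >= 1L)
  out <- list()
  for (ci in seq_along(config$classes)) {
    for (j in seq_len(n_per_class)) {
      out[[length(out) + 1L]] <- generate_sequence(
        config, config$classes[ci],
        seed = child_seed(seed, ci * 1009L + j)
      )
    }
  }
  out
}

#' Generate an unsegmented action stream with ground truth
#'
#' Freshly generated sequences are concatenated back to back with no neutral
#' pause; ground-truth intervals (1-based start, exclusive end) delimit each
#' constituent action exactly.
#'
#' @param config A [generator_config()].
#' @param class_order Character or integer vector of classes to perform, in
#'   order.
#' @param seed Master seed.
#' @return An [action_stream()].
#' @export
generate_stream <- function(config, class_order, seed = config$seed) {
  stopifnot(length(class_order) >= 1L)
  if (is.numeric(class_order)) class_order <- config$classes[class_order]
  frames <- list()
  ti <- tibble::tibble(start = integer(0), end = integer(0),
                       label = character(0))
  for (k in seq_along(class_order)) {
    s <- generate_sequence(config, class_order[k],
                           seed = child_seed(seed, 70001L + k))
    start <- length(frames) + 1L
    frames <- c(frames, s$frames)
    ti <- dplyr::bind_rows(ti, tibble::tibble(
      start = start, end = start + n_frames(s), label = s$label
    ))
  }
  action_stream(frames, ti)
}
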