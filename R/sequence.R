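#' Action sequences and streams
#'
#' An `action_sequence` is an ordered list of 20 x 3 posture frames with an
#' optional class label and provenance tags. An `action_stream` is an
#' unsegmented concatenation of actions: the same frame list plus ground-truth
#' intervals `(start, end, label)` with 1-based start and exclusive end.
#'
#' @param frames List of 20 x 3 numeric matrices (canonical joint order).
#' @param label Optional action-class label (character scalar).
#' @param subject_id,event_id Optional provenance tags.
#' @param frame_index Optional strictly increasing integer vector of frame
#'   indices (defaults to `seq_along(frames)`).
#' @return An object of class `action_sequence`.
#' @examples
#' f <- matrix(0, 20, 3)
#' f[3, 2] <- 0.5 # put the neck above the stomach
#' seq <- action_sequence(list(f, f + 0.01), label = "wave")
#' n_frames(seq)
#' @export
action_sequence <- function(frames, label = NULL, subject_id = NULL,
                            event_id = NULL, frame_index = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  frames <- lapply(frames, function(f) {
    check_frame(f)
    dimnames(f) <- list(joint_names(), c("x", "y", "z"))
    f
  })
  if (is.null(frame_index)) frame_index <- seq_along(frames)
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != length(frames) ||
      (length(frame_index) > 1L && any(diff(frame_index) <= 0L))) {
    stop("frame_index must be strictly increasing and match frames",
         call. = FALSE)
  }
  structure(
    list(
      frames = frames, frame_index = frame_index,
      label = if (is.null(label)) NULL else as.character(label),
      subject_id = subject_id, event_id = event_id
    ),
    class = "action_sequence"
  )
}

#' @rdname action_sequence
#' @param truth_intervals A data frame with columns `start`, `end`, `label`:
#'   1-based start frame, exclusive end frame, class label. Intervals must be
#'   sorted, non-overlapping and within the frame range.
#' @export
action_stream <- function(frames, truth_intervals) {
  seq <- action_sequence(frames)
  ti <- tibble::as_tibble(truth_intervals)
  stopifnot(all(c("start", "end", "label") %in% names(ti)))
  ti$start <- as.integer(ti$start)
  ti$end <- as.integer(ti$end)
  ti$label <- as.character(ti$label)
  if (nrow(ti) > 0L) {
    if (any(ti$start < 1L) || any(ti$end > length(frames) + 1L) ||
        any(ti$end <= ti$start)) {
      stop("truth intervals out of frame range", call. = FALSE)
    }
    if (nrow(ti) > 1L && any(ti$start[-1L] < ti$end[-nrow(ti)])) {
      stop("truth intervals overlap or are unsorted", call. = FALSE)
    }
  }
  structure(
    list(frames = seq$frames, frame_index = seq$frame_index,
         truth_intervals = ti),
    class = c("action_stream", "action_sequence")
  )
}

#' @rdname action_sequence
#' @param x An `action_sequence` or `action_stream`.
#' @export
n_frames <- function(x) length(x$frames)

#' @export
print.action_sequence <- function(x, ...) {
  cat(sprintf(
    "<action_sequence> %d frames, 20 joints%s\n", n_frames(x),
    if (is.null(x$label)) "" else sprintf(", label \"%s\"", x$label)
  ))
  invisible(x)
}

#' @export
print.action_stream <- function(x, ...) {
  cat(sprintf(
    "<action_stream> %d frames, %d ground-truth intervals\n",
    n_frames(x), nrow(x$truth_intervals)
  ))
  invisible(x)
}

#' Tabulate a sequence as a tidy frame-by-joint tibble
#'
#' One row per (frame, joint) with coordinates, convenient for ggplot2 and
#' dplyr summaries.
#'
#' @param x An `action_sequence` or `action_stream`.
#' @return A tibble with columns `frame`, `joint`, `x`, `y`, `z`.
#' @export
as_posture_tbl <- function(x) {
  stopifnot(inherits(x, "action_sequence"))
  purrr::map2_dfr(x$frames, x$frame_index, function(f, i) {
    tibble::tibble(
      frame = i, joint = joint_names(),
      x = f[, 1L], y = f[, 2L], z = f[, 3L]
    )
  })
}
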