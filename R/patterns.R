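#' Extract key activations from a winner stream
#'
#' Consecutive repeats of the same winner (similar consecutive postures, e.g.
#' from a slowly performed action) are collapsed to a single key activation,
#' keeping the frame index of the first occurrence. Non-consecutive repeats
#' are retained: the same neuron may appear again later in the sequence.
#' The operation is idempotent and invariant under any consecutive
#' duplication of the input, which is what makes the downstream segmentation
#' robust to performance speed.
#'
#' @param winners Integer matrix `n x 2` of 0-based winner `(row, col)`
#'   coordinates, in stream order.
#' @param source_frames Optional integer vector of originating frame indices
#'   (defaults to `1:n`).
#' @return A tibble with columns `row`, `col`, `source_frame`, one row per
#'   key activation, carrying class `key_activation_seq`.
#' @export
extract_key_activations <- function(winners, source_frames = NULL) {
  if (is.null(dim(winners))) winners <- matrix(winners, ncol = 2L)
  n <- nrow(winners)
  if (n == 0L) stop("empty winner stream", call. = FALSE)
  if (is.null(source_frames)) source_frames <- seq_len(n)
  stopifnot(length(source_frames) == n)
  if (n == 1L) {
    keep <- TRUE
  } else {
    same <- winners[-1L, 1L] == winners[-n, 1L] &
      winners[-1L, 2L] == winners[-n, 2L]
    keep <- c(TRUE, !same)
  }
  out <- tibble::tibble(
    row = as.integer(winners[keep, 1L]),
    col = as.integer(winners[keep, 2L]),
    source_frame = as.integer(source_frames[keep])
  )
  class(out) <- c("key_activation_seq", class(out))
  out
}

#' Segmentation length from training key-activation traces
#'
#' The window length T is seeded by the mean length of the key-activation
#' traces over the training set (rounded half up by default), and is then a
#' plain configuration value that can be tuned; the shipped default
#' configuration uses T = 30.
#'
#' @param key_lengths Integer vector of key-activation trace lengths, or a
#'   list of `key_activation_seq` objects.
#' @param rounding `"half-up"` (default), `"floor"`, or `"ceiling"`.
#' @return Suggested integer T >= 1.
#' @export
mean_key_length <- function(key_lengths, rounding = c("half-up", "floor",
                                                      "ceiling")) {
  rounding <- match.arg(rounding)
  if (is.list(key_lengths)) {
    key_lengths <- vapply(key_lengths, nrow, integer(1))
  }
  if (length(key_lengths) == 0L) {
    stop("no training traces given", call. = FALSE)
  }
  m <- mean(key_lengths)
  t_val <- switch(rounding,
    "half-up" = floor(m + 0.5),
    "floor" = floor(m),
    "ceiling" = ceiling(m)
  )
  max(1L, as.integer(t_val))
}

#' Segment a key-activation sequence into fixed-length pattern windows
#'
#' Cuts the sequence into consecutive, non-overlapping blocks of exactly `T`
#' key activations; a trailing partial block is returned with
#' `complete = FALSE`. The windows partition the input exactly.
#'
#' @param key_seq A `key_activation_seq` tibble.
#' @param T Window length (>= 1).
#' @return List of `pattern_window` objects: each a list with `coords`
#'   (m x 2 integer matrix), `source_frames`, `filled`, `complete`, `T`.
#' @export
segment_stream <- function(key_seq, T) {
  stopifnot(T >= 1L)
  L <- nrow(key_seq)
  starts <- seq.int(1L, L, by = T)
  lapply(starts, function(s) {
    e <- min(s + T - 1L, L)
    new_pattern_window(
      coords = cbind(key_seq$row[s:e], key_seq$col[s:e]),
      source_frames = key_seq$source_frame[s:e],
      T = as.integer(T)
    )
  })
}

new_pattern_window <- function(coords, source_frames, T) {
  filled <- nrow(coords)
  stopifnot(filled <= T)
  structure(
    list(coords = coords, source_frames = as.integer(source_frames),
         filled = as.integer(filled), complete = filled == T,
         T = as.integer(T)),
    class = "pattern_window"
  )
}

#' Encode a pattern window as the second-layer input vector
#'
#' Slot q holds `((row+1)/rows, (col+1)/cols)` of the q-th key activation;
#' unfilled slots hold the padding sentinel (default 0), which is
#' unambiguous because filled entries are always positive. Length is exactly
#' `2T`.
#'
#' @param window A `pattern_window`.
#' @param rows,cols Dimensions of the first-layer SOM lattice.
#' @param pad_value Sentinel for unfilled slots (default 0).
#' @return Numeric vector of length `2 * window$T`.
#' @export
window_to_vector <- function(window, rows, cols, pad_value = 0) {
  stopifnot(inherits(window, "pattern_window"))
  co <- window$coords
  if (window$filled > 0L &&
      (any(co[, 1L] < 0L) || any(co[, 1L] >= rows) ||
       any(co[, 2L] < 0L) || any(co[, 2L] >= cols))) {
    stop("winner coordinate out of grid range", call. = FALSE)
  }
  v <- rep(pad_value, 2L * window$T)
  if (window$filled > 0L) {
    q <- seq_len(window$filled)
    v[2L * q - 1L] <- (co[, 1L] + 1) / rows
    v[2L * q] <- (co[, 2L] + 1) / cols
  }
  v
}

#' Online pattern buffer
#'
#' Streaming counterpart of [extract_key_activations()] +
#' [segment_stream()]: winners arrive one at a time; consecutive duplicates
#' are absorbed; when the buffer holds `T` key activations, the complete
#' window is emitted and the buffer resets to empty (the stream's "updating
#' process"). Feeding a winner stream step by step yields exactly the
#' windows of batch segmentation on the same stream.
#'
#' @param T Window length.
#' @return An empty `pattern_buffer`.
#' @export
pattern_buffer <- function(T) {
  structure(
    list(rows = integer(0), cols = integer(0), frames = integer(0),
         last_row = NA_integer_, last_col = NA_integer_,
         T = as.integer(T)),
    class = "pattern_buffer"
  )
}

#' @rdname pattern_buffer
#' @param buffer A `pattern_buffer`.
#' @param winner 0-based `(row, col)` winner coordinate.
#' @param source_frame Originating frame index.
#' @return List with `buffer` (the updated buffer), `is_key` (did this step
#'   add a key activation), and `emitted` (the completed `pattern_window`,
#'   or `NULL`).
#' @export
online_buffer_step <- function(buffer, winner, source_frame = NA_integer_) {
  # dedup against the last key activation, which survives window resets so
  # that a duplicate straddling a reset collapses exactly as in batch mode
  if (!is.na(buffer$last_row) &&
      buffer$last_row == winner[1L] && buffer$last_col == winner[2L]) {
    return(list(buffer = buffer, is_key = FALSE, emitted = NULL))
  }
  buffer$rows <- c(buffer$rows, as.integer(winner[1L]))
  buffer$cols <- c(buffer$cols, as.integer(winner[2L]))
  buffer$frames <- c(buffer$frames, as.integer(source_frame))
  buffer$last_row <- as.integer(winner[1L])
  buffer$last_col <- as.integer(winner[2L])
  emitted <- NULL
  if (length(buffer$rows) == buffer$T) {
    emitted <- new_pattern_window(
      coords = cbind(buffer$rows, buffer$cols),
      source_frames = buffer$frames, T = buffer$T
    )
    last_r <- buffer$last_row
    last_c <- buffer$last_col
    buffer <- pattern_buffer(buffer$T)
    buffer$last_row <- last_r
    buffer$last_col <- last_c
  }
  list(buffer = buffer, is_key = TRUE, emitted = emitted)
}

#' Current (possibly partial) window held by an online buffer
#'
#' @param buffer A `pattern_buffer`.
#' @return A `pattern_window` with the buffered key activations (may have
#'   `filled = 0`).
#' @export
buffer_window <- function(buffer) {
  new_pattern_window(
    coords = cbind(buffer$rows, buffer$cols),
    source_frames = buffer$frames, T = buffer$T
  )
}
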