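#' MSR-style skeleton text dialect
#'
#' Plain-text skeleton files in the MSR-Action3D family store one joint per
#' row as whitespace-separated numeric columns, 20 joint rows per frame,
#' frames concatenated. Variants differ in columns per row (x y z plus
#' trailing confidence values), rows per joint (some dumps interleave a
#' screen-coordinate row) and an optional header line. The dialect object
#' declares the variant; the default is no header, one row per joint, four
#' columns with the fourth (confidence) ignored.
#'
#' @param columns Numeric columns per joint row (>= 3; only the first three
#'   are kept as x, y, z).
#' @param joints Joints per frame (fixed at 20 in this package).
#' @param rows_per_joint 1 or 2; with 2, the second row of each joint is
#'   skipped.
#' @param header Logical; if `TRUE` the first line of the file is skipped.
#' @return A `msr_dialect` list.
#' @export
msr_dialect <- function(columns = 4L, joints = 20L, rows_per_joint = 1L,
                        header = FALSE) {
  stopifnot(columns >= 3L, joints == N_JOINTS, rows_per_joint %in% c(1L, 2L))
  structure(
    list(columns = as.integer(columns), joints = as.integer(joints),
         rows_per_joint = as.integer(rows_per_joint), header = isTRUE(header)),
    class = "msr_dialect"
  )
}

#' Read an MSR-style skeleton text file
#'
#' @param path Path to the text file.
#' @param dialect A [msr_dialect()] describing the file layout.
#' @param label,subject_id,event_id Optional tags attached to the result
#'   (the format itself carries none).
#' @return An [action_sequence()].
#' @export
read_msr_skeleton <- function(path, dialect = msr_dialect(), label = NULL,
                              subject_id = NULL, event_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  first_data_line <- 1L
  if (dialect$header) first_data_line <- 2L
  data_lines <- lines[seq.int(first_data_line, length(lines))]
  data_lines <- data_lines[nzchar(trimws(data_lines))]

  rows_per_frame <- dialect$joints * dialect$rows_per_joint
  if (length(data_lines) %% rows_per_frame != 0L) {
    stop(sprintf(
      "malformed skeleton file: %d data rows is not a multiple of %d (joints x rows-per-joint); last line %d",
      length(data_lines), rows_per_frame,
      length(lines)
    ), call. = FALSE)
  }

  parse_row <- function(line, lineno) {
    toks <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      stop(sprintf("non-numeric token on line %d: \"%s\"", lineno, line),
           call. = FALSE)
    }
    if (length(vals) < 3L) {
      stop(sprintf("line %d has %d columns, need at least 3", lineno,
                   length(vals)), call. = FALSE)
    }
    vals[1:3]
  }

  n_frames <- length(data_lines) %/% rows_per_frame
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    mat <- matrix(0, N_JOINTS, 3L)
    for (j in seq_len(dialect$joints)) {
      row_in_file <- (f - 1L) * rows_per_frame +
        (j - 1L) * dialect$rows_per_joint + 1L
      lineno <- row_in_file + (first_data_line - 1L)
      mat[j, ] <- parse_row(data_lines[row_in_file], lineno)
    }
    frames[[f]] <- mat
  }
  action_sequence(frames, label = label, subject_id = subject_id,
                  event_id = event_id)
}

#' Write an action sequence in an MSR-style text dialect
#'
#' Inverse of [read_msr_skeleton()] for round-trip checks and export; pads
#' extra columns with zeros.
#'
#' @inheritParams read_msr_skeleton
#' @param x An [action_sequence()].
#' @export
write_msr_skeleton <- function(x, path, dialect = msr_dialect()) {
  stopifnot(inherits(x, "action_sequence"))
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect$header) {
    writeLines(sprintf("%d %d", n_frames(x), dialect$joints), con)
  }
  pad <- rep(0, dialect$columns - 3L)
  for (f in x$frames) {
    for (j in seq_len(N_JOINTS)) {
      writeLines(paste(format(c(f[j, ], pad), digits = 17, trim = TRUE,
                              scientific = FALSE),
                       collapse = " "), con)
      if (dialect$rows_per_joint == 2L) {
        writeLines(paste(rep("0", dialect$columns), collapse = " "), con)
      }
    }
  }
  invisible(path)
}

CANONICAL_FORMAT <- "hsomact-skeleton"
CANONICAL_VERSION <- 1L

#' Canonical JSON skeleton format
#'
#' A self-describing JSON document: `format` and `version` fields, the
#' canonical 20 joint names (validated on read), `frames` as a list of
#' 20 x 3 arrays, and optionally `label`, `subject_id`, `event_id` and
#' `truth_intervals` (records with 1-based `start`, exclusive `end`,
#' `label`). A document with `truth_intervals` reads back as an
#' [action_stream()], otherwise as an [action_sequence()].
#'
#' @param x An `action_sequence` or `action_stream`.
#' @param path Output path.
#' @return `write_canonical_json()` returns `path` invisibly;
#'   `read_canonical_json()` returns the reconstructed object.
#' @export
write_canonical_json <- function(x, path) {
  stopifnot(inherits(x, "action_sequence"))
  doc <- list(
    format = CANONICAL_FORMAT,
    version = CANONICAL_VERSION,
    joints = joint_names(),
    frame_index = x$frame_index,
    frames = lapply(x$frames, function(f) unname(f))
  )
  if (inherits(x, "action_stream")) {
    doc$truth_intervals <- lapply(seq_len(nrow(x$truth_intervals)), function(i) {
      list(start = x$truth_intervals$start[i],
           end = x$truth_intervals$end[i],
           label = x$truth_intervals$label[i])
    })
  } else {
    if (!is.null(x$label)) doc$label <- x$label
    if (!is.null(x$subject_id)) doc$subject_id <- x$subject_id
    if (!is.null(x$event_id)) doc$event_id <- x$event_id
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_canonical_json
#' @export
read_canonical_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, CANONICAL_FORMAT)) {
    stop("not a canonical skeleton document (format field mismatch)",
         call. = FALSE)
  }
  jn <- vapply(doc$joints, as.character, character(1))
  if (!identical(jn, joint_names())) {
    stop("joint-name list does not match the canonical 20-joint convention",
         call. = FALSE)
  }
  frames <- lapply(seq_along(doc$frames), function(i) {
    fr <- doc$frames[[i]]
    if (length(fr) != N_JOINTS) {
      stop(sprintf("frame %d has %d joints, expected %d", i, length(fr),
                   N_JOINTS), call. = FALSE)
    }
    rows <- lapply(fr, function(r) {
      v <- vapply(r, as.numeric, numeric(1))
      if (length(v) != 3L) stop(sprintf("ragged frame %d: joint row of length %d",
                                        i, length(v)), call. = FALSE)
      v
    })
    do.call(rbind, rows)
  })
  frame_index <- if (!is.null(doc$frame_index)) {
    vapply(doc$frame_index, as.integer, integer(1))
  } else NULL
  if (!is.null(doc$truth_intervals)) {
    ti <- purrr::map_dfr(doc$truth_intervals, function(iv) {
      tibble::tibble(start = as.integer(iv$start), end = as.integer(iv$end),
                     label = as.character(iv$label))
    })
    action_stream(frames, ti)
  } else {
    action_sequence(frames, label = doc$label, subject_id = doc$subject_id,
                    event_id = doc$event_id, frame_index = frame_index)
  }
}
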