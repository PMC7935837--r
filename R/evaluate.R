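#' Offline evaluation on pre-segmented test sequences
#'
#' Classifies each labeled test sequence with [classify_sequence()] and
#' tabulates overall accuracy, per-class accuracy and the confusion matrix.
#'
#' @param model A trained `hsom_model`.
#' @param sequences Labeled test [action_sequence()] list.
#' @return An `hsom_eval` object.
#' @export
evaluate_offline <- function(model, sequences) {
  if (length(sequences) == 0L) stop("empty test set", call. = FALSE)
  truth <- vapply(sequences, function(s) s$label %||% NA_character_,
                  character(1))
  if (anyNA(truth)) stop("all test sequences must be labeled", call. = FALSE)
  predicted <- vapply(sequences, function(s) classify_sequence(model, s)$label,
                      character(1))
  new_hsom_eval(
    mode = "offline",
    results = tibble::tibble(truth = truth, predicted = predicted),
    classes = model$classes
  )
}

new_hsom_eval <- function(mode, results, classes, extra = list()) {
  results$correct <- !is.na(results$predicted) &
    results$truth == results$predicted
  per_class <- results |>
    dplyr::group_by(class = .data$truth) |>
    dplyr::summarise(n = dplyr::n(), n_correct = sum(.data$correct),
                     accuracy = mean(.data$correct), .groups = "drop")
  confusion <- results |>
    dplyr::count(truth = .data$truth,
                 predicted = dplyr::coalesce(.data$predicted,
                                             "(no emission)"))
  structure(
    c(list(mode = mode, overall = mean(results$correct),
           n = nrow(results), per_class = per_class, confusion = confusion,
           results = results, classes = classes),
      extra),
    class = "hsom_eval"
  )
}

#' @export
print.hsom_eval <- function(x, ...) {
  cat(sprintf("<hsom_eval> %s: overall accuracy %.3f on %d cases\n",
              x$mode, x$overall, x$n))
  if (!is.null(x$emission_accuracy)) {
    cat(sprintf("  emissions: %d (%d intervals without emission), emission-level accuracy %.3f\n",
                x$n_emissions, x$n_no_emission, x$emission_accuracy))
  }
  print(x$per_class)
  invisible(x)
}

# Majority truth interval of a set of source frames; ties to the earlier
# interval. Returns the interval row index or NA.
majority_interval <- function(frames, intervals) {
  frames <- frames[!is.na(frames)]
  if (length(frames) == 0L || nrow(intervals) == 0L) return(NA_integer_)
  iv <- findInterval(frames, intervals$start)
  iv[iv >= 1L & frames >= intervals$end[pmax(iv, 1L)]] <- NA_integer_
  iv[iv < 1L] <- NA_integer_
  iv <- iv[!is.na(iv)]
  if (length(iv) == 0L) return(NA_integer_)
  counts <- table(iv)
  as.integer(names(counts)[which.max(counts)])
}

#' Online evaluation on unsegmented streams
#'
#' Runs the streaming recognizer over each ground-truth-annotated stream.
#' Every emission is attributed to the truth interval containing the frame
#' at which the certainty gate fired and scored against that interval's
#' label. The
#' report's overall accuracy is interval-level: a truth interval counts as
#' correct iff its last attributed emission (the recognizer's settled answer
#' for that action) carries the right label, and
#' intervals that never receive an emission count as wrong (and are tallied
#' in `n_no_emission`). Emission-level accuracy (correct emissions over all
#' emissions) and per-iteration accuracy curves per class are also returned.
#'
#' @param model A trained `hsom_model`.
#' @param streams List of [action_stream()] objects with truth intervals.
#' @return An `hsom_eval` with extra fields `emission_accuracy`,
#'   `n_emissions`, `n_no_emission`, `curves`, `emissions`, `traces`.
#' @export
evaluate_online <- function(model, streams) {
  if (inherits(streams, "action_stream")) streams <- list(streams)
  if (length(streams) == 0L) stop("empty stream set", call. = FALSE)

  interval_rows <- list()
  emission_rows <- list()
  curve_rows <- list()
  traces <- list()

  for (si in seq_along(streams)) {
    stream <- streams[[si]]
    stopifnot(inherits(stream, "action_stream"))
    iv <- stream$truth_intervals
    out <- run_stream(model, stream)
    traces[[si]] <- dplyr::mutate(out$trace, stream = si, .before = 1L)

    em <- out$emissions
    # attribute each emission to the interval containing the frame at which
    # the gate fired; the recognizer asserts what is happening *now*, and
    # the agreeing predictions that opened the gate came from the most
    # recent key activations
    em$interval <- vapply(em$frame, function(fr)
      majority_interval(fr, iv), integer(1))
    em$truth <- ifelse(is.na(em$interval), NA_character_,
                       iv$label[em$interval])
    em$correct <- !is.na(em$truth) & em$label == em$truth
    em$stream <- si
    emission_rows[[si]] <- em

    for (k in seq_len(nrow(iv))) {
      mine <- em[!is.na(em$interval) & em$interval == k, ]
      # the interval's recognized label is the system's settled answer:
      # the last emission attributed to it
      last_label <- if (nrow(mine) > 0L) {
        mine$label[which.max(mine$frame)]
      } else NA_character_
      interval_rows[[length(interval_rows) + 1L]] <- tibble::tibble(
        stream = si, interval = k, truth = iv$label[k],
        predicted = last_label
      )

      # per-iteration accuracy curve: latched emitted label at iteration j
      # within the interval
      tr <- out$trace[!is.na(out$trace$iteration) &
                        out$trace$frame >= iv$start[k] &
                        out$trace$frame < iv$end[k], ]
      if (nrow(tr) > 0L) {
        latched <- rep(NA_character_, nrow(tr))
        if (nrow(mine) > 0L) {
          for (j in seq_len(nrow(tr))) {
            fired <- mine[mine$frame <= tr$frame[j], ]
            if (nrow(fired) > 0L) {
              latched[j] <- fired$label[which.max(fired$frame)]
            }
          }
        }
        curve_rows[[length(curve_rows) + 1L]] <- tibble::tibble(
          class = iv$label[k], stream = si, interval = k,
          iteration = seq_len(nrow(tr)),
          correct = !is.na(latched) & latched == iv$label[k]
        )
      }
    }
  }

  emissions <- dplyr::bind_rows(emission_rows)
  intervals <- dplyr::bind_rows(interval_rows)
  curves_raw <- dplyr::bind_rows(curve_rows)
  curves <- if (nrow(curves_raw) > 0L) {
    curves_raw |>
      dplyr::group_by(.data$class, .data$iteration) |>
      dplyr::summarise(accuracy = mean(.data$correct), n = dplyr::n(),
                       .groups = "drop")
  } else {
    tibble::tibble(class = character(0), iteration = integer(0),
                   accuracy = numeric(0), n = integer(0))
  }

  new_hsom_eval(
    mode = "online",
    results = tibble::tibble(truth = intervals$truth,
                             predicted = intervals$predicted),
    classes = model$classes,
    extra = list(
      emission_accuracy = if (nrow(emissions) > 0L) {
        mean(emissions$correct)
      } else NA_real_,
      n_emissions = nrow(emissions),
      n_no_emission = sum(is.na(intervals$predicted)),
      curves = curves,
      emissions = emissions,
      intervals = intervals,
      traces = dplyr::bind_rows(traces)
    )
  )
}
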