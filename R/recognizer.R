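#' Configuration of the three-layer recognizer
#'
#' Collects every tunable of the architecture with its default: the
#' first-layer posture SOM (30 x 30, 12-dim input from 4 attended joints),
#' the second-layer pattern SOM (35 x 35, input length 2T), the supervised
#' output head, the segmentation length T = 30, the preprocessing settings
#' and the online certainty gate (N_c = 5 consecutive agreeing predictions,
#' the low end of the 5-7 band, minimizing latency).
#'
#' `layer1_sigma_exp` defaults to `1e6`; there the activity is only ranked,
#' so the value is inert. The second-layer activity map that feeds the output
#' head is computed winner-relative (normalized so the winner's activity is
#' 1, a pure rescaling that the cosine head cannot see) with
#' `layer2_sigma_exp` defaulting to 0.02 -- the scale of meaningful
#' net-input differences between distinct pattern windows -- so the map
#' keeps real contrast between strongly and weakly matching neurons; see the
#' methods vignette for the numerical rationale.
#'
#' @param layer1_rows,layer1_cols First-layer lattice size.
#' @param layer2_rows,layer2_cols Second-layer lattice size.
#' @param layer1_epochs,layer2_epochs Training passes for each SOM.
#' @param layer1_sigma_exp,layer2_sigma_exp Exponential activity factors.
#' @param alpha0 Initial first-layer SOM adaptation strength.
#' @param layer2_alpha0 Initial second-layer adaptation strength; higher than
#'   the first layer's because far fewer pattern windows than posture frames
#'   are available per run.
#' @param layer1_nb_end Final neighborhood width of the first-layer
#'   schedule; it sets the granularity of posture quantization, and with it
#'   how readily near-identical postures collapse to one key activation.
#'   The default of 1.5 keeps quantization bins wide enough that smooth
#'   speed variation does not inflate the key trace (stabilizing window
#'   content across repetitions) while preserving posture discrimination.
#' @param layer2_nb_end Final neighborhood width of the second-layer
#'   schedule; below 1 so that the pattern map differentiates down to
#'   near-single-neuron granularity.
#' @param T Segmentation window length (key activations per pattern window).
#' @param pad_value Padding sentinel for unfilled window slots.
#' @param target_len Stomach-to-neck length after size scaling.
#' @param n_attend Number of attended joints.
#' @param attention_buffer Trailing frames used for online attention.
#' @param head_beta,head_epochs Output-head learning rate and passes.
#' @param n_c Certainty-gate length (consecutive identical predictions
#'   required before emission), in the 5-7 band.
#' @param gate_min_fill Minimum number of key activations the current window
#'   must hold before its classification is allowed to feed the certainty
#'   gate: certainty is only meaningful once the sliding window actually
#'   contains a substantial part of an action's key activations.
#' @param substr_offset_step,substr_len_step,substr_min_len,substr_cap
#'   Phase-2 substring augmentation: the output head (and, for complete
#'   offset windows, the second-layer SOM) is trained on contiguous
#'   substrings of each training key trace -- start offsets every
#'   `substr_offset_step` keys, lengths from `substr_min_len` up to T every
#'   `substr_len_step` -- because in a running stream a freshly reset window
#'   picks up an action at an arbitrary key offset. Substrings shorter than
#'   `substr_min_len` are intrinsically ambiguous (several actions can share
#'   a short sub-movement) and are left out. `substr_cap` bounds the
#'   training substrings per class so long key traces do not bias the head.
#' @param squared_distance,sign_as_printed Variant flags, see [som_params()]
#'   and [head_init()].
#' @param seed Master seed for all randomness in training.
#' @return An `hsom_config` list.
#' @export
hsom_config <- function(layer1_rows = 30L, layer1_cols = 30L,
                        layer2_rows = 35L, layer2_cols = 35L,
                        layer1_epochs = 20L, layer2_epochs = 60L,
                        layer1_sigma_exp = 1e6, layer2_sigma_exp = 0.02,
                        alpha0 = 0.2, layer2_alpha0 = 0.3,
                        layer1_nb_end = 1.5, layer2_nb_end = 0.5,
                        T = 30L, pad_value = 0,
                        target_len = 1, n_attend = 4L,
                        attention_buffer = 15L,
                        head_beta = 0.01, head_epochs = 100L, n_c = 5L,
                        gate_min_fill = 10L,
                        substr_offset_step = 4L, substr_len_step = 3L,
                        substr_min_len = 12L, substr_cap = 300L,
                        mixed_per_seq = 12L,
                        squared_distance = FALSE, sign_as_printed = FALSE,
                        seed = 1L) {
  stopifnot(T >= 1L, n_c >= 1L, attention_buffer >= 2L, gate_min_fill >= 0L)
  structure(
    list(layer1_rows = as.integer(layer1_rows),
         layer1_cols = as.integer(layer1_cols),
         layer2_rows = as.integer(layer2_rows),
         layer2_cols = as.integer(layer2_cols),
         layer1_epochs = as.integer(layer1_epochs),
         layer2_epochs = as.integer(layer2_epochs),
         layer1_sigma_exp = layer1_sigma_exp,
         layer2_sigma_exp = layer2_sigma_exp,
         alpha0 = alpha0, layer2_alpha0 = layer2_alpha0,
         layer1_nb_end = layer1_nb_end, layer2_nb_end = layer2_nb_end,
         T = as.integer(T), pad_value = pad_value,
         target_len = target_len, n_attend = as.integer(n_attend),
         attention_buffer = as.integer(attention_buffer),
         head_beta = head_beta, head_epochs = as.integer(head_epochs),
         n_c = as.integer(n_c), gate_min_fill = as.integer(gate_min_fill),
         substr_offset_step = as.integer(substr_offset_step),
         substr_len_step = as.integer(substr_len_step),
         substr_min_len = as.integer(substr_min_len),
         substr_cap = as.integer(substr_cap),
         mixed_per_seq = as.integer(mixed_per_seq),
         squared_distance = isTRUE(squared_distance),
         sign_as_printed = isTRUE(sign_as_printed),
         seed = as.integer(seed)),
    class = "hsom_config"
  )
}

#' Stratified train/test split
#'
#' Randomly splits labeled sequences class by class; a class with fewer than
#' two instances is kept whole in the training set with a warning.
#'
#' @param sequences List of labeled [action_sequence()] objects.
#' @param fraction Training fraction in (0, 1).
#' @param seed Split seed.
#' @return List with `train` and `test` (disjoint, union = input).
#' @export
split_dataset <- function(sequences, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  labels <- vapply(sequences, function(s) s$label %||% NA_character_,
                   character(1))
  if (anyNA(labels)) stop("all sequences must be labeled", call. = FALSE)
  train_idx <- integer(0)
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < 2L) {
        warning(sprintf("class \"%s\" has < 2 instances; kept whole in train",
                        cl), call. = FALSE)
        train_idx <- c(train_idx, idx)
        next
      }
      n_train <- max(1L, min(length(idx) - 1L,
                             as.integer(floor(fraction * length(idx) + 0.5))))
      train_idx <- c(train_idx, sample(idx, n_train))
    }
  })
  train_idx <- sort(train_idx)
  list(train = sequences[train_idx],
       test = sequences[setdiff(seq_along(sequences), train_idx)])
}

#' Train the full three-layer model
#'
#' Two-phase protocol: phase 1 trains the first-layer SOM on the
#' preprocessed posture vectors of all training frames; phase 2 freezes it,
#' maps every training sequence to its key-activation windows, trains the
#' second-layer SOM on the encoded pattern windows, and finally trains the
#' supervised head on the second-layer activity maps with one-hot targets.
#' Fully deterministic given (data, config).
#'
#' @param sequences Labeled training [action_sequence()] list (>= 2 classes).
#' @param config An [hsom_config()].
#' @param verbose Print phase progress.
#' @return An `hsom_model` bundle.
#' @export
train_model <- function(sequences, config = hsom_config(), verbose = FALSE) {
  labels <- vapply(sequences, function(s) s$label %||% NA_character_,
                   character(1))
  if (length(sequences) == 0L) stop("empty training set", call. = FALSE)
  if (anyNA(labels)) stop("all training sequences must be labeled",
                          call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("training needs at least 2 classes", call. = FALSE)
  }

  if (verbose) message("phase 1: preprocessing + first-layer SOM")
  prep <- lapply(sequences, preprocess_sequence,
                 target_len = config$target_len, n_attend = config$n_attend)
  all_vectors <- do.call(rbind, lapply(prep, `[[`, "vectors"))

  l1 <- som_grid(som_params(
    rows = config$layer1_rows, cols = config$layer1_cols,
    input_dim = 3L * config$n_attend, sigma_exp = config$layer1_sigma_exp,
    alpha0 = config$alpha0, nb_sigma_end = config$layer1_nb_end,
    epochs = config$layer1_epochs,
    squared_distance = config$squared_distance, seed = config$seed
  ))
  l1 <- som_train(l1, all_vectors, verbose = verbose)

  if (verbose) message("phase 2: pattern windows + second-layer SOM")
  # Encode the substring of a key trace starting after `o` keys, length `m`,
  # as a zero-padded pattern vector. Offset 0 with m = min(T, L) is the
  # ordinary first window.
  encode_substring <- function(keys, o, m) {
    v <- rep(config$pad_value, 2L * config$T)
    idx <- (o + 1L):(o + m)
    q <- seq_len(m)
    v[2L * q - 1L] <- (keys$row[idx] + 1) / config$layer1_rows
    v[2L * q] <- (keys$col[idx] + 1) / config$layer1_cols
    v
  }

  win_vectors <- list()      # action-aligned windows (layer-2 + head)
  off_vectors <- list()      # complete windows at key offsets (layer 2)
  sub_vectors <- list()      # substrings of key traces (head)
  win_labels <- integer(0)
  sub_labels <- integer(0)
  key_lengths <- integer(0)
  keyseqs <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    winners <- som_map(l1, prep[[i]]$vectors)
    keys <- extract_key_activations(winners)
    keyseqs[[i]] <- keys
    L <- nrow(keys)
    key_lengths <- c(key_lengths, L)
    lab <- match(labels[i], classes)
    for (w in segment_stream(keys, config$T)) {
      win_vectors[[length(win_vectors) + 1L]] <-
        window_to_vector(w, config$layer1_rows, config$layer1_cols,
                         pad_value = config$pad_value)
      win_labels <- c(win_labels, lab)
    }
    # in a stream, a freshly reset window picks up the ongoing action at an
    # arbitrary key offset: train on shifted windows and their tails too
    for (o in seq(0L, max(L - config$substr_min_len, 0L),
                  by = config$substr_offset_step)) {
      top <- min(config$T, L - o)
      if (top < config$substr_min_len) next
      if (o > 0L) {
        off_vectors[[length(off_vectors) + 1L]] <- encode_substring(keys, o, top)
      }
      for (m in unique(c(seq(config$substr_min_len, top,
                             by = config$substr_len_step), top))) {
        sub_vectors[[length(sub_vectors) + 1L]] <- encode_substring(keys, o, m)
        sub_labels <- c(sub_labels, lab)
      }
    }
  }
  # boundary-style windows: a stale tail of another sequence's key trace in
  # the early slots, this sequence's opening keys after it -- the shape a
  # stream window takes while straddling an action boundary
  mix_vectors <- list()
  mix_labels <- integer(0)
  if (config$mixed_per_seq > 0L && length(sequences) > 1L) {
    withr::with_seed(config$seed + 5L, {
      for (i in seq_along(sequences)) {
        Li <- nrow(keyseqs[[i]])
        for (r in seq_len(config$mixed_per_seq)) {
          j <- sample(setdiff(seq_along(sequences), i), 1L)
          Lj <- nrow(keyseqs[[j]])
          k <- sample(3:12, 1L)
          k <- min(k, Lj)
          m <- min(config$T - k, Li)
          if (m < config$substr_min_len) next
          head_i <- encode_substring(keyseqs[[i]], 0L, m)
          v <- rep(config$pad_value, 2L * config$T)
          tail_j <- encode_substring(keyseqs[[j]], Lj - k, k)
          v[seq_len(2L * k)] <- tail_j[seq_len(2L * k)]
          v[(2L * k + 1L):(2L * (k + m))] <- head_i[seq_len(2L * m)]
          mix_vectors[[length(mix_vectors) + 1L]] <- v
          mix_labels <- c(mix_labels, match(labels[i], classes))
        }
      }
    })
  }

  win_matrix <- do.call(rbind, c(win_vectors, off_vectors, mix_vectors))

  l2 <- som_grid(som_params(
    rows = config$layer2_rows, cols = config$layer2_cols,
    input_dim = 2L * config$T, sigma_exp = config$layer2_sigma_exp,
    alpha0 = config$layer2_alpha0, nb_sigma_end = config$layer2_nb_end,
    epochs = config$layer2_epochs,
    squared_distance = config$squared_distance, seed = config$seed + 1L
  ))
  l2 <- som_train(l2, win_matrix, verbose = verbose)

  if (verbose) message("phase 2: supervised output head")
  # aligned windows + substrings, balanced per class so long key traces do
  # not dominate the head
  head_vectors <- c(win_vectors, sub_vectors, mix_vectors)
  head_labels <- c(win_labels, sub_labels, mix_labels)
  keep <- withr::with_seed(config$seed + 4L, {
    unlist(lapply(split(seq_along(head_labels), head_labels), function(idx) {
      if (length(idx) > config$substr_cap) sample(idx, config$substr_cap)
      else idx
    }), use.names = FALSE)
  })
  head_matrix <- do.call(rbind, head_vectors)[keep, , drop = FALSE]
  act_maps <- t(apply(head_matrix, 1L, function(v) {
    winner_relative_activity(net_input(l2, v), config$layer2_sigma_exp)
  }))
  head <- head_init(length(classes), config$layer2_rows * config$layer2_cols,
                    seed = config$seed + 2L)
  head <- head_train(head, act_maps, head_labels[keep],
                     beta = config$head_beta,
                     epochs = config$head_epochs, seed = config$seed + 3L,
                     sign_as_printed = config$sign_as_printed)

  structure(
    list(layer1 = l1, layer2 = l2, head = head, classes = classes,
         config = config, key_lengths = key_lengths,
         version = 1L),
    class = "hsom_model"
  )
}

#' @export
print.hsom_model <- function(x, ...) {
  cat(sprintf(
    "<hsom_model> layers %dx%d -> %dx%d -> %d classes (T = %d)\n",
    x$config$layer1_rows, x$config$layer1_cols,
    x$config$layer2_rows, x$config$layer2_cols,
    length(x$classes), x$config$T
  ))
  invisible(x)
}

# Winner-relative activity map: exp(-(s - min(s)) / sigma). A positive
# rescaling of the plain exponential activity (invisible to the cosine
# head), but numerically stable at sharp sigma and scale-stable for the
# head's updates.
winner_relative_activity <- function(net, sigma_exp) {
  exp(-(net - min(net)) / sigma_exp)
}

# Layer-2 activity map for one encoded pattern window.
pattern_activity <- function(model, window) {
  v <- window_to_vector(window, model$config$layer1_rows,
                        model$config$layer1_cols,
                        pad_value = model$config$pad_value)
  winner_relative_activity(net_input(model$layer2, v),
                           model$config$layer2_sigma_exp)
}

#' Classify one pre-segmented action sequence (offline mode)
#'
#' Runs the full chain on a single sequence and classifies its first
#' (complete or partial) pattern window.
#'
#' @param model A trained `hsom_model`.
#' @param sequence An [action_sequence()].
#' @return List with `label` (predicted class name), `activities` (head
#'   activities, named by class), `n_keys` (key-activation count).
#' @export
classify_sequence <- function(model, sequence) {
  stopifnot(inherits(model, "hsom_model"))
  prep <- preprocess_sequence(sequence, target_len = model$config$target_len,
                              n_attend = model$config$n_attend)
  winners <- som_map(model$layer1, prep$vectors)
  keys <- extract_key_activations(winners)
  if (nrow(keys) == 0L) stop("sequence yields zero key activations",
                             call. = FALSE)
  win <- segment_stream(keys, model$config$T)[[1L]]
  a <- pattern_activity(model, win)
  pred <- head_predict(model$head, a)
  acts <- pred$activities
  names(acts) <- model$classes
  list(label = model$classes[pred$label], activities = acts,
       n_keys = nrow(keys))
}

#' Online recognizer state
#'
#' Holds the trailing attention buffer, the pattern-window buffer, the
#' certainty gate and the iteration counter for one stream.
#'
#' @param model A trained `hsom_model`.
#' @return A `stream_state`.
#' @export
stream_state <- function(model) {
  structure(
    list(buffer = pattern_buffer(model$config$T),
         attention = NULL,
         att_frames = list(),
         prev_frame = NULL,
         iteration = 0L,
         frames_since_key = 0L,
         gate_label = NA_integer_, gate_streak = 0L,
         last_emitted = NA_integer_),
    class = "stream_state"
  )
}

#' One streaming step of the online recognizer
#'
#' Processes one posture frame: a frame identical to the previous one does
#' not count as an iteration; otherwise the frame is preprocessed, attended,
#' quantized by the first-layer SOM and pushed through the online pattern
#' buffer. Whenever a new key activation arrives, the current (zero-padded)
#' window is classified and the prediction fed to the certainty gate, which
#' emits a label only after `n_c` consecutive identical predictions and does
#' not re-emit the same label until the next window reset. A completed
#' window resets the buffer, the gate, and re-evaluates the attention set
#' from the trailing frame buffer (after the iteration is scored).
#'
#' @param model A trained `hsom_model`.
#' @param state A `stream_state`.
#' @param frame A 20 x 3 posture frame.
#' @param frame_index Index of the frame in the stream (for the trace).
#' @return List with `state`, `emission` (`NULL` or a list with `label`,
#'   `frame`, `source_frames`), and `record` (a one-row trace tibble).
#' @export
stream_step <- function(model, state, frame, frame_index = NA_integer_) {
  cfg <- model$config
  record <- tibble::tibble(
    frame = as.integer(frame_index), iteration = NA_integer_,
    is_key = FALSE, prediction = NA_character_,
    gate_streak = NA_integer_, emitted = FALSE
  )

  if (!is.null(state$prev_frame) && identical(dim(frame), dim(state$prev_frame)) &&
      all(frame == state$prev_frame)) {
    return(list(state = state, emission = NULL, record = record))
  }
  state$prev_frame <- frame
  state$iteration <- state$iteration + 1L
  record$iteration <- state$iteration

  pf <- preprocess_frame(frame, target_len = cfg$target_len)
  state$att_frames <- c(state$att_frames, list(pf))
  nb <- length(state$att_frames)
  if (nb > cfg$attention_buffer) {
    state$att_frames <- state$att_frames[(nb - cfg$attention_buffer + 1L):nb]
  }
  if (is.null(state$attention)) {
    # wait for a full trailing buffer before the first attention evaluation:
    # two or three frames of motion are noise-dominated, and a wrong joint
    # set would garble the whole first pattern window
    if (length(state$att_frames) < cfg$attention_buffer) {
      return(list(state = state, emission = NULL, record = record))
    }
    state$attention <- select_attention(motion_scores(state$att_frames),
                                        n = cfg$n_attend)
  }

  # stall recovery: a degenerate attention set can freeze the winner, so no
  # key ever arrives, the window never completes and the normal reset-time
  # re-evaluation never triggers; after a full buffer span without a key
  # activation, re-evaluate attention from the trailing frames
  if (state$frames_since_key >= cfg$attention_buffer) {
    state$attention <- select_attention(motion_scores(state$att_frames),
                                        n = cfg$n_attend)
    state$frames_since_key <- 0L
  }

  x <- frame_to_vector(pf, state$attention)
  winner <- som_map_vector(model$layer1, x)
  res <- online_buffer_step(state$buffer, winner, frame_index)
  state$buffer <- res$buffer
  state$frames_since_key <- if (res$is_key) 0L else
    state$frames_since_key + 1L

  emission <- NULL
  if (res$is_key) {
    record$is_key <- TRUE
    window <- if (!is.null(res$emitted)) res$emitted else
      buffer_window(state$buffer)
    a <- pattern_activity(model, window)
    pred <- head_predict(model$head, a)$label
    record$prediction <- model$classes[pred]

    if (window$filled >= (cfg$gate_min_fill %||% 0L)) {
      if (!is.na(state$gate_label) && pred == state$gate_label) {
        state$gate_streak <- state$gate_streak + 1L
      } else {
        state$gate_label <- pred
        state$gate_streak <- 1L
      }
      if (state$gate_streak >= cfg$n_c &&
          (is.na(state$last_emitted) || state$last_emitted != pred)) {
        emission <- list(label = model$classes[pred],
                         frame = as.integer(frame_index),
                         source_frames = window$source_frames)
        state$last_emitted <- pred
        record$emitted <- TRUE
      }
    }
    record$gate_streak <- state$gate_streak

    if (!is.null(res$emitted)) {
      # window complete: reset gate and re-evaluate attention (buffer was
      # already reset by online_buffer_step)
      state$gate_label <- NA_integer_
      state$gate_streak <- 0L
      state$last_emitted <- NA_integer_
      if (length(state$att_frames) >= 2L) {
        state$attention <- select_attention(motion_scores(state$att_frames),
                                            n = cfg$n_attend)
      }
    }
  }
  list(state = state, emission = emission, record = record)
}

#' Run the online recognizer over a whole stream
#'
#' @param model A trained `hsom_model`.
#' @param stream An [action_stream()] (or any `action_sequence`).
#' @return List with `trace` (per-frame tibble) and `emissions` (tibble with
#'   `frame`, `label`, and list-column `source_frames`).
#' @export
run_stream <- function(model, stream) {
  state <- stream_state(model)
  records <- vector("list", n_frames(stream))
  emissions <- list()
  for (i in seq_len(n_frames(stream))) {
    out <- stream_step(model, state, stream$frames[[i]],
                       frame_index = stream$frame_index[i])
    state <- out$state
    records[[i]] <- out$record
    if (!is.null(out$emission)) {
      emissions[[length(emissions) + 1L]] <- out$emission
    }
  }
  em <- if (length(emissions) > 0L) {
    tibble::tibble(
      frame = vapply(emissions, `[[`, integer(1), "frame"),
      label = vapply(emissions, `[[`, character(1), "label"),
      source_frames = lapply(emissions, `[[`, "source_frames")
    )
  } else {
    tibble::tibble(frame = integer(0), label = character(0),
                   source_frames = list())
  }
  list(trace = dplyr::bind_rows(records), emissions = em)
}
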