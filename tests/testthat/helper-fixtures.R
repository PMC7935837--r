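# Small deterministic fixtures shared across the test files.

# A canonical standing frame with distinct coordinates per joint.
base_frame <- function() {
  f <- skeleton_template()
  dimnames(f) <- NULL
  f
}

# A frame where only the listed joints (1-based positions) are displaced.
moved_frame <- function(frame, joints, delta) {
  for (j in joints) frame[j, ] <- frame[j, ] + delta
  frame
}

random_rotation <- function() {
  # QR of a random Gaussian matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Apply a rigid motion plus uniform scale to every joint of a frame.
transform_frame <- function(frame, rot, trans, scale = 1) {
  scale * (frame %*% t(rot)) + matrix(trans, nrow(frame), 3, byrow = TRUE)
}

# A tiny trained model on well-separated classes, small lattices, for
# recognizer-level tests. Cached per test run.
tiny_model_cache <- new.env(parent = emptyenv())
tiny_model <- function() {
  if (!is.null(tiny_model_cache$model)) return(tiny_model_cache$model)
  cfg <- generator_config(
    classes = c("punch", "wave_horizontal", "swing"),
    frames_range = c(16L, 22L), seed = 5
  )
  train <- generate_dataset(cfg, 4, seed = 5)
  mcfg <- hsom_config(
    layer1_rows = 10L, layer1_cols = 10L, layer2_rows = 12L,
    layer2_cols = 12L, layer1_epochs = 5L, layer2_epochs = 15L,
    head_epochs = 20L, T = 8L, gate_min_fill = 3L, n_c = 3L,
    attention_buffer = 4L, seed = 9
  )
  m <- train_model(train, mcfg)
  tiny_model_cache$model <- m
  tiny_model_cache$train <- train
  tiny_model_cache$gen_config <- cfg
  m
}
tiny_train_set <- function() {
  tiny_model()
  tiny_model_cache$train
}
tiny_gen_config <- function() {
  tiny_model()
  tiny_model_cache$gen_config
}
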