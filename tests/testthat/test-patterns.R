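rand_winner_stream <- function(n, rows = 5, cols = 5) {
  cbind(sample(0:(rows - 1), n, replace = TRUE),
        sample(0:(cols - 1), n, replace = TRUE))
}

test_that("key extraction collapses exactly consecutive duplicates", {
  w <- rbind(c(1, 1), c(1, 1), c(2, 3))
  keys <- extract_key_activations(w)
  expect_equal(keys$row, c(1L, 2L))
  expect_equal(keys$col, c(1L, 3L))
  expect_equal(keys$source_frame, c(1L, 3L)) # first occurrence kept
  # non-consecutive repeats are retained
  w2 <- rbind(c(0, 0), c(1, 1), c(0, 0))
  expect_equal(nrow(extract_key_activations(w2)), 3L)
  expect_error(extract_key_activations(matrix(0, 0, 2)), "empty")
})

test_that("key extraction is idempotent and speed-invariant", {
  withr::with_seed(14, {
    for (i in 1:20) {
      w <- rand_winner_stream(40)
      keys <- extract_key_activations(w)
      # idempotent
      again <- extract_key_activations(cbind(keys$row, keys$col))
      expect_equal(again$row, keys$row)
      expect_equal(again$col, keys$col)
      # no consecutive duplicates remain
      if (nrow(keys) > 1) {
        expect_false(any(diff(keys$row) == 0 & diff(keys$col) == 0))
      }
      # k-fold duplication of every element changes nothing
      k <- sample(2:4, 1)
      dup <- w[rep(seq_len(nrow(w)), each = k), ]
      keys_dup <- extract_key_activations(dup)
      expect_equal(keys_dup$row, keys$row)
      expect_equal(keys_dup$col, keys$col)
    }
  })
})

test_that("mean key length follows the configured rounding", {
  expect_equal(mean_key_length(c(10L, 20L, 30L)), 20L)
  expect_equal(mean_key_length(c(12L, 59L)), 36L) # 35.5 rounds half up
  expect_equal(mean_key_length(c(12L, 59L), rounding = "floor"), 35L)
  expect_equal(mean_key_length(c(12L, 59L), rounding = "ceiling"), 36L)
  expect_error(mean_key_length(integer(0)), "no training")
  # list-of-traces input
  keys <- extract_key_activations(rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_equal(mean_key_length(list(keys, keys)), 3L)
})

test_that("segmentation partitions the key sequence into T-blocks", {
  keys <- extract_key_activations(rand_winner_stream(200))
  L <- nrow(keys)
  wins <- segment_stream(keys, 30)
  expect_equal(sum(vapply(wins, `[[`, integer(1), "filled")), L)
  expect_true(all(vapply(wins[-length(wins)], `[[`, logical(1), "complete")))
  # concatenating window coords reproduces the key sequence exactly
  all_rows <- unlist(lapply(wins, function(w) w$coords[, 1]))
  expect_equal(all_rows, keys$row)
  # 60 keys, T = 30: exactly two complete windows
  keys60 <- keys[1:60, ]
  w60 <- segment_stream(keys60, 30)
  expect_length(w60, 2L)
  expect_true(all(vapply(w60, `[[`, logical(1), "complete")))
  # 45 keys: one complete plus one partial of 15
  w45 <- segment_stream(keys[1:45, ], 30)
  expect_equal(vapply(w45, `[[`, integer(1), "filled"), c(30L, 15L))
  expect_equal(vapply(w45, `[[`, logical(1), "complete"), c(TRUE, FALSE))
})

test_that("window encoding maps coordinates to (index+1)/dim with padding", {
  keys <- extract_key_activations(rbind(c(29, 29), c(0, 0)))
  win <- segment_stream(keys, 4)[[1]]
  v <- window_to_vector(win, 30, 30)
  expect_length(v, 8L)
  expect_equal(v[1:4], c(1, 1, 1 / 30, 1 / 30))
  expect_equal(v[5:8], rep(0, 4))
  # decoding filled slots recovers the integer coordinates exactly
  expect_equal(v[1] * 30 - 1, 29)
  expect_equal(v[3] * 30 - 1, 0)
  # out-of-range coordinate errors
  badwin <- segment_stream(extract_key_activations(rbind(c(30, 0))), 2)[[1]]
  expect_error(window_to_vector(badwin, 30, 30), "out of grid")
  # empty window encodes to all padding
  empty <- hsomact:::new_pattern_window(matrix(0L, 0, 2), integer(0), 4L)
  expect_equal(window_to_vector(empty, 30, 30), rep(0, 8))
})

test_that("online buffering reproduces batch segmentation exactly", {
  withr::with_seed(25, {
    for (i in 1:15) {
      stream <- rand_winner_stream(sample(30:120, 1), rows = 4, cols = 4)
      T <- sample(3:8, 1)
      keys <- extract_key_activations(stream)
      batch <- segment_stream(keys, T)
      buf <- pattern_buffer(T)
      online <- list()
      for (t in seq_len(nrow(stream))) {
        res <- online_buffer_step(buf, stream[t, ], source_frame = t)
        buf <- res$buffer
        if (!is.null(res$emitted)) online[[length(online) + 1]] <- res$emitted
      }
      trailing <- buffer_window(buf)
      if (trailing$filled > 0) online[[length(online) + 1]] <- trailing
      expect_equal(length(online), length(batch))
      for (k in seq_along(batch)) {
        expect_equal(online[[k]]$coords, batch[[k]]$coords,
                     ignore_attr = TRUE)
        expect_equal(online[[k]]$source_frames, batch[[k]]$source_frames)
      }
    }
  })
})

test_that("online buffer collapses duplicates across window resets", {
  buf <- pattern_buffer(2)
  r1 <- online_buffer_step(buf, c(1, 1), 1)
  expect_true(r1$is_key)
  r1b <- online_buffer_step(r1$buffer, c(1, 1), 2)
  expect_false(r1b$is_key) # in-window duplicate
  r2 <- online_buffer_step(r1b$buffer, c(2, 2), 3)
  expect_false(is.null(r2$emitted)) # window of 2 emitted, buffer reset
  expect_equal(length(r2$buffer$rows), 0L)
  # duplicate of the last pre-reset key is still collapsed
  r3 <- online_buffer_step(r2$buffer, c(2, 2), 4)
  expect_false(r3$is_key)
})
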