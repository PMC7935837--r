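test_that("stratified split is disjoint, exhaustive and reproducible", {
  cfg <- generator_config(classes = c("punch", "swing"),
                          frames_range = c(10L, 12L), seed = 1)
  ds <- generate_dataset(cfg, 10, seed = 1)
  sp <- split_dataset(ds, 0.8, seed = 2)
  labs <- function(x) as.integer(table(vapply(x, `[[`, character(1), "label")))
  expect_equal(labs(sp$train), rep(8L, 2))
  expect_equal(labs(sp$test), rep(2L, 2))
  expect_identical(split_dataset(ds, 0.8, seed = 2), sp)
  # union and disjointness on fuzzed fractions
  withr::with_seed(3, {
    for (f in runif(5, 0.3, 0.9)) {
      spf <- split_dataset(ds, f, seed = sample(1e4, 1))
      expect_equal(length(spf$train) + length(spf$test), length(ds))
      key <- function(s) paste(s$label, n_frames(s),
                               signif(sum(unlist(s$frames)), 12))
      expect_length(intersect(sapply(spf$train, key), sapply(spf$test, key)),
                    0L)
    }
  })
  # a singleton class stays whole in train, with a warning
  ds1 <- c(ds[1:10], ds[11])
  expect_warning(sp1 <- split_dataset(ds1, 0.8, seed = 4), "kept whole")
  expect_equal(sum(vapply(sp1$train, `[[`, character(1), "label") == "swing"),
               1L)
})

test_that("train_model validates its inputs", {
  cfg <- generator_config(classes = c("punch", "swing"),
                          frames_range = c(10L, 12L), seed = 1)
  ds <- generate_dataset(cfg, 2, seed = 1)
  expect_error(train_model(list()), "empty")
  one_class <- ds[vapply(ds, `[[`, character(1), "label") == "punch"]
  expect_error(train_model(one_class), "2 classes")
  unlabeled <- list(action_sequence(ds[[1]]$frames))
  expect_error(train_model(c(one_class, unlabeled)), "labeled")
})

test_that("the trained bundle ties layer dimensions together", {
  m <- tiny_model()
  expect_equal(m$layer2$params$input_dim, 2L * m$config$T)
  expect_equal(ncol(m$head), m$config$layer2_rows * m$config$layer2_cols)
  expect_equal(nrow(m$head), length(m$classes))
  expect_equal(sort(m$classes), m$classes)
  expect_true(all(m$key_lengths >= 1L))
})

test_that("training end-to-end separates well-separated classes", {
  m <- tiny_model()
  train <- tiny_train_set()
  ev <- evaluate_offline(m, train)
  expect_gte(ev$overall, 0.9)
  # held-out sequences from the same generator
  test <- generate_dataset(tiny_gen_config(), 2, seed = 77)
  expect_gte(evaluate_offline(m, test)$overall, 0.75)
})

test_that("retraining with identical config is bit-identical", {
  cfg <- generator_config(classes = c("punch", "wave_horizontal"),
                          frames_range = c(12L, 16L), seed = 31)
  train <- generate_dataset(cfg, 3, seed = 31)
  mcfg <- hsom_config(layer1_rows = 8L, layer1_cols = 8L, layer2_rows = 9L,
                      layer2_cols = 9L, layer1_epochs = 3L,
                      layer2_epochs = 8L, head_epochs = 10L, T = 6L,
                      attention_buffer = 4L, seed = 17)
  m1 <- train_model(train, mcfg)
  m2 <- train_model(train, mcfg)
  expect_identical(m1, m2)
})

test_that("classify_sequence is speed-invariant and handles degenerate input", {
  m <- tiny_model()
  s <- tiny_train_set()[[1]]
  lab <- classify_sequence(m, s)$label
  # half-speed replay: every frame duplicated
  slow <- action_sequence(s$frames[rep(seq_len(n_frames(s)), each = 2)],
                          label = s$label)
  expect_equal(classify_sequence(m, slow)$label, lab)
  # identical frames: exactly one key activation, still classifiable
  still <- action_sequence(rep(list(s$frames[[1]]), 5))
  res <- classify_sequence(m, still)
  expect_equal(res$n_keys, 1L)
  expect_true(res$label %in% m$classes)
})

test_that("stream_step ignores repeated frames when counting iterations", {
  m <- tiny_model()
  s <- tiny_train_set()[[2]]
  frames <- s$frames[rep(seq_len(n_frames(s)), each = 2)]
  st <- action_stream(frames,
                      tibble::tibble(start = 1L,
                                     end = length(frames) + 1L,
                                     label = s$label))
  out <- run_stream(m, st)
  its <- out$trace$iteration
  expect_equal(max(its, na.rm = TRUE), n_frames(s))
  expect_equal(sum(!is.na(its)), n_frames(s))
})

test_that("the certainty gate never emits below n_c agreeing predictions", {
  m <- tiny_model()
  n_c <- m$config$n_c
  # fuzzed streams: random concatenations drive the gate through many
  # prediction changes
  withr::with_seed(55, {
    for (rep in 1:3) {
      st <- generate_stream(tiny_gen_config(),
                            sample(c("punch", "wave_horizontal", "swing"), 4,
                                   replace = TRUE),
                            seed = sample(1e4, 1))
      out <- run_stream(m, st)
      tr <- out$trace[out$trace$is_key %in% TRUE, ]
      emitted_rows <- which(tr$emitted)
      for (r in emitted_rows) {
        expect_gte(tr$gate_streak[r], n_c)
        # the previous n_c key-level predictions must agree
        expect_true(all(tr$prediction[(r - n_c + 1):r] == tr$prediction[r]))
      }
    }
  })
})

test_that("emissions on a clean stream recover the action order", {
  m <- tiny_model()
  st <- generate_stream(tiny_gen_config(),
                        c("punch", "wave_horizontal", "swing"), seed = 41)
  ev <- evaluate_online(m, list(st))
  expect_equal(ev$n, 3L)
  expect_gte(ev$overall, 2 / 3)
})

test_that("model persistence round-trips bit-exactly", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_identical(load_model(path), m)
  saveRDS(list(1), path)
  expect_error(load_model(path), "hsom_model")
})

test_that("tidiers summarize models and reports", {
  m <- tiny_model()
  td <- tidy(m)
  expect_equal(td$component, c("layer1_som", "layer2_som", "output_head"))
  expect_equal(glance(m)$n_classes, 3L)
  ev <- evaluate_offline(m, tiny_train_set())
  expect_s3_class(tidy(ev), "tbl_df")
  g <- glance(ev)
  expect_equal(g$mode, "offline")
  expect_true(g$accuracy >= 0 && g$accuracy <= 1)
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(autoplot(m$layer1), "ggplot")
})
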