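test_that("ego basis of the symmetric canonical pose is the identity", {
  f <- matrix(0, 20, 3)
  f[17, ] <- c(-0.1, -0.05, 0) # right hip
  f[13, ] <- c(0.1, -0.05, 0)  # left hip
  f[3, 2] <- 0.5               # neck, breaks degeneracy elsewhere
  b <- build_ego_basis(f)
  expect_equal(unname(b$origin), c(0, 0, 0))
  expect_equal(unname(b$axes), diag(3), tolerance = 1e-12)

  # translation moves the origin, not the axes
  b2 <- build_ego_basis(f + matrix(c(3, 1, 2), 20, 3, byrow = TRUE))
  expect_equal(unname(b2$origin), c(3, 1, 2))
  expect_equal(b2$axes, b$axes, tolerance = 1e-12)
})

test_that("ego basis is equivariant under rotation and orthonormal", {
  withr::with_seed(42, {
    for (i in 1:20) {
      f <- base_frame() + matrix(rnorm(60, sd = 0.02), 20, 3)
      b <- build_ego_basis(f)
      expect_equal(unname(b$axes %*% t(b$axes)), diag(3), tolerance = 1e-9)
      expect_equal(det(b$axes), 1, tolerance = 1e-9)
      r <- random_rotation()
      br <- build_ego_basis(transform_frame(f, r, c(0, 0, 0)))
      expect_equal(br$axes, b$axes %*% t(r), tolerance = 1e-9)
    }
  })
})

test_that("degenerate anchor geometry raises a degenerate-pose error", {
  f <- base_frame()
  f[17, ] <- f[1, ]
  f[13, ] <- f[1, ]
  expect_error(build_ego_basis(f), "degenerate")
})

test_that("to_ego sends the stomach to the origin and undoes rigid motion", {
  withr::with_seed(7, {
    for (i in 1:10) {
      f <- base_frame() + matrix(rnorm(60, sd = 0.02), 20, 3)
      e <- to_ego(f, build_ego_basis(f))
      expect_equal(unname(e[1, ]), c(0, 0, 0), tolerance = 1e-12)
      g <- transform_frame(f, random_rotation(), rnorm(3, sd = 2))
      expect_equal(to_ego(g, build_ego_basis(g)), e, tolerance = 1e-9)
    }
  })
})

test_that("scale_frame fixes the reference segment length", {
  f <- base_frame()
  s <- scale_frame(f, target_len = 1)
  expect_equal(sqrt(sum((s[3, ] - s[1, ])^2)), 1, tolerance = 1e-12)
  # pre-scaling is neutralized
  expect_equal(scale_frame(f * 3.7, target_len = 1), s, tolerance = 1e-9)
  # identity when already at target
  expect_equal(scale_frame(s, target_len = 1), s, tolerance = 1e-12)
  bad <- f; bad[3, ] <- bad[1, ]
  expect_error(scale_frame(bad), "zero length")
})

test_that("motion scores match a brute-force double loop", {
  withr::with_seed(8, {
    frames <- lapply(1:6, function(i) base_frame() + matrix(rnorm(60, sd = 0.1), 20, 3))
  })
  sc <- motion_scores(frames)
  brute <- numeric(20)
  for (j in 1:20) {
    for (t in 2:6) {
      brute[j] <- brute[j] +
        sqrt(sum((frames[[t]][j, ] - frames[[t - 1]][j, ])^2))
    }
  }
  expect_equal(unname(sc), brute, tolerance = 1e-12)
  expect_error(motion_scores(frames[1]), "at least 2")
  # static sequence scores zero; known single-joint motion is additive
  expect_true(all(motion_scores(list(base_frame(), base_frame())) == 0))
  fs <- list(base_frame())
  for (t in 1:5) fs[[t + 1]] <- moved_frame(fs[[t]], 12, c(0, 0.1, 0))
  sc2 <- motion_scores(fs)
  expect_equal(unname(sc2[12]), 0.5, tolerance = 1e-12)
  expect_true(all(sc2[-12] == 0))
})

test_that("attention selects the top movers with index tie-breaking", {
  sc <- rep(0, 20)
  sc[c(9, 10, 11, 12)] <- c(1, 2, 3, 4)
  expect_equal(select_attention(sc)$joints, c(9L, 10L, 11L, 12L))
  # all-zero scores: lowest positions win
  expect_equal(select_attention(rep(0, 20))$joints, 1:4)
  # random scores match a brute-force sort with the same tie rule
  withr::with_seed(21, {
    for (i in 1:50) {
      sc <- sample(0:5, 20, replace = TRUE) / 2
      got <- select_attention(sc)$joints
      ord <- order(-sc, seq_along(sc))
      expect_identical(got, sort(ord[1:4]))
      expect_length(unique(got), 4L)
    }
  })
})

test_that("frame_to_vector concatenates attended joints in index order", {
  f <- base_frame()
  att <- select_attention(c(rep(0, 8), 4, 3, 2, 1, rep(0, 8)))
  v <- frame_to_vector(f, att)
  expect_length(v, 12L)
  expect_equal(v, as.numeric(t(f[9:12, ])))
  expect_equal(frame_to_vector(matrix(0, 20, 3), att), rep(0, 12))
})

test_that("full preprocessing is invariant under rigid motion plus scale", {
  withr::with_seed(13, {
    f <- base_frame() + matrix(rnorm(60, sd = 0.02), 20, 3)
    ref <- preprocess_frame(f)
    for (i in 1:10) {
      g <- transform_frame(f, random_rotation(), rnorm(3, sd = 3),
                           scale = exp(rnorm(1)))
      expect_equal(preprocess_frame(g), ref, tolerance = 1e-6)
    }
  })
})

test_that("preprocess_sequence wires attention and vector layout together", {
  cfg <- generator_config(classes = "punch", frames_range = c(12L, 14L),
                          seed = 2)
  s <- generate_sequence(cfg, "punch", seed = 2)
  pr <- preprocess_sequence(s)
  expect_equal(dim(pr$vectors), c(n_frames(s), 12L))
  expect_equal(pr$attention$joints, c(9L, 10L, 11L, 12L))
  expect_true(all(is.finite(pr$vectors)))
})
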