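small_grid <- function(rows = 5, cols = 6, k = 4, seed = 1, ...) {
  som_grid(som_params(rows, cols, k, seed = seed, ...))
}

test_that("net input is the Euclidean distance to every weight vector", {
  g <- small_grid()
  x <- g$weights[8, ]
  s <- net_input(g, x)
  expect_equal(s[8], 0, tolerance = 1e-12)
  # analytic 2-d case
  g2 <- small_grid(1, 1, 2)
  g2$weights[1, ] <- c(0, 1)
  expect_equal(net_input(g2, c(1, 0)), sqrt(2), tolerance = 1e-12)
  # brute force oracle on random instances
  withr::with_seed(5, {
    for (i in 1:10) {
      x <- rnorm(4)
      s <- net_input(g, x)
      brute <- apply(g$weights, 1, function(w) sqrt(sum((x - w)^2)))
      expect_equal(s, brute, tolerance = 1e-12)
    }
  })
  expect_error(net_input(g, 1:3), "expects 4")
})

test_that("exponential activity obeys its analytic values and bounds", {
  expect_equal(som_activity(0, 1), 1)
  expect_equal(som_activity(1, 1), exp(-1))
  expect_equal(som_activity(2, 1e6), exp(-2e-6))
  s <- runif(50, 0, 5)
  a <- som_activity(s, 1e6)
  expect_true(all(a > 0 & a <= 1))
  # with sigma = 1e6 and inputs of magnitude O(1), activities are confined
  # to [exp(-1e-5), 1]
  expect_true(all(som_activity(runif(50, 0, 10), 1e6) >= exp(-1e-5)))
})

test_that("winner selection matches brute-force argmin with row-major ties", {
  g <- small_grid()
  # uniform activity: tie resolves to neuron (0,0)
  expect_equal(unname(som_winner(rep(0.5, 30), g)), c(0L, 0L))
  withr::with_seed(9, {
    for (i in 1:50) {
      x <- rnorm(4)
      s <- net_input(g, x)
      w <- som_winner(som_activity(s, 1e6), g)
      # oracle: scan lattice in row-major order for the strict minimum
      best <- c(0L, 0L); bestv <- Inf
      for (r in 0:4) for (cc in 0:5) {
        v <- s[r * 6 + cc + 1]
        if (v < bestv) { bestv <- v; best <- c(r, cc) }
      }
      expect_equal(unname(w), best)
      expect_equal(unname(som_map_vector(g, x)), best)
    }
  })
})

test_that("neighborhood kernel matches its printed form", {
  g <- small_grid()
  nb <- som_neighborhood(g, c(2, 3), nb_sigma = 1.5)
  expect_equal(nb[2 * 6 + 3 + 1], 1)
  brute <- apply(g$coords, 1, function(rc) {
    d <- sqrt(sum((rc - c(2, 3))^2))
    exp(-d / (2 * 1.5^2))
  })
  expect_equal(nb, brute, tolerance = 1e-12)
  # distance equal to 2 sigma^2 gives exactly 1/e
  g1 <- small_grid(1, 9, 2)
  nb1 <- som_neighborhood(g1, c(0, 0), nb_sigma = sqrt(2))
  expect_equal(nb1[5], exp(-1), tolerance = 1e-12)
  # squared-distance variant
  gs <- small_grid(squared_distance = TRUE)
  nbs <- som_neighborhood(gs, c(2, 3), nb_sigma = 1.5)
  brute_s <- apply(gs$coords, 1, function(rc) {
    exp(-sum((rc - c(2, 3))^2) / (2 * 1.5^2))
  })
  expect_equal(nbs, brute_s, tolerance = 1e-12)
})

test_that("adaptation moves weights as printed and renormalizes", {
  g <- small_grid()
  w0 <- g$weights
  # alpha = 0 leaves weights untouched
  g0 <- som_adapt(g, rnorm(4), alpha = 0, nb_sigma = 1)
  expect_equal(g0$weights, w0)
  expect_equal(g0$trained_steps, 1L)
  # at the winner with G = 1 the pre-normalization update is w + a(x - w)
  x <- c(2, 0, 0, 0)
  win <- som_map_vector(g, x)
  idx <- win[1] * 6 + win[2] + 1
  g1 <- som_adapt(g, x, alpha = 0.5, nb_sigma = 1e-6)
  manual <- w0[idx, ] + 0.5 * (x - w0[idx, ])
  expect_equal(g1$weights[idx, ], manual / sqrt(sum(manual^2)),
               tolerance = 1e-12)
  # unit-norm invariant after random adaptation batches
  withr::with_seed(2, {
    for (i in 1:50) {
      g <- som_adapt(g, rnorm(4), alpha = runif(1, 0, 0.9),
                     nb_sigma = runif(1, 0.3, 3))
      expect_equal(sqrt(rowSums(g$weights^2)), rep(1, 30), tolerance = 1e-9)
    }
  })
})

test_that("training reduces quantization error on 2-D toy data", {
  withr::with_seed(31, {
    data <- matrix(runif(600, -1, 1), ncol = 2)
  })
  g <- som_grid(som_params(8, 8, 2, epochs = 5, alpha0 = 0.3, seed = 4))
  gt <- som_train(g, data)
  expect_equal(nrow(gt$qe_log), 5L)
  expect_lte(gt$qe_log$mean_qe[5], gt$qe_log$mean_qe[1])
  expect_equal(gt$trained_steps, 5L * 300L)
  # epochs = 0 leaves the initialized grid untouched
  g0 <- som_train(som_grid(som_params(4, 4, 2, epochs = 0, seed = 4)), data)
  expect_equal(g0$weights, som_grid(som_params(4, 4, 2, epochs = 0, seed = 4))$weights)
  expect_error(som_train(g, data[0, , drop = FALSE]), "empty")
})

test_that("a repeated input pulls the winner weight toward its direction", {
  x <- c(3, 1, 0.5, 2)
  g <- som_grid(som_params(4, 4, 4, alpha0 = 0.3, epochs = 20, seed = 6))
  gt <- som_train(g, matrix(x, nrow = 1))
  win <- som_map_vector(gt, x)
  w <- gt$weights[win[1] * 4 + win[2] + 1, ]
  cosine <- sum(w * x) / sqrt(sum(x^2))
  expect_gt(cosine, 0.999)
})

test_that("training is reproducible for identical seeds and parameters", {
  withr::with_seed(77, data <- matrix(runif(200), ncol = 4))
  g1 <- som_train(som_grid(som_params(5, 5, 4, epochs = 3, seed = 12)), data)
  g2 <- som_train(som_grid(som_params(5, 5, 4, epochs = 3, seed = 12)), data)
  expect_identical(g1$weights, g2$weights)
  g3 <- som_train(som_grid(som_params(5, 5, 4, epochs = 3, seed = 13)), data)
  expect_false(identical(g1$weights, g3$weights))
})
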