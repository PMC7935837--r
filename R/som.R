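#' Parameters of a self-organizing map
#'
#' A SOM is an `rows x cols` lattice of neurons, each holding a unit-norm
#' weight vector of the input dimension. Matching is Euclidean on the raw
#' (un-normalized) input; activities are `exp(-s / sigma_exp)`; adaptation
#' uses a Gaussian neighborhood around the winner with exponentially decaying
#' strength `alpha(t) = alpha0 * exp(-t / alpha_decay)` and width
#' `sigma(t) = nb_sigma0 * exp(-t / nb_decay)`, and every weight vector is
#' renormalized to unit length after each adaptation step.
#'
#' The neighborhood kernel defaults to `exp(-d / (2 sigma(t)^2))` with the
#' unsquared lattice distance `d`; `squared_distance = TRUE` switches to the
#' textbook Gaussian `exp(-d^2 / (2 sigma(t)^2))`.
#'
#' Decay constants default to values spanning the whole training run: when
#' `som_train()` knows the total step count `S`, `alpha_decay` defaults to
#' `S` (strength ends at `alpha0/e`) and `nb_decay` to
#' `S / log(nb_sigma0 / nb_sigma_end)` (width shrinks to `nb_sigma_end`
#' by the end of the run).
#'
#' @param rows,cols Lattice dimensions.
#' @param input_dim Input dimension K.
#' @param sigma_exp Exponential activity factor (default `1e6`).
#' @param alpha0 Initial adaptation strength in (0, 1].
#' @param alpha_decay,nb_decay Exponential decay constants in steps;
#'   `NULL` = derive from the training length (see `nb_sigma_end`).
#' @param nb_sigma_end Neighborhood width the default schedule reaches at the
#'   end of training; `nb_decay` defaults to
#'   `total_steps / log(nb_sigma0 / nb_sigma_end)`.
#' @param nb_sigma0 Initial neighborhood width in lattice units. The default
#'   makes the initial neighborhood *radius* (lattice distance at which the
#'   kernel falls to 1/e) equal to half the larger lattice side under either
#'   kernel variant: `max(rows, cols) / 2` for the squared-distance Gaussian,
#'   `sqrt(max(rows, cols) / 4)` for the default unsquared kernel whose 1/e
#'   radius is `2 * sigma^2`.
#' @param epochs Training epochs (full passes over the data).
#' @param squared_distance Use the squared-distance Gaussian neighborhood.
#' @param seed RNG seed for initialization and presentation order.
#' @return A `som_params` list.
#' @export
som_params <- function(rows, cols, input_dim, sigma_exp = 1e6,
                       alpha0 = 0.1, alpha_decay = NULL,
                       nb_sigma0 = NULL, nb_decay = NULL,
                       nb_sigma_end = 1,
                       epochs = 10L, squared_distance = FALSE, seed = 1L) {
  stopifnot(rows >= 1L, cols >= 1L, input_dim >= 1L, sigma_exp > 0,
            alpha0 > 0, alpha0 <= 1, epochs >= 0L)
  if (is.null(nb_sigma0)) {
    nb_sigma0 <- if (isTRUE(squared_distance)) {
      max(rows, cols) / 2
    } else {
      sqrt(max(rows, cols) / 4)
    }
  }
  stopifnot(nb_sigma0 > 0)
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         input_dim = as.integer(input_dim), sigma_exp = sigma_exp,
         alpha0 = alpha0, alpha_decay = alpha_decay,
         nb_sigma0 = nb_sigma0, nb_decay = nb_decay,
         nb_sigma_end = nb_sigma_end,
         epochs = as.integer(epochs),
         squared_distance = isTRUE(squared_distance),
         seed = as.integer(seed)),
    class = "som_params"
  )
}

#' Create (initialize) a SOM lattice
#'
#' Weights are drawn uniformly from (0, 1) and normalized to unit vectors.
#' Neurons are stored row-major (row 0 col 0, row 0 col 1, ...), and all
#' coordinates are 0-based `(row, col)` pairs.
#'
#' @param params A [som_params()].
#' @return A `som_grid` with fields `weights` (`(rows*cols) x input_dim`
#'   matrix of unit rows), `coords` (`(rows*cols) x 2` 0-based lattice
#'   positions), `params`, `trained_steps`, `qe_log`.
#' @export
som_grid <- function(params) {
  stopifnot(inherits(params, "som_params"))
  n <- params$rows * params$cols
  w <- withr::with_seed(params$seed, {
    matrix(stats::runif(n * params$input_dim), nrow = n)
  })
  w <- w / sqrt(rowSums(w^2))
  coords <- cbind(
    row = rep(0:(params$rows - 1L), each = params$cols),
    col = rep(0:(params$cols - 1L), times = params$rows)
  )
  structure(
    list(weights = w, coords = coords, params = params,
         trained_steps = 0L, qe_log = NULL),
    class = "som_grid"
  )
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("<som_grid> %d x %d lattice, input dim %d, %d trained steps\n",
              x$params$rows, x$params$cols, x$params$input_dim,
              x$trained_steps))
  invisible(x)
}

#' Net input: Euclidean distance from the input to every weight vector
#'
#' @param grid A `som_grid`.
#' @param x Input vector of length `input_dim`.
#' @return Numeric vector of length `rows*cols` in row-major neuron order.
#' @export
net_input <- function(grid, x) {
  if (length(x) != grid$params$input_dim) {
    stop(sprintf("input has length %d, SOM expects %d", length(x),
                 grid$params$input_dim), call. = FALSE)
  }
  w <- grid$weights
  # ||x - w||^2 = ||x||^2 - 2 x.w + ||w||^2 ; rows of w are unit norm only
  # after adaptation, so compute the norms explicitly
  d2 <- rowSums(w^2) - 2 * drop(w %*% x) + sum(x^2)
  sqrt(pmax(d2, 0))
}

#' Exponential SOM activity
#'
#' `y = exp(-s / sigma_exp)`, strictly decreasing in the net input, values in
#' (0, 1].
#'
#' @param net Non-negative net-input vector.
#' @param sigma_exp Positive exponential factor.
#' @return Activity vector, same shape as `net`.
#' @export
som_activity <- function(net, sigma_exp) {
  stopifnot(sigma_exp > 0)
  exp(-net / sigma_exp)
}

#' Winner neuron of an activity map
#'
#' Argmax of the activity; ties broken row-major (lowest row, then lowest
#' column), which the row-major storage order gives for free.
#'
#' @param activity Activity vector in row-major neuron order.
#' @param grid The `som_grid` the activity came from.
#' @return Integer 0-based `(row, col)` pair.
#' @export
som_winner <- function(activity, grid) {
  idx <- which.max(activity)
  grid$coords[idx, ]
}

#' Winner by direct nearest-weight lookup
#'
#' Equivalent to `som_winner(som_activity(net_input(grid, x)))` since exp is
#' monotone; used as the fast path in training and the streaming recognizer.
#'
#' @inheritParams net_input
#' @return Integer 0-based `(row, col)` pair.
#' @export
som_map_vector <- function(grid, x) {
  grid$coords[which.min(net_input(grid, x)), ]
}

#' Gaussian neighborhood kernel around a winner
#'
#' `G = exp(-d / (2 nb_sigma^2))` with `d` the Euclidean lattice distance
#' between each neuron and the winner; with `squared_distance = TRUE` in the
#' grid parameters, `d^2` replaces `d`. Equals 1 at the winner and decreases
#' with lattice distance.
#'
#' @param grid A `som_grid`.
#' @param winner 0-based `(row, col)` of the winner.
#' @param nb_sigma Positive neighborhood width (lattice units).
#' @return Numeric vector over neurons, row-major.
#' @export
som_neighborhood <- function(grid, winner, nb_sigma) {
  stopifnot(nb_sigma > 0)
  d2 <- (grid$coords[, 1L] - winner[1L])^2 + (grid$coords[, 2L] - winner[2L])^2
  d <- if (grid$params$squared_distance) d2 else sqrt(d2)
  exp(-d / (2 * nb_sigma^2))
}

#' One adaptation step
#'
#' Moves every weight toward the input by `alpha * G`, then renormalizes all
#' weight vectors to unit length.
#'
#' @param grid A `som_grid`.
#' @param x Input vector.
#' @param winner 0-based winner coordinate (computed if `NULL`).
#' @param alpha Adaptation strength; defaults to the schedule value at
#'   `grid$trained_steps`.
#' @param nb_sigma Neighborhood width; defaults to the schedule value.
#' @return The updated `som_grid` (with `trained_steps` incremented).
#' @export
som_adapt <- function(grid, x, winner = NULL,
                      alpha = NULL, nb_sigma = NULL) {
  p <- grid$params
  t <- grid$trained_steps
  if (is.null(alpha)) {
    stopifnot(!is.null(p$alpha_decay))
    alpha <- p$alpha0 * exp(-t / p$alpha_decay)
  }
  if (is.null(nb_sigma)) {
    stopifnot(!is.null(p$nb_decay))
    nb_sigma <- max(p$nb_sigma0 * exp(-t / p$nb_decay), 1e-3)
  }
  if (is.null(winner)) winner <- som_map_vector(grid, x)
  g <- som_neighborhood(grid, winner, nb_sigma)
  w <- grid$weights
  step <- alpha * g
  w <- w + step * (matrix(x, nrow(w), length(x), byrow = TRUE) - w)
  nrm <- sqrt(rowSums(w^2))
  if (any(nrm < 1e-12)) {
    stop("weight vector annihilated during adaptation; cannot renormalize",
         call. = FALSE)
  }
  grid$weights <- w / nrm
  grid$trained_steps <- t + 1L
  grid
}

#' Train a SOM on a dataset of input vectors
#'
#' Runs `epochs` passes over the data in seeded random order, decaying
#' adaptation strength and neighborhood width over the whole run, and logs
#' the per-epoch mean quantization error (mean distance from each input to
#' its winner's weight vector, measured before that epoch's updates).
#'
#' @param grid A freshly initialized or partially trained `som_grid`.
#' @param data Numeric matrix, one input vector per row.
#' @param epochs Number of passes (default from the grid parameters).
#' @param verbose Print the per-epoch quantization error.
#' @return The trained `som_grid`; `qe_log` holds a tibble with columns
#'   `epoch`, `mean_qe`.
#' @export
som_train <- function(grid, data, epochs = grid$params$epochs,
                      verbose = FALSE) {
  stopifnot(is.matrix(data), ncol(data) == grid$params$input_dim)
  if (nrow(data) == 0L) stop("empty training dataset", call. = FALSE)
  p <- grid$params
  total_steps <- max(epochs * nrow(data), 1L)
  if (is.null(p$alpha_decay)) p$alpha_decay <- total_steps
  if (is.null(p$nb_decay)) {
    ratio <- max(p$nb_sigma0 / p$nb_sigma_end, 1.01)
    p$nb_decay <- total_steps / log(ratio)
  }
  grid$params <- p

  qe <- numeric(0)
  if (epochs >= 1L) {
    for (e in seq_len(epochs)) {
      ord <- withr::with_seed(p$seed + 7919L * e, sample.int(nrow(data)))
      qe_e <- mean_quantization_error(grid, data)
      qe <- c(qe, qe_e)
      if (verbose) message(sprintf("epoch %d: mean QE %.5f", e, qe_e))
      for (i in ord) {
        grid <- som_adapt(grid, data[i, ])
      }
    }
  }
  grid$qe_log <- tibble::tibble(epoch = seq_along(qe), mean_qe = qe)
  grid
}

#' Mean quantization error of a dataset under a SOM
#'
#' @inheritParams som_train
#' @return Mean Euclidean distance from each row to its winner's weights.
#' @export
mean_quantization_error <- function(grid, data) {
  mean(apply(data, 1L, function(x) min(net_input(grid, x))))
}

#' Map every row of a dataset to its winner coordinates
#'
#' @inheritParams som_train
#' @return Integer matrix `n x 2` of 0-based `(row, col)` winners.
#' @export
som_map <- function(grid, data) {
  stopifnot(is.matrix(data))
  t(apply(data, 1L, function(x) som_map_vector(grid, x)))
}
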