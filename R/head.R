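#' One-layer supervised output head
#'
#' The output layer maps the second-layer SOM activity map (length L =
#' rows x cols) to N class activities with the cosine metric,
#' `y_i = (a . w_i) / (||a|| ||w_i||)`, and learns with the error-descent
#' rule `w_i <- w_i + beta * a * (d_i - y_i)` against one-hot targets d.
#' Rows are initialized uniform(0,1) and normalized once; they are not
#' renormalized during learning.
#'
#' `sign_as_printed = TRUE` flips the bracket to `(y_i - d_i)`, the literal
#' published form, which climbs rather than descends the error surface; it
#' exists for auditability only.
#'
#' @param n_classes Number of classes N (>= 2).
#' @param input_len Input length L.
#' @param seed RNG seed for initialization.
#' @return `head_init()` returns an N x L weight matrix of class
#'   `head_weights`.
#' @export
head_init <- function(n_classes, input_len, seed = 1L) {
  stopifnot(n_classes >= 2L, input_len >= 1L)
  w <- withr::with_seed(seed, {
    matrix(stats::runif(n_classes * input_len), nrow = n_classes)
  })
  w <- w / sqrt(rowSums(w^2))
  structure(w, class = c("head_weights", "matrix", "array"))
}

#' @rdname head_init
#' @param weights An N x L `head_weights` matrix.
#' @param a Input activity vector of length L with positive norm.
#' @return `head_activity()` returns the N cosine activities in `[-1, 1]`.
#' @export
head_activity <- function(weights, a) {
  stopifnot(ncol(weights) == length(a))
  na <- sqrt(sum(a^2))
  if (na < 1e-300) stop("zero input vector has no cosine activity",
                        call. = FALSE)
  nw <- sqrt(rowSums(weights^2))
  drop(weights %*% a) / (na * nw)
}

#' @rdname head_init
#' @param d One-hot target vector of length N.
#' @param beta Adaptation strength.
#' @param sign_as_printed Use the literal `(y - d)` bracket (see above).
#' @return `head_adapt()` returns the updated weights.
#' @export
head_adapt <- function(weights, a, d, beta, sign_as_printed = FALSE) {
  stopifnot(length(d) == nrow(weights))
  y <- head_activity(weights, a)
  err <- if (sign_as_printed) y - d else d - y
  w <- weights + beta * outer(err, a)
  class(w) <- class(weights)
  w
}

#' @rdname head_init
#' @return `head_predict()` returns a list with `label` (1-based argmax
#'   class index, ties to the lowest index) and `activities`.
#' @export
head_predict <- function(weights, a) {
  y <- head_activity(weights, a)
  list(label = which.max(y), activities = y)
}

#' Train the output head on labeled activity maps
#'
#' Runs `epochs` seeded-shuffled passes of [head_adapt()] over the dataset.
#'
#' @param weights An initialized `head_weights` matrix.
#' @param data Numeric matrix, one activity map per row.
#' @param labels Integer class indices (1..N), one per row.
#' @param beta Adaptation strength (default 0.01).
#' @param epochs Passes over the data (default 100).
#' @param seed RNG seed for presentation order.
#' @param sign_as_printed See [head_init()].
#' @return The trained weights.
#' @export
head_train <- function(weights, data, labels, beta = 0.01, epochs = 100L,
                       seed = 1L, sign_as_printed = FALSE) {
  stopifnot(is.matrix(data), nrow(data) == length(labels),
            all(labels >= 1L), all(labels <= nrow(weights)))
  n_classes <- nrow(weights)
  for (e in seq_len(epochs)) {
    ord <- withr::with_seed(seed + 104729L * e, sample.int(nrow(data)))
    for (i in ord) {
      d <- numeric(n_classes)
      d[labels[i]] <- 1
      weights <- head_adapt(weights, data[i, ], d, beta,
                            sign_as_printed = sign_as_printed)
    }
  }
  weights
}
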