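#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Broom-style tidiers for evaluation reports
#'
#' `tidy()` returns the per-class accuracy table; `glance()` a one-row
#' summary of the whole report.
#'
#' @param x An `hsom_eval`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy hsom_eval
#' @export
tidy.hsom_eval <- function(x, ...) x$per_class

#' @rdname tidy.hsom_eval
#' @method glance hsom_eval
#' @export
glance.hsom_eval <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, accuracy = x$overall, n = x$n,
    emission_accuracy = x$emission_accuracy %||% NA_real_,
    n_emissions = x$n_emissions %||% NA_integer_,
    n_no_emission = x$n_no_emission %||% NA_integer_
  )
}

#' Broom-style tidiers for trained models
#'
#' `tidy()` lists the model components with their sizes and training step
#' counts; `glance()` gives a one-row structural summary.
#'
#' @param x An `hsom_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy hsom_model
#' @export
tidy.hsom_model <- function(x, ...) {
  tibble::tibble(
    component = c("layer1_som", "layer2_som", "output_head"),
    rows = c(x$config$layer1_rows, x$config$layer2_rows,
             length(x$classes)),
    cols = c(x$config$layer1_cols, x$config$layer2_cols,
             x$config$layer2_rows * x$config$layer2_cols),
    input_dim = c(3L * x$config$n_attend, 2L * x$config$T,
                  x$config$layer2_rows * x$config$layer2_cols),
    trained_steps = c(x$layer1$trained_steps, x$layer2$trained_steps,
                      NA_integer_)
  )
}

#' @rdname tidy.hsom_model
#' @method glance hsom_model
#' @export
glance.hsom_model <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes), T = x$config$T,
    layer1 = sprintf("%dx%d", x$config$layer1_rows, x$config$layer1_cols),
    layer2 = sprintf("%dx%d", x$config$layer2_rows, x$config$layer2_cols),
    n_c = x$config$n_c, seed = x$config$seed
  )
}

#' Plot an evaluation report
#'
#' Confusion-matrix tile plot; counts are annotated.
#'
#' @param object An `hsom_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hsom_eval
#' @export
autoplot.hsom_eval <- function(object, ...) {
  ggplot2::ggplot(object$confusion,
                  ggplot2::aes(x = .data$predicted, y = .data$truth,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::labs(x = "predicted", y = "truth",
                  title = sprintf("%s evaluation, accuracy %.1f%%",
                                  object$mode, 100 * object$overall)) +
    ggplot2::theme_minimal()
}

#' Plot per-iteration online accuracy curves
#'
#' One line per action class: the fraction of test repetitions whose gated
#' (latched) prediction is correct at each iteration into the action.
#'
#' @param eval An online `hsom_eval`.
#' @return A ggplot object.
#' @export
plot_iteration_curves <- function(eval) {
  stopifnot(inherits(eval, "hsom_eval"), !is.null(eval$curves))
  ggplot2::ggplot(eval$curves,
                  ggplot2::aes(x = .data$iteration, y = .data$accuracy,
                               color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration (unique posture frames into the action)",
                  y = "recognition accuracy") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot SOM training progress
#'
#' Per-epoch mean quantization error of a trained lattice.
#'
#' @param object A trained `som_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot som_grid
#' @export
autoplot.som_grid <- function(object, ...) {
  stopifnot(!is.null(object$qe_log))
  ggplot2::ggplot(object$qe_log,
                  ggplot2::aes(x = .data$epoch, y = .data$mean_qe)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "mean quantization error") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' Save / load a trained model archive
#'
#' A single versioned archive file holding all layer weights, the
#' configuration and the seeds; reloads bit-exactly.
#'
#' @param model An `hsom_model`.
#' @param path Archive path (conventionally `.rds`).
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hsom_model"))
  saveRDS(model, path, version = 3L)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "hsom_model")) {
    stop("archive does not contain an hsom_model", call. = FALSE)
  }
  model
}
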