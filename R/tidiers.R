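#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the FAR/FRR threshold sweep of a metrics object
#'
#' @param x A `vein_metrics` object.
#' @param ... Unused.
#' @return Tibble with `threshold`, `far`, `frr`.
#' @exportS3Method generics::tidy
tidy.vein_metrics <- function(x, ...) {
  x$sweep
}

#' One-row summary of a metrics object
#'
#' @param x A `vein_metrics` object.
#' @param ... Unused.
#' @return Tibble with `accuracy` and `eer` (percent), `eer_threshold`,
#'   `n_genuine`, `n_impostor`.
#' @exportS3Method generics::glance
glance.vein_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, eer = x$eer,
                 eer_threshold = x$eer_threshold,
                 n_genuine = length(x$genuine),
                 n_impostor = length(x$impostor))
}

#' Tidy one-vs-rest decision scores
#'
#' @param x An `ovr_svm_result`.
#' @param ... Unused.
#' @return Long tibble with `sample`, `class`, `score`, `predicted`.
#' @exportS3Method generics::tidy
tidy.ovr_svm_result <- function(x, ...) {
  n <- nrow(x$scores)
  tibble::tibble(
    sample = rep(seq_len(n), times = ncol(x$scores)),
    class = rep(colnames(x$scores), each = n),
    score = as.vector(x$scores),
    predicted = rep(as.character(x$labels), times = ncol(x$scores))
  )
}

#' Plot the FAR/FRR trade-off of a metrics object
#'
#' Draws both error curves against the decision threshold and marks the
#' equal-error operating point.
#'
#' @param object A `vein_metrics` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.vein_metrics <- function(object, ...) {
  sw <- object$sweep
  df <- tibble::tibble(
    threshold = rep(sw$threshold, 2),
    rate = c(sw$far, sw$frr),
    curve = rep(c("FAR", "FRR"), each = nrow(sw))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$rate,
                                   colour = .data$curve)) +
    ggplot2::geom_step() +
    ggplot2::annotate("point", x = object$eer_threshold,
                      y = object$eer / 100, shape = 4, size = 3) +
    ggplot2::labs(x = "decision threshold", y = "error rate",
                  colour = NULL,
                  subtitle = sprintf("EER = %.2f%%", object$eer)) +
    ggplot2::theme_minimal()
}

#' Plot filter-bank kernels
#'
#' @param object A `filter_bank`.
#' @param ... Unused.
#' @return A ggplot object with one facet per kernel.
#' @exportS3Method ggplot2::autoplot
autoplot.filter_bank <- function(object, ...) {
  dfs <- lapply(seq_along(object$kernels), function(i) {
    k <- object$kernels[[i]]
    tibble::tibble(
      channel = object$channel_meta[i],
      row = rep(seq_len(nrow(k)), times = ncol(k)),
      col = rep(seq_len(ncol(k)), each = nrow(k)),
      value = as.vector(k)
    )
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
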