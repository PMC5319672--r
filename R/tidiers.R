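#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted filtration model
#'
#' @param x A `glmvc_model`.
#' @param ... Unused.
#' @return Tibble with one row per term (`"(Intercept)"` first): `term`,
#'   `estimate`.
#' @method tidy glmvc_model
#' @export
tidy.glmvc_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' One-row summary of a fitted filtration model
#'
#' @param x A `glmvc_model`.
#' @param ... Unused.
#' @return Tibble: `platform`, `variant_type`, `n_covariates`, `aic`,
#'   `threshold`, `converged`.
#' @method glance glmvc_model
#' @export
glance.glmvc_model <- function(x, ...) {
  tibble::tibble(
    platform = x$platform,
    variant_type = x$variant_type,
    n_covariates = length(x$coefficients),
    aic = x$aic,
    threshold = x$threshold,
    converged = x$converged
  )
}

#' Plot a relative-variable-importance table
#'
#' Horizontal bar chart of normalized RVI per parameter, ordered by
#' importance.
#'
#' @param object A `glmvc_rvi` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot glmvc_rvi
#' @export
autoplot.glmvc_rvi <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$normalized_rvi,
    y = stats::reorder(.data$parameter, .data$normalized_rvi)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = paste0("normalized RVI (", df$mode[1], ")"),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the probability separation achieved by a model
#'
#' Histogram of predicted true-positive probabilities by label, with the
#' retention threshold marked; the visual counterpart of the
#' sensitivity-preserving threshold rule.
#'
#' @param model A trained `glmvc_model`.
#' @param tbl Labeled feature table.
#' @return A ggplot object.
#' @export
plot_separation <- function(model, tbl) {
  scored <- apply_model(model, tbl)
  ggplot2::ggplot(scored, ggplot2::aes(x = .data$p_hat, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = model$threshold, linetype = "dashed") +
    ggplot2::labs(x = "predicted P(true positive)", y = "calls",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a forward-selection AIC trace
#'
#' @param model A `glmvc_model` trained by [forward_select()] /
#'   [train_pipeline()] (needs `$trace`).
#' @return A ggplot object.
#' @export
plot_aic_trace <- function(model) {
  if (is.null(model$trace)) rlang::abort("model carries no selection trace")
  tr <- model$trace
  tr$added[1] <- "(intercept)"
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$aic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$added), vjust = -0.8, size = 3) +
    ggplot2::labs(x = "forward-selection step", y = "AIC") +
    ggplot2::theme_minimal()
}
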