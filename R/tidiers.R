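#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' Tidy a fitted spatiotemporal model
#'
#' @param x An [fit_st()] result.
#' @param effects Which table: `"fixed"` (default), `"hyper"`, or
#'   `"random"` (per-element latent summaries).
#' @param ... Unused.
#' @return A tibble in broom conventions.
#' @export
tidy.st_fit <- function(x, effects = c("fixed", "hyper", "random"), ...) {
  effects <- match.arg(effects)
  switch(effects,
    fixed = x$fixed,
    hyper = x$hyper,
    random = x$effects
  )
}

#' @export
tidy.st_mcmc <- function(x, effects = c("fixed", "hyper"), ...) {
  effects <- match.arg(effects)
  switch(effects, fixed = x$fixed_summary, hyper = x$hyper_summary)
}

#' One-row fit summary
#'
#' @param x An [fit_st()] result.
#' @param ... Unused.
#' @return A one-row tibble: dimensions, interaction type, number of
#'   hyperparameter design points, log evidence (unnormalized), and the
#'   maximum Newton iteration count.
#' @export
glance.st_fit <- function(x, ...) {
  int <- x$internals$int
  tibble::tibble(
    n_areas = int$pm$S,
    n_periods = int$pm$T,
    n_cells = int$pm$S * int$pm$T,
    interaction = x$model$interaction,
    n_hyper = nrow(x$hyper),
    n_grid_points = nrow(x$grid$theta),
    grid_strategy = x$grid$strategy,
    log_evidence = x$log_evidence,
    max_newton_iter = max(x$iterations)
  )
}

#' Augment a panel with fitted quantities
#'
#' @param x An [fit_st()] result.
#' @param ... Unused.
#' @return The per-cell tibble: data columns plus SMR, posterior mean/sd of
#'   the log relative risk, fitted relative risk and 95% interval.
#' @export
augment.st_fit <- function(x, ...) {
  x$cells
}

#' Plot a fitted spatiotemporal field
#'
#' Heat-tile panels of the posterior mean log relative risk by area and
#' period. When the graph carries lattice coordinates (see
#' [lattice_graph()]) areas are drawn at their grid positions, giving a
#' schematic map per period; otherwise areas are indexed on the x axis.
#'
#' @param object An [fit_st()] result.
#' @param value Cell column to plot (default `"eta_mean"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.st_fit <- function(object, value = "eta_mean", ...) {
  cells <- object$cells
  coords <- attr(object$graph, "coords")
  if (!is.null(coords)) {
    df <- dplyr::left_join(cells, coords, by = "area_id")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                     fill = .data[[value]])) +
      ggplot2::geom_tile(colour = "grey30") +
      ggplot2::facet_wrap(~time, labeller = ggplot2::label_both) +
      ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                    high = "darkred", midpoint = 0) +
      ggplot2::coord_equal() +
      ggplot2::labs(fill = value, x = NULL, y = NULL,
                    title = "Posterior mean log relative risk") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text = ggplot2::element_blank())
  } else {
    ggplot2::ggplot(cells, ggplot2::aes(x = factor(.data$time),
                                        y = .data$area_id,
                                        fill = .data[[value]])) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                    high = "darkred", midpoint = 0) +
      ggplot2::labs(x = "period", y = "area", fill = value) +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the fitted temporal trend
#'
#' Posterior mean of the structured temporal (RW1) effect with a 95%
#' interval band.
#'
#' @param fit An [fit_st()] result with an active `gamma` effect.
#' @return A ggplot object.
#' @export
plot_temporal_trend <- function(fit) {
  if (!inherits(fit, "st_fit")) abort("Expected an `st_fit`.")
  eff <- fit$effects
  g <- eff[eff$block == "gamma", , drop = FALSE]
  if (!nrow(g)) abort("No structured temporal effect in this fit.")
  g$time <- seq_len(nrow(g))
  ggplot2::ggplot(g, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - 1.96 * .data$sd,
                                      ymax = .data$mean + 1.96 * .data$sd),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "period", y = "temporal effect (log RR)",
                  title = "Structured temporal trend") +
    ggplot2::theme_minimal()
}

#' Plot standardized mortality ratios
#'
#' SMR by area and period for a panel (computed on the fly if absent).
#'
#' @param panel A panel tibble.
#' @return A ggplot object.
#' @export
plot_smr <- function(panel) {
  tab <- smr_table(panel)
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$time), y = .data$area_id,
                                    fill = .data$smr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "darkred", midpoint = 1) +
    ggplot2::labs(x = "period", y = "area", fill = "SMR") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
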