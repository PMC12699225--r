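# ggplot2 front-ends for the main result types.

#' Plot an activation map
#'
#' @param map Matrix from [activation_map()] (fractional change).
#' @param roi Optional `mask_image` outlined on top.
#' @return A ggplot.
#' @export
plot_activation_map <- function(map, roi = NULL) {
  df <- tibble::tibble(row = rep(seq_len(nrow(map)), times = ncol(map)),
                       col = rep(seq_len(ncol(map)), each = nrow(map)),
                       value = as.vector(map))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "dF/F0") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
  if (!is.null(roi)) {
    rdf <- tibble::tibble(row = rep(seq_len(nrow(map)), times = ncol(map)),
                          col = rep(seq_len(ncol(map)), each = nrow(map)),
                          on = as.vector(roi$grid))
    p <- p + ggplot2::geom_tile(data = rdf[rdf$on, ],
                                ggplot2::aes(x = .data$col, y = .data$row),
                                inherit.aes = FALSE, fill = NA,
                                colour = "red", linewidth = 0.1)
  }
  p
}

#' Plot an evoked or reactivity trace
#'
#' @param trace Tibble with `time` and one of `dff`/`frac`.
#' @param stim_duration Optional stimulus window shading (s).
#' @return A ggplot.
#' @export
plot_trace <- function(trace, stim_duration = NULL) {
  ycol <- intersect(c("dff", "frac"), names(trace))[1L]
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time,
                                           y = 100 * .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "fractional change (%)") +
    ggplot2::theme_minimal()
  if (!is.null(stim_duration)) {
    p <- p + ggplot2::annotate("rect", xmin = 0, xmax = stim_duration,
                               ymin = -Inf, ymax = Inf, alpha = 0.1,
                               fill = "steelblue")
  }
  p
}

#' Autoplot a mixed-model fit (fixed-effect estimates and CIs)
#'
#' @param object A `vasc_lme`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vasc_lme
#' @export
autoplot.vasc_lme <- function(object, ...) {
  fe <- object$fixed_effects
  fe <- fe[fe$term != "(Intercept)", , drop = FALSE]
  ggplot2::ggplot(fe, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot a Johnson-Neyman region
#'
#' Conditional slope of the predictor with its pointwise confidence band
#' across the moderator; significance boundaries as vertical lines.
#'
#' @param object A `vasc_jn`.
#' @param m_range Moderator range to draw (defaults to the boundary
#'   neighbourhood, or -1..1 around zero when boundless).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vasc_jn
#' @export
autoplot.vasc_jn <- function(object, m_range = NULL, ...) {
  if (is.null(m_range)) {
    m_range <- if (length(object$boundaries) > 0) {
      range(object$boundaries) + c(-1, 1) * max(1, diff(range(object$boundaries)))
    } else c(-1, 1)
  }
  m <- seq(m_range[1L], m_range[2L], length.out = 200)
  th <- object$b1 + object$b3 * m
  se <- sqrt(object$v11 + m^2 * object$v33 + 2 * m * object$v13)
  df <- tibble::tibble(m = m, theta = th,
                       lo = th - object$t_crit * se,
                       hi = th + object$t_crit * se)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$theta)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = object$moderator,
                  y = sprintf("conditional slope of %s", object$predictor)) +
    ggplot2::theme_minimal()
  for (b in object$boundaries) {
    p <- p + ggplot2::geom_vline(xintercept = b, colour = "red",
                                 linetype = 3)
  }
  p
}
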