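# ggplot2 views of the result objects.

#' @method autoplot ez_km
#' @export
autoplot.ez_km <- function(object, ...) {
  d <- object |>
    group_by(.data$group) |>
    arrange(.data$time, .by_group = TRUE) |>
    ungroup()
  start <- distinct(d, .data$group) |> mutate(time = 0, survival = 1)
  ggplot2::ggplot(bind_rows(start[c("group", "time", "survival")],
                            d[c("group", "time", "survival")]),
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "overall survival",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot ez_maxstat
#' @export
autoplot.ez_maxstat <- function(object, ...) {
  scan <- attr(object, "scan")
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$cutpoint,
                                     y = abs(.data$statistic))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$cutpoint, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "candidate cutpoint",
                  y = "|standardized log-rank statistic|") +
    ggplot2::theme_minimal()
}

#' @method autoplot ez_scores
#' @export
autoplot.ez_scores <- function(object, ...) {
  d <- as_tibble(object) |> arrange(.data$score) |>
    mutate(rank = seq_len(n()))
  thr <- attr(object, "threshold")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$score))
  p <- if ("risk_group" %in% names(d)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$risk_group), size = 1)
  } else {
    p + ggplot2::geom_point(size = 1)
  }
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = 2)
  }
  p + ggplot2::labs(x = "samples ranked by score", y = "EZ score",
                    colour = "risk") +
    ggplot2::theme_minimal()
}

#' @method autoplot ez_surv_assoc
#' @export
autoplot.ez_surv_assoc <- function(object, ...) {
  autoplot.ez_km(object$km) +
    ggplot2::labs(subtitle = sprintf("log-rank p = %.3g; threshold = %.3f",
                                     object$logrank$p_value,
                                     object$threshold %||% NA_real_))
}
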