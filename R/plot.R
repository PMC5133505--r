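#' QQ plot of observed versus expected p-values
#'
#' Straight diagonal behaviour indicates a calibrated null; systematic
#' early lift-off indicates inflation.
#'
#' @param p Numeric vector of p-values.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_qq <- function(p, title = NULL) {
  qq <- qq_data(p)
  ggplot(qq, aes(x = .data$expected, y = .data$observed)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(size = 0.8) +
    labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      title = title
    ) +
    theme_bw()
}

#' @rdname wu_screen
#' @param object A `wu_screen` result.
#' @param mode Which mode's p-values to plot (default: all run modes,
#'   faceted together with phenotypes).
#' @param ... Unused.
#' @method autoplot wu_screen
#' @export
autoplot.wu_screen <- function(object, mode = NULL, ...) {
  modes <- mode %||% attr(object, "modes")
  long <- list_rbind(lapply(modes, function(md) {
    pcol <- paste0("p_", tolower(md))
    object |>
      as_tibble() |>
      group_by(.data$phenotype) |>
      reframe(qq_data(.data[[pcol]])) |>
      mutate(mode = md)
  }))
  ggplot(long, aes(x = .data$expected, y = .data$observed)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(size = 0.8) +
    facet_wrap(~ phenotype + mode) +
    labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p))
    ) +
    theme_bw()
}

#' @rdname wu_screen
#' @param x A `wu_screen` result.
#' @method tidy wu_screen
#' @export
tidy.wu_screen <- function(x, ...) {
  as_tibble(x)
}

#' @rdname wu_screen
#' @method glance wu_screen
#' @export
glance.wu_screen <- function(x, ...) {
  modes <- attr(x, "modes")
  out <- tibble(
    n_tests = nrow(x),
    n_regions = dplyr::n_distinct(x$gene_id),
    n_phenotypes = dplyr::n_distinct(x$phenotype)
  )
  for (md in modes) {
    pcol <- paste0("p_", tolower(md))
    out[[paste0("min_p_", tolower(md))]] <- suppressWarnings(min(x[[pcol]],
                                                                 na.rm = TRUE))
  }
  out
}
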