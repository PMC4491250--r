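#' Overlay percentile curves
#'
#' Plots one or more percentile tables on a gestational-age vs weight chart,
#' one line per (table, percentile): solid lines for model-based curves,
#' dashed for empirical ones — the convention of published growth-chart
#' overlays.
#'
#' @param tables A [percentile_table()] or a list of them.
#' @param labels Optional character labels, one per table; default each
#'   table's own label (or `table 1`, `table 2`, ...).
#' @param outfile Optional output path (`.png`, `.svg` or `.pdf`); when
#'   given, the figure is written there.
#' @param width,height Figure size in inches when writing to file.
#' @return The ggplot object, invisibly.
#' @export
overlay_plot <- function(tables, labels = NULL, outfile = NULL,
                         width = 7, height = 5) {
  if (inherits(tables, "percentile_table")) tables <- list(tables)
  if (length(tables) == 0L ||
      !all(vapply(tables, inherits, logical(1), "percentile_table"))) {
    stop("`tables` must be one or more percentile_table objects", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- vapply(seq_along(tables), function(i) {
      if (nzchar(tables[[i]]$label)) tables[[i]]$label else paste("table", i)
    }, character(1))
  }
  if (length(labels) != length(tables)) {
    stop("`labels` must match `tables` in length", call. = FALSE)
  }
  long <- do.call(rbind, lapply(seq_along(tables), function(i) {
    tab <- tables[[i]]
    data.frame(
      ga_weeks = rep(tab$ga_weeks, times = length(tab$percentiles)),
      weight_g = as.vector(tab$weights),
      percentile = factor(rep(tab$percentiles, each = length(tab$ga_weeks))),
      table = labels[i],
      source = tab$source
    )
  }))
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$ga_weeks, y = .data$weight_g,
    group = interaction(.data$table, .data$percentile),
    colour = .data$percentile, linetype = .data$source
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(
      values = c(model = "solid", empirical = "dashed"), drop = FALSE) +
    ggplot2::labs(x = "Gestational age (exact weeks)",
                  y = "Fetal weight (g)",
                  linetype = "source", colour = "percentile") +
    ggplot2::theme_minimal()
  if (!is.null(outfile)) {
    ok <- tryCatch({
      ggplot2::ggsave(outfile, plot = p, width = width, height = height,
                      dpi = 150)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop("could not write figure to '", outfile, "': ",
           conditionMessage(ok), call. = FALSE)
    }
  }
  invisible(p)
}
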