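#' Observed weekly birthweight percentiles
#'
#' Empirical quantiles of birthweight per completed gestational week, by
#' linear interpolation between order statistics (the type-7 convention).
#' Weeks with fewer records than `min_n` are omitted with a warning —
#' tail quantiles are unstable in thin strata. Each reported week is placed
#' at its interval midpoint (`week + 0.5` exact weeks) so empirical rows
#' align with model curves evaluated under the same convention.
#'
#' @param records A data.frame with `birthweight_g` and a completed-week
#'   column (default `resolved_weeks`).
#' @param percentiles Levels in (0, 100); default 10, 50, 90 — the set
#'   conventionally displayed on growth-chart overlays.
#' @param ga_range Completed-week window to report, default `c(24, 38)`.
#' @param min_n Minimum records per week, default 20.
#' @param week_col Name of the completed-week column; pass `"lmp_weeks"` to
#'   tabulate against uncorrected LMP dating (e.g. for dating-error
#'   diagnostics).
#' @return A [percentile_table()] with `source = "empirical"`.
#' @export
empirical_percentiles <- function(records, percentiles = c(10, 50, 90),
                                  ga_range = c(24, 38), min_n = 20,
                                  week_col = "resolved_weeks") {
  stopifnot(is.data.frame(records), "birthweight_g" %in% names(records))
  if (week_col == "resolved_weeks" && !"resolved_weeks" %in% names(records) &&
      all(c("lmp_weeks", "ce_weeks") %in% names(records))) {
    records$resolved_weeks <-
      reconcile_ga(records$lmp_weeks, records$ce_weeks,
                   on_unresolved = "na")$resolved_weeks
  }
  if (!week_col %in% names(records)) {
    stop(sprintf("records carry no `%s` column", week_col), call. = FALSE)
  }
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop("percentile levels must lie strictly between 0 and 100", call. = FALSE)
  }
  wk <- records[[week_col]]
  keep <- !is.na(wk) & !is.na(records$birthweight_g) &
    wk >= ga_range[1] & wk <= ga_range[2]
  wk <- wk[keep]
  bw <- records$birthweight_g[keep]
  weeks <- sort(unique(wk))
  counts <- vapply(weeks, function(w) sum(wk == w), integer(1))
  thin <- weeks[counts < min_n]
  weeks <- weeks[counts >= min_n]
  if (length(thin)) {
    warning(sprintf("omitting week(s) %s with fewer than %d records",
                    paste(thin, collapse = ", "), min_n), call. = FALSE)
  }
  if (length(weeks) == 0L) {
    stop(sprintf("no gestational week has at least %d records in [%g, %g]",
                 min_n, ga_range[1], ga_range[2]), call. = FALSE)
  }
  q <- t(vapply(
    weeks,
    function(w) stats::quantile(bw[wk == w], probs = percentiles / 100,
                                type = 7, names = FALSE),
    numeric(length(percentiles))
  ))
  percentile_table(weeks + 0.5, percentiles, q, source = "empirical",
                   label = "observed weekly quantiles (type 7)")
}

#' Compare two percentile tables
#'
#' Per-percentile relative deviations of table `b` from table `a` over their
#' common grid. Rows are aligned by completed gestational week (the floor of
#' each table's exact-week coordinate), so an empirical table at week
#' midpoints and a model table on the same convention compare row-for-row.
#' Pass the observed table as `a` to express deviation relative to the
#' observed curves.
#'
#' @param a Baseline [percentile_table()] (the denominator).
#' @param b Comparison table.
#' @return An object of class `comparison_summary`: a list with
#'   `per_percentile` (data.frame: `percentile`, `mean_abs_dev_pct`,
#'   `max_abs_dev_pct`, `ga_at_max`), `ga_weeks` (the common completed
#'   weeks), and the two labels.
#' @export
compare_tables <- function(a, b) {
  stopifnot(inherits(a, "percentile_table"), inherits(b, "percentile_table"))
  p_common <- intersect(a$percentiles, b$percentiles)
  wa <- floor(a$ga_weeks)
  wb <- floor(b$ga_weeks)
  w_common <- intersect(wa, wb)
  if (length(p_common) < 1L || length(w_common) < 2L) {
    stop(paste("tables are not comparable: need at least one shared",
               "percentile level and two shared gestational weeks"),
         call. = FALSE)
  }
  w_common <- sort(w_common)
  ia <- match(w_common, wa); ja <- match(p_common, a$percentiles)
  ib <- match(w_common, wb); jb <- match(p_common, b$percentiles)
  rel <- (b$weights[ib, jb, drop = FALSE] - a$weights[ia, ja, drop = FALSE]) /
    a$weights[ia, ja, drop = FALSE]
  per <- data.frame(
    percentile = p_common,
    mean_abs_dev_pct = 100 * colMeans(abs(rel)),
    max_abs_dev_pct = 100 * apply(abs(rel), 2L, max),
    ga_at_max = w_common[apply(abs(rel), 2L, which.max)]
  )
  rownames(per) <- NULL
  structure(
    list(per_percentile = per, ga_weeks = w_common,
         baseline = a$label, comparison = b$label,
         quantile_convention = "type 7"),
    class = "comparison_summary"
  )
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf("Percentile-table comparison over completed weeks %d-%d\n",
              min(x$ga_weeks), max(x$ga_weeks)))
  cat(sprintf("  baseline: %s\n  comparison: %s\n",
              x$baseline, x$comparison))
  print(transform(x$per_percentile,
                  mean_abs_dev_pct = round(mean_abs_dev_pct, 3),
                  max_abs_dev_pct = round(max_abs_dev_pct, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Write a comparison summary as JSON
#'
#' @param x A [compare_tables()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  stopifnot(inherits(x, "comparison_summary"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
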