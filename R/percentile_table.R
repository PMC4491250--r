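#' Percentile-by-gestational-week table
#'
#' Container for a grid of weights indexed by gestational age (rows) and
#' percentile level (columns), either model-based (from a
#' [twin_standard()]) or empirical (weekly quantiles of observed weights).
#'
#' @param ga_weeks Numeric vector of exact gestational ages (decimal weeks),
#'   strictly increasing.
#' @param percentiles Numeric vector of percentile levels in (0, 100),
#'   strictly increasing.
#' @param weights Numeric matrix of grams, one row per gestational age, one
#'   column per percentile; must be strictly increasing across percentiles
#'   within each row.
#' @param source Either `"model"` or `"empirical"`.
#' @param label Free-text description.
#' @return An object of class `percentile_table`.
#' @export
percentile_table <- function(ga_weeks, percentiles, weights,
                             source = c("model", "empirical"), label = "") {
  source <- match.arg(source)
  ga_weeks <- as.numeric(ga_weeks)
  percentiles <- as.numeric(percentiles)
  weights <- as.matrix(weights)
  if (length(ga_weeks) == 0L || length(percentiles) == 0L) {
    stop("`ga_weeks` and `percentiles` must be non-empty", call. = FALSE)
  }
  if (anyNA(ga_weeks) || is.unsorted(ga_weeks, strictly = TRUE)) {
    stop("`ga_weeks` must be strictly increasing", call. = FALSE)
  }
  if (anyNA(percentiles) || is.unsorted(percentiles, strictly = TRUE) ||
      any(percentiles <= 0 | percentiles >= 100)) {
    stop("`percentiles` must be strictly increasing within (0, 100)", call. = FALSE)
  }
  if (nrow(weights) != length(ga_weeks) || ncol(weights) != length(percentiles)) {
    stop("`weights` must be a length(ga_weeks) x length(percentiles) matrix",
         call. = FALSE)
  }
  # model curves are strictly ordered in p; empirical quantiles may tie
  if (ncol(weights) > 1L) {
    d <- t(apply(weights, 1L, diff))
    bad <- if (source == "model") any(d <= 0) else any(d < 0)
    if (bad) {
      stop("weights must be ordered across percentile levels in every row",
           call. = FALSE)
    }
  }
  dimnames(weights) <- list(
    format(ga_weeks, trim = TRUE),
    paste0("p", format(percentiles, trim = TRUE))
  )
  structure(
    list(ga_weeks = ga_weeks, percentiles = percentiles, weights = weights,
         source = source, label = as.character(label)),
    class = "percentile_table"
  )
}

#' Build a model percentile table
#'
#' Evaluates a twin standard's percentile curves over a grid of exact
#' gestational ages. Defaults mirror the published chart layout: percentiles
#' 3, 5, 10, 25, 50, 75, 90, 95, 97 on whole weeks 24 to 38.
#'
#' @param std A [twin_standard()].
#' @param ga_grid Exact gestational ages (decimal weeks) within the
#'   standard's range.
#' @param percentiles Strictly increasing levels in (0, 100).
#' @return A [percentile_table()] with `source = "model"`.
#' @examples
#' tab <- build_table(twin_standard(2727, 374, "US White twins"))
#' tab
#' @export
build_table <- function(std, ga_grid = seq(24, 38, by = 1),
                        percentiles = c(3, 5, 10, 25, 50, 75, 90, 95, 97)) {
  stopifnot(inherits(std, "twin_standard"))
  if (length(ga_grid) == 0L || length(percentiles) == 0L) {
    stop("`ga_grid` and `percentiles` must be non-empty", call. = FALSE)
  }
  w <- outer(adjusted_median(std, ga_grid),
             1 + stats::qnorm(percentiles / 100) * std$cv)
  percentile_table(ga_grid, percentiles, w, source = "model", label = std$label)
}

#' @export
print.percentile_table <- function(x, ...) {
  cat(sprintf("Percentile table (%s%s): %d gestational ages x %d percentiles\n",
              x$source, if (nzchar(x$label)) paste0(", ", x$label) else "",
              length(x$ga_weeks), length(x$percentiles)))
  print(round(x$weights))
  invisible(x)
}

#' @export
as.data.frame.percentile_table <- function(x, ...) {
  df <- data.frame(ga_weeks = x$ga_weeks, x$weights, check.names = FALSE)
  rownames(df) <- NULL
  df
}

#' Write a percentile table as CSV
#'
#' Header `ga_weeks,p3,p5,...` following the table's percentile set;
#' weights rounded half-away-from-zero to integer grams, gestational age in
#' decimal weeks. [read_percentile_table()] reads the format back.
#'
#' @param x A [percentile_table()].
#' @param path Output file path.
#' @param source Declared provenance when reading: `"model"` or `"empirical"`.
#' @param label Label to attach when reading.
#' @return `write_percentile_table()` returns `path` invisibly;
#'   `read_percentile_table()` returns a [percentile_table()].
#' @export
write_percentile_table <- function(x, path) {
  stopifnot(inherits(x, "percentile_table"))
  df <- as.data.frame(x)
  for (j in seq_along(df)[-1]) df[[j]] <- .round_half_up(df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_percentile_table
#' @export
read_percentile_table <- function(path, source = c("model", "empirical"),
                                  label = "") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "ga_weeks" || ncol(df) < 2L) {
    stop("expected a CSV with header `ga_weeks,p<level>,...`", call. = FALSE)
  }
  p <- as.numeric(sub("^p", "", names(df)[-1]))
  if (anyNA(p)) stop("percentile columns must be named p<level>", call. = FALSE)
  percentile_table(df$ga_weeks, p, as.matrix(df[-1]),
                   source = match.arg(source), label = label)
}

# round half away from zero (CSV presentation; base round() is half-to-even)
.round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)
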