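#' Create an adjustable twin fetal weight standard
#'
#' Anchors the Hadlock median curve to a population's mean birthweight at 37
#' completed weeks (exact gestational age 37.5 weeks, the interval midpoint).
#' The proportionality ratio is `mean_37` divided by the Hadlock median at
#' 37.5 weeks (~3,133 g) and is assumed constant across gestation; the
#' coefficient of variation `sd_37 / mean_37` is likewise assumed constant,
#' so every percentile band scales with the adjusted median.
#'
#' The divisor is the unrounded curve value (3,133.40... g) rather than the
#' rounded 3,133 g constant, so that an anchor equal to the Hadlock value
#' reproduces the Hadlock curve exactly (ratio 1).
#'
#' @param mean_37 Population mean birthweight in grams at 37 completed weeks.
#' @param sd_37 Corresponding standard deviation in grams.
#' @param label Free-text population name.
#' @param ga_range Exact-week interval over which curves are emitted; default
#'   24 to 38.99 weeks (the standard's validated window), restricted to the
#'   Hadlock validity window 10-41 weeks.
#' @return An object of class `twin_standard` with components `ratio`, `cv`,
#'   `mean_37`, `sd_37`, `ga_range` and `label`.
#' @examples
#' std <- twin_standard(2727, 374, label = "US White twins")
#' std$ratio
#' adjusted_median(std, 34)
#' @seealso [adjusted_median()], [percentile_weight()], [build_table()]
#' @export
twin_standard <- function(mean_37, sd_37, label = "", ga_range = c(24, 38.99)) {
  stopifnot(is.numeric(mean_37), length(mean_37) == 1L,
            is.numeric(sd_37), length(sd_37) == 1L)
  if (is.na(mean_37) || mean_37 <= 0) {
    stop("`mean_37` must be a positive birthweight in grams", call. = FALSE)
  }
  if (is.na(sd_37) || sd_37 <= 0) {
    stop("`sd_37` must be a positive standard deviation in grams", call. = FALSE)
  }
  cv <- sd_37 / mean_37
  if (cv >= 0.5) {
    stop(sprintf(
      "implausible dispersion: sd/mean = %.3f; a coefficient of variation below 0.5 is required",
      cv
    ), call. = FALSE)
  }
  k <- hadlock_constants()
  ga_range <- as.numeric(ga_range)
  if (length(ga_range) != 2L || anyNA(ga_range) || ga_range[1] >= ga_range[2] ||
      ga_range[1] < k$ga_min || ga_range[2] > k$ga_max) {
    stop(sprintf("`ga_range` must be an increasing pair within [%g, %g] weeks",
                 k$ga_min, k$ga_max), call. = FALSE)
  }
  structure(
    list(
      ratio = mean_37 / k$anchor_weight_g,
      cv = cv,
      mean_37 = mean_37,
      sd_37 = sd_37,
      ga_range = ga_range,
      label = as.character(label)
    ),
    class = "twin_standard"
  )
}

#' @export
print.twin_standard <- function(x, ...) {
  cat("Adjustable twin fetal weight standard",
      if (nzchar(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  cat(sprintf("  anchor: mean %.0f g, SD %.0f g at 37 completed weeks\n",
              x$mean_37, x$sd_37))
  cat(sprintf("  ratio to Hadlock reference: %.4f   CV: %.1f%%\n",
              x$ratio, 100 * x$cv))
  cat(sprintf("  emission range: %.2f-%.2f exact weeks\n",
              x$ga_range[1], x$ga_range[2]))
  invisible(x)
}

.check_standard_ga <- function(std, ga) {
  stopifnot(inherits(std, "twin_standard"))
  if (!is.numeric(ga) || length(ga) == 0L || anyNA(ga)) {
    stop("`ga` must be numeric and non-missing", call. = FALSE)
  }
  if (any(ga < std$ga_range[1] | ga > std$ga_range[2])) {
    stop(sprintf(
      "gestational age outside the standard's range [%.2f, %.2f] weeks",
      std$ga_range[1], std$ga_range[2]
    ), call. = FALSE)
  }
  invisible(ga)
}

#' Adjusted median fetal weight
#'
#' The population-adjusted median at exact gestational age `ga`: the Hadlock
#' median multiplied by the standard's proportionality ratio. The quotient
#' adjusted/Hadlock is by construction the same at every gestational age.
#'
#' @param std A [twin_standard()].
#' @param ga Exact gestational age in decimal weeks, within the standard's
#'   emission range. Vectorised.
#' @return Adjusted median weight in grams.
#' @export
adjusted_median <- function(std, ga) {
  .check_standard_ga(std, ga)
  std$ratio * hadlock_median(ga)
}

#' Percentile fetal weight
#'
#' Weight at percentile `p` under the constant-CV normal model:
#' `adjusted_median(ga) * (1 + z_p * cv)` where `z_p` is the standard-normal
#' quantile of `p/100`.
#'
#' @inheritParams adjusted_median
#' @param p Percentile level in (0, 100). Vectorised jointly with `ga`
#'   (recycled as usual).
#' @return Weight in grams at the requested percentile.
#' @examples
#' std <- twin_standard(2727, 374)
#' percentile_weight(std, 37.5, c(10, 50, 90))
#' @export
percentile_weight <- function(std, ga, p) {
  .check_standard_ga(std, ga)
  if (!is.numeric(p) || length(p) == 0L || anyNA(p) || any(p <= 0 | p >= 100)) {
    stop("percentile levels must lie strictly between 0 and 100", call. = FALSE)
  }
  w <- adjusted_median(std, ga) * (1 + stats::qnorm(p / 100) * std$cv)
  if (any(w <= 0)) {
    stop(paste(
      "degenerate percentile: the normal model yields a non-positive weight",
      "at this (percentile, CV) combination"
    ), call. = FALSE)
  }
  w
}

#' Birthweight z-score under a twin standard
#'
#' Inverse of the percentile construction: the number of (CV-scaled) standard
#' deviations a weight lies from the adjusted median at that gestational age.
#'
#' @inheritParams adjusted_median
#' @param weight Observed weight in grams, positive. Vectorised.
#' @return Dimensionless z-score.
#' @export
weight_zscore <- function(std, ga, weight) {
  .check_standard_ga(std, ga)
  if (!is.numeric(weight) || anyNA(weight) || any(weight <= 0)) {
    stop("`weight` must be positive grams", call. = FALSE)
  }
  m <- adjusted_median(std, ga)
  (weight - m) / (std$cv * m)
}

#' SGA/AGA/LGA classification
#'
#' Classifies a weight as small (below the 10th percentile), appropriate, or
#' large (above the 90th percentile) for gestational age. Weights exactly on
#' the 10th or 90th percentile classify as AGA (the conventional strict
#' "<10th" / ">90th" definitions).
#'
#' @inheritParams weight_zscore
#' @return A factor with levels `SGA`, `AGA`, `LGA`.
#' @export
classify_weight <- function(std, ga, weight) {
  if (!is.numeric(weight) || anyNA(weight) || any(weight <= 0)) {
    stop("`weight` must be positive grams", call. = FALSE)
  }
  # compare on the weight scale so a weight exactly on a cut point ties AGA
  p10 <- percentile_weight(std, ga, 10)
  p90 <- percentile_weight(std, ga, 90)
  factor(
    ifelse(weight < p10, "SGA", ifelse(weight > p90, "LGA", "AGA")),
    levels = c("SGA", "AGA", "LGA")
  )
}
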