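#' Bundled US twin anchor defaults by race/ethnicity
#'
#' Week-37 anchor parameters for low-risk US twin births, 1995-2004, by
#' maternal race/ethnicity: group size, share of the analytic cohort, mean
#' birthweight and SD at 37 completed weeks, and the implied coefficient of
#' variation. These are the bundled defaults behind `race = "white"` etc.;
#' any other population supplies its own mean and SD to [twin_standard()].
#'
#' @return A data.frame with columns `race`, `n`, `share_pct`, `mean_g`,
#'   `sd_g`, `cv_pct`.
#' @examples
#' race_anchors()
#' @export
race_anchors <- function() {
  d <- data.frame(
    race = c("white", "black", "hispanic", "asian"),
    n = c(380295L, 90228L, 41905L, 13189L),
    share_pct = c(70.9, 16.8, 7.8, 2.5),
    mean_g = c(2727, 2605, 2663, 2581),
    sd_g = c(374, 378, 381, 372)
  )
  d$cv_pct <- 100 * d$sd_g / d$mean_g
  d
}

#' Twin standard from a bundled race/ethnicity anchor
#'
#' @param race One of `"white"`, `"black"`, `"hispanic"`, `"asian"`.
#' @param ... Passed on to [twin_standard()] (e.g. `ga_range`).
#' @return A [twin_standard()] anchored at the bundled week-37 mean and SD.
#' @examples
#' twin_standard_for_race("black")
#' @export
twin_standard_for_race <- function(race, ...) {
  d <- race_anchors()
  race <- match.arg(tolower(race), d$race)
  row <- d[d$race == race, ]
  twin_standard(row$mean_g, row$sd_g,
                label = sprintf("US %s twins 1995-2004", race), ...)
}
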