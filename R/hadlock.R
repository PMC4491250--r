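#' Hadlock median fetal growth model constants
#'
#' The ultrasound-derived singleton median fetal-weight curve of Hadlock,
#' an exponential of a quadratic in gestational age:
#' \deqn{w(GA) = \exp(b_0 + b_1 GA - b_2 GA^2)}
#' with \eqn{b_0 = 0.578}, \eqn{b_1 = 0.332} per week and
#' \eqn{b_2 = 0.00354} per week squared, valid for exact gestational ages
#' between 10 and 41 weeks. The curve evaluated at 37.5 exact weeks (the
#' midpoint of 37 completed weeks) is the reference weight used to anchor
#' adjustable twin standards; it rounds to 3,133 g.
#'
#' @return A named list with components `b0`, `b1`, `b2`, `ga_min`, `ga_max`,
#'   `anchor_ga` (37.5 exact weeks) and `anchor_weight_g` (the unrounded
#'   median at `anchor_ga`).
#' @examples
#' hadlock_constants()$anchor_weight_g  # ~3133.4 g
#' @export
hadlock_constants <- function() {
  list(
    b0 = 0.578,
    b1 = 0.332,
    b2 = 0.00354,
    ga_min = 10,
    ga_max = 41,
    anchor_ga = 37.5,
    anchor_weight_g = .hadlock_eval(37.5)
  )
}

# unchecked evaluation of the Hadlock quadratic-exponential
.hadlock_eval <- function(ga) {
  exp(0.578 + 0.332 * ga - 0.00354 * ga^2)
}

#' Hadlock median fetal weight
#'
#' Evaluates the Hadlock median fetal-weight curve at exact gestational age
#' `ga` (decimal weeks). Vectorised over `ga`.
#'
#' @param ga Exact gestational age in decimal weeks; must lie in the model's
#'   validity window of 10 to 41 weeks.
#' @return Median fetal weight in grams (unrounded double).
#' @examples
#' round(hadlock_median(37.5))  # 3133
#' hadlock_median(c(24.5, 34, 38.5))
#' @export
hadlock_median <- function(ga) {
  if (!is.numeric(ga) || length(ga) == 0L || anyNA(ga)) {
    stop("`ga` must be numeric and non-missing", call. = FALSE)
  }
  k <- hadlock_constants()
  if (any(ga < k$ga_min | ga > k$ga_max)) {
    stop(sprintf(
      "gestational age outside the Hadlock validity window [%g, %g] weeks",
      k$ga_min, k$ga_max
    ), call. = FALSE)
  }
  .hadlock_eval(ga)
}
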