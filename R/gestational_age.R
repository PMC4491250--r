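#' Reconcile LMP-based and clinically estimated gestational age
#'
#' US birth certificates carry two gestational-age estimates in completed
#' weeks: one from the self-reported last menstrual period (LMP) and a
#' clinical estimate (CE). Large LMP dating errors are corrected by
#' substituting the CE whenever the two differ by more than 2 weeks; a
#' difference of exactly 2 weeks keeps the LMP value. Records with only one
#' estimate fall back to that estimate (flagged `replaced = FALSE`).
#'
#' @param lmp_weeks,ce_weeks Integer completed weeks (0-47); `NA` = missing.
#'   Vectorised; recycled to a common length.
#' @param on_unresolved What to do when both estimates are missing:
#'   `"error"` (default) or `"na"` (return `NA` resolved weeks so a
#'   downstream reliability filter can drop the record).
#' @return A data.frame with columns `lmp_weeks`, `ce_weeks`,
#'   `resolved_weeks`, `replaced`.
#' @examples
#' reconcile_ga(lmp_weeks = c(36, 36, NA), ce_weeks = c(33, 34, 30))
#' @export
reconcile_ga <- function(lmp_weeks, ce_weeks, on_unresolved = c("error", "na")) {
  on_unresolved <- match.arg(on_unresolved)
  n <- max(length(lmp_weeks), length(ce_weeks))
  lmp <- rep_len(as.numeric(lmp_weeks), n)
  ce <- rep_len(as.numeric(ce_weeks), n)
  .check_completed(lmp, "lmp_weeks")
  .check_completed(ce, "ce_weeks")
  both_missing <- is.na(lmp) & is.na(ce)
  if (any(both_missing) && on_unresolved == "error") {
    stop(sprintf(
      "%d record(s) have neither an LMP nor a clinical gestational-age estimate",
      sum(both_missing)
    ), call. = FALSE)
  }
  resolved <- lmp
  replaced <- rep(FALSE, n)
  discordant <- !is.na(lmp) & !is.na(ce) & abs(lmp - ce) > 2
  resolved[discordant] <- ce[discordant]
  replaced[discordant] <- TRUE
  lmp_only_missing <- is.na(lmp) & !is.na(ce)
  resolved[lmp_only_missing] <- ce[lmp_only_missing]
  data.frame(lmp_weeks = lmp, ce_weeks = ce,
             resolved_weeks = resolved, replaced = replaced)
}

.check_completed <- function(x, what) {
  bad <- !is.na(x) & (x < 0 | x > 47 | x != trunc(x))
  if (any(bad)) {
    stop(sprintf("`%s` must be integer completed weeks in [0, 47]", what),
         call. = FALSE)
  }
}

#' Completed weeks to exact weeks
#'
#' Registry data record gestational age in completed weeks (week 37 spans
#' 37+0 to 37+6 days). The mid-interval convention maps completed week `w`
#' to exact age `w + 0.5` decimal weeks, the convention under which the
#' week-37 anchor sits at 37.5 exact weeks. Day-resolved ages use
#' [exact_weeks()] instead.
#'
#' @param completed_weeks Non-negative integer completed weeks. Vectorised.
#' @return Exact gestational age in decimal weeks.
#' @examples
#' completed_to_exact(37)  # 37.5
#' @export
completed_to_exact <- function(completed_weeks) {
  x <- as.numeric(completed_weeks)
  if (anyNA(x) || any(x < 0 | x != trunc(x))) {
    stop("`completed_weeks` must be non-negative integers", call. = FALSE)
  }
  x + 0.5
}

#' Exact gestational age from weeks and days
#'
#' Day-resolved inputs bypass the mid-interval convention:
#' 36 weeks + 5 days = 36 + 5/7 = 36.71 decimal weeks.
#'
#' @param weeks Non-negative integer weeks.
#' @param days Integer days 0-6. Vectorised with `weeks`.
#' @return Exact gestational age in decimal weeks.
#' @examples
#' exact_weeks(36, 5)  # 36.714...
#' @export
exact_weeks <- function(weeks, days = 0) {
  w <- as.numeric(weeks); d <- as.numeric(days)
  if (anyNA(w) || any(w < 0 | w != trunc(w))) {
    stop("`weeks` must be non-negative integers", call. = FALSE)
  }
  if (anyNA(d) || any(d < 0 | d > 6 | d != trunc(d))) {
    stop("`days` must be integers in 0-6", call. = FALSE)
  }
  w + d / 7
}
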