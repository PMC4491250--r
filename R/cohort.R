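#' Low-risk cohort selection
#'
#' Applies the low-risk selection cascade to a twin-birth registry: reliable
#' gestational age and birthweight, maternal age 20-35 years inclusive, high
#' school education or higher, non-smoker, no hypertensive disorder of
#' pregnancy, no pre-existing or gestational diabetes, prenatal care begun
#' in the first trimester. Records are attributed to the first step that
#' excludes them; the retained set itself is order-independent (each record
#' must satisfy every criterion). A missing covariate excludes the record at
#' that step, counted separately from substantive non-compliance.
#'
#' "Reliable" means a reconciled gestational age within `ga_range` completed
#' weeks and a birthweight within `weight_range` grams — standard natality
#' plausibility screens, both configurable.
#'
#' If the records lack a `resolved_weeks` column, [reconcile_ga()] is applied
#' first (records with both estimates missing resolve to `NA` and fall out
#' at the reliable-gestational-age step).
#'
#' @param records A registry data.frame (see [registry_columns()]).
#' @param ga_range Admissible completed-week range, default `c(17, 47)`.
#' @param weight_range Admissible birthweight range in grams, default
#'   `c(250, 6000)`.
#' @return A list of class `low_risk_cohort` with elements `records` (the
#'   retained rows, with `resolved_weeks`/`replaced` added if absent) and
#'   `report` (a data.frame with one row per cascade step: `step`, `input`,
#'   `excluded`, `excluded_missing`, `retained`).
#' @examples
#' reg <- simulate_registry(sim_config(n = 500, seed = 1))
#' lr <- low_risk_filter(reg)
#' lr$report
#' @export
low_risk_filter <- function(records, ga_range = c(17, 47),
                            weight_range = c(250, 6000)) {
  stopifnot(is.data.frame(records))
  if (!"resolved_weeks" %in% names(records) && nrow(records) > 0L) {
    rec <- reconcile_ga(records$lmp_weeks, records$ce_weeks, on_unresolved = "na")
    records$resolved_weeks <- rec$resolved_weeks
    records$replaced <- rec$replaced
  }
  steps <- list(
    reliable_ga = function(d) list(
      ok = !is.na(d$resolved_weeks) & d$resolved_weeks >= ga_range[1] &
        d$resolved_weeks <= ga_range[2],
      miss = rep(FALSE, nrow(d))),
    reliable_birthweight = function(d) list(
      ok = !is.na(d$birthweight_g) & d$birthweight_g >= weight_range[1] &
        d$birthweight_g <= weight_range[2],
      miss = rep(FALSE, nrow(d))),
    maternal_age = function(d) list(
      ok = !is.na(d$maternal_age_y) & d$maternal_age_y >= 20 &
        d$maternal_age_y <= 35,
      miss = is.na(d$maternal_age_y)),
    education = function(d) list(
      ok = !is.na(d$education) & d$education == "highschool_plus",
      miss = is.na(d$education)),
    smoking = function(d) list(
      ok = !is.na(d$smoker) & !d$smoker,
      miss = is.na(d$smoker)),
    hypertensive_disorder = function(d) list(
      ok = !is.na(d$hypertensive_disorder) & !d$hypertensive_disorder,
      miss = is.na(d$hypertensive_disorder)),
    diabetes = function(d) list(
      ok = !is.na(d$diabetes) & !d$diabetes,
      miss = is.na(d$diabetes)),
    prenatal_care = function(d) list(
      ok = !is.na(d$prenatal_care_trimester) &
        d$prenatal_care_trimester == "first",
      miss = is.na(d$prenatal_care_trimester))
  )
  report <- data.frame(step = names(steps), input = 0L, excluded = 0L,
                       excluded_missing = 0L, retained = 0L)
  cur <- records
  for (i in seq_along(steps)) {
    res <- steps[[i]](cur)
    report$input[i] <- nrow(cur)
    report$excluded[i] <- sum(!res$ok & !res$miss)
    report$excluded_missing[i] <- sum(!res$ok & res$miss)
    cur <- cur[res$ok, , drop = FALSE]
    report$retained[i] <- nrow(cur)
  }
  structure(list(records = cur, report = report), class = "low_risk_cohort")
}

#' @export
print.low_risk_cohort <- function(x, ...) {
  cat(sprintf("Low-risk twin cohort: %d of %d records retained\n",
              nrow(x$records),
              if (nrow(x$report)) x$report$input[1] else 0L))
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Estimate the week-37 anchor from a cohort
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of
#' birthweight among records whose reconciled gestational age equals the
#' anchor completed week (default 37), with the coefficient of variation as
#' a percentage. Feeding the result into [twin_standard()] anchors a
#' population-specific standard.
#'
#' @param records A filtered registry data.frame with `resolved_weeks` and
#'   `birthweight_g`.
#' @param completed_week Anchor stratum in completed weeks, default 37.
#' @return An object of class `anchor_estimate`: list with `mean_g`, `sd_g`,
#'   `n`, `cv_pct`, `completed_week` and a `degenerate` flag (`TRUE` when the
#'   stratum has zero spread, making the CV unusable).
#' @export
estimate_anchor <- function(records, completed_week = 37) {
  stopifnot(is.data.frame(records),
            all(c("resolved_weeks", "birthweight_g") %in% names(records)))
  w <- records$birthweight_g[!is.na(records$resolved_weeks) &
                               records$resolved_weeks == completed_week]
  w <- w[!is.na(w)]
  if (length(w) < 2L) {
    stop(sprintf(
      "insufficient stratum: %d record(s) at %d completed weeks (need at least 2)",
      length(w), completed_week
    ), call. = FALSE)
  }
  m <- mean(w)
  s <- stats::sd(w)
  degenerate <- s == 0
  if (degenerate) {
    warning(sprintf("degenerate anchor at %d weeks: zero birthweight spread",
                    completed_week), call. = FALSE)
  }
  structure(
    list(mean_g = m, sd_g = s, n = length(w), cv_pct = 100 * s / m,
         completed_week = completed_week, degenerate = degenerate),
    class = "anchor_estimate"
  )
}

#' @export
print.anchor_estimate <- function(x, ...) {
  cat(sprintf(
    "Anchor at %d completed weeks: mean %.0f g, SD %.0f g, CV %.1f%% (n = %d)%s\n",
    x$completed_week, x$mean_g, x$sd_g, x$cv_pct, x$n,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Week-37 anchors by race/ethnicity
#'
#' Per-race anchor estimates plus each race's share of the full cohort
#' (share is computed over all retained records, not just the anchor
#' stratum, matching how registry summary tables report group sizes).
#' Races with fewer than 2 records at the anchor week are reported with
#' `NA` anchor columns and a warning.
#'
#' @inheritParams estimate_anchor
#' @return A data.frame with columns `race`, `n`, `share_pct`, `n_week`,
#'   `mean_g`, `sd_g`, `cv_pct`, one row per race present in the data.
#' @export
anchor_by_race <- function(records, completed_week = 37) {
  stopifnot(is.data.frame(records), "race" %in% names(records))
  if (nrow(records) == 0L) stop("no records to anchor", call. = FALSE)
  races <- unique(records$race)
  canonical <- c("white", "black", "hispanic", "asian", "other")
  races <- c(intersect(canonical, races), setdiff(races, canonical))
  n_total <- nrow(records)
  out <- lapply(races, function(r) {
    sub <- records[records$race == r, , drop = FALSE]
    row <- data.frame(race = r, n = nrow(sub),
                      share_pct = 100 * nrow(sub) / n_total,
                      n_week = NA_integer_, mean_g = NA_real_,
                      sd_g = NA_real_, cv_pct = NA_real_)
    est <- tryCatch(estimate_anchor(sub, completed_week), error = function(e) NULL)
    if (is.null(est)) {
      warning(sprintf("race '%s': fewer than 2 records at %d completed weeks; anchor omitted",
                      r, completed_week), call. = FALSE)
    } else {
      row$n_week <- est$n; row$mean_g <- est$mean_g
      row$sd_g <- est$sd_g; row$cv_pct <- est$cv_pct
    }
    row
  })
  do.call(rbind, out)
}

#' Write race anchors as CSV
#'
#' Columns `race,n,share_pct,mean_g,sd_g,cv_pct`; percentages to one
#' decimal, grams to one decimal.
#'
#' @param anchors Output of [anchor_by_race()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_anchors <- function(anchors, path) {
  out <- anchors[, c("race", "n", "share_pct", "mean_g", "sd_g", "cv_pct")]
  out$share_pct <- round(out$share_pct, 1)
  out$cv_pct <- round(out$cv_pct, 1)
  out$mean_g <- round(out$mean_g, 1)
  out$sd_g <- round(out$sd_g, 1)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
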