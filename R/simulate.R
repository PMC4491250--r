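#' Synthetic twin-registry configuration
#'
#' Parameters of the synthetic twin-birth registry generator. The generator
#' embodies the distributional assumptions behind the adjustable standard:
#' per-race birthweights normal around the race's adjusted median with a
#' constant coefficient of variation, a categorical true gestational-age
#' distribution over completed weeks, LMP dating errors producing LMP/CE
#' discordance, and independent per-criterion violation of the low-risk
#' filters.
#'
#' The gestational-age error model is symmetric: with probability
#' `ga_error` the LMP week is offset from the (true) clinical estimate by
#' a signed offset of 1 to `max_offset` weeks whose magnitude has
#' geometric-decay mass `error_decay^(k-1)`. Only offsets beyond 2 weeks
#' trigger a replacement under the LMP/CE rule, so the expected replaced
#' fraction is `ga_error * P(|offset| > 2)`.
#'
#' @param n Number of twin births (rows) to generate.
#' @param race_mix Named probabilities per race, summing to 1. Default:
#'   the bundled US 1995-2004 cohort shares (white 70.9%, black 16.8%,
#'   hispanic 7.8%, asian 2.5%, other 2.0%).
#' @param anchors Named list `race -> c(mean_g, sd_g)` of week-37 anchors.
#'   Default: the bundled race anchors; `other` defaults to the share-
#'   weighted average of the four named groups (the published table reports
#'   no anchor for it).
#' @param ga_distribution Named probabilities over completed weeks (names
#'   are weeks). Default: a left-skewed twin distribution over 24-40 weeks
#'   peaking at 37.
#' @param ga_error Probability that LMP misreports, default 0.2.
#' @param error_decay Geometric decay of the offset-magnitude mass, default 0.5.
#' @param max_offset Largest LMP offset in weeks, default 6.
#' @param noncompliance Named per-criterion violation probabilities for
#'   `maternal_age`, `education`, `smoking`, `hypertensive_disorder`,
#'   `diabetes`, `prenatal_care`.
#' @param seed Integer seed; generation refuses to run without one.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n = 1000, seed = 42)
#' reg <- simulate_registry(cfg)
#' @export
sim_config <- function(n,
                       race_mix = c(white = 0.709, black = 0.168,
                                    hispanic = 0.078, asian = 0.025,
                                    other = 0.020),
                       anchors = NULL,
                       ga_distribution = c(
                         `24` = 0.004, `25` = 0.004, `26` = 0.005,
                         `27` = 0.006, `28` = 0.008, `29` = 0.010,
                         `30` = 0.015, `31` = 0.020, `32` = 0.030,
                         `33` = 0.050, `34` = 0.080, `35` = 0.120,
                         `36` = 0.170, `37` = 0.200, `38` = 0.170,
                         `39` = 0.080, `40` = 0.028),
                       ga_error = 0.2,
                       error_decay = 0.5,
                       max_offset = 6,
                       noncompliance = c(maternal_age = 0.25,
                                         education = 0.15,
                                         smoking = 0.10,
                                         hypertensive_disorder = 0.08,
                                         diabetes = 0.05,
                                         prenatal_care = 0.15),
                       seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != trunc(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  race_mix <- unlist(race_mix)
  if (is.null(names(race_mix)) || any(!nzchar(names(race_mix)))) {
    stop("`race_mix` must be named by race", call. = FALSE)
  }
  if (any(race_mix < 0 | race_mix > 1) || abs(sum(race_mix) - 1) > 1e-9) {
    stop("`race_mix` probabilities must lie in [0, 1] and sum to 1", call. = FALSE)
  }
  if (is.null(anchors)) {
    d <- race_anchors()
    anchors <- stats::setNames(
      lapply(seq_len(nrow(d)), function(i) c(mean_g = d$mean_g[i], sd_g = d$sd_g[i])),
      d$race)
    w <- d$share_pct / sum(d$share_pct)
    anchors$other <- round(c(mean_g = sum(w * d$mean_g), sd_g = sum(w * d$sd_g)), 1)
  }
  missing_anchor <- setdiff(names(race_mix)[race_mix > 0], names(anchors))
  if (length(missing_anchor)) {
    stop("no anchor supplied for race(s): ",
         paste(missing_anchor, collapse = ", "), call. = FALSE)
  }
  for (a in anchors) {
    if (length(a) != 2L || any(a <= 0) || a[2] / a[1] >= 0.5) {
      stop("each anchor must be c(mean_g, sd_g) with 0 < sd/mean < 0.5",
           call. = FALSE)
    }
  }
  ga_distribution <- unlist(ga_distribution)
  wk <- suppressWarnings(as.numeric(names(ga_distribution)))
  if (anyNA(wk) || any(wk != trunc(wk)) || any(ga_distribution < 0) ||
      sum(ga_distribution) <= 0) {
    stop("`ga_distribution` must be non-negative mass named by completed week",
         call. = FALSE)
  }
  ga_distribution <- ga_distribution / sum(ga_distribution)
  probs <- c(ga_error = ga_error, error_decay = error_decay,
             unlist(noncompliance))
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  needed <- c("maternal_age", "education", "smoking",
              "hypertensive_disorder", "diabetes", "prenatal_care")
  if (!all(needed %in% names(noncompliance))) {
    stop("`noncompliance` must name all of: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed) &&
      (!is.numeric(seed) || length(seed) != 1L || seed != trunc(seed))) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), race_mix = race_mix, anchors = anchors,
         ga_distribution = ga_distribution, ga_error = ga_error,
         error_decay = error_decay, max_offset = as.integer(max_offset),
         noncompliance = unlist(noncompliance),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config"
  )
}

#' Expected LMP replacement fraction under a configuration
#'
#' `ga_error` times the probability that a drawn offset magnitude exceeds
#' 2 weeks (the LMP/CE substitution threshold).
#'
#' @param config A [sim_config()].
#' @return A probability.
#' @export
expected_replaced_fraction <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- seq_len(config$max_offset)
  mass <- config$error_decay^(k - 1)
  config$ga_error * sum(mass[k > 2]) / sum(mass)
}

#' Generate a synthetic twin-birth registry
#'
#' Draws `config$n` twin births: race from `race_mix`; true gestational age
#' from `ga_distribution`; birthweight normal with mean equal to the race's
#' proportionality ratio times the Hadlock median at the week midpoint and
#' SD equal to the race CV times that mean, truncated below at 250 g; the
#' clinical estimate equals the true completed week while the LMP estimate
#' carries a dating error with probability `ga_error`; risk covariates
#' violate each low-risk criterion independently with the configured
#' probabilities. Fully reproducible for a fixed seed.
#'
#' @param config A [sim_config()] with a non-`NULL` seed.
#' @return A registry data.frame with the [registry_columns()].
#' @export
simulate_registry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$seed)) {
    stop("stochastic generation requires an explicit seed in `sim_config()`",
         call. = FALSE)
  }
  set.seed(config$seed, kind = "Mersenne-Twister")
  n <- config$n
  race <- sample(names(config$race_mix), n, replace = TRUE,
                 prob = config$race_mix)
  weeks_avail <- as.integer(names(config$ga_distribution))
  true_week <- weeks_avail[sample.int(length(weeks_avail), n, replace = TRUE,
                                      prob = config$ga_distribution)]
  ref <- hadlock_constants()$anchor_weight_g
  amean <- vapply(config$anchors, `[[`, numeric(1), 1L)
  asd <- vapply(config$anchors, `[[`, numeric(1), 2L)
  ratio <- amean[race] / ref
  cv <- (asd / amean)[race]
  mu <- ratio * .hadlock_eval(true_week + 0.5)
  bw <- stats::rnorm(n, mu, cv * mu)
  # truncate at the plausibility floor by redrawing (keeps the normal shape)
  while (any(low <- bw < 250)) {
    bw[low] <- stats::rnorm(sum(low), mu[low], (cv * mu)[low])
  }
  ce <- true_week
  has_err <- stats::runif(n) < config$ga_error
  k <- seq_len(config$max_offset)
  mag <- sample(k, n, replace = TRUE, prob = config$error_decay^(k - 1))
  offset <- ifelse(has_err, mag * sample(c(-1L, 1L), n, replace = TRUE), 0L)
  lmp <- pmin(pmax(ce + offset, 0L), 47L)
  nc <- config$noncompliance
  viol <- function(p) stats::runif(n) < p
  v_age <- viol(nc[["maternal_age"]])
  maternal_age <- ifelse(v_age,
                         sample(c(16:19, 36:45), n, replace = TRUE),
                         sample(20:35, n, replace = TRUE))
  education <- ifelse(viol(nc[["education"]]), "lt_highschool", "highschool_plus")
  smoker <- viol(nc[["smoking"]])
  htn <- viol(nc[["hypertensive_disorder"]])
  dm <- viol(nc[["diabetes"]])
  pnc <- ifelse(viol(nc[["prenatal_care"]]),
                sample(c("later", "none"), n, replace = TRUE), "first")
  sex <- sample(c("male", "female"), n, replace = TRUE)
  data.frame(
    id = sprintf("tw%07d", seq_len(n)),
    lmp_weeks = as.integer(lmp),
    ce_weeks = as.integer(ce),
    birthweight_g = round(bw),
    maternal_age_y = as.integer(maternal_age),
    education = education,
    smoker = smoker,
    hypertensive_disorder = htn,
    diabetes = dm,
    prenatal_care_trimester = pnc,
    race = race,
    sex = sex,
    stringsAsFactors = FALSE
  )
}

#' Ground-truth manifest of a simulation
#'
#' Serialises the generating parameters (anchors, race mix, gestational-age
#' distribution, error model, filter-violation rates, seed) together with
#' the implied expected replaced fraction, for use as ground truth in
#' parameter-recovery checks. [read_truth_manifest()] reconstructs the
#' [sim_config()] exactly.
#'
#' @param config A [sim_config()].
#' @param path Optional output file; when given, the JSON is written there.
#' @return JSON text (class `json`), invisibly when `path` is given.
#' @export
truth_manifest <- function(config, path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  payload <- list(
    n = config$n,
    race_mix = as.list(config$race_mix),
    anchors = lapply(config$anchors, function(a)
      list(mean_g = unname(a[[1]]), sd_g = unname(a[[2]]))),
    ga_distribution = as.list(config$ga_distribution),
    ga_error = config$ga_error,
    error_decay = config$error_decay,
    max_offset = config$max_offset,
    noncompliance = as.list(config$noncompliance),
    seed = config$seed,
    expected_replaced_fraction = expected_replaced_fraction(config)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @rdname truth_manifest
#' @param x JSON text or a file path produced by [truth_manifest()].
#' @export
read_truth_manifest <- function(x) {
  src <- if (length(x) == 1L && file.exists(x)) x else paste(x, collapse = "\n")
  m <- jsonlite::fromJSON(src)
  sim_config(
    n = m$n,
    race_mix = unlist(m$race_mix),
    anchors = lapply(m$anchors, function(a) c(mean_g = a$mean_g, sd_g = a$sd_g)),
    ga_distribution = unlist(m$ga_distribution),
    ga_error = m$ga_error,
    error_decay = m$error_decay,
    max_offset = m$max_offset,
    noncompliance = unlist(m$noncompliance),
    seed = m$seed
  )
}
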