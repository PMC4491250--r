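# A fully low-risk-compliant registry row; override fields to break criteria.
compliant_record <- function(id = "r1", lmp_weeks = 37, ce_weeks = 37,
                             birthweight_g = 2700, maternal_age_y = 28,
                             education = "highschool_plus", smoker = FALSE,
                             hypertensive_disorder = FALSE, diabetes = FALSE,
                             prenatal_care_trimester = "first",
                             race = "white", sex = "female") {
  data.frame(id = id, lmp_weeks = lmp_weeks, ce_weeks = ce_weeks,
             birthweight_g = birthweight_g, maternal_age_y = maternal_age_y,
             education = education, smoker = smoker,
             hypertensive_disorder = hypertensive_disorder,
             diabetes = diabetes,
             prenatal_care_trimester = prenatal_care_trimester,
             race = race, sex = sex, stringsAsFactors = FALSE)
}

compliant_registry <- function(n, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    compliant_record(id = sprintf("r%03d", i), ...)
  }))
}

# a single-population generator config with everything optional switched off
clean_config <- function(n, seed, mean_g = 2727, sd_g = 374, weeks = 24:38,
                         ga_error = 0, ...) {
  sim_config(
    n = n,
    race_mix = c(white = 1),
    anchors = list(white = c(mean_g = mean_g, sd_g = sd_g)),
    ga_distribution = stats::setNames(rep(1, length(weeks)), weeks),
    ga_error = ga_error,
    noncompliance = c(maternal_age = 0, education = 0, smoking = 0,
                      hypertensive_disorder = 0, diabetes = 0,
                      prenatal_care = 0),
    seed = seed, ...)
}
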