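#' Registry CSV columns
#'
#' Column layout of a twin-birth registry file, one twin per row. Blank
#' fields are missing values (registry convention).
#' @return Character vector of column names.
#' @export
registry_columns <- function() {
  c("id", "lmp_weeks", "ce_weeks", "birthweight_g", "maternal_age_y",
    "education", "smoker", "hypertensive_disorder", "diabetes",
    "prenatal_care_trimester", "race", "sex")
}

#' Read / write a twin-birth registry CSV
#'
#' @param path File path.
#' @param records A data.frame carrying at least the [registry_columns()]
#'   (extra columns such as `resolved_weeks`/`replaced` are preserved).
#' @return `read_registry()` returns a data.frame with typed columns
#'   (`smoker`, `hypertensive_disorder`, `diabetes` logical);
#'   `write_registry()` returns `path` invisibly.
#' @export
read_registry <- function(path) {
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  missing_cols <- setdiff(registry_columns(), names(df))
  if (length(missing_cols)) {
    stop("registry CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("smoker", "hypertensive_disorder", "diabetes", "replaced")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  for (col in c("lmp_weeks", "ce_weeks", "resolved_weeks")) {
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  }
  df
}

#' @rdname read_registry
#' @export
write_registry <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
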