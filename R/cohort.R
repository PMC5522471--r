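cohort_columns <- c("patient_id", "sex", "age_years", "topography",
                    "nodule_size_mm", "tirads", "bethesda",
                    "visual_pattern", "ri", "woind_percent", "histology")

cohort_domains <- list(
  sex = c("F", "M"),
  topography = c("LL", "RL", "I", "RL-I"),
  tirads = c("3", "4A", "4B"),
  bethesda = c("III", "IV"),
  histology = c("DTC", "BenignAdenoma", "ColloidGoitre")
)

#' Path of the packaged 20-patient cohort fixture
#' @return Path to the installed CSV.
#' @export
cohort_fixture_path <- function() {
  system.file("extdata", "table1_cohort.csv", package = "mibiquant",
              mustWork = TRUE)
}

#' Load a per-patient cohort table
#'
#' Reads the cohort CSV (demographics, nodule characteristics, both index
#' values, histology) with full schema validation: parsing is header-keyed,
#' every categorical column is checked against its value domain, and every
#' numeric column against its range. Any violation raises a schema error
#' naming the offending row and column. The histology column maps to the
#' binary truth used for evaluation: malignant if and only if `"DTC"`.
#'
#' Columns: `patient_id, sex, age_years, topography, nodule_size_mm,
#' tirads, bethesda, visual_pattern, ri, woind_percent, histology`.
#'
#' @param source Path to a CSV; defaults to the packaged 20-patient
#'   fixture.
#' @return A data frame, one row per patient, in file order.
#' @export
load_cohort_table <- function(source = cohort_fixture_path()) {
  if (!file.exists(source)) {
    stop(format_error(paste0("no such file: ", source), "mibiquant_io_error"))
  }
  raw <- utils::read.csv(source, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  missing <- setdiff(cohort_columns, names(raw))
  if (length(missing)) {
    stop(format_error(paste0("missing column(s): ",
                             paste(missing, collapse = ", ")),
                      "mibiquant_schema_error"))
  }
  raw <- raw[cohort_columns]  # header-keyed: column order is irrelevant

  num <- function(col, integer = FALSE, positive = FALSE) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | (integer & v != floor(v)) | (positive & v <= 0))
    if (length(bad)) {
      stop(format_error(sprintf("row %d, column '%s': unparsable value '%s'",
                                bad[1], col, raw[[col]][bad[1]]),
                        "mibiquant_schema_error"))
    }
    if (integer) as.integer(v) else v
  }
  cat_ <- function(col) {
    v <- raw[[col]]
    bad <- which(!v %in% cohort_domains[[col]])
    if (length(bad)) {
      stop(format_error(sprintf("row %d, column '%s': value '%s' not in {%s}",
                                bad[1], col, v[bad[1]],
                                paste(cohort_domains[[col]], collapse = ", ")),
                        "mibiquant_schema_error"))
    }
    v
  }
  out <- data.frame(
    patient_id = num("patient_id", integer = TRUE),
    sex = cat_("sex"),
    age_years = num("age_years", integer = TRUE, positive = TRUE),
    topography = cat_("topography"),
    nodule_size_mm = num("nodule_size_mm", integer = TRUE, positive = TRUE),
    tirads = cat_("tirads"),
    bethesda = cat_("bethesda"),
    visual_pattern = num("visual_pattern", integer = TRUE),
    ri = num("ri"),
    woind_percent = num("woind_percent"),
    histology = cat_("histology"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$patient_id)) {
    stop(format_error("duplicate patient_id", "mibiquant_schema_error"))
  }
  out
}

#' Cohort descriptive statistics
#'
#' @param records Cohort data frame.
#' @return List: `n`, `n_female`, `n_male`, `age_median`, `age_mean`,
#'   `age_range`, `n_malignant`, `malignant_percent`.
#' @export
cohort_descriptives <- function(records) {
  mal <- records$histology == "DTC"
  list(
    n = nrow(records),
    n_female = sum(records$sex == "F"),
    n_male = sum(records$sex == "M"),
    age_median = stats::median(records$age_years),
    age_mean = mean(records$age_years),
    age_range = range(records$age_years),
    n_malignant = sum(mal),
    malignant_percent = 100 * mean(mal)
  )
}
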