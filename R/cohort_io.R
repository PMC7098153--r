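# Delimited-text reader/writer for two-wave cohort files.

COHORT_COLUMNS <- c("id", "wave", "sex", "age", "grip_max", "bmi", "height",
                    "gait_speed", "weight", "prior_weight", "act_mild",
                    "act_moderate", "act_vigorous", "exh_effort",
                    "exh_get_going", "status")

#' Read a two-wave cohort CSV
#'
#' The file contract is one row per participant per wave with header columns
#' `id, wave, sex, age, grip_max, bmi, height, gait_speed, weight,
#' prior_weight, act_mild, act_moderate, act_vigorous, exh_effort,
#' exh_get_going, status`. Units: grip kg, BMI kg/m2, height cm, gait m/s,
#' weight kg; activity columns use the levels `never`, `monthly_1_3`,
#' `weekly_1`, `weekly_gt1`; exhaustion columns `yes`/`no`; `status` is
#' `assessed`, `dead` or `dropped_out`. Missing values are empty fields.
#' Units are taken as declared; no autodetection is attempted.
#'
#' @param path CSV file path.
#' @return A data frame with the columns above.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Write a scored cohort to CSV
#'
#' Serialises the output of [score_cohort()] (input columns plus the five
#' flags, score and category) with empty fields for missing values.
#'
#' @param scored Data frame from [score_cohort()].
#' @param path Output file path.
#' @export
write_scored_csv <- function(scored, path) {
  utils::write.csv(scored, path, row.names = FALSE, na = "")
  invisible(path)
}
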