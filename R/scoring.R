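# Phenotypic (Fried) frailty scoring on ELSA-style component measures.
# All component evaluators are vectorised and propagate NA as the
# "component could not be evaluated" signal; score_cohort() turns any NA
# component into the "unscorable" category (the completeness rule).

ACTIVITY_LEVELS <- c("never", "monthly_1_3", "weekly_1", "weekly_gt1")
FRAILTY_CATEGORIES <- c("robust", "prefrail", "frail", "unscorable")

sex_pick <- function(sex, male, female) {
  sex <- match.arg_vec(sex, c("male", "female"))
  ifelse(sex == "male", male, female)
}

match.arg_vec <- function(x, choices) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% choices)
  if (any(bad))
    stop(sprintf("invalid value(s): %s (expected one of %s)",
                 paste(unique(x[bad]), collapse = ", "),
                 paste(choices, collapse = ", ")))
  x
}

#' Grip strength adjusted for body mass index
#'
#' Adjusted grip = maximum grip − (BMI − centre) × slope, with sex-specific
#' centring constant and slope (defaults: 27.6 and 0.31 for men, 27.9 and
#' 0.07 for women). Missing grip or BMI yields `NA`, which scoring treats as
#' an unevaluable component.
#'
#' @param sex Character vector, `"male"` or `"female"`.
#' @param grip_max Maximum recorded grip strength (kg); where several
#'   attempts were recorded, reduce to the maximum before calling.
#' @param bmi Body mass index (kg/m2).
#' @param cfg A [default_thresholds()] configuration.
#' @return Adjusted grip strength (kg).
#' @export
#' @examples
#' adjust_grip("male", 30, 30.6)   # 29.07
adjust_grip <- function(sex, grip_max, bmi, cfg = default_thresholds()) {
  if (any(grip_max < 0, na.rm = TRUE)) stop("grip_max must be >= 0")
  if (any(bmi <= 0, na.rm = TRUE)) stop("bmi must be > 0")
  centre <- sex_pick(sex, cfg$grip_adj_coef$male[1], cfg$grip_adj_coef$female[1])
  slope <- sex_pick(sex, cfg$grip_adj_coef$male[2], cfg$grip_adj_coef$female[2])
  grip_max - (bmi - centre) * slope
}

#' Gait speed adjusted for height
#'
#' Adjusted gait = gait speed − (height − centre) × slope, with sex-specific
#' centring height and slope (defaults: 172 cm and 0.00941 for men, 158 cm
#' and 0.010 for women). Where two timed walks were recorded, the faster one
#' is used (reduce before calling).
#'
#' @inheritParams adjust_grip
#' @param gait_speed Gait speed over a 4 m course (m/s).
#' @param height Standing height (cm).
#' @return Adjusted gait speed (m/s).
#' @export
#' @examples
#' adjust_gait("male", 0.8, 182)   # 0.7059
adjust_gait <- function(sex, gait_speed, height, cfg = default_thresholds()) {
  if (any(gait_speed < 0, na.rm = TRUE)) stop("gait_speed must be >= 0")
  if (any(height <= 0, na.rm = TRUE)) stop("height must be > 0")
  centre <- sex_pick(sex, cfg$gait_adj_coef$male[1], cfg$gait_adj_coef$female[1])
  slope <- sex_pick(sex, cfg$gait_adj_coef$male[2], cfg$gait_adj_coef$female[2])
  gait_speed - (height - centre) * slope
}

#' MET-weighted physical activity index
#'
#' Self-reported frequencies of mild, moderate and vigorous activity are
#' weighted by 1.5, 3 and 6 METs respectively and by a frequency multiplier:
#' never ×0, 1--3 times per month ×2, once a week ×4, more than once a week
#' ×8. The index is the sum over the three intensities; any missing
#' frequency makes the index `NA`.
#'
#' @param mild,moderate,vigorous Character vectors with levels `"never"`,
#'   `"monthly_1_3"`, `"weekly_1"`, `"weekly_gt1"`.
#' @inheritParams adjust_grip
#' @return Activity index (activity units).
#' @export
#' @examples
#' activity_index("weekly_1", "monthly_1_3", "never")   # 12
activity_index <- function(mild, moderate, vigorous,
                           cfg = default_thresholds()) {
  mult <- function(x) {
    x <- match.arg_vec(x, ACTIVITY_LEVELS)
    unname(cfg$freq_multipliers[x])
  }
  w <- cfg$met_weights
  w[["mild"]] * mult(mild) + w[["moderate"]] * mult(moderate) +
    w[["vigorous"]] * mult(vigorous)
}

#' Weight-loss / low-BMI component
#'
#' Flagged when BMI < 18.5 kg/m2 or when weight fell by strictly more than
#' 10% since the prior wave. The dual criterion keeps the component
#' evaluable when the prior-wave weight is missing (BMI alone decides); it
#' is unevaluable (`NA`) only when neither criterion can be assessed.
#' A loss of exactly 10% is not flagged.
#'
#' @param bmi Current BMI (kg/m2); may be `NA`.
#' @param weight Current weight (kg).
#' @param prior_weight Prior-wave weight (kg); may be `NA`.
#' @inheritParams adjust_grip
#' @return Logical vector (`NA` = unevaluable).
#' @export
weight_loss_flag <- function(bmi, weight, prior_weight,
                             cfg = default_thresholds()) {
  if (any(bmi <= 0, na.rm = TRUE)) stop("bmi must be > 0")
  n <- max(length(bmi), length(weight), length(prior_weight))
  bmi <- rep_len(bmi, n); weight <- rep_len(weight, n)
  prior_weight <- rep_len(prior_weight, n)
  loss_eval <- !is.na(prior_weight) & !is.na(weight)
  loss <- ifelse(loss_eval, (prior_weight - weight) / prior_weight, NA)
  low_bmi <- bmi < cfg$bmi_low_cut                 # NA where bmi missing
  big_loss <- loss > cfg$weight_loss_frac          # NA where loss unevaluable
  out <- rep(NA, n)
  out <- ifelse(!is.na(low_bmi) & low_bmi, TRUE, out)
  out <- ifelse(!is.na(big_loss) & big_loss, TRUE, out)
  # evaluable as FALSE when every assessable criterion is negative
  neg <- (!is.na(low_bmi) & !low_bmi & (!loss_eval | (!is.na(big_loss) & !big_loss))) |
    (is.na(low_bmi) & !is.na(big_loss) & !big_loss)
  out <- ifelse(is.na(out) & neg, FALSE, out)
  as.logical(out)
}

#' Self-reported exhaustion component
#'
#' Flagged when either CES-D item ("everything I did was an effort", "I
#' could not get going") is answered yes. A positive answer dominates
#' missingness; a negative requires both answers, so one missing answer with
#' the other "no" is unevaluable.
#'
#' @param effort,get_going Character vectors `"yes"`/`"no"` (or `NA`).
#' @return Logical vector (`NA` = unevaluable).
#' @export
exhaustion_flag <- function(effort, get_going) {
  effort <- match.arg_vec(effort, c("yes", "no"))
  get_going <- match.arg_vec(get_going, c("yes", "no"))
  n <- max(length(effort), length(get_going))
  effort <- rep_len(effort, n); get_going <- rep_len(get_going, n)
  any_yes <- (!is.na(effort) & effort == "yes") |
    (!is.na(get_going) & get_going == "yes")
  both_no <- !is.na(effort) & !is.na(get_going) &
    effort == "no" & get_going == "no"
  ifelse(any_yes, TRUE, ifelse(both_no, FALSE, NA))
}

#' Derive sex-specific quintile thresholds from a baseline cohort
#'
#' Recomputes the "lowest fifth" cut points for adjusted grip strength,
#' adjusted gait speed and the activity index as the empirical 20th
#' percentile of the sex-specific distributions (inverse empirical CDF /
#' order-statistic convention, `stats::quantile` type 1). All other fields
#' keep their values from `base`. Scoring flags values strictly below the
#' cut, so ties at the cut are not flagged.
#'
#' @param cohort A cohort data frame in the format documented at
#'   [read_cohort_csv()] (one wave; typically the baseline wave).
#' @param base Configuration supplying the non-derived constants.
#' @param min_per_stratum Minimum number of evaluable values required per
#'   sex per component (default 25); fewer is an error naming the stratum.
#' @return A `threshold_config` with re-derived grip/gait/activity cuts.
#' @export
derive_thresholds <- function(cohort, base = default_thresholds(),
                              min_per_stratum = 25) {
  grip <- adjust_grip(cohort$sex, cohort$grip_max, cohort$bmi, base)
  gait <- adjust_gait(cohort$sex, cohort$gait_speed, cohort$height, base)
  act <- activity_index(cohort$act_mild, cohort$act_moderate,
                        cohort$act_vigorous, base)
  cut20 <- function(x, sex, component, which_sex) {
    v <- x[!is.na(x) & !is.na(sex) & sex == which_sex]
    if (length(v) < min_per_stratum)
      stop(sprintf(
        "insufficient data to derive the %s threshold for stratum '%s': %d evaluable values (need >= %d)",
        component, which_sex, length(v), min_per_stratum))
    unname(stats::quantile(v, 0.2, type = 1, names = FALSE))
  }
  cfg <- base
  cfg$grip_cut_male <- cut20(grip, cohort$sex, "grip", "male")
  cfg$grip_cut_female <- cut20(grip, cohort$sex, "grip", "female")
  cfg$gait_cut_male <- cut20(gait, cohort$sex, "gait", "male")
  cfg$gait_cut_female <- cut20(gait, cohort$sex, "gait", "female")
  cfg$activity_cut_male <- cut20(act, cohort$sex, "activity", "male")
  cfg$activity_cut_female <- cut20(act, cohort$sex, "activity", "female")
  cfg
}

#' Score a cohort on the five-component frailty phenotype
#'
#' Evaluates the five deficit flags (weight loss, exhaustion, low grip, low
#' gait speed, low activity) for every row, sums them into the 0--5 score
#' and maps the score to a category: 0 = robust, 1--2 = prefrail, 3--5 =
#' frail. A participant with any unevaluable component is `unscorable` and
#' carries no score (the completeness rule). Low grip, gait and activity use
#' strict `<` against the sex-specific cuts in `cfg`.
#'
#' @param cohort Data frame in the [read_cohort_csv()] format (a single wave).
#' @param cfg A `threshold_config`; use [derive_thresholds()] for
#'   cohort-derived quintile cuts or [default_thresholds()] for the
#'   published ELSA wave-2 values.
#' @return `cohort` with columns added: `flag_weight_loss`,
#'   `flag_exhaustion`, `flag_low_grip`, `flag_low_gait`,
#'   `flag_low_activity`, `score` (integer, `NA` when unscorable) and
#'   `category` (factor robust/prefrail/frail/unscorable).
#' @export
score_cohort <- function(cohort, cfg = default_thresholds()) {
  grip_adj <- adjust_grip(cohort$sex, cohort$grip_max, cohort$bmi, cfg)
  gait_adj <- adjust_gait(cohort$sex, cohort$gait_speed, cohort$height, cfg)
  act <- activity_index(cohort$act_mild, cohort$act_moderate,
                        cohort$act_vigorous, cfg)
  grip_cut <- sex_pick(cohort$sex, cfg$grip_cut_male, cfg$grip_cut_female)
  gait_cut <- sex_pick(cohort$sex, cfg$gait_cut_male, cfg$gait_cut_female)
  act_cut <- sex_pick(cohort$sex, cfg$activity_cut_male, cfg$activity_cut_female)

  out <- cohort
  out$flag_weight_loss <- weight_loss_flag(cohort$bmi, cohort$weight,
                                           cohort$prior_weight, cfg)
  out$flag_exhaustion <- exhaustion_flag(cohort$exh_effort, cohort$exh_get_going)
  out$flag_low_grip <- grip_adj < grip_cut
  out$flag_low_gait <- gait_adj < gait_cut
  out$flag_low_activity <- act < act_cut

  flags <- cbind(out$flag_weight_loss, out$flag_exhaustion, out$flag_low_grip,
                 out$flag_low_gait, out$flag_low_activity)
  scorable <- rowSums(is.na(flags)) == 0
  score <- ifelse(scorable, rowSums(flags), NA_integer_)
  category <- rep("unscorable", nrow(flags))
  category[scorable & score == 0] <- "robust"
  category[scorable & score >= 1 & score <= 2] <- "prefrail"
  category[scorable & score >= 3] <- "frail"
  out$score <- as.integer(score)
  out$category <- factor(category, levels = FRAILTY_CATEGORIES)
  out
}

#' Score a single participant record
#'
#' Convenience wrapper around [score_cohort()] for one record.
#'
#' @param rec A one-row data frame or named list with the cohort columns.
#' @inheritParams score_cohort
#' @return A list with elements `flags` (named logical vector of the five
#'   components), `score` (integer or `NA`) and `category` (character).
#' @export
score_participant <- function(rec, cfg = default_thresholds()) {
  df <- as.data.frame(lapply(rec, function(x) if (is.null(x)) NA else x),
                      stringsAsFactors = FALSE)
  scored <- score_cohort(df, cfg)
  list(
    flags = c(weight_loss = scored$flag_weight_loss,
              exhaustion = scored$flag_exhaustion,
              low_grip = scored$flag_low_grip,
              low_gait = scored$flag_low_gait,
              low_activity = scored$flag_low_activity),
    score = scored$score,
    category = as.character(scored$category)
  )
}
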