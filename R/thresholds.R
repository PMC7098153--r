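#' Threshold configuration for phenotypic frailty scoring
#'
#' Bundles every constant needed to evaluate the five Fried frailty
#' components on ELSA-style measurements: the sex-specific covariate
#' adjustment coefficients for grip strength and gait speed, the MET weights
#' and frequency multipliers of the physical-activity index, the low-BMI and
#' weight-loss criteria, and the sex-specific "lowest fifth" cut points for
#' adjusted grip, adjusted gait speed and activity.
#'
#' The default cut points are the published ELSA wave-2 values: grip
#' < 31.12 kg (men) / < 17.60 kg (women); gait speed < 0.691 m/s (men) /
#' < 0.619 m/s (women); activity < 16.5 units (men) / < 13.5 units (women);
#' BMI < 18.5 kg/m2 or > 10% weight loss since the prior wave. For a new
#' cohort the quintile cuts can be re-derived with [derive_thresholds()].
#'
#' @param grip_cut_male,grip_cut_female Low-grip cut points (kg), applied as
#'   strict `<` to BMI-adjusted grip.
#' @param gait_cut_male,gait_cut_female Low-gait cut points (m/s), applied as
#'   strict `<` to height-adjusted gait speed.
#' @param activity_cut_male,activity_cut_female Low-activity cut points
#'   (activity units, MET-weighted frequency score).
#' @param bmi_low_cut Low-BMI criterion for the weight-loss component (kg/m2).
#' @param weight_loss_frac Proportional weight loss since the prior wave that
#'   triggers the weight-loss component (strict `>`).
#' @param grip_adj_coef Named list `male`/`female`, each `c(centre, slope)`:
#'   adjusted grip = grip − (BMI − centre) × slope.
#' @param gait_adj_coef Named list `male`/`female`, each `c(centre, slope)`:
#'   adjusted gait = gait − (height − centre) × slope.
#' @param met_weights MET weights for (mild, moderate, vigorous) activity.
#' @param freq_multipliers Named numeric vector mapping reported frequency
#'   categories (`never`, `monthly_1_3`, `weekly_1`, `weekly_gt1`) to
#'   multipliers.
#' @return An object of class `threshold_config` (a named list).
#' @export
#' @examples
#' cfg <- default_thresholds()
#' cfg$grip_cut_male
default_thresholds <- function(grip_cut_male = 31.12,
                               grip_cut_female = 17.60,
                               gait_cut_male = 0.691,
                               gait_cut_female = 0.619,
                               activity_cut_male = 16.5,
                               activity_cut_female = 13.5,
                               bmi_low_cut = 18.5,
                               weight_loss_frac = 0.10,
                               grip_adj_coef = list(male = c(27.6, 0.31),
                                                    female = c(27.9, 0.07)),
                               gait_adj_coef = list(male = c(172, 0.00941),
                                                    female = c(158, 0.010)),
                               met_weights = c(mild = 1.5, moderate = 3,
                                               vigorous = 6),
                               freq_multipliers = c(never = 0, monthly_1_3 = 2,
                                                    weekly_1 = 4,
                                                    weekly_gt1 = 8)) {
  cuts <- c(grip_cut_male, grip_cut_female, gait_cut_male, gait_cut_female,
            activity_cut_male, activity_cut_female, bmi_low_cut)
  if (any(!is.finite(cuts)) || any(cuts <= 0))
    stop("all threshold cut values must be positive and finite")
  if (!is.finite(weight_loss_frac) || weight_loss_frac <= 0 ||
      weight_loss_frac >= 1)
    stop("weight_loss_frac must lie in (0, 1)")
  structure(list(
    grip_cut_male = grip_cut_male, grip_cut_female = grip_cut_female,
    gait_cut_male = gait_cut_male, gait_cut_female = gait_cut_female,
    activity_cut_male = activity_cut_male,
    activity_cut_female = activity_cut_female,
    bmi_low_cut = bmi_low_cut, weight_loss_frac = weight_loss_frac,
    grip_adj_coef = grip_adj_coef, gait_adj_coef = gait_adj_coef,
    met_weights = met_weights, freq_multipliers = freq_multipliers
  ), class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("Frailty scoring thresholds\n")
  cat(sprintf("  low grip (kg):      M < %.4g, F < %.4g\n",
              x$grip_cut_male, x$grip_cut_female))
  cat(sprintf("  low gait (m/s):     M < %.4g, F < %.4g\n",
              x$gait_cut_male, x$gait_cut_female))
  cat(sprintf("  low activity:       M < %.4g, F < %.4g units\n",
              x$activity_cut_male, x$activity_cut_female))
  cat(sprintf("  weight loss:        BMI < %.3g or > %.0f%% loss\n",
              x$bmi_low_cut, 100 * x$weight_loss_frac))
  invisible(x)
}

#' Read or write a threshold configuration as YAML
#'
#' A round-trippable plain-text serialisation of a [default_thresholds()]
#' object, so that cohort-derived cut points can be pinned and reused (the
#' published ELSA thresholds are shipped in
#' `system.file("extdata", "thresholds_elsa_wave2.yaml", package =
#' "frailtrans")`).
#'
#' @param path File path.
#' @return `read_threshold_config()` returns a `threshold_config`.
#' @export
read_threshold_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$grip_adj_coef <- lapply(raw$grip_adj_coef, as.numeric)
  raw$gait_adj_coef <- lapply(raw$gait_adj_coef, as.numeric)
  raw$met_weights <- unlist(raw$met_weights)
  raw$freq_multipliers <- unlist(raw$freq_multipliers)
  do.call(default_thresholds, raw)
}

#' @param cfg A `threshold_config`.
#' @rdname read_threshold_config
#' @export
write_threshold_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "threshold_config"))
  out <- unclass(cfg)
  # named atomic vectors must be serialised as maps to keep their names
  out$met_weights <- as.list(out$met_weights)
  out$freq_multipliers <- as.list(out$freq_multipliers)
  yaml::write_yaml(out, path)
  invisible(path)
}
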