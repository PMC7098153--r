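test_that("grip and gait covariate adjustments match the published formulas", {
  # hand-computed from the adjustment definitions
  expect_equal(adjust_grip("male", 30, 27.6), 30)
  expect_equal(adjust_grip("male", 30, 30.6), 30 - 3 * 0.31)
  expect_equal(adjust_grip("female", 20, 25.9), 20 + 2 * 0.07)
  expect_equal(adjust_gait("male", 0.8, 172), 0.8)
  expect_equal(adjust_gait("male", 0.8, 182), 0.8 - 10 * 0.00941)
  expect_equal(adjust_gait("female", 0.6, 148), 0.6 + 10 * 0.010)
  # missing inputs propagate as component-unevaluable
  expect_true(is.na(adjust_grip("male", NA, 25)))
  expect_true(is.na(adjust_gait("female", 0.8, NA)))
  expect_error(adjust_grip("male", -1, 25), "grip_max")
  expect_error(adjust_gait("male", 0.8, -170), "height")
})

test_that("adjustments are affine in the measured value", {
  set.seed(1)
  for (i in 1:20) {
    g <- runif(1, 10, 50); bmi <- runif(1, 18, 40); d <- runif(1, -5, 5)
    expect_equal(adjust_grip("female", g + d, bmi) -
                   adjust_grip("female", g, bmi), d)
    v <- runif(1, 0.3, 1.5); h <- runif(1, 150, 190)
    expect_equal(adjust_gait("male", v + d / 100, h) -
                   adjust_gait("male", v, h), d / 100)
  }
})

test_that("activity index applies MET weights and frequency multipliers", {
  expect_equal(activity_index("never", "never", "never"), 0)
  expect_equal(activity_index("weekly_gt1", "weekly_gt1", "weekly_gt1"),
               1.5 * 8 + 3 * 8 + 6 * 8)
  expect_equal(activity_index("weekly_1", "monthly_1_3", "never"), 12)
  expect_true(is.na(activity_index("weekly_1", NA, "never")))
  expect_error(activity_index("sometimes", "never", "never"), "invalid")
})

test_that("weight-loss component uses the dual BMI / 10% loss criterion", {
  expect_true(weight_loss_flag(17.0, 50, 50))           # low BMI alone
  expect_false(weight_loss_flag(24.0, 63, 70))          # exactly 10%: not flagged
  expect_true(weight_loss_flag(24.0, 62.9, 70))         # > 10% loss
  expect_false(weight_loss_flag(24.0, 69, NA))          # BMI-only path
  expect_true(is.na(weight_loss_flag(NA, 69, NA)))      # nothing assessable
  expect_true(weight_loss_flag(NA, 60, 70))             # loss path with BMI missing
})

test_that("exhaustion needs one yes, or both answers for a negative", {
  expect_true(exhaustion_flag("yes", "no"))
  expect_false(exhaustion_flag("no", "no"))
  expect_true(exhaustion_flag("yes", NA))               # positive dominates
  expect_true(is.na(exhaustion_flag(NA, "no")))         # negative needs both
  expect_true(is.na(exhaustion_flag(NA, NA)))
})

test_that("scoring maps deficit counts to categories with the completeness rule", {
  cfg <- default_thresholds()
  favourable <- score_participant(participant(), cfg)
  expect_equal(favourable$score, 0L)
  expect_equal(favourable$category, "robust")
  expect_true(!any(favourable$flags))

  three <- score_participant(
    participant(grip_max = 20, exh_effort = "yes",
                act_mild = "never", act_moderate = "never",
                act_vigorous = "never"), cfg)
  expect_equal(three$score, 3L)
  expect_equal(three$category, "frail")

  one <- score_participant(participant(exh_get_going = "yes"), cfg)
  expect_equal(one$category, "prefrail")

  # any missing component -> unscorable, no score, regardless of other flags
  for (rec in list(participant(gait_speed = NA),
                   participant(grip_max = NA, exh_effort = "yes"),
                   participant(act_mild = NA),
                   participant(exh_effort = NA, exh_get_going = "no"),
                   participant(bmi = NA, prior_weight = NA))) {
    res <- score_participant(rec, cfg)
    expect_equal(res$category, "unscorable")
    expect_true(is.na(res$score))
  }
})

test_that("scoring a cohort twice is bit-identical", {
  spec <- cohort_spec(n = 500, seed = 42)
  cohort <- generate_cohort(spec)
  s1 <- score_cohort(cohort)
  s2 <- score_cohort(cohort)
  expect_identical(s1, s2)
})

test_that("derived thresholds are the sex-specific 20th percentile", {
  # identical values: cut equals the common value, strict < flags nobody
  same <- do.call(cohort_of, lapply(1:30, function(i)
    participant(id = paste0("m", i), grip_max = 33, bmi = 27.6)))
  same_f <- do.call(cohort_of, lapply(1:30, function(i)
    participant(id = paste0("f", i), sex = "female", grip_max = 20,
                bmi = 27.9, height = 158)))
  cfg <- derive_thresholds(rbind(same, same_f))
  expect_equal(cfg$grip_cut_male, 33)
  scored <- score_cohort(same, cfg)
  expect_false(any(scored$flag_low_grip))

  # 1..100: type-1 quantile agrees with a sort-and-count oracle
  grips <- sample(1:100)
  hundred <- do.call(cohort_of, lapply(1:100, function(i)
    participant(id = paste0("m", i), grip_max = grips[i], bmi = 27.6)))
  cfg2 <- derive_thresholds(rbind(hundred, same_f))
  oracle <- sort(grips)[ceiling(0.2 * 100)]
  expect_equal(cfg2$grip_cut_male, oracle)

  # insufficient stratum names the component and sex
  expect_error(derive_thresholds(same), "female")
})

test_that("quintile derivation flags close to 20% per sex per component", {
  spec <- cohort_spec(n = 6000, seed = 9)
  cohort <- generate_cohort(spec)
  baseline <- cohort[cohort$wave == 1, ]
  cfg <- derive_thresholds(baseline)
  scored <- score_cohort(baseline, cfg)
  for (sx in c("male", "female")) {
    stratum <- scored[scored$sex == sx, ]
    n_s <- nrow(stratum)
    for (flag in c("flag_low_grip", "flag_low_gait", "flag_low_activity")) {
      frac <- mean(stratum[[flag]], na.rm = TRUE)
      expect_lte(frac, 0.20 + 1 / n_s)
      # lower bound allows tie mass at the cut (activity is discrete)
      expect_gte(frac, if (flag == "flag_low_activity") 0.10 else 0.15)
    }
  }
  # construction percentiles recovered within simulation tolerance
  expect_lt(abs(cfg$grip_cut_male - 31.12), 0.5)
  expect_lt(abs(cfg$gait_cut_female - 0.619), 0.02)
})

test_that("cohort CSV round-trips through the reader and scored writer", {
  spec <- cohort_spec(n = 50, seed = 5)
  cohort <- generate_cohort(spec)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(cohort[, setdiff(names(cohort), "true_category")], path,
                   row.names = FALSE, na = "")
  back <- read_cohort_csv(path)
  expect_equal(nrow(back), nrow(cohort))
  scored <- score_cohort(back[back$wave == 1, ])
  out <- tempfile(fileext = ".csv")
  write_scored_csv(scored, out)
  expect_true(all(c("score", "category", "flag_low_grip") %in%
                    names(utils::read.csv(out))))
  expect_error(read_cohort_csv(tempfile()), "not found")
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(id = 1), bad, row.names = FALSE)
  expect_error(read_cohort_csv(bad), "required column")
})

test_that("threshold configs round-trip through YAML", {
  cfg <- default_thresholds(grip_cut_male = 30.5)
  path <- tempfile(fileext = ".yaml")
  write_threshold_config(cfg, path)
  back <- read_threshold_config(path)
  expect_equal(back, cfg)
  expect_error(default_thresholds(weight_loss_frac = 1.2), "weight_loss_frac")
  expect_error(default_thresholds(bmi_low_cut = -1), "positive")
})
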