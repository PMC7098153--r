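test_that("design spec carries the standard normal quantiles", {
  d <- design_spec()
  expect_lt(abs(d$z_alpha - 1.959964), 1e-5)
  expect_lt(abs(d$z_beta - 1.281552), 1e-5)
  expect_error(design_spec(alpha = 0), "alpha")
  expect_error(design_spec(power = 1), "power")
})

test_that("two-proportion sample size matches hand evaluation and is symmetric", {
  expect_equal(n_two_proportions(0.113, rrr = 0.5), 509L)
  # symmetry in the two arms
  expect_equal(n_two_proportions(0.3, p_treat = 0.2),
               n_two_proportions(0.2, p_treat = 0.3))
  expect_error(n_two_proportions(0.5, p_treat = 0.5), "undefined effect")
  expect_error(n_two_proportions(0.5), "rrr or p_treat")
  expect_error(n_two_proportions(1.1, rrr = 0.2), "p_control")
})

test_that("RRR maps to a proportional-odds effect with consistent arms", {
  eff <- rrr_to_ordinal(c(0.159, 0.494, 0.347), 0.2)
  expect_equal(round(eff$theta, 4), 1.3828)
  expect_equal(eff$treat[[3]], 0.347 * 0.8)
  expect_equal(sum(eff$treat), 1, tolerance = 1e-12)

  # rrr 0 is the null: theta 1, arms identical
  null <- rrr_to_ordinal(c(0.2, 0.5, 0.3), 0)
  expect_equal(null$theta, 1)
  expect_equal(unname(null$treat), c(0.2, 0.5, 0.3))

  set.seed(8)
  for (i in 1:20) {
    p <- rexp(3); p <- p / sum(p)
    eff <- rrr_to_ordinal(p, runif(1, 0.05, 0.8))
    expect_equal(sum(eff$treat), 1, tolerance = 1e-12)
    expect_true(all(eff$treat > 0))
    expect_gt(eff$theta, 1)
  }
  expect_error(rrr_to_ordinal(c(0, 0.5, 0.5), 0.2), "degenerate")
  expect_error(rrr_to_ordinal(c(0.2, 0.3, 0.4), 0.2), "sum to 1")
})

test_that("ordinal sample size is monotone and near the binary form when collapsed", {
  d <- design_spec()
  # decreasing in |log theta| at fixed category mix
  pbar <- c(0.2, 0.5, 0.3)
  ns <- vapply(c(1.2, 1.5, 2, 3),
               function(th) n_whitehead_ordinal(list(theta = th, pbar = pbar),
                                                d), integer(1))
  expect_true(all(diff(ns) < 0))
  expect_error(n_whitehead_ordinal(list(theta = 1, pbar = pbar)),
               "undefined effect")

  # two-category collapse approximates the two-proportion calculator
  for (p1 in c(0.1, 0.2, 0.3, 0.4, 0.5)) {
    p2 <- p1 * 0.7
    theta <- (p1 / (1 - p1)) / (p2 / (1 - p2))
    pbar <- (p1 + p2) / 2
    n_ord <- n_whitehead_ordinal(
      list(theta = theta, pbar = c(1 - pbar, pbar)), d)
    n_bin <- n_two_proportions(p1, p_treat = p2, design = d)
    expect_lt(abs(n_ord - n_bin) / n_bin, 0.15)
  }
})

test_that("continuous calculator reproduces the published walk-speed and SPPB cells", {
  # the published table's four distinct (MCID, SD) patterns
  expect_equal(n_continuous(0.05, 0.25), 526L)
  expect_equal(n_continuous(0.05, 0.25, rho = 0.5), 395L)
  expect_equal(n_continuous(0.10, 0.25), 132L)
  expect_equal(n_continuous(0.10, 0.25, rho = 0.5), 99L)
  expect_equal(n_continuous(0.5, 2.5), 526L)
  expect_equal(n_continuous(1.0, 2.5, rho = 0.5), 99L)
  # rho = 0 leaves the unadjusted size unchanged
  expect_equal(n_continuous(0.3, 1.2, rho = 0), n_continuous(0.3, 1.2))
  expect_error(n_continuous(0, 1), "mcid")
  expect_error(n_continuous(1, -1), "sd")
  expect_error(n_continuous(1, 1, rho = 1), "rho")
})

test_that("all calculators respond to alpha, power, and effect size correctly", {
  strict <- design_spec(alpha = 0.01)
  strong <- design_spec(power = 0.95)
  base <- design_spec()
  expect_gt(n_two_proportions(0.3, rrr = 0.3, design = strict),
            n_two_proportions(0.3, rrr = 0.3, design = base))
  expect_gt(n_two_proportions(0.3, rrr = 0.3, design = strong),
            n_two_proportions(0.3, rrr = 0.3, design = base))
  expect_gt(n_continuous(0.3, 1.2, design = strict), n_continuous(0.3, 1.2))
  eff <- rrr_to_ordinal(c(0.2, 0.5, 0.3), 0.3)
  expect_gt(n_whitehead_ordinal(eff, strict), n_whitehead_ordinal(eff, base))
  # ~ 1/effect^2 scaling in the small-effect limit
  n_small <- n_two_proportions(0.3, rrr = 0.005)
  n_half <- n_two_proportions(0.3, rrr = 0.01)
  expect_lt(abs(n_small / n_half - 4), 0.1)
})

test_that("design tables preserve the ordinal <= composite <= simple ordering", {
  row <- c(robust = 0.159, prefrail = 0.494, frail = 0.113,
           dead_or_too_ill = 0.234)
  tabs <- build_design_tables(row)
  tr <- tabs$transitions
  expect_true(all(tr$n_ordinal <= tr$n_composite))
  expect_true(all(tr$n_composite <= tr$n_frail_only))
  # every column strictly decreasing over the increasing RRR grid
  for (col in c("n_frail_only", "n_composite", "n_ordinal"))
    expect_true(all(diff(tr[[col]]) < 0))
  expect_equal(nrow(tabs$continuous), 5)
  expect_equal(tabs$continuous$n_unadjusted[2], 526L)
  expect_error(build_design_tables(c(a = 1)), "entries")
})

test_that("empirical power validates the calculators at their returned n", {
  set.seed(1234)
  n <- n_two_proportions(0.347, rrr = 0.3)
  sim <- simulate_power_two_proportions(n, 0.347, 0.347 * 0.7, nsim = 4000)
  expect_gte(sim$power, 0.90 - 2 * sim$mc_se)

  eff <- rrr_to_ordinal(c(0.159, 0.494, 0.347), 0.2)
  n_ord <- n_whitehead_ordinal(eff)
  sim_ord <- simulate_power_ordinal(n_ord, eff$control, eff$treat,
                                    nsim = 4000)
  expect_gte(sim_ord$power, 0.87)
  expect_lte(sim_ord$power, 0.93)
})
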