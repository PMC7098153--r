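# Monte-Carlo power validation of the sample-size calculators. Both
# simulators are fully vectorised across replicates so 10,000-trial
# validations run in well under a second. Neither sets a seed: callers
# control reproducibility with set.seed().

#' Empirical power of the two-proportion test by simulation
#'
#' Simulates two-arm binomial trials of `n` per group and applies the
#' two-sided pooled-variance z-test (the test whose approximation underlies
#' [n_two_proportions()]).
#'
#' @param n Per-group sample size.
#' @param p_control,p_treat Arm event probabilities.
#' @param alpha Two-sided significance level.
#' @param nsim Number of simulated trials.
#' @return A list with `power` (rejection proportion), `mc_se` (Monte-Carlo
#'   standard error) and `nsim`.
#' @export
simulate_power_two_proportions <- function(n, p_control, p_treat,
                                           alpha = 0.05, nsim = 10000) {
  x1 <- stats::rbinom(nsim, n, p_control)
  x2 <- stats::rbinom(nsim, n, p_treat)
  p1 <- x1 / n; p2 <- x2 / n
  pp <- (x1 + x2) / (2 * n)
  se <- sqrt(pp * (1 - pp) * 2 / n)
  z <- ifelse(se > 0, (p1 - p2) / se, 0)
  crit <- stats::qnorm(1 - alpha / 2)
  pw <- mean(abs(z) > crit)
  list(power = pw, mc_se = sqrt(pw * (1 - pw) / nsim), nsim = nsim)
}

#' Empirical power of the ordinal (proportional-odds score) test
#'
#' Simulates two-arm trials with three-category ordinal outcomes drawn from
#' the control and treated distributions and applies the two-sided
#' Wilcoxon-Mann-Whitney test with tie-corrected normal approximation --
#' asymptotically the score test of the proportional-odds model, and the
#' test underlying Whitehead's sample-size formula
#' ([n_whitehead_ordinal()]). The U statistic and its null variance are
#' computed in closed form from the per-arm category counts, so the whole
#' simulation is vectorised.
#'
#' @param n Per-group sample size.
#' @param control_probs,treat_probs Length-3 category probability vectors
#'   (best to worst).
#' @param alpha Two-sided significance level.
#' @param nsim Number of simulated trials.
#' @return As [simulate_power_two_proportions()].
#' @export
simulate_power_ordinal <- function(n, control_probs, treat_probs,
                                   alpha = 0.05, nsim = 10000) {
  stopifnot(length(control_probs) == 3, length(treat_probs) == 3)
  a <- stats::rmultinom(nsim, n, control_probs)   # 3 x nsim, control counts
  b <- stats::rmultinom(nsim, n, treat_probs)
  # Mann-Whitney U for grouped data: pairs where control ranks below treated
  # count 1, ties 1/2 (ordering direction is immaterial two-sided).
  U <- a[1, ] * (b[2, ] + b[3, ]) + a[2, ] * b[3, ] +
    0.5 * (a[1, ] * b[1, ] + a[2, ] * b[2, ] + a[3, ] * b[3, ])
  N <- 2 * n
  mu <- n * n / 2
  t_j <- a + b                                    # combined ties per category
  tie_term <- colSums(t_j^3 - t_j) / (N * (N - 1))
  v <- n * n / 12 * ((N + 1) - tie_term)
  z <- ifelse(v > 0, (U - mu) / sqrt(v), 0)
  crit <- stats::qnorm(1 - alpha / 2)
  pw <- mean(abs(z) > crit)
  list(power = pw, mc_se = sqrt(pw * (1 - pw) / nsim), nsim = nsim)
}
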