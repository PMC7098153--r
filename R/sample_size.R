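# Sample-size calculators for frailty prevention trial outcomes: simple and
# composite binary transitions (pooled-variance normal approximation),
# three-category ordinal analysis under proportional odds (Whitehead's
# method), and continuous comparator measures with optional baseline
# (ANCOVA) adjustment. All designs are two-arm, 1:1 allocation.

#' Trial design parameters
#'
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power 1 - beta (default 0.90).
#' @return A `design_spec` list with `alpha`, `power` and the corresponding
#'   normal quantiles `z_alpha` (= qnorm(1 - alpha/2)) and `z_beta`
#'   (= qnorm(power)).
#' @export
design_spec <- function(alpha = 0.05, power = 0.90) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (!(power > 0 && power < 1)) stop("power must lie in (0, 1)")
  structure(list(alpha = alpha, power = power,
                 z_alpha = stats::qnorm(1 - alpha / 2),
                 z_beta = stats::qnorm(power)),
            class = "design_spec")
}

check_prob <- function(p, name) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop(name, " must lie strictly in (0, 1)")
  p
}

#' Per-group sample size for comparing two proportions
#'
#' Pooled-variance normal approximation for a two-sided two-sample test of
#' proportions:
#' n = ceil[ (z_{1-a/2} sqrt(2 pbar qbar) + z_{1-b} sqrt(p1 q1 + p2 q2))^2
#'           / (p1 - p2)^2 ]
#' with pbar the mean of the two proportions. Specify the treated arm either
#' directly (`p_treat`) or as a relative risk reduction (`rrr`, so
#' p_treat = p_control (1 - rrr)).
#'
#' @param p_control Control-arm event probability.
#' @param rrr Relative risk reduction in (0, 1); ignored when `p_treat`
#'   given.
#' @param p_treat Treated-arm event probability.
#' @param design A [design_spec()].
#' @return Integer per-group sample size.
#' @export
#' @examples
#' n_two_proportions(0.113, rrr = 0.5)   # 509
n_two_proportions <- function(p_control, rrr = NULL, p_treat = NULL,
                              design = design_spec()) {
  check_prob(p_control, "p_control")
  if (is.null(p_treat)) {
    if (is.null(rrr)) stop("supply either rrr or p_treat")
    if (!(rrr > 0 && rrr < 1)) stop("rrr must lie in (0, 1)")
    p_treat <- p_control * (1 - rrr)
  }
  check_prob(p_treat, "p_treat")
  if (p_control == p_treat)
    stop("undefined effect: p_control equals p_treat")
  pbar <- (p_control + p_treat) / 2
  num <- design$z_alpha * sqrt(2 * pbar * (1 - pbar)) +
    design$z_beta * sqrt(p_control * (1 - p_control) +
                           p_treat * (1 - p_treat))
  as.integer(ceiling((num / (p_control - p_treat))^2))
}

#' Map a relative risk reduction onto a proportional-odds ordinal effect
#'
#' Converts a relative risk reduction on the worst category of a
#' three-category outcome (robust < prefrail < frail/dead/too-ill) into a
#' cumulative odds ratio. The treated worst-category probability is
#' p3 (1 - rrr); theta is the ratio of control to treated odds of the worst
#' category, and the same theta is applied to the second cumulative split
#' (prefrail-or-worse) under proportional odds to derive the full treated
#' distribution. theta > 1 encodes benefit.
#'
#' @param control_probs Numeric length-3 probability vector (best to worst
#'   category), summing to 1.
#' @param rrr Relative risk reduction on the worst category, in [0, 1).
#' @return An `ordinal_effect` list: `theta`, `control`, `treat`, and `pbar`
#'   (per-category means of the two arms).
#' @export
#' @examples
#' rrr_to_ordinal(c(0.159, 0.494, 0.347), 0.2)$theta   # 1.3829
rrr_to_ordinal <- function(control_probs, rrr) {
  if (length(control_probs) != 3)
    stop("control_probs must have exactly 3 categories")
  if (any(control_probs <= 0))
    stop("degenerate ordinal outcome: every control category needs probability > 0")
  if (abs(sum(control_probs) - 1) > 1e-12)
    stop("control_probs must sum to 1")
  if (!(rrr >= 0 && rrr < 1)) stop("rrr must lie in [0, 1)")
  p3 <- control_probs[3]
  p3_t <- p3 * (1 - rrr)
  odds <- function(p) p / (1 - p)
  theta <- odds(p3) / odds(p3_t)
  q2 <- control_probs[2] + control_probs[3]     # P(prefrail or worse), control
  o2_t <- odds(q2) / theta
  q2_t <- o2_t / (1 + o2_t)
  treat <- c(1 - q2_t, q2_t - p3_t, p3_t)
  names(treat) <- names(control_probs)
  stopifnot(abs(sum(treat) - 1) < 1e-12)
  structure(list(theta = theta, control = control_probs, treat = treat,
                 pbar = (control_probs + treat) / 2),
            class = "ordinal_effect")
}

#' Per-group sample size for an ordinal outcome (Whitehead's method)
#'
#' Whitehead's closed form for ordered categorical outcomes under the
#' proportional-odds model gives, for 1:1 allocation, the per-group size
#' n = ceil[ 6 (z_{1-a/2} + z_{1-b})^2 / ( (log theta)^2 (1 - sum_k pbar_k^3) ) ],
#' where pbar_k are the category probabilities averaged over the two arms.
#' (Equivalently: the Mann-Whitney/proportional-odds score test needs about
#' z^2 (1 - sum pbar^3) / (6 shift^2) participants per group; the
#' [simulate_power_ordinal()] validator confirms the per-group reading.)
#'
#' @param effect An `ordinal_effect` from [rrr_to_ordinal()], or a list with
#'   `theta` and `pbar`.
#' @param design A [design_spec()].
#' @return Integer per-group sample size.
#' @export
n_whitehead_ordinal <- function(effect, design = design_spec()) {
  theta <- effect$theta
  pbar <- effect$pbar
  if (theta == 1) stop("undefined effect: theta = 1 (no treatment effect)")
  n <- 6 * (design$z_alpha + design$z_beta)^2 /
    ((log(theta))^2 * (1 - sum(pbar^3)))
  as.integer(ceiling(n))
}

#' Per-group sample size for a continuous outcome
#'
#' Standard normal-approximation formula for a two-arm comparison of means:
#' n = ceil[ 2 (z_{1-a/2} + z_{1-b})^2 (sd / mcid)^2 ], multiplied by
#' (1 - rho^2) when the analysis adjusts for the baseline value of the
#' outcome (ANCOVA) with baseline/follow-up correlation rho.
#'
#' @param mcid Minimum clinically important difference (outcome units).
#' @param sd Outcome standard deviation at follow-up (same units).
#' @param rho Baseline/follow-up correlation in [0, 1) for the
#'   baseline-adjusted analysis; `NULL` for the unadjusted analysis.
#' @param design A [design_spec()].
#' @return Integer per-group sample size.
#' @export
#' @examples
#' n_continuous(0.05, 0.25)              # 526 (4 m walk speed, unadjusted)
#' n_continuous(1.0, 2.5, rho = 0.5)     # 99  (SPPB, adjusted)
n_continuous <- function(mcid, sd, rho = NULL, design = design_spec()) {
  if (!(mcid > 0)) stop("mcid must be > 0")
  if (!(sd > 0)) stop("sd must be > 0")
  n <- 2 * (design$z_alpha + design$z_beta)^2 * (sd / mcid)^2
  if (!is.null(rho)) {
    if (!(rho >= 0 && rho < 1)) stop("rho must lie in [0, 1)")
    n <- n * (1 - rho^2)
  }
  as.integer(ceiling(n))
}

#' Comparative sample-size tables for a frailty prevention trial
#'
#' Builds the two design tables: per-group sample sizes over a grid of
#' relative risk reductions for (i) the simple transition to frail, (ii) the
#' composite transition to frail/dead/too-ill, and (iii) the three-category
#' ordinal analysis (robust vs prefrail vs composite), all driven by one
#' interpolated transition-probability row for prefrail baseline; and the
#' continuous-comparator table (unadjusted and baseline-adjusted).
#'
#' The composite control probability is the sum of the frail and
#' dead/too-ill entries of `transition_row`.
#'
#' @param transition_row Named 4-state probability vector for the prefrail
#'   baseline at the trial horizon (e.g.
#'   `extract_row(matrix_root(P, 2), "prefrail")` for a two-year trial),
#'   with entries `robust`, `prefrail`, `frail`, `dead_or_too_ill`.
#' @param rrr_grid Relative risk reductions (default `c(0.20, 0.25, 0.30,
#'   0.40, 0.50)`).
#' @param continuous_specs Data frame with columns `measure`, `mcid`, `sd`
#'   for the continuous comparators (default: Fried score as a continuous
#'   measure, 4 m walk speed at two MCIDs, SPPB at two MCIDs).
#' @param rho Baseline/follow-up correlation for the adjusted continuous
#'   analysis (default 0.5).
#' @param design A [design_spec()].
#' @return List of data frames `transitions` (columns `rrr`, `n_frail_only`,
#'   `n_composite`, `n_ordinal`, per group) and `continuous` (columns
#'   `measure`, `mcid`, `sd`, `n_unadjusted`, `n_adjusted`, per group).
#' @export
build_design_tables <- function(transition_row,
                                rrr_grid = c(0.20, 0.25, 0.30, 0.40, 0.50),
                                continuous_specs = default_continuous_specs(),
                                rho = 0.5,
                                design = design_spec()) {
  needed <- c("robust", "prefrail", "frail", "dead_or_too_ill")
  if (!all(needed %in% names(transition_row)))
    stop("transition_row needs entries ", paste(needed, collapse = ", "))
  p_frail <- transition_row[["frail"]]
  p_comp <- transition_row[["frail"]] + transition_row[["dead_or_too_ill"]]
  ctrl3 <- c(robust = transition_row[["robust"]],
             prefrail = transition_row[["prefrail"]],
             composite = p_comp)
  ctrl3 <- ctrl3 / sum(ctrl3)
  transitions <- data.frame(
    rrr = rrr_grid,
    n_frail_only = vapply(rrr_grid, function(r)
      n_two_proportions(p_frail, rrr = r, design = design), integer(1)),
    n_composite = vapply(rrr_grid, function(r)
      n_two_proportions(p_comp, rrr = r, design = design), integer(1)),
    n_ordinal = vapply(rrr_grid, function(r)
      n_whitehead_ordinal(rrr_to_ordinal(ctrl3, r), design), integer(1))
  )
  continuous <- continuous_specs
  continuous$n_unadjusted <- mapply(n_continuous, continuous$mcid,
                                    continuous$sd,
                                    MoreArgs = list(design = design))
  continuous$n_adjusted <- mapply(n_continuous, continuous$mcid,
                                  continuous$sd,
                                  MoreArgs = list(rho = rho, design = design))
  list(transitions = transitions, continuous = continuous)
}

#' Default continuous comparator measures
#'
#' The standard comparator set: the Fried score treated as a continuous
#' variable (MCID 0.3 points, SD 1.2), the 4 m walk speed (MCID 0.05 and
#' 0.10 m/s, SD 0.25) and the SPPB (MCID 0.5 and 1.0 points, SD 2.5).
#'
#' @return Data frame with columns `measure`, `mcid`, `sd`.
#' @export
default_continuous_specs <- function() {
  data.frame(
    measure = c("Fried frailty score", "4 m walk speed", "4 m walk speed",
                "SPPB", "SPPB"),
    mcid = c(0.3, 0.05, 0.10, 0.5, 1.0),
    sd = c(1.2, 0.25, 0.25, 2.5, 2.5),
    stringsAsFactors = FALSE
  )
}
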