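# Multi-state transition estimation over the frailty state space
# {robust, prefrail, frail, dead, dropped_out}, with the three dropout
# attribution scenarios.

LIVE_STATES <- c("robust", "prefrail", "frail")
FOLLOWUP_STATES <- c("robust", "prefrail", "frail", "dead", "dropped_out")

#' Count four-year transitions between frailty states
#'
#' Tabulates paired baseline/follow-up outcomes into a 3 x 5 count matrix
#' (rows: baseline robust/prefrail/frail; columns: follow-up robust,
#' prefrail, frail, dead, dropped_out). Participants alive and not withdrawn
#' but unscorable at follow-up belong in `dropped_out` (they could not
#' complete all tests); apply that recoding before calling, or use
#' [pair_waves()]. A recorded death takes precedence over non-assessment.
#'
#' @param baseline Character/factor vector of baseline categories
#'   (`robust`, `prefrail`, `frail`).
#' @param followup Character/factor vector of follow-up outcomes
#'   (`robust`, `prefrail`, `frail`, `dead`, `dropped_out`).
#' @return A `transition_counts` object: an integer matrix with a
#'   `row_totals` attribute.
#' @export
#' @examples
#' count_transitions(c("frail"), c("dead"))
count_transitions <- function(baseline, followup) {
  baseline <- as.character(baseline); followup <- as.character(followup)
  if (length(baseline) != length(followup))
    stop("baseline and followup must have equal length")
  bad_b <- setdiff(unique(baseline), LIVE_STATES)
  if (length(bad_b) > 0)
    stop("unknown baseline state(s): ", paste(bad_b, collapse = ", "))
  bad_f <- setdiff(unique(followup), FOLLOWUP_STATES)
  if (length(bad_f) > 0)
    stop("unknown follow-up state(s): ", paste(bad_f, collapse = ", "))
  tab <- table(factor(baseline, levels = LIVE_STATES),
               factor(followup, levels = FOLLOWUP_STATES))
  counts <- matrix(as.numeric(tab), nrow = 3,
                   dimnames = list(LIVE_STATES, FOLLOWUP_STATES))
  new_transition_counts(counts)
}

new_transition_counts <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  structure(counts, row_totals = rowSums(counts),
            class = c("transition_counts", "matrix"))
}

#' Pair baseline and follow-up waves of a scored cohort
#'
#' Joins the two waves of a scored long-format cohort on `id` and derives
#' the follow-up outcome: `dead` when the follow-up status records death
#' (death takes precedence over non-assessment), otherwise `dropped_out`
#' when the participant withdrew or was assessed but unscorable, otherwise
#' the follow-up frailty category. Participants unscorable at baseline are
#' excluded (they could not be categorised for enrolment).
#'
#' @param scored Long data frame from [score_cohort()] covering both waves,
#'   with a `wave` column.
#' @param baseline_wave,followup_wave Values of `wave` identifying the waves.
#' @return Data frame with columns `id`, `baseline`, `followup`.
#' @export
pair_waves <- function(scored, baseline_wave = 1, followup_wave = 2) {
  b <- scored[scored$wave == baseline_wave, c("id", "category")]
  f <- scored[scored$wave == followup_wave,
              c("id", "category", "status")]
  names(b)[2] <- "baseline"
  m <- merge(b, f, by = "id", all.x = TRUE)
  m <- m[m$baseline %in% LIVE_STATES, ]
  status <- ifelse(is.na(m$status), "dropped_out", m$status)
  outcome <- ifelse(status == "dead", "dead",
             ifelse(status == "dropped_out", "dropped_out",
             ifelse(is.na(m$category) | m$category == "unscorable",
                    "dropped_out", as.character(m$category))))
  data.frame(id = m$id, baseline = as.character(m$baseline),
             followup = outcome, stringsAsFactors = FALSE)
}

#' Dropout-attribution scenario
#'
#' The panel data cannot distinguish dropout due to illness from dropout for
#' other reasons, so three assumptions are entertained: `all_ill` (every
#' dropout was too ill to continue; dropout merges into the dead/too-ill
#' state, giving a 4-state space), `none_ill` (dropout is a separate
#' absorbing state; 5 states) and `half_ill` (half of each row's dropout
#' count is reattributed to dead/too-ill; 5 states, non-integer cells).
#'
#' @param variant `"all_ill"`, `"none_ill"` or `"half_ill"`.
#' @return A `dropout_scenario` list with `variant` and `ill_fraction`
#'   (1, 0 or 0.5).
#' @export
dropout_scenario <- function(variant = c("all_ill", "none_ill", "half_ill")) {
  variant <- match.arg(variant)
  frac <- c(all_ill = 1, none_ill = 0, half_ill = 0.5)[[variant]]
  structure(list(variant = variant, ill_fraction = frac),
            class = "dropout_scenario")
}

#' Build the square transition probability matrix under a dropout scenario
#'
#' Reattributes `ill_fraction` of each row's dropout count to the
#' dead/too-ill state (`all_ill` merges the two columns into one 4-state
#' space; `half_ill` splits the count 50/50 deterministically),
#' row-normalises the live rows, and appends exact unit-vector rows for the
#' absorbing states so the matrix is square and row-stochastic.
#'
#' `digits` optionally rounds the live-row probabilities to a fixed number
#' of decimals (renormalising afterwards) before the matrix is returned.
#' This matters only for reproducing published interpolations: the original
#' ELSA analysis interpolated from transition probabilities at their
#' two-decimal reporting precision, so `digits = 2` reproduces the published
#' one- and two-year tables while the default `NULL` keeps full precision.
#'
#' @param counts A `transition_counts` matrix (3 live rows x 5 outcome
#'   columns), or any non-negative 3 x 5 matrix with those dimnames.
#' @param scenario A [dropout_scenario()] or its variant name.
#' @param digits Optional rounding (decimal places) of the live-row
#'   probabilities before renormalisation; `NULL` = full precision.
#' @return A `transition_matrix`: square row-stochastic matrix (4 x 4 for
#'   `all_ill`, 5 x 5 otherwise) with attributes `scenario` and `counts`.
#' @export
#' @examples
#' P <- apply_scenario(elsa_transition_counts(), "all_ill")
#' P["prefrail", ]
apply_scenario <- function(counts, scenario = "all_ill", digits = NULL) {
  if (is.character(scenario)) scenario <- dropout_scenario(scenario)
  stopifnot(inherits(scenario, "dropout_scenario"))
  counts <- unclass(counts)
  if (!all(FOLLOWUP_STATES %in% colnames(counts)))
    stop("counts must have columns ", paste(FOLLOWUP_STATES, collapse = ", "))
  counts <- counts[LIVE_STATES, FOLLOWUP_STATES]
  zero_rows <- rownames(counts)[rowSums(counts) == 0]
  if (length(zero_rows) > 0)
    stop("zero row total for baseline state(s): ",
         paste(zero_rows, collapse = ", "))

  moved <- scenario$ill_fraction * counts[, "dropped_out"]
  adj <- counts
  adj[, "dead"] <- adj[, "dead"] + moved
  adj[, "dropped_out"] <- adj[, "dropped_out"] - moved
  if (scenario$variant == "all_ill") {
    adj <- adj[, c("robust", "prefrail", "frail", "dead")]
    colnames(adj)[4] <- "dead_or_too_ill"
  } else if (scenario$variant == "half_ill") {
    colnames(adj)[4] <- "dead_or_too_ill"
  }
  probs <- adj / rowSums(adj)
  if (!is.null(digits)) {
    probs <- round(probs, digits)
    probs <- probs / rowSums(probs)
  }
  states <- colnames(probs)
  n_abs <- length(states) - length(LIVE_STATES)
  absorbing <- diag(length(states))[(length(LIVE_STATES) + 1):length(states), ,
                                    drop = FALSE]
  P <- rbind(probs, absorbing)
  rownames(P) <- states
  stopifnot(max(abs(rowSums(P) - 1)) < 1e-12)
  structure(P, scenario = scenario, counts = counts, digits = digits,
            class = c("transition_matrix", "matrix"))
}

#' @export
print.transition_matrix <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("Transition probability matrix (%s scenario, ill fraction %.2f)\n",
              sc$variant, sc$ill_fraction))
  print(round(unclass(x)[, , drop = FALSE], 4))
  invisible(x)
}

#' Published ELSA wave-2 to wave-4 transition counts
#'
#' Loads the packaged 3 x 5 count matrix of four-year frailty-state
#' transitions among the 4650 ELSA participants with a complete baseline
#' frailty score (rows: baseline robust/prefrail/frail; columns: follow-up
#' robust, prefrail, frail, dead, dropped out). This printed table is the
#' anchor input for the transition and interpolation pipeline.
#'
#' @return A `transition_counts` matrix.
#' @export
elsa_transition_counts <- function() {
  path <- system.file("extdata", "elsa_wave2_wave4_counts.csv",
                      package = "frailtrans")
  read_transition_counts(path)
}

#' Read a transition count table from CSV
#'
#' Expects a `state` column naming the baseline live states and the five
#' follow-up outcome columns.
#'
#' @param path CSV file path.
#' @return A `transition_counts` matrix.
#' @export
read_transition_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, FOLLOWUP_STATES])
  rownames(m) <- df$state
  new_transition_counts(m[LIVE_STATES, ])
}

#' Write a transition probability matrix to CSV with scenario metadata
#'
#' The scenario and any input rounding are recorded as `#`-prefixed header
#' comment lines; probabilities are written at full precision.
#'
#' @param P A `transition_matrix`.
#' @param path Output file path.
#' @export
write_transition_matrix <- function(P, path) {
  sc <- attr(P, "scenario")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scenario: %s (ill fraction %g)", sc$variant,
                     sc$ill_fraction), con)
  dg <- attr(P, "digits")
  writeLines(sprintf("# input rounding: %s",
                     if (is.null(dg)) "none (full precision)" else
                       sprintf("%d decimal places", dg)), con)
  df <- data.frame(state = rownames(P), unclass(P), check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
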