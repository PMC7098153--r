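test_that("transition counting tabulates pairs and rejects unknown labels", {
  expect_equal(sum(count_transitions(character(0), character(0))), 0)
  one <- count_transitions("frail", "dead")
  expect_equal(one["frail", "dead"], 1)
  expect_equal(sum(one), 1)
  expect_error(count_transitions("moribund", "dead"), "moribund")
  expect_error(count_transitions("frail", "cured"), "cured")
  expect_error(count_transitions(c("frail", "robust"), "dead"), "length")
})

test_that("the packaged count fixture matches the published table", {
  counts <- elsa_transition_counts()
  expect_equal(unname(counts["prefrail", ]), c(335, 546, 189, 178, 659))
  expect_equal(unname(attr(counts, "row_totals")),
               c(2226, 1907, 517))
  expect_equal(sum(counts), 4650)
})

test_that("scenario application reproduces the published prefrail probabilities", {
  counts <- elsa_transition_counts()
  all_ill <- apply_scenario(counts, "all_ill")
  # full-precision row: 335/1907 etc., dead/too-ill = (178+659)/1907
  expect_equal(unname(all_ill["prefrail", ]),
               c(335, 546, 189, 178 + 659) / 1907, tolerance = 1e-12)
  expect_equal(round(all_ill["prefrail", "dead_or_too_ill"], 3), 0.439)
  half <- apply_scenario(counts, "half_ill")
  expect_equal(half["prefrail", "dead_or_too_ill"], (178 + 659 / 2) / 1907,
               tolerance = 1e-12)
  expect_equal(round(half["prefrail", "dead_or_too_ill"], 3), 0.266)
  # square form with exact absorbing unit rows
  expect_equal(dim(all_ill), c(4, 4))
  expect_equal(unname(unclass(all_ill)[4, ]), c(0, 0, 0, 1))
  none <- apply_scenario(counts, "none_ill")
  expect_equal(dim(none), c(5, 5))
  expect_equal(max(abs(rowSums(none) - 1)), 0)
})

test_that("scenarios conserve probability mass and leave live columns alone", {
  set.seed(4)
  for (i in 1:10) {
    counts <- matrix(rpois(15, 200) + 1, 3,
                     dimnames = list(c("robust", "prefrail", "frail"),
                                     c("robust", "prefrail", "frail", "dead",
                                       "dropped_out")))
    counts <- frailtrans:::new_transition_counts(counts)
    p_all <- apply_scenario(counts, "all_ill")
    p_none <- apply_scenario(counts, "none_ill")
    p_half <- apply_scenario(counts, "half_ill")
    live <- c("robust", "prefrail", "frail")
    # live columns identical across scenarios
    expect_equal(unclass(p_all)[live, live], unclass(p_none)[live, live])
    expect_equal(unclass(p_half)[live, live], unclass(p_none)[live, live])
    # summed absorbing mass identical (conservation)
    expect_equal(unname(unclass(p_all)[live, "dead_or_too_ill"]),
                 unname(unclass(p_none)[live, "dead"] +
                          unclass(p_none)[live, "dropped_out"]))
    # probabilities invariant to uniform row scaling
    bare <- function(m) matrix(unclass(m), nrow(m), dimnames = dimnames(m))
    scaled <- frailtrans:::new_transition_counts(unclass(counts) * 7.5)
    expect_equal(bare(apply_scenario(scaled, "half_ill")), bare(p_half),
                 tolerance = 1e-12)
  }
})

test_that("degenerate inputs are rejected with the offending state named", {
  counts <- unclass(elsa_transition_counts())
  counts["frail", ] <- 0
  expect_error(apply_scenario(frailtrans:::new_transition_counts(counts)),
               "frail")
  expect_error(apply_scenario(counts[, 1:4]), "columns")
})

test_that("reporting-precision rounding matches the published arithmetic", {
  counts <- elsa_transition_counts()
  p2 <- apply_scenario(counts, "all_ill", digits = 2)
  # merged dead/too-ill proportions round to whole percent before renormalising
  expect_equal(unname(unclass(p2)["prefrail", ] *
                        sum(round(c(335, 546, 189, 837) / 1907, 2))),
               round(c(335, 546, 189, 837) / 1907, 2))
  expect_equal(max(abs(rowSums(p2) - 1)), 0)
})

test_that("transition matrices round-trip through the CSV writer", {
  P <- apply_scenario(elsa_transition_counts(), "half_ill")
  path <- tempfile(fileext = ".csv")
  write_transition_matrix(P, path)
  lines <- readLines(path)
  expect_match(lines[1], "half_ill")
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(as.matrix(back[, -1]), unclass(P), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("wave pairing applies death precedence and the dropout residual rule", {
  scored <- data.frame(
    id = rep(c("a", "b", "c", "d"), each = 2),
    wave = rep(1:2, 4),
    category = factor(c("prefrail", "frail",        # a: real transition
                        "prefrail", "unscorable",   # b: assessed, incomplete
                        "frail", "unscorable",      # c: died
                        "unscorable", "robust"),    # d: unscorable baseline
                      levels = c("robust", "prefrail", "frail", "unscorable")),
    status = c("assessed", "assessed", "assessed", "assessed",
               "assessed", "dead", "assessed", "assessed"),
    stringsAsFactors = FALSE)
  pairs <- pair_waves(scored)
  expect_equal(nrow(pairs), 3)  # d excluded
  expect_equal(pairs$followup[pairs$id == "a"], "frail")
  expect_equal(pairs$followup[pairs$id == "b"], "dropped_out")
  expect_equal(pairs$followup[pairs$id == "c"], "dead")
})
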