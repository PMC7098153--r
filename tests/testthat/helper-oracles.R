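# Independent oracles and small data builders shared across tests.

# Denman-Beavers iteration: an eigendecomposition-free matrix square root
# (valid for matrices with no eigenvalues on the closed negative real axis).
# k = 4 roots are obtained by applying it twice.
db_sqrt <- function(A, iter = 60) {
  Y <- A
  Z <- diag(nrow(A))
  for (i in seq_len(iter)) {
    Y1 <- (Y + solve(Z)) / 2
    Z1 <- (Z + solve(Y)) / 2
    Y <- Y1; Z <- Z1
  }
  Y
}

# Random upper-triangular row-stochastic matrix with distinct positive
# diagonal entries (always diagonalizable with positive real spectrum).
random_triangular_stochastic <- function() {
  d <- sort(runif(3, 0.3, 0.99), decreasing = TRUE)
  m <- diag(d)
  m[1, 2] <- runif(1, 0, 1 - d[1]); m[1, 3] <- 1 - d[1] - m[1, 2]
  m[2, 3] <- 1 - d[2]
  m[3, 3] <- 1
  m / rowSums(m)
}

# Random diagonalizable stochastic matrix with positive real spectrum: a
# lazy reversible random walk. Q = W / rowsums with W symmetric has real
# eigenvalues in [-1, 1]; P = a I + (1 - a) Q then has spectrum in
# [2a - 1, 1], positive for a > 1/2.
random_lazy_stochastic <- function(n = 4, a = 0.6) {
  M <- matrix(rexp(n * n), n)
  W <- (M + t(M)) / 2
  Q <- W / rowSums(W)
  a * diag(n) + (1 - a) * Q
}

# One fully favourable participant record; override fields to construct
# scoring cases.
participant <- function(...) {
  rec <- list(id = "p1", wave = 1L, sex = "male", age = 70,
              grip_max = 40, bmi = 27.6, height = 172, gait_speed = 1.1,
              weight = 80, prior_weight = 80,
              act_mild = "weekly_gt1", act_moderate = "weekly_gt1",
              act_vigorous = "weekly_1",
              exh_effort = "no", exh_get_going = "no", status = "assessed")
  mods <- list(...)
  rec[names(mods)] <- mods
  rec
}

# A small cohort data frame from a list of participant() records.
cohort_of <- function(...) {
  recs <- list(...)
  do.call(rbind, lapply(recs, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}
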