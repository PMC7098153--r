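# k-th roots of transition probability matrices via eigendecomposition,
# used to interpolate 4-year panel transition probabilities to 1- and 2-year
# horizons. Complex arithmetic is used throughout; realness of the result is
# a verified postcondition, not an assumption.

#' Spectral (eigen) factorisation of a transition matrix
#'
#' Factorises a square row-stochastic matrix as P = Z A Z^-1 where the
#' columns of Z are eigenvectors and A is diagonal with the eigenvalues. The
#' inverse is computed with `solve()` when Z is well conditioned and with
#' the Moore-Penrose generalised inverse (`MASS::ginv`) when the condition
#' number exceeds `cond_tol` (repeated eigenvalues, e.g. two absorbing
#' states, can make Z nearly singular). The factorisation is accepted only
#' if it reconstructs P to within 1e-8 (max absolute entry), the practical
#' test of diagonalisability.
#'
#' @param P Square numeric matrix, rows summing to 1.
#' @param cond_tol Condition-number threshold above which the generalised
#'   inverse replaces `solve()` (default 1e12).
#' @return A `spectral_factors` list: `values` (complex eigenvalues),
#'   `vectors` (complex matrix Z), `inverse` (Z^-1) and `residual`
#'   (max abs reconstruction error).
#' @export
spectral_decompose <- function(P, cond_tol = 1e12) {
  P <- unclass(P)
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (max(abs(rowSums(P) - 1)) > 1e-8)
    stop("P must be row-stochastic (rows summing to 1)")
  e <- eigen(P)
  Z <- e$vectors
  kap <- tryCatch(kappa(Z, exact = FALSE), error = function(e) Inf)
  Zinv <- if (is.finite(kap) && kap < cond_tol) {
    tryCatch(solve(Z), error = function(e) MASS::ginv(Z))
  } else {
    MASS::ginv(Z)
  }
  recon <- Z %*% diag(e$values, nrow = length(e$values)) %*% Zinv
  residual <- max(abs(recon - P))
  if (residual > 1e-8)
    stop(sprintf(
      "matrix is numerically non-diagonalizable: reconstruction residual %.3g exceeds 1e-8",
      residual))
  structure(list(values = e$values, vectors = Z, inverse = Zinv,
                 residual = residual, states = rownames(P)),
            class = "spectral_factors")
}

#' k-th root of a transition probability matrix
#'
#' Computes R = Z A^(1/k) Z^-1 with principal roots of the eigenvalues, the
#' interpolation estimator for transition probabilities over 1/k of the
#' panel interval (k = 2 gives two-year and k = 4 one-year probabilities
#' from a four-year matrix).
#'
#' Validity is checked, not assumed:
#'
#' * any eigenvalue with negative real part, or with non-negligible
#'   imaginary part, has no admissible principal root (the model requires
#'   positive eigenvalues) -- error;
#' * imaginary parts of R above 1e-8 signal numerical failure -- error;
#' * entries below `-neg_tol` mean the matrix is not usefully embeddable at
#'   order k -- error carrying the offending value.
#'
#' Real panel matrices are often not *strictly* embeddable: their roots can
#' carry small negative entries (of order 0.01 for the packaged ELSA
#' fixture, in the robust and frail rows) even though every row still sums
#' to 1. By default such entries are retained, so the root is exact
#' (R^k = P to machine precision) and its rows sum to 1 analytically; the
#' most negative entry is reported in the diagnostics. Set
#' `clip_negatives = TRUE` to clip them to 0 and renormalise the affected
#' rows, which yields a proper stochastic matrix at the cost of exact
#' closure (the resulting R^k vs P error is reported). Numerical noise
#' (entries above -1e-8) is always clipped. Rows of P that are exact unit
#' vectors (absorbing states) are restored exactly in R.
#'
#' @param P Square row-stochastic matrix (e.g. from [apply_scenario()]).
#' @param k Integer root order >= 1 (2 and 4 for the published horizons;
#'   any k is accepted).
#' @param factors Optional precomputed [spectral_decompose()] result.
#' @param clip_negatives Clip visible negative entries and renormalise
#'   (default `FALSE`: keep the exact root).
#' @param neg_tol Most negative entry tolerated before the matrix is
#'   declared non-embeddable at order k (default 0.02).
#' @return An `interpolated_matrix`: list with `matrix` (real root, rows
#'   summing to 1), `k`, and `diagnostics` (max imaginary residual, min raw
#'   entry, negative mass clipped, eigen reconstruction residual, max abs
#'   error of R^k vs P).
#' @export
#' @examples
#' P <- apply_scenario(elsa_transition_counts(), "all_ill", digits = 2)
#' R2 <- matrix_root(P, 2)
#' round(extract_row(R2, "prefrail"), 3)
matrix_root <- function(P, k, factors = NULL, clip_negatives = FALSE,
                        neg_tol = 0.02) {
  stopifnot(length(k) == 1, k >= 1, k == round(k))
  Pm <- unclass(P)
  if (is.null(factors)) factors <- spectral_decompose(Pm)
  lam <- factors$values
  imag_tol <- 1e-8
  bad_imag <- abs(Im(lam)) > imag_tol * pmax(1, abs(lam))
  bad_neg <- Re(lam) < -1e-8
  if (any(bad_imag | bad_neg))
    stop(sprintf(
      "non-embeddable at order %d: eigenvalue(s) %s are not positive reals",
      k, paste(format(lam[bad_imag | bad_neg], digits = 4), collapse = ", ")))
  lam_root <- as.complex(lam)^(1 / k)
  R <- factors$vectors %*% diag(lam_root, nrow = length(lam_root)) %*%
    factors$inverse
  max_imag <- max(abs(Im(R)))
  if (max_imag > 1e-8)
    stop(sprintf(
      "non-embeddable at order %d: max imaginary component %.3g exceeds 1e-8",
      k, max_imag))
  R <- Re(R)
  min_entry <- min(R)
  if (min_entry < -neg_tol)
    stop(sprintf(
      "non-embeddable at order %d: entry %.3g below -%g (negative probability)",
      k, min_entry, neg_tol))
  R[R > -1e-8 & R < 0] <- 0            # numerical noise
  neg_mass <- 0
  if (clip_negatives && min(R) < 0) {
    neg_mass <- sum(abs(R[R < 0]))
    R[R < 0] <- 0
    R <- R / rowSums(R)
  }
  # absorbing rows stay exact unit vectors
  unit_rows <- which(apply(Pm, 1, function(r) {
    j <- which.max(r); r[j] == 1 && all(r[-j] == 0)
  }))
  for (i in unit_rows) R[i, ] <- Pm[i, ]
  dimnames(R) <- dimnames(Pm)
  closure <- max(abs(matrix_power(R, k) - Pm))
  structure(list(
    matrix = R, k = as.integer(k),
    diagnostics = c(max_imag = max_imag, min_entry = min_entry,
                    clipped_mass = neg_mass,
                    max_rowsum_dev = max(abs(rowSums(R) - 1)),
                    eigen_residual = factors$residual,
                    closure_error = closure)
  ), class = "interpolated_matrix")
}

matrix_power <- function(M, k) {
  out <- diag(nrow(M))
  for (i in seq_len(k)) out <- out %*% M
  out
}

#' @export
print.interpolated_matrix <- function(x, ...) {
  cat(sprintf("Matrix %d-th root (interpolated transition probabilities)\n",
              x$k))
  print(round(x$matrix, 4))
  cat(sprintf("diagnostics: closure %.2g, max imag %.2g, min raw entry %.2g\n",
              x$diagnostics["closure_error"], x$diagnostics["max_imag"],
              x$diagnostics["min_entry"]))
  invisible(x)
}

#' Extract one baseline state's row of transition probabilities
#'
#' @param R An `interpolated_matrix` from [matrix_root()] or a plain square
#'   matrix with state dimnames.
#' @param state Baseline state label (e.g. `"prefrail"`).
#' @return Named probability vector summing to 1 (within 1e-9).
#' @export
extract_row <- function(R, state) {
  M <- if (inherits(R, "interpolated_matrix")) R$matrix else unclass(R)
  if (!state %in% rownames(M))
    stop("unknown state label: ", state, " (have: ",
         paste(rownames(M), collapse = ", "), ")")
  row <- M[state, ]
  stopifnot(abs(sum(row) - 1) < 1e-9)
  row
}
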