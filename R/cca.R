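#' Canonical correlation analysis
#'
#' Solves `argmax_{A,B} corr(XA, YB)`: finds linear combinations of the
#' columns of `X` (e.g. EEG channels) and of `Y` (model signals) with
#' maximal correlation, for `d = min(rank X, rank Y)` successive mutually
#' uncorrelated component pairs sorted by descending canonical correlation.
#'
#' Both matrices are column-centered, reduced by pivoted thin QR (rank
#' determined by the tolerance `max(n, d) * eps * |R[1,1]|`), and the
#' canonical structure is read off the SVD of `Qx' Qy`; coefficients are
#' back-solved from the R factors and scaled so the canonical variates have
#' unit sample variance. Rows of `A`/`B` belonging to columns dropped as
#' rank-deficient are zero. Since CCA signs are arbitrary, each component is
#' deterministically oriented so that the largest-magnitude entry of the
#' corresponding column of `B` is positive.
#'
#' @param X numeric matrix `n x d1` (observations in rows).
#' @param Y numeric matrix `n x d2`.
#' @return an object of class `cca_result`: coefficient matrices `A`
#'   (`d1 x d`) and `B` (`d2 x d`), canonical correlations `rho` (descending,
#'   in `[0, 1]`), per-component p-values `pvals` (see [cca_significance];
#'   `NA` when `n` is too small for the approximation), the number of rows
#'   `n`, ranks `rank_x`/`rank_y`, and the column means used for centering.
#' @export
cca_fit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n != nrow(Y)) stop("X and Y must have the same number of rows")
  if (n < 2L) stop_named("cca_too_few_rows", "need at least 2 observations")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2L, mx); Yc <- sweep(Y, 2L, my)
  if (max(abs(Xc)) == 0 || max(abs(Yc)) == 0)
    stop_named("cca_zero_variance", "all columns of X or Y are constant")

  qx <- qr_rank(Xc, n); qy <- qr_rank(Yc, n)
  if (qx$rank == 0L || qy$rank == 0L)
    stop_named("cca_zero_variance", "zero numerical rank after centering")
  d <- min(qx$rank, qy$rank)
  sv <- svd(crossprod(qx$Q, qy$Q), nu = d, nv = d)
  rho <- pmin(pmax(sv$d[seq_len(d)], 0), 1)

  A <- coef_backsolve(qx, sv$u[, seq_len(d), drop = FALSE], ncol(X), n)
  B <- coef_backsolve(qy, sv$v[, seq_len(d), drop = FALSE], ncol(Y), n)

  for (j in seq_len(d)) {
    i <- which.max(abs(B[, j]))
    if (B[i, j] < 0) { B[, j] <- -B[, j]; A[, j] <- -A[, j] }
  }
  pvals <- if (n > (qx$rank + qy$rank + 3) / 2)
    cca_significance(rho, n, qx$rank, qy$rank) else rep(NA_real_, d)

  structure(list(A = A, B = B, rho = rho, pvals = pvals, d = d, n = n,
                 rank_x = qx$rank, rank_y = qy$rank,
                 means = list(x = mx, y = my)),
            class = "cca_result")
}

qr_rank <- function(M, n) {
  qrm <- qr(M, LAPACK = TRUE)
  R <- qr.R(qrm)
  dg <- abs(diag(R))
  tol <- max(n, ncol(M)) * .Machine$double.eps * max(dg, 0)
  rank <- sum(dg > tol)
  list(qr = qrm, R = R, rank = rank, pivot = qrm$pivot,
       Q = qr.Q(qrm)[, seq_len(rank), drop = FALSE])
}

coef_backsolve <- function(qd, Uv, p, n) {
  r <- qd$rank
  W <- backsolve(qd$R[seq_len(r), seq_len(r), drop = FALSE], Uv) * sqrt(n - 1)
  out <- matrix(0, p, ncol(Uv))
  out[qd$pivot[seq_len(r)], ] <- W
  out
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result> d = %d components from n = %d rows (ranks %d, %d)\n",
              x$d, x$n, x$rank_x, x$rank_y))
  cat("  rho:", paste(sprintf("%.3f", utils::head(x$rho, 8)), collapse = " "),
      if (x$d > 8) "...\n" else "\n")
  invisible(x)
}

#' Per-component significance of canonical correlations
#'
#' Sequential tests that canonical correlations `k..d` are all zero, via
#' Wilks' Lambda `prod_{i>=k} (1 - rho_i^2)` with Bartlett's chi-square
#' approximation: the statistic `-(n - 1 - (d1 + d2 + 1)/2) * log(Lambda_k)`
#' is referred to a chi-square distribution with
#' `(d1 - k + 1) * (d2 - k + 1)` degrees of freedom. The approximation is
#' asymptotic and conservative for small `n`.
#'
#' @param rho canonical correlations (descending).
#' @param n number of observations used by the CCA.
#' @param d1,d2 ranks of the two variable sets.
#' @return p-values in `[0, 1]`, one per component.
#' @export
cca_significance <- function(rho, n, d1, d2) {
  if (n <= (d1 + d2 + 3) / 2)
    stop_named("cca_n_too_small",
               "too few observations for Bartlett's approximation")
  d <- length(rho)
  lam <- rev(cumprod(rev(pmax(1 - rho^2, 1e-300))))
  k <- seq_len(d)
  stat <- -(n - 1 - (d1 + d2 + 1) / 2) * log(lam)
  df <- (d1 - k + 1) * (d2 - k + 1)
  stats::pchisq(pmax(stat, 0), df, lower.tail = FALSE)
}
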